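# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops, textbook formulas) so they cannot
# share a code path with the package implementation.

# textbook Pearson correlation by explicit loops
oracle_pearson <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n
  mb <- sum(b) / n
  num <- 0; va <- 0; vb <- 0
  for (t in seq_len(n)) {
    num <- num + (a[t] - ma) * (b[t] - mb)
    va <- va + (a[t] - ma)^2
    vb <- vb + (b[t] - mb)^2
  }
  if (va == 0 || vb == 0) return(0)
  num / sqrt(va * vb)
}

# minimum heavy-atom distance by an all-pairs double loop
oracle_min_dist <- function(atoms_a, atoms_b) {
  best <- Inf
  for (p in seq_len(nrow(atoms_a))) {
    for (q in seq_len(nrow(atoms_b))) {
      d <- sqrt(sum((atoms_a[p, ] - atoms_b[q, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

# filter score by a 6-way loop of masked Pearson correlations, centre
# removed from both window and filter, intersection-mask border rule
oracle_filter_score <- function(window, bank) {
  k <- bank$k
  centre <- (k * k + 1) %/% 2
  d <- as.vector(window$values)
  mask <- as.vector(window$mask)
  mask[centre] <- FALSE
  best <- -Inf; best_f <- NA_integer_
  for (f in seq_along(bank$filters)) {
    fv <- as.vector(bank$filters[[f]])
    r <- oracle_pearson(d[mask], fv[mask])
    if (r > best) { best <- r; best_f <- f }
  }
  list(score = best, best_filter = best_f)
}

# a filter bank of random matrices (no clustering involved)
random_bank <- function(k, seed = 1) {
  set.seed(seed)
  filters <- lapply(1:6, function(f) matrix(runif(k * k), k, k))
  structure(list(k = as.integer(k), filters = filters,
                 class = rep(c("HH", "EE"), each = 3L),
                 sizes = rep(1, 6), seed = as.integer(seed)),
            class = "filter_bank")
}

# synthetic PDB text: 3 residues, one with a hydrogen and an altloc pair
write_tiny_pdb <- function(path) {
  fmt <- "ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s"
  lines <- c(
    sprintf(fmt, 1, " N", " ", "ALA", "A", 1, 0, 0, 0, " N"),
    sprintf(fmt, 2, " CA", " ", "ALA", "A", 1, 1.5, 0, 0, " C"),
    sprintf(fmt, 3, " H", " ", "ALA", "A", 1, 9, 9, 9, " H"),
    sprintf(fmt, 4, " CA", "A", "GLY", "A", 2, 4.0, 0, 0, " C"),
    sprintf(fmt, 5, " CA", "B", "GLY", "A", 2, 40, 40, 40, " C"),
    sprintf(fmt, 6, " CA", " ", "SER", "A", 3, 0, 3, 0, " C"),
    sprintf(fmt, 7, " OG", " ", "SER", "A", 3, 0, 5, 0, " O")
  )
  writeLines(lines, path)
  invisible(path)
}

# expected conditional window probabilities around a planted contact in a
# generated map: motif template with background off-pattern probability
expected_motif <- function(motif, k, p_contact = 0.9, p_background = 0.002) {
  motif_template(motif, k, p_hi = p_contact, p_lo = p_background)
}

rms <- function(a, b) sqrt(mean((a - b)^2))
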