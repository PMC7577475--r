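# Synthetic domain-pair generator. Emulates the structural features the
# method exploits -- helical contact lattices with one-turn (period-4)
# spacing, parallel / anti-parallel strand diagonals -- and DCA-like score
# matrices in which the contact and non-contact score distributions overlap,
# the overlap being controlled by a detection probability p_det standing in
# for alignment depth (M_eff).

#' Generate a 3-state secondary-structure layout
#'
#' Segments are sampled i.i.d. with type probabilities chosen so that the
#' expected composition is ~35% H, ~25% E, ~40% O given the run-length
#' ranges (H: 8-20, E: 4-8, O: 2-6 residues).
#'
#' @param l domain length (>= 10).
#' @param seed RNG seed.
#' @return 3-state string of length `l`.
#' @export
generate_ss_layout <- function(l, seed = 1L) {
  stop_if_not_scalar_number(l, "l")
  if (l < 10) stop("domain length must be at least 10", call. = FALSE)
  target <- c(H = 0.35, E = 0.25, O = 0.40)
  with_seed(seed, {
    out <- character(0)
    counts <- c(H = 0, E = 0, O = 0)
    # segment types chase the composition target: the sampling weight of a
    # class is its current deficit, which keeps single realisations close
    # to the target even for short domains
    repeat {
      deficit <- pmax(target * (length(out) + 10) - counts, 0.01)
      ty <- sample(names(target), 1L, prob = deficit)
      len <- switch(ty, H = sample(8:20, 1L), E = sample(4:8, 1L),
                    O = sample(2:6, 1L))
      out <- c(out, rep(ty, len))
      counts[ty] <- counts[ty] + len
      if (length(out) >= l) break
    }
    paste(out[seq_len(l)], collapse = "")
  })
}

#' Planted motif templates
#'
#' The per-cell contact probability of a k x k window centred on a contact
#' of the given motif class: `"helix"` is a period-4 lattice (one helical
#' turn per period; high probability where both offsets are multiples of 4),
#' `"parallel"` / `"antiparallel"` are main- resp. anti-diagonal stripes.
#' The centre is 1 by construction.
#'
#' @param motif `"helix"`, `"parallel"`, or `"antiparallel"`.
#' @param k odd window size.
#' @param p_hi,p_lo on- and off-pattern contact probabilities.
#' @return k x k probability matrix.
#' @export
motif_template <- function(motif = c("helix", "parallel", "antiparallel"),
                           k, p_hi = 0.9, p_lo = 0.002) {
  motif <- match.arg(motif)
  k <- check_odd_k(k)
  h <- (k - 1L) %/% 2L
  di <- matrix(-h:h, k, k)
  dj <- t(di)
  on <- switch(motif,
               helix = di %% 4L == 0L & dj %% 4L == 0L,
               parallel = di == dj,
               antiparallel = di == -dj)
  tpl <- matrix(p_lo, k, k)
  tpl[on] <- p_hi
  tpl[h + 1L, h + 1L] <- 1
  tpl
}

#' Sample window realisations of a planted motif
#'
#' Each window is an independent Bernoulli realisation of the motif
#' template with the central contact forced to 1; rows are flattened
#' column-major, matching [collect_class_windows].
#'
#' @param n number of windows.
#' @inheritParams motif_template
#' @param seed RNG seed.
#' @return n x k^2 numeric 0/1 matrix.
#' @export
sample_motif_windows <- function(n, motif, k, p_hi = 0.9, p_lo = 0.002,
                                 seed = 1L) {
  tpl <- as.vector(motif_template(motif, k, p_hi, p_lo))
  with_seed(seed, {
    w <- matrix(stats::rbinom(n * length(tpl), 1L,
                              rep(tpl, each = n)), n, length(tpl))
    storage.mode(w) <- "double"
    w
  })
}

ss_runs <- function(ss, type, min_len) {
  ch <- check_ss(ss)
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values == type & r$lengths >= min_len
  cbind(start = starts[ok], len = r$lengths[ok])
}

#' Generate a contact map with secondary-structure-driven interface blocks
#'
#' Each interface block pairs a structured run of domain A with one of
#' domain B. Helix-helix blocks receive contacts on a period-4 lattice
#' anchored at the run starts (one helical turn between consecutive
#' same-face residues); strand-strand blocks receive a main-diagonal
#' (parallel) or anti-diagonal (anti-parallel) stripe of width 1. Each
#' planted cell is realised with probability `p_contact`; sparse background
#' contacts are added everywhere with probability `p_background`.
#'
#' @param ss_a,ss_b 3-state strings.
#' @param n_interface_blocks number of blocks to plant.
#' @param seed RNG seed.
#' @param p_contact probability that a planted lattice/stripe cell is a
#'   contact.
#' @param p_background background contact probability per cell.
#' @return A `contact_map`; attribute `blocks` records the planted blocks
#'   (class, runs, orientation).
#' @export
generate_contact_map <- function(ss_a, ss_b, n_interface_blocks = 3L,
                                 seed = 1L, p_contact = 0.9,
                                 p_background = 0.002) {
  a <- check_ss(ss_a, "ss_a"); b <- check_ss(ss_b, "ss_b")
  la <- length(a); lb <- length(b)
  runs_h_a <- ss_runs(ss_a, "H", 5L); runs_h_b <- ss_runs(ss_b, "H", 5L)
  runs_e_a <- ss_runs(ss_a, "E", 3L); runs_e_b <- ss_runs(ss_b, "E", 3L)
  can_hh <- nrow(runs_h_a) > 0L && nrow(runs_h_b) > 0L
  can_ee <- nrow(runs_e_a) > 0L && nrow(runs_e_b) > 0L
  if (n_interface_blocks > 0L && !can_hh && !can_ee) {
    stop("no helix or strand runs available to place interface blocks",
         call. = FALSE)
  }
  with_seed(seed, {
    m <- matrix(0L, la, lb)
    blocks <- list()
    for (bl in seq_len(n_interface_blocks)) {
      type <- if (can_hh && can_ee) {
        sample(c("HH", "EE"), 1L)
      } else if (can_hh) "HH" else "EE"
      if (type == "HH") {
        ra <- runs_h_a[sample.int(nrow(runs_h_a), 1L), ]
        rb <- runs_h_b[sample.int(nrow(runs_h_b), 1L), ]
        ii <- ra["start"] + seq(0L, ra["len"] - 1L, by = 4L)
        jj <- rb["start"] + seq(0L, rb["len"] - 1L, by = 4L)
        cells <- as.matrix(expand.grid(i = ii, j = jj))
        ori <- "lattice"
      } else {
        ra <- runs_e_a[sample.int(nrow(runs_e_a), 1L), ]
        rb <- runs_e_b[sample.int(nrow(runs_e_b), 1L), ]
        len <- min(ra["len"], rb["len"])
        t <- seq_len(len) - 1L
        ori <- sample(c("parallel", "antiparallel"), 1L)
        cells <- if (ori == "parallel") {
          cbind(i = ra["start"] + t, j = rb["start"] + t)
        } else {
          cbind(i = ra["start"] + t, j = rb["start"] + len - 1L - t)
        }
      }
      keep <- stats::runif(nrow(cells)) < p_contact
      m[cells[keep, , drop = FALSE]] <- 1L
      blocks[[bl]] <- list(class = type, run_a = unname(ra),
                           run_b = unname(rb), orientation = ori)
    }
    if (p_background > 0) {
      bg <- matrix(stats::runif(la * lb) < p_background, la, lb)
      m[bg] <- 1L
    }
    out <- as_contact_map(m)
    attr(out, "blocks") <- blocks
    out
  })
}

#' Generate a DCA-like score matrix for a contact map
#'
#' `F_ij = s * c_ij * B_ij + e_ij` with `c_ij` the contact indicator,
#' `B_ij ~ Bernoulli(p_det)` i.i.d. (a contact carries signal only when
#' "detected"; `p_det` is the proxy for alignment depth M_eff), and
#' `e_ij ~ Normal(0, sigma^2)`. At `p_det = 0` the contact and non-contact
#' score distributions coincide, emulating the shallow-alignment regime.
#'
#' @param cmap `contact_map`.
#' @param s signal strength (>= 0).
#' @param p_det detection probability in [0, 1].
#' @param sigma noise standard deviation (> 0).
#' @param seed RNG seed.
#' @param meff M_eff value recorded on the score matrix.
#' @param family family identifier.
#' @return A [score_matrix].
#' @export
generate_scores <- function(cmap, s = 0.3, p_det = 0.5, sigma = 0.1,
                            seed = 1L, meff = 300, family = "synthetic") {
  if (s < 0) stop("`s` must be >= 0", call. = FALSE)
  if (p_det < 0 || p_det > 1) stop("`p_det` must be in [0, 1]", call. = FALSE)
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  m <- unclass(cmap)
  with_seed(seed, {
    det <- matrix(stats::rbinom(length(m), 1L, p_det), nrow(m), ncol(m))
    eps <- matrix(stats::rnorm(length(m), 0, sigma), nrow(m), ncol(m))
    score_matrix(s * m * det + eps, meff = meff, family = family)
  })
}

#' Generate one synthetic domain-pair family
#'
#' Draws secondary-structure layouts (re-drawn, deterministically, until a
#' helix or strand pairing exists so the requested blocks can be placed),
#' plants the contact map, and simulates the score matrix.
#'
#' @param family_id identifier string.
#' @param l_a,l_b domain lengths.
#' @param n_blocks interface blocks.
#' @param s,p_det,sigma score-model parameters (see [generate_scores]).
#' @param meff M_eff recorded for the family.
#' @param seed RNG seed.
#' @param ss_a,ss_b optional fixed secondary-structure strings (bypass the
#'   layout generator).
#' @return A `synthetic_family`: list with `family`, `l_a`, `l_b`, `ss_a`,
#'   `ss_b`, `contact_map`, `scores`, `meff`, `params`, `seed`.
#' @export
generate_family <- function(family_id = "fam1", l_a = 60L, l_b = 60L,
                            n_blocks = 3L, s = 0.3, p_det = 0.5,
                            sigma = 0.1, meff = 300, seed = 1L,
                            ss_a = NULL, ss_b = NULL) {
  if (is.null(ss_a) || is.null(ss_b)) {
    for (attempt in 1:50) {
      sa <- generate_ss_layout(l_a, derive_seed(seed, 2L * attempt))
      sb <- generate_ss_layout(l_b, derive_seed(seed, 2L * attempt + 1L))
      hh <- nrow(ss_runs(sa, "H", 5L)) > 0L && nrow(ss_runs(sb, "H", 5L)) > 0L
      ee <- nrow(ss_runs(sa, "E", 3L)) > 0L && nrow(ss_runs(sb, "E", 3L)) > 0L
      if (hh || ee) { ss_a <- sa; ss_b <- sb; break }
    }
    if (is.null(ss_a)) stop("could not draw a pairable layout", call. = FALSE)
  }
  cmap <- generate_contact_map(ss_a, ss_b, n_blocks,
                               seed = derive_seed(seed, 101L))
  scores <- generate_scores(cmap, s = s, p_det = p_det, sigma = sigma,
                            seed = derive_seed(seed, 202L), meff = meff,
                            family = family_id)
  structure(list(family = family_id, l_a = nchar(ss_a), l_b = nchar(ss_b),
                 ss_a = ss_a, ss_b = ss_b, contact_map = cmap,
                 scores = scores, meff = meff,
                 params = list(s = s, p_det = p_det, sigma = sigma,
                               n_blocks = n_blocks),
                 seed = as.integer(seed)),
            class = "synthetic_family")
}

#' Generate a synthetic benchmark of independent families
#'
#' Per-family seeds are derived deterministically from the master seed, so
#' the same master seed reproduces the benchmark byte-identically.
#'
#' @param n_families number of families (>= 2).
#' @inheritParams generate_family
#' @param seed master seed.
#' @param prefix family-id prefix.
#' @return list of [generate_family] objects.
#' @export
generate_benchmark <- function(n_families, l_a = 60L, l_b = 60L,
                               n_blocks = 3L, s = 0.3, p_det = 0.5,
                               sigma = 0.1, meff = 300, seed = 1L,
                               prefix = "fam") {
  if (n_families < 2L) stop("need at least 2 families", call. = FALSE)
  lapply(seq_len(n_families), function(i) {
    generate_family(sprintf("%s%03d", prefix, i), l_a = l_a, l_b = l_b,
                    n_blocks = n_blocks, s = s, p_det = p_det,
                    sigma = sigma, meff = meff,
                    seed = derive_seed(seed, 1000L + i))
  })
}

#' Write a synthetic family to disk in the package text formats
#'
#' Writes `<id>.scores` (triplet score file with Meff header),
#' `<id>.contacts` (pair list), and `<id>.ss` (two-line secondary
#' structure).
#'
#' @param fam `synthetic_family`.
#' @param dir output directory.
#' @return the three paths, invisibly.
#' @export
write_family <- function(fam, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, fam$family)
  write_scores(fam$scores, paste0(base, ".scores"), indexing = "split")
  write_contact_map(fam$contact_map, paste0(base, ".contacts"))
  write_ss(fam$ss_a, fam$ss_b, paste0(base, ".ss"))
  invisible(paste0(base, c(".scores", ".contacts", ".ss")))
}
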