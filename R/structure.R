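# Contact maps from coordinates, secondary-structure handling, and the
# dataset-level filters applied to domain-domain interfaces.

#' Residue coordinates for one domain
#'
#' A `residue_coords` object is a list with one element per residue, each an
#' n x 3 numeric matrix of heavy-atom coordinates (Angstrom). Residue order
#' must match the axis of the corresponding DCA score matrix.
#'
#' @param atoms list of numeric matrices (n_atoms x 3), one per residue.
#' @return An object of class `residue_coords`.
#' @export
residue_coords <- function(atoms) {
  if (!is.list(atoms) || length(atoms) == 0L) {
    stop("`atoms` must be a non-empty list of coordinate matrices", call. = FALSE)
  }
  for (r in seq_along(atoms)) {
    m <- atoms[[r]]
    if (is.null(dim(m))) m <- matrix(m, ncol = 3L)
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (ncol(m) != 3L) {
      stop(sprintf("residue %d: coordinates must have 3 columns", r), call. = FALSE)
    }
    if (nrow(m) < 1L) {
      stop(sprintf("residue %d has zero atoms", r), call. = FALSE)
    }
    if (!all(is.finite(m))) {
      stop(sprintf("residue %d has non-finite coordinates", r), call. = FALSE)
    }
    atoms[[r]] <- m
  }
  structure(atoms, class = "residue_coords")
}

#' @export
length.residue_coords <- function(x) length(unclass(x))

#' Read heavy-atom coordinates from a PDB file
#'
#' Minimal fixed-column reader for ATOM records. Hydrogens (element H or D)
#' are discarded; for alternate locations only the first conformer seen per
#' (residue, atom name) is kept. Residues are returned in order of first
#' appearance along the chain.
#'
#' @param path PDB file.
#' @param chain single chain identifier, or `NULL` to accept all chains.
#' @return A [residue_coords] object; residue identifiers (chain + resseq +
#'   insertion code) are stored in `names`.
#' @export
read_pdb_coords <- function(path, chain = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[startsWith(lines, "ATOM")]
  if (!is.null(chain)) lines <- lines[substring(lines, 22, 22) == chain]
  if (length(lines) == 0L) stop("no ATOM records found", call. = FALSE)

  atom_name <- trimws(substring(lines, 13, 16))
  altloc <- substring(lines, 17, 17)
  resid <- paste0(substring(lines, 22, 22), trimws(substring(lines, 23, 26)),
                  trimws(substring(lines, 27, 27)))
  x <- as.numeric(substring(lines, 31, 38))
  y <- as.numeric(substring(lines, 39, 46))
  z <- as.numeric(substring(lines, 47, 54))
  element <- toupper(trimws(substring(lines, 77, 78)))
  # Fall back to the first alphabetic character of the atom name when the
  # element column is absent (common in hand-made or legacy files).
  no_elem <- element == ""
  if (any(no_elem)) {
    guess <- sub("^[0-9']*", "", atom_name[no_elem])
    element[no_elem] <- toupper(substring(guess, 1, 1))
  }
  keep <- !(element %in% c("H", "D"))
  # first conformer per (residue, atom name): among heavy atoms, keep the
  # first occurrence in file order (altloc A precedes B etc.)
  key <- paste(resid, atom_name)
  keep[keep] <- !duplicated(key[keep])
  lines_ok <- which(keep)
  if (length(lines_ok) == 0L) stop("no heavy atoms found", call. = FALSE)

  resid <- resid[lines_ok]
  xyz <- unname(cbind(x, y, z))[lines_ok, , drop = FALSE]
  ord <- unique(resid)
  atoms <- lapply(ord, function(r) xyz[resid == r, , drop = FALSE])
  names(atoms) <- ord
  residue_coords(atoms)
}

#' Minimal heavy-atom distances between two domains
#'
#' Entry (i, j) is the minimum Euclidean distance over all heavy-atom pairs
#' of residue i of domain A and residue j of domain B.
#'
#' @param coords_a,coords_b [residue_coords] objects.
#' @return An L_A x L_B numeric matrix (class `distance_matrix`).
#' @export
min_heavy_atom_distances <- function(coords_a, coords_b) {
  coords_a <- residue_coords(unclass(coords_a))
  coords_b <- residue_coords(unclass(coords_b))
  la <- length(coords_a); lb <- length(coords_b)
  d <- matrix(NA_real_, la, lb)
  sq_b <- lapply(unclass(coords_b), function(m) rowSums(m^2))
  for (i in seq_len(la)) {
    ai <- coords_a[[i]]
    sa <- rowSums(ai^2)
    for (j in seq_len(lb)) {
      bj <- coords_b[[j]]
      d2 <- outer(sa, sq_b[[j]], "+") - 2 * (ai %*% t(bj))
      d[i, j] <- sqrt(max(0, min(d2)))
    }
  }
  structure(d, class = c("distance_matrix", "matrix"))
}

#' Element-wise minimum over distance matrices from multiple structures
#'
#' When the same domain pair is resolved in several PDB structures, the
#' per-pair distance is the minimum over all copies.
#'
#' @param matrices list of equally shaped distance matrices.
#' @return A single `distance_matrix`.
#' @export
merge_distance_matrices <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0L) {
    stop("`matrices` must be a non-empty list", call. = FALSE)
  }
  dims <- lapply(matrices, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("all distance matrices must share the same shape", call. = FALSE)
  }
  out <- Reduce(pmin, lapply(matrices, unclass))
  structure(out, class = c("distance_matrix", "matrix"))
}

#' Threshold distances into a binary contact map
#'
#' A residue pair is a contact when its minimal heavy-atom distance is
#' strictly below the threshold (default 8 Angstrom).
#'
#' @param distances numeric L_A x L_B matrix of distances.
#' @param threshold positive distance cutoff in Angstrom.
#' @return A `contact_map`: integer 0/1 matrix with attributes `threshold`
#'   and (optionally) `distances`.
#' @export
contact_map <- function(distances, threshold = 8.0) {
  stop_if_not_scalar_number(threshold, "threshold")
  if (threshold <= 0) stop("`threshold` must be positive", call. = FALSE)
  d <- unclass(as.matrix(distances))
  cm <- matrix(as.integer(d < threshold), nrow(d), ncol(d))
  structure(cm, class = c("contact_map", "matrix"),
            threshold = threshold, distances = d)
}

as_contact_map <- function(m, threshold = 8.0) {
  m <- as.matrix(m)
  if (!all(m %in% c(0L, 1L))) stop("contact map entries must be 0/1", call. = FALSE)
  structure(matrix(as.integer(m), nrow(m), ncol(m)),
            class = c("contact_map", "matrix"), threshold = threshold)
}

DSSP8 <- c(H = "H", G = "H", I = "H", E = "E", B = "E",
           T = "O", S = "O", C = "O", "-" = "O", "." = "O", " " = "O")

#' Collapse an 8-state secondary-structure string to 3 states
#'
#' DSSP convention: H, G, I map to helix (H); E, B map to extended (E);
#' everything else (turns, bends, coil, gaps) maps to other (O).
#'
#' @param eight_state character string over the DSSP alphabet
#'   `H G I E B T S C - .` (space allowed for unassigned).
#' @return 3-state string over `{H, E, O}`.
#' @export
ss_three_state <- function(eight_state) {
  if (!is.character(eight_state) || length(eight_state) != 1L) {
    stop("`eight_state` must be a single string", call. = FALSE)
  }
  ch <- strsplit(eight_state, "", fixed = TRUE)[[1]]
  bad <- setdiff(ch, names(DSSP8))
  if (length(bad) > 0L) {
    stop(sprintf("unknown secondary-structure character(s): %s",
                 paste(unique(bad), collapse = " ")), call. = FALSE)
  }
  paste(DSSP8[ch], collapse = "")
}

check_ss <- function(ss, name = "ss") {
  if (!is.character(ss) || length(ss) != 1L) {
    stop(sprintf("`%s` must be a single string", name), call. = FALSE)
  }
  ch <- strsplit(ss, "", fixed = TRUE)[[1]]
  if (!all(ch %in% c("H", "E", "O"))) {
    stop(sprintf("`%s` must use only the alphabet {H, E, O}", name), call. = FALSE)
  }
  ch
}

#' Secondary-structure class of a residue pair
#'
#' @param i,j 1-based residue indices into domain A resp. B.
#' @param ss_a,ss_b 3-state strings over `{H, E, O}`.
#' @return `"HH"`, `"EE"`, or `"other"`.
#' @export
classify_contact <- function(i, j, ss_a, ss_b) {
  a <- check_ss(ss_a, "ss_a"); b <- check_ss(ss_b, "ss_b")
  if (i < 1 || i > length(a) || j < 1 || j > length(b)) {
    stop("residue index out of range", call. = FALSE)
  }
  if (a[i] == "H" && b[j] == "H") return("HH")
  if (a[i] == "E" && b[j] == "E") return("EE")
  "other"
}

#' Dataset-level inclusion filters for a domain-domain interface
#'
#' An interface enters the corpus when it has between 10 and 2000 contacts
#' (inclusive) and the structural mapping covers at least 40% of the domains.
#'
#' @param cmap `contact_map`.
#' @param coverage_fraction fraction of the domain lengths mapped to
#'   structure, in `[0, 1]`.
#' @param min_contacts,max_contacts,min_coverage bounds; defaults follow the
#'   reference corpus construction.
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   violated rules, empty when passing).
#' @export
dataset_filters <- function(cmap, coverage_fraction,
                            min_contacts = 10L, max_contacts = 2000L,
                            min_coverage = 0.40) {
  n <- sum(unclass(cmap))
  reasons <- character(0)
  if (n < min_contacts) {
    reasons <- c(reasons, sprintf("too few contacts (%d < %d)", n, min_contacts))
  }
  if (n > max_contacts) {
    reasons <- c(reasons, sprintf("too many contacts (%d > %d)", n, max_contacts))
  }
  if (coverage_fraction < min_coverage) {
    reasons <- c(reasons, sprintf("coverage %.3f below %.2f",
                                  coverage_fraction, min_coverage))
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Write / read a contact map as a plain-text pair list
#'
#' Format: a header line `# shape L_A L_B`, then one `i j` pair per line,
#' 1-based.
#'
#' @param cmap `contact_map`.
#' @param path output file.
#' @return `write_contact_map` returns `path` invisibly; `read_contact_map`
#'   returns a `contact_map`.
#' @export
write_contact_map <- function(cmap, path) {
  m <- unclass(cmap)
  idx <- which(m == 1L, arr.ind = TRUE)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# shape %d %d", nrow(m), ncol(m)), con)
  if (nrow(idx) > 0L) {
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    writeLines(sprintf("%d\t%d", idx[, 1], idx[, 2]), con)
  }
  invisible(path)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[1]
  if (!grepl("^# shape ", hdr)) stop("missing '# shape L_A L_B' header", call. = FALSE)
  shp <- as.integer(strsplit(trimws(sub("^# shape", "", hdr)), "\\s+")[[1]])
  m <- matrix(0L, shp[1], shp[2])
  body <- lines[-1]
  body <- body[nzchar(trimws(body)) & !startsWith(body, "#")]
  if (length(body) > 0L) {
    ij <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.integer))
    if (any(ij[, 1] < 1 | ij[, 1] > shp[1] | ij[, 2] < 1 | ij[, 2] > shp[2])) {
      stop("contact index out of declared shape", call. = FALSE)
    }
    m[ij] <- 1L
  }
  as_contact_map(m)
}

#' Write / read secondary-structure annotations
#'
#' Plain text, one 3-state string per line (line 1 = domain A, line 2 =
#' domain B).
#'
#' @param ss_a,ss_b 3-state strings.
#' @param path file path.
#' @export
write_ss <- function(ss_a, ss_b, path) {
  check_ss(ss_a, "ss_a"); check_ss(ss_b, "ss_b")
  writeLines(c(ss_a, ss_b), path)
  invisible(path)
}

#' @rdname write_ss
#' @export
read_ss <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("expected two secondary-structure lines", call. = FALSE)
  check_ss(lines[1], "ss_a"); check_ss(lines[2], "ss_b")
  list(ss_a = lines[1], ss_b = lines[2])
}

#' Read a distance matrix from TSV
#'
#' Expects a header row and header column of 1-based residue indices.
#'
#' @param path TSV file.
#' @return A `distance_matrix`.
#' @export
read_distance_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("distances must be finite and non-negative", call. = FALSE)
  }
  dimnames(m) <- NULL
  structure(m, class = c("distance_matrix", "matrix"))
}
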