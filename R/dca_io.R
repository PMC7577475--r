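# Parsing plmDCA-style score files into dense inter-domain score matrices,
# and binning families by effective sequence number.

#' Construct a score matrix object
#'
#' @param mat L_A x L_B numeric matrix of inter-domain DCA scores F_ij.
#'   `NA` marks pairs absent from the source file; absent pairs are excluded
#'   from feature tables and ranking, never imputed.
#' @param meff effective sequence number of the joint alignment (> 0).
#' @param family family identifier string.
#' @return An object of class `score_matrix`.
#' @export
score_matrix <- function(mat, meff, family = "family") {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  if (any(is.infinite(mat))) stop("scores must be finite or NA", call. = FALSE)
  stop_if_not_scalar_number(meff, "meff")
  if (meff <= 0) stop("`meff` must be positive", call. = FALSE)
  structure(mat, class = c("score_matrix", "matrix"),
            meff = meff, family = as.character(family))
}

#' Effective-sequence-number bin of a family
#'
#' Families are analysed separately by alignment depth: `large` for
#' M_eff > 200, `medium` for 50 < M_eff <= 200, `small` for M_eff <= 50
#' (inclusive upper bounds; the three bins partition the positive axis).
#'
#' @param meff positive effective sequence number.
#' @return `"large"`, `"medium"`, or `"small"`.
#' @export
meff_bin <- function(meff) {
  stop_if_not_scalar_number(meff, "meff")
  if (meff <= 0) stop("`meff` must be positive", call. = FALSE)
  if (meff > 200) "large" else if (meff > 50) "medium" else "small"
}

#' Parse a plmDCA-style score file
#'
#' Rows are whitespace-separated `i j score` triplets, 1-based. With
#' `indexing = "joint"` indices run over the concatenated domains
#' (1..L_A + L_B) and only inter-domain rows (i <= L_A < j) are kept;
#' intra-domain rows are skipped and counted. With `indexing = "split"`
#' i indexes domain A (1..L_A) and j domain B (1..L_B) directly. Comment
#' lines start with `#`; a `# Meff= <value>` header supplies M_eff unless
#' overridden by the `meff` argument.
#'
#' @param path score file.
#' @param l_a,l_b domain lengths.
#' @param indexing `"joint"` or `"split"`.
#' @param meff optional M_eff override.
#' @param family family identifier (defaults to the file name).
#' @return A [score_matrix]; missing pairs are `NA`. The number of skipped
#'   intra-domain rows is stored in attribute `skipped`.
#' @export
parse_scores <- function(path, l_a, l_b, indexing = c("joint", "split"),
                         meff = NULL, family = NULL) {
  indexing <- match.arg(indexing)
  if (is.null(family)) family <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#\\s*Meff\\s*=", lines, ignore.case = TRUE, value = TRUE)
  if (is.null(meff)) {
    if (length(hdr) == 0L) {
      stop("M_eff not found: supply `meff` or a '# Meff=' header", call. = FALSE)
    }
    meff <- as.numeric(sub(".*=\\s*", "", hdr[1]))
  }
  body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  mat <- matrix(NA_real_, l_a, l_b)
  skipped <- 0L
  if (length(body) > 0L) {
    fields <- strsplit(trimws(body), "\\s+")
    if (any(lengths(fields) < 3L)) stop("malformed score row", call. = FALSE)
    i <- as.integer(vapply(fields, `[`, character(1), 1L))
    j <- as.integer(vapply(fields, `[`, character(1), 2L))
    s <- as.numeric(vapply(fields, `[`, character(1), 3L))
    if (indexing == "joint") {
      n <- l_a + l_b
      if (any(i < 1 | i > n | j < 1 | j > n)) {
        stop("score index outside 1..L_A+L_B", call. = FALSE)
      }
      # orient pairs so the smaller index comes first, then select
      # inter-domain rows: i in domain A, j in domain B
      lo <- pmin(i, j); hi <- pmax(i, j)
      inter <- lo <= l_a & hi > l_a
      skipped <- sum(!inter)
      i <- lo[inter]; j <- hi[inter] - l_a; s <- s[inter]
    } else {
      if (any(i < 1 | i > l_a | j < 1 | j > l_b)) {
        stop("score index outside declared domain lengths", call. = FALSE)
      }
    }
    if (length(i) > 0L) {
      key <- paste(i, j)
      dup <- duplicated(key)
      if (any(dup)) {
        first <- match(key[dup], key)
        if (any(s[dup] != s[first])) {
          stop("duplicate pair with conflicting scores", call. = FALSE)
        }
        i <- i[!dup]; j <- j[!dup]; s <- s[!dup]
      }
      mat[cbind(i, j)] <- s
    }
  }
  out <- score_matrix(mat, meff, family)
  attr(out, "skipped") <- skipped
  out
}

#' Write a score matrix in the triplet text format
#'
#' Inverse of [parse_scores]; `NA` (absent) pairs are omitted. Writes a
#' `# Meff=` header. Full (17 significant digit) precision so that a
#' parse-write-parse round trip is exact.
#'
#' @param sm [score_matrix].
#' @param path output file.
#' @param indexing `"joint"` or `"split"` (see [parse_scores]).
#' @export
write_scores <- function(sm, path, indexing = c("joint", "split")) {
  indexing <- match.arg(indexing)
  m <- unclass(sm)
  idx <- which(!is.na(m), arr.ind = TRUE)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# Meff= %.17g", attr(sm, "meff")), con)
  if (nrow(idx) > 0L) {
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    j_out <- if (indexing == "joint") idx[, 2] + nrow(m) else idx[, 2]
    writeLines(sprintf("%d %d %.17g", idx[, 1], j_out, m[idx]), con)
  }
  invisible(path)
}
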