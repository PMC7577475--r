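# The two features of the predictor: x1, the raw DCA coupling score of a
# residue pair, and x2, the filter score = maximum Pearson correlation
# between the DCA-score window around the pair and the six structural
# filters, the central element removed from both.

#' Pearson correlation over a masked subset of positions
#'
#' Sample Pearson correlation of `a` and `b` restricted to positions where
#' `mask` is `TRUE`. If either masked vector is constant the correlation is
#' undefined; the neutral fallback 0 is returned so that ranking falls back
#' to the DCA score alone.
#'
#' @param a,b numeric vectors of equal length.
#' @param mask logical vector selecting at least 2 positions.
#' @return Correlation in `[-1, 1]`, or 0 for a degenerate (constant) input.
#' @export
pearson_masked <- function(a, b, mask = rep(TRUE, length(a))) {
  if (length(a) != length(b) || length(a) != length(mask)) {
    stop("`a`, `b` and `mask` must have equal length", call. = FALSE)
  }
  if (sum(mask) < 2L) stop("mask must select at least 2 positions", call. = FALSE)
  x <- a[mask]; y <- b[mask]
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sqrt(sum(xc^2)); sy <- sqrt(sum(yc^2))
  if (sx == 0 || sy == 0) return(0)
  max(-1, min(1, sum(xc * yc) / (sx * sy)))
}

#' Filter score of a DCA-score window
#'
#' Correlates the window against each filter of the bank over the positions
#' that are valid in the window AND inside the filter, with the central
#' element removed from both (it is a contact by construction in the filters
#' and its DCA score enters the classifier directly as x1). Returns the
#' maximum correlation and the winning filter (first index on ties).
#'
#' @param window `dca_window` (from [extract_window]) with the bank's `k`.
#' @param bank `filter_bank`.
#' @return list with `score` (max correlation) and `best_filter` (index
#'   into `bank$filters`).
#' @export
filter_score <- function(window, bank) {
  if (!inherits(window, "dca_window")) stop("`window` must be a dca_window", call. = FALSE)
  if (window$k != bank$k) stop("window and filter bank sizes differ", call. = FALSE)
  k <- bank$k
  centre <- ((k * k) + 1L) %/% 2L
  mask <- as.vector(window$mask)
  mask[centre] <- FALSE
  if (sum(mask) < 2L) {
    stop("fewer than 2 usable non-centre positions in the window", call. = FALSE)
  }
  d <- as.vector(window$values)
  scores <- vapply(bank$filters, function(f) {
    pearson_masked(d, as.vector(f), mask)
  }, numeric(1))
  best <- which.max(scores)
  list(score = scores[best], best_filter = best)
}

#' Compute the feature table of a score matrix
#'
#' One row per represented (non-`NA`) residue pair with the two features
#' x1 = F_ij and x2 = filter score, the winning filter, and (when a truth
#' contact map is supplied) the binary contact label. Pairs closer than
#' (k-1)/2 to the matrix border use the truncated-overlap rule of
#' [filter_score]; absent score entries are likewise treated as invalid
#' window positions.
#'
#' @param sm [score_matrix].
#' @param bank `filter_bank`.
#' @param truth optional `contact_map` of the same shape.
#' @return data.frame with columns `i`, `j` (1-based), `x1`, `x2`,
#'   `best_filter`, `label` (0/1 integer or `NA`), `family`.
#' @export
feature_table <- function(sm, bank, truth = NULL) {
  f <- unclass(sm)
  la <- nrow(f); lb <- ncol(f)
  k <- bank$k
  h <- (k - 1L) %/% 2L
  if (la < 2L || lb < 2L) {
    stop("score matrix too small for a usable window", call. = FALSE)
  }
  if (!is.null(truth)) {
    tm <- unclass(truth)
    if (nrow(tm) != la || ncol(tm) != lb) {
      stop("truth contact map shape differs from the score matrix", call. = FALSE)
    }
  }
  # pad with NA so every window is a contiguous k^2 slice of the padded matrix
  fp <- matrix(NA_real_, la + 2L * h, lb + 2L * h)
  fp[h + seq_len(la), h + seq_len(lb)] <- f
  pairs <- which(!is.na(f), arr.ind = TRUE)
  if (nrow(pairs) == 0L) stop("score matrix has no represented pairs", call. = FALSE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  np <- nrow(fp)
  offs <- as.matrix(expand.grid(di = -h:h, dj = -h:h))
  delta <- offs[, "dj"] * np + offs[, "di"]
  centres <- (pairs[, 2] + h - 1L) * np + (pairs[, 1] + h)
  w <- matrix(fp[outer(centres, delta, "+")], nrow(pairs), k * k)
  centre_col <- ((k * k) + 1L) %/% 2L
  w <- w[, -centre_col, drop = FALSE]

  fmat <- vapply(bank$filters, function(fl) as.vector(fl)[-centre_col],
                 numeric(k * k - 1L))

  # masked Pearson against all filters at once via one-pass sums:
  # for each pair, the valid positions are the window cells inside the
  # matrix (truncated-overlap border rule); means and variances of BOTH the
  # window and the filter are taken over that intersection.
  valid <- !is.na(w)
  n_valid <- rowSums(valid)
  if (any(n_valid < 2L)) {
    r <- which(n_valid < 2L)[1]
    stop(sprintf("pair (%d, %d): fewer than 2 usable window positions",
                 pairs[r, 1], pairs[r, 2]), call. = FALSE)
  }
  w0 <- w; w0[!valid] <- 0
  vnum <- matrix(as.numeric(valid), nrow(valid), ncol(valid))
  sx <- rowSums(w0)
  sxx <- rowSums(w0^2)
  sf <- vnum %*% fmat
  sff <- vnum %*% fmat^2
  sxf <- w0 %*% fmat
  covxf <- sxf - sx * sf / n_valid
  varx <- pmax(sxx - sx^2 / n_valid, 0)
  varf <- pmax(sff - sf^2 / n_valid, 0)
  den <- sqrt(varx * varf)
  corr <- ifelse(den > 0, covxf / den, 0)
  corr <- pmax(pmin(corr, 1), -1)
  best <- max.col(corr, ties.method = "first")
  x2 <- corr[cbind(seq_len(nrow(corr)), best)]
  label <- if (is.null(truth)) NA_integer_ else as.integer(tm[pairs])
  data.frame(i = pairs[, 1], j = pairs[, 2],
             x1 = f[pairs], x2 = x2, best_filter = best,
             label = label,
             family = attr(sm, "family") %||% "family",
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a feature table as TSV
#'
#' Columns: `i`, `j` (1-based), `x1`, `x2`, `best_filter`, `label`, `family`.
#'
#' @param features data.frame from [feature_table].
#' @param path TSV file.
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(i = "integer", j = "integer",
                                   x1 = "numeric", x2 = "numeric",
                                   best_filter = "integer",
                                   label = "integer", family = "character"))
}
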