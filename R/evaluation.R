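# Evaluation of ranked contact predictions: positive predictive value as a
# function of the number of predictions, family averages, and the
# probability calibration table.

#' Rank residue pairs by score
#'
#' Stable, deterministic ordering by decreasing score with ties broken by
#' (i, j).
#'
#' @param df data.frame with columns `score` (or `p`), `i`, `j`.
#' @return `df` reordered, with a `rank` column.
#' @export
rank_pairs <- function(df) {
  s <- if ("score" %in% names(df)) df$score else df$p
  if (is.null(s)) stop("need a `score` or `p` column", call. = FALSE)
  if (any(is.na(s))) stop("ranking scores contain NA/NaN", call. = FALSE)
  out <- df[order(-s, df$i, df$j), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Positive predictive value curve
#'
#' `PPV(n) = TP(n) / n` over the top-n ranked predictions, for
#' `n = 1, ..., N`.
#'
#' @param labels 0/1 labels in rank order (best first), or a data.frame
#'   with `score`/`p`, `i`, `j`, `label` which is ranked first via
#'   [rank_pairs].
#' @param n_max number of predictions N (defaults to all available).
#' @return numeric vector of length N, class `ppv_curve`.
#' @export
ppv_curve <- function(labels, n_max = NULL) {
  if (is.data.frame(labels)) labels <- rank_pairs(labels)$label
  labels <- as.integer(labels)
  if (any(is.na(labels))) stop("labels contain NA", call. = FALSE)
  if (is.null(n_max)) n_max <- length(labels)
  if (n_max < 1L || n_max > length(labels)) {
    stop("`n_max` must be between 1 and the number of ranked pairs", call. = FALSE)
  }
  structure(cumsum(labels[seq_len(n_max)]) / seq_len(n_max),
            class = "ppv_curve")
}

#' Family-averaged PPV curve
#'
#' Per-n arithmetic mean over families. Families with fewer than n scorable
#' pairs contribute up to their own maximum only: the average at each n is
#' over the families whose curve reaches n (no padding).
#'
#' @param curves list of [ppv_curve] vectors.
#' @param n_max length of the averaged curve (default: longest input).
#' @return numeric vector of length `n_max`, class `ppv_curve`; attribute
#'   `n_families` gives the per-n family count.
#' @export
average_ppv <- function(curves, n_max = NULL) {
  if (!is.list(curves) || length(curves) == 0L) {
    stop("`curves` must be a non-empty list", call. = FALSE)
  }
  lens <- lengths(curves)
  if (is.null(n_max)) n_max <- max(lens)
  out <- numeric(n_max)
  cnt <- integer(n_max)
  for (n in seq_len(n_max)) {
    have <- lens >= n
    cnt[n] <- sum(have)
    out[n] <- if (cnt[n] > 0L) {
      mean(vapply(curves[have], `[`, numeric(1), n))
    } else NA_real_
  }
  structure(out, class = "ppv_curve", n_families = cnt)
}

#' Probability calibration table
#'
#' Bins predicted contact probabilities into equal-width bins on [0, 1] and
#' tabulates the empirical contact fraction per bin. The slope of a
#' count-weighted least-squares fit of fraction against bin midpoint is
#' reported: a perfectly calibrated predictor has slope 1; overfitting
#' pushes the slope below 1.
#'
#' @param p predicted probabilities in [0, 1].
#' @param labels 0/1 contact labels.
#' @param bins number of equal-width bins (default 10).
#' @return list with `table` (data.frame: `midpoint`, `count`, `fraction`)
#'   and `slope`.
#' @export
calibration <- function(p, labels, bins = 10L) {
  if (length(p) == 0L) stop("empty input", call. = FALSE)
  if (length(p) != length(labels)) stop("length mismatch", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]", call. = FALSE)
  labels <- as.integer(labels)
  edges <- seq(0, 1, length.out = bins + 1L)
  idx <- pmin(pmax(findInterval(p, edges, rightmost.closed = TRUE), 1L), bins)
  count <- tabulate(idx, bins)
  frac <- rep(NA_real_, bins)
  pos <- tapply(labels, factor(idx, levels = seq_len(bins)), sum)
  frac[count > 0] <- pos[count > 0] / count[count > 0]
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  tab <- data.frame(midpoint = mid, count = count, fraction = frac)
  occ <- count > 0
  slope <- if (sum(occ) >= 2L && stats::var(mid[occ]) > 0) {
    stats::coef(stats::lm(fraction ~ midpoint, data = tab[occ, ],
                          weights = count[occ]))[["midpoint"]]
  } else NA_real_
  list(table = tab, slope = slope)
}

#' Remove pairs near the domain concatenation point
#'
#' Drops pairs whose residue i is within `d` positions of the end of domain
#' A or whose residue j is within `d` positions of the start of domain B.
#' Used for fair comparison with convolutional predictors, which receive
#' incoherent input across the junction; off by default for this method
#' itself.
#'
#' @param features data.frame with `i`, `j`.
#' @param l_a length of domain A.
#' @param d exclusion distance in positions.
#' @return filtered data.frame.
#' @export
exclude_junction <- function(features, l_a, d = 5L) {
  keep <- features$i <= l_a - d & features$j > d
  features[keep, , drop = FALSE]
}

#' Write a PPV curve / calibration table as TSV
#'
#' @param curve `ppv_curve` vector.
#' @param path TSV file.
#' @export
write_ppv_curve <- function(curve, path) {
  utils::write.table(data.frame(n = seq_along(curve), ppv = as.numeric(curve)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ppv_curve
#' @param cal list from [calibration].
#' @export
write_calibration <- function(cal, path) {
  utils::write.table(cal$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
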