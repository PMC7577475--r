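# The logistic-regression head: min-max scaling of the filter score,
# L2-penalised fit of (w0, w1, w2) on training families, contact
# probabilities, and the decision boundary in the (filter score, DCA score)
# plane.

#' Min-max scale a filter score with training-set bounds
#'
#' `(x2 - min) / (max - min)`. The bounds are the extremes of the filter
#' score over the (restricted) training set and are reused verbatim at test
#' time, so test values may fall outside `[0, 1]`; no clamping is applied.
#'
#' @param x2 numeric vector of raw filter scores.
#' @param bounds numeric `c(min, max)` with `min < max`.
#' @return scaled values.
#' @export
scale_x2 <- function(x2, bounds) {
  if (length(bounds) != 2L || !all(is.finite(bounds)) || bounds[1] >= bounds[2]) {
    stop("`bounds` must be c(min, max) with min < max", call. = FALSE)
  }
  (x2 - bounds[1]) / (bounds[2] - bounds[1])
}

# Penalised logistic regression by Newton/IRLS.
# Minimises  -loglik + (lambda/2) * (w1^2 + w2^2); the bias is unpenalised.
irls_logistic <- function(X, y, lambda, max_iter = 200L, tol = 1e-12) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    wgt <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(X, y - mu)) - pen %*% beta
    hess <- crossprod(X * wgt, X) + pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

#' Fit the two-feature logistic contact classifier
#'
#' Training rows are restricted to pairs with positive DCA score
#' (`x1 > 0`) — contacts are a ~1% minority and this restriction
#' concentrates learning on pairs carrying coevolutionary signal. The filter
#' score is min-max scaled with bounds computed on the restricted rows (and
#' stored in the model for reuse at prediction time), then
#' `P(contact | x) = plogis(w0 + w1 x1 + w2 x2_scaled)` is fitted by
#' L2-penalised maximum likelihood.
#'
#' The penalty convention is `(lambda/2) * (w1^2 + w2^2)` added to the
#' negative log-likelihood summed over rows (not averaged), bias
#' unpenalised; duplicating every row is therefore equivalent to halving
#' `lambda`.
#'
#' @param features data.frame from [feature_table] with binary `label`.
#' @param l2_strength penalty weight lambda (> 0 recommended; default 1).
#' @param seed unused (the fit is deterministic); kept for interface
#'   stability.
#' @param k,bin optional window size and M_eff bin recorded in the model.
#' @param restrict_positive apply the `x1 > 0` training restriction
#'   (default `TRUE`).
#' @return A `logistic_model`: list with `w0`, `w` (length 2), `l2`,
#'   `bounds`, `k`, `bin`, `seed`, `fitted = TRUE`.
#' @export
fit_logistic <- function(features, l2_strength = 1.0, seed = NULL,
                         k = NA_integer_, bin = NA_character_,
                         restrict_positive = TRUE) {
  stop_if_not_scalar_number(l2_strength, "l2_strength")
  if (l2_strength < 0) stop("`l2_strength` must be >= 0", call. = FALSE)
  rows <- features[!is.na(features$label), , drop = FALSE]
  if (restrict_positive) rows <- rows[rows$x1 > 0, , drop = FALSE]
  if (nrow(rows) < 2L || length(unique(rows$label)) < 2L) {
    stop("training set has a single class after the x1 > 0 restriction",
         call. = FALSE)
  }
  bounds <- range(rows$x2)
  if (bounds[1] >= bounds[2]) {
    stop("filter scores are constant on the training set", call. = FALSE)
  }
  X <- cbind(1, rows$x1, scale_x2(rows$x2, bounds))
  beta <- irls_logistic(X, rows$label, l2_strength)
  structure(list(w0 = beta[1], w = beta[2:3], l2 = l2_strength,
                 bounds = bounds, k = as.integer(k), bin = as.character(bin),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 fitted = TRUE),
            class = "logistic_model")
}

#' Predicted contact probability of residue pairs
#'
#' Applies the stored min-max scaling to the raw filter score, then the
#' logistic: `P = plogis(w0 + w1 x1 + w2 x2_scaled)`.
#'
#' @param model fitted `logistic_model`.
#' @param x1 DCA scores.
#' @param x2_raw raw (unscaled) filter scores.
#' @return probabilities in `(0, 1)`.
#' @export
predict_proba <- function(model, x1, x2_raw) {
  if (!inherits(model, "logistic_model") || !isTRUE(model$fitted)) {
    stop("`model` is not a fitted logistic_model", call. = FALSE)
  }
  stats::plogis(model$w0 + model$w[1] * x1 +
                  model$w[2] * scale_x2(x2_raw, model$bounds))
}

#' Score and rank all pairs of a feature table
#'
#' All represented pairs are scored — the `x1 > 0` restriction applies to
#' training only. A model trained for one M_eff bin refuses to score a
#' family from another bin unless `force = TRUE` (then it proceeds with a
#' warning).
#'
#' @param model fitted `logistic_model`.
#' @param features data.frame from [feature_table].
#' @param meff optional M_eff of the scored family, checked against the
#'   model's bin.
#' @param force score despite a bin mismatch.
#' @return `features` with added columns `p` and `rank` (1 = best), ranked
#'   by decreasing probability, ties broken by (i, j).
#' @export
predict_contacts <- function(model, features, meff = NULL, force = FALSE) {
  if (!is.null(meff) && !is.na(model$bin)) {
    b <- meff_bin(meff)
    if (b != model$bin) {
      msg <- sprintf("family M_eff bin '%s' differs from model bin '%s'",
                     b, model$bin)
      if (!force) stop(paste0(msg, "; use force = TRUE to override"),
                       call. = FALSE)
      warning(msg, call. = FALSE)
    }
  }
  p <- predict_proba(model, features$x1, features$x2)
  ord <- order(-p, features$i, features$j)
  out <- features
  out$p <- p
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Decision boundary in the (raw filter score, DCA score) plane
#'
#' The locus `P(contact | x) = 1/2`, i.e. `w0 + w1 x1 + w2 s(x2) = 0` with
#' `s` the stored min-max scaling, expressed as `x1 = intercept +
#' slope * x2_raw`. A model with `w1 = 0` has a vertical boundary in this
#' parameterisation.
#'
#' @param model fitted `logistic_model`.
#' @return list with `vertical` (logical); when `FALSE`, `intercept` and
#'   `slope`; when `TRUE`, `x2_raw` (the boundary's filter-score location).
#' @export
decision_boundary <- function(model) {
  if (!inherits(model, "logistic_model")) stop("not a logistic_model", call. = FALSE)
  rg <- model$bounds[2] - model$bounds[1]
  if (model$w[1] == 0) {
    if (model$w[2] == 0) stop("degenerate model: w1 = w2 = 0", call. = FALSE)
    s <- -model$w0 / model$w[2]
    return(list(vertical = TRUE, x2_raw = model$bounds[1] + s * rg))
  }
  list(vertical = FALSE,
       intercept = -(model$w0 - model$w[2] * model$bounds[1] / rg) / model$w[1],
       slope = -model$w[2] / (rg * model$w[1]))
}

#' Family-level train/test split
#'
#' Families (not residue pairs) are assigned at random to the training or
#' test side; deterministic under `seed`.
#'
#' @param family_ids character vector of (unique or repeated) family ids.
#' @param fraction training fraction (default 0.5).
#' @param seed RNG seed.
#' @return A `split_plan`: list with `train`, `test` (character vectors),
#'   `fraction`, `seed`.
#' @export
split_families <- function(family_ids, fraction = 0.5, seed = 1L) {
  ids <- unique(as.character(family_ids))
  n <- length(ids)
  if (n < 2L) stop("need at least 2 families to split", call. = FALSE)
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1)", call. = FALSE)
  n_train <- max(1L, min(n - 1L, as.integer(round(fraction * n))))
  train <- with_seed(seed, sample(ids, n_train))
  structure(list(train = sort(train), test = sort(setdiff(ids, train)),
                 fraction = fraction, seed = as.integer(seed)),
            class = "split_plan")
}

#' Serialise / deserialise a logistic model as JSON
#'
#' Full precision; a write-read round trip is bit-exact.
#'
#' @param model `logistic_model`.
#' @param path JSON file.
#' @export
write_model <- function(model, path) {
  obj <- list(w0 = model$w0, w1 = model$w[1], w2 = model$w[2],
              l2 = model$l2, bounds = model$bounds, k = model$k,
              bin = model$bin, seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       na = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(w0 = as.numeric(o$w0),
                 w = c(as.numeric(o$w1), as.numeric(o$w2)),
                 l2 = as.numeric(o$l2),
                 bounds = as.numeric(o$bounds),
                 k = if (is.null(o$k)) NA_integer_ else as.integer(o$k),
                 bin = if (is.null(o$bin)) NA_character_ else as.character(o$bin),
                 seed = if (is.null(o$seed)) NA_integer_ else as.integer(o$seed),
                 fitted = TRUE),
            class = "logistic_model")
}
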