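make_model <- function(w0, w1, w2, bounds = c(0, 1), bin = NA_character_) {
  structure(list(w0 = w0, w = c(w1, w2), l2 = 1, bounds = bounds,
                 k = NA_integer_, bin = bin, seed = NA_integer_,
                 fitted = TRUE),
            class = "logistic_model")
}

coef_vec <- function(m) c(m$w0, m$w)

fake_features <- function(x1, x2, label, family = "f") {
  data.frame(i = seq_along(x1), j = rep(1L, length(x1)), x1 = x1, x2 = x2,
             best_filter = 1L, label = label, family = family)
}

test_that("scale_x2 is the affine map with no clamping", {
  expect_equal(scale_x2(0.2, c(0.2, 0.8)), 0)
  expect_equal(scale_x2(0.8, c(0.2, 0.8)), 1)
  expect_equal(scale_x2(0.2 - 0.6, c(0.2, 0.8)), -1)   # extrapolates
  expect_error(scale_x2(0.5, c(0.8, 0.2)), "min < max")
  expect_error(scale_x2(0.5, c(0.5, 0.5)), "min < max")
})

test_that("fit separates a separable toy set and respects the x1 > 0 rule", {
  set.seed(3)
  n <- 200
  x1 <- c(runif(n, 0.5, 1), runif(n, 0.01, 0.3))
  x2 <- c(runif(n, 0.6, 1), runif(n, 0, 0.4))
  ft <- fake_features(x1, x2, rep(c(1L, 0L), each = n))
  m <- fit_logistic(ft, l2_strength = 1)
  acc <- mean((predict_proba(m, x1, x2) > 0.5) == ft$label)
  expect_equal(acc, 1.0)

  # rows with x1 <= 0 never reach training: bounds ignore them
  ft2 <- rbind(ft, fake_features(c(-5, -6), c(-10, 10), c(0L, 1L)))
  m2 <- fit_logistic(ft2)
  expect_identical(m2$bounds, m$bounds)
  expect_equal(coef_vec(m2), coef_vec(m))

  only_pos <- fake_features(c(0.5, -0.2), c(0.1, 0.9), c(1L, 0L))
  expect_error(fit_logistic(only_pos), "single class")
})

test_that("fit recovers known coefficients from simulated data", {
  set.seed(11)
  n <- 20000
  x1 <- runif(n); x2 <- runif(n)
  truth <- c(-3, 8, 4)
  p <- plogis(truth[1] + truth[2] * x1 + truth[3] * x2)
  ft <- fake_features(x1, x2, rbinom(n, 1, p))
  ft <- rbind(ft, fake_features(c(0.5, 0.5), c(0, 1), c(0L, 1L)))  # pin bounds
  m <- fit_logistic(ft, l2_strength = 1e-6)
  expect_lt(max(abs(coef_vec(m) - truth) / abs(truth)), 0.10)
})

test_that("duplicating rows is equivalent to halving the penalty", {
  set.seed(13)
  n <- 500
  x1 <- runif(n); x2 <- runif(n)
  ft <- fake_features(x1, x2, rbinom(n, 1, plogis(-1 + 2 * x1 + x2)))
  m1 <- fit_logistic(ft, l2_strength = 5)
  m2 <- fit_logistic(rbind(ft, ft), l2_strength = 10)
  expect_equal(coef_vec(m2), coef_vec(m1), tolerance = 1e-8)
})

test_that("predict_proba evaluates the logistic exactly", {
  m0 <- make_model(0, 0, 0)
  expect_equal(predict_proba(m0, 5, 0.3), 0.5)

  # w x + w0 = ln 3  ->  P = 3/4
  ml <- make_model(log(3), 0, 0)
  expect_equal(predict_proba(ml, 0, 0), 0.75)

  set.seed(17)
  for (rep in 1:50) {
    m <- make_model(rnorm(1), rnorm(1, sd = 3), rnorm(1, sd = 3),
                    bounds = sort(runif(2)))
    x1 <- rnorm(1); x2 <- rnorm(1)
    eta <- m$w0 + m$w[1] * x1 +
      m$w[2] * (x2 - m$bounds[1]) / (m$bounds[2] - m$bounds[1])
    expect_equal(predict_proba(m, x1, x2), exp(eta) / (1 + exp(eta)),
                 tolerance = 1e-12)
    expect_equal(predict_proba(m, x1, x2) + 1 / (1 + exp(eta)), 1,
                 tolerance = 1e-12)
  }

  expect_error(predict_proba(list(w0 = 1), 1, 1), "fitted")
})

test_that("probability is monotone in each feature with positive weights", {
  m <- make_model(-1, 2, 3)
  x1 <- seq(-2, 2, length.out = 50)
  expect_true(all(diff(predict_proba(m, x1, 0.5)) > 0))
  x2 <- seq(-1, 2, length.out = 50)
  expect_true(all(diff(predict_proba(m, 0.1, x2)) > 0))
})

test_that("decision boundary algebra and plug-back", {
  # w2 = 0: horizontal boundary at x1 = -w0 / w1 (DCA-score-only regime)
  mh <- make_model(-2, 4, 0)
  db <- decision_boundary(mh)
  expect_false(db$vertical)
  expect_equal(db$slope, 0)
  expect_equal(db$intercept, 0.5)

  # identity scaling, w = (1, 1), w0 = -1: x1 = 1 - x2
  mi <- make_model(-1, 1, 1, bounds = c(0, 1))
  db2 <- decision_boundary(mi)
  expect_equal(db2$intercept, 1)
  expect_equal(db2$slope, -1)

  set.seed(19)
  for (rep in 1:20) {
    m <- make_model(rnorm(1), rnorm(1, sd = 2) + 3, rnorm(1, sd = 2),
                    bounds = sort(rnorm(2)))
    db <- decision_boundary(m)
    for (x2 in c(-1, 0, 0.5, 2)) {
      x1 <- db$intercept + db$slope * x2
      expect_equal(predict_proba(m, x1, x2), 0.5, tolerance = 1e-12)
    }
  }

  mv <- make_model(-1, 0, 2, bounds = c(0, 1))
  dbv <- decision_boundary(mv)
  expect_true(dbv$vertical)
  expect_equal(dbv$x2_raw, 0.5)
})

test_that("split_families is family-level, deterministic, balanced", {
  s2 <- split_families(c("a", "b"), 0.5, seed = 1)
  expect_length(s2$train, 1L); expect_length(s2$test, 1L)

  expect_identical(split_families(letters, seed = 42),
                   split_families(letters, seed = 42))

  ids <- sprintf("fam%04d", 1:1000)
  s <- split_families(ids, 0.5, seed = 7)
  expect_true(abs(length(s$train) - 500) <= 1)
  expect_setequal(c(s$train, s$test), ids)
  expect_length(intersect(s$train, s$test), 0L)

  expect_error(split_families("a"), "at least 2")
})

test_that("ranking by probability equals ranking by the linear score", {
  set.seed(23)
  ft <- fake_features(rnorm(200), runif(200), rbinom(200, 1, 0.5))
  ft$j <- sample(5, 200, replace = TRUE)
  m <- make_model(-1, 2, 1.5)
  pred <- predict_contacts(m, ft)
  lin <- m$w0 + m$w[1] * ft$x1 + m$w[2] * scale_x2(ft$x2, m$bounds)
  ft$score <- lin
  expect_equal(pred$i, rank_pairs(ft)$i)
  expect_equal(pred$j, rank_pairs(ft)$j)
})

test_that("a model refuses other M_eff bins unless forced", {
  ft <- fake_features(c(0.5, 0.1), c(0.2, 0.8), c(1L, 0L))
  m <- make_model(-1, 2, 1, bin = "large")
  expect_error(predict_contacts(m, ft, meff = 100), "differs from model bin")
  expect_warning(p <- predict_contacts(m, ft, meff = 100, force = TRUE),
                 "differs")
  expect_equal(nrow(p), 2L)
  expect_silent(predict_contacts(m, ft, meff = 500))
})

test_that("model JSON serialisation round-trips bit-exactly", {
  set.seed(29)
  ft <- fake_features(runif(300), runif(300),
                      rbinom(300, 1, plogis(runif(300) * 4 - 2)))
  m <- fit_logistic(ft, l2_strength = 0.5, k = 9, bin = "medium")
  p <- withr::local_tempfile(fileext = ".json")
  write_model(m, p)
  back <- read_model(p)
  expect_identical(back$w0, m$w0)
  expect_identical(back$w, m$w)
  expect_identical(back$bounds, m$bounds)
  expect_identical(back$bin, m$bin)
  expect_identical(back$k, m$k)
})
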