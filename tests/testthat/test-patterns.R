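test_that("extract_window slices interior and border windows correctly", {
  m <- matrix(1:25, 5, 5)
  w <- extract_window(m, 3, 3, 3)
  expect_equal(w$values, m[2:4, 2:4])
  expect_true(all(w$mask))

  wc <- extract_window(m, 1, 1, 3)
  expect_equal(sum(wc$mask), 4L)            # 2x2 valid corner
  expect_equal(sum(!wc$mask), 5L)
  expect_equal(wc$values[2:3, 2:3], m[1:2, 1:2])

  # random centre, k = 5: compare with explicit index arithmetic
  set.seed(13)
  mr <- matrix(rnorm(144), 12, 12)
  for (rep in 1:20) {
    i <- sample(12, 1); j <- sample(12, 1)
    w5 <- extract_window(mr, i, j, 5)
    for (a in -2:2) for (b in -2:2) {
      inside <- i + a >= 1 && i + a <= 12 && j + b >= 1 && j + b <= 12
      expect_equal(w5$mask[a + 3, b + 3], inside)
      if (inside) expect_equal(w5$values[a + 3, b + 3], mr[i + a, j + b])
    }
  }

  expect_error(extract_window(m, 2, 2, 4), "odd")
  expect_error(extract_window(m, 6, 1, 3), "outside")
})

test_that("mean_contact_pattern averages fully valid windows", {
  m0 <- matrix(0, 3, 3); m1 <- matrix(1, 3, 3)
  mk <- function(v) structure(list(values = v, mask = matrix(TRUE, 3, 3),
                                   center = c(2, 2), k = 3L),
                              class = "dca_window")
  expect_equal(mean_contact_pattern(list(mk(m1))), m1)
  expect_equal(mean_contact_pattern(list(mk(m0), mk(m1))), matrix(0.5, 3, 3))

  set.seed(17)
  ws <- lapply(1:50, function(x) mk(matrix(rbinom(9, 1, 0.4), 3, 3)))
  got <- mean_contact_pattern(ws)
  acc <- matrix(0, 3, 3)
  for (w in ws) acc <- acc + w$values
  expect_equal(got, acc / 50)

  # truncated windows are dropped
  big <- matrix(1:25, 5, 5)
  ws2 <- list(extract_window(big, 3, 3, 3), extract_window(big, 1, 1, 3))
  expect_equal(mean_contact_pattern(ws2), big[2:4, 2:4])
  expect_error(mean_contact_pattern(list(extract_window(big, 1, 1, 3))),
               "no fully valid")
  expect_error(mean_contact_pattern(list()), "non-empty")
})

test_that("k-means assigns every window to its nearest centroid", {
  set.seed(31)
  x <- rbind(matrix(rnorm(200, 0), 20), matrix(rnorm(200, 4), 20),
             matrix(rnorm(200, -4), 20))
  fit <- filterDCA:::with_seed(4, filterDCA:::run_kmeans(x, 3L))
  d2 <- vapply(seq_len(nrow(fit$centers)), function(c) {
    rowSums((x - matrix(fit$centers[c, ], nrow(x), ncol(x), byrow = TRUE))^2)
  }, numeric(nrow(x)))
  expect_equal(unname(fit$cluster), unname(apply(d2, 1, which.min)))
})

test_that("planted window motifs are recovered by 3-means centroids", {
  k <- 9
  n <- 1200
  hh <- rbind(sample_motif_windows(n, "helix", k, seed = 1),
              sample_motif_windows(n, "parallel", k, seed = 2),
              sample_motif_windows(n, "antiparallel", k, seed = 3))
  # single-class recovery: cluster the mixed collection into 3
  fit <- filterDCA:::with_seed(7, filterDCA:::run_kmeans(hh, 3L))
  for (motif in c("helix", "parallel", "antiparallel")) {
    tpl <- motif_template(motif, k)
    errs <- apply(fit$centers, 1, function(c) mean(abs(matrix(c, k, k) - tpl)))
    expect_lt(min(errs), 0.05)
  }
})

test_that("build_filters_from_windows: k=1 equals the mean; seeds reproduce", {
  k <- 7
  hh <- sample_motif_windows(300, "helix", k, seed = 5)
  ee <- sample_motif_windows(300, "antiparallel", k, seed = 6)
  bank1 <- build_filters_from_windows(hh, ee, k, n_clusters = 1L, seed = 9)
  expect_equal(as.vector(t(bank1$filters[[1]])),
               as.vector(t(matrix(colMeans(hh), k, k))), tolerance = 1e-12)
  expect_equal(matrix(as.vector(bank1$filters[[2]]), k, k),
               matrix(colMeans(ee), k, k), tolerance = 1e-12)

  b_a <- build_filters_from_windows(hh, ee, k, seed = 11)
  b_b <- build_filters_from_windows(hh, ee, k, seed = 11)
  expect_identical(b_a, b_b)
  expect_error(build_filters_from_windows(hh[1:2, ], ee, k), "too few HH")
})

test_that("filters built from contact maps are probabilities with a contact centre", {
  fams <- generate_benchmark(6, seed = 41)
  bank <- build_filters(fams, k = 9, seed = 2)
  centre <- (9 * 9 + 1) %/% 2
  for (f in bank$filters) {
    expect_true(all(f >= 0 & f <= 1))
    expect_equal(as.vector(f)[centre], 1)   # centre is a contact by construction
  }
  expect_equal(bank$class, rep(c("HH", "EE"), each = 3L))
})

test_that("helical mean pattern carries the one-turn periodicity", {
  # all-helical domains -> every contact window follows the period-4 lattice
  ssh <- strrep("H", 60)
  fams <- lapply(1:6, function(i) {
    generate_family(paste0("h", i), ss_a = ssh, ss_b = ssh, n_blocks = 1,
                    seed = 100 + i)
  })
  k <- 9
  wins <- do.call(rbind, lapply(fams, function(f) {
    filterDCA:::collect_class_windows(f$contact_map, f$ss_a, f$ss_b, k, "HH")
  }))
  mp <- matrix(colMeans(wins), k, k)
  h <- (k - 1) / 2
  col_mass <- colMeans(mp)
  names(col_mass) <- -h:h
  on_set <- col_mass[as.character(c(0, -3, 3, -4, 4))]
  off_set <- col_mass[as.character(c(-2, 2))]
  expect_gt(min(on_set[c("0", "-4", "4")]), max(off_set))
  expect_gt(sum(on_set), sum(off_set))
})

test_that("bootstrap resampling leaves centroids nearly unchanged", {
  k <- 7
  n <- 10002
  third <- n / 3
  mk_class <- function(seeds) {
    rbind(sample_motif_windows(third, "helix", k, seed = seeds[1]),
          sample_motif_windows(third, "parallel", k, seed = seeds[2]),
          sample_motif_windows(third, "antiparallel", k, seed = seeds[3]))
  }
  hh <- mk_class(21:23)
  ee <- mk_class(24:26)
  bank <- build_filters_from_windows(hh, ee, k, seed = 3)
  set.seed(77)
  bank_b <- build_filters_from_windows(hh[sample(n, n, replace = TRUE), ],
                                       ee[sample(n, n, replace = TRUE), ],
                                       k, seed = 3)
  for (f in seq_along(bank$filters)) {
    errs <- vapply(bank_b$filters, function(g) rms(bank$filters[[f]], g),
                   numeric(1))
    expect_lt(min(errs), 0.05)
  }
})

test_that("filter bank JSON serialisation is bit-exact", {
  fams <- generate_benchmark(4, seed = 8)
  bank <- build_filters(fams, k = 7, seed = 5)
  p <- withr::local_tempfile(fileext = ".json")
  write_filter_bank(bank, p)
  back <- read_filter_bank(p)
  expect_identical(back$k, bank$k)
  expect_identical(back$class, bank$class)
  for (f in 1:6) expect_identical(back$filters[[f]], bank$filters[[f]])
})
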