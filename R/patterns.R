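# Construction of the structural filter bank: windows around HH and EE
# contacts are collected, averaged, and sub-clustered with 3-means; the
# cluster centroids are the filters.

#' Extract a k x k window centred on a matrix entry
#'
#' Positions of the window that fall outside the matrix are marked invalid
#' in the mask and carry `NA` in `values`; the window itself always has the
#' full k x k shape with the centre at position ((k+1)/2, (k+1)/2).
#'
#' @param m numeric matrix.
#' @param i,j 1-based centre indices.
#' @param k odd window size (>= 3).
#' @return A `dca_window`: list with `values` (k x k, `NA` outside), `mask`
#'   (logical k x k, `TRUE` = inside the matrix), `center = c(i, j)`, `k`.
#' @export
extract_window <- function(m, i, j, k) {
  k <- check_odd_k(k)
  m <- as.matrix(m)
  if (i < 1 || i > nrow(m) || j < 1 || j > ncol(m)) {
    stop("window centre outside the matrix", call. = FALSE)
  }
  h <- (k - 1L) %/% 2L
  rows <- (i - h):(i + h)
  cols <- (j - h):(j + h)
  ok_r <- rows >= 1L & rows <= nrow(m)
  ok_c <- cols >= 1L & cols <= ncol(m)
  vals <- matrix(NA_real_, k, k)
  vals[ok_r, ok_c] <- m[rows[ok_r], cols[ok_c], drop = FALSE]
  mask <- outer(ok_r, ok_c, "&") & !is.na(vals)
  structure(list(values = vals, mask = mask, center = c(i, j), k = k),
            class = "dca_window")
}

window_is_full <- function(w) all(w$mask)

#' Average contact pattern over a set of windows
#'
#' Element-wise mean over fully valid (untruncated) windows; windows touching
#' a matrix border are dropped. For binary contact-map windows the entries
#' are the estimated probabilities of finding another contact at each
#' position relative to the central contact.
#'
#' @param windows list of `dca_window` objects sharing the same `k`.
#' @return k x k numeric matrix.
#' @export
mean_contact_pattern <- function(windows) {
  if (!is.list(windows) || length(windows) == 0L) {
    stop("`windows` must be a non-empty list", call. = FALSE)
  }
  ks <- vapply(windows, function(w) w$k, integer(1))
  if (length(unique(ks)) != 1L) stop("windows differ in size k", call. = FALSE)
  full <- Filter(window_is_full, windows)
  if (length(full) == 0L) stop("no fully valid windows", call. = FALSE)
  Reduce(`+`, lapply(full, `[[`, "values")) / length(full)
}

# Flatten fully valid windows centred on contacts of one class into an
# n x k^2 matrix (row-major per window: R column-major of the k x k values).
collect_class_windows <- function(cmap, ss_a, ss_b, k, class) {
  k <- check_odd_k(k)
  a <- check_ss(ss_a, "ss_a"); b <- check_ss(ss_b, "ss_b")
  m <- unclass(cmap)
  if (nrow(m) != length(a) || ncol(m) != length(b)) {
    stop("contact map shape does not match secondary-structure lengths",
         call. = FALSE)
  }
  h <- (k - 1L) %/% 2L
  idx <- which(m == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(matrix(numeric(0), 0L, k * k))
  want <- substring(class, 1, 1)
  cls <- a[idx[, 1]] == want & b[idx[, 2]] == substring(class, 2, 2)
  interior <- idx[, 1] > h & idx[, 1] <= nrow(m) - h &
    idx[, 2] > h & idx[, 2] <= ncol(m) - h
  idx <- idx[cls & interior, , drop = FALSE]
  if (nrow(idx) == 0L) return(matrix(numeric(0), 0L, k * k))
  offs <- as.matrix(expand.grid(di = -h:h, dj = -h:h))
  delta <- offs[, "dj"] * nrow(m) + offs[, "di"]
  centres <- (idx[, 2] - 1L) * nrow(m) + idx[, 1]
  w <- matrix(m[outer(centres, delta, "+")], nrow(idx), k * k)
  storage.mode(w) <- "double"
  w
}

# k-means++ seeding (Arthur & Vassilvitskii): first centre uniform, each
# further centre sampled with probability proportional to squared distance
# to the nearest chosen centre.
kmeanspp_init <- function(x, n_clusters) {
  n <- nrow(x)
  centres <- integer(n_clusters)
  centres[1] <- sample.int(n, 1L)
  d2 <- colSums((t(x) - x[centres[1], ])^2)
  if (n_clusters > 1L) {
    for (c in 2:n_clusters) {
      p <- d2 / sum(d2)
      if (!all(is.finite(p)) || sum(d2) == 0) p <- rep(1 / n, n)
      centres[c] <- sample.int(n, 1L, prob = p)
      d2 <- pmin(d2, colSums((t(x) - x[centres[c], ])^2))
    }
  }
  x[centres, , drop = FALSE]
}

run_kmeans <- function(x, n_clusters, restarts = 10L, iter_max = 100L) {
  if (nrow(x) < n_clusters) stop("fewer windows than clusters", call. = FALSE)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- kmeanspp_init(x, n_clusters)
    # jitter exact duplicate seeds so stats::kmeans accepts them
    if (anyDuplicated(init)) {
      init <- init + matrix(stats::rnorm(length(init), sd = 1e-8),
                            nrow(init), ncol(init))
    }
    fit <- suppressWarnings(
      stats::kmeans(x, centers = init, iter.max = iter_max,
                    algorithm = "Lloyd")
    )
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Build the six structural filters from window collections
#'
#' Runs k-means (`n_clusters` clusters, k-means++ seeding, 10 restarts,
#' Lloyd iterations) separately on the HH and EE window collections; the
#' cluster centroids, reshaped to k x k, are the filters. Within each class
#' the filters are ordered by decreasing cluster size (ties broken by the
#' centroid entries) so the bank is deterministic under a fixed seed.
#'
#' @param hh_windows,ee_windows numeric matrices, one flattened fully valid
#'   k x k window per row (as produced by [collect_class_windows] or
#'   [sample_motif_windows]).
#' @param k odd window size.
#' @param n_clusters clusters per class (default 3).
#' @param seed RNG seed for the clustering.
#' @return A `filter_bank`: list with `k`, `filters` (list of 2 * n_clusters
#'   k x k matrices), `class` (`"HH"`/`"EE"` per filter), `sizes`, `seed`.
#' @export
build_filters_from_windows <- function(hh_windows, ee_windows, k,
                                       n_clusters = 3L, seed = 1L) {
  k <- check_odd_k(k)
  for (nm in c("hh", "ee")) {
    w <- if (nm == "hh") hh_windows else ee_windows
    if (!is.matrix(w) || ncol(w) != k * k) {
      stop(sprintf("%s windows must be an n x k^2 matrix", toupper(nm)),
           call. = FALSE)
    }
    if (nrow(w) < n_clusters) {
      stop(sprintf("too few %s windows (%d) for %d clusters",
                   toupper(nm), nrow(w), n_clusters), call. = FALSE)
    }
  }
  cluster_class <- function(w) {
    fit <- run_kmeans(w, n_clusters)
    ord <- order(-fit$size, apply(fit$centers, 1, paste, collapse = ","))
    list(centers = fit$centers[ord, , drop = FALSE], sizes = fit$size[ord])
  }
  res <- with_seed(seed, {
    hh <- cluster_class(hh_windows)
    ee <- cluster_class(ee_windows)
    list(hh = hh, ee = ee)
  })
  filters <- c(
    lapply(seq_len(n_clusters), function(c) matrix(res$hh$centers[c, ], k, k)),
    lapply(seq_len(n_clusters), function(c) matrix(res$ee$centers[c, ], k, k))
  )
  structure(list(k = k,
                 filters = filters,
                 class = rep(c("HH", "EE"), each = n_clusters),
                 sizes = c(res$hh$sizes, res$ee$sizes),
                 seed = as.integer(seed)),
            class = "filter_bank")
}

#' Build the filter bank from a collection of annotated contact maps
#'
#' Collects fully valid k x k contact-map windows around every HH and every
#' EE contact of the collection (border-truncated windows are excluded from
#' construction) and clusters each class with [build_filters_from_windows].
#' The collection should be disjoint from the families used for training
#' and testing the classifier.
#'
#' @param families list of lists, each with elements `contact_map`, `ss_a`,
#'   `ss_b` (a [synthetic_family] qualifies).
#' @inheritParams build_filters_from_windows
#' @return A `filter_bank`.
#' @export
build_filters <- function(families, k, n_clusters = 3L, seed = 1L) {
  k <- check_odd_k(k)
  gather <- function(class) {
    do.call(rbind, lapply(families, function(f) {
      collect_class_windows(f$contact_map, f$ss_a, f$ss_b, k, class)
    }))
  }
  hh <- gather("HH"); ee <- gather("EE")
  if (is.null(hh) || nrow(hh) < n_clusters) {
    stop("too few fully valid HH windows in the collection", call. = FALSE)
  }
  if (is.null(ee) || nrow(ee) < n_clusters) {
    stop("too few fully valid EE windows in the collection", call. = FALSE)
  }
  build_filters_from_windows(hh, ee, k, n_clusters, seed)
}

#' Serialise / deserialise a filter bank as JSON
#'
#' Matrices are stored row-major at full precision; a write-read round trip
#' reproduces the bank bit-exactly.
#'
#' @param bank `filter_bank`.
#' @param path JSON file.
#' @export
write_filter_bank <- function(bank, path) {
  obj <- list(
    k = bank$k,
    class = bank$class,
    sizes = bank$sizes,
    seed = bank$seed,
    filters = lapply(bank$filters, function(f) as.vector(t(f)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_filter_bank
#' @export
read_filter_bank <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- as.integer(obj$k)
  filters <- lapply(seq_len(nrow_or_len(obj$filters)), function(c) {
    v <- if (is.matrix(obj$filters)) obj$filters[c, ] else obj$filters[[c]]
    matrix(as.numeric(v), k, k, byrow = TRUE)
  })
  structure(list(k = k, filters = filters,
                 class = as.character(obj$class),
                 sizes = as.numeric(obj$sizes),
                 seed = as.integer(obj$seed)),
            class = "filter_bank")
}

nrow_or_len <- function(x) if (is.matrix(x)) nrow(x) else length(x)
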