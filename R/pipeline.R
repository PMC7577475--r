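# End-to-end pipeline and command-line entry point:
# simulate/ingest -> build-filters -> score -> train -> predict -> evaluate.

#' Validated run configuration
#'
#' @param k odd filter window size, between 5 and 69 (default 45, the size
#'   at which ranking accuracy peaks on the reference corpus; large enough
#'   to see coherent neighbourhood structure, small enough to avoid
#'   structurally variable distant regions).
#' @param contact_threshold contact distance cutoff in Angstrom.
#' @param split_fraction family-level training fraction.
#' @param l2_strength logistic penalty weight (see [fit_logistic]).
#' @param n_filter_families families reserved (disjointly) for filter
#'   construction in simulated runs.
#' @param p_det,s,sigma synthetic score-model parameters.
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(k = 45L, contact_threshold = 8.0,
                       split_fraction = 0.5, l2_strength = 1.0,
                       n_filter_families = 10L, p_det = 0.5, s = 0.3,
                       sigma = 0.1, seed = 1L) {
  k <- check_odd_k(k)
  if (k < 5L || k > 69L) {
    stop("window size k must be an odd number between 5 and 69", call. = FALSE)
  }
  if (contact_threshold <= 0) stop("contact threshold must be positive", call. = FALSE)
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split fraction must be in (0, 1)", call. = FALSE)
  }
  structure(list(k = k, contact_threshold = contact_threshold,
                 split_fraction = split_fraction, l2_strength = l2_strength,
                 n_filter_families = as.integer(n_filter_families),
                 p_det = p_det, s = s, sigma = sigma,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full simulated pipeline
#'
#' Generates a synthetic benchmark, builds the filter bank on a disjoint
#' filter collection, computes feature tables, splits the remaining
#' families 50/50 at family level, trains the logistic head on the training
#' side (x1 > 0 restriction), predicts and ranks every pair of every test
#' family, and evaluates family-averaged PPV and calibration. All artifacts
#' are written under `out_dir` with a provenance summary; a rerun with the
#' same configuration is byte-identical.
#'
#' @param config [run_config].
#' @param n_families benchmark families (excluding the filter collection).
#' @param out_dir output directory (`NULL` = do not write artifacts).
#' @param n_ppv length of the reported PPV curve.
#' @param quiet suppress progress messages.
#' @return list with `bank`, `model`, `split`, `ppv_filterdca`, `ppv_dca`,
#'   `calibration`, `summary`.
#' @export
run_pipeline <- function(config = run_config(), n_families = 40L,
                         out_dir = NULL, n_ppv = 100L, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))

  total <- n_families + config$n_filter_families
  fams <- generate_benchmark(total, p_det = config$p_det, s = config$s,
                             sigma = config$sigma, seed = config$seed)
  filter_fams <- fams[seq_len(config$n_filter_families)]
  bench <- fams[-seq_len(config$n_filter_families)]
  say("simulate: %d filter-collection + %d benchmark families",
      length(filter_fams), length(bench))

  bank <- build_filters(filter_fams, k = config$k,
                        seed = derive_seed(config$seed, 11L))
  say("build-filters: k = %d, cluster sizes %s", config$k,
      paste(bank$sizes, collapse = "/"))

  feats <- lapply(bench, function(f) {
    feature_table(f$scores, bank, truth = f$contact_map)
  })
  names(feats) <- vapply(bench, `[[`, character(1), "family")

  split <- split_families(names(feats), fraction = config$split_fraction,
                          seed = derive_seed(config$seed, 22L))
  train_tab <- do.call(rbind, feats[split$train])
  n_pos_rows <- sum(train_tab$x1 > 0)
  say("train: %d families, %d pairs (%d after x1 > 0 restriction)",
      length(split$train), nrow(train_tab), n_pos_rows)
  model <- fit_logistic(train_tab, l2_strength = config$l2_strength,
                        k = config$k, bin = meff_bin(bench[[1]]$meff))

  preds <- lapply(split$test, function(id) {
    predict_contacts(model, feats[[id]],
                     meff = bench[[match(id, names(feats))]]$meff)
  })
  names(preds) <- split$test

  n_eval <- min(n_ppv, min(vapply(preds, nrow, integer(1))))
  ppv_fdca <- average_ppv(lapply(preds, function(p) {
    ppv_curve(p$label, n_eval)
  }), n_eval)
  ppv_dca <- average_ppv(lapply(split$test, function(id) {
    ppv_curve(feats[[id]][, c("i", "j", "x1", "label")] |>
                (\(d) { d$score <- d$x1; d })(), n_eval)
  }), n_eval)
  all_pred <- do.call(rbind, preds)
  cal <- calibration(all_pred$p, all_pred$label)
  say("evaluate: PPV@%d filterDCA %.3f vs DCA %.3f; calibration slope %.2f",
      n_eval, ppv_fdca[n_eval], ppv_dca[n_eval], cal$slope)

  summary <- list(
    config = unclass(config),
    config_hash = config_hash(config),
    n_families = n_families,
    n_train_pairs = nrow(train_tab),
    n_train_pairs_restricted = n_pos_rows,
    model = list(w0 = model$w0, w1 = model$w[1], w2 = model$w[2]),
    ppv_at_n = list(n = n_eval, filterdca = ppv_fdca[n_eval],
                    dca = ppv_dca[n_eval]),
    calibration_slope = cal$slope
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_filter_bank(bank, file.path(out_dir, "filters.json"))
    write_model(model, file.path(out_dir, "model.json"))
    for (id in names(feats)) {
      write_feature_table(feats[[id]],
                          file.path(out_dir, paste0(id, ".features.tsv")))
    }
    for (id in names(preds)) {
      utils::write.table(preds[[id]][, c("i", "j", "p", "rank")],
                         file.path(out_dir, paste0(id, ".pred.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_ppv_curve(ppv_fdca, file.path(out_dir, "ppv_filterdca.tsv"))
    write_ppv_curve(ppv_dca, file.path(out_dir, "ppv_dca.tsv"))
    write_calibration(cal, file.path(out_dir, "calibration.tsv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(bank = bank, model = model, split = split,
       ppv_filterdca = ppv_fdca, ppv_dca = ppv_dca, calibration = cal,
       summary = summary)
}

config_hash <- function(config) {
  s <- paste(names(unclass(config)),
             vapply(unclass(config), function(x) paste(format(x, digits = 17),
                                                       collapse = ","),
                    character(1)),
             sep = "=", collapse = ";")
  # small stable polynomial hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 1e9
  sprintf("%09.0f", h)
}

cli_args_to_list <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop(sprintf("unexpected argument '%s'", a), call. = FALSE)
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  out
}

num_or <- function(x, default) if (is.null(x)) default else as.numeric(x)

#' Command-line interface
#'
#' Subcommands: `simulate` (write a synthetic benchmark to disk),
#' `build-filters`, `score` (feature table for one family), `train`,
#' `predict`, `evaluate` (PPV curve from a prediction + contact file), and
#' `run` (all-in-one simulated pipeline). Designed to be called from the
#' `filterdca` script in `inst/cli/`.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return invisibly, the subcommand's main result.
#' @export
filterdca_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: filterdca <simulate|build-filters|score|train|predict|evaluate|run> [--flag value ...]\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opt <- cli_args_to_list(args[-1])
  seed <- as.integer(num_or(opt$seed, 1))
  res <- switch(
    cmd,
    simulate = {
      fams <- generate_benchmark(as.integer(num_or(opt$families, 10)),
                                 p_det = num_or(opt$p_det, 0.5),
                                 s = num_or(opt$s, 0.3),
                                 sigma = num_or(opt$sigma, 0.1),
                                 seed = seed)
      for (f in fams) write_family(f, opt$out %||% ".")
      fams
    },
    `build-filters` = {
      ids <- strsplit(opt$families, ",")[[1]]
      fams <- lapply(ids, function(id) {
        ss <- read_ss(file.path(opt$dir %||% ".", paste0(id, ".ss")))
        list(contact_map = read_contact_map(
               file.path(opt$dir %||% ".", paste0(id, ".contacts"))),
             ss_a = ss$ss_a, ss_b = ss$ss_b)
      })
      bank <- build_filters(fams, k = as.integer(num_or(opt$k, 45)),
                            seed = seed)
      write_filter_bank(bank, opt$out %||% "filters.json")
      bank
    },
    score = {
      bank <- read_filter_bank(opt$filters)
      ss <- if (!is.null(opt$contacts)) read_contact_map(opt$contacts)
      l <- strsplit(opt$shape, ",")[[1]]
      sm <- parse_scores(opt$scores, as.integer(l[1]), as.integer(l[2]),
                         indexing = opt$indexing %||% "split",
                         meff = if (is.null(opt$meff)) NULL else as.numeric(opt$meff))
      ft <- feature_table(sm, bank, truth = ss)
      write_feature_table(ft, opt$out %||% "features.tsv")
      ft
    },
    train = {
      feats <- do.call(rbind, lapply(strsplit(opt$features, ",")[[1]],
                                     read_feature_table))
      model <- fit_logistic(feats, l2_strength = num_or(opt$l2, 1.0),
                            k = as.integer(num_or(opt$k, NA)),
                            bin = opt$bin %||% NA_character_)
      write_model(model, opt$out %||% "model.json")
      model
    },
    predict = {
      model <- read_model(opt$model)
      feats <- read_feature_table(opt$features)
      pred <- predict_contacts(model, feats,
                               meff = if (is.null(opt$meff)) NULL
                                      else as.numeric(opt$meff),
                               force = isTRUE(opt$force))
      utils::write.table(pred[, c("i", "j", "p", "rank")],
                         opt$out %||% "pred.tsv", sep = "\t",
                         quote = FALSE, row.names = FALSE)
      pred
    },
    evaluate = {
      pred <- utils::read.delim(opt$predictions)
      cm <- read_contact_map(opt$contacts)
      pred$label <- unclass(cm)[cbind(pred$i, pred$j)]
      curve <- ppv_curve(pred$label[order(pred$rank)],
                         as.integer(num_or(opt$n, nrow(pred))))
      write_ppv_curve(curve, opt$out %||% "ppv.tsv")
      curve
    },
    run = {
      cfg <- run_config(k = as.integer(num_or(opt$k, 45)),
                        p_det = num_or(opt$p_det, 0.5),
                        seed = seed)
      run_pipeline(cfg, n_families = as.integer(num_or(opt$families, 40)),
                   out_dir = opt$out %||% "filterdca_run")
    },
    stop(sprintf("unknown subcommand '%s'", cmd), call. = FALSE)
  )
  invisible(res)
}
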