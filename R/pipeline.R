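#' Experiment configuration
#'
#' Defaults reproduce the reference protocol: 500 hidden neurons, bipolar
#' sigmoid hidden activation with linear outputs, 30 independent runs with
#' freshly drawn random input weights per run, a 50/50 ordered split of the
#' signal collection, moving-average window 100 samples, and a 5-sample
#' (about 20 ms at 256 Hz) candidate-to-annotation matching tolerance.
#'
#' @param models Character vector of peak-model names to sweep (subset of
#'   dumpala, dingle, acir, liu, all16).
#' @param n_hidden Hidden-neuron count.
#' @param activation Hidden activation, `"bipolar"` or `"unipolar"`.
#' @param runs Number of independent runs.
#' @param seed Base seed; run `r` uses `seed + r` for its random weights.
#' @param split_fraction Fraction of signals used for training.
#' @param tolerance Matching tolerance in samples.
#' @param mac_window Moving-average window in samples.
#' @param delta Optional prominence threshold for candidate detection.
#' @param balance_classes Weight training samples inversely to class
#'   frequency; off by default, as in the reference protocol.
#' @param sampling_rate_hz Sampling rate used when reading signal files.
#' @param ... Unknown keys (e.g. from a configuration file) are ignored.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(models = c("dumpala", "dingle", "acir", "liu"),
                              n_hidden = 500L,
                              activation = c("bipolar", "unipolar"),
                              runs = 30L,
                              seed = 1L,
                              split_fraction = 0.5,
                              tolerance = 5L,
                              mac_window = 100L,
                              delta = 0,
                              balance_classes = FALSE,
                              sampling_rate_hz = 256,
                              ...) {
  activation <- match.arg(activation)
  models <- match.arg(models,
                      c("dumpala", "dingle", "acir", "liu", "all16"),
                      several.ok = TRUE)
  structure(list(models = models, n_hidden = as.integer(n_hidden),
                 activation = activation, runs = as.integer(runs),
                 seed = as.integer(seed), split_fraction = split_fraction,
                 tolerance = as.integer(tolerance),
                 mac_window = as.integer(mac_window), delta = delta,
                 balance_classes = isTRUE(balance_classes),
                 sampling_rate_hz = sampling_rate_hz),
            class = "experiment_config")
}

# candidates + 16 features + truth labels, pooled over a list of signals
pool_candidates <- function(signals, config) {
  feats <- vector("list", length(signals))
  labels <- vector("list", length(signals))
  for (i in seq_along(signals)) {
    sig <- signals[[i]]
    cands <- detect_candidates(sig, delta = config$delta)
    feats[[i]] <- feature_matrix(sig, cands, mac_window = config$mac_window)
    labels[[i]] <- match_candidates_to_truth(cands, sig$true_peaks,
                                             tolerance = config$tolerance)
  }
  list(X = do.call(rbind, feats), labels = unlist(labels))
}

#' Run the full multi-run, multi-model peak-detection experiment
#'
#' End-to-end protocol: the ordered signal collection is split into training
#' and testing halves; candidates are detected and their 16 features
#' extracted once; then, for every peak model and every run, an ELM with
#' fresh random input weights is trained on the min-max-scaled training
#' candidates (scaling extrema come from the training set only; the test
#' phase sees training annotations through nothing but the trained weights
#' and those extrema) and evaluated on both halves by G_mean. When two or
#' more models are swept, the per-run test G_means feed a Friedman rank test
#' with Holm post-hoc comparisons at alpha 0.05 and 0.10.
#'
#' @param signals List of [eeg_signal]; or a [synth_spec], in which case the
#'   corpus is generated first.
#' @param config An [experiment_config()].
#' @param out_dir Optional directory for CSV reports (per-model summary,
#'   per-run G_mean matrices, sensitivity/specificity, Friedman ranks, Holm
#'   tables).
#' @param verbose Print a one-line summary per model.
#' @return A list of class `peak_experiment` with elements `summary`
#'   (data.frame of train/test average/max/min/stdev G_mean in percent, plus
#'   mean test sensitivity/specificity), `acc_train` and `acc_test` (runs x
#'   models G_mean matrices), `friedman`, `holm_05`, `holm_10` (when >= 2
#'   models), `n_train_candidates`, `n_test_candidates`, `config`.
#' @export
run_experiment <- function(signals, config = experiment_config(),
                           out_dir = NULL, verbose = FALSE) {
  if (inherits(signals, "synth_spec")) signals <- generate_dataset(signals)
  split <- split_dataset(signals, config$split_fraction)
  train <- pool_candidates(split$train, config)
  test <- if (length(split$test)) pool_candidates(split$test, config) else NULL

  acc_train <- matrix(NA_real_, config$runs, length(config$models),
                      dimnames = list(NULL, config$models))
  acc_test <- acc_train
  sens <- spec_ <- matrix(NA_real_, config$runs, length(config$models),
                          dimnames = list(NULL, config$models))

  for (mname in config$models) {
    model_def <- peak_model(mname)
    Xtr <- select_model_features(train$X, model_def)
    scaler <- fit_scaler(Xtr)
    Xtr_s <- apply_scaler(scaler, Xtr)
    Xte_s <- if (!is.null(test)) {
      apply_scaler(scaler, select_model_features(test$X, model_def))
    } else NULL
    targets <- one_hot(train$labels)
    w <- if (config$balance_classes) {
      nf <- table(factor(train$labels, c(FALSE, TRUE)))
      ifelse(train$labels, sum(nf) / (2 * nf[["TRUE"]]),
             sum(nf) / (2 * nf[["FALSE"]]))
    } else NULL

    for (r in seq_len(config$runs)) {
      res <- tryCatch({
        net <- init_elm(ncol(Xtr_s), config$n_hidden, 2L,
                        seed = config$seed + r,
                        activation = config$activation)
        net <- train_elm(net, Xtr_s, targets, weights = w)
        gtr <- g_mean(confusion(predict(net, Xtr_s), train$labels))
        if (!is.null(Xte_s)) {
          cte <- confusion(predict(net, Xte_s), test$labels)
          ss <- sensitivity_specificity(cte)
          list(gtr = gtr, gte = g_mean(cte), ss = ss)
        } else list(gtr = gtr, gte = NA_real_,
                    ss = c(sensitivity = NA_real_, specificity = NA_real_))
      }, error = function(e) {
        message(sprintf("[%s run %d] classification stage failed: %s",
                        mname, r, conditionMessage(e)))
        NULL
      })
      if (is.null(res)) next
      acc_train[r, mname] <- res$gtr
      acc_test[r, mname] <- res$gte
      sens[r, mname] <- res$ss[["sensitivity"]]
      spec_[r, mname] <- res$ss[["specificity"]]
    }
    if (verbose) {
      message(sprintf("model %-8s train G_mean %.3f  test G_mean %.3f",
                      mname, mean(acc_train[, mname], na.rm = TRUE),
                      mean(acc_test[, mname], na.rm = TRUE)))
    }
  }

  summarise_pct <- function(v) 100 * summarize_runs(v[!is.na(v)])
  summary_df <- do.call(rbind, lapply(config$models, function(mname) {
    str <- summarise_pct(acc_train[, mname])
    ste <- if (!all(is.na(acc_test[, mname]))) summarise_pct(acc_test[, mname])
           else rep(NA_real_, 4)
    data.frame(model = mname,
               train_avg = str[[1]], train_max = str[[2]],
               train_min = str[[3]], train_stdev = str[[4]],
               test_avg = ste[[1]], test_max = ste[[2]],
               test_min = ste[[3]], test_stdev = ste[[4]],
               sensitivity = mean(sens[, mname], na.rm = TRUE),
               specificity = mean(spec_[, mname], na.rm = TRUE))
  }))

  out <- list(summary = summary_df, acc_train = acc_train,
              acc_test = acc_test, config = config,
              n_train_candidates = length(train$labels),
              n_test_candidates = if (is.null(test)) 0L else length(test$labels),
              n_train_peaks = sum(train$labels),
              n_test_peaks = if (is.null(test)) 0L else sum(test$labels))

  if (length(config$models) >= 2L && !is.null(test)) {
    complete <- stats::complete.cases(acc_test)
    acc <- acc_test[complete, , drop = FALSE]
    if (nrow(acc) >= 2L) {
      out$friedman <- friedman_ranks(acc)
      pw <- pairwise_wilcoxon(acc)
      out$holm_05 <- holm_posthoc(pw, alpha = 0.05)
      out$holm_10 <- holm_posthoc(pw, alpha = 0.10)
    }
  }
  class(out) <- "peak_experiment"
  if (!is.null(out_dir)) write_reports(out, out_dir)
  out
}

#' @export
print.peak_experiment <- function(x, ...) {
  cat(sprintf("<peak_experiment> %d run(s), %d train / %d test candidates (%d / %d true peaks)\n",
              x$config$runs, x$n_train_candidates, x$n_test_candidates,
              x$n_train_peaks, x$n_test_peaks))
  df <- x$summary
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 1)
  print(df, row.names = FALSE)
  if (!is.null(x$friedman)) {
    cat("Friedman average ranks (1 = best):\n")
    print(round(x$friedman$avg_ranks, 4))
    cat(sprintf("chi-square = %.4f, df = %d, p = %.3g\n",
                x$friedman$statistic, x$friedman$df, x$friedman$p_value))
  }
  invisible(x)
}

#' Write CSV reports for an experiment
#'
#' @param experiment A `peak_experiment`.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the directory.
#' @export
write_reports <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(experiment$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(experiment$acc_train),
                   file.path(dir, "gmean_train_runs.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(experiment$acc_test),
                   file.path(dir, "gmean_test_runs.csv"), row.names = FALSE)
  if (!is.null(experiment$friedman)) {
    fr <- experiment$friedman
    utils::write.csv(data.frame(model = names(fr$avg_ranks),
                                avg_rank = as.numeric(fr$avg_ranks),
                                statistic = fr$statistic, df = fr$df,
                                p_value = fr$p_value),
                     file.path(dir, "friedman.csv"), row.names = FALSE)
    utils::write.csv(experiment$holm_05, file.path(dir, "holm_alpha05.csv"),
                     row.names = FALSE)
    utils::write.csv(experiment$holm_10, file.path(dir, "holm_alpha10.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
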