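# Multi-seed experiment harnesses: fingerprint-panel selection,
# architecture ablations, and label-noise robustness.

.harness_metric <- function(fit) {
  rep <- evaluate_model(fit)
  if (fit$task_type == "classification") rep$mean$roc_auc else rep$mean$rmse
}

#' Fingerprint-combination selection experiment
#'
#' Trains one fingerprint-only feed-forward model per combination of `k`
#' fingerprint families per seed -- identical architecture throughout,
#' only the input width changes -- and ranks combinations by the mean test
#' metric.  The tally counts how often each family appears among the top-3
#' combinations.
#'
#' @param data a `cf_dataset`.
#' @param k combination size (1, 2 or 3).
#' @param families candidate families (default: all eight).
#' @param seeds integer vector; each seed drives its own random split and
#'   initialization.
#' @param ... training options forwarded to [chemformer()] (e.g. `epochs`,
#'   `hidden_dim`).
#' @return a `cf_fpselect` list: `results` (one row per combination x
#'   seed), `summary` (mean metric per combination, ranked best-first) and
#'   `top3_tally` (named counts of family membership in the top 3).
#' @export
run_fingerprint_selection <- function(data, k, families = fp_families()$name,
                                      seeds = 1:3, ...) {
  combos <- fp_combinations(k, families)
  classification <- data$task_type == "classification"
  rows <- list()
  for (ci in seq_along(combos)) {
    for (s in seeds) {
      fit <- chemformer(data, variant = "FP",
                        split = split_random(data, seed = s),
                        fingerprint_families = combos[[ci]], seed = s, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        combination = paste(combos[[ci]], collapse = "+"),
        k = k, seed = s, metric = .harness_metric(fit))
    }
  }
  results <- do.call(rbind, rows)
  # single-class test partitions yield NA metrics; average over the rest
  agg <- stats::aggregate(metric ~ combination, results,
                          function(x) mean(x, na.rm = TRUE),
                          na.action = stats::na.pass)
  agg <- agg[order(if (classification) -agg$metric else agg$metric), ]
  rownames(agg) <- NULL
  top3 <- utils::head(agg$combination, 3)
  tally <- table(unlist(strsplit(top3, "\\+")))
  structure(list(results = results, summary = agg,
                 top3_tally = tally,
                 metric = if (classification) "roc_auc" else "rmse",
                 n_combinations = length(combos)),
            class = "cf_fpselect")
}

#' @export
print.cf_fpselect <- function(x, ...) {
  cat("fingerprint selection over ", x$n_combinations,
      " combinations (metric: ", x$metric, ")\n", sep = "")
  print(utils::head(x$summary, 5))
  invisible(x)
}

#' Architecture ablation experiment
#'
#' Trains every requested variant on the same random splits (one per
#' seed) and summarizes the test metric as mean and standard deviation per
#' variant.  Identical splits across variants are part of the protocol and
#' are recorded as an index signature.
#'
#' @param data a `cf_dataset`.
#' @param seeds integer vector of split/initialization seeds.
#' @param variants variants to compare; defaults to the six-member family
#'   `GCN`, `Atom`, `AtomBond`, `FP`, `AtomBondFP`, `Full`.
#' @param ... training options forwarded to [chemformer()].
#' @return a `cf_ablation` list: `results` (variant x seed rows with the
#'   split signature) and `summary` (mean, sd per variant).
#' @export
run_ablation <- function(data, seeds = 1:10,
                         variants = c("GCN", "Atom", "AtomBond", "FP",
                                      "AtomBondFP", "Full"), ...) {
  splits <- lapply(seeds, function(s) split_random(data, seed = s))
  signatures <- vapply(splits, function(sp) {
    sum(sp$train * seq_along(sp$train)) %% 1e9
  }, numeric(1))
  rows <- list()
  for (v in variants) {
    for (si in seq_along(seeds)) {
      fit <- chemformer(data, variant = v, split = splits[[si]],
                        seed = seeds[si], ...)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, seed = seeds[si], split_signature = signatures[si],
        metric = .harness_metric(fit))
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results, results$variant), function(d) {
    data.frame(variant = d$variant[1], mean = mean(d$metric, na.rm = TRUE),
               sd = stats::sd(d$metric, na.rm = TRUE), n = nrow(d))
  }))
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary,
                 metric = if (data$task_type == "classification")
                   "roc_auc" else "rmse"),
            class = "cf_ablation")
}

#' @export
print.cf_ablation <- function(x, ...) {
  cat("ablation (metric: ", x$metric, ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Label-noise robustness experiment
#'
#' For each seed and each noise rate, reverses that fraction of
#' train/validation labels ([inject_label_noise()]; test labels stay
#' clean) and retrains, reporting the test ROC-AUC.
#'
#' @param data a classification `cf_dataset`.
#' @param rates noise fractions to scan.
#' @param seeds integer vector of seeds.
#' @param variant architecture variant to train.
#' @param ... training options forwarded to [chemformer()].
#' @return a `cf_noise_bench` list: `results` (rate x seed rows) and
#'   `summary` (mean test ROC-AUC per rate).
#' @export
run_noise_benchmark <- function(data, rates = c(0, 0.1, 0.2, 0.3),
                                seeds = 1:5, variant = "Full", ...) {
  rows <- list()
  for (s in seeds) {
    sp <- split_random(data, seed = s)
    for (rate in rates) {
      noisy <- inject_label_noise(data, rate, sp, seed = s)
      fit <- chemformer(noisy, variant = variant, split = sp, seed = s, ...)
      # test labels are never flipped, so the fit's own test partition is clean
      rep <- evaluate_model(fit)
      rows[[length(rows) + 1L]] <- data.frame(rate = rate, seed = s,
                                              roc_auc = rep$mean$roc_auc)
    }
  }
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(roc_auc ~ rate, results,
                              function(x) mean(x, na.rm = TRUE),
                              na.action = stats::na.pass)
  structure(list(results = results, summary = summary),
            class = "cf_noise_bench")
}

#' @export
print.cf_noise_bench <- function(x, ...) {
  cat("label-noise robustness (mean test ROC-AUC per rate)\n")
  print(x$summary)
  invisible(x)
}
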