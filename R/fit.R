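# Model fitting: the `chemformer()` estimator and its methods.

.fp_scaler_fit <- function(fpm, families, train_idx) {
  fams <- fp_families()
  widths <- fams$width[match(families, fams$name)]
  kinds <- fams$kind[match(families, fams$name)]
  stops <- cumsum(widths); starts <- c(1L, utils::head(stops, -1L) + 1L)
  real_cols <- unlist(lapply(which(kinds == "real"), function(k) {
    starts[k]:stops[k]
  }))
  if (!length(real_cols)) {
    return(list(cols = integer(0), mean = numeric(0), sd = numeric(0)))
  }
  tr <- fpm[train_idx, real_cols, drop = FALSE]
  mu <- colMeans(tr, na.rm = TRUE)
  sd <- apply(tr, 2, stats::sd, na.rm = TRUE)
  sd[!is.finite(sd) | sd == 0] <- 1
  mu[!is.finite(mu)] <- 0
  list(cols = real_cols, mean = mu, sd = sd)
}

.fp_scaler_apply <- function(fpm, scaler) {
  if (length(scaler$cols)) {
    fpm[, scaler$cols] <- sweep(sweep(fpm[, scaler$cols, drop = FALSE], 2,
                                      scaler$mean), 2, scaler$sd, "/")
  }
  fpm
}

.schema_hash <- function(config) {
  paste0("atom", attr(atom_feature_schema(), "total_width"),
         ".bond", attr(bond_feature_schema(), "total_width"),
         ".fp[", paste(config$fingerprint_families, collapse = ","), "]")
}

.val_metric <- function(pred, targets, task_type) {
  vals <- vapply(seq_len(ncol(targets)), function(t) {
    y <- targets[, t]; p <- pred[, t]
    tryCatch({
      if (task_type == "classification") roc_auc(p, y) else rmse(p, y)
    }, error = function(e) NA_real_)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Fit a multi-scale molecular property model
#'
#' The central estimator.  Molecules are embedded in 3D (seeded distance
#' geometry + force field), featurized into atom and bond graphs and a
#' fingerprint panel according to the chosen architecture variant, and the
#' encoder is trained by minibatch Adam on masked binary cross-entropy
#' (classification; missing labels excluded from the loss) or on
#' mean-squared error over standardized targets (regression), with early
#' stopping on the validation metric and restoration of the best epoch.
#' Fully deterministic for fixed seeds.
#'
#' @param data a `cf_dataset`.
#' @param variant architecture variant (see [make_variant()]); default
#'   `"Full"`.
#' @param split a `cf_split`; defaults to [split_random()] of `data` with
#'   `seed`.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param seed seed for initialization, shuffling and dropout.
#' @param embed_seed seed for 3D conformer embedding.
#' @param forcefield force field for conformer refinement.
#' @param verbose print per-epoch progress.
#' @param ... configuration options passed to [model_config()]
#'   (`hidden_dim`, `gcn_layers`, `encoder_blocks`, `attention_heads`,
#'   `dropout`, `fingerprint_families`, `egnn_agg`).
#' @return an object of class `chemformer` with `print`, `summary`,
#'   `coef`, `predict`, `plot` and `residuals` methods.
#' @export
chemformer <- function(data, variant = "Full", split = NULL,
                       epochs = 50L, batch_size = 32L, lr = 1e-3,
                       patience = 20L, seed = 1L, embed_seed = 1L,
                       forcefield = c("uff", "mmff94"), verbose = FALSE,
                       ...) {
  stopifnot(inherits(data, "cf_dataset"))
  forcefield <- match.arg(forcefield)
  cl <- match.call()
  config <- model_config(variant = variant, task_type = data$task_type,
                         n_tasks = ncol(data$targets), ...)
  if (is.null(split)) split <- split_random(data, seed = seed)
  n <- length(data$smiles)
  if (any(unlist(split[c("train", "val", "test")]) > n)) {
    stop("split indices exceed the dataset")
  }
  needs_graphs <- any(c("atom", "bond", "gcn") %in% config$channels)
  if (needs_graphs) {
    data <- embed_conformers(data, seed = embed_seed, forcefield = forcefield)
  }
  drop_invalid <- function(idx) idx[data$valid[idx]]
  split$train <- drop_invalid(split$train)
  split$val <- drop_invalid(split$val)
  split$test <- drop_invalid(split$test)
  if (!length(split$train)) stop("training partition is empty")

  fpm <- NULL; fp_scaler <- NULL
  if ("fp" %in% config$channels) {
    fpm <- fingerprint_matrix(data, config$fingerprint_families)
    fp_scaler <- .fp_scaler_fit(fpm, config$fingerprint_families, split$train)
    fpm <- .fp_scaler_apply(fpm, fp_scaler)
  }

  target_scaler <- NULL
  targets <- data$targets
  if (config$task_type == "regression") {
    mu <- colMeans(targets[split$train, , drop = FALSE], na.rm = TRUE)
    sd <- apply(targets[split$train, , drop = FALSE], 2, stats::sd, na.rm = TRUE)
    sd[!is.finite(sd) | sd == 0] <- 1
    target_scaler <- list(mean = mu, sd = sd)
    targets <- sweep(sweep(targets, 2, mu), 2, sd, "/")
  }

  active <- sort(unique(c(split$train, split$val, split$test)))
  feats <- vector("list", n)
  for (r in active) {
    feats[[r]] <- .featurize_record(
      if (needs_graphs) data$mols[[r]] else list(n = NA),
      config, fp_vec = if (!is.null(fpm)) fpm[r, ] else NULL)
  }
  dims <- list(
    atom_in = attr(atom_feature_schema(), "total_width"),
    bond_in = attr(bond_feature_schema(), "total_width"),
    fp_in = if (!is.null(fpm)) ncol(fpm) else 0L)

  set.seed(seed)
  params <- .init_params(config, dims)
  opt <- .adam_new()
  classification <- config$task_type == "classification"
  best_metric <- if (classification) -Inf else Inf
  best_params <- params; best_epoch <- 0L; stall <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_metric = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- sample(split$train)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1, length(ord), by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, length(ord))]
      bg <- .batch_grad(params, config, feats[idx],
                        targets[idx, , drop = FALSE], training = TRUE)
      params <- .adam_step(opt, params, bg$grads, lr = lr)
      ep_loss <- ep_loss + bg$loss; nb <- nb + 1L
    }
    ep_loss <- ep_loss / max(nb, 1)
    vm <- NA_real_
    if (length(split$val)) {
      logits <- .predict_logits(params, config, feats[split$val])
      pred <- if (classification) 1 / (1 + exp(-logits)) else logits
      vm <- .val_metric(pred, targets[split$val, , drop = FALSE],
                        config$task_type)
    }
    history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss,
                                         val_metric = vm))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val %.4f", ep, ep_loss, vm))
    }
    if (is.na(vm)) {
      best_params <- params; best_epoch <- ep
    } else {
      strictly <- if (classification) vm > best_metric + 1e-9 else
        vm < best_metric - 1e-9
      tie_or_better <- if (classification) vm >= best_metric - 1e-12 else
        vm <= best_metric + 1e-12
      if (tie_or_better) {
        # ties go to the later epoch: training keeps refining while the
        # validation metric plateaus
        best_metric <- vm; best_params <- params; best_epoch <- ep
      }
      if (strictly) stall <- 0L else stall <- stall + 1L
      if (stall >= patience) break
    }
  }

  object <- structure(list(
    config = config, params = best_params, fp_scaler = fp_scaler,
    target_scaler = target_scaler, history = history,
    best_epoch = best_epoch, best_val_metric = best_metric,
    split = split, task_names = data$task_names,
    task_type = config$task_type, data = data,
    embed_seed = as.integer(embed_seed), forcefield = forcefield,
    schema_hash = .schema_hash(config), seed = as.integer(seed),
    dims = dims, call = cl), class = "chemformer")
  fitted_logits <- matrix(NA_real_, n, config$n_tasks)
  fitted_logits[active, ] <- .predict_logits(best_params, config, feats[active])
  object$fitted_values <- .logits_to_response(object, fitted_logits)
  object
}

.logits_to_response <- function(object, logits) {
  out <- if (object$task_type == "classification") {
    1 / (1 + exp(-logits))
  } else if (!is.null(object$target_scaler)) {
    sweep(sweep(logits, 2, object$target_scaler$sd, "*"), 2,
          object$target_scaler$mean, "+")
  } else logits
  colnames(out) <- object$task_names
  out
}

# featurize new records with the fitted model's scalers
.featurize_newdata <- function(object, data) {
  config <- object$config
  needs_graphs <- any(c("atom", "bond", "gcn") %in% config$channels)
  if (needs_graphs) {
    data <- embed_conformers(data, seed = object$embed_seed,
                             forcefield = object$forcefield)
  }
  fpm <- NULL
  if ("fp" %in% config$channels) {
    fpm <- fingerprint_matrix(data, config$fingerprint_families)
    fpm <- .fp_scaler_apply(fpm, object$fp_scaler)
  }
  feats <- vector("list", length(data$smiles))
  for (r in seq_along(feats)) {
    if (!data$valid[r]) next
    feats[[r]] <- .featurize_record(
      if (needs_graphs) data$mols[[r]] else list(n = NA),
      config, fp_vec = if (!is.null(fpm)) fpm[r, ] else NULL)
  }
  feats
}

#' Predict molecular properties from a fitted model
#'
#' @param object a fitted `chemformer` model.
#' @param newdata a `cf_dataset`, a character vector of SMILES, or `NULL`
#'   (fitted values on the training dataset).
#' @param type `"response"` (probabilities / original units, default) or
#'   `"logit"` (raw network output).
#' @param ... unused.
#' @return numeric matrix (molecules x tasks); invalid molecules give `NA`
#'   rows.
#' @export
predict.chemformer <- function(object, newdata = NULL,
                               type = c("response", "logit"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "response") return(object$fitted_values)
    newdata <- object$data
  }
  if (is.character(newdata)) {
    newdata <- cf_dataset(newdata,
                          matrix(NA_real_, length(newdata),
                                 object$config$n_tasks),
                          object$task_names, object$task_type)
  }
  stopifnot(inherits(newdata, "cf_dataset"))
  feats <- .featurize_newdata(object, newdata)
  logits <- .predict_logits(object$params, object$config, feats)
  colnames(logits) <- object$task_names
  if (type == "logit") logits else .logits_to_response(object, logits)
}

#' Evaluate a fitted model on a partition
#'
#' @param object a fitted `chemformer`.
#' @param data dataset to evaluate on (default: the training dataset).
#' @param indices record indices (default: the model's test partition).
#' @return a `cf_metric_report`: per-task and mean ROC-AUC and PRC-AUC
#'   (classification) or RMSE (regression).  Tasks whose metric is
#'   undefined (single-class partition) are reported as `NA`.
#' @export
evaluate_model <- function(object, data = NULL, indices = NULL) {
  if (is.null(data)) data <- object$data
  if (is.null(indices)) indices <- object$split$test
  pred <- if (identical(data, object$data)) {
    object$fitted_values
  } else {
    predict(object, data)
  }
  pred <- pred[indices, , drop = FALSE]
  obs <- data$targets[indices, , drop = FALSE]
  per_task <- function(f) {
    vapply(seq_len(ncol(obs)), function(t) {
      tryCatch(f(pred[, t], obs[, t]), error = function(e) NA_real_)
    }, numeric(1))
  }
  metrics <- if (object$task_type == "classification") {
    list(roc_auc = per_task(roc_auc), prc_auc = per_task(prc_auc))
  } else {
    list(rmse = per_task(function(p, y) rmse(p, y)))
  }
  means <- lapply(metrics, mean, na.rm = TRUE)
  structure(list(per_task = metrics, mean = means,
                 task_names = object$task_names, n = length(indices),
                 variant = object$config$variant),
            class = "cf_metric_report")
}

#' @export
print.cf_metric_report <- function(x, ...) {
  cat("<metrics (", x$variant, ", n=", x$n, "): ",
      paste(sprintf("%s=%.4f", names(x$mean), unlist(x$mean)),
            collapse = ", "), ">\n", sep = "")
  invisible(x)
}

#' @export
print.chemformer <- function(x, ...) {
  cat("Multi-scale molecular property model (variant ", x$config$variant,
      ")\n", sep = "")
  cat("  tasks: ", paste(x$task_names, collapse = ", "), " (",
      x$task_type, ")\n", sep = "")
  cat("  trained ", nrow(x$history), " epochs; best epoch ", x$best_epoch,
      sprintf(" (validation %s %.4f)\n",
              if (x$task_type == "classification") "ROC-AUC" else "RMSE",
              x$best_val_metric), sep = "")
  invisible(x)
}

#' @export
summary.chemformer <- function(object, ...) {
  npar <- sum(vapply(object$params, length, 0L))
  out <- list(config = object$config, n_parameters = npar,
              history = object$history, best_epoch = object$best_epoch,
              best_val_metric = object$best_val_metric,
              split_sizes = lengths(object$split[c("train", "val", "test")]),
              test_metrics = tryCatch(evaluate_model(object),
                                      error = function(e) NULL))
  class(out) <- "summary.chemformer"
  out
}

#' @export
print.summary.chemformer <- function(x, ...) {
  print(x$config)
  cat("  parameters: ", x$n_parameters, "\n", sep = "")
  cat("  split sizes: ", paste(x$split_sizes, collapse = "/"), "\n", sep = "")
  cat("  best epoch ", x$best_epoch, " of ", nrow(x$history),
      sprintf(", validation metric %.4f\n", x$best_val_metric), sep = "")
  if (!is.null(x$test_metrics)) print(x$test_metrics)
  invisible(x)
}

#' @export
coef.chemformer <- function(object, ...) object$params

#' @export
residuals.chemformer <- function(object, ...) {
  object$data$targets - object$fitted_values
}

#' @export
plot.chemformer <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(x$history$epoch, x$history$train_loss, type = "l",
                 xlab = "epoch", ylab = "training loss", ...)
  graphics::plot(x$history$epoch, x$history$val_metric, type = "l",
                 xlab = "epoch",
                 ylab = if (x$task_type == "classification")
                   "validation ROC-AUC" else "validation RMSE", ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}

#' Save a fitted model checkpoint
#'
#' Writes configuration, parameters, scalers and a feature-schema tag to a
#' single JSON archive.  [load_chemformer()] refuses checkpoints whose
#' schema tag does not match the running package.
#'
#' @param object a fitted `chemformer`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
save_chemformer <- function(object, path) {
  chk <- list(
    schema_hash = object$schema_hash,
    config = unclass(object$config),
    params = lapply(object$params, function(m) list(dim = dim(m),
                                                    data = as.numeric(m))),
    fp_scaler = object$fp_scaler, target_scaler = object$target_scaler,
    task_names = object$task_names, task_type = object$task_type,
    embed_seed = object$embed_seed, forcefield = object$forcefield,
    dims = object$dims, best_epoch = object$best_epoch)
  jsonlite::write_json(chk, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Load a fitted model checkpoint
#'
#' @param path a file written by [save_chemformer()].
#' @return a `chemformer` object usable with [predict.chemformer()].
#' @export
load_chemformer <- function(path) {
  chk <- jsonlite::read_json(path, simplifyVector = TRUE)
  config <- chk$config
  class(config) <- "cf_config"
  object <- list(config = config,
                 params = lapply(chk$params, function(p) {
                   matrix(p$data, p$dim[1], p$dim[2])
                 }),
                 fp_scaler = chk$fp_scaler,
                 target_scaler = chk$target_scaler,
                 task_names = chk$task_names, task_type = chk$task_type,
                 embed_seed = chk$embed_seed, forcefield = chk$forcefield,
                 dims = chk$dims, best_epoch = chk$best_epoch,
                 schema_hash = chk$schema_hash)
  class(object) <- "chemformer"
  current <- .schema_hash(config)
  if (!identical(object$schema_hash, current)) {
    stop("checkpoint schema '", object$schema_hash,
         "' does not match this package ('", current, "')")
  }
  if (!is.null(object$fp_scaler)) {
    object$fp_scaler$cols <- as.integer(object$fp_scaler$cols)
  }
  object
}
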