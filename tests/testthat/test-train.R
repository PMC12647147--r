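test_that("fingerprint-only model learns a noiseless motif task to high AUC", {
  d <- fx_clf_data()
  fit <- chemformer(d, variant = "FP", split = split_random(d, seed = 1),
                    hidden_dim = 16L, epochs = 25, seed = 1, dropout = 0)
  p <- predict(fit)[fit$split$train, 1]
  y <- d$targets[fit$split$train, 1]
  expect_gte(roc_auc(p, y), 0.99)
})

test_that("training is deterministic: identical seeds give identical histories", {
  d <- fx_clf_data()
  sp <- split_random(d, seed = 4)
  f1 <- chemformer(d, variant = "FP", split = sp, hidden_dim = 8L,
                   epochs = 3, seed = 11)
  f2 <- chemformer(d, variant = "FP", split = sp, hidden_dim = 8L,
                   epochs = 3, seed = 11)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  f3 <- chemformer(d, variant = "FP", split = sp, hidden_dim = 8L,
                   epochs = 3, seed = 12)
  expect_false(identical(f1$params, f3$params))
})

test_that("regression on constant targets collapses to the constant", {
  smi <- generate_molecules(24, seed = 41)
  d <- cf_dataset(smi, rep(2.5, 24), "y", "regression")
  fit <- chemformer(d, variant = "FP", split = split_random(d, seed = 1),
                    hidden_dim = 8L, epochs = 10, seed = 1, dropout = 0)
  p <- predict(fit)
  expect_equal(unname(p[!is.na(p[, 1]), 1]),
               rep(2.5, sum(!is.na(p[, 1]))), tolerance = 0.05)
  expect_lt(rmse(p[, 1], d$targets[, 1]), 0.05)
})

test_that("records with all-missing labels contribute no gradient or loss", {
  d <- fx_clf_data()
  cfg <- model_config("FP", hidden_dim = 8L,
                      task_type = "classification", n_tasks = 1,
                      fingerprint_families = c("maccs", "estate"))
  fpm <- fingerprint_matrix(d, cfg$fingerprint_families)
  feats <- lapply(seq_len(10), function(r) {
    chemformer:::.featurize_record(list(n = NA), cfg, fpm[r, ])
  })
  set.seed(2)
  params <- chemformer:::.init_params(
    cfg, list(atom_in = 136, bond_in = 39, fp_in = ncol(fpm)))
  targets <- d$targets[1:10, , drop = FALSE]
  base <- chemformer:::.batch_grad(params, cfg, feats, targets,
                                   training = FALSE)
  aug <- chemformer:::.batch_grad(params, cfg, c(feats, feats[1]),
                                  rbind(targets, NA), training = FALSE)
  expect_equal(aug$loss, base$loss)
  expect_equal(aug$grads, base$grads)
})

test_that("early stopping restores the best validation epoch", {
  d <- fx_clf_data()
  fit <- chemformer(d, variant = "FP", split = split_random(d, seed = 2),
                    hidden_dim = 8L, epochs = 30, patience = 3, seed = 3)
  expect_lte(fit$best_epoch, nrow(fit$history))
  expect_equal(fit$best_val_metric,
               max(fit$history$val_metric, na.rm = TRUE))
  # history exposes one row per epoch run
  expect_true(all(diff(fit$history$epoch) == 1))
})

test_that("model object methods behave", {
  d <- fx_clf_data()
  fit <- chemformer(d, variant = "FP", split = split_random(d, seed = 2),
                    hidden_dim = 8L, epochs = 2, seed = 1)
  expect_output(print(fit), "variant FP")
  s <- summary(fit)
  expect_s3_class(s, "summary.chemformer")
  expect_gt(s$n_parameters, 0)
  expect_type(coef(fit), "list")
  r <- residuals(fit)
  expect_equal(dim(r), dim(d$targets))
  rep <- evaluate_model(fit)
  expect_true(rep$mean$roc_auc >= 0 && rep$mean$roc_auc <= 1)
  expect_true(rep$mean$prc_auc >= 0 && rep$mean$prc_auc <= 1)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("fingerprint selection harness enumerates and ranks combinations", {
  d <- fx_clf_data()
  sel <- run_fingerprint_selection(d, k = 1,
                                   families = c("maccs", "estate", "erg"),
                                   seeds = 1, hidden_dim = 8L, epochs = 2)
  expect_equal(sel$n_combinations, 3)
  expect_equal(nrow(sel$results), 3)
  expect_equal(nrow(sel$summary), 3)
  # ranked best-first for classification (undefined metrics sort last)
  expect_true(all(stats::na.omit(diff(sel$summary$metric)) <= 1e-12))
  expect_true(sum(sel$top3_tally) >= 3)
})

test_that("ablation harness reuses identical splits across variants", {
  d <- fx_clf_data()
  ab <- run_ablation(d, seeds = 1:2, variants = c("FP", "GCN"),
                     hidden_dim = 8L, epochs = 2)
  expect_equal(nrow(ab$results), 4)
  sig <- tapply(ab$results$split_signature, ab$results$seed, unique)
  expect_true(all(lengths(sig) == 1))
  expect_equal(nrow(ab$summary), 2)
  expect_true(all(c("mean", "sd") %in% names(ab$summary)))
})
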