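test_that("adjacency normalization matches direct matrix arithmetic", {
  expect_equal(normalize_adjacency(matrix(0, 1, 1)), matrix(1, 1, 1))
  # 2-node edge: D_tilde = 2I
  A <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(normalize_adjacency(A), matrix(0.5, 2, 2))
  # disconnected nodes keep only self-loops
  expect_equal(normalize_adjacency(matrix(0, 2, 2)), diag(2))
  expect_error(normalize_adjacency(matrix(0, 2, 3)), "square")
  # brute-force oracle on all graphs with <= 4 nodes
  for (n in 2:4) {
    for (rep in 1:10) {
      set.seed(n * 100 + rep)
      A <- matrix(0, n, n)
      up <- which(upper.tri(A))
      on <- up[stats::runif(length(up)) < 0.5]
      A[on] <- 1; A <- A + t(A)
      At <- A + diag(n)
      D <- diag(1 / sqrt(rowSums(At)))
      expect_equal(normalize_adjacency(A), D %*% At %*% D)
      # regular-graph rows sum to 1
      if (length(unique(rowSums(A))) == 1) {
        expect_equal(rowSums(normalize_adjacency(A)), rep(1, n))
      }
    }
  }
})

test_that("gcn_layer equals the brute-force triple product", {
  set.seed(8)
  # identity case: single node, W = I, identity activation
  H <- matrix(rnorm(3), 1)
  expect_equal(gcn_layer(H, matrix(1, 1, 1), diag(3), identity), H)
  # zero input stays zero (no bias)
  expect_equal(gcn_layer(matrix(0, 3, 4), normalize_adjacency(diag(0, 3)),
                         matrix(rnorm(8), 4, 2)), matrix(0, 3, 2))
  # 3-node path with random H, W against dense oracle
  A <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  Ah <- normalize_adjacency(A)
  H <- matrix(rnorm(12), 3, 4); W <- matrix(rnorm(8), 4, 2)
  expect_equal(gcn_layer(H, Ah, W), pmax(Ah %*% H %*% W, 0))
  expect_error(gcn_layer(matrix(0, 2, 3), Ah, W), "match")
})

test_that("attention layer: row-stochastic weights, uniform under equal keys, scalar oracle", {
  set.seed(9)
  h <- 8; n <- 5
  layer <- list(Wq = chemformer:::.glorot(h, h), Wk = chemformer:::.glorot(h, h),
                Wv = chemformer:::.glorot(h, h), Wo = chemformer:::.glorot(h, h),
                g = matrix(1, 1, h), b = matrix(0, 1, h))
  H <- matrix(rnorm(n * h), n, h)
  out <- attention_layer(list(H = H), layer, heads = 4)
  for (W in out$weights) {
    expect_equal(rowSums(W), rep(1, n))
    expect_true(all(W >= 0))
  }
  # identical rows -> identical keys -> uniform weights 1/n
  Hc <- matrix(rep(rnorm(h), each = n), n, h)
  outc <- attention_layer(list(H = Hc), layer, heads = 4)
  for (W in outc$weights) expect_equal(W, matrix(1 / n, n, n))

  # 2-row toy against direct softmax arithmetic, single head
  h2 <- 2
  l2 <- list(Wq = diag(h2), Wk = diag(h2), Wv = diag(h2), Wo = diag(h2),
             g = matrix(1, 1, h2), b = matrix(0, 1, h2))
  H2 <- matrix(c(1, 0, 0, 2), 2, 2)
  res <- attention_layer(list(H = H2), l2, heads = 1)
  S <- H2 %*% t(H2) / sqrt(2)
  Wo_ <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(res$weights[[1]], Wo_)
  R <- H2 + Wo_ %*% H2
  mu <- rowMeans(R); xc <- R - mu
  expect_equal(res$H, xc / sqrt(rowMeans(xc^2) + 1e-5))
  expect_error(attention_layer(list(H = H), layer, heads = 3), "divide")
})

test_that("equivariant update: isolated nodes fixed, translation/rotation symmetry", {
  set.seed(10)
  h <- 6
  layer <- list(e1_W = chemformer:::.glorot(2 * h + 1, h), e1_b = matrix(0, 1, h),
                e2_W = chemformer:::.glorot(h, h), e2_b = matrix(0, 1, h),
                h1_W = chemformer:::.glorot(2 * h, h), h1_b = matrix(0, 1, h),
                h2_W = chemformer:::.glorot(h, h), h2_b = matrix(0, 1, h),
                x_W = chemformer:::.glorot(h, 1))
  # isolated node: x unchanged
  st <- list(H = matrix(rnorm(h), 1), X = matrix(c(1, 2, 3), 1))
  up <- egnn_update(st, matrix(0, 1, 1), layer)
  expect_equal(up$X, st$X)
  # connected graph
  n <- 4
  A <- matrix(0, n, n); A[1, 2] <- A[2, 1] <- A[2, 3] <- A[3, 2] <- 1
  A[3, 4] <- A[4, 3] <- 1
  H <- matrix(rnorm(n * h), n, h); X <- matrix(rnorm(n * 3), n, 3)
  base <- egnn_update(list(H = H, X = X), A, layer)
  # translation: features identical, coordinates shifted by exactly t
  tvec <- c(2, -1, 0.5)
  tr <- egnn_update(list(H = H, X = sweep(X, 2, tvec, "+")), A, layer)
  expect_equal(tr$H, base$H)
  expect_equal(tr$X, sweep(base$X, 2, tvec, "+"))
  # rotation: features identical, coordinates rotate with the input
  R <- qr.Q(qr(matrix(rnorm(9), 3))); if (det(R) < 0) R[, 1] <- -R[, 1]
  ro <- egnn_update(list(H = H, X = X %*% R), A, layer)
  expect_equal(ro$H, base$H)
  expect_equal(ro$X, base$X %*% R)
  # X row count never changes
  expect_equal(dim(base$X), dim(X))
})

test_that("variant configurations instantiate the right channels", {
  expect_equal(model_config("GCN")$channels, "gcn")
  expect_equal(make_variant("FP")$channels, "fp")
  expect_true(make_variant("Full")$use_egnn)
  expect_false(make_variant("Mini")$use_egnn)
  expect_false(make_variant("AtomBondFP")$use_egnn)
  expect_error(make_variant("tiny"), "unknown variant")
  expect_error(model_config(hidden_dim = 10, attention_heads = 4), "divide")
  # default head count
  expect_equal(model_config()$attention_heads, 4L)
  # FP variant has zero graph-channel parameters
  p <- chemformer:::.init_params(make_variant("FP", hidden_dim = 8),
                                 list(atom_in = 136, bond_in = 39, fp_in = 10))
  expect_false(any(grepl("^(a|b)_", names(p))))
  # Mini has attention but no equivariant blocks
  pm <- chemformer:::.init_params(
    make_variant("Mini", hidden_dim = 8, attention_heads = 2),
    list(atom_in = 136, bond_in = 39, fp_in = 10))
  expect_true(any(grepl("_at1_", names(pm))))
  expect_false(any(grepl("_eg", names(pm))))
})

test_that("tape forward agrees with the reference layer implementations", {
  set.seed(11)
  h <- 8; n <- 5
  cfg <- list(hidden_dim = h, attention_heads = 2, dropout = 0,
              egnn_agg = "mean")
  at <- list(Wq = chemformer:::.glorot(h, h), Wk = chemformer:::.glorot(h, h),
             Wv = chemformer:::.glorot(h, h), Wo = chemformer:::.glorot(h, h),
             g = matrix(1 + rnorm(h, sd = 0.1), 1), b = matrix(rnorm(h, sd = 0.1), 1))
  names(at) <- paste0("z_", names(at))
  H0 <- matrix(rnorm(n * h), n, h)
  tape <- chemformer:::.tape_new()
  res <- chemformer:::.attention_tape(tape, at, "z_",
                                      chemformer:::ad_const(tape, H0), cfg,
                                      FALSE, NULL)
  pl <- at; names(pl) <- sub("^z_", "", names(pl))
  plain <- attention_layer(list(H = H0), pl, heads = 2)
  expect_equal(chemformer:::.val(tape, res$H), plain$H, tolerance = 1e-12)
  expect_equal(res$weights, plain$weights, tolerance = 1e-12)
})

test_that("encoder embedding is finite for degenerate graphs and invariant", {
  # methane's empty bond graph -> CLS-only attention, finite embedding
  cfg <- fx_small_config("Full")
  gb <- build_bond_graph(fx_mol("C"))
  enc <- encode_graph(gb, cfg, channel = "bond", seed = 2)
  expect_length(enc$embedding, cfg$hidden_dim)
  expect_all_finite(enc$embedding)
  expect_error(
    encode_graph(structure(list(adjacency = matrix(0, 0, 0),
                                features = matrix(0, 0, 136),
                                coords = matrix(0, 0, 3)),
                           class = "cf_atom_graph"), cfg),
    "empty")
})

test_that("predictions: channel isolation, probability range, batch independence", {
  d <- fx_clf_data()
  fitfp <- chemformer(d, variant = "FP", split = split_random(d, seed = 2),
                      hidden_dim = 8L, epochs = 2, seed = 1)
  # FP channel ignores coordinates entirely
  d2 <- d
  d2$mols <- lapply(d2$mols, function(m) {
    if (!is.null(m$coords)) m$coords <- m$coords + 1
    m
  })
  expect_identical(predict(fitfp, d), predict(fitfp, d2))
  p <- predict(fitfp, d)
  expect_true(all(p >= 0 & p <= 1, na.rm = TRUE))
  # batch of one vs batch of many
  single <- predict(fitfp, d[7])
  many <- predict(fitfp, d[1:10])
  expect_equal(unname(single[1, ]), unname(many[7, ]), tolerance = 1e-12)
})

test_that("checkpoints round-trip and reject schema mismatches", {
  d <- fx_clf_data()
  fit <- chemformer(d, variant = "FP", split = split_random(d, seed = 2),
                    hidden_dim = 8L, epochs = 2, seed = 1,
                    fingerprint_families = c("maccs", "estate"))
  path <- withr::local_tempfile(fileext = ".json")
  save_chemformer(fit, path)
  back <- load_chemformer(path)
  expect_equal(predict(back, d[1:5]), predict(fit, d[1:5]), tolerance = 1e-10)
  # corrupt the schema tag
  chk <- jsonlite::read_json(path, simplifyVector = TRUE)
  chk$schema_hash <- "atom999.bond1.fp[x]"
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(chk, path2, digits = NA, auto_unbox = TRUE, null = "null")
  expect_error(load_chemformer(path2), "schema")
})
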