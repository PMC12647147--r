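test_that("random split: 8:1:1 floor allocation, determinism, disjoint-exhaustive", {
  s <- split_random(100, seed = 3)
  expect_length(s$train, 80)
  expect_length(s$val, 10)
  expect_length(s$test, 10)
  expect_identical(split_random(100, seed = 3), s)
  expect_false(identical(split_random(100, seed = 4)$train, s$train))
  # disjoint and exhaustive over random sizes and seeds
  for (rep in 1:20) {
    set.seed(rep)
    n <- sample(3:200, 1); sd_ <- sample(1e6, 1)
    sp <- split_random(n, seed = sd_)
    all_idx <- c(sp$train, sp$val, sp$test)
    expect_equal(sort(all_idx), seq_len(n))
    expect_equal(anyDuplicated(all_idx), 0)
  }
  expect_error(split_random(2), "too small")
})

test_that("scaffold split keeps scaffold groups together", {
  # two share the benzene scaffold; they must co-locate
  d <- cf_dataset(c("CCc1ccccc1", "OCc1ccccc1", "C1CCCCC1O", "CCCNC"),
                  c(1, 0, 1, 0), "act", "classification")
  s <- split_scaffold(d, ratio = c(2, 1, 1), seed = 1)
  part_of <- function(i) {
    if (i %in% s$train) "train" else if (i %in% s$val) "val" else "test"
  }
  expect_equal(part_of(1), part_of(2))
  expect_equal(sort(c(s$train, s$val, s$test)), 1:4)

  # property over generated pools: no scaffold straddles partitions
  smi <- generate_molecules(40, seed = 55)
  d2 <- cf_dataset(smi, rep(0:1, 20), "act", "classification")
  s2 <- split_scaffold(d2, seed = 9)
  keys <- vapply(smi, murcko_scaffold, character(1))
  for (key in unique(keys)) {
    members <- which(keys == key)
    parts <- unique(vapply(members, function(i) {
      if (i %in% s2$train) "train" else if (i %in% s2$val) "val" else "test"
    }, character(1)))
    expect_length(parts, 1)
  }

  # all-distinct scaffolds -> sizes equal random-split sizes
  distinct <- cf_dataset(c("CCO", "CCCN", "CCCCS", "CCCl", "CCCCCBr",
                           "CCF", "CCCCO", "CCCC", "CCN", "CCCBr"),
                         rep(0:1, 5), "act", "classification")
  sd3 <- split_scaffold(distinct, seed = 1)
  sr3 <- split_random(10, seed = 1)
  expect_equal(lengths(sd3[c("train", "val", "test")]),
               lengths(sr3[c("train", "val", "test")]))

  # one shared scaffold group -> everything lands in train
  same <- cf_dataset(c("CCc1ccccc1", "CCCc1ccccc1", "OCc1ccccc1",
                       "NCc1ccccc1"), rep(1, 4), "act", "classification")
  s4 <- split_scaffold(same, seed = 1)
  expect_length(s4$train, 4)
})

test_that("roc_auc matches the brute-force pairwise oracle", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(roc_auc(c(0.2, 0.3), c(1, 1)), "both classes")
  oracle <- function(s, y) {
    pos <- which(y == 1); neg <- which(y == 0); tot <- 0
    for (p in pos) for (q in neg) {
      tot <- tot + (s[p] > s[q]) + 0.5 * (s[p] == s[q])
    }
    tot / (length(pos) * length(neg))
  }
  set.seed(17)
  for (rep in 1:50) {
    n <- sample(2:8, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(stats::runif(n), 1)      # rounded scores force ties
    expect_equal(roc_auc(s, y), oracle(s, y))
  }
})

test_that("prc_auc behaves like average precision", {
  expect_equal(prc_auc(c(0.9, 0.8, 0.1), c(1, 1, 0)), 1)
  expect_equal(prc_auc(c(0.9, 0.1), c(0, 1)), 0.5)
  expect_error(prc_auc(c(0.2, 0.3), c(0, 0)), "both classes")
})

test_that("rmse: identity, hand arithmetic, constant offset", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  x <- stats::rnorm(20)
  expect_equal(rmse(x + 0.7, x), 0.7)
  expect_error(rmse(1:3, 1:4), "length")
})

test_that("label noise flips exactly round(rate * |train+val|), never test", {
  d <- cf_dataset(generate_molecules(20, seed = 77),
                  rep(0:1, 10), "act", "classification")
  sp <- split_random(d, ratio = c(6, 2, 2), seed = 1)
  # rate 0 is a no-op
  expect_identical(inject_label_noise(d, 0, sp), d)
  noisy <- inject_label_noise(d, 0.3, sp, seed = 5)
  tv <- c(sp$train, sp$val)
  expect_equal(sum(noisy$targets[tv, ] != d$targets[tv, ]),
               round(0.3 * length(tv)))
  expect_identical(noisy$targets[sp$test, ], d$targets[sp$test, ])
  # missing labels are never flipped
  d2 <- d; d2$targets[sp$train[1], 1] <- NA
  noisy2 <- inject_label_noise(d2, 0.3, sp, seed = 5)
  expect_true(is.na(noisy2$targets[sp$train[1], 1]))
  expect_error(inject_label_noise(d, 1.5, sp), "rate")
  dreg <- cf_dataset("CCO", 1.2, "y", "regression")
  expect_error(inject_label_noise(dreg, 0.1, sp), "classification")
})

test_that("murcko scaffolds strip side chains and key acyclics individually", {
  expect_equal(murcko_scaffold("CCc1ccccc1"), murcko_scaffold("OCc1ccccc1"))
  expect_equal(murcko_scaffold("Cc1ccccc1"), canonical_smiles("c1ccccc1"))
  expect_match(murcko_scaffold("CCO"), "^acyclic:")
  expect_false(murcko_scaffold("CCO") == murcko_scaffold("CCN"))
  # linker between two rings is retained
  expect_equal(murcko_scaffold("Cc1ccc(CCc2ccccc2)cc1"),
               canonical_smiles("c1ccc(CCc2ccccc2)cc1"))
})
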