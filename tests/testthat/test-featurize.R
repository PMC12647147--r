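test_that("feature schemas define the contracted widths", {
  as_ <- atom_feature_schema()
  bs <- bond_feature_schema()
  expect_equal(sum(as_$width), attr(as_, "total_width"))
  expect_equal(sum(bs$width), attr(bs, "total_width"))
  expect_equal(attr(as_, "total_width"), 136L)
  expect_equal(attr(bs, "total_width"), 39L)
})

test_that("atom graph of benzene: 6 nodes, 6 undirected edges, symmetric rows", {
  g <- build_atom_graph(fx_mol("c1ccccc1"))
  expect_equal(nrow(g$adjacency), 6)
  expect_equal(sum(g$adjacency), 12)      # 6 undirected edges
  expect_true(isSymmetric(g$adjacency))
  expect_true(all(diag(g$adjacency) == 0))
  expect_equal(ncol(g$features), 136)
  # all carbons equivalent: identical feature rows
  expect_equal(nrow(unique(g$features)), 1)
  # aromaticity flag active
  arom_col <- sum(atom_feature_schema()$width[1:6]) + 1
  expect_true(all(g$features[, arom_col] == 1))
})

test_that("atom features: one active entry per one-hot block, index checks", {
  sch <- atom_feature_schema()
  stops <- cumsum(sch$width); starts <- c(1, head(stops, -1) + 1)
  for (mol in fx_pool()[1:10]) {
    F <- chemformer:::.atom_feature_matrix(mol)
    for (b in which(sch$kind == "one-hot")) {
      block <- F[, starts[b]:stops[b], drop = FALSE]
      expect_true(all(rowSums(block) == 1), label = sch$name[b])
    }
  }
  m <- fx_mol("CCO")
  expect_length(atom_features(m, 1), 136)
  expect_error(atom_features(m, 4), "out of range")
})

test_that("bond graph: line-graph adjacency, midpoints, empty case", {
  # ethanol: 2 bonds sharing the middle carbon -> one undirected adjacency
  ge <- build_bond_graph(fx_mol("CCO"))
  expect_equal(nrow(ge$adjacency), 2)
  expect_equal(sum(ge$adjacency), 2)
  # benzene line graph is a 6-cycle
  gb <- build_bond_graph(fx_mol("c1ccccc1"))
  expect_equal(nrow(gb$adjacency), 6)
  expect_equal(sum(gb$adjacency), 12)
  # methane: bondless molecule
  gm <- build_bond_graph(fx_mol("C"))
  expect_equal(dim(gm$adjacency), c(0, 0))
  expect_equal(nrow(gm$features), 0)
  # midpoints
  m <- fx_mol("CCO")
  expect_equal(ge$coords[1, ],
               (m$coords[m$bonds$i[1], ] + m$coords[m$bonds$j[1], ]) / 2)
  # bond feature vector
  expect_length(bond_features(m, 1), 39)
  expect_error(bond_features(m, 5), "out of range")
})

test_that("line-graph handshake matches brute-force bond-intersection oracle", {
  for (mol in fx_pool()) {
    g <- build_bond_graph(mol)
    nb <- nrow(mol$bonds)
    # oracle: count pairs of distinct bonds sharing exactly one atom
    oracle <- 0
    ends <- cbind(mol$bonds$i, mol$bonds$j)
    if (nb > 1) {
      for (b1 in 1:(nb - 1)) for (b2 in (b1 + 1):nb) {
        if (length(intersect(ends[b1, ], ends[b2, ])) == 1) oracle <- oracle + 2
      }
    }
    expect_equal(sum(g$adjacency), oracle)
    # degree identity: sum of adjacency = sum over atoms deg*(deg-1)
    deg <- chemformer:::.atom_degree(mol)
    expect_equal(sum(g$adjacency), sum(deg * (deg - 1)))
  }
})

test_that("features are invariant under rigid motion of coordinates", {
  mol <- fx_mol("CC(=O)Nc1ccc(O)cc1")
  R <- qr.Q(qr(matrix(c(0.1, 0.7, -0.2, 0.5, -0.3, 0.8, 0.9, 0.2, 0.4), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  mol2 <- mol
  mol2$coords <- mol$coords %*% R + matrix(c(5, -2, 1), mol$n, 3, byrow = TRUE)
  expect_equal(chemformer:::.atom_feature_matrix(mol2),
               chemformer:::.atom_feature_matrix(mol))
  expect_equal(chemformer:::.bond_feature_matrix(mol2),
               chemformer:::.bond_feature_matrix(mol), tolerance = 1e-10)
})

test_that("atom relabeling permutes adjacency as P A P^T", {
  set.seed(4)
  for (mol in fx_pool()[1:10]) {
    perm <- sample(mol$n)
    g <- build_atom_graph(mol)
    gp <- build_atom_graph(chemformer:::.permute_mol(mol, perm))
    P <- diag(mol$n)[perm, , drop = FALSE]     # row k of new = perm[k] of old
    expect_equal(gp$adjacency, P %*% g$adjacency %*% t(P))
    expect_equal(gp$features, g$features[perm, , drop = FALSE])
  }
})

test_that("graphs survive a JSON round trip", {
  g <- build_atom_graph(fx_mol("CC(=O)Nc1ccc(O)cc1"))
  path <- withr::local_tempfile(fileext = ".json")
  write_graph_json(g, path)
  back <- read_graph_json(path)
  expect_equal(back$adjacency, g$adjacency)
  expect_equal(back$features, g$features, tolerance = 1e-12)
  expect_equal(back$coords, g$coords, tolerance = 1e-12)
})

test_that("missing coordinates raise a state error pointing at embedding", {
  flat <- parse_molecule("CCO")
  expect_error(build_atom_graph(flat), "embed_conformer")
  expect_error(build_bond_graph(flat), "embed_conformer")
})
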