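# Atom-graph and bond-graph featurization.
#
# The atom graph has heavy atoms as nodes and covalent bonds as edges; the
# bond graph is its line graph (bonds become nodes, bonds sharing an atom
# are connected).  Feature widths are fixed contracts: 136 per atom and 39
# per bond.  Block composition is documented in the schema accessors below.

.ATOM_ELEMENTS <- 1:99                      # one-hot over atomic number, + other
.BOND_END_ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")

.ELEMENT_Z <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
                F = 9, Ne = 10, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15,
                S = 16, Cl = 17, Ar = 18, K = 19, Ca = 20, Fe = 26, Cu = 29,
                Zn = 30, As = 33, Se = 34, Br = 35, Ag = 47, Sn = 50, I = 53,
                Pt = 78, Au = 79, Hg = 80)

#' Atom feature schema
#'
#' Ordered blocks of the 136-dimensional atom feature vector.  One-hot
#' blocks carry exactly one active entry (an "other" slot catches unlisted
#' categories); binary blocks are free flags.
#'
#' @return a data.frame with columns `name`, `kind`, `width`, plus an
#'   attribute `total_width` (136).
#' @export
atom_feature_schema <- function() {
  s <- data.frame(
    name = c("atomic_number", "degree", "formal_charge", "chirality",
             "hybridization", "n_hydrogens", "aromatic", "in_ring",
             "ring_size"),
    kind = c("one-hot", "one-hot", "one-hot", "one-hot", "one-hot",
             "one-hot", "binary", "binary", "binary"),
    width = c(100L, 7L, 6L, 4L, 7L, 6L, 1L, 1L, 4L))
  attr(s, "total_width") <- sum(s$width)
  s
}

#' Bond feature schema
#'
#' Ordered blocks of the 39-dimensional bond feature vector.  End-atom
#' blocks are symmetrized (sum of the two endpoint one-hots), so the vector
#' is invariant to bond direction.  The final block is the 3D bond length
#' in Angstrom computed from the embedded conformer.
#'
#' @return a data.frame with columns `name`, `kind`, `width`, plus an
#'   attribute `total_width` (39).
#' @export
bond_feature_schema <- function() {
  s <- data.frame(
    name = c("bond_type", "conjugated", "in_ring", "stereo",
             "end_elements", "end_hybridization", "end_aromatic_count",
             "ring_size", "end_in_ring_count", "bond_order", "bond_length"),
    kind = c("one-hot", "binary", "binary", "one-hot", "sym-sum", "sym-sum",
             "one-hot", "binary", "one-hot", "scalar", "scalar"),
    width = c(5L, 1L, 1L, 4L, 10L, 4L, 3L, 6L, 3L, 1L, 1L))
  attr(s, "total_width") <- sum(s$width)
  s
}

.one_hot <- function(width, idx) { v <- numeric(width); v[idx] <- 1; v }

# heuristic hybridization from bond orders and total connections
.hybridization <- function(mol) {
  n <- mol$n
  ndouble <- integer(n); ntriple <- integer(n); degree <- integer(n)
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
    degree[i] <- degree[i] + 1L; degree[j] <- degree[j] + 1L
    if (mol$bonds$order[b] == 2) { ndouble[i] <- ndouble[i] + 1L; ndouble[j] <- ndouble[j] + 1L }
    if (mol$bonds$order[b] == 3) { ntriple[i] <- ntriple[i] + 1L; ntriple[j] <- ntriple[j] + 1L }
  }
  conn <- degree + mol$nH
  vapply(seq_len(n), function(a) {
    if (conn[a] <= 1 && degree[a] == 0) return("s")
    if (ntriple[a] > 0 || ndouble[a] >= 2) return("sp")
    if (ndouble[a] > 0 || mol$aromatic[a]) return("sp2")
    if (conn[a] <= 4) return("sp3")
    if (conn[a] == 5) return("sp3d")
    if (conn[a] == 6) return("sp3d2")
    "other"
  }, character(1))
}

.atom_degree <- function(mol) {
  degree <- integer(mol$n)
  for (b in seq_len(nrow(mol$bonds))) {
    degree[mol$bonds$i[b]] <- degree[mol$bonds$i[b]] + 1L
    degree[mol$bonds$j[b]] <- degree[mol$bonds$j[b]] + 1L
  }
  degree
}

#' Compute the feature vector of one atom
#'
#' @param mol a valid `cf_mol`.
#' @param atom_index 1-based heavy-atom index.
#' @return numeric vector of length 136 following [atom_feature_schema()].
#' @export
atom_features <- function(mol, atom_index) {
  if (atom_index < 1 || atom_index > mol$n) stop("atom index out of range")
  .atom_feature_matrix(mol)[atom_index, ]
}

.atom_feature_matrix <- function(mol) {
  stopifnot(isTRUE(mol$valid))
  n <- mol$n
  hyb <- .hybridization(mol)
  degree <- .atom_degree(mol)
  hyb_levels <- c("s", "sp", "sp2", "sp3", "sp3d", "sp3d2")
  out <- matrix(0, n, attr(atom_feature_schema(), "total_width"))
  for (a in seq_len(n)) {
    z <- .ELEMENT_Z[mol$elem[a]]
    f <- c(
      .one_hot(100, if (!is.na(z) && z <= 99) z else 100),
      .one_hot(7, if (degree[a] <= 5) degree[a] + 1 else 7),
      .one_hot(6, if (abs(mol$charge[a]) <= 2) mol$charge[a] + 3 else 6),
      .one_hot(4, 1),                      # chirality: none/cw/ccw/other (not perceived)
      .one_hot(7, {
        k <- match(hyb[a], hyb_levels); if (is.na(k)) 7 else k
      }),
      .one_hot(6, if (mol$nH[a] <= 4) mol$nH[a] + 1 else 6),
      as.numeric(mol$aromatic[a]),
      as.numeric(mol$in_ring[a]),
      as.numeric(!is.na(mol$ring_size[a]) & mol$ring_size[a] == 3:6))
    out[a, ] <- f
  }
  out
}

# conjugation: aromatic, or multiple bond with a multiple-bond neighbour,
# or single bond joining two unsaturated (sp/sp2) atoms
.bond_conjugated <- function(mol, hyb) {
  nb <- nrow(mol$bonds)
  unsat <- hyb %in% c("sp", "sp2")
  vapply(seq_len(nb), function(b) {
    if (mol$bonds$aromatic[b]) return(TRUE)
    i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
    unsat[i] && unsat[j]
  }, logical(1))
}

#' Compute the feature vector of one bond
#'
#' @param mol a valid `cf_mol` with embedded coordinates.
#' @param bond_index 1-based bond index (order of `mol$bonds`).
#' @return numeric vector of length 39 following [bond_feature_schema()].
#' @export
bond_features <- function(mol, bond_index) {
  if (bond_index < 1 || bond_index > nrow(mol$bonds)) {
    stop("bond index out of range")
  }
  .bond_feature_matrix(mol)[bond_index, ]
}

.bond_feature_matrix <- function(mol) {
  stopifnot(isTRUE(mol$valid))
  if (is.null(mol$coords)) {
    stop("molecule has no coordinates; run embed_conformer() first")
  }
  nb <- nrow(mol$bonds)
  hyb <- .hybridization(mol)
  conj <- .bond_conjugated(mol, hyb)
  out <- matrix(0, nb, attr(bond_feature_schema(), "total_width"))
  if (nb == 0) return(out)
  hyb4 <- function(h) switch(h, sp = 1, sp2 = 2, sp3 = 3, 4)
  for (b in seq_len(nb)) {
    i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
    aromatic <- mol$bonds$aromatic[b]
    order <- mol$bonds$order[b]
    type_idx <- if (aromatic) 4 else if (order %in% 1:3) order else 5
    ee <- numeric(10)
    for (a in c(i, j)) {
      k <- match(mol$elem[a], .BOND_END_ELEMENTS)
      k <- if (is.na(k)) 10 else k
      ee[k] <- ee[k] + 1
    }
    eh <- numeric(4)
    for (a in c(i, j)) eh[hyb4(hyb[a])] <- eh[hyb4(hyb[a])] + 1
    len <- sqrt(sum((mol$coords[i, ] - mol$coords[j, ])^2))
    out[b, ] <- c(
      .one_hot(5, type_idx),
      as.numeric(conj[b]),
      as.numeric(mol$bonds$in_ring[b]),
      .one_hot(4, 1),                      # stereo: none/Z/E/other (not perceived)
      ee,
      eh,
      .one_hot(3, sum(mol$aromatic[c(i, j)]) + 1),
      as.numeric(!is.na(mol$bonds$ring_size[b]) & mol$bonds$ring_size[b] == 3:8),
      .one_hot(3, sum(mol$in_ring[c(i, j)]) + 1),
      if (aromatic) 1.5 else order,
      len)
  }
  out
}

#' Build the atom graph of a molecule
#'
#' Nodes are heavy atoms, edges are covalent bonds; node features follow
#' [atom_feature_schema()] and node coordinates come from the embedded 3D
#' conformer.
#'
#' @param mol a valid, embedded `cf_mol`.
#' @return an object of class `cf_atom_graph` with fields `adjacency`
#'   (N x N binary, symmetric, zero diagonal), `features` (N x 136),
#'   `coords` (N x 3) and `atom_index_map`.
#' @export
build_atom_graph <- function(mol) {
  stopifnot(isTRUE(mol$valid))
  if (is.null(mol$coords)) {
    stop("molecule has no coordinates; run embed_conformer() first")
  }
  n <- mol$n
  A <- matrix(0, n, n)
  for (b in seq_len(nrow(mol$bonds))) {
    A[mol$bonds$i[b], mol$bonds$j[b]] <- 1
    A[mol$bonds$j[b], mol$bonds$i[b]] <- 1
  }
  structure(list(adjacency = A, features = .atom_feature_matrix(mol),
                 coords = mol$coords, atom_index_map = seq_len(n)),
            class = "cf_atom_graph")
}

#' Build the bond (line) graph of a molecule
#'
#' Bonds become nodes; two distinct bonds are adjacent iff they share
#' exactly one atom.  Node coordinates are bond midpoints, giving the bond
#' channel a geometry consistent with the atom channel.
#'
#' @param mol a valid, embedded `cf_mol`.
#' @return an object of class `cf_bond_graph` with fields `adjacency`
#'   (M x M), `features` (M x 39), `coords` (M x 3 midpoints) and
#'   `bond_index_map` (M x 2 matrix of end-atom indices).  `M = 0` yields
#'   empty matrices.
#' @export
build_bond_graph <- function(mol) {
  stopifnot(isTRUE(mol$valid))
  if (is.null(mol$coords)) {
    stop("molecule has no coordinates; run embed_conformer() first")
  }
  nb <- nrow(mol$bonds)
  A <- matrix(0, nb, nb)
  if (nb > 1) {
    ends <- cbind(mol$bonds$i, mol$bonds$j)
    for (b1 in seq_len(nb - 1)) {
      for (b2 in (b1 + 1):nb) {
        if (length(intersect(ends[b1, ], ends[b2, ])) == 1) {
          A[b1, b2] <- 1; A[b2, b1] <- 1
        }
      }
    }
  }
  coords <- matrix(0, nb, 3)
  if (nb > 0) {
    coords <- (mol$coords[mol$bonds$i, , drop = FALSE] +
               mol$coords[mol$bonds$j, , drop = FALSE]) / 2
  }
  structure(list(adjacency = A, features = .bond_feature_matrix(mol),
                 coords = coords,
                 bond_index_map = cbind(i = mol$bonds$i, j = mol$bonds$j)),
            class = "cf_bond_graph")
}

# Reorder the atoms of a cf_mol by a permutation (new[k] = old[perm[k]]).
# Used by permutation-invariance tests.
.permute_mol <- function(mol, perm) {
  stopifnot(isTRUE(mol$valid), length(perm) == mol$n)
  inv <- order(perm)
  out <- mol
  out$elem <- mol$elem[perm]
  out$charge <- mol$charge[perm]
  out$nH <- mol$nH[perm]
  out$aromatic <- mol$aromatic[perm]
  out$in_ring <- mol$in_ring[perm]
  out$ring_size <- mol$ring_size[perm]
  if (!is.null(mol$coords)) out$coords <- mol$coords[perm, , drop = FALSE]
  out$bonds$i <- inv[mol$bonds$i]
  out$bonds$j <- inv[mol$bonds$j]
  out$rings <- lapply(mol$rings, function(r) inv[r])
  out
}

#' Serialize a featurized graph to JSON
#'
#' Writes adjacency as an edge list and features as dense rows; the inverse
#' of [read_graph_json()].  Intended for golden-file tests and external
#' inspection.
#'
#' @param graph a `cf_atom_graph` or `cf_bond_graph`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  A <- graph$adjacency
  edges <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  obj <- list(n = nrow(A),
              edges = unname(apply(edges, 1, as.integer, simplify = FALSE)),
              features = unname(apply(graph$features, 1, as.numeric,
                                      simplify = FALSE)),
              coords = unname(apply(graph$coords, 1, as.numeric,
                                    simplify = FALSE)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a featurized graph from JSON
#'
#' @param path a file written by [write_graph_json()].
#' @return a list with `adjacency`, `features`, `coords`.
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- obj$n
  A <- matrix(0, n, n)
  edges <- obj$edges
  if (length(edges)) {
    em <- if (is.matrix(edges)) edges else do.call(rbind, edges)
    for (r in seq_len(nrow(em))) {
      A[em[r, 1], em[r, 2]] <- 1; A[em[r, 2], em[r, 1]] <- 1
    }
  }
  feat <- if (is.matrix(obj$features)) obj$features else do.call(rbind, obj$features)
  coords <- if (is.matrix(obj$coords)) obj$coords else do.call(rbind, obj$coords)
  list(adjacency = A, features = feat, coords = coords)
}
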