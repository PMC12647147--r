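# Deterministic synthetic molecule and label generation.
#
# A seeded grammar combines curated drug-like scaffold templates with a
# substituent pool, so every emitted SMILES is valid by construction and
# the whole pipeline is testable without external downloads.  Labels come
# in three modes: substructure-driven classification, additive per-element
# regression, and geometry regression (radius of gyration of the embedded
# conformer, which only the 3D channel can see).

.FIXTURE_TEMPLATES_1 <- c(
  "c1ccc(%s)cc1", "Cc1ccc(%s)cc1", "c1ccc2cc(%s)ccc2c1",
  "c1cc(%s)ccn1", "c1cc(%s)oc1", "c1cc(%s)sc1", "c1cnc(%s)nc1",
  "C1CCC(%s)CC1", "C1CCC(%s)C1", "C1CCOC(%s)C1",
  "CCCC%s", "CC(C)C%s", "CCOCC%s")

.FIXTURE_TEMPLATES_2 <- c(
  "c1cc(%s)ccc1%s", "O=C(%s)N%s", "O=C(O%s)%s")

.FIXTURE_SUBSTITUENTS <- c(
  "C", "CC", "CCC", "C(C)C", "O", "OC", "N", "NC", "F", "Cl", "Br",
  "C#N", "C(=O)O", "C(=O)OC", "C(=O)N", "CO", "CCO", "CCN", "S", "SC",
  "C=C", "CC=C", "OCC", "N(C)C", "CCl",
  "c2ccccc2", "Cc2ccccc2", "C2CC2", "c2ccco2", "c2ccncc2", "C2CCCCC2")

#' Generate deterministic synthetic molecules
#'
#' Draws scaffold templates and substituents from a curated pool with a
#' seeded RNG, canonicalizes and de-duplicates.  All outputs parse; the
#' list is identical for identical seeds.
#'
#' @param n number of molecules.
#' @param seed integer seed.
#' @return character vector of `n` distinct canonical SMILES.
#' @export
#' @examples
#' generate_molecules(5, seed = 1)
generate_molecules <- function(n, seed = 1L) {
  if (n == 0) return(character(0))
  set.seed(seed)
  out <- character(0)
  tries <- 0L; max_tries <- 60L * n + 200L
  while (length(out) < n && tries < max_tries) {
    tries <- tries + 1L
    if (stats::runif(1) < 0.8) {
      smi <- sprintf(sample(.FIXTURE_TEMPLATES_1, 1),
                     sample(.FIXTURE_SUBSTITUENTS, 1))
    } else {
      smi <- sprintf(sample(.FIXTURE_TEMPLATES_2, 1),
                     sample(.FIXTURE_SUBSTITUENTS, 1),
                     sample(.FIXTURE_SUBSTITUENTS, 1))
    }
    can <- canonical_smiles(smi)
    if (is.na(can) || can %in% out) next
    out <- c(out, can)
  }
  if (length(out) < n) {
    stop("fixture grammar exhausted after ", tries, " draws (got ",
         length(out), " of ", n, ")")
  }
  out
}

# labelled molecular graph for subgraph-isomorphism matching
.mol_igraph <- function(mol) {
  g <- igraph::make_graph(if (nrow(mol$bonds)) rbind(mol$bonds$i, mol$bonds$j)
                          else integer(0), n = mol$n, directed = FALSE)
  vcol <- .elem_class(mol$elem) * 2L + as.integer(mol$aromatic)
  ecol <- ifelse(mol$bonds$aromatic, 4L, mol$bonds$order)
  list(g = g, vcol = vcol, ecol = as.integer(ecol))
}

#' Substructure match by labeled subgraph isomorphism
#'
#' Matches a motif given as SMILES (element class, aromaticity and bond
#' order must all agree) against a molecule using VF2.
#'
#' @param mol a valid `cf_mol` or SMILES string.
#' @param motif motif SMILES (e.g. `"c1ccccc1"` for a benzene ring).
#' @return `TRUE` if the motif occurs in the molecule.
#' @export
has_motif <- function(mol, motif) {
  length(motif_atoms(mol, motif)) > 0
}

#' Atoms covered by a substructure motif
#'
#' @inheritParams has_motif
#' @return sorted integer vector of heavy-atom indices that belong to at
#'   least one embedding of the motif (empty if no match).
#' @export
motif_atoms <- function(mol, motif) {
  if (is.character(mol)) mol <- parse_molecule(mol)
  stopifnot(isTRUE(mol$valid))
  pat <- if (is.character(motif)) parse_molecule(motif) else motif
  stopifnot(isTRUE(pat$valid))
  gt <- .mol_igraph(mol); gp <- .mol_igraph(pat)
  if (pat$n > mol$n) return(integer(0))
  maps <- igraph::subgraph_isomorphisms(
    pattern = gp$g, target = gt$g, method = "vf2",
    vertex.color1 = gt$vcol, vertex.color2 = gp$vcol,
    edge.color1 = gt$ecol, edge.color2 = gp$ecol)
  sort(unique(unlist(lapply(maps, as.integer))))
}

# fixed per-element contributions for the additive regression mode
.ADDITIVE_CONTRIB <- c(C = 0.35, N = -0.30, O = -0.45, S = 0.60, P = 0.20,
                       F = 0.18, Cl = 0.65, Br = 0.85, I = 1.05)

#' Radius of gyration of an embedded conformer
#'
#' `sqrt(mean(||x_i - centroid||^2))` over heavy atoms, in Angstrom.
#'
#' @param mol an embedded `cf_mol`.
#' @return nonnegative scalar.
#' @export
radius_of_gyration <- function(mol) {
  if (is.null(mol$coords)) stop("molecule has no coordinates")
  ctr <- colMeans(mol$coords)
  sqrt(mean(rowSums(sweep(mol$coords, 2, ctr)^2)))
}

#' Synthetic labels for fixture molecules
#'
#' * `motif_classification`: label 1 iff the molecule contains `motif`,
#'   then flipped with probability `noise_rate`.
#' * `additive_regression`: sum of fixed per-element contributions plus
#'   Gaussian noise of sd `noise_sd`.
#' * `geometry_regression`: radius of gyration of the embedded 3D
#'   conformer plus Gaussian noise -- a target only the geometry-aware
#'   channel can fully resolve.
#'
#' @param smiles character vector of valid SMILES.
#' @param label_mode one of the three modes above.
#' @param motif motif SMILES for classification labels.
#' @param noise_rate label-flip probability (classification).
#' @param noise_sd Gaussian noise sd (regression).
#' @param seed integer seed (noise and embedding).
#' @param forcefield force field for geometry labels.
#' @return numeric label vector; for classification, the attribute
#'   `flipped` records which labels were reversed.
#' @export
synth_labels <- function(smiles,
                         label_mode = c("motif_classification",
                                        "additive_regression",
                                        "geometry_regression"),
                         motif = "c1ccccc1", noise_rate = 0, noise_sd = 0,
                         seed = 1L, forcefield = "uff") {
  label_mode <- match.arg(label_mode)
  mols <- lapply(smiles, parse_molecule)
  if (any(!vapply(mols, function(m) isTRUE(m$valid), logical(1)))) {
    stop("synth_labels requires valid SMILES")
  }
  set.seed(seed)
  if (label_mode == "motif_classification") {
    y <- vapply(mols, function(m) as.numeric(has_motif(m, motif)), 0)
    flip <- stats::runif(length(y)) < noise_rate
    y[flip] <- 1 - y[flip]
    attr(y, "flipped") <- flip
    return(y)
  }
  if (label_mode == "additive_regression") {
    y <- vapply(mols, function(m) {
      contrib <- .ADDITIVE_CONTRIB[m$elem]
      contrib[is.na(contrib)] <- 0
      sum(contrib)
    }, 0)
    return(y + stats::rnorm(length(y), 0, noise_sd))
  }
  embedded <- .embed_smiles(vapply(mols, `[[`, "", "smiles"), seed = seed,
                            forcefield = forcefield)
  y <- vapply(embedded, radius_of_gyration, 0)
  y + stats::rnorm(length(y), 0, noise_sd)
}

#' Generate a ready-to-train synthetic dataset
#'
#' Combines [generate_molecules()] and [synth_labels()] into a
#' `cf_dataset`; geometry labels embed the conformers once and keep them
#' on the dataset so training reuses them.
#'
#' @inheritParams synth_labels
#' @param n number of molecules.
#' @param seed integer seed driving generation, labels and embedding.
#' @return a `cf_dataset` with one task named after the label mode.
#' @export
make_fixture_dataset <- function(n, seed = 1L,
                                 label_mode = "motif_classification",
                                 motif = "c1ccccc1", noise_rate = 0,
                                 noise_sd = 0, forcefield = "uff") {
  smiles <- generate_molecules(n, seed = seed)
  task_type <- if (label_mode == "motif_classification") "classification"
  else "regression"
  y <- synth_labels(smiles, label_mode, motif = motif,
                    noise_rate = noise_rate, noise_sd = noise_sd,
                    seed = seed, forcefield = forcefield)
  data <- cf_dataset(smiles, y, task_names = label_mode,
                     task_type = task_type)
  if (label_mode == "geometry_regression") {
    data <- embed_conformers(data, seed = seed, forcefield = forcefield)
  }
  attr(data, "motif") <- motif
  attr(data, "seed") <- as.integer(seed)
  data
}

#' Write a fixture dataset to CSV
#'
#' @param data a `cf_dataset`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_dataset_csv <- function(data, path) {
  df <- data.frame(smiles = data$smiles, data$targets, check.names = FALSE)
  colnames(df) <- c("smiles", data$task_names)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
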