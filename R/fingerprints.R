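# Molecular fingerprint families and panels.
#
# Eight families are available.  ecfp/path/maccs/fgroup are computed by
# OpenBabel (ChemmineOB); estate, erg, atompair and torsion are computed
# here from the perceived heavy-atom graph (no reference implementation of
# these families is available in the R stack).  All families are
# deterministic functions of the canonical SMILES.

#' Available fingerprint families
#'
#' * `ecfp` -- extended-connectivity (circular) fingerprint, radius 2,
#'   folded to 2048 bits.
#' * `path` -- linear-path fingerprint (fragments up to 7 atoms), 1024 bits.
#' * `maccs` -- 166 structural keys plus the conventional unused key 0
#'   (length 167).
#' * `estate` -- electrotopological-state indices summed per atom type
#'   (10 element classes x aromatic/non-aromatic; real-valued, length 20).
#' * `erg` -- pharmacophore pair-count fingerprint in the extended
#'   reduced-graph style: 21 property pairs x topological distances 1-15
#'   (real-valued counts, length 315).
#' * `atompair` -- hashed atom-pair fingerprint, 2048 bits.
#' * `torsion` -- hashed topological-torsion (4-atom path) fingerprint,
#'   2048 bits.
#' * `fgroup` -- functional-group SMARTS-pattern fingerprint, 512 bits.
#'
#' @return data.frame with columns `name`, `width`, `kind`.
#' @export
fp_families <- function() {
  data.frame(
    name = c("ecfp", "path", "maccs", "estate", "erg", "atompair",
             "torsion", "fgroup"),
    width = c(2048L, 1024L, 167L, 20L, 315L, 2048L, 2048L, 512L),
    kind = c("binary", "binary", "binary", "real", "real", "binary",
             "binary", "binary"))
}

#' Default fingerprint panels per task type
#'
#' Classification panels combine the pharmacophore (erg), circular (ecfp)
#' and path fingerprints; regression panels combine estate, erg and ecfp.
#'
#' @param task_type `"classification"` or `"regression"`.
#' @return character vector of family names in panel order.
#' @export
default_families <- function(task_type = c("classification", "regression")) {
  task_type <- match.arg(task_type)
  if (task_type == "classification") c("erg", "ecfp", "path")
  else c("estate", "erg", "ecfp")
}

.fp_ob <- function(smiles, which_fp) {
  m <- tryCatch(ChemmineOB::forEachMol("SMILES", smiles, identity),
                error = function(e) NULL)
  if (is.null(m)) stop("cannot compute fingerprint for invalid SMILES")
  ChemmineOB::fingerprint_OB(m, which_fp)
}

.elem_class <- function(e) {
  k <- match(e, c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I"))
  ifelse(is.na(k), 10L, k)
}

.mol_topo_dist <- function(mol) {
  if (mol$n == 1) return(matrix(0, 1, 1))
  g <- igraph::make_graph(rbind(mol$bonds$i, mol$bonds$j), n = mol$n,
                          directed = FALSE)
  igraph::distances(g)
}

# Kier-Hall electrotopological state indices summed per atom type.
.fp_estate <- function(mol) {
  zv <- c(B = 3, C = 4, N = 5, O = 6, F = 7, Si = 4, P = 5, S = 6,
          Cl = 7, Br = 7, I = 7)
  pqn <- c(B = 2, C = 2, N = 2, O = 2, F = 2, Si = 3, P = 3, S = 3,
           Cl = 3, Br = 4, I = 5)
  degree <- .atom_degree(mol)
  d <- pmax(degree, 1)
  dv <- zv[mol$elem] - mol$nH
  dv[is.na(dv)] <- d[is.na(dv)]
  L <- pqn[mol$elem]; L[is.na(L)] <- 4
  I <- ((2 / L)^2 * dv + 1) / d
  D <- .mol_topo_dist(mol)
  S <- I
  if (mol$n > 1) {
    for (a in seq_len(mol$n)) {
      S[a] <- I[a] + sum((I[a] - I[-a]) / (D[a, -a] + 1)^2)
    }
  }
  type <- (.elem_class(mol$elem) - 1L) * 2L + as.integer(mol$aromatic) + 1L
  out <- numeric(20)
  for (a in seq_len(mol$n)) out[type[a]] <- out[type[a]] + S[a]
  out
}

# pharmacophore properties used by the reduced-graph pair fingerprint
.pharmacophore_flags <- function(mol) {
  nbr_het <- logical(mol$n)
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[b]; j <- mol$bonds$j[b]
    if (!(mol$elem[j] %in% c("C", "H"))) nbr_het[i] <- TRUE
    if (!(mol$elem[i] %in% c("C", "H"))) nbr_het[j] <- TRUE
  }
  cbind(donor = mol$elem %in% c("N", "O") & mol$nH >= 1,
        acceptor = mol$elem %in% c("N", "O"),
        positive = mol$charge > 0,
        negative = mol$charge < 0,
        aromatic = mol$aromatic,
        hydrophobe = (mol$elem == "C" & !mol$aromatic & !nbr_het) |
          mol$elem %in% c("F", "Cl", "Br", "I"))
}

.fp_erg <- function(mol) {
  flags <- .pharmacophore_flags(mol)
  D <- .mol_topo_dist(mol)
  np <- 6L
  pair_index <- matrix(0L, np, np)
  k <- 0L
  for (p in 1:np) for (q in p:np) {
    k <- k + 1L; pair_index[p, q] <- k; pair_index[q, p] <- k
  }
  out <- numeric(21 * 15)
  if (mol$n < 2) return(out)
  for (a in 1:(mol$n - 1)) for (b in (a + 1):mol$n) {
    d <- D[a, b]
    if (!is.finite(d) || d < 1 || d > 15) next
    for (p in which(flags[a, ])) for (q in which(flags[b, ])) {
      idx <- (pair_index[p, q] - 1L) * 15L + d
      out[idx] <- out[idx] + 1
    }
  }
  out
}

.ap_atom_type <- function(mol) {
  degree <- .atom_degree(mol)
  (.elem_class(mol$elem) - 1L) * 16L + pmin(degree, 7L) * 2L +
    as.integer(mol$aromatic)
}

.fp_atompair <- function(mol, nbits = 2048L) {
  out <- numeric(nbits)
  if (mol$n < 2) return(out)
  t <- .ap_atom_type(mol)
  D <- .mol_topo_dist(mol)
  for (a in 1:(mol$n - 1)) for (b in (a + 1):mol$n) {
    d <- D[a, b]
    if (!is.finite(d) || d < 1 || d > 30) next
    lo <- min(t[a], t[b]); hi <- max(t[a], t[b])
    h <- ((lo * 8191 + hi) * 31 + d) %% nbits
    out[h + 1] <- 1
  }
  out
}

.fp_torsion <- function(mol, nbits = 2048L) {
  out <- numeric(nbits)
  nb <- nrow(mol$bonds)
  if (nb == 0) return(out)
  t <- .ap_atom_type(mol)
  nbrs <- vector("list", mol$n)
  for (b in seq_len(nb)) {
    nbrs[[mol$bonds$i[b]]] <- c(nbrs[[mol$bonds$i[b]]], mol$bonds$j[b])
    nbrs[[mol$bonds$j[b]]] <- c(nbrs[[mol$bonds$j[b]]], mol$bonds$i[b])
  }
  for (b in seq_len(nb)) {
    j <- mol$bonds$i[b]; k <- mol$bonds$j[b]
    for (i in setdiff(nbrs[[j]], k)) for (l in setdiff(nbrs[[k]], c(j, i))) {
      s <- t[c(i, j, k, l)]
      r <- rev(s)
      key <- if (paste(s, collapse = ",") <= paste(r, collapse = ",")) s else r
      h <- 0
      for (v in key) h <- (h * 8191 + v) %% 1048573
      out[(h %% nbits) + 1] <- 1
    }
  }
  out
}

#' Compute one fingerprint family for a molecule
#'
#' @param mol a valid `cf_mol` or a SMILES string.
#' @param family family name from [fp_families()].
#' @return numeric vector of the family's width; binary families emit 0/1,
#'   `estate` and `erg` emit real values.
#' @export
#' @examples
#' length(compute_fingerprint("CCO", "maccs"))
compute_fingerprint <- function(mol, family) {
  fams <- fp_families()
  if (!family %in% fams$name) {
    stop("unknown fingerprint family: ", family)
  }
  if (is.character(mol)) mol <- parse_molecule(mol)
  if (!isTRUE(mol$valid)) stop("cannot fingerprint an invalid molecule")
  switch(family,
    ecfp = {
      v <- .fp_ob(mol$smiles, "ECFP4")
      as.numeric(v[1:2048] + v[2049:4096] > 0)
    },
    path = as.numeric(.fp_ob(mol$smiles, "FP2") > 0),
    maccs = c(0, as.numeric(.fp_ob(mol$smiles, "MACCS")[1:166] > 0)),
    fgroup = as.numeric(.fp_ob(mol$smiles, "FP4")[1:512] > 0),
    estate = .fp_estate(mol),
    erg = .fp_erg(mol),
    atompair = .fp_atompair(mol),
    torsion = .fp_torsion(mol))
}

#' Concatenate fingerprint families into a panel
#'
#' @param mol a valid `cf_mol` or a SMILES string.
#' @param families character vector of distinct family names, in panel
#'   order.
#' @return numeric vector of length `sum of family widths`, with attributes
#'   `families` and `widths`.
#' @export
fingerprint_panel <- function(mol, families) {
  if (!length(families)) stop("families must be nonempty")
  if (anyDuplicated(families)) stop("duplicate fingerprint family in panel")
  if (is.character(mol)) mol <- parse_molecule(mol)
  parts <- lapply(families, function(f) compute_fingerprint(mol, f))
  v <- unlist(parts, use.names = FALSE)
  attr(v, "families") <- families
  attr(v, "widths") <- lengths(parts)
  v
}

#' Fingerprint panel matrix for a dataset
#'
#' @param data a `cf_dataset` (invalid records yield all-`NA` rows).
#' @param families character vector of family names.
#' @return numeric matrix, one molecule per row.
#' @export
fingerprint_matrix <- function(data, families) {
  stopifnot(inherits(data, "cf_dataset"))
  width <- sum(fp_families()$width[match(families, fp_families()$name)])
  out <- matrix(NA_real_, length(data$smiles), width)
  for (r in seq_along(data$smiles)) {
    if (!data$valid[r]) next
    mol <- data$mols[[r]]
    if (is.null(mol)) mol <- parse_molecule(data$smiles[r])
    out[r, ] <- fingerprint_panel(mol, families)
  }
  out
}

#' Export fingerprint panels to CSV
#'
#' One molecule per row (canonical SMILES in the first column), suitable as
#' input for external baseline models.
#'
#' @inheritParams fingerprint_matrix
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
export_fingerprints <- function(data, families, path) {
  m <- fingerprint_matrix(data, families)
  colnames(m) <- paste0("fp", seq_len(ncol(m)))
  utils::write.csv(data.frame(smiles = data$smiles, m, check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' Enumerate fingerprint family combinations
#'
#' @param k combination size (1, 2 or 3).
#' @param families character vector of candidate families (default all 8).
#' @return list of character vectors, one per combination.
#' @export
fp_combinations <- function(k, families = fp_families()$name) {
  if (!k %in% 1:3) stop("k must be 1, 2 or 3")
  utils::combn(families, k, simplify = FALSE)
}
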