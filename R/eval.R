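# Dataset splits, evaluation metrics, and label-noise injection.

# V2000 molfile writer for scaffold canonicalization (subgraphs of a
# perceived molecule; coordinates optional).
.write_molfile <- function(elem, charge, bonds, coords = NULL) {
  n <- length(elem); nb <- nrow(bonds)
  if (is.null(coords)) coords <- matrix(0, n, 3)
  lines <- c("scaffold", " chemformer", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (a in seq_len(n)) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      coords[a, 1], coords[a, 2], coords[a, 3], elem[a]))
  }
  for (b in seq_len(nb)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              bonds$i[b], bonds$j[b], bonds$order[b]))
  }
  chg <- which(charge != 0)
  if (length(chg)) {
    lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(chg)),
                             paste0(sprintf("%4d%4d", chg, charge[chg]),
                                    collapse = "")))
  }
  paste(c(lines, "M  END", "$$$$", ""), collapse = "\n")
}

#' Bemis-Murcko scaffold of a molecule
#'
#' Iteratively prunes terminal (degree-1) atoms, leaving ring systems and
#' their linkers, and returns the canonical SMILES of the remainder.
#' Acyclic molecules have no ring scaffold; they are keyed by their own
#' canonical SMILES (prefixed `acyclic:`) so that each forms its own
#' scaffold group.
#'
#' @param mol a valid `cf_mol` or SMILES string.
#' @return a scaffold key string.
#' @export
murcko_scaffold <- function(mol) {
  if (is.character(mol)) mol <- parse_molecule(mol)
  if (!isTRUE(mol$valid)) return(NA_character_)
  keep <- rep(TRUE, mol$n)
  bonds <- mol$bonds
  repeat {
    deg <- integer(mol$n)
    for (b in seq_len(nrow(bonds))) {
      if (keep[bonds$i[b]] && keep[bonds$j[b]]) {
        deg[bonds$i[b]] <- deg[bonds$i[b]] + 1L
        deg[bonds$j[b]] <- deg[bonds$j[b]] + 1L
      }
    }
    leaves <- which(keep & deg <= 1)
    if (!length(leaves) || sum(keep) <= length(leaves)) {
      if (length(leaves)) keep[leaves] <- FALSE
      break
    }
    keep[leaves] <- FALSE
  }
  if (!any(keep)) return(paste0("acyclic:", mol$smiles))
  idx <- which(keep)
  map <- integer(mol$n); map[idx] <- seq_along(idx)
  sub_bonds <- bonds[keep[bonds$i] & keep[bonds$j], , drop = FALSE]
  sub_bonds$i <- map[sub_bonds$i]; sub_bonds$j <- map[sub_bonds$j]
  mf <- .write_molfile(mol$elem[idx], mol$charge[idx], sub_bonds)
  can <- tryCatch(ChemmineOB::convertFormat("SDF", "CAN", mf),
                  error = function(e) "")
  can <- sub("[ \t].*$", "", sub("[\n\r]+$", "", can))
  if (!nzchar(can)) paste0("acyclic:", mol$smiles) else can
}

.check_split_ratio <- function(n, ratio) {
  if (n < 3) stop("dataset too small to split (need at least 3 records)")
  ratio <- ratio / sum(ratio)
  n_val <- floor(n * ratio[2]); n_test <- floor(n * ratio[3])
  c(train = n - n_val - n_test, val = n_val, test = n_test)
}

.new_split <- function(train, val, test, method, seed, ratio) {
  structure(list(train = train, val = val, test = test, method = method,
                 seed = as.integer(seed), ratio = ratio),
            class = "cf_split")
}

#' @export
print.cf_split <- function(x, ...) {
  cat("<cf_split (", x$method, ", seed ", x$seed, "): ",
      length(x$train), "/", length(x$val), "/", length(x$test),
      " train/val/test>\n", sep = "")
  invisible(x)
}

#' Random train/validation/test split
#'
#' Floor allocation of the validation and test shares with the remainder
#' going to training, so an 8:1:1 split of 100 molecules gives 80/10/10.
#' Deterministic for a fixed seed.
#'
#' @param data a `cf_dataset` (or an integer count of records).
#' @param ratio length-3 numeric ratio, default `c(8, 1, 1)`.
#' @param seed integer seed.
#' @return a `cf_split` with disjoint exhaustive index vectors.
#' @export
split_random <- function(data, ratio = c(8, 1, 1), seed = 1L) {
  n <- if (inherits(data, "cf_dataset")) length(data$smiles) else as.integer(data)
  sizes <- .check_split_ratio(n, ratio)
  set.seed(seed)
  perm <- sample.int(n)
  .new_split(perm[seq_len(sizes[1])],
             perm[sizes[1] + seq_len(sizes[2])],
             perm[sizes[1] + sizes[2] + seq_len(sizes[3])],
             "random", seed, ratio)
}

#' Scaffold-based train/validation/test split
#'
#' Molecules sharing a Bemis-Murcko scaffold never straddle partitions.
#' Scaffold groups are sorted by decreasing size (ties shuffled by seed)
#' and fill the training partition first, then validation, then test --
#' the usual out-of-scaffold generalization protocol.
#'
#' @inheritParams split_random
#' @return a `cf_split`.
#' @export
split_scaffold <- function(data, ratio = c(8, 1, 1), seed = 1L) {
  stopifnot(inherits(data, "cf_dataset"))
  n <- length(data$smiles)
  sizes <- .check_split_ratio(n, ratio)
  keys <- vapply(seq_len(n), function(r) {
    if (!data$valid[r]) return(paste0("invalid:", r))
    mol <- data$mols[[r]]
    if (is.null(mol)) mol <- parse_molecule(data$smiles[r])
    murcko_scaffold(mol)
  }, character(1))
  groups <- split(seq_len(n), keys)
  set.seed(seed)
  ord <- order(-lengths(groups), sample.int(length(groups)))
  groups <- groups[ord]
  train <- integer(0); val <- integer(0); test <- integer(0)
  for (g in groups) {
    if (length(train) < sizes[1]) train <- c(train, g)
    else if (length(val) < sizes[2]) val <- c(val, g)
    else test <- c(test, g)
  }
  .new_split(train, val, test, "scaffold", seed, ratio)
}

#' Area under the ROC curve
#'
#' Probability that a random positive is ranked above a random negative,
#' with ties counted one half (rank/Wilcoxon formulation).
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1); both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
roc_auc <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) {
    stop("roc_auc undefined: both classes must be present")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve
#'
#' Computed as average precision (step-wise interpolation), the standard
#' estimator for ranked retrieval.
#'
#' @inheritParams roc_auc
#' @return PRC-AUC in `[0, 1]`.
#' @export
prc_auc <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  npos <- sum(labels == 1)
  if (npos == 0 || sum(labels == 0) == 0) {
    stop("prc_auc undefined: both classes must be present")
  }
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  prec <- cumsum(y) / seq_along(y)
  sum(prec[y == 1]) / npos
}

#' Root-mean-square error
#'
#' @param pred numeric predictions.
#' @param obs numeric observed values (same length).
#' @return `sqrt(mean((pred - obs)^2))` over non-missing pairs.
#' @export
rmse <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch")
  keep <- !is.na(pred) & !is.na(obs)
  if (!any(keep)) stop("no observed pairs")
  sqrt(mean((pred[keep] - obs[keep])^2))
}

#' Flip a fixed number of training/validation labels
#'
#' Reverses the labels of exactly `round(rate * |train U val|)` randomly
#' chosen train/validation records (classification only).  Test labels and
#' missing labels are never touched; flips happen after splitting so the
#' test partition is provably clean.
#'
#' @param data a classification `cf_dataset`.
#' @param rate fraction in `[0, 1]`.
#' @param split a `cf_split` on `data`.
#' @param seed integer seed choosing which records flip.
#' @return the dataset with flipped targets.
#' @export
inject_label_noise <- function(data, rate, split, seed = 1L) {
  stopifnot(inherits(data, "cf_dataset"), inherits(split, "cf_split"))
  if (data$task_type != "classification") {
    stop("label noise applies to classification tasks only")
  }
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  tv <- c(split$train, split$val)
  n_flip <- round(rate * length(tv))
  if (n_flip == 0) return(data)
  candidates <- tv[rowSums(!is.na(data$targets[tv, , drop = FALSE])) > 0]
  if (n_flip > length(candidates)) {
    stop("not enough labelled train/val records to flip")
  }
  set.seed(seed)
  chosen <- sample(candidates, n_flip)
  for (r in chosen) {
    obs <- !is.na(data$targets[r, ])
    data$targets[r, obs] <- 1 - data$targets[r, obs]
  }
  data
}
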