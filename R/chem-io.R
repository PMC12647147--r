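# Molecule input, canonicalization, cleaning, and 3D conformer embedding.
#
# SMILES handling (parsing, canonicalization, 2D layout, SMARTS matching,
# bit fingerprints) goes through OpenBabel via ChemmineOB/ChemmineR.
# Seeded 3D embedding uses distance geometry + force-field refinement via
# the RDKit available on the system `python` (OpenBabel's conformer search
# cannot be seeded).  All graph perception downstream works on a plain-R
# molecule object (`cf_mol`) built from the resulting molfile blocks.

#' Canonicalize SMILES strings
#'
#' Converts each SMILES to its OpenBabel canonical form.  Strings that do
#' not parse, or that contain no heavy atom, yield `NA`.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where invalid.
#' @export
#' @examples
#' canonical_smiles(c("OCC", "CCO", "not_a_smiles"))
canonical_smiles <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", s),
                    error = function(e) "")
    out <- sub("[ \t\n\r]+$", "", out)
    # require at least one heavy atom: any element letter other than H/h
    if (!nzchar(out) || !grepl("[A-GI-Za-gi-z]", out)) return(NA_character_)
    out
  }, character(1), USE.NAMES = FALSE)
}

# decode the old-style molfile atom-block charge field
.molfile_charge_codes <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L,
                           `4` = 0L, `5` = -1L, `6` = -2L, `7` = -3L)

# Build a cf_mol from ChemmineR SDF blocks.  Explicit hydrogens are folded
# into per-heavy-atom counts and dropped from the graph.
.mol_from_sdf_blocks <- function(sdf, raw_smiles, smiles,
                                 embedded = FALSE, fallback = FALSE,
                                 nh_override = NULL, chg_override = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem_all <- sub("_.*$", "", rownames(ab))
  n_all <- nrow(ab)
  coords_all <- matrix(as.numeric(ab[, 1:3, drop = FALSE]), ncol = 3)
  chg_all <- .molfile_charge_codes[as.character(ab[, 5])]
  chg_all[is.na(chg_all)] <- 0L
  if (is.matrix(bb) && nrow(bb) > 0) {
    bonds_all <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                            order = as.integer(bb[, 3]))
  } else {
    bonds_all <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  }

  heavy <- which(elem_all != "H")
  map <- integer(n_all); map[heavy] <- seq_along(heavy)
  n <- length(heavy)
  nH <- integer(n)
  keep <- logical(nrow(bonds_all))
  for (b in seq_len(nrow(bonds_all))) {
    i <- bonds_all$i[b]; j <- bonds_all$j[b]
    hi <- elem_all[i] == "H"; hj <- elem_all[j] == "H"
    if (hi && !hj) nH[map[j]] <- nH[map[j]] + 1L
    if (hj && !hi) nH[map[i]] <- nH[map[i]] + 1L
    keep[b] <- !hi && !hj
  }
  bonds <- bonds_all[keep, , drop = FALSE]
  bonds$i <- map[bonds$i]; bonds$j <- map[bonds$j]
  rownames(bonds) <- NULL

  elem <- elem_all[heavy]
  charge <- if (is.null(chg_override)) as.integer(chg_all[heavy]) else
    as.integer(chg_override)
  coords <- if (embedded) coords_all[heavy, , drop = FALSE] else NULL
  had_explicit_h <- any(elem_all == "H")
  if (!is.null(nh_override)) {
    nH <- as.integer(nh_override)
  } else if (!had_explicit_h) {
    nH <- .implicit_h_counts(elem, charge, bonds, n)
  }
  mol <- list(raw_smiles = raw_smiles, smiles = smiles, n = n,
              elem = elem, charge = charge, nH = nH,
              bonds = bonds, coords = coords,
              embedded = embedded, embed_fallback = fallback, valid = n >= 1)
  mol <- .perceive_rings_aromaticity(mol)
  class(mol) <- "cf_mol"
  mol
}

# default-valence implicit hydrogen counts (used when the molfile carries
# no explicit hydrogens; charges adjust N/P up and halogens/chalcogens down)
.implicit_h_counts <- function(elem, charge, bonds, n) {
  base <- c(B = 3L, C = 4L, N = 3L, O = 2L, F = 1L, Si = 4L, P = 3L,
            S = 2L, Cl = 1L, Br = 1L, I = 1L)
  osum <- integer(n)
  for (b in seq_len(nrow(bonds))) {
    o <- bonds$order[b]
    osum[bonds$i[b]] <- osum[bonds$i[b]] + o
    osum[bonds$j[b]] <- osum[bonds$j[b]] + o
  }
  out <- integer(n)
  for (a in seq_len(n)) {
    v <- base[elem[a]]
    if (is.na(v)) { out[a] <- 0L; next }
    v <- if (elem[a] %in% c("N", "P", "O", "S")) v + charge[a] else v - abs(charge[a])
    out[a] <- max(0L, v - osum[a])
  }
  out
}

# Ring perception from graph topology: every non-bridge bond closes a ring;
# its smallest ring is that bond plus the shortest path between its ends in
# the graph with the bond removed.  Aromaticity is a simplified Hueckel
# test on rings of size 3-7 (all members pi-capable, 4n+2 pi electrons).
.perceive_rings_aromaticity <- function(mol) {
  n <- mol$n; bonds <- mol$bonds
  nb <- nrow(bonds)
  mol$bonds$in_ring <- logical(nb)
  mol$bonds$aromatic <- logical(nb)
  mol$bonds$ring_size <- rep(NA_integer_, nb)
  mol$in_ring <- logical(n)
  mol$aromatic <- logical(n)
  mol$ring_size <- rep(NA_integer_, n)
  mol$rings <- list()
  if (nb == 0 || n < 3) return(mol)

  g <- igraph::make_graph(rbind(bonds$i, bonds$j), n = n, directed = FALSE)
  bridge_ids <- as.integer(igraph::bridges(g))
  ring_bonds <- setdiff(seq_len(nb), bridge_ids)
  rings <- list()
  for (b in ring_bonds) {
    g2 <- igraph::delete_edges(g, b)
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = bonds$i[b], to = bonds$j[b])$vpath[[1]])
    if (length(sp) < 2) next
    ring <- as.integer(sp)
    mol$bonds$in_ring[b] <- TRUE
    mol$bonds$ring_size[b] <- length(ring)
    key <- paste(sort(ring), collapse = "-")
    if (is.null(rings[[key]])) rings[[key]] <- ring
  }
  mol$rings <- unname(rings)

  # mark non-closing ring bonds (both ends consecutive in some ring)
  for (ring in mol$rings) {
    k <- length(ring)
    mol$in_ring[ring] <- TRUE
    mol$ring_size[ring] <- pmin(mol$ring_size[ring], k, na.rm = TRUE)
    for (t in seq_len(k)) {
      a <- ring[t]; b2 <- ring[if (t == k) 1 else t + 1]
      hit <- which((bonds$i == a & bonds$j == b2) | (bonds$i == b2 & bonds$j == a))
      if (length(hit)) {
        mol$bonds$in_ring[hit] <- TRUE
        mol$bonds$ring_size[hit] <- pmin(mol$bonds$ring_size[hit], k, na.rm = TRUE)
      }
    }
  }

  has_double <- logical(n); has_triple <- logical(n)
  for (b in seq_len(nb)) {
    if (bonds$order[b] == 2) has_double[c(bonds$i[b], bonds$j[b])] <- TRUE
    if (bonds$order[b] == 3) has_triple[c(bonds$i[b], bonds$j[b])] <- TRUE
  }
  for (ring in mol$rings) {
    k <- length(ring)
    if (k < 3 || k > 7) next
    pi_total <- 0L; ok <- TRUE
    for (a in ring) {
      e <- mol$elem[a]
      if (!(e %in% c("C", "N", "O", "S", "B")) || has_triple[a]) { ok <- FALSE; break }
      if (has_double[a]) {
        pi_total <- pi_total + 1L
      } else if (e %in% c("N", "O", "S")) {
        pi_total <- pi_total + 2L          # lone pair in the ring plane
      } else if (e == "C" && mol$charge[a] > 0) {
        pi_total <- pi_total + 0L          # empty p orbital (tropylium-like)
      } else {
        ok <- FALSE; break                 # saturated carbon breaks conjugation
      }
    }
    if (ok && pi_total %% 4L == 2L) {
      mol$aromatic[ring] <- TRUE
      for (t in seq_len(k)) {
        a <- ring[t]; b2 <- ring[if (t == k) 1 else t + 1]
        hit <- which((bonds$i == a & bonds$j == b2) | (bonds$i == b2 & bonds$j == a))
        mol$bonds$aromatic[hit] <- TRUE
      }
    }
  }
  mol
}

# SMILES -> SDFset through OpenBabel with a planar layout and explicit
# hydrogens (exact H counts; zero-bond records stay parseable)
.ob_sdf <- function(can) {
  tryCatch({
    txt <- ChemmineOB::convertFormat(
      "SMI", "SDF", can,
      options = data.frame(names = c("gen2D", "h"), args = c("", "")))
    suppressWarnings(ChemmineR::read.SDFset(strsplit(txt, "\n")[[1]]))
  }, error = function(e) NULL)
}

#' Parse a SMILES string into a molecule object
#'
#' Builds the heavy-atom molecular graph (elements, formal charges, hydrogen
#' counts, bonds, ring and aromaticity perception) used by featurization and
#' the hand-computed fingerprints.  Coordinates stay empty until
#' [embed_conformer()] is applied.
#'
#' @param smiles a single SMILES string.
#' @return an object of class `cf_mol`, with `valid = FALSE` if the SMILES
#'   does not parse or has no heavy atom.
#' @export
parse_molecule <- function(smiles) {
  can <- canonical_smiles(smiles)
  if (is.na(can)) {
    return(structure(list(raw_smiles = smiles, smiles = NA_character_,
                          n = 0L, valid = FALSE, embedded = FALSE),
                     class = "cf_mol"))
  }
  sdf <- .ob_sdf(can)
  if (is.null(sdf) || length(sdf) < 1) {
    return(structure(list(raw_smiles = smiles, smiles = NA_character_,
                          n = 0L, valid = FALSE, embedded = FALSE),
                     class = "cf_mol"))
  }
  .mol_from_sdf_blocks(sdf[[1]], raw_smiles = smiles, smiles = can)
}

#' @export
print.cf_mol <- function(x, ...) {
  if (!isTRUE(x$valid)) {
    cat("<cf_mol: invalid SMILES '", x$raw_smiles, "'>\n", sep = "")
    return(invisible(x))
  }
  cat("<cf_mol ", x$smiles, ": ", x$n, " heavy atoms, ",
      nrow(x$bonds), " bonds",
      if (isTRUE(x$embedded)) ", 3D embedded" else "",
      if (isTRUE(x$embed_fallback)) " (2D fallback)" else "", ">\n", sep = "")
  invisible(x)
}

# locate the bundled python embedding helper
.embed_script <- function() {
  p <- system.file("python", "embed_conformers.py", package = "chemformer")
  if (!nzchar(p)) stop("embed_conformers.py not found in installed package")
  p
}

# Batched seeded 3D embedding; returns a list of cf_mol (NULL where invalid).
.embed_smiles <- function(smiles, seed = 1L, forcefield = c("uff", "mmff94")) {
  forcefield <- match.arg(forcefield)
  out <- vector("list", length(smiles))
  ok <- !is.na(smiles)
  if (!any(ok)) return(out)
  tsv <- tempfile(fileext = ".tsv"); sdf_path <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(tsv, sdf_path)), add = TRUE)
  writeLines(paste0("m", which(ok), "\t", smiles[ok]), tsv)
  status <- system2("python", c(.embed_script(), tsv, sdf_path,
                                as.integer(seed), forcefield),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(sdf_path)) {
    stop("conformer embedding subprocess failed (python + RDKit required)")
  }
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(sdf_path))
  for (k in seq_along(sdfs)) {
    sdf <- sdfs[[k]]
    id <- as.integer(sub("^m", "", ChemmineR::sdfid(sdfs[k])))
    db <- ChemmineR::datablock(sdf)
    dbget <- function(tag) unname(db[grep(paste0("^", tag, "\\b"), names(db))][1])
    fallback <- identical(dbget("cf_fallback"), "1")
    nh <- as.integer(strsplit(dbget("cf_nh"), ",")[[1]])
    chg <- as.integer(strsplit(dbget("cf_chg"), ",")[[1]])
    out[[id]] <- .mol_from_sdf_blocks(sdf, raw_smiles = smiles[id],
                                      smiles = smiles[id], embedded = TRUE,
                                      fallback = fallback,
                                      nh_override = nh, chg_override = chg)
  }
  # molecules RDKit could not parse: planar fallback from the 2D layout
  for (k in which(ok)) {
    if (is.null(out[[k]])) {
      m <- parse_molecule(smiles[k])
      if (isTRUE(m$valid)) {
        sdf <- .ob_sdf(m$smiles)[[1]]
        ab <- ChemmineR::atomblock(sdf)
        heavy <- sub("_.*$", "", rownames(ab)) != "H"
        m$coords <- matrix(as.numeric(ab[heavy, 1:3, drop = FALSE]), ncol = 3)
        m$embedded <- TRUE; m$embed_fallback <- TRUE
        out[[k]] <- m
      }
    }
  }
  out
}

#' Embed a 3D conformer for one molecule
#'
#' Generates a single conformer by distance-geometry embedding followed by
#' force-field optimization (UFF by default).  Deterministic for a fixed
#' seed.  If 3D embedding fails, a planar 2D layout with z = 0 is used and
#' `embed_fallback` is set on the returned molecule.
#'
#' @param mol a `cf_mol` (from [parse_molecule()]) or a SMILES string.
#' @param seed integer seed for the distance-geometry embedding.
#' @param forcefield `"uff"` (universal force field, default) or `"mmff94"`.
#' @return the `cf_mol` with `coords` (heavy atoms x 3, Angstrom) populated.
#' @export
#' @examples
#' \donttest{
#' m <- embed_conformer("CCO", seed = 1)
#' m$coords
#' }
embed_conformer <- function(mol, seed = 1L, forcefield = c("uff", "mmff94")) {
  if (is.character(mol)) mol <- parse_molecule(mol)
  if (!isTRUE(mol$valid)) stop("cannot embed an invalid molecule")
  res <- .embed_smiles(mol$smiles, seed = seed, forcefield = forcefield)[[1]]
  if (is.null(res)) stop("embedding failed for ", mol$smiles)
  res$raw_smiles <- mol$raw_smiles
  res
}

#' Construct a molecular property dataset
#'
#' @param smiles character vector of SMILES.
#' @param targets numeric matrix (molecules x tasks), data.frame, or vector;
#'   `NA` marks a missing label.
#' @param task_names character vector naming the target columns.
#' @param task_type `"classification"` or `"regression"`.
#' @return an object of class `cf_dataset`.
#' @export
cf_dataset <- function(smiles, targets, task_names = NULL,
                       task_type = c("classification", "regression")) {
  task_type <- match.arg(task_type)
  smiles <- as.character(smiles)
  if (is.null(dim(targets))) targets <- matrix(as.numeric(targets), ncol = 1)
  targets <- as.matrix(targets)
  storage.mode(targets) <- "double"
  if (is.null(task_names)) {
    task_names <- colnames(targets)
    if (is.null(task_names)) task_names <- paste0("task", seq_len(ncol(targets)))
  }
  stopifnot(length(smiles) == nrow(targets),
            length(task_names) == ncol(targets))
  can <- canonical_smiles(smiles)
  structure(list(raw_smiles = smiles, smiles = can, valid = !is.na(can),
                 targets = targets, task_names = task_names,
                 task_type = task_type,
                 mols = vector("list", length(smiles))),
            class = "cf_dataset")
}

#' @export
print.cf_dataset <- function(x, ...) {
  cat("<cf_dataset: ", length(x$smiles), " molecules (",
      sum(!x$valid), " invalid), ", length(x$task_names), " ",
      x$task_type, " task(s): ", paste(x$task_names, collapse = ", "),
      ">\n", sep = "")
  invisible(x)
}

#' @export
length.cf_dataset <- function(x) length(x$smiles)

#' @export
`[.cf_dataset` <- function(x, i, ...) {
  out <- x
  out$raw_smiles <- x$raw_smiles[i]
  out$smiles <- x$smiles[i]
  out$valid <- x$valid[i]
  out$targets <- x$targets[i, , drop = FALSE]
  out$mols <- x$mols[i]
  out
}

#' Read a molecular dataset from CSV
#'
#' Expects one row per molecule with a SMILES column and one or more target
#' columns.  Target cells that are empty or not numeric become missing
#' labels; rows are kept in file order.
#'
#' @param path path to a CSV file.
#' @param smiles_column name of the SMILES column.
#' @param target_columns character vector of target column names.
#' @param task_type `"classification"` or `"regression"`.
#' @return a `cf_dataset`.
#' @export
read_dataset <- function(path, smiles_column = "smiles", target_columns,
                         task_type = c("classification", "regression")) {
  task_type <- match.arg(task_type)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  missing_cols <- setdiff(c(smiles_column, target_columns), names(df))
  if (length(missing_cols)) {
    stop("column(s) not present in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  targets <- sapply(target_columns, function(cn) {
    suppressWarnings(as.numeric(df[[cn]]))
  })
  if (is.null(dim(targets))) targets <- matrix(targets, ncol = length(target_columns))
  colnames(targets) <- target_columns
  cf_dataset(df[[smiles_column]], targets, target_columns, task_type)
}

#' Remove invalid and duplicate molecules
#'
#' Drops records whose SMILES does not parse (or has no heavy atom) and all
#' but the first occurrence of each canonical-SMILES duplicate group.  Label
#' conflicts within a duplicate group are reported via `message()`, never
#' merged.
#'
#' @param data a `cf_dataset`.
#' @return a list with elements `data` (the cleaned `cf_dataset`) and
#'   `report` (a `cf_cleaning_report` with fields `n_input`,
#'   `n_duplicates_removed`, `n_invalid_removed`, `n_output`).
#' @export
clean_dataset <- function(data) {
  stopifnot(inherits(data, "cf_dataset"))
  n_input <- length(data$smiles)
  valid_idx <- which(data$valid)
  n_invalid <- n_input - length(valid_idx)
  first <- !duplicated(data$smiles[valid_idx])
  keep <- valid_idx[first]
  n_dup <- length(valid_idx) - length(keep)
  # surface conflicting labels among duplicate groups
  if (n_dup > 0) {
    dup_groups <- split(valid_idx, data$smiles[valid_idx])
    for (grp in dup_groups) {
      if (length(grp) > 1) {
        tg <- data$targets[grp, , drop = FALSE]
        if (nrow(unique(tg)) > 1) {
          message("conflicting labels among duplicates of ",
                  data$smiles[grp[1]], "; keeping first occurrence")
        }
      }
    }
  }
  report <- structure(list(n_input = n_input, n_duplicates_removed = n_dup,
                           n_invalid_removed = n_invalid,
                           n_output = length(keep)),
                      class = "cf_cleaning_report")
  list(data = data[keep], report = report)
}

#' @export
print.cf_cleaning_report <- function(x, ...) {
  cat("cleaning report: ", x$n_input, " in, ",
      x$n_duplicates_removed, " duplicates removed, ",
      x$n_invalid_removed, " invalid removed, ",
      x$n_output, " out\n", sep = "")
  invisible(x)
}

#' Write a cleaning report as JSON
#'
#' @param report a `cf_cleaning_report` from [clean_dataset()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE)
  invisible(path)
}

#' Read molecules with precomputed 3D coordinates from an SDF file
#'
#' V2000/V3000 records with coordinates skip conformer embedding entirely.
#' Optional SD tags supply targets.
#'
#' @param path path to an SDF file.
#' @param target_tags character vector of SD tag names holding target
#'   values (optional; missing/unparseable tags become missing labels).
#' @param task_type `"classification"` or `"regression"`.
#' @return a `cf_dataset` with `mols` populated from the file coordinates.
#' @export
read_sdf_dataset <- function(path, target_tags = character(0),
                             task_type = c("classification", "regression")) {
  task_type <- match.arg(task_type)
  if (!file.exists(path)) stop("file not found: ", path)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  n <- length(sdfs)
  smiles <- character(n)
  mols <- vector("list", n)
  targets <- matrix(NA_real_, n, max(length(target_tags), 1))
  for (k in seq_len(n)) {
    sdf <- sdfs[[k]]
    txt <- paste(c(ChemmineR::sdf2str(sdf), ""), collapse = "\n")
    can <- tryCatch(ChemmineOB::convertFormat("SDF", "CAN", txt),
                    error = function(e) "")
    can <- sub("[ \t].*$", "", sub("[\n\r].*$", "", can))
    smiles[k] <- if (nzchar(can)) can else NA_character_
    if (!is.na(smiles[k])) {
      mols[[k]] <- .mol_from_sdf_blocks(sdf, raw_smiles = smiles[k],
                                        smiles = smiles[k], embedded = TRUE)
    }
    if (length(target_tags)) {
      db <- ChemmineR::datablock(sdf)
      for (t in seq_along(target_tags)) {
        hit <- grep(paste0("^", target_tags[t], "\\b"), names(db))
        if (length(hit)) {
          targets[k, t] <- suppressWarnings(as.numeric(db[hit[1]]))
        }
      }
    }
  }
  data <- cf_dataset(smiles, targets,
                     if (length(target_tags)) target_tags else "target",
                     task_type)
  data$mols <- mols
  data$valid <- data$valid & !vapply(mols, is.null, logical(1))
  data
}

#' Embed 3D conformers for every molecule in a dataset
#'
#' Runs the seeded distance-geometry + force-field pipeline once for the
#' whole table (one subprocess).  Invalid records are left untouched.
#'
#' @param data a `cf_dataset`.
#' @inheritParams embed_conformer
#' @return the dataset with `mols` populated with embedded `cf_mol` objects.
#' @export
embed_conformers <- function(data, seed = 1L, forcefield = c("uff", "mmff94")) {
  stopifnot(inherits(data, "cf_dataset"))
  forcefield <- match.arg(forcefield)
  todo <- which(data$valid & vapply(data$mols, function(m) {
    is.null(m) || !isTRUE(m$embedded)
  }, logical(1)))
  if (!length(todo)) return(data)
  res <- .embed_smiles(data$smiles[todo], seed = seed, forcefield = forcefield)
  for (k in seq_along(todo)) {
    if (!is.null(res[[k]])) {
      res[[k]]$raw_smiles <- data$raw_smiles[todo[k]]
      data$mols[[todo[k]]] <- res[[k]]
    } else {
      data$valid[todo[k]] <- FALSE
    }
  }
  attr(data, "embed_seed") <- as.integer(seed)
  attr(data, "forcefield") <- forcefield
  data
}
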