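# Attention-based interpretability: per-atom and per-bond saliency from
# the CLS row of the final encoder block.

.cls_attention_map <- function(object, mol, channel) {
  config <- object$config
  prefix_graph <- if (channel == "atom") build_atom_graph(mol) else
    build_bond_graph(mol)
  enc <- encode_graph(prefix_graph, config, params = object$params,
                      channel = channel)
  if (is.null(enc$cls_attention)) {
    stop("variant '", config$variant, "' has no attention layers")
  }
  w <- Reduce(`+`, enc$cls_attention) / length(enc$cls_attention)
  w <- w[-1]                        # drop the CLS self-entry
  if (length(w)) w <- w / sum(w)    # renormalize for cross-molecule comparison
  w
}

.prepare_attention_mol <- function(object, mol) {
  if (is.character(mol)) mol <- parse_molecule(mol)
  if (!isTRUE(mol$valid)) stop("invalid molecule")
  if (is.null(mol$coords)) {
    mol <- embed_conformer(mol$smiles, seed = object$embed_seed,
                           forcefield = object$forcefield)
  }
  mol
}

#' Per-atom attention weights of a fitted model
#'
#' Extracts the CLS query row of the final atom-channel encoder block,
#' averages it over heads, drops the CLS self-entry and renormalizes to
#' sum 1.  Higher weight marks atoms the graph representation attends to
#' more strongly.
#'
#' @param object a fitted `chemformer` whose variant includes the atom
#'   channel.
#' @param mol a `cf_mol` or SMILES string.
#' @return a `cf_attention` object with `atom_weights` (length N, sums to
#'   1), `elements`, `smiles`, `source_block` and `head_reduction`.
#' @export
atom_attention <- function(object, mol) {
  if (!"atom" %in% object$config$channels) {
    stop("variant '", object$config$variant,
         "' has no atom attention channel")
  }
  mol <- .prepare_attention_mol(object, mol)
  w <- .cls_attention_map(object, mol, "atom")
  structure(list(atom_weights = w, bond_weights = NULL,
                 bond_index_map = NULL,
                 elements = mol$elem, smiles = mol$smiles,
                 source_block = object$config$encoder_blocks,
                 head_reduction = "mean"),
            class = "cf_attention")
}

#' Per-bond attention weights of a fitted model
#'
#' Same CLS-row extraction as [atom_attention()] but on the bond (line)
#' graph channel; weights are keyed by the end-atom pairs of each bond.
#'
#' @inheritParams atom_attention
#' @return a `cf_attention` with `bond_weights` and `bond_index_map`.
#'   A bondless molecule yields an empty map with a warning.
#' @export
bond_attention <- function(object, mol) {
  if (!"bond" %in% object$config$channels) {
    stop("variant '", object$config$variant,
         "' has no bond attention channel")
  }
  mol <- .prepare_attention_mol(object, mol)
  if (nrow(mol$bonds) == 0) {
    warning("molecule has no bonds; empty attention map")
    return(structure(list(atom_weights = NULL, bond_weights = numeric(0),
                          bond_index_map = cbind(i = integer(0), j = integer(0)),
                          elements = mol$elem, smiles = mol$smiles,
                          source_block = object$config$encoder_blocks,
                          head_reduction = "mean"),
                     class = "cf_attention"))
  }
  w <- .cls_attention_map(object, mol, "bond")
  structure(list(atom_weights = NULL, bond_weights = w,
                 bond_index_map = cbind(i = mol$bonds$i, j = mol$bonds$j),
                 elements = mol$elem, smiles = mol$smiles,
                 source_block = object$config$encoder_blocks,
                 head_reduction = "mean"),
            class = "cf_attention")
}

#' @export
print.cf_attention <- function(x, ...) {
  cat("<cf_attention for ", x$smiles, ": ", sep = "")
  if (!is.null(x$atom_weights)) {
    cat(length(x$atom_weights), " atom weights", sep = "")
  }
  if (!is.null(x$bond_weights)) {
    cat(length(x$bond_weights), " bond weights", sep = "")
  }
  cat(" (block ", x$source_block, ", head ", x$head_reduction, ")>\n",
      sep = "")
  invisible(x)
}

#' Export an attention map as JSON
#'
#' Writes atom entries (index, element, weight) and/or bond entries
#' (end-atom pair, weight); [read_attention()] restores the weights
#' exactly.
#'
#' @param map a `cf_attention`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
export_attention <- function(map, path) {
  obj <- list(smiles = map$smiles, source_block = map$source_block,
              head_reduction = map$head_reduction)
  if (!is.null(map$atom_weights)) {
    obj$atoms <- lapply(seq_along(map$atom_weights), function(a) {
      list(index = a, element = map$elements[a],
           weight = map$atom_weights[a])
    })
  }
  if (!is.null(map$bond_weights)) {
    obj$bonds <- lapply(seq_along(map$bond_weights), function(b) {
      list(i = map$bond_index_map[b, 1], j = map$bond_index_map[b, 2],
           weight = map$bond_weights[b])
    })
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read an exported attention map
#'
#' @param path a file written by [export_attention()].
#' @return a list with `smiles`, and `atoms`/`bonds` data.frames.
#' @export
read_attention <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Monotone color ramp for attention weights
#'
#' Maps weights to greys, darker = higher weight (0 maps to near-white,
#' the maximum weight to near-black).
#'
#' @param w nonnegative numeric weights.
#' @return character vector of colors.
#' @export
attention_colors <- function(w) {
  if (!length(w)) return(character(0))
  mx <- max(w)
  rel <- if (mx > 0) w / mx else w * 0
  grDevices::gray(0.95 - 0.9 * rel)
}

#' Plot an attention map on a 2D depiction
#'
#' Draws the molecule with a planar layout; atoms (or bond midpoints) are
#' shaded with the monotone ramp of [attention_colors()], darker meaning
#' higher attention.
#'
#' @param x a `cf_attention`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cf_attention <- function(x, ...) {
  mol <- parse_molecule(x$smiles)
  sdf <- .ob_sdf(mol$smiles)[[1]]
  ab <- ChemmineR::atomblock(sdf)
  heavy <- sub("_.*$", "", rownames(ab)) != "H"
  xy <- matrix(as.numeric(ab[heavy, 1:2, drop = FALSE]), ncol = 2)
  graphics::plot(xy, type = "n", axes = FALSE, xlab = "", ylab = "",
                 asp = 1, ...)
  for (b in seq_len(nrow(mol$bonds))) {
    graphics::segments(xy[mol$bonds$i[b], 1], xy[mol$bonds$i[b], 2],
                       xy[mol$bonds$j[b], 1], xy[mol$bonds$j[b], 2],
                       col = "grey60")
  }
  if (!is.null(x$atom_weights)) {
    graphics::points(xy, pch = 21, cex = 2.4,
                     bg = attention_colors(x$atom_weights))
    graphics::text(xy, labels = mol$elem, cex = 0.6)
  }
  if (!is.null(x$bond_weights) && length(x$bond_weights)) {
    mid <- (xy[x$bond_index_map[, 1], , drop = FALSE] +
            xy[x$bond_index_map[, 2], , drop = FALSE]) / 2
    graphics::points(mid, pch = 22, cex = 2,
                     bg = attention_colors(x$bond_weights))
  }
  invisible(x)
}
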