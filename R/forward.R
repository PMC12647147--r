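# Differentiable forward pass of the multi-scale encoder.
#
# Mirrors the reference operations in model.R on the autodiff tape.  One
# tape per molecule; minibatch gradients are the observation-weighted sum
# of per-molecule gradients, so molecules with all-missing labels
# contribute nothing.

# Precompute per-record featurization for the channels a config needs.
.featurize_record <- function(mol, config, fp_vec = NULL) {
  out <- list(n_heavy = mol$n)
  need_atom <- any(c("atom", "gcn") %in% config$channels)
  if (need_atom) {
    g <- build_atom_graph(mol)
    out$atom <- .prep_graph(g)
  }
  if ("bond" %in% config$channels) {
    g <- build_bond_graph(mol)
    out$bond <- .prep_graph(g)
    out$bond_index_map <- g$bond_index_map
  }
  if ("fp" %in% config$channels) out$fp <- fp_vec
  out
}

.prep_graph <- function(graph) {
  A <- graph$adjacency
  n <- nrow(A)
  ed <- which(A == 1, arr.ind = TRUE)
  agg <- matrix(0, n, nrow(ed))
  if (nrow(ed)) agg[cbind(ed[, 1], seq_len(nrow(ed)))] <- 1
  list(n = n,
       Ahat = if (n > 0) normalize_adjacency(A) else A,
       F = graph$features,
       X = graph$coords,
       edges = ed,
       agg = agg,
       deg = if (n > 0) pmax(rowSums(A), 1) else numeric(0))
}

.egnn_tape <- function(tape, params, prefix, Hn, Xn, gf, config) {
  h <- config$hidden_dim
  n <- gf$n
  ed <- gf$edges
  P <- function(s) ad_param(tape, params, paste0(prefix, s))
  if (nrow(ed) > 0) {
    i <- ed[, 1]; j <- ed[, 2]
    Xi <- ad_rows(tape, Xn, i); Xj <- ad_rows(tape, Xn, j)
    rel <- ad_sub(tape, Xj, Xi)
    relsq <- ad_mul(tape, rel, rel)
    d2 <- ad_mm(tape, relsq, ad_const(tape, matrix(1, 3, 1)))
    Hi <- ad_rows(tape, Hn, i); Hj <- ad_rows(tape, Hn, j)
    min_ <- ad_cbind(tape, list(Hi, Hj, d2))
    m <- ad_relu(tape, ad_add_vec(tape, ad_mm(tape, min_, P("e1_W")), P("e1_b")))
    m <- ad_relu(tape, ad_add_vec(tape, ad_mm(tape, m, P("e2_W")), P("e2_b")))
    aggc <- ad_const(tape, gf$agg)
    msum <- ad_mm(tape, aggc, m)
    w <- ad_mm(tape, m, P("x_W"))
    w3 <- ad_cbind(tape, list(w, w, w))
    wrel <- ad_mul(tape, w3, rel)
    dx <- ad_mm(tape, aggc, wrel)
    if (config$egnn_agg == "mean") {
      dx <- ad_mul(tape, dx, ad_const(tape, matrix(1 / gf$deg, n, 3)))
    }
    Xn <- ad_add(tape, Xn, dx)
  } else {
    msum <- ad_const(tape, matrix(0, n, h))
  }
  hin <- ad_cbind(tape, list(Hn, msum))
  up <- ad_relu(tape, ad_add_vec(tape, ad_mm(tape, hin, P("h1_W")), P("h1_b")))
  up <- ad_add_vec(tape, ad_mm(tape, up, P("h2_W")), P("h2_b"))
  list(H = ad_add(tape, Hn, up), X = Xn)
}

.attention_tape <- function(tape, params, prefix, H, config, training, drop_rng) {
  h <- config$hidden_dim
  heads <- config$attention_heads
  dk <- h / heads
  P <- function(s) ad_param(tape, params, paste0(prefix, s))
  Q <- ad_mm(tape, H, P("Wq")); K <- ad_mm(tape, H, P("Wk"))
  V <- ad_mm(tape, H, P("Wv"))
  outs <- vector("list", heads); wts <- vector("list", heads)
  for (hd in seq_len(heads)) {
    cols <- ((hd - 1) * dk + 1):(hd * dk)
    S <- ad_mm(tape, ad_cols(tape, Q, cols),
               ad_transpose(tape, ad_cols(tape, K, cols)))
    W <- ad_softmax_rows(tape, ad_smul(tape, S, 1 / sqrt(dk)))
    wts[[hd]] <- .val(tape, W)
    outs[[hd]] <- ad_mm(tape, W, ad_cols(tape, V, cols))
  }
  O <- ad_mm(tape, ad_cbind(tape, outs), P("Wo"))
  if (training && config$dropout > 0) {
    dims <- dim(.val(tape, O))
    mask <- matrix(stats::runif(prod(dims)) >= config$dropout, dims[1], dims[2])
    O <- ad_dropout(tape, O, mask, config$dropout)
  }
  R <- ad_add(tape, H, O)
  list(H = ad_layernorm(tape, R, P("g"), P("b")), weights = wts)
}

# full graph-channel encoder on the tape; returns CLS embedding node id
# and per-block attention weights
.encode_channel_tape <- function(tape, params, config, gf, prefix, training) {
  n <- gf$n
  H <- NULL
  if (n > 0) {
    H <- ad_const(tape, gf$F)
    Ahat <- ad_const(tape, gf$Ahat)
    for (l in seq_len(config$gcn_layers)) {
      W <- ad_param(tape, params, paste0(prefix, "_gcn", l, "_W"))
      H <- ad_relu(tape, ad_mm(tape, ad_mm(tape, Ahat, H), W))
    }
  }
  if (config$variant == "GCN") {
    return(list(emb = ad_colmeans(tape, H), attn = NULL))
  }
  cls <- ad_param(tape, params, paste0(prefix, "_cls"))
  H <- if (is.null(H)) cls else ad_rbind(tape, list(cls, H))
  X <- if (n > 0) ad_const(tape, gf$X) else NULL
  attn <- vector("list", config$encoder_blocks)
  for (k in seq_len(config$encoder_blocks)) {
    if (config$use_egnn && n > 0) {
      Hn <- ad_rows(tape, H, 2:(n + 1))
      upd <- .egnn_tape(tape, params, paste0(prefix, "_eg", k, "_"),
                        Hn, X, gf, config)
      X <- upd$X
      H <- ad_rbind(tape, list(ad_rows(tape, H, 1), upd$H))
    }
    at <- .attention_tape(tape, params, paste0(prefix, "_at", k, "_"),
                          H, config, training, NULL)
    H <- at$H
    attn[[k]] <- at$weights
  }
  list(emb = ad_rows(tape, H, 1), attn = attn)
}

# forward pass for one featurized record; returns tape, logit node id and
# attention weights per channel
.forward_one <- function(params, config, feat, training = FALSE) {
  tape <- .tape_new()
  embs <- list(); attn <- list()
  for (ch in config$channels) {
    if (ch %in% c("atom", "gcn")) {
      enc <- .encode_channel_tape(tape, params, config, feat$atom, "a", training)
      embs <- c(embs, enc$emb); attn$atom <- enc$attn
    } else if (ch == "bond") {
      enc <- .encode_channel_tape(tape, params, config, feat$bond, "b", training)
      embs <- c(embs, enc$emb); attn$bond <- enc$attn
    } else if (ch == "fp") {
      v <- ad_const(tape, matrix(feat$fp, 1))
      l1 <- ad_relu(tape, ad_add_vec(tape, ad_mm(tape, v,
             ad_param(tape, params, "fp_W1")), ad_param(tape, params, "fp_b1")))
      if (training && config$dropout > 0) {
        mask <- matrix(stats::runif(config$hidden_dim) >= config$dropout, 1)
        l1 <- ad_dropout(tape, l1, mask, config$dropout)
      }
      emb <- ad_relu(tape, ad_add_vec(tape, ad_mm(tape, l1,
             ad_param(tape, params, "fp_W2")), ad_param(tape, params, "fp_b2")))
      embs <- c(embs, emb); attn$fp <- NULL
    }
  }
  cat_emb <- if (length(embs) > 1) ad_cbind(tape, embs) else embs[[1]]
  h1 <- ad_relu(tape, ad_add_vec(tape, ad_mm(tape, cat_emb,
         ad_param(tape, params, "hd_W1")), ad_param(tape, params, "hd_b1")))
  if (training && config$dropout > 0) {
    mask <- matrix(stats::runif(config$hidden_dim) >= config$dropout, 1)
    h1 <- ad_dropout(tape, h1, mask, config$dropout)
  }
  logits <- ad_add_vec(tape, ad_mm(tape, h1,
             ad_param(tape, params, "hd_W2")), ad_param(tape, params, "hd_b2"))
  list(tape = tape, logits = logits, attn = attn)
}

# observation-weighted minibatch loss and parameter gradients
.batch_grad <- function(params, config, feats, targets, training = TRUE) {
  nobs_r <- rowSums(!is.na(targets))
  nobs_total <- max(sum(nobs_r), 1)
  grads <- list(); total_loss <- 0
  for (r in seq_len(nrow(targets))) {
    w_r <- nobs_r[r] / nobs_total
    if (w_r == 0) next
    fw <- .forward_one(params, config, feats[[r]], training = training)
    y <- matrix(targets[r, ], 1)
    mask <- matrix(as.numeric(!is.na(y)), 1)
    y[is.na(y)] <- 0
    loss <- if (config$task_type == "classification") {
      ad_bce_logits(fw$tape, fw$logits, y, mask)
    } else {
      ad_mse(fw$tape, fw$logits, y, mask)
    }
    total_loss <- total_loss + w_r * .val(fw$tape, loss)[1, 1]
    g <- ad_backward(fw$tape, loss)
    for (nm in names(g)) {
      if (is.null(g[[nm]])) next
      gw <- g[[nm]] * w_r
      grads[[nm]] <- if (is.null(grads[[nm]])) gw else grads[[nm]] + gw
    }
  }
  list(grads = grads, loss = total_loss)
}

# plain prediction (logit scale) for featurized records
.predict_logits <- function(params, config, feats) {
  out <- matrix(NA_real_, length(feats), config$n_tasks)
  for (r in seq_along(feats)) {
    if (is.null(feats[[r]])) next
    fw <- .forward_one(params, config, feats[[r]], training = FALSE)
    out[r, ] <- .val(fw$tape, fw$logits)
  }
  out
}

#' Encode a single graph into its CLS embedding
#'
#' Runs the graph-channel encoder (GCN stack, CLS prepend, encoder blocks)
#' on one atom or bond graph and returns the graph-representation embedding
#' together with the final block's CLS attention row.
#'
#' @param graph a `cf_atom_graph` or `cf_bond_graph`.
#' @param config a `cf_config` (its atom/bond channel settings are used).
#' @param params named parameter list from a fitted model; if `NULL`, fresh
#'   parameters are initialized from `seed`.
#' @param channel `"atom"` or `"bond"`; selects which channel's parameters
#'   encode the graph.
#' @param seed seed for fresh-parameter initialization.
#' @return list with `embedding` (numeric hidden vector) and `cls_attention`
#'   (per-head list of final-block CLS rows, or `NULL` for the GCN variant).
#' @export
encode_graph <- function(graph, config, params = NULL,
                         channel = c("atom", "bond"), seed = 1L) {
  channel <- match.arg(channel)
  if (inherits(graph, "cf_atom_graph") && nrow(graph$adjacency) == 0) {
    stop("empty atom graph cannot be encoded")
  }
  if (is.null(params)) {
    set.seed(seed)
    dims <- list(atom_in = ncol(graph$features),
                 bond_in = ncol(graph$features), fp_in = 8L)
    params <- .init_params(config, dims)
  }
  gf <- .prep_graph(graph)
  prefix <- if (channel == "atom") "a" else "b"
  tape <- .tape_new()
  enc <- .encode_channel_tape(tape, params, config, gf, prefix,
                              training = FALSE)
  cls_attn <- NULL
  if (!is.null(enc$attn)) {
    last <- enc$attn[[config$encoder_blocks]]
    cls_attn <- lapply(last, function(w) w[1, ])
  }
  list(embedding = as.numeric(.val(tape, enc$emb)), cls_attention = cls_attn)
}
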