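# Encoder building blocks and model configuration.
#
# The exported functions here are the reference (plain matrix) forms of the
# encoder operations; training runs the same math on the autodiff tape
# (forward.R).  Tests cross-check the two paths against each other and
# against brute-force oracles.

#' Symmetric normalization of a graph adjacency matrix
#'
#' Adds self-loops and scales symmetrically:
#' `D^{-1/2} (A + I) D^{-1/2}` with `D` the degree matrix of `A + I`.
#' For a degree-regular graph every row sums to 1.
#'
#' @param A square binary adjacency matrix (symmetric, zero diagonal).
#' @return the normalized real matrix, same shape.
#' @export
#' @examples
#' normalize_adjacency(matrix(c(0, 1, 1, 0), 2))
normalize_adjacency <- function(A) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stop("adjacency must be a square matrix")
  }
  At <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(At))
  At * outer(dinv, dinv)
}

#' One graph-convolution layer
#'
#' `H' = activation(A_hat %*% H %*% W)` with no bias; the default
#' activation is ReLU.
#'
#' @param H node-feature matrix (n x f).
#' @param A_hat normalized adjacency from [normalize_adjacency()].
#' @param W weight matrix (f x h).
#' @param activation activation function (identity for raw output).
#' @return matrix n x h.
#' @export
gcn_layer <- function(H, A_hat, W, activation = function(x) pmax(x, 0)) {
  if (nrow(H) != nrow(A_hat)) stop("H rows must match A_hat rows")
  activation(A_hat %*% H %*% W)
}

.relu <- function(x) pmax(x, 0)

#' Equivariant graph update of node features and coordinates
#'
#' Messages `m_ij = phi_e(h_i, h_j, ||x_i - x_j||^2)` over graph
#' neighbours; features update through `phi_h(h_i, sum_j m_ij)` with a
#' residual connection; coordinates move along weighted relative positions,
#' `x_i' = x_i + (1/|N(i)|) * sum_j w_ij (x_j - x_i)` with the scalar
#' `w_ij = phi_x(m_ij)`.  Features only ever see squared distances, so the
#' update commutes with rigid rotations and translations; isolated nodes
#' keep their position.
#'
#' @param state list with `H` (n x h node features) and `X` (n x 3
#'   coordinates).  The CLS row is not part of this state.
#' @param adjacency binary n x n adjacency.
#' @param layer named list of parameter matrices: `e1_W`, `e1_b`, `e2_W`,
#'   `e2_b` (message MLP), `h1_W`, `h1_b`, `h2_W`, `h2_b` (feature MLP),
#'   `x_W` (h x 1 coordinate weight head).
#' @param agg `"mean"` (degree-normalized, default) or `"sum"` coordinate
#'   aggregation.
#' @return updated `list(H, X)`.
#' @export
egnn_update <- function(state, adjacency, layer, agg = c("mean", "sum")) {
  agg <- match.arg(agg)
  H <- state$H; X <- state$X
  n <- nrow(H)
  if (n == 0) return(state)
  stopifnot(nrow(adjacency) == n)
  ed <- which(adjacency == 1, arr.ind = TRUE)   # directed edges (i <- j)
  if (nrow(ed) == 0) {
    msum <- matrix(0, n, ncol(layer$e2_W))
  } else {
    i <- ed[, 1]; j <- ed[, 2]
    rel <- X[j, , drop = FALSE] - X[i, , drop = FALSE]
    d2 <- matrix(rowSums(rel^2), ncol = 1)
    min_ <- cbind(H[i, , drop = FALSE], H[j, , drop = FALSE], d2)
    m <- .relu(sweep(min_ %*% layer$e1_W, 2, as.numeric(layer$e1_b), "+"))
    m <- .relu(sweep(m %*% layer$e2_W, 2, as.numeric(layer$e2_b), "+"))
    agg_m <- matrix(0, n, nrow(ed))
    agg_m[cbind(i, seq_len(nrow(ed)))] <- 1
    msum <- agg_m %*% m
    w <- m %*% layer$x_W
    dx <- agg_m %*% (matrix(as.numeric(w), nrow(ed), 3) * rel)
    deg <- rowSums(adjacency)
    if (agg == "mean") dx <- dx / pmax(deg, 1)
    X <- X + dx
  }
  hin <- cbind(H, msum)
  up <- .relu(sweep(hin %*% layer$h1_W, 2, as.numeric(layer$h1_b), "+"))
  up <- sweep(up %*% layer$h2_W, 2, as.numeric(layer$h2_b), "+")
  list(H = H + up, X = X)
}

#' Multi-head self-attention encoder layer
#'
#' Standard scaled dot-product self-attention over all node rows (including
#' the CLS row), with per-head weights `softmax(Q K^T / sqrt(d_k))`, head
#' concatenation, output projection, residual connection and row-wise layer
#' normalization.  Coordinates are untouched by attention.
#'
#' @param state list with `H` ((n+1) x h features, CLS row first).
#' @param layer named list with `Wq`, `Wk`, `Wv`, `Wo` (h x h) and
#'   layer-norm `g`, `b` (1 x h).
#' @param heads number of attention heads; must divide `ncol(H)`.
#' @return `list(H, weights)` where `weights` is a list of per-head
#'   attention matrices (rows sum to 1).
#' @export
attention_layer <- function(state, layer, heads = 4) {
  H <- state$H
  h <- ncol(H)
  if (h %% heads != 0) stop("heads must divide the hidden dimension")
  dk <- h / heads
  Q <- H %*% layer$Wq; K <- H %*% layer$Wk; V <- H %*% layer$Wv
  outs <- vector("list", heads); wts <- vector("list", heads)
  for (hd in seq_len(heads)) {
    cols <- ((hd - 1) * dk + 1):(hd * dk)
    S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dk)
    E <- exp(S - apply(S, 1, max))
    W <- E / rowSums(E)
    wts[[hd]] <- W
    outs[[hd]] <- W %*% V[, cols, drop = FALSE]
  }
  O <- do.call(cbind, outs) %*% layer$Wo
  R <- H + O
  mu <- rowMeans(R); xc <- R - mu
  xhat <- xc / sqrt(rowMeans(xc^2) + 1e-5)
  Hn <- sweep(sweep(xhat, 2, as.numeric(layer$g), "*"), 2,
              as.numeric(layer$b), "+")
  state$H <- Hn
  state$weights <- wts
  state
}

.VARIANTS <- c("GCN", "Atom", "AtomBond", "FP", "AtomBondFP", "Full", "Mini")

#' Model configuration
#'
#' @param variant architecture variant; see [make_variant()].
#' @param hidden_dim hidden width of every channel (default 256).
#' @param gcn_layers number of graph-convolution layers preceding the
#'   encoder blocks (default 2); they replace positional encoding.
#' @param encoder_blocks number of encoder blocks (default 3).
#' @param attention_heads number of attention heads (default 4); must
#'   divide `hidden_dim`.
#' @param dropout dropout fraction applied during training (default 0.1).
#' @param fingerprint_families fingerprint panel for the FP channel;
#'   defaults to [default_families()] of the task type.
#' @param task_type `"classification"` or `"regression"`.
#' @param n_tasks number of prediction targets.
#' @param egnn_agg `"mean"` (default) or `"sum"` coordinate aggregation.
#' @return an object of class `cf_config`.
#' @export
model_config <- function(variant = "Full", hidden_dim = 256L,
                         gcn_layers = 2L, encoder_blocks = 3L,
                         attention_heads = 4L, dropout = 0.1,
                         fingerprint_families = NULL,
                         task_type = c("classification", "regression"),
                         n_tasks = 1L, egnn_agg = c("mean", "sum")) {
  task_type <- match.arg(task_type)
  egnn_agg <- match.arg(egnn_agg)
  if (!variant %in% .VARIANTS) {
    stop("unknown variant '", variant, "'; one of: ",
         paste(.VARIANTS, collapse = ", "))
  }
  if (hidden_dim %% attention_heads != 0) {
    stop("attention_heads must divide hidden_dim")
  }
  channels <- switch(variant,
    GCN = "gcn",
    Atom = "atom",
    AtomBond = c("atom", "bond"),
    FP = "fp",
    AtomBondFP = c("atom", "bond", "fp"),
    Full = c("atom", "bond", "fp"),
    Mini = c("atom", "bond", "fp"))
  if (is.null(fingerprint_families)) {
    fingerprint_families <- default_families(task_type)
  }
  structure(list(variant = variant, hidden_dim = as.integer(hidden_dim),
                 gcn_layers = as.integer(gcn_layers),
                 encoder_blocks = as.integer(encoder_blocks),
                 attention_heads = as.integer(attention_heads),
                 dropout = dropout,
                 fingerprint_families = fingerprint_families,
                 task_type = task_type, n_tasks = as.integer(n_tasks),
                 egnn_agg = egnn_agg,
                 channels = channels,
                 use_egnn = identical(variant, "Full")),
            class = "cf_config")
}

#' Build the configuration of a named architecture variant
#'
#' The ablation family: `GCN` (graph-convolution baseline with pooled
#' readout), `Atom` (atom-graph transformer), `AtomBond` (both graph
#' channels), `FP` (fingerprint feed-forward network only), `AtomBondFP`
#' (both graphs + fingerprints, no equivariant update), `Full` (everything
#' including the equivariant update), and `Mini` (`Full` without the
#' equivariant update, trading 3D sensitivity for speed).
#'
#' @param name variant name.
#' @param ... further arguments passed to [model_config()].
#' @return a `cf_config`.
#' @export
make_variant <- function(name, ...) {
  model_config(variant = name, ...)
}

#' @export
print.cf_config <- function(x, ...) {
  cat("<cf_config ", x$variant, ": hidden ", x$hidden_dim, ", ",
      x$gcn_layers, " GCN layers, ", x$encoder_blocks, " blocks x ",
      x$attention_heads, " heads",
      if (x$use_egnn) ", equivariant update" else "",
      "; channels: ", paste(x$channels, collapse = "+"),
      "; task: ", x$task_type, " (", x$n_tasks, ")>\n", sep = "")
  invisible(x)
}

# Initialize all learnable parameters for a configuration.
# dims: list(atom_in, bond_in, fp_in)
.init_params <- function(config, dims) {
  h <- config$hidden_dim
  p <- list()
  add_graph_channel <- function(p, prefix, fin) {
    for (l in seq_len(config$gcn_layers)) {
      p[[paste0(prefix, "_gcn", l, "_W")]] <-
        .glorot(if (l == 1) fin else h, h)
    }
    if (config$variant != "GCN") {
      p[[paste0(prefix, "_cls")]] <- matrix(stats::rnorm(h, sd = 0.02), 1)
      for (k in seq_len(config$encoder_blocks)) {
        if (config$use_egnn) {
          p[[paste0(prefix, "_eg", k, "_e1_W")]] <- .glorot(2 * h + 1, h)
          p[[paste0(prefix, "_eg", k, "_e1_b")]] <- matrix(0, 1, h)
          p[[paste0(prefix, "_eg", k, "_e2_W")]] <- .glorot(h, h)
          p[[paste0(prefix, "_eg", k, "_e2_b")]] <- matrix(0, 1, h)
          p[[paste0(prefix, "_eg", k, "_h1_W")]] <- .glorot(2 * h, h)
          p[[paste0(prefix, "_eg", k, "_h1_b")]] <- matrix(0, 1, h)
          p[[paste0(prefix, "_eg", k, "_h2_W")]] <- .glorot(h, h)
          p[[paste0(prefix, "_eg", k, "_h2_b")]] <- matrix(0, 1, h)
          p[[paste0(prefix, "_eg", k, "_x_W")]] <- .glorot(h, 1) * 0.1
        }
        p[[paste0(prefix, "_at", k, "_Wq")]] <- .glorot(h, h)
        p[[paste0(prefix, "_at", k, "_Wk")]] <- .glorot(h, h)
        p[[paste0(prefix, "_at", k, "_Wv")]] <- .glorot(h, h)
        p[[paste0(prefix, "_at", k, "_Wo")]] <- .glorot(h, h)
        p[[paste0(prefix, "_at", k, "_g")]] <- matrix(1, 1, h)
        p[[paste0(prefix, "_at", k, "_b")]] <- matrix(0, 1, h)
      }
    }
    p
  }
  if (any(c("atom", "gcn") %in% config$channels)) {
    p <- add_graph_channel(p, "a", dims$atom_in)
  }
  if ("bond" %in% config$channels) p <- add_graph_channel(p, "b", dims$bond_in)
  if ("fp" %in% config$channels) {
    p$fp_W1 <- .glorot(dims$fp_in, h)
    p$fp_b1 <- matrix(0, 1, h)
    p$fp_W2 <- .glorot(h, h)
    p$fp_b2 <- matrix(0, 1, h)
  }
  nch <- length(config$channels)
  p$hd_W1 <- .glorot(nch * h, h)
  p$hd_b1 <- matrix(0, 1, h)
  p$hd_W2 <- .glorot(h, config$n_tasks)
  p$hd_b2 <- matrix(0, 1, config$n_tasks)
  p
}

# subset the named parameter list for one encoder layer, stripping prefixes
.layer_params <- function(params, prefix) {
  sel <- grep(paste0("^", prefix), names(params), value = TRUE)
  out <- params[sel]
  names(out) <- sub(paste0("^", prefix), "", sel)
  out
}
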