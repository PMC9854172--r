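# The graph message-passing encoder: node/edge updates on the k-NN residue
# graph, projection of final edge embeddings into a Potts model, and the
# matching analytic backward pass (gradients are verified against finite
# differences in the test suite).

LN_EPS <- 1e-5

#' Encoder configuration
#'
#' @param hidden_dim embedding width (model dimensionality).
#' @param n_layers number of message-passing layers.
#' @param dropout dropout rate applied to messages in training mode.
#' @param k k-NN neighbor count used at featurization.
#' @param seed initialization seed.
#' @return object of class `EncoderConfig`.
#' @export
encoder_config <- function(hidden_dim = 128L, n_layers = 3L, dropout = 0.1,
                           k = 30L, seed = 1L) {
  if (hidden_dim < 1) stop("hidden_dim must be >= 1")
  if (n_layers < 1) stop("n_layers must be >= 1")
  stopifnot(dropout >= 0, dropout < 1, k >= 1)
  x <- list(hidden_dim = as.integer(hidden_dim), n_layers = as.integer(n_layers),
            dropout = dropout, k = as.integer(k), seed = as.integer(seed))
  class(x) <- "EncoderConfig"
  x
}

# uniform fan-in init
.winit <- function(nin, nout) {
  matrix(runif(nin * nout, -1, 1) / sqrt(nin), nin, nout)
}

#' Initialize encoder parameters
#'
#' Weights drawn uniform with fan-in scaling, biases zero, layer-norm gains
#' one; deterministic given `config$seed`.
#'
#' @param config an [encoder_config()].
#' @return named list of parameter arrays (class `EncoderParams`) with the
#'   config attached as attribute `config`. Names starting with `out.` form
#'   the output projection; everything else is the trunk (the partition used
#'   by [finetune()]).
#' @export
init_encoder <- function(config) {
  h <- config$hidden_dim
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  p <- list()
  p[["embed.Wn"]] <- .winit(D_NODE, h); p[["embed.bn"]] <- numeric(h)
  p[["embed.We"]] <- .winit(D_EDGE, h); p[["embed.be"]] <- numeric(h)
  p[["embed.ln_n.g"]] <- rep(1, h); p[["embed.ln_n.b"]] <- numeric(h)
  p[["embed.ln_e.g"]] <- rep(1, h); p[["embed.ln_e.b"]] <- numeric(h)
  for (l in seq_len(config$n_layers)) {
    for (blk in c("edge", "node")) {
      p[[sprintf("layer%d.%s.W1", l, blk)]] <- .winit(3 * h, h)
      p[[sprintf("layer%d.%s.b1", l, blk)]] <- numeric(h)
      p[[sprintf("layer%d.%s.W2", l, blk)]] <- .winit(h, h)
      p[[sprintf("layer%d.%s.b2", l, blk)]] <- numeric(h)
      p[[sprintf("layer%d.%s.W3", l, blk)]] <- .winit(h, h)
      p[[sprintf("layer%d.%s.b3", l, blk)]] <- numeric(h)
    }
    p[[sprintf("layer%d.ln_e.g", l)]] <- rep(1, h)
    p[[sprintf("layer%d.ln_e.b", l)]] <- numeric(h)
    p[[sprintf("layer%d.ln_n.g", l)]] <- rep(1, h)
    p[[sprintf("layer%d.ln_n.b", l)]] <- numeric(h)
  }
  # zero-initialized output head: the untrained encoder emits the uniform
  # (all-zero) Potts model, so training starts from the exact ncpl baseline
  # log(400) with no initialization noise in the energy tables
  p[["out.W"]] <- matrix(0, h, 400)
  p[["out.b"]] <- numeric(400)
  attr(p, "config") <- config
  class(p) <- "EncoderParams"
  p
}

#' Names of the trunk (frozen during fine-tuning) parameters
#' @param params an `EncoderParams`.
#' @return character vector.
#' @export
trunk_param_names <- function(params) {
  nm <- names(params)
  nm[!startsWith(nm, "out.")]
}

# layer norm forward: returns list(y, cache)
.ln_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + LN_EPS)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2, g, "*"), 2, b, "+")
  list(y = y, xhat = xhat, inv = inv)
}

.ln_bwd <- function(dy, cache, g) {
  dxhat <- sweep(dy, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dx <- (dxhat - m1 - cache$xhat * m2) * cache$inv
  list(dx = dx, dg = colSums(dy * cache$xhat), db = colSums(dy))
}

# 3-linear MLP with ReLU after the first two layers
.mlp_fwd <- function(x, W1, b1, W2, b2, W3, b3) {
  z1 <- sweep(x %*% W1, 2, b1, "+"); a1 <- pmax(z1, 0)
  z2 <- sweep(a1 %*% W2, 2, b2, "+"); a2 <- pmax(z2, 0)
  y <- sweep(a2 %*% W3, 2, b3, "+")
  list(y = y, x = x, z1 = z1, a1 = a1, z2 = z2, a2 = a2)
}

.mlp_bwd <- function(dy, cache, W1, W2, W3) {
  gW3 <- t(cache$a2) %*% dy; gb3 <- colSums(dy)
  da2 <- dy %*% t(W3)
  dz2 <- da2 * (cache$z2 > 0)
  gW2 <- t(cache$a1) %*% dz2; gb2 <- colSums(dz2)
  da1 <- dz2 %*% t(W2)
  dz1 <- da1 * (cache$z1 > 0)
  gW1 <- t(cache$x) %*% dz1; gb1 <- colSums(dz1)
  list(dx = dz1 %*% t(W1), gW1 = gW1, gb1 = gb1, gW2 = gW2, gb2 = gb2,
       gW3 = gW3, gb3 = gb3)
}

# scatter-add row gradients by integer group into an L x h matrix
.scatter_rows <- function(gx, group, L) {
  acc <- rowsum(gx, group)
  out <- matrix(0, L, ncol(gx))
  out[as.integer(rownames(acc)), ] <- acc
  out
}

# flattened directed-edge indexing: row r of the E x d edge matrix has
# src = ((r - 1) %% L) + 1 and dst = neighbors[src, (r - 1) %/% L + 1]
.edge_endpoints <- function(graph) {
  list(src = rep(seq_len(graph$L), graph$k), dst = as.vector(graph$neighbors))
}

#' Run the message-passing encoder
#'
#' Per layer, each edge embedding is updated from its own state and the two
#' endpoint node states; each node embedding is updated from the mean of
#' messages over its incident (out-)edges, self-edge included. Residual
#' connections and layer normalization follow each update; dropout is
#' active only in training mode.
#'
#' @param params an [init_encoder()] `EncoderParams`.
#' @param graph a featurized `ResidueGraph` (see [featurize()]).
#' @param training logical; enables dropout (uses the current RNG stream).
#' @param keep_cache logical; retain intermediates for [encode_backward()].
#' @return list with `node_embeddings` (`L x h`), `edge_embeddings`
#'   (`(L*k) x h`, rows in column-major (residue, neighbor-slot) order) and,
#'   if requested, `cache`.
#' @export
encode <- function(params, graph, training = FALSE, keep_cache = FALSE) {
  cfg <- attr(params, "config")
  h <- cfg$hidden_dim
  L <- graph$L; k <- graph$k
  ep <- .edge_endpoints(graph)
  src <- ep$src; dst <- ep$dst
  X <- graph$node_features
  Fe <- matrix(graph$edge_features, L * k, dim(graph$edge_features)[3])
  drop_rate <- if (training) cfg$dropout else 0

  lnn0 <- .ln_fwd(sweep(X %*% params[["embed.Wn"]], 2, params[["embed.bn"]], "+"),
                  params[["embed.ln_n.g"]], params[["embed.ln_n.b"]])
  lne0 <- .ln_fwd(sweep(Fe %*% params[["embed.We"]], 2, params[["embed.be"]], "+"),
                  params[["embed.ln_e.g"]], params[["embed.ln_e.b"]])
  H <- lnn0$y
  E <- lne0$y
  cache <- list(X = X, Fe = Fe, lnn0 = lnn0, lne0 = lne0, layers = vector("list", cfg$n_layers))
  for (l in seq_len(cfg$n_layers)) {
    lc <- list(H_in = H, E_in = E)
    U <- cbind(H[src, , drop = FALSE], H[dst, , drop = FALSE], E)
    me <- .mlp_fwd(U, params[[sprintf("layer%d.edge.W1", l)]],
                   params[[sprintf("layer%d.edge.b1", l)]],
                   params[[sprintf("layer%d.edge.W2", l)]],
                   params[[sprintf("layer%d.edge.b2", l)]],
                   params[[sprintf("layer%d.edge.W3", l)]],
                   params[[sprintf("layer%d.edge.b3", l)]])
    med <- me$y
    if (drop_rate > 0) {
      lc$mask_e <- (matrix(runif(length(med)), nrow(med)) >= drop_rate) / (1 - drop_rate)
      med <- med * lc$mask_e
    }
    lne <- .ln_fwd(E + med, params[[sprintf("layer%d.ln_e.g", l)]],
                   params[[sprintf("layer%d.ln_e.b", l)]])
    E <- lne$y
    V <- cbind(H[src, , drop = FALSE], H[dst, , drop = FALSE], E)
    mn <- .mlp_fwd(V, params[[sprintf("layer%d.node.W1", l)]],
                   params[[sprintf("layer%d.node.b1", l)]],
                   params[[sprintf("layer%d.node.W2", l)]],
                   params[[sprintf("layer%d.node.b2", l)]],
                   params[[sprintf("layer%d.node.W3", l)]],
                   params[[sprintf("layer%d.node.b3", l)]])
    mnd <- mn$y
    if (drop_rate > 0) {
      lc$mask_n <- (matrix(runif(length(mnd)), nrow(mnd)) >= drop_rate) / (1 - drop_rate)
      mnd <- mnd * lc$mask_n
    }
    agg <- rowsum(mnd, src) / k
    lnn <- .ln_fwd(H + agg, params[[sprintf("layer%d.ln_n.g", l)]],
                   params[[sprintf("layer%d.ln_n.b", l)]])
    H <- lnn$y
    if (!all(is.finite(H)) || !all(is.finite(E))) {
      stop("non-finite embeddings at layer ", l)
    }
    lc$me <- me; lc$mn <- mn; lc$lne <- lne; lc$lnn <- lnn
    cache$layers[[l]] <- lc
  }
  out <- list(node_embeddings = H, edge_embeddings = E)
  if (keep_cache) out$cache <- cache
  out
}

#' Backward pass of [encode()]
#'
#' @param params `EncoderParams` used in the forward pass.
#' @param graph the same featurized graph.
#' @param cache cache returned by `encode(..., keep_cache = TRUE)`.
#' @param gE gradient w.r.t. the final edge embeddings (`(L*k) x h`).
#' @param gH optional gradient w.r.t. the final node embeddings.
#' @return named list of parameter gradients (same shapes as `params`).
#' @export
encode_backward <- function(params, graph, cache, gE, gH = NULL) {
  cfg <- attr(params, "config")
  h <- cfg$hidden_dim
  L <- graph$L; k <- graph$k
  ep <- .edge_endpoints(graph)
  src <- ep$src; dst <- ep$dst
  if (is.null(gH)) gH <- matrix(0, L, h)
  grads <- list()
  for (l in rev(seq_len(cfg$n_layers))) {
    lc <- cache$layers[[l]]
    # node-side LN
    bn <- .ln_bwd(gH, lc$lnn, params[[sprintf("layer%d.ln_n.g", l)]])
    grads[[sprintf("layer%d.ln_n.g", l)]] <- bn$dg
    grads[[sprintf("layer%d.ln_n.b", l)]] <- bn$db
    gH <- bn$dx                      # gradient on H_in via residual
    gmnd <- bn$dx[src, , drop = FALSE] / k
    if (!is.null(lc$mask_n)) gmnd <- gmnd * lc$mask_n
    bm <- .mlp_bwd(gmnd, lc$mn, params[[sprintf("layer%d.node.W1", l)]],
                   params[[sprintf("layer%d.node.W2", l)]],
                   params[[sprintf("layer%d.node.W3", l)]])
    grads[[sprintf("layer%d.node.W1", l)]] <- bm$gW1
    grads[[sprintf("layer%d.node.b1", l)]] <- bm$gb1
    grads[[sprintf("layer%d.node.W2", l)]] <- bm$gW2
    grads[[sprintf("layer%d.node.b2", l)]] <- bm$gb2
    grads[[sprintf("layer%d.node.W3", l)]] <- bm$gW3
    grads[[sprintf("layer%d.node.b3", l)]] <- bm$gb3
    gH <- gH + .scatter_rows(bm$dx[, 1:h, drop = FALSE], src, L) +
      .scatter_rows(bm$dx[, (h + 1):(2 * h), drop = FALSE], dst, L)
    gE <- gE + bm$dx[, (2 * h + 1):(3 * h), drop = FALSE]
    # edge-side LN
    be <- .ln_bwd(gE, lc$lne, params[[sprintf("layer%d.ln_e.g", l)]])
    grads[[sprintf("layer%d.ln_e.g", l)]] <- be$dg
    grads[[sprintf("layer%d.ln_e.b", l)]] <- be$db
    gE <- be$dx                      # residual into E_in
    gmed <- be$dx
    if (!is.null(lc$mask_e)) gmed <- gmed * lc$mask_e
    bme <- .mlp_bwd(gmed, lc$me, params[[sprintf("layer%d.edge.W1", l)]],
                    params[[sprintf("layer%d.edge.W2", l)]],
                    params[[sprintf("layer%d.edge.W3", l)]])
    grads[[sprintf("layer%d.edge.W1", l)]] <- bme$gW1
    grads[[sprintf("layer%d.edge.b1", l)]] <- bme$gb1
    grads[[sprintf("layer%d.edge.W2", l)]] <- bme$gW2
    grads[[sprintf("layer%d.edge.b2", l)]] <- bme$gb2
    grads[[sprintf("layer%d.edge.W3", l)]] <- bme$gW3
    grads[[sprintf("layer%d.edge.b3", l)]] <- bme$gb3
    gH <- gH + .scatter_rows(bme$dx[, 1:h, drop = FALSE], src, L) +
      .scatter_rows(bme$dx[, (h + 1):(2 * h), drop = FALSE], dst, L)
    gE <- gE + bme$dx[, (2 * h + 1):(3 * h), drop = FALSE]
  }
  bn0 <- .ln_bwd(gH, cache$lnn0, params[["embed.ln_n.g"]])
  grads[["embed.ln_n.g"]] <- bn0$dg
  grads[["embed.ln_n.b"]] <- bn0$db
  grads[["embed.Wn"]] <- t(cache$X) %*% bn0$dx
  grads[["embed.bn"]] <- colSums(bn0$dx)
  be0 <- .ln_bwd(gE, cache$lne0, params[["embed.ln_e.g"]])
  grads[["embed.ln_e.g"]] <- be0$dg
  grads[["embed.ln_e.b"]] <- be0$db
  grads[["embed.We"]] <- t(cache$Fe) %*% be0$dx
  grads[["embed.be"]] <- colSums(be0$dx)
  grads
}

# directed-edge row lookup: .edge_row(graph)[i + (j-1)*L] = flattened row of
# edge i -> j, or 0 if absent
.edge_row <- function(graph) {
  L <- graph$L
  ep <- .edge_endpoints(graph)
  eid <- integer(L * L)
  eid[ep$src + (ep$dst - 1L) * L] <- seq_along(ep$src)
  eid
}

#' Project edge embeddings into a PottsModel
#'
#' Each directed edge (i -> j) is projected to a 20x20 matrix of pair
#' energies (rows: letter at i, columns: letter at j). Duplicate
#' bidirectional matrices are averaged, `P_ij = (M_ij + t(M_ji)) / 2`; an
#' edge present in one direction only passes through as-is. The self-edge
#' matrix contributes its diagonal as the residue's self energies; its
#' off-diagonal entries are discarded.
#'
#' @param params `EncoderParams` (uses `out.W`, `out.b`).
#' @param graph the featurized graph.
#' @param edge_embeddings `(L*k) x h` matrix from [encode()].
#' @return a `PottsModel`.
#' @export
project_potts <- function(params, graph, edge_embeddings) {
  L <- graph$L
  M <- sweep(edge_embeddings %*% params[["out.W"]], 2, params[["out.b"]], "+")
  eid <- .edge_row(graph)
  self <- matrix(0, L, 20)
  diag_idx <- seq(1, 400, by = 21)
  for (i in seq_len(L)) {
    r <- eid[i + (i - 1L) * L]
    if (r == 0L) stop("missing self-edge for residue ", i)
    self[i, ] <- M[r, diag_idx]
  }
  ep <- .edge_endpoints(graph)
  und <- unique(cbind(pmin(ep$src, ep$dst), pmax(ep$src, ep$dst)))
  und <- und[und[, 1] != und[, 2], , drop = FALSE]
  np <- nrow(und)
  mats <- array(0, c(np, 20, 20))
  for (p in seq_len(np)) {
    i <- und[p, 1]; j <- und[p, 2]
    r1 <- eid[i + (j - 1L) * L]
    r2 <- eid[j + (i - 1L) * L]
    if (r1 > 0L && r2 > 0L) {
      mats[p, , ] <- (matrix(M[r1, ], 20, 20) + t(matrix(M[r2, ], 20, 20))) / 2
    } else if (r1 > 0L) {
      mats[p, , ] <- matrix(M[r1, ], 20, 20)
    } else {
      mats[p, , ] <- t(matrix(M[r2, ], 20, 20))
    }
  }
  potts_new(self, und[, 1], und[, 2], mats)
}

#' Backward pass of [project_potts()]
#'
#' @param params,graph,edge_embeddings as in the forward call.
#' @param g_self gradient w.r.t. the self-energy table (`L x 20`).
#' @param g_pairs gradient w.r.t. the canonical pair tables
#'   (`n_pairs x 20 x 20`, same pair order as the projected model).
#' @return list with `g_edge` (`(L*k) x h`), `g_out_W`, `g_out_b`.
#' @export
project_potts_backward <- function(params, graph, edge_embeddings, g_self, g_pairs) {
  L <- graph$L
  eid <- .edge_row(graph)
  Erows <- nrow(edge_embeddings)
  gM <- matrix(0, Erows, 400)
  diag_idx <- seq(1, 400, by = 21)
  for (i in seq_len(L)) {
    r <- eid[i + (i - 1L) * L]
    gM[r, diag_idx] <- gM[r, diag_idx] + g_self[i, ]
  }
  ep <- .edge_endpoints(graph)
  und <- unique(cbind(pmin(ep$src, ep$dst), pmax(ep$src, ep$dst)))
  und <- und[und[, 1] != und[, 2], , drop = FALSE]
  for (p in seq_len(nrow(und))) {
    i <- und[p, 1]; j <- und[p, 2]
    gP <- g_pairs[p, , ]
    r1 <- eid[i + (j - 1L) * L]
    r2 <- eid[j + (i - 1L) * L]
    if (r1 > 0L && r2 > 0L) {
      gM[r1, ] <- gM[r1, ] + as.vector(gP) / 2
      gM[r2, ] <- gM[r2, ] + as.vector(t(gP)) / 2
    } else if (r1 > 0L) {
      gM[r1, ] <- gM[r1, ] + as.vector(gP)
    } else {
      gM[r2, ] <- gM[r2, ] + as.vector(t(gP))
    }
  }
  list(g_edge = gM %*% t(params[["out.W"]]),
       g_out_W = t(edge_embeddings) %*% gM,
       g_out_b = colSums(gM))
}

#' Structure to Potts model (full forward pipeline)
#'
#' featurize -> encode (eval mode) -> project; deterministic for fixed
#' parameters.
#'
#' @param params `EncoderParams`.
#' @param structure a `Structure`.
#' @param graph optional precomputed featurized graph.
#' @return a `PottsModel`.
#' @export
potts_forward <- function(params, structure, graph = NULL) {
  cfg <- attr(params, "config")
  if (is.null(graph)) graph <- featurize(structure, cfg$k)
  enc <- encode(params, graph, training = FALSE)
  project_potts(params, graph, enc$edge_embeddings)
}

#' Save / load encoder parameter checkpoints
#' @param params `EncoderParams`; `path` file path.
#' @export
write_checkpoint <- function(params, path) {
  saveRDS(params, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) readRDS(path)
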