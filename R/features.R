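# Featurization: global k-NN residue graph with dihedral node features and
# RBF / local-frame / positional edge features.

RBF_COUNT <- 16L
RBF_MAX <- 20  # Angstroms
POS_CLAMP <- 32L
D_NODE <- 6L
D_EDGE <- RBF_COUNT + 4L + 3L + (2L * POS_CLAMP + 1L) + 1L  # 89

#' Build the global k-nearest-neighbor residue graph
#'
#' Each residue's neighbor list contains the `min(k, L)` residues nearest by
#' CA-CA Euclidean distance, the residue itself always included (self-edge at
#' distance 0), sorted by ascending distance with ties broken by lower
#' residue index.
#'
#' @param structure a `Structure` with L >= 2.
#' @param k neighbor count (slots include the self-edge).
#' @return object of class `ResidueGraph` with fields `L`, `k` (effective),
#'   `neighbors` (`L x k` integer matrix), `dist` (`L x k` CA distances),
#'   `chain_id`, and after [featurize()] also `node_features`
#'   (`L x 6`) and `edge_features` (`L x k x 89`).
#' @export
knn_graph <- function(structure, k = 30L) {
  L <- structure$n
  stopifnot(L >= 2, k >= 1)
  ca <- ca_coords(structure)
  if (!all(is.finite(ca))) stop("missing CA coordinates")
  D <- as.matrix(dist(ca))
  kk <- min(as.integer(k), L)
  neighbors <- matrix(0L, L, kk)
  dmat <- matrix(0, L, kk)
  for (i in seq_len(L)) {
    ord <- order(D[i, ], seq_len(L))[seq_len(kk)]  # ties -> lower index
    neighbors[i, ] <- ord
    dmat[i, ] <- D[i, ord]
  }
  g <- list(L = L, k = kk, neighbors = neighbors, dist = dmat,
            chain_id = structure$chain_id)
  class(g) <- "ResidueGraph"
  g
}

# Per-residue (phi, psi, omega) in radians; NA where undefined (chain
# termini and virtual chain breaks).
backbone_dihedrals <- function(structure) {
  L <- structure$n
  co <- structure$coords
  # segment id: new segment at each chain start or recorded break
  seg <- cumsum(c(1L, as.integer(structure$chain_id[-1] != structure$chain_id[-L] |
                                   (seq_len(L - 1) %in% structure$breaks))))
  phi <- psi <- omega <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    if (i > 1 && seg[i - 1] == seg[i]) {
      phi[i] <- dihedral_angle(co[i - 1, "C", ], co[i, "N", ], co[i, "CA", ],
                               co[i, "C", ])
      omega[i] <- dihedral_angle(co[i - 1, "CA", ], co[i - 1, "C", ],
                                 co[i, "N", ], co[i, "CA", ])
    }
    if (i < L && seg[i + 1] == seg[i]) {
      psi[i] <- dihedral_angle(co[i, "N", ], co[i, "CA", ], co[i, "C", ],
                               co[i + 1, "N", ])
    }
  }
  cbind(phi = phi, psi = psi, omega = omega)
}

#' Dihedral node features
#'
#' Sine and cosine of the backbone torsions (phi, psi, omega) per residue;
#' angles undefined at termini or chain breaks are encoded as (0, 0).
#'
#' @param structure a `Structure`.
#' @return `L x 6` matrix, columns
#'   (sin phi, cos phi, sin psi, cos psi, sin omega, cos omega).
#' @export
node_features <- function(structure) {
  ang <- backbone_dihedrals(structure)
  out <- matrix(0, structure$n, D_NODE)
  for (a in 1:3) {
    def <- !is.na(ang[, a])
    out[def, 2 * a - 1] <- sin(ang[def, a])
    out[def, 2 * a] <- cos(ang[def, a])
  }
  colnames(out) <- c("sin_phi", "cos_phi", "sin_psi", "cos_psi",
                     "sin_omega", "cos_omega")
  out
}

# Local backbone frame per residue from N, CA, C: columns are orthonormal
# axes. Degenerate (collinear) frames fall back to identity with a warning.
local_frames <- function(structure) {
  L <- structure$n
  co <- structure$coords
  frames <- array(NA_real_, c(L, 3, 3))
  degen <- FALSE
  for (i in seq_len(L)) {
    e1 <- vunit(co[i, "C", ] - co[i, "CA", ])
    v2 <- co[i, "N", ] - co[i, "CA", ]
    e3 <- if (is.null(e1)) NULL else vunit(vcross(v2, e1))
    if (is.null(e1) || is.null(e3)) {
      frames[i, , ] <- diag(3)
      degen <- TRUE
      next
    }
    e2 <- vcross(e3, e1)
    frames[i, , ] <- cbind(e1, e2, e3)
  }
  if (degen) warning("degenerate backbone frame(s); identity frame used")
  frames
}

#' Edge features on the k-NN graph
#'
#' Per directed edge i -> j: 16 Gaussian RBF activations of the CA-CA
#' distance (centers evenly spaced on 0-20 A, width = spacing), the unit
#' quaternion of the rotation between the two residues' local N-CA-C
#' frames, the CA_j position in residue i's local frame, a one-hot encoding
#' of the sequence offset j - i clamped to +/-32 (65 bins), and a same-chain
#' indicator. `d_edge` = 89.
#'
#' @param structure a `Structure`.
#' @param graph the [knn_graph()] built from it.
#' @return `L x k x 89` array.
#' @export
edge_features <- function(structure, graph) {
  L <- graph$L; k <- graph$k
  centers <- seq(0, RBF_MAX, length.out = RBF_COUNT)
  sigma <- centers[2] - centers[1]
  frames <- local_frames(structure)
  ca <- ca_coords(structure)
  out <- array(0, c(L, k, D_EDGE))
  for (i in seq_len(L)) {
    Ri <- frames[i, , ]
    for (c_ in seq_len(k)) {
      j <- graph$neighbors[i, c_]
      d <- graph$dist[i, c_]
      rbf <- exp(-((d - centers) / sigma)^2)
      Rj <- frames[j, , ]
      q <- quat_from_rotation(t(Ri) %*% Rj)
      off <- as.numeric(t(Ri) %*% (ca[j, ] - ca[i, ]))
      same <- as.numeric(structure$chain_id[i] == structure$chain_id[j])
      pos <- numeric(2L * POS_CLAMP + 1L)
      if (same == 1) {
        # relative sequence position is only meaningful within a chain;
        # cross-chain edges keep a zero one-hot (flagged by same-chain = 0)
        # so that energies are invariant to chain relabeling
        t_ <- max(-POS_CLAMP, min(POS_CLAMP, j - i))
        pos[t_ + POS_CLAMP + 1L] <- 1
      }
      out[i, c_, ] <- c(rbf, q, off, pos, same)
    }
  }
  out
}

#' Full featurization of a structure
#'
#' Builds the k-NN graph and attaches node and edge features.
#'
#' @inheritParams knn_graph
#' @return `ResidueGraph` with `node_features` and `edge_features` set.
#' @export
featurize <- function(structure, k = 30L) {
  g <- knn_graph(structure, k)
  g$node_features <- node_features(structure)
  g$edge_features <- edge_features(structure, g)
  g
}

#' Save / load a featurized graph archive
#'
#' Bit-exact round-trip of the arrays in a `ResidueGraph`.
#'
#' @param graph a featurized `ResidueGraph`.
#' @param path archive path (RDS).
#' @export
write_graph <- function(graph, path) {
  saveRDS(graph, path)
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) readRDS(path)
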