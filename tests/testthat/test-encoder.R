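test_that("parameter initialization is deterministic and validated", {
  cfg <- encoder_config(hidden_dim = 16, n_layers = 2, k = 8, seed = 3)
  a <- init_encoder(cfg)
  b <- init_encoder(cfg)
  expect_identical(unclass(a), unclass(b))
  c_ <- init_encoder(encoder_config(hidden_dim = 16, n_layers = 2, k = 8, seed = 4))
  expect_false(identical(a[["embed.Wn"]], c_[["embed.Wn"]]))
  expect_error(encoder_config(hidden_dim = 0), "hidden_dim")
  expect_error(encoder_config(n_layers = 0), "n_layers")
  # trunk/output partition
  expect_true(all(c("out.W", "out.b") %in% setdiff(names(a), trunk_param_names(a))))
})

test_that("zero-weight message passing reduces to normalized lifted features", {
  st <- make_toy_dataset(1, size_range = c(10, 10), seed = 5)[[1]]
  cfg <- encoder_config(hidden_dim = 8, n_layers = 2, dropout = 0, k = 4, seed = 1)
  params <- init_encoder(cfg)
  for (nm in grep("^layer.*\\.W", names(params), value = TRUE)) params[[nm]][] <- 0
  g <- featurize(st, cfg$k)
  enc <- encode(params, g)
  # all message MLPs emit zero, so the residual stream carries the
  # normalized lifted inputs unchanged through every layer (LN with unit
  # gain and zero bias is idempotent)
  lift_n <- coordesign:::.ln_fwd(
    sweep(g$node_features %*% params[["embed.Wn"]], 2, params[["embed.bn"]], "+"),
    params[["embed.ln_n.g"]], params[["embed.ln_n.b"]])$y
  expect_equal(enc$node_embeddings, lift_n, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_true(all(is.finite(enc$edge_embeddings)))
  expect_identical(encode(params, g)$edge_embeddings, enc$edge_embeddings)
})

test_that("node aggregation is invariant to neighbor-slot order", {
  st <- make_toy_dataset(1, size_range = c(12, 12), seed = 6)[[1]]
  cfg <- encoder_config(hidden_dim = 8, n_layers = 2, dropout = 0, k = 5, seed = 2)
  params <- init_encoder(cfg)
  g <- featurize(st, cfg$k)
  enc <- encode(params, g)
  # permute the neighbor slots of residue 4 (same set, different order)
  g2 <- g
  perm <- c(1L, 3L, 2L, 5L, 4L)
  g2$neighbors[4, ] <- g$neighbors[4, perm]
  g2$dist[4, ] <- g$dist[4, perm]
  g2$edge_features[4, , ] <- g$edge_features[4, perm, ]
  enc2 <- encode(params, g2)
  expect_lt(max(abs(enc2$node_embeddings - enc$node_embeddings)), 1e-6)
})

test_that("projection averages bidirectional tables and passes singletons", {
  # three collinear residues with uneven spacing: pair {1,3} exists in one
  # direction only at k = 2, pairs {1,2} and {2,3} in both
  st <- make_ideal_helix(3)
  for (i in 1:3) {
    st$coords[i, , ] <- sweep(st$coords[i, , ], 2,
                              st$coords[i, "CA", ] - c(c(0, 3.8, 8.2)[i], 0, 0))
  }
  g <- featurize(st, 2)
  eid <- coordesign:::.edge_row(g)
  expect_gt(eid[2 + (1 - 1) * 3], 0)  # edge 2 -> 1 exists
  expect_equal(eid[1 + (3 - 1) * 3], 0)  # no 1 -> 3 edge
  expect_gt(eid[3 + (2 - 1) * 3], 0)

  # hidden dim 400 with identity output projection exposes the raw tables
  cfg <- encoder_config(hidden_dim = 400, n_layers = 1, dropout = 0, k = 2, seed = 1)
  params <- init_encoder(cfg)
  params[["out.W"]] <- diag(400)
  params[["out.b"]] <- numeric(400)
  emb <- matrix(0, 6, 400)
  A <- matrix(rnorm(400), 20, 20)
  emb[eid[1 + (2 - 1) * 3], ] <- as.vector(A)      # M_12 = A
  emb[eid[2 + (1 - 1) * 3], ] <- as.vector(t(A))   # M_21 = t(A): fixed point
  B <- matrix(rnorm(400), 20, 20)
  emb[eid[3 + (2 - 1) * 3], ] <- as.vector(B)      # M_32 present, M_23 absent
  D <- matrix(rnorm(400), 20, 20)
  emb[eid[1 + (1 - 1) * 3], ] <- as.vector(D)      # self-edge of residue 1
  potts <- project_potts(params, g, emb)
  expect_equal(pair_energy_matrix(potts, 1, 2), A, tolerance = 1e-12)
  expect_equal(pair_energy_matrix(potts, 3, 2), B, tolerance = 1e-12)
  expect_equal(potts$self[1, ], diag(D), tolerance = 1e-12)
  # M_21 = 0 alongside M_12 = A averages to A / 2
  emb[eid[2 + (1 - 1) * 3], ] <- 0
  potts2 <- project_potts(params, g, emb)
  expect_equal(pair_energy_matrix(potts2, 1, 2), A / 2, tolerance = 1e-12)
})

test_that("emitted models satisfy exchange symmetry on every pair", {
  st <- make_toy_dataset(1, size_range = c(15, 15), seed = 7)[[1]]
  params <- init_encoder(encoder_config(hidden_dim = 12, n_layers = 2, k = 6, seed = 9))
  # give the zero-initialized output head random weights so tables are nonzero
  params[["out.W"]] <- matrix(rnorm(12 * 400, sd = 0.2), 12, 400)
  potts <- potts_forward(params, st)
  expect_gt(sd(potts$pair_mats), 0)
  for (r in seq_along(potts$pair_i)) {
    expect_identical(pair_energy_matrix(potts, potts$pair_i[r], potts$pair_j[r]),
                     t(pair_energy_matrix(potts, potts$pair_j[r], potts$pair_i[r])))
  }
})

test_that("forward pipeline is deterministic, complete at small L, invariant", {
  st5 <- make_toy_dataset(1, size_range = c(8, 8), seed = 8)[[1]]
  params <- init_encoder(encoder_config(hidden_dim = 8, n_layers = 2, k = 30, seed = 2))
  params[["out.W"]] <- matrix(rnorm(8 * 400, sd = 0.2), 8, 400)
  p1 <- potts_forward(params, st5)
  p2 <- potts_forward(params, st5)
  expect_identical(p1$self, p2$self)
  expect_identical(p1$pair_mats, p2$pair_mats)
  expect_equal(length(p1$pair_i), choose(8, 2))  # complete graph at L <= k
  set.seed(33)
  for (rep in 1:3) {
    pr <- potts_forward(params, rigid_structure(st5))
    expect_lt(max(abs(pr$self - p1$self)), 1e-5)
    expect_lt(max(abs(pr$pair_mats - p1$pair_mats)), 1e-5)
  }
})

test_that("chain relabeling permutes the emitted energies consistently", {
  st <- toy_bundle_structure(seed = 91, L_range = c(24, 24))
  L <- st$n
  l1 <- st$chains$end[1]
  perm <- c((l1 + 1):L, 1:l1)  # chain B first
  st2 <- structure_new(st$coords[perm, , ], paste(strsplit(st$sequence, "")[[1]][perm],
                                                  collapse = ""),
                       chain_id = rev(LETTERS[1:2])[as.integer(factor(st$chain_id[perm]))],
                       resno = st$resno[perm])
  params <- init_encoder(encoder_config(hidden_dim = 10, n_layers = 2, k = 8, seed = 4))
  params[["out.W"]] <- matrix(rnorm(10 * 400, sd = 0.2), 10, 400)
  pa <- potts_forward(params, st)
  pb <- potts_forward(params, st2)
  inv <- order(perm)  # position of old residue i in the permuted structure
  expect_lt(max(abs(pa$self - pb$self[perm, ])), 1e-5)
  for (r in seq_along(pa$pair_i)) {
    i2 <- inv[pa$pair_i[r]]; j2 <- inv[pa$pair_j[r]]
    expect_lt(max(abs(pair_energy_matrix(pa, pa$pair_i[r], pa$pair_j[r]) -
                        pair_energy_matrix(pb, i2, j2))), 1e-5)
  }
})

test_that("analytic gradients of the training loss match finite differences", {
  st <- make_toy_dataset(1, size_range = c(9, 9), seed = 10)[[1]]
  cfg <- encoder_config(hidden_dim = 8, n_layers = 2, dropout = 0, k = 5, seed = 7)
  params <- init_encoder(cfg)
  params[["out.W"]] <- matrix(rnorm(8 * 400, sd = 0.1), 8, 400)
  g <- featurize(st, cfg$k)
  loss_fn <- function(p) {
    attr(p, "config") <- cfg
    class(p) <- "EncoderParams"
    potts <- potts_forward(p, NULL, graph = g)
    ng <- coordesign:::ncpl_grad_potts(potts, st$sequence)
    nq <- coordesign:::norm_grad_potts(potts)
    ng$loss_sum / ng$n_pairs + 0.5 * nq$value
  }
  enc <- encode(params, g, keep_cache = TRUE)
  potts <- project_potts(params, g, enc$edge_embeddings)
  ng <- coordesign:::ncpl_grad_potts(potts, st$sequence)
  nq <- coordesign:::norm_grad_potts(potts)
  gs <- ng$g_self / ng$n_pairs + 0.5 * nq$g_self
  gp <- ng$g_pairs / ng$n_pairs + 0.5 * nq$g_pairs
  pb <- project_potts_backward(params, g, enc$edge_embeddings, gs, gp)
  grads <- encode_backward(params, g, enc$cache, pb$g_edge)
  grads[["out.W"]] <- pb$g_out_W
  grads[["out.b"]] <- pb$g_out_b
  set.seed(99)
  eps <- 1e-5
  checked <- 0
  for (nm in sample(names(params), 10)) {
    idx <- sample(length(params[[nm]]), 1)
    p1 <- params; p1[[nm]][idx] <- p1[[nm]][idx] + eps
    p2 <- params; p2[[nm]][idx] <- p2[[nm]][idx] - eps
    fd <- (loss_fn(p1) - loss_fn(p2)) / (2 * eps)
    an <- grads[[nm]][idx]
    if (abs(fd) < 1e-8 && abs(an) < 1e-8) next
    expect_lt(abs(fd - an) / max(abs(fd), abs(an)), 1e-4)
    checked <- checked + 1
  }
  expect_gt(checked, 3)
})

test_that("checkpoints round-trip the full parameter set", {
  params <- init_encoder(encoder_config(hidden_dim = 6, n_layers = 1, k = 4, seed = 11))
  tf <- withr::local_tempfile(fileext = ".rds")
  write_checkpoint(params, tf)
  got <- read_checkpoint(tf)
  expect_identical(unclass(got), unclass(params))
  expect_identical(attr(got, "config"), attr(params, "config"))
})
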