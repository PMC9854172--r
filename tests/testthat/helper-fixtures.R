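# Shared fixtures and independent oracles used across test files.

# a minimal hand-written PDB: ALA-GLY-ALA with all backbone atoms
pdb_aga <- function() {
  st <- make_ideal_helix(3)
  st$sequence <- "AGA"
  write_backbone(st)
}

# apply a random rigid motion to a Structure (rotation + translation)
rigid_structure <- function(st, R = NULL, t = NULL) {
  if (is.null(R)) R <- coordesign:::random_rotation()
  if (is.null(t)) t <- rnorm(3, sd = 25)
  cc <- st$coords
  dn <- dimnames(cc)
  dim(cc) <- c(st$n * 4, 3)
  cc <- coordesign:::apply_rigid(cc, R, t)
  dim(cc) <- c(st$n, 4, 3)
  dimnames(cc) <- dn
  st$coords <- cc
  st
}

# mirror image (improper transformation): negate x
mirror_structure <- function(st) {
  st$coords[, , 1] <- -st$coords[, , 1]
  st
}

# brute-force contextual pair energy straight from the written formula
brute_ecp <- function(potts, s, i, m, j, n) {
  e <- potts$self[i, m] + potts$self[j, n] + pair_energy_matrix(potts, i, j)[m, n]
  for (u in setdiff(seq_len(potts$L), c(i, j))) {
    e <- e + pair_energy_matrix(potts, i, u)[m, s[u]] +
      pair_energy_matrix(potts, u, j)[s[u], n]
  }
  e
}

# brute-force total energy from the written formula
brute_total <- function(potts, s) {
  e <- sum(potts$self[cbind(seq_len(potts$L), s)])
  for (i in seq_len(potts$L - 1)) for (j in (i + 1):potts$L) {
    e <- e + pair_energy_matrix(potts, i, j)[s[i], s[j]]
  }
  e
}

# enumerate all 20^3 sequences of a 3-residue Potts model; returns energies
# in expand.grid order
enumerate_l3 <- function(potts) {
  grid <- as.matrix(expand.grid(1:20, 1:20, 1:20))
  apply(grid, 1, function(r) total_energy(potts, int_to_seq(r)))
}

# tiny two-chain bundle with planted sequence, memoized
toy_bundle_structure <- function(seed = 77, L_range = c(30, 44)) {
  make_toy_dataset(1, size_range = L_range, two_chain_fraction = 1,
                   seed = seed)[[1]]
}

# Memoized desk-scale training runs shared by the acceptance tests (the
# unpenalized run, its norm-penalty twin, and the fine-tuning trunk), so
# the suite trains each model once.
.toy_cache <- new.env(parent = emptyenv())

toy_training_data <- function() {
  if (is.null(.toy_cache$data)) {
    ds <- make_toy_dataset(70, rule = toy_rule(), two_chain_fraction = 0.3,
                           seed = 101)
    .toy_cache$data <- list(train = ds[1:40], val = ds[41:50], test = ds[51:70])
  }
  .toy_cache$data
}

toy_trained_fit <- function(norm_weight = 0) {
  key <- paste0("fit", norm_weight)
  if (is.null(.toy_cache[[key]])) {
    d <- toy_training_data()
    ec <- encoder_config(hidden_dim = 32, n_layers = 2, dropout = 0.1,
                         k = 12, seed = 5)
    tc <- train_config(max_epochs = 15, batch_residue_cap = 450,
                       warmup_steps = 50, patience = 3, seed = 5, k = 12,
                       lr_scale = 0.2,
                       loss_weights = list(ncpl = 1, norm = norm_weight))
    .toy_cache[[key]] <- train_encoder(d$train, d$val, tc, encoder_cfg = ec)
  }
  .toy_cache[[key]]
}

# held-out argmax-of-self-energy recovery (zero-sum gauge; see vignette)
self_argmax_recovery <- function(params, structures, gauge = TRUE) {
  mean(vapply(structures, function(st) {
    potts <- potts_forward(params, st)
    if (gauge) potts <- zero_sum_gauge(potts)
    mean(AA_ALPHABET[apply(potts$self, 1, which.min)] ==
           strsplit(st$sequence, "")[[1]])
  }, numeric(1)))
}

mean_emitted_norm <- function(params, structures) {
  mean(vapply(structures, function(st) norm_penalty(potts_forward(params, st)),
              numeric(1)))
}

# synthetic affinity records from a ground-truth Potts on a template
make_affinity_records <- function(truth, tmpl, pep, n, seed, noise_frac = 0.1) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    s <- seq_to_int(tmpl$sequence)
    idx <- sample(pep, max(1, rbinom(1, length(pep), 0.5)))
    s[idx] <- sample.int(20, length(idx), replace = TRUE)
    int_to_seq(s)
  }, "")
  sc <- vapply(seqs, function(sq) peptide_binding_score(truth, sq, pep),
               numeric(1), USE.NAMES = FALSE)
  data.frame(sequence = seqs, value = sc + rnorm(n, sd = noise_frac * sd(sc)))
}
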