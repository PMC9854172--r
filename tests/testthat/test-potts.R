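test_that("total_energy decomposes and matches direct summation", {
  zero <- potts_new(matrix(0, 4, 20))
  expect_equal(total_energy(zero, "ACDE"), 0)
  # self-only additivity
  self <- matrix(0, 4, 20)
  s <- seq_to_int("GYLK")
  self[cbind(1:4, s)] <- -1
  expect_equal(total_energy(potts_new(self), "GYLK"), -4)
  # random full-pair model vs brute force
  set.seed(10)
  p <- random_potts(3)
  for (sq in c("AAA", "WKD", "YYC")) {
    expect_equal(total_energy(p, sq), brute_total(p, seq_to_int(sq)))
  }
  expect_error(total_energy(p, "AA"), "length")
  expect_error(total_energy(p, "AAB"), "alphabet")
  bd <- total_energy(p, "WKD", breakdown = TRUE)
  expect_equal(bd$energy, sum(bd$self_terms) + sum(bd$pair_terms))
})

test_that("contextual pair energy matches an independent term collection", {
  zero <- potts_new(matrix(0, 5, 20), t(combn(5, 2))[, 1], t(combn(5, 2))[, 2],
                    array(0, c(10, 20, 20)))
  expect_equal(contextual_pair_energy(zero, "ACDEF", 1, "W", 4, "Y"), 0)
  # L = 2: empty context sum, exact closed form
  set.seed(11)
  p2 <- random_potts(2)
  e <- contextual_pair_energy(p2, "AC", 1, "M", 2, "H")
  m <- seq_to_int("M"); h <- seq_to_int("H")
  expect_equal(e, p2$self[1, m] + p2$self[2, h] + pair_energy_matrix(p2, 1, 2)[m, h])
  # 1000 random instances vs the term-collection oracle
  set.seed(12)
  for (rep in 1:40) {
    L <- sample(3:6, 1)
    p <- random_potts(L)
    s <- sample.int(20, L, replace = TRUE)
    for (inst in 1:25) {
      ij <- sample(L, 2)
      m <- sample.int(20, 1); n <- sample.int(20, 1)
      expect_equal(contextual_pair_energy(p, int_to_seq(s), ij[1], m, ij[2], n),
                   brute_ecp(p, s, ij[1], m, ij[2], n), tolerance = 1e-10)
    }
  }
  expect_error(contextual_pair_energy(p2, "AC", 1, 1, 1, 2), "differ")
})

test_that("pair pseudo-likelihood is a proper 400-way softmax", {
  set.seed(13)
  zero <- potts_new(matrix(0, 2, 20), 1L, 2L, array(0, c(1, 20, 20)))
  expect_equal(pair_pseudolikelihood(zero, "AA", 1, 2), 1 / 400)
  # strongly biased self energy vs brute-force enumeration
  p <- potts_new(matrix(0, 3, 20), c(1L, 1L, 2L), c(2L, 3L, 3L),
                 array(0, c(3, 20, 20)))
  p$self[1, seq_to_int("A")] <- -50
  E <- cpe_matrix(p, "AAA", 1, 2)
  brute <- exp(-E) / sum(exp(-E))
  expect_equal(pair_pseudolikelihood(p, "AAA", 1, 2), brute[1, 1],
               tolerance = 1e-12)
  # normalizer: mapped over all 400 label pairs the values sum to 1
  pr <- random_potts(3)
  tot <- sum(outer(1:20, 1:20, Vectorize(function(m, n) {
    pair_pseudolikelihood(pr, "CDE", 1, 3, m, n)
  })))
  expect_equal(tot, 1, tolerance = 1e-12)
  # overflow safety at extreme energies
  px <- random_potts(2, sd = 400)
  expect_true(is.finite(pair_pseudolikelihood(px, "AA", 1, 2)))
  expect_error(pair_pseudolikelihood(zero, "AA", 1, 1))
})

test_that("ncpl loss equals the mean brute-force negative log likelihood", {
  zero <- potts_new(matrix(0, 4, 20), c(1L, 2L, 3L), c(2L, 3L, 4L),
                    array(0, c(3, 20, 20)))
  expect_equal(ncpl_loss(zero, "ACDE"), log(400))
  # near-deterministic native labels: loss approaches 0
  pdet <- zero
  s <- seq_to_int("ACDE")
  for (i in 1:4) pdet$self[i, s[i]] <- -1e3
  expect_lt(ncpl_loss(pdet, "ACDE"), 1e-6)
  # random model: arithmetic mean of per-pair brute-force values
  set.seed(14)
  p <- random_potts(4, pairs = cbind(c(1L, 2L, 3L), c(2L, 3L, 4L)))
  vals <- vapply(1:3, function(r) {
    E <- cpe_matrix(p, "MKYW", p$pair_i[r], p$pair_j[r])
    sidx <- seq_to_int("MKYW")
    -log(exp(-E[sidx[p$pair_i[r]], sidx[p$pair_j[r]]]) / sum(exp(-E)))
  }, numeric(1))
  expect_equal(ncpl_loss(p, "MKYW"), mean(vals), tolerance = 1e-10)
  expect_error(ncpl_loss(p, "MKYW", pairs = matrix(0, 0, 2)), "empty")
})

test_that("norm penalty matches the ordered-pair double sum", {
  expect_equal(norm_penalty(potts_new(matrix(0, 3, 20))), 0)
  single <- potts_new(matrix(c(3, rep(0, 19)), 1, 20))
  expect_equal(norm_penalty(single), 3)
  set.seed(15)
  p <- random_potts(3)
  acc <- sum(p$self^2)
  for (i in 1:3) for (j in setdiff(1:3, i)) {
    acc <- acc + sum(pair_energy_matrix(p, i, j)^2)
  }
  expect_equal(norm_penalty(p), sqrt(acc) / 3, tolerance = 1e-12)
})

test_that("mutation delta is exact and incremental", {
  set.seed(16)
  p <- random_potts(6)
  sq <- "ACDEFG"
  expect_equal(mutation_delta(p, sq, 3, "D"), 0)  # identity mutation
  pself <- potts_new(p$self)
  expect_equal(mutation_delta(pself, sq, 2, "W"),
               pself$self[2, seq_to_int("W")] - pself$self[2, seq_to_int("C")])
  for (rep in 1:20) {
    i <- sample(6, 1); m <- sample.int(20, 1)
    s2 <- seq_to_int(sq); s2[i] <- m
    expect_equal(mutation_delta(p, sq, i, m),
                 total_energy(p, int_to_seq(s2)) - total_energy(p, sq),
                 tolerance = 1e-10)
  }
})

test_that("peptide binding score classifies self and pair terms correctly", {
  set.seed(17)
  p <- random_potts(4)
  sq <- "MKYW"
  expect_equal(peptide_binding_score(p, sq, 1:4), total_energy(p, sq))
  expect_error(peptide_binding_score(p, sq, integer(0)), "empty")
  s <- seq_to_int(sq)
  pep <- c(1L, 2L)
  manual <- p$self[1, s[1]] + p$self[2, s[2]]
  for (r in seq_along(p$pair_i)) {
    if (p$pair_i[r] %in% pep || p$pair_j[r] %in% pep) {
      manual <- manual + p$pair_mats[r, s[p$pair_i[r]], s[p$pair_j[r]]]
    }
  }
  expect_equal(peptide_binding_score(p, sq, pep), manual)
})

test_that("energy tables round-trip in text and binary formats", {
  set.seed(18)
  p <- random_potts(4)
  tf <- withr::local_tempfile(fileext = ".etab")
  write_etab(p, tf, "text")
  p2 <- read_etab(tf)
  expect_equal(p2$self, p$self, tolerance = 0)
  expect_equal(p2$pair_mats, p$pair_mats, tolerance = 0)
  tb <- withr::local_tempfile(fileext = ".rds")
  write_etab(p, tb, "binary")
  expect_identical(read_etab(tb)$pair_mats, p$pair_mats)
  # a pair line with j < i is canonicalized to transpose storage
  lines <- c("ETAB 2 20 ACDEFGHIKLMNPQRSTVWY", "pair 2 1 C A 1.5")
  tf2 <- withr::local_tempfile()
  writeLines(lines, tf2)
  p3 <- read_etab(tf2)
  expect_equal(pair_energy_matrix(p3, 2, 1)[seq_to_int("C"), seq_to_int("A")], 1.5)
  expect_equal(pair_energy_matrix(p3, 1, 2)[seq_to_int("A"), seq_to_int("C")], 1.5)
  # malformed line reports its number
  writeLines(c(lines, "garbage"), tf2)
  expect_error(read_etab(tf2), "line 3")
})

test_that("exchange symmetry and gauge shifts behave as Potts theory requires", {
  set.seed(19)
  p <- random_potts(5)
  for (r in seq_along(p$pair_i)) {
    i <- p$pair_i[r]; j <- p$pair_j[r]
    expect_identical(pair_energy_matrix(p, i, j), t(pair_energy_matrix(p, j, i)))
  }
  # adding c to a whole self row shifts total energy by c and leaves the
  # pair pseudo-likelihood untouched (the normalizer cancels it)
  sq <- "ACDEF"
  base_pl <- pair_pseudolikelihood(p, sq, 2, 4)
  base_e <- total_energy(p, sq)
  p$self[2, ] <- p$self[2, ] + 2.5
  expect_equal(total_energy(p, sq), base_e + 2.5)
  expect_equal(pair_pseudolikelihood(p, sq, 2, 4), base_pl, tolerance = 1e-12)
})

test_that("zero-sum gauge preserves all energetics and zeroes table means", {
  set.seed(20)
  p <- random_potts(4)
  pz <- zero_sum_gauge(p)
  const <- attr(pz, "constant")
  for (sq in c("AAAA", "WKDY", "MMHH")) {
    expect_equal(total_energy(pz, sq), total_energy(p, sq) + const,
                 tolerance = 1e-10)
    expect_equal(pair_pseudolikelihood(pz, sq, 1, 3),
                 pair_pseudolikelihood(p, sq, 1, 3), tolerance = 1e-12)
  }
  for (r in seq_along(pz$pair_i)) {
    expect_lt(max(abs(rowMeans(pz$pair_mats[r, , ]))), 1e-12)
    expect_lt(max(abs(colMeans(pz$pair_mats[r, , ]))), 1e-12)
  }
})

test_that("pairwise conditionals agree with exact Boltzmann enumeration", {
  set.seed(21)
  p <- random_potts(3, sd = 0.7)
  en <- enumerate_l3(p)
  w <- exp(-(en - min(en)))
  grid <- as.matrix(expand.grid(1:20, 1:20, 1:20))
  sq <- "AGL"
  s <- seq_to_int(sq)
  # condition on residue 3 = its native letter; joint of (1, 2) from the
  # full Boltzmann distribution must equal the composite pseudo-likelihood
  sel <- grid[, 3] == s[3]
  for (pair in list(c(5, 9), c(s[1], s[2]), c(20, 1))) {
    num <- sum(w[sel & grid[, 1] == pair[1] & grid[, 2] == pair[2]])
    expect_equal(pair_pseudolikelihood(p, sq, 1, 2, pair[1], pair[2]),
                 num / sum(w[sel]), tolerance = 1e-9)
  }
})
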