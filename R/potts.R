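# The Potts energy model over 20-letter sequence space: self-energy table
# E_s (L x 20) and symmetric pair-energy tables E_p (20 x 20) on graph
# edges. Lower energy is more favorable; Boltzmann weights use exp(-E).

#' Construct a PottsModel
#'
#' @param self_energy `L x 20` matrix, `self_energy[i, m]` = E_s(R_i = m),
#'   columns in [AA_ALPHABET] order.
#' @param pair_i,pair_j integer vectors of unordered pair endpoints; pairs
#'   are canonicalized to `i < j` (the 20x20 table of a flipped pair is
#'   transposed). Pairs absent from the list have zero pair energy.
#' @param pair_mats numeric array `n_pairs x 20 x 20`;
#'   `pair_mats[p, m, n]` = E_p(R_i = m, R_j = n) for the p-th pair.
#' @return object of class `PottsModel`: fields `L`, `self`, `pair_i`,
#'   `pair_j`, `pair_mats`, `pair_index` (`L x L` lookup, 0 = absent).
#' @export
potts_new <- function(self_energy, pair_i = integer(0), pair_j = integer(0),
                      pair_mats = NULL) {
  L <- nrow(self_energy)
  stopifnot(ncol(self_energy) == 20, all(is.finite(self_energy)))
  np <- length(pair_i)
  stopifnot(length(pair_j) == np)
  if (is.null(pair_mats)) pair_mats <- array(0, c(0, 20, 20))
  stopifnot(dim(pair_mats)[1] == np, all(is.finite(pair_mats)))
  if (np > 0) {
    stopifnot(all(pair_i >= 1), all(pair_j >= 1), all(pair_i <= L),
              all(pair_j <= L), all(pair_i != pair_j))
    flip <- pair_i > pair_j
    if (any(flip)) {
      for (p in which(flip)) pair_mats[p, , ] <- t(pair_mats[p, , ])
      tmp <- pair_i[flip]; pair_i[flip] <- pair_j[flip]; pair_j[flip] <- tmp
    }
    if (anyDuplicated(cbind(pair_i, pair_j))) stop("duplicate pair")
  }
  idx <- matrix(0L, L, L)
  if (np > 0) {
    idx[cbind(pair_i, pair_j)] <- seq_len(np)
    idx[cbind(pair_j, pair_i)] <- seq_len(np)
  }
  x <- list(L = L, self = self_energy, pair_i = as.integer(pair_i),
            pair_j = as.integer(pair_j), pair_mats = pair_mats,
            pair_index = idx)
  class(x) <- "PottsModel"
  x
}

#' @export
print.PottsModel <- function(x, ...) {
  cat(sprintf("PottsModel: L = %d, %d pair edge(s)\n", x$L, length(x$pair_i)))
  invisible(x)
}

#' Pair-energy table of one unordered pair
#'
#' @param potts a `PottsModel`.
#' @param i,j distinct positions. The returned matrix is oriented so that
#'   rows index the letter at `i` and columns the letter at `j`
#'   (endpoint-exchange symmetry: `pair_energy_matrix(p, j, i)` is the
#'   transpose).
#' @return 20 x 20 matrix (all zeros when the pair carries no edge).
#' @export
pair_energy_matrix <- function(potts, i, j) {
  stopifnot(i != j)
  p <- potts$pair_index[i, j]
  if (p == 0L) return(matrix(0, 20, 20))
  m <- potts$pair_mats[p, , ]
  if (i < j) m else t(m)
}

# indices (into pair list) of pairs incident to each node, with orientation
.incidence <- function(potts) {
  inc <- vector("list", potts$L)
  np <- length(potts$pair_i)
  if (np == 0) return(inc)
  for (p in seq_len(np)) {
    i <- potts$pair_i[p]; j <- potts$pair_j[p]
    inc[[i]] <- rbind(inc[[i]], c(p, j, 1L))  # 1: stored rows = letters at i
    inc[[j]] <- rbind(inc[[j]], c(p, i, 2L))  # 2: stored cols = letters at j
  }
  inc
}

#' Total Potts energy of a sequence
#'
#' E(S) = sum_i E_s(i, s_i) + sum over unordered pair edges of
#' E_p(i, s_i, j, s_j), each pair counted once.
#'
#' @param potts a `PottsModel`.
#' @param seq sequence (string or letter vector) of length L.
#' @param breakdown if TRUE, also return the per-term decomposition.
#' @return numeric scalar, or a list with `energy`, `self_terms`,
#'   `pair_terms` when `breakdown` is TRUE.
#' @export
total_energy <- function(potts, seq, breakdown = FALSE) {
  s <- seq_to_int(seq)
  if (length(s) != potts$L) stop("sequence length != L")
  self_terms <- potts$self[cbind(seq_len(potts$L), s)]
  np <- length(potts$pair_i)
  pair_terms <- if (np > 0) {
    potts$pair_mats[cbind(seq_len(np), s[potts$pair_i], s[potts$pair_j])]
  } else numeric(0)
  e <- sum(self_terms) + sum(pair_terms)
  if (breakdown) list(energy = e, self_terms = self_terms,
                      pair_terms = pair_terms) else e
}

#' Contextual pairwise energy E_cp
#'
#' Energy of residue `i` with identity `m` and residue `j` with identity
#' `n`, given all other residues fixed at their `seq` identities:
#' E_s(i,m) + E_s(j,n) + E_p(i,m,j,n) +
#' sum over u != i,j of E_p(i,m,u,r_u) + E_p(u,r_u,j,n). Pairs without an
#' edge contribute zero.
#'
#' @param potts a `PottsModel`.
#' @param seq context sequence of length L.
#' @param i,j distinct positions.
#' @param m,n letters (or 1..20 codes) for positions i and j.
#' @return numeric scalar.
#' @export
contextual_pair_energy <- function(potts, seq, i, m, j, n) {
  if (i == j) stop("i and j must differ")
  mi <- if (is.character(m)) seq_to_int(m) else as.integer(m)
  ni <- if (is.character(n)) seq_to_int(n) else as.integer(n)
  E <- cpe_matrix(potts, seq, i, j)
  E[mi, ni]
}

#' All 400 contextual pair energies for one pair
#'
#' @inheritParams contextual_pair_energy
#' @return 20 x 20 matrix `E[m, n]` = E_cp(R_i = m, R_j = n | context).
#' @export
cpe_matrix <- function(potts, seq, i, j) {
  stopifnot(i != j)
  s <- seq_to_int(seq)
  if (length(s) != potts$L) stop("sequence length != L")
  a <- potts$self[i, ]
  b <- potts$self[j, ]
  np <- length(potts$pair_i)
  if (np > 0) {
    for (p in seq_len(np)) {
      pi_ <- potts$pair_i[p]; pj_ <- potts$pair_j[p]
      if (pi_ == i && pj_ != j) a <- a + potts$pair_mats[p, , s[pj_]]
      else if (pj_ == i && pi_ != j) a <- a + potts$pair_mats[p, s[pi_], ]
      else if (pi_ == j && pj_ != i) b <- b + potts$pair_mats[p, , s[pj_]]
      else if (pj_ == j && pi_ != i) b <- b + potts$pair_mats[p, s[pi_], ]
    }
  }
  outer(a, b, "+") + pair_energy_matrix(potts, i, j)
}

#' Composite pseudo-likelihood of one residue pair
#'
#' p(R_i = m, R_j = n | context) =
#' exp(-E_cp(m, n)) / sum over all 400 label pairs (k, l) of exp(-E_cp(k, l)),
#' computed with max-subtraction for overflow safety.
#'
#' @inheritParams contextual_pair_energy
#' @param m,n letters scored; default the native letters of `seq`.
#' @return probability in (0, 1).
#' @export
pair_pseudolikelihood <- function(potts, seq, i, j, m = NULL, n = NULL) {
  if (potts$pair_index[i, j] == 0L) stop("pair {", i, ",", j, "} is not a graph edge")
  s <- seq_to_int(seq)
  mi <- if (is.null(m)) s[i] else if (is.character(m)) seq_to_int(m) else as.integer(m)
  ni <- if (is.null(n)) s[j] else if (is.character(n)) seq_to_int(n) else as.integer(n)
  E <- cpe_matrix(potts, seq, i, j)
  neg <- -E
  mx <- max(neg)
  w <- exp(neg - mx)
  w[mi, ni] / sum(w)
}

# per-pair negative log composite pseudo-likelihood terms (stable)
.ncpl_terms <- function(potts, seq, pairs) {
  s <- seq_to_int(seq)
  vapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    E <- cpe_matrix(potts, seq, i, j)
    neg <- -E
    mx <- max(neg)
    E[s[i], s[j]] + mx + log(sum(exp(neg - mx)))
  }, numeric(1))
}

#' Negative log composite pseudo-likelihood loss
#'
#' Mean over interacting residue pairs of -log p(native pair | context).
#'
#' @param potts a `PottsModel`.
#' @param seq sequence of length L.
#' @param pairs optional 2-column matrix of pairs; defaults to every pair
#'   edge of the model.
#' @return nonnegative scalar.
#' @export
ncpl_loss <- function(potts, seq, pairs = NULL) {
  if (is.null(pairs)) pairs <- cbind(potts$pair_i, potts$pair_j)
  if (!nrow(pairs)) stop("empty pair set")
  mean(.ncpl_terms(potts, seq, pairs))
}

#' Normalized L2 norm of all Potts energies
#'
#' (1/L) * sqrt(sum of squared self energies + sum over ordered position
#' pairs of squared pair energies). Each unordered pair edge contributes
#' twice to the pair block (the double summation is kept literal).
#'
#' @param potts a `PottsModel`.
#' @return nonnegative scalar.
#' @export
norm_penalty <- function(potts) {
  sqrt(sum(potts$self^2) + 2 * sum(potts$pair_mats^2)) / potts$L
}

#' Energy change of a point mutation
#'
#' total_energy with `s_i -> m` minus total_energy of `seq`, computed
#' incrementally in O(degree(i)).
#'
#' @param potts a `PottsModel`.
#' @param seq sequence of length L.
#' @param i position; `m` new letter (or code).
#' @return numeric scalar (0 for the identity mutation).
#' @export
mutation_delta <- function(potts, seq, i, m) {
  s <- seq_to_int(seq)
  mi <- if (is.character(m)) seq_to_int(m) else as.integer(m)
  if (mi == s[i]) return(0)
  d <- potts$self[i, mi] - potts$self[i, s[i]]
  np <- length(potts$pair_i)
  if (np > 0) {
    for (p in seq_len(np)) {
      if (potts$pair_i[p] == i) {
        u <- potts$pair_j[p]
        d <- d + potts$pair_mats[p, mi, s[u]] - potts$pair_mats[p, s[i], s[u]]
      } else if (potts$pair_j[p] == i) {
        u <- potts$pair_i[p]
        d <- d + potts$pair_mats[p, s[u], mi] - potts$pair_mats[p, s[u], s[i]]
      }
    }
  }
  d
}

#' Peptide binding score
#'
#' Sum of self-energy contributions at the peptide positions plus every
#' pair-energy contribution touching at least one peptide position
#' (peptide-internal and peptide-protein cross pairs), each unordered pair
#' counted once.
#'
#' @param potts a `PottsModel`.
#' @param seq complex sequence of length L.
#' @param peptide_positions nonempty set of positions in 1..L.
#' @return numeric scalar.
#' @export
peptide_binding_score <- function(potts, seq, peptide_positions) {
  if (!length(peptide_positions)) stop("empty peptide position set")
  pep <- as.integer(peptide_positions)
  stopifnot(all(pep >= 1), all(pep <= potts$L))
  s <- seq_to_int(seq)
  e <- sum(potts$self[cbind(pep, s[pep])])
  np <- length(potts$pair_i)
  if (np > 0) {
    touch <- potts$pair_i %in% pep | potts$pair_j %in% pep
    if (any(touch)) {
      w <- which(touch)
      e <- e + sum(potts$pair_mats[cbind(w, s[potts$pair_i[w]], s[potts$pair_j[w]])])
    }
  }
  e
}

# Serialization ------------------------------------------------------------

#' Write / read a Potts energy table
#'
#' The text format has a header line `ETAB <L> 20 <alphabet>`, then lines
#' `self <i> <AA> <value>` and `pair <i> <j> <AA_i> <AA_j> <value>` with
#' `i < j` canonical order and values at 17 significant digits. The binary
#' format (RDS) round-trips bit-exactly.
#'
#' @param potts a `PottsModel`.
#' @param path output path.
#' @param format `"text"` or `"binary"`.
#' @export
write_etab <- function(potts, path, format = c("text", "binary")) {
  format <- match.arg(format)
  if (format == "binary") {
    saveRDS(potts, path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("ETAB %d 20 %s", potts$L, paste(AA_ALPHABET, collapse = "")), con)
  for (i in seq_len(potts$L)) {
    writeLines(sprintf("self %d %s %.17g", i, AA_ALPHABET, potts$self[i, ]), con)
  }
  for (p in seq_along(potts$pair_i)) {
    i <- potts$pair_i[p]; j <- potts$pair_j[p]
    for (m in 1:20) {
      writeLines(sprintf("pair %d %d %s %s %.17g", i, j, AA_ALPHABET[m],
                         AA_ALPHABET, potts$pair_mats[p, m, ]), con)
    }
  }
  invisible(path)
}

#' @rdname write_etab
#' @param path input path; format is detected (RDS binary vs text header).
#' @return a `PottsModel`.
#' @export
read_etab <- function(path) {
  first <- tryCatch(readLines(path, n = 1, warn = FALSE), error = function(e) "")
  if (!length(first) || !startsWith(first, "ETAB")) {
    x <- readRDS(path)
    if (!inherits(x, "PottsModel")) stop("not a Potts energy table archive")
    return(x)
  }
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " +")[[1]]
  L <- as.integer(hdr[2])
  self <- matrix(0, L, 20)
  pair_env <- new.env(parent = emptyenv())
  for (ln in seq(2L, length(lines))) {
    f <- strsplit(lines[ln], " +")[[1]]
    if (f[1] == "self" && length(f) == 4) {
      self[as.integer(f[2]), seq_to_int(f[3])] <- as.numeric(f[4])
    } else if (f[1] == "pair" && length(f) == 6) {
      i <- as.integer(f[2]); j <- as.integer(f[3])
      m <- seq_to_int(f[4]); n <- seq_to_int(f[5])
      if (i > j) { tmp <- i; i <- j; j <- tmp; tmp <- m; m <- n; n <- tmp }
      key <- paste(i, j)
      if (is.null(pair_env[[key]])) pair_env[[key]] <- matrix(0, 20, 20)
      pair_env[[key]][m, n] <- as.numeric(f[6])
    } else {
      stop("malformed etab line ", ln, ": ", lines[ln])
    }
  }
  keys <- ls(pair_env)
  np <- length(keys)
  pi_ <- pj_ <- integer(np)
  mats <- array(0, c(np, 20, 20))
  for (p in seq_len(np)) {
    ij <- as.integer(strsplit(keys[p], " ")[[1]])
    pi_[p] <- ij[1]; pj_[p] <- ij[2]
    mats[p, , ] <- pair_env[[keys[p]]]
  }
  potts_new(self, pi_, pj_, mats)
}

#' Transform a Potts model to the zero-sum (Ising) gauge
#'
#' Potts parameters are only identified up to gauge transformations that
#' move per-position letter functions between self and pair tables without
#' changing any energy difference or pseudo-likelihood. The zero-sum gauge
#' is the canonical representative: every pair table has zero row and
#' column means, and the absorbed means are moved into the self energies
#' (plus a sequence-independent constant, returned as `constant`).
#' Interpreting or comparing single-site preferences (e.g. argmax of self
#' energy, self- vs pair-energy magnitudes) is only meaningful in this
#' gauge.
#'
#' @param potts a `PottsModel`.
#' @return a `PottsModel` in zero-sum gauge with attribute `constant` (the
#'   energy offset such that old and new total energies differ by it).
#' @export
zero_sum_gauge <- function(potts) {
  self <- potts$self
  mats <- potts$pair_mats
  const <- 0
  for (p in seq_along(potts$pair_i)) {
    P <- mats[p, , ]
    rm_ <- rowMeans(P)
    cm <- colMeans(P)
    gm <- mean(P)
    self[potts$pair_i[p], ] <- self[potts$pair_i[p], ] + rm_ - gm
    self[potts$pair_j[p], ] <- self[potts$pair_j[p], ] + cm - gm
    mats[p, , ] <- P - outer(rm_, rep(1, 20)) - outer(rep(1, 20), cm) + gm
    const <- const - gm
  }
  out <- potts_new(self, potts$pair_i, potts$pair_j, mats)
  attr(out, "constant") <- const  # total_energy(new) = total_energy(old) + constant
  out
}

# random Potts model on given pair set, for tests and simulations
#' Random PottsModel (testing utility)
#'
#' @param L length; `pairs` 2-column matrix (default: all unordered pairs).
#' @param sd energy scale of the N(0, sd) entries.
#' @return a `PottsModel`.
#' @export
random_potts <- function(L, pairs = NULL, sd = 1) {
  if (is.null(pairs)) pairs <- t(combn(L, 2))
  np <- nrow(pairs)
  potts_new(matrix(rnorm(L * 20, sd = sd), L, 20),
            pairs[, 1], pairs[, 2],
            array(rnorm(np * 400, sd = sd), c(np, 20, 20)))
}
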