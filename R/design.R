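# Sequence design: exact arrangement counting, Wootton-Federhen-style
# complexity, penalized energies, MCMC simulated annealing, the two-stage
# design protocol, and NSR-matched randomized control sequences.

# --- exact big-integer arithmetic (base 1e9, little-endian digit vector) ---
# Only multiplication and exact division by machine-size integers are
# needed: the multinomial is built by the incremental binomial recurrence
# result <- result * n / t, whose intermediates are always integers.

.BIGBASE <- 1e9

.big_one <- function() c(1)

.big_mul_small <- function(x, m) {
  carry <- 0
  for (d in seq_along(x)) {
    v <- x[d] * m + carry
    x[d] <- v %% .BIGBASE
    carry <- (v - x[d]) / .BIGBASE
  }
  while (carry > 0) {
    x <- c(x, carry %% .BIGBASE)
    carry <- (carry - carry %% .BIGBASE) / .BIGBASE
  }
  x
}

.big_div_small <- function(x, m) {
  rem <- 0
  for (d in rev(seq_along(x))) {
    v <- rem * .BIGBASE + x[d]
    q <- v %/% m
    rem <- v - q * m
    x[d] <- q
  }
  if (rem != 0) stop("inexact big-integer division")  # cannot happen here
  while (length(x) > 1 && x[length(x)] == 0) x <- x[-length(x)]
  x
}

.big_to_string <- function(x) {
  n <- length(x)
  paste0(format(x[n], scientific = FALSE),
         paste(sprintf("%09.0f", rev(x[-n])), collapse = ""))
}

#' Number of distinct arrangements of a sequence's letters
#'
#' The exact multinomial coefficient Omega(S) = L! / prod(n_i!) where n_i
#' counts occurrences of letter i, computed in big-integer arithmetic (no
#' floating-point overflow at any length).
#'
#' @param seq nonempty sequence string.
#' @return object of class `bigint`; use [as.character()] for the exact
#'   decimal value or [as.numeric()] (exact below 2^53).
#' @export
arrangements <- function(seq) {
  s <- seq_to_int(seq)
  if (!length(s)) stop("empty sequence")
  counts <- tabulate(s, 20)
  x <- .big_one()
  n <- 0
  for (cnt in counts[counts > 0]) {
    for (t in seq_len(cnt)) {
      n <- n + 1
      x <- .big_mul_small(x, n)
      x <- .big_div_small(x, t)
    }
  }
  structure(list(digits = x), class = "bigint")
}

#' @export
as.character.bigint <- function(x, ...) .big_to_string(x$digits)

#' @export
as.numeric.bigint <- function(x, ...) {
  sum(x$digits * .BIGBASE^(seq_along(x$digits) - 1))
}

#' @export
print.bigint <- function(x, ...) {
  cat(.big_to_string(x$digits), "\n")
  invisible(x)
}

#' Natural log of the arrangement count
#'
#' `log Omega(S)` evaluated with log-gamma (overflow-free).
#'
#' @param seq sequence string.
#' @return numeric scalar.
#' @export
log_arrangements <- function(seq) {
  s <- seq_to_int(seq)
  counts <- tabulate(s, 20)
  lgamma(length(s) + 1) - sum(lgamma(counts + 1))
}

#' Sequence complexity K(S)
#'
#' K(S) = (1/L) log Omega(S), natural-log convention, in [0, ln 20).
#' Designs with K below 1.67 are classified low-complexity.
#'
#' @param seq sequence string.
#' @return numeric scalar.
#' @export
complexity <- function(seq) {
  log_arrangements(seq) / nchar(seq)
}

#' Low-complexity classification threshold
#' @export
LOW_COMPLEXITY_THRESHOLD <- 1.67

#' Complexity-penalized design energy
#'
#' E_new(S) = E_potts(S) - a * log Omega(S); the default a = 1.
#'
#' @param potts a `PottsModel`.
#' @param seq sequence of length L.
#' @param a penalty weight (>= 0).
#' @return numeric scalar.
#' @export
penalized_energy <- function(potts, seq, a = 1) {
  stopifnot(a >= 0)
  total_energy(potts, seq) - a * log_arrangements(seq)
}

#' Annealing schedule
#'
#' @param n_cycles Metropolis cycles per restart.
#' @param kT_start,kT_end temperatures (kT_start >= kT_end > 0); the
#'   temperature decays geometrically (default) or linearly across cycles.
#' @param n_restarts independent restarts; the best-seen sequence across
#'   restarts is reported (ties broken lexicographically).
#' @param seed RNG seed.
#' @param decay `"geometric"` or `"linear"`.
#' @return object of class `AnnealSchedule`.
#' @export
anneal_schedule <- function(n_cycles = 1e6, kT_start = 1, kT_end = 0.1,
                            n_restarts = 1L, seed = 1L,
                            decay = c("geometric", "linear")) {
  stopifnot(n_cycles >= 1, kT_start >= kT_end, kT_end > 0, n_restarts >= 1)
  x <- list(n_cycles = n_cycles, kT_start = kT_start, kT_end = kT_end,
            n_restarts = as.integer(n_restarts), seed = as.integer(seed),
            decay = match.arg(decay))
  class(x) <- "AnnealSchedule"
  x
}

# CSR adjacency of the pair list, as consumed by the C++ core
.potts_adjacency <- function(potts) {
  L <- potts$L
  np <- length(potts$pair_i)
  deg <- integer(L)
  if (np > 0) {
    for (p in seq_len(np)) {
      deg[potts$pair_i[p]] <- deg[potts$pair_i[p]] + 1L
      deg[potts$pair_j[p]] <- deg[potts$pair_j[p]] + 1L
    }
  }
  start <- c(0L, cumsum(deg))
  fill <- integer(L)
  adj_pair <- adj_other <- adj_orient <- integer(sum(deg))
  if (np > 0) {
    for (p in seq_len(np)) {
      i <- potts$pair_i[p]; j <- potts$pair_j[p]
      k <- start[i] + fill[i] + 1L
      adj_pair[k] <- p - 1L; adj_other[k] <- j - 1L; adj_orient[k] <- 1L
      fill[i] <- fill[i] + 1L
      k <- start[j] + fill[j] + 1L
      adj_pair[k] <- p - 1L; adj_other[k] <- i - 1L; adj_orient[k] <- 2L
      fill[j] <- fill[j] + 1L
    }
  }
  list(start = start, pair = adj_pair, other = adj_other, orient = adj_orient)
}

#' MCMC simulated annealing over sequence space
#'
#' Metropolis sampling with single-site uniform mutations and a decaying
#' temperature; the best-seen (not final) sequence is returned. With a
#' `PottsModel` energy the inner loop runs in compiled code with
#' incremental O(degree) deltas and supports the low-complexity penalty
#' `E_new = E_potts - a log Omega`; with an arbitrary R function
#' `energy(seq_string)` a reference R loop is used.
#'
#' @param energy a `PottsModel` or a function of a sequence string.
#' @param L sequence length (required for a function energy; implied by a
#'   Potts model).
#' @param schedule an [anneal_schedule()].
#' @param a low-complexity penalty weight (Potts energies only).
#' @return list with `sequence`, `energy` (Potts energy of the returned
#'   sequence), `objective` (penalized energy when `a > 0`), `complexity`,
#'   and `restarts` (per-restart summaries).
#' @export
anneal <- function(energy, L = NULL, schedule = anneal_schedule(), a = 0) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(schedule$seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  geometric <- schedule$decay == "geometric"
  if (inherits(energy, "PottsModel")) {
    potts <- energy
    L <- potts$L
    adj <- .potts_adjacency(potts)
    np <- length(potts$pair_i)
    runs <- vector("list", schedule$n_restarts)
    for (r in seq_len(schedule$n_restarts)) {
      start <- sample.int(20L, L, replace = TRUE)
      runs[[r]] <- .anneal_potts_cpp(potts$self, as.vector(potts$pair_mats),
                                     np, potts$pair_i, potts$pair_j,
                                     adj$start, adj$pair, adj$other,
                                     adj$orient, start, schedule$n_cycles,
                                     schedule$kT_start, schedule$kT_end,
                                     geometric, a)
      runs[[r]]$sequence <- int_to_seq(runs[[r]]$sequence)
      runs[[r]]$final_sequence <- int_to_seq(runs[[r]]$final_sequence)
      if (a == 0) runs[[r]]$objective <- runs[[r]]$energy
    }
    objs <- vapply(runs, `[[`, numeric(1), "objective")
    seqs <- vapply(runs, `[[`, character(1), "sequence")
    best <- order(objs, seqs)[1]  # ties -> lexicographically smallest
    res <- runs[[best]]
    list(sequence = res$sequence, energy = res$energy,
         objective = res$objective, complexity = complexity(res$sequence),
         final_sequence = res$final_sequence, final_energy = res$final_energy,
         restarts = data.frame(energy = vapply(runs, `[[`, numeric(1), "energy"),
                               objective = objs, sequence = seqs,
                               final_energy = vapply(runs, `[[`, numeric(1), "final_energy")))
  } else {
    stopifnot(is.function(energy), !is.null(L))
    best_seq <- NULL; best_e <- Inf
    uphill_attempts <- 0L; uphill_accepts <- 0L
    runs <- data.frame()
    for (r in seq_len(schedule$n_restarts)) {
      s <- sample.int(20L, L, replace = TRUE)
      e <- energy(int_to_seq(s))
      rbest_s <- s; rbest_e <- e
      n <- schedule$n_cycles
      for (t in seq_len(n)) {
        kT <- if (n == 1) schedule$kT_start else if (geometric) {
          schedule$kT_start * (schedule$kT_end / schedule$kT_start)^((t - 1) / (n - 1))
        } else {
          schedule$kT_start + (schedule$kT_end - schedule$kT_start) * (t - 1) / (n - 1)
        }
        pos <- sample.int(L, 1L)
        prop <- sample.int(19L, 1L)
        if (prop >= s[pos]) prop <- prop + 1L
        s2 <- s; s2[pos] <- prop
        e2 <- energy(int_to_seq(s2))
        uphill <- e2 > e
        if (uphill) uphill_attempts <- uphill_attempts + 1L
        if (!uphill || runif(1) < exp(-(e2 - e) / kT)) {
          if (uphill) uphill_accepts <- uphill_accepts + 1L
          s <- s2; e <- e2
          if (e < rbest_e) { rbest_e <- e; rbest_s <- s }
        }
      }
      runs <- rbind(runs, data.frame(energy = rbest_e,
                                     sequence = int_to_seq(rbest_s),
                                     final_energy = e))
      if (rbest_e < best_e ||
          (rbest_e == best_e && int_to_seq(rbest_s) < best_seq)) {
        best_e <- rbest_e; best_seq <- int_to_seq(rbest_s)
        final_seq <- int_to_seq(s); final_e <- e
      }
    }
    list(sequence = best_seq, energy = best_e, objective = best_e,
         complexity = complexity(best_seq), final_sequence = final_seq,
         final_energy = final_e, restarts = runs,
         uphill_attempts = uphill_attempts, uphill_accepts = uphill_accepts)
  }
}

#' Two-stage sequence design protocol
#'
#' Stage 1 samples `restarts1` sequences by simulated annealing
#' (`cycles1` cycles each, kT 1 -> 0.1) and keeps the lowest-energy one.
#' If its complexity falls below `threshold` it is flagged low-complexity
#' and redesigned: `restarts2` runs of `cycles2` cycles at kT 10 -> 0.1 on
#' the penalized energy E_new with weight `a`, keeping the lowest E_new.
#'
#' @param potts a `PottsModel`.
#' @param threshold low-complexity threshold on K(S).
#' @param a penalty weight for the redesign stage.
#' @param restarts1,cycles1 stage-1 budget (defaults 100 x 1e6).
#' @param restarts2,cycles2 redesign budget (defaults 10 x 2e6).
#' @param kT1,kT2 temperature ranges of the two stages.
#' @param seed RNG seed.
#' @return object of class `DesignResult`: `sequence`, `potts_energy`,
#'   `penalized_energy` (redesigns only), `complexity`,
#'   `low_complexity_flag`, `stage`, `stage1` (its result), seeds and
#'   schedules used.
#' @export
design_protocol <- function(potts, threshold = LOW_COMPLEXITY_THRESHOLD, a = 1,
                            restarts1 = 100L, cycles1 = 1e6,
                            restarts2 = 10L, cycles2 = 2e6,
                            kT1 = c(1, 0.1), kT2 = c(10, 0.1), seed = 1L) {
  sch1 <- anneal_schedule(cycles1, kT1[1], kT1[2], restarts1, seed)
  s1 <- anneal(potts, schedule = sch1, a = 0)
  flagged <- s1$complexity < threshold
  res <- list(sequence = s1$sequence, potts_energy = s1$energy,
              penalized_energy = NULL, complexity = s1$complexity,
              low_complexity_flag = flagged, stage = "primary",
              stage1 = list(sequence = s1$sequence, energy = s1$energy,
                            complexity = s1$complexity),
              schedules = list(stage1 = sch1), seed = seed, threshold = threshold)
  if (flagged) {
    sch2 <- anneal_schedule(cycles2, kT2[1], kT2[2], restarts2, seed + 1L)
    s2 <- anneal(potts, schedule = sch2, a = a)
    res$sequence <- s2$sequence
    res$potts_energy <- s2$energy
    res$penalized_energy <- s2$objective
    res$complexity <- s2$complexity
    res$stage <- "redesign"
    res$schedules$stage2 <- sch2
  }
  class(res) <- "DesignResult"
  res
}

#' @export
print.DesignResult <- function(x, ...) {
  cat(sprintf("DesignResult (%s): E = %.4f, K = %.4f%s\n", x$stage,
              x$potts_energy, x$complexity,
              if (x$low_complexity_flag) " [low-complexity, redesigned]" else ""))
  cat(x$sequence, "\n")
  invisible(x)
}

#' NSR-matched randomized control sequence
#'
#' Keeps exactly `ceiling(L * nsr / 100)` randomly chosen positions native
#' and assigns every other position a uniform draw from the 19 letters
#' different from its native letter.
#'
#' @param native_seq native sequence string.
#' @param target_nsr_percent target native sequence recovery in [0, 100].
#' @param seed RNG seed.
#' @return sequence string.
#' @export
randomized_control <- function(native_seq, target_nsr_percent, seed = 1L) {
  stopifnot(target_nsr_percent >= 0, target_nsr_percent <= 100)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  s <- seq_to_int(native_seq)
  L <- length(s)
  n_native <- as.integer(ceiling(L * target_nsr_percent / 100))
  keep <- if (n_native > 0) sample.int(L, n_native) else integer(0)
  out <- s
  for (i in setdiff(seq_len(L), keep)) {
    prop <- sample.int(19L, 1L)
    out[i] <- if (prop >= s[i]) prop + 1L else prop
  }
  int_to_seq(out)
}
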