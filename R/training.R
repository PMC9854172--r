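# Training: composite pseudo-likelihood gradients, semi-shuffle batching,
# Noam-scheduled Adam, early stopping, and affinity fine-tuning with a
# frozen trunk.

#' Training configuration
#'
#' @param max_epochs epoch cap.
#' @param batch_residue_cap greedy packing cap on total residues per batch.
#' @param partition_size size of the sorted partitions that are shuffled
#'   internally before packing.
#' @param warmup_steps Noam schedule warm-up.
#' @param loss_weights named list: `ncpl`, `norm`, `cor` weights.
#' @param patience epochs without validation improvement before stopping.
#' @param seed RNG seed for batching, dropout and initialization.
#' @param k neighbor count for featurization.
#' @param lr_scale multiplier on the Noam learning rate.
#' @param finetune_lr constant Adam learning rate used by [finetune()].
#' @return object of class `TrainConfig`.
#' @export
train_config <- function(max_epochs = 100L, batch_residue_cap = 6000L,
                         partition_size = 500L, warmup_steps = 4000L,
                         loss_weights = list(ncpl = 1, norm = 0, cor = 0),
                         patience = 10L, seed = 1L, k = 30L, lr_scale = 1,
                         finetune_lr = 1e-3) {
  stopifnot(batch_residue_cap > 0, partition_size > 0, max_epochs >= 1,
            warmup_steps >= 1)
  w <- modifyList(list(ncpl = 1, norm = 0, cor = 0), as.list(loss_weights))
  if (any(unlist(w) < 0)) stop("loss weights must be >= 0")
  x <- list(max_epochs = as.integer(max_epochs),
            batch_residue_cap = as.integer(batch_residue_cap),
            partition_size = as.integer(partition_size),
            warmup_steps = as.integer(warmup_steps), loss_weights = w,
            patience = as.integer(patience), seed = as.integer(seed),
            k = as.integer(k), lr_scale = lr_scale, finetune_lr = finetune_lr)
  class(x) <- "TrainConfig"
  x
}

#' Semi-shuffle batching
#'
#' Proteins are sorted by residue count, partitioned into partitions of
#' `partition_size`, shuffled within each partition, then greedily packed
#' into batches while a batch holds fewer than `cap` residues; finally the
#' batch order is fully shuffled. A single protein above the cap forms a
#' singleton batch (never dropped). Deterministic given the current RNG
#' state is not assumed: pass `seed`.
#'
#' @param dataset list of `Structure`s.
#' @param cap residue cap per batch.
#' @param partition_size partition size for the local shuffle.
#' @param seed RNG seed.
#' @return list of integer index vectors into `dataset`.
#' @export
semi_shuffle_batches <- function(dataset, cap = 6000L, partition_size = 500L,
                                 seed = 1L) {
  if (!length(dataset)) stop("empty dataset")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed, kind = "Mersenne-Twister", sample.kind = "Rejection")
  sizes <- vapply(dataset, function(s) s$n, integer(1))
  ord <- order(sizes, seq_along(sizes))
  n <- length(ord)
  parts <- split(ord, ceiling(seq_len(n) / partition_size))
  ord <- unlist(lapply(parts, function(p) if (length(p) > 1) sample(p) else p),
                use.names = FALSE)
  batches <- list()
  cur <- integer(0); cur_res <- 0L
  for (idx in ord) {
    if (length(cur) && cur_res + sizes[idx] > cap) {
      batches[[length(batches) + 1L]] <- cur
      cur <- integer(0); cur_res <- 0L
    }
    if (sizes[idx] > cap) {
      message("protein of ", sizes[idx], " residues exceeds batch cap; singleton batch")
    }
    cur <- c(cur, idx); cur_res <- cur_res + sizes[idx]
  }
  if (length(cur)) batches[[length(batches) + 1L]] <- cur
  if (length(batches) > 1) batches <- batches[sample(length(batches))]
  batches
}

#' Noam learning rate
#'
#' `dim^(-0.5) * min(step^(-0.5), step * warmup^(-1.5))`: linear warm-up to
#' the maximum at `step = warmup`, then inverse-square-root decay.
#'
#' @param step optimizer step (>= 1).
#' @param dim model dimensionality.
#' @param warmup warm-up step count.
#' @return learning rate.
#' @export
noam_lr <- function(step, dim = 128, warmup = 4000) {
  if (any(step < 1)) stop("step must be >= 1")
  dim^(-0.5) * pmin(step^(-0.5), step * warmup^(-1.5))
}

#' Negated Pearson correlation loss
#'
#' @param pred,exp numeric vectors (length >= 3, nonzero variance).
#' @return `-r`, in `[-1, 1]`.
#' @export
pearson_loss <- function(pred, exp) {
  if (length(pred) < 3 || length(pred) != length(exp)) {
    stop("need >= 3 paired values")
  }
  if (sd(pred) == 0 || sd(exp) == 0) stop("undefined correlation: zero variance")
  -cor(pred, exp)
}

# gradient of pearson_loss w.r.t. pred
.pearson_loss_grad <- function(pred, exp) {
  pc <- pred - mean(pred)
  ec <- exp - mean(exp)
  sp <- sqrt(sum(pc^2)); se <- sqrt(sum(ec^2))
  r <- sum(pc * ec) / (sp * se)
  -(ec / se - r * pc / sp) / sp
}

# Summed (not averaged) ncpl loss over all pair edges of a Potts model, with
# gradients w.r.t. the Potts tables. Returns list(loss_sum, n_pairs, g_self,
# g_pairs); caller normalizes.
ncpl_grad_potts <- function(potts, seq) {
  s <- seq_to_int(seq)
  L <- potts$L
  np <- length(potts$pair_i)
  if (np == 0) stop("Potts model has no pair edges")
  # context sums C[i, k] = sum over partners u of E_p(i, k, u, s_u)
  C <- matrix(0, L, 20)
  for (p in seq_len(np)) {
    i <- potts$pair_i[p]; j <- potts$pair_j[p]
    C[i, ] <- C[i, ] + potts$pair_mats[p, , s[j]]
    C[j, ] <- C[j, ] + potts$pair_mats[p, s[i], ]
  }
  inc <- .incidence(potts)
  g_self <- matrix(0, L, 20)
  g_pairs <- array(0, c(np, 20, 20))
  loss <- 0
  for (p in seq_len(np)) {
    i <- potts$pair_i[p]; j <- potts$pair_j[p]
    pm <- potts$pair_mats[p, , ]
    a <- potts$self[i, ] + C[i, ] - pm[, s[j]]
    b <- potts$self[j, ] + C[j, ] - pm[s[i], ]
    E <- outer(a, b, "+") + pm
    neg <- -E
    mx <- max(neg)
    w <- exp(neg - mx)
    Z <- sum(w)
    loss <- loss + E[s[i], s[j]] + mx + log(Z)
    g <- -w / Z
    g[s[i], s[j]] <- g[s[i], s[j]] + 1   # d(-log p)/dE_cp = delta - q
    rg <- rowSums(g)                      # into terms linear in letter at i
    cg <- colSums(g)                      # into terms linear in letter at j
    g_self[i, ] <- g_self[i, ] + rg
    g_self[j, ] <- g_self[j, ] + cg
    g_pairs[p, , ] <- g_pairs[p, , ] + g
    for (r in seq_len(nrow(inc[[i]]))) {
      q <- inc[[i]][r, 1]; u <- inc[[i]][r, 2]
      if (u == j) next
      if (inc[[i]][r, 3] == 1L) {
        g_pairs[q, , s[u]] <- g_pairs[q, , s[u]] + rg
      } else {
        g_pairs[q, s[u], ] <- g_pairs[q, s[u], ] + rg
      }
    }
    for (r in seq_len(nrow(inc[[j]]))) {
      q <- inc[[j]][r, 1]; u <- inc[[j]][r, 2]
      if (u == i) next
      if (inc[[j]][r, 3] == 1L) {
        g_pairs[q, , s[u]] <- g_pairs[q, , s[u]] + cg
      } else {
        g_pairs[q, s[u], ] <- g_pairs[q, s[u], ] + cg
      }
    }
  }
  list(loss_sum = loss, n_pairs = np, g_self = g_self, g_pairs = g_pairs)
}

# norm penalty and its gradient w.r.t. the Potts tables
norm_grad_potts <- function(potts) {
  S <- sum(potts$self^2) + 2 * sum(potts$pair_mats^2)
  if (S == 0) {
    return(list(value = 0, g_self = potts$self * 0, g_pairs = potts$pair_mats * 0))
  }
  r <- sqrt(S)
  list(value = r / potts$L,
       g_self = potts$self / (potts$L * r),
       g_pairs = 2 * potts$pair_mats / (potts$L * r))
}

# Adam with Noam schedule (Vaswani defaults: beta1 .9, beta2 .98, eps 1e-9)
.adam_new <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr, names = NULL,
                       beta1 = 0.9, beta2 = 0.98, eps = 1e-9) {
  state$t <- state$t + 1L
  if (is.null(names)) names <- names(grads)
  for (nm in names) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# accumulate grads (named lists of arrays) in place
.acc_grads <- function(acc, g, scale = 1) {
  for (nm in names(g)) {
    acc[[nm]] <- if (is.null(acc[[nm]])) g[[nm]] * scale else acc[[nm]] + g[[nm]] * scale
  }
  acc
}

# loss + parameter gradients for one structure (ncpl summed over pairs plus
# optional norm penalty); featurized graph supplied by the caller
.structure_loss_grad <- function(params, graph, sequence, w_norm, training = FALSE) {
  enc <- encode(params, graph, training = training, keep_cache = TRUE)
  potts <- project_potts(params, graph, enc$edge_embeddings)
  ng <- ncpl_grad_potts(potts, sequence)
  g_self <- ng$g_self
  g_pairs <- ng$g_pairs
  norm_val <- 0
  if (w_norm > 0) {
    nq <- norm_grad_potts(potts)
    norm_val <- nq$value
    # norm term enters per structure with weight w_norm (ncpl term is a sum
    # here; the caller divides by the batch pair total and scales this term
    # by n_pairs so both are per-pair comparable after normalization)
    g_self <- g_self + w_norm * ng$n_pairs * nq$g_self
    g_pairs <- g_pairs + w_norm * ng$n_pairs * nq$g_pairs
  }
  pb <- project_potts_backward(params, graph, enc$edge_embeddings, g_self, g_pairs)
  grads <- encode_backward(params, graph, enc$cache, pb$g_edge)
  grads[["out.W"]] <- pb$g_out_W
  grads[["out.b"]] <- pb$g_out_b
  list(grads = grads, ncpl_sum = ng$loss_sum, n_pairs = ng$n_pairs,
       norm = norm_val)
}

# mean ncpl over a list of (graph, sequence), pair-count weighted
.validation_ncpl <- function(params, graphs, sequences) {
  tot <- 0; n <- 0
  for (i in seq_along(graphs)) {
    potts <- potts_forward(params, NULL, graph = graphs[[i]])
    pairs <- cbind(potts$pair_i, potts$pair_j)
    tot <- tot + sum(.ncpl_terms(potts, sequences[[i]], pairs))
    n <- n + nrow(pairs)
  }
  tot / n
}

#' Train the encoder by composite pseudo-likelihood
#'
#' Minimizes `w_ncpl * ncpl + w_norm * mean Lnorm` per batch (pair-count
#' weighted across the proteins of a batch) with Noam-scheduled Adam,
#' tracks validation ncpl each epoch, and restores the best-validation
#' checkpoint (early stopping after `patience` epochs without improvement).
#'
#' @param train_set,val_set lists of `Structure`s with native sequences.
#' @param config a [train_config()].
#' @param params optional warm-start `EncoderParams`; default a fresh
#'   [init_encoder()] at `config$seed` and dimensionality from
#'   `encoder_cfg`.
#' @param encoder_cfg an [encoder_config()] used when `params` is NULL.
#' @param verbose print per-epoch losses.
#' @return list with `params` (best checkpoint) and `history` (data.frame
#'   epoch / train_loss / val_loss / lr).
#' @export
train_encoder <- function(train_set, val_set, config = train_config(),
                          params = NULL, encoder_cfg = NULL, verbose = FALSE) {
  if (!length(train_set) || !length(val_set)) stop("need train and validation sets")
  if (is.null(params)) {
    if (is.null(encoder_cfg)) {
      encoder_cfg <- encoder_config(seed = config$seed, k = config$k)
    }
    params <- init_encoder(encoder_cfg)
  }
  cfg <- attr(params, "config")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed + 1L, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  tr_graphs <- lapply(train_set, featurize, k = cfg$k)
  va_graphs <- lapply(val_set, featurize, k = cfg$k)
  tr_seqs <- lapply(train_set, `[[`, "sequence")
  va_seqs <- lapply(val_set, `[[`, "sequence")
  w <- config$loss_weights
  adam <- .adam_new(params)
  step <- 0L
  best_val <- Inf
  best_params <- params
  bad_epochs <- 0L
  hist <- data.frame()
  for (epoch in seq_len(config$max_epochs)) {
    batches <- semi_shuffle_batches(train_set, config$batch_residue_cap,
                                    config$partition_size,
                                    seed = config$seed + 1000L * epoch)
    ep_loss <- 0; ep_pairs <- 0
    for (b in batches) {
      acc <- list()
      b_ncpl <- 0; b_pairs <- 0; b_norm <- 0
      for (idx in b) {
        sl <- .structure_loss_grad(params, tr_graphs[[idx]], tr_seqs[[idx]],
                                   w_norm = w$norm, training = TRUE)
        acc <- .acc_grads(acc, sl$grads)
        b_ncpl <- b_ncpl + sl$ncpl_sum
        b_pairs <- b_pairs + sl$n_pairs
        b_norm <- b_norm + sl$norm * sl$n_pairs
      }
      if (!is.finite(b_ncpl)) stop("training diverged (non-finite loss)")
      scale <- w$ncpl / b_pairs
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] * scale
      step <- step + 1L
      lr <- config$lr_scale * noam_lr(step, cfg$hidden_dim, config$warmup_steps)
      upd <- .adam_step(params, acc, adam, lr)
      params <- upd$params; adam <- upd$state
      ep_loss <- ep_loss + b_ncpl
      ep_pairs <- ep_pairs + b_pairs
    }
    val <- .validation_ncpl(params, va_graphs, va_seqs)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / ep_pairs,
                                   val_loss = val, lr = lr))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      ep_loss / ep_pairs, val))
    }
    if (val < best_val) {
      best_val <- val
      best_params <- params
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs > config$patience) break
    }
  }
  list(params = best_params, history = hist, best_val = best_val)
}

#' Assemble an affinity dataset
#'
#' @param template `Structure` of the complex.
#' @param records data.frame with columns `sequence` (full complex
#'   sequences, length L of the template) and `value` (measured affinity on
#'   an energy-like scale: lower = tighter).
#' @param peptide_positions positions of the peptide within the complex.
#' @param id template identifier.
#' @return object of class `AffinityDataset`.
#' @export
affinity_dataset <- function(template, records, peptide_positions, id = "template") {
  stopifnot(is.data.frame(records), all(c("sequence", "value") %in% names(records)))
  if (nrow(records) < 3) stop("need >= 3 affinity records")
  if (any(nchar(records$sequence) != template$n)) {
    stop("record sequences must match template length")
  }
  x <- list(template = template, records = records,
            peptide_positions = as.integer(peptide_positions), id = id)
  class(x) <- "AffinityDataset"
  x
}

#' Read / write affinity TSV (sequence, value)
#' @param path TSV path with header `sequence value`.
#' @return data.frame.
#' @export
read_affinity_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("sequence", "value") %in% names(df)))
  df
}

#' @rdname read_affinity_tsv
#' @param records data.frame with `sequence` and `value`.
#' @export
write_affinity_tsv <- function(records, path) {
  utils::write.table(records[, c("sequence", "value")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# binding-score predictions for every record of an affinity dataset, plus the
# gradient scaffold (list of index matrices) reused across steps
.binding_predictions <- function(potts, ads) {
  vapply(ads$records$sequence, function(sq) {
    peptide_binding_score(potts, sq, ads$peptide_positions)
  }, numeric(1), USE.NAMES = FALSE)
}

# gradient of sum_r dL[r] * score_r w.r.t. Potts tables
.binding_score_grad <- function(potts, ads, dL) {
  L <- potts$L
  pep <- ads$peptide_positions
  np <- length(potts$pair_i)
  touch <- which(potts$pair_i %in% pep | potts$pair_j %in% pep)
  g_self <- matrix(0, L, 20)
  g_pairs <- array(0, c(np, 20, 20))
  for (r in seq_len(nrow(ads$records))) {
    if (dL[r] == 0) next
    s <- seq_to_int(ads$records$sequence[r])
    idx <- cbind(pep, s[pep])
    g_self[idx] <- g_self[idx] + dL[r]
    if (length(touch)) {
      pidx <- cbind(touch, s[potts$pair_i[touch]], s[potts$pair_j[touch]])
      g_pairs[pidx] <- g_pairs[pidx] + dL[r]
    }
  }
  list(g_self = g_self, g_pairs = g_pairs)
}

#' Fine-tune the output projection on affinity data
#'
#' All trunk weights are frozen; only the output projection (`out.W`,
#' `out.b`) is trained. Per step and template the loss is
#' `w_ncpl * ncpl(native | template) + w_cor * pearson_loss(predicted
#' binding scores, measurements)` with the 1:100 default weighting; early
#' stopping monitors the mean validation pearson_loss.
#'
#' @param params trained `EncoderParams`.
#' @param train_sets,val_sets lists of [affinity_dataset()]s.
#' @param config a [train_config()]; uses `loss_weights$ncpl`,
#'   `loss_weights$cor` (default here 1 and 100), `max_epochs`, `patience`,
#'   `finetune_lr`.
#' @return list with `params`, `history` (epoch / train_loss / val_cor_loss).
#' @export
finetune <- function(params, train_sets, val_sets,
                     config = train_config(max_epochs = 100L, patience = 10L,
                                           loss_weights = list(ncpl = 1, cor = 100))) {
  if (inherits(train_sets, "AffinityDataset")) train_sets <- list(train_sets)
  if (inherits(val_sets, "AffinityDataset")) val_sets <- list(val_sets)
  cfg <- attr(params, "config")
  w <- config$loss_weights
  if (is.null(w$cor) || w$cor == 0) {
    w$cor <- 0
  }
  # frozen trunk: encode each template once
  prep <- function(ads) {
    g <- featurize(ads$template, cfg$k)
    enc <- encode(params, g, training = FALSE)
    list(ads = ads, graph = g, emb = enc$edge_embeddings)
  }
  tr <- lapply(train_sets, prep)
  va <- lapply(val_sets, prep)
  adam <- .adam_new(params[c("out.W", "out.b")])
  names(adam$m) <- c("out.W", "out.b"); names(adam$v) <- c("out.W", "out.b")
  best <- Inf
  best_out <- params[c("out.W", "out.b")]
  bad <- 0L
  hist <- data.frame()
  val_cor_loss <- function(p) {
    mean(vapply(va, function(x) {
      potts <- project_potts(p, x$graph, x$emb)
      preds <- .binding_predictions(potts, x$ads)
      if (sd(preds) == 0) return(0)
      pearson_loss(preds, x$ads$records$value)
    }, numeric(1)))
  }
  for (epoch in seq_len(config$max_epochs)) {
    ep_loss <- 0
    for (x in tr) {  # per-template round-robin
      potts <- project_potts(params, x$graph, x$emb)
      ng <- ncpl_grad_potts(potts, x$ads$template$sequence)
      g_self <- w$ncpl * ng$g_self / ng$n_pairs
      g_pairs <- w$ncpl * ng$g_pairs / ng$n_pairs
      loss <- w$ncpl * ng$loss_sum / ng$n_pairs
      if (w$cor > 0) {
        preds <- .binding_predictions(potts, x$ads)
        if (sd(preds) > 0) {
          loss <- loss + w$cor * pearson_loss(preds, x$ads$records$value)
          dL <- w$cor * .pearson_loss_grad(preds, x$ads$records$value)
          bg <- .binding_score_grad(potts, x$ads, dL)
          g_self <- g_self + bg$g_self
          g_pairs <- g_pairs + bg$g_pairs
        }
      }
      pb <- project_potts_backward(params, x$graph, x$emb, g_self, g_pairs)
      grads <- list(out.W = pb$g_out_W, out.b = pb$g_out_b)
      upd <- .adam_step(params, grads, adam, config$finetune_lr,
                        names = c("out.W", "out.b"))
      params <- upd$params; adam <- upd$state
      ep_loss <- ep_loss + loss
    }
    vl <- val_cor_loss(params)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / length(tr),
                                   val_cor_loss = vl))
    if (vl < best) {
      best <- vl
      best_out <- params[c("out.W", "out.b")]
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad > config$patience) break
    }
  }
  params[["out.W"]] <- best_out[["out.W"]]
  params[["out.b"]] <- best_out[["out.b"]]
  list(params = params, history = hist, best_val_cor_loss = best)
}
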