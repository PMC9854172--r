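# Evaluation: native sequence recovery, amino-acid confusion matrices, and
# per-template Pearson benchmarks.

#' Native sequence recovery
#'
#' Percent residue identity between a designed and a native sequence of
#' equal length. Multi-chain designs are compared on the concatenated
#' chains.
#'
#' @param designed,native sequence strings of equal length.
#' @return percent in [0, 100].
#' @export
nsr <- function(designed, native) {
  a <- strsplit(designed, "")[[1]]
  b <- strsplit(native, "")[[1]]
  if (length(a) != length(b)) stop("sequence length mismatch")
  100 * mean(a == b)
}

#' Amino-acid confusion matrix
#'
#' Aggregates native (rows) vs predicted (columns) residue counts over
#' aligned sequence pairs and row-normalizes by the native-residue counts.
#' Positions with letters outside the alphabet are skipped and counted in
#' `n_skipped`; rows with zero native occurrences are `NA` in the
#' normalized matrix (flagged, not NaN-propagated).
#'
#' @param designed,native equal-length character vectors of sequence pairs
#'   (or two single sequences).
#' @return object of class `ConfusionMatrix`: `counts` (20x20 integer),
#'   `normalized` (rows sum to 1 where defined), `n_skipped`.
#' @export
confusion <- function(designed, native) {
  stopifnot(length(designed) == length(native))
  counts <- matrix(0L, 20, 20, dimnames = list(native = AA_ALPHABET,
                                               predicted = AA_ALPHABET))
  skipped <- 0L
  for (p in seq_along(designed)) {
    a <- strsplit(native[p], "")[[1]]
    b <- strsplit(designed[p], "")[[1]]
    if (length(a) != length(b)) stop("sequence length mismatch in pair ", p)
    ia <- match(a, AA_ALPHABET)
    ib <- match(b, AA_ALPHABET)
    ok <- !is.na(ia) & !is.na(ib)
    skipped <- skipped + sum(!ok)
    if (any(ok)) {
      t_ <- table(factor(ia[ok], levels = 1:20), factor(ib[ok], levels = 1:20))
      counts <- counts + matrix(as.integer(t_), 20, 20)
    }
  }
  rs <- rowSums(counts)
  normalized <- counts / ifelse(rs > 0, rs, NA_real_)
  x <- list(counts = counts, normalized = normalized, n_skipped = skipped)
  class(x) <- "ConfusionMatrix"
  x
}

#' @export
print.ConfusionMatrix <- function(x, ...) {
  cat("ConfusionMatrix:", sum(x$counts), "positions",
      sprintf("(%d skipped)\n", x$n_skipped))
  cat("diagonal (per-native recovery):\n")
  print(round(diag(x$normalized), 3))
  invisible(x)
}

#' Per-template Pearson benchmark of predicted binding energies
#'
#' For each affinity dataset: run the encoder on the template, score every
#' record with [peptide_binding_score()], and correlate predictions with
#' the measured values; aggregate mean and SD (sample, n-1) across
#' templates. Templates with zero-variance predictions get an undefined
#' (NA) r, are excluded from the aggregate, and trigger a warning.
#'
#' @param model `EncoderParams`, or a function(AffinityDataset) returning a
#'   `PottsModel` for its template.
#' @param datasets list of [affinity_dataset()]s.
#' @return object of class `BenchmarkReport`: `per_template` data.frame
#'   (template_id, n_records, pearson_r), `family_mean`, `family_sd`.
#' @export
benchmark_correlation <- function(model, datasets) {
  if (inherits(datasets, "AffinityDataset")) datasets <- list(datasets)
  get_potts <- if (inherits(model, "EncoderParams")) {
    function(ads) potts_forward(model, ads$template)
  } else if (is.function(model)) {
    model
  } else stop("model must be EncoderParams or a function")
  rows <- data.frame()
  for (ads in datasets) {
    if (nrow(ads$records) < 3) stop("dataset ", ads$id, " has < 3 records")
    potts <- get_potts(ads)
    preds <- .binding_predictions(potts, ads)
    r <- if (sd(preds) == 0) {
      warning("zero-variance predictions for template ", ads$id,
              "; r undefined")
      NA_real_
    } else {
      cor(preds, ads$records$value)
    }
    rows <- rbind(rows, data.frame(template_id = ads$id,
                                   n_records = nrow(ads$records),
                                   pearson_r = r))
  }
  ok <- !is.na(rows$pearson_r)
  x <- list(per_template = rows,
            family_mean = mean(rows$pearson_r[ok]),
            family_sd = if (sum(ok) > 1) sd(rows$pearson_r[ok]) else NA_real_)
  class(x) <- "BenchmarkReport"
  x
}

#' @export
print.BenchmarkReport <- function(x, ...) {
  print(x$per_template)
  cat(sprintf("family mean r = %.4f, SD = %.4f\n", x$family_mean, x$family_sd))
  invisible(x)
}
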