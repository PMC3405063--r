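#' Confusion counts of a predicted set against an actual set
#'
#' Standard 2 x 2 counts over a finite universe of items (atoms or
#' residues).
#'
#' @param predicted,actual Subsets of `universe` (same type).
#' @param universe Vector of all items under evaluation (non-empty).
#' @return A one-row tibble with columns `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(predicted, actual, universe) {
  if (!length(universe)) rlang::abort("empty universe")
  if (!all(predicted %in% universe) || !all(actual %in% universe)) {
    rlang::abort("predicted and actual must be subsets of the universe")
  }
  p <- universe %in% predicted
  a <- universe %in% actual
  tibble::tibble(tp = sum(p & a), tn = sum(!p & !a),
                 fp = sum(p & !a), fn = sum(!p & a))
}

#' The six benchmark scores from confusion counts
#'
#' Accuracy, precision, sensitivity (recall), specificity, F-score and
#' Matthews correlation coefficient. Vectorised over rows, so a whole
#' benchmark table can be scored at once. Zero-denominator conventions:
#' precision, sensitivity, specificity and the F-score fall back to 0 when
#' undefined, and the MCC is 0 when any marginal is empty.
#'
#' @param counts A data frame with columns `tp`, `tn`, `fp`, `fn`
#'   (non-negative; each row must have a positive total).
#' @return A tibble with columns `acc`, `pre`, `sen`, `spe`, `mcc`, `fsc`
#'   appended to the counts.
#' @export
benchmark_scores <- function(counts) {
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  if (any(c(tp, tn, fp, fn) < 0)) rlang::abort("negative confusion counts")
  total <- tp + tn + fp + fn
  if (any(total == 0)) rlang::abort("zero total count")
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  pre <- safe(tp, tp + fp)
  sen <- safe(tp, tp + fn)
  spe <- safe(tn, tn + fp)
  fsc <- safe(2 * pre * sen, pre + sen)
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- ifelse(denom > 0, (tp * tn - fp * fn) / denom, 0)
  dplyr::bind_cols(tibble::as_tibble(counts),
                   tibble::tibble(acc = (tp + tn) / total, pre = pre,
                                  sen = sen, spe = spe, mcc = mcc,
                                  fsc = fsc))
}

#' Atom-type composition of predicted binding sites
#'
#' The Fig-style enrichment statistic: for each protein atom type i, the
#' fraction `n_i / N_i` of atoms of that type predicted with confidence
#' above `threshold`, normalised over types so that uniform enrichment
#' gives the 1/30 baseline.
#'
#' @param confidences Numeric per-atom confidence levels.
#' @param type_ids Integer protein atom types (1--30), same length.
#' @param threshold Confidence threshold (default 0.1).
#' @return A tibble with columns `type_id`, `n_total`, `n_above`, `p`
#'   (`p` sums to 1 over the types present; absent types have `p = NA`).
#' @export
atom_type_composition <- function(confidences, type_ids, threshold = 0.1) {
  stopifnot(length(confidences) == length(type_ids))
  out <- tibble::tibble(type_id = 1:30) |>
    dplyr::mutate(
      n_total = vapply(.data$type_id, function(t) sum(type_ids == t), integer(1)),
      n_above = vapply(.data$type_id,
                       function(t) sum(type_ids == t & confidences > threshold),
                       integer(1)),
      ratio = ifelse(.data$n_total > 0, .data$n_above / .data$n_total, NA))
  norm <- sum(out$ratio, na.rm = TRUE)
  out$p <- if (norm > 0) out$ratio / norm else ifelse(is.na(out$ratio), NA, 0)
  dplyr::select(out, -"ratio")
}

#' Write a benchmark report TSV
#'
#' Column layout: one row per case with the six scores followed by the raw
#' confusion counts.
#'
#' @param scores Output of [benchmark_scores()], optionally with an `id`
#'   column.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_benchmark_tsv <- function(scores, path) {
  cols <- intersect(c("id", "acc", "pre", "sen", "spe", "mcc", "fsc",
                      "tp", "tn", "fp", "fn"), names(scores))
  utils::write.table(scores[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
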