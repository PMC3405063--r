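#' Build a confidence lookup table from validation predictions
#'
#' Classifier outputs are sorted into ten bins of width 0.1 (the top bin
#' closed so an output of exactly 1 is representable); the positive
#' confidence of a bin is the fraction of true positives among the
#' validation cases falling into it, and the negative confidence is its
#' complement. Empty bins are filled by linear interpolation between the
#' nearest non-empty neighbours (edge gaps take the nearest value).
#'
#' @param outputs Numeric validation outputs in `[0, 1]`.
#' @param labels Logical validation labels.
#' @param shrink Pseudo-count weight pulling small-count bins toward the
#'   validation base rate (default 2; 0 gives the raw TP fraction). With
#'   sparse validation sets a bin holding one or two cases would otherwise
#'   report confidence 0 or 1 on no evidence.
#' @return A tibble (`glyco_confidence`) with columns `bin`, `lo`, `hi`,
#'   `n`, `n_pos`, `confidence`, `interpolated`.
#' @export
build_confidence_table <- function(outputs, labels, shrink = 2) {
  if (!length(outputs)) rlang::abort("no validation data for confidence table")
  case_bin <- pmin(floor(outputs / 0.1) + 1L, 10L)
  n_cases <- vapply(1:10, function(b) sum(case_bin == b), integer(1))
  n_pos <- vapply(1:10, function(b) sum(case_bin == b & labels), integer(1))
  out <- tibble::tibble(
    bin = 1:10,
    lo = (0:9) / 10,
    hi = (1:10) / 10,
    n = n_cases,
    n_pos = n_pos)
  base_rate <- mean(labels)
  out$confidence <- ifelse(out$n > 0,
                           (out$n_pos + shrink * base_rate) /
                             (out$n + shrink), NA_real_)
  out$interpolated <- is.na(out$confidence)
  if (any(out$interpolated)) {
    known <- which(!out$interpolated)
    out$confidence <- if (length(known) == 1) {
      rep(out$confidence[known], 10)
    } else {
      stats::approx(known, out$confidence[known], xout = 1:10, rule = 2)$y
    }
  }
  class(out) <- c("glyco_confidence", class(out))
  out
}

#' Convert classifier activities to confidence levels
#'
#' Deterministic bin lookup in a confidence table. Activities outside
#' `[0, 1]` are clamped with a warning.
#'
#' @param activity Numeric classifier outputs.
#' @param table A `glyco_confidence` table.
#' @return Numeric confidence levels in `[0, 1]`.
#' @export
to_confidence <- function(activity, table) {
  if (any(activity < 0 | activity > 1)) {
    rlang::warn("activity outside [0, 1]; clamping")
    activity <- pmin(pmax(activity, 0), 1)
  }
  bin <- pmin(floor(activity / 0.1) + 1L, 10L)
  table$confidence[bin]
}
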