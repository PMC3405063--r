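#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trained site predictor
#'
#' One row per atom-type model with its decision threshold and the
#' top-bin confidence of its lookup table.
#'
#' @param x A `glyco_predictor`.
#' @param ... Unused.
#' @return A tibble with columns `type_id`, `code`, `threshold`,
#'   `top_bin_confidence`.
#' @export
tidy.glyco_predictor <- function(x, ...) {
  types <- as.integer(names(x$models))
  tibble::tibble(
    type_id = types,
    code = atom_type_table()$code[types],
    threshold = purrr::map_dbl(as.character(types), ~ x$thresholds[[.x]]),
    top_bin_confidence = purrr::map_dbl(as.character(types),
                                        ~ x$conf_tables[[.x]]$confidence[10]))
}

#' @rdname tidy.glyco_predictor
#' @export
glance.glyco_predictor <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, n_models = length(x$models),
                 config_hash = x$config_hash)
}

#' Tidy a binding-site prediction
#'
#' @param x A `glyco_prediction`.
#' @param ... Unused.
#' @return The per-atom tibble (activity, confidence, predicted flag).
#' @export
tidy.glyco_prediction <- function(x, ...) x$atoms

#' @rdname tidy.glyco_prediction
#' @export
glance.glyco_prediction <- function(x, ...) {
  tibble::tibble(id = x$id, n_surface_atoms = nrow(x$atoms),
                 n_patches = nrow(x$patches),
                 n_residues = length(x$residues),
                 max_confidence = max(c(0, x$atoms$confidence)))
}

#' Plot a confidence lookup table
#'
#' @param object A `glyco_confidence` table.
#' @param ... Unused.
#' @return A ggplot: positive (and complementary negative) confidence per
#'   activity bin.
#' @export
autoplot.glyco_confidence <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(object, negative = 1 - .data$confidence),
    c("confidence", "negative"),
    names_to = "kind", values_to = "level")
  df$kind <- ifelse(df$kind == "confidence", "positive", "negative")
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$lo + .data$hi) / 2,
                                   y = .data$level,
                                   colour = .data$kind)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "classifier output bin (midpoint)",
                  y = "confidence level", colour = NULL) +
    ggplot2::ylim(0, 1)
}

#' Plot an attribute significance screen
#'
#' Heat map of signed -log10 p-values over (atom type, attribute), the
#' standard view of which attributes separate binding from non-binding
#' surface atoms per atom type.
#'
#' @param object A `glyco_significance` tibble.
#' @param p_threshold Significance threshold to mark (default 0.025).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.glyco_significance <- function(object, p_threshold = 0.025, ...) {
  df <- dplyr::mutate(object,
    slp = ifelse(is.na(.data$p_value), NA,
                 ifelse(.data$sign == "+", 1, -1) *
                   -log10(pmax(.data$p_value, 1e-12))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$attribute, y = .data$type_id,
                                   fill = .data$slp)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0,
                                  name = "signed -log10 p") +
    ggplot2::labs(x = "attribute", y = "protein atom type")
}

#' Plot predicted patches on the surface-atom cloud
#'
#' 2-D projection of the surface atoms coloured by prediction confidence,
#' with patch members outlined.
#'
#' @param object A `glyco_prediction`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.glyco_prediction <- function(object, ...) {
  at <- object$atoms
  at$in_patch <- seq_len(nrow(at)) %in% unlist(object$patches$members)
  ggplot2::ggplot(at, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$confidence,
                                     shape = .data$in_patch), size = 2) +
    ggplot2::scale_colour_gradient(low = "grey80", high = "red",
                                   limits = c(0, 1)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$id, shape = "patch member")
}

#' Plot the atom-type composition of predicted sites
#'
#' @param composition Output of [atom_type_composition()].
#' @return A ggplot with the uniform 1/30 baseline marked.
#' @export
plot_atom_type_composition <- function(composition) {
  df <- dplyr::filter(composition, !is.na(.data$p))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$type_id), y = .data$p)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1 / 30, linetype = "dashed") +
    ggplot2::labs(x = "protein atom type", y = "composition P")
}
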