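#' Label surface atoms as carbohydrate-binding or not
#'
#' A surface atom is a positive case when it lies within `cutoff` of any
#' carbohydrate-typed ligand atom. Atoms near only aglycone atoms (the
#' non-sugar part of a glycoconjugate, e.g. an attached peptide) are
#' negative; buried atoms (SASA = 0) carry no label at all.
#'
#' @param structure A `glyco_structure` with SASA computed.
#' @param cutoff Contact distance in Angstrom (default 5).
#' @return A tibble with one row per surface atom: `atom_idx`, `serial`,
#'   `label` (logical) and `ligand_group` (nearest contacting group or NA).
#' @export
label_atoms <- function(structure, cutoff = 5) {
  a <- structure$atoms
  surf <- surface_atoms(structure)
  lig <- which(a$is_carb)
  out <- tibble::tibble(atom_idx = surf, serial = a$serial[surf],
                        label = FALSE, ligand_group = NA_integer_)
  if (!length(lig)) {
    rlang::warn("no carbohydrate ligand: all surface atoms labelled negative")
    return(out)
  }
  co_s <- structure_coords(structure, surf)
  co_l <- structure_coords(structure, lig)
  d2 <- outer(rowSums(co_s^2), rowSums(co_l^2), "+") - 2 * co_s %*% t(co_l)
  hit <- d2 <= cutoff^2 + 1e-9
  out$label <- rowSums(hit) > 0
  nearest <- apply(d2, 1, which.min)
  out$ligand_group[out$label] <- a$ligand_group[lig[nearest[out$label]]]
  out
}

#' Two-sided Mann-Whitney U-test with direction
#'
#' Rank-sum test comparing two samples: exact for small samples (both
#' groups of size at most `exact_max`, no ties), tie-corrected normal
#' approximation otherwise. The sign is `+` when the first sample's mean
#' exceeds the second's.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param exact_max Largest per-group size for the exact branch (default 8).
#' @return A list with `p_value` and `sign` (`"+"` or `"-"`).
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  if (!length(x) || !length(y)) rlang::abort("both samples must be non-empty")
  use_exact <- length(x) <= exact_max && length(y) <= exact_max &&
    !anyDuplicated(c(x, y))
  # the approximate branch is the tie-corrected normal approximation with
  # continuity correction, mirroring the usual ranksum implementation
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = !use_exact)$p.value)
  if (is.nan(p)) p <- 1  # identical constant samples
  list(p_value = min(p, 1), sign = if (mean(x) >= mean(y)) "+" else "-")
}

#' Attribute significance screen per protein atom type
#'
#' For every (protein atom type, attribute) combination, compares the
#' attribute values of binding-site atoms with those of non-binding
#' surface atoms by a two-sided Mann-Whitney U-test, recording the p-value
#' and the direction of the shift. Attributes can be screened on the
#' aggregated raw values (`A`, the default) or the scaled values (`a`).
#'
#' @param features A `glyco_features` tibble (possibly several structures
#'   bound together) with a logical `label` column attached.
#' @param value `"A"` (aggregated raw) or `"a"` (scaled).
#' @return A tibble (`glyco_significance`) with columns `type_id`
#'   (1--30), `attribute` (1--37), `p_value`, `sign` and `n_pos`, `n_neg`;
#'   atom types absent from the corpus are marked by `NA` p-values.
#' @export
significance_screen <- function(features, value = c("A", "a")) {
  value <- match.arg(value)
  cols <- if (value == "A") .A_cols() else .a_cols()
  stopifnot("label" %in% names(features))
  grid <- tidyr::expand_grid(type_id = 1:30, attribute = 1:37)
  res <- purrr::pmap(grid, function(type_id, attribute) {
    sub <- features[features$type_id == type_id, ]
    xs <- sub[[cols[attribute]]][sub$label]
    ys <- sub[[cols[attribute]]][!sub$label]
    if (!length(xs) || !length(ys)) {
      return(tibble::tibble(p_value = NA_real_, sign = NA_character_,
                            n_pos = length(xs), n_neg = length(ys)))
    }
    u <- mann_whitney_u(xs, ys)
    tibble::tibble(p_value = u$p_value, sign = u$sign,
                   n_pos = length(xs), n_neg = length(ys))
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  class(out) <- c("glyco_significance", class(out))
  out
}

#' Pearson correlation of each attribute with a response
#'
#' Computes the Pearson correlation coefficient between a per-atom
#' response (prediction confidence level, or a 0/1 binding label) and each
#' of the 37 attributes. Zero-variance attributes are reported as r = 0
#' and flagged.
#'
#' @param features A `glyco_features` tibble with scaled columns.
#' @param response Numeric vector, one value per feature row.
#' @return A tibble with columns `attribute` (1--37), `r`, `constant`.
#' @export
correlation_profile <- function(features, response) {
  stopifnot(length(response) == nrow(features))
  vals <- purrr::map(1:37, function(j) {
    v <- features[[.a_cols()[j]]]
    if (stats::sd(v) == 0 || stats::sd(response) == 0) {
      tibble::tibble(attribute = j, r = 0, constant = TRUE)
    } else {
      tibble::tibble(attribute = j, r = stats::cor(v, response),
                     constant = FALSE)
    }
  })
  dplyr::bind_rows(vals)
}

#' Export a significance matrix as signed log10 p-values (TSV)
#'
#' @param sig A `glyco_significance` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_significance_tsv <- function(sig, path) {
  wide <- sig |>
    dplyr::mutate(value = ifelse(is.na(.data$p_value), NA,
                                 ifelse(.data$sign == "+", 1, -1) *
                                   -log10(pmax(.data$p_value, 1e-300)))) |>
    dplyr::select("type_id", "attribute", "value") |>
    tidyr::pivot_wider(names_from = "attribute", names_prefix = "attr",
                       values_from = "value")
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
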