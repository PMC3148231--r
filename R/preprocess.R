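#' Subtract a per-sample background offset
#'
#' Each intensity is replaced by `max(value - offset, 0)`; "not detected"
#' (`NA`) cells are left untouched.
#'
#' @param expr Expression tibble (`feature_id` plus sample columns).
#' @param background A single non-negative offset, or a vector with one
#'   offset per sample (named or in column order).
#' @return The background-subtracted expression tibble.
#' @export
subtract_background <- function(expr, background = 0) {
  sample_ids <- setdiff(names(expr), "feature_id")
  if (length(background) == 1) background <- rep(background, length(sample_ids))
  if (!is.null(names(background))) {
    missing <- setdiff(sample_ids, names(background))
    if (length(missing) > 0) stop_config(paste0("no background offset for sample(s): ", paste(missing, collapse = ", ")))
    background <- background[sample_ids]
  }
  if (length(background) != length(sample_ids)) {
    stop_config("background must be length 1 or one offset per sample")
  }
  if (any(background < 0)) stop_config("background offsets must be >= 0")
  for (j in seq_along(sample_ids)) {
    expr[[sample_ids[j]]] <- pmax(expr[[sample_ids[j]]] - background[j], 0)
  }
  expr
}

#' Detection filter by per-stratum mean intensity
#'
#' A feature counts as detected in a `(species, source)` stratum when its
#' mean background-subtracted intensity across that stratum's samples is
#' strictly greater than the threshold ("above 300" read literally). Cells
#' that are `NA` are excluded from the mean; a feature missing in every
#' sample of a stratum is not detected there. Detection is applied before
#' normalization, matching the stated processing order.
#'
#' @param expr Background-subtracted expression tibble.
#' @param samples Sample sheet tibble.
#' @param threshold Intensity threshold (default 300).
#' @return A tibble with columns `species`, `source`, `feature_id`, one row
#'   per detected feature per stratum.
#' @export
detection_filter <- function(expr, samples, threshold = 300) {
  samples <- validate_sample_sheet(samples)
  strata <- dplyr::distinct(samples, .data$species, .data$source)
  purrr::pmap_dfr(strata, function(species, source) {
    ids <- samples$sample_id[samples$species == species & samples$source == source]
    if (length(ids) == 0) stop_config(paste0("stratum ", species, "/", source, " has zero samples"))
    m <- as.matrix(expr[, ids, drop = FALSE])
    mu <- rowMeans(m, na.rm = TRUE)
    keep <- !is.nan(mu) & mu > threshold
    tibble::tibble(species = species, source = source,
                   feature_id = expr$feature_id[keep])
  })
}

#' Normalize against the U6 small nuclear RNA
#'
#' Scales every sample (column) so its normalizer value equals the
#' across-sample geometric mean of the normalizer row. Within-sample ratios
#' between features are unchanged, and anchoring to the geometric mean makes
#' the result invariant to sample order. Applying the normalization twice is
#' the same as applying it once.
#'
#' @param expr Expression tibble.
#' @param normalizer_id Identifier of the normalizer feature (default
#'   `"U6"`).
#' @return The normalized expression tibble.
#' @export
normalize_u6 <- function(expr, normalizer_id = "U6") {
  sample_ids <- setdiff(names(expr), "feature_id")
  row <- which(expr$feature_id == normalizer_id)
  if (length(row) != 1) stop_config(paste0("normalizer '", normalizer_id, "' not found (or duplicated)"))
  u6 <- as.numeric(expr[row, sample_ids])
  bad <- sample_ids[is.na(u6) | u6 <= 0]
  if (length(bad) > 0) {
    stop_config(paste0("normalizer '", normalizer_id, "' is missing or non-positive in sample(s): ",
                       paste(bad, collapse = ", ")))
  }
  factors <- geometric_mean(u6) / u6
  for (j in seq_along(sample_ids)) {
    expr[[sample_ids[j]]] <- expr[[sample_ids[j]]] * factors[j]
  }
  expr
}

#' Illumina-style mRNA prefilter
#'
#' Keeps genes passing the manufacturer's suggested differential-expression
#' screen: p-value below `p_max`, absolute differential score strictly
#' greater than `diffscore_min`, and average signal strictly greater than
#' `avg_signal_min`.
#'
#' @param stats Tibble with columns `gene_id`, `p_value`, `diff_score`,
#'   `avg_signal`.
#' @param p_max,diffscore_min,avg_signal_min Filter thresholds (defaults
#'   0.05, 20, 100).
#' @return The subset of `stats` that passes, as a tibble.
#' @export
mrna_prefilter <- function(stats, p_max = 0.05, diffscore_min = 20, avg_signal_min = 100) {
  needed <- c("gene_id", "p_value", "diff_score", "avg_signal")
  missing <- setdiff(needed, names(stats))
  if (length(missing) > 0) stop_format(paste0("mRNA stats missing column(s): ", paste(missing, collapse = ", ")))
  if (!all(is.finite(stats$p_value) & is.finite(stats$diff_score) & is.finite(stats$avg_signal))) {
    stop_format("mRNA stats must be finite")
  }
  dplyr::filter(tibble::as_tibble(stats),
                .data$p_value < p_max,
                abs(.data$diff_score) > diffscore_min,
                .data$avg_signal > avg_signal_min)
}

#' Differential score from a p-value
#'
#' Illumina's BeadStudio differential score convention:
#' `-10 * sign(case - control) * log10(p)`, so |score| = 20 corresponds to
#' p = 0.01. Useful when only p-values are available for the mRNA prefilter.
#'
#' @param p P-values in (0, 1].
#' @param direction Sign of the case-minus-control difference (+1/-1, or
#'   any numeric whose sign is used).
#' @return Numeric differential scores.
#' @export
#' @examples
#' diff_score_from_p(0.01, 1)  # 20
diff_score_from_p <- function(p, direction = 1) {
  if (any(p <= 0 | p > 1)) stop_config("p must be in (0, 1]")
  -10 * sign(direction) * log10(p)
}
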