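#' Reference-corrected threshold cycle
#'
#' \eqn{\Delta Ct = Ct_{target} - Ct_{reference}} (lower values mean higher
#' expression). Vectorized.
#'
#' @param ct_target,ct_reference Threshold-cycle values.
#' @return \eqn{\Delta Ct} in cycles.
#' @export
#' @examples
#' delta_ct(25, 15)  # 10
delta_ct <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    stop_config("Ct values must be finite")
  }
  ct_target - ct_reference
}

#' Fold change from a ddCt value
#'
#' \eqn{FC = E^{-\Delta\Delta Ct}} with amplification efficiency `E`
#' (default 2, one full doubling per cycle).
#'
#' @param ddct \eqn{\Delta\Delta Ct} values.
#' @param efficiency Amplification efficiency (default 2).
#' @return Positive fold changes.
#' @export
#' @examples
#' ddct_to_fold(-1)  # 2
ddct_to_fold <- function(ddct, efficiency = 2) {
  if (efficiency <= 1) stop_config("efficiency must be > 1")
  efficiency^(-ddct)
}

#' Relative expression from a Ct table (2^-ddCt)
#'
#' Per target: replicate Ct values are reference-corrected within each
#' group (\eqn{\Delta Ct}), averaged per group, differenced case minus
#' control (\eqn{\Delta\Delta Ct}), and exponentiated. The SEM of the fold
#' change is propagated from the per-replicate \eqn{\Delta Ct} spread via
#' the delta method (`sem_fc = ln(E) * fc * sem_ddct`). The raw ratio is
#' retained; the signed negative-reciprocal convention is a reporting
#' column only.
#'
#' @param ct_table Tibble with `feature_id`, `group`, `replicate`, `ct`
#'   (see [generate_qpcr_plate()]); the reference gene must be present in
#'   every group.
#' @param reference_id Reference gene identifier (defaults to the table's
#'   `reference_id` attribute, else `"18S"`).
#' @param case_group,control_group Group labels to contrast; defaults pick
#'   `control` and the single other group.
#' @param efficiency Amplification efficiency (default 2).
#' @return A tibble: `feature_id`, `contrast`, `delta_ct_case`,
#'   `delta_ct_control`, `ddct`, `fold_change`, `signed_fc`, `sem`.
#' @export
ddct_fold_change <- function(ct_table, reference_id = NULL,
                             case_group = NULL, control_group = "control",
                             efficiency = 2) {
  ct_table <- tibble::as_tibble(ct_table)
  needed <- c("feature_id", "group", "replicate", "ct")
  missing <- setdiff(needed, names(ct_table))
  if (length(missing) > 0) stop_format(paste0("Ct table missing column(s): ", paste(missing, collapse = ", ")))
  if (any(!is.finite(ct_table$ct) | ct_table$ct <= 0)) stop_format("Ct values must be finite and > 0")
  if (is.null(reference_id)) reference_id <- attr(ct_table, "reference_id") %||% "18S"
  if (is.null(case_group)) {
    others <- setdiff(unique(ct_table$group), control_group)
    if (length(others) != 1) stop_config("case_group must be given when the table has several case groups")
    case_group <- others
  }
  groups <- c(control_group, case_group)
  tab <- dplyr::filter(ct_table, .data$group %in% groups)
  ref <- dplyr::filter(tab, .data$feature_id == reference_id)
  if (!all(groups %in% unique(ref$group))) {
    stop_config(paste0("reference '", reference_id, "' must be present in both groups"))
  }
  ref_mean <- dplyr::summarise(dplyr::group_by(ref, .data$group),
                               ref_ct = mean(.data$ct), .groups = "drop")
  tg <- dplyr::filter(tab, .data$feature_id != reference_id)
  tg <- dplyr::left_join(tg, ref_mean, by = "group")
  tg$dct <- delta_ct(tg$ct, tg$ref_ct)
  per_group <- dplyr::summarise(
    dplyr::group_by(tg, .data$feature_id, .data$group),
    mean_dct = mean(.data$dct),
    var_dct = if (dplyr::n() > 1) var(.data$dct) else 0,
    n = dplyr::n(), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(per_group, names_from = "group",
                             values_from = c("mean_dct", "var_dct", "n"))
  mc <- paste0("mean_dct_", case_group); mk <- paste0("mean_dct_", control_group)
  vc <- paste0("var_dct_", case_group); vk <- paste0("var_dct_", control_group)
  nc <- paste0("n_", case_group); nk <- paste0("n_", control_group)
  if (!all(c(mc, mk) %in% names(wide))) {
    stop_config("every target must have replicates in both groups")
  }
  ddct <- wide[[mc]] - wide[[mk]]
  fc <- ddct_to_fold(ddct, efficiency)
  sem_ddct <- sqrt(wide[[vc]] / wide[[nc]] + wide[[vk]] / wide[[nk]])
  tibble::tibble(
    feature_id = wide$feature_id,
    contrast = paste0(case_group, "_vs_", control_group),
    delta_ct_case = wide[[mc]],
    delta_ct_control = wide[[mk]],
    ddct = ddct,
    fold_change = fc,
    signed_fc = ratio_to_signed_fc(fc),
    sem = log(efficiency) * fc * sem_ddct
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
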