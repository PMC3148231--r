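#' Signed fold change (negative reciprocal convention)
#'
#' The ratio `case_mean / control_mean` is reported as-is when at least 1
#' and as its negative reciprocal when below 1, so `|signed_fc| >= 1`
#' always and down-regulation reads as a negative magnitude.
#'
#' @param case_mean,control_mean Positive group means (vectorized).
#' @return Signed fold changes.
#' @export
#' @examples
#' signed_fold_change(300, 100)  # +3
#' signed_fold_change(100, 300)  # -3
signed_fold_change <- function(case_mean, control_mean) {
  if (any(case_mean <= 0 | control_mean <= 0, na.rm = TRUE)) {
    stop_config("group means must be positive (non-detected features should be filtered first)")
  }
  r <- case_mean / control_mean
  ifelse(r >= 1, r, -1 / r)
}

#' Signed fold change from a raw ratio
#'
#' @param ratio Positive ratios.
#' @return `ratio` when >= 1, else `-1/ratio`.
#' @export
ratio_to_signed_fc <- function(ratio) {
  if (any(ratio <= 0, na.rm = TRUE)) stop_config("ratio must be positive")
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Direction implied by a signed fold change
#'
#' @param signed_fc Signed fold changes (|fc| >= 1).
#' @return `+1` for up, `-1` for down, `0` for exactly no change.
#' @export
fc_direction <- function(signed_fc) {
  ifelse(abs(signed_fc) == 1, 0, sign(signed_fc))
}

#' Two-tailed Welch t-test p-value
#'
#' Unequal-variance t-test between two groups; in the pipeline it is applied
#' to log2 intensities (variance stabilization) while fold changes are taken
#' on linear means. Degenerate inputs (both groups essentially constant) are
#' resolved without a test: equal means give p = 1, unequal means are
#' perfectly separated and give p = 0; both carry a warning attribute.
#'
#' @param case_values,control_values Numeric vectors, each with at least two
#'   non-missing values.
#' @return A p-value in \[0, 1\]; attribute `degenerate` is `TRUE` when the
#'   zero-variance branch was taken.
#' @export
two_tailed_t <- function(case_values, control_values) {
  x <- case_values[!is.na(case_values)]
  y <- control_values[!is.na(control_values)]
  if (length(x) < 2 || length(y) < 2) stop_config("need >= 2 values per group")
  tol <- 1e-12 * max(1, abs(mean(x)), abs(mean(y)))
  if (sd(x) <= tol && sd(y) <= tol) {
    p <- if (abs(mean(x) - mean(y)) <= tol) 1 else 0
    warn("degenerate (zero-variance) groups in two_tailed_t")
    return(structure(p, degenerate = TRUE))
  }
  structure(t.test(x, y, var.equal = FALSE)$p.value, degenerate = FALSE)
}

#' Fraction of case subjects replicating the group direction
#'
#' Each case subject contributes one ratio (subject intensity over the
#' control-group mean). A subject replicates an up-regulated group change
#' when its ratio is strictly above 1, a down-regulated change when
#' strictly below 1; a ratio of exactly 1 never replicates.
#'
#' @param per_subject_ratios Positive ratios, one per case subject.
#' @param group_direction `"up"` or `"down"`.
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' replication_fraction(c(2.0, 1.8, 0.6, 2.2), "up")  # 0.75
replication_fraction <- function(per_subject_ratios, group_direction = c("up", "down")) {
  group_direction <- match.arg(group_direction)
  r <- per_subject_ratios[!is.na(per_subject_ratios)]
  if (length(r) == 0) stop_config("no per-subject ratios supplied")
  if (group_direction == "up") mean(r > 1) else mean(r < 1)
}

#' Filter thresholds for differential calls
#'
#' Defaults follow the study's published screen: raw p below 0.05, at least
#' a 1.5-fold change in either direction, and direction replicated in at
#' least half of the case subjects. No multiple-testing correction is
#' applied to the filter itself; a Benjamini-Hochberg column is emitted for
#' information only.
#'
#' @param p_max Significance cut (default 0.05).
#' @param min_abs_fc Minimum |signed fold change| (default 1.5).
#' @param min_replication Minimum replication fraction (default 0.5,
#'   inclusive: "at least 50%").
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(p_max = 0.05, min_abs_fc = 1.5, min_replication = 0.5) {
  if (p_max <= 0 || p_max >= 1) stop_config("p_max must be in (0, 1)")
  if (min_abs_fc < 1) stop_config("min_abs_fc must be >= 1")
  if (min_replication < 0 || min_replication > 1) stop_config("min_replication must be in [0, 1]")
  structure(list(p_max = p_max, min_abs_fc = min_abs_fc, min_replication = min_replication),
            class = "filter_config")
}

#' Differential contrast within one stratum
#'
#' For one `(species, source)` stratum and one case label, computes per
#' detected feature: the linear-mean ratio and signed fold change, a Welch
#' two-tailed p-value on log2 intensities, a BH-adjusted p-value (reported,
#' not filtered on), the per-subject replication fraction, and the three
#' filter flags (significance, magnitude, replication).
#'
#' @param expr Normalized expression tibble.
#' @param samples Sample sheet.
#' @param species,source Stratum selector.
#' @param case_label Which case group to contrast against the stratum's
#'   controls.
#' @param config A [filter_config()].
#' @param features Optional feature ids to evaluate (typically the detected
#'   set from [detection_filter()]); defaults to all features except
#'   `normalizer_id`.
#' @param normalizer_id Feature excluded from testing by default.
#' @return A `FoldChangeRecord` tibble: `feature_id`, `species`, `source`,
#'   `case_label`, `n_case`, `n_control`, `ratio`, `signed_fc`, `p_value`,
#'   `p_adj`, `replication_fraction`, `degenerate`, and logical
#'   `significant`, `magnitude`, `replicated`, `passes_all`.
#' @export
contrast <- function(expr, samples, species, source, case_label,
                     config = filter_config(), features = NULL,
                     normalizer_id = "U6") {
  samples <- validate_sample_sheet(samples)
  in_stratum <- samples$species == species & samples$source == source
  if (!any(in_stratum)) stop_config(paste0("unknown stratum: ", species, "/", source))
  ctl <- samples[in_stratum & samples$group == "control", ]
  cas <- samples[in_stratum & samples$group == "case" & samples$case_label == case_label, ]
  if (nrow(ctl) == 0 || nrow(cas) == 0) {
    stop_config(paste0("stratum ", species, "/", source, " lacks control or '",
                       case_label, "' case samples"))
  }
  if (is.null(features)) features <- setdiff(expr$feature_id, normalizer_id)
  rows <- match(features, expr$feature_id)
  if (anyNA(rows)) {
    stop_config(paste0("feature(s) not in matrix: ",
                       paste(features[is.na(rows)][1], collapse = ", ")))
  }
  ctl_m <- as.matrix(expr[rows, ctl$sample_id, drop = FALSE])
  cas_m <- as.matrix(expr[rows, cas$sample_id, drop = FALSE])

  # Per-case-subject intensities (subjects may contribute replicate samples)
  subj <- unique(cas$subject_id)
  subj_m <- vapply(subj, function(sj) {
    rowMeans(cas_m[, cas$subject_id == sj, drop = FALSE], na.rm = TRUE)
  }, numeric(length(rows)))
  if (is.null(dim(subj_m))) subj_m <- matrix(subj_m, nrow = length(rows))

  res <- purrr::map_dfr(seq_along(rows), function(i) {
    cvals <- ctl_m[i, ]
    xvals <- cas_m[i, ]
    cmean <- mean(cvals, na.rm = TRUE)
    xmean <- mean(xvals, na.rm = TRUE)
    if (!is.finite(cmean) || !is.finite(xmean) || cmean <= 0 || xmean <= 0) {
      return(tibble::tibble(
        feature_id = features[i], ratio = NA_real_, signed_fc = NA_real_,
        p_value = NA_real_, replication_fraction = NA_real_, degenerate = NA
      ))
    }
    p <- suppressWarnings(two_tailed_t(log2(xvals), log2(cvals)))
    ratio <- xmean / cmean
    dir <- if (ratio > 1) "up" else "down"
    rep_frac <- if (ratio == 1) 0 else {
      sr <- subj_m[i, ] / cmean
      replication_fraction(sr[is.finite(sr)], dir)
    }
    tibble::tibble(
      feature_id = features[i], ratio = ratio,
      signed_fc = ratio_to_signed_fc(ratio),
      p_value = as.numeric(p), replication_fraction = rep_frac,
      degenerate = isTRUE(attr(p, "degenerate"))
    )
  })
  res$species <- species
  res$source <- source
  res$case_label <- case_label
  res$n_case <- nrow(cas)
  res$n_control <- nrow(ctl)
  res$p_adj <- p.adjust(res$p_value, method = "BH")
  res$significant <- !is.na(res$p_value) & res$p_value < config$p_max
  res$magnitude <- !is.na(res$signed_fc) & abs(res$signed_fc) >= config$min_abs_fc
  res$replicated <- !is.na(res$replication_fraction) &
    res$replication_fraction >= config$min_replication
  res$passes_all <- res$significant & res$magnitude & res$replicated
  res[, c("feature_id", "species", "source", "case_label", "n_case", "n_control",
          "ratio", "signed_fc", "p_value", "p_adj", "replication_fraction",
          "degenerate", "significant", "magnitude", "replicated", "passes_all")]
}

#' Run every contrast present in a study
#'
#' Applies [detection_filter()] per stratum, then [contrast()] for each
#' `(species, source, case_label)` combination found in the sample sheet,
#' restricted to the stratum's detected features.
#'
#' @param expr Normalized expression tibble.
#' @param samples Sample sheet.
#' @param config A [filter_config()].
#' @param detection_threshold Intensity threshold for detection (default
#'   300); applied to `expr` as supplied (run it on pre-normalization
#'   intensities for the published order, see [detection_filter()]).
#' @param detected Optional precomputed detection tibble; when given,
#'   `detection_threshold` is ignored.
#' @param normalizer_id Normalizer feature, excluded from contrasts.
#' @return A single tibble of fold-change records across all contrasts.
#' @export
run_contrasts <- function(expr, samples, config = filter_config(),
                          detection_threshold = 300, detected = NULL,
                          normalizer_id = "U6") {
  samples <- validate_sample_sheet(samples)
  if (is.null(detected)) detected <- detection_filter(expr, samples, detection_threshold)
  combos <- dplyr::distinct(samples[samples$group == "case", ],
                            .data$species, .data$source, .data$case_label)
  purrr::pmap_dfr(combos, function(species, source, case_label) {
    feats <- detected$feature_id[detected$species == species & detected$source == source]
    feats <- setdiff(feats, normalizer_id)
    if (length(feats) == 0) return(NULL)
    contrast(expr, samples, species, source, case_label,
             config = config, features = feats, normalizer_id = normalizer_id)
  })
}

#' One-way ANOVA with Fisher's LSD across three or more groups
#'
#' Optional alternative to pairwise Welch tests when a stratum has several
#' case groups at once (for example CTL/IFG/T2D blood cohorts): a one-way
#' ANOVA p-value per feature on log2 intensities, plus unadjusted
#' Fisher's-LSD pairwise p-values computed from the pooled mean square
#' error.
#'
#' @param expr Normalized expression tibble.
#' @param samples Sample sheet (one stratum's samples are selected).
#' @param species,source Stratum selector.
#' @param features Optional feature subset.
#' @return A tibble with `feature_id`, `anova_p`, and one `lsd_p_*` column
#'   per group pair.
#' @export
anova_lsd <- function(expr, samples, species = "human", source = "blood",
                      features = NULL) {
  samples <- validate_sample_sheet(samples)
  sel <- samples[samples$species == species & samples$source == source, ]
  if (nrow(sel) == 0) stop_config(paste0("unknown stratum: ", species, "/", source))
  grp <- ifelse(sel$group == "control", "CTL", sel$case_label)
  if (length(unique(grp)) < 3) stop_config("anova_lsd needs at least three groups")
  if (is.null(features)) features <- setdiff(expr$feature_id, "U6")
  m <- as.matrix(expr[match(features, expr$feature_id), sel$sample_id, drop = FALSE])
  pairs <- utils::combn(sort(unique(grp)), 2, simplify = FALSE)
  purrr::map_dfr(seq_along(features), function(i) {
    y <- log2(m[i, ])
    ok <- is.finite(y)
    if (sum(ok) < 4 || length(unique(grp[ok])) < 3) {
      return(tibble::tibble(feature_id = features[i], anova_p = NA_real_))
    }
    fit <- aov(y[ok] ~ factor(grp[ok]))
    an <- summary(fit)[[1]]
    mse <- an["Residuals", "Mean Sq"]
    dfr <- an["Residuals", "Df"]
    out <- tibble::tibble(feature_id = features[i], anova_p = an[1, "Pr(>F)"])
    for (pr in pairs) {
      a <- y[ok][grp[ok] == pr[1]]; b <- y[ok][grp[ok] == pr[2]]
      tstat <- (mean(a) - mean(b)) / sqrt(mse * (1 / length(a) + 1 / length(b)))
      out[[paste0("lsd_p_", pr[1], "_vs_", pr[2])]] <- 2 * stats::pt(-abs(tstat), dfr)
    }
    out
  })
}
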