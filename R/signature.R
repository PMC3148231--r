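#' Venn region counts for named feature sets
#'
#' Exact counts for every non-empty membership pattern of 2..6 named sets
#' (the multi-source intersection diagram). Region counts are disjoint and
#' sum to the union size.
#'
#' @param sets Named list of character vectors.
#' @return A tibble of class `mirsig_venn` with one logical column per set,
#'   a `count` column per region (all 2^k - 1 regions, including empty
#'   ones), and the union size in the `union_size` attribute.
#' @export
#' @examples
#' venn_counts(list(blood = c("a", "b"), liver = c("b", "c")))
venn_counts <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 6) stop_config("venn_counts supports 2 to 6 sets")
  if (is.null(names(sets)) || any(names(sets) == "") ) stop_config("sets must be named")
  if (anyDuplicated(names(sets))) stop_config("duplicate set names")
  sets <- purrr::map(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1, dimnames = list(NULL, names(sets)))
  patterns <- tidyr::expand_grid(!!!setNames(rep(list(c(FALSE, TRUE)), k), names(sets)))
  patterns <- patterns[rowSums(patterns) > 0, ]
  key <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
  pat_key <- apply(as.matrix(patterns), 1, function(r) paste(as.integer(r), collapse = ""))
  counts <- table(factor(key, levels = pat_key))
  patterns$count <- as.integer(counts)
  out <- tibble::as_tibble(patterns)
  attr(out, "union_size") <- length(universe)
  class(out) <- c("mirsig_venn", class(out))
  out
}

#' @export
glance.mirsig_venn <- function(x, ...) {
  tibble::tibble(
    n_sets = ncol(x) - 1L,
    union_size = attr(x, "union_size"),
    n_regions = nrow(x),
    n_nonempty_regions = sum(x$count > 0),
    all_sets_count = x$count[rowSums(as.matrix(x[, -ncol(x)])) == (ncol(x) - 1L)]
  )
}

#' Cross-source signature selection
#'
#' Retains miRNAs that pass every filter flag (significance, magnitude,
#' replication) in every one of the required sources, with the same
#' direction of change everywhere. This is the multi-tissue intersection
#' step that reduces per-source differential lists to one concordant
#' signature.
#'
#' @param records Fold-change record tibble covering all required sources
#'   (one species).
#' @param sources Required source names (default all five: pancreas, liver,
#'   adipose, skeletal muscle, blood).
#' @return A tibble with `mirna_id`, `direction`, and one `fc_<source>`
#'   signed fold-change column per source.
#' @export
cross_source_signature <- function(records, sources = .mirsig_sources) {
  missing <- setdiff(sources, unique(records$source))
  if (length(missing) > 0) {
    stop_config(paste0("missing source(s): ", paste(missing, collapse = ", ")))
  }
  rec <- dplyr::filter(records, .data$source %in% sources)
  passed <- dplyr::filter(rec, .data$passes_all)
  wide <- tidyr::pivot_wider(
    passed[, c("feature_id", "source", "signed_fc")],
    names_from = "source", values_from = "signed_fc", names_prefix = "fc_"
  )
  fc_cols <- paste0("fc_", sources)
  for (cc in setdiff(fc_cols, names(wide))) wide[[cc]] <- NA_real_
  wide <- wide[stats::complete.cases(wide[, fc_cols]), , drop = FALSE]
  if (nrow(wide) > 0) {
    dirs <- sign(as.matrix(wide[, fc_cols]))
    same <- apply(dirs, 1, function(d) all(d == d[1]))
    wide <- wide[same, , drop = FALSE]
  }
  out <- tibble::tibble(
    mirna_id = wide$feature_id,
    direction = if (nrow(wide) > 0) ifelse(wide[[fc_cols[1]]] > 0, "up", "down") else character(0)
  )
  dplyr::bind_cols(out, wide[, fc_cols, drop = FALSE])
}

#' Cross-species signature concordance
#'
#' Matches the rat multi-source signature against human blood contrasts. An
#' entry is concordant when the rat direction agrees with the human T2D
#' blood direction and the human T2D record is significant; the IFG fold
#' change is recorded for reporting but does not enter the concordance rule
#' (pre-diabetic discordance is biology, not an exclusion criterion).
#'
#' @param rat_signature Output of [cross_source_signature()].
#' @param human_records Fold-change records for human blood contrasts
#'   (case labels `T2D` and optionally `IFG`).
#' @param alias Optional identifier alias table applied to both sides, see
#'   [apply_aliases()].
#' @return A tibble of class `mirsig_signature`: `mirna_id`, `direction`
#'   (rat), rat per-source `fc_*` columns, `human_t2d_fc`, `human_t2d_p`,
#'   `human_ifg_fc`, `concordant`.
#' @export
cross_species_signature <- function(rat_signature, human_records, alias = NULL) {
  if (nrow(rat_signature) == 0) {
    warn("empty rat signature; returning no entries")
    out <- tibble::tibble(mirna_id = character(), direction = character(),
                          human_t2d_fc = numeric(), human_t2d_p = numeric(),
                          human_ifg_fc = numeric(), concordant = logical())
    class(out) <- c("mirsig_signature", class(out))
    return(out)
  }
  rat_signature$mirna_id <- apply_aliases(rat_signature$mirna_id, alias)
  human_records$feature_id <- apply_aliases(human_records$feature_id, alias)

  t2d <- dplyr::filter(human_records, .data$case_label == "T2D")
  ifg <- dplyr::filter(human_records, .data$case_label == "IFG")
  out <- rat_signature
  idx_t <- match(out$mirna_id, t2d$feature_id)
  idx_i <- match(out$mirna_id, ifg$feature_id)
  out$human_t2d_fc <- t2d$signed_fc[idx_t]
  out$human_t2d_p <- t2d$p_value[idx_t]
  out$human_ifg_fc <- ifg$signed_fc[idx_i]
  rat_dir <- ifelse(out$direction == "up", 1, -1)
  human_dir <- fc_direction(out$human_t2d_fc)
  out$concordant <- !is.na(out$human_t2d_fc) &
    human_dir == rat_dir &
    !is.na(out$human_t2d_p) & t2d$significant[idx_t]
  class(out) <- c("mirsig_signature", class(out))
  out
}

#' @export
glance.mirsig_signature <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x),
    n_concordant = sum(x$concordant, na.rm = TRUE),
    n_up = sum(x$direction == "up" & x$concordant, na.rm = TRUE),
    n_down = sum(x$direction == "down" & x$concordant, na.rm = TRUE)
  )
}

#' Per-source significant feature sets
#'
#' Convenience extractor for the Venn step: feature sets that pass the
#' significance flag only (the magnitude cut is a later filter in the
#' pipeline, so the intersection diagram is drawn on significance alone).
#'
#' @param records Fold-change record tibble.
#' @return Named list of feature-id character vectors, one per source.
#' @export
significant_sets <- function(records) {
  sig <- dplyr::filter(records, .data$significant)
  split(sig$feature_id, sig$source)
}
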