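#' Fold-change profile matrix
#'
#' Arranges fold-change records into a profiles-by-features matrix of log2
#' ratios for clustering and ordination. A profile is one contrast (for
#' example one tissue source, or one case label), identified by the
#' `profile_cols` combination; features missing from a profile stay `NA`
#' ("not detected") and are excluded pairwise downstream.
#'
#' @param records Fold-change record tibble.
#' @param profile_cols Columns whose combination labels a profile (default
#'   `species`, `source`, `case_label`).
#' @return A numeric matrix, rownames = profile labels, colnames = feature
#'   ids, values = `log2(ratio)`.
#' @export
fold_change_profile_matrix <- function(records,
                                       profile_cols = c("species", "source", "case_label")) {
  rec <- tibble::as_tibble(records)
  rec$.profile <- do.call(paste, c(rec[profile_cols], sep = "."))
  profiles <- unique(rec$.profile)
  if (length(profiles) < 2) stop_config("need at least two profiles")
  features <- unique(rec$feature_id)
  m <- matrix(NA_real_, length(profiles), length(features),
              dimnames = list(profiles, features))
  m[cbind(match(rec$.profile, profiles), match(rec$feature_id, features))] <- log2(rec$ratio)
  m
}

#' Average-linkage hierarchical clustering of profiles
#'
#' UPGMA-style clustering on pairwise Euclidean distances between profile
#' rows. Missing cells are excluded pairwise (each distance is computed
#' over the features both profiles detect, rescaled to the full feature
#' count). Identical profiles merge at height 0.
#'
#' @param profile_matrix Profiles-by-features numeric matrix, e.g. from
#'   [fold_change_profile_matrix()].
#' @return An object of class `mirsig_dendro`: the `hclust` fit, labels,
#'   and a Newick serialization with branch lengths derived from merge
#'   heights.
#' @export
hierarchical_cluster <- function(profile_matrix) {
  if (nrow(profile_matrix) < 2) stop_config("need at least two profiles to cluster")
  all_missing <- rowSums(!is.na(profile_matrix)) == 0
  if (any(all_missing)) {
    stop_config(paste0("profile(s) with no detected features: ",
                       paste(rownames(profile_matrix)[all_missing], collapse = ", ")))
  }
  d <- dist(profile_matrix, method = "euclidean")
  hc <- hclust(d, method = "average")
  phy <- ape::as.phylo(hc)
  structure(
    list(hclust = hc, labels = rownames(profile_matrix),
         newick = ape::write.tree(phy)),
    class = "mirsig_dendro"
  )
}

#' @export
print.mirsig_dendro <- function(x, ...) {
  cat("<mirsig_dendro> average-linkage tree over", length(x$labels), "profiles\n")
  cat(x$newick, "\n")
  invisible(x)
}

#' @export
tidy.mirsig_dendro <- function(x, ...) {
  hc <- x$hclust
  tibble::tibble(
    merge_step = seq_len(nrow(hc$merge)),
    left = hc$merge[, 1], right = hc$merge[, 2],
    height = hc$height
  )
}

#' Principal component analysis of fold-change profiles
#'
#' Column-centered PCA via the singular value decomposition. Features with
#' any missing value are dropped first (PCA needs a complete matrix), and a
#' deterministic sign convention is applied: within each component the
#' loading of largest magnitude is made positive.
#'
#' @param profile_matrix Profiles-by-features numeric matrix.
#' @param n_components Number of components to keep (default: all); values
#'   beyond the matrix rank are truncated with a warning.
#' @return An object of class `mirsig_pca`: `scores` (profiles x
#'   components), `loadings` (features x components), `explained_variance`
#'   fractions, `n_features_used`.
#' @export
pca_profiles <- function(profile_matrix, n_components = NULL) {
  if (nrow(profile_matrix) < 2) stop_config("need at least two profiles")
  complete <- colSums(is.na(profile_matrix)) == 0
  m <- profile_matrix[, complete, drop = FALSE]
  if (ncol(m) < 1) stop_config("no feature is complete across all profiles")
  fit <- prcomp(m, center = TRUE, scale. = FALSE)
  rank <- sum(fit$sdev > fit$sdev[1] * 1e-12)
  if (is.null(n_components)) n_components <- rank
  if (n_components > rank) {
    warn(paste0("n_components truncated to the rank (", rank, ")"))
    n_components <- rank
  }
  keep <- seq_len(n_components)
  scores <- fit$x[, keep, drop = FALSE]
  loadings <- fit$rotation[, keep, drop = FALSE]
  # Sign convention: the largest-magnitude loading of each PC is positive
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  total_var <- sum(fit$sdev^2)
  structure(
    list(scores = scores, loadings = loadings,
         explained_variance = fit$sdev[keep]^2 / total_var,
         sdev = fit$sdev, center = fit$center,
         n_features_used = ncol(m)),
    class = "mirsig_pca"
  )
}

#' @export
print.mirsig_pca <- function(x, ...) {
  cat("<mirsig_pca>", nrow(x$scores), "profiles,", ncol(x$scores), "components;",
      "variance fractions:", paste(signif(x$explained_variance, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.mirsig_pca <- function(x, ...) {
  sc <- tibble::as_tibble(x$scores, rownames = "profile")
  tidyr::pivot_longer(sc, -"profile", names_to = "component", values_to = "score")
}

#' @export
glance.mirsig_pca <- function(x, ...) {
  tibble::tibble(
    n_profiles = nrow(x$scores),
    n_components = ncol(x$scores),
    n_features_used = x$n_features_used,
    variance_pc1 = x$explained_variance[1],
    variance_total = sum(x$explained_variance)
  )
}

#' @export
autoplot.mirsig_pca <- function(object, ...) {
  sc <- tibble::as_tibble(object$scores, rownames = "profile")
  if (ncol(object$scores) < 2) stop_config("autoplot needs at least two components")
  pct <- round(100 * object$explained_variance[1:2], 1)
  ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2, label = .data$profile)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = paste0("PC1 (", pct[1], "%)"),
                  y = paste0("PC2 (", pct[2], "%)")) +
    ggplot2::theme_minimal()
}

#' Per-subject fold-change profile matrix
#'
#' Subject-level analog of [fold_change_profile_matrix()]: each case
#' subject of a stratum contributes one profile of log2 ratios (subject
#' mean intensity over the control-group mean), so cohorts can be
#' clustered or ordinated at the individual level rather than pooled.
#'
#' @param expr Normalized expression tibble.
#' @param samples Sample sheet.
#' @param species,source Stratum selector.
#' @param features Optional feature subset (default all but `U6`).
#' @return A numeric matrix, one row per case subject (rownames
#'   `<case_label>.<subject_id>`), one column per feature.
#' @export
subject_profile_matrix <- function(expr, samples, species = "human",
                                   source = "blood", features = NULL) {
  samples <- validate_sample_sheet(samples)
  sel <- samples[samples$species == species & samples$source == source, ]
  if (nrow(sel) == 0) stop_config(paste0("unknown stratum: ", species, "/", source))
  ctl <- sel[sel$group == "control", ]
  cas <- sel[sel$group == "case", ]
  if (nrow(ctl) == 0 || nrow(cas) == 0) stop_config("stratum needs control and case samples")
  if (is.null(features)) features <- setdiff(expr$feature_id, "U6")
  rows <- match(features, expr$feature_id)
  ctl_mean <- rowMeans(as.matrix(expr[rows, ctl$sample_id, drop = FALSE]), na.rm = TRUE)
  subj <- dplyr::distinct(cas, .data$subject_id, .data$case_label)
  m <- t(vapply(seq_len(nrow(subj)), function(i) {
    ids <- cas$sample_id[cas$subject_id == subj$subject_id[i]]
    v <- rowMeans(as.matrix(expr[rows, ids, drop = FALSE]), na.rm = TRUE)
    log2(v / ctl_mean)
  }, numeric(length(rows))))
  dimnames(m) <- list(paste(subj$case_label, subj$subject_id, sep = "."), features)
  m[is.nan(m) | is.infinite(m)] <- NA_real_
  m
}

#' Pearson product-moment correlation
#'
#' Standard Pearson correlation over pairwise-complete observations, with
#' the validation the pipeline needs (equal lengths of at least 3, and
#' non-degenerate variance).
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return The correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_config("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop_config("need at least 3 complete pairs")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) stop_config("zero variance in x or y")
  cor(x[ok], y[ok], method = "pearson")
}

#' Fold-change heatmap
#'
#' Green/red/grey heatmap of signed expression change: log2 ratios with
#' down-regulation in green, up-regulation in red, and "not detected"
#' cells in grey.
#'
#' @param records Fold-change record tibble.
#' @param profile_cols Columns labeling a profile, as in
#'   [fold_change_profile_matrix()].
#' @return A ggplot object.
#' @export
plot_fold_change_heatmap <- function(records,
                                     profile_cols = c("species", "source", "case_label")) {
  m <- fold_change_profile_matrix(records, profile_cols)
  df <- tibble::as_tibble(m, rownames = "profile")
  df <- tidyr::pivot_longer(df, -"profile", names_to = "feature_id", values_to = "log2_fc")
  ggplot2::ggplot(df, ggplot2::aes(.data$feature_id, .data$profile, fill = .data$log2_fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "green4", mid = "black", high = "red3",
                                  midpoint = 0, na.value = "grey60",
                                  name = "log2 FC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5, size = 6))
}

#' Venn region bar chart
#'
#' @param venn A `mirsig_venn` object from [venn_counts()].
#' @return A ggplot object showing the non-empty region counts.
#' @export
plot_venn_counts <- function(venn) {
  set_cols <- setdiff(names(venn), "count")
  lab <- apply(as.matrix(venn[, set_cols]), 1, function(r) {
    paste(set_cols[as.logical(r)], collapse = "&")
  })
  df <- tibble::tibble(region = lab, count = venn$count)
  df <- df[df$count > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$region, .data$count), .data$count)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "Venn region", y = "miRNAs") +
    ggplot2::theme_minimal()
}
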