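#' Run the full signature-discovery pipeline
#'
#' End-to-end orchestration: obtain inputs (either generated synthetically
#' or read from files), normalize against U6, apply the detection filter,
#' run every contrast, draw the per-source significance Venn, select the
#' cross-source and cross-species signature, optionally vote consensus
#' targets and evaluate miRNA-mRNA pairs, optionally reduce a qPCR plate,
#' and cluster/ordinate the fold-change profiles. All tables are written as
#' TSV, the dendrogram as Newick text, and a machine-readable run log
#' (seed, thresholds, package version) as JSON.
#'
#' @param config A list, or path to a YAML file, with optional entries:
#'   `mode` (`"synthetic"`, the default, or `"files"`), `generator`
#'   (arguments to [generator_config()]), `expression`/`samples` (paths,
#'   `files` mode), `predictions` (paths to per-database tables),
#'   `filters` (arguments to [filter_config()]), `detection_threshold`
#'   (default 300), `normalizer_id` (default `"U6"`), `alias` (named
#'   list/vector), `qpcr` (logical, synthetic mode: also simulate and
#'   reduce a validation plate), `min_votes` (default 3).
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param seed Integer seed forwarded to the generator (overrides the
#'   config's seed).
#' @return Invisibly, a list of class `mirsig_report` with elements
#'   `records`, `venn`, `rat_signature`, `signature`, `votes`, `pairs`,
#'   `qpcr`, `dendrogram`, `pca`, `run_log`.
#' @export
#' @examples
#' rep <- run_pipeline(list(generator = list(seed = 3)))
#' glance(rep$signature)
run_pipeline <- function(config = list(), out_dir = NULL, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_config(paste0("config file not found: '", config, "'"))
    config <- yaml::read_yaml(config)
  }
  mode <- config$mode %||% "synthetic"
  filters <- do.call(filter_config, config$filters %||% list())
  threshold <- config$detection_threshold %||% 300
  normalizer_id <- config$normalizer_id %||% "U6"
  alias <- unlist(config$alias)
  min_votes <- config$min_votes %||% 3

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
            class = "mirsig_pipeline_error", parent = e)
    })
  }

  gen_cfg <- NULL
  if (mode == "synthetic") {
    gen_args <- config$generator %||% list()
    if (!is.null(seed)) gen_args$seed <- seed
    gen_cfg <- do.call(generator_config, gen_args)
    study <- stage("simulate", generate_microarray_study(gen_cfg))
    expr <- study$expr
    samples <- study$samples
  } else {
    for (p in c(config$expression, config$samples)) {
      if (is.null(p) || !file.exists(p)) {
        stop_config(paste0("input path missing or not found: '", p %||% "<unset>", "'"))
      }
    }
    expr <- stage("read", read_expression_matrix(config$expression, normalizer_id))
    samples <- stage("read", read_sample_sheet(config$samples))
  }

  detected <- stage("preprocess", detection_filter(expr, samples, threshold))
  normalized <- stage("preprocess", normalize_u6(expr, normalizer_id))
  records <- stage("diffexp", run_contrasts(normalized, samples, filters,
                                            detected = detected,
                                            normalizer_id = normalizer_id))

  rat <- dplyr::filter(records, .data$species == "rat")
  human <- dplyr::filter(records, .data$species == "human")
  venn <- if (length(unique(rat$source)) >= 2) {
    stage("signature", venn_counts(significant_sets(rat)))
  } else NULL
  rat_sig <- stage("signature", cross_source_signature(rat))
  signature <- stage("signature", cross_species_signature(rat_sig, human, alias = alias))

  votes <- NULL; pairs <- NULL
  if (!is.null(config$predictions)) {
    preds <- stage("targets", read_prediction_tables(unlist(config$predictions)))
    votes <- stage("targets", consensus_targets(preds, min_votes))
    mrna <- if (!is.null(config$mrna_records)) {
      readr::read_tsv(config$mrna_records, show_col_types = FALSE)
    } else NULL
    if (!is.null(mrna)) {
      pairs <- stage("targets", evaluate_pairs(signature, mrna, votes, filters))
    }
  }

  qpcr <- NULL
  if (isTRUE(config$qpcr) && mode == "synthetic") {
    plate <- stage("qpcr", generate_qpcr_plate(gen_cfg, unique(gen_cfg$planted$feature_id)))
    qpcr <- stage("qpcr", ddct_fold_change(plate, case_group = "T2D"))
  }

  profile_m <- stage("report", fold_change_profile_matrix(records))
  dendro <- stage("report", hierarchical_cluster(profile_m))
  pca <- stage("report", pca_profiles(profile_m))

  run_log <- list(
    package = "mirsig",
    version = as.character(utils::packageVersion("mirsig")),
    mode = mode,
    seed = if (!is.null(gen_cfg)) gen_cfg$seed else seed,
    detection_threshold = threshold,
    normalizer_id = normalizer_id,
    filters = unclass(filters),
    min_votes = min_votes,
    n_features = nrow(expr),
    n_samples = nrow(samples),
    n_signature = sum(signature$concordant, na.rm = TRUE)
  )

  out <- structure(
    list(records = records, venn = venn, rat_signature = rat_sig,
         signature = signature, votes = votes, pairs = pairs, qpcr = qpcr,
         dendrogram = dendro, pca = pca, run_log = run_log),
    class = "mirsig_report"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) if (!is.null(x)) readr::write_tsv(tibble::as_tibble(x), file.path(out_dir, f), progress = FALSE)
    wt(records, "fold_changes.tsv")
    wt(signature, "signature.tsv")
    if (!is.null(venn)) wt(venn, "venn_counts.tsv")
    if (!is.null(votes)) {
      v <- votes
      v$databases <- purrr::map_chr(v$databases, paste, collapse = ";")
      wt(v, "target_votes.tsv")
    }
    wt(pairs, "pair_evaluations.tsv")
    wt(qpcr, "qpcr_fold_changes.tsv")
    writeLines(dendro$newick, file.path(out_dir, "dendrogram.nwk"))
    wt(tibble::as_tibble(pca$scores, rownames = "profile"), "pca_scores.tsv")
    jsonlite::write_json(run_log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}

#' @export
print.mirsig_report <- function(x, ...) {
  cat("<mirsig_report>\n")
  cat("  contrasts:", nrow(x$records), "fold-change records\n")
  cat("  signature:", sum(x$signature$concordant, na.rm = TRUE), "concordant miRNAs\n")
  if (!is.null(x$votes)) cat("  targets:", sum(x$votes$accepted), "accepted consensus pairs\n")
  invisible(x)
}
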