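#' Consensus target voting across prediction databases
#'
#' Counts, for every distinct (miRNA, gene) pair, how many databases
#' predict it, and accepts pairs detected in at least `min_votes` databases
#' (default 3, the 3-of-5 consensus rule). Invariant to database order and
#' to duplicate pairs within one database.
#'
#' @param predictions Prediction tibble (`database`, `mirna_id`,
#'   `gene_id`), see [read_prediction_tables()].
#' @param min_votes Minimum number of databases (default 3); must not
#'   exceed the number of databases.
#' @return A tibble `mirna_id`, `gene_id`, `votes`, `databases` (list
#'   column), `accepted`, sorted by decreasing votes.
#' @export
#' @examples
#' preds <- tibble::tibble(
#'   database = c("d1", "d2", "d3", "d1"),
#'   mirna_id = c("miR-144", "miR-144", "miR-144", "miR-150"),
#'   gene_id  = c("IRS1", "IRS1", "IRS1", "GLUT4")
#' )
#' consensus_targets(preds, min_votes = 3)
consensus_targets <- function(predictions, min_votes = 3) {
  k <- n_databases(predictions)
  if (min_votes > k) {
    stop_config(paste0("min_votes (", min_votes, ") exceeds the number of databases (", k, ")"))
  }
  dedup <- dplyr::distinct(tibble::as_tibble(predictions),
                           .data$database, .data$mirna_id, .data$gene_id)
  out <- dplyr::summarise(
    dplyr::group_by(dedup, .data$mirna_id, .data$gene_id),
    votes = dplyr::n_distinct(.data$database),
    databases = list(sort(unique(.data$database))),
    .groups = "drop"
  )
  out$accepted <- out$votes >= min_votes
  dplyr::arrange(out, dplyr::desc(.data$votes), .data$mirna_id, .data$gene_id)
}

#' The insulin-signaling reporting panel
#'
#' Editable list of insulin-pathway genes used only to subset reporting
#' (never to change any computation): the receptor, the GLUT4 transporter,
#' and the adaptor/effector genes examined alongside the signature miRNAs.
#'
#' @return Character vector of gene symbols.
#' @export
insulin_gene_panel <- function() {
  c("INSR", "SLC2A4", "GLUT4", "IRS1", "CBL", "FOXO1", "PTPN1",
    "INS", "INS1", "INS2", "AKT2")
}

#' Evaluate miRNA-mRNA pair relationships
#'
#' For every accepted consensus pair whose miRNA is in the signature,
#' labels the pair per condition: `inverse` when the miRNA and mRNA signed
#' fold changes strictly oppose (the canonical repression pattern),
#' `concordant` when they strictly agree and both magnitudes pass
#' `min_abs_fc` (the proposed RNA-activator pattern), and `null` otherwise.
#' Pairs whose gene has no mRNA record in a condition are labeled `null`
#' with a warning.
#'
#' @param signature A `mirsig_signature` tibble (or any tibble with
#'   `mirna_id`, `human_t2d_fc`, `human_ifg_fc`).
#' @param mrna_records mRNA fold-change records with `feature_id`,
#'   `case_label`, `signed_fc` (gene ids in `feature_id`).
#' @param votes Consensus vote tibble from [consensus_targets()]; only
#'   accepted rows are used.
#' @param config A [filter_config()] supplying `min_abs_fc` for the
#'   concordant label.
#' @return A tibble: `mirna_id`, `gene_id`, `condition`, `mirna_signed_fc`,
#'   `mrna_signed_fc`, `relationship`.
#' @export
evaluate_pairs <- function(signature, mrna_records, votes, config = filter_config()) {
  acc <- dplyr::filter(tibble::as_tibble(votes), .data$accepted,
                       .data$mirna_id %in% signature$mirna_id)
  conditions <- sort(unique(mrna_records$case_label))
  if (length(conditions) == 0) stop_config("mrna_records carries no case labels")
  fc_col <- function(cond) {
    col <- paste0("human_", tolower(cond), "_fc")
    if (col %in% names(signature)) col else NA_character_
  }
  grid <- tidyr::expand_grid(acc[, c("mirna_id", "gene_id")], condition = conditions)
  n_missing <- 0L
  out <- purrr::pmap_dfr(grid, function(mirna_id, gene_id, condition) {
    col <- fc_col(condition)
    mi_fc <- if (!is.na(col)) signature[[col]][match(mirna_id, signature$mirna_id)] else NA_real_
    rec <- mrna_records[mrna_records$feature_id == gene_id &
                          mrna_records$case_label == condition, ]
    mr_fc <- if (nrow(rec) > 0) rec$signed_fc[1] else NA_real_
    if (nrow(rec) == 0) n_missing <<- n_missing + 1L
    d_mi <- fc_direction(mi_fc)
    d_mr <- fc_direction(mr_fc)
    rel <- if (is.na(mi_fc) || is.na(mr_fc) || d_mi == 0 || d_mr == 0) {
      "null"
    } else if (d_mi * d_mr < 0) {
      "inverse"
    } else if (abs(mi_fc) >= config$min_abs_fc && abs(mr_fc) >= config$min_abs_fc) {
      "concordant"
    } else {
      "null"
    }
    tibble::tibble(mirna_id = mirna_id, gene_id = gene_id, condition = condition,
                   mirna_signed_fc = mi_fc, mrna_signed_fc = mr_fc,
                   relationship = rel)
  })
  if (n_missing > 0) {
    warn(paste0(n_missing, " pair-condition(s) had no mRNA record; labeled null"))
  }
  out
}
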