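#' Read a feature-by-sample expression matrix
#'
#' Reads a tab-separated intensity table: first column holds unique probe
#' identifiers, the header row holds unique sample identifiers, and the body
#' is numeric. Blank cells are kept as `NA` ("not detected"), never coerced
#' to zero; downstream means and tests exclude them.
#'
#' @param path Path to a TSV file.
#' @param normalizer_id Optional identifier of the normalizer probe (for
#'   example `"U6"`); an error is raised if it is absent from the file.
#' @return A tibble whose first column is `feature_id`, with one numeric
#'   column per sample.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_expression_matrix(
#'   tibble::tibble(feature_id = c("miR-144", "U6"), s1 = c(400, 5000), s2 = c(900, 5100)),
#'   tf
#' )
#' read_expression_matrix(tf, normalizer_id = "U6")
read_expression_matrix <- function(path, normalizer_id = NULL) {
  if (!file.exists(path)) {
    stop_format(paste0("expression matrix file not found: '", path, "'"))
  }
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"),
    name_repair = "minimal",
    progress = FALSE
  )
  if (ncol(raw) < 2) stop_format("expression matrix needs a feature column and at least one sample column")
  sample_ids <- names(raw)[-1]
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s) > 0) {
    stop_format(paste0("duplicate sample identifier(s): ", paste(unique(dup_s), collapse = ", ")))
  }
  feature_ids <- raw[[1]]
  dup_f <- feature_ids[duplicated(feature_ids)]
  if (length(dup_f) > 0) {
    stop_format(paste0("duplicate feature identifier(s): ", paste(unique(dup_f), collapse = ", ")))
  }
  body <- raw[-1]
  for (j in seq_along(body)) {
    col <- body[[j]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (length(bad) > 0) {
      stop_format(paste0(
        "non-numeric cell at feature '", feature_ids[bad[1]],
        "', sample '", sample_ids[j], "': '", col[bad[1]], "'"
      ))
    }
    if (any(num < 0, na.rm = TRUE)) {
      stop_format(paste0("negative intensity in sample '", sample_ids[j], "'"))
    }
    body[[j]] <- num
  }
  out <- tibble::tibble(feature_id = feature_ids)
  out <- dplyr::bind_cols(out, body)
  if (!is.null(normalizer_id) && !normalizer_id %in% feature_ids) {
    stop_config(paste0("normalizer '", normalizer_id, "' is not among the features of '", path, "'"))
  }
  out
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]: `NA` cells are written as empty
#' strings so that a round trip preserves the "not detected" state.
#'
#' @param x Expression tibble (`feature_id` plus sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  readr::write_tsv(x, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' The sheet binds each array to its subject, species, tissue source, and
#' group. Comma- or tab-separated (chosen by file extension). Required
#' columns: `sample_id`, `subject_id`, `species` (`rat`/`human`), `source`
#' (`pancreas`, `liver`, `adipose`, `skeletal_muscle`, `blood`), `group`
#' (`control`/`case`), and `case_label` (`T2D`, `IFG`, or `HFD`; empty for
#' controls that serve every contrast in their stratum).
#'
#' @param path Path to a CSV or TSV file.
#' @return A validated tibble with the six columns above.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop_format(paste0("sample sheet file not found: '", path, "'"))
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) readr::read_csv else readr::read_tsv
  sheet <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                  na = c("", "NA"), progress = FALSE)
  validate_sample_sheet(sheet)
}

#' Validate a sample sheet tibble
#'
#' @param sheet A data frame with the sample-sheet columns.
#' @return The validated tibble (character columns, `case_label` `NA` on
#'   control rows).
#' @export
validate_sample_sheet <- function(sheet) {
  required <- c("sample_id", "subject_id", "species", "source", "group", "case_label")
  missing <- setdiff(required, names(sheet))
  if (length(missing) > 0) {
    stop_format(paste0("sample sheet is missing column(s): ", paste(missing, collapse = ", ")))
  }
  sheet <- tibble::as_tibble(sheet)[required]
  dup <- sheet$sample_id[duplicated(sheet$sample_id)]
  if (length(dup) > 0) {
    stop_format(paste0("duplicate sample_id(s): ", paste(unique(dup), collapse = ", ")))
  }
  check_tokens <- function(col, allowed, allow_na = FALSE) {
    vals <- sheet[[col]]
    bad <- if (allow_na) setdiff(unique(vals[!is.na(vals)]), allowed) else setdiff(unique(vals), c(allowed))
    if (length(bad) > 0 || (!allow_na && anyNA(vals))) {
      stop_format(paste0(
        "unknown ", col, " token(s): ",
        paste(c(bad, if (!allow_na && anyNA(vals)) "<missing>"), collapse = ", ")
      ))
    }
  }
  check_tokens("species", .mirsig_species)
  check_tokens("source", .mirsig_sources)
  check_tokens("group", .mirsig_groups)
  check_tokens("case_label", .mirsig_case_labels, allow_na = TRUE)
  if (any(sheet$group == "case" & is.na(sheet$case_label))) {
    stop_format("case samples must carry a case_label (T2D, IFG, or HFD)")
  }
  sheet
}

#' Read per-database miRNA-target prediction tables
#'
#' One two-column delimited file per prediction database (`mirna_id`,
#' `gene_id`, with a header). Pairs are deduplicated within each database;
#' an empty file raises a warning and the database is kept with an empty
#' set, so the vote denominator is still the number of files supplied.
#'
#' @param paths Character vector of file paths; names become database names
#'   (defaults to the file base names).
#' @return A tibble with columns `database`, `mirna_id`, `gene_id`, carrying
#'   the number of databases as the number of distinct `database` values
#'   (empty databases contribute zero rows but are recorded in the
#'   `databases` attribute).
#' @export
read_prediction_tables <- function(paths) {
  if (length(paths) < 1) stop_config("at least one prediction table is required")
  nm <- names(paths)
  if (is.null(nm)) nm <- rep(NA_character_, length(paths))
  nm <- ifelse(is.na(nm) | nm == "", sub("\\.[^.]*$", "", basename(paths)), nm)
  if (anyDuplicated(nm)) {
    stop_format(paste0("duplicate database name(s): ", paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  tabs <- purrr::map2(paths, nm, function(p, n) {
    if (!file.exists(p)) stop_format(paste0("prediction table not found: '", p, "'"))
    tb <- readr::read_tsv(p, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    if (ncol(tb) < 2) stop_format(paste0("prediction table '", p, "' needs two columns (mirna_id, gene_id)"))
    tb <- tb[, 1:2]
    names(tb) <- c("mirna_id", "gene_id")
    if (nrow(tb) == 0) warn(paste0("prediction database '", n, "' is empty; kept with an empty set"))
    dplyr::distinct(dplyr::mutate(tb, database = n), .data$database, .data$mirna_id, .data$gene_id)
  })
  out <- dplyr::bind_rows(tabs)
  out <- out[, c("database", "mirna_id", "gene_id")]
  attr(out, "databases") <- nm
  out
}

#' Number of databases behind a prediction set
#'
#' @param predictions Tibble from [read_prediction_tables()] or
#'   [generate_prediction_tables()].
#' @return Integer count of databases (including empty ones when known).
#' @export
n_databases <- function(predictions) {
  dbs <- attr(predictions, "databases")
  if (is.null(dbs)) dbs <- unique(predictions$database)
  length(dbs)
}

#' Apply an identifier alias table
#'
#' Probe namespaces differ between platforms (for example `miR-320` on one
#' array versus `miR-320a` on another). The alias table is user-supplied
#' configuration, mapping old identifier to canonical identifier; matching
#' is exact and case-sensitive.
#'
#' @param ids Character vector of identifiers.
#' @param alias Named character vector, `c(old = "new")`, or `NULL`.
#' @return The vector with aliases replaced.
#' @export
#' @examples
#' apply_aliases(c("miR-320", "miR-144"), c("miR-320" = "miR-320a"))
apply_aliases <- function(ids, alias = NULL) {
  if (is.null(alias) || length(alias) == 0) return(ids)
  hit <- ids %in% names(alias)
  ids[hit] <- unname(alias[ids[hit]])
  ids
}
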