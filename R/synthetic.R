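#' Default planted signature effects
#'
#' The eight signature miRNAs with their directions and fold-change
#' magnitudes: up-regulated miR-144, miR-150, miR-192, miR-29a and miR-320a;
#' down-regulated miR-146a, miR-30d and miR-182 (rat, all five sources, and
#' human T2D blood). Magnitudes use the study's printed per-tissue values
#' where available (miR-144: pancreas 7.94, liver 4.26, adipose 4.34;
#' miR-150: adipose 3.21, liver 2.07; miR-146a: adipose 4.62 down; miR-30d:
#' pancreas 2.81 down; miR-182: skeletal muscle 4.23 down; human blood
#' miR-144: T2D 3.07, IFG 1.385) and a 2.5-fold default elsewhere. In the
#' IFG cohort miR-30d and miR-182 flip to up-regulated and miR-144 shrinks,
#' mirroring the pre-diabetic discordance.
#'
#' @return A tibble with columns `feature_id`, `species`, `source`,
#'   `case_label`, `direction` (`up`/`down`), `fold_change` (> 1) and
#'   `log2_effect` (> 0).
#' @export
default_planted_effects <- function() {
  up8 <- c("miR-144", "miR-150", "miR-192", "miR-29a", "miR-320a")
  down8 <- c("miR-146a", "miR-30d", "miR-182")
  rat_sources <- .mirsig_sources
  default_fc <- 2.5
  printed <- list(
    "miR-144"  = c(pancreas = 7.94, liver = 4.26, adipose = 4.34),
    "miR-150"  = c(adipose = 3.21, liver = 2.07),
    "miR-146a" = c(adipose = 4.62),
    "miR-30d"  = c(pancreas = 2.81),
    "miR-182"  = c(skeletal_muscle = 4.23)
  )
  rat <- tidyr::expand_grid(feature_id = c(up8, down8), source = rat_sources)
  rat$species <- "rat"
  rat$case_label <- "HFD"
  rat$direction <- ifelse(rat$feature_id %in% up8, "up", "down")
  rat$fold_change <- purrr::map2_dbl(rat$feature_id, rat$source, function(f, s) {
    v <- printed[[f]]
    if (!is.null(v) && s %in% names(v)) unname(v[s]) else default_fc
  })

  t2d <- tibble::tibble(
    feature_id = c(up8, down8),
    species = "human", source = "blood", case_label = "T2D",
    direction = c(rep("up", 5), rep("down", 3)),
    fold_change = c(3.07, rep(default_fc, 4), rep(default_fc, 3))
  )
  ifg <- tibble::tibble(
    feature_id = c(up8, down8),
    species = "human", source = "blood", case_label = "IFG",
    direction = c(rep("up", 5), "down", "up", "up"),
    fold_change = c(1.385, rep(default_fc, 4), default_fc, 2.0, 2.0)
  )
  out <- dplyr::bind_rows(rat, t2d, ifg)
  out$log2_effect <- log2(out$fold_change)
  out[, c("feature_id", "species", "source", "case_label", "direction", "fold_change", "log2_effect")]
}

#' Build and validate a synthetic-study configuration
#'
#' Defaults encode the study design the generator emulates: ~200 detectable
#' background miRNAs per source, six animals per rat group across five
#' sources (pancreas, liver, adipose, skeletal muscle, blood), a human
#' whole-blood cohort of 7 controls, 6 IFG and 8 T2D subjects, a constant
#' U6 normalizer probe, log-normal intensity noise (sd 0.25 on the log2
#' scale), per-array multiplicative scale jitter, and a 10% chance that a
#' background feature sits below the 300-intensity detection threshold in a
#' given source.
#'
#' @param n_background_features Number of non-signature miRNAs.
#' @param n_control,n_case Rat group sizes per source.
#' @param n_human Named integer vector `c(CTL=, IFG=, T2D=)`.
#' @param baseline_log2_mean,baseline_log2_sd Log2 baseline intensity
#'   distribution for detectable features.
#' @param noise_sd Per-cell log2 measurement noise sd.
#' @param scale_sd Per-sample log2 array-scale jitter sd (applied to every
#'   feature including the normalizer; U6 normalization removes it).
#' @param u6_intensity Normalizer level before jitter.
#' @param dropout_rate Probability a background feature falls below the
#'   detection threshold in a source (drawn as a low baseline, not deleted).
#' @param dropout_log2_mean Log2 baseline used for dropped-out features.
#' @param planted_min_log2_baseline Lower truncation for planted-feature
#'   baselines (default 10, about four times the detection threshold).
#'   Signature miRNAs are modeled as robustly expressed in every source --
#'   the planted truth is defined as *detectable* differential expression --
#'   so their baselines are drawn from the same log-normal distribution
#'   truncated above the detection floor.
#' @param ct_noise_sd Per-replicate Ct noise sd for qPCR plates.
#' @param planted Planted-effect tibble, see [default_planted_effects()].
#' @param seed Integer seed; a fixed seed makes every output bit-reproducible.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_background_features = 200,
                             n_control = 6,
                             n_case = 6,
                             n_human = c(CTL = 7, IFG = 6, T2D = 8),
                             baseline_log2_mean = 12,
                             baseline_log2_sd = 1.5,
                             noise_sd = 0.25,
                             scale_sd = 0.2,
                             u6_intensity = 5000,
                             dropout_rate = 0.1,
                             dropout_log2_mean = 6,
                             planted_min_log2_baseline = 10,
                             ct_noise_sd = 0.15,
                             planted = default_planted_effects(),
                             seed = 1L) {
  cfg <- list(
    n_background_features = as.integer(n_background_features),
    n_control = as.integer(n_control), n_case = as.integer(n_case),
    n_human = n_human,
    baseline_log2_mean = baseline_log2_mean, baseline_log2_sd = baseline_log2_sd,
    noise_sd = noise_sd, scale_sd = scale_sd,
    u6_intensity = u6_intensity,
    dropout_rate = dropout_rate, dropout_log2_mean = dropout_log2_mean,
    planted_min_log2_baseline = planted_min_log2_baseline,
    ct_noise_sd = ct_noise_sd,
    planted = tibble::as_tibble(planted),
    seed = as.integer(seed)
  )
  if (cfg$baseline_log2_sd <= 0) stop_config("baseline_log2_sd must be > 0")
  if (cfg$noise_sd < 0 || cfg$scale_sd < 0 || cfg$ct_noise_sd < 0) {
    stop_config("noise standard deviations must be >= 0")
  }
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) stop_config("dropout_rate must be in [0, 1)")
  if (cfg$n_control < 2 || cfg$n_case < 2) stop_config("need at least two samples per group")
  if (!all(c("CTL", "IFG", "T2D") %in% names(cfg$n_human))) {
    stop_config("n_human must name CTL, IFG and T2D counts")
  }
  needed <- c("feature_id", "species", "source", "case_label", "direction", "log2_effect")
  if (!all(needed %in% names(cfg$planted))) {
    stop_config(paste0("planted effects must have columns: ", paste(needed, collapse = ", ")))
  }
  if (any(cfg$planted$log2_effect <= 0)) stop_config("planted log2_effect must be > 0")
  if (any(cfg$planted$feature_id == "U6")) {
    stop_config("a planted feature may not collide with the normalizer id 'U6'")
  }
  structure(cfg, class = "generator_config")
}

# Sample sheet for the emulated design: five rat sources sampled from the
# same 12 animals, plus one human blood cohort.
synthetic_sample_sheet <- function(cfg) {
  rat <- tidyr::expand_grid(source = .mirsig_sources,
                            idx = seq_len(cfg$n_control + cfg$n_case))
  rat$group <- ifelse(rat$idx <= cfg$n_control, "control", "case")
  rat$subject_id <- ifelse(rat$group == "control",
                           sprintf("rat_nfd_%02d", rat$idx),
                           sprintf("rat_hfd_%02d", rat$idx - cfg$n_control))
  rat$sample_id <- paste(rat$subject_id, rat$source, sep = ".")
  rat$species <- "rat"
  rat$case_label <- ifelse(rat$group == "case", "HFD", NA_character_)

  hn <- cfg$n_human
  hum <- tibble::tibble(
    cohort = rep(c("CTL", "IFG", "T2D"), times = hn[c("CTL", "IFG", "T2D")]),
    idx = unlist(lapply(hn[c("CTL", "IFG", "T2D")], seq_len))
  )
  hum$subject_id <- sprintf("h_%s_%02d", tolower(hum$cohort), hum$idx)
  hum$sample_id <- paste0(hum$subject_id, ".blood")
  hum$species <- "human"
  hum$source <- "blood"
  hum$group <- ifelse(hum$cohort == "CTL", "control", "case")
  hum$case_label <- ifelse(hum$group == "case", hum$cohort, NA_character_)

  validate_sample_sheet(dplyr::bind_rows(
    rat[, c("sample_id", "subject_id", "species", "source", "group", "case_label")],
    hum[, c("sample_id", "subject_id", "species", "source", "group", "case_label")]
  ))
}

#' Generate a synthetic microarray study with a planted signature
#'
#' Simulates the full two-species design: five rat sources with
#' control/case groups and a human blood cohort (CTL/IFG/T2D), one
#' expression matrix over all samples. Log2 intensity of a feature is
#' `baseline(feature, stratum) + effect + scale_jitter(sample) +
#' N(0, noise_sd)`; the planted effect shifts case samples by
#' `±log2_effect`, background features have equal expectation in case and
#' control, and the U6 normalizer row is constant apart from the per-sample
#' scale jitter. Dropout is emulated by drawing a low baseline below the
#' detection threshold rather than deleting cells, so the detection filter
#' has something to do.
#'
#' @param config A [generator_config()].
#' @return A list of class `mirsig_study` with elements `expr` (expression
#'   tibble), `samples` (sample sheet), and `truth` (tibble flagging the
#'   planted signature features with their true directions and fold
#'   changes).
#' @export
#' @examples
#' study <- generate_microarray_study(generator_config(seed = 7))
#' dim(study$expr)
generate_microarray_study <- function(config) {
  cfg <- if (inherits(config, "generator_config")) config else do.call(generator_config, config)
  set.seed(cfg$seed)
  samples <- synthetic_sample_sheet(cfg)

  background_ids <- sprintf("miR-sim-%03d", seq_len(cfg$n_background_features))
  planted_ids <- unique(cfg$planted$feature_id)
  clash <- intersect(planted_ids, background_ids)
  if (length(clash) > 0) stop_config(paste0("planted ids collide with background ids: ", clash[1]))
  feature_ids <- c(planted_ids, background_ids, "U6")
  n_feat <- length(feature_ids)

  strata <- dplyr::distinct(samples, .data$species, .data$source)
  # Per-stratum baselines; dropout redraws a background baseline low.
  baselines <- matrix(NA_real_, n_feat, nrow(strata),
                      dimnames = list(feature_ids, paste(strata$species, strata$source)))
  for (k in seq_len(nrow(strata))) {
    b <- rnorm(n_feat, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
    is_bg <- feature_ids %in% background_ids
    drop <- is_bg & runif(n_feat) < cfg$dropout_rate
    b[drop] <- rnorm(sum(drop), cfg$dropout_log2_mean, 0.5)
    # planted signature features are robustly expressed above the detection
    # floor in every source: truncated draw from the same distribution
    is_planted <- feature_ids %in% planted_ids
    p_lo <- stats::pnorm(cfg$planted_min_log2_baseline,
                         cfg$baseline_log2_mean, cfg$baseline_log2_sd)
    b[is_planted] <- stats::qnorm(runif(sum(is_planted), p_lo, 1),
                                  cfg$baseline_log2_mean, cfg$baseline_log2_sd)
    baselines[, k] <- b
  }

  jitter <- rnorm(nrow(samples), 0, cfg$scale_sd)
  names(jitter) <- samples$sample_id

  # Effect lookup: feature x sample log2 shift for case samples
  eff_key <- paste(cfg$planted$feature_id, cfg$planted$species,
                   cfg$planted$source, cfg$planted$case_label)
  eff_val <- ifelse(cfg$planted$direction == "up", 1, -1) * cfg$planted$log2_effect
  names(eff_val) <- eff_key

  mat <- matrix(NA_real_, n_feat, nrow(samples),
                dimnames = list(feature_ids, samples$sample_id))
  for (i in seq_len(nrow(samples))) {
    s <- samples[i, ]
    k <- which(strata$species == s$species & strata$source == s$source)
    lg <- baselines[, k] + jitter[i] + rnorm(n_feat, 0, cfg$noise_sd)
    if (s$group == "case") {
      key <- paste(feature_ids, s$species, s$source, s$case_label)
      shift <- eff_val[key]
      shift[is.na(shift)] <- 0
      lg <- lg + shift
    }
    lg["U6"] <- log2(cfg$u6_intensity) + jitter[i]
    mat[, i] <- 2^lg
  }

  expr <- tibble::as_tibble(mat, rownames = "feature_id")

  truth_planted <- dplyr::mutate(cfg$planted, signature = TRUE)
  truth_bg <- tidyr::expand_grid(
    feature_id = background_ids,
    dplyr::distinct(samples[samples$group == "case", ],
                    .data$species, .data$source, .data$case_label)
  )
  truth_bg$direction <- "none"
  truth_bg$fold_change <- 1
  truth_bg$log2_effect <- 0
  truth_bg$signature <- FALSE
  truth <- dplyr::bind_rows(
    truth_planted[, c("feature_id", "species", "source", "case_label",
                      "direction", "fold_change", "log2_effect", "signature")],
    truth_bg[, c("feature_id", "species", "source", "case_label",
                 "direction", "fold_change", "log2_effect", "signature")]
  )

  structure(list(expr = expr, samples = samples, truth = truth, config = cfg),
            class = "mirsig_study")
}

#' @export
print.mirsig_study <- function(x, ...) {
  cat("<mirsig_study> ", nrow(x$expr), " features x ", nrow(x$samples), " samples; ",
      sum(x$truth$signature & !duplicated(x$truth$feature_id)), " planted signature miRNAs\n",
      sep = "")
  invisible(x)
}

#' Generate a synthetic qPCR plate
#'
#' Emulates a stem-loop RT-PCR validation plate: triplicate Ct values per
#' (feature, group) for the requested targets plus a reference gene (18S
#' rRNA by default). A feature planted with log2 effect `e` in the chosen
#' stratum has its case-group Ct lowered by `e` cycles, so the expected
#' \eqn{\Delta\Delta Ct} is `-e` and the recovered fold change `2^e`.
#'
#' @param config A [generator_config()]; supplies planted effects and
#'   `ct_noise_sd`.
#' @param targets Character vector of assayed features (must not include the
#'   reference).
#' @param reference_id Reference gene identifier (default `"18S"`).
#' @param species,source,case_label Stratum whose planted effects drive the
#'   plate (default human blood T2D).
#' @param n_replicates Technical replicates per well group.
#' @return A tibble `CtTable` with columns `feature_id`, `group`
#'   (`control` or the case label), `replicate`, `ct`, and the reference id
#'   stored in the `reference_id` attribute.
#' @export
generate_qpcr_plate <- function(config, targets, reference_id = "18S",
                                species = "human", source = "blood",
                                case_label = "T2D", n_replicates = 3) {
  cfg <- if (inherits(config, "generator_config")) config else do.call(generator_config, config)
  if (length(targets) == 0) stop_config("empty target list")
  if (reference_id %in% targets) stop_config("reference_id must not be among the targets")
  set.seed(cfg$seed + 104729L)  # offset so plates differ from arrays at the same seed

  pl <- cfg$planted
  pl <- pl[pl$species == species & pl$source == source & pl$case_label == case_label, ]
  eff <- setNames(ifelse(pl$direction == "up", 1, -1) * pl$log2_effect, pl$feature_id)

  groups <- c("control", case_label)
  base_ct <- setNames(rnorm(length(targets), 25, 2), targets)
  rows <- tidyr::expand_grid(feature_id = c(targets, reference_id),
                             group = groups, replicate = seq_len(n_replicates))
  rows$ct <- purrr::pmap_dbl(rows, function(feature_id, group, replicate) {
    mu <- if (feature_id == reference_id) 15 else {
      e <- if (group == "control") 0 else if (feature_id %in% names(eff)) eff[[feature_id]] else 0
      base_ct[[feature_id]] - e  # higher expression -> fewer cycles
    }
    mu + rnorm(1, 0, cfg$ct_noise_sd)
  })
  attr(rows, "reference_id") <- reference_id
  rows
}

#' Generate planted miRNA-target prediction tables
#'
#' Emulates the multi-database target search: each true pair is written into
#' exactly `votes_per_true_pair` databases; decoy pairs appear in at most
#' `min(2, k - 1)` databases so they can never reach a 3-of-5 consensus.
#'
#' @param config A [generator_config()] (used for the seed).
#' @param true_pairs Tibble or data frame with columns `mirna_id`,
#'   `gene_id`.
#' @param k Number of databases (default 5).
#' @param votes_per_true_pair Databases carrying each true pair (default 3).
#' @param n_decoys Number of random decoy pairs.
#' @return List with `predictions` (tibble `database`, `mirna_id`,
#'   `gene_id`, with a `databases` attribute) and `truth` (per-pair planted
#'   vote counts and a `is_true` flag).
#' @export
generate_prediction_tables <- function(config, true_pairs, k = 5,
                                       votes_per_true_pair = 3, n_decoys = 20) {
  cfg <- if (inherits(config, "generator_config")) config else do.call(generator_config, config)
  true_pairs <- tibble::as_tibble(true_pairs)
  if (!all(c("mirna_id", "gene_id") %in% names(true_pairs))) {
    stop_config("true_pairs needs columns mirna_id and gene_id")
  }
  if (n_decoys < 0) stop_config("n_decoys must be >= 0")
  if (votes_per_true_pair > k) stop_config("votes_per_true_pair must be <= k")
  if (votes_per_true_pair < 1) stop_config("votes_per_true_pair must be >= 1")
  set.seed(cfg$seed + 7919L)

  canonical <- c("RegRNA", "miRBase", "TargetScan", "Mirgen", "microRNA.org")
  dbs <- if (k <= length(canonical)) canonical[seq_len(k)] else c(canonical, sprintf("db%02d", seq_len(k - length(canonical))))

  assign_rows <- function(pair_df, votes) {
    purrr::pmap_dfr(cbind(pair_df, votes = votes), function(mirna_id, gene_id, votes) {
      tibble::tibble(database = sample(dbs, votes),
                     mirna_id = mirna_id, gene_id = gene_id)
    })
  }
  true_rows <- assign_rows(true_pairs[, c("mirna_id", "gene_id")],
                           rep(votes_per_true_pair, nrow(true_pairs)))
  decoy_cap <- min(2, k - 1)
  decoys <- tibble::tibble(
    mirna_id = sprintf("miR-decoy-%03d", seq_len(n_decoys)),
    gene_id = sprintf("GENE%03d", sample(900, max(n_decoys, 1))[seq_len(n_decoys)])
  )
  decoy_votes <- if (n_decoys > 0 && decoy_cap >= 1) sample(decoy_cap, n_decoys, replace = TRUE) else integer(0)
  decoy_rows <- if (n_decoys > 0 && decoy_cap >= 1) assign_rows(decoys, decoy_votes) else
    tibble::tibble(database = character(), mirna_id = character(), gene_id = character())

  predictions <- dplyr::bind_rows(true_rows, decoy_rows)
  attr(predictions, "databases") <- dbs
  truth <- dplyr::bind_rows(
    dplyr::mutate(true_pairs[, c("mirna_id", "gene_id")],
                  votes = votes_per_true_pair, is_true = TRUE),
    if (n_decoys > 0 && decoy_cap >= 1) dplyr::mutate(decoys, votes = decoy_votes, is_true = FALSE)
  )
  list(predictions = predictions, truth = truth)
}
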