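test_that("noiseless planting yields exact fold changes", {
  planted <- tibble::tibble(
    feature_id = "miR-144", species = "rat", source = "pancreas",
    case_label = "HFD", direction = "up", fold_change = 8, log2_effect = 3
  )
  cfg <- noiseless_config(seed = 4, planted = planted)
  study <- generate_microarray_study(cfg)
  rec <- contrast(study$expr, study$samples, "rat", "pancreas", "HFD",
                  features = "miR-144")
  expect_equal(rec$signed_fc, 8)
  # background features show no change at all without noise
  bg <- contrast(study$expr, study$samples, "rat", "pancreas", "HFD",
                 features = c("miR-sim-001", "miR-sim-002"))
  expect_equal(bg$ratio, c(1, 1))
})

test_that("the generator is bit-reproducible under a fixed seed", {
  a <- generate_microarray_study(generator_config(seed = 42))
  b <- generate_microarray_study(generator_config(seed = 42))
  expect_identical(a$expr, b$expr)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)
  c <- generate_microarray_study(generator_config(seed = 43))
  expect_false(identical(a$expr, c$expr))
})

test_that("config validation rejects impossible settings", {
  expect_error(generator_config(dropout_rate = 1), class = "mirsig_config_error")
  expect_error(generator_config(baseline_log2_sd = 0), class = "mirsig_config_error")
  bad <- default_planted_effects()
  bad$feature_id[1] <- "U6"
  expect_error(generator_config(planted = bad), class = "mirsig_config_error")
  expect_error(generate_qpcr_plate(generator_config(), character(0)),
               class = "mirsig_config_error")
  expect_error(generate_qpcr_plate(generator_config(), c("18S", "miR-144")),
               class = "mirsig_config_error")
  expect_error(generate_prediction_tables(generator_config(),
                                          tibble::tibble(mirna_id = "a", gene_id = "b"),
                                          k = 5, votes_per_true_pair = 6),
               class = "mirsig_config_error")
  expect_error(generate_prediction_tables(generator_config(),
                                          tibble::tibble(mirna_id = "a", gene_id = "b"),
                                          n_decoys = -1),
               class = "mirsig_config_error")
})

test_that("background log2 fold-change spread matches the sampling variance", {
  # closed form: sd of a difference of two 6-sample means = noise_sd * sqrt(1/6 + 1/6)
  cfg0 <- generator_config()
  expected_sd <- cfg0$noise_sd * sqrt(1 / cfg0$n_case + 1 / cfg0$n_control)
  lfc <- unlist(lapply(1:20, function(s) {
    study <- generate_microarray_study(generator_config(seed = s, dropout_rate = 0))
    norm <- normalize_u6(study$expr)  # removes the array-scale jitter
    rat <- study$samples[study$samples$species == "rat" & study$samples$source == "liver", ]
    bg_rows <- grepl("^miR-sim-", norm$feature_id)
    m <- log2(as.matrix(norm[bg_rows, rat$sample_id]))
    rowMeans(m[, rat$group == "case"]) - rowMeans(m[, rat$group == "control"])
  }))
  expect_lt(abs(sd(lfc) - expected_sd) / expected_sd, 0.15)
})

test_that("planted group-mean fold changes are recovered within 3 standard errors", {
  study <- generate_microarray_study(generator_config(seed = 9))
  norm <- normalize_u6(study$expr)
  rec <- run_contrasts(norm, study$samples)
  truth <- study$truth[study$truth$signature, ]
  merged <- merge(rec, truth, by = c("feature_id", "species", "source", "case_label"))
  expect_gt(nrow(merged), 30)
  # 3-sem band on the log2 scale for a difference of group means,
  # widened to 3.3 for simultaneity across the ~40 planted records
  sem <- 0.25 * sqrt(1 / merged$n_case + 1 / merged$n_control)
  dir_eff <- ifelse(merged$direction == "up", 1, -1) * merged$log2_effect
  expect_true(all(abs(log2(merged$ratio) - dir_eff) < 3.3 * sem))
})

test_that("qPCR plates recover planted effects (noiseless exactly, noisy within 3 sems)", {
  planted <- tibble::tibble(
    feature_id = c("miR-144", "miR-146a"), species = "human", source = "blood",
    case_label = "T2D", direction = c("up", "down"),
    fold_change = c(2, 2), log2_effect = c(1, 1)
  )
  cfg <- generator_config(planted = planted, ct_noise_sd = 0)
  plate <- generate_qpcr_plate(cfg, c("miR-144", "miR-146a", "miR-999"))
  fc <- ddct_fold_change(plate, case_group = "T2D")
  expect_equal(fc$fold_change[fc$feature_id == "miR-144"], 2)
  expect_equal(fc$fold_change[fc$feature_id == "miR-146a"], 0.5)
  expect_equal(fc$fold_change[fc$feature_id == "miR-999"], 1)  # no planted effect

  e <- 1.618
  planted2 <- tibble::tibble(feature_id = "miR-144", species = "human",
                             source = "blood", case_label = "T2D",
                             direction = "up", fold_change = 2^e, log2_effect = e)
  recov <- vapply(1:100, function(s) {
    cfgn <- generator_config(planted = planted2, ct_noise_sd = 0.1, seed = s)
    p <- generate_qpcr_plate(cfgn, "miR-144")
    ddct_fold_change(p, case_group = "T2D")$fold_change
  }, numeric(1))
  sem <- sd(recov) / sqrt(length(recov))
  expect_lt(abs(mean(recov) - 2^e), 3 * sem + 1e-9)
})

test_that("prediction generator vote counts equal the requested counts", {
  set.seed(1)
  for (i in 1:50) {
    k <- sample(3:6, 1)
    v <- sample(seq_len(k), 1)
    nd <- sample(0:15, 1)
    truep <- tibble::tibble(mirna_id = sprintf("miR-%d", 1:3),
                            gene_id = sprintf("G%d", 1:3))
    gen <- generate_prediction_tables(generator_config(seed = i), truep,
                                      k = k, votes_per_true_pair = v, n_decoys = nd)
    counts <- oracle_vote_counts(gen$predictions)
    truth <- gen$truth
    key <- paste(truth$mirna_id, truth$gene_id, sep = "\r")
    expect_equal(unname(counts[key]), truth$votes)
    expect_true(all(truth$votes[!truth$is_true] <= min(2, k - 1)))
  }
})
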