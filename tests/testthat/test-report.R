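test_that("profile matrix holds log2 ratios with missing features as NA", {
  recs <- tibble::tibble(
    feature_id = c("a", "b", "a"),
    species = "rat",
    source = c("liver", "liver", "blood"),
    case_label = "HFD",
    ratio = c(8, 0.125, 2)
  )
  m <- fold_change_profile_matrix(recs)
  expect_equal(m["rat.liver.HFD", "a"], 3)
  expect_equal(m["rat.liver.HFD", "b"], -3)
  expect_true(is.na(m["rat.blood.HFD", "b"]))
  expect_error(fold_change_profile_matrix(recs[1:2, ]), class = "mirsig_config_error")
})

test_that("average-linkage clustering: toy case, ties at zero, newick output", {
  m <- matrix(c(0, 1, 10), ncol = 1, dimnames = list(c("p0", "p1", "p10"), "f"))
  dn <- hierarchical_cluster(m)
  expect_equal(sort(dn$hclust$merge[1, ]), c(-2, -1))  # 0 and 1 merge first
  expect_equal(dn$hclust$height[1], 1)
  expect_match(dn$newick, "^\\(")
  expect_setequal(ape::read.tree(text = dn$newick)$tip.label, c("p0", "p1", "p10"))

  dup <- matrix(rep(c(1, 2), each = 2), 2, 2, dimnames = list(c("x", "y"), NULL))
  expect_equal(hierarchical_cluster(dup)$hclust$height[1], 0)
})

test_that("clustering matches a brute-force UPGMA oracle on random instances", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    m <- matrix(rnorm(n * 5), n, 5, dimnames = list(paste0("p", 1:n), NULL))
    dn <- hierarchical_cluster(m)
    got <- as.matrix(stats::cophenetic(dn$hclust))
    want <- oracle_upgma_cophenetic(m)
    expect_equal(got[rownames(want), colnames(want)], want, tolerance = 1e-9)
  }
})

test_that("blood clusters with peripheral tissues when pancreas diverges", {
  planted <- default_planted_effects()
  boost <- planted$species == "rat" & planted$source == "pancreas"
  planted$fold_change[boost] <- 12
  planted$log2_effect <- log2(planted$fold_change)
  study <- generate_microarray_study(generator_config(seed = 44, noise_sd = 0.1,
                                                      planted = planted))
  norm <- normalize_u6(study$expr)
  rec <- run_contrasts(norm, study$samples)
  m <- fold_change_profile_matrix(rec[rec$species == "rat", ],
                                  profile_cols = "source")
  d <- as.matrix(dist(m))
  nn <- names(which.min(d["blood", setdiff(rownames(d), "blood")]))
  expect_true(nn %in% c("liver", "adipose", "skeletal_muscle"))
})

test_that("PCA: orientation, variance conservation, reconstruction", {
  set.seed(10)
  t_par <- rnorm(40)
  cloud <- cbind(t_par + rnorm(40, 0, 0.05), t_par + rnorm(40, 0, 0.05))
  rownames(cloud) <- paste0("p", 1:40)
  fit <- pca_profiles(cloud)
  expect_equal(abs(fit$loadings[, 1]), c(1, 1) / sqrt(2), tolerance = 0.05,
               ignore_attr = TRUE)
  expect_true(all(fit$loadings[which.max(abs(fit$loadings[, 1])), 1] > 0))
  expect_equal(sum(fit$explained_variance), 1, tolerance = 1e-9)

  m <- matrix(rnorm(60), 10, 6, dimnames = list(paste0("p", 1:10), paste0("f", 1:6)))
  full <- pca_profiles(m)
  recon <- full$scores %*% t(full$loadings)
  centered <- sweep(m, 2, colMeans(m))
  expect_lt(max(abs(recon - centered)) / max(abs(centered)), 1e-8)

  expect_warning(tr <- pca_profiles(m, n_components = 50), "rank")
  expect_lte(ncol(tr$scores), 10)
})

test_that("cohort PCA separates IFG from T2D subjects in nearly all seeds", {
  hits <- vapply(1:20, function(s) {
    study <- generate_microarray_study(generator_config(seed = 300 + s))
    norm <- normalize_u6(study$expr)
    m <- subject_profile_matrix(norm, study$samples, "human", "blood")
    fit <- pca_profiles(m, n_components = 2)
    grp <- sub("\\..*", "", rownames(fit$scores))
    sc <- fit$scores
    cent <- rbind(IFG = colMeans(sc[grp == "IFG", , drop = FALSE]),
                  T2D = colMeans(sc[grp == "T2D", , drop = FALSE]))
    pred <- apply(sc, 1, function(r) {
      rownames(cent)[which.min(colSums((t(cent) - r)^2))]
    })
    all(pred == grp)
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("pearson correlation: closed forms and input validation", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, rep(1, 10)), class = "mirsig_config_error")
  expect_error(pearson_r(1:3, 1:4), class = "mirsig_config_error")
  # pairwise-complete handling
  y <- 2 * x; y[3] <- NA
  expect_equal(pearson_r(x, y), 1)
})

test_that("tidiers and plots return well-formed objects", {
  rep <- run_pipeline(list(generator = list(seed = 51)))
  expect_s3_class(tidy(rep$pca), "tbl_df")
  expect_s3_class(glance(rep$pca), "tbl_df")
  expect_s3_class(tidy(rep$dendrogram), "tbl_df")
  expect_s3_class(glance(rep$venn), "tbl_df")
  expect_s3_class(glance(rep$signature), "tbl_df")
  expect_s3_class(autoplot(rep$pca), "ggplot")
  expect_s3_class(plot_fold_change_heatmap(rep$records), "ggplot")
  expect_s3_class(plot_venn_counts(rep$venn), "ggplot")
})

test_that("pipeline outputs are deterministic and fail loudly on bad inputs", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_pipeline(list(generator = list(seed = 77), qpcr = TRUE), out_dir = d1)
  run_pipeline(list(generator = list(seed = 77), qpcr = TRUE), out_dir = d2)
  for (f in c("fold_changes.tsv", "signature.tsv", "venn_counts.tsv",
              "dendrogram.nwk", "pca_scores.tsv", "qpcr_fold_changes.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  log <- jsonlite::read_json(file.path(d1, "run_log.json"))
  expect_equal(log$seed, 77)
  expect_equal(log$n_signature, 8)

  expect_error(run_pipeline(list(mode = "files", expression = "/nope/missing.tsv",
                                 samples = "/nope/sheet.csv")),
               "missing.tsv", class = "mirsig_config_error")
})

test_that("pipeline results are invariant to sample-column permutation", {
  study <- generate_microarray_study(generator_config(seed = 88))
  norm1 <- normalize_u6(study$expr)
  perm <- c("feature_id", sample(setdiff(names(study$expr), "feature_id")))
  norm2 <- normalize_u6(study$expr[, perm])
  r1 <- run_contrasts(norm1, study$samples)
  r2 <- run_contrasts(norm2, study$samples)
  expect_equal(r1, r2)
})
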