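test_that("venn counts: small closed-form cases", {
  v <- venn_counts(list(first = c("a", "b"), second = c("b", "c")))
  cnt <- function(f, s) v$count[v$first == f & v$second == s]
  expect_equal(cnt(TRUE, FALSE), 1L)
  expect_equal(cnt(FALSE, TRUE), 1L)
  expect_equal(cnt(TRUE, TRUE), 1L)
  expect_equal(attr(v, "union_size"), 3L)

  # five identical sets: everything in the all-five region
  ids <- paste0("m", 1:84)
  v5 <- venn_counts(setNames(replicate(5, ids, simplify = FALSE), paste0("s", 1:5)))
  expect_equal(glance(v5)$all_sets_count, 84L)
  expect_equal(sum(v5$count), 84L)

  expect_error(venn_counts(list(a = "x")), class = "mirsig_config_error")
  expect_error(venn_counts(setNames(list("x", "y"), c("a", "a"))),
               class = "mirsig_config_error")
})

test_that("venn regions match exhaustive set algebra and conserve the union", {
  set.seed(19)
  for (i in 1:100) {
    k <- 5
    sets <- setNames(lapply(1:k, function(j) {
      sample(paste0("m", 1:30), sample(3:20, 1))
    }), paste0("set", 1:k))
    v <- venn_counts(sets)
    expect_equal(sum(v$count), length(unique(unlist(sets))))
    # spot-check 6 random regions against the brute-force oracle
    for (r in sample(nrow(v), 6)) {
      pattern <- as.logical(v[r, paste0("set", 1:k)])
      expect_equal(v$count[r], oracle_venn_region(sets, pattern))
    }
  }
})

make_record <- function(feature_id, source, signed_fc, p = 0.001, rep_frac = 1,
                        passes = TRUE, species = "rat", case_label = "HFD") {
  tibble::tibble(
    feature_id = feature_id, species = species, source = source,
    case_label = case_label, ratio = ifelse(signed_fc >= 1, signed_fc, -1 / signed_fc),
    signed_fc = signed_fc, p_value = p, replication_fraction = rep_frac,
    significant = p < 0.05, magnitude = abs(signed_fc) >= 1.5,
    replicated = rep_frac >= 0.5,
    passes_all = passes & p < 0.05 & abs(signed_fc) >= 1.5 & rep_frac >= 0.5
  )
}

test_that("cross-source selection requires all five sources with one sign", {
  sources <- c("pancreas", "liver", "adipose", "skeletal_muscle", "blood")
  recs <- dplyr::bind_rows(
    purrr::map_dfr(sources, ~make_record("miR-up", .x, 3)),
    purrr::map_dfr(sources, ~make_record("miR-flip", .x, c(3, 3, 3, 3, -3)[match(.x, sources)])),
    purrr::map_dfr(sources[1:4], ~make_record("miR-partial", .x, 3)),
    purrr::map_dfr(sources, ~make_record("miR-weak", .x, 3, p = 0.2))
  )
  sig <- cross_source_signature(recs)
  expect_equal(sig$mirna_id, "miR-up")
  expect_equal(sig$direction, "up")
  expect_error(cross_source_signature(recs[recs$source != "blood", ]),
               "blood", class = "mirsig_config_error")
})

test_that("noiseless study recovers exactly the eight planted miRNAs", {
  study <- generate_microarray_study(noiseless_config(seed = 23))
  rec <- run_contrasts(study$expr, study$samples)
  sig <- cross_source_signature(rec[rec$species == "rat", ])
  planted <- unique(study$truth$feature_id[study$truth$signature])
  expect_setequal(sig$mirna_id, planted)
  xsp <- cross_species_signature(sig, rec[rec$species == "human", ])
  expect_setequal(xsp$mirna_id[xsp$concordant], planted)
})

test_that("signature is monotone: raising the fold cut never grows it", {
  study <- generate_microarray_study(generator_config(seed = 29))
  norm <- normalize_u6(study$expr)
  det <- detection_filter(study$expr, study$samples)
  sizes <- vapply(c(1.2, 1.5, 2.0, 3.0), function(cut) {
    rec <- run_contrasts(norm, study$samples, filter_config(min_abs_fc = cut),
                         detected = det)
    nrow(cross_source_signature(rec[rec$species == "rat", ]))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("cross-source signature lies inside the all-sources venn region", {
  study <- generate_microarray_study(generator_config(seed = 37))
  norm <- normalize_u6(study$expr)
  rec <- run_contrasts(norm, study$samples)
  rat <- rec[rec$species == "rat", ]
  sig <- cross_source_signature(rat)
  all_five <- Reduce(intersect, significant_sets(rat))
  expect_true(all(sig$mirna_id %in% all_five))
})

test_that("cross-species concordance is keyed to T2D, not IFG", {
  sources <- c("pancreas", "liver", "adipose", "skeletal_muscle", "blood")
  rat <- cross_source_signature(purrr::map_dfr(sources, ~make_record("miR-x", .x, 3)))
  human_disc <- dplyr::bind_rows(
    make_record("miR-x", "blood", -2.5, species = "human", case_label = "T2D"),
    make_record("miR-x", "blood", 2.5, species = "human", case_label = "IFG")
  )
  xsp <- cross_species_signature(rat, human_disc)
  expect_false(xsp$concordant)  # rat-up vs human-T2D-down

  human_conc <- dplyr::bind_rows(
    make_record("miR-x", "blood", 2.5, species = "human", case_label = "T2D"),
    make_record("miR-x", "blood", -2.5, species = "human", case_label = "IFG")
  )
  xsp2 <- cross_species_signature(rat, human_conc)
  expect_true(xsp2$concordant)  # IFG discordance does not exclude
  expect_equal(xsp2$human_ifg_fc, -2.5)

  # non-significant human T2D record blocks concordance
  human_ns <- make_record("miR-x", "blood", 2.5, p = 0.3,
                          species = "human", case_label = "T2D")
  expect_false(cross_species_signature(rat, human_ns)$concordant)
})

test_that("alias reconciliation merges platform namespaces into one entry", {
  sources <- c("pancreas", "liver", "adipose", "skeletal_muscle", "blood")
  rat <- cross_source_signature(purrr::map_dfr(sources, ~make_record("miR-320a", .x, 2)))
  human <- make_record("miR-320", "blood", 2.2, species = "human", case_label = "T2D")
  xsp <- cross_species_signature(rat, human, alias = c("miR-320" = "miR-320a"))
  expect_equal(nrow(xsp), 1)
  expect_equal(xsp$mirna_id, "miR-320a")
  expect_true(xsp$concordant)

  expect_warning(empty <- cross_species_signature(rat[0, ], human), "empty")
  expect_equal(nrow(empty), 0)
})
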