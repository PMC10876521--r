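test_that("retention-time culling applies the closed window", {
  x <- make_toy_table()
  x$features$rt <- c(100, 500, 1100, 180, 1080, 700)
  kept <- cull_by_rt(x, pipeline_config(rt_window = c(180, 1080)))
  expect_identical(kept$features$rt, c(500, 180, 1080, 700)) # boundaries survive
  wide <- cull_by_rt(x, pipeline_config(rt_window = c(60, 1080)))
  expect_true(100 %in% wide$features$rt)
  empty <- filter_features(x, rep(FALSE, 6))
  expect_equal(nrow(cull_by_rt(empty)$features), 0L)
})

test_that("blank subtraction keeps features five-fold over blank, with zero-blank guard", {
  x <- make_toy_table()
  out <- blank_subtract(x, pipeline_config())
  # blanky: worm mean 40500 vs blank mean 31000 -> ratio < 5, removed;
  # ref/diffy have blank mean 0 -> kept via pseudo-intensity
  expect_false("blanky" %in% out$features$feature_id)
  expect_true(all(c("keep_big", "ref", "diffy") %in% out$features$feature_id))
  # worm mean equal to blank mean is removed
  eq <- x
  eq$features$blank_1 <- eq$features$WT_1
  eq$features$blank_2 <- eq$features$WT_1
  expect_false("keep_big" %in% blank_subtract(eq, pipeline_config())$features$feature_id)
  # idempotent
  twice <- blank_subtract(out, pipeline_config())
  expect_identical(twice$features$feature_id, out$features$feature_id)
  # missing blank group
  nb <- x; nb$manifest$group[nb$manifest$group == "blank"] <- "worm2"
  expect_error(blank_subtract(nb, pipeline_config()), "blank")
})

test_that("intensity filter uses a closed threshold on the group mean", {
  boundary <- tibble::tibble(
    feature_id = c("below", "at", "above"),
    mz = c(200, 300, 400), rt = 500, ion_mode = "neg",
    a1 = c(9999, 10000, 10001), a2 = c(9999, 10000, 10001)
  )
  manifest <- tibble::tibble(sample_id = c("a1", "a2"), group = "worm")
  x <- feature_table(boundary, manifest)
  out <- intensity_filter(x, pipeline_config(), group = "worm")
  expect_identical(out$features$feature_id, c("at", "above"))
  # threshold 0 is the identity; all-zero features die for any positive threshold
  expect_equal(nrow(intensity_filter(x, pipeline_config(min_group_mean_intensity = 0))$features), 3L)
  zero <- x; zero$features$a1 <- 0; zero$features$a2 <- 0
  expect_equal(nrow(intensity_filter(zero, pipeline_config(min_group_mean_intensity = 1))$features), 0L)
  expect_error(intensity_filter(x, pipeline_config(), group = "nope"), "unknown group")
  # idempotent
  expect_identical(intensity_filter(out, pipeline_config(), "worm")$features, out$features)
})

test_that("reference normalization is invariant to per-sample scaling and flags degenerates", {
  x <- make_toy_table()
  x <- drop_group(x, "blank")
  cfg <- pipeline_config(reference_feature_id = "ref")
  norm0 <- normalize_to_reference(x, cfg)
  # scaling one sample (all features incl. reference): every per-sample
  # loading difference is removed, so normalized tables agree up to the one
  # global constant coming from the geometric-mean anchor, and all
  # downstream statistics are unchanged
  scaled <- x
  scaled$features$WT_1 <- scaled$features$WT_1 * 2
  norm1 <- normalize_to_reference(scaled, cfg)
  ratios <- unlist(norm1$features[sample_ids(x)]) / unlist(norm0$features[sample_ids(x)])
  expect_equal(unname(ratios), rep(2^(1 / 4), length(ratios)), tolerance = 1e-12)
  cfg_small_pseudo <- pipeline_config(reference_feature_id = "ref",
                                      log2fc_pseudo_intensity = 1e-9)
  w0 <- welch_volcano(normalize_to_reference(x, cfg_small_pseudo), "WT", "mut", cfg_small_pseudo)
  w1 <- welch_volcano(normalize_to_reference(scaled, cfg_small_pseudo), "WT", "mut", cfg_small_pseudo)
  expect_equal(w1$p, w0$p, tolerance = 1e-9)
  expect_equal(w1$log2fc, w0$log2fc, tolerance = 1e-6)
  # reference equal in all samples -> identity
  expect_equal(norm0$features$mut_1, x$features$mut_1, tolerance = 1e-12)
  # a feature at ref mz + 13C offset and co-eluting is excluded from testing
  iso <- x
  iso$features$mz[2] <- iso$features$mz[5] + 1.00336
  iso$features$rt[2] <- iso$features$rt[5] + 2
  normi <- normalize_to_reference(iso, cfg)
  expect_true(all(c("ref", "low_int") %in% normi$excluded))
  # zero reference intensity is an error
  bad <- x; bad$features$WT_1[5] <- 0
  expect_error(normalize_to_reference(bad, cfg), "zero intensity")
})

test_that("welch_volcano matches an independently coded Welch oracle", {
  a <- c(1000, 1100, 900)
  b <- c(4000, 4400, 3600)
  features <- tibble::tibble(
    feature_id = "f1", mz = 200, rt = 500, ion_mode = "neg",
    a1 = a[1], a2 = a[2], a3 = a[3], b1 = b[1], b2 = b[2], b3 = b[3]
  )
  manifest <- tibble::tibble(
    sample_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
    group = rep(c("A", "B"), each = 3)
  )
  x <- feature_table(features, manifest)

  # raw-scale test against the textbook formulas and stats::t.test
  cfg_raw <- pipeline_config(welch_on_log = FALSE)
  res <- welch_volcano(x, "A", "B", cfg_raw)
  orc <- welch_oracle(a, b)
  expect_equal(res$p, orc$p, tolerance = 1e-10)
  expect_equal(res$t, orc$t, tolerance = 1e-10)
  tt <- t.test(b, a, var.equal = FALSE)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  expect_equal(res$df, unname(tt$parameter), tolerance = 1e-10)

  # log-scale test equals t.test on the transformed data
  cfg_log <- pipeline_config(welch_on_log = TRUE, log2fc_pseudo_intensity = 1)
  res_log <- welch_volcano(x, "A", "B", cfg_log)
  tt_log <- t.test(log2(b + 1), log2(a + 1), var.equal = FALSE)
  expect_equal(res_log$p, tt_log$p.value, tolerance = 1e-10)
  # fold change is always the ratio of raw means
  expect_equal(res_log$log2fc, log2((mean(b) + 1) / (mean(a) + 1)), tolerance = 1e-12)
})

test_that("welch_volcano: identical groups give t = 0, p = 1; swapping groups flips signs", {
  features <- tibble::tibble(
    feature_id = "f1", mz = 200, rt = 500, ion_mode = "neg",
    a1 = 1000, a2 = 1100, b1 = 1000, b2 = 1100
  )
  manifest <- tibble::tibble(sample_id = c("a1", "a2", "b1", "b2"),
                             group = rep(c("A", "B"), each = 2))
  x <- feature_table(features, manifest)
  res <- welch_volcano(x, "A", "B")
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_equal(res$log2fc, 0)

  set.seed(5)
  features2 <- features
  features2[c("a1", "a2", "b1", "b2")] <- as.list(rlnorm(4, 10, 0.3))
  y <- feature_table(features2, manifest)
  fwd <- welch_volcano(y, "A", "B")
  rev <- welch_volcano(y, "B", "A")
  expect_equal(fwd$t, -rev$t, tolerance = 1e-12)
  expect_equal(fwd$log2fc, -rev$log2fc, tolerance = 1e-12)
  expect_equal(fwd$p, rev$p, tolerance = 1e-12)

  # a group with fewer than 2 samples is rejected
  one <- feature_table(features, tibble::tibble(
    sample_id = c("a1", "a2", "b1", "b2"), group = c("A", "A", "A", "B")
  ))
  expect_error(welch_volcano(one, "A", "B"), "at least 2 samples")
})

test_that("BH adjustment is the step-up procedure with q >= p and monotone q", {
  adj <- bh_adjust(c(0.01, 0.02, 0.03, 0.04), fdr_q = 0.15)
  expect_true(all(adj$significant))
  expect_equal(adj$q, c(0.04, 0.04, 0.04, 0.04)) # min over j>=i of m p_(j)/j
  single <- bh_adjust(0.2, fdr_q = 0.15)
  expect_equal(single$q, 0.2)
  expect_false(single$significant)
  set.seed(6)
  p <- runif(200)
  adj2 <- bh_adjust(p)
  expect_true(all(adj2$q >= adj2$p))
  ord <- order(p)
  expect_false(is.unsorted(adj2$q[ord]))
  expect_equal(adj2$q, p.adjust(p, "BH"))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("run_differential composes the stages in order with a monotone cascade", {
  sim <- generate_differential_table(n_features = 50, n_differential = 5, seed = 99)
  cfg <- pipeline_config(reference_feature_id = "ref_ascr3")
  res <- run_differential(sim$table, cfg, "WT", "mut")

  # stage counts equal composing the stage operations manually
  x <- cull_by_rt(sim$table, cfg)
  n_rt <- nrow(x$features)
  x <- blank_subtract(x, cfg)
  n_blank <- nrow(x$features)
  x <- drop_group(x, "blank")
  x <- intensity_filter(x, cfg)
  n_int <- nrow(x$features)
  x <- normalize_to_reference(x, cfg)
  manual <- welch_volcano(x, "WT", "mut", cfg)
  expect_equal(unname(res$stage_counts["rt_cull"]), n_rt)
  expect_equal(unname(res$stage_counts["blank_subtraction"]), n_blank)
  expect_equal(unname(res$stage_counts["intensity_filter"]), n_int)
  expect_equal(unname(res$stage_counts["tested"]), nrow(manual))
  expect_equal(res$table$p, manual$p, tolerance = 1e-12)

  # cascade is monotone
  counts <- res$stage_counts[c("input", "rt_cull", "blank_subtraction", "intensity_filter", "tested")]
  expect_false(is.unsorted(rev(counts)))
})

test_that("run_differential recovers planted eight-fold features and drops blank-only tables", {
  sim <- generate_differential_table(
    n_features = 200, n_differential = 10, fold_change = 8,
    n_per_group = 6, noise_sigma = 0.2, seed = 2024
  )
  cfg <- pipeline_config(reference_feature_id = "ref_ascr3")
  res <- run_differential(sim$table, cfg, "WT", "mut")
  planted <- sim$truth$feature_id[sim$truth$class == "differential"]
  hits <- res$table$feature_id[res$table$significant]
  expect_true(all(planted %in% hits))

  # a table of only blank-enriched features yields an empty result
  allblank <- generate_differential_table(
    n_features = 30, n_differential = 0, fold_change = 1,
    blank_contaminated_fraction = 1, seed = 3
  )
  tab <- filter_features(allblank$table, allblank$truth$class == "blank_contaminated")
  res2 <- run_differential(tab, pipeline_config(), "WT", "mut")
  expect_equal(nrow(res2$table), 0L)
})
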