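#' Configuration for the comparative-metabolomics pipeline
#'
#' Collects every threshold of the differential workflow. Defaults are the
#' workflow's standard operating values: retention-time window 180-1080 s
#' (60-1080 s for the wider early-eluting window), 5-fold blank-subtraction
#' rule, 10,000 AU mean-intensity floor, 15% Benjamini-Hochberg FDR, and
#' 3-ppm m/z windows.
#'
#' @param rt_window Closed retention-time window in seconds, default `c(180, 1080)`.
#' @param blank_fold_threshold Keep a feature only if its pooled biological
#'   mean is at least this many times the blank mean; default 5.
#' @param blank_pseudo_intensity Denominator used when the blank mean is 0 so
#'   that detected-only-in-samples features are kept; default 1 AU.
#' @param min_group_mean_intensity Mean-intensity floor in AU, default 10000.
#' @param fdr_q BH false-discovery-rate threshold, default 0.15.
#' @param reference_feature_id Feature id of the internal normalization
#'   reference (the ascr#3 stand-in in negative mode); `NULL` disables
#'   normalization.
#' @param reference_exclusion_deltas Numeric m/z offsets (Da) whose windows
#'   around the reference m/z are excluded from testing, covering the
#'   reference's isotopes/adducts; default the 13C isotope offset +1.00336.
#' @param exclusion_ppm,exclusion_rt_tol ppm and RT (s) tolerances for the
#'   reference-degenerate exclusion; defaults 3 ppm and 5 s.
#' @param log2fc_pseudo_intensity Pseudo-intensity added to group means
#'   before the log2 ratio so fold changes stay finite; default 1 AU.
#' @param welch_on_log Compute the Welch t-test on log2-transformed
#'   intensities (default `TRUE`); fold changes are always reported as the
#'   ratio of raw group means. Set `FALSE` to test raw intensities.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(rt_window = c(180, 1080),
                            blank_fold_threshold = 5,
                            blank_pseudo_intensity = 1,
                            min_group_mean_intensity = 10000,
                            fdr_q = 0.15,
                            reference_feature_id = NULL,
                            reference_exclusion_deltas = c(`13C` = 1.00336),
                            exclusion_ppm = 3,
                            exclusion_rt_tol = 5,
                            log2fc_pseudo_intensity = 1,
                            welch_on_log = TRUE) {
  stopifnot(
    length(rt_window) == 2L, rt_window[1] < rt_window[2],
    blank_fold_threshold > 1,
    blank_pseudo_intensity > 0,
    min_group_mean_intensity >= 0,
    fdr_q > 0, fdr_q < 1,
    log2fc_pseudo_intensity > 0
  )
  structure(
    list(
      rt_window = rt_window,
      blank_fold_threshold = blank_fold_threshold,
      blank_pseudo_intensity = blank_pseudo_intensity,
      min_group_mean_intensity = min_group_mean_intensity,
      fdr_q = fdr_q,
      reference_feature_id = reference_feature_id,
      reference_exclusion_deltas = reference_exclusion_deltas,
      exclusion_ppm = exclusion_ppm,
      exclusion_rt_tol = exclusion_rt_tol,
      log2fc_pseudo_intensity = log2fc_pseudo_intensity,
      welch_on_log = isTRUE(welch_on_log)
    ),
    class = "pipeline_config"
  )
}

group_mean_intensity <- function(x, groups) {
  samples <- unlist(lapply(groups, samples_in_group, x = x))
  rowMeans(intensity_matrix(x, samples))
}

biological_groups <- function(x, blank_group = "blank") {
  setdiff(unique(x$manifest$group), blank_group)
}

#' Cull features by retention time
#'
#' Keeps only features whose retention time lies inside the closed
#' `config$rt_window` (the first filtering stage of the workflow).
#'
#' @param x A `feature_table`.
#' @param config A [pipeline_config()].
#' @return Filtered `feature_table`.
#' @export
cull_by_rt <- function(x, config = pipeline_config()) {
  keep <- x$features$rt >= config$rt_window[1] & x$features$rt <= config$rt_window[2]
  filter_features(
    x, keep,
    sprintf("rt cull [%g, %g] s: %d -> %d", config$rt_window[1], config$rt_window[2],
            length(keep), sum(keep))
  )
}

#' Blank subtraction by the fold-enrichment rule
#'
#' Removes any feature less than `blank_fold_threshold`-fold more abundant in
#' the pooled biological samples than in solvent blanks. All biological
#' groups are pooled (blank subtraction precedes genotype regrouping). A
#' blank mean of zero is replaced by `blank_pseudo_intensity` in the
#' denominator so features detected only in biological samples survive.
#'
#' @param x A `feature_table` whose manifest contains `blank_group`.
#' @param config A [pipeline_config()].
#' @param blank_group Manifest label of the solvent blanks, default `"blank"`.
#' @return Filtered `feature_table`.
#' @export
blank_subtract <- function(x, config = pipeline_config(), blank_group = "blank") {
  if (!blank_group %in% x$manifest$group) {
    stop("manifest has no '", blank_group, "' group for blank subtraction", call. = FALSE)
  }
  bio <- biological_groups(x, blank_group)
  if (length(bio) == 0L) stop("no biological groups besides the blank", call. = FALSE)
  worm_mean <- group_mean_intensity(x, bio)
  blank_mean <- group_mean_intensity(x, blank_group)
  denom <- ifelse(blank_mean > 0, blank_mean, config$blank_pseudo_intensity)
  keep <- worm_mean >= config$blank_fold_threshold * denom
  filter_features(
    x, keep,
    sprintf("blank subtraction (>= %g-fold over blank): %d -> %d",
            config$blank_fold_threshold, length(keep), sum(keep))
  )
}

#' Mean-intensity filter
#'
#' Keeps features whose mean intensity over the named group(s) is at least
#' `min_group_mean_intensity` (closed threshold). By default the mean is
#' taken over all biological (non-blank) samples pooled.
#'
#' @param x A `feature_table`.
#' @param config A [pipeline_config()].
#' @param group Group label(s) to average over; default all non-blank groups.
#' @return Filtered `feature_table`.
#' @export
intensity_filter <- function(x, config = pipeline_config(), group = NULL) {
  if (is.null(group)) group <- biological_groups(x)
  missing_grp <- setdiff(group, x$manifest$group)
  if (length(missing_grp)) {
    stop("unknown group(s): ", paste(missing_grp, collapse = ", "), call. = FALSE)
  }
  m <- group_mean_intensity(x, group)
  keep <- m >= config$min_group_mean_intensity
  filter_features(
    x, keep,
    sprintf("mean-intensity filter (>= %g AU over %s): %d -> %d",
            config$min_group_mean_intensity, paste(group, collapse = "+"),
            length(keep), sum(keep))
  )
}

#' Normalize intensities to an internal reference feature
#'
#' Divides every intensity in sample `s` by the per-sample factor
#' `reference[s] / geometric_mean(reference)`. Anchoring the factors to the
#' reference's geometric mean preserves the overall intensity scale, so
#' AU-denominated thresholds stay meaningful, while removing per-sample
#' loading differences: scaling any single sample by a constant leaves its
#' normalized values unchanged. The reference feature itself and any feature
#' within `exclusion_ppm` of (reference m/z + each configured offset) and
#' within `exclusion_rt_tol` seconds of the reference RT are flagged as
#' excluded from downstream testing (the reference's isotopes and adducts).
#'
#' @param x A raw `feature_table` containing `config$reference_feature_id`.
#' @param config A [pipeline_config()] with a non-`NULL` reference id.
#' @return Normalized `feature_table` with `$excluded` populated.
#' @export
normalize_to_reference <- function(x, config = pipeline_config()) {
  ref_id <- config$reference_feature_id
  if (is.null(ref_id)) stop("config$reference_feature_id is not set", call. = FALSE)
  idx <- match(ref_id, x$features$feature_id)
  if (is.na(idx)) stop("reference feature '", ref_id, "' not in table", call. = FALSE)
  samples <- sample_ids(x)
  ref <- as.numeric(x$features[idx, samples])
  if (any(ref <= 0)) {
    stop("reference feature '", ref_id, "' has zero intensity in some sample", call. = FALSE)
  }
  factor_s <- ref / exp(mean(log(ref)))
  ints <- intensity_matrix(x)
  ints <- sweep(ints, 2L, factor_s, "/")
  x$features[samples] <- tibble::as_tibble(as.data.frame(ints))
  x$normalized <- TRUE

  ref_mz <- x$features$mz[idx]
  ref_rt <- x$features$rt[idx]
  excluded <- ref_id
  for (delta in config$reference_exclusion_deltas) {
    win <- ppm_window(ref_mz + delta, config$exclusion_ppm)
    hit <- x$features$mz >= win[1] & x$features$mz <= win[2] &
      abs(x$features$rt - ref_rt) <= config$exclusion_rt_tol
    excluded <- union(excluded, x$features$feature_id[hit])
  }
  x$excluded <- union(x$excluded, excluded)
  note_provenance(
    x,
    sprintf("normalized to reference '%s'; %d feature(s) flagged excluded",
            ref_id, length(x$excluded))
  )
}

# vectorized Welch t-test over the rows of two intensity matrices;
# zero pooled variance with equal means is the identical-groups case (t = 0)
welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  zero <- se2 == 0
  t[zero] <- ifelse(mb[zero] == ma[zero], 0, sign(mb - ma)[zero] * Inf)
  df[zero] <- na + nb - 2
  p <- 2 * stats::pt(-abs(t), df)
  list(mean_a = ma, mean_b = mb, t = t, df = df, p = p)
}

#' Two-group Welch volcano statistics
#'
#' Per feature: the log2 fold change `log2((mean_b + pseudo) / (mean_a +
#' pseudo))` on raw group means, and an unpaired two-sided Welch t-test with
#' Welch-Satterthwaite degrees of freedom. By default the test is computed on
#' log2-transformed intensities, under which the package's log-normal noise
#' model is exactly normal; set `welch_on_log = FALSE` in the config to test
#' raw intensities. Features flagged excluded (the normalization reference
#' and its degenerates) are omitted.
#'
#' @param x A `feature_table`.
#' @param group_a,group_b Manifest group labels; fold changes are b over a.
#' @param config A [pipeline_config()].
#' @return Tibble with columns `feature_id, mz, rt, mean_a, mean_b, log2fc,
#'   t, df, p`.
#' @export
welch_volcano <- function(x, group_a, group_b, config = pipeline_config()) {
  sa <- samples_in_group(x, group_a)
  sb <- samples_in_group(x, group_b)
  if (length(sa) < 2L || length(sb) < 2L) {
    stop("each group needs at least 2 samples for a Welch test", call. = FALSE)
  }
  keep <- !x$features$feature_id %in% x$excluded
  feats <- x$features[keep, , drop = FALSE]
  a <- as.matrix(feats[sa]); b <- as.matrix(feats[sb])
  pseudo <- config$log2fc_pseudo_intensity
  if (config$welch_on_log) {
    w <- welch_rows(log2(a + pseudo), log2(b + pseudo))
    mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  } else {
    w <- welch_rows(a, b)
    mean_a <- w$mean_a; mean_b <- w$mean_b
  }
  tibble::tibble(
    feature_id = feats$feature_id,
    mz = feats$mz,
    rt = feats$rt,
    mean_a = mean_a,
    mean_b = mean_b,
    log2fc = log2((mean_b + pseudo) / (mean_a + pseudo)),
    t = w$t,
    df = w$df,
    p = w$p
  )
}

#' Benjamini-Hochberg adjustment with a significance call
#'
#' Standard step-up BH q-values (via [stats::p.adjust()]) and the
#' significance flag `q <= fdr_q`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param fdr_q FDR threshold, default 0.15.
#' @return Tibble with columns `p, q, significant`.
#' @export
bh_adjust <- function(p, fdr_q = 0.15) {
  stopifnot(is.numeric(p))
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  tibble::tibble(p = p, q = q, significant = q <= fdr_q)
}

#' Run the full differential pipeline
#'
#' Applies the workflow stages in their standard order -- retention-time
#' cull, blank subtraction, mean-intensity filter, reference normalization
#' (if a reference is configured), Welch volcano statistics between the two
#' genotype groups, and BH adjustment -- and returns the per-feature results
#' together with per-stage survivor counts.
#'
#' @param x A raw `feature_table` (biological groups plus a blank group).
#' @param config A [pipeline_config()].
#' @param group_a,group_b Genotype group labels (fold change is b over a).
#' @param blank_group Manifest label of the blanks, default `"blank"`.
#' @return A `differential_result`: list with `table` (feature_id, mz, rt,
#'   means, log2fc, t, df, p, q, significant), `stage_counts` (named integer
#'   vector), `excluded` (reference-degenerate ids), and `config`.
#' @export
run_differential <- function(x, config = pipeline_config(), group_a, group_b,
                             blank_group = "blank") {
  counts <- c(input = nrow(x$features))
  x <- cull_by_rt(x, config)
  counts["rt_cull"] <- nrow(x$features)
  x <- blank_subtract(x, config, blank_group)
  counts["blank_subtraction"] <- nrow(x$features)
  x <- drop_group(x, blank_group) # blanks are spent once subtraction is done
  x <- intensity_filter(x, config)
  counts["intensity_filter"] <- nrow(x$features)
  if (!is.null(config$reference_feature_id)) {
    x <- normalize_to_reference(x, config)
  }
  res <- welch_volcano(x, group_a, group_b, config)
  counts["tested"] <- nrow(res)
  adj <- bh_adjust(res$p, config$fdr_q)
  res$q <- adj$q
  res$significant <- adj$significant
  counts["significant"] <- sum(res$significant)
  structure(
    list(table = res, stage_counts = counts, excluded = x$excluded, config = config),
    class = "differential_result"
  )
}

#' @export
print.differential_result <- function(x, ...) {
  cat("<differential_result>\n  stage survivors:\n")
  for (nm in names(x$stage_counts)) {
    cat(sprintf("    %-18s %d\n", nm, x$stage_counts[[nm]]))
  }
  invisible(x)
}
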