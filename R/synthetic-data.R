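#' Synthetic two-genotype feature table with planted ground truth
#'
#' Generates a post-peak-picking feature table emulating the comparative
#' metabolomics design: two biological groups (`"WT"`, `"mut"`) plus solvent
#' blanks, log-normal multiplicative intensity noise, a stratum of
#' blank-contaminated features that the 5-fold blank rule should remove, a
#' low-variance internal-reference feature (the ascr#3 stand-in, absent from
#' blanks), and a chosen number of differential features whose `mut`
#' intensities are scaled by `fold_change`. Feature m/z are uniform over the
#' instrument scan range 117-1000 Th and retention times uniform over
#' `rt_range`. The generator is a pure function of its arguments including
#' `seed`.
#'
#' @param n_features Number of ordinary (null + differential) features.
#' @param n_differential How many of them are differential; planted base
#'   means are kept above the 10,000 AU filter so planted truth survives the
#'   filter cascade.
#' @param fold_change True fold change (mut over WT) of differential
#'   features; `1` plants nothing.
#' @param n_per_group Biological replicates per genotype group.
#' @param noise_sigma Log-normal noise sigma (natural-log scale), default 0.2
#'   (about 20% multiplicative noise).
#' @param n_blank Number of blank injections, default 2.
#' @param blank_contaminated_fraction Fraction of null features whose blank
#'   mean is comparable to the biological mean (ratio below the 5-fold
#'   rule), default 0.1; all other features are absent from blanks.
#' @param rt_range Retention-time range in seconds, default `c(180, 1080)`.
#' @param base_log10_range Range of per-feature base mean intensities on the
#'   log10 scale, default `c(3.5, 6)`.
#' @param seed Mandatory integer seed.
#' @return List with elements `table` (a [feature_table()]) and `truth`
#'   (tibble: `feature_id, class, true_fold, n_d, base_mean`).
#' @export
generate_differential_table <- function(n_features = 200,
                                        n_differential = 10,
                                        fold_change = 8,
                                        n_per_group = 6,
                                        noise_sigma = 0.2,
                                        n_blank = 2,
                                        blank_contaminated_fraction = 0.1,
                                        rt_range = c(180, 1080),
                                        base_log10_range = c(3.5, 6),
                                        seed) {
  stopifnot(
    n_features >= 1, n_differential >= 0, n_differential <= n_features,
    fold_change > 0, n_per_group >= 2, noise_sigma >= 0, n_blank >= 1,
    blank_contaminated_fraction >= 0, blank_contaminated_fraction <= 1
  )
  if (missing(seed)) stop("seed is a mandatory argument", call. = FALSE)
  set.seed(seed)

  n_diff <- if (fold_change == 1) 0L else as.integer(n_differential)
  ids <- sprintf("F%04d", seq_len(n_features))
  cls <- rep("null", n_features)
  if (n_diff > 0) cls[seq_len(n_diff)] <- "differential"
  # contaminated stratum drawn from the null features only
  null_idx <- which(cls == "null")
  n_contam <- round(blank_contaminated_fraction * length(null_idx))
  if (n_contam > 0) {
    contam <- sample(null_idx, n_contam)
    cls[contam] <- "blank_contaminated"
  }

  base_mean <- 10^stats::runif(n_features, base_log10_range[1], base_log10_range[2])
  # planted features sit above the intensity filter so truth is recoverable
  base_mean[cls == "differential"] <- 10^stats::runif(n_diff, 4.5, 5.5)

  wt_ids <- paste0("WT_", seq_len(n_per_group))
  mut_ids <- paste0("mut_", seq_len(n_per_group))
  blank_ids <- paste0("blank_", seq_len(n_blank))

  rln <- function(mean_vec, n_col) {
    matrix(
      stats::rlnorm(length(mean_vec) * n_col,
                    meanlog = rep(log(mean_vec), n_col),
                    sdlog = noise_sigma),
      ncol = n_col
    )
  }
  wt <- rln(base_mean, n_per_group)
  mut_mean <- base_mean * ifelse(cls == "differential", fold_change, 1)
  mut <- rln(mut_mean, n_per_group)
  blank_mean <- ifelse(cls == "blank_contaminated",
                       base_mean * stats::runif(n_features, 0.3, 1), 0)
  blank <- matrix(0, nrow = n_features, ncol = n_blank)
  contam_rows <- which(blank_mean > 0)
  if (length(contam_rows) > 0) {
    blank[contam_rows, ] <- rln(blank_mean[contam_rows], n_blank)
  }

  features <- tibble::tibble(
    feature_id = ids,
    mz = stats::runif(n_features, 117, 1000),
    rt = stats::runif(n_features, rt_range[1], rt_range[2]),
    ion_mode = "neg"
  )
  features[wt_ids] <- tibble::as_tibble(as.data.frame(wt))
  features[mut_ids] <- tibble::as_tibble(as.data.frame(mut))
  features[blank_ids] <- tibble::as_tibble(as.data.frame(blank))

  # internal reference: intense, low-variance, absent from blanks
  ref <- tibble::tibble(
    feature_id = "ref_ascr3",
    mz = stats::runif(1, 117, 1000),
    rt = stats::runif(1, rt_range[1], rt_range[2]),
    ion_mode = "neg"
  )
  ref_base <- 5e5
  ref[wt_ids] <- as.list(stats::rlnorm(n_per_group, log(ref_base), 0.02))
  ref[mut_ids] <- as.list(stats::rlnorm(n_per_group, log(ref_base), 0.02))
  ref[blank_ids] <- as.list(rep(0, n_blank))
  features <- dplyr::bind_rows(features, ref)

  manifest <- tibble::tibble(
    sample_id = c(wt_ids, mut_ids, blank_ids),
    group = c(rep("WT", n_per_group), rep("mut", n_per_group), rep("blank", n_blank)),
    experiment = 1L
  )
  truth <- tibble::tibble(
    feature_id = c(ids, "ref_ascr3"),
    class = c(cls, "reference"),
    true_fold = c(ifelse(cls == "differential", fold_change, 1), 1),
    n_d = 0L,
    base_mean = c(base_mean, ref_base)
  )
  tab <- feature_table(features, manifest,
                       provenance = sprintf("synthetic differential table (seed %d)", seed))
  list(table = tab, truth = truth)
}

#' Synthetic tracer feature table with planted isotopologue partners
#'
#' Starting from a base table with exchangeable `"labeled"` and `"control"`
#' conditions (generated here unless supplied), plants a deuterium-labeled
#' partner for a fraction of features: partner m/z is the parent m/z plus
#' `deuterium_shift(n)` with Gaussian ppm jitter, partner RT is the parent
#' RT plus `rt_shift`, and the partner is intense only in the labeled
#' condition (zero in control). Jitter larger than the downstream matching
#' tolerance is allowed -- it degrades recall, which is part of what the
#' generator is for.
#'
#' @param base_table Optional `feature_table` with `labeled`/`control`
#'   groups; generated internally when `NULL`.
#' @param labeled_fraction Fraction of base features given a partner.
#' @param n_d_values Deuterium counts to draw partners from (e.g. `3` for a
#'   labeled methyl group, `11` for the distal-label pattern).
#' @param ppm_jitter Standard deviation of the partner's mass error in ppm.
#' @param rt_shift Partner RT offset in seconds, default -2 (earlier
#'   elution of the deuterated species).
#' @param n_features,n_per_group,noise_sigma,rt_range Base-table parameters
#'   when `base_table` is `NULL`.
#' @param partner_log10_range Partner intensity range (log10 AU), default
#'   `c(4.5, 5.5)` -- above the detection floor.
#' @param seed Mandatory integer seed.
#' @return List with `table` (a [feature_table()]) and `truth` (tibble:
#'   `feature_id, class, partner_of, n_d`).
#' @export
generate_tracer_table <- function(base_table = NULL,
                                  labeled_fraction = 0.2,
                                  n_d_values = 3L,
                                  ppm_jitter = 0,
                                  rt_shift = -2,
                                  n_features = 100,
                                  n_per_group = 3,
                                  noise_sigma = 0.2,
                                  rt_range = c(180, 1080),
                                  partner_log10_range = c(4.5, 5.5),
                                  seed) {
  stopifnot(labeled_fraction >= 0, labeled_fraction <= 1, ppm_jitter >= 0,
            all(n_d_values >= 1))
  if (missing(seed)) stop("seed is a mandatory argument", call. = FALSE)
  set.seed(seed)

  if (is.null(base_table)) {
    lab_ids <- paste0("lab_", seq_len(n_per_group))
    ctl_ids <- paste0("ctl_", seq_len(n_per_group))
    base_mean <- 10^stats::runif(n_features, 3.5, 6)
    ints <- matrix(
      stats::rlnorm(n_features * 2 * n_per_group,
                    meanlog = rep(log(base_mean), 2 * n_per_group),
                    sdlog = noise_sigma),
      ncol = 2 * n_per_group
    )
    features <- tibble::tibble(
      feature_id = sprintf("F%04d", seq_len(n_features)),
      mz = stats::runif(n_features, 117, 1000),
      rt = stats::runif(n_features, rt_range[1], rt_range[2]),
      ion_mode = "neg"
    )
    features[c(lab_ids, ctl_ids)] <- tibble::as_tibble(as.data.frame(ints))
    manifest <- tibble::tibble(
      sample_id = c(lab_ids, ctl_ids),
      group = c(rep("labeled", n_per_group), rep("control", n_per_group)),
      experiment = 1L
    )
    base_table <- feature_table(features, manifest,
                                provenance = sprintf("synthetic tracer base (seed %d)", seed))
  }
  validate_feature_table(base_table)
  feats <- base_table$features
  samples <- sample_ids(base_table)
  lab_samples <- samples_in_group(base_table, "labeled")

  n_base <- nrow(feats)
  n_part <- round(labeled_fraction * n_base)
  truth <- tibble::tibble(
    feature_id = feats$feature_id,
    class = "base",
    partner_of = NA_character_,
    n_d = 0L
  )
  if (n_part > 0) {
    parents <- sample(n_base, n_part)
    n_d <- sample(rep(as.integer(n_d_values), length.out = n_part))
    partner_mz <- (feats$mz[parents] + deuterium_shift(n_d)) *
      (1 + stats::rnorm(n_part, 0, ppm_jitter) * 1e-6)
    partner <- tibble::tibble(
      feature_id = sprintf("L%04d", seq_len(n_part)),
      mz = partner_mz,
      rt = feats$rt[parents] + rt_shift,
      ion_mode = feats$ion_mode[1]
    )
    part_int <- matrix(0, nrow = n_part, ncol = length(samples),
                       dimnames = list(NULL, samples))
    part_mean <- 10^stats::runif(n_part, partner_log10_range[1], partner_log10_range[2])
    part_int[, lab_samples] <- matrix(
      stats::rlnorm(n_part * length(lab_samples),
                    meanlog = rep(log(part_mean), length(lab_samples)),
                    sdlog = noise_sigma),
      ncol = length(lab_samples)
    )
    partner[samples] <- tibble::as_tibble(as.data.frame(part_int))
    feats <- dplyr::bind_rows(feats, partner)
    truth <- dplyr::bind_rows(
      truth,
      tibble::tibble(
        feature_id = partner$feature_id,
        class = "labeled_partner",
        partner_of = base_table$features$feature_id[parents],
        n_d = n_d
      )
    )
  }
  tab <- feature_table(
    feats, base_table$manifest,
    provenance = c(base_table$provenance,
                   sprintf("planted %d labeled partners (seed %d)", n_part, seed))
  )
  list(table = tab, truth = truth)
}
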