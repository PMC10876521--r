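#' Design of a stable-isotope tracer comparison
#'
#' Parameters for detecting deuterium-labeled isotopologue partners between a
#' labeled-supplement condition and an unlabeled control, as in
#' D3-methyl-methionine or D13-vaccenic-acid feeding experiments.
#'
#' @param labeled_group Manifest group of the labeled condition.
#' @param control_group Manifest group of the unlabeled control.
#' @param n_range Candidate deuterium counts, default `1:13` (up to the full
#'   D13 fatty-acid label).
#' @param ppm_tol Mass tolerance in ppm, default 3 (the quantification window).
#' @param rt_window Signed co-elution window in seconds for
#'   `rt(labeled) - rt(unlabeled)`, default `c(-10, 2)`: deuterated species
#'   elute slightly earlier on reversed phase.
#' @param detection_floor Intensity (AU) above which a feature counts as
#'   detected, default 10000.
#' @param enrichment_fold Labeled/control mean ratio that counts as
#'   enrichment when the labeled species is detected in both conditions;
#'   default 5.
#' @return A `tracer_design` list.
#' @export
tracer_design <- function(labeled_group, control_group,
                          n_range = 1:13, ppm_tol = 3,
                          rt_window = c(-10, 2),
                          detection_floor = 10000,
                          enrichment_fold = 5) {
  stopifnot(
    labeled_group != control_group,
    length(n_range) >= 1L, all(n_range >= 1L),
    ppm_tol >= 0,
    length(rt_window) == 2L, rt_window[1] <= rt_window[2],
    detection_floor >= 0, enrichment_fold > 1
  )
  structure(
    list(
      labeled_group = labeled_group, control_group = control_group,
      n_range = as.integer(n_range), ppm_tol = ppm_tol,
      rt_window = rt_window, detection_floor = detection_floor,
      enrichment_fold = enrichment_fold
    ),
    class = "tracer_design"
  )
}

#' Find deuterium-labeled isotopologue partners
#'
#' For every feature `u` and every candidate deuterium count `n` in the
#' design, searches for partner features whose m/z lies within `ppm_tol` of
#' `u$mz + deuterium_shift(n)` and whose retention time differs from `u`'s
#' by an amount inside the signed co-elution window. The best candidate per
#' `(u, n)` is chosen by absolute ppm error, ties broken by absolute RT
#' difference; each candidate labeled feature is then assigned to at most
#' one pair, greedily in order of increasing mass error, so one observed
#' isotopologue never supports several deuterium hypotheses. The result is
#' independent of table row order.
#'
#' @param x A `feature_table` containing both conditions.
#' @param design A [tracer_design()].
#' @return Tibble of pairs: `unlabeled_id, labeled_id, n_d, observed_dmz,
#'   expected_dmz, mass_error_ppm, d_rt`; zero rows is a valid result.
#' @export
find_label_pairs <- function(x, design) {
  validate_feature_table(x)
  feats <- x$features
  if (nrow(feats) < 2L) {
    return(empty_pairs())
  }
  ord <- order(feats$mz)
  smz <- feats$mz[ord]
  srt <- feats$rt[ord]
  sid <- feats$feature_id[ord]

  cand <- list()
  for (n in design$n_range) {
    expected <- smz + deuterium_shift(n)
    lo <- expected * (1 - design$ppm_tol * 1e-6)
    hi <- expected * (1 + design$ppm_tol * 1e-6)
    first <- findInterval(lo, smz, left.open = TRUE) + 1L
    last <- findInterval(hi, smz)
    has <- last >= first
    if (!any(has)) next
    u_idx <- rep.int(which(has), last[has] - first[has] + 1L)
    v_idx <- unlist(lapply(which(has), function(i) seq.int(first[i], last[i])))
    keep <- u_idx != v_idx
    u_idx <- u_idx[keep]; v_idx <- v_idx[keep]
    if (length(u_idx) == 0L) next
    d_rt <- srt[v_idx] - srt[u_idx]
    in_rt <- d_rt >= design$rt_window[1] & d_rt <= design$rt_window[2]
    u_idx <- u_idx[in_rt]; v_idx <- v_idx[in_rt]; d_rt <- d_rt[in_rt]
    if (length(u_idx) == 0L) next
    cand[[length(cand) + 1L]] <- tibble::tibble(
      unlabeled_id = sid[u_idx],
      labeled_id = sid[v_idx],
      n_d = n,
      observed_dmz = smz[v_idx] - smz[u_idx],
      expected_dmz = deuterium_shift(n),
      mass_error_ppm = ppm_error(smz[v_idx], smz[u_idx] + deuterium_shift(n)),
      d_rt = d_rt
    )
  }
  if (length(cand) == 0L) {
    return(empty_pairs())
  }
  cand <- dplyr::bind_rows(cand)
  # best candidate per (u, n): |ppm| then |dRT|
  cand <- cand[order(cand$unlabeled_id, cand$n_d, abs(cand$mass_error_ppm), abs(cand$d_rt)), ]
  cand <- cand[!duplicated(cand[c("unlabeled_id", "n_d")]), ]
  # greedy one-to-one assignment of labeled features by mass error
  cand <- cand[order(abs(cand$mass_error_ppm), abs(cand$d_rt)), ]
  cand <- cand[!duplicated(cand$labeled_id), ]
  cand[order(cand$unlabeled_id, cand$n_d), ]
}

empty_pairs <- function() {
  tibble::tibble(
    unlabeled_id = character(), labeled_id = character(), n_d = integer(),
    observed_dmz = numeric(), expected_dmz = numeric(),
    mass_error_ppm = numeric(), d_rt = numeric()
  )
}

#' Score label enrichment for matched pairs
#'
#' A pair is `"enriched"` when its labeled feature is detected (mean
#' intensity at or above the detection floor) in the labeled condition and
#' either undetected in the control or at least `enrichment_fold`-fold more
#' intense than in the control. It is `"not-enriched"` when the labeled
#' feature is undetected in the labeled condition or shows no elevation
#' (ratio at most 1), and `"ambiguous"` when detected in both conditions at
#' an intermediate ratio.
#'
#' @param pairs Pairs from [find_label_pairs()].
#' @param x The `feature_table` the pairs came from.
#' @param design The [tracer_design()].
#' @return `pairs` with added columns `labeled_mean, control_mean, verdict`.
#' @export
score_enrichment <- function(pairs, x, design) {
  if (nrow(pairs) == 0L) {
    pairs$labeled_mean <- numeric()
    pairs$control_mean <- numeric()
    pairs$verdict <- character()
    return(pairs)
  }
  lab_mean <- group_mean_intensity(x, design$labeled_group)
  ctl_mean <- group_mean_intensity(x, design$control_group)
  idx <- match(pairs$labeled_id, x$features$feature_id)
  lm <- unname(lab_mean[idx])
  cm <- unname(ctl_mean[idx])
  ratio <- lm / pmax(cm, .Machine$double.eps)
  verdict <- ifelse(
    lm < design$detection_floor, "not-enriched",
    ifelse(
      cm < design$detection_floor | ratio >= design$enrichment_fold, "enriched",
      ifelse(ratio <= 1, "not-enriched", "ambiguous")
    )
  )
  pairs$labeled_mean <- lm
  pairs$control_mean <- cm
  pairs$verdict <- verdict
  pairs
}

#' Annotate pairs with tracer-fate model predictions
#'
#' Tags each pair with any predicted metabolite (from
#' [predict_metabolite()] / [predict_c11_family()]) whose deuterium count
#' equals the pair's and whose predicted ion m/z lies within `ppm_tol` of
#' the labeled feature's m/z.
#'
#' @param pairs Pairs from [find_label_pairs()] (optionally scored).
#' @param x The `feature_table` the pairs came from (for labeled-feature m/z).
#' @param predictions Tibble with columns `name, n_d, mz`.
#' @param ppm_tol Match tolerance in ppm, default 3.
#' @return `pairs` with an `annotation` column (comma-separated prediction
#'   names, `NA` when nothing matches).
#' @export
annotate_predictions <- function(pairs, x, predictions, ppm_tol = 3) {
  labeled_mz <- x$features$mz[match(pairs$labeled_id, x$features$feature_id)]
  pairs$annotation <- vapply(seq_len(nrow(pairs)), function(k) {
    if (is.null(predictions) || nrow(predictions) == 0L) return(NA_character_)
    hit <- predictions$n_d == pairs$n_d[k] &
      abs(ppm_error(labeled_mz[k], predictions$mz)) <= ppm_tol
    if (!any(hit)) NA_character_ else paste(predictions$name[hit], collapse = ",")
  }, character(1))
  pairs
}
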