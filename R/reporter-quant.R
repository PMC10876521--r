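#' Normalize GFP reporter intensities within experiments
#'
#' Implements the imaging quantification scheme: within each experiment the
#' background is the mean of the minimum intensities of all outlined
#' animals; it is subtracted from each animal's mean intensity (floored at
#' zero, with a warning, for animals dimmer than background); corrected
#' values are then divided by the mean corrected intensity of the untreated
#' control animals of the same experiment, so control animals average to
#' exactly 1 per experiment. Because the background is a per-experiment
#' constant, adding any constant offset to all measured intensities leaves
#' the normalized values unchanged.
#'
#' @param measurements Tibble/data frame with columns `animal_id`,
#'   `mean_intensity`, `min_intensity`, `treatment`, `experiment`.
#' @param control_label Treatment label of the untreated controls.
#' @return `measurements` with added columns `background, corrected,
#'   normalized`.
#' @export
normalize_gfp <- function(measurements, control_label) {
  m <- tibble::as_tibble(measurements)
  needed <- c("animal_id", "mean_intensity", "min_intensity", "treatment", "experiment")
  missing_cols <- setdiff(needed, names(m))
  if (length(missing_cols)) {
    stop("measurements missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(m$min_intensity > m$mean_intensity)) {
    stop("min_intensity must not exceed mean_intensity", call. = FALSE)
  }
  out <- m |>
    dplyr::group_by(.data$experiment) |>
    dplyr::mutate(
      background = mean(.data$min_intensity),
      corrected = .data$mean_intensity - .data$background
    ) |>
    dplyr::ungroup()
  if (any(out$corrected < 0)) {
    warning("corrected intensity below background for ", sum(out$corrected < 0),
            " animal(s); floored at 0", call. = FALSE)
    out$corrected <- pmax(out$corrected, 0)
  }
  out <- out |>
    dplyr::group_by(.data$experiment) |>
    dplyr::group_modify(function(df, key) {
      ctrl <- df$corrected[df$treatment == control_label]
      if (length(ctrl) == 0L) {
        stop("experiment ", key$experiment, " has no '", control_label,
             "' control animals", call. = FALSE)
      }
      if (mean(ctrl) == 0) {
        stop("experiment ", key$experiment, ": control corrected mean is 0", call. = FALSE)
      }
      df$normalized <- df$corrected / mean(ctrl)
      df
    }) |>
    dplyr::ungroup()
  out[c(needed, "background", "corrected", "normalized")]
}

#' Relative expression by the delta-delta-Ct method
#'
#' Averages technical replicates per sample and gene, forms
#' `dCt = Ct(target) - Ct(reference)` per sample, centers it on the mean
#' `dCt` of the control samples (`ddCt`), and reports `fold = 2^(-ddCt)`.
#' With controls normalized against their own mean, the geometric mean of
#' control fold changes is exactly 1. Multiple target genes are handled
#' independently against the shared reference gene.
#'
#' @param records Tibble/data frame with columns `sample_id`, `gene`,
#'   `treatment`, `ct` (one row per technical replicate).
#' @param reference_gene Reference gene name, default `"act-1"`.
#' @param control_label Treatment label of the mock/control samples.
#' @return Tibble with one row per sample and target gene: `sample_id,
#'   gene, treatment, dct, ddct, fold`.
#' @export
ddct_expression <- function(records, reference_gene = "act-1", control_label) {
  r <- tibble::as_tibble(records)
  needed <- c("sample_id", "gene", "treatment", "ct")
  missing_cols <- setdiff(needed, names(r))
  if (length(missing_cols)) {
    stop("records missing column(s): ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(r$ct))) stop("Ct values must be finite", call. = FALSE)
  # technical replicates are averaged before any dCt arithmetic
  avg <- r |>
    dplyr::group_by(.data$sample_id, .data$gene, .data$treatment) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  ref <- avg[avg$gene == reference_gene, c("sample_id", "ct")]
  names(ref)[2] <- "ct_ref"
  targets <- avg[avg$gene != reference_gene, ]
  if (nrow(targets) == 0L) stop("no target-gene records", call. = FALSE)
  merged <- dplyr::left_join(targets, ref, by = "sample_id")
  if (anyNA(merged$ct_ref)) {
    bad <- unique(merged$sample_id[is.na(merged$ct_ref)])
    stop("missing reference gene '", reference_gene, "' for sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  merged$dct <- merged$ct - merged$ct_ref
  merged |>
    dplyr::group_by(.data$gene) |>
    dplyr::group_modify(function(df, key) {
      ctrl <- df$dct[df$treatment == control_label]
      if (length(ctrl) == 0L) {
        stop("gene ", key$gene, ": no '", control_label, "' control samples", call. = FALSE)
      }
      df$ddct <- df$dct - mean(ctrl)
      df$fold <- 2^(-df$ddct)
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "gene", "treatment", "dct", "ddct", "fold")
}
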