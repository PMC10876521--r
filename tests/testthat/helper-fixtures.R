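# hand-built fixtures shared across test files; everything is constructed in
# code so expected values can be computed by eye

# small two-genotype table with blanks: intensities chosen so each filter
# stage has a known survivor set
make_toy_table <- function() {
  features <- tibble::tibble(
    feature_id = c("keep_big", "low_int", "blanky", "early_rt", "ref", "diffy"),
    mz = c(200.1, 250.2, 300.3, 350.4, 247.1, 400.5),
    rt = c(400, 500, 600, 100, 450, 700),
    ion_mode = "neg",
    WT_1 = c(50000, 5000, 40000, 30000, 100000, 20000),
    WT_2 = c(52000, 5200, 42000, 31000, 100000, 22000),
    mut_1 = c(51000, 5100, 41000, 30500, 100000, 80000),
    mut_2 = c(49000, 4900, 39000, 29500, 100000, 88000),
    blank_1 = c(1000, 100, 30000, 500, 0, 0),
    blank_2 = c(1200, 120, 32000, 600, 0, 0)
  )
  manifest <- tibble::tibble(
    sample_id = c("WT_1", "WT_2", "mut_1", "mut_2", "blank_1", "blank_2"),
    group = c("WT", "WT", "mut", "mut", "blank", "blank"),
    experiment = 1L
  )
  feature_table(features, manifest)
}

# independently coded Welch t-test (textbook formulas), the oracle for the
# vectorized implementation
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  t <- (mean(b) - mean(a)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# brute-force linear scan, the oracle for query_mz
query_oracle <- function(x, mz, tol_ppm, rt_range = NULL) {
  f <- x$features
  ok <- abs(f$mz - mz) <= mz * tol_ppm * 1e-6
  if (!is.null(rt_range)) ok <- ok & f$rt >= rt_range[1] & f$rt <= rt_range[2]
  sort(f$feature_id[ok])
}
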