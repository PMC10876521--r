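test_that("vaccenic acid constructor gives C18H34O2 with the d13 label pattern", {
  va <- make_vaccenic("none")
  expect_identical(format(chain_formula(va)), "C18H34O2")
  expect_equal(chain_d_total(va), 0L)

  d13 <- make_vaccenic("d13_cis")
  expect_equal(chain_d_total(d13), 13L)
  expect_equal(d13$d[13:18], c(2L, 2L, 2L, 2L, 2L, 3L))
  expect_identical(d13$double_bonds$geometry, "cis")

  d13t <- make_vaccenic("d13_trans")
  expect_identical(d13t$double_bonds$geometry, "trans")
  expect_identical(d13t$d, d13$d) # only geometry differs
  expect_identical(format(chain_formula(d13t)), format(chain_formula(d13)))

  # custom label pattern is honored
  custom <- make_vaccenic("none", label_d = c(rep(0L, 17), 3L))
  expect_equal(chain_d_total(custom), 3L)
})

test_that("methyl transfer adds CH2, migrates the bond to trans, abstracts one D", {
  d13 <- make_vaccenic("d13_cis")
  m <- apply_methyl_transfer(d13)
  expect_equal(chain_d_total(m), 12L)
  expect_equal(m$d[13], 1L) # the abstraction happened at C13
  expect_identical(m$double_bonds$geometry, "trans")
  expect_equal(m$double_bonds$i, 12L)
  expect_equal(m$branches$at, 11L)
  expect_identical(format(chain_formula(m)), "C19H24D12O2")

  un <- apply_methyl_transfer(make_vaccenic("none"))
  expect_identical(format(chain_formula(un)), "C19H36O2")
  expect_equal(chain_d_total(un), 0L)

  # cis specificity: the trans-labeled substrate is rejected
  expect_error(apply_methyl_transfer(make_vaccenic("d13_trans")), "not a substrate")
  sat <- labeled_chain(10)
  expect_error(apply_methyl_transfer(sat), "not a substrate")
})

test_that("cyclopropanation inserts an unlabeled bridge without abstraction", {
  un <- apply_cyclopropanation(make_vaccenic("none"))
  expect_identical(format(chain_formula(un)), "C19H36O2")
  expect_equal(nrow(un$bridges), 1L)
  expect_equal(un$bridges$i, 11L)

  d13 <- apply_cyclopropanation(make_vaccenic("d13_cis"))
  expect_equal(chain_d_total(d13), 13L) # nothing abstracted

  # isomer property: same formula as the methyl-transfer product
  expect_identical(
    format(chain_formula(un)),
    format(chain_formula(apply_methyl_transfer(make_vaccenic("none"))))
  )
  expect_error(apply_cyclopropanation(make_vaccenic("d13_trans")), "not a substrate")
})

test_that("four beta-oxidation rounds produce the C11 acids with diagnostic D counts", {
  # methylation route: C11 beta-methyl acid with 12 D, single D at product C5
  bemeth1_d <- apply_beta_oxidation(apply_methyl_transfer(make_vaccenic("d13_cis")), 4)
  expect_equal(bemeth1_d$n + nrow(bemeth1_d$branches), 11L)
  expect_equal(chain_d_total(bemeth1_d), 12L)
  expect_equal(bemeth1_d$d[5], 1L)
  expect_equal(bemeth1_d$branches$at, 3L)
  expect_equal(bemeth1_d$double_bonds$i, 4L)

  # cyclopropanation route: becyp#1 at the printed C11H20O2 / 183.1391
  becyp1 <- apply_beta_oxidation(apply_cyclopropanation(make_vaccenic("none")), 4)
  expect_identical(format(chain_formula(becyp1)), "C11H20O2")
  expect_equal(round(mz_for_adduct(chain_formula(becyp1), "[M-H]-"), 4), 183.1391)

  # a fifth round is beta-blocked on both skeletons
  expect_error(apply_beta_oxidation_round(bemeth1_d), "beta-blocked")
  expect_error(apply_beta_oxidation_round(becyp1), "beta-blocked")
  expect_error(apply_beta_oxidation_round(labeled_chain(3)), "shorter than 4")
})

test_that("alpha oxidation yields the 2-hydroxy intermediate then a C10 alpha-methyl acid", {
  bemeth1 <- apply_beta_oxidation(apply_methyl_transfer(make_vaccenic("none")), 4)
  a <- apply_alpha_oxidation(bemeth1)
  expect_identical(format(chain_formula(a$intermediate)), "C11H20O3")
  expect_equal(round(mz_for_adduct(chain_formula(a$intermediate), "[M-H]-"), 4), 199.1340)
  expect_equal(a$intermediate$hydroxyls, 2L)

  # product: one carbon shorter, branch now alpha
  expect_equal(a$product$n + nrow(a$product$branches), 10L)
  expect_equal(a$product$branches$at, 2L)
  expect_equal(unclass(chain_formula(a$product))[["O"]], 2L)

  # C2 with no hydrogens cannot be 2-hydroxylated
  blocked <- labeled_chain(6, branches = data.frame(at = 2L, d = 0L),
                           hydroxyls = 2L)
  expect_error(apply_alpha_oxidation(blocked), "C2")
})

test_that("hydroxylation displaces a deuterium when the carbon carries one", {
  bemeth1_d <- apply_beta_oxidation(apply_methyl_transfer(make_vaccenic("d13_cis")), 4)
  # omega-1 carbon (C9) carries two D; one is displaced by the hydroxyl
  h <- apply_hydroxylation(bemeth1_d, "omega-1")
  expect_equal(chain_d_total(h), 11L)
  expect_equal(h$hydroxyls, 9L)
  # hydroxylation at an unlabeled carbon leaves the D count unchanged
  h2 <- apply_hydroxylation(bemeth1_d, 2)
  expect_equal(chain_d_total(h2), 12L)
  # a mono-hydrogen carbon can be hydroxylated once, not twice
  once <- apply_hydroxylation(bemeth1_d, 5) # sp2 carbon, one slot
  expect_error(apply_hydroxylation(once, 5), "fully substituted")
})

test_that("predicted m/z values hit the printed ions; the D11 dihydroxy acid is within 2 ppm", {
  fam <- predict_c11_family("none")
  expect_equal(round(fam$mz[fam$name == "bemeth#1"], 4), 183.1391)
  expect_equal(round(fam$mz[fam$name == "becyp#1"], 4), 183.1391)
  expect_equal(round(fam$mz[fam$name == "bemeth#3"], 4), 215.1289)
  expect_equal(round(fam$mz[fam$name == "bemeth#2"], 4), 199.1340)
  # co-mass isomers, distinct transformation traces
  expect_false(fam$trace[fam$name == "bemeth#1"] == fam$trace[fam$name == "becyp#1"])

  famd <- predict_c11_family("d13_cis")
  b3 <- famd[famd$name == "bemeth#3", ]
  expect_identical(b3$formula, "C11H9D11O4")
  expect_equal(b3$n_d, 11L)
  expect_lt(abs(ppm_error(226.1982, b3$mz)), 2)
  # the distal position does not change the predicted D count
  famw <- predict_c11_family("d13_cis", distal = "omega")
  expect_equal(famw$n_d[famw$name == "bemeth#3"], 11L)

  # trans-labeled precursor feeds no route
  expect_equal(nrow(predict_c11_family("d13_trans")), 0L)
})

test_that("carbon and deuterium bookkeeping is conserved and deterministic", {
  routes <- list(
    function() apply_beta_oxidation(apply_methyl_transfer(make_vaccenic("d13_cis")), 4),
    function() apply_beta_oxidation(apply_cyclopropanation(make_vaccenic("d13_cis")), 4),
    function() apply_alpha_oxidation(
      apply_beta_oxidation(apply_methyl_transfer(make_vaccenic("d13_cis")), 4)
    )$product
  )
  beta_rounds <- c(4, 4, 4)
  alpha_rounds <- c(0, 0, 1)
  for (k in seq_along(routes)) {
    out <- routes[[k]]()
    # carbons(product) + 2 beta + 1 alpha = carbons(precursor) + 1 (the added CH2/CH3)
    expect_equal(
      out$n + nrow(out$branches) + nrow(out$bridges) +
        2 * beta_rounds[k] + alpha_rounds[k],
      18 + 1
    )
    # no operation ever increases D
    expect_lte(chain_d_total(out), 13L)
    # identical inputs give identical traces
    expect_identical(out$trace, routes[[k]]()$trace)
  }
})

test_that("chain construction enforces valence and slot limits", {
  expect_error(labeled_chain(10, d = c(0L, 3L, rep(0L, 8))), "exceeds hydrogen slots")
  expect_error(labeled_chain(10, d = c(rep(0L, 9), 4L)), "exceeds hydrogen slots")
  expect_error(
    labeled_chain(10, double_bonds = data.frame(i = 4L, geometry = "cis"),
                  bridges = data.frame(i = 4L, d = 0L)),
    "must not overlap"
  )
  # terminal methyl holds 3 D, sp2 carbon only 1
  ok <- labeled_chain(10, d = c(rep(0L, 9), 3L),
                      double_bonds = data.frame(i = 4L, geometry = "cis"))
  expect_equal(chain_d_total(ok), 3L)
  expect_error(
    labeled_chain(10, d = c(0, 0, 0, 2, rep(0, 6)),
                  double_bonds = data.frame(i = 4L, geometry = "cis")),
    "exceeds hydrogen slots"
  )
})
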