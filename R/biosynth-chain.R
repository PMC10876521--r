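#' Fatty-acid carbon skeletons with per-carbon deuterium bookkeeping
#'
#' A `labeled_chain` models a free fatty acid as an ordered carbon skeleton,
#' numbered IUPAC-style from the carboxyl carbon (C1), with explicit
#' per-carbon deuterium counts. Hydrogen counts are never stored: each
#' carbon's hydrogen slots are derived from its bonding (chain bonds, double
#' bonds, cyclopropane bridges, methyl branches, hydroxyls, the carboxyl
#' group), and every slot not occupied by a D carries an H. This makes the
#' valence invariant structural: an operation cannot gain or lose hydrogens
#' silently, and deuterium moves only when a rule explicitly removes it.
#'
#' @param n_carbons Main-chain length (C1 = carboxyl carbon).
#' @param d Integer vector of deuterium counts, one per main-chain carbon.
#' @param double_bonds Data frame with columns `i` (bond between carbons `i`
#'   and `i + 1`) and `geometry` (`"cis"` or `"trans"`).
#' @param branches Data frame with columns `at` (carbon bearing a methyl
#'   branch) and `d` (deuterium on the branch methyl, 0-3).
#' @param bridges Data frame with columns `i` (cyclopropane CH2 bridging
#'   carbons `i` and `i + 1`) and `d` (deuterium on the bridge CH2, 0-2).
#' @param hydroxyls Integer vector of hydroxylated carbon positions.
#' @param annotations Character notes (e.g. stereochemistry tags); carried,
#'   never used in mass arithmetic.
#' @param trace Character log of the transformations applied so far.
#' @return A validated `labeled_chain`.
#' @export
labeled_chain <- function(n_carbons,
                          d = integer(n_carbons),
                          double_bonds = data.frame(i = integer(), geometry = character()),
                          branches = data.frame(at = integer(), d = integer()),
                          bridges = data.frame(i = integer(), d = integer()),
                          hydroxyls = integer(),
                          annotations = character(),
                          trace = character()) {
  chain <- structure(
    list(
      n = as.integer(n_carbons),
      d = as.integer(d),
      double_bonds = as.data.frame(double_bonds),
      branches = as.data.frame(branches),
      bridges = as.data.frame(bridges),
      hydroxyls = as.integer(hydroxyls),
      annotations = annotations,
      trace = trace
    ),
    class = "labeled_chain"
  )
  validate_chain(chain)
}

# hydrogen slots per main-chain carbon, from valence:
# 4 minus chain bonds, minus 1 per double-bond membership, bridge membership,
# branch, hydroxyl; minus 3 for the carboxyl oxygens at C1
chain_slots <- function(chain) {
  n <- chain$n
  bonds <- ifelse(seq_len(n) %in% c(1L, n), 1L, 2L)
  bonds[1] <- bonds[1] + 3L # carboxyl: =O (2) + -OH (1)
  for (i in chain$double_bonds$i) bonds[c(i, i + 1L)] <- bonds[c(i, i + 1L)] + 1L
  for (i in chain$bridges$i) bonds[c(i, i + 1L)] <- bonds[c(i, i + 1L)] + 1L
  for (a in chain$branches$at) bonds[a] <- bonds[a] + 1L
  for (p in chain$hydroxyls) bonds[p] <- bonds[p] + 1L
  4L - bonds
}

validate_chain <- function(chain) {
  n <- chain$n
  stopifnot(n >= 2L, length(chain$d) == n)
  if (any(chain$d < 0)) stop("negative deuterium count", call. = FALSE)
  db <- chain$double_bonds
  if (nrow(db) > 0) {
    stopifnot(all(db$i >= 2L), all(db$i < n), all(db$geometry %in% c("cis", "trans")))
  }
  if (nrow(chain$bridges) > 0) {
    stopifnot(all(chain$bridges$i >= 2L), all(chain$bridges$i < n),
              all(chain$bridges$d >= 0), all(chain$bridges$d <= 2))
  }
  if (nrow(chain$branches) > 0) {
    stopifnot(all(chain$branches$at >= 2L), all(chain$branches$at <= n),
              all(chain$branches$d >= 0), all(chain$branches$d <= 3))
  }
  if (length(chain$hydroxyls) > 0) {
    stopifnot(all(chain$hydroxyls >= 2L), all(chain$hydroxyls <= n))
  }
  db_carbons <- unlist(lapply(db$i, function(i) c(i, i + 1L)))
  br_carbons <- unlist(lapply(chain$bridges$i, function(i) c(i, i + 1L)))
  if (length(intersect(db_carbons, br_carbons)) > 0) {
    stop("double bonds and cyclopropane bridges must not overlap", call. = FALSE)
  }
  slots <- chain_slots(chain)
  if (any(slots < 0)) stop("valence exceeded at carbon(s) ",
                           paste(which(slots < 0), collapse = ", "), call. = FALSE)
  if (any(chain$d > slots)) {
    stop("deuterium count exceeds hydrogen slots at carbon(s) ",
         paste(which(chain$d > slots), collapse = ", "), call. = FALSE)
  }
  chain
}

#' Total deuterium carried by a chain
#' @param chain A `labeled_chain`.
#' @return Integer D count (main chain + branches + bridges).
#' @export
chain_d_total <- function(chain) {
  sum(chain$d) + sum(chain$branches$d) + sum(chain$bridges$d)
}

#' Molecular formula of a chain (free acid)
#'
#' Assembles the neutral formula from the skeleton: carbons from the main
#' chain plus branches and bridge CH2 units; hydrogens from unoccupied
#' slots plus the carboxyl OH and one per hydroxyl; oxygens 2 (carboxyl)
#' plus one per hydroxyl.
#'
#' @param chain A `labeled_chain`.
#' @return A [mol_formula()].
#' @export
chain_formula <- function(chain) {
  slots <- chain_slots(chain)
  n_c <- chain$n + nrow(chain$branches) + nrow(chain$bridges)
  d <- chain_d_total(chain)
  h <- sum(slots - chain$d) +
    sum(3L - chain$branches$d) +
    sum(2L - chain$bridges$d) +
    1L + # carboxyl OH
    length(chain$hydroxyls) # one OH hydrogen each
  o <- 2L + length(chain$hydroxyls)
  mol_formula(c(C = n_c, H = h, D = d, O = o))
}

#' @export
print.labeled_chain <- function(x, ...) {
  f <- chain_formula(x)
  cat("<labeled_chain> C", x$n, " skeleton, formula ", format(f),
      " (", chain_d_total(x), " D)\n", sep = "")
  slots <- chain_slots(x)
  lab <- vapply(seq_len(x$n), function(i) {
    tag <- sprintf("C%d[%dH%s]", i, slots[i] - x$d[i],
                   if (x$d[i] > 0) paste0(" ", x$d[i], "D") else "")
    tag
  }, character(1))
  cat("  ", paste(lab, collapse = " "), "\n", sep = "")
  if (nrow(x$double_bonds)) {
    cat("  double bonds: ",
        paste(sprintf("%d-%d (%s)", x$double_bonds$i, x$double_bonds$i + 1,
                      x$double_bonds$geometry), collapse = ", "), "\n", sep = "")
  }
  if (nrow(x$branches)) {
    cat("  methyl branches at: ", paste(x$branches$at, collapse = ", "), "\n", sep = "")
  }
  if (nrow(x$bridges)) {
    cat("  cyclopropane bridges at: ",
        paste(sprintf("%d-%d", x$bridges$i, x$bridges$i + 1), collapse = ", "), "\n", sep = "")
  }
  if (length(x$hydroxyls)) {
    cat("  hydroxyls at: ", paste(x$hydroxyls, collapse = ", "), "\n", sep = "")
  }
  if (length(x$trace)) cat("  trace: ", paste(x$trace, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Vaccenic acid (cis-11 18:1), optionally D13-labeled
#'
#' Builds the 18-carbon omega-7 monounsaturated fatty acid with its double
#' bond between C11 and C12. The commercial D13 label places two deuteriums
#' on each of C13-C17 and three on the terminal C18; the `d13_trans` variant
#' differs only in double-bond geometry, mirroring the labeled cis/trans
#' feeding pair used as substrate vs. negative control.
#'
#' @param label `"none"`, `"d13_cis"`, or `"d13_trans"`.
#' @param label_d Optional custom per-carbon deuterium vector (length 18)
#'   overriding the d13 pattern, for alternative labeling schemes.
#' @return A `labeled_chain` (C18H34O2 when unlabeled).
#' @export
make_vaccenic <- function(label = c("none", "d13_cis", "d13_trans"), label_d = NULL) {
  label <- match.arg(label)
  geometry <- if (label == "d13_trans") "trans" else "cis"
  d <- integer(18)
  if (label != "none") {
    d[13:17] <- 2L
    d[18] <- 3L
  }
  if (!is.null(label_d)) {
    stopifnot(length(label_d) == 18L)
    d <- as.integer(label_d)
  }
  labeled_chain(
    18L,
    d = d,
    double_bonds = data.frame(i = 11L, geometry = geometry),
    trace = paste0("vaccenic(", label, ")")
  )
}

single_cis_bond <- function(chain, what) {
  cis <- chain$double_bonds[chain$double_bonds$geometry == "cis", , drop = FALSE]
  if (nrow(cis) != 1L) {
    stop("not a substrate for ", what, ": chain has ", nrow(cis),
         " cis double bond(s) (exactly one required)", call. = FALSE)
  }
  cis$i[[1]]
}

#' Methyl transfer across a cis double bond (FCMT-1 / CFA-type chemistry)
#'
#' SAM-dependent C-methyltransfer to the proximal carbon of the chain's
#' single cis double bond, with concomitant double-bond migration one
#' position distal and isomerization to trans: cis-11 18:1 becomes
#' 11-methyl-12-trans 18:1. The migration turns carbon `i + 2` sp2, which
#' abstracts one of its hydrogens -- a deuterium when present (isotope
#' effects ignored). Net formula change +CH2. Trans-only or saturated chains
#' are rejected, reproducing the enzyme's cis specificity.
#'
#' @param chain A `labeled_chain` with exactly one cis double bond.
#' @return The methylated `labeled_chain`.
#' @export
apply_methyl_transfer <- function(chain) {
  i <- single_cis_bond(chain, "methyl transfer")
  if (i + 2L > chain$n - 1L + 1L) stop("double bond too close to chain end", call. = FALSE)
  abstracted <- "H"
  if (chain$d[i + 2L] > 0L) {
    chain$d[i + 2L] <- chain$d[i + 2L] - 1L
    abstracted <- "D"
  }
  chain$double_bonds <- data.frame(i = i + 1L, geometry = "trans")
  chain$branches <- rbind(chain$branches, data.frame(at = i, d = 0L))
  chain$trace <- c(chain$trace,
                   sprintf("methyl_transfer(at C%d, bond -> %d-%d trans, %s abstracted from C%d)",
                           i, i + 1L, i + 2L, abstracted, i + 2L))
  validate_chain(chain)
}

#' Cyclopropanation of a cis double bond (CFA synthase chemistry)
#'
#' Replaces the chain's single cis double bond with a cyclopropane ring by
#' inserting an unlabeled CH2 bridge across the two olefinic carbons, which
#' retain their single hydrogens (no abstraction). Net formula change +CH2:
#' the product is constitutionally isomeric with the methyl-transfer product
#' of the same substrate.
#'
#' @param chain A `labeled_chain` with exactly one cis double bond.
#' @return The cyclopropanated `labeled_chain`.
#' @export
apply_cyclopropanation <- function(chain) {
  i <- single_cis_bond(chain, "cyclopropanation")
  chain$double_bonds <- chain$double_bonds[chain$double_bonds$i != i, , drop = FALSE]
  chain$bridges <- rbind(chain$bridges, data.frame(i = i, d = 0L))
  chain$trace <- c(chain$trace, sprintf("cyclopropanation(bridge %d-%d)", i, i + 1L))
  validate_chain(chain)
}

beta_block_reason <- function(chain) {
  if (chain$n < 4L) return("chain shorter than 4 carbons")
  if (any(chain$branches$at %in% c(2L, 3L))) {
    return("beta-blocked: methyl branch at C2/C3")
  }
  if (any(chain$bridges$i %in% c(1L, 2L, 3L))) {
    return("beta-blocked: cyclopropane ring involving C2/C3")
  }
  if (any(chain$hydroxyls %in% c(2L, 3L))) {
    return("beta-blocked: hydroxyl at C2/C3")
  }
  if (chain_slots(chain)[3L] < 1L) return("no hydrogen at C3")
  NULL
}

#' One round of beta-oxidation (net two-carbon chain shortening)
#'
#' Collapses the dehydrogenation/hydration/thiolysis cycle into its net
#' effect on the free acid: carbons C1 and C2 are removed (with any
#' deuterium they carry), the former C3 becomes the new carboxyl carbon and
#' is stripped of its hydrogens/deuteriums (they are lost to the redox steps
#' of the cycle), and all positions renumber down by two. A beta
#' substituent -- methyl branch, cyclopropane ring, or hydroxyl at C2/C3 --
#' blocks the round, the termination condition that parks C11 beta-branched
#' acids as end products.
#'
#' @param chain A `labeled_chain` of at least 4 carbons, unsubstituted at
#'   the alpha/beta positions.
#' @return The shortened `labeled_chain`.
#' @export
apply_beta_oxidation_round <- function(chain) {
  reason <- beta_block_reason(chain)
  if (!is.null(reason)) stop(reason, call. = FALSE)
  lost_d <- sum(chain$d[1:3]) # C1, C2 removed; new carboxyl carbon stripped
  chain$d <- c(0L, chain$d[-(1:3)])
  chain$n <- chain$n - 2L
  chain$double_bonds$i <- chain$double_bonds$i - 2L
  chain$bridges$i <- chain$bridges$i - 2L
  chain$branches$at <- chain$branches$at - 2L
  chain$hydroxyls <- chain$hydroxyls - 2L
  chain$trace <- c(chain$trace,
                   sprintf("beta_oxidation(-C2 unit, %d D lost, now C%d)", lost_d, chain$n))
  validate_chain(chain)
}

#' Several consecutive beta-oxidation rounds
#' @param chain A `labeled_chain`.
#' @param rounds Number of rounds to apply.
#' @return The shortened `labeled_chain`.
#' @export
apply_beta_oxidation <- function(chain, rounds) {
  stopifnot(rounds >= 0, rounds == round(rounds))
  for (k in seq_len(rounds)) chain <- apply_beta_oxidation_round(chain)
  chain
}

#' Peroxisomal alpha-oxidation (net one-carbon chain shortening)
#'
#' Two-stage model of the PHYH/HACL-1 pathway. Stage 1 (2-hydroxylation)
#' replaces one hydrogen at C2 with a hydroxyl (an H is taken when present,
#' a D only from a fully deuterated position), yielding the 2-hydroxy acid
#' intermediate -- the shunt metabolite observed when the lyase step is
#' lost. Stage 2 (C1-C2 lyase cleavage plus aldehyde oxidation) removes C1;
#' the former C2 becomes the new carboxyl carbon, losing its remaining
#' hydrogen/deuterium and the hydroxyl.
#'
#' @param chain A `labeled_chain` with at least one hydrogen slot at C2.
#' @return List with elements `intermediate` (the 2-hydroxy chain) and
#'   `product` (the one-carbon-shortened acid).
#' @export
apply_alpha_oxidation <- function(chain) {
  slots <- chain_slots(chain)
  if (slots[2L] < 1L) stop("C2 is fully substituted; cannot 2-hydroxylate", call. = FALSE)
  if (2L %in% chain$hydroxyls) stop("C2 already hydroxylated", call. = FALSE)
  intermediate <- chain
  intermediate$hydroxyls <- sort(c(intermediate$hydroxyls, 2L))
  # the OH displaces an H when one is present; a D only at a fully labeled C2
  if (slots[2L] - chain$d[2L] == 0L) {
    intermediate$d[2L] <- intermediate$d[2L] - 1L
  }
  intermediate$trace <- c(intermediate$trace, "alpha_oxidation:2-hydroxylation")
  intermediate <- validate_chain(intermediate)

  product <- intermediate
  product$d <- c(0L, product$d[-(1:2)])
  product$n <- product$n - 1L
  product$hydroxyls <- setdiff(product$hydroxyls, 2L) - 1L
  product$double_bonds$i <- product$double_bonds$i - 1L
  product$bridges$i <- product$bridges$i - 1L
  product$branches$at <- product$branches$at - 1L
  product$trace <- c(product$trace,
                     sprintf("alpha_oxidation:cleavage(-C1, now C%d)", product$n))
  product <- validate_chain(product)
  list(intermediate = intermediate, product = product)
}

#' Hydroxylation at a chosen carbon
#'
#' Replaces one hydrogen slot at the target carbon with a hydroxyl. When the
#' carbon carries deuterium, a deuterium is removed (isotope effects
#' ignored) -- this is what makes distal oxidation of labeled chains leave a
#' diagnostic deuterium count. `"omega"` targets the terminal main-chain
#' carbon, `"omega-1"` the one before it.
#'
#' @param chain A `labeled_chain`.
#' @param position Carbon index, or `"omega"` / `"omega-1"`.
#' @return The hydroxylated `labeled_chain`.
#' @export
apply_hydroxylation <- function(chain, position) {
  if (is.character(position)) {
    position <- switch(position,
      "omega" = chain$n,
      "omega-1" = chain$n - 1L,
      stop("position must be a carbon index, 'omega', or 'omega-1'", call. = FALSE)
    )
  }
  position <- as.integer(position)
  stopifnot(position >= 2L, position <= chain$n)
  slots <- chain_slots(chain)
  if (slots[position] < 1L) {
    stop("carbon C", position, " is fully substituted; cannot hydroxylate", call. = FALSE)
  }
  chain$hydroxyls <- sort(c(chain$hydroxyls, position))
  removed <- "H"
  if (chain$d[position] > 0L) {
    chain$d[position] <- chain$d[position] - 1L
    removed <- "D"
  }
  chain$trace <- c(chain$trace, sprintf("hydroxylation(C%d, %s displaced)", position, removed))
  validate_chain(chain)
}

#' Predicted metabolite record for a chain
#'
#' Assembles the chain's neutral formula, total deuterium count, and ion m/z
#' under the requested adduct, together with the transformation trace.
#'
#' @param chain A `labeled_chain`.
#' @param a Adduct name or [adduct()] descriptor; default `"[M-H]-"`.
#' @param name Optional metabolite name tag.
#' @return One-row tibble: `name, formula, n_d, mz, trace`.
#' @export
predict_metabolite <- function(chain, a = "[M-H]-", name = NA_character_) {
  f <- chain_formula(chain)
  tibble::tibble(
    name = name,
    formula = format(f),
    n_d = chain_d_total(chain),
    mz = mz_for_adduct(f, a),
    trace = paste(chain$trace, collapse = " -> ")
  )
}

#' Predict the C11 branched-acid metabolite family from vaccenic acid
#'
#' Runs the full tracer-fate routes from (optionally D13-labeled) vaccenic
#' acid: methyl transfer plus four beta-oxidation rounds to the beta-methyl
#' C11 acid (bemeth#1 skeleton), cyclopropanation plus four rounds to the
#' beta-cyclopropyl isomer (becyp#1), 2-hydroxylation of the beta-methyl
#' acid (bemeth#2), and additional distal hydroxylation (bemeth#3).
#'
#' @param label Label of the vaccenic precursor: `"none"`, `"d13_cis"`, or
#'   `"d13_trans"`. The trans label is not a methyl-transfer substrate, so
#'   only the cyclopropanation route would apply to it; routes whose first
#'   step rejects the substrate are omitted from the output.
#' @param distal Distal hydroxylation position for the dihydroxy acid,
#'   `"omega-1"` (default) or `"omega"`; the predicted deuterium count is
#'   identical for any deuterated distal carbon.
#' @param a Adduct for m/z, default `"[M-H]-"`.
#' @return Tibble of predictions (`name, formula, n_d, mz, trace`).
#' @export
predict_c11_family <- function(label = "none", distal = "omega-1", a = "[M-H]-") {
  va <- make_vaccenic(label)
  out <- list()
  methylated <- tryCatch(apply_methyl_transfer(va), error = function(e) NULL)
  if (!is.null(methylated)) {
    bemeth1 <- apply_beta_oxidation(methylated, 4L)
    alpha <- apply_alpha_oxidation(bemeth1)
    bemeth3 <- apply_hydroxylation(alpha$intermediate, distal)
    out$bemeth1 <- predict_metabolite(bemeth1, a, "bemeth#1")
    out$bemeth2 <- predict_metabolite(alpha$intermediate, a, "bemeth#2")
    out$bemeth3 <- predict_metabolite(bemeth3, a, "bemeth#3")
  }
  cyclo <- tryCatch(apply_cyclopropanation(va), error = function(e) NULL)
  if (!is.null(cyclo)) {
    becyp1 <- apply_beta_oxidation(cyclo, 4L)
    out$becyp1 <- predict_metabolite(becyp1, a, "becyp#1")
    out$becyp2 <- predict_metabolite(apply_hydroxylation(becyp1, "omega-1"), a, "becyp#2")
  }
  dplyr::bind_rows(out)
}
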