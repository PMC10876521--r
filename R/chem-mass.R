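#' Monoisotopic masses of the supported isotopes
#'
#' Named vector of exact monoisotopic masses (Da) for the isotopes handled by
#' the formula engine, plus the electron rest mass. Deuterium (`D`) is carried
#' as its own symbol so that formula arithmetic on labeled species stays
#' integer-exact. Values are the NIST/CODATA reference masses.
#'
#' @format Named numeric vector with elements `C`, `H`, `D`, `O`, `N`, `S`,
#'   `P`, and `electron`, in Da.
#' @examples
#' isotope_masses[["D"]] - isotope_masses[["H"]] # the per-deuterium mass shift
#' @export
isotope_masses <- c(
  C = 12.0,
  H = 1.0078250319,
  D = 2.0141017779,
  O = 15.9949146221,
  N = 14.0030740052,
  S = 31.97207069,
  P = 30.97376151,
  electron = 0.0005485799
)

# element symbols accepted in formulas, in canonical (Hill) output order:
# C, H, then the rest alphabetically (D sorts with the rest, giving e.g.
# "C11H9D11O4" for labeled species)
.formula_elements <- c("C", "H", "D", "N", "O", "P", "S")

#' Parse a molecular formula string
#'
#' Parses compact formulas such as `"C11H20O2"` or `"C11H9D11O4"` into a
#' `mol_formula` object (named integer counts). Deuterium is written `D` and
#' counted separately from `H`.
#'
#' @param text A single formula string over elements C, H, D, O, N, S, P.
#'   An omitted count means 1 (e.g. `"H2O"`).
#' @return A `mol_formula`: named integer vector of element counts.
#' @examples
#' parse_formula("C11H20O2")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!nzchar(text)) {
    stop("empty formula string", call. = FALSE)
  }
  matched <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (paste(matched, collapse = "") != text) {
    bad <- substr(gsub("[A-Z][a-z]?[0-9]*", "", text), 1, 8)
    stop("malformed formula token: '", bad, "' in '", text, "'", call. = FALSE)
  }
  counts <- stats::setNames(integer(length(.formula_elements)), .formula_elements)
  for (tok in matched) {
    sym <- sub("[0-9]*$", "", tok)
    if (!sym %in% .formula_elements) {
      stop("unknown element symbol '", sym, "' in formula '", text, "'", call. = FALSE)
    }
    digits <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(digits)) as.integer(digits) else 1L
    counts[[sym]] <- counts[[sym]] + n
  }
  mol_formula(counts)
}

#' Construct a molecular formula from element counts
#'
#' @param counts Named integer vector (or named arguments via `...`) of
#'   non-negative counts per element among C, H, D, O, N, S, P.
#' @param ... Alternative to `counts`: named counts, e.g. `mol_formula(C = 11, H = 20, O = 2)`.
#' @return A `mol_formula` object.
#' @export
mol_formula <- function(counts = NULL, ...) {
  if (is.null(counts)) counts <- unlist(list(...))
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  unknown <- setdiff(names(counts), .formula_elements)
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  full <- stats::setNames(integer(length(.formula_elements)), .formula_elements)
  full[names(counts)] <- as.integer(round(counts))
  if (any(full < 0)) {
    stop("negative element count in formula", call. = FALSE)
  }
  if (sum(full) == 0L) {
    stop("formula must contain at least one atom", call. = FALSE)
  }
  structure(full, class = "mol_formula")
}

#' @export
format.mol_formula <- function(x, ...) {
  present <- x[x > 0L]
  paste0(names(present), ifelse(present == 1L, "", present), collapse = "")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<mol_formula> ", format(x), "  (", monoisotopic_mass(x), " Da)\n", sep = "")
  invisible(x)
}

#' @export
as.character.mol_formula <- function(x, ...) format(x)

#' @export
`+.mol_formula` <- function(e1, e2) {
  mol_formula(unclass(e1) + unclass(e2))
}

#' @export
`-.mol_formula` <- function(e1, e2) {
  out <- unclass(e1) - unclass(e2)
  if (any(out < 0)) {
    stop("formula subtraction would produce a negative element count", call. = FALSE)
  }
  mol_formula(out)
}

#' Exact monoisotopic mass of a formula
#'
#' Sum of count times isotope mass over all elements, using
#' [isotope_masses]. Deterministic and additive: the mass of `f1 + f2` equals
#' the sum of the two masses.
#'
#' @param f A `mol_formula` or a formula string.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O") # 18.010565
#' @export
monoisotopic_mass <- function(f) {
  f <- as_mol_formula(f)
  sum(unclass(f) * isotope_masses[.formula_elements])
}

as_mol_formula <- function(f) {
  if (inherits(f, "mol_formula")) f else parse_formula(f)
}

#' Supported electrospray adducts
#'
#' Builds an adduct descriptor for the singly charged species used in
#' negative- and positive-mode ESI: `"[M-H]-"` (lose a proton) and
#' `"[M+H]+"` (gain a proton). The ion m/z bookkeeping includes the electron
#' mass: `[M-H]-` keeps the electron of the lost hydrogen atom, `[M+H]+`
#' lacks one. Many back-of-envelope calculators omit the ~0.00055 Da
#' electron term; it is required to reproduce 4-decimal instrument m/z.
#'
#' @param name `"[M-H]-"` or `"[M+H]+"`.
#' @return List with `name`, `charge`, `h_delta`, `e_delta`.
#' @export
adduct <- function(name = c("[M-H]-", "[M+H]+")) {
  name <- match.arg(name)
  if (name == "[M-H]-") {
    list(name = name, charge = -1L, h_delta = -1L, e_delta = +1L)
  } else {
    list(name = name, charge = +1L, h_delta = +1L, e_delta = -1L)
  }
}

#' Ion m/z of a neutral formula under an adduct
#'
#' `m/z = monoisotopic_mass(M) + h_delta * m(1H) + e_delta * m(electron)`
#' for singly charged adducts. Full double precision is retained; round to 4
#' decimals for display against instrument-reported values.
#'
#' @param f Neutral molecule as `mol_formula` or string.
#' @param a Adduct name or descriptor from [adduct()].
#' @return m/z in Th (full precision).
#' @examples
#' round(mz_for_adduct("C11H20O2", "[M-H]-"), 4) # 183.1391
#' @export
mz_for_adduct <- function(f, a = "[M-H]-") {
  f <- as_mol_formula(f)
  if (is.character(a)) a <- adduct(a)
  if (a$h_delta < 0 && f[["H"]] + f[["D"]] < 1L) {
    stop("cannot deprotonate a hydrogen-free formula", call. = FALSE)
  }
  monoisotopic_mass(f) +
    a$h_delta * isotope_masses[["H"]] +
    a$e_delta * isotope_masses[["electron"]]
}

#' Exact mass shift of n deuterium-for-protium substitutions
#'
#' `n * (m(2H) - m(1H))`, with the per-deuterium shift
#' 1.0062767460 Da. Three substitutions give the diagnostic 3.0188 Da shift
#' seen for methyl-group labeling from D3-methyl-methionine.
#'
#' @param n Non-negative integer count of D-for-H substitutions.
#' @return Mass shift in Da, linear in `n`.
#' @examples
#' round(deuterium_shift(3), 4) # 3.0188
#' @export
deuterium_shift <- function(n) {
  stopifnot(is.numeric(n), all(n >= 0), all(n == round(n)))
  n * (isotope_masses[["D"]] - isotope_masses[["H"]])
}

#' Symmetric ppm window around an m/z
#'
#' The closed interval `[mz * (1 - tol * 1e-6), mz * (1 + tol * 1e-6)]` used
#' for EIC-style lookups and isotopologue matching (quantification windows in
#' the source workflow are 3 ppm).
#'
#' @param mz Center m/z in Th; must be positive.
#' @param tol_ppm Tolerance in parts per million; non-negative.
#' @return Numeric length-2 vector `c(lo, hi)`.
#' @export
ppm_window <- function(mz, tol_ppm) {
  stopifnot(is.numeric(mz), length(mz) == 1L, is.numeric(tol_ppm), length(tol_ppm) == 1L)
  if (mz <= 0) stop("mz must be positive", call. = FALSE)
  if (tol_ppm < 0) stop("tol_ppm must be non-negative", call. = FALSE)
  c(mz * (1 - tol_ppm * 1e-6), mz * (1 + tol_ppm * 1e-6))
}

#' Mass error in parts per million
#'
#' @param observed,expected m/z values in Th.
#' @return Signed ppm error `(observed - expected) / expected * 1e6`.
#' @export
ppm_error <- function(observed, expected) {
  (observed - expected) / expected * 1e6
}
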