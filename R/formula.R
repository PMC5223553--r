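#' @importFrom stats optimize quantile sd median rnorm rlnorm runif rbinom
#'   pt phyper p.adjust t.test fisher.test cor setNames qchisq uniroot
NULL

ELEMENT_ORDER <- c("C", "H", "O", "N", "S", "P")

#' Construct an elemental formula from element counts
#'
#' @param ... named integer counts, e.g. `elemental_formula(C = 6, H = 12, O = 6)`.
#' @param counts alternatively, a named numeric vector of counts.
#' @return A named integer vector of class `elemental_formula` with one
#'   entry per known element (missing elements are 0). All counts must be
#'   non-negative and at least one must be positive.
#' @examples
#' elemental_formula(C = 6, H = 12, O = 6)
#' @export
elemental_formula <- function(..., counts = NULL) {
  if (is.null(counts)) counts <- unlist(list(...))
  if (length(counts) == 0) stop("empty formula: no element counts given")
  bad <- setdiff(names(counts), ELEMENT_ORDER)
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  if (any(counts < 0)) stop("negative element count")
  if (any(counts != round(counts))) stop("non-integer element count")
  out <- setNames(integer(length(ELEMENT_ORDER)), ELEMENT_ORDER)
  out[names(counts)] <- as.integer(counts)
  if (sum(out) == 0) stop("empty formula: all counts are zero")
  structure(out, class = "elemental_formula")
}

#' Parse a molecular formula string
#'
#' Accepts the usual element-count grammar: an element symbol (one capital
#' letter, optionally followed by a lowercase letter) followed by an optional
#' positive count, e.g. `"C6H12O6"`, `"CH2"`. Repeated symbols are summed.
#'
#' @param text a single formula string.
#' @return An `elemental_formula`.
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("CH2")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula string")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  toks <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop("malformed formula string: ", text)
  sym <- sub("[0-9]*$", "", toks)
  cnt <- sub("^[A-Za-z]+", "", toks)
  cnt <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
  if (anyNA(cnt)) stop("malformed count in formula: ", text)
  bad <- setdiff(sym, ELEMENT_ORDER)
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  counts <- tapply(cnt, factor(sym, levels = ELEMENT_ORDER), sum, default = 0L)
  elemental_formula(counts = counts)
}

#' Write a formula in canonical Hill order
#'
#' Carbon first, hydrogen second, remaining elements alphabetically; counts
#' of 1 are omitted and zero-count elements are dropped. `parse_formula()`
#' round-trips through this writer.
#'
#' @param f an `elemental_formula` (or named count vector).
#' @return A single string.
#' @examples
#' write_formula(parse_formula("H12C6O6"))  # "C6H12O6"
#' @export
write_formula <- function(f) {
  f <- as_formula_counts(f)
  hill <- c("C", "H", sort(setdiff(names(f), c("C", "H"))))
  f <- f[hill]
  nz <- f > 0
  paste0(names(f)[nz], ifelse(f[nz] == 1, "", f[nz]), collapse = "")
}

as_formula_counts <- function(f) {
  if (inherits(f, "elemental_formula")) return(unclass(f))
  if (is.character(f)) return(unclass(parse_formula(f)))
  if (is.numeric(f) && !is.null(names(f))) {
    return(unclass(elemental_formula(counts = f)))
  }
  stop("not an elemental formula")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula>", write_formula(x), "\n")
  invisible(x)
}

#' Element-wise formula addition and subtraction
#'
#' Addition and subtraction are element-wise on counts; subtraction that
#' would drive any count negative is an error (formulas are bags of atoms,
#' not signed vectors).
#'
#' @param a,b elemental formulas (or formula strings).
#' @return An `elemental_formula`.
#' @examples
#' formula_add("C6H12O6", "CH2")
#' formula_subtract("C6H12O6", "H2O")
#' @export
formula_add <- function(a, b) {
  elemental_formula(counts = as_formula_counts(a) + as_formula_counts(b))
}

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) {
  d <- as_formula_counts(a) - as_formula_counts(b)
  if (any(d < 0)) {
    stop("formula subtraction yields negative count for ",
         paste(names(d)[d < 0], collapse = ", "))
  }
  elemental_formula(counts = d)
}

#' Monoisotopic mass of a neutral formula
#'
#' Sum of element counts times monoisotopic masses from the element table.
#'
#' @param f an `elemental_formula` or formula string.
#' @param elements an [element_table()].
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C6H14N4O2")  # arginine, 174.111676
#' @export
monoisotopic_mass <- function(f, elements = element_table()) {
  f <- as_formula_counts(f)
  sum(f * elements$mass[match(names(f), elements$element)])
}

#' m/z of the deprotonated ion [M-H]-
#'
#' The package models negative-mode electrospray exclusively: the observed
#' ion is the deprotonated molecule, so m/z = neutral mass minus the proton
#' mass. `neutral_mass()` is the exact inverse.
#'
#' @param neutral_mass neutral monoisotopic mass in Da (vectorized).
#' @param mode ionization mode; only `"[M-H]-"` is supported.
#' @return m/z values.
#' @examples
#' mz_of_ion(monoisotopic_mass("C16H32O2"))
#' @export
mz_of_ion <- function(neutral_mass, mode = "[M-H]-") {
  if (!identical(mode, "[M-H]-"))
    stop("unsupported ionization mode: ", mode, " (only [M-H]- is modeled)")
  neutral_mass - proton_mass()
}

#' @rdname mz_of_ion
#' @param mz observed m/z of the deprotonated ion.
#' @export
neutral_mass <- function(mz, mode = "[M-H]-") {
  if (!identical(mode, "[M-H]-"))
    stop("unsupported ionization mode: ", mode, " (only [M-H]- is modeled)")
  mz + proton_mass()
}

#' Signed relative mass error in parts per million
#'
#' @param observed,theoretical m/z or mass values (vectorized); the
#'   theoretical value must be positive.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @examples
#' ppm_error(400.0004, 400)  # +1 ppm
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical mass must be positive")
  1e6 * (observed - theoretical) / theoretical
}

#' Senior-rule validity and double-bond equivalents
#'
#' A formula can correspond to a connected closed-shell molecule only if
#' (i) the ring-and-double-bond count
#' DBE = 1 + sum(count * (valence - 2)) / 2 is a non-negative integer and
#' (ii) the total valence sum is even (no unpaired electrons).
#'
#' @param f an `elemental_formula` or formula string.
#' @param elements an [element_table()] supplying valences.
#' @return A list with `valid` (logical) and `dbe` (possibly half-integer).
#' @examples
#' senior_check("C6H6")  # valid, dbe 4
#' senior_check("CH3")   # invalid: odd valence sum
#' @export
senior_check <- function(f, elements = element_table()) {
  f <- as_formula_counts(f)
  val <- elements$valence[match(names(f), elements$element)]
  if (any(is.na(val) & f > 0)) stop("element without configured valence")
  dbe <- 1 + sum(f * (val - 2)) / 2
  vsum <- sum(f * val)
  list(valid = (dbe >= 0) && (dbe == round(dbe)) && (vsum %% 2 == 0),
       dbe = dbe)
}

#' Elemental-ratio plausibility check
#'
#' Tests whether each configured element-to-carbon ratio of a formula lies
#' inside the closed bounds of a [ratio_bounds()] object. Requires at least
#' one carbon (the assignment grid enforces C >= 1).
#'
#' @param f an `elemental_formula` or formula string.
#' @param bounds a [ratio_bounds()].
#' @return Logical.
#' @examples
#' ratio_check("C16H32O2")  # TRUE: H/C = 2
#' ratio_check("C1H50")     # FALSE: H/C above default upper bound
#' @export
ratio_check <- function(f, bounds = ratio_bounds()) {
  f <- as_formula_counts(f)
  if (f["C"] < 1) stop("ratio_check requires at least one carbon")
  C <- f["C"]
  hc <- f["H"] / C
  unname((hc >= bounds$hc_min) && (hc <= bounds$hc_max) &&
    (f["O"] / C <= bounds$oc_max) &&
    (f["N"] / C <= bounds$nc_max) &&
    (f["S"] / C <= bounds$sc_max) &&
    (f["P"] / C <= bounds$pc_max) &&
    (f["O"] >= bounds$o_per_p_min * f["P"]) &&
    (f["N"] <= bounds$n_needs_o_above || f["O"] >= f["N"]))
}

#' Expected first-isotopologue intensity ratio
#'
#' First-order approximation of the M+1 (13C) isotopologue intensity
#' relative to the monoisotopic peak: nC * r(13C). With `channel = "M+2"`
#' the 34S contribution nS * r(34S) is returned instead. At ultrahigh
#' resolution the isotopologue is treated as a single exact-mass peak (no
#' peak-shape convolution).
#'
#' @param f an `elemental_formula` or formula string; must contain carbon
#'   for the M+1 channel.
#' @param elements an [element_table()] supplying abundance ratios.
#' @param channel `"M+1"` (13C, default) or `"M+2"` (34S).
#' @return Expected intensity ratio (unitless).
#' @examples
#' expected_isotopologue_ratio("C16H32O2")  # ~0.173
#' @export
expected_isotopologue_ratio <- function(f, elements = element_table(),
                                        channel = c("M+1", "M+2")) {
  channel <- match.arg(channel)
  f <- as_formula_counts(f)
  if (channel == "M+1") {
    if (f["C"] < 1) stop("M+1 isotopologue ratio requires at least one carbon")
    unname(f["C"] * elements$iso_ratio[elements$element == "C"])
  } else {
    unname(f["S"] * elements$iso_ratio[elements$element == "S"])
  }
}

#' @rdname expected_isotopologue_ratio
#' @return `isotopologue_shift()`: the m/z offset of the isotopologue peak
#'   relative to the monoisotopic peak, in Da.
#' @export
isotopologue_shift <- function(elements = element_table(),
                               channel = c("M+1", "M+2")) {
  channel <- match.arg(channel)
  el <- if (channel == "M+1") "C" else "S"
  elements$iso_shift[elements$element == el]
}
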