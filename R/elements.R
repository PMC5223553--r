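#' Element constants: monoisotopic masses, valences, heavy-isotope ratios
#'
#' Single source of physical constants for every mass computation in the
#' package. Monoisotopic masses are IUPAC/CODATA values at >= 9 significant
#' digits. Valences are the lowest common organic valence (C=4, H=1, O=2,
#' N=3, S=2, P=3), used by the Senior-rule check; they can be overridden.
#' `iso_ratio` is the natural abundance ratio of the first heavy isotope to
#' the light one (13C/12C, 34S/32S); `iso_shift` is the corresponding mass
#' shift in Da. Elements without a modeled isotopologue carry NA.
#'
#' @param masses,valences,iso_ratios named numeric vectors overriding the
#'   defaults for individual elements.
#' @return A data.frame with one row per element and columns
#'   `element`, `mass`, `valence`, `iso_ratio`, `iso_shift`.
#' @examples
#' element_table()
#' element_table(valences = c(N = 5))
#' @export
element_table <- function(masses = NULL, valences = NULL, iso_ratios = NULL) {
  tab <- data.frame(
    element  = c("C", "H", "O", "N", "S", "P"),
    mass     = c(12.0, 1.00782503207, 15.9949146196, 14.0030740048,
                 31.9720710015, 30.9737616320),
    valence  = c(4L, 1L, 2L, 3L, 2L, 3L),
    # 13C/12C = 1.07/98.93, 34S/32S = 4.25/94.99 (natural abundances)
    iso_ratio = c(1.07 / 98.93, NA, NA, NA, 4.25 / 94.99, NA),
    # mass(13C) - mass(12C); mass(34S) - mass(32S)
    iso_shift = c(13.0033548378 - 12.0, NA, NA, NA,
                  33.9678669 - 31.9720710015, NA),
    stringsAsFactors = FALSE
  )
  override <- function(tab, col, vals) {
    if (is.null(vals)) return(tab)
    bad <- setdiff(names(vals), tab$element)
    if (length(bad)) stop("unknown element(s): ", paste(bad, collapse = ", "))
    tab[[col]][match(names(vals), tab$element)] <- vals
    tab
  }
  tab <- override(tab, "mass", masses)
  tab <- override(tab, "valence", valences)
  tab <- override(tab, "iso_ratio", iso_ratios)
  stopifnot(all(tab$mass > 0))
  tab
}

#' Proton mass used for ion m/z arithmetic
#'
#' Mass of the proton in Da, used to convert between neutral monoisotopic
#' mass and the m/z of the deprotonated ion.
#' @return Numeric scalar, Da.
#' @export
proton_mass <- function() 1.007276466

#' Elemental-ratio bounds for formula plausibility filtering
#'
#' Heuristic element-per-carbon ranges that biomolecular formulas occupy.
#' A candidate formula is kept only when every configured ratio lies inside
#' its closed interval. Defaults are standard screening ranges for
#' biological small molecules; all bounds are configuration, not constants
#' baked into the check.
#'
#' In addition to the per-carbon ratios, two heteroatom plausibility
#' relationships are enforced (both standard in exact-mass formula
#' filtering, both disabled by setting them to 0/Inf): phosphorus occurs in
#' metabolites as phosphate-like moieties, so `O >= o_per_p_min * P`; and
#' nitrogen counts beyond what purine/peptide chemistry produces come with
#' oxygen, so formulas with `N > n_needs_o_above` must satisfy `O >= N`.
#' These relationships are what separates near-isobaric artifacts (e.g.
#' N14 vs C2H12O10 replacements, ~0.02 ppm apart) that no mass accuracy can
#' resolve.
#'
#' @param hc_min,hc_max bounds on H/C.
#' @param oc_max,nc_max,sc_max,pc_max upper bounds on O/C, N/C, S/C, P/C
#'   (lower bounds are 0).
#' @param o_per_p_min minimum oxygens required per phosphorus.
#' @param n_needs_o_above nitrogen count above which O >= N is required.
#' @return A named list of class `ratio_bounds`.
#' @examples
#' ratio_bounds()
#' ratio_bounds(hc_max = 4)
#' @export
ratio_bounds <- function(hc_min = 0.2, hc_max = 3.1, oc_max = 1.2,
                         nc_max = 1.3, sc_max = 0.8, pc_max = 0.3,
                         o_per_p_min = 4, n_needs_o_above = 6) {
  stopifnot(hc_min <= hc_max, oc_max >= 0, nc_max >= 0, sc_max >= 0,
            pc_max >= 0, o_per_p_min >= 0, n_needs_o_above >= 0)
  structure(list(hc_min = hc_min, hc_max = hc_max, oc_max = oc_max,
                 nc_max = nc_max, sc_max = sc_max, pc_max = pc_max,
                 o_per_p_min = o_per_p_min,
                 n_needs_o_above = n_needs_o_above),
            class = "ratio_bounds")
}
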