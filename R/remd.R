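default_remd_table <- function() {
  # curated biochemical building blocks: common condensation/modification
  # deltas, monosaccharide and amino-acid residues, phospho/sulfo groups,
  # and fatty-acyl units
  df <- data.frame(rbind(
    c("hydrogenation",        "H2"),
    c("oxygenation",          "O"),
    c("hydration",            "H2O"),
    c("methylene",            "CH2"),
    c("carbonyl",             "CO"),
    c("carboxylation",        "CO2"),
    c("hydroxymethyl",        "CH2O"),
    c("ethylene",             "C2H4"),
    c("acetylene",            "C2H2"),
    c("acetyl",               "C2H2O"),
    c("glycolyl",             "C2H2O2"),
    c("acetaldehyde",         "C2H4O"),
    c("acetate",              "C2H4O2"),
    c("propionyl",            "C3H4O"),
    c("malonyl",              "C3H2O3"),
    c("pyruvyl",              "C3H2O2"),
    c("lactyl",               "C3H4O2"),
    c("glyceryl",             "C3H6O2"),
    c("butyryl",              "C4H6O"),
    c("succinyl",             "C4H4O3"),
    c("isoprene",             "C5H8"),
    c("hexose",               "C6H10O5"),
    c("pentose",              "C5H8O4"),
    c("deoxyhexose",          "C6H10O4"),
    c("glucuronyl",           "C6H8O6"),
    c("amination",            "NH3"),
    c("imine",                "NH"),
    c("glycine-residue",      "C2H3NO"),
    c("alanine-residue",      "C3H5NO"),
    c("serine-residue",       "C3H5NO2"),
    c("cysteine-residue",     "C3H5NOS"),
    c("valine-residue",       "C5H9NO"),
    c("leucine-residue",      "C6H11NO"),
    c("threonine-residue",    "C4H7NO2"),
    c("aspartyl-residue",     "C4H5NO3"),
    c("glutamyl-residue",     "C5H7NO3"),
    c("asparagine-residue",   "C4H6N2O2"),
    c("glutamine-residue",    "C5H8N2O2"),
    c("lysine-residue",       "C6H12N2O"),
    c("arginine-residue",     "C6H12N4O"),
    c("histidine-residue",    "C6H7N3O"),
    c("proline-residue",      "C5H7NO"),
    c("phenylalanine-residue","C9H9NO"),
    c("tyrosine-residue",     "C9H9NO2"),
    c("tryptophan-residue",   "C11H10N2O"),
    c("methionine-residue",   "C5H9NOS"),
    c("phosphorylation",      "HPO3"),
    c("phosphate",            "H3PO4"),
    c("sulfonation",          "SO3"),
    c("sulfur",               "S"),
    c("hydrogen-sulfide",     "H2S"),
    c("phosphocholine",       "C5H12NO3P"),
    c("phosphoethanolamine",  "C2H6NO3P"),
    c("glycerophosphate",     "C3H7O5P"),
    c("palmitoyl",            "C16H30O"),
    c("stearoyl",             "C18H34O"),
    c("oleoyl",               "C18H32O")
  ), stringsAsFactors = FALSE)
  names(df) <- c("name", "formula")
  df
}

#' Load a reaction-equivalent mass difference (REMD) library
#'
#' REMDs are exact formula deltas corresponding to biochemical building
#' blocks (CH2, H2O, amino-acid residues, HPO3, ...). They become the edge
#' types of the mass difference network. Without a file, a curated in-repo
#' library of ~57 building blocks is used; a user file (one formula per
#' line, or `name<TAB>formula`) replaces it. Entries are normalized to Hill
#' order and deduplicated by canonical formula; the same name mapping to two
#' different formulas is an error.
#'
#' @param path optional path to a headerless text file: column 1 = name (or
#'   formula if only one column), column 2 = formula.
#' @return data.frame of class `remd_library`: `name`, `formula` (canonical
#'   Hill string), `mass` (Da).
#' @export
load_remds <- function(path = NULL) {
  if (is.null(path)) {
    df <- default_remd_table()
  } else {
    raw <- utils::read.table(path, header = FALSE, sep = "\t",
                             comment.char = "#",
                             stringsAsFactors = FALSE, fill = TRUE)
    if (ncol(raw) == 1) {
      df <- data.frame(name = raw[[1]], formula = raw[[1]],
                       stringsAsFactors = FALSE)
    } else {
      df <- data.frame(name = raw[[1]], formula = raw[[2]],
                       stringsAsFactors = FALSE)
    }
  }
  canon <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    canon[i] <- tryCatch(write_formula(parse_formula(df$formula[i])),
                         error = function(e) {
                           stop("REMD entry ", i, " ('", df$name[i],
                                "'): ", conditionMessage(e), call. = FALSE)
                         })
  }
  df$formula <- canon
  # same name, different formula -> error; exact duplicates -> collapse
  by_name <- split(df$formula, df$name)
  clash <- names(by_name)[vapply(by_name, function(x) length(unique(x)) > 1,
                                 logical(1))]
  if (length(clash)) {
    stop("duplicate REMD name(s) with different formulas: ",
         paste(clash, collapse = ", "))
  }
  df <- df[!duplicated(df$formula), , drop = FALSE]
  df$mass <- vapply(df$formula, monoisotopic_mass, numeric(1))
  stopifnot(all(df$mass > 0))
  rownames(df) <- NULL
  structure(df, class = c("remd_library", "data.frame"))
}
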