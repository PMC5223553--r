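#' Built-in seed formula table for the metabolome simulator
#'
#' A curated table of plausible lung-metabolome formulas spanning four
#' compound classes: glycerophospholipid-like (PA/PE-PC/PG/PS/PI/lyso
#' series), fatty-acid-like (saturated, unsaturated, hydroxy and dicarboxylic
#' acids), sugar/glycolysis-like (sugars, sugar phosphates, TCA/glycolysis
#' intermediates) and amino-acid-like (proteinogenic acids and derivatives),
#' plus nucleotides/cofactors. The table is generated from homologous series
#' at load time; every entry passes the Senior and elemental-ratio checks,
#' lies on the default assignment grid, has its [M-H]- ion inside 129-1000
#' m/z, and is at least 3 ppm in mass from every other entry (closer pairs
#' are dropped deterministically) so that simulated features are uniquely
#' resolvable at the 1 ppm alignment window.
#'
#' @return data.frame: `formula` (canonical Hill string), `class`, `mass`
#'   (neutral monoisotopic, Da), `mz` ([M-H]-).
#' @export
seed_formula_table <- function() {
  rows <- list()
  add <- function(cls, C, H, O = 0, N = 0, S = 0, P = 0) {
    rows[[length(rows) + 1L]] <<- data.frame(
      class = cls, C = C, H = H, O = O, N = N, S = S, P = P,
      stringsAsFactors = FALSE)
  }
  # glycerophospholipids: diacyl series with 0-2 extra double bonds
  for (n in 32:42) add("glycerophospholipid", n, 2 * n - 1, O = 8, P = 1)   # PA
  for (n in 34:42) add("glycerophospholipid", n, 2 * n - 3, O = 8, P = 1)
  for (n in 34:46) add("glycerophospholipid", n, 2 * n, O = 8, N = 1, P = 1) # PE/PC
  for (n in 36:44) add("glycerophospholipid", n, 2 * n - 2, O = 8, N = 1, P = 1)
  for (n in 38:44) add("glycerophospholipid", n, 2 * n - 4, O = 8, N = 1, P = 1)
  for (n in 34:44) add("glycerophospholipid", n, 2 * n - 1, O = 10, P = 1)  # PG
  for (n in 38:48) add("glycerophospholipid", n, 2 * n - 4, O = 10, N = 1, P = 1) # PS
  for (n in 39:49) add("glycerophospholipid", n, 2 * n - 3, O = 13, P = 1)  # PI
  for (n in 18:28) add("glycerophospholipid", n, 2 * n + 2, O = 7, N = 1, P = 1) # LPE/LPC
  for (n in 18:25) add("glycerophospholipid", n, 2 * n + 1, O = 7, P = 1)   # LPA
  # fatty acids
  for (n in 8:34) add("fatty_acid", n, 2 * n, O = 2)
  for (n in 14:24) add("fatty_acid", n, 2 * n - 2, O = 2)
  for (n in 16:24) add("fatty_acid", n, 2 * n - 4, O = 2)
  for (n in 18:24) add("fatty_acid", n, 2 * n - 6, O = 2)
  for (n in 20:24) add("fatty_acid", n, 2 * n - 8, O = 2)
  for (n in c(22, 24)) add("fatty_acid", n, 2 * n - 12, O = 2)
  for (n in 12:30) add("fatty_acid", n, 2 * n, O = 3)       # hydroxy acids
  for (n in 12:22) add("fatty_acid", n, 2 * n - 2, O = 3)   # oxo acids
  for (n in 9:24) add("fatty_acid", n, 2 * n - 2, O = 4)    # dicarboxylic
  for (n in 10:18) add("fatty_acid", n, 2 * n, O = 5)       # hydroxy diacids
  # sugars / glycolysis intermediates
  for (k in 1:5) add("sugar_glycolysis", 6 * k, 10 * k + 2, O = 5 * k + 1) # hexose oligomers
  for (k in 1:4) add("sugar_glycolysis", 5 * k, 8 * k + 2, O = 4 * k + 1)  # pentose oligomers
  add("sugar_glycolysis", 6, 10, O = 8)           # hexaric acid
  add("sugar_glycolysis", 5, 10, O = 6)           # pentonic acid
  add("sugar_glycolysis", 5, 8, O = 7)            # pentaric acid
  add("sugar_glycolysis", 6, 12, O = 5)           # deoxyhexose
  add("sugar_glycolysis", 6, 8, O = 6)            # ascorbate
  add("sugar_glycolysis", 4, 4, O = 5)            # oxaloacetate
  add("sugar_glycolysis", 6, 6, O = 6)            # aconitate
  add("sugar_glycolysis", 7, 10, O = 5)           # shikimate
  add("sugar_glycolysis", 7, 12, O = 6)           # quinate
  add("sugar_glycolysis", 6, 10, O = 6)           # gluconolactone
  add("sugar_glycolysis", 10, 18, O = 9)
  add("sugar_glycolysis", 6, 13, O = 9, P = 1)    # hexose phosphate
  add("sugar_glycolysis", 6, 14, O = 12, P = 2)   # hexose bisphosphate
  add("sugar_glycolysis", 5, 11, O = 8, P = 1)    # pentose phosphate
  add("sugar_glycolysis", 7, 15, O = 10, P = 1)   # heptulose phosphate
  add("sugar_glycolysis", 4, 9, O = 7, P = 1)     # tetrose phosphate
  add("sugar_glycolysis", 3, 7, O = 6, P = 1)     # triose phosphate
  add("sugar_glycolysis", 3, 7, O = 7, P = 1)     # glycerate phosphate
  add("sugar_glycolysis", 3, 5, O = 6, P = 1)     # phosphoenolpyruvate
  add("sugar_glycolysis", 3, 9, O = 6, P = 1)     # glycerol phosphate
  add("sugar_glycolysis", 6, 13, O = 10, P = 1)   # phosphogluconate
  add("sugar_glycolysis", 6, 8, O = 7)            # citrate
  add("sugar_glycolysis", 4, 6, O = 5)            # malate
  add("sugar_glycolysis", 5, 6, O = 5)            # 2-oxoglutarate
  add("sugar_glycolysis", 6, 12, O = 7)           # gluconate
  add("sugar_glycolysis", 6, 14, O = 6); add("sugar_glycolysis", 5, 12, O = 5)
  add("sugar_glycolysis", 12, 24, O = 11)         # maltitol-like
  add("sugar_glycolysis", 6, 13, O = 5, N = 1)    # hexosamine
  add("sugar_glycolysis", 8, 15, O = 6, N = 1)    # N-acetylhexosamine
  add("sugar_glycolysis", 11, 19, O = 9, N = 1)   # sialic acid
  # amino acids and derivatives
  aa <- list(c(6,13,2,1), c(4,8,3,2), c(4,7,4,1), c(5,10,3,2), c(6,14,2,2),
             c(5,9,4,1), c(6,9,2,3), c(9,11,2,1), c(6,14,2,4), c(9,11,3,1),
             c(11,12,2,2))
  for (v in aa) add("amino_acid", v[1], v[2], O = v[3], N = v[4])
  add("amino_acid", 5, 11, O = 2, N = 1, S = 1)   # methionine
  add("amino_acid", 10, 17, O = 6, N = 3, S = 1)  # glutathione
  add("amino_acid", 4, 9, O = 2, N = 3)           # creatine
  add("amino_acid", 7, 15, O = 3, N = 1)          # carnitine
  add("amino_acid", 9, 17, O = 4, N = 1)          # acylcarnitine
  add("amino_acid", 9, 9, O = 3, N = 1)           # hippurate
  add("amino_acid", 10, 12, O = 3, N = 2)         # kynurenine
  add("amino_acid", 6, 13, O = 3, N = 3)          # citrulline
  add("amino_acid", 5, 12, O = 2, N = 2)          # ornithine
  add("amino_acid", 7, 11, O = 2, N = 3)          # methylhistidine
  add("amino_acid", 6, 12, O = 4, N = 2, S = 2)   # cystine
  add("amino_acid", 7, 11, O = 5, N = 1)          # N-acetylglutamate
  add("amino_acid", 6, 9, O = 5, N = 1)           # N-acetylaspartate
  add("amino_acid", 8, 16, O = 3, N = 2)          # Gly-Leu dipeptide
  add("amino_acid", 11, 14, O = 3, N = 2)         # Gly-Phe dipeptide
  add("amino_acid", 7, 12, O = 5, N = 2)          # Gly-Glu dipeptide
  add("amino_acid", 8, 14, O = 5, N = 2, S = 1)   # gamma-Glu-Cys
  add("amino_acid", 5, 10, O = 3, N = 2, S = 1)   # Cys-Gly
  add("amino_acid", 5, 11, O = 3, N = 1, S = 1)   # methionine sulfoxide
  add("amino_acid", 7, 14, O = 4, N = 2, S = 1)   # cystathionine
  add("amino_acid", 14, 20, O = 5, N = 6, S = 1)  # S-adenosylhomocysteine
  add("amino_acid", 4, 9, O = 2, N = 1, S = 1)    # homocysteine
  add("amino_acid", 9, 17, O = 5, N = 1)          # pantothenate
  add("amino_acid", 8, 11, O = 2, N = 1)          # dopamine
  add("amino_acid", 10, 12, O = 1, N = 2)         # serotonin
  add("amino_acid", 10, 12, N = 2)                # tryptamine
  # nucleotides / cofactors
  nt <- list(c(10,14,7,5,0,1), c(10,14,8,5,0,1), c(9,13,9,2,0,1),
             c(9,14,8,3,0,1), c(10,12,5,4,0,0), c(10,13,4,5,0,0),
             c(10,13,5,5,0,0), c(9,12,6,2,0,0), c(21,27,14,7,0,2),
             c(27,33,15,9,0,2), c(10,16,13,5,0,3), c(10,15,10,5,0,2),
             c(15,24,17,2,0,2), c(20,32,12,6,2,0), c(21,36,16,7,1,3),
             c(10,12,6,5,0,1), c(10,12,7,5,0,1), c(10,14,6,5,0,1),
             c(10,15,8,2,0,1), c(10,13,8,4,0,1), c(10,13,9,4,0,1),
             c(10,15,11,5,0,2), c(9,15,15,2,0,3), c(9,16,14,3,0,3),
             c(10,16,14,5,0,3), c(9,14,12,2,0,2), c(17,20,6,4,0,0),
             c(8,10,6,1,0,1), c(17,27,17,3,0,2), c(23,38,17,7,1,3))
  for (v in nt) add("nucleotide", v[1], v[2], O = v[3], N = v[4],
                    S = v[5], P = v[6])

  df <- do.call(rbind, rows)
  counts <- as.matrix(df[, ELEMENT_ORDER])
  el <- element_table()
  mass <- as.vector(counts %*% el$mass[match(ELEMENT_ORDER, el$element)])
  mz <- mz_of_ion(mass)
  ok <- senior_valid_matrix(counts) & ratio_valid_matrix(counts) &
    mz >= 129 & mz <= 1000
  df <- df[ok, , drop = FALSE]; counts <- counts[ok, , drop = FALSE]
  mass <- mass[ok]; mz <- mz[ok]
  formula <- hill_strings(counts)
  dup <- duplicated(formula)
  df <- df[!dup, , drop = FALSE]; mass <- mass[!dup]; mz <- mz[!dup]
  formula <- formula[!dup]
  # enforce >= 3 ppm pairwise mass separation (drop the later entry)
  o <- order(mass)
  drop <- logical(length(mass))
  om <- mass[o]
  too_close <- which(diff(om) / om[-length(om)] * 1e6 < 3)
  drop[o[too_close + 1L]] <- TRUE
  out <- data.frame(formula = formula[!drop], class = df$class[!drop],
                    mass = mass[!drop], mz = mz[!drop],
                    stringsAsFactors = FALSE)
  out[order(out$mass), ]
}

#' Reference m/z list for linear calibration
#'
#' Theoretical [M-H]- m/z values of the seed formula table, playing the role
#' of a reference list of metabolite masses that occur ubiquitously across
#' biological samples.
#'
#' @param formulas optional character vector of formulas; default: the full
#'   seed table.
#' @return Sorted numeric vector of m/z values.
#' @export
calibration_reference <- function(formulas = NULL) {
  if (is.null(formulas)) return(sort(seed_formula_table()$mz))
  sort(mz_of_ion(vapply(formulas, monoisotopic_mass, numeric(1))))
}

#' Simulation configuration
#'
#' Defines the study conditions the simulator emulates: a 4-group design
#' with 3 replicates per group (untreated control, acute infection, latent
#' infection plus particle second hit, particle only), sub-ppm mass error,
#' per-sample linear calibration drift, 13C isotopologue peaks, uniform
#' noise peaks, independent missingness, and planted group effects
#' (glycerophospholipids up and glycolysis-type metabolites down in the
#' acute and second-hit groups).
#'
#' @param seed RNG seed; a fixed seed makes the output byte-identical.
#' @param groups named integer vector: replicates per group.
#' @param n_formulas number of true formulas drawn from the seed table.
#' @param mass_error_ppb standard deviation of the per-peak Gaussian mass
#'   error, in ppb.
#' @param drift_slope_sd,drift_offset_sd per-sample calibration drift: the
#'   observed m/z is `slope * true + offset` with slope ~ 1 +
#'   N(0, drift_slope_sd) and offset ~ N(0, drift_offset_sd) Da.
#' @param noise_peaks uniform-random noise peaks per sample.
#' @param missing_prob independent per-peak per-sample missingness.
#' @param base_meanlog,base_sdlog lognormal base-intensity distribution.
#' @param intensity_sdlog multiplicative lognormal intensity noise (log-sd).
#' @param isotope_sdlog lognormal noise on the isotopologue intensity ratio.
#' @param effect_map data.frame (`class`, `group`, `log2fc`) of planted
#'   effects; `NULL` plants nothing.
#' @param mz_range recorded m/z window.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       groups = c(control = 3L, virus_acute = 3L,
                                  virus_np = 3L, np_only = 3L),
                       n_formulas = 300L,
                       mass_error_ppb = 100,
                       drift_slope_sd = 2e-7,
                       drift_offset_sd = 2e-5,
                       noise_peaks = 150L,
                       missing_prob = 0.1,
                       base_meanlog = log(5e6), base_sdlog = 1,
                       intensity_sdlog = 0.3,
                       isotope_sdlog = 0.05,
                       effect_map = default_effect_map(),
                       mz_range = c(129, 1000)) {
  stopifnot(mz_range[1] < mz_range[2], missing_prob >= 0, missing_prob <= 1,
            mass_error_ppb >= 0, noise_peaks >= 0, all(groups >= 1))
  structure(list(seed = as.integer(seed), groups = groups,
                 n_formulas = as.integer(n_formulas),
                 mass_error_ppb = mass_error_ppb,
                 drift_slope_sd = drift_slope_sd,
                 drift_offset_sd = drift_offset_sd,
                 noise_peaks = as.integer(noise_peaks),
                 missing_prob = missing_prob,
                 base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                 intensity_sdlog = intensity_sdlog,
                 isotope_sdlog = isotope_sdlog,
                 effect_map = effect_map, mz_range = mz_range),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_effect_map <- function() {
  data.frame(
    class = c("glycerophospholipid", "glycerophospholipid",
              "sugar_glycolysis", "sugar_glycolysis"),
    group = c("virus_acute", "virus_np", "virus_acute", "virus_np"),
    log2fc = c(1.5, 1.5, -1, -1),
    stringsAsFactors = FALSE)
}

#' Simulate a ground-truthed multi-sample metabolome
#'
#' For every sample, emits a peak list containing (i) the [M-H]- peak of
#' each non-missing true formula, with Gaussian ppm mass error and the
#' sample's linear drift applied, (ii) its 13C isotopologue at the expected
#' intensity ratio with lognormal noise, and (iii) uniform-random noise
#' peaks whose intensities are drawn from the lower quartile of the true
#' intensity distribution. Group effects act multiplicatively on the class
#' mean intensities per the effect map. The reported S/N is the intensity
#' over a per-sample noise floor derived from the noise-peak intensities,
#' so typical noise peaks sit below the S/N = 4 picking cutoff.
#'
#' @param config a [sim_config()].
#' @param formulas optional user formula table (columns `formula`, `class`)
#'   replacing the built-in seed table.
#' @return A list: `peaklists` (named list of `peak_list`), `truth`
#'   (data.frame: formula, class, mz_theoretical, base_intensity, and one
#'   `intensity.<sample>` column per sample, zero where missing),
#'   `noise_truth` (per-sample noise peak m/z), `samples` (sample/group
#'   table), `config`.
#' @export
simulate_metabolome <- function(config = sim_config(), formulas = NULL) {
  seedtab <- if (is.null(formulas)) seed_formula_table() else {
    data.frame(formula = formulas$formula, class = formulas$class,
               mass = vapply(formulas$formula, monoisotopic_mass, numeric(1)),
               stringsAsFactors = FALSE)
  }
  if (is.null(seedtab$mz)) seedtab$mz <- mz_of_ion(seedtab$mass)
  if (config$n_formulas > nrow(seedtab)) {
    stop("requested ", config$n_formulas, " formulas but the seed table has ",
         nrow(seedtab), "; supply a larger user formula table")
  }
  set.seed(config$seed, kind = "Mersenne-Twister")
  pick <- sort(sample.int(nrow(seedtab), config$n_formulas))
  tab <- seedtab[pick, , drop = FALSE]
  nfl <- nrow(tab)

  samples <- data.frame(
    sample = unlist(lapply(names(config$groups), function(g)
      paste0(g, "_", seq_len(config$groups[[g]])))),
    group = rep(names(config$groups), config$groups),
    stringsAsFactors = FALSE)
  ns <- nrow(samples)

  base <- rlnorm(nfl, config$base_meanlog, config$base_sdlog)
  # planted per-class, per-group multiplicative effects
  shift <- matrix(0, nfl, ns)
  if (!is.null(config$effect_map) && nrow(config$effect_map)) {
    for (k in seq_len(nrow(config$effect_map))) {
      e <- config$effect_map[k, ]
      shift[tab$class == e$class, samples$group == e$group] <- e$log2fc
    }
  }
  iso_ratio <- vapply(tab$formula, function(f)
    expected_isotopologue_ratio(f), numeric(1))
  iso_shift <- isotopologue_shift()

  eps <- config$mass_error_ppb * 1e-9
  intensity_truth <- matrix(0, nfl, ns)
  peaklists <- vector("list", ns)
  noise_truth <- vector("list", ns)
  for (j in seq_len(ns)) {
    slope <- 1 + rnorm(1, 0, config$drift_slope_sd)
    offset <- rnorm(1, 0, config$drift_offset_sd)
    present <- runif(nfl) >= config$missing_prob
    inten <- base * 2^shift[, j] * rlnorm(nfl, 0, config$intensity_sdlog)
    inten[!present] <- 0
    intensity_truth[, j] <- inten

    mono_mz <- tab$mz * (1 + rnorm(nfl, 0, eps))
    iso_mz <- (tab$mz + iso_shift) * (1 + rnorm(nfl, 0, eps))
    iso_int <- inten * iso_ratio * rlnorm(nfl, 0, config$isotope_sdlog)

    q1 <- quantile(inten[present], 0.25, names = FALSE)
    n_noise <- config$noise_peaks
    noise_mz <- runif(n_noise, config$mz_range[1], config$mz_range[2])
    noise_int <- rlnorm(n_noise, log(max(q1, 1)) - 1, 0.8)
    noise_truth[[j]] <- noise_mz

    mzs <- c(mono_mz[present], iso_mz[present], noise_mz)
    ints <- c(inten[present], iso_int[present], noise_int)
    obs <- slope * mzs + offset
    keep <- obs >= config$mz_range[1] & obs <= config$mz_range[2]
    floor_j <- stats::median(noise_int) / 3
    sn <- ints / floor_j
    peaklists[[j]] <- peak_list(obs[keep], ints[keep], sn = sn[keep],
                                sample = samples$sample[j])
  }
  names(peaklists) <- samples$sample
  truth <- data.frame(formula = tab$formula, class = tab$class,
                      mz_theoretical = tab$mz, base_intensity = base,
                      stringsAsFactors = FALSE)
  it <- as.data.frame(intensity_truth)
  names(it) <- paste0("intensity.", samples$sample)
  truth <- cbind(truth, it)
  names(noise_truth) <- samples$sample
  list(peaklists = peaklists, truth = truth, noise_truth = noise_truth,
       samples = samples, config = config)
}

#' Write simulator output to a directory
#'
#' One plain-text peak list per sample (m/z, intensity, S/N), the ground
#' truth as a tab-separated table, and the sample/group map.
#'
#' @param sim result of [simulate_metabolome()].
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(sim$peaklists)) {
    write_peak_list(sim$peaklists[[nm]], file.path(dir, paste0(nm, ".txt")))
  }
  utils::write.table(sim$truth, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
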