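#' Element-count grid for combinatorial formula assignment
#'
#' Per-element minimum and maximum counts searched during combinatorial
#' assignment. Defaults follow the standard biomolecule search space
#' C1-100, H0-200, O0-70, N0-20, S0-3, P0-3 (the grid omits a published H
#' range; 0-200 covers every formula the other bounds admit below 1000 Da).
#'
#' @param C,H,O,N,S,P length-2 integer vectors `c(min, max)`.
#' @return A list of class `element_grid`.
#' @export
element_grid <- function(C = c(1L, 100L), H = c(0L, 200L), O = c(0L, 70L),
                         N = c(0L, 20L), S = c(0L, 3L), P = c(0L, 3L)) {
  g <- list(C = C, H = H, O = O, N = N, S = S, P = P)
  for (el in names(g)) {
    if (length(g[[el]]) != 2 || g[[el]][1] > g[[el]][2] || g[[el]][1] < 0)
      stop("invalid grid range for ", el)
  }
  if (g$C[1] < 1) stop("grid must require at least one carbon")
  structure(g, class = "element_grid")
}

# vectorized Senior check on a counts matrix (columns C,H,O,N,S,P);
# must agree with the scalar senior_check() — covered by tests
senior_valid_matrix <- function(counts, elements = element_table()) {
  val <- elements$valence[match(colnames(counts), elements$element)]
  dbe <- 1 + as.vector(counts %*% (val - 2)) / 2
  vsum <- as.vector(counts %*% val)
  dbe >= 0 & dbe == round(dbe) & vsum %% 2 == 0
}

# vectorized elemental-ratio check on a counts matrix
ratio_valid_matrix <- function(counts, bounds = ratio_bounds()) {
  C <- counts[, "C"]
  hc <- counts[, "H"] / C
  hc >= bounds$hc_min & hc <= bounds$hc_max &
    counts[, "O"] / C <= bounds$oc_max &
    counts[, "N"] / C <= bounds$nc_max &
    counts[, "S"] / C <= bounds$sc_max &
    counts[, "P"] / C <= bounds$pc_max &
    counts[, "O"] >= bounds$o_per_p_min * counts[, "P"] &
    (counts[, "N"] <= bounds$n_needs_o_above |
       counts[, "O"] >= counts[, "N"])
}

hill_strings <- function(counts) {
  # counts: matrix with columns C,H,O,N,S,P -> Hill-order strings
  out <- character(nrow(counts))
  for (el in c("C", "H", "N", "O", "P", "S")) {
    k <- counts[, el]
    out <- paste0(out, ifelse(k == 0, "",
                              paste0(el, ifelse(k == 1, "", k))))
  }
  out
}

#' Combinatorial molecular-formula candidates for a neutral mass
#'
#' Enumerates every formula on the element grid whose monoisotopic mass lies
#' within `tol` ppm of `mass` and which passes the Senior-rule and
#' elemental-ratio checks. The search runs nested loops over S, P, N with
#' cumulative-mass pruning; for each branch the O x C plane is evaluated as
#' a matrix and the hydrogen count is solved from the mass residual (the
#' tolerance is orders of magnitude below one hydrogen mass, so at most one
#' H count can match per branch point).
#'
#' @param mass neutral monoisotopic mass in Da.
#' @param tol assignment tolerance in ppm (default 0.5).
#' @param grid an [element_grid()].
#' @param bounds a [ratio_bounds()].
#' @param elements an [element_table()].
#' @return A data.frame sorted by |ppm error|: columns `formula`, `mass`,
#'   `ppm`, and the element counts `C`, `H`, `O`, `N`, `S`, `P`. Zero rows
#'   is a valid result.
#' @examples
#' enumerate_candidates(256.240230)  # palmitic acid -> C16H32O2
#' @export
enumerate_candidates <- function(mass, tol = 0.5, grid = element_grid(),
                                 bounds = ratio_bounds(),
                                 elements = element_table()) {
  stopifnot(length(mass) == 1, mass > 0, tol > 0)
  em <- setNames(elements$mass, elements$element)
  tol_da <- tol * mass / 1e6
  upper <- mass + tol_da
  floor_mass <- grid$C[1] * em["C"] + grid$H[1] * em["H"]

  acc <- vector("list", 64L); n_acc <- 0L
  for (s in grid$S[1]:grid$S[2]) {
    base_s <- s * em["S"]
    if (base_s + floor_mass > upper) break
    for (p in grid$P[1]:grid$P[2]) {
      base_p <- base_s + p * em["P"]
      if (base_p + floor_mass > upper) break
      for (nn in grid$N[1]:grid$N[2]) {
        base_n <- base_p + nn * em["N"]
        if (base_n + floor_mass > upper) break
        o_hi <- min(grid$O[2], floor((upper - base_n - floor_mass) / em["O"]))
        if (o_hi < grid$O[1]) next
        o <- grid$O[1]:o_hi
        c_hi <- min(grid$C[2], floor((upper - base_n) / em["C"]))
        if (c_hi < grid$C[1]) next
        cc <- grid$C[1]:c_hi
        base_oc <- outer(o * em["O"], cc * em["C"], "+") + base_n
        rem <- mass - base_oc
        h <- round(rem / em["H"])
        total <- base_oc + h * em["H"]
        ok <- h >= grid$H[1] & h <= grid$H[2] & abs(total - mass) <= tol_da
        if (any(ok)) {
          idx <- which(ok, arr.ind = TRUE)
          n_acc <- n_acc + 1L
          if (n_acc > length(acc)) acc <- c(acc, vector("list", length(acc)))
          acc[[n_acc]] <- cbind(C = cc[idx[, 2]], H = h[ok], O = o[idx[, 1]],
                                N = nn, S = s, P = p,
                                mass = total[ok])
        }
      }
    }
  }
  if (n_acc == 0L) {
    return(data.frame(formula = character(0), mass = numeric(0),
                      ppm = numeric(0), C = integer(0), H = integer(0),
                      O = integer(0), N = integer(0), S = integer(0),
                      P = integer(0)))
  }
  hits <- do.call(rbind, acc[seq_len(n_acc)])
  counts <- hits[, ELEMENT_ORDER, drop = FALSE]
  keep <- senior_valid_matrix(counts, elements) &
    ratio_valid_matrix(counts, bounds)
  counts <- counts[keep, , drop = FALSE]
  masses <- hits[keep, "mass"]
  ppm <- ppm_error(rep(mass, length(masses)), masses)
  o <- order(abs(ppm))
  data.frame(formula = hill_strings(counts)[o], mass = masses[o],
             ppm = ppm[o],
             as.data.frame(counts[o, , drop = FALSE]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Dataset noise level
#'
#' The intensity below which an isotopologue pattern is considered
#' unobservable: the minimum over samples of each sample's maximum feature
#' intensity.
#'
#' @param m a [feature_matrix()].
#' @return Intensity scalar.
#' @export
noise_level <- function(m) {
  stopifnot(length(m$mz) > 0)
  min(apply(m$intensity, 2, max))
}

#' 13C isotopologue verification of a candidate formula
#'
#' For a candidate formula on a monoisotopic feature, the expected M+1 peak
#' sits one 13C-12C mass shift above the feature m/z with intensity
#' `parent * expected_isotopologue_ratio(formula)`. If that expected
#' intensity never exceeds the dataset noise level, the pattern is
#' unobservable and the candidate is accepted by default. Otherwise a
#' feature must exist within `window` ppm of the expected position whose
#' intensity is within `rel_tol` of the expectation in at least one sample
#' where the parent was detected.
#'
#' @param feature index of the parent feature in `m`.
#' @param counts named count vector of the candidate formula.
#' @param m a [feature_matrix()].
#' @param noise dataset noise level (see [noise_level()]).
#' @param rel_tol relative intensity tolerance in (0, 1].
#' @param window m/z match window in ppm.
#' @param elements an [element_table()].
#' @param detail return the match diagnostics instead of a logical.
#' @return Logical (validated or not); with `detail = TRUE` a list:
#'   `ok`, `observable` (pattern expected above noise), `n_obs` (samples
#'   with a measured ratio), `mean_log_rel` (mean log observed/expected
#'   ratio, 0 when unobservable).
#' @export
isotope_verify <- function(feature, counts, m, noise, rel_tol = 0.5,
                           window = 1, elements = element_table(),
                           detail = FALSE) {
  stopifnot(rel_tol > 0, rel_tol <= 1)
  ratio <- counts[["C"]] * elements$iso_ratio[elements$element == "C"]
  parent <- m$intensity[feature, ]
  expected <- parent * ratio
  observable <- max(expected) > noise
  iso_mz <- m$mz[feature] + isotopologue_shift(elements)
  cand <- setdiff(which(abs(ppm_error(m$mz, iso_mz)) <= window), feature)
  # measured ratio diagnostics: any sample where the parent and a matching
  # M+1 feature were both detected, regardless of the noise threshold
  best <- list(n_obs = 0L, mean_log_rel = 0, within = FALSE,
               iso_feature = NA_integer_)
  for (j in cand) {
    obs <- m$intensity[j, ]
    use <- parent > 0 & obs > 0
    if (!any(use)) next
    rel <- obs[use] / expected[use]
    mlr <- mean(log(rel))
    if (best$n_obs == 0L || abs(mlr) < abs(best$mean_log_rel)) {
      best <- list(n_obs = sum(use), mean_log_rel = mlr,
                   within = any(rel >= 1 - rel_tol & rel <= 1 + rel_tol),
                   iso_feature = j)
    }
  }
  # acceptance: an unobservable pattern validates by default; an observable
  # one requires a measured ratio within the relative tolerance
  ok <- if (!observable) TRUE else best$n_obs > 0L && best$within
  if (detail) {
    list(ok = ok, observable = observable, n_obs = best$n_obs,
         mean_log_rel = best$mean_log_rel, iso_feature = best$iso_feature)
  } else ok
}

#' Network propagation of formulas to unassigned features
#'
#' Breadth-first expansion from the validated formulas: for every frontier
#' formula and every reaction-equivalent mass difference (REMD), the target
#' masses `mass(f) +/- mass(remd)` are searched among still-unassigned
#' features; a match within `tol` ppm acquires the formula `f +/- remd`
#' provided it stays on the element grid and passes the Senior and ratio
#' checks. Conflicting proposals for one feature are resolved by smallest
#' |ppm error|, then shortest propagation depth, then lexicographically
#' smallest formula. Newly assigned features join the next frontier, up to
#' `max_depth` levels.
#'
#' @param seeds data.frame with columns `feature` (index) and `formula`
#'   (Hill string) for the validated starting points.
#' @param m a [feature_matrix()].
#' @param remds an REMD library (see [load_remds()]).
#' @param tol propagation tolerance in ppm; defaults to the assignment
#'   tolerance (propagation asserts chemistry, not alignment identity).
#' @param grid an [element_grid()].
#' @param bounds a [ratio_bounds()].
#' @param max_depth maximum number of expansion levels.
#' @param exclude feature indices never to assign (e.g. recognized
#'   isotopologue peaks).
#' @param elements an [element_table()].
#' @return data.frame: `feature`, `formula`, `ppm`, `depth`, `seed_feature`,
#'   `remd` for every newly assigned feature.
#' @export
propagate_network <- function(seeds, m, remds = load_remds(), tol = 0.5,
                              grid = element_grid(), bounds = ratio_bounds(),
                              max_depth = 10, exclude = integer(0),
                              elements = element_table()) {
  stopifnot(nrow(seeds) >= 1)
  implied <- neutral_mass(m$mz)
  assigned <- rep(FALSE, length(m$mz))
  assigned[seeds$feature] <- TRUE
  assigned[exclude] <- TRUE
  frontier <- data.frame(feature = seeds$feature, formula = seeds$formula,
                         stringsAsFactors = FALSE)
  out <- list()
  depth <- 0L
  while (nrow(frontier) > 0 && depth < max_depth && nrow(remds) > 0) {
    depth <- depth + 1L
    proposals <- list()
    for (k in seq_len(nrow(frontier))) {
      f_counts <- as_formula_counts(frontier$formula[k])
      f_mass <- monoisotopic_mass(frontier$formula[k], elements)
      for (r in seq_len(nrow(remds))) {
        d_counts <- as_formula_counts(remds$formula[r])
        for (sgn in c(1, -1)) {
          target <- f_mass + sgn * remds$mass[r]
          if (target <= 0) next
          hits <- which(!assigned &
                          abs(ppm_error(implied, target)) <= tol)
          if (!length(hits)) next
          new_counts <- f_counts + sgn * d_counts
          if (any(new_counts < 0)) next
          on_grid <- all(vapply(ELEMENT_ORDER, function(el) {
            new_counts[[el]] >= grid[[el]][1] && new_counts[[el]] <= grid[[el]][2]
          }, logical(1)))
          if (!on_grid) next
          if (!senior_check(elemental_formula(counts = new_counts),
                            elements)$valid) next
          if (!ratio_check(elemental_formula(counts = new_counts), bounds)) next
          new_mass <- monoisotopic_mass(elemental_formula(counts = new_counts),
                                        elements)
          for (h in hits) {
            proposals[[length(proposals) + 1L]] <- data.frame(
              feature = h,
              formula = write_formula(elemental_formula(counts = new_counts)),
              ppm = ppm_error(implied[h], new_mass),
              depth = depth, seed_feature = frontier$feature[k],
              remd = remds$name[r], stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (!length(proposals)) break
    prop <- do.call(rbind, proposals)
    prop <- prop[abs(prop$ppm) <= tol, , drop = FALSE]
    if (!nrow(prop)) break
    # resolve conflicts: |ppm|, then depth (equal within a level), then formula
    prop <- prop[order(prop$feature, abs(prop$ppm), prop$formula), ,
                 drop = FALSE]
    prop <- prop[!duplicated(prop$feature), , drop = FALSE]
    assigned[prop$feature] <- TRUE
    out[[depth]] <- prop
    frontier <- prop[, c("feature", "formula")]
  }
  if (!length(out)) {
    return(data.frame(feature = integer(0), formula = character(0),
                      ppm = numeric(0), depth = integer(0),
                      seed_feature = integer(0), remd = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate a feature matrix with molecular formulas
#'
#' Runs the full assignment cascade in three stages.
#'
#' Stage 1 (isotope-confirmed): for every feature with a measured M+1
#' isotopologue, the compatible candidate (see [isotope_verify()])
#' minimizing the joint score
#' `(ppm / mass_sigma_ppm)^2 + n_obs * (mean_log_rel / iso_sigma_log)^2`
#' is accepted (`validated-isotope`). The isotopologue term is what
#' separates near-isobaric grid formulas with different carbon counts; the
#' scales are the typical mass accuracy (0.1 ppm = 100 ppb) and
#' isotopologue-ratio repeatability (5%) of ultrahigh-resolution spectra.
#'
#' Stage 2 (network): the confirmed formulas seed breadth-first REMD
#' propagation ([propagate_network()]) over the remaining features — the
#' low-abundance majority whose isotopologue pattern is unobservable —
#' imposing biochemical consistency where isotope evidence is missing
#' (`validated-network`).
#'
#' Stage 3 (default): features the network never reaches fall back to their
#' best mass-only candidate, accepted by default when the expected pattern
#' lies below the noise level (`validated-isotope`); features whose pattern
#' should have been visible but is absent, and features without candidates,
#' stay `unassigned`.
#'
#' @param m a [feature_matrix()].
#' @param tol assignment tolerance in ppm.
#' @param grid,bounds,elements search space and validity configuration.
#' @param rel_tol isotopologue intensity tolerance (see [isotope_verify()]).
#' @param mass_sigma_ppm,iso_sigma_log scoring scales (see above).
#' @param remds REMD library for propagation; `NULL` disables propagation.
#' @param max_depth propagation depth limit.
#' @return An assignment object (list): `assignments` — data.frame with one
#'   row per feature (`feature`, `mz`, `formula`, `ppm`, `status`,
#'   `provenance`, `seed_feature`, `remd`); `summary` — named counts;
#'   `noise` — the noise level used.
#' @export
assign_formulas <- function(m, tol = 0.5, grid = element_grid(),
                            bounds = ratio_bounds(), rel_tol = 0.5,
                            mass_sigma_ppm = 0.1, iso_sigma_log = 0.05,
                            remds = load_remds(), max_depth = 10,
                            elements = element_table()) {
  nf <- length(m$mz)
  noise <- noise_level(m)
  formula <- rep(NA_character_, nf)
  ppm <- rep(NA_real_, nf)
  status <- rep("unassigned", nf)
  provenance <- rep(NA_character_, nf)
  seed_feature <- rep(NA_integer_, nf)
  remd_used <- rep(NA_character_, nf)
  n_candidates <- 0L

  # stage 1: enumerate everywhere; confirm where isotope evidence exists
  deferred <- vector("list", nf)   # fallback candidate per evidence-less feature
  iso_partner <- rep(NA_integer_, nf)
  for (i in seq_len(nf)) {
    cand <- enumerate_candidates(neutral_mass(m$mz[i]), tol = tol,
                                 grid = grid, bounds = bounds,
                                 elements = elements)
    n_candidates <- n_candidates + nrow(cand)
    if (!nrow(cand)) next
    best_score <- Inf
    best <- NULL
    has_evidence <- FALSE
    for (k in seq_len(nrow(cand))) {
      counts <- setNames(as.numeric(cand[k, ELEMENT_ORDER]), ELEMENT_ORDER)
      iso <- isotope_verify(i, counts, m, noise, rel_tol = rel_tol,
                            elements = elements, detail = TRUE)
      if (iso$n_obs > 0) has_evidence <- TRUE
      if (!iso$ok) next
      score <- (cand$ppm[k] / mass_sigma_ppm)^2 +
        iso$n_obs * (iso$mean_log_rel / iso_sigma_log)^2
      if (score < best_score) {
        best_score <- score
        best <- list(formula = cand$formula[k], ppm = cand$ppm[k],
                     iso_feature = iso$iso_feature)
      }
    }
    if (is.null(best)) next                   # all candidates rejected
    if (has_evidence) {
      formula[i] <- best$formula
      ppm[i] <- best$ppm
      status[i] <- "validated-isotope"
      provenance[i] <- "combinatorial"
      iso_partner[i] <- best$iso_feature
    } else {
      deferred[[i]] <- best                   # wait for network consistency
    }
  }

  # de-isotoping: the M+1 partner of a confirmed formula is an isotopologue
  # peak, not a metabolite; it receives no formula of its own
  iso_peaks <- unique(iso_partner[!is.na(iso_partner)])
  iso_peaks <- iso_peaks[status[iso_peaks] != "validated-isotope"]
  if (length(iso_peaks)) {
    status[iso_peaks] <- "isotopologue"
    deferred[iso_peaks] <- list(NULL)
  }

  confirmed <- which(status == "validated-isotope")
  if (!is.null(remds) && length(confirmed) &&
      any(status == "unassigned")) {
    seeds <- data.frame(feature = confirmed,
                        formula = formula[confirmed],
                        stringsAsFactors = FALSE)
    prop <- propagate_network(seeds, m, remds = remds, tol = tol,
                              grid = grid, bounds = bounds,
                              max_depth = max_depth,
                              exclude = which(status == "isotopologue"),
                              elements = elements)
    if (nrow(prop)) {
      formula[prop$feature] <- prop$formula
      ppm[prop$feature] <- prop$ppm
      status[prop$feature] <- "validated-network"
      provenance[prop$feature] <- "propagated"
      seed_feature[prop$feature] <- prop$seed_feature
      remd_used[prop$feature] <- prop$remd
    }
  }

  # stage 3: evidence-less features the network never reached fall back to
  # their best mass-only candidate (default validation, pattern unobservable)
  for (i in seq_len(nf)) {
    if (status[i] == "unassigned" && !is.null(deferred[[i]])) {
      formula[i] <- deferred[[i]]$formula
      ppm[i] <- deferred[[i]]$ppm
      status[i] <- "validated-isotope"
      provenance[i] <- "combinatorial"
    }
  }

  records <- data.frame(feature = seq_len(nf), mz = m$mz, formula = formula,
                        ppm = ppm, status = status, provenance = provenance,
                        seed_feature = seed_feature, remd = remd_used,
                        stringsAsFactors = FALSE)
  finalize_assignments(records, n_candidates = n_candidates, noise = noise)
}

#' Finalize an assignment table
#'
#' Checks internal consistency (exactly one accepted formula per feature)
#' and attaches summary counts: features in, candidate formulas considered,
#' isotope-validated, network-propagated, unassigned.
#'
#' @param records per-feature assignment data.frame (see [assign_formulas()]).
#' @param n_candidates total candidate formulas enumerated.
#' @param noise noise level used for isotope verification.
#' @return List with `assignments`, `summary`, `noise`.
#' @export
finalize_assignments <- function(records, n_candidates = NA_integer_,
                                 noise = NA_real_) {
  if (anyDuplicated(records$feature))
    stop("internal consistency error: multiple accepted formulas per feature")
  smry <- c(features = nrow(records),
            candidates = n_candidates,
            isotope_validated = sum(records$status == "validated-isotope"),
            network_propagated = sum(records$status == "validated-network"),
            isotopologue = sum(records$status == "isotopologue"),
            unassigned = sum(records$status == "unassigned"))
  if (smry[["isotope_validated"]] + smry[["network_propagated"]] +
      smry[["isotopologue"]] + smry[["unassigned"]] != smry[["features"]])
    stop("internal consistency error: status counts do not sum to features")
  structure(list(assignments = records, summary = smry, noise = noise),
            class = "formula_assignments")
}

#' @export
print.formula_assignments <- function(x, ...) {
  s <- x$summary
  cat("<formula_assignments> ", s[["features"]], " features: ",
      s[["isotope_validated"]], " isotope-validated, ",
      s[["network_propagated"]], " network-propagated, ",
      s[["unassigned"]], " unassigned\n", sep = "")
  invisible(x)
}

#' Write an assignment table as tab-separated text
#'
#' Columns: feature m/z, formula (Hill, empty if unassigned), ppm error,
#' status, provenance.
#' @param a a `formula_assignments` object.
#' @param path output file.
#' @export
write_assignments <- function(a, path) {
  df <- a$assignments
  df$formula[is.na(df$formula)] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
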