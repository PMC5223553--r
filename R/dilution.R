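#' Limiting-dilution series
#'
#' One row per dilution step of a limiting-dilution reactivation assay:
#' cells plated per well, wells plated, wells scored positive for cytopathic
#' effect. The default plate design is serial threefold dilutions starting
#' at 1000 cells/well with 24 wells per dilution.
#'
#' @param cells_per_well positive cell numbers, strictly decreasing.
#' @param wells wells plated per dilution.
#' @param positives CPE-positive wells per dilution (0 <= positives <= wells).
#' @return data.frame of class `dilution_series`.
#' @export
dilution_series <- function(cells_per_well, wells, positives) {
  stopifnot(all(cells_per_well > 0), all(wells >= 1),
            all(positives >= 0), all(positives <= wells),
            length(cells_per_well) == length(wells),
            length(wells) == length(positives))
  if (is.unsorted(rev(cells_per_well), strictly = TRUE))
    stop("cells_per_well must be strictly decreasing")
  structure(data.frame(cells_per_well = cells_per_well, wells = wells,
                       positives = positives),
            class = c("dilution_series", "data.frame"))
}

#' @rdname dilution_series
#' @param n_dilutions number of threefold dilution steps.
#' @param top_dose cells per well at the highest dose.
#' @param f true frequency of virus-producing cells, for simulation.
#' @return `simulate_dilution_series()`: a `dilution_series` with positives
#'   drawn from the single-hit Poisson model
#'   P(positive) = 1 - exp(-f * cells).
#' @export
simulate_dilution_series <- function(f, top_dose = 1000, n_dilutions = 8,
                                     wells = 24) {
  cells <- top_dose / 3^(seq_len(n_dilutions) - 1)
  p <- 1 - exp(-f * cells)
  dilution_series(cells, rep(wells, n_dilutions),
                  rbinom(n_dilutions, wells, p))
}

# single-hit Poisson log-likelihood of frequency f
single_hit_loglik <- function(f, s) {
  mu <- f * s$cells_per_well
  p <- -expm1(-mu)
  sum(ifelse(s$positives > 0, s$positives * log(pmax(p, 1e-300)), 0) -
        (s$wells - s$positives) * mu)
}

# profile-likelihood 95% CI around the MLE; chi-square(1) cutoff 3.84
profile_ci <- function(s, f_mle, ll_max, level_cut = stats::qchisq(0.95, 1)) {
  g <- function(f) 2 * (ll_max - single_hit_loglik(f, s)) - level_cut
  rtol <- max(.Machine$double.eps, f_mle * 1e-9)
  lo <- if (f_mle <= 1e-12 || g(1e-12) < 0) 0 else {
    stats::uniroot(g, c(1e-12, f_mle), tol = rtol)$root
  }
  hi <- if (f_mle >= 1 || g(1) < 0) 1 else {
    stats::uniroot(g, c(f_mle, 1), tol = rtol)$root
  }
  c(lo, hi)
}

finish_estimate <- function(f, method, s, flag = "ok") {
  f <- min(max(f, 0), 1)
  mle <- ld_mle_point(s)
  ci <- profile_ci(s, mle$f, mle$ll)
  ci <- range(c(ci, f))   # CI always contains the point estimate
  structure(list(f = f, method = method, ci = ci, flag = flag),
            class = "frequency_estimate")
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat(sprintf("<frequency_estimate> f = %.4g (1 in %.1f cells), %s [%s], 95%% CI %.4g-%.4g\n",
              x$f, ifelse(x$f > 0, 1 / x$f, Inf), x$method, x$flag,
              x$ci[1], x$ci[2]))
  invisible(x)
}

#' Limiting-dilution frequency via the 63.2% crossing
#'
#' Under the single-hit Poisson model, a well is positive with probability
#' 1 - exp(-f * c); at the cell number c* where 63.2% (= 1 - 1/e) of wells
#' are positive, f * c* = 1, so f = 1/c*. The crossing is located by linear
#' interpolation of the complementary-log-log-transformed positive fractions
#' against log cell number (the scale on which the model is exactly linear
#' with slope 1). Dilutions with 0% or 100% positives carry no interpolation
#' information and are excluded; a single informative dilution yields the
#' closed form f = -log(1 - p)/c.
#'
#' @param s a [dilution_series()].
#' @return A `frequency_estimate`: `f`, `method`, 95% `ci` (profile
#'   likelihood under the same Poisson model), `flag` ("ok",
#'   "all-negative" = zero estimate with one-sided CI, "all-positive" =
#'   lower-bound-only).
#' @export
ld_frequency_crossing <- function(s) {
  p <- s$positives / s$wells
  usable <- p > 0 & p < 1
  if (all(s$positives == 0)) {
    return(finish_estimate(0, "crossing", s, flag = "all-negative"))
  }
  if (all(s$positives == s$wells)) {
    # every dose saturated: only a lower bound is identified
    return(finish_estimate(1 / min(s$cells_per_well), "crossing", s,
                           flag = "all-positive"))
  }
  if (sum(usable) == 1) {
    f <- -log(1 - p[usable]) / s$cells_per_well[usable]
    return(finish_estimate(f, "crossing", s))
  }
  x <- log(s$cells_per_well[usable])
  y <- log(-log(1 - p[usable]))      # model: y = log f + x, crossing at y = 0
  o <- order(x)
  x <- x[o]; y <- y[o]
  if (any(y <= 0) && any(y >= 0)) {
    i <- max(which(y <= 0))
    j <- min(which(y >= 0))
    if (i == j) {
      xstar <- x[i]
    } else {
      xstar <- x[i] + (0 - y[i]) * (x[j] - x[i]) / (y[j] - y[i])
    }
  } else {
    # no bracket: extrapolate from the two points nearest the crossing
    k <- order(abs(y))[1:2]
    k <- sort(k)
    sl <- (y[k[2]] - y[k[1]]) / (x[k[2]] - x[k[1]])
    xstar <- x[k[1]] - y[k[1]] / sl
  }
  finish_estimate(1 / exp(xstar), "crossing", s)
}

ld_mle_point <- function(s) {
  if (all(s$positives == 0)) return(list(f = 0, ll = 0, flag = "all-negative"))
  opt <- stats::optimize(function(lf) single_hit_loglik(exp(lf), s),
                         interval = c(log(1e-9), log(1)), maximum = TRUE,
                         tol = 1e-10)
  flag <- if (all(s$positives == s$wells)) "all-positive" else "ok"
  list(f = exp(opt$maximum), ll = opt$objective, flag = flag)
}

#' Limiting-dilution frequency by maximum likelihood
#'
#' Maximizes the single-hit binomial log-likelihood
#' sum_d [ k_d log(1 - e^(-f c_d)) - (n_d - k_d) f c_d ] over f by a
#' one-dimensional bounded search on the log scale, with a 95% profile
#' likelihood CI (chi-square(1) cutoff 3.84).
#'
#' @param s a [dilution_series()].
#' @return A `frequency_estimate` (see [ld_frequency_crossing()]).
#' @export
ld_frequency_mle <- function(s) {
  m <- ld_mle_point(s)
  finish_estimate(m$f, "mle", s, flag = m$flag)
}

#' Genomic-load-normalized relative reactivation frequency
#'
#' Expresses a reactivation frequency relative to an untreated control after
#' correcting both for viral genomic load:
#' `(f / genomic_load) / (control_f / control_load)`. The control against
#' itself is exactly 1.
#'
#' @param f,genomic_load treated-condition frequency and genomic load.
#' @param control_f,control_load untreated-control frequency and load.
#' @return Relative value (unitless).
#' @export
normalize_reactivation <- function(f, genomic_load, control_f, control_load) {
  stopifnot(f >= 0, genomic_load > 0, control_f > 0, control_load > 0)
  (f / genomic_load) / (control_f / control_load)
}
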