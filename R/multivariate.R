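#' Feature-wise Z-transformation
#'
#' Scales every feature (row) to mean 0 and unit sample standard deviation
#' (n-1 denominator). Zero-variance features cannot be scaled and are
#' dropped with a warning.
#'
#' @param m a [feature_matrix()] with at least 2 samples.
#' @return The scaled `feature_matrix` (intensities may be negative).
#' @export
ztransform <- function(m) {
  if (ncol(m$intensity) < 2) stop("Z-transformation needs at least 2 samples")
  mu <- rowMeans(m$intensity)
  s <- apply(m$intensity, 1, stats::sd)
  keep <- s > 0
  if (!all(keep)) {
    warning("dropped ", sum(!keep), " zero-variance feature(s)")
  }
  z <- (m$intensity[keep, , drop = FALSE] - mu[keep]) / s[keep]
  structure(list(mz = m$mz[keep], intensity = z, samples = m$samples),
            class = "feature_matrix")
}

#' Principal component analysis of a feature matrix
#'
#' Deterministic PCA via singular value decomposition of the column-centered
#' samples x features matrix. Scores are the sample projections, loadings
#' the feature weights, and the explained variance fractions come from the
#' squared singular values. The sign of each component is fixed by making
#' its largest-magnitude loading positive.
#'
#' @param m a [feature_matrix()] (typically Z-transformed) with >= 2 samples.
#' @return A list of class `pca_result`: `scores` (samples x components),
#'   `loadings` (features x components), `explained` (variance fractions),
#'   `mz`, `samples`.
#' @export
pca_features <- function(m) {
  x <- t(m$intensity)                      # samples x features
  if (nrow(x) < 2) stop("PCA needs at least 2 samples")
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  ncomp <- sum(sv$d > max(sv$d) * 1e-12)
  d <- sv$d[seq_len(ncomp)]
  u <- sv$u[, seq_len(ncomp), drop = FALSE]
  v <- sv$v[, seq_len(ncomp), drop = FALSE]
  # sign convention: largest-|loading| per component made positive
  for (k in seq_len(ncomp)) {
    i <- which.max(abs(v[, k]))
    if (v[i, k] < 0) { v[, k] <- -v[, k]; u[, k] <- -u[, k] }
  }
  scores <- u %*% diag(d, ncomp)
  dimnames(scores) <- list(m$samples$sample, paste0("PC", seq_len(ncomp)))
  dimnames(v) <- list(NULL, paste0("PC", seq_len(ncomp)))
  structure(list(scores = scores, loadings = v,
                 explained = d^2 / sum(sv$d^2), mz = m$mz,
                 samples = m$samples),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", ncol(x$scores), " components; explained: ",
      paste(sprintf("%.1f%%", 100 * x$explained[seq_len(min(3, ncol(x$scores)))]),
            collapse = ", "), " ...\n", sep = "")
  invisible(x)
}

#' Group tests on principal component scores
#'
#' Two-sided two-sample Student t-tests (equal variance by default; Welch
#' behind `var_equal = FALSE`) on the scores of the first `components`
#' principal components, for every pair of groups.
#'
#' @param r a [pca_features()] result.
#' @param components which components to test (default first three).
#' @param var_equal equal-variance Student test (default) or Welch.
#' @return data.frame: `component`, `group1`, `group2`, `t`, `p`.
#' @export
score_group_test <- function(r, components = 1:3, var_equal = TRUE) {
  components <- components[components <= ncol(r$scores)]
  grp <- r$samples$group
  gs <- unique(grp)
  sizes <- table(grp)
  if (any(sizes < 2)) stop("every group needs at least 2 samples")
  pairs <- utils::combn(gs, 2, simplify = FALSE)
  out <- list()
  for (k in components) {
    for (pr in pairs) {
      a <- r$scores[grp == pr[1], k]
      b <- r$scores[grp == pr[2], k]
      tt <- stats::t.test(a, b, var.equal = var_equal)
      out[[length(out) + 1L]] <- data.frame(
        component = paste0("PC", k), group1 = pr[1], group2 = pr[2],
        t = unname(tt$statistic), p = tt$p.value, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Correlation between two PC loading vectors
#'
#' Pearson correlation over the shared features of two loading vectors,
#' with p-value from the t-distribution on n-2 degrees of freedom. Because
#' the sign of a principal component is arbitrary, the orientation of `b`
#' maximizing |r| is reported and the flip is flagged.
#'
#' @param a,b named numeric loading vectors (names identify features, e.g.
#'   formula strings or formatted m/z).
#' @return List: `r` (non-negative by orientation choice), `p`, `n`,
#'   `flipped`.
#' @export
loading_correlation <- function(a, b) {
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3) stop("fewer than 3 shared features")
  x <- a[shared]; y <- b[shared]
  r <- stats::cor(x, y)
  flipped <- r < 0
  r_rep <- abs(r)
  n <- length(shared)
  tstat <- r_rep * sqrt((n - 2) / max(1 - r_rep^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(r = r_rep, p = p, n = n, flipped = flipped)
}

#' Assemble second-hit comparison datasets
#'
#' For each second-hit exposure group, forms the dataset {second-hit group,
#' time-matched controls, acute infection group} on which scaling and PCA
#' are run separately.
#'
#' @param m a [feature_matrix()].
#' @param second_hits character vector of second-hit group names.
#' @param control control group name.
#' @param acute acute-infection group name.
#' @return Named list of `feature_matrix` objects, one per second-hit group.
#' @export
split_datasets <- function(m, second_hits, control, acute) {
  out <- lapply(second_hits, function(g) {
    keep <- m$samples$group %in% c(g, control, acute)
    if (!any(m$samples$group == g)) stop("group not found: ", g)
    feature_matrix(m$mz, m$intensity[, keep, drop = FALSE],
                   m$samples$sample[keep], m$samples$group[keep])
  })
  names(out) <- second_hits
  out
}
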