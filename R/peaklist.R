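#' Construct a peak list
#'
#' A peak list is one sample's picked spectrum: m/z, intensity and an
#' optional signal-to-noise column. On construction, peaks are sorted by
#' ascending m/z and duplicates closer than 1e-6 Da are collapsed to the
#' most intense one.
#'
#' @param mz numeric vector of m/z values (Da), all positive.
#' @param intensity non-negative intensities.
#' @param sn optional signal-to-noise values (NA = not available).
#' @param sample sample identifier.
#' @return A data.frame of class `peak_list` with attribute `sample`.
#' @export
peak_list <- function(mz, intensity, sn = NULL, sample = "sample") {
  stopifnot(length(mz) == length(intensity), all(mz > 0), all(intensity >= 0))
  if (is.null(sn)) sn <- rep(NA_real_, length(mz))
  stopifnot(length(sn) == length(mz))
  o <- order(mz)
  df <- data.frame(mz = mz[o], intensity = intensity[o], sn = sn[o])
  if (nrow(df) > 1) {
    # collapse near-duplicate m/z (< 1e-6 Da apart) to the max-intensity peak
    grp <- cumsum(c(TRUE, diff(df$mz) >= 1e-6))
    if (max(grp) < nrow(df)) {
      keep <- vapply(split(seq_len(nrow(df)), grp),
                     function(i) i[which.max(df$intensity[i])], integer(1))
      df <- df[sort(keep), , drop = FALSE]
      rownames(df) <- NULL
    }
  }
  structure(df, class = c("peak_list", "data.frame"), sample = sample)
}

#' Read / write a plain-text peak list
#'
#' The on-disk format is a whitespace- or tab-delimited table with columns
#' m/z, intensity and optionally S/N; lines starting with `#` are comments.
#' One file per sample; the sample id defaults to the file name.
#'
#' @param path file path.
#' @param sample sample id (default: file name without extension).
#' @return [read_peak_list()]: a `peak_list`.
#' @export
read_peak_list <- function(path, sample = NULL) {
  if (is.null(sample)) sample <- tools::file_path_sans_ext(basename(path))
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("mz", "intensity", "sn")[1:3],
                          fill = TRUE)
  if (ncol(df) < 2) stop("peak list needs at least m/z and intensity columns")
  sn <- if ("sn" %in% names(df)) df$sn else NULL
  peak_list(df$mz, df$intensity, sn = sn, sample = sample)
}

#' @rdname read_peak_list
#' @param p a `peak_list`.
#' @export
write_peak_list <- function(p, path) {
  df <- data.frame(mz = sprintf("%.9f", p$mz),
                   intensity = sprintf("%.6g", p$intensity),
                   sn = ifelse(is.na(p$sn), "NA", sprintf("%.4g", p$sn)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Signal-to-noise and mass-range filter
#'
#' Retains peaks whose S/N is at least `threshold` (peaks without an S/N
#' value pass unchanged) and whose m/z lies inside `range`. The default
#' range matches the recorded spectrum window of 129-1000 m/z and the
#' default threshold the S/N = 4 picking cutoff.
#'
#' @param p a `peak_list`.
#' @param threshold minimum S/N (>= 0); boundary inclusive.
#' @param range length-2 numeric m/z window, closed.
#' @return The filtered `peak_list`.
#' @export
sn_filter <- function(p, threshold = 4, range = c(129, 1000)) {
  stopifnot(threshold >= 0, length(range) == 2, range[1] < range[2])
  keep <- (is.na(p$sn) | p$sn >= threshold) &
    p$mz >= range[1] & p$mz <= range[2]
  if (!any(keep)) warning("S/N filter removed every peak for sample ",
                          attr(p, "sample"))
  out <- p[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = class(p), sample = attr(p, "sample"))
}

#' Linear m/z recalibration against a reference mass list
#'
#' Each reference mass is paired with its nearest observed peak within
#' `match_window` ppm; a least-squares line observed -> reference is fitted
#' and applied to every peak (`corrected = slope * mz + offset`). The
#' residual standard deviation of the matched references, in ppb, is
#' reported and compared against an acceptance bound; fewer than
#' `min_matches` paired references is an error (mirroring calibration on at
#' least 4 reference clusters).
#'
#' @param p a `peak_list`.
#' @param reference numeric vector of reference m/z values.
#' @param match_window pairing window in ppm. The default (2 ppm) is wider
#'   than the post-calibration alignment window because pre-calibration
#'   errors exceed it.
#' @param min_matches minimum number of paired references.
#' @param max_residual_ppb acceptance bound on the residual sd.
#' @return A list with `peaks` (corrected `peak_list`) and `calibration`
#'   (slope, offset, n_matched, residual_ppb, accepted).
#' @export
calibrate <- function(p, reference, match_window = 2, min_matches = 4,
                      max_residual_ppb = 100) {
  stopifnot(length(reference) > 0, match_window > 0)
  reference <- sort(reference)
  # nearest observed peak per reference mass
  idx <- findInterval(reference, p$mz)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, nrow(p))
  nearer <- ifelse(abs(p$mz[lo] - reference) <= abs(p$mz[hi] - reference),
                   lo, hi)
  obs <- p$mz[nearer]
  ok <- abs(ppm_error(obs, reference)) <= match_window
  n_matched <- sum(ok)
  if (n_matched < min_matches) {
    stop("calibration failed: only ", n_matched, " reference masses matched (",
         min_matches, " required)")
  }
  fit <- stats::lm.fit(cbind(1, obs[ok]), reference[ok])
  offset <- fit$coefficients[1]
  slope <- fit$coefficients[2]
  corrected_ref <- slope * obs[ok] + offset
  residual_ppb <- stats::sd((corrected_ref - reference[ok]) / reference[ok]) * 1e9
  if (is.na(residual_ppb)) residual_ppb <- 0
  cal <- list(slope = unname(slope), offset = unname(offset),
              n_matched = n_matched, residual_ppb = residual_ppb,
              accepted = residual_ppb < max_residual_ppb)
  if (!cal$accepted) {
    warning("calibration residual sd ", format(residual_ppb, digits = 4),
            " ppb exceeds acceptance bound ", max_residual_ppb, " ppb")
  }
  out <- p
  out$mz <- slope * p$mz + offset
  out <- peak_list(out$mz, out$intensity, sn = out$sn,
                   sample = attr(p, "sample"))
  list(peaks = out, calibration = cal)
}
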