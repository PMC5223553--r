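#' Construct an aligned feature matrix
#'
#' Features (rows, identified by consensus m/z) by samples (columns)
#' intensity table, with a sample-to-group map. Zero means "not detected".
#'
#' @param mz strictly increasing consensus m/z per feature.
#' @param intensity matrix, features x samples, non-negative.
#' @param samples character vector of sample ids (one per column).
#' @param groups character vector of group labels, one per sample.
#' @return An object of class `feature_matrix`: a list with elements `mz`,
#'   `intensity` and `samples` (data.frame with columns sample, group).
#' @export
feature_matrix <- function(mz, intensity, samples, groups = NULL) {
  intensity <- as.matrix(intensity)
  stopifnot(length(mz) == nrow(intensity),
            length(samples) == ncol(intensity),
            all(intensity >= 0), !is.unsorted(mz, strictly = TRUE))
  if (is.null(groups)) groups <- rep("all", length(samples))
  stopifnot(length(groups) == length(samples))
  colnames(intensity) <- samples
  rownames(intensity) <- NULL
  structure(list(mz = as.numeric(mz), intensity = intensity,
                 samples = data.frame(sample = samples, group = groups,
                                      stringsAsFactors = FALSE)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix> ", length(x$mz), " features x ",
      nrow(x$samples), " samples (",
      length(unique(x$samples$group)), " groups)\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$intensity)

#' Align peak lists into a feature matrix
#'
#' Greedy single-linkage clustering over the pooled, m/z-sorted peaks of all
#' samples: a peak joins the open cluster while it lies within `window` ppm
#' of the cluster's running intensity-weighted mean m/z, otherwise a new
#' cluster opens. Each sample contributes at most one peak per feature; on a
#' same-sample collision the peak nearer the running mean stays and the
#' other spawns its own feature. Consensus m/z is the intensity-weighted
#' mean of the member peaks.
#'
#' @param peaklists list of `peak_list` objects (one per sample).
#' @param window alignment window in ppm (default 1).
#' @param groups optional named character vector mapping sample id to group.
#' @return A [feature_matrix()].
#' @export
align <- function(peaklists, window = 1, groups = NULL) {
  stopifnot(length(peaklists) >= 1, window > 0)
  ids <- vapply(peaklists, attr, character(1), "sample")
  if (anyDuplicated(ids)) stop("duplicate sample ids among peak lists")
  pool_mz <- unlist(lapply(peaklists, `[[`, "mz"), use.names = FALSE)
  pool_int <- unlist(lapply(peaklists, `[[`, "intensity"), use.names = FALSE)
  pool_smp <- rep(seq_along(peaklists),
                  vapply(peaklists, nrow, integer(1)))
  o <- order(pool_mz)
  pool_mz <- pool_mz[o]; pool_int <- pool_int[o]; pool_smp <- pool_smp[o]
  n <- length(pool_mz)

  feat_of <- integer(n)        # feature id per pooled peak
  n_feat <- 0L
  if (n > 0) {
    # open cluster state
    members <- integer(0)      # indices into pool
    wsum <- 0; isum <- 0       # running weighted m/z sum and intensity sum
    close_cluster <- function() {
      n_feat <<- n_feat + 1L
      feat_of[members] <<- n_feat
    }
    open_with <- function(i) {
      members <<- i
      wsum <<- pool_mz[i] * pool_int[i]
      isum <<- pool_int[i]
    }
    open_with(1L)
    for (i in seq_len(n)[-1]) {
      wm <- if (isum > 0) wsum / isum else mean(pool_mz[members])
      if (abs(ppm_error(pool_mz[i], wm)) <= window) {
        clash <- members[pool_smp[members] == pool_smp[i]]
        if (length(clash)) {
          # nearest to the running mean wins; ties go to higher intensity
          d_new <- abs(pool_mz[i] - wm); d_old <- abs(pool_mz[clash] - wm)
          new_wins <- d_new < d_old ||
            (d_new == d_old && pool_int[i] > pool_int[clash])
          if (new_wins) {
            # displaced member becomes its own singleton feature
            n_feat <- n_feat + 1L
            feat_of[clash] <- n_feat
            members <- setdiff(members, clash)
            wsum <- wsum - pool_mz[clash] * pool_int[clash]
            isum <- isum - pool_int[clash]
            members <- c(members, i)
            wsum <- wsum + pool_mz[i] * pool_int[i]
            isum <- isum + pool_int[i]
          } else {
            close_cluster()
            open_with(i)
          }
        } else {
          members <- c(members, i)
          wsum <- wsum + pool_mz[i] * pool_int[i]
          isum <- isum + pool_int[i]
        }
      } else {
        close_cluster()
        open_with(i)
      }
    }
    close_cluster()
  }

  # consensus m/z per feature (intensity-weighted mean)
  cmz <- vapply(split(seq_len(n), feat_of), function(ii) {
    w <- pool_int[ii]
    if (sum(w) > 0) sum(pool_mz[ii] * w) / sum(w) else mean(pool_mz[ii])
  }, numeric(1))
  ord <- order(cmz)
  rank_of <- integer(length(cmz)); rank_of[ord] <- seq_along(ord)
  mat <- matrix(0, nrow = length(cmz), ncol = length(peaklists))
  mat[cbind(rank_of[feat_of], pool_smp)] <- pool_int
  grp <- if (is.null(groups)) rep("all", length(ids)) else unname(groups[ids])
  if (anyNA(grp)) stop("group missing for sample(s): ",
                       paste(ids[is.na(grp)], collapse = ", "))
  # strictly increasing consensus m/z: nudge exact ties apart is not needed
  # in practice; assert instead
  cmz <- sort(cmz)
  feature_matrix(cmz, mat, ids, grp)
}

#' Replicate-presence ("triplicate") filter
#'
#' A feature is retained only if there is at least one replicate group in
#' which it was detected (non-zero) in every member. Features never seen in
#' a complete replicate set are treated as irreproducible and dropped.
#'
#' @param m a [feature_matrix()] whose samples carry group labels.
#' @param triplet_size declared replicate count per group (default 3); a
#'   group with a different number of samples is an error.
#' @return The filtered `feature_matrix`.
#' @export
triplicate_filter <- function(m, triplet_size = 3) {
  grp <- m$samples$group
  sizes <- table(grp)
  if (any(sizes != triplet_size)) {
    stop("group(s) ", paste(names(sizes)[sizes != triplet_size], collapse = ", "),
         " do not have the declared replicate count of ", triplet_size)
  }
  keep <- rep(FALSE, length(m$mz))
  for (g in unique(grp)) {
    cols <- which(grp == g)
    keep <- keep | rowSums(m$intensity[, cols, drop = FALSE] > 0) == length(cols)
  }
  feature_matrix(m$mz[keep], m$intensity[keep, , drop = FALSE],
                 m$samples$sample, m$samples$group)
}

#' IQR-Euclidean sample normalization
#'
#' Per sample: the interquartile range of the non-zero intensities is
#' computed (linear-interpolation quantile convention, closed interval);
#' the Euclidean norm of the intensities lying inside [Q1, Q3] becomes that
#' sample's size factor, and every intensity of the sample is divided by it.
#' The normalization is exactly invariant to positive rescaling of a sample.
#'
#' @param m a [feature_matrix()]; every sample needs at least 4 non-zero
#'   entries.
#' @return The normalized `feature_matrix`.
#' @export
iqr_euclidean_normalize <- function(m) {
  out <- m$intensity
  for (j in seq_len(ncol(out))) {
    x <- out[, j]
    nz <- x[x > 0]
    if (length(nz) < 4) {
      stop("sample ", m$samples$sample[j],
           " has fewer than 4 non-zero intensities")
    }
    q <- stats::quantile(nz, c(0.25, 0.75), type = 7, names = FALSE)
    inside <- nz[nz >= q[1] & nz <= q[2]]
    nrm <- sqrt(sum(inside^2))
    if (nrm == 0) stop("IQR-Euclidean norm is zero for sample ",
                       m$samples$sample[j])
    out[, j] <- x / nrm
  }
  feature_matrix(m$mz, out, m$samples$sample, m$samples$group)
}

#' Read / write a feature matrix as tab-separated text
#'
#' The matrix file has the consensus m/z (9 decimals) as first column and
#' one column per sample; the companion metadata file maps sample to group.
#'
#' @param m a [feature_matrix()].
#' @param path matrix file path.
#' @param meta_path metadata file path (default `<path>.groups.tsv`).
#' @export
write_feature_matrix <- function(m, path,
                                 meta_path = paste0(path, ".groups.tsv")) {
  df <- data.frame(mz = sprintf("%.9f", m$mz), m$intensity,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(m$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path, meta_path = paste0(path, ".groups.tsv")) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  samples <- colnames(mat)
  grp <- meta$group[match(samples, meta$sample)]
  feature_matrix(df[[1]], mat, samples, grp)
}
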