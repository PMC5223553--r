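#' Build a mass difference network (MDiN)
#'
#' Nodes are unique molecular formulas; an undirected edge of type `remd`
#' connects two nodes whenever their element-wise formula difference equals
#' that REMD's formula exactly. Parallel edges with distinct REMDs are
#' allowed; self-loops cannot occur (REMD formulas are non-empty). The edge
#' search is delta-keyed: for every node and REMD the sum formula is hashed
#' against the node set, which is equivalent to the all-pairs comparison.
#'
#' @param formulas character vector of formulas (duplicates collapsed to one
#'   node) or a data.frame with columns `formula` and `feature` (feature ids
#'   are concatenated per node).
#' @param remds an REMD library from [load_remds()].
#' @return An undirected `igraph` graph; vertex attributes `name` (canonical
#'   formula) and `features`; edge attribute `remd`.
#' @export
build_mdin <- function(formulas, remds = load_remds()) {
  if (is.data.frame(formulas)) {
    df <- formulas
  } else {
    df <- data.frame(formula = formulas,
                     feature = seq_along(formulas),
                     stringsAsFactors = FALSE)
  }
  df <- df[!is.na(df$formula), , drop = FALSE]
  df$formula <- vapply(df$formula,
                       function(f) write_formula(parse_formula(f)),
                       character(1), USE.NAMES = FALSE)
  feats <- vapply(split(as.character(df$feature), df$formula),
                  paste, character(1), collapse = ",")
  nodes <- data.frame(name = names(feats), features = unname(feats),
                      stringsAsFactors = FALSE)
  counts <- t(vapply(nodes$name, function(f) as_formula_counts(f),
                     numeric(length(ELEMENT_ORDER))))
  idx <- seq_len(nrow(nodes))
  names(idx) <- nodes$name

  edges <- list()
  for (r in seq_len(nrow(remds))) {
    d <- as_formula_counts(remds$formula[r])
    # hash lookup: partner = node + delta
    partner <- sweep(counts, 2, d, "+")
    keys <- hill_strings(partner)
    hit <- match(keys, nodes$name)
    ok <- which(!is.na(hit))
    if (length(ok)) {
      edges[[length(edges) + 1L]] <- data.frame(
        from = nodes$name[ok], to = nodes$name[hit[ok]],
        remd = remds$name[r], stringsAsFactors = FALSE)
    }
  }
  if (length(edges)) {
    e <- do.call(rbind, edges)
  } else {
    e <- data.frame(from = character(0), to = character(0),
                    remd = character(0))
  }
  igraph::graph_from_data_frame(e, directed = FALSE, vertices = nodes)
}

#' Label up/down-regulated features between two groups
#'
#' Computes per-feature log2 fold changes of group mean intensities (zeros
#' imputed with half the feature's smallest positive intensity, the usual
#' missing-not-detected convention) and a Welch t-test on log2 intensities.
#' A feature is `up` when the fold change is at least `fc_threshold` with
#' p < `alpha`, `down` for the symmetric rule, otherwise `unchanged`.
#'
#' @param m a normalized [feature_matrix()].
#' @param group_a,group_b group labels to contrast (fold change is A over B).
#' @param fc_threshold fold-change threshold (default 1.5).
#' @param alpha significance level for the Welch test.
#' @return data.frame: `feature`, `mz`, `log2fc`, `p`, `label`.
#' @export
select_nodes_of_interest <- function(m, group_a, group_b, fc_threshold = 1.5,
                                     alpha = 0.05) {
  grp <- m$samples$group
  ia <- which(grp == group_a); ib <- which(grp == group_b)
  if (!length(ia)) stop("group not found: ", group_a)
  if (!length(ib)) stop("group not found: ", group_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("both groups need at least 2 replicates")
  if (!any(m$intensity > 0)) stop("empty intensity matrix")
  x <- m$intensity
  for (i in seq_len(nrow(x))) {
    z <- x[i, ] == 0
    if (any(z)) {
      pos <- x[i, !z]
      x[i, z] <- if (length(pos)) min(pos) / 2 else NA
    }
  }
  if (anyNA(x)) stop("feature with no positive intensity")
  lx <- log2(x)
  log2fc <- rowMeans(lx[, ia, drop = FALSE]) - rowMeans(lx[, ib, drop = FALSE])
  p <- vapply(seq_len(nrow(lx)), function(i) {
    a <- lx[i, ia]; b <- lx[i, ib]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    }
    stats::t.test(a, b)$p.value
  }, numeric(1))
  thr <- log2(fc_threshold)
  label <- ifelse(log2fc >= thr & p < alpha, "up",
                  ifelse(log2fc <= -thr & p < alpha, "down", "unchanged"))
  data.frame(feature = seq_len(nrow(lx)), mz = m$mz, log2fc = log2fc,
             p = p, label = label, stringsAsFactors = FALSE)
}

#' Mass difference enrichment analysis (MDEA)
#'
#' Tests each REMD (edge type) of a mass difference network for association
#' with the nodes of interest. An edge is a "hit" when both endpoints are of
#' interest (`mode = "both"`, default) or at least one is (`mode = "any"`).
#' With N total edges, n total hit edges, K edges of a given REMD and a of
#' them hits, the one-sided enrichment p-value is the hypergeometric upper
#' tail (Fisher's exact test) and the Z-score the standardized hypergeometric
#' deviate `(a - Kn/N) / sqrt(Kn/N (N-K)/N (N-n)/(N-1))`. Benjamini-Hochberg
#' adjustment is applied across REMDs.
#'
#' @param net an MDiN from [build_mdin()].
#' @param interest character vector of the formulas of interest (e.g. the
#'   `up` nodes from [select_nodes_of_interest()] joined to assignments).
#' @param mode hit-edge definition, `"both"` or `"any"`.
#' @return data.frame sorted by p: `remd`, `a`, `K`, `n`, `N`, `p`, `z`, `q`.
#' @export
mdea <- function(net, interest, mode = c("both", "any")) {
  mode <- match.arg(mode)
  N <- igraph::ecount(net)
  if (N == 0) stop("network has no edges")
  ends <- igraph::as_edgelist(net, names = TRUE)
  hit_end <- matrix(ends %in% interest, ncol = 2)
  hit <- if (mode == "both") hit_end[, 1] & hit_end[, 2]
  else hit_end[, 1] | hit_end[, 2]
  remd <- igraph::edge_attr(net, "remd")
  n <- sum(hit)
  K <- tapply(rep(1L, N), remd, sum)
  a <- tapply(as.integer(hit), remd, sum)
  p <- stats::phyper(a - 1, n, N - n, K, lower.tail = FALSE)
  ex <- K * n / N
  v <- K * (n / N) * ((N - K) / N) * ((N - n) / max(N - 1, 1))
  z <- ifelse(v > 0, (a - ex) / sqrt(v), 0)
  out <- data.frame(remd = names(K), a = as.integer(a), K = as.integer(K),
                    n = n, N = N, p = as.numeric(p), z = as.numeric(z),
                    stringsAsFactors = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, -out$z), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compound-class summary of regulated formulas
#'
#' Counts up/down/unchanged formulas per compound class (from a user-supplied
#' formula-to-class map; unmapped formulas fall into "unclassified") and
#' tests each class for over/under-representation among the of-interest
#' formulas with a two-sided Fisher's exact test on the 2x2 table
#' (in-class vs not) x (of-interest vs not).
#'
#' @param labels data.frame with columns `formula` and `label`
#'   (up/down/unchanged); rows without a formula are ignored.
#' @param class_map data.frame with columns `formula`, `class`, or a path to
#'   a two-column tab-separated file.
#' @param direction which regulated nodes form the of-interest set: `"any"`
#'   (default, up or down), `"up"`, or `"down"`.
#' @return data.frame: `class`, `up`, `down`, `unchanged`, `total`, `p`.
#' @export
class_summary <- function(labels, class_map = NULL,
                          direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  df <- labels[!is.na(labels$formula), , drop = FALSE]
  if (is.character(class_map)) {
    class_map <- utils::read.table(class_map, header = FALSE, sep = "\t",
                                   col.names = c("formula", "class"),
                                   stringsAsFactors = FALSE)
  }
  cls <- if (is.null(class_map)) rep(NA_character_, nrow(df))
  else class_map$class[match(df$formula, class_map$formula)]
  cls[is.na(cls)] <- "unclassified"
  interest <- if (direction == "any") df$label != "unchanged"
  else df$label == direction
  out <- do.call(rbind, lapply(unique(cls), function(cl) {
    inside <- cls == cl
    tab <- matrix(c(sum(inside & interest), sum(inside & !interest),
                    sum(!inside & interest), sum(!inside & !interest)),
                  nrow = 2)
    p <- if (sum(interest) == 0 || sum(!interest) == 0) 1
    else stats::fisher.test(tab)$p.value
    data.frame(class = cl,
               up = sum(inside & df$label == "up"),
               down = sum(inside & df$label == "down"),
               unchanged = sum(inside & df$label == "unchanged"),
               total = sum(inside), p = p, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an MDiN to disk
#'
#' `write_mdin_graphml()` writes GraphML; `write_mdin_edgelist()` writes a
#' plain tab-separated edge list (node1, node2, REMD, and the endpoints'
#' regulation labels when provided).
#'
#' @param net an MDiN from [build_mdin()].
#' @param path output file.
#' @param labels optional data.frame with `formula`, `label` columns.
#' @export
write_mdin_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' @rdname write_mdin_graphml
#' @export
write_mdin_edgelist <- function(net, path, labels = NULL) {
  ends <- igraph::as_edgelist(net, names = TRUE)
  df <- data.frame(node1 = ends[, 1], node2 = ends[, 2],
                   remd = igraph::edge_attr(net, "remd"),
                   stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    df$label1 <- labels$label[match(df$node1, labels$formula)]
    df$label2 <- labels$label[match(df$node2, labels$formula)]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
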