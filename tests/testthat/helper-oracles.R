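# Independent oracles used across the suite. These deliberately take the
# naive route (full-grid evaluation, all-pairs comparison, explicit pmf
# sums) so they share no search logic with the implementation they check.

# naive full-grid formula enumeration: every (C,O,N,S,P) grid point is
# visited with no mass-based pruning; H is recovered as the (at most one)
# integer count bringing the total within tolerance (the tolerance is
# ~1e-4 of a hydrogen mass, so floor/ceil of the residual cover all
# possibilities). Validity is checked per row with the scalar predicates.
naive_grid_env <- new.env()

naive_grid <- function() {
  if (is.null(naive_grid_env$grid)) {
    g <- expand.grid(C = 1:100, O = 0:70, N = 0:20, S = 0:3, P = 0:3)
    el <- element_table()
    m <- setNames(el$mass, el$element)
    g$base <- g$C * m["C"] + g$O * m["O"] + g$N * m["N"] +
      g$S * m["S"] + g$P * m["P"]
    naive_grid_env$grid <- g
  }
  naive_grid_env$grid
}

naive_enumerate <- function(mass, tol = 0.5) {
  g <- naive_grid()
  mH <- element_table()$mass[element_table()$element == "H"]
  tol_da <- tol * mass / 1e6
  rem <- mass - g$base
  hits <- list()
  for (h in list(floor(rem / mH), ceiling(rem / mH))) {
    ok <- h >= 0 & h <= 200 & abs(g$base + h * mH - mass) <= tol_da
    if (any(ok)) {
      hits[[length(hits) + 1L]] <- data.frame(
        C = g$C[ok], H = h[ok], O = g$O[ok], N = g$N[ok],
        S = g$S[ok], P = g$P[ok])
    }
  }
  if (!length(hits)) return(character(0))
  df <- unique(do.call(rbind, hits))
  keep <- vapply(seq_len(nrow(df)), function(i) {
    f <- elemental_formula(counts = unlist(df[i, ]))
    senior_check(f)$valid && ratio_check(f)
  }, logical(1))
  df <- df[keep, , drop = FALSE]
  if (!nrow(df)) return(character(0))
  sort(vapply(seq_len(nrow(df)), function(i)
    write_formula(elemental_formula(counts = unlist(df[i, ]))), character(1)))
}

# exact one-sided hypergeometric enrichment p by explicit pmf summation
enum_hyper_p <- function(a, K, n, N) {
  lo <- max(0, K + n - N)
  hi <- min(K, n)
  pmf <- vapply(lo:hi, function(x)
    choose(n, x) * choose(N - n, K - x) / choose(N, K), numeric(1))
  sum(pmf[(lo:hi) >= a])
}

# all-pairs O(V^2 R) mass difference network oracle: edge set as sorted
# "u|v|remd" strings
allpairs_edges <- function(formulas, remds) {
  formulas <- sort(unique(formulas))
  counts <- lapply(formulas, function(f) unclass(parse_formula(f)))
  out <- character(0)
  if (length(formulas) < 2) return(out)
  for (i in seq_along(formulas)) {
    for (j in seq_along(formulas)) {
      if (i >= j) next
      d <- counts[[i]] - counts[[j]]
      key <- if (all(d <= 0)) {
        write_formula(elemental_formula(counts = -d))
      } else if (all(d >= 0)) {
        write_formula(elemental_formula(counts = d))
      } else NA_character_
      if (is.na(key)) next
      hit <- remds$name[remds$formula == key]
      for (r in hit) {
        out <- c(out, paste(formulas[i], formulas[j], r, sep = "|"))
      }
    }
  }
  sort(out)
}

# canonical edge strings of an MDiN for comparison with the oracle
mdin_edge_strings <- function(net) {
  e <- igraph::as_edgelist(net, names = TRUE)
  r <- igraph::edge_attr(net, "remd")
  u <- pmin(e[, 1], e[, 2])
  v <- pmax(e[, 1], e[, 2])
  sort(paste(u, v, r, sep = "|"))
}
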