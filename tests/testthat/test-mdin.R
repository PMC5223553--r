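test_that("REMD library loads, deduplicates and validates", {
  lib <- load_remds()
  expect_gte(nrow(lib), 50)
  expect_true(all(lib$mass > 0))
  expect_false(anyDuplicated(lib$formula) > 0)
  expect_true(all(c("CH2", "H2O", "HO3P") %in% lib$formula))

  f <- tempfile()
  writeLines(c("CH2", "CH2", "H2O"), f)
  lib2 <- load_remds(f)
  expect_equal(nrow(lib2), 2)

  f2 <- tempfile()
  writeLines(c("CH2", "Xx9"), f2)
  expect_error(load_remds(f2), "entry 2")

  f3 <- tempfile()
  writeLines(c("block\tCH2", "block\tH2O"), f3)
  expect_error(load_remds(f3), "duplicate REMD name")
})

test_that("MDiN construction matches hand-checked edge sets", {
  lib <- load_remds()
  n1 <- build_mdin(c("C6H12O6", "C7H14O6"), lib)
  expect_equal(igraph::ecount(n1), 1)
  expect_equal(igraph::edge_attr(n1, "remd"), "methylene")

  # glucose, +H2O, +CH2: two edges, no chain edge between the derived pair
  # unless that delta is itself in the library
  fs <- c("C6H12O6",
          write_formula(formula_add("C6H12O6", "H2O")),
          write_formula(formula_add("C6H12O6", "CH2")))
  lib2 <- lib[lib$formula %in% c("H2O", "CH2"), ]
  n2 <- build_mdin(fs, lib2)
  expect_equal(igraph::ecount(n2), 2)

  n3 <- build_mdin(fs, lib[0, ])
  expect_equal(igraph::ecount(n3), 0)
  expect_equal(igraph::vcount(n3), 3)

  # no self loops; duplicate formulas collapse to one node
  n4 <- build_mdin(data.frame(formula = c("C6H12O6", "C6H12O6"),
                              feature = 1:2), lib)
  expect_equal(igraph::vcount(n4), 1)
  expect_equal(igraph::ecount(n4), 0)
  expect_equal(igraph::vertex_attr(n4, "features"), "1,2")
})

test_that("hashed MDiN equals the all-pairs oracle on random node sets", {
  lib <- load_remds()
  st <- seed_formula_table()
  set.seed(23)
  for (rep in 1:3) {
    fs <- sample(st$formula, 50)
    net <- build_mdin(fs, lib)
    expect_identical(mdin_edge_strings(net), allpairs_edges(fs, lib))
  }
})

test_that("regulation labels behave under swaps and planted effects", {
  set.seed(3)
  base <- rlnorm(40, 10, 0.5)
  mat <- matrix(rep(base, 6), 40, 6) * rlnorm(240, 0, 0.05)
  mat[1:10, 1:3] <- mat[1:10, 1:3] * 4          # planted 4-fold, small sd
  fm <- fm_of(sort(runif(40, 130, 900)), mat, c(A = 3, B = 3))
  lab <- select_nodes_of_interest(fm, "A", "B")
  expect_gte(mean(lab$label[1:10] == "up"), 0.9)
  expect_true(all(lab$label[11:40] == "unchanged"))
  # swapping the groups flips up and down exactly
  lab2 <- select_nodes_of_interest(fm, "B", "A")
  expect_equal(lab2$log2fc, -lab$log2fc, tolerance = 1e-12)
  expect_identical(lab2$label[lab$label == "up"],
                   rep("down", sum(lab$label == "up")))
  # identical group means stay unchanged
  flat <- fm_of(1:3, matrix(rep(c(5, 6, 7), 6), 3, 6), c(A = 3, B = 3))
  lab3 <- select_nodes_of_interest(flat, "A", "B")
  expect_true(all(lab3$label == "unchanged"))
  expect_error(select_nodes_of_interest(fm, "A", "Z"), "group not found")
})

test_that("MDEA p-values are exact hypergeometric tails", {
  # worked example: N=20 edges, K=10 of one REMD, n=6 hits, a=6
  # p = C(10,6)/C(20,6) by the oracle's symmetric form
  lib <- load_remds()
  # construct N=20, K=10, n=6, a=6: a CH2 ladder (10 edges, 6 of them between
  # nodes of interest) plus an H2 desaturation ladder (10 edges, none hit)
  fs_a <- sprintf("C%dH%dO2", 10:20, 2 * (10:20))       # 10 CH2 edges
  fs_b <- sprintf("C20H%dO2", 2 * 20 - 2 * (1:10))      # 10 H2 edges via C20H40O2
  lib2 <- lib[lib$formula %in% c("CH2", "H2"), ]
  net <- build_mdin(c(fs_a, fs_b), lib2)
  expect_equal(igraph::ecount(net), 20)
  expect_equal(sum(igraph::edge_attr(net, "remd") == "methylene"), 10)
  interest <- fs_a[1:7]    # 6 adjacent CH2 pairs -> n = 6 hit edges
  e <- mdea(net, interest)
  ch2 <- e[e$remd == "methylene", ]
  expect_equal(ch2$n, 6)
  expect_equal(ch2$N, 20)
  expect_equal(ch2$a, 6)
  expect_equal(ch2$K, 10)
  expect_equal(ch2$p, choose(10, 6) / choose(20, 6), tolerance = 1e-12)
  expect_equal(ch2$p, enum_hyper_p(6, 10, 6, 20), tolerance = 1e-12)

  # random tables: implementation vs explicit pmf enumeration and fisher.test
  set.seed(9)
  pick1 <- function(lo, hi) if (lo == hi) lo else sample(lo:hi, 1)
  for (i in 1:20) {
    N <- pick1(5, 30); K <- pick1(1, N); n <- pick1(0, N)
    a <- pick1(max(0, K + n - N), min(K, n))
    p_pkg <- stats::phyper(a - 1, n, N - n, K, lower.tail = FALSE)
    expect_equal(p_pkg, enum_hyper_p(a, K, n, N), tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(c(a, K - a, n - a, N - K - n + a), 2),
                             alternative = "greater")
    expect_equal(p_pkg, ft$p.value, tolerance = 1e-9)
  }
})

test_that("MDEA degenerate margins and count bookkeeping", {
  lib <- load_remds()
  fs <- sprintf("C%dH%dO2", 10:16, 2 * (10:16))
  net <- build_mdin(fs, lib[lib$formula %in% c("CH2", "C2H4"), ])
  # no hits: every REMD has a = 0, p = 1, z <= 0
  e0 <- mdea(net, character(0))
  expect_true(all(e0$a == 0))
  expect_true(all(e0$p == 1))
  expect_true(all(e0$z == 0))
  # saturation: every node of interest -> a = K, p = 1 (enrichment impossible)
  e1 <- mdea(net, fs)
  expect_equal(e1$a, e1$K)
  expect_true(all(e1$p == 1))
  # bookkeeping: sum(K) = N, sum(a) = n with parallel-edge multiplicity
  e2 <- mdea(net, fs[1:4])
  expect_equal(sum(e2$K), e2$N[1])
  expect_equal(sum(e2$a), e2$n[1])
  expect_error(mdea(build_mdin(fs, lib[0, ]), fs), "no edges")
})

test_that("complement relabeling flips MDEA Z-scores", {
  # an edge misses "both endpoints in I" exactly when it has "any endpoint
  # in the complement of I", so enrichment under mode both maps to depletion
  # (sign-flipped Z) under mode any on the complement
  lib <- load_remds()
  st <- seed_formula_table()
  set.seed(12)
  fs <- sample(st$formula, 60)
  net <- build_mdin(fs, lib)
  interest <- sample(fs, 20)
  e_in <- mdea(net, interest, mode = "both")
  e_out <- mdea(net, setdiff(fs, interest), mode = "any")
  m <- match(e_in$remd, e_out$remd)
  expect_equal(e_in$a, e_in$K - e_out$a[m])
  expect_equal(e_in$z, -e_out$z[m], tolerance = 1e-9)
})

test_that("class summaries count regulation and test representation", {
  labels <- data.frame(
    formula = c("C6H12O6", "C7H14O6", "C16H32O2", "C18H36O2", NA),
    label = c("down", "down", "up", "unchanged", "up"))
  map <- data.frame(formula = c("C6H12O6", "C7H14O6", "C16H32O2"),
                    class = c("sugar", "sugar", "fatty_acid"))
  cs <- class_summary(labels, map)
  sugar <- cs[cs$class == "sugar", ]
  expect_equal(sugar$down, 2)
  expect_equal(sugar$total, 2)
  expect_equal(cs[cs$class == "unclassified", ]$total, 1)
  # empty map: single unclassified row
  cs2 <- class_summary(labels, NULL)
  expect_equal(cs2$class, "unclassified")
  # all members unchanged -> p = 1 under a degenerate margin
  lab3 <- data.frame(formula = c("C6H12O6", "C7H14O6"),
                     label = c("unchanged", "unchanged"))
  cs3 <- class_summary(lab3, map)
  expect_true(all(cs3$p == 1))
  # direction filter
  cs_up <- class_summary(labels, map, direction = "up")
  expect_equal(cs_up[cs_up$class == "sugar", ]$total, 2)
})

test_that("network exports write text formats", {
  lib <- load_remds()
  net <- build_mdin(c("C6H12O6", "C7H14O6"), lib)
  f1 <- tempfile(fileext = ".graphml")
  write_mdin_graphml(net, f1)
  expect_true(any(grepl("graphml", readLines(f1, n = 5))))
  f2 <- tempfile(fileext = ".tsv")
  labels <- data.frame(formula = c("C6H12O6", "C7H14O6"),
                       label = c("up", "unchanged"))
  write_mdin_edgelist(net, f2, labels)
  el <- utils::read.table(f2, header = TRUE, sep = "\t")
  expect_equal(nrow(el), 1)
  expect_equal(el$remd, "methylene")
  expect_setequal(c(el$label1, el$label2), c("up", "unchanged"))
})
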