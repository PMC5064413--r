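test_that("TF overlap ranking puts the dominant candidate first", {
  set.seed(101)
  med1 <- rand_rs(50, "MED1"); smc <- rand_rs(50, "SMC1A")
  nip <- rand_rs(50, "NIPBL")
  cof <- list(MED1 = med1, SMC1A = smc, NIPBL = nip)
  tfs <- list(GOOD = med1,
              FAR = region_set("chrZ", c(0, 100), c(50, 150),
                               regulator = "FAR"),
              NONE = region_set(regulator = "NONE"))
  attr(tfs$GOOD, "regulator") <- "GOOD"
  r <- rank_tf_overlap(cof, tfs, k = 20)
  expect_equal(r$tf_symbol[1], "GOOD")
  expect_equal(r$MED1[1], 1)
  expect_equal(r$summary[r$tf_symbol == "NONE"], 0)
  expect_equal(r$tf_symbol[3], "NONE")  # ties at 0 break lexicographically
  expect_equal(r$rank, 1:3)
})

test_that("TF overlap ranking equals brute-force recomputation", {
  set.seed(103)
  cof <- setNames(lapply(c("MED1", "SMC1A", "NIPBL"), function(n)
    rand_rs(60, n)), c("MED1", "SMC1A", "NIPBL"))
  tfs <- setNames(lapply(1:30, function(i) rand_rs(40, sprintf("T%02d", i))),
                  sprintf("T%02d", 1:30))
  r <- rank_tf_overlap(cof, tfs, k = 30)
  want <- vapply(tfs, function(tf) mean(c(
    oracle_overlap_fraction(cof$MED1, tf),
    oracle_overlap_fraction(cof$SMC1A, tf),
    oracle_overlap_fraction(cof$NIPBL, tf))), 0)
  want <- sort(want, decreasing = TRUE)
  expect_equal(r$summary, unname(want), tolerance = 1e-12)
  for (i in seq_len(nrow(r)))
    expect_equal(r$summary[i], unname(want[r$tf_symbol[i]]))
})

test_that("candidate cross-referencing intersects TF and motif symbols", {
  expect_equal(candidate_tfs(c("FOXA1", "CTCF", "JUND"), c("FOXA1", "ESR1")),
               "FOXA1")
  expect_warning(out <- candidate_tfs(c("A", "B"), c("C", "D")),
                 "no candidate")
  expect_equal(out, character(0))
  ## alias table: the ERa motif label matches the ESR1 gene symbol
  expect_equal(candidate_tfs(c("ESR1", "JUND"), c("ERa", "ZZZ")), "ESR1")
  ## case-insensitive matching
  expect_equal(candidate_tfs(c("FoxA1"), c("FOXA1")), "FoxA1")
})

test_that("regulatory windows are strand-aware and clamped at zero", {
  g <- gene_models(c("g1", "g2", "g3"), c("A", "B", "C"),
                   rep("chr1", 3), c(50000, 50000, 4000),
                   c(60000, 60000, 9000), c("+", "-", "+"))
  w <- regulatory_window(g, 10000)
  expect_equal(w$w_start[w$symbol == "A"], 40000)
  expect_equal(w$w_end[w$symbol == "A"], 60000)
  expect_equal(w$w_start[w$symbol == "B"], 50000)
  expect_equal(w$w_end[w$symbol == "B"], 70000)
  expect_equal(w$w_start[w$symbol == "C"], 0)  # clamped
  ## window always contains the gene body; length = gene + upstream
  expect_true(all(w$w_start <= g$start & g$end <= w$w_end))
  extra <- setNames(w$w_end - w$w_start - (g$end - g$start), w$symbol)
  expect_equal(extra[c("A", "B", "C")],
               c(A = 10000, B = 10000, C = 4000))  # C clamped at zero
})

test_that("circuitry edges follow the window-overlap rule", {
  genes <- toy_genes()
  ## TF1 peak inside its own window only -> self-loop
  tfs <- list(TF1 = region_set("chrA", 45000, 45400, regulator = "TF1"),
              TF2 = region_set("chrB", 100, 500, regulator = "TF2"))
  coocc <- region_set("chrA", 45000, 45300, regulator = "coocc")
  g <- build_circuitry("TF1", tfs, genes, coocc)
  expect_equal(g$edges, data.frame(from = "TF1", to = "TF1", n_peaks = 1L))
  expect_true(g$nodes$autoregulatory)
  expect_true(g$nodes$cofactor_at_own_locus)
  expect_equal(leading_candidates(g), "TF1")

  ## two TFs binding only each other's windows: a 2-cycle, no autoregulation
  tfs2 <- list(TF1 = region_set("chrA", 205000, 205400, regulator = "TF1"),
               TF2 = region_set("chrA", 45000, 45400, regulator = "TF2"))
  g2 <- build_circuitry(c("TF1", "TF2"), tfs2, genes, region_set())
  expect_equal(g2$edges$from, c("TF1", "TF2"))
  expect_equal(g2$edges$to, c("TF2", "TF1"))
  expect_false(any(g2$nodes$autoregulatory))
  expect_equal(leading_candidates(g2), character(0))

  ## self-loop without cofactor co-occupancy at the locus is not leading
  g3 <- build_circuitry("TF1", tfs, genes, region_set("chrB", 0, 100))
  expect_true(g3$nodes$autoregulatory)
  expect_equal(leading_candidates(g3), character(0))

  expect_error(build_circuitry("NOPE", tfs, genes, coocc), "NOPE")
})

test_that("circuitry adjacency equals a brute-force window oracle and is order-independent", {
  set.seed(107)
  n <- 8
  genes <- gene_models(sprintf("g%d", 1:n), sprintf("TF%d", 1:n),
                       sample(c("chrA", "chrB"), n, replace = TRUE),
                       start = s <- sample.int(400000, n) + 20000,
                       end = s + 2000,
                       strand = sample(c("+", "-"), n, replace = TRUE))
  tfs <- setNames(lapply(1:n, function(i) {
    st <- sample.int(430000, 15)
    region_set(sample(c("chrA", "chrB"), 15, replace = TRUE), st, st + 300,
               regulator = sprintf("TF%d", i))
  }), sprintf("TF%d", 1:n))
  coocc <- rand_rs(30, "coocc", chroms = c("chrA", "chrB"), len = 430000)
  g <- build_circuitry(genes$symbol, tfs, genes, coocc)
  ## oracle: interval arithmetic written out longhand
  for (a in genes$symbol) for (b in genes$symbol) {
    gb <- genes[genes$symbol == b, ]
    ws <- if (gb$strand == "+") max(0, gb$start - 10000) else gb$start
    we <- if (gb$strand == "+") gb$end else gb$end + 10000
    pk <- tfs[[a]]
    want <- any(pk$chrom == gb$chrom & pk$start < we & ws < pk$end)
    expect_equal(any(g$edges$from == a & g$edges$to == b), want)
  }
  ## permuting the candidate order leaves the edge set unchanged
  g2 <- build_circuitry(sample(genes$symbol), tfs, genes, coocc)
  expect_identical(g2$edges, g$edges)
  expect_identical(g2$nodes, g$nodes)
})

test_that("circuitry graph exports igraph and files", {
  genes <- toy_genes()
  tfs <- list(TF1 = region_set("chrA", 45000, 45400, regulator = "TF1"))
  g <- build_circuitry("TF1", tfs, genes, region_set("chrA", 45000, 45300))
  ig <- as_igraph(g)
  expect_equal(igraph::vcount(ig), 1)
  expect_equal(igraph::ecount(ig), 1)
  d <- withr::local_tempdir()
  write_circuitry(g, d)
  expect_true(all(file.exists(file.path(d, c("circuitry_nodes.tsv",
                                             "circuitry_edges.tsv",
                                             "circuitry.graphml")))))
})
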