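test_that("occupancy matrix is built over merged union regions", {
  A <- region_set("chr1", 0, 10, regulator = "A")
  B <- region_set("chr1", 5, 15, regulator = "B")
  m <- build_occupancy_matrix(list(A = A, B = B))
  expect_equal(nrow(m$M), 1)
  expect_equal(as.vector(m$M), c(1L, 1L))
  expect_equal(m$regions$start, 0)
  expect_equal(m$regions$end, 15)

  m2 <- build_occupancy_matrix(list(A = region_set("chr1", 0, 10, regulator = "A"),
                                    B = region_set("chr1", 20, 30, regulator = "B")))
  expect_equal(unname(m2$M), matrix(c(1L, 0L, 0L, 1L), 2))
  expect_error(build_occupancy_matrix(list(A = A)), "at least 2")
  expect_error(build_occupancy_matrix(list(A = A, B = region_set())),
               "non-empty")
})

test_that("occupancy rows are nonzero and column sums match brute force", {
  set.seed(5)
  for (case in 1:8) {
    sets <- setNames(lapply(1:4, function(i) rand_rs(50, paste0("R", i))),
                     paste0("R", 1:4))
    m <- build_occupancy_matrix(sets)
    expect_true(all(rowSums(m$M) >= 1))
    for (j in 1:4) {
      want <- sum(vapply(seq_len(nrow(m$regions)), function(r) {
        s <- sets[[j]]
        any(s$chrom == m$regions$chrom[r] & s$start < m$regions$end[r] &
              m$regions$start[r] < s$end)
      }, TRUE))
      expect_equal(sum(m$M[, j]), want)
    }
  }
})

test_that("PCA handles duplicate and anti-correlated variables", {
  set.seed(3)
  x <- rbinom(50, 1, 0.5)
  x[1:2] <- c(0L, 1L)
  m <- structure(list(regions = NULL, regulators = c("A", "B", "C"),
                      M = cbind(A = x, B = x, C = 1L - x)),
                 class = "occupancy_matrix")
  p <- pca_regulators(m)
  expect_equal(p$variable_coords["A", ], p$variable_coords["B", ])
  expect_equal(p$variable_coords["A", 1], -p$variable_coords["C", 1])
  ## sign convention: lexicographically smallest regulator non-negative
  expect_gte(p$variable_coords["A", 1], 0)
  expect_equal(sum(p$explained), 1, tolerance = 1e-9)
  expect_true(all(abs(p$variable_coords) <= 1 + 1e-9))
})

test_that("PCA scores match an eigendecomposition oracle up to sign", {
  set.seed(17)
  M <- cbind(a = rbinom(500, 1, 0.4), b = rbinom(500, 1, 0.5),
             c = rbinom(500, 1, 0.3), d = rbinom(500, 1, 0.6))
  m <- structure(list(regions = NULL, regulators = colnames(M), M = M),
                 class = "occupancy_matrix")
  p <- pca_regulators(m)
  X <- scale(M, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(X) / 1)        # eigenvectors of X'X
  sc1 <- X %*% ev$vectors[, 1]
  r <- as.numeric(cor(p$region_scores[, 1], sc1))
  expect_equal(abs(r), 1, tolerance = 1e-8)
  ## full reconstruction of the centered matrix
  expect_equal(p$region_scores %*% t(p$rotation), unclass(X),
               ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("PCA warns on zero-variance columns and zeroes their coordinates", {
  M <- cbind(A = rep(1L, 10), B = rbinom(10, 1, 0.5))
  M[1, 2] <- 1L; M[2, 2] <- 0L
  m <- structure(list(regions = NULL, regulators = colnames(M), M = M),
                 class = "occupancy_matrix")
  expect_warning(p <- pca_regulators(m), "zero-variance")
  expect_true(all(p$variable_coords["A", ] == 0))
})

test_that("dim1 densities are normalized to a maximum of exactly 1", {
  set.seed(23)
  sets <- setNames(lapply(1:3, function(i) rand_rs(80, paste0("R", i))),
                   paste0("R", 1:3))
  p <- pca_regulators(build_occupancy_matrix(sets))
  for (d in p$dim1_density)
    if (!is.null(d)) expect_equal(max(d$y), 1)
})

test_that("regulator correlation matches the hand formula and edge cases", {
  set.seed(9)
  x <- rbinom(200, 1, 0.5); y <- rbinom(200, 1, 0.5)
  x[1:2] <- c(0L, 1L); y[1:2] <- c(0L, 1L)
  m <- structure(list(regions = NULL, regulators = c("a", "b", "id", "neg"),
                      M = cbind(a = x, b = y, id = x, neg = 1L - x)),
                 class = "occupancy_matrix")
  r <- regulator_correlation(m, "a", "b")
  expect_equal(r$R, oracle_pearson(x, y))
  expect_true(r$p > 0 && r$p <= 1)
  expect_equal(regulator_correlation(m, "a", "id")$R, 1)
  expect_equal(regulator_correlation(m, "a", "neg")$R, -1)
  m$M <- cbind(m$M, const = 1L)
  m$regulators <- c(m$regulators, "const")
  expect_error(regulator_correlation(m, "a", "const"), "zero-variance")
  expect_error(regulator_correlation(m, "a", "nope"), "not present")
})

test_that("CTCF partition splits Cohesin peaks exactly", {
  smc <- region_set(c("chr1", "chr1"), c(0, 20), c(10, 30), regulator = "SMC1A")
  part <- partition_by_ctcf(smc, region_set("chr1", 25, 28))
  expect_equal(part$with_ctcf$start, 20)
  expect_equal(part$no_ctcf$start, 0)
  ## empty CTCF: everything is "no CTCF"
  p2 <- partition_by_ctcf(smc, region_set())
  expect_equal(nrow(p2$with_ctcf), 0)
  expect_equal(nrow(p2$no_ctcf), 2)
  ## random inputs: exact partition, membership matches brute force
  set.seed(31)
  for (case in 1:10) {
    s <- rand_rs(80, "SMC1A"); c <- rand_rs(40, "CTCF")
    pp <- partition_by_ctcf(s, c)
    expect_equal(nrow(pp$with_ctcf) + nrow(pp$no_ctcf), nrow(s))
    both <- rbind(as.data.frame(pp$with_ctcf), as.data.frame(pp$no_ctcf))
    both <- both[order(both$chrom, both$start, both$end), ]
    expect_equal(both$start, s$start)
    if (nrow(pp$with_ctcf))
      expect_equal(oracle_overlap_fraction(pp$with_ctcf, c), 1)
    if (nrow(pp$no_ctcf))
      expect_equal(oracle_overlap_fraction(pp$no_ctcf, c), 0)
  }
})

test_that("state overlap ratios are exact fractions of occupied bases", {
  seg <- region_set(rep("chr1", 4), c(0, 100, 200, 300),
                    c(100, 200, 300, 400),
                    name = c("1_TssA", "9_EnhA1", "1_TssA", "18_Quies"),
                    regulator = "seg")
  rs <- region_set("chr1", 10, 60, regulator = "X")
  pr <- state_overlap_profile(rs, seg)
  expect_equal(unname(pr$ratios["1_TssA"]), 1)
  expect_equal(sum(pr$ratios), 1)
  ## 50/50 straddle of two equal-width states
  pr2 <- state_overlap_profile(region_set("chr1", 50, 150), seg)
  expect_equal(unname(pr2$ratios[c("1_TssA", "9_EnhA1")]), c(0.5, 0.5))
  ## bases beyond the segmentation fall under "unannotated"
  pr3 <- state_overlap_profile(region_set("chr1", 350, 450), seg)
  expect_equal(unname(pr3$ratios["unannotated"]), 0.5)
  expect_error(state_overlap_profile(rs, region_set(
    c("chr1", "chr1"), c(0, 50), c(100, 150), name = "1_TssA")), "overlap")
})

test_that("state ratios match a per-base counting oracle on random tilings", {
  set.seed(41)
  for (case in 1:6) {
    bounds <- sort(sample(50:1950, 8))
    starts <- c(0, bounds); ends <- c(bounds, 2000)
    labs <- sample(c("s1", "s2", "s3"), length(starts), replace = TRUE)
    seg <- region_set(rep("chrA", length(starts)), starts, ends, name = labs)
    rs <- rand_rs(30, "X", chroms = "chrA")
    pr <- state_overlap_profile(rs, seg)
    cov <- cover_bases(merge_regions(rs), "chrA")
    for (lab in unique(labs)) {
      sel <- seg$name == lab
      segcov <- cover_bases(region_set(seg$chrom[sel], seg$start[sel],
                                       seg$end[sel]), "chrA")
      expect_equal(unname(pr$ratios[lab]), sum(cov & segcov) / sum(cov))
    }
    expect_equal(sum(pr$ratios), 1, tolerance = 1e-9)
  }
})

test_that("colocalization matrix reproduces overlap fractions with clustering order", {
  A <- region_set("chr1", c(0, 100), c(50, 150), regulator = "A")
  cm <- colocalization_matrix(list(A = A, B = A))
  expect_equal(unname(cm$F), matrix(1, 2, 2))
  set.seed(53)
  sets <- setNames(lapply(1:5, function(i) rand_rs(60, paste0("R", i))),
                   paste0("R", 1:5))
  cm <- colocalization_matrix(sets)
  expect_equal(unname(diag(cm$F)), rep(1, 5))
  for (i in 1:5) for (j in 1:5)
    expect_equal(cm$F[i, j], oracle_overlap_fraction(sets[[i]], sets[[j]]))
  ## a duplicated set clusters next to its twin
  sets$R6 <- sets$R2
  attr(sets$R6, "regulator") <- "R6"
  ord <- colocalization_matrix(sets)$order
  expect_equal(abs(which(ord == "R2") - which(ord == "R6")), 1)
})

test_that("bimodality detector separates one- and two-peaked curves", {
  x <- seq(-3, 3, length.out = 200)
  uni <- exp(-x^2); uni <- uni / max(uni)
  bi <- exp(-(x - 1.5)^2) + 0.9 * exp(-(x + 1.5)^2); bi <- bi / max(bi)
  expect_false(is_bimodal(list(x = x, y = uni)))
  expect_true(is_bimodal(list(x = x, y = bi)))
})
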