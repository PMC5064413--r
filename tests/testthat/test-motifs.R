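test_that("PWM loading applies the pseudocount before normalization", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(">M_UNIFORM",
               rep("25\t25\t25\t25", 8),
               ">M_SHARP",
               "0\t0\t0\t100",
               "100\t0\t0\t0",
               "0\t100\t0\t0",
               "0\t0\t100\t0"), f)
  pw <- load_pwms(f, pseudocount = 1)
  expect_equal(unname(pw$M_UNIFORM$probs), matrix(26 / 104, 4, 8))
  expect_equal(unname(pw$M_SHARP$probs[, 1]),
               c(1 / 104, 1 / 104, 1 / 104, 101 / 104))
  expect_equal(pwm_consensus(pw$M_SHARP), "TACG")
  ## column sums are 1 within tolerance for every loaded motif
  for (p in pw) expect_true(all(abs(colSums(p$probs) - 1) < 1e-6))
})

test_that("PWM loading attaches TF symbols and rejects ragged rows", {
  f <- withr::local_tempfile(fileext = ".txt")
  m <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(">MA", rep("1\t2\t3\t4", 5), ">MB", rep("4\t3\t2\t1", 5)), f)
  writeLines(c("motif_id\ttf_symbol", "MA\tFOXA1"), m)
  pw <- load_pwms(f, m)
  expect_equal(pw$MA$tf_symbol, "FOXA1")
  expect_true(is.na(pw$MB$tf_symbol))
  writeLines(c(">MC", "1\t2\t3", "1\t2\t3\t4"), f)
  expect_error(load_pwms(f), "ragged")
})

test_that("log-odds scoring follows the closed form", {
  bg <- background_model()
  uni <- pwm("U", matrix(0.25, 4, 6))
  expect_equal(log_odds_score(uni, bg, "ACGTAC"), 0)
  eps <- 0.01
  single <- pwm("S", matrix(c(1 - 3 * eps, eps, eps, eps), 4, 1))
  expect_equal(log_odds_score(single, bg, "A"), log2((1 - 3 * eps) / 0.25))
  expect_error(log_odds_score(single, bg, "N"), "invalid character")
  expect_error(log_odds_score(uni, bg, "ACGT"), "length")
  ## random PWM/sequence vs position-by-position hand summation
  set.seed(61)
  for (case in 1:10) {
    probs <- rand_pwm_probs(7)
    p <- pwm("R", probs)
    s <- rand_dna(7)
    ch <- strsplit(s, "")[[1]]
    want <- sum(vapply(1:7, function(j)
      log2(probs[ch[j], j] / 0.25), 0))
    expect_equal(log_odds_score(p, bg, s), want)
  }
})

test_that("a PWM's consensus attains the maximal score over all sequences", {
  ## under a uniform background: log-odds order equals probability order
  set.seed(67)
  bg <- background_model()
  probs <- rand_pwm_probs(5, alpha = 0.5)
  p <- pwm("R", probs)
  cons <- pwm_consensus(p)
  all_seqs <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 5)), 1,
                    paste, collapse = "")
  scores <- vapply(all_seqs, function(s) log_odds_score(p, bg, s), 0)
  expect_equal(max(scores), log_odds_score(p, bg, cons))
})

test_that("the exact background score distribution is a probability distribution", {
  set.seed(71)
  bg_gc <- background_model(c(A = 0.295, C = 0.205, G = 0.205, T = 0.295),
                            "genome-estimated")
  for (probs in list(rand_pwm_probs(5), rand_pwm_probs(10, 0.3),
                     matrix(c(0.91, 0.03, 0.03, 0.03), 4, 8))) {
    d <- score_distribution(pwm("X", probs), bg_gc)
    expect_equal(sum(d$prob), 1, tolerance = 1e-9)
    expect_true(all(diff(d$score) > 0))
  }
})

test_that("the DP threshold matches the empirical background quantile", {
  set.seed(73)
  bg <- background_model(c(A = 0.3, C = 0.2, G = 0.2, T = 0.3), "genome")
  p <- pwm("X", rand_pwm_probs(5))
  d <- score_distribution(p, bg)
  thr <- score_threshold(d, 0.99)
  lom <- log2(p$probs / bg$freqs)
  n <- 1e6
  draws <- matrix(sample.int(4, 5 * n, replace = TRUE,
                             prob = as.numeric(bg$freqs)), nrow = 5)
  sc <- colSums(matrix(lom[cbind(as.vector(draws), rep(1:5, n))], nrow = 5))
  emp <- unname(quantile(sc, 0.99, type = 1))
  expect_equal(thr, emp, tolerance = 0.02)
  ## exceedance probability is close to the nominal tail
  expect_lt(abs(mean(sc >= thr) - sum(d$prob[d$score >= thr])), 0.002)
})

test_that("scanning finds planted consensus and skips N windows", {
  bg <- background_model()
  sharp <- pwm("S", matrix(c(0.94, 0.02, 0.02, 0.02), 4, 8))  # poly-A
  hit_seq <- paste0("CGTCGT", "AAAAAAAA", "GCGGCG")
  expect_gte(scan_regions(sharp, bg, hit_seq, threshold_quantile = 0.999), 1)
  expect_equal(scan_regions(sharp, bg, strrep("N", 40)), 0L)
  expect_equal(scan_regions(sharp, bg, "ACG"), 0L)  # shorter than the motif
  ## reverse strand: the reverse complement of the consensus still hits
  rc_seq <- paste0("CGTCGT", "TTTTTTTT", "GCGGCG")
  expect_gte(scan_regions(sharp, bg, rc_seq, threshold_quantile = 0.999), 1)
  expect_equal(scan_regions(sharp, bg, rc_seq, threshold_quantile = 0.999,
                            both_strands = FALSE), 0L)
})

test_that("hit counts equal exhaustive window scoring on random sequences", {
  set.seed(79)
  bg <- background_model(c(A = 0.28, C = 0.22, G = 0.22, T = 0.28), "genome")
  for (len in c(5, 6)) {
    probs <- rand_pwm_probs(len, alpha = 0.6)
    p <- pwm("X", probs)
    thr <- score_threshold(score_distribution(p, bg), 0.95)
    seqs <- vapply(1:50, function(i) rand_dna(30), "")
    seqs[3] <- paste0(substr(seqs[3], 1, 10), "NN", substr(seqs[3], 13, 30))
    got <- scan_regions(p, bg, seqs, threshold = thr)
    want <- vapply(seqs, oracle_scan_hits, 0L, probs = probs,
                   bg_freqs = as.numeric(bg$freqs), thr = thr,
                   USE.NAMES = FALSE)
    expect_equal(got, want)
  }
})

test_that("binomial enrichment p-value equals direct summation", {
  bg <- background_model()
  sharp <- pwm("S", matrix(c(0.94, 0.02, 0.02, 0.02), 4, 6), tf_symbol = "TFA")
  hit <- paste0("GCGCGC", "AAAAAA", "GCGCGC")
  miss <- strrep("GC", 9)
  ## 8 of 10 target regions hit; 1 of 10 background regions -> bg_rate 0.1
  res <- motif_enrichment(sharp, bg, c(rep(hit, 8), rep(miss, 2)),
                          c(hit, rep(miss, 9)), threshold_quantile = 0.999)
  expect_equal(res$target_hits, 8)
  expect_equal(res$bg_rate, 0.1)
  expect_equal(res$p, oracle_binom_tail(8, 10, 0.1))
  ## zero target hits gives p = 1
  res0 <- motif_enrichment(sharp, bg, rep(miss, 5), rep(miss, 5),
                           threshold_quantile = 0.999)
  expect_equal(res0$target_hits, 0)
  expect_equal(res0$p, 1)
  ## background rate is floored to avoid zero
  expect_equal(res0$bg_rate, 1 / 10)
  expect_error(motif_enrichment(sharp, bg, character(), miss), "empty")
})

test_that("identical target and background collections are not enriched", {
  set.seed(83)
  bg <- background_model()
  seqs <- vapply(1:30, function(i) rand_dna(60), "")
  ps <- vapply(1:20, function(i) {
    p <- pwm("X", rand_pwm_probs(6))
    motif_enrichment(p, bg, seqs, seqs, threshold_quantile = 0.99)$p
  }, 0)
  expect_gte(mean(ps), 0.3)
})

test_that("motif ranking orders by p with hit-count and id tie-breaks", {
  mk <- function(id, p, hits, sym = NA) structure(
    list(motif_id = id, tf_symbol = sym, target_hits = hits, target_n = 20,
         bg_rate = 0.1, p = p, threshold = 0), class = "motif_enrichment")
  r <- rank_motifs(list(mk("m1", 0.5, 1), mk("m2", 0.001, 5),
                        mk("m3", 0.01, 3)))
  expect_equal(r$motif_id, c("m2", "m3", "m1"))
  expect_equal(r$rank, 1:3)
  ## equal p and hits: lexicographic by id
  r2 <- rank_motifs(list(mk("zz", 0.1, 2), mk("aa", 0.1, 2)))
  expect_equal(r2$motif_id, c("aa", "zz"))
  ## top-k is the prefix of the full sort
  set.seed(89)
  res <- lapply(1:50, function(i)
    mk(sprintf("m%02d", i), runif(1), sample(0:20, 1)))
  expect_equal(rank_motifs(res, k = 20)$motif_id,
               rank_motifs(res, k = 50)$motif_id[1:20])
})

test_that("shuffled background regions match widths and avoid exclusions", {
  set.seed(97)
  rs <- rand_rs(40, "X")
  sh <- shuffle_regions(rs, setNames(c(2000, 2000), ORACLE_CHROMS),
                        exclude = rs)
  expect_equal(sort(sh$end - sh$start), sort(rs$end - rs$start))
  expect_equal(oracle_overlap_fraction(sh, rs), 0)
})
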