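## Independent brute-force oracles used across the suite.  All of them are
## deliberately naive (per-base boolean arrays, all-pairs scans, exhaustive
## enumeration, hand-written formulas) and share no code with the package
## internals they check.

ORACLE_CHROMS <- c("chrA", "chrB")
ORACLE_LEN <- 2000L

rand_rs <- function(n, regulator = "X", chroms = ORACLE_CHROMS,
                    len = ORACLE_LEN, max_w = 60L) {
  s <- sample.int(len - max_w - 1L, n, replace = TRUE)
  w <- sample.int(max_w, n, replace = TRUE)
  region_set(sample(chroms, n, replace = TRUE), s, s + w,
             regulator = regulator)
}

## per-base boolean coverage of one chromosome
cover_bases <- function(rs, chrom, len = ORACLE_LEN) {
  v <- logical(len)
  rows <- which(rs$chrom == chrom)
  for (i in rows) v[(rs$start[i] + 1):rs$end[i]] <- TRUE
  v
}

## per-base comparison of two region sets' coverage
same_coverage <- function(a, b, chroms = ORACLE_CHROMS) {
  all(vapply(chroms, function(cc)
    identical(cover_bases(a, cc), cover_bases(b, cc)), TRUE))
}

## merged: no same-chromosome overlap or abutment
is_properly_merged <- function(rs) {
  for (cc in unique(rs$chrom)) {
    r <- rs[rs$chrom == cc, , drop = FALSE]
    if (nrow(r) > 1 && any(r$start[-1] <= r$end[-nrow(r)])) return(FALSE)
  }
  TRUE
}

## all-pairs interval overlap scan
oracle_overlap_fraction <- function(a, b) {
  hit <- vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & a$start[i] < b$end)
  }, TRUE)
  mean(hit)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

## exhaustive hypergeometric upper tail by enumerating all C(N, n) draws
oracle_hyper_enum <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

## direct-summation hypergeometric upper tail (choose products)
oracle_hyper_sum <- function(N, K, n, k) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

## hand-applied Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

## direct binomial upper tail
oracle_binom_tail <- function(k, n, r) {
  j <- k:n
  sum(choose(n, j) * r^j * (1 - r)^(n - j))
}

oracle_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

## exhaustive double-loop window scan (both strands), N windows skipped
oracle_scan_hits <- function(seq, probs, bg_freqs, thr) {
  lo <- log2(probs / bg_freqs)
  count_one <- function(s) {
    ch <- strsplit(s, "")[[1]]
    w <- ncol(lo)
    hits <- 0L
    if (length(ch) < w) return(0L)
    for (i in seq_len(length(ch) - w + 1)) {
      win <- ch[i:(i + w - 1)]
      if (any(!win %in% c("A", "C", "G", "T"))) next
      sc <- 0
      for (j in seq_len(w)) sc <- sc + lo[win[j], j]
      if (sc >= thr) hits <- hits + 1L
    }
    hits
  }
  count_one(seq) + count_one(oracle_revcomp(seq))
}

rand_dna <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

## random sharp-ish PWM as a plain probability matrix
rand_pwm_probs <- function(len, alpha = 1) {
  m <- vapply(seq_len(len), function(j) {
    g <- rgamma(4, alpha) + 1e-3
    g / sum(g)
  }, numeric(4))
  rownames(m) <- c("A", "C", "G", "T")
  m
}

## small deterministic gene table used by several suites
toy_genes <- function() {
  gene_models(gene_id = c("g1", "g2", "g3"),
              symbol = c("TF1", "TF2", "GENE3"),
              chrom = c("chrA", "chrA", "chrB"),
              start = c(50000, 200000, 50000),
              end = c(60000, 210000, 52000),
              strand = c("+", "-", "+"))
}

## fast bundle for pipeline-level tests (smaller genome, fewer decoys)
small_bundle <- function(seed = 1, ...) {
  generate_bundle(synthetic_config(seed = seed, n_chroms = 1,
                                   chrom_length = 250000, n_genes = 18,
                                   n_decoy_tfs = 10, n_decoy_motifs = 10,
                                   n_cofactor_sites = 60, n_ctcf_only = 15,
                                   n_pathways = 8, ...))
}
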