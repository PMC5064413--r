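## DNA encoding: A=1 C=2 G=3 T=4, anything else NA (N windows are skipped)
.DNA_CODE <- local({
  v <- rep(NA_integer_, 127L)
  v[utf8ToInt("A")] <- 1L; v[utf8ToInt("a")] <- 1L
  v[utf8ToInt("C")] <- 2L; v[utf8ToInt("c")] <- 2L
  v[utf8ToInt("G")] <- 3L; v[utf8ToInt("g")] <- 3L
  v[utf8ToInt("T")] <- 4L; v[utf8ToInt("t")] <- 4L
  v
})

encode_dna <- function(seq) {
  ints <- utf8ToInt(seq)
  ints[ints > 127L] <- 127L
  .DNA_CODE[ints]
}

.DNA_BASES <- c("A", "C", "G", "T")

#' Position weight matrix
#'
#' A PWM stores per-position base probabilities over A/C/G/T for one binding
#' motif, together with the gene symbol of the transcription factor it
#' belongs to and the pseudocount used at load time.
#'
#' @param motif_id motif identifier.
#' @param probs 4 x L numeric matrix (rows A, C, G, T); each column must sum
#'   to 1 within 1e-6 with all entries > 0.
#' @param tf_symbol associated TF gene symbol (NA when unmapped).
#' @param pseudocount pseudocount applied when the PWM was built from counts.
#' @return A `pwm` object.
#' @export
pwm <- function(motif_id, probs, tf_symbol = NA_character_,
                pseudocount = NA_real_) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4) stop_input("PWM must have 4 rows (A, C, G, T)")
  rownames(probs) <- .DNA_BASES
  if (ncol(probs) < 1) stop_input("PWM must have at least one position")
  if (any(probs <= 0)) stop_input("PWM probabilities must all be > 0")
  if (any(abs(colSums(probs) - 1) > 1e-6))
    stop_input("PWM column probabilities must sum to 1")
  structure(list(motif_id = as.character(motif_id),
                 tf_symbol = as.character(tf_symbol),
                 probs = probs, pseudocount = pseudocount),
            class = "pwm")
}

#' Build a PWM from a count (or frequency) matrix
#'
#' The pseudocount is added to every cell before per-position normalization.
#'
#' @param motif_id motif identifier.
#' @param counts 4 x L matrix of counts (rows A, C, G, T).
#' @param pseudocount per-cell pseudocount (default 0.8).
#' @param tf_symbol associated TF gene symbol.
#' @return A `pwm` object.
#' @export
pwm_from_counts <- function(motif_id, counts, pseudocount = 0.8,
                            tf_symbol = NA_character_) {
  counts <- as.matrix(counts) + pseudocount
  pwm(motif_id, sweep(counts, 2, colSums(counts), "/"),
      tf_symbol = tf_symbol, pseudocount = pseudocount)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (%s), length %d, consensus %s\n", x$motif_id,
              x$tf_symbol, ncol(x$probs), pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM
#' @param x a `pwm`.
#' @return Character scalar (highest-probability base per position).
#' @export
pwm_consensus <- function(x) {
  paste(.DNA_BASES[apply(x$probs, 2, which.max)], collapse = "")
}

#' Load PWMs from a HOCOMOCO-style plain-text matrix file
#'
#' The format is `>motif_id` header lines followed by one row per motif
#' position with 4 whitespace-separated counts or frequencies (A C G T).
#' A pseudocount is added per cell before normalization.  An optional mapping
#' TSV (columns `motif_id`, `tf_symbol`) attaches gene symbols; motifs
#' without a mapping entry keep `tf_symbol = NA`.
#'
#' @param path matrix file.
#' @param mapping_path optional motif-to-TF mapping TSV.
#' @param pseudocount per-cell pseudocount (default 0.8).
#' @return A named list of `pwm` objects.
#' @export
load_pwms <- function(path, mapping_path = NULL, pseudocount = 0.8) {
  if (!file.exists(path)) stop_input("PWM file not found: ", path)
  lines <- readLines(path)
  map <- NULL
  if (!is.null(mapping_path)) {
    map <- read.delim(mapping_path, header = TRUE, stringsAsFactors = FALSE)
    if (!all(c("motif_id", "tf_symbol") %in% names(map)))
      stop_input("mapping file needs columns motif_id and tf_symbol")
  }
  hdr <- which(startsWith(lines, ">"))
  if (!length(hdr)) stop_input("no PWM records in ", path)
  bounds <- c(hdr, length(lines) + 1L)
  out <- list()
  for (i in seq_along(hdr)) {
    id <- trimws(sub("^>", "", lines[hdr[i]]))
    id <- strsplit(id, "[\t ]")[[1]][1]
    block <- lines[seq(hdr[i] + 1L, bounds[i + 1L] - 1L)]
    block <- block[nzchar(trimws(block))]
    if (!length(block)) stop_input("PWM ", id, " has no matrix rows")
    rows <- lapply(strsplit(trimws(block), "[\t ]+"), function(f)
      suppressWarnings(as.numeric(f)))
    if (any(lengths(rows) != 4) || any(vapply(rows, anyNA, TRUE)))
      stop_input("ragged or non-numeric matrix row in PWM ", id)
    counts <- t(do.call(rbind, rows))  # 4 x L, rows A C G T
    sym <- NA_character_
    if (!is.null(map)) {
      hit <- match(id, map$motif_id)
      if (!is.na(hit)) sym <- map$tf_symbol[hit]
    }
    out[[id]] <- pwm_from_counts(id, counts, pseudocount, tf_symbol = sym)
  }
  out
}

#' Background base composition model
#'
#' @param freqs named numeric vector of A/C/G/T frequencies (sum 1, all > 0).
#' @param source label: `"uniform"`, `"genome-estimated"` or
#'   `"region-estimated"`.
#' @return A `background_model`.
#' @export
background_model <- function(freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                             source = "uniform") {
  freqs <- freqs[.DNA_BASES]
  if (anyNA(freqs) || any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-9)
    stop_input("background frequencies must be positive over A/C/G/T and sum to 1")
  structure(list(freqs = freqs, source = source), class = "background_model")
}

#' Estimate a background model from sequences
#'
#' @param seqs character vector of DNA sequences (or a `DNAStringSet`);
#'   non-ACGT characters are ignored.
#' @param source label recorded on the model (default `"region-estimated"`).
#' @return A `background_model`.
#' @export
background_from_seqs <- function(seqs, source = "region-estimated") {
  seqs <- as.character(seqs)
  enc <- unlist(lapply(seqs, encode_dna), use.names = FALSE)
  tab <- tabulate(enc, nbins = 4)
  if (sum(tab) == 0) stop_input("no ACGT bases in input sequences")
  background_model(setNames(tab / sum(tab), .DNA_BASES), source = source)
}

#' @rdname background_from_seqs
#' @param genome named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @export
background_from_genome <- function(genome) {
  background_from_seqs(as.character(genome), source = "genome-estimated")
}

## internal: 4 x L log2-odds matrix
log_odds_matrix <- function(pwm, bg) {
  log2(pwm$probs / bg$freqs)
}

#' Log-odds score of a sequence under a PWM
#'
#' The sum over positions of `log2(p_pos(base) / bg(base))` for a sequence of
#' exactly the motif length.  Characters outside A/C/G/T (including N) are
#' invalid here.
#'
#' @param pwm a `pwm`.
#' @param bg a `background_model`.
#' @param seq DNA string of the motif's length.
#' @return Numeric score (bits).
#' @export
log_odds_score <- function(pwm, bg, seq) {
  enc <- encode_dna(seq)
  if (length(enc) != ncol(pwm$probs))
    stop_input("sequence length must equal the PWM length")
  if (anyNA(enc)) stop_input("invalid character in sequence (only ACGT allowed)")
  lom <- log_odds_matrix(pwm, bg)
  sum(lom[cbind(enc, seq_along(enc))])
}

#' Exact score distribution of a PWM under the background model
#'
#' Dynamic programming over independent positions on a rounded-score lattice:
#' the distribution of the log-odds score of a random background window.
#' Total probability is 1 up to floating error.
#'
#' @param pwm a `pwm`.
#' @param bg a `background_model`.
#' @param granularity lattice spacing in bits (default 1e-3).
#' @return A `pwm_score_distribution`: sorted `score`, `prob`, `granularity`.
#' @export
score_distribution <- function(pwm, bg, granularity = 1e-3) {
  lom <- log_odds_matrix(pwm, bg)
  keys <- round(lom / granularity)
  bgp <- as.numeric(bg$freqs)
  cur <- 1
  cur_lo <- 0
  for (j in seq_len(ncol(keys))) {
    kj <- keys[, j]
    new_lo <- cur_lo + min(kj)
    new_hi <- cur_lo + length(cur) - 1 + max(kj)
    new <- numeric(new_hi - new_lo + 1)
    for (b in 1:4) {
      idx <- seq_along(cur) + (cur_lo + kj[b] - new_lo)
      new[idx] <- new[idx] + cur * bgp[b]
    }
    cur <- new
    cur_lo <- new_lo
  }
  keep <- cur > 0
  structure(list(score = ((seq_along(cur) - 1) + cur_lo)[keep] * granularity,
                 prob = cur[keep], granularity = granularity),
            class = "pwm_score_distribution")
}

#' Score threshold at a background quantile
#'
#' The smallest lattice score whose cumulative background probability reaches
#' the requested quantile; windows scoring at or above it are motif hits.
#'
#' @param dist a `pwm_score_distribution`.
#' @param quantile background quantile (default 0.9999).
#' @return Numeric threshold score.
#' @export
score_threshold <- function(dist, quantile = 0.9999) {
  if (quantile <= 0 || quantile > 1) stop_input("quantile must be in (0, 1]")
  cum <- cumsum(dist$prob)
  dist$score[which(cum >= quantile - 1e-12)[1]]
}

## internal: window scores of an encoded sequence (NA propagates for N)
score_windows <- function(enc, lom) {
  L <- length(enc)
  w <- ncol(lom)
  if (L < w) return(numeric(0))
  n <- L - w + 1L
  s <- lom[enc[seq_len(n)], 1L]
  if (w > 1L)
    for (j in 2:w) s <- s + lom[enc[j:(n + j - 1L)], j]
  s
}

#' Scan sequences for motif hits
#'
#' Counts, per sequence, the windows whose log-odds score reaches the
#' threshold (the given quantile of the exact background score distribution).
#' Both strands are scanned (the reverse strand scores the reverse
#' complement); windows containing N are skipped; sequences shorter than the
#' motif yield 0 hits.
#'
#' @param pwm a `pwm`.
#' @param bg a `background_model`.
#' @param seqs character vector of region sequences (or `DNAStringSet`).
#' @param threshold_quantile background quantile for the hit threshold
#'   (default 0.9999).
#' @param threshold optional explicit score threshold (overrides the
#'   quantile).
#' @param both_strands scan the reverse complement as well (default TRUE).
#' @return Integer vector of per-region hit counts.
#' @export
scan_regions <- function(pwm, bg, seqs, threshold_quantile = 0.9999,
                         threshold = NULL, both_strands = TRUE) {
  seqs <- as.character(seqs)
  lom <- log_odds_matrix(pwm, bg)
  if (is.null(threshold))
    threshold <- score_threshold(score_distribution(pwm, bg),
                                 threshold_quantile)
  vapply(seqs, function(s) {
    enc <- encode_dna(s)
    hits <- sum(score_windows(enc, lom) >= threshold, na.rm = TRUE)
    if (both_strands) {
      enc_rc <- rev(5L - enc)
      hits <- hits + sum(score_windows(enc_rc, lom) >= threshold, na.rm = TRUE)
    }
    as.integer(hits)
  }, integer(1), USE.NAMES = FALSE)
}

#' Motif enrichment of target regions against background regions
#'
#' A region counts as hit when it contains at least one motif hit on either
#' strand.  The background hit rate (floored at `1 / (2 * n_bg)` to avoid
#' zero) parameterizes an upper-tail binomial test on the number of hit
#' target regions.
#'
#' @param pwm a `pwm`.
#' @param bg a `background_model`.
#' @param target_seqs non-empty character vector of target region sequences.
#' @param background_seqs non-empty character vector of background region
#'   sequences.
#' @param threshold_quantile background quantile for the hit threshold.
#' @return A `motif_enrichment` object: `motif_id`, `tf_symbol`,
#'   `target_hits`, `target_n`, `bg_rate`, `p`, `threshold`.
#' @export
motif_enrichment <- function(pwm, bg, target_seqs, background_seqs,
                             threshold_quantile = 0.9999) {
  if (!length(target_seqs)) stop_input("motif_enrichment: empty target set")
  if (!length(background_seqs))
    stop_input("motif_enrichment: empty background set")
  thr <- score_threshold(score_distribution(pwm, bg), threshold_quantile)
  th <- scan_regions(pwm, bg, target_seqs, threshold = thr)
  bh <- scan_regions(pwm, bg, background_seqs, threshold = thr)
  n <- length(th)
  target_hits <- sum(th > 0)
  bg_rate <- max(mean(bh > 0), 1 / (2 * length(bh)))
  p <- min(pbinom(target_hits - 1, n, bg_rate, lower.tail = FALSE), 1)
  structure(list(motif_id = pwm$motif_id, tf_symbol = pwm$tf_symbol,
                 target_hits = target_hits, target_n = n,
                 bg_rate = bg_rate, p = p, threshold = thr),
            class = "motif_enrichment")
}

#' Rank motif enrichment results
#'
#' Ascending by p-value; ties broken by descending target hit count, then
#' motif id; ranks assigned 1..k without gaps.
#'
#' @param results a list of `motif_enrichment` objects.
#' @param k number of top motifs to keep (default 20).
#' @return A data frame with columns `motif_id`, `tf_symbol`, `target_hits`,
#'   `target_n`, `bg_rate`, `p`, `rank`.
#' @export
rank_motifs <- function(results, k = 20) {
  if (!length(results)) stop_input("rank_motifs: no results")
  df <- data.frame(
    motif_id = vapply(results, `[[`, "", "motif_id"),
    tf_symbol = vapply(results, function(r) as.character(r$tf_symbol), ""),
    target_hits = vapply(results, `[[`, 0, "target_hits"),
    target_n = vapply(results, `[[`, 0, "target_n"),
    bg_rate = vapply(results, `[[`, 0, "bg_rate"),
    p = vapply(results, `[[`, 0, "p"),
    stringsAsFactors = FALSE)
  ord <- order(df$p, -df$target_hits, df$motif_id)
  df <- df[ord, , drop = FALSE][seq_len(min(k, nrow(df))), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Extract region sequences from a genome
#'
#' @param genome named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @param rs a `region_set`; intervals are clipped to chromosome bounds.
#' @return Character vector of sequences, one per interval.
#' @export
extract_sequences <- function(genome, rs) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!nrow(rs)) return(character())
  missing <- setdiff(unique(rs$chrom), names(genome))
  if (length(missing))
    stop_input("chromosome(s) absent from genome: ",
               paste(missing, collapse = ", "))
  lens <- setNames(Biostrings::width(genome), names(genome))
  vapply(seq_len(nrow(rs)), function(i) {
    s <- max(rs$start[i] + 1, 1)
    e <- min(rs$end[i], lens[[rs$chrom[i]]])
    if (s > e) return("")
    as.character(Biostrings::subseq(genome[[rs$chrom[i]]], start = s, end = e))
  }, "")
}

#' Shuffle regions to random genomic positions of matched lengths
#'
#' Draws, for each input interval, a random position (chromosome chosen
#' proportional to length) avoiding the excluded regions; widths are
#' preserved.  Uses the current RNG state, so results are reproducible under
#' `set.seed()`.
#'
#' @param rs a `region_set`.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param exclude optional `region_set` the shuffled regions must not touch.
#' @param max_tries rejection-sampling cap per interval.
#' @return A `region_set` labelled `"background"`.
#' @export
shuffle_regions <- function(rs, chrom_lengths, exclude = NULL,
                            max_tries = 1000) {
  if (!nrow(rs)) return(region_set(regulator = "background"))
  gex <- if (!is.null(exclude) && nrow(exclude)) as_granges(exclude) else NULL
  widths <- rs$end - rs$start
  chroms <- names(chrom_lengths)
  pl <- chrom_lengths / sum(chrom_lengths)
  out_chrom <- character(length(widths))
  out_start <- numeric(length(widths))
  for (i in seq_along(widths)) {
    for (try in seq_len(max_tries)) {
      cc <- sample(chroms, 1, prob = pl)
      maxs <- chrom_lengths[[cc]] - widths[i]
      if (maxs < 1) next
      st <- floor(runif(1, 0, maxs))
      if (!is.null(gex)) {
        cand <- GenomicRanges::GRanges(cc, IRanges::IRanges(st + 1,
                                                            st + widths[i]))
        if (suppressWarnings(any(IRanges::overlapsAny(cand, gex)))) next
      }
      out_chrom[i] <- cc
      out_start[i] <- st
      break
    }
    if (out_chrom[i] == "")
      stop_input("shuffle_regions: could not place interval ", i,
                 " after ", max_tries, " tries")
  }
  region_set(out_chrom, out_start, out_start + widths,
             regulator = "background")
}
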