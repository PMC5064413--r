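#' Configuration of the synthetic input bundle
#'
#' Parameters of the planted study conditions the generator emulates:
#' cofactor sites shared by MED1/SMC1A/NIPBL at enhancers and promoters of
#' active genes, a CTCF-associated Cohesin subpopulation on disjoint sites, a
#' small planted CRC of interconnected autoregulatory TFs whose consensus
#' motifs are written into the genome under their peaks, decoy TFs with
#' random peaks, decoy motifs mapped to non-assayed TF symbols, a chromatin
#' state segmentation tiling each chromosome, and pathway gene sets with one
#' planted set.
#'
#' @param seed RNG seed; the bundle is fully determined by it.
#' @param n_chroms,chrom_length genome shape.
#' @param n_genes total gene count.
#' @param n_crc_tfs planted CRC size (default 3).
#' @param n_decoy_tfs decoy ChIP'd TFs (default 27).
#' @param n_decoy_motifs decoy PWMs (default 30).
#' @param coocc_prob probability a cofactor site carries the full
#'   MED1/SMC1A/NIPBL trio (default 0.8).
#' @param ctcf_smc1a_frac fraction of SMC1A peaks placed at CTCF-only sites
#'   (default 0.4; must be < 1).
#' @param motif_plant_rate_target fraction of cofactor sites carrying each
#'   CRC TF's peaks and planted consensus motif (default 0.6).
#' @param motif_plant_rate_bg background consensus copies per CRC motif,
#'   expressed as a fraction of the cofactor site count (default 0.05).
#' @param n_cofactor_sites number of cofactor sites (default 150).
#' @param n_ctcf_only CTCF sites without Cohesin (default 40).
#' @param n_decoy_peaks peaks per decoy TF (default 60).
#' @param peak_meanlog,peak_sdlog log-normal peak width parameters
#'   (median 400 bp).
#' @param gene_length_range uniform range of gene body lengths in bp.
#' @param gc_content genome GC fraction.
#' @param autoregulatory indices (within the CRC TFs) of the autoregulatory
#'   subset; default all of them.
#' @param active_gene_frac fraction of genes flagged active.
#' @param n_pathways gene sets in the GMT (one planted + decoys).
#' @return A validated `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1, n_chroms = 2, chrom_length = 500000,
                             n_genes = 60, n_crc_tfs = 3, n_decoy_tfs = 27,
                             n_decoy_motifs = 30, coocc_prob = 0.8,
                             ctcf_smc1a_frac = 0.4,
                             motif_plant_rate_target = 0.6,
                             motif_plant_rate_bg = 0.05,
                             n_cofactor_sites = 150, n_ctcf_only = 40,
                             n_decoy_peaks = 60,
                             peak_meanlog = log(400), peak_sdlog = 0.3,
                             gene_length_range = c(800, 1200),
                             gc_content = 0.41,
                             autoregulatory = NULL,
                             active_gene_frac = 0.7,
                             n_pathways = 20) {
  probs <- c(coocc_prob, motif_plant_rate_target, motif_plant_rate_bg,
             gc_content, active_gene_frac)
  if (any(probs < 0) || any(probs > 1))
    stop_input("synthetic_config: probabilities must lie in [0, 1]")
  if (ctcf_smc1a_frac < 0 || ctcf_smc1a_frac >= 1)
    stop_input("synthetic_config: ctcf_smc1a_frac must lie in [0, 1)")
  counts <- c(n_chroms, n_genes, n_crc_tfs, n_decoy_motifs,
              n_cofactor_sites, n_pathways)
  if (any(counts < 1)) stop_input("synthetic_config: counts must be >= 1")
  if (n_crc_tfs + n_decoy_tfs > n_genes)
    stop_input("synthetic_config: need n_genes >= n_crc_tfs + n_decoy_tfs")
  if (is.null(autoregulatory)) autoregulatory <- seq_len(n_crc_tfs)
  if (length(autoregulatory) &&
      (any(autoregulatory < 1) || any(autoregulatory > n_crc_tfs)))
    stop_input("synthetic_config: autoregulatory indices out of range")
  mean_gene <- mean(gene_length_range)
  if (n_chroms * chrom_length <= 10 * n_genes * mean_gene)
    stop_input("synthetic_config: chrom_length too small; total genome must ",
               "exceed 10 x n_genes x mean gene length")
  structure(list(seed = seed, n_chroms = n_chroms,
                 chrom_length = chrom_length, n_genes = n_genes,
                 n_crc_tfs = n_crc_tfs, n_decoy_tfs = n_decoy_tfs,
                 n_decoy_motifs = n_decoy_motifs, coocc_prob = coocc_prob,
                 ctcf_smc1a_frac = ctcf_smc1a_frac,
                 motif_plant_rate_target = motif_plant_rate_target,
                 motif_plant_rate_bg = motif_plant_rate_bg,
                 n_cofactor_sites = n_cofactor_sites,
                 n_ctcf_only = n_ctcf_only, n_decoy_peaks = n_decoy_peaks,
                 peak_meanlog = peak_meanlog, peak_sdlog = peak_sdlog,
                 gene_length_range = gene_length_range,
                 gc_content = gc_content, autoregulatory = autoregulatory,
                 active_gene_frac = active_gene_frac,
                 n_pathways = n_pathways),
            class = "synthetic_config")
}

## internal: random peak widths
.peak_widths <- function(n, cfg) {
  pmax(100, round(rlnorm(n, cfg$peak_meanlog, cfg$peak_sdlog)))
}

## internal: jittered copy of site intervals (overlap preserved; widths>=100)
.jitter_sites <- function(chrom, start, end, max_shift = 40) {
  a <- round(runif(length(start), -max_shift, max_shift))
  b <- round(runif(length(end), -max_shift, max_shift))
  s <- pmax(0, start + a)
  e <- pmax(s + 1, end + b)
  list(chrom = chrom, start = s, end = e)
}

## internal: place n disjoint intervals by rejection against `occupied`
.place_disjoint <- function(n, widths, chroms, chrom_length, occupied,
                            gap = 200, max_tries = 2000) {
  out <- data.frame(chrom = character(n), start = numeric(n),
                    end = numeric(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cc <- sample(chroms, 1)
      st <- floor(runif(1, 1000, chrom_length - widths[i] - 1000))
      en <- st + widths[i]
      same <- occupied$chrom == cc
      if (!any(same & occupied$start < en + gap & st < occupied$end + gap)) {
        out$chrom[i] <- cc; out$start[i] <- st; out$end[i] <- en
        occupied <- rbind(occupied,
                          data.frame(chrom = cc, start = st, end = en,
                                     stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop_input("could not place synthetic site ", i,
                 "; increase chrom_length")
  }
  list(sites = out, occupied = occupied)
}

#' Generate a synthetic input bundle with planted ground truth
#'
#' Deterministic given `cfg$seed`.  Returns every pipeline input in memory
#' (genome, gene models, peak sets, segmentation, PWMs, motif map, pathways)
#' together with the planted truth; when `outdir` is given the bundle is also
#' written to disk in the standard formats (FASTA, GTF, BED, ChromHMM-dense
#' BED, PWM text, TSV, GMT, truth JSON and a ready-to-run pipeline
#' `config.yaml`).
#'
#' @param cfg a `synthetic_config`.
#' @param outdir optional output directory.
#' @return A `crc_bundle` list: `config`, `chrom_lengths`, `genome`,
#'   `genes`, `peaks` (named `region_set` list: MED1, SMC1A, NIPBL, CTCF and
#'   one set per TF), `segmentation`, `pwms`, `pwm_counts`, `motif_map`,
#'   `pathways`, `truth`, and `paths` when written.
#' @export
generate_bundle <- function(cfg, outdir = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  clen <- setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)

  ## ---- gene layout: evenly slotted along chromosomes -------------------
  per_chrom <- diff(round(seq(0, cfg$n_genes, length.out = cfg$n_chroms + 1)))
  gene_chrom <- rep(chroms, per_chrom)
  gene_start <- numeric(cfg$n_genes)
  gene_len <- round(runif(cfg$n_genes, cfg$gene_length_range[1],
                          cfg$gene_length_range[2]))
  idx <- 1L
  for (ci in seq_len(cfg$n_chroms)) {
    g <- per_chrom[ci]
    if (g == 0) next
    usable <- cfg$chrom_length - 27000
    slot_w <- floor(usable / g)
    if (slot_w < max(cfg$gene_length_range) + 4000)
      stop_input("generate_bundle: regulatory windows collide; ",
                 "increase chrom_length")
    for (j in seq_len(g)) {
      gene_start[idx] <- 12000 + (j - 1) * slot_w + round(runif(1, 0, 2000))
      idx <- idx + 1L
    }
  }
  gene_end <- gene_start + gene_len
  gene_strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  if (any(gene_end + 12000 > cfg$chrom_length))
    stop_input("generate_bundle: regulatory windows exceed chromosome; ",
               "increase chrom_length")

  ## symbols: CRC TF genes spread across the genome, decoy TF genes random
  crc_idx <- unique(round(seq(1, cfg$n_genes,
                              length.out = cfg$n_crc_tfs + 2)))[-c(1, cfg$n_crc_tfs + 2)]
  crc_idx <- crc_idx[seq_len(cfg$n_crc_tfs)]
  decoy_idx <- sample(setdiff(seq_len(cfg$n_genes), crc_idx),
                      cfg$n_decoy_tfs)
  crc_syms <- sprintf("CRC%d", seq_len(cfg$n_crc_tfs))
  decoy_syms <- sprintf("DTF%02d", seq_len(cfg$n_decoy_tfs))
  symbol <- sprintf("GENE%03d", seq_len(cfg$n_genes))
  symbol[crc_idx] <- crc_syms
  symbol[decoy_idx] <- decoy_syms
  genes <- gene_models(gene_id = sprintf("g%03d", seq_len(cfg$n_genes)),
                       symbol = symbol, chrom = gene_chrom,
                       start = gene_start, end = gene_end,
                       strand = gene_strand)
  auto_syms <- crc_syms[cfg$autoregulatory]

  ## active genes: all CRC genes plus a random draw of the rest
  n_active <- max(cfg$n_crc_tfs,
                  round(cfg$active_gene_frac * cfg$n_genes))
  other <- setdiff(genes$symbol, crc_syms)
  active_syms <- c(crc_syms,
                   sample(other, min(length(other),
                                     n_active - cfg$n_crc_tfs)))

  ## ---- cofactor sites ---------------------------------------------------
  ## promoter sites at CRC TSSs (forced trio) + some active promoters;
  ## remaining sites are intergenic enhancers.
  crc_rows <- match(crc_syms, genes$symbol)
  n_prom_other <- min(length(active_syms) - cfg$n_crc_tfs,
                      max(0, round(0.4 * cfg$n_cofactor_sites) -
                            cfg$n_crc_tfs))
  prom_other_syms <- if (n_prom_other > 0)
    sample(setdiff(active_syms, crc_syms), n_prom_other) else character()
  prom_rows <- c(crc_rows, match(prom_other_syms, genes$symbol))
  n_prom <- length(prom_rows)
  n_enh <- cfg$n_cofactor_sites - n_prom
  if (n_enh < 0) stop_input("n_cofactor_sites too small for promoter sites")

  w_prom <- .peak_widths(n_prom, cfg)
  site_chrom <- genes$chrom[prom_rows]
  site_start <- pmax(1000, round(genes$tss[prom_rows] - w_prom / 2))
  site_end <- site_start + w_prom
  site_class <- rep("promoter", n_prom)
  site_gene <- genes$symbol[prom_rows]
  occupied <- data.frame(chrom = site_chrom, start = site_start,
                         end = site_end, stringsAsFactors = FALSE)
  if (n_enh > 0) {
    pl <- .place_disjoint(n_enh, .peak_widths(n_enh, cfg), chroms,
                          cfg$chrom_length, occupied)
    occupied <- pl$occupied
    site_chrom <- c(site_chrom, pl$sites$chrom)
    site_start <- c(site_start, pl$sites$start)
    site_end <- c(site_end, pl$sites$end)
    site_class <- c(site_class, rep("enhancer", n_enh))
    site_gene <- c(site_gene, rep(NA_character_, n_enh))
  }
  n_sites <- length(site_start)

  ## trio membership: MED1 everywhere; one Bernoulli(coocc_prob) indicator
  ## adds both SMC1A and NIPBL, otherwise each appears independently at 0.1
  trio <- rbinom(n_sites, 1, cfg$coocc_prob) == 1
  trio[site_gene %in% crc_syms] <- TRUE
  has_nipbl <- trio | rbinom(n_sites, 1, 0.1) == 1
  has_smc1a <- trio | rbinom(n_sites, 1, 0.1) == 1

  mk_peaks <- function(sel, reg) {
    j <- .jitter_sites(site_chrom[sel], site_start[sel], site_end[sel])
    region_set(j$chrom, j$start, j$end, regulator = reg)
  }
  med1 <- mk_peaks(rep(TRUE, n_sites), "MED1")
  nipbl <- mk_peaks(has_nipbl, "NIPBL")

  ## ---- CTCF sites (disjoint from cofactor sites) ------------------------
  n_smc1a_enh <- sum(has_smc1a)
  n_ctcf_smc1a <- round(cfg$ctcf_smc1a_frac / (1 - cfg$ctcf_smc1a_frac) *
                          n_smc1a_enh)
  n_ctcf <- n_ctcf_smc1a + cfg$n_ctcf_only
  pl <- .place_disjoint(n_ctcf, .peak_widths(n_ctcf, cfg), chroms,
                        cfg$chrom_length, occupied)
  occupied <- pl$occupied
  ctcf_sites <- pl$sites
  ctcf_smc1a_sel <- seq_len(n_ctcf) %in% sample(n_ctcf, n_ctcf_smc1a)
  jc <- .jitter_sites(ctcf_sites$chrom, ctcf_sites$start, ctcf_sites$end)
  ctcf <- region_set(jc$chrom, jc$start, jc$end, regulator = "CTCF")
  js1 <- .jitter_sites(site_chrom[has_smc1a], site_start[has_smc1a],
                       site_end[has_smc1a])
  js2 <- .jitter_sites(ctcf_sites$chrom[ctcf_smc1a_sel],
                       ctcf_sites$start[ctcf_smc1a_sel],
                       ctcf_sites$end[ctcf_smc1a_sel])
  smc1a <- region_set(c(js1$chrom, js2$chrom), c(js1$start, js2$start),
                      c(js1$end, js2$end), regulator = "SMC1A")

  ## ---- PWMs -------------------------------------------------------------
  crc_motif_len <- 10L
  crc_motif_ids <- sprintf("%s_SYN.M1", crc_syms)
  motif_tf_syms <- sprintf("MTF%02d", seq_len(cfg$n_decoy_motifs))
  decoy_motif_ids <- sprintf("%s_SYN.M1", motif_tf_syms)
  pwm_counts <- list()
  consensus <- character(cfg$n_crc_tfs)
  for (t in seq_len(cfg$n_crc_tfs)) {
    cons <- sample(.DNA_BASES, crc_motif_len, replace = TRUE)
    consensus[t] <- paste(cons, collapse = "")
    cnt <- matrix(2, 4, crc_motif_len, dimnames = list(.DNA_BASES, NULL))
    cnt[cbind(match(cons, .DNA_BASES), seq_len(crc_motif_len))] <- 94
    pwm_counts[[crc_motif_ids[t]]] <- cnt
  }
  for (d in seq_len(cfg$n_decoy_motifs)) {
    len <- sample(8:12, 1)
    cnt <- vapply(seq_len(len), function(j) {
      g <- rgamma(4, 0.7)
      as.numeric(rmultinom(1, 100, g / sum(g)))
    }, numeric(4))
    rownames(cnt) <- .DNA_BASES
    pwm_counts[[decoy_motif_ids[d]]] <- cnt
  }
  motif_map <- data.frame(motif_id = c(crc_motif_ids, decoy_motif_ids),
                          tf_symbol = c(crc_syms, motif_tf_syms),
                          stringsAsFactors = FALSE)
  pwms <- lapply(seq_len(nrow(motif_map)), function(i)
    pwm_from_counts(motif_map$motif_id[i], pwm_counts[[motif_map$motif_id[i]]],
                    pseudocount = 0.8, tf_symbol = motif_map$tf_symbol[i]))
  names(pwms) <- motif_map$motif_id

  ## ---- CRC TF peaks + motif placements ----------------------------------
  placements <- list()
  tf_peaks <- list()
  n_target_sites <- ceiling(cfg$motif_plant_rate_target * n_sites)
  win <- regulatory_window(genes[crc_rows, , drop = FALSE], 10000)
  for (t in seq_len(cfg$n_crc_tfs)) {
    ## a non-autoregulatory CRC TF must not pick sites inside its own
    ## regulatory window (that would plant a spurious self-edge)
    pool <- seq_len(n_sites)
    if (!(t %in% cfg$autoregulatory)) {
      w <- win[win$symbol == crc_syms[t], ]
      own <- site_chrom == w$chrom & site_start < w$w_end &
        w$w_start < site_end
      pool <- pool[!own]
    }
    sel <- sort(sample(pool, min(n_target_sites, length(pool))))
    j <- .jitter_sites(site_chrom[sel], site_start[sel], site_end[sel])
    pc <- j$chrom; ps <- j$start; pe <- j$end
    ## one peak in every CRC TF's regulatory window (self only if
    ## autoregulatory), centred on the target gene's TSS
    for (u in seq_len(cfg$n_crc_tfs)) {
      if (u == t && !(t %in% cfg$autoregulatory)) next
      g <- crc_rows[u]
      w <- .peak_widths(1, cfg)
      st <- max(0, round(genes$tss[g] - w / 2 + runif(1, -30, 30)))
      pc <- c(pc, genes$chrom[g]); ps <- c(ps, st); pe <- c(pe, st + w)
    }
    tf_peaks[[crc_syms[t]]] <- region_set(pc, ps, pe,
                                          regulator = crc_syms[t])
    ## plant the consensus at a fixed per-TF offset around each target
    ## site's centre (deep enough inside to survive peak-boundary jitter)
    pos <- floor((site_start[sel] + site_end[sel]) / 2) - 5 +
      round((t - (cfg$n_crc_tfs + 1) / 2) * 15)
    strnd <- sample(c("+", "-"), length(sel), replace = TRUE)
    placements[[length(placements) + 1L]] <-
      data.frame(motif_id = crc_motif_ids[t], chrom = site_chrom[sel],
                 pos = pos, strand = strnd, class = "target",
                 stringsAsFactors = FALSE)
    ## scattered background copies outside planted sites
    n_bg <- max(1, round(cfg$motif_plant_rate_bg * n_sites))
    bg <- .place_disjoint(n_bg, rep(crc_motif_len, n_bg), chroms,
                          cfg$chrom_length, occupied, gap = 0)
    occupied <- bg$occupied
    placements[[length(placements) + 1L]] <-
      data.frame(motif_id = crc_motif_ids[t], chrom = bg$sites$chrom,
                 pos = bg$sites$start,
                 strand = sample(c("+", "-"), n_bg, replace = TRUE),
                 class = "background", stringsAsFactors = FALSE)
  }
  placements <- do.call(rbind, placements)

  ## ---- decoy TF peaks: uniform random positions -------------------------
  for (d in seq_len(cfg$n_decoy_tfs)) {
    w <- .peak_widths(cfg$n_decoy_peaks, cfg)
    cc <- sample(chroms, cfg$n_decoy_peaks, replace = TRUE)
    st <- floor(runif(cfg$n_decoy_peaks, 0, cfg$chrom_length - w))
    tf_peaks[[decoy_syms[d]]] <- region_set(cc, st, st + w,
                                            regulator = decoy_syms[d])
  }

  ## ---- genome sequence with planted consensus copies --------------------
  base_probs <- c((1 - cfg$gc_content) / 2, cfg$gc_content / 2,
                  cfg$gc_content / 2, (1 - cfg$gc_content) / 2)
  genome_chars <- lapply(chroms, function(cc)
    sample(.DNA_BASES, cfg$chrom_length, replace = TRUE, prob = base_probs))
  names(genome_chars) <- chroms
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  cons_by_motif <- setNames(consensus, crc_motif_ids)
  for (i in seq_len(nrow(placements))) {
    s <- cons_by_motif[[placements$motif_id[i]]]
    if (placements$strand[i] == "-") s <- rc(s)
    p0 <- placements$pos[i]
    genome_chars[[placements$chrom[i]]][(p0 + 1):(p0 + nchar(s))] <-
      strsplit(s, "")[[1]]
  }
  genome <- Biostrings::DNAStringSet(vapply(genome_chars, paste,
                                            "", collapse = ""))
  names(genome) <- chroms

  ## ---- segmentation: sites tiled with quiescent background --------------
  seg_df <- rbind(
    data.frame(chrom = site_chrom, start = site_start, end = site_end,
               state = ifelse(site_class == "promoter", "1_TssA", "9_EnhA1"),
               stringsAsFactors = FALSE),
    data.frame(chrom = ctcf_sites$chrom, start = ctcf_sites$start,
               end = ctcf_sites$end, state = "16_CTCF",
               stringsAsFactors = FALSE))
  seg <- do.call(rbind, lapply(chroms, function(cc) {
    s <- seg_df[seg_df$chrom == cc, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    bounds <- c(0, as.vector(rbind(s$start, s$end)), cfg$chrom_length)
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1]
    states <- character(length(starts))
    states[seq(1, length(states), by = 2)] <- "18_Quies"
    if (nrow(s)) states[seq(2, length(states), by = 2)] <- s$state
    keep <- ends > starts
    data.frame(chrom = cc, start = starts[keep], end = ends[keep],
               state = states[keep], stringsAsFactors = FALSE)
  }))
  segmentation <- region_set(seg$chrom, seg$start, seg$end, name = seg$state,
                             regulator = "segmentation")

  ## ---- pathways ----------------------------------------------------------
  planted_pathway <- sort(unique(site_gene[!is.na(site_gene)]))
  pathways <- list(COFACTOR_TARGET_GENES = planted_pathway)
  for (i in seq_len(cfg$n_pathways - 1)) {
    sz <- sample(10:min(30, cfg$n_genes), 1)
    pathways[[sprintf("RANDOM_SET_%02d", i)]] <- sort(sample(genes$symbol, sz))
  }

  peaks <- c(list(MED1 = med1, SMC1A = smc1a, NIPBL = nipbl, CTCF = ctcf),
             tf_peaks)
  truth <- list(crc_tfs = crc_syms, autoregulatory = auto_syms,
                decoy_tfs = decoy_syms, crc_motifs = crc_motif_ids,
                consensus = setNames(consensus, crc_motif_ids),
                placements = placements,
                sites = data.frame(chrom = site_chrom, start = site_start,
                                   end = site_end, class = site_class,
                                   gene = site_gene, trio = trio,
                                   nipbl = has_nipbl, smc1a = has_smc1a,
                                   stringsAsFactors = FALSE),
                planted_pathway = "COFACTOR_TARGET_GENES",
                config = unclass(cfg))
  bundle <- structure(list(config = cfg, chrom_lengths = clen,
                           genome = genome, genes = genes, peaks = peaks,
                           segmentation = segmentation, pwms = pwms,
                           pwm_counts = pwm_counts, motif_map = motif_map,
                           pathways = pathways, truth = truth),
                      class = "crc_bundle")
  if (!is.null(outdir)) bundle$paths <- write_bundle(bundle, outdir)
  bundle
}

#' @export
print.crc_bundle <- function(x, ...) {
  cat(sprintf(paste0("<crc_bundle> seed %s: %d chrom(s) x %d bp, %d genes, ",
                     "%d peak sets, %d PWMs\n"),
              format(x$config$seed), x$config$n_chroms,
              x$config$chrom_length, nrow(x$genes), length(x$peaks),
              length(x$pwms)))
  cat("planted CRC:", paste(x$truth$crc_tfs, collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic bundle to disk
#'
#' Emits exactly the formats the pipeline reads: `genome.fa`, `genes.gtf`,
#' `peaks/<REGULATOR>.bed`, `segmentation.bed` (ChromHMM dense), `pwms.txt`,
#' `motif_map.tsv`, `pathways.gmt`, `truth.json` and a pipeline
#' `config.yaml`.  Byte-identical for identical bundles.
#'
#' @param bundle a `crc_bundle`.
#' @param outdir output directory (created; must be writable).
#' @return Named list of the written paths.
#' @export
write_bundle <- function(bundle, outdir) {
  ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir))
    stop_input("write_bundle: cannot create output directory ", outdir)
  pdir <- file.path(outdir, "peaks")
  dir.create(pdir, showWarnings = FALSE)
  paths <- list(genome = file.path(outdir, "genome.fa"),
                genes = file.path(outdir, "genes.gtf"),
                segmentation = file.path(outdir, "segmentation.bed"),
                pwms = file.path(outdir, "pwms.txt"),
                motif_map = file.path(outdir, "motif_map.tsv"),
                pathways = file.path(outdir, "pathways.gmt"),
                truth = file.path(outdir, "truth.json"),
                config = file.path(outdir, "config.yaml"))
  Biostrings::writeXStringSet(bundle$genome, paths$genome)
  g <- bundle$genes
  writeLines(sprintf(paste0("%s\tcoreCRC\tgene\t%d\t%d\t.\t%s\t.\t",
                            "gene_id \"%s\"; gene_name \"%s\";"),
                     g$chrom, g$start + 1, g$end, g$strand, g$gene_id,
                     g$symbol),
             paths$genes)
  for (nm in names(bundle$peaks)) {
    paths[[paste0("peaks_", nm)]] <- file.path(pdir, paste0(nm, ".bed"))
    write_bed(bundle$peaks[[nm]], file.path(pdir, paste0(nm, ".bed")))
  }
  write_bed(bundle$segmentation, paths$segmentation)
  con <- file(paths$pwms, "w")
  for (id in names(bundle$pwm_counts)) {
    writeLines(paste0(">", id), con)
    cnt <- bundle$pwm_counts[[id]]
    writeLines(apply(cnt, 2, function(col)
      paste(format(col, scientific = FALSE, trim = TRUE), collapse = "\t")),
      con)
  }
  close(con)
  writeLines(c("motif_id\ttf_symbol",
               paste(bundle$motif_map$motif_id, bundle$motif_map$tf_symbol,
                     sep = "\t")),
             paths$motif_map)
  writeLines(vapply(names(bundle$pathways), function(id)
    paste(c(id, "synthetic gene set",
            bundle$pathways[[id]]), collapse = "\t"), ""),
    paths$pathways)
  jsonlite::write_json(bundle$truth, paths$truth, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, dataframe = "columns")
  tf_syms <- setdiff(names(bundle$peaks), c("MED1", "SMC1A", "NIPBL", "CTCF"))
  ## paths inside config.yaml are relative to the bundle directory, so a
  ## bundle can be moved (and two same-seed bundles are byte-identical)
  cfgy <- list(
    inputs = c(list(med1 = "peaks/MED1.bed", smc1a = "peaks/SMC1A.bed",
                    nipbl = "peaks/NIPBL.bed", ctcf = "peaks/CTCF.bed",
                    genes = "genes.gtf", genes_format = "gtf",
                    genome = "genome.fa", pwms = "pwms.txt",
                    motif_map = "motif_map.tsv",
                    segmentation = "segmentation.bed",
                    pathways = "pathways.gmt"),
               list(tf_peaks = setNames(
                 as.list(file.path("peaks", paste0(tf_syms, ".bed"))),
                 tf_syms))),
    params = list(k = 20, upstream = 10000, threshold_quantile = 0.9999,
                  pseudocount = 0.8, max_assign_distance = 50000,
                  seed = bundle$config$seed))
  writeLines(yaml::as.yaml(cfgy), paths$config)
  paths
}
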