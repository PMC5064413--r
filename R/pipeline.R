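#' Infer the core transcriptional regulatory circuitry
#'
#' Runs the complete inference on peak sets, gene models, a genome and a PWM
#' collection: co-occupancy structure (occupancy matrix, PCA, pairwise
#' correlations, CTCF partition of Cohesin, colocalization clustering,
#' optional chromatin-state profiles), motif enrichment inside the
#' cofactor co-occupied regions against shuffled background regions, TF
#' overlap ranking, candidate cross-referencing, circuitry graph with
#' autoregulation detection, leading-candidate selection and (optionally)
#' pathway enrichment of the genes assigned to co-occupied regions.
#'
#' Background region shuffling draws from the current RNG state; call
#' `set.seed()` (or use [run_crc_pipeline()]) for reproducible runs.
#'
#' @param med1,smc1a,nipbl cofactor peak `region_set`s.
#' @param ctcf CTCF peak `region_set` (optional but recommended).
#' @param tf_sets named list of TF peak `region_set`s.
#' @param genes gene-model data frame ([read_genes()]).
#' @param genome named character vector or `DNAStringSet`.
#' @param pwms named list of `pwm` objects ([load_pwms()]).
#' @param segmentation optional labelled `region_set` (ChromHMM dense).
#' @param pathways optional named list of gene sets ([read_gmt()]).
#' @param k top-list size for TF and motif rankings (default 20).
#' @param upstream regulatory-window extension in bp (default 10000).
#' @param threshold_quantile motif hit threshold quantile (default 0.9999).
#' @param max_assign_distance peak-to-gene nearest-TSS cap (default 50000).
#' @param aliases motif/protein alias table ([read_tf_aliases()]).
#' @return A `crc` object with components `occupancy`, `pca`,
#'   `correlations`, `smc1a_partition`, `colocalization`, `state_profiles`,
#'   `coocc` (co-occupied regions), `motif_ranking`, `tf_ranking`,
#'   `candidates`, `graph`, `leading`, `pathway_enrichment`, `parameters`.
#' @seealso [generate_bundle()] for a synthetic input bundle;
#'   [run_crc_pipeline()] for the file-based front end.
#' @export
infer_crc <- function(med1, smc1a, nipbl, ctcf = NULL, tf_sets, genes,
                      genome, pwms, segmentation = NULL, pathways = NULL,
                      k = 20, upstream = 10000, threshold_quantile = 0.9999,
                      max_assign_distance = 50000,
                      aliases = read_tf_aliases()) {
  cofactors <- list(MED1 = med1, SMC1A = smc1a, NIPBL = nipbl)
  occ_sets <- cofactors
  if (!is.null(ctcf)) occ_sets$CTCF <- ctcf
  occ <- build_occupancy_matrix(occ_sets)
  pca <- pca_regulators(occ)
  pairs <- utils::combn(names(occ_sets), 2)
  correlations <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    r <- regulator_correlation(occ, pairs[1, i], pairs[2, i])
    data.frame(a = pairs[1, i], b = pairs[2, i], R = r$R, p = r$p,
               stringsAsFactors = FALSE)
  }))
  part <- if (!is.null(ctcf)) partition_by_ctcf(smc1a, ctcf) else NULL
  coloc_sets <- list(MED1 = med1, NIPBL = nipbl)
  if (!is.null(part)) {
    if (nrow(part$no_ctcf)) coloc_sets[["SMC1A (no CTCF)"]] <- part$no_ctcf
    if (nrow(part$with_ctcf)) coloc_sets[["SMC1A (with CTCF)"]] <- part$with_ctcf
    coloc_sets$CTCF <- ctcf
  } else coloc_sets$SMC1A <- smc1a
  coloc <- colocalization_matrix(coloc_sets)
  coocc <- intersect_all(cofactors)
  state_profiles <- NULL
  if (!is.null(segmentation)) {
    prof_sets <- c(coloc_sets, list(`MED1-SMC1A-NIPBL` = coocc))
    state_profiles <- lapply(prof_sets, state_overlap_profile, segmentation)
  }
  motif_ranking <- NULL
  if (nrow(coocc) > 0 && length(pwms)) {
    bgmodel <- background_from_genome(genome)
    target_seqs <- extract_sequences(genome, coocc)
    if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
    clens <- setNames(Biostrings::width(genome), names(genome))
    bg_regions <- shuffle_regions(coocc, clens, exclude = coocc)
    bg_seqs <- extract_sequences(genome, bg_regions)
    enr <- lapply(pwms, motif_enrichment, bg = bgmodel,
                  target_seqs = target_seqs, background_seqs = bg_seqs,
                  threshold_quantile = threshold_quantile)
    motif_ranking <- rank_motifs(enr, k)
  } else warning("no cofactor co-occupied regions; motif stage skipped")
  tf_ranking <- rank_tf_overlap(cofactors, tf_sets, k)
  candidates <- if (!is.null(motif_ranking))
    candidate_tfs(tf_ranking, motif_ranking, aliases) else character()
  graph <- NULL
  leading <- character()
  if (length(candidates)) {
    graph <- build_circuitry(candidates, tf_sets, genes, coocc, upstream)
    leading <- leading_candidates(graph)
  }
  pw <- NULL
  assignments <- NULL
  if (!is.null(pathways) && nrow(coocc)) {
    assignments <- assign_peaks_to_genes(coocc, genes, upstream,
                                         max_assign_distance)
    target <- unique(assignments$symbol[!is.na(assignments$symbol)])
    pw <- pathway_enrichment(target, pathways, universe = genes$symbol)
  }
  structure(list(occupancy = occ, pca = pca, correlations = correlations,
                 smc1a_partition = part, colocalization = coloc,
                 state_profiles = state_profiles, coocc = coocc,
                 motif_ranking = motif_ranking, tf_ranking = tf_ranking,
                 candidates = candidates, graph = graph, leading = leading,
                 assignments = assignments, pathway_enrichment = pw,
                 parameters = list(k = k, upstream = upstream,
                                   threshold_quantile = threshold_quantile,
                                   max_assign_distance = max_assign_distance)),
            class = "crc")
}

#' @export
print.crc <- function(x, ...) {
  cat("Core transcriptional regulatory circuitry inference\n")
  cat(sprintf("  occupancy: %d union regions x %d regulators\n",
              nrow(x$occupancy$M), ncol(x$occupancy$M)))
  cat(sprintf("  co-occupied regions (MED1 & SMC1A & NIPBL): %d\n",
              nrow(x$coocc)))
  cat(sprintf("  candidates: %s\n",
              if (length(x$candidates)) paste(x$candidates, collapse = ", ")
              else "(none)"))
  cat(sprintf("  leading (autoregulatory + cofactor at own locus): %s\n",
              if (length(x$leading)) paste(x$leading, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' @export
summary.crc <- function(object, n = 5, ...) {
  structure(list(fit = object, n = n), class = "summary.crc")
}

#' @export
print.summary.crc <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nPairwise occupancy correlations:\n")
  print(transform(f$correlations, R = round(R, 3), p = signif(p, 3)),
        row.names = FALSE)
  cat(sprintf("\nTop %d co-occupying TFs:\n", x$n))
  print(head(f$tf_ranking, x$n), row.names = FALSE, digits = 3)
  if (!is.null(f$motif_ranking)) {
    cat(sprintf("\nTop %d enriched motifs:\n", x$n))
    print(head(f$motif_ranking, x$n), row.names = FALSE, digits = 3)
  }
  if (!is.null(f$pathway_enrichment)) {
    cat(sprintf("\nTop %d enriched pathways:\n", x$n))
    print(head(f$pathway_enrichment, x$n), row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Plot components of a CRC fit
#'
#' `which = "pca"`: variable factor map on the first two components;
#' `"density"`: per-regulator normalized densities of region scores on
#' component 1; `"colocalization"`: clustered overlap heat map;
#' `"circuitry"`: the candidate TF graph (requires candidates).
#'
#' @param x a `crc` object.
#' @param which one of `"pca"`, `"density"`, `"colocalization"`,
#'   `"circuitry"`.
#' @param ... passed to the underlying plotting routine.
#' @return Invisibly, `x`.
#' @export
plot.crc <- function(x, which = c("pca", "density", "colocalization",
                                  "circuitry"), ...) {
  which <- match.arg(which)
  if (which == "pca") {
    vc <- x$pca$variable_coords
    plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), xlab =
           sprintf("PC1 (%.1f%%)", 100 * x$pca$explained[1]),
         ylab = sprintf("PC2 (%.1f%%)", 100 * x$pca$explained[2]),
         main = "PCA variable factor map", asp = 1, ...)
    abline(h = 0, v = 0, col = "grey80")
    arrows(0, 0, vc[, 1], vc[, 2], length = 0.08, col = "steelblue")
    text(vc[, 1], vc[, 2], rownames(vc), pos = 3, cex = 0.9)
  } else if (which == "density") {
    dens <- x$pca$dim1_density
    dens <- dens[!vapply(dens, is.null, TRUE)]
    xr <- range(unlist(lapply(dens, `[[`, "x")))
    plot(NA, xlim = xr, ylim = c(0, 1.05), xlab = "PC1 score",
         ylab = "normalized density",
         main = "Region scores on component 1", ...)
    cols <- hcl.colors(length(dens), "Dark 3")
    for (i in seq_along(dens))
      lines(dens[[i]]$x, dens[[i]]$y, col = cols[i], lwd = 2)
    legend("topright", legend = names(dens), col = cols, lwd = 2, bty = "n")
  } else if (which == "colocalization") {
    ord <- x$colocalization$order
    F <- x$colocalization$F[ord, ord, drop = FALSE]
    n <- nrow(F)
    image(seq_len(n), seq_len(n), t(F[n:1, , drop = FALSE]),
          col = hcl.colors(64, "YlOrRd", rev = TRUE), zlim = c(0, 1),
          axes = FALSE, xlab = "", ylab = "",
          main = "Colocalization frequencies", ...)
    axis(1, seq_len(n), colnames(F), las = 2, cex.axis = 0.8)
    axis(2, seq_len(n), rev(rownames(F)), las = 2, cex.axis = 0.8)
  } else {
    if (is.null(x$graph)) stop_input("no circuitry graph in this fit")
    ig <- as_igraph(x$graph)
    plot(ig, vertex.color = ifelse(
      igraph::V(ig)$autoregulatory & igraph::V(ig)$cofactor_at_own_locus,
      "tomato", "lightsteelblue"),
      edge.arrow.size = 0.4, main = "Core regulatory circuitry", ...)
  }
  invisible(x)
}

## ---------------------------------------------------------------------------
## file-based pipeline front end

#' Read and validate a pipeline configuration
#'
#' YAML with an `inputs` block (paths: `med1`, `smc1a`, `nipbl`, optional
#' `ctcf`, `genes` + `genes_format`, `genome`, `pwms`, optional `motif_map`,
#' `segmentation`, `pathways`, and `tf_peaks`: a map TF symbol to BED path)
#' and a `params` block (`k`, `upstream`, `threshold_quantile`,
#' `pseudocount`, `max_assign_distance`, `seed`, optional
#' `extra_candidates`).  All referenced paths must exist; validation happens
#' before any stage runs.
#'
#' @param config path to a YAML file, or an equivalent list.
#' @return The validated configuration list.
#' @export
read_pipeline_config <- function(config) {
  base <- NULL
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop_input("config file not found: ", config)
    base <- dirname(normalizePath(config))
    yaml::read_yaml(config)
  } else config
  if (is.null(cfg$inputs)) stop_input("config: missing 'inputs' block")
  ## input paths in a config *file* may be relative to its directory
  if (!is.null(base)) {
    anchor <- function(p) {
      if (is.list(p)) return(lapply(p, anchor))
      if (!file.exists(p) && file.exists(file.path(base, p)))
        file.path(base, p) else p
    }
    keep <- setdiff(names(cfg$inputs), "genes_format")
    cfg$inputs[keep] <- lapply(cfg$inputs[keep], anchor)
  }
  req <- c("med1", "smc1a", "nipbl", "genes", "genome", "pwms")
  miss <- setdiff(req, names(cfg$inputs))
  if (length(miss))
    stop_input("config: missing required input(s): ",
               paste(miss, collapse = ", "))
  defaults <- list(k = 20, upstream = 10000, threshold_quantile = 0.9999,
                   pseudocount = 0.8, max_assign_distance = 50000, seed = 1,
                   extra_candidates = character())
  cfg$params <- utils::modifyList(defaults, cfg$params %||% list())
  if (cfg$params$k < 1) stop_input("config: k must be >= 1")
  if (cfg$params$upstream < 0) stop_input("config: upstream must be >= 0")
  if (is.null(cfg$inputs$tf_peaks) || !length(cfg$inputs$tf_peaks))
    stop_input("config: 'tf_peaks' must map TF symbols to BED paths")
  paths <- c(cfg$inputs[setdiff(names(cfg$inputs),
                                c("tf_peaks", "genes_format"))],
             cfg$inputs$tf_peaks)
  for (nm in names(paths))
    if (!file.exists(paths[[nm]]))
      stop_input("config: input path does not exist (", nm, "): ",
                 paths[[nm]])
  cfg
}

#' Run the full pipeline from a configuration file
#'
#' Validates the configuration, seeds the RNG, loads every input, runs
#' [infer_crc()] and (when `outdir` is given) writes TSV/JSON outputs plus a
#' machine-readable `run_report.json` (package version, parameters, per-stage
#' summaries).  Identical configuration and inputs produce identical outputs.
#'
#' @param config YAML path or configuration list (see
#'   [read_pipeline_config()]).
#' @param outdir optional output directory.
#' @return Invisibly, the `crc` fit.
#' @export
run_crc_pipeline <- function(config, outdir = NULL) {
  cfg <- read_pipeline_config(config)
  set.seed(cfg$params$seed)
  inp <- cfg$inputs
  message("[coreCRC] loading inputs")
  med1 <- read_bed(inp$med1, "MED1")
  smc1a <- read_bed(inp$smc1a, "SMC1A")
  nipbl <- read_bed(inp$nipbl, "NIPBL")
  ctcf <- if (!is.null(inp$ctcf)) read_bed(inp$ctcf, "CTCF")
  genes <- read_genes(inp$genes, inp$genes_format %||% "gtf")
  genome <- Biostrings::readDNAStringSet(inp$genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  pwms <- load_pwms(inp$pwms, inp$motif_map, cfg$params$pseudocount)
  segmentation <- if (!is.null(inp$segmentation)) {
    s <- read_bed(inp$segmentation, "segmentation")
    if (any(is.na(s$name)))
      stop_input("segmentation BED needs a state label in column 4")
    s
  }
  pathways <- if (!is.null(inp$pathways)) read_gmt(inp$pathways)
  tf_sets <- lapply(names(inp$tf_peaks), function(nm)
    read_bed(inp$tf_peaks[[nm]], nm))
  names(tf_sets) <- names(inp$tf_peaks)
  message("[coreCRC] running inference")
  fit <- infer_crc(med1, smc1a, nipbl, ctcf, tf_sets, genes, genome, pwms,
                   segmentation, pathways, k = cfg$params$k,
                   upstream = cfg$params$upstream,
                   threshold_quantile = cfg$params$threshold_quantile,
                   max_assign_distance = cfg$params$max_assign_distance)
  if (!is.null(outdir)) {
    message("[coreCRC] writing outputs to ", outdir)
    write_crc_outputs(fit, outdir, cfg)
  }
  invisible(fit)
}

## internal: TSV/JSON output writers
write_crc_outputs <- function(fit, outdir, cfg = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, nm) write.table(df, file.path(outdir, nm), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
  occ <- cbind(as.data.frame(fit$occupancy$regions)[c("chrom", "start", "end")],
               fit$occupancy$M)
  wt(occ, "occupancy.tsv")
  wt(fit$correlations, "correlations.tsv")
  Fm <- fit$colocalization$F
  wt(cbind(regulator = rownames(Fm), as.data.frame(Fm)), "colocalization.tsv")
  if (!is.null(fit$state_profiles)) {
    sp <- do.call(rbind, lapply(names(fit$state_profiles), function(nm) {
      r <- fit$state_profiles[[nm]]$ratios
      cbind(data.frame(set = nm), as.data.frame(t(r)))
    }))
    wt(sp, "state_ratios.tsv")
  }
  jsonlite::write_json(
    list(explained = fit$pca$explained,
         variable_coords = as.data.frame(fit$pca$variable_coords),
         regulators = fit$pca$regulators,
         clustering = list(linkage = fit$colocalization$linkage,
                           distance = fit$colocalization$distance,
                           order = fit$colocalization$order)),
    file.path(outdir, "pca.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  wt(fit$tf_ranking, "tf_ranking.tsv")
  if (!is.null(fit$motif_ranking)) wt(fit$motif_ranking, "motif_ranking.tsv")
  extra <- if (!is.null(cfg)) cfg$params$extra_candidates else character()
  jsonlite::write_json(
    list(candidates = fit$candidates, leading = fit$leading,
         manual_additions = list(
           symbols = extra,
           note = if (length(extra))
             "rule-external additions requested in the configuration"
           else "none"),
         parameters = fit$parameters),
    file.path(outdir, "candidates.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  if (!is.null(fit$graph)) write_circuitry(fit$graph, outdir)
  if (!is.null(fit$pathway_enrichment))
    wt(fit$pathway_enrichment, "pathway_enrichment.tsv")
  report <- list(package = "coreCRC",
                 version = as.character(utils::packageVersion("coreCRC")),
                 parameters = if (!is.null(cfg)) cfg$params else fit$parameters,
                 stages = list(
                   cooccupancy = list(union_regions = nrow(fit$occupancy$M),
                                      regulators = fit$occupancy$regulators),
                   coocc_regions = nrow(fit$coocc),
                   motifs = if (!is.null(fit$motif_ranking))
                     list(ranked = nrow(fit$motif_ranking)) else "skipped",
                   circuitry = list(candidates = fit$candidates,
                                    leading = fit$leading),
                   enrichment = if (!is.null(fit$pathway_enrichment))
                     list(pathways_tested = nrow(fit$pathway_enrichment))
                   else "skipped"))
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
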