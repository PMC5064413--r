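#' Assign peaks to genes
#'
#' Each peak is assigned to the gene whose regulatory window contains the
#' peak midpoint (nearest TSS wins when windows overlap); peaks outside any
#' window fall back to the nearest TSS within `max_distance`; remaining peaks
#' are reported unassigned.  Each peak maps to at most one gene.
#'
#' @param peaks a `region_set`.
#' @param genes gene-model data frame (at least one gene).
#' @param upstream window extension past the TSS (default 10000).
#' @param max_distance nearest-TSS fallback cap in bp (default 50000).
#' @return A data frame with one row per peak: coordinates, `gene_id`,
#'   `symbol`, the assignment `rule` (`"window"`, `"nearest"`,
#'   `"unassigned"`) and `distance` from peak midpoint to the TSS.
#' @export
assign_peaks_to_genes <- function(peaks, genes, upstream = 10000,
                                  max_distance = 50000) {
  if (!nrow(genes)) stop_input("assign_peaks_to_genes: no genes")
  wins <- regulatory_window(genes, upstream)
  mid <- floor((peaks$start + peaks$end) / 2)
  n <- nrow(peaks)
  gene_id <- rep(NA_character_, n)
  symbol <- rep(NA_character_, n)
  rule <- rep("unassigned", n)
  distance <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    same <- which(genes$chrom == peaks$chrom[i])
    if (!length(same)) next
    inwin <- same[wins$w_start[same] <= mid[i] & mid[i] < wins$w_end[same]]
    if (length(inwin)) {
      d <- abs(mid[i] - genes$tss[inwin])
      j <- inwin[order(d, genes$gene_id[inwin])][1]
      gene_id[i] <- genes$gene_id[j]
      symbol[i] <- genes$symbol[j]
      rule[i] <- "window"
      distance[i] <- abs(mid[i] - genes$tss[j])
    } else {
      d <- abs(mid[i] - genes$tss[same])
      j <- same[order(d, genes$gene_id[same])][1]
      dm <- abs(mid[i] - genes$tss[j])
      if (dm <= max_distance) {
        gene_id[i] <- genes$gene_id[j]
        symbol[i] <- genes$symbol[j]
        rule[i] <- "nearest"
        distance[i] <- dm
      }
    }
  }
  data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
             gene_id = gene_id, symbol = symbol, rule = rule,
             distance = distance, stringsAsFactors = FALSE)
}

#' Hypergeometric upper-tail probability
#'
#' The probability of drawing at least `k` pathway genes when `n` genes are
#' drawn without replacement from a universe of `N` genes containing `K`
#' pathway genes.
#'
#' @param N universe size.
#' @param K pathway genes in the universe.
#' @param n target genes drawn.
#' @param k observed overlap.
#' @return p in (0, 1].
#' @export
hypergeom_upper <- function(N, K, n, k) {
  vals <- c(N, K, n, k)
  if (anyNA(vals) || any(vals < 0) || any(vals != floor(vals)))
    stop_input("hypergeom_upper: arguments must be non-negative integers")
  if (K > N || n > N || k > min(K, n))
    stop_input("hypergeom_upper: need K <= N, n <= N, k <= min(K, n)")
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  min(max(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; monotone in the sorted p-values,
#' never below the raw p-value, invariant to input order.
#'
#' @param pvalues numeric vector with all entries in (0, 1].
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric())
  if (anyNA(pvalues) || any(pvalues <= 0) || any(pvalues > 1))
    stop_input("bh_adjust: p-values must lie in (0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Read a GMT gene-set file
#'
#' Tab-separated: set id, description, then member genes.
#'
#' @param path GMT file.
#' @return Named list of gene vectors; descriptions kept as an attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_input("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3))
    stop_input("GMT lines need at least id, description and one gene")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  attr(sets, "description") <- setNames(vapply(fields, `[[`, "", 2L),
                                        names(sets))
  sets
}

#' Pathway enrichment by hypergeometric test
#'
#' One upper-tail hypergeometric test per pathway (restricted to the
#' universe; pathways with no universe genes are skipped), with
#' Benjamini-Hochberg q-values across the tested pathways and significance
#' stars on the raw p-values at 0.05 / 0.01 / 0.001.
#'
#' @param target_genes character vector of target gene identifiers (must be
#'   contained in the universe).
#' @param pathways named list of gene vectors (see [read_gmt()]).
#' @param universe character vector of all gene identifiers considered.
#' @return A data frame, sorted by p: `pathway_id`, `N`, `K`, `n`, `k`, `p`,
#'   `q`, `stars`.
#' @export
pathway_enrichment <- function(target_genes, pathways, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop_input("pathway_enrichment: empty universe")
  target <- unique(target_genes)
  if (!all(target %in% universe))
    stop_input("pathway_enrichment: target genes must be contained in the universe")
  N <- length(universe)
  n <- length(target)
  rows <- lapply(names(pathways), function(id) {
    members <- intersect(pathways[[id]], universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(target, members))
    data.frame(pathway_id = id, N = N, K = K, n = n, k = k,
               p = hypergeom_upper(N, K, n, k), stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) stop_input("pathway_enrichment: no pathway intersects the universe")
  rows$q <- bh_adjust(rows$p)
  rows$stars <- ifelse(rows$p < 0.001, "***",
                ifelse(rows$p < 0.01, "**",
                ifelse(rows$p < 0.05, "*", "")))
  rows <- rows[order(rows$p, rows$pathway_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
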