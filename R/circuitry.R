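#' Rank transcription factors by overlap with the cofactor regions
#'
#' For each TF, the fraction of each cofactor's regions overlapped by the
#' TF's peaks ([overlap_fraction()] keyed on the cofactor set), summarized as
#' the mean of the three fractions; TFs are ranked by descending summary
#' (ties by symbol) and truncated to the top `k`.  A TF with no peaks scores
#' 0 on all cofactors.
#'
#' @param cofactors named list of the three non-empty cofactor `region_set`s
#'   (MED1, SMC1A, NIPBL).
#' @param tf_sets named list (by TF symbol) of TF peak `region_set`s.
#' @param k ranking truncation (default 20).
#' @return A data frame: `tf_symbol`, one overlap column per cofactor,
#'   `summary`, `rank`.
#' @export
rank_tf_overlap <- function(cofactors, tf_sets, k = 20) {
  if (length(cofactors) != 3 || any(vapply(cofactors, nrow, 0L) == 0))
    stop_input("rank_tf_overlap needs exactly 3 non-empty cofactor sets")
  if (!length(tf_sets)) stop_input("rank_tf_overlap needs at least one TF set")
  if (is.null(names(cofactors)))
    names(cofactors) <- vapply(cofactors, function(s)
      as.character(attr(s, "regulator")), "")
  if (is.null(names(tf_sets)))
    names(tf_sets) <- vapply(tf_sets, function(s)
      as.character(attr(s, "regulator")), "")
  fr <- t(vapply(tf_sets, function(tf) {
    vapply(cofactors, function(cf)
      if (nrow(tf)) overlap_fraction(cf, tf) else 0, 0)
  }, numeric(3)))
  colnames(fr) <- names(cofactors)
  df <- data.frame(tf_symbol = names(tf_sets), fr,
                   summary = rowMeans(fr), stringsAsFactors = FALSE,
                   check.names = FALSE)
  ord <- order(-df$summary, df$tf_symbol)
  df <- df[ord, , drop = FALSE][seq_len(min(k, nrow(df))), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Default motif/protein-name alias table
#'
#' Maps informal protein names used for motifs (e.g. ERa) to gene symbols
#' (ESR1) so that motif and ChIP lists can be cross-referenced.  Shipped as
#' `inst/extdata/tf_aliases.tsv`; users can supply their own table of the
#' same shape.
#'
#' @param path alias TSV with columns `alias` and `symbol`.
#' @return A data frame with columns `alias`, `symbol`.
#' @export
read_tf_aliases <- function(path = system.file("extdata", "tf_aliases.tsv",
                                               package = "coreCRC")) {
  read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}

canonical_symbol <- function(x, aliases) {
  x <- toupper(x)
  i <- match(x, toupper(aliases$alias))
  ifelse(is.na(i), x, toupper(aliases$symbol[i]))
}

#' Cross-reference co-occupying TFs with enriched motifs
#'
#' Candidates are the TF symbols appearing in the top-k overlap ranking whose
#' symbol matches (case-insensitively, after alias resolution) the TF symbol
#' of at least one top-k enriched motif.  ChIP evidence is required: a TF
#' present only in the motif list cannot become a candidate.
#'
#' @param top_tfs result of [rank_tf_overlap()] (or a character vector of TF
#'   symbols).
#' @param top_motifs result of [rank_motifs()] (or a character vector of
#'   motif TF symbols).
#' @param aliases alias table (see [read_tf_aliases()]).
#' @return Sorted character vector of candidate TF symbols (empty, with a
#'   warning, when the lists are disjoint).
#' @export
candidate_tfs <- function(top_tfs, top_motifs, aliases = read_tf_aliases()) {
  tf_syms <- if (is.data.frame(top_tfs)) top_tfs$tf_symbol else top_tfs
  motif_syms <- if (is.data.frame(top_motifs)) top_motifs$tf_symbol
                else top_motifs
  motif_syms <- motif_syms[!is.na(motif_syms) & nzchar(motif_syms)]
  hit <- canonical_symbol(tf_syms, aliases) %in%
    canonical_symbol(motif_syms, aliases)
  out <- sort(unique(tf_syms[hit]))
  if (!length(out))
    warning("no candidate TFs: overlap ranking and motif ranking share no symbols")
  out
}

#' Build the core regulatory circuitry graph
#'
#' A directed edge A -> B is drawn when at least one peak of TF A overlaps
#' the regulatory window of B's gene ([regulatory_window()]).  A self-edge
#' marks B as autoregulatory; `cofactor_at_own_locus` is set when B's window
#' overlaps the cofactor co-occupied region set (MED1 \eqn{\cap} SMC1A
#' \eqn{\cap} NIPBL).  The edge set is independent of candidate input order.
#'
#' @param candidates character vector of candidate TF symbols.
#' @param tf_sets named list of TF peak `region_set`s covering all
#'   candidates.
#' @param genes gene-model data frame containing a row (by `symbol`) for
#'   every candidate.
#' @param cofactor_coocc `region_set` of cofactor co-occupied regions.
#' @param upstream window extension past the TSS (default 10000).
#' @return A `circuitry_graph`: `nodes` (symbol, gene_id, autoregulatory,
#'   cofactor_at_own_locus), `edges` (from, to, n_peaks), `windows`.
#' @export
build_circuitry <- function(candidates, tf_sets, genes, cofactor_coocc,
                            upstream = 10000) {
  candidates <- sort(unique(candidates))
  if (!length(candidates)) stop_input("build_circuitry: no candidates")
  gi <- match(candidates, genes$symbol)
  if (anyNA(gi))
    stop_input("no gene model for candidate TF(s): ",
               paste(candidates[is.na(gi)], collapse = ", "))
  if (any(!candidates %in% names(tf_sets)))
    stop_input("no peak set for candidate TF(s): ",
               paste(setdiff(candidates, names(tf_sets)), collapse = ", "))
  wins <- regulatory_window(genes[gi, , drop = FALSE], upstream)
  gwin <- GenomicRanges::GRanges(wins$chrom,
                                 IRanges::IRanges(wins$w_start + 1,
                                                  wins$w_end))
  edges <- do.call(rbind, lapply(candidates, function(a) {
    cnt <- suppressWarnings(GenomicRanges::countOverlaps(
      gwin, as_granges(tf_sets[[a]])))
    keep <- cnt > 0
    if (!any(keep)) return(NULL)
    data.frame(from = a, to = candidates[keep], n_peaks = cnt[keep],
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        n_peaks = integer(), stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  auto <- candidates %in% edges$from[edges$from == edges$to]
  own <- if (nrow(cofactor_coocc))
    suppressWarnings(IRanges::overlapsAny(gwin, as_granges(cofactor_coocc)))
  else rep(FALSE, length(candidates))
  nodes <- data.frame(symbol = candidates, gene_id = genes$gene_id[gi],
                      autoregulatory = auto, cofactor_at_own_locus = own,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, windows = wins,
                 upstream = upstream),
            class = "circuitry_graph")
}

#' @export
print.circuitry_graph <- function(x, ...) {
  cat(sprintf("<circuitry_graph> %d TF(s), %d edge(s); autoregulatory: %s\n",
              nrow(x$nodes), nrow(x$edges),
              paste(x$nodes$symbol[x$nodes$autoregulatory], collapse = ", ")))
  invisible(x)
}

#' Leading CRC candidates
#'
#' The TFs that occupy their own regulatory region (autoregulatory self-edge)
#' *and* whose window is co-occupied by Mediator, Cohesin and NIPBL.
#'
#' @param g a `circuitry_graph`.
#' @return Character vector of leading candidate symbols.
#' @export
leading_candidates <- function(g) {
  g$nodes$symbol[g$nodes$autoregulatory & g$nodes$cofactor_at_own_locus]
}

#' Convert a circuitry graph to igraph
#'
#' @param g a `circuitry_graph`.
#' @return An `igraph` directed graph with node flags and `n_peaks` edge
#'   attribute.
#' @export
as_igraph <- function(g) {
  igraph::graph_from_data_frame(g$edges, directed = TRUE,
                                vertices = g$nodes)
}

#' Export a circuitry graph
#'
#' Writes `circuitry_nodes.tsv`, `circuitry_edges.tsv` and
#' `circuitry.graphml` under `dir`.
#'
#' @param g a `circuitry_graph`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
write_circuitry <- function(g, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(g$nodes, file.path(dir, "circuitry_nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(g$edges, file.path(dir, "circuitry_edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  igraph::write_graph(as_igraph(g), file.path(dir, "circuitry.graphml"),
                      format = "graphml")
  invisible(dir)
}
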