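#' Gene models and strand-aware regulatory windows
#'
#' Gene models are kept as a plain data frame in 0-based half-open
#' coordinates with a derived transcription start site (`tss`): the 5'
#' boundary, i.e. `start` on the `+` strand and `end` on the `-` strand.
#'
#' @param gene_id,symbol character identifiers.
#' @param chrom chromosome names.
#' @param start,end 0-based half-open gene body coordinates.
#' @param strand `"+"` or `"-"`.
#' @return A data frame with columns `gene_id`, `symbol`, `chrom`, `start`,
#'   `end`, `strand`, `tss`, sorted by (chrom, start).
#' @export
gene_models <- function(gene_id, symbol, chrom, start, end, strand) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start >= end)) stop_input("gene models must satisfy start < end")
  if (any(!strand %in% c("+", "-")))
    stop_input("unknown strand character in gene models (must be '+' or '-')")
  df <- data.frame(gene_id = as.character(gene_id),
                   symbol = as.character(symbol),
                   chrom = as.character(chrom),
                   start = start, end = end, strand = as.character(strand),
                   tss = ifelse(strand == "+", start, end),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read gene models from GTF or BED12
#'
#' GTF records (1-based closed) are converted to 0-based half-open; one model
#' is produced per `gene`-typed record (per `gene_id` when no gene records
#' exist).  BED12/BED6 coordinates are taken verbatim.  An unknown strand
#' character is a parse error.
#'
#' @param path annotation file.
#' @param format `"gtf"` or `"bed12"`.
#' @return A gene-model data frame (see [gene_models()]).
#' @export
read_genes <- function(path, format = c("gtf", "bed12")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("annotation file not found: ", path)
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    if (!is.null(gr$type) && any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
    if (!length(gr)) stop_input("no gene records in ", path)
    strand <- as.character(GenomicRanges::strand(gr))
    if (any(!strand %in% c("+", "-")))
      stop_input("unknown strand character in ", path,
                 " (must be '+' or '-')")
    symbol <- if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id
    gene_models(gene_id = gr$gene_id, symbol = symbol,
                chrom = as.character(GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr) - 1,
                end = GenomicRanges::end(gr), strand = strand)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 6))
      stop_input("BED12 gene records need at least 6 columns")
    strand <- vapply(fields, `[[`, "", 6L)
    if (any(!strand %in% c("+", "-")))
      stop_input("unknown strand character in ", path,
                 " (must be '+' or '-')")
    nm <- vapply(fields, `[[`, "", 4L)
    gene_models(gene_id = nm, symbol = nm,
                chrom = vapply(fields, `[[`, "", 1L),
                start = as.numeric(vapply(fields, `[[`, "", 2L)),
                end = as.numeric(vapply(fields, `[[`, "", 3L)),
                strand = strand)
  }
}

#' Strand-aware regulatory window of a gene
#'
#' The operational regulatory region of a gene locus: the gene body extended
#' `upstream` bp past its TSS (from -`upstream`/1000 kb upstream of the TSS to
#' the end of the gene).  On the `+` strand this is
#' `[start - upstream, end)`; on the `-` strand `[start, end + upstream)`.
#' Window starts are clamped at 0.
#'
#' @param genes a gene-model data frame (see [gene_models()]), any rows.
#' @param upstream non-negative extension past the TSS in bp (default 10000).
#' @return A data frame with `gene_id`, `symbol`, `chrom`, `w_start`, `w_end`
#'   and the `derivation` rule applied.
#' @export
regulatory_window <- function(genes, upstream = 10000) {
  if (upstream < 0) stop_input("upstream must be >= 0")
  plus <- genes$strand == "+"
  w_start <- ifelse(plus, pmax(0, genes$start - upstream), genes$start)
  w_end <- ifelse(plus, genes$end, genes$end + upstream)
  data.frame(gene_id = genes$gene_id, symbol = genes$symbol,
             chrom = genes$chrom, w_start = w_start, w_end = w_end,
             derivation = sprintf("TSS-%dbp to gene end (%s strand)",
                                  upstream, genes$strand),
             stringsAsFactors = FALSE)
}
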