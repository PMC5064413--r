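#' Genomic region sets
#'
#' A `region_set` holds the occupied ("enriched") regions of one regulator as
#' a data frame of intervals in 0-based half-open coordinates (the BED
#' convention: `start` inclusive, `end` exclusive), sorted by
#' (chrom, start, end).  The `regulator` attribute names the factor the set
#' belongs to; the `merged` attribute records whether overlapping or abutting
#' intervals have been unioned.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start,end integer-valued positions with `0 <= start < end`.
#' @param name optional per-interval labels.
#' @param score optional per-interval numeric scores.
#' @param regulator name of the factor/cofactor the set belongs to.
#' @param merged logical; `TRUE` asserts no two intervals on the same
#'   chromosome overlap or abut.
#' @return A `region_set` object (a sorted data frame with columns
#'   `chrom`, `start`, `end`, `name`, `score`).
#' @examples
#' rs <- region_set(c("chr1", "chr1"), c(0, 5), c(10, 15), regulator = "MED1")
#' merge_regions(rs)
#' @export
region_set <- function(chrom = character(), start = numeric(), end = numeric(),
                       name = NA_character_, score = NA_real_,
                       regulator = NA_character_, merged = FALSE) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- length(start)
  if (length(end) != n)
    stop_input("start and end must have equal length")
  chrom <- rep_len(as.character(chrom), n)
  if (n > 0) {
    if (any(is.na(chrom)) || any(!nzchar(chrom)))
      stop_input("chromosome names must be non-empty")
    if (any(is.na(start)) || any(is.na(end)))
      stop_input("interval coordinates must not be NA")
    if (any(start != floor(start)) || any(end != floor(end)))
      stop_input("interval coordinates must be integer-valued")
    if (any(start < 0) || any(start >= end))
      stop_input("intervals must satisfy 0 <= start < end")
  }
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = rep_len(as.character(name), n),
                   score = rep_len(as.numeric(score), n),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("region_set", "data.frame"),
            regulator = as.character(regulator), merged = isTRUE(merged))
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %s: %d interval(s)%s\n",
              attr(x, "regulator"), nrow(x),
              if (isTRUE(attr(x, "merged"))) " (merged)" else ""))
  if (nrow(x)) print(head(as.data.frame(x), 10L))
  invisible(x)
}

#' Name of the regulator a region set belongs to
#' @param rs a `region_set`.
#' @return Character scalar.
#' @export
regulator <- function(rs) attr(rs, "regulator")

## internal: region_set <-> GRanges (GRanges is 1-based closed)
as_granges <- function(rs) {
  GenomicRanges::GRanges(seqnames = rs$chrom,
                         ranges = IRanges::IRanges(start = rs$start + 1,
                                                   end = rs$end))
}

granges_to_rs <- function(gr, regulator = NA_character_, merged = FALSE) {
  region_set(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             regulator = regulator, merged = merged)
}

rs_subset <- function(rs, idx, regulator = attr(rs, "regulator")) {
  region_set(rs$chrom[idx], rs$start[idx], rs$end[idx],
             rs$name[idx], rs$score[idx],
             regulator = regulator, merged = attr(rs, "merged"))
}

#' Read a BED file into a region set
#'
#' Reads BED3/BED6 (tab-separated, 0-based half-open).  Coordinates are taken
#' verbatim.  Track/browser/comment lines are skipped.  Malformed lines
#' (fewer than 3 columns, non-integer coordinates, `start >= end`) raise a
#' parse error naming the offending line.
#'
#' @param path path to an existing BED file.
#' @param regulator regulator name attached to the result; defaults to the
#'   file base name without extension.
#' @return A `region_set` with `merged = FALSE`.
#' @export
read_bed <- function(path, regulator = sub("\\.bed$", "", basename(path))) {
  if (!file.exists(path)) stop_input("BED file not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#") &
                  !startsWith(lines, "track") & !startsWith(lines, "browser"))
  if (!length(keep)) return(region_set(regulator = regulator))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop_input("BED parse error at line ", keep[which(nf < 3)[1]],
               ": fewer than 3 tab-separated columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(s) | is.na(e) | s != floor(s) | e != floor(e))
  if (length(bad))
    stop_input("BED parse error at line ", keep[bad[1]],
               ": non-integer coordinates")
  bad <- which(s < 0 | s >= e)
  if (length(bad))
    stop_input("BED parse error at line ", keep[bad[1]],
               ": coordinates must satisfy 0 <= start < end")
  nm <- vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, "")
  sc <- suppressWarnings(as.numeric(
    vapply(fields, function(f) if (length(f) >= 5) f[[5]] else NA_character_, "")))
  region_set(chrom, s, e, nm, sc, regulator = regulator)
}

#' Write a region set as BED
#'
#' Emits sorted BED3 (or BED4/BED5 when names/scores are present); coordinates
#' round-trip bit-exactly through [read_bed()].
#'
#' @param rs a `region_set`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(rs, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  has_name <- any(!is.na(rs$name))
  has_score <- any(!is.na(rs$score))
  lines <- if (nrow(rs)) paste(rs$chrom, fmt(rs$start), fmt(rs$end), sep = "\t")
           else character()
  if (nrow(rs) && (has_name || has_score))
    lines <- paste(lines, ifelse(is.na(rs$name), ".", rs$name), sep = "\t")
  if (nrow(rs) && has_score)
    lines <- paste(lines, ifelse(is.na(rs$score), "0", fmt(rs$score)), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Union overlapping or abutting intervals
#'
#' Returns a region set covering exactly the same bases with overlapping or
#' abutting intervals merged; idempotent.
#'
#' @param rs a `region_set`.
#' @return A merged `region_set` (`merged = TRUE`).
#' @export
merge_regions <- function(rs) {
  if (!nrow(rs)) {
    attr(rs, "merged") <- TRUE
    return(rs)
  }
  granges_to_rs(GenomicRanges::reduce(as_granges(rs)),
                regulator = attr(rs, "regulator"), merged = TRUE)
}

#' Fraction of query regions overlapping another set
#'
#' The default statistic counts regions of the query set `a` having at least
#' one shared base with any interval of `b` (half-open arithmetic); it is
#' asymmetric by design, matching a "percentage of overlap" ranking keyed on
#' the query set.  `method = "jaccard"` instead returns the base-pair Jaccard
#' index of the two merged sets.
#'
#' @param a query `region_set` (must be non-empty).
#' @param b subject `region_set`.
#' @param method `"fraction"` (default) or `"jaccard"`.
#' @return A number in \[0, 1\].
#' @export
overlap_fraction <- function(a, b, method = c("fraction", "jaccard")) {
  method <- match.arg(method)
  if (!nrow(a)) stop_input("overlap_fraction: query set is empty")
  ga <- as_granges(a)
  gb <- as_granges(b)
  if (method == "fraction") {
    if (!nrow(b)) return(0)
    return(mean(suppressWarnings(IRanges::overlapsAny(ga, gb))))
  }
  ga <- GenomicRanges::reduce(ga)
  gb <- GenomicRanges::reduce(gb)
  inter <- sum(GenomicRanges::width(suppressWarnings(
    GenomicRanges::intersect(ga, gb))))
  uni <- sum(GenomicRanges::width(GenomicRanges::reduce(
    suppressWarnings(c(ga, gb)))))
  if (uni == 0) 0 else inter / uni
}

#' Base-level intersection of several region sets
#'
#' Maximal intervals covered by every input set, merged.  Used to define the
#' regions co-occupied by all three cofactors.
#'
#' @param sets a list of at least two `region_set` objects.
#' @return A merged `region_set`.
#' @export
intersect_all <- function(sets) {
  if (length(sets) < 2) stop_input("intersect_all needs at least 2 region sets")
  grs <- lapply(sets, function(s) GenomicRanges::reduce(as_granges(s)))
  res <- suppressWarnings(Reduce(GenomicRanges::intersect, grs))
  regs <- vapply(sets, function(s) as.character(attr(s, "regulator") %||% NA), "")
  granges_to_rs(res, regulator = paste(regs, collapse = "&"), merged = TRUE)
}
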