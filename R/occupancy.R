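#' Binary regulator occupancy matrix over atomic union regions
#'
#' The union of all input peak sets is merged into atomic regions; entry
#' `M[r, c]` is 1 when union region `r` overlaps at least one interval of
#' regulator `c`'s set.  Every row has at least one nonzero entry by
#' construction.  This matrix is the substrate of the PCA and correlation
#' analyses.
#'
#' @param sets a named list of at least two non-empty `region_set` objects
#'   (names default to each set's `regulator` attribute).
#' @return An `occupancy_matrix`: list with `regions` (merged union
#'   `region_set`), `regulators` and the binary matrix `M`.
#' @export
build_occupancy_matrix <- function(sets) {
  if (length(sets) < 2)
    stop_input("build_occupancy_matrix needs at least 2 region sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- vapply(sets, function(s) as.character(attr(s, "regulator")), "")
  if (any(vapply(sets, nrow, 0L) == 0))
    stop_input("all region sets must be non-empty")
  all_chrom <- unlist(lapply(sets, `[[`, "chrom"), use.names = FALSE)
  all_start <- unlist(lapply(sets, `[[`, "start"), use.names = FALSE)
  all_end <- unlist(lapply(sets, `[[`, "end"), use.names = FALSE)
  union_rs <- merge_regions(region_set(all_chrom, all_start, all_end,
                                       regulator = "union"))
  gu <- as_granges(union_rs)
  M <- matrix(0L, nrow = nrow(union_rs), ncol = length(sets),
              dimnames = list(NULL, names(sets)))
  for (j in seq_along(sets))
    M[, j] <- as.integer(suppressWarnings(
      IRanges::overlapsAny(gu, as_granges(sets[[j]]))))
  structure(list(regions = union_rs, regulators = names(sets), M = M),
            class = "occupancy_matrix")
}

#' @export
print.occupancy_matrix <- function(x, ...) {
  cat(sprintf("<occupancy_matrix> %d regions x %d regulators (%s)\n",
              nrow(x$M), ncol(x$M), paste(x$regulators, collapse = ", ")))
  invisible(x)
}

#' PCA of the regulator occupancy matrix
#'
#' Columns are centered (not variance-scaled by default: all variables live on
#' a common 0/1 scale) and decomposed by SVD.  `variable_coords[c, k]` is the
#' Pearson correlation between regulator `c`'s column and the region scores on
#' component `k` (the variable factor map).  The sign of each component is
#' fixed by forcing the lexicographically smallest regulator to a
#' non-negative coordinate.  `dim1_density` holds, per regulator, the density
#' of its member regions' component-1 scores rescaled so each curve's maximum
#' is exactly 1.
#'
#' @param m an `occupancy_matrix` with >= 2 regulators and >= 3 regions.
#' @param scale logical; also divide columns by their standard deviation.
#' @return A `crc_pca` object: `region_scores`, `variable_coords`,
#'   `explained` (variance fractions summing to 1), `rotation`, `center`,
#'   `dim1_density`.
#' @export
pca_regulators <- function(m, scale = FALSE) {
  M <- m$M
  if (ncol(M) < 2 || nrow(M) < 3)
    stop_input("PCA needs >= 2 regulators and >= 3 regions")
  sds <- apply(M, 2, sd)
  zero <- sds == 0
  if (any(zero))
    warning("zero-variance regulator column(s): ",
            paste(m$regulators[zero], collapse = ", "),
            "; their variable coordinates are set to 0")
  X <- scale(M, center = TRUE, scale = if (scale) ifelse(zero, 1, sds) else FALSE)
  attr(X, "scaled:center") -> ctr
  sv <- svd(X)
  ncomp <- length(sv$d)
  scores <- sv$u %*% diag(sv$d, nrow = ncomp)
  rotation <- sv$v
  vc <- matrix(0, nrow = ncol(M), ncol = ncomp,
               dimnames = list(m$regulators, paste0("PC", seq_len(ncomp))))
  score_sd <- apply(scores, 2, sd)
  for (k in seq_len(ncomp)) {
    if (score_sd[k] == 0) next
    ok <- !zero
    vc[ok, k] <- apply(X[, ok, drop = FALSE], 2, cor, y = scores[, k])
  }
  ## deterministic sign: smallest regulator name non-negative per component
  ref_order <- order(m$regulators)
  ref <- ref_order[!zero[ref_order]][1]
  if (!is.na(ref)) {
    for (k in seq_len(ncomp)) {
      if (vc[ref, k] < 0) {
        scores[, k] <- -scores[, k]
        rotation[, k] <- -rotation[, k]
        vc[, k] <- -vc[, k]
      }
    }
  }
  explained <- sv$d^2 / sum(sv$d^2)
  dens <- setNames(vector("list", ncol(M)), m$regulators)
  for (j in seq_len(ncol(M))) {
    xs <- scores[M[, j] == 1, 1]
    if (length(unique(xs)) >= 2) {
      d <- suppressWarnings(density(xs))
      dens[[j]] <- list(x = d$x, y = d$y / max(d$y))
    }
  }
  structure(list(region_scores = scores, variable_coords = vc,
                 explained = explained, rotation = rotation, center = ctr,
                 dim1_density = dens, regulators = m$regulators),
            class = "crc_pca")
}

#' @export
print.crc_pca <- function(x, ...) {
  cat("<crc_pca> explained variance:",
      paste(sprintf("PC%d %.1f%%", seq_along(x$explained), 100 * x$explained),
            collapse = ", "), "\n")
  print(round(x$variable_coords[, seq_len(min(2, ncol(x$variable_coords))),
                                drop = FALSE], 3))
  invisible(x)
}

#' Pearson correlation between two regulators' occupancy columns
#'
#' The correlation of the two binary membership columns over the atomic union
#' regions; the p-value uses the t transform with `n - 2` degrees of freedom.
#'
#' @param m an `occupancy_matrix`.
#' @param a,b regulator names present in `m`.
#' @return A `crc_correlation`: `pair`, `R`, `p`, `n`.
#' @export
regulator_correlation <- function(m, a, b) {
  i <- match(a, m$regulators)
  j <- match(b, m$regulators)
  if (is.na(i) || is.na(j))
    stop_input("regulator not present in occupancy matrix: ",
               paste(c(a, b)[is.na(c(i, j))], collapse = ", "))
  x <- m$M[, i]; y <- m$M[, j]
  if (sd(x) == 0 || sd(y) == 0)
    stop_input("undefined correlation: zero-variance occupancy column")
  n <- length(x)
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(list(pair = c(a, b), R = r, p = p, n = n),
            class = "crc_correlation")
}

#' @export
print.crc_correlation <- function(x, ...) {
  cat(sprintf("%s ~ %s: R = %.3f (p = %.3g, n = %d)\n",
              x$pair[1], x$pair[2], x$R, x$p, x$n))
  invisible(x)
}

#' Partition Cohesin peaks by CTCF co-occupancy
#'
#' Splits a Cohesin (SMC1A) peak set into the subpopulation overlapping at
#' least one CTCF interval ("with CTCF") and the remainder ("no CTCF"); the
#' two parts partition the input exactly.
#'
#' @param smc1a non-empty `region_set` of Cohesin peaks.
#' @param ctcf `region_set` of CTCF peaks (may be empty).
#' @return A list with elements `with_ctcf` and `no_ctcf`.
#' @export
partition_by_ctcf <- function(smc1a, ctcf) {
  if (!nrow(smc1a)) stop_input("partition_by_ctcf: empty SMC1A set")
  hit <- if (nrow(ctcf))
    suppressWarnings(IRanges::overlapsAny(as_granges(smc1a), as_granges(ctcf)))
  else rep(FALSE, nrow(smc1a))
  reg <- attr(smc1a, "regulator")
  list(with_ctcf = rs_subset(smc1a, hit, paste0(reg, " (with CTCF)")),
       no_ctcf = rs_subset(smc1a, !hit, paste0(reg, " (no CTCF)")))
}

#' Chromatin-state overlap profile of a region set
#'
#' For each state label of a (non-overlapping) segmentation, the fraction of
#' the region set's occupied base pairs falling in that state; bases outside
#' any segment accumulate under the reserved label `"unannotated"`.  Ratios
#' always sum to 1.
#'
#' @param rs non-empty `region_set`.
#' @param segmentation a labelled `region_set` (ChromHMM dense BED: column 4
#'   is the state label); intervals must not overlap.
#' @return A `state_overlap_profile`: `regulator` and named `ratios`.
#' @export
state_overlap_profile <- function(rs, segmentation) {
  if (!nrow(rs)) stop_input("state_overlap_profile: empty region set")
  if (any(is.na(segmentation$name)))
    stop_input("segmentation intervals must carry state labels")
  gseg <- as_granges(segmentation)
  if (sum(GenomicRanges::width(GenomicRanges::reduce(gseg))) <
        sum(GenomicRanges::width(gseg)))
    stop_input("segmentation intervals overlap")
  grs <- GenomicRanges::reduce(as_granges(rs))
  total <- sum(GenomicRanges::width(grs))
  hits <- suppressWarnings(IRanges::findOverlaps(grs, gseg))
  w <- GenomicRanges::width(GenomicRanges::pintersect(
    grs[S4Vectors::queryHits(hits)], gseg[S4Vectors::subjectHits(hits)]))
  states <- sort(unique(segmentation$name))
  per_state <- setNames(numeric(length(states)), states)
  if (length(w)) {
    agg <- tapply(w, segmentation$name[S4Vectors::subjectHits(hits)], sum)
    per_state[names(agg)] <- agg
  }
  unann <- total - sum(per_state)
  ratios <- c(per_state, unannotated = unann) / total
  structure(list(regulator = attr(rs, "regulator"), ratios = ratios),
            class = "state_overlap_profile")
}

#' @export
print.state_overlap_profile <- function(x, ...) {
  cat(sprintf("<state_overlap_profile> %s\n", x$regulator))
  print(round(x$ratios, 3))
  invisible(x)
}

#' Pairwise colocalization matrix with clustered ordering
#'
#' `F[i, j]` is the fraction of set `i`'s regions overlapping set `j`
#' ([overlap_fraction()]; asymmetric, unit diagonal).  The display order is
#' the leaf order of average-linkage hierarchical clustering under the
#' distance 1 - Pearson correlation between rows of `F`.
#'
#' @param sets a named list of >= 2 non-empty `region_set` objects.
#' @return A `colocalization_matrix`: `regulators`, matrix `F`, `order`,
#'   plus the `linkage` and `distance` metadata.
#' @export
colocalization_matrix <- function(sets) {
  if (length(sets) < 2)
    stop_input("colocalization_matrix needs at least 2 region sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- vapply(sets, function(s) as.character(attr(s, "regulator")), "")
  k <- length(sets)
  F <- matrix(NA_real_, k, k, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(k))
    for (j in seq_len(k))
      F[i, j] <- overlap_fraction(sets[[i]], sets[[j]])
  d <- 1 - suppressWarnings(cor(t(F)))
  d[is.na(d)] <- 0
  ord <- if (k > 2) {
    hc <- hclust(as.dist(d), method = "average")
    names(sets)[hc$order]
  } else names(sets)
  structure(list(regulators = names(sets), F = F, order = ord,
                 linkage = "average", distance = "1 - Pearson correlation"),
            class = "colocalization_matrix")
}

#' @export
print.colocalization_matrix <- function(x, ...) {
  cat("<colocalization_matrix> order:", paste(x$order, collapse = ", "), "\n")
  print(round(x$F, 3))
  invisible(x)
}

#' Detect a bimodal normalized density curve
#'
#' A curve (maximum rescaled to 1) is called bimodal when it has two local
#' maxima separated by a valley at least `valley_drop` below both peaks.
#' Used to flag the split component-1 distribution of Cohesin regions.
#'
#' @param dens a list with `x` and `y` (as in `crc_pca$dim1_density`), or a
#'   numeric vector of density values.
#' @param valley_drop required relative drop of the valley below the smaller
#'   peak (default 0.2).
#' @return Logical scalar.
#' @export
is_bimodal <- function(dens, valley_drop = 0.2) {
  y <- if (is.list(dens)) dens$y else dens
  if (is.null(y) || length(y) < 3) return(FALSE)
  n <- length(y)
  loc <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (length(loc) < 2) return(FALSE)
  loc <- loc[order(-y[loc])][1:2]
  loc <- sort(loc)
  valley <- min(y[loc[1]:loc[2]])
  valley <= (1 - valley_drop) * min(y[loc])
}
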