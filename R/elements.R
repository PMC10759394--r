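#' Enhancer-like elements from peak intersection
#'
#' An enhancer-like element (ELE) is a genomic interval supported by both an
#' H3K27ac peak and an accessible-chromatin peak in the same tissue or cell
#' context. `intersect_peaks()` computes the base-level intersection of the
#' two peak sets and merges it into maximal sorted intervals; every base of
#' the result is covered by both inputs.
#'
#' @param h3k27ac,accessible `GRanges` of peak calls on the same assembly.
#' @return A sorted `GRanges` of elements (conservation class "NC": no
#'   conservation requirement applied).
#' @seealso [classify_conservation()], [merge_omnibus()]
#' @export
intersect_peaks <- function(h3k27ac, accessible) {
  stopifnot(is(h3k27ac, "GRanges"), is(accessible, "GRanges"))
  .check_same_assembly(h3k27ac, accessible)
  out <- GenomicRanges::intersect(reduce(h3k27ac, ignore.strand = TRUE),
                                  reduce(accessible, ignore.strand = TRUE),
                                  ignore.strand = TRUE)
  out <- sort(out, ignore.strand = TRUE)
  mcols(out)$conservation_class <- rep("NC", length(out))
  out
}

#' Paired gapless alignment blocks between two genomes
#'
#' Container for ungapped aligned segments: each source-genome interval is
#' paired with a target-genome interval of identical length. Source blocks
#' must be pairwise non-overlapping. Blocks are stored sorted by source
#' coordinate.
#'
#' @param source,target `GRanges` of equal length and equal per-block widths;
#'   `source` intervals must be disjoint.
#' @return An object of class `alignment_blocks`: a list with elements
#'   `source` and `target`.
#' @export
alignment_blocks <- function(source, target) {
  stopifnot(is(source, "GRanges"), is(target, "GRanges"))
  if (length(source) != length(target))
    .err("source and target must have the same number of blocks")
  if (length(source) && any(width(source) != width(target)))
    .err("gapless blocks require equal source and target widths")
  if (!isDisjoint(source, ignore.strand = TRUE))
    .err("source blocks must be pairwise non-overlapping")
  o <- order(source)
  structure(list(source = source[o], target = target[o]),
            class = "alignment_blocks")
}

#' @export
print.alignment_blocks <- function(x, ...) {
  cat(sprintf("alignment_blocks: %d gapless blocks, %s bases\n",
              length(x$source),
              format(sum(width(x$source)), big.mark = ",")))
  invisible(x)
}

# accept alignment_blocks or a bare GRanges of source blocks
.block_source <- function(blocks) {
  if (inherits(blocks, "alignment_blocks")) blocks$source
  else if (is(blocks, "GRanges")) blocks
  else .err("blocks must be an alignment_blocks object or a GRanges")
}

#' Fraction of element bases inside gapless alignment blocks
#'
#' For each element, the proportion of its bases covered by source-genome
#' alignment blocks. This is the quantity thresholded by the minMatch levels
#' used to call an element conserved.
#'
#' @param elements `GRanges` of elements.
#' @param blocks An [alignment_blocks] object (or a `GRanges` of source
#'   blocks).
#' @return Numeric vector in \[0, 1\], one value per element.
#' @export
conservation_fraction <- function(elements, blocks) {
  stopifnot(is(elements, "GRanges"))
  src <- reduce(.block_source(blocks), ignore.strand = TRUE)
  frac <- numeric(length(elements))
  if (length(src) && length(elements)) {
    ov <- findOverlaps(elements, src, ignore.strand = TRUE)
    if (length(ov)) {
      w <- width(pintersect(elements[queryHits(ov)], src[subjectHits(ov)]))
      cov <- tapply(w, queryHits(ov), sum)
      frac[as.integer(names(cov))] <- as.numeric(cov)
    }
  }
  frac / width(elements)
}

#' Classify elements by sequence-conservation level
#'
#' An element joins the level-`m` set when at least a fraction `m` of its
#' bases falls in gapless alignment blocks (the minMatch rule). The retained
#' record is the original source-genome interval. Because the levels are
#' increasing, the returned sets are nested: each level is a subset of the
#' previous one.
#'
#' @param nc `GRanges` of elements (the unconserved "NC" set).
#' @param blocks An [alignment_blocks] object.
#' @param levels Named, strictly increasing thresholds in (0, 1\]. Defaults
#'   to the low/moderate/high conservation levels `c(LC = 0.1, MC = 0.5,
#'   HC = 0.9)`.
#' @return Named list of `GRanges`, one per level, each carrying
#'   `conservation_fraction` and `conservation_class` metadata columns.
#' @export
classify_conservation <- function(nc, blocks,
                                  levels = c(LC = 0.1, MC = 0.5, HC = 0.9)) {
  stopifnot(is(nc, "GRanges"))
  if (length(levels) == 0L || any(!is.finite(levels)) ||
      any(levels <= 0) || any(levels > 1))
    .err("levels must lie in (0, 1]")
  if (is.unsorted(levels, strictly = TRUE))
    .err("levels must be strictly increasing")
  if (is.null(names(levels)))
    names(levels) <- paste0("m", levels)
  frac <- conservation_fraction(nc, blocks)
  out <- lapply(seq_along(levels), function(i) {
    keep <- frac >= levels[[i]]
    g <- nc[keep]
    mcols(g)$conservation_fraction <- frac[keep]
    mcols(g)$conservation_class <- rep(names(levels)[i], sum(keep))
    g
  })
  names(out) <- names(levels)
  out
}

#' Merge context-specific element sets into an omnibus set
#'
#' Aggregates element sets from multiple contexts and merges overlapping or
#' bookended segments into non-overlapping sorted intervals. All inputs must
#' share the same conservation class (as recorded in their
#' `conservation_class` metadata column, when present).
#'
#' @param element_sets A list of `GRanges` (or a `GRangesList`).
#' @return A sorted, pairwise-disjoint `GRanges`.
#' @export
merge_omnibus <- function(element_sets) {
  if (is(element_sets, "GRanges")) element_sets <- list(element_sets)
  if (is(element_sets, "GRangesList")) element_sets <- as.list(element_sets)
  stopifnot(is.list(element_sets), length(element_sets) > 0L)
  classes <- unique(unlist(lapply(element_sets, function(g) {
    cc <- mcols(g)$conservation_class
    if (is.null(cc)) NULL else unique(as.character(cc))
  })))
  if (length(classes) > 1L)
    .err("cannot merge element sets with mixed conservation classes: %s",
         paste(classes, collapse = ", "))
  all <- do.call(c, lapply(element_sets, function(g) {
    mcols(g) <- NULL
    g
  }))
  out <- reduce(sort(all, ignore.strand = TRUE), ignore.strand = TRUE)
  if (length(classes) == 1L)
    mcols(out)$conservation_class <- rep(classes, length(out))
  out
}

#' Classify elements by proximity to transcription start sites
#'
#' Distance is the minimum over element bases and TSS positions of the
#' absolute base distance `|tss - base|` (0 when the TSS falls inside the
#' element). Elements within 200 bp of a TSS are `proximal200`, within
#' 2,000 bp (boundary inclusive) `proximal2k`, and otherwise `distal`.
#'
#' @param elements `GRanges` of elements.
#' @param tss TSS positions: a `GRanges` of width-1 sites or a data frame
#'   with columns `chrom` and `pos` (1-based).
#' @return Factor with levels `proximal200`, `proximal2k`, `distal`.
#' @export
tss_proximity_class <- function(elements, tss) {
  stopifnot(is(elements, "GRanges"))
  if (is.data.frame(tss)) {
    if (nrow(tss) == 0L) .err("TSS list must be non-empty")
    tss <- GRanges(tss$chrom, IRanges(tss$pos, width = 1L))
  }
  stopifnot(is(tss, "GRanges"))
  if (length(tss) == 0L) .err("TSS list must be non-empty")
  d <- rep(Inf, length(elements))
  el_chr <- as.character(seqnames(elements))
  tss_chr <- as.character(seqnames(tss))
  tpos <- start(tss)
  for (chr in unique(el_chr)) {
    i <- which(el_chr == chr)
    tp <- sort(tpos[tss_chr == chr])
    if (!length(tp)) next
    s <- start(elements)[i]
    e <- end(elements)[i]
    # nearest TSS at or left of the element end
    left <- findInterval(e, tp)
    dl <- ifelse(left >= 1L, pmax(s - tp[pmax(left, 1L)], 0L), Inf)
    right <- left + 1L
    dr <- ifelse(right <= length(tp), pmax(tp[pmin(right, length(tp))] - e, 0L), Inf)
    d[i] <- pmin(dl, dr)
  }
  cls <- ifelse(d <= 200, "proximal200", ifelse(d <= 2000, "proximal2k", "distal"))
  factor(cls, levels = c("proximal200", "proximal2k", "distal"))
}
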