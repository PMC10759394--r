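# non-overlapping interval placement by rejection sampling; plain integer
# vectors per chromosome to avoid per-interval GRanges overhead
.place_disjoint <- function(genome, lengths, occupied = NULL,
                            max_tries = 500L) {
  chroms <- names(genome)
  occ <- lapply(chroms, function(ch) {
    if (is.null(occupied)) return(list(s = integer(), e = integer()))
    i <- as.character(seqnames(occupied)) == ch
    list(s = start(occupied)[i], e = end(occupied)[i])
  })
  names(occ) <- chroms
  out_chr <- character(length(lengths))
  out_start <- integer(length(lengths))
  for (i in seq_along(lengths)) {
    L <- lengths[i]
    room <- pmax(as.numeric(genome) - L + 1, 0)
    if (all(room == 0)) .err("genome too small for a peak of length %d", L)
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      ch <- sample(chroms, 1L, prob = room)
      s <- sample.int(genome[[ch]] - L + 1L, 1L)  # 1-based start
      e <- s + L - 1L
      o <- occ[[ch]]
      if (!any(s <= o$e & e >= o$s)) {
        occ[[ch]]$s <- c(o$s, s)
        occ[[ch]]$e <- c(o$e, e)
        out_chr[i] <- ch
        out_start[i] <- s
        placed <- TRUE
        break
      }
    }
    if (!placed)
      .err("could not place %d disjoint peaks; genome too crowded",
           length(lengths))
  }
  GRanges(out_chr, IRanges(out_start, width = lengths),
          seqinfo = .genome_seqinfo(genome))
}

#' Simulate paired H3K27ac and accessibility peak sets for one context
#'
#' Generates a non-overlapping H3K27ac peak set and an accessible-chromatin
#' peak set whose expected base overlap with the H3K27ac set equals
#' `overlap_frac`: each H3K27ac peak is duplicated into the accessibility
#' set with probability `overlap_frac`, and the remaining accessibility
#' peaks are placed disjoint from all H3K27ac peaks.
#'
#' @param genome A [genome_spec].
#' @param n_peaks Number of peaks in each set.
#' @param length_dist Function of `n` returning `n` peak lengths (bases).
#' @param overlap_frac Expected fraction of H3K27ac bases covered by
#'   accessibility peaks, in \[0, 1\].
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return List with sorted `GRanges` components `h3k27ac` and `accessible`.
#' @export
simulate_context_peaks <- function(genome, n_peaks,
                                   length_dist = function(n)
                                     pmax(50, round(rlnorm(n, log(500), 0.35))),
                                   overlap_frac, seed = NULL) {
  genome <- genome_spec(unclass(genome))
  if (!.is_count(n_peaks)) .err("n_peaks must be a positive count")
  if (!.is_prop(overlap_frac)) .err("overlap_frac must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  h3k <- .place_disjoint(genome, as.integer(length_dist(n_peaks)))
  keep <- if (overlap_frac == 1) rep(TRUE, n_peaks)
          else if (overlap_frac == 0) rep(FALSE, n_peaks)
          else runif(n_peaks) < overlap_frac
  shared <- h3k[keep]
  n_new <- n_peaks - sum(keep)
  acc <- if (n_new > 0L) {
    fresh <- .place_disjoint(genome, as.integer(length_dist(n_new)),
                             occupied = c(granges(h3k), granges(shared)))
    c(granges(shared), fresh)
  } else granges(shared)
  list(h3k27ac = sort(h3k, ignore.strand = TRUE),
       accessible = sort(acc, ignore.strand = TRUE))
}

#' Simulate gapless alignment blocks at a target genome coverage
#'
#' Lays non-overlapping ungapped blocks along each source chromosome so that
#' the covered base fraction equals `target_coverage` exactly (up to
#' rounding to whole bases per chromosome). Block lengths are drawn from
#' `block_length_dist` and the uncovered bases are distributed among the
#' gaps at random. Each source block is paired with an equally long interval
#' laid out sequentially on a synthetic target chromosome.
#'
#' @param genome A [genome_spec] for the source genome.
#' @param target_coverage Desired covered base fraction, in \[0, 1\].
#' @param block_length_dist Function of `n` returning `n` block lengths.
#' @param target_prefix Prefix for target chromosome names.
#' @param seed Optional integer seed.
#' @return An [alignment_blocks] object.
#' @export
simulate_alignment_blocks <- function(genome, target_coverage,
                                      block_length_dist = function(n)
                                        pmax(20, round(rexp(n, 1 / 300))),
                                      target_prefix = "t_", seed = NULL) {
  genome <- genome_spec(unclass(genome))
  if (!.is_prop(target_coverage)) .err("target_coverage must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  src_chr <- character(); src_start <- integer(); src_len <- integer()
  for (ch in names(genome)) {
    G <- genome[[ch]]
    B <- round(target_coverage * G)
    if (B < 1) next
    lens <- integer()
    while (sum(lens) < B)
      lens <- c(lens, as.integer(block_length_dist(max(8L, ceiling(B / 200)))))
    k <- which(cumsum(lens) >= B)[1L]
    lens <- lens[seq_len(k)]
    lens[k] <- lens[k] - (sum(lens) - B)
    lens <- lens[lens > 0L]
    k <- length(lens)
    free <- G - B
    gaps <- if (free > 0L) as.integer(rmultinom(1L, free, rep(1, k + 1L)))
            else integer(k + 1L)
    # start_i = 1 + gaps_1..i + lens_1..(i-1)
    starts <- 1L + cumsum(gaps[seq_len(k)]) + c(0L, cumsum(lens[-k]))
    src_chr <- c(src_chr, rep(ch, k))
    src_start <- c(src_start, starts)
    src_len <- c(src_len, lens)
  }
  if (!length(src_len)) {
    empty <- GRanges()
    return(alignment_blocks(empty, GRanges()))
  }
  source <- GRanges(src_chr, IRanges(src_start, width = src_len),
                    seqinfo = .genome_seqinfo(genome))
  # sequential layout on target chromosomes with small random gaps
  tgt_chr <- paste0(target_prefix, src_chr)
  tgt_start <- integer(length(src_len))
  for (ch in unique(tgt_chr)) {
    i <- which(tgt_chr == ch)
    tg <- as.integer(runif(length(i), 0, 500))
    tgt_start[i] <- 1L + cumsum(tg) + c(0L, cumsum(src_len[i][-length(i)]))
  }
  target <- GRanges(tgt_chr, IRanges(tgt_start, width = src_len))
  alignment_blocks(source, target)
}
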