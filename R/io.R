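#' Read peak or element intervals from a BED file
#'
#' Thin wrapper around [rtracklayer::import()]; BED's 0-based half-open
#' coordinates are converted to the 1-based closed convention used by
#' `GRanges` throughout this package.
#'
#' @param path Path to a BED3+ file.
#' @param genome Optional [genome_spec] used to attach sequence lengths.
#' @return A sorted `GRanges`.
#' @export
read_bed <- function(path, genome = NULL) {
  n_fields <- length(strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]])
  extra <- c(conservation_fraction = "numeric",
             conservation_class = "character")
  gr <- if (n_fields > 6L)
    rtracklayer::import(path, format = "BED",
                        extraCols = extra[seq_len(n_fields - 6L)])
  else rtracklayer::import(path, format = "BED")
  strand(gr) <- "*"
  if (!is.null(genome)) {
    seqlevels(gr) <- union(seqlevels(gr), names(genome))
    seqlengths(gr) <- genome[seqlevels(gr)]
  }
  sort(gr, ignore.strand = TRUE)
}

#' Write elements to a BED file
#'
#' Writes BED6 when the elements carry no conservation metadata; otherwise
#' appends `conservation_fraction` and `conservation_class` as two extra
#' tab-separated columns.
#'
#' @param elements `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_elements_bed <- function(elements, path) {
  df <- data.table(
    chrom = as.character(seqnames(elements)),
    start = start(elements) - 1L,
    end   = end(elements),
    name  = if (!is.null(names(elements))) names(elements) else
      sprintf("el%06d", seq_along(elements)),
    score = 0L,
    strand = "."
  )
  mc <- mcols(elements)
  if (!is.null(mc$conservation_fraction))
    df[, "conservation_fraction" := round(mc$conservation_fraction, 6)]
  if (!is.null(mc$conservation_class))
    df[, "conservation_class" := as.character(mc$conservation_class)]
  fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read gapless alignment blocks
#'
#' `read_blocks_tsv()` reads the simplified two-sided block table (columns
#' `chrom`, `start`, `end`, `target_chrom`, `target_start`, `target_end`;
#' 0-based half-open). `read_chain_blocks()` decomposes a UCSC chain file
#' into its ungapped blocks via [rtracklayer::import.chain()];
#' negative-strand chains are converted to forward-strand target
#' coordinates.
#'
#' @param path Path to the block TSV or chain file.
#' @return An [alignment_blocks] object.
#' @export
read_blocks_tsv <- function(path) {
  df <- fread(path, col.names = c("chrom", "start", "end",
                                  "target_chrom", "target_start",
                                  "target_end"))
  alignment_blocks(
    GRanges(df$chrom, IRanges(df$start + 1L, df$end)),
    GRanges(df$target_chrom, IRanges(df$target_start + 1L, df$target_end))
  )
}

#' @rdname read_blocks_tsv
#' @export
read_chain_blocks <- function(path) {
  ch <- rtracklayer::import.chain(path)
  src <- list(); tgt <- list()
  for (chr in names(ch)) {
    b <- ch[[chr]]
    r <- ranges(b)
    off <- b@offset
    sp <- as.character(b@space)
    rev <- as.logical(b@reversed)
    src[[chr]] <- GRanges(chr, r)
    tgt[[chr]] <- GRanges(sp, IRanges(start(r) - off, end(r) - off),
                          strand = ifelse(rev, "-", "+"))
  }
  # combining per-chromosome pieces trips the seqinfo-merge notice even
  # though disjoint sequence levels are expected here
  suppressWarnings(
    alignment_blocks(do.call(c, unname(src)), do.call(c, unname(tgt))))
}

#' @rdname read_blocks_tsv
#' @param blocks An [alignment_blocks] object.
#' @export
write_blocks_tsv <- function(blocks, path) {
  stopifnot(inherits(blocks, "alignment_blocks"))
  df <- data.table(
    chrom = as.character(seqnames(blocks$source)),
    start = start(blocks$source) - 1L,
    end = end(blocks$source),
    target_chrom = as.character(seqnames(blocks$target)),
    target_start = start(blocks$target) - 1L,
    target_end = end(blocks$target)
  )
  fwrite(df, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read and write GWAS summary statistics
#'
#' Tab-separated with columns `snp_id`, `chrom`, `pos` (1-based), `a1`,
#' `a2`, `beta`, `se`, `n`, `z`.
#'
#' @param path File path.
#' @return `read_gwas_tsv()`: a data.frame of summary statistics.
#' @export
read_gwas_tsv <- function(path) {
  df <- setDF(fread(path))
  need <- c("snp_id", "chrom", "pos", "a1", "a2", "beta", "se", "n")
  miss <- setdiff(need, names(df))
  if (length(miss)) .err("GWAS table lacks columns: %s",
                         paste(miss, collapse = ", "))
  if (is.null(df$z)) df$z <- df$beta / df$se
  df
}

#' @rdname read_gwas_tsv
#' @param gwas Data frame of summary statistics.
#' @export
write_gwas_tsv <- function(gwas, path) {
  fwrite(as.data.table(gwas), path, sep = "\t")
  invisible(path)
}

#' Read and write fine-mapping PIP tables
#'
#' Tab-separated with columns `snp_id`, `trait`, `method`, `pip` and any
#' optional QC flag columns.
#'
#' @param path File path.
#' @return `read_pips_tsv()`: a data.frame.
#' @export
read_pips_tsv <- function(path) {
  df <- setDF(fread(path))
  need <- c("snp_id", "pip")
  miss <- setdiff(need, names(df))
  if (length(miss)) .err("PIP table lacks columns: %s",
                         paste(miss, collapse = ", "))
  if (any(df$pip < 0 | df$pip > 1)) .err("PIPs must lie in [0, 1]")
  df
}

#' @rdname read_pips_tsv
#' @param pips Data frame with at least `snp_id` and `pip`.
#' @export
write_pips_tsv <- function(pips, path) {
  fwrite(as.data.table(pips), path, sep = "\t")
  invisible(path)
}

#' Write per-SNP annotations as a thin-annot style TSV
#'
#' Columns `snp_id`, `chrom`, `pos`, then one 0/1 column per annotation
#' label.
#'
#' @param snps SNP table (data frame with `snp_id`, `chrom`, `pos`).
#' @param annotations Named list of 0/1 vectors aligned to `snps`, or a
#'   matrix with column names.
#' @param path Output path.
#' @export
write_annotations_tsv <- function(snps, annotations, path) {
  if (is.matrix(annotations))
    annotations <- as.data.frame(annotations)
  df <- data.table(snp_id = snps$snp_id, chrom = snps$chrom, pos = snps$pos)
  for (lab in names(annotations)) df[, (lab) := as.integer(annotations[[lab]])]
  fwrite(df, path, sep = "\t")
  invisible(path)
}
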