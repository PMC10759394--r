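#' Define a genome for the simulators
#'
#' A genome specification is a named integer vector of chromosome lengths in
#' bases. It is the coordinate frame for all simulated peaks, alignment
#' blocks, and elements.
#'
#' @param lengths Named numeric vector of chromosome lengths (bases); all
#'   lengths must be positive and names unique.
#' @return A named integer vector of class `genome_spec`.
#' @examples
#' genome_spec(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genome_spec <- function(lengths) {
  if (length(lengths) == 0L)
    .err("genome must contain at least one chromosome")
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))) ||
      anyDuplicated(names(lengths)))
    .err("chromosome names must be non-empty and unique")
  if (!is.numeric(lengths) || any(!is.finite(lengths)) || any(lengths < 1))
    .err("chromosome lengths must be positive")
  structure(setNames(as.integer(lengths), names(lengths)),
            class = "genome_spec")
}

# coerce a genome_spec into a Seqinfo for GRanges construction
.genome_seqinfo <- function(genome) {
  Seqinfo(seqnames = names(genome), seqlengths = as.integer(genome))
}

# validate that two GRanges live on compatible assemblies: any annotated
# genome build must agree
.check_same_assembly <- function(x, y) {
  gx <- unique(stats::na.omit(genome(x)))
  gy <- unique(stats::na.omit(genome(y)))
  if (length(gx) && length(gy) && !identical(sort(gx), sort(gy)))
    .err("assembly mismatch: '%s' vs '%s'",
         paste(gx, collapse = ","), paste(gy, collapse = ","))
  invisible(TRUE)
}
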