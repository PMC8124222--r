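#' @importFrom data.table data.table as.data.table setkey setorder := fread fwrite .N .SD
#' @importFrom stats rbeta rbinom rnbinom dhyper phyper p.adjust cor hclust
#'   as.dist median wilcox.test runif
NULL

# round half away from zero at `digits` decimals (base round() is banker's;
# reported percentages use conventional half-up rounding)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample with replacement from the *values* of x, immune to base sample()'s
# scalar expansion (sample(4) means 1:4, not the value 4)
sample_from <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]

stop_if_not_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    stop(sprintf("'%s' must be a single number in [%s, %s]", name,
                 format(min), format(max)), call. = FALSE)
  }
  invisible(x)
}

# Normalise genome inputs to a named character vector of upper-case sequences.
# Accepts a FASTA path, a Biostrings::DNAStringSet, or a named character vector.
as_genome_seqs <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    genome <- as.character(genome)
  }
  if (!is.character(genome) || is.null(names(genome)) || any(names(genome) == "")) {
    stop("genome must be a FASTA path, DNAStringSet, or named character vector",
         call. = FALSE)
  }
  toupper(genome)
}

#' @importFrom methods is
NULL
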