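#' Parse a samtools-style region string
#'
#' Region strings are 1-based inclusive (`"6:69000000-71000000"`); the
#' returned interval uses the package's internal 0-based half-open
#' convention, so start is decremented by one.
#'
#' @param region A string `chrom:start-end` (commas allowed in numbers).
#' @return A [GenomicInterval-class].
#' @examples
#' parseRegion("6:69000000-71000000")
#' @export
parseRegion <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", region))[[1L]]
  if (length(m) != 4L)
    stop("malformed region string (expected chrom:start-end): ", region)
  start1 <- as.numeric(gsub(",", "", m[3L]))
  end1 <- as.numeric(gsub(",", "", m[4L]))
  if (start1 < 1 || end1 < start1)
    stop("invalid region coordinates in: ", region)
  genomicInterval(m[2L], start1 - 1, end1)
}

# Random DNA string of length n under the current RNG state.
randomDna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

reverseComplement1 <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Split a CIGAR string into (length, op) pairs; ops restricted to the
# PAF cg alphabet.
parseCigar <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar)) stop("empty CIGAR")
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  if (nchar(paste0(ops, collapse = "")) != nchar(cigar))
    stop("malformed CIGAR: ", cigar)
  data.frame(len = as.numeric(sub("[MIDNSHP=X]$", "", ops)),
             op = sub("^[0-9]+", "", ops))
}

cigarQueryLen <- function(ops) sum(ops$len[ops$op %in% c("M", "=", "X", "I", "S")])
cigarTargetLen <- function(ops) sum(ops$len[ops$op %in% c("M", "=", "X", "D", "N")])

# Deterministic sub-seed derivation; keeps values within 32-bit range.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %% .Machine$integer.max)
}

# Stable md5 of an R object via its deparsed canonical form.
configHash <- function(x) {
  canon <- function(v) {
    if (is.list(v)) {
      if (!is.null(names(v))) v <- v[order(names(v))]
      lapply(v, canon)
    } else v
  }
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(canon(x)), tmp)
  unname(tools::md5sum(tmp))
}
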