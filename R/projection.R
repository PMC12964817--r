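#' Project a reference interval onto assembly contigs
#'
#' For every alignment record overlapping `target` on the reference,
#' computes the contig-coordinate image of the clipped reference overlap.
#' When the record carries a `cg` CIGAR the image is computed by walking
#' the CIGAR base-accounting ops; otherwise it is obtained by
#' proportional interpolation across the alignment block and the segment
#' is marked `approximate`. Minus-strand alignments map
#' reference-forward order onto query-reverse coordinates.
#'
#' @param records PAF `data.frame` from [parsePaf()].
#' @param target A [GenomicInterval-class] on the reference.
#' @return A `data.frame` of projected segments: `chrom`, `srcStart`,
#'   `srcEnd` (clipped source, reference), `contig`, `contigLength`,
#'   `imgStart`, `imgEnd` (image, contig, 0-based half-open), `strand`,
#'   `identity`, `approximate`, `via` (row index of the source record).
#'   Non-overlapping records contribute no row.
#' @examples
#' paf <- parsePaf(text = "q\t1000\t0\t1000\t+\tref\t5000\t1000\t2000\t1000\t1000\t60")
#' projectInterval(paf, genomicInterval("ref", 1100, 1200))
#' @export
projectInterval <- function(records, target) {
  out <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    if (rec$tname != target@chrom) next
    lo <- max(rec$tstart, target@start)
    hi <- min(rec$tend, target@end)
    if (hi <= lo) next
    if (!is.na(rec$cg)) {
      qo <- cigarQueryOffsets(rec$cg, rec$tstart, lo, hi)
      approx <- FALSE
    } else {
      scale <- (rec$qend - rec$qstart) / (rec$tend - rec$tstart)
      qo <- c(round((lo - rec$tstart) * scale), round((hi - rec$tstart) * scale))
      approx <- TRUE
    }
    if (is.null(qo) || qo[2L] <= qo[1L]) next
    if (rec$strand == "+") {
      img <- c(rec$qstart + qo[1L], rec$qstart + qo[2L])
    } else {
      img <- c(rec$qend - qo[2L], rec$qend - qo[1L])
    }
    out[[length(out) + 1L]] <- data.frame(
      chrom = target@chrom, srcStart = lo, srcEnd = hi,
      contig = rec$qname, contigLength = rec$qlen,
      imgStart = img[1L], imgEnd = img[2L], strand = rec$strand,
      identity = rec$matches / rec$alnlen, approximate = approx, via = i)
  }
  if (!length(out))
    return(data.frame(chrom = character(), srcStart = numeric(),
                      srcEnd = numeric(), contig = character(),
                      contigLength = numeric(), imgStart = numeric(),
                      imgEnd = numeric(), strand = character(),
                      identity = numeric(), approximate = logical(),
                      via = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Query-offset interval [qlo, qhi) (offsets in alignment orientation,
# counted from the start of the aligned query span) covering the aligned
# bases whose target positions fall in [lo, hi). NULL when no aligned
# base overlaps (e.g. the window sits inside a deletion).
cigarQueryOffsets <- function(cigar, tstart, lo, hi) {
  ops <- parseCigar(cigar)
  t <- tstart
  q <- 0
  qlo <- Inf
  qhi <- -Inf
  for (k in seq_len(nrow(ops))) {
    len <- ops$len[k]
    op <- ops$op[k]
    if (op %in% c("M", "=", "X")) {
      a <- max(lo, t)
      b <- min(hi, t + len)
      if (b > a) {
        qlo <- min(qlo, q + (a - t))
        qhi <- max(qhi, q + (b - t))
      }
      t <- t + len
      q <- q + len
    } else if (op == "I" || op == "S") {
      q <- q + len
    } else if (op == "D" || op == "N") {
      t <- t + len
    }
    if (t >= hi && qhi > -Inf) break
  }
  if (!is.finite(qlo)) NULL else c(qlo, qhi)
}

#' Admit additional contigs under length and coverage filters
#'
#' Contigs whose projected segments do not arise from the primary
#' reference chromosome ("additional" sequences) are admitted into the
#' downstream graph only when the aligned segment is at least `minLen`
#' bp long and covers at least `minFrac` of the total contig length.
#' Every decision is reported, with the failing rule(s) named, not only
#' the passes.
#'
#' @param segments Projected-segment `data.frame` (from
#'   [projectInterval()]) or any `data.frame` with `contig`, `imgStart`,
#'   `imgEnd` columns; per-contig aligned length is the union of image
#'   intervals (overlaps are not double-counted).
#' @param contigLengths Named numeric vector of total contig lengths; a
#'   contig with no entry is an error.
#' @param minLen Minimum aligned length in bp (default 10,000).
#' @param minFrac Minimum covered fraction of the contig (default 0.80).
#' @return `data.frame`: `contig`, `alignedLength`, `contigLength`,
#'   `coverageFraction`, `passLength`, `passFraction`, `admitted`,
#'   `reason` (empty string for admitted contigs).
#' @export
admitAdditionalContigs <- function(segments, contigLengths,
                                   minLen = 10000, minFrac = 0.80) {
  contigs <- unique(segments$contig)
  missing <- setdiff(contigs, names(contigLengths))
  if (length(missing))
    stop("unknown contig length for: ", paste(missing, collapse = ", "))
  rows <- lapply(contigs, function(ct) {
    seg <- segments[segments$contig == ct, , drop = FALSE]
    aligned <- unionLength(seg$imgStart, seg$imgEnd)
    total <- unname(contigLengths[ct])
    frac <- aligned / total
    pl <- aligned >= minLen
    pf <- frac >= minFrac
    reason <- paste(c(
      if (!pl) sprintf("aligned length %d below %d bp minimum", aligned, minLen),
      if (!pf) sprintf("coverage fraction %.3f below %.2f minimum", frac, minFrac)),
      collapse = "; ")
    data.frame(contig = ct, alignedLength = aligned, contigLength = total,
               coverageFraction = frac, passLength = pl, passFraction = pf,
               admitted = pl && pf, reason = reason)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# Total length of the union of half-open intervals.
unionLength <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]
  ends <- ends[o]
  total <- 0
  cur_s <- starts[1L]
  cur_e <- ends[1L]
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] > cur_e) {
      total <- total + (cur_e - cur_s)
      cur_s <- starts[i]
      cur_e <- ends[i]
    } else cur_e <- max(cur_e, ends[i])
  }
  as.integer(total + (cur_e - cur_s))
}

#' Detect translocation signatures among contig alignments
#'
#' For every contig with at least one alignment intersecting `target`,
#' lists its alignment blocks in contig-coordinate order (blocks shorter
#' than `minBlock` are suppressed as noise) and flags contigs whose
#' blocks span multiple reference chromosomes or whose same-chromosome
#' blocks are out of reference order -- the serial-translocation pattern
#' in which a downstream reference segment is repositioned upstream on
#' the contig.
#'
#' @param records PAF `data.frame` from [parsePaf()].
#' @param target A [GenomicInterval-class].
#' @param minBlock Minimum alignment block length retained (default
#'   5,000 bp).
#' @return A named list (one element per contig) of lists with elements
#'   `contig`, `blocks` (`data.frame`: `chrom`, `refStart`, `refEnd`,
#'   `strand`, `contigStart`, `contigEnd`), `multiChromosome`,
#'   `nonColinear`.
#' @export
detectTranslocationSignatures <- function(records, target, minBlock = 5000) {
  hit <- records$tname == target@chrom &
    records$tstart < target@end & records$tend > target@start
  contigs <- unique(records$qname[hit])
  sigs <- lapply(contigs, function(ct) {
    blk <- records[records$qname == ct &
                     (records$qend - records$qstart) >= minBlock, , drop = FALSE]
    blk <- blk[order(blk$qstart), , drop = FALSE]
    blocks <- data.frame(chrom = blk$tname, refStart = blk$tstart,
                         refEnd = blk$tend, strand = blk$strand,
                         contigStart = blk$qstart, contigEnd = blk$qend)
    rownames(blocks) <- NULL
    list(contig = ct, blocks = blocks,
         multiChromosome = length(unique(blocks$chrom)) > 1L,
         nonColinear = anyNonColinear(blocks))
  })
  names(sigs) <- contigs
  sigs
}

# TRUE when, for some chromosome, the blocks taken in contig order are
# not monotone in reference coordinates (ascending for '+' runs,
# descending for '-' runs), or mix strands.
anyNonColinear <- function(blocks) {
  for (chrom in unique(blocks$chrom)) {
    b <- blocks[blocks$chrom == chrom, , drop = FALSE]
    if (nrow(b) < 2L) next
    if (length(unique(b$strand)) > 1L) return(TRUE)
    inc <- !is.unsorted(b$refStart, strictly = FALSE)
    dec <- !is.unsorted(rev(b$refStart), strictly = FALSE)
    if (b$strand[1L] == "+" && !inc) return(TRUE)
    if (b$strand[1L] == "-" && !dec) return(TRUE)
  }
  FALSE
}

#' Extract contig sequences for projected segments
#'
#' One FASTA record per segment; minus-strand images are
#' reverse-complemented. Headers encode `contig:start-end:strand` in the
#' internal 0-based half-open convention.
#'
#' @param fasta Path to a FASTA file or a [Biostrings::DNAStringSet].
#' @param segments Projected-segment `data.frame` with `contig`,
#'   `imgStart`, `imgEnd`, `strand`.
#' @return A [Biostrings::DNAStringSet] of segment images.
#' @export
extractRegionSequences <- function(fasta, segments) {
  seqs <- if (is.character(fasta)) Biostrings::readDNAStringSet(fasta) else fasta
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  out <- Biostrings::DNAStringSet(vapply(seq_len(nrow(segments)), function(i) {
    s <- segments[i, ]
    if (!s$contig %in% names(seqs)) stop("contig not in FASTA: ", s$contig)
    full <- seqs[[s$contig]]
    if (s$imgStart < 0 || s$imgEnd > length(full))
      stop(sprintf("segment [%d, %d) outside contig %s (length %d)",
                   s$imgStart, s$imgEnd, s$contig, length(full)))
    sub <- as.character(Biostrings::subseq(full, s$imgStart + 1L, s$imgEnd))
    if (s$strand == "-") reverseComplement1(sub) else sub
  }, character(1L)))
  names(out) <- sprintf("%s:%d-%d:%s", segments$contig,
                        as.integer(segments$imgStart),
                        as.integer(segments$imgEnd), segments$strand)
  out
}
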