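#' Read PAF alignment records
#'
#' Parses the 12 mandatory PAF columns plus an optional `cg:Z:` CIGAR
#' tag. Records that violate the coordinate invariants (`0 <= qstart <=
#' qend <= qlen`, same on the target, and CIGAR-consumed lengths equal to
#' the aligned spans when a CIGAR is present) are rejected individually;
#' rejected line numbers and reasons are attached as the `"rejected"`
#' attribute. A structurally malformed line (too few columns, non-numeric
#' coordinate) is an error naming the line and field.
#'
#' @param file Path to a PAF file, a connection, or a character vector of
#'   lines (via `text`).
#' @param text Optional character vector of PAF lines (overrides `file`).
#' @return A `data.frame` with columns `qname, qlen, qstart, qend,
#'   strand, tname, tlen, tstart, tend, matches, alnlen, mapq, cg`
#'   (`cg` is `NA` when absent), with a `"rejected"` attribute.
#' @export
parsePaf <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(file)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  rejected <- data.frame(line = integer(), reason = character())
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12L)
      stop(sprintf("PAF line %d: expected >= 12 columns, found %d", i, length(f)))
    num <- suppressWarnings(as.numeric(f[c(2, 3, 4, 7, 8, 9, 10, 11, 12)]))
    if (anyNA(num)) {
      bad <- c(2, 3, 4, 7, 8, 9, 10, 11, 12)[which(is.na(num))[1L]]
      stop(sprintf("PAF line %d: non-numeric value in column %d", i, bad))
    }
    if (!f[5] %in% c("+", "-"))
      stop(sprintf("PAF line %d: invalid strand '%s' in column 5", i, f[5]))
    cg <- NA_character_
    if (length(f) > 12L) {
      tag <- grep("^cg:Z:", f[-(1:12)], value = TRUE)
      if (length(tag)) cg <- sub("^cg:Z:", "", tag[1L])
    }
    rec <- data.frame(qname = f[1], qlen = num[1], qstart = num[2],
                      qend = num[3], strand = f[5], tname = f[6],
                      tlen = num[4], tstart = num[5], tend = num[6],
                      matches = num[7], alnlen = num[8], mapq = num[9],
                      cg = cg)
    reason <- pafRecordProblem(rec)
    if (is.null(reason)) rows[[i]] <- rec
    else rejected <- rbind(rejected, data.frame(line = i, reason = reason))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out))
    out <- data.frame(qname = character(), qlen = numeric(), qstart = numeric(),
                      qend = numeric(), strand = character(), tname = character(),
                      tlen = numeric(), tstart = numeric(), tend = numeric(),
                      matches = numeric(), alnlen = numeric(), mapq = numeric(),
                      cg = character())
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

# NULL when the record satisfies the PAF invariants, else a reason string.
pafRecordProblem <- function(rec) {
  if (!(rec$qstart >= 0 && rec$qstart <= rec$qend && rec$qend <= rec$qlen))
    return("query coordinates violate 0 <= qstart <= qend <= qlen")
  if (!(rec$tstart >= 0 && rec$tstart <= rec$tend && rec$tend <= rec$tlen))
    return("target coordinates violate 0 <= tstart <= tend <= tlen")
  if (!is.na(rec$cg)) {
    ops <- tryCatch(parseCigar(rec$cg), error = function(e) NULL)
    if (is.null(ops)) return("unparseable cg CIGAR")
    if (cigarQueryLen(ops) != rec$qend - rec$qstart)
      return("CIGAR query length differs from qend - qstart")
    if (cigarTargetLen(ops) != rec$tend - rec$tstart)
      return("CIGAR target length differs from tend - tstart")
  }
  NULL
}

#' Write PAF records
#'
#' Inverse of [parsePaf()]: emits 12 mandatory columns plus `cg:Z:` when
#' present.
#'
#' @param records PAF `data.frame` as returned by [parsePaf()].
#' @param file Output path or connection.
#' @export
writePaf <- function(records, file) {
  tag <- ifelse(is.na(records$cg), "", paste0("\tcg:Z:", records$cg))
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d%s",
                   records$qname, as.integer(records$qlen),
                   as.integer(records$qstart), as.integer(records$qend),
                   records$strand, records$tname, as.integer(records$tlen),
                   as.integer(records$tstart), as.integer(records$tend),
                   as.integer(records$matches), as.integer(records$alnlen),
                   as.integer(records$mapq), tag)
  writeLines(lines, file)
}
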