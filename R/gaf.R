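#' Read GAF graph-alignment records
#'
#' Parses the 12 standard GAF columns. The path column is an oriented
#' segment string (`>`/`<` steps) or a single named path. Records
#' violating the coordinate invariants (`0 <= qstart <= qend <= qlen`,
#' `0 <= pathStart <= pathEnd <= pathLen`) are rejected individually
#' with reasons (attribute `"rejected"`). Whether a path step names a
#' node that actually exists is checked against the companion graph at
#' accumulation time, not at parse time.
#'
#' @param file Path or connection; or raw lines via `text`.
#' @param text Optional character vector of GAF lines.
#' @return `data.frame` with columns `qname, qlen, qstart, qend, strand,
#'   path, pathLen, pathStart, pathEnd, matches, alnlen, mapq` and a
#'   `"rejected"` attribute.
#' @export
parseGaf <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(file)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- data.frame(qname = character(), qlen = numeric(), qstart = numeric(),
                      qend = numeric(), strand = character(), path = character(),
                      pathLen = numeric(), pathStart = numeric(),
                      pathEnd = numeric(), matches = numeric(),
                      alnlen = numeric(), mapq = numeric())
    attr(out, "rejected") <- data.frame(line = integer(), reason = character())
    return(out)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(f)
  if (any(ncol < 12L))
    stop(sprintf("GAF line %d: expected >= 12 columns, found %d",
                 which(ncol < 12L)[1L], min(ncol)))
  m <- t(vapply(f, `[`, character(12L), 1:12))
  out <- data.frame(qname = m[, 1L], qlen = as.numeric(m[, 2L]),
                    qstart = as.numeric(m[, 3L]), qend = as.numeric(m[, 4L]),
                    strand = m[, 5L], path = m[, 6L],
                    pathLen = as.numeric(m[, 7L]),
                    pathStart = as.numeric(m[, 8L]),
                    pathEnd = as.numeric(m[, 9L]),
                    matches = as.numeric(m[, 10L]),
                    alnlen = as.numeric(m[, 11L]),
                    mapq = as.numeric(m[, 12L]))
  bad_q <- !(out$qstart >= 0 & out$qstart <= out$qend & out$qend <= out$qlen)
  bad_p <- !(out$pathStart >= 0 & out$pathStart <= out$pathEnd &
               out$pathEnd <= out$pathLen)
  reason <- ifelse(bad_q, "query coordinates violate 0 <= qstart <= qend <= qlen",
                   ifelse(bad_p,
                          "path coordinates violate 0 <= start <= end <= path length",
                          NA_character_))
  rejected <- data.frame(line = which(!is.na(reason)),
                         reason = reason[!is.na(reason)])
  out <- out[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Write GAF records
#'
#' @param records GAF `data.frame` as returned by [parseGaf()].
#' @param file Output path or connection.
#' @export
writeGaf <- function(records, file) {
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                   records$qname, as.integer(records$qlen),
                   as.integer(records$qstart), as.integer(records$qend),
                   records$strand, records$path, as.integer(records$pathLen),
                   as.integer(records$pathStart), as.integer(records$pathEnd),
                   as.integer(records$matches), as.integer(records$alnlen),
                   as.integer(records$mapq))
  writeLines(lines, file)
}

# Split oriented path strings into per-record step tables.
gafSteps <- function(path) {
  regmatches(path, gregexpr("[><][^><]+", path))
}

#' Keep the single best alignment per read
#'
#' Emulates a best-alignment (`max-multimap 1`) policy on a GAF that may
#' contain several records per read: the record with the highest residue
#' matches is kept; ties broken by mapping quality, then by the
#' lexicographically smallest path string, so the result is
#' deterministic.
#'
#' @param records GAF `data.frame`.
#' @return The filtered `data.frame`, at most one row per `qname`, in
#'   the order reads first appear.
#' @export
filterBestAlignment <- function(records) {
  if (!nrow(records)) return(records)
  first_seen <- match(unique(records$qname), records$qname)
  o <- order(match(records$qname, records$qname[first_seen]),
             -records$matches, -records$mapq, records$path)
  rec <- records[o, , drop = FALSE]
  rec <- rec[!duplicated(rec$qname), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Accumulate aligned bases per node from GAF records
#'
#' Intersects each record's aligned span `[pathStart, pathEnd)` with the
#' node intervals along its oriented path and adds the overlap length to
#' each node. Repeated traversals of a node within one path accumulate
#' separately, so the per-record assigned bases always sum to
#' `pathEnd - pathStart` (conservation). Soft-clipped read portions are
#' outside the aligned span and therefore excluded.
#'
#' @param gaf A GAF `data.frame` (one sample) or a named list of them
#'   (one element per sample).
#' @param graph The companion [VariationGraph-class]; a path step naming
#'   a node absent from the graph is an error naming read and node.
#' @return A [NodeCoverageTable-class] (samples x all graph nodes). The
#'   per-record assigned base totals are attached as attribute
#'   `"perRecord"` (named list of `data.frame(read, assigned, span)`).
#' @export
accumulateNodeCoverage <- function(gaf, graph) {
  if (is.data.frame(gaf)) gaf <- list(sample1 = gaf)
  if (is.null(names(gaf)) || any(!nzchar(names(gaf))))
    stop("'gaf' list must be named by sample")
  ids <- graph@nodes$id
  node_len <- structure(graph@nodes$length, names = ids)
  bases <- matrix(0, nrow = length(gaf), ncol = length(ids),
                  dimnames = list(names(gaf), ids))
  per_record <- vector("list", length(gaf))
  names(per_record) <- names(gaf)
  for (s in names(gaf)) {
    rec <- gaf[[s]]
    if (!nrow(rec)) {
      per_record[[s]] <- data.frame(read = character(), assigned = numeric(),
                                    span = numeric())
      next
    }
    steps <- gafSteps(rec$path)
    L <- lengths(steps)
    if (any(L == 0L))
      stop(sprintf("read '%s': path '%s' has no oriented steps",
                   rec$qname[which(L == 0L)[1L]], rec$path[which(L == 0L)[1L]]))
    grp <- rep.int(seq_len(nrow(rec)), L)
    node <- substring(unlist(steps), 2L)
    unknown <- !(node %in% ids)
    if (any(unknown)) {
      k <- which(unknown)[1L]
      stop(sprintf("read '%s': path step names unknown node '%s'",
                   rec$qname[grp[k]], node[k]))
    }
    len <- node_len[node]
    cs <- cumsum(len)
    idx_end <- cumsum(L)
    offset <- rep.int(c(0, cs[idx_end[-length(idx_end)]]), L)
    node_start <- cs - len - offset
    node_end <- node_start + len
    tot <- cs[idx_end] - c(0, cs[idx_end[-length(idx_end)]])
    bad <- which(tot != rec$pathLen)
    if (length(bad))
      stop(sprintf("read '%s': stated path length %d differs from sum of node lengths %d",
                   rec$qname[bad[1L]], rec$pathLen[bad[1L]], tot[bad[1L]]))
    ov <- pmax(0, pmin(rec$pathEnd[grp], node_end) -
                 pmax(rec$pathStart[grp], node_start))
    acc <- rowsum(ov, node)
    bases[s, rownames(acc)] <- bases[s, rownames(acc)] + acc[, 1L]
    assigned <- rowsum(ov, grp)[, 1L]
    per_record[[s]] <- data.frame(read = rec$qname, assigned = unname(assigned),
                                  span = rec$pathEnd - rec$pathStart)
  }
  out <- new("NodeCoverageTable", bases = bases, nodeLength = node_len)
  attr(out, "perRecord") <- per_record
  out
}

#' Estimate per-sample sequencing depth from core-node coverage
#'
#' Depth is the median over core nodes of assigned bases per node
#' length: robust to the structural variant itself (whose nodes are not
#' core) and to local coverage noise. A user-supplied override is used
#' verbatim.
#'
#' @param coverage A [NodeCoverageTable-class].
#' @param coreNodes Character vector of core node ids (non-empty unless
#'   `override` is given).
#' @param override Optional numeric depth (single value or named per
#'   sample) used instead of the estimate.
#' @return Named numeric vector, one depth per sample.
#' @export
estimateSampleDepth <- function(coverage, coreNodes, override = NULL) {
  samples <- rownames(coverage@bases)
  if (!is.null(override)) {
    if (length(override) == 1L && is.null(names(override)))
      return(structure(rep(as.numeric(override), length(samples)),
                       names = samples))
    return(structure(as.numeric(override[samples]), names = samples))
  }
  if (!length(coreNodes)) stop("empty core node set and no depth override")
  missing <- setdiff(coreNodes, colnames(coverage@bases))
  if (length(missing))
    stop("core nodes absent from coverage table: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  per_base <- sweep(coverage@bases[, coreNodes, drop = FALSE], 2L,
                    coverage@nodeLength[coreNodes], "/")
  apply(per_base, 1L, stats::median)
}

#' Normalized coverage of a node set
#'
#' Raw per-base coverage of the region (total assigned bases divided by
#' the region length) divided by the sample's sequencing depth, so a
#' region present on both haplotypes sits near 1.0, a heterozygous
#' region near 0.5, and a duplicated region above 1.5.
#'
#' @param coverage A [NodeCoverageTable-class].
#' @param nodes Non-empty character vector of node ids defining the
#'   region.
#' @param depth Per-sample depth (named vector or single value), all
#'   `> 0`.
#' @param regionLength Region length in bp used as the denominator;
#'   defaults to the sum of member node lengths. Pass the alternative
#'   path's walk length (e.g. a subregion call's `totalLength`) when the
#'   region traverses shared nodes repeatedly.
#' @return `data.frame` with columns `sample`, `raw` (per-base
#'   coverage), `depth`, `normalized`.
#' @export
normalizedRegionCoverage <- function(coverage, nodes, depth,
                                     regionLength = NULL) {
  if (!length(nodes)) stop("empty node set")
  missing <- setdiff(nodes, colnames(coverage@bases))
  if (length(missing))
    stop("nodes absent from coverage table: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  samples <- rownames(coverage@bases)
  depth <- if (length(depth) == 1L && is.null(names(depth)))
    structure(rep(as.numeric(depth), length(samples)), names = samples)
  else structure(as.numeric(depth[samples]), names = samples)
  if (any(is.na(depth) | depth <= 0))
    stop("sample depth must be > 0 for all samples")
  if (is.null(regionLength))
    regionLength <- sum(coverage@nodeLength[nodes])
  raw <- rowSums(coverage@bases[, nodes, drop = FALSE]) / regionLength
  data.frame(sample = samples, raw = unname(raw), depth = unname(depth),
             normalized = unname(raw / depth))
}

#' Call a diploid SV genotype from normalized coverage
#'
#' Thresholds are placed symmetrically around the expected states 0
#' (absent), 0.5 (heterozygous) and 1.0 (homozygous), with the diploid
#' band's upper edge at 1.5 separating duplications. Intervals are
#' half-open with boundary values falling in the upper class; the copy
#' number estimate is `round(2 x normalized)` with half-even rounding.
#'
#' @param norm Output of [normalizedRegionCoverage()] (or a numeric
#'   vector of normalized values, optionally named by sample).
#' @param tAbsent,tHetHi,tDup Strictly increasing positive thresholds
#'   (defaults 0.25, 0.75, 1.5).
#' @return `data.frame` with columns `sample`, `normalized`, `call`
#'   (`absent`/`het`/`hom`/`dup`), `copyNumber`.
#' @examples
#' callGenotype(c(a = 0.02, b = 0.52, c = 1.01, d = 2.92))
#' @export
callGenotype <- function(norm, tAbsent = 0.25, tHetHi = 0.75, tDup = 1.5) {
  if (!(tAbsent > 0 && tAbsent < tHetHi && tHetHi < tDup))
    stop("thresholds must satisfy 0 < tAbsent < tHetHi < tDup")
  if (is.data.frame(norm)) {
    values <- norm$normalized
    samples <- norm$sample
  } else {
    values <- as.numeric(norm)
    samples <- if (!is.null(names(norm))) names(norm)
    else paste0("sample", seq_along(norm))
  }
  if (any(values < 0)) stop("normalized coverage must be >= 0")
  call <- ifelse(values < tAbsent, "absent",
                 ifelse(values < tHetHi, "het",
                        ifelse(values < tDup, "hom", "dup")))
  data.frame(sample = samples, normalized = values, call = call,
             copyNumber = round(2 * values))
}
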