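#' Length of a half-open genomic interval
#'
#' Returns `end - start` under the 0-based half-open convention, so the
#' printed coordinate pair of a segment gives its size directly (e.g.
#' chromosome-29 interval 18,563,290-19,251,547 spans 688,257 bp).
#'
#' @param x A [GenomicInterval-class].
#' @return Numeric length in bp (0 for an empty interval).
#' @examples
#' intervalLength(genomicInterval("29", 18563290, 19251547))
#' @export
setGeneric("intervalLength", function(x) standardGeneric("intervalLength"))

#' @rdname intervalLength
#' @export
setMethod("intervalLength", "GenomicInterval", function(x) x@end - x@start)

#' Basic size statistics of a variation graph
#'
#' @param x A [VariationGraph-class].
#' @return Named list: `nodes`, `edges`, `nucleotides` (sum of node
#'   lengths), `paths`.
#' @export
setGeneric("graphStats", function(x) standardGeneric("graphStats"))

#' @rdname graphStats
#' @export
setMethod("graphStats", "VariationGraph", function(x) {
  list(nodes = nrow(x@nodes), edges = nrow(x@edges),
       nucleotides = sum(x@nodes$length), paths = length(x@paths))
})

# ---- accessors -------------------------------------------------------

#' Accessors for VariationGraph
#'
#' @param x A [VariationGraph-class].
#' @return `graphNodes()` / `graphEdges()` return the node / edge
#'   `data.frame`; `graphPaths()` the named list of path step tables;
#'   `pathNames()` the path names.
#' @name graph-accessors
NULL

#' @rdname graph-accessors
#' @export
graphNodes <- function(x) x@nodes

#' @rdname graph-accessors
#' @export
graphEdges <- function(x) x@edges

#' @rdname graph-accessors
#' @export
graphPaths <- function(x) x@paths

#' @rdname graph-accessors
#' @export
pathNames <- function(x) names(x@paths)

#' Reconstruct the sequence spelled by a path
#'
#' Concatenates node sequences along the oriented steps of a path
#' (reverse-complementing `-` steps). Requires node sequences.
#'
#' @param x A [VariationGraph-class].
#' @param path Path name.
#' @return A character string.
#' @export
pathSequence <- function(x, path) {
  p <- x@paths[[path]]
  if (is.null(p)) stop("unknown path: ", path)
  seqs <- x@nodes$seq[match(p$node, x@nodes$id)]
  if (anyNA(seqs)) stop("graph lacks sequences for path ", path)
  rev_idx <- p$orient == "-"
  if (any(rev_idx))
    seqs[rev_idx] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[rev_idx])))
  paste0(seqs, collapse = "")
}

#' Coverage matrix accessors
#'
#' @param x A [NodeCoverageTable-class].
#' @return `coverageBases()` returns the samples x nodes base-count
#'   matrix; `coverageNodeLengths()` the named node-length vector;
#'   `sampleTotals()` per-sample total aligned bases.
#' @name coverage-accessors
NULL

#' @rdname coverage-accessors
#' @export
coverageBases <- function(x) x@bases

#' @rdname coverage-accessors
#' @export
coverageNodeLengths <- function(x) x@nodeLength

#' @rdname coverage-accessors
#' @export
sampleTotals <- function(x) rowSums(x@bases)

#' Per-node depth table accessor
#'
#' @param x A [NodeDepthTable-class].
#' @return `depthTable()` returns the per-node summary `data.frame`
#'   (`node`, `length`, `multiplicity`, `depth`); `depthMultiplicity()`
#'   the long per-path traversal table.
#' @name depth-accessors
NULL

#' @rdname depth-accessors
#' @export
depthTable <- function(x) x@depth

#' @rdname depth-accessors
#' @export
depthMultiplicity <- function(x) x@multiplicity

# ---- show methods ----------------------------------------------------

setMethod("show", "GenomicInterval", function(object) {
  cat(sprintf("GenomicInterval %s:[%s, %s) strand %s (%s bp)\n",
              object@chrom, format(object@start, big.mark = ",", scientific = FALSE),
              format(object@end, big.mark = ",", scientific = FALSE),
              object@strand,
              format(intervalLength(object), big.mark = ",", scientific = FALSE)))
})

setMethod("show", "VariationGraph", function(object) {
  st <- graphStats(object)
  cat(sprintf(
    "VariationGraph: %d nodes, %d edges, %s bp, %d paths\n",
    st$nodes, st$edges, format(st$nucleotides, big.mark = ","), st$paths))
  if (st$paths) {
    shown <- utils::head(names(object@paths), 4L)
    cat("  paths: ", paste(shown, collapse = ", "),
        if (st$paths > 4L) ", ..." else "", "\n", sep = "")
  }
})

setMethod("show", "NodeDepthTable", function(object) {
  cat(sprintf("NodeDepthTable: %d nodes, %d samples (depth range %d-%d)\n",
              nrow(object@depth), object@nSamples,
              min(object@depth$depth), max(object@depth$depth)))
})

setMethod("show", "NodeCoverageTable", function(object) {
  cat(sprintf("NodeCoverageTable: %d samples x %d nodes, %s aligned bases\n",
              nrow(object@bases), ncol(object@bases),
              format(sum(object@bases), big.mark = ",")))
})
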