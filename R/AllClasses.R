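#' @import methods
NULL

#' GenomicInterval: a half-open interval on a named sequence
#'
#' A minimal interval container using the 0-based half-open convention of
#' PAF/BED. Region strings in the 1-based inclusive samtools convention
#' (e.g. `"6:69000000-71000000"`) are converted at the boundary by
#' [parseRegion()].
#'
#' @slot chrom Sequence (chromosome or contig) name.
#' @slot start,end Numeric positions, `0 <= start <= end`, half-open.
#' @slot strand One of `"+"`, `"-"`, `"*"` (unspecified).
#' @seealso [genomicInterval()], [intervalLength()], [parseRegion()]
#' @exportClass GenomicInterval
setClass("GenomicInterval",
  representation(chrom = "character", start = "numeric", end = "numeric",
                 strand = "character"),
  prototype(strand = "*"))

setValidity("GenomicInterval", function(object) {
  msg <- character()
  if (length(object@chrom) != 1L || !nzchar(object@chrom))
    msg <- c(msg, "'chrom' must be a single non-empty string")
  if (length(object@start) != 1L || length(object@end) != 1L)
    msg <- c(msg, "'start' and 'end' must be single numbers")
  else {
    if (object@start < 0) msg <- c(msg, "'start' must be >= 0")
    if (object@end < object@start) msg <- c(msg, "'end' must be >= 'start'")
  }
  if (!object@strand %in% c("+", "-", "*"))
    msg <- c(msg, "'strand' must be one of '+', '-', '*'")
  if (length(msg)) msg else TRUE
})

#' Construct a GenomicInterval
#'
#' @param chrom Sequence name.
#' @param start,end 0-based half-open coordinates.
#' @param strand `"+"`, `"-"` or `"*"`.
#' @return A [GenomicInterval-class] object.
#' @examples
#' genomicInterval("29", 18563290, 19251547)
#' @export
genomicInterval <- function(chrom, start, end, strand = "*") {
  new("GenomicInterval", chrom = as.character(chrom), start = as.numeric(start),
      end = as.numeric(end), strand = strand)
}

#' VariationGraph: nodes, oriented edges and haplotype paths
#'
#' The unified coordinate system of the analysis: a bidirected sequence
#' graph in GFA terms. Nodes carry a length and (optionally) a sequence;
#' paths are the embedded haplotype walks (GFA `P` lines, or `W` walks
#' converted to the same semantics).
#'
#' @slot nodes `data.frame` with columns `id`, `length`, `seq` (`seq` may
#'   be `NA` when the source GFA stored `*` segments).
#' @slot edges `data.frame` with columns `from`, `fromOrient`, `to`,
#'   `toOrient`.
#' @slot paths Named list; each element a `data.frame` with columns
#'   `node` and `orient` (`"+"`/`"-"`), one row per oriented step.
#' @seealso [parseGfa()], [writeGfa()], [graphStats()], [pathNodeDepth()]
#' @exportClass VariationGraph
setClass("VariationGraph",
  representation(nodes = "data.frame", edges = "data.frame", paths = "list"))

setValidity("VariationGraph", function(object) {
  msg <- character()
  nd <- object@nodes
  if (!all(c("id", "length", "seq") %in% names(nd)))
    return("'nodes' must have columns id, length, seq")
  if (anyDuplicated(nd$id)) msg <- c(msg, "duplicate node ids")
  if (any(nd$length <= 0)) msg <- c(msg, "node lengths must be > 0")
  has_seq <- !is.na(nd$seq)
  if (any(nchar(nd$seq[has_seq]) != nd$length[has_seq]))
    msg <- c(msg, "node sequence length disagrees with 'length'")
  ed <- object@edges
  if (!all(c("from", "fromOrient", "to", "toOrient") %in% names(ed)))
    return("'edges' must have columns from, fromOrient, to, toOrient")
  if (nrow(ed) && !all(c(ed$from, ed$to) %in% nd$id))
    msg <- c(msg, "edge references a missing node")
  if (length(object@paths)) {
    if (is.null(names(object@paths)) || any(!nzchar(names(object@paths))))
      msg <- c(msg, "paths must be named")
    for (pn in names(object@paths)) {
      p <- object@paths[[pn]]
      if (!all(c("node", "orient") %in% names(p))) {
        msg <- c(msg, sprintf("path '%s' lacks node/orient columns", pn))
        next
      }
      bad <- setdiff(p$node, nd$id)
      if (length(bad))
        msg <- c(msg, sprintf("path '%s' references missing node '%s'",
                              pn, bad[1L]))
    }
  }
  if (length(msg)) msg else TRUE
})

#' NodeDepthTable: per-node path traversal and sample depth
#'
#' @slot multiplicity `data.frame` with columns `node`, `path`, `sample`,
#'   `multiplicity`: how many times each path traverses each node.
#' @slot depth `data.frame` with columns `node`, `length`, `multiplicity`
#'   (total traversals) and `depth` (number of distinct samples whose
#'   paths traverse the node; untraversed nodes have depth 0).
#' @slot nSamples Number of distinct samples among the graph's paths.
#' @seealso [pathNodeDepth()], [classifyNodes()]
#' @exportClass NodeDepthTable
setClass("NodeDepthTable",
  representation(multiplicity = "data.frame", depth = "data.frame",
                 nSamples = "integer"))

#' NodeCoverageTable: aligned bases per sample and node
#'
#' Built from GAF records by [accumulateNodeCoverage()]: entry `[s, v]`
#' is the number of aligned bases sample `s` placed on node `v`.
#'
#' @slot bases Numeric matrix, samples x nodes (column names are node
#'   ids).
#' @slot nodeLength Named numeric vector of node lengths.
#' @seealso [accumulateNodeCoverage()], [estimateSampleDepth()],
#'   [normalizedRegionCoverage()]
#' @exportClass NodeCoverageTable
setClass("NodeCoverageTable",
  representation(bases = "matrix", nodeLength = "numeric"))

setValidity("NodeCoverageTable", function(object) {
  msg <- character()
  if (any(object@bases < 0)) msg <- c(msg, "negative base counts")
  if (!identical(colnames(object@bases), names(object@nodeLength)))
    msg <- c(msg, "column names must match nodeLength names")
  if (length(msg)) msg else TRUE
})
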