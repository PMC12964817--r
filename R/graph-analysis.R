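#' Per-node path depth of a variation graph
#'
#' For every node, counts how many times each embedded path traverses it
#' (multiplicity, so cycles count repeatedly) and how many distinct
#' *samples* traverse it (depth). Sample identity is the path-name
#' prefix before `sampleDelim` (PanSN style), so the two haplotypes of
#' one sample count once toward depth while their traversal
#' multiplicities are retained for copy-number interpretation.
#'
#' @param graph A [VariationGraph-class] with at least one path.
#' @param sampleDelim Delimiter separating sample from haplotype in path
#'   names (default `"#"`).
#' @return A [NodeDepthTable-class].
#' @export
pathNodeDepth <- function(graph, sampleDelim = "#") {
  if (!length(graph@paths)) stop("graph has no paths")
  samples <- pathSample(names(graph@paths), sampleDelim)
  long <- do.call(rbind, lapply(seq_along(graph@paths), function(i) {
    tab <- table(graph@paths[[i]]$node)
    data.frame(node = names(tab), path = names(graph@paths)[i],
               sample = samples[i], multiplicity = as.integer(tab))
  }))
  rownames(long) <- NULL
  depth <- vapply(split(long$sample, long$node),
                  function(s) length(unique(s)), integer(1L))
  mult <- vapply(split(long$multiplicity, long$node), sum, integer(1L))
  nd <- graph@nodes
  dt <- data.frame(node = nd$id, length = nd$length,
                   multiplicity = unname(mult[match(nd$id, names(mult))]),
                   depth = unname(depth[match(nd$id, names(depth))]))
  dt$multiplicity[is.na(dt$multiplicity)] <- 0L
  dt$depth[is.na(dt$depth)] <- 0L
  new("NodeDepthTable", multiplicity = long, depth = dt,
      nSamples = length(unique(samples)))
}

pathSample <- function(pathNames, sampleDelim = "#") {
  vapply(strsplit(pathNames, sampleDelim, fixed = TRUE), `[[`, character(1L), 1L)
}

#' Classify nodes as core, variable or private
#'
#' Core nodes are traversed by all samples; private nodes by exactly
#' one; the remainder of traversed nodes are variable. Untraversed nodes
#' (depth 0) are labelled `"untraversed"` and excluded from the class
#' counts.
#'
#' @param depths A [NodeDepthTable-class] from [pathNodeDepth()].
#' @param nSamples Number of samples; defaults to the count recorded in
#'   `depths`. A node depth exceeding `nSamples` is an error.
#' @return `data.frame` with columns `node`, `depth`, `class`; the
#'   per-class counts are attached as attribute `"counts"`.
#' @export
classifyNodes <- function(depths, nSamples = NULL) {
  if (is.null(nSamples)) nSamples <- depths@nSamples
  if (nSamples < 1L) stop("nSamples must be >= 1")
  d <- depths@depth
  if (any(d$depth > nSamples))
    stop("node depth exceeds the number of samples: inconsistent input")
  cls <- ifelse(d$depth == 0L, "untraversed",
                ifelse(d$depth == nSamples, "core",
                       ifelse(d$depth == 1L, "private", "variable")))
  out <- data.frame(node = d$node, depth = d$depth, class = cls)
  counts <- c(core = sum(cls == "core"), variable = sum(cls == "variable"),
              private = sum(cls == "private"))
  attr(out, "counts") <- counts
  out
}

# Backbone coordinates for every node: position (bp offset of the
# backbone path's first traversal) and rank (index of that traversal).
# Nodes absent from the backbone inherit their nearest backbone
# neighbour's position/rank via breadth-first search over the
# (orientation-ignored) edge set.
backbonePositions <- function(graph, backbone) {
  p <- graph@paths[[backbone]]
  if (is.null(p)) stop("backbone path not found: ", backbone)
  lens <- graph@nodes$length[match(p$node, graph@nodes$id)]
  starts <- c(0, cumsum(lens))[seq_len(nrow(p))]
  first <- !duplicated(p$node)
  pos <- structure(starts[first], names = p$node[first])
  rank <- structure(which(first), names = p$node[first])
  all_ids <- graph@nodes$id
  res_pos <- structure(rep(NA_real_, length(all_ids)), names = all_ids)
  res_rank <- structure(rep(NA_real_, length(all_ids)), names = all_ids)
  res_pos[names(pos)] <- pos
  res_rank[names(rank)] <- rank
  todo <- all_ids[is.na(res_pos)]
  if (length(todo)) {
    ed <- graph@edges
    adj <- split(c(ed$to, ed$from), c(ed$from, ed$to))
    queue <- all_ids[!is.na(res_pos)]
    while (length(queue) && anyNA(res_pos)) {
      nxt <- character()
      for (v in queue) {
        for (w in adj[[v]]) {
          if (is.na(res_pos[w])) {
            res_pos[w] <- res_pos[v]
            res_rank[w] <- res_rank[v]
            nxt <- c(nxt, w)
          }
        }
      }
      queue <- nxt
    }
  }
  list(pos = res_pos, rank = res_rank)
}

#' Detect differential subregions (structural-variant candidates)
#'
#' Groups non-core traversed nodes by their carrier-sample-set
#' signature, orders each group along a designated backbone path, merges
#' group members separated by at most `maxGap` intervening backbone
#' nodes, and emits calls whose total walk length and carrier count pass
#' the thresholds. The total length of a call is the length of the
#' alternative path through its nodes: each node's length times the
#' median traversal multiplicity among the carrier paths that traverse
#' it, so an insertion made of repeated units reports the full inserted
#' length even though the unit is a single shared node.
#'
#' @param graph A [VariationGraph-class].
#' @param depths A [NodeDepthTable-class] from [pathNodeDepth()].
#' @param backbone Name of the backbone (reference) path used for
#'   ordering; required.
#' @param minTotalLen Minimum call length in bp (default 1,000).
#' @param minCarriers Minimum number of carrier samples (default 2).
#' @param maxGap Maximum number of intervening backbone nodes merged
#'   across (default 5).
#' @param sampleDelim Path-name sample delimiter (default `"#"`).
#' @return A list of calls sorted by total length (descending; ties by
#'   smallest backbone position), each a list with elements `nodes`,
#'   `totalLength`, `carriers`, `anchor` (backbone bp position).
#' @export
detectDifferentialSubregions <- function(graph, depths, backbone,
                                         minTotalLen = 1000, minCarriers = 2,
                                         maxGap = 5, sampleDelim = "#") {
  if (is.null(graph@paths[[backbone]]))
    stop("backbone path not found: ", backbone)
  bb <- backbonePositions(graph, backbone)
  d <- depths@depth
  n <- depths@nSamples
  cand <- d$node[d$depth > 0L & d$depth < n]
  if (!length(cand)) return(list())
  long <- depths@multiplicity[depths@multiplicity$node %in% cand, , drop = FALSE]
  carriers_by_node <- lapply(split(long$sample, long$node),
                             function(s) sort(unique(s)))
  sig <- vapply(carriers_by_node, paste, character(1L), collapse = ",")
  med_mult <- vapply(split(long$multiplicity, long$node),
                     stats::median, numeric(1L))
  node_len <- structure(d$length, names = d$node)
  calls <- list()
  for (key in unique(sig)) {
    members <- names(sig)[sig == key]
    members <- members[order(bb$rank[members], bb$pos[members])]
    ranks <- bb$rank[members]
    grp <- cumsum(c(1, diff(ranks) - 1 > maxGap))
    for (g in unique(grp)) {
      nodes <- members[grp == g]
      totalLength <- sum(node_len[nodes] * med_mult[nodes])
      carriers <- carriers_by_node[[nodes[1L]]]
      if (totalLength >= minTotalLen && length(carriers) >= minCarriers)
        calls[[length(calls) + 1L]] <- list(
          nodes = unname(nodes), totalLength = unname(totalLength),
          carriers = carriers, anchor = unname(min(bb$pos[nodes])))
    }
  }
  if (!length(calls)) return(list())
  o <- order(-vapply(calls, `[[`, numeric(1L), "totalLength"),
             vapply(calls, `[[`, numeric(1L), "anchor"))
  calls[o]
}

#' Extract an induced subgraph around a node set
#'
#' Returns the induced subgraph over `nodes` plus `flank` backbone nodes
#' on either side of the backbone span covered by the set (when a
#' backbone is given). Paths are trimmed to their maximal sub-walks
#' within the retained node set; a path split into several sub-walks is
#' renamed with a `#part<i>` suffix, while a path reduced to a single
#' sub-walk keeps its name (so extraction with the same set is
#' idempotent).
#'
#' @param graph A [VariationGraph-class].
#' @param nodes Non-empty character vector of node ids.
#' @param flank Number of backbone nodes of context on each side
#'   (default 50; ignored without `backbone`).
#' @param backbone Optional backbone path name.
#' @return A [VariationGraph-class].
#' @export
extractSubgraph <- function(graph, nodes, flank = 50, backbone = NULL) {
  if (!length(nodes)) stop("empty node set")
  missing <- setdiff(nodes, graph@nodes$id)
  if (length(missing)) stop("unknown nodes: ", paste(missing, collapse = ", "))
  keep <- nodes
  if (!is.null(backbone) && !is.null(graph@paths[[backbone]]) && flank > 0) {
    bbp <- graph@paths[[backbone]]$node
    bb <- backbonePositions(graph, backbone)
    ranks <- bb$rank[nodes]
    ranks <- ranks[!is.na(ranks)]
    if (length(ranks)) {
      lo <- max(1L, min(ranks) - flank)
      hi <- min(length(bbp), max(ranks) + flank)
      keep <- union(keep, bbp[lo:hi])
    }
  }
  nd <- graph@nodes[graph@nodes$id %in% keep, , drop = FALSE]
  ed <- graph@edges[graph@edges$from %in% keep & graph@edges$to %in% keep, ,
                    drop = FALSE]
  paths <- list()
  for (pn in names(graph@paths)) {
    p <- graph@paths[[pn]]
    inset <- p$node %in% keep
    if (!any(inset)) next
    runs <- rle(inset)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    idx <- which(runs$values)
    subwalks <- lapply(idx, function(k) p[starts[k]:ends[k], , drop = FALSE])
    if (length(subwalks) == 1L) {
      paths[[pn]] <- subwalks[[1L]]
    } else {
      for (k in seq_along(subwalks))
        paths[[sprintf("%s#part%d", pn, k)]] <- subwalks[[k]]
    }
  }
  rownames(nd) <- NULL
  rownames(ed) <- NULL
  variationGraph(nd, ed, paths, addPathEdges = FALSE)
}
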