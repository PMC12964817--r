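#' Construct a VariationGraph
#'
#' @param nodes `data.frame` with columns `id`, `length`, `seq` (or
#'   `seq` omitted / `NA`; `length` may be omitted when `seq` is given).
#' @param edges `data.frame` with columns `from`, `fromOrient`, `to`,
#'   `toOrient` (may be empty).
#' @param paths Named list; each element either a `data.frame` with
#'   `node`/`orient` columns or a character vector of oriented steps
#'   like `c("n1+", "n2-")`.
#' @param addPathEdges Add any path-implied adjacency missing from
#'   `edges` (default `TRUE`), so that every consecutive step pair of a
#'   path is an edge.
#' @return A validated [VariationGraph-class].
#' @export
variationGraph <- function(nodes, edges = NULL, paths = list(),
                           addPathEdges = TRUE) {
  if (is.null(nodes$seq)) nodes$seq <- NA_character_
  if (is.null(nodes$length)) nodes$length <- nchar(nodes$seq)
  nodes <- data.frame(id = as.character(nodes$id),
                      length = as.numeric(nodes$length),
                      seq = as.character(nodes$seq))
  if (is.null(edges) || !nrow(edges))
    edges <- data.frame(from = character(), fromOrient = character(),
                        to = character(), toOrient = character())
  paths <- lapply(paths, function(p) {
    if (is.character(p))
      p <- data.frame(node = sub("[+-]$", "", p),
                      orient = sub("^.*([+-])$", "\\1", p))
    data.frame(node = as.character(p$node), orient = as.character(p$orient))
  })
  if (addPathEdges && length(paths)) {
    implied <- do.call(rbind, lapply(paths, function(p) {
      n <- nrow(p)
      if (n < 2L) return(NULL)
      data.frame(from = p$node[-n], fromOrient = p$orient[-n],
                 to = p$node[-1L], toOrient = p$orient[-1L])
    }))
    if (!is.null(implied)) {
      edges <- rbind(edges, implied)
      edges <- edges[!duplicated(edges), , drop = FALSE]
    }
  }
  rownames(edges) <- NULL
  new("VariationGraph", nodes = nodes, edges = edges, paths = paths)
}

#' Read a GFA variation graph
#'
#' Accepts GFA 1.0 `S`/`L`/`P` lines; GFA 1.1 `W` walk lines are
#' converted to path semantics (path name
#' `sample#haplotype#sequence`). Sequence-less `S` lines must carry an
#' `LN:i:` tag. A `P` or `W` line referencing a missing node is an
#' error naming the path and the node, as is an `L` line with a dangling
#' endpoint.
#'
#' @param file Path or connection; or supply raw lines via `text`.
#' @param text Optional character vector of GFA lines.
#' @return A [VariationGraph-class].
#' @export
parseGfa <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(file)
  lines <- lines[nzchar(lines)]
  type <- substr(lines, 1L, 1L)
  nodes <- list(); edges <- list(); paths <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (type[i] == "S") {
      seq <- f[3L]
      if (seq == "*") {
        ln <- grep("^LN:i:", f, value = TRUE)
        if (!length(ln))
          stop(sprintf("GFA line %d: sequence-less segment '%s' lacks LN tag",
                       i, f[2L]))
        nodes[[f[2L]]] <- data.frame(id = f[2L],
                                     length = as.numeric(sub("^LN:i:", "", ln[1L])),
                                     seq = NA_character_)
      } else {
        nodes[[f[2L]]] <- data.frame(id = f[2L], length = nchar(seq), seq = seq)
      }
    } else if (type[i] == "L") {
      edges[[length(edges) + 1L]] <- data.frame(
        from = f[2L], fromOrient = f[3L], to = f[4L], toOrient = f[5L])
    } else if (type[i] == "P") {
      steps <- strsplit(f[3L], ",", fixed = TRUE)[[1L]]
      paths[[f[2L]]] <- data.frame(node = sub("[+-]$", "", steps),
                                   orient = sub("^.*([+-])$", "\\1", steps))
    } else if (type[i] == "W") {
      name <- paste(f[2L], f[3L], f[4L], sep = "#")
      walk <- f[7L]
      steps <- regmatches(walk, gregexpr("[><][^><]+", walk))[[1L]]
      paths[[name]] <- data.frame(
        node = substring(steps, 2L),
        orient = ifelse(substr(steps, 1L, 1L) == ">", "+", "-"))
    }
  }
  nodes <- if (length(nodes)) do.call(rbind, nodes) else
    data.frame(id = character(), length = numeric(), seq = character())
  rownames(nodes) <- NULL
  edges <- if (length(edges)) do.call(rbind, edges) else NULL
  if (!is.null(edges)) {
    dangling <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(dangling))
      stop("GFA L line references missing node: ",
           paste(dangling, collapse = ", "))
  }
  for (pn in names(paths)) {
    bad <- setdiff(paths[[pn]]$node, nodes$id)
    if (length(bad))
      stop(sprintf("GFA path '%s' references missing node '%s'", pn, bad[1L]))
  }
  variationGraph(nodes, edges, paths)
}

#' Write a VariationGraph as GFA 1.0
#'
#' Emits `H`, `S`, `L` and `P` lines; nodes without sequences are
#' written as `*` with an `LN:i:` tag.
#'
#' @param graph A [VariationGraph-class].
#' @param file Output path or connection.
#' @export
writeGfa <- function(graph, file) {
  nd <- graph@nodes
  s_lines <- ifelse(is.na(nd$seq),
                    sprintf("S\t%s\t*\tLN:i:%d", nd$id, as.integer(nd$length)),
                    sprintf("S\t%s\t%s", nd$id, nd$seq))
  ed <- graph@edges
  l_lines <- if (nrow(ed))
    sprintf("L\t%s\t%s\t%s\t%s\t0M", ed$from, ed$fromOrient, ed$to, ed$toOrient)
  else character()
  p_lines <- vapply(names(graph@paths), function(pn) {
    p <- graph@paths[[pn]]
    sprintf("P\t%s\t%s\t*", pn, paste0(p$node, p$orient, collapse = ","))
  }, character(1L))
  writeLines(c("H\tVN:Z:1.0", s_lines, l_lines, p_lines), file)
}
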