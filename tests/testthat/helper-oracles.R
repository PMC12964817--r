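# Independent brute-force oracles used across the suite.

# Enumerate aligned (targetPos, queryForwardPos) base pairs of a PAF
# record by walking its CIGAR one op at a time.
alignedPairs <- function(rec) {
  ops <- panloc:::parseCigar(rec$cg)
  t <- rec$tstart
  qoff <- 0
  tp <- integer(0)
  qo <- integer(0)
  for (k in seq_len(nrow(ops))) {
    len <- ops$len[k]
    op <- ops$op[k]
    if (op %in% c("M", "=", "X")) {
      tp <- c(tp, t + seq_len(len) - 1L)
      qo <- c(qo, qoff + seq_len(len) - 1L)
      t <- t + len
      qoff <- qoff + len
    } else if (op == "I") qoff <- qoff + len
    else if (op %in% c("D", "N")) t <- t + len
  }
  qf <- if (rec$strand == "+") rec$qstart + qo else rec$qend - 1L - qo
  data.frame(t = tp, q = qf)
}

# Image of target window [lo, hi) as min/max aligned query positions.
projectOracle <- function(rec, lo, hi) {
  pairs <- alignedPairs(rec)
  keep <- pairs$t >= lo & pairs$t < hi
  if (!any(keep)) return(NULL)
  c(min(pairs$q[keep]), max(pairs$q[keep]) + 1L)
}

# Random small PAF record with a random CIGAR (M runs interleaved with
# I/D), both strands, total target span <= around maxLen.
randomPafRecord <- function(maxLen = 500L) {
  n_ops <- sample(1:6, 1L)
  ops <- character(0)
  for (k in seq_len(n_ops)) {
    ops <- c(ops, sprintf("%dM", sample.int(maxLen %/% (2L * n_ops), 1L)))
    if (k < n_ops)
      ops <- c(ops, sprintf("%d%s", sample.int(40L, 1L),
                            sample(c("I", "D"), 1L)))
  }
  cg <- paste0(ops, collapse = "")
  parsed <- panloc:::parseCigar(cg)
  qspan <- panloc:::cigarQueryLen(parsed)
  tspan <- panloc:::cigarTargetLen(parsed)
  qstart <- sample.int(50L, 1L)
  tstart <- sample.int(50L, 1L)
  data.frame(qname = "q", qlen = qstart + qspan + sample.int(50L, 1L),
             qstart = qstart, qend = qstart + qspan,
             strand = sample(c("+", "-"), 1L), tname = "ref",
             tlen = tstart + tspan + sample.int(50L, 1L),
             tstart = tstart, tend = tstart + tspan,
             matches = qspan, alnlen = max(qspan, tspan), mapq = 60,
             cg = cg)
}

# Per-node depth/multiplicity by direct scan of every path step list.
bruteDepth <- function(graph, sampleDelim = "#") {
  nodes <- graphNodes(graph)$id
  samples <- sub(paste0(sampleDelim, ".*$"), "", pathNames(graph))
  mult <- structure(integer(length(nodes)), names = nodes)
  seen <- lapply(nodes, function(x) character(0))
  names(seen) <- nodes
  for (i in seq_along(graphPaths(graph))) {
    for (step in graphPaths(graph)[[i]]$node) {
      mult[step] <- mult[step] + 1L
      seen[[step]] <- union(seen[[step]], samples[i])
    }
  }
  data.frame(node = nodes, multiplicity = unname(mult),
             depth = unname(vapply(seen, length, integer(1L))))
}

# Per-node aligned bases by assigning every aligned base of every GAF
# record individually.
bruteCoverage <- function(gaf, graph) {
  node_len <- structure(graphNodes(graph)$length, names = graphNodes(graph)$id)
  acc <- structure(numeric(length(node_len)), names = names(node_len))
  for (i in seq_len(nrow(gaf))) {
    steps <- regmatches(gaf$path[i], gregexpr("[><][^><]+", gaf$path[i]))[[1L]]
    ids <- substring(steps, 2L)
    ends <- cumsum(node_len[ids])
    starts <- ends - node_len[ids]
    for (p in seq(gaf$pathStart[i], gaf$pathEnd[i] - 1L)) {
      j <- which(p >= starts & p < ends)[1L]
      acc[ids[j]] <- acc[ids[j]] + 1
    }
  }
  acc
}

# Per-base pileup depth over a haplotype from read start positions.
pileupCoverage <- function(starts, readLen, hlen) {
  inc <- tabulate(starts + 1L, nbins = hlen)
  dec <- tabulate(starts + readLen + 1L, nbins = hlen)
  cumsum(inc - dec)
}

# Two-sided minimum-likelihood p-values for every table on fixed
# margins (row totals m, n; first-column total k), computed in one shot
# by sorting the hypergeometric point probabilities and cumulating:
# independent of the per-table summation route of the implementation.
enumOracleP <- function(m, n, k) {
  support <- max(0L, k - n):min(m, k)
  probs <- stats::dhyper(support, m, n, k)
  o <- order(probs)
  cum <- cumsum(probs[o])
  pos <- findInterval(probs * (1 + 1e-7), probs[o])
  structure(pmin(1, cum[pos]), names = support)
}

# Small cohort run used by recovery tests: simulate, build the truth
# graph, detect the subregion, genotype from truth-GAF coverage.
runCohort <- function(seed, nCarrier = 20L, nNoncarrier = 20L, depth = 30,
                      errorRate = 0.001) {
  cfg <- simConfig(seed = seed, nCarrierSamples = nCarrier,
                   nNoncarrierSamples = nNoncarrier, depth = depth,
                   substitutionErrorRate = errorRate)
  sim <- simulateHaplotypes(cfg)
  graph <- emitTruthGraph(sim)
  depths <- pathNodeDepth(graph)
  classes <- classifyNodes(depths)
  calls <- detectDifferentialSubregions(graph, depths, backbone = "REF#0")
  reads <- simulateReads(sim)
  cov <- accumulateNodeCoverage(reads$gaf, graph)
  core <- classes$node[classes$class == "core"]
  depth_est <- estimateSampleDepth(cov, core)
  top <- calls[[1L]]
  norm <- normalizedRegionCoverage(cov, top$nodes, depth_est,
                                   regionLength = top$totalLength)
  geno <- callGenotype(norm)
  list(sim = sim, graph = graph, calls = calls, cov = cov, norm = norm,
       geno = geno, truth = sim$truth)
}
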