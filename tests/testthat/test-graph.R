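linear_gfa <- c("H\tVN:Z:1.0",
                "S\tn1\tACGT",
                "S\tn2\tGGGG",
                "S\tn3\tTT",
                "L\tn1\t+\tn2\t+\t0M",
                "L\tn2\t+\tn3\t+\t0M",
                "P\tA#1\tn1+,n2+,n3+\t*")

test_that("parseGfa reads S/L/P lines and validates references", {
  g <- parseGfa(text = linear_gfa)
  st <- graphStats(g)
  expect_equal(st[c("nodes", "edges", "paths")],
               list(nodes = 3L, edges = 2L, paths = 1L))
  expect_equal(st$nucleotides, 10)
  expect_identical(pathSequence(g, "A#1"), "ACGTGGGGTT")

  expect_error(parseGfa(text = c(linear_gfa, "L\tn3\t+\tn9\t+\t0M")), "n9")
  expect_error(parseGfa(text = c(linear_gfa[1:6], "P\tB#1\tn1+,nX+\t*")),
               "nX")
  # sequence-less segments need LN
  expect_error(parseGfa(text = "S\tn1\t*"), "LN")
  g2 <- parseGfa(text = c("S\tn1\t*\tLN:i:7"))
  expect_equal(graphNodes(g2)$length, 7)
})

test_that("W-line walks build the same in-memory graph as equivalent P lines", {
  w <- c("S\tn1\tACGT", "S\tn2\tGGGG", "S\tn3\tTT",
         "L\tn1\t+\tn2\t+\t0M", "L\tn2\t+\tn3\t+\t0M",
         "W\tA\t1\tchr1\t0\t10\t>n1>n2>n3")
  p <- c("S\tn1\tACGT", "S\tn2\tGGGG", "S\tn3\tTT",
         "L\tn1\t+\tn2\t+\t0M", "L\tn2\t+\tn3\t+\t0M",
         "P\tA#1#chr1\tn1+,n2+,n3+\t*")
  gw <- parseGfa(text = w)
  gp <- parseGfa(text = p)
  expect_identical(graphPaths(gw), graphPaths(gp))
  expect_identical(graphNodes(gw), graphNodes(gp))
  # reverse-orientation walk steps parse with '-'
  gr <- parseGfa(text = c("S\tn1\tACGT", "W\tB\t1\tchr1\t0\t4\t<n1"))
  expect_equal(graphPaths(gr)[["B#1#chr1"]]$orient, "-")
  expect_identical(pathSequence(gr, "B#1#chr1"), "ACGT")
})

test_that("path depth counts multiplicity per path and distinct samples", {
  g <- variationGraph(
    nodes = data.frame(id = c("a", "b", "sv"), length = c(5, 5, 10)),
    paths = list("S1#1" = c("a+", "sv+", "sv+", "b+"),
                 "S1#2" = c("a+", "b+"),
                 "S2#1" = c("a+", "b+"),
                 "S2#2" = c("a+", "b+"),
                 "S3#1" = c("a+", "sv+", "sv+", "b+"),
                 "S3#2" = c("a+", "sv+", "sv+", "b+")))
  d <- pathNodeDepth(g)
  dt <- depthTable(d)
  expect_equal(dt$depth[dt$node == "a"], 3L)
  expect_equal(dt$depth[dt$node == "sv"], 2L)   # S1 and S3, S1 via one hap only
  mult <- depthMultiplicity(d)
  expect_equal(mult$multiplicity[mult$node == "sv" & mult$path == "S1#1"], 2L)
  expect_equal(d@nSamples, 3L)
})

test_that("path depth agrees with a brute-force scan on random graphs", {
  set.seed(21)
  for (rep in 1:10) {
    n <- 8L
    ids <- paste0("n", seq_len(n))
    paths <- list()
    for (s in 1:3) for (h in 1:2) {
      steps <- sample(ids, sample(2:10, 1L), replace = TRUE)
      paths[[sprintf("S%d#%d", s, h)]] <- paste0(steps, "+")
    }
    g <- variationGraph(data.frame(id = ids, length = sample.int(50L, n)),
                        paths = paths)
    d <- pathNodeDepth(g)
    oracle <- bruteDepth(g)
    got <- depthTable(d)[, c("node", "multiplicity", "depth")]
    expect_equal(got[order(got$node), ], oracle[order(oracle$node), ],
                 ignore_attr = TRUE)
  }
})

test_that("node classification partitions traversed nodes by depth", {
  g <- parseGfa(text = linear_gfa)
  d <- pathNodeDepth(g)
  cl <- classifyNodes(d)
  expect_true(all(cl$class == "core"))
  g2 <- variationGraph(
    nodes = data.frame(id = c("a", "v", "p", "u"), length = rep(10, 4)),
    paths = list("S1#1" = c("a+", "v+", "p+"), "S2#1" = c("a+", "v+"),
                 "S3#1" = "a+"))
  cl2 <- classifyNodes(pathNodeDepth(g2))
  expect_equal(structure(cl2$class, names = cl2$node),
               c(a = "core", v = "variable", p = "private", u = "untraversed"))
  counts <- attr(cl2, "counts")
  expect_equal(sum(counts), 3L)  # traversed nodes only
  expect_error(classifyNodes(pathNodeDepth(g2), nSamples = 2), "exceeds")
})

test_that("depth conservation: multiplicity-weighted node lengths equal path lengths", {
  sim <- simulateHaplotypes(simConfig(seed = 17, nCarrierSamples = 2,
                                      nNoncarrierSamples = 2))
  g <- emitTruthGraph(sim)
  d <- pathNodeDepth(g)
  node_len <- structure(graphNodes(g)$length, names = graphNodes(g)$id)
  mult <- depthMultiplicity(d)
  for (nm in names(sim$haplotypes)) {
    m <- mult[mult$path == nm, ]
    expect_equal(sum(m$multiplicity * node_len[m$node]),
                 nchar(sim$haplotypes[[nm]]$sequence), label = nm)
  }
})

test_that("differential subregions recover the simulated insertion", {
  sim <- simulateHaplotypes(simConfig(seed = 19, nCarrierSamples = 3,
                                      nNoncarrierSamples = 7))
  g <- emitTruthGraph(sim)
  d <- pathNodeDepth(g)
  calls <- detectDifferentialSubregions(g, d, backbone = "REF#0")
  expect_length(calls, 1L)
  expect_equal(calls[[1L]]$carriers,
               sort(sim$truth$sample[sim$truth$genotype != "absent"]))
  expect_lt(abs(calls[[1L]]$totalLength - 6900) / 6900, 0.10)
  expect_error(detectDifferentialSubregions(g, d, backbone = "nope"),
               "backbone")
})

test_that("all-core graphs yield no subregion calls and distinct carrier sets split calls", {
  g <- parseGfa(text = linear_gfa)
  d <- pathNodeDepth(g)
  expect_length(detectDifferentialSubregions(g, d, backbone = "A#1"), 0L)
  # two insertions with different carrier sets -> two calls
  mk <- function(s, ins) paste0(c("a+", if (ins == "x") rep("x+", 2),
                                  "b+", if (ins == "y") rep("y+", 2), "c+"))
  g2 <- variationGraph(
    nodes = data.frame(id = c("a", "b", "c", "x", "y"),
                       length = c(400, 400, 400, 600, 800)),
    paths = list("REF#0" = c("a+", "b+", "c+"),
                 "S1#1" = mk(1, "x"), "S2#1" = mk(2, "x"),
                 "S3#1" = mk(3, "y"), "S4#1" = mk(4, "y"),
                 "S5#1" = c("a+", "b+", "c+")))
  calls <- detectDifferentialSubregions(g2, pathNodeDepth(g2),
                                        backbone = "REF#0")
  expect_length(calls, 2L)
  sets <- lapply(calls, `[[`, "carriers")
  expect_setequal(vapply(sets, paste, character(1L), collapse = ","),
                  c("S1,S2", "S3,S4"))
  expect_equal(calls[[1L]]$totalLength, 1600)  # 2 traversals of y, 800 bp
})

test_that("subgraph extraction is identity on the full set and idempotent", {
  sim <- simulateHaplotypes(simConfig(seed = 23, nCarrierSamples = 2,
                                      nNoncarrierSamples = 2))
  g <- emitTruthGraph(sim)
  full <- extractSubgraph(g, graphNodes(g)$id)
  expect_equal(graphStats(full), graphStats(g))
  expect_identical(sort(names(graphPaths(full))), sort(names(graphPaths(g))))

  d <- pathNodeDepth(g)
  calls <- detectDifferentialSubregions(g, d, backbone = "REF#0")
  sub <- extractSubgraph(g, calls[[1L]]$nodes, flank = 10, backbone = "REF#0")
  sub2 <- extractSubgraph(sub, intersect(calls[[1L]]$nodes,
                                         graphNodes(sub)$id),
                          flank = 10, backbone = "REF#0")
  expect_equal(graphStats(sub2), graphStats(sub))
  # carrier paths retain SV traversals, non-carriers reduce to backbone
  carriers <- sim$truth$sample[sim$truth$genotype != "absent"]
  for (nm in names(graphPaths(sub))) {
    s <- sub("#.*", "", nm)
    n_sv <- sum(graphPaths(sub)[[nm]]$node == "sv")
    if (s %in% carriers) expect_gte(n_sv, 0L) else expect_equal(n_sv, 0L)
  }
  expect_true(any(vapply(graphPaths(sub), function(p) any(p$node == "sv"),
                         logical(1L))))
  expect_error(extractSubgraph(g, character(0)), "empty")
})

test_that("disjoint extraction sets split paths into part-suffixed sub-walks", {
  g <- variationGraph(
    nodes = data.frame(id = letters[1:5], length = rep(10, 5)),
    paths = list("S1#1" = paste0(letters[1:5], "+")))
  sub <- extractSubgraph(g, c("a", "b", "d"))
  expect_setequal(names(graphPaths(sub)), c("S1#1#part1", "S1#1#part2"))
  expect_equal(graphPaths(sub)[["S1#1#part1"]]$node, c("a", "b"))
  expect_equal(graphPaths(sub)[["S1#1#part2"]]$node, "d")
})

test_that("graph stats are invariant under relabeling and GFA round-trips", {
  g <- variationGraph(data.frame(id = c("a", "b", "c"), length = c(10, 20, 30)),
                      paths = list("S#1" = c("a+", "b+", "c+")))
  expect_equal(graphStats(g)$nucleotides, 60)
  relab <- variationGraph(data.frame(id = c("z9", "z8", "z7"),
                                     length = c(10, 20, 30)),
                          paths = list("S#1" = c("z9+", "z8+", "z7+")))
  expect_equal(graphStats(relab), graphStats(g))
  f <- tempfile(fileext = ".gfa")
  sim <- simulateHaplotypes(simConfig(seed = 29, nCarrierSamples = 1,
                                      nNoncarrierSamples = 1))
  gg <- emitTruthGraph(sim)
  writeGfa(gg, f)
  back <- parseGfa(f)
  expect_equal(graphStats(back), graphStats(gg))
  expect_identical(pathSequence(back, "S001#1"),
                   sim$haplotypes[["S001#1"]]$sequence)
})
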