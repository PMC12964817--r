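#' Build a pipeline run configuration
#'
#' A run is driven either by a `simulation` block (arguments to
#' [simConfig()]) or by real `inputs` (paths to PAF/GFA/GAF/phenotype
#' files), never both. Module parameters can be overridden; everything
#' else takes the documented defaults.
#'
#' @param outputDir Output directory for all stage outputs.
#' @param seed Integer seed for every stochastic stage.
#' @param simulation Named list of [simConfig()] overrides, or `NULL`.
#' @param inputs Named list of real input paths (`paf`, `gfa`, `gaf`
#'   (directory or vector), `phenotypes`, `region`, `backbone`), or
#'   `NULL`.
#' @param thresholds Genotype thresholds `list(tAbsent, tHetHi, tDup)`.
#' @param minTotalLen,minCarriers,maxGap Subregion-detection parameters
#'   (see [detectDifferentialSubregions()]).
#' @param depthOverride Optional fixed sequencing depth.
#' @param writeReads Write per-sample FASTQ/GAF files in simulation
#'   mode (default `TRUE`).
#' @return A list of class `"runConfig"`.
#' @export
runConfig <- function(outputDir, seed = 1L, simulation = list(),
                      inputs = NULL,
                      thresholds = list(tAbsent = 0.25, tHetHi = 0.75,
                                        tDup = 1.5),
                      minTotalLen = 1000, minCarriers = 2, maxGap = 5,
                      depthOverride = NULL, writeReads = TRUE) {
  cfg <- list(outputDir = outputDir, seed = as.integer(seed),
              simulation = simulation, inputs = inputs,
              thresholds = thresholds, minTotalLen = minTotalLen,
              minCarriers = minCarriers, maxGap = maxGap,
              depthOverride = depthOverride, writeReads = writeReads)
  class(cfg) <- "runConfig"
  cfg
}

#' Load a run configuration from YAML
#'
#' @param file Path to a YAML file whose keys mirror the [runConfig()]
#'   arguments.
#' @return A `"runConfig"` list.
#' @export
loadRunConfig <- function(file) {
  y <- yaml::read_yaml(file)
  do.call(runConfig, y[intersect(names(y), names(formals(runConfig)))])
}

#' Validate a run configuration
#'
#' Lists every violated invariant; an empty result means the
#' configuration is runnable. Unreadable input files are findings, not
#' errors.
#'
#' @param config A `"runConfig"` list.
#' @return Character vector of findings (empty when valid).
#' @export
validateConfig <- function(config) {
  findings <- character()
  has_sim <- !is.null(config$simulation)
  has_inputs <- !is.null(config$inputs) && length(config$inputs) > 0
  if (has_sim && has_inputs)
    findings <- c(findings,
                  "exactly one of 'simulation' and 'inputs' may be given, found both")
  if (!has_sim && !has_inputs)
    findings <- c(findings, "one of 'simulation' or 'inputs' is required")
  if (has_sim) {
    sc <- tryCatch(do.call(simConfig, c(list(seed = config$seed),
                                        config$simulation)),
                   error = function(e) conditionMessage(e))
    if (is.character(sc)) findings <- c(findings, sc)
  }
  if (has_inputs) {
    for (k in intersect(c("paf", "gfa", "phenotypes"), names(config$inputs))) {
      p <- config$inputs[[k]]
      if (!file.exists(p))
        findings <- c(findings, sprintf("input '%s' not readable: %s", k, p))
    }
  }
  th <- config$thresholds
  if (!(th$tAbsent > 0 && th$tAbsent < th$tHetHi && th$tHetHi < th$tDup))
    findings <- c(findings,
                  "'thresholds' must satisfy 0 < tAbsent < tHetHi < tDup")
  if (config$minTotalLen <= 0)
    findings <- c(findings, "'minTotalLen' must be > 0")
  if (config$minCarriers < 1)
    findings <- c(findings, "'minCarriers' must be >= 1")
  findings
}

stageBanner <- function(name) {
  message(sprintf("== panloc stage: %s ==", name))
}

#' Run the full analysis end to end
#'
#' Orchestrates simulate -> project -> classify -> detect -> genotype ->
#' associate, writing every stage's outputs under `outputDir`
#' (`sim/`, `projection/`, `graph/`, `genotypes/`, `association/`,
#' `summary.json`). Reruns with an identical configuration reproduce
#' identical stage outputs byte for byte. A stage failure halts the run
#' with an error naming the stage.
#'
#' @param config A `"runConfig"` list (simulation mode).
#' @return The run summary (also serialized as `summary.json`):
#'   per-stage record counts and timings, subregion calls, genotype
#'   concordance against the simulated truth, association result and
#'   the configuration hash.
#' @export
runEndToEnd <- function(config) {
  findings <- validateConfig(config)
  if (length(findings))
    stop("invalid configuration: ", paste(findings, collapse = "; "))
  if (!is.null(config$inputs) && length(config$inputs))
    return(runFromInputs(config))
  out <- config$outputDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash_cfg <- unclass(config)
  hash_cfg$outputDir <- NULL  # the hash identifies the analysis, not its location
  summary <- list(configHash = configHash(hash_cfg), stages = list())
  t0 <- function() proc.time()[["elapsed"]]
  run_stage <- function(name, fun) {
    stageBanner(name)
    start <- t0()
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    summary$stages[[name]] <<- c(res$counts, list(elapsed = t0() - start))
    res$value
  }

  sc <- do.call(simConfig, c(list(seed = config$seed), config$simulation))
  message(sprintf("panloc run: seed=%d, samples=%d+%d, depth=%g, out=%s",
                  sc$seed, sc$nCarrierSamples, sc$nNoncarrierSamples,
                  sc$depth, out))

  sim_res <- run_stage("simulate", function() {
    sim <- simulateHaplotypes(sc)
    writeSimOutputs(sim, file.path(out, "sim"))
    graph <- emitTruthGraph(sim)
    writeGfa(graph, file.path(out, "sim", "graph.gfa"))
    paf <- emitPaf(sim)
    writePaf(paf, file.path(out, "sim", "haplotypes.paf"))
    reads <- simulateReads(sim, dir = if (config$writeReads)
      file.path(out, "sim", "reads") else NULL)
    list(value = list(sim = sim, graph = graph, paf = paf, reads = reads),
         counts = list(haplotypes = length(sim$haplotypes),
                       samples = nrow(sim$truth),
                       reads = sum(vapply(reads$reads, nrow, integer(1L)))))
  })
  sim <- sim_res$sim
  graph <- sim_res$graph

  run_stage("project", function() {
    target <- genomicInterval("ref", 0, sc$backboneLength)
    segments <- projectInterval(sim_res$paf, target)
    dir.create(file.path(out, "projection"), showWarnings = FALSE)
    bed <- segments[, c("contig", "imgStart", "imgEnd")]
    utils::write.table(bed, file.path(out, "projection", "segments.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    lens <- vapply(sim$haplotypes, function(h) nchar(h$sequence), numeric(1L))
    adm <- admitAdditionalContigs(segments, lens)
    utils::write.table(adm, file.path(out, "projection", "admissions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = NULL, counts = list(segments = nrow(segments),
                                     admitted = sum(adm$admitted)))
  })

  graph_res <- run_stage("classify", function() {
    depths <- pathNodeDepth(graph)
    classes <- classifyNodes(depths)
    dir.create(file.path(out, "graph"), showWarnings = FALSE)
    utils::write.table(classes, file.path(out, "graph", "node_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    calls <- detectDifferentialSubregions(
      graph, depths, backbone = "REF#0", minTotalLen = config$minTotalLen,
      minCarriers = config$minCarriers, maxGap = config$maxGap)
    calls_df <- data.frame(
      call = seq_along(calls),
      nodes = vapply(calls, function(cl) paste(cl$nodes, collapse = ","),
                     character(1L)),
      totalLength = vapply(calls, `[[`, numeric(1L), "totalLength"),
      carriers = vapply(calls, function(cl) paste(cl$carriers, collapse = ","),
                        character(1L)),
      anchor = vapply(calls, `[[`, numeric(1L), "anchor"))
    utils::write.table(calls_df, file.path(out, "graph", "subregions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(calls)) {
      sub <- extractSubgraph(graph, calls[[1L]]$nodes, flank = 50,
                             backbone = "REF#0")
      writeGfa(sub, file.path(out, "graph", "subregion1.gfa"))
    }
    st <- graphStats(graph)
    list(value = list(depths = depths, classes = classes, calls = calls),
         counts = list(nodes = st$nodes, edges = st$edges,
                       subregionCalls = length(calls)))
  })
  calls <- graph_res$calls
  if (!length(calls)) stop("stage 'classify' found no differential subregion")
  top <- calls[[1L]]

  geno_res <- run_stage("genotype", function() {
    cov <- accumulateNodeCoverage(sim_res$reads$gaf, graph)
    core <- graph_res$classes$node[graph_res$classes$class == "core"]
    depth_est <- estimateSampleDepth(cov, core, override = config$depthOverride)
    norm <- normalizedRegionCoverage(cov, top$nodes, depth_est,
                                     regionLength = top$totalLength)
    th <- config$thresholds
    geno <- callGenotype(norm, th$tAbsent, th$tHetHi, th$tDup)
    dir.create(file.path(out, "genotypes"), showWarnings = FALSE)
    utils::write.table(cbind(norm, call = geno$call,
                             copyNumber = geno$copyNumber),
                       file.path(out, "genotypes", "genotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = list(norm = norm, geno = geno),
         counts = list(samples = nrow(geno)))
  })
  geno <- geno_res$geno

  assoc_res <- run_stage("associate", function() {
    truth <- sim$truth
    carriers <- data.frame(sample = geno$sample,
                           carrier = geno$call != "absent")
    phen <- truth[, c("sample", "breed", "phenotype")]
    summ <- breedCarrierSummary(carriers, phen)
    m <- merge(carriers, phen, by = "sample")
    tab <- matrix(c(sum(m$carrier & m$phenotype == "white"),
                    sum(!m$carrier & m$phenotype == "white"),
                    sum(m$carrier & m$phenotype == "colored"),
                    sum(!m$carrier & m$phenotype == "colored")), 2L, 2L)
    fish <- fisherExactTwoSided(tab)
    dom <- dominanceConcordance(structure(geno$call, names = geno$sample), phen)
    truth_geno <- structure(truth$genotype, names = truth$sample)
    concordance <- mean(geno$call == truth_geno[geno$sample])
    dir.create(file.path(out, "association"), showWarnings = FALSE)
    utils::write.table(summ$perBreed,
                       file.path(out, "association", "per_breed.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c("# Association report",
                 sprintf("Fisher exact two-sided p: %.6g", fish$p.value),
                 sprintf("Odds ratio%s: %.4g",
                         if (fish$haldane) " (Haldane-corrected)" else "",
                         fish$odds.ratio),
                 sprintf("Dominance concordance: %.4f", dom$concordance),
                 sprintf("Genotype-vs-truth concordance: %.4f", concordance)),
               file.path(out, "association", "report.md"))
    list(value = list(p = fish$p.value, oddsRatio = fish$odds.ratio,
                      dominance = dom$concordance, concordance = concordance),
         counts = list(pValue = fish$p.value,
                       dominanceConcordance = dom$concordance,
                       genotypeConcordance = concordance))
  })

  summary$subregion <- list(nodes = length(top$nodes),
                            totalLength = top$totalLength,
                            carriers = top$carriers, anchor = top$anchor)
  summary$association <- assoc_res
  summary$genotypes <- as.list(table(geno$call))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

# Real-input flow: precomputed GFA (+ per-sample GAFs + phenotype TSV,
# optionally a PAF + region) are processed through the same stages as a
# simulated run, minus simulation. GAF files are matched to samples by
# their basename (sans extension).
runFromInputs <- function(config) {
  inp <- config$inputs
  out <- config$outputDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash_cfg <- unclass(config)
  hash_cfg$outputDir <- NULL
  summary <- list(configHash = configHash(hash_cfg), stages = list())
  t0 <- function() proc.time()[["elapsed"]]
  run_stage <- function(name, fun) {
    stageBanner(name)
    start <- t0()
    res <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    summary$stages[[name]] <<- c(res$counts, list(elapsed = t0() - start))
    res$value
  }
  if (is.null(inp$gfa)) stop("real-input mode requires 'gfa'")
  if (is.null(inp$backbone)) stop("real-input mode requires 'backbone' path name")
  graph <- parseGfa(inp$gfa)

  if (!is.null(inp$paf) && !is.null(inp$region)) {
    run_stage("project", function() {
      target <- parseRegion(inp$region)
      paf <- parsePaf(inp$paf)
      segments <- projectInterval(paf, target)
      dir.create(file.path(out, "projection"), showWarnings = FALSE)
      utils::write.table(segments[, c("contig", "imgStart", "imgEnd")],
                         file.path(out, "projection", "segments.bed"),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
      lens <- structure(paf$qlen, names = paf$qname)
      lens <- lens[!duplicated(names(lens))]
      adm <- admitAdditionalContigs(segments, lens)
      utils::write.table(adm, file.path(out, "projection", "admissions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(value = NULL, counts = list(segments = nrow(segments),
                                       admitted = sum(adm$admitted)))
    })
  }

  graph_res <- run_stage("classify", function() {
    depths <- pathNodeDepth(graph)
    classes <- classifyNodes(depths)
    dir.create(file.path(out, "graph"), showWarnings = FALSE)
    utils::write.table(classes, file.path(out, "graph", "node_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    calls <- detectDifferentialSubregions(
      graph, depths, backbone = inp$backbone,
      minTotalLen = config$minTotalLen, minCarriers = config$minCarriers,
      maxGap = config$maxGap)
    st <- graphStats(graph)
    list(value = list(classes = classes, calls = calls),
         counts = list(nodes = st$nodes, edges = st$edges,
                       subregionCalls = length(calls)))
  })
  calls <- graph_res$calls
  if (!length(calls)) stop("stage 'classify' found no differential subregion")
  top <- calls[[1L]]
  summary$subregion <- list(nodes = length(top$nodes),
                            totalLength = top$totalLength,
                            carriers = top$carriers, anchor = top$anchor)

  geno <- NULL
  if (!is.null(inp$gaf)) {
    geno <- run_stage("genotype", function() {
      gaf_files <- inp$gaf
      if (length(gaf_files) == 1L && dir.exists(gaf_files))
        gaf_files <- list.files(gaf_files, pattern = "\\.gaf$",
                                full.names = TRUE)
      gaf <- lapply(gaf_files, function(f) filterBestAlignment(parseGaf(f)))
      names(gaf) <- sub("\\.[^.]*$", "", basename(gaf_files))
      cov <- accumulateNodeCoverage(gaf, graph)
      core <- graph_res$classes$node[graph_res$classes$class == "core"]
      depth_est <- estimateSampleDepth(cov, core,
                                       override = config$depthOverride)
      norm <- normalizedRegionCoverage(cov, top$nodes, depth_est,
                                       regionLength = top$totalLength)
      th <- config$thresholds
      g <- callGenotype(norm, th$tAbsent, th$tHetHi, th$tDup)
      dir.create(file.path(out, "genotypes"), showWarnings = FALSE)
      utils::write.table(cbind(norm, call = g$call,
                               copyNumber = g$copyNumber),
                         file.path(out, "genotypes", "genotypes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(value = g, counts = list(samples = nrow(g)))
    })
  }

  if (!is.null(geno) && !is.null(inp$phenotypes)) {
    assoc <- run_stage("associate", function() {
      phen <- utils::read.delim(inp$phenotypes, stringsAsFactors = FALSE)
      carriers <- data.frame(sample = geno$sample,
                             carrier = geno$call != "absent")
      summ <- breedCarrierSummary(carriers, phen)
      m <- merge(carriers, phen, by = "sample")
      tab <- matrix(c(sum(m$carrier & m$phenotype == "white"),
                      sum(!m$carrier & m$phenotype == "white"),
                      sum(m$carrier & m$phenotype == "colored"),
                      sum(!m$carrier & m$phenotype == "colored")), 2L, 2L)
      fish <- fisherExactTwoSided(tab)
      dom <- dominanceConcordance(structure(geno$call, names = geno$sample),
                                  phen)
      dir.create(file.path(out, "association"), showWarnings = FALSE)
      utils::write.table(summ$perBreed,
                         file.path(out, "association", "per_breed.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(value = list(p = fish$p.value, oddsRatio = fish$odds.ratio,
                        dominance = dom$concordance),
           counts = list(pValue = fish$p.value))
    })
    summary$association <- assoc
  }
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
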