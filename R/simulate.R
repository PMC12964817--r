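#' Simulation configuration
#'
#' Parameters of the synthetic cohort: a shared backbone haplotype, an
#' insertion of repeated identical units at a fixed breakpoint carried
#' by a subset of samples (one unit ~2.3 kb, three copies ~7 kb by
#' default), private substitution SNPs per haplotype, and uniform
#' single-end read sampling at a configurable depth.
#'
#' @param seed Integer master seed; all randomness derives from it
#'   (per-sample sub-seeds are seed + sample index, so adding samples
#'   does not perturb earlier ones).
#' @param backboneLength Backbone length in bp (default 30,000).
#' @param svBreakpoint Insertion breakpoint, bp offset into the backbone
#'   (default midpoint).
#' @param svUnitLength Length of one repeat unit in bp (default 2,300).
#' @param svCopies Repeat copies per carrier haplotype (integer >= 1,
#'   default 3).
#' @param nCarrierSamples,nNoncarrierSamples Cohort composition.
#' @param carrierZygosityProbs Probabilities over `c(het, hom)` for
#'   carrier samples (must sum to 1).
#' @param readLength Read length in bp (default 150).
#' @param depth Fold coverage per sample (default 30).
#' @param substitutionErrorRate Per-base sequencing substitution error
#'   probability (default 0.001).
#' @param snpRate Per-bp probability of a private substitution per
#'   haplotype (default 5e-4).
#' @return A validated list of class `"simConfig"`.
#' @export
simConfig <- function(seed = 1L, backboneLength = 30000,
                      svBreakpoint = NULL, svUnitLength = 2300,
                      svCopies = 3L, nCarrierSamples = 20L,
                      nNoncarrierSamples = 20L,
                      carrierZygosityProbs = c(het = 0.5, hom = 0.5),
                      readLength = 150, depth = 30,
                      substitutionErrorRate = 0.001, snpRate = 5e-4) {
  if (is.null(svBreakpoint)) svBreakpoint <- backboneLength %/% 2L
  cfg <- list(seed = as.integer(seed), backboneLength = backboneLength,
              svBreakpoint = svBreakpoint, svUnitLength = svUnitLength,
              svCopies = svCopies, nCarrierSamples = nCarrierSamples,
              nNoncarrierSamples = nNoncarrierSamples,
              carrierZygosityProbs = carrierZygosityProbs,
              readLength = readLength, depth = depth,
              substitutionErrorRate = substitutionErrorRate,
              snpRate = snpRate)
  problems <- validateSimConfig(cfg)
  if (length(problems)) stop(paste(problems, collapse = "; "))
  class(cfg) <- "simConfig"
  cfg
}

# Character vector of violated-invariant messages (empty when valid).
validateSimConfig <- function(cfg) {
  p <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) p <<- c(p, msg)
  chk(cfg$backboneLength > 0, "'backboneLength' must be > 0")
  chk(cfg$svUnitLength > 0, "'svUnitLength' must be > 0")
  chk(cfg$svCopies >= 1, "'svCopies' must be an integer >= 1")
  chk(cfg$readLength > 0, "'readLength' must be > 0")
  chk(cfg$depth > 0, "'depth' must be > 0")
  chk(cfg$nCarrierSamples >= 0, "'nCarrierSamples' must be >= 0")
  chk(cfg$nNoncarrierSamples >= 0, "'nNoncarrierSamples' must be >= 0")
  chk(cfg$svBreakpoint > 0 &&
        cfg$svBreakpoint + cfg$readLength < cfg$backboneLength,
      "'svBreakpoint' must satisfy 0 < svBreakpoint + readLength < backboneLength")
  pr <- cfg$carrierZygosityProbs
  chk(length(pr) == 2L && all(pr >= 0) && all(pr <= 1) &&
        abs(sum(pr) - 1) < 1e-9,
      "'carrierZygosityProbs' must be two probabilities summing to 1")
  chk(cfg$substitutionErrorRate >= 0 && cfg$substitutionErrorRate <= 1,
      "'substitutionErrorRate' must be in [0, 1]")
  chk(cfg$snpRate >= 0 && cfg$snpRate <= 1, "'snpRate' must be in [0, 1]")
  p
}

#' Simulate haplotypes with a known repeat-unit insertion
#'
#' Generates a random backbone and repeat unit, assigns each carrier
#' sample a zygosity, sprinkles private substitution SNPs per haplotype,
#' and composes every haplotype as an ordered walk over shared segments:
#' backbone intervals (split at the breakpoint and at all SNP
#' positions), per-haplotype 1-bp SNP alleles, and `svCopies`
#' consecutive copies of the shared unit segment on carrier haplotypes.
#' Phenotypes follow a dominant model: white if and only if the genotype
#' is not `absent`.
#'
#' @param config A [simConfig()].
#' @return A list of class `"panlocSim"` with elements `backbone`,
#'   `unit` (character sequences), `segments` (`data.frame`: `id`,
#'   `kind`, `length`, `seq`), `haplotypes` (named list of
#'   `list(name, composition, sequence)`), `truth` (`data.frame`:
#'   `sample`, `breed`, `phenotype`, `genotype`, `hap1`, `hap2`) and
#'   `config`. Deterministic given the seed.
#' @export
simulateHaplotypes <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  B <- config$backboneLength
  set.seed(config$seed)
  backbone <- randomDna(B)
  unit <- randomDna(config$svUnitLength)

  n <- config$nCarrierSamples + config$nNoncarrierSamples
  samples <- sprintf("S%03d", seq_len(n))
  is_carrier <- seq_len(n) <= config$nCarrierSamples
  # per-sample draws under sub-seeds: zygosity, then SNPs per haplotype
  snp <- list()
  genotype <- character(n)
  for (i in seq_len(n)) {
    set.seed(deriveSeed(config$seed, i))
    if (is_carrier[i]) {
      genotype[i] <- sample(c("het", "hom"), 1L,
                            prob = config$carrierZygosityProbs)
    } else genotype[i] <- "absent"
    for (h in 1:2) {
      nSnp <- stats::rbinom(1L, B, config$snpRate)
      pos <- sort(sample.int(B, nSnp))
      alt <- vapply(pos, function(p) {
        ref <- substr(backbone, p, p)
        sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      }, character(1L))
      snp[[paste0(samples[i], "#", h)]] <- data.frame(pos = pos, alt = alt)
    }
  }

  # partition the backbone at the breakpoint and every SNP position
  all_pos <- sort(unique(unlist(lapply(snp, `[[`, "pos"))))
  cuts <- sort(unique(c(0, config$svBreakpoint, all_pos - 1L, all_pos, B)))
  seg_start <- cuts[-length(cuts)]
  seg_end <- cuts[-1L]
  bseg <- data.frame(id = sprintf("b%06d", seg_start), kind = "backbone",
                     start = seg_start, length = seg_end - seg_start,
                     seq = substring(backbone, seg_start + 1L, seg_end))
  alts <- unique(do.call(rbind, snp))
  aseg <- NULL
  if (!is.null(alts) && nrow(alts)) {
    aseg <- data.frame(id = sprintf("s%06d_%s", alts$pos, alts$alt),
                       kind = "snp", start = alts$pos - 1L, length = 1L,
                       seq = alts$alt)
    aseg <- aseg[!duplicated(aseg$id), , drop = FALSE]
  }
  useg <- data.frame(id = "sv", kind = "unit", start = NA_real_,
                     length = config$svUnitLength, seq = unit)
  segments <- rbind(bseg, aseg, useg)
  rownames(segments) <- NULL

  compose <- function(hap_name, carrier_hap) {
    s <- snp[[hap_name]]
    comp <- bseg$id
    if (nrow(s)) {
      at <- match(sprintf("b%06d", s$pos - 1L), comp)
      comp[at] <- sprintf("s%06d_%s", s$pos, s$alt)
    }
    if (carrier_hap) {
      k <- match(sprintf("b%06d", config$svBreakpoint), comp)
      comp <- append(comp, rep("sv", config$svCopies), after = k - 1L)
    }
    comp
  }
  seg_seq <- structure(segments$seq, names = segments$id)
  haplotypes <- list()
  for (i in seq_len(n)) {
    carrier_haps <- switch(genotype[i], absent = c(FALSE, FALSE),
                           het = c(TRUE, FALSE), hom = c(TRUE, TRUE))
    for (h in 1:2) {
      nm <- paste0(samples[i], "#", h)
      comp <- compose(nm, carrier_haps[h])
      haplotypes[[nm]] <- list(name = nm, composition = comp,
                               sequence = paste0(seg_seq[comp], collapse = ""))
    }
  }

  white_breeds <- c("WhiteheadA", "WhiteheadB")
  color_breeds <- c("ColorheadA", "ColorheadB")
  breed <- ifelse(is_carrier,
                  white_breeds[(seq_len(n) %% 2L) + 1L],
                  color_breeds[(seq_len(n) %% 2L) + 1L])
  truth <- data.frame(sample = samples, breed = breed,
                      phenotype = ifelse(genotype == "absent", "colored", "white"),
                      genotype = genotype,
                      hap1 = paste0(samples, "#1"), hap2 = paste0(samples, "#2"))
  structure(list(backbone = backbone, unit = unit, segments = segments,
                 haplotypes = haplotypes, truth = truth, config = config),
            class = "panlocSim")
}

#' Emit the truth variation graph of a simulated cohort
#'
#' Builds the variation graph implied by the known haplotype
#' compositions: one node per distinct segment appearing in any
#' composition, edges from consecutive composition pairs, and one path
#' per haplotype (plus a pure-backbone reference path, `REF#0`, used as
#' the backbone for ordering and subgraph extraction). Carrier paths
#' traverse the shared repeat-unit node `svCopies` times; concatenating
#' node sequences along any path reproduces that haplotype's sequence
#' exactly.
#'
#' @param sim A `"panlocSim"` from [simulateHaplotypes()].
#' @param includeReference Add the `REF#0` backbone path (default
#'   `TRUE`).
#' @return A [VariationGraph-class].
#' @export
emitTruthGraph <- function(sim, includeReference = TRUE) {
  stopifnot(inherits(sim, "panlocSim"))
  comps <- lapply(sim$haplotypes, `[[`, "composition")
  if (any(vapply(comps, is.null, logical(1L))))
    stop("haplotype with unknown composition")
  if (includeReference)
    comps <- c(list("REF#0" = sim$segments$id[sim$segments$kind == "backbone"]),
               comps)
  used <- unique(unlist(comps))
  nd <- sim$segments[match(used, sim$segments$id), c("id", "length", "seq")]
  paths <- lapply(comps, function(cp)
    data.frame(node = cp, orient = rep("+", length(cp))))
  variationGraph(nd, edges = NULL, paths = paths, addPathEdges = TRUE)
}

#' Simulate reads and their truth graph alignments
#'
#' Single-end reads are placed uniformly over each haplotype at half the
#' sample depth per haplotype (read counts Poisson around the coverage
#' identity `depth/2 x length / readLength`), substitution errors
#' applied at the configured rate. Each read's truth GAF record is the
#' sub-walk of its haplotype's path covering the read, with
#' path-coordinate start/end, so errors never alter placement.
#'
#' @param sim A `"panlocSim"` from [simulateHaplotypes()].
#' @param dir Optional output directory: per-sample FASTQ
#'   (`<sample>.fq`) and truth GAF (`<sample>.gaf`) are written there.
#' @return List with `reads` (per sample: `data.frame` `read`, `hap`,
#'   `start`, `seq`, `errors`) and `gaf` (per sample: GAF
#'   `data.frame`).
#' @export
simulateReads <- function(sim, dir = NULL) {
  stopifnot(inherits(sim, "panlocSim"))
  cfg <- sim$config
  if (cfg$depth <= 0) stop("'depth' must be > 0")
  L <- cfg$readLength
  seg_len <- structure(sim$segments$length, names = sim$segments$id)
  reads_out <- list()
  gaf_out <- list()
  for (i in seq_len(nrow(sim$truth))) {
    srow <- sim$truth[i, ]
    per_hap <- list()
    for (h in 1:2) {
      hap <- sim$haplotypes[[srow[[paste0("hap", h)]]]]
      hlen <- nchar(hap$sequence)
      set.seed(deriveSeed(cfg$seed, 100000 + i * 10 + h))
      nReads <- stats::rpois(1L, cfg$depth / 2 * hlen / L)
      if (nReads == 0L) next
      starts <- sample.int(hlen - L + 1L, nReads, replace = TRUE) - 1L
      seqs <- substring(hap$sequence, starts + 1L, starts + L)
      nerr <- integer(nReads)
      if (cfg$substitutionErrorRate > 0) {
        hit <- which(stats::runif(nReads * L) < cfg$substitutionErrorRate)
        for (k in hit) {
          r <- (k - 1L) %/% L + 1L
          off <- (k - 1L) %% L + 1L
          old <- substr(seqs[r], off, off)
          substr(seqs[r], off, off) <- sample(setdiff(c("A", "C", "G", "T"),
                                                      old), 1L)
          nerr[r] <- nerr[r] + 1L
        }
      }
      names_r <- sprintf("%s_h%d_r%06d", srow$sample, h, seq_len(nReads))
      # truth sub-walk along the haplotype path
      comp <- hap$composition
      lens <- seg_len[comp]
      cs0 <- c(0, cumsum(lens))
      first <- findInterval(starts, cs0)
      last <- findInterval(starts + L - 1L, cs0)
      step_str <- paste0(">", comp)
      co <- c(0, cumsum(nchar(step_str)))
      full <- paste0(step_str, collapse = "")
      path <- substring(full, co[first] + 1L, co[last + 1L])
      per_hap[[h]] <- list(
        reads = data.frame(read = names_r, hap = hap$name, start = starts,
                           seq = seqs, errors = nerr),
        gaf = data.frame(qname = names_r, qlen = L, qstart = 0, qend = L,
                         strand = "+", path = path,
                         pathLen = cs0[last + 1L] - cs0[first],
                         pathStart = starts - cs0[first],
                         pathEnd = starts - cs0[first] + L,
                         matches = L - nerr, alnlen = L, mapq = 60))
    }
    reads_out[[srow$sample]] <- do.call(rbind, lapply(per_hap, `[[`, "reads"))
    gaf_out[[srow$sample]] <- do.call(rbind, lapply(per_hap, `[[`, "gaf"))
    rownames(reads_out[[srow$sample]]) <- NULL
    rownames(gaf_out[[srow$sample]]) <- NULL
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    qual <- strrep("I", L)
    for (s in names(reads_out)) {
      rd <- reads_out[[s]]
      writeLines(paste0("@", rd$read, "\n", rd$seq, "\n+\n", qual),
                 file.path(dir, paste0(s, ".fq")))
      writeGaf(gaf_out[[s]], file.path(dir, paste0(s, ".gaf")))
    }
  }
  list(reads = reads_out, gaf = gaf_out)
}

#' Emit assembly-vs-reference PAF for simulated haplotypes
#'
#' Each haplotype is aligned (by construction) against the backbone
#' reference: non-carrier haplotypes yield a single match-spanning
#' record; carrier haplotypes carry an insertion of
#' `svCopies x svUnitLength` bp at the breakpoint in the `cg` CIGAR.
#' Private SNPs stay inside `M` ops and reduce the residue-match count.
#'
#' @param sim A `"panlocSim"` from [simulateHaplotypes()].
#' @param refName Reference sequence name (default `"ref"`).
#' @return A PAF `data.frame` (see [parsePaf()]), one record per
#'   haplotype.
#' @export
emitPaf <- function(sim, refName = "ref") {
  stopifnot(inherits(sim, "panlocSim"))
  B <- sim$config$backboneLength
  seg <- sim$segments
  kind <- structure(seg$kind, names = seg$id)
  len <- structure(seg$length, names = seg$id)
  rows <- lapply(sim$haplotypes, function(hap) {
    k <- kind[hap$composition]
    l <- len[hap$composition]
    is_ins <- k == "unit"
    runs <- rle(is_ins)
    cig <- character(length(runs$lengths))
    pos <- 1L
    for (j in seq_along(runs$lengths)) {
      span <- sum(l[pos:(pos + runs$lengths[j] - 1L)])
      cig[j] <- sprintf("%d%s", span, if (runs$values[j]) "I" else "M")
      pos <- pos + runs$lengths[j]
    }
    n_snp <- sum(k == "snp")
    qlen <- sum(l)
    data.frame(qname = hap$name, qlen = qlen, qstart = 0, qend = qlen,
               strand = "+", tname = refName, tlen = B, tstart = 0, tend = B,
               matches = B - n_snp, alnlen = qlen, mapq = 60,
               cg = paste0(cig, collapse = ""))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a translocation-bearing contig
#'
#' Builds a toy two-chromosome reference and a contig reproducing the
#' serial-translocation signature in which the downstream part of a
#' donor-chromosome fragment (segment DE) is repositioned upstream of
#' the rest (segment AD) inside an acceptor chromosome: contig =
#' chr29 flank + chr6 DE + chr6 AD + chr29 flank. A colinear control
#' contig covering AD+DE in reference order is included. The emitted
#' PAF reflects the block structure and the truth signature records the
#' ordered (chrom, interval, strand) block list per contig.
#'
#' @param seed Integer seed.
#' @return List with `reference` and `contigs`
#'   ([Biostrings::DNAStringSet]), `paf` (PAF `data.frame`), `target`
#'   (the donor-chromosome [GenomicInterval-class] of interest) and
#'   `truth` (named list per contig: `blocks` `data.frame`,
#'   `multiChromosome`, `nonColinear`).
#' @export
simulateTranslocationContig <- function(seed = 1L) {
  set.seed(as.integer(seed))
  chr6 <- randomDna(40000)
  chr29 <- randomDna(30000)
  segAD <- substring(chr6, 5001, 20000)     # chr6 [5000, 20000)
  segDE <- substring(chr6, 20001, 30000)    # chr6 [20000, 30000)
  flank1 <- substring(chr29, 1, 10000)      # chr29 [0, 10000)
  flank2 <- substring(chr29, 10001, 20000)  # chr29 [10000, 20000)
  contig <- paste0(flank1, segDE, segAD, flank2)
  control <- paste0(segAD, segDE)
  blocks <- data.frame(
    chrom = c("chr29", "chr6", "chr6", "chr29"),
    refStart = c(0, 20000, 5000, 10000),
    refEnd = c(10000, 30000, 20000, 20000),
    strand = "+",
    contigStart = c(0, 10000, 20000, 35000),
    contigEnd = c(10000, 20000, 35000, 45000))
  ctl_blocks <- data.frame(chrom = "chr6", refStart = 5000, refEnd = 30000,
                           strand = "+", contigStart = 0, contigEnd = 25000)
  mkrec <- function(qname, qlen, b) {
    data.frame(qname = qname, qlen = qlen, qstart = b$contigStart,
               qend = b$contigEnd, strand = b$strand,
               tname = b$chrom, tlen = ifelse(b$chrom == "chr6", 40000, 30000),
               tstart = b$refStart, tend = b$refEnd,
               matches = b$refEnd - b$refStart,
               alnlen = b$refEnd - b$refStart, mapq = 60,
               cg = sprintf("%dM", as.integer(b$refEnd - b$refStart)))
  }
  paf <- rbind(mkrec("transContig", nchar(contig), blocks),
               mkrec("ctlContig", nchar(control), ctl_blocks))
  rownames(paf) <- NULL
  list(reference = Biostrings::DNAStringSet(c(chr6 = chr6, chr29 = chr29)),
       contigs = Biostrings::DNAStringSet(c(transContig = contig,
                                            ctlContig = control)),
       paf = paf,
       target = genomicInterval("chr6", 5000, 30000),
       truth = list(
         transContig = list(blocks = blocks, multiChromosome = TRUE,
                            nonColinear = TRUE),
         ctlContig = list(blocks = ctl_blocks, multiChromosome = FALSE,
                          nonColinear = FALSE)))
}

#' Write simulated haplotypes and reference as FASTA
#'
#' @param sim A `"panlocSim"`.
#' @param dir Output directory; writes `reference.fa`, `haplotypes.fa`
#'   and `truth.tsv`.
#' @return Invisibly, the directory.
#' @export
writeSimOutputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(ref = sim$backbone)),
    file.path(dir, "reference.fa"))
  haps <- vapply(sim$haplotypes, `[[`, character(1L), "sequence")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(haps),
                              file.path(dir, "haplotypes.fa"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
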