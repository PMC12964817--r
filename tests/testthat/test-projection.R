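test_that("parsePaf accepts valid records and rejects invariant violations individually", {
  ok <- parsePaf(text = "q\t1000\t0\t1000\t+\tref\t5000\t1000\t2000\t990\t1000\t60")
  expect_equal(nrow(ok), 1L)
  expect_equal(ok$strand, "+")
  expect_true(is.na(ok$cg))

  bad <- parsePaf(text = c(
    "q1\t1000\t0\t1000\t+\tref\t5000\t1000\t2000\t990\t1000\t60",
    "q2\t1000\t900\t100\t+\tref\t5000\t1000\t2000\t990\t1000\t60"))
  expect_equal(nrow(bad), 1L)
  rej <- attr(bad, "rejected")
  expect_equal(rej$line, 2L)
  expect_match(rej$reason, "qstart")

  cg_ok <- parsePaf(text = "q\t200\t0\t100\t+\tref\t500\t0\t100\t100\t100\t60\tcg:Z:100M")
  expect_equal(nrow(cg_ok), 1L)
  cg_bad <- parsePaf(text = "q\t200\t0\t100\t+\tref\t500\t0\t100\t100\t100\t60\tcg:Z:90M")
  expect_equal(nrow(cg_bad), 0L)
  expect_match(attr(cg_bad, "rejected")$reason, "CIGAR")

  expect_error(parsePaf(text = "q\t1000\t0"), "12 columns")
  expect_error(parsePaf(text = "q\tX\t0\t1000\t+\tref\t5000\t1000\t2000\t990\t1000\t60"),
               "non-numeric")
})

test_that("projectInterval maps match-only alignments by identity offset", {
  paf <- parsePaf(text = "q\t1000\t0\t1000\t+\tref\t5000\t1000\t2000\t1000\t1000\t60\tcg:Z:1000M")
  seg <- projectInterval(paf, genomicInterval("ref", 1100, 1200))
  expect_equal(nrow(seg), 1L)
  expect_equal(c(seg$imgStart, seg$imgEnd), c(100, 200))
  expect_equal(c(seg$srcStart, seg$srcEnd), c(1100, 1200))
  expect_false(seg$approximate)
  # non-overlapping target yields nothing
  expect_equal(nrow(projectInterval(paf, genomicInterval("ref", 0, 500))), 0L)
  # no CIGAR on a non-trivial alignment -> approximate interpolation
  paf2 <- parsePaf(text = "q\t1200\t0\t1200\t+\tref\t5000\t1000\t2000\t900\t1200\t60")
  seg2 <- projectInterval(paf2, genomicInterval("ref", 1000, 2000))
  expect_true(seg2$approximate)
  expect_equal(c(seg2$imgStart, seg2$imgEnd), c(0, 1200))
})

test_that("projectInterval walks deletions exactly as the aligned-pair oracle", {
  rec <- data.frame(qname = "q", qlen = 1100, qstart = 50, qend = 1050,
                    strand = "+", tname = "ref", tlen = 3000, tstart = 1000,
                    tend = 2100, matches = 1000, alnlen = 1100, mapq = 60,
                    cg = "500M100D500M")
  seg <- projectInterval(rec, genomicInterval("ref", 1400, 1700))
  oracle <- projectOracle(rec, 1400, 1700)
  expect_equal(c(seg$imgStart, seg$imgEnd), oracle)
  # window entirely inside the deletion: no aligned base, no segment
  expect_equal(nrow(projectInterval(rec, genomicInterval("ref", 1510, 1590))), 0L)
})

test_that("minus-strand projection is reverse-complement consistent", {
  rec <- data.frame(qname = "q", qlen = 1200, qstart = 100, qend = 1100,
                    strand = "-", tname = "ref", tlen = 4000, tstart = 1000,
                    tend = 2000, matches = 1000, alnlen = 1000, mapq = 60,
                    cg = "1000M")
  full <- projectInterval(rec, genomicInterval("ref", 1000, 2000))
  expect_equal(c(full$imgStart, full$imgEnd), c(100, 1100))
  sub <- projectInterval(rec, genomicInterval("ref", 1000, 1100))
  # first 100 reference bases map to the *last* 100 query bases
  expect_equal(c(sub$imgStart, sub$imgEnd), c(1000, 1100))
  expect_equal(c(sub$imgStart, sub$imgEnd), projectOracle(rec, 1000, 1100))
})

test_that("projection agrees with the aligned-pair oracle on random alignments", {
  set.seed(42)
  for (i in 1:300) {
    rec <- randomPafRecord()
    lo <- rec$tstart + sample.int(max(1L, rec$tend - rec$tstart), 1L) - 1L
    hi <- min(rec$tend, lo + sample.int(200L, 1L))
    if (hi <= lo) next
    seg <- projectInterval(rec, genomicInterval("ref", lo, hi))
    oracle <- projectOracle(rec, lo, hi)
    if (is.null(oracle)) {
      expect_equal(nrow(seg), 0L)
    } else {
      expect_equal(c(seg$imgStart, seg$imgEnd), oracle,
                   label = sprintf("cg=%s [%d,%d) strand %s", rec$cg, lo, hi,
                                   rec$strand))
    }
  }
})

test_that("match-only projections round-trip ref -> contig -> ref", {
  set.seed(7)
  for (i in 1:50) {
    span <- sample.int(500L, 1L)
    qstart <- sample.int(100L, 1L)
    tstart <- sample.int(100L, 1L)
    strand <- sample(c("+", "-"), 1L)
    rec <- data.frame(qname = "q", qlen = qstart + span + 20, qstart = qstart,
                      qend = qstart + span, strand = strand, tname = "ref",
                      tlen = tstart + span + 20, tstart = tstart,
                      tend = tstart + span, matches = span, alnlen = span,
                      mapq = 60, cg = sprintf("%dM", span))
    lo <- tstart + sample.int(span, 1L) - 1L
    hi <- min(tstart + span, lo + sample.int(span, 1L))
    if (hi <= lo) next
    seg <- projectInterval(rec, genomicInterval("ref", lo, hi))
    inv <- data.frame(qname = "ref", qlen = rec$tlen, qstart = rec$tstart,
                      qend = rec$tend, strand = strand, tname = "q",
                      tlen = rec$qlen, tstart = rec$qstart, tend = rec$qend,
                      matches = span, alnlen = span, mapq = 60, cg = rec$cg)
    back <- projectInterval(inv, genomicInterval("q", seg$imgStart, seg$imgEnd))
    expect_equal(c(back$imgStart, back$imgEnd), c(lo, hi))
  }
})

test_that("intervalLength follows the end-minus-start convention", {
  expect_equal(intervalLength(genomicInterval("29", 18563290, 19251547)), 688257)
  expect_equal(intervalLength(genomicInterval("1", 5, 5)), 0)
  expect_equal(intervalLength(genomicInterval("6", 69000000, 71000000)), 2000000)
  # additivity over a partition
  set.seed(1)
  for (i in 1:20) {
    a <- sample.int(1000L, 1L)
    b <- a + sample.int(1000L, 1L)
    m <- sample(a:b, 1L)
    expect_equal(intervalLength(genomicInterval("x", a, m)) +
                   intervalLength(genomicInterval("x", m, b)),
                 intervalLength(genomicInterval("x", a, b)))
  }
  expect_error(genomicInterval("x", 10, 5))
  # region strings are 1-based inclusive at the boundary
  r <- parseRegion("6:69,000,001-71,000,000")
  expect_equal(c(r@start, r@end), c(69000000, 71000000))
  expect_error(parseRegion("6:100"), "malformed")
})

test_that("contig admission applies the 10 kb and 80% rules and reports all decisions", {
  seg <- data.frame(contig = c("ctg4037", "ctgShort", "ctg696"),
                    imgStart = 0,
                    imgEnd = c(17822, 9999, 29216))
  lens <- c(ctg4037 = 20779, ctgShort = 10000, ctg696 = 39067)
  adm <- admitAdditionalContigs(seg, lens)
  adm <- adm[match(names(lens), adm$contig), ]
  expect_equal(adm$admitted, c(TRUE, FALSE, FALSE))
  expect_equal(adm$coverageFraction[1L], 17822 / 20779)
  expect_match(adm$reason[2L], "below 10000 bp")
  expect_match(adm$reason[3L], "fraction 0.748")
  expect_equal(adm$reason[1L], "")
  # overlapping segments are unioned, not double-counted
  seg2 <- data.frame(contig = "c", imgStart = c(0, 500), imgEnd = c(1000, 1500))
  expect_equal(admitAdditionalContigs(seg2, c(c = 2000))$alignedLength, 1500L)
  expect_error(admitAdditionalContigs(seg, lens[-1L]), "ctg4037")
})

test_that("admission is monotone in aligned length", {
  set.seed(5)
  for (i in 1:50) {
    total <- sample(5000:50000, 1L)
    a1 <- sample.int(total, 1L)
    a2 <- min(total, a1 + sample.int(10000L, 1L))
    adm1 <- admitAdditionalContigs(
      data.frame(contig = "c", imgStart = 0, imgEnd = a1), c(c = total))
    adm2 <- admitAdditionalContigs(
      data.frame(contig = "c", imgStart = 0, imgEnd = a2), c(c = total))
    expect_false(adm1$admitted && !adm2$admitted)
  }
})

test_that("translocation flags stay unset for in-order same-chromosome blocks", {
  paf <- parsePaf(text = c(
    "ctg\t30000\t0\t10000\t+\tchr6\t50000\t5000\t15000\t10000\t10000\t60",
    "ctg\t30000\t12000\t22000\t+\tchr6\t50000\t20000\t30000\t10000\t10000\t60"))
  sig <- detectTranslocationSignatures(paf, genomicInterval("chr6", 0, 50000))
  expect_equal(nrow(sig$ctg$blocks), 2L)
  expect_false(sig$ctg$multiChromosome)
  expect_false(sig$ctg$nonColinear)
  # short blocks are suppressed as noise
  paf2 <- rbind(paf, parsePaf(text =
    "ctg\t30000\t23000\t24000\t+\tchr29\t40000\t0\t1000\t1000\t1000\t60"))
  sig2 <- detectTranslocationSignatures(paf2, genomicInterval("chr6", 0, 50000))
  expect_equal(nrow(sig2$ctg$blocks), 2L)
  expect_false(sig2$ctg$multiChromosome)
})

test_that("extractRegionSequences honours strand and bounds", {
  set.seed(9)
  fa <- Biostrings::DNAStringSet(c(ctgA = paste0(
    sample(c("A", "C", "G", "T"), 500, replace = TRUE), collapse = "")))
  segs <- data.frame(contig = "ctgA", imgStart = c(0, 100), imgEnd = c(500, 200),
                     strand = c("+", "-"))
  out <- extractRegionSequences(fa, segs)
  expect_identical(as.character(out[[1L]]), as.character(fa[[1L]]))
  fwd <- extractRegionSequences(fa, transform(segs[2L, ], strand = "+"))
  expect_identical(as.character(out[[2L]]),
                   as.character(Biostrings::reverseComplement(fwd[[1L]])))
  expect_equal(names(out), c("ctgA:0-500:+", "ctgA:100-200:-"))
  expect_error(extractRegionSequences(
    fa, data.frame(contig = "ctgA", imgStart = 0, imgEnd = 501, strand = "+")),
    "outside")
})
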