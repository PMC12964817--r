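#' Per-breed carrier tabulation
#'
#' Tabulates, per breed, the number of samples (assemblies) and the
#' number carrying the variant, together with totals per phenotype
#' group. Each assembly counts once.
#'
#' @param carriers `data.frame` with columns `sample` and `carrier`
#'   (logical), or a named logical vector.
#' @param phenotypes `data.frame` with columns `sample`, `breed`,
#'   `phenotype` (`"white"` or `"colored"`); every sample in `carriers`
#'   must be present, else an error lists the missing names.
#' @return List with `perBreed` (`data.frame`: `breed`, `phenotype`,
#'   `n`, `carriers`) and `totals` (`data.frame` per phenotype group:
#'   `phenotype`, `n`, `carriers`).
#' @export
breedCarrierSummary <- function(carriers, phenotypes) {
  if (!is.data.frame(carriers))
    carriers <- data.frame(sample = names(carriers),
                           carrier = as.logical(carriers))
  bad_ph <- setdiff(unique(phenotypes$phenotype), c("white", "colored"))
  if (length(bad_ph))
    stop("phenotype values must be 'white' or 'colored'; found: ",
         paste(bad_ph, collapse = ", "))
  missing <- setdiff(carriers$sample, phenotypes$sample)
  if (length(missing))
    stop("samples missing from phenotype table: ",
         paste(missing, collapse = ", "))
  if (!nrow(carriers))
    return(list(perBreed = data.frame(breed = character(),
                                      phenotype = character(), n = integer(),
                                      carriers = integer()),
                totals = data.frame(phenotype = character(), n = integer(),
                                    carriers = integer())))
  m <- merge(carriers, phenotypes, by = "sample")
  per <- aggregate(cbind(n = rep(1L, nrow(m)), carriers = as.integer(m$carrier)),
                   by = list(breed = m$breed, phenotype = m$phenotype), FUN = sum)
  per <- per[order(per$phenotype, per$breed), , drop = FALSE]
  rownames(per) <- NULL
  tot <- aggregate(per[, c("n", "carriers")],
                   by = list(phenotype = per$phenotype), FUN = sum)
  list(perBreed = per, totals = tot)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Computes the exact two-sided p-value by full enumeration over the
#' hypergeometric support of the fixed margins, summing the point
#' probabilities of all tables no more probable than the observed one
#' (the minimum-likelihood rule, with a `1e-7` relative tolerance on the
#' probability comparison for floating-point determinism). The odds
#' ratio is the sample odds ratio, with a +0.5 Haldane-Anscombe
#' correction applied -- and flagged -- only when a cell is zero.
#'
#' @param table 2x2 matrix (or length-4 vector `a, c, b, d` column-wise)
#'   of non-negative integer counts: rows carrier / non-carrier, columns
#'   e.g. white / colored. An all-zero table is an error.
#' @return List with `p.value`, `odds.ratio`, `haldane` (logical: was
#'   the correction applied) and `table`.
#' @examples
#' fisherExactTwoSided(matrix(c(2, 0, 0, 2), 2))  # p = 1/3
#' @export
fisherExactTwoSided <- function(table) {
  tab <- matrix(as.numeric(table), 2L, 2L)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (sum(tab) == 0) stop("all-zero contingency table")
  a <- tab[1L, 1L]
  m <- sum(tab[1L, ])        # row-1 margin (carriers)
  n <- sum(tab[2L, ])        # row-2 margin
  k <- sum(tab[, 1L])        # column-1 margin
  support <- max(0L, k - n):min(m, k)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- probs[match(a, support)]
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p <- min(1, p)
  haldane <- any(tab == 0)
  t_or <- if (haldane) tab + 0.5 else tab
  or <- (t_or[1L, 1L] * t_or[2L, 2L]) / (t_or[1L, 2L] * t_or[2L, 1L])
  list(p.value = p, odds.ratio = or, haldane = haldane, table = tab)
}

#' Dominance concordance between genotype and phenotype
#'
#' Under a dominant model a single carrier allele suffices for the
#' phenotype, so a sample is concordant when
#' `(genotype != "absent") == (phenotype == "white")`.
#'
#' @param genotypes Named character vector (or `data.frame` with
#'   `sample`, `call`) of genotype calls (`absent`/`het`/`hom`/`dup`).
#' @param phenotypes `data.frame` with columns `sample`, `phenotype`.
#'   An empty cohort is an error.
#' @return List with `concordance` (fraction in `[0, 1]`) and
#'   `discordant` (character vector of discordant sample names).
#' @export
dominanceConcordance <- function(genotypes, phenotypes) {
  if (is.data.frame(genotypes))
    genotypes <- structure(genotypes$call, names = genotypes$sample)
  if (!length(genotypes)) stop("empty cohort")
  missing <- setdiff(names(genotypes), phenotypes$sample)
  if (length(missing))
    stop("samples missing from phenotype table: ",
         paste(missing, collapse = ", "))
  ph <- structure(phenotypes$phenotype, names = phenotypes$sample)
  carrier <- genotypes != "absent"
  white <- ph[names(genotypes)] == "white"
  ok <- carrier == white
  list(concordance = mean(ok), discordant = names(genotypes)[!ok])
}

#' Load the bundled breed assembly panel
#'
#' Reads the per-breed assembly panel distributed with the package
#' (breed, head phenotype, number of assemblies in the pangenome and
#' number showing the alternative path) and expands it to one row per
#' assembly with a carrier flag, suitable for [breedCarrierSummary()].
#'
#' @param file Path to a panel TSV; defaults to the bundled table.
#' @return `data.frame` with columns `sample`, `breed`, `phenotype`,
#'   `carrier`.
#' @export
loadBreedPanel <- function(file = system.file("extdata", "breed_panel.tsv",
                                              package = "panloc")) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    n <- tab$n_assemblies[i]
    data.frame(sample = sprintf("%s_%02d", gsub("[^A-Za-z]", "", tab$breed[i]),
                                seq_len(n)),
               breed = tab$breed[i], phenotype = tab$phenotype[i],
               carrier = seq_len(n) <= tab$n_carriers[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
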