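# Reading, harmonizing and grouping GWAS summary statistics into
# gene-level test units.

.requiredSummaryCols <- c("snp", "trait", "z", "counted_allele",
                          "other_allele")

#' Read a summary-statistics table
#'
#' Reads a delimited text file with one row per (SNP, trait) pair and
#' columns `snp`, `trait`, `z`, `counted_allele`, `other_allele` and
#' optionally `chrom`, `pos` (1-based).
#'
#' @param path file path (whitespace- or tab-delimited, with header).
#' @param strict if `TRUE`, rows with unparsable Z are an error; by
#'   default they are dropped with a message.
#' @return data.frame with the validated records.
#' @export
readSummaryStats <- function(path, strict = FALSE) {
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  missing <- setdiff(.requiredSummaryCols, names(df))
  if (length(missing))
    stop("summary-statistics file is missing column(s): ",
         paste(missing, collapse = ", "))
  df$z <- suppressWarnings(as.numeric(df$z))
  bad <- !is.finite(df$z)
  if (any(bad)) {
    if (strict) stop(sum(bad), " row(s) with unparsable Z statistic")
    message("dropping ", sum(bad), " row(s) with unparsable Z statistic")
    df <- df[!bad, , drop = FALSE]
  }
  key <- paste(df$snp, df$trait, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (SNP, trait) records, e.g. ",
         sub("\r", " / ", key[duplicated(key)][1]))
  rownames(df) <- NULL
  df
}

#' Write a summary-statistics table
#'
#' @param x data.frame of summary records.
#' @param path output file path (tab-delimited).
#' @return `path`, invisibly.
#' @export
writeSummaryStats <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.flipAllele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

.strandAmbiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize summary-statistics alleles against a reference panel
#'
#' The default (`mode = "strict"`) keeps only SNPs whose (counted, other)
#' allele pair matches the panel exactly, dropping everything else. With
#' `mode = "swap"`, SNPs whose allele pair is swapped relative to the
#' panel are additionally kept with the Z sign flipped; strand-ambiguous
#' SNPs (A/T, C/G) are never sign-flipped because the strand cannot be
#' resolved without allele frequencies, and are dropped in swap mode
#' unless they match exactly. SNPs absent from the panel are dropped.
#' Membership and (in swap mode) sign are the only things this function
#' changes; |Z| is never altered.
#'
#' @param summary data.frame as returned by [readSummaryStats()].
#' @param panelAlleles data.frame with columns `snp`, `counted_allele`,
#'   `other_allele` describing the panel coding.
#' @param mode `"strict"` (default) or `"swap"`.
#' @return the filtered (and possibly sign-flipped) summary data.frame.
#' @export
harmonizeAlleles <- function(summary, panelAlleles,
                             mode = c("strict", "swap")) {
  mode <- match.arg(mode)
  idx <- match(summary$snp, panelAlleles$snp)
  absent <- is.na(idx)
  if (any(absent))
    message("dropping ", length(unique(summary$snp[absent])),
            " SNP(s) absent from the reference panel")
  keep <- !absent
  pa <- panelAlleles$counted_allele[idx]
  po <- panelAlleles$other_allele[idx]
  exact <- keep & summary$counted_allele == pa & summary$other_allele == po
  out <- summary
  if (mode == "strict") {
    sel <- exact
  } else {
    swapped <- keep & summary$counted_allele == po &
      summary$other_allele == pa &
      !.strandAmbiguous(summary$counted_allele, summary$other_allele)
    out$z[swapped] <- -out$z[swapped]
    sel <- exact | swapped
    if (any(swapped))
      message("sign-flipped ", sum(swapped), " swapped-allele record(s)")
  }
  dropped <- sum(keep & !sel)
  if (dropped > 0)
    message("dropping ", dropped,
            " record(s) with mismatched allele coding")
  out <- out[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene regions from a BED file
#'
#' BED intervals are 0-based half-open; they are converted to the 1-based
#' inclusive convention used throughout the package (start + 1, end).
#'
#' @param path BED file (chrom, start, end, name).
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
readGeneRegions <- function(path) {
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("BED file needs chrom, start, end, name columns")
  data.frame(gene = df[[4]], chrom = as.character(df[[1]]),
             start = df[[2]] + 1L, end = df[[3]],
             stringsAsFactors = FALSE)
}

#' Assign SNPs to gene windows
#'
#' A SNP belongs to every gene whose `[start - flank, end + flank]`
#' window (1-based inclusive) contains its position; SNPs in overlapping
#' windows are assigned to all of the genes involved. Genes whose SNP
#' count falls outside `[mMin, mMax]` are excluded (logged).
#'
#' @param snps data.frame with columns `snp`, `chrom`, `pos` (1-based).
#' @param regions data.frame with columns `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive), e.g. from [readGeneRegions()].
#' @param flank window extension in bp on each side (default 5000).
#' @param mMin,mMax retained range of SNPs per gene (defaults 2 and 500).
#' @return named list mapping gene id to the character vector of its SNP
#'   ids, ordered by position.
#' @export
assignSnpsToGenes <- function(snps, regions, flank = 5000,
                              mMin = 2L, mMax = 500L) {
  stopifnot(all(c("snp", "chrom", "pos") %in% names(snps)),
            all(c("gene", "chrom", "start", "end") %in% names(regions)))
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  snpGr <- GenomicRanges::GRanges(
    seqnames = as.character(snps$chrom),
    ranges = IRanges::IRanges(start = snps$pos, width = 1L))
  geneGr <- GenomicRanges::GRanges(
    seqnames = as.character(regions$chrom),
    ranges = IRanges::IRanges(start = pmax(1L, regions$start - flank),
                              end = regions$end + flank))
  hits <- GenomicRanges::findOverlaps(snpGr, geneGr)
  if (length(hits) == 0L) return(list())
  assign <- split(snps$snp[S4Vectors::queryHits(hits)],
                  regions$gene[S4Vectors::subjectHits(hits)])
  sizes <- lengths(assign)
  small <- sizes < mMin
  large <- sizes > mMax
  if (any(small | large))
    message("excluding ", sum(small), " gene(s) below mMin and ",
            sum(large), " above mMax")
  assign[!small & !large]
}

#' Build gene-level test units
#'
#' Composes the pipeline for each gene: assembles the traits x SNPs
#' Z matrix from the harmonized summary table and estimates the gene's
#' SNP correlation matrix from the reference panel under the configured
#' covariate case. Genes with any missing (trait, SNP) Z entry are
#' skipped with a message.
#'
#' @param summary harmonized summary data.frame (see
#'   [harmonizeAlleles()]).
#' @param panel N x (all SNPs) dosage matrix with SNP colnames.
#' @param geneSnps named list mapping gene to SNP ids (from
#'   [assignSnpsToGenes()]).
#' @param design optional [CovariateDesign] for partial correlation;
#'   `NULL` uses the plain Pearson estimate.
#' @param epsPd regularization floor for the SNP correlation.
#' @return list of [GeneTestUnit].
#' @export
buildGeneUnits <- function(summary, panel, geneSnps, design = NULL,
                           epsPd = 1e-6) {
  traits <- sort(unique(summary$trait))
  units <- list()
  for (gene in names(geneSnps)) {
    snpIds <- geneSnps[[gene]]
    snpIds <- snpIds[snpIds %in% colnames(panel)]
    sub <- summary[summary$snp %in% snpIds, , drop = FALSE]
    zm <- matrix(NA_real_, length(traits), length(snpIds),
                 dimnames = list(traits, snpIds))
    zm[cbind(match(sub$trait, traits), match(sub$snp, snpIds))] <- sub$z
    if (anyNA(zm) || length(snpIds) < 1L) {
      message("skipping gene ", gene,
              ": incomplete trait x SNP Z matrix")
      next
    }
    gpanel <- panel[, snpIds, drop = FALSE]
    theta <- if (is.null(design)) pearsonGenotypeCorrelation(gpanel) else
      partialGenotypeCorrelation(gpanel, design)
    theta <- regularizeCorrelation(theta, epsPd)
    units[[gene]] <- new("GeneTestUnit", gene = gene, z = ZMatrix(zm),
                         snpCorr = theta)
  }
  units
}

#' Run the Three-Way Test over gene units
#'
#' Applies [twtTest()] to each [GeneTestUnit] (a fresh truncation
#' calibration per gene, since the SNP correlation differs) and reports a
#' per-gene table with Bonferroni significance across the tested genes.
#'
#' @param units list of [GeneTestUnit] from [buildGeneUnits()].
#' @param traitCorr the shared [TraitCorrMatrix].
#' @param alpha familywise level for the Bonferroni flag (default 0.05).
#' @param B,seed,etas,pFloor forwarded to [twtTest()].
#' @return data.frame: gene, q, m, P1, P2, P3, twt_pvalue, bonferroni.
#' @export
twtGenes <- function(units, traitCorr, alpha = 0.05, B = 1e5, seed = 1L,
                     etas = defaultTruncationGrid(), pFloor = 1e-14) {
  if (length(units) == 0L) stop("no gene units to test")
  rows <- lapply(seq_along(units), function(i) {
    u <- units[[i]]
    res <- twtTest(u@z, u@snpCorr, traitCorr, etas = etas, B = B,
                   seed = seed + i - 1L, pFloor = pFloor)
    resultRecord(res, gene = u@gene)
  })
  out <- do.call(rbind, rows)
  out$bonferroni <- out$twt_pvalue < alpha / nrow(out)
  out
}

#' Read a reference panel from a VCF file
#'
#' Extracts GT-based allele dosages from a (possibly bgzipped) VCF. The
#' counted allele is the ALT allele, so dosages are ALT-allele counts in
#' \{0, 1, 2\}; missing genotypes become `NA`.
#'
#' @param path VCF file path.
#' @return list with `dosage` (N x m matrix, SNP ids as colnames) and
#'   `info` (data.frame: snp, chrom, pos, counted_allele, other_allele).
#' @export
readPanelVcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF panels requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- fix[, "ID"]
  noId <- is.na(ids) | ids == "."
  ids[noId] <- paste0(fix[noId, "CHROM"], ":", fix[noId, "POS"])
  dose <- apply(gt, 2, function(col) {
    alleles <- strsplit(gsub("\\|", "/", col), "/", fixed = TRUE)
    vapply(alleles, function(a) {
      if (any(is.na(a)) || any(a == ".")) return(NA_real_)
      sum(a != "0")
    }, 0)
  })
  dose <- matrix(dose, nrow = nrow(gt),
                 dimnames = list(ids, colnames(gt)))
  info <- data.frame(snp = ids, chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     counted_allele = fix[, "ALT"],
                     other_allele = fix[, "REF"],
                     stringsAsFactors = FALSE)
  list(dosage = t(dose), info = info)
}
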