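makeSummaryFile <- function() {
  df <- data.frame(
    snp = rep(c("rs1", "rs2", "rs3"), each = 2),
    trait = rep(c("tA", "tB"), times = 3),
    z = c(1.2, -0.4, 2.5, 0.1, -1.7, 0.9),
    counted_allele = rep(c("A", "C", "G"), each = 2),
    other_allele = rep(c("G", "T", "A"), each = 2),
    chrom = "1",
    pos = rep(c(1000L, 8000L, 20000L), each = 2))
  path <- tempfile(fileext = ".tsv")
  writeSummaryStats(df, path)
  list(df = df, path = path)
}

test_that("summary tables read, validate and round-trip", {
  fx <- makeSummaryFile()
  got <- readSummaryStats(fx$path)
  expect_equal(nrow(got), 6L)
  expect_equal(got$z, fx$df$z)
  expect_identical(got$snp, fx$df$snp)

  # missing required column is named in the error
  df2 <- fx$df[, setdiff(names(fx$df), "counted_allele")]
  p2 <- tempfile(); writeSummaryStats(df2, p2)
  expect_error(readSummaryStats(p2), "counted_allele")

  # unparsable Z dropped with a message, or an error in strict mode
  df3 <- fx$df
  df3$z <- as.character(df3$z)
  df3$z[2] <- "NA"
  p3 <- tempfile(); writeSummaryStats(df3, p3)
  expect_message(got3 <- readSummaryStats(p3), "dropping 1")
  expect_equal(nrow(got3), 5L)
  expect_error(readSummaryStats(p3, strict = TRUE), "unparsable")

  # duplicate (SNP, trait) keys rejected
  df4 <- rbind(fx$df, fx$df[1, ])
  p4 <- tempfile(); writeSummaryStats(df4, p4)
  expect_error(readSummaryStats(p4), "duplicate")
})

test_that("allele harmonization drops, keeps or sign-flips as specified", {
  summary <- data.frame(
    snp = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    trait = "tA",
    z = c(1, 2, 3, 4, 5),
    counted_allele = c("A", "G", "A", "A", "C"),
    other_allele = c("G", "A", "C", "T", "G"))
  panel <- data.frame(
    snp = c("rs1", "rs2", "rs3", "rs4"),
    counted_allele = c("A", "A", "G", "T"),
    other_allele = c("G", "G", "T", "A"))

  strict <- suppressMessages(harmonizeAlleles(summary, panel))
  expect_identical(strict$snp, "rs1")      # only the exact match survives
  expect_identical(strict$z, 1)

  swap <- suppressMessages(harmonizeAlleles(summary, panel, mode = "swap"))
  expect_setequal(swap$snp, c("rs1", "rs2"))
  expect_identical(swap$z[swap$snp == "rs2"], -2)  # swapped pair: sign flip
  expect_false("rs3" %in% swap$snp)        # allele mismatch in all modes
  expect_false("rs4" %in% swap$snp)        # A/T strand-ambiguous swap
  expect_false("rs5" %in% swap$snp)        # absent from the panel
  # |Z| never changes
  expect_true(all(abs(swap$z) %in% abs(summary$z)))
})

test_that("BED regions convert to 1-based inclusive coordinates", {
  p <- tempfile(fileext = ".bed")
  writeLines(c("1\t999\t2000\tGENE1", "2\t0\t500\tGENE2"), p)
  reg <- readGeneRegions(p)
  expect_identical(reg$start, c(1000L, 1L))
  expect_identical(reg$end, c(2000L, 500L))
  expect_identical(reg$gene, c("GENE1", "GENE2"))
})

test_that("SNP-to-gene assignment respects flanks, overlaps and size limits", {
  regions <- data.frame(gene = c("G1", "G2", "G3"),
                        chrom = c("1", "1", "2"),
                        start = c(10000L, 11000L, 5000L),
                        end = c(12000L, 15000L, 6000L))
  snps <- data.frame(
    snp = c("a", "b", "c", "d", "e", "f"),
    chrom = c("1", "1", "1", "1", "2", "2"),
    pos = c(5000L, 4999L, 11500L, 16000L, 5500L, 5600L))
  # a: exactly start - 5000 of G1 (inclusive); b: one bp outside
  out <- assignSnpsToGenes(snps, regions, flank = 5000, mMin = 1L)
  expect_true("a" %in% out$G1)
  expect_false("b" %in% out$G1)
  expect_true("c" %in% out$G1 && "c" %in% out$G2)  # overlap: both genes
  expect_true("d" %in% out$G1 && "d" %in% out$G2)  # both windows reach 16000
  expect_setequal(out$G3, c("e", "f"))
  expect_setequal(out$G1, c("a", "c", "d"))

  # independence of input SNP order
  out2 <- assignSnpsToGenes(snps[sample(nrow(snps)), ], regions,
                            flank = 5000, mMin = 1L)
  expect_identical(out, out2)

  # size limits: G1 carries 3 SNPs and is excluded by mMax = 2
  out3 <- suppressMessages(
    assignSnpsToGenes(snps, regions, flank = 5000, mMin = 2L, mMax = 2L))
  expect_false("G1" %in% names(out3))
  expect_setequal(names(out3), c("G2", "G3"))
})

test_that("gene units assemble consistent Z matrices and correlations", {
  set.seed(17)
  n <- 80
  panel <- matrix(rbinom(n * 5, 2, 0.35), n, 5,
                  dimnames = list(NULL, paste0("rs", 1:5)))
  traits <- c("tA", "tB", "tC")
  summary <- expand.grid(snp = paste0("rs", 1:5), trait = traits,
                         stringsAsFactors = FALSE)
  summary$z <- rnorm(nrow(summary))
  geneSnps <- list(G1 = c("rs1", "rs2"), G2 = c("rs3", "rs4", "rs5"))
  units <- buildGeneUnits(summary, panel, geneSnps)
  expect_length(units, 2L)
  expect_identical(zSnps(units$G1@z), c("rs1", "rs2"))
  expect_identical(dim(zValues(units$G2@z)), c(3L, 3L))
  expect_identical(corrLabels(units$G2@snpCorr), c("rs3", "rs4", "rs5"))

  # missing (trait, SNP) entry: the gene is skipped with a message
  summary2 <- summary[-1, ]
  expect_message(units2 <- buildGeneUnits(summary2, panel, geneSnps),
                 "skipping gene G1")
  expect_length(units2, 1L)

  res <- twtGenes(units, TraitCorrMatrix(diag(3), traits), B = 2000,
                  seed = 5)
  expect_identical(res$gene, c("G1", "G2"))
  expect_true(all(res$twt_pvalue >= 1e-14 & res$twt_pvalue <= 1))
  expect_type(res$bonferroni, "logical")
})

test_that("VCF panels yield ALT-allele dosages and allele info", {
  skip_if_not_installed("vcfR")
  p <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t1000\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t2000\trs2\tC\tT\t.\tPASS\t.\tGT\t0|1\t1|1\t./.",
    "2\t500\t.\tG\tA\t.\tPASS\t.\tGT\t0/0\t0/0\t0/1"), p)
  panel <- readPanelVcf(p)
  expect_identical(dim(panel$dosage), c(3L, 3L))
  expect_equal(unname(panel$dosage[, "rs1"]), c(0, 1, 2))
  expect_equal(unname(panel$dosage[, "rs2"]), c(1, 2, NA))
  expect_equal(unname(panel$dosage[, "2:500"]), c(0, 0, 1))
  expect_identical(panel$info$counted_allele, c("G", "T", "A"))
  expect_identical(panel$info$other_allele, c("A", "C", "G"))
  expect_identical(panel$info$pos, c(1000L, 2000L, 500L))
})

test_that("PLINK .bed decoding matches hand-encoded bytes", {
  prefix <- tempfile()
  # 5 individuals, 2 SNPs; A1 dosages snp1: 2,1,0,NA,2  snp2: 0,0,1,2,1
  # codes (00=2, 10=1, 11=0, 01=NA), packed little end first per byte
  snp1 <- c(0L, 2L, 3L, 1L, 0L)
  snp2 <- c(3L, 3L, 2L, 0L, 2L)
  pack <- function(codes) {
    codes <- c(codes, rep(0L, 4 - length(codes) %% 4)[
      seq_len((4 - length(codes) %% 4) %% 4)])
    vapply(seq(1, length(codes), by = 4), function(i)
      as.raw(codes[i] + codes[i + 1] * 4 + codes[i + 2] * 16 +
               codes[i + 3] * 64), raw(1))
  }
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), pack(snp1), pack(snp2)),
           paste0(prefix, ".bed"))
  writeLines(c("1\trs1\t0\t1000\tA\tG", "1\trs2\t0\t2000\tT\tC"),
             paste0(prefix, ".bim"))
  writeLines(sprintf("F%d I%d 0 0 0 -9", 1:5, 1:5),
             paste0(prefix, ".fam"))
  panel <- readPanelPlink(prefix)
  expect_equal(unname(panel$dosage[, "rs1"]), c(2, 1, 0, NA, 2))
  expect_equal(unname(panel$dosage[, "rs2"]), c(0, 0, 1, 2, 1))
  expect_identical(panel$info$counted_allele, c("A", "T"))
  expect_identical(panel$info$pos, c(1000L, 2000L))
  expect_error(readPanelPlink(tempfile()), "missing PLINK")
  # corrupt magic
  bad <- tempfile()
  writeBin(as.raw(c(1, 2, 3, 4)), paste0(bad, ".bed"))
  file.copy(paste0(prefix, ".bim"), paste0(bad, ".bim"))
  file.copy(paste0(prefix, ".fam"), paste0(bad, ".fam"))
  expect_error(readPanelPlink(bad), "magic|truncated")
})
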