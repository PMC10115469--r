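# Minimal reader for PLINK binary genotype triplets (.bed/.bim/.fam).
# The .bed format: 3 magic bytes (0x6c, 0x1b, 0x01 for SNP-major), then
# per SNP ceil(N/4) bytes, each packing four individuals as 2-bit codes:
# 00 = homozygous A1, 10 = heterozygous, 11 = homozygous A2,
# 01 = missing. Dosages count the A1 allele (bim column 5).

#' Read a reference panel from PLINK .bed/.bim/.fam files
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim` and `.fam` must
#'   exist. Only SNP-major bed files are supported (the PLINK default).
#' @return list with `dosage` (N x m matrix of A1-allele counts, SNP ids
#'   as colnames, `NA` for missing) and `info` (data.frame: snp, chrom,
#'   pos, counted_allele = A1, other_allele = A2).
#' @export
readPanelPlink <- function(prefix) {
  bedPath <- paste0(prefix, ".bed")
  bimPath <- paste0(prefix, ".bim")
  famPath <- paste0(prefix, ".fam")
  for (p in c(bedPath, bimPath, famPath))
    if (!file.exists(p)) stop("missing PLINK file: ", p)
  bim <- read.table(bimPath, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "snp", "cm", "pos", "a1", "a2"))
  fam <- read.table(famPath, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam)
  m <- nrow(bim)
  bytesPerSnp <- ceiling(n / 4)
  raw <- readBin(bedPath, what = "raw", n = 3 + m * bytesPerSnp)
  if (length(raw) < 3 + m * bytesPerSnp)
    stop("truncated .bed file: expected ", 3 + m * bytesPerSnp,
         " bytes, got ", length(raw))
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK .bed file (bad magic bytes)")
  body <- as.integer(raw[-(1:3)])
  # unpack the four 2-bit codes of every byte, little end first
  codes <- rbind(body %% 4L, (body %/% 4L) %% 4L,
                 (body %/% 16L) %% 4L, body %/% 64L)
  codes <- matrix(codes, nrow = 4L * bytesPerSnp, ncol = m)
  codes <- codes[seq_len(n), , drop = FALSE]
  lookup <- c(2, NA, 1, 0)  # codes 0b00, 0b01, 0b10, 0b11 -> A1 count
  dosage <- matrix(lookup[codes + 1L], n, m,
                   dimnames = list(fam[[2]], bim$snp))
  info <- data.frame(snp = bim$snp, chrom = as.character(bim$chrom),
                     pos = bim$pos, counted_allele = bim$a1,
                     other_allele = bim$a2, stringsAsFactors = FALSE)
  list(dosage = dosage, info = info)
}
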