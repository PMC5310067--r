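# a tiny two-amplicon panel with hand-checkable sequences
tiny_panel <- function() {
  seqs <- c(
    # GA1: CpGs at 2 and 7; non-CpG Cs at 5, 10, 12
    GA1 = "ACGTCACGTCACATAG",
    # GA2: CpGs at 3 and 8; non-CpG Cs at 1, 6, 11, 13
    GA2 = "CACGTCTCGTCACATAGAAT"
  )
  meta <- data.frame(
    gene = names(seqs), chrom = c("chr1", "chr2"),
    start = c(101, 201), end = c(101, 201) + nchar(seqs) - 1,
    declared_n_cpg = c(2L, 2L), declared_size = nchar(seqs)
  )
  amplicon_panel(meta, seqs)
}

# FASTQ lines for raw reads
fastq_lines <- function(ids, seqs) {
  as.vector(rbind(paste0("@", ids), seqs, "+", strrep("I", nchar(seqs))))
}

tiny_sheet <- function(barcodes = c("AAGGTTCC", "GGCCAATT"),
                       libs = c("L1", "L2")) {
  data.frame(library_id = libs, barcode = barcodes,
             sample_id = libs, group = c("control", "mild"),
             severity = c(0L, 1L), tissue = "blood",
             replicate = 1L, dosage = 0L, stringsAsFactors = FALSE)
}

rc <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# independent two-sided Fisher oracle: enumerate the hypergeometric support
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + c; n1 <- a + b; n <- a + b + c + d
  if (n == 0) return(1)
  k <- max(0, n1 - (n - m1)):min(n1, m1)
  dens <- dhyper(k, m1, n - m1, n1)
  obs <- dhyper(a, m1, n - m1, n1)
  sum(dens[dens <= obs * (1 + 1e-7)])
}
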