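# Shared fixtures, all built in code.

# deterministic hand-sized panel
tiny_panel <- function() {
  snp_panel(chrom = c("1", "1", "1", "2", "2"),
            pos = c(0L, 5L, 9L, 0L, 3L),
            f = c(0.01, 0.2, 0.5, 0.8, 0.05))
}

# genotype matrix with fully specified entries
manual_genotypes <- function(entries, panel = tiny_panel()) {
  g <- matrix(as.integer(entries), ncol = nrow(panel), byrow = TRUE)
  structure(g, class = c("genotype_matrix", "matrix", "array"), panel = panel)
}

# minimal multi-sample VCF written as plain text
write_tiny_vcf <- function(path, all_ref = FALSE) {
  gt <- if (all_ref) {
    c("0/0\t0/0\t0/0", "0|0\t0/0\t0/0")
  } else {
    c("0/1\t0/0\t0/0",        # single het: one present triple
      "0|0\t1/2\t2/2")        # multi-allelic: both alts carried
  }
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    paste0("20\t100\t.\tA\tG\t.\tPASS\t.\tGT\t", gt[1]),
    paste0("20\t200\t.\tC\tT,G\t.\tPASS\t.\tGT\t", gt[2])
  )
  writeLines(lines, path)
  path
}
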