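# Write a small synthetic SAM file of proper pairs and convert it to BAM.
# Each pair i sits at 1-based position pos[i] with template length
# tlen[i]; both mates carry mapq[i].
write_pair_bam <- function(pos, tlen, mapq, chrom = "chrT",
                           chrom_len = 100000L, dir = tempdir()) {
  sam <- file.path(dir, paste0("pairs-", as.integer(stats::runif(1, 1e6, 9e6)),
                               ".sam"))
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  recs <- character(0)
  for (i in seq_along(pos)) {
    p1 <- pos[i]
    p2 <- pos[i] + tlen[i] - 50L  # mate placed so outer span = tlen
    seq1 <- paste(rep("A", 50L), collapse = "")
    recs <- c(recs,
      sprintf("frag%03d\t99\t%s\t%d\t%d\t50M\t=\t%d\t%d\t%s\t*",
              i, chrom, p1, mapq[i], p2, tlen[i], seq1),
      sprintf("frag%03d\t147\t%s\t%d\t%d\t50M\t=\t%d\t%d\t%s\t*",
              i, chrom, p2, mapq[i], p1, -tlen[i], seq1))
  }
  # SAM must be coordinate sorted for asBam's sort step to be trivial
  writeLines(c(lines, recs), sam)
  bam <- Rsamtools::asBam(sam, sub("\\.sam$", "", sam),
                          overwrite = TRUE, indexDestination = TRUE)
  bam
}
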