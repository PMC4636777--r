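# Shared in-code fixtures: a tiny hand-built reference exercising every
# annotation path, and small writers for FASTA/FASTQ fixtures.

write_fasta <- function(named_seqs, path = tempfile(fileext = ".fa")) {
  writeLines(as.vector(rbind(paste0(">", names(named_seqs)),
                             unname(named_seqs))), path)
  path
}

# Toy reference layout (DNA alphabet):
#  ssc-miR-A   in hairpin ssc-mir-A at 10..32 with >=6 nt flanks
#  ssc-miR-B   occurs in BOTH ssc-mir-B1 and ssc-mir-B2 (multi-copy)
#  ssc-miR-C5p / ssc-miR-C3p: two matures on one hairpin, 4 nt apart,
#     so a substring overlapping both is ambiguous
#  ssc-miR-lost: not present in any hairpin (locus-less)
#  hsa-miR-X: other-species mature, no ssc hairpin
toy_reference <- function() {
  matA <- "TACCACAGGGTAGAACCACGG"             # 21 nt (miR-140-3p-like)
  matB <- "TGGCTCAGTTCAGCAGGAACAG"            # 22 nt
  hpA <- paste0("CCCCCCCCCC", matA, "ATTTTTTTTT")          # matA at 10..31
  hpB_core <- paste0("AACCGGTT", matB, "CGCGCGCG")
  armC <- "ACGTACGTACGTACGTAACCGGTTAACCGG"    # 30 nt shared arm
  matC5 <- substr(armC, 1, 21)                # locus 4..25 on hpC
  matC3 <- substr(armC, 8, 29)                # locus 11..33, overlaps matC5
  hpC <- paste0("TTTT", armC, "GGGGTTTT")
  mature <- c(
    "ssc-miR-A" = matA,
    "ssc-miR-B" = matB,
    "ssc-miR-C5p" = matC5,
    "ssc-miR-C3p" = matC3,
    "ssc-miR-lost" = "AAAACCCCGGGGTTTTAAAC",
    "hsa-miR-X" = "TTTTGGGGCCCCAAAATTTG"
  )
  hairpin <- c(
    "ssc-mir-A" = hpA,
    "ssc-mir-B1" = hpB_core,
    "ssc-mir-B2" = paste0("TTTTTT", hpB_core),
    "ssc-mir-C" = hpC
  )
  suppressWarnings(load_reference(write_fasta(mature), write_fasta(hairpin),
                                  species_primary = "ssc"))
}

# independent counting of mismatches for the adapter oracle
chars <- function(x) strsplit(x, "")[[1]]

expect_same_partition <- function(a, b) {
  expect_equal(mclust::adjustedRandIndex(a, b), 1)
}
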