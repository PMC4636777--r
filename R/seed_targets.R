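site_rank <- c("6mer" = 1L, "7mer-A1" = 2L, "7mer-m8" = 3L, "8mer" = 4L)

#' Scan a 3'UTR for canonical seed-match sites
#'
#' Finds every occurrence of the Watson-Crick match to the miRNA seed core
#' (positions 2-7) on the UTR. Each occurrence is typed by the standard
#' hierarchy: an additional match to miRNA position 8 immediately 5' of the
#' site upgrades it to 7mer-m8; an A immediately 3' of the site (opposite
#' miRNA position 1) upgrades it to 7mer-A1; both together make an 8mer;
#' neither leaves a 6mer. Site efficacy ranks
#' 8mer > 7mer-m8 > 7mer-A1 > 6mer, and each position is reported once at
#' its highest type. Ambiguous UTR bases never match.
#'
#' @param utr_sequence 3'UTR sequence (DNA text, 5'->3').
#' @param mirna_sequence miRNA sequence (RNA or DNA text, length >= 8).
#' @return Data frame: `position` (0-based start of the 6mer core on the
#'   UTR), `site_type`, `seed_used` (the miRNA's 7-nt seed, RNA alphabet).
#' @export
scan_sites <- function(utr_sequence, mirna_sequence) {
  mir <- as_dna(mirna_sequence)
  if (nchar(mir) < 8L) stop("miRNA must be at least 8 nt")
  utr <- as_dna(utr_sequence)
  core6 <- revcomp(substr(mir, 2L, 7L))
  m8 <- revcomp(substr(mir, 8L, 8L))
  hits <- Biostrings::matchPattern(core6, Biostrings::DNAString(utr))
  empty <- data.frame(position = integer(), site_type = character(),
                      seed_used = character(), stringsAsFactors = FALSE)
  if (!length(hits)) return(empty)
  starts <- Biostrings::start(hits)   # 1-based core start
  has_m8 <- vapply(starts, function(s)
    s > 1L && substr(utr, s - 1L, s - 1L) == m8, TRUE)
  has_a1 <- vapply(starts, function(s)
    s + 6L <= nchar(utr) && substr(utr, s + 6L, s + 6L) == "A", TRUE)
  type <- ifelse(has_m8 & has_a1, "8mer",
                 ifelse(has_m8, "7mer-m8",
                        ifelse(has_a1, "7mer-A1", "6mer")))
  data.frame(position = starts - 1L, site_type = type,
             seed_used = as_rna(extract_seed(mir)),
             stringsAsFactors = FALSE)
}

#' Predicted target set of a miRNA over a UTR panel
#'
#' @param utrs Named character vector (or DNAStringSet) of 3'UTR sequences.
#' @param mirna miRNA sequence.
#' @param min_site_type Weakest site type that still qualifies a UTR
#'   (default `"7mer-A1"`).
#' @return Character vector of qualifying UTR ids.
#' @export
target_set <- function(utrs, mirna, min_site_type = "7mer-A1") {
  if (!min_site_type %in% names(site_rank)) stop("unknown site type")
  utrs <- setNames(as.character(utrs), names(utrs))
  if (is.null(names(utrs))) stop("utrs must be named")
  thr <- site_rank[[min_site_type]]
  hit <- vapply(utrs, function(u) {
    s <- scan_sites(u, mirna)
    any(site_rank[s$site_type] >= thr)
  }, TRUE)
  names(utrs)[hit]
}

#' Compare targets of a canonical miRNA and its 5' isomiR
#'
#' The isomiR is obtained by deleting `shift5` leading bases, which shifts
#' the seed window and hence the predicted target repertoire.
#'
#' @param utrs Named character vector of 3'UTRs.
#' @param canonical_seq Canonical miRNA sequence.
#' @param shift5 Number of leading bases deleted (>= 1).
#' @param min_site_type Site-type threshold passed to [target_set()].
#' @return List: `seeds` (canonical and isomiR 7-nt seeds, RNA),
#'   `regions` (named integers: only_canonical, common, only_isomir),
#'   `targets` (list of the two target-id sets).
#' @export
compare_canonical_vs_isomir <- function(utrs, canonical_seq, shift5 = 1L,
                                        min_site_type = "7mer-A1") {
  can <- as_dna(canonical_seq)
  if (shift5 < 1L) stop("shift5 must be >= 1")
  if (shift5 >= nchar(can) - 7L)
    stop("shift5 = ", shift5, " leaves fewer than 8 bases; no seed")
  iso <- substr(can, shift5 + 1L, nchar(can))
  t_can <- target_set(utrs, can, min_site_type)
  t_iso <- target_set(utrs, iso, min_site_type)
  list(seeds = c(canonical = as_rna(extract_seed(can)),
                 isomir = as_rna(extract_seed(iso))),
       regions = c(only_canonical = length(setdiff(t_can, t_iso)),
                   common = length(intersect(t_can, t_iso)),
                   only_isomir = length(setdiff(t_iso, t_can))),
       targets = list(canonical = t_can, isomir = t_iso))
}
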