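# Internal sequence helpers. All sequences are held internally in the DNA
# alphabet (U -> T on input); RNA rendering (T -> U) happens only in
# user-facing display strings.

as_dna <- function(x) chartr("uU", "tT", toupper(x))

as_rna <- function(x) chartr("tT", "uU", toupper(x))

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_clean_dna <- function(x) !grepl("[^ACGT]", x)

#' @importFrom stats cor quantile rnorm runif rpois rnbinom dbinom dnbinom
#'   hclust as.dist cutree sd setNames var
#' @importFrom utils read.delim write.table head combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a
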