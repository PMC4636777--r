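#' Preprocessing parameters
#'
#' Bundles the read-cleaning thresholds. The quality gate is strict: a read
#' is kept only if every base quality is strictly greater than `min_phred`
#' (switch to a non-strict gate with `strict = FALSE`).
#'
#' @param adapter 3' adapter sequence (DNA text); required for trimming.
#' @param min_phred Per-base Phred threshold (default 20; kept reads have
#'   all qualities > 20).
#' @param strict If `TRUE` (default) the gate is `> min_phred`, else
#'   `>= min_phred`.
#' @param min_adapter_overlap Minimum aligned adapter prefix length
#'   (default 8).
#' @param max_adapter_mismatch_rate Maximum fraction of mismatching bases in
#'   the aligned adapter prefix (default 0.1).
#' @param min_len Minimum insert length after trimming (default 17).
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(adapter,
                              min_phred = 20L,
                              strict = TRUE,
                              min_adapter_overlap = 8L,
                              max_adapter_mismatch_rate = 0.1,
                              min_len = 17L) {
  stopifnot(min_phred >= 0, min_len >= 1,
            max_adapter_mismatch_rate >= 0, max_adapter_mismatch_rate < 0.5,
            nchar(adapter) >= min_adapter_overlap)
  structure(list(adapter = as_dna(adapter), min_phred = as.integer(min_phred),
                 strict = strict,
                 min_adapter_overlap = as.integer(min_adapter_overlap),
                 max_adapter_mismatch_rate = max_adapter_mismatch_rate,
                 min_len = as.integer(min_len)),
            class = "preprocess_params")
}

#' Per-base quality filter
#'
#' @param quality Integer vector of Phred scores for one read.
#' @param min_phred Threshold; the read passes iff `min(quality) > min_phred`
#'   (or `>=` when `strict = FALSE`). An empty read is discarded.
#' @param strict Use strict inequality (default `TRUE`).
#' @return Logical: keep the read?
#' @export
quality_filter <- function(quality, min_phred = 20L, strict = TRUE) {
  if (length(quality) == 0L) return(FALSE)
  if (strict) min(quality) > min_phred else min(quality) >= min_phred
}

#' Locate and trim the 3' adapter
#'
#' Scans alignment offsets left to right and accepts the leftmost position
#' where an adapter prefix of length >= `min_adapter_overlap` aligns with a
#' mismatch rate <= `max_adapter_mismatch_rate`; the prefix may be shortened
#' when the adapter runs off the 3' end of the read. The sequence upstream
#' of the accepted position is the insert.
#'
#' @param sequence Read sequence (DNA text).
#' @param params A [preprocess_params()] object.
#' @return The trimmed insert (possibly `""`), or `NA_character_` when no
#'   qualifying adapter match exists (such reads are discarded by
#'   [preprocess_sample()]).
#' @export
find_and_trim_adapter <- function(sequence, params) {
  n <- nchar(sequence)
  ad <- params$adapter
  la <- nchar(ad)
  ov <- params$min_adapter_overlap
  if (n < ov) return(NA_character_)
  sq <- utf8ToInt(sequence)
  av <- utf8ToInt(ad)
  for (i in seq_len(n - ov + 1L)) {
    len <- min(la, n - i + 1L)
    mm <- sum(sq[i:(i + len - 1L)] != av[seq_len(len)])
    if (mm / len <= params$max_adapter_mismatch_rate) {
      return(substr(sequence, 1L, i - 1L))
    }
  }
  NA_character_
}

#' Length and ambiguity filter
#'
#' @param sequence Trimmed insert.
#' @param min_len Minimum length (default 17 nt).
#' @return Logical: `TRUE` iff the insert is at least `min_len` long and
#'   contains only A/C/G/T.
#' @export
length_ambiguity_filter <- function(sequence, min_len = 17L) {
  nchar(sequence) >= min_len && is_clean_dna(sequence)
}

#' Clean one library
#'
#' Applies the chain quality filter -> adapter trim -> length/ambiguity
#' filter and tallies survivors at each step.
#'
#' @param records FASTQ records ([read_fastq()]) or a path to a FASTQ file.
#' @param params A [preprocess_params()] object.
#' @return List with `valid` (character vector of cleaned insert sequences)
#'   and `tally` (named integers: raw, pass_quality, adapter_found, valid).
#' @export
preprocess_sample <- function(records, params) {
  if (is.character(records) && length(records) == 1L)
    records <- read_fastq(records)
  raw <- length(records)
  keep_q <- vapply(records, function(r)
    quality_filter(r$quality, params$min_phred, params$strict), TRUE)
  seqs <- vapply(records[keep_q], function(r) as_dna(r$sequence), "")
  trimmed <- vapply(seqs, find_and_trim_adapter, "", params = params,
                    USE.NAMES = FALSE)
  found <- !is.na(trimmed)
  inserts <- trimmed[found]
  valid <- inserts[vapply(inserts, length_ambiguity_filter, TRUE,
                          min_len = params$min_len, USE.NAMES = FALSE)]
  list(valid = valid,
       tally = c(raw = raw, pass_quality = sum(keep_q),
                 adapter_found = sum(found), valid = length(valid)))
}

#' Collapse cleaned reads to unique tags
#'
#' One tag per distinct sequence across all samples, with per-sample counts.
#' Tags are ordered by decreasing total count, ties broken by sequence, and
#' assigned ids `tag1`, `tag2`, ...
#'
#' @param valid_by_sample Named list (sample_id -> character vector of
#'   cleaned insert sequences).
#' @return A data.frame of class `unique_tags` with columns `tag_id`,
#'   `sequence` and one integer count column per sample.
#' @export
collapse_reads <- function(valid_by_sample) {
  stopifnot(!is.null(names(valid_by_sample)))
  samples <- names(valid_by_sample)
  all_seq <- sort(unique(unlist(valid_by_sample, use.names = FALSE)))
  if (length(all_seq) == 0L) {
    df <- data.frame(tag_id = character(), sequence = character(),
                     stringsAsFactors = FALSE)
    for (s in samples) df[[s]] <- integer()
    class(df) <- c("unique_tags", "data.frame")
    return(df)
  }
  cnt <- vapply(valid_by_sample, function(v)
    tabulate(match(v, all_seq), nbins = length(all_seq)),
    integer(length(all_seq)))
  cnt <- matrix(cnt, nrow = length(all_seq),
                dimnames = list(NULL, samples))
  ord <- order(-rowSums(cnt), all_seq)
  df <- data.frame(tag_id = paste0("tag", seq_along(all_seq)),
                   sequence = all_seq[ord], stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(cnt[ord, , drop = FALSE]))
  rownames(df) <- NULL
  class(df) <- c("unique_tags", "data.frame")
  df
}

#' Run the full preprocessing chain over several libraries
#'
#' @param fastq_by_sample Named list: sample_id -> FASTQ path or record list.
#' @param params A [preprocess_params()] object.
#' @return List with `tags` (a `unique_tags` data.frame, see
#'   [collapse_reads()]) and `report` (per-sample data.frame with columns
#'   sample_id, raw, pass_quality, adapter_found, valid, unique_tags, plus a
#'   pooled `total` row).
#' @export
preprocess_libraries <- function(fastq_by_sample, params) {
  per <- lapply(fastq_by_sample, preprocess_sample, params = params)
  tags <- collapse_reads(lapply(per, `[[`, "valid"))
  rep_rows <- do.call(rbind, lapply(per, function(x) as.data.frame(t(x$tally))))
  report <- data.frame(sample_id = names(per), rep_rows,
                       stringsAsFactors = FALSE, row.names = NULL)
  report$unique_tags <- vapply(report$sample_id, function(s)
    if (nrow(tags)) sum(tags[[s]] > 0L) else 0L, 0L, USE.NAMES = FALSE)
  total <- data.frame(sample_id = "total",
                      t(colSums(report[, -1, drop = FALSE])))
  total$unique_tags <- nrow(tags)
  report <- rbind(report, total)
  list(tags = tags, report = report)
}

#' Turn unique tags into a count table
#'
#' @param tags A `unique_tags` data.frame.
#' @param groups Named character vector sample_id -> group.
#' @return A [count_table()] (rows named by tag_id).
#' @export
tags_to_count_table <- function(tags, groups) {
  cnt <- as.matrix(tags[, setdiff(names(tags), c("tag_id", "sequence")),
                        drop = FALSE])
  rownames(cnt) <- tags$tag_id
  storage.mode(cnt) <- "integer"
  count_table(cnt, groups)
}
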