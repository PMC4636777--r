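#' Read a FASTQ file into records
#'
#' Parses a four-line-record FASTQ file with Phred+33 quality encoding.
#' Records are returned in file order.
#'
#' @param path Path to an (uncompressed or gzipped) FASTQ file.
#' @return A list with one element per read: `id` (text after `@`, up to the
#'   first whitespace), `sequence` (upper-case DNA text) and `quality`
#'   (integer Phred scores, one per base).
#' @details A record whose quality string length differs from its sequence
#'   length, or whose header/separator lines are malformed, raises an error
#'   naming the (1-based) record index.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(list())
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: ", path, " has ", length(lines),
         " lines (not a multiple of 4); record ",
         length(lines) %/% 4L + 1L, " is truncated")
  }
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- toupper(lines[seq(2L, by = 4L, length.out = n)])
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) stop("malformed FASTQ record ", bad[1L], ": header does not start with '@'")
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) stop("malformed FASTQ record ", bad[1L], ": separator line does not start with '+'")
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) {
    stop("malformed FASTQ record ", bad[1L], ": quality length ",
         nchar(qual[bad[1L]]), " != sequence length ", nchar(seqs[bad[1L]]))
  }
  ids <- sub("\\s.*$", "", substring(hdr, 2L))
  mapply(function(id, s, q) {
    list(id = id, sequence = s, quality = utf8ToInt(q) - 33L)
  }, ids, seqs, qual, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write FASTQ records
#'
#' Inverse of [read_fastq()]: writes four-line records with Phred+33 quality
#' encoding.
#'
#' @param records List of records as returned by [read_fastq()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  lines <- unlist(lapply(records, function(r) {
    c(paste0("@", r$id), r$sequence, "+", intToUtf8(r$quality + 33L))
  }))
  writeLines(lines %||% character(), path)
  invisible(path)
}

#' Load a miRBase-style mature + hairpin reference
#'
#' Reads mature and hairpin FASTA files, normalizes the alphabet to DNA
#' (U -> T), and locates every mature sequence inside the same-species
#' hairpins by exact substring search. The first whitespace-delimited token
#' of each FASTA header is taken as the name, so both bare names and long
#' miRBase headers (`ssc-miR-21 MIMAT...`) are accepted.
#'
#' @param mature_fasta Path to the mature miRNA FASTA.
#' @param hairpin_fasta Path to the hairpin (precursor) FASTA.
#' @param species_primary Species prefix of the study organism (e.g.
#'   `"ssc"`); matures/hairpins whose name starts with this prefix form the
#'   primary annotation universe; all other matures are retained as
#'   other-species ("mammalian") sequences usable for canonical matching
#'   only.
#' @return An object of class `mirna_reference`: a list with
#'   `mature` (data.frame: name, sequence, species, primary),
#'   `hairpin` (data.frame: name, sequence, species) and
#'   `locus` (data.frame: mature, hairpin, start, end; 0-based half-open
#'   coordinates of each exact occurrence of a mature in a same-species
#'   hairpin). A mature absent from every same-species hairpin has no locus
#'   row (usable for canonical matching only) and triggers a warning.
#' @export
load_reference <- function(mature_fasta, hairpin_fasta, species_primary = "ssc") {
  mat <- Biostrings::readBStringSet(mature_fasta)
  hp <- Biostrings::readBStringSet(hairpin_fasta)
  mk <- function(ss) {
    data.frame(
      name = sub("\\s.*$", "", names(ss)),
      sequence = as_dna(as.character(ss)),
      stringsAsFactors = FALSE
    )
  }
  mature <- mk(mat)
  hairpin <- mk(hp)
  if (anyDuplicated(mature$name)) stop("duplicate mature names in ", mature_fasta)
  if (anyDuplicated(hairpin$name)) stop("duplicate hairpin names in ", hairpin_fasta)
  species_of <- function(nm) sub("-.*$", "", nm)
  mature$species <- species_of(mature$name)
  hairpin$species <- species_of(hairpin$name)
  mature$primary <- mature$species == species_primary
  rownames(mature) <- rownames(hairpin) <- NULL

  loci <- vector("list", nrow(mature))
  for (i in seq_len(nrow(mature))) {
    same <- hairpin[hairpin$species == mature$species[i], , drop = FALSE]
    if (!nrow(same)) next
    hits <- lapply(seq_len(nrow(same)), function(j) {
      m <- Biostrings::matchPattern(mature$sequence[i],
                                    Biostrings::DNAString(same$sequence[j]))
      if (!length(m)) return(NULL)
      data.frame(mature = mature$name[i], hairpin = same$name[j],
                 start = Biostrings::start(m) - 1L,
                 end = Biostrings::end(m),
                 stringsAsFactors = FALSE)
    })
    loci[[i]] <- do.call(rbind, hits)
  }
  locus <- do.call(rbind, loci)
  if (is.null(locus)) {
    locus <- data.frame(mature = character(), hairpin = character(),
                        start = integer(), end = integer(),
                        stringsAsFactors = FALSE)
  }
  rownames(locus) <- NULL
  missing <- setdiff(mature$name[mature$primary], locus$mature)
  if (length(missing)) {
    warning(length(missing), " primary-species mature(s) not found in any ",
            "same-species hairpin (canonical matching only): ",
            paste(head(missing, 5L), collapse = ", "))
  }
  structure(list(mature = mature, hairpin = hairpin, locus = locus,
                 species_primary = species_primary),
            class = "mirna_reference")
}

#' @export
print.mirna_reference <- function(x, ...) {
  cat("miRNA reference:", nrow(x$mature), "matures (",
      sum(x$mature$primary), "primary '", x$species_primary, "'),",
      nrow(x$hairpin), "hairpins,", nrow(x$locus), "mature loci\n")
  invisible(x)
}

#' Write collapsed unique tags as FASTA
#'
#' Headers follow the collapsed-read convention `>tagID_xTOTAL` where TOTAL
#' is the tag's summed count over all samples.
#'
#' @param tags A `unique_tags` object (see [collapse_reads()]) or a
#'   data.frame with columns `tag_id`, `sequence` and numeric count columns.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(tags, path) {
  df <- as.data.frame(tags)
  if (nrow(df) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  total <- tag_totals(df)
  lines <- as.vector(rbind(paste0(">", df$tag_id, "_x", total), df$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Read a collapsed-tag FASTA written by [write_collapsed_fasta()]
#'
#' @param path FASTA path with `>tagID_xTOTAL` headers.
#' @return Data frame with columns `tag_id`, `sequence`, `total`.
#' @export
read_collapsed_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (!length(ss)) {
    return(data.frame(tag_id = character(), sequence = character(),
                      total = integer(), stringsAsFactors = FALSE))
  }
  hdr <- names(ss)
  m <- regmatches(hdr, regexec("^(.*)_x(\\d+)$", hdr))
  bad <- which(lengths(m) != 3L)
  if (length(bad)) stop("header ", bad[1L], " ('", hdr[bad[1L]],
                        "') does not match '>id_xCOUNT'")
  data.frame(
    tag_id = vapply(m, `[`, "", 2L),
    sequence = as_dna(as.character(ss)),
    total = as.integer(vapply(m, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
}

tag_totals <- function(df) {
  cnt <- df[, setdiff(names(df), c("tag_id", "sequence")), drop = FALSE]
  cnt <- cnt[, vapply(cnt, is.numeric, TRUE), drop = FALSE]
  if (!ncol(cnt)) stop("no count columns found")
  as.integer(round(rowSums(cnt)))
}

#' Read a sample sheet (TSV or YAML)
#'
#' A sample sheet maps libraries to experimental groups. TSV sheets need
#' columns `sample_id` and `group` (and optionally `fastq_path`); YAML
#' sheets are a list of `samples:` entries with the same fields.
#'
#' @param path Sheet path; format chosen by `.yml`/`.yaml` extension.
#' @return A data.frame (sample_id, group, fastq_path) with an attribute
#'   `group_sizes` (named integer vector).
#' @export
read_sample_sheet <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    entries <- y$samples %||% y
    df <- do.call(rbind, lapply(entries, function(e) {
      data.frame(sample_id = e$sample_id, group = e$group,
                 fastq_path = e$fastq_path %||% NA_character_,
                 stringsAsFactors = FALSE)
    }))
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
    if (!"fastq_path" %in% names(df)) df$fastq_path <- NA_character_
    df <- df[, c("sample_id", "group", "fastq_path")]
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_ids in sample sheet")
  attr(df, "group_sizes") <- table(df$group) |> c()
  df
}

#' Construct a count table
#'
#' Light container pairing a tags-by-samples integer count matrix with the
#' sample-to-group mapping, analogous to a DGEList.
#'
#' @param counts Non-negative integer matrix, rows = tags, columns = samples
#'   (dimnames required).
#' @param groups Named character vector mapping sample_id -> group; names
#'   must cover `colnames(counts)`.
#' @return An object of class `count_table` with elements `counts` and
#'   `groups`.
#' @export
count_table <- function(counts, groups) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    stop("counts must have column (sample) names")
  if (is.null(rownames(counts)) && nrow(counts) > 0L)
    rownames(counts) <- paste0("tag", seq_len(nrow(counts)))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (!all(colnames(counts) %in% names(groups)))
    stop("groups must name every sample in counts")
  groups <- groups[colnames(counts)]
  structure(list(counts = counts, groups = groups), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", nrow(x$counts), "tags x", ncol(x$counts), "samples;",
      "groups:", paste(sprintf("%s(%d)", names(table(x$groups)),
                               table(x$groups)), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Write / read a count table as TSV
#'
#' First column `tag_id`, remaining columns samples. Group labels are kept
#' in a companion sample sheet, not in the TSV.
#'
#' @param ct A `count_table`.
#' @param path TSV path.
#' @return `path` invisibly (write); for the reader, a counts matrix.
#' @export
write_count_tsv <- function(ct, path) {
  df <- data.frame(tag_id = rownames(ct$counts), ct$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_tsv
#' @export
read_count_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}
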