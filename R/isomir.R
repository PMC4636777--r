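#' Classify tag-vs-mature interval offsets
#'
#' Given the 0-based half-open intervals of a tag and of a mature miRNA on
#' the same hairpin, derives the 5' and 3' end modifications. With
#' `d5 = tag_start - mature_start`: a positive `d5` is a 5' deletion of
#' `d5` bases, a negative one a 5' addition. With
#' `d3 = tag_end - mature_end`: positive is a 3' addition, negative a 3'
#' deletion. Modified bases are read off the hairpin sequence.
#'
#' @param tag_interval,mature_interval Integer vectors `c(start, end)`,
#'   0-based half-open, on the same hairpin.
#' @param hairpin_seq Hairpin sequence (DNA text) the intervals refer to.
#' @return List with `end5` and `end3` (each `list(kind, n, bases)` where
#'   kind is `"ADD"`, `"DEL"` or `"none"`) and `category` (one of
#'   `"canonical"`, `"isomir_3p_only"`, `"isomir_5p_only"`, `"isomir_both"`).
#' @export
classify_offsets <- function(tag_interval, mature_interval, hairpin_seq) {
  ts <- tag_interval[1]; te <- tag_interval[2]
  ms <- mature_interval[1]; me <- mature_interval[2]
  if (te <= ms || me <= ts)
    stop("tag and mature intervals do not overlap; not an isomiR of this mature")
  sub0 <- function(a, b) substr(hairpin_seq, a + 1L, b)  # 0-based half-open
  d5 <- ts - ms
  end5 <- if (d5 > 0) {
    list(kind = "DEL", n = d5, bases = sub0(ms, ts))
  } else if (d5 < 0) {
    list(kind = "ADD", n = -d5, bases = sub0(ts, ms))
  } else list(kind = "none", n = 0L, bases = "")
  d3 <- te - me
  end3 <- if (d3 > 0) {
    list(kind = "ADD", n = d3, bases = sub0(me, te))
  } else if (d3 < 0) {
    list(kind = "DEL", n = -d3, bases = sub0(te, me))
  } else list(kind = "none", n = 0L, bases = "")
  category <- if (d5 == 0 && d3 == 0) "canonical"
  else if (d5 == 0) "isomir_3p_only"
  else if (d3 == 0) "isomir_5p_only"
  else "isomir_both"
  list(end5 = end5, end3 = end3, category = category)
}

#' Extract the seed (positions 2-8) of a miRNA/isomiR sequence
#'
#' @param sequence miRNA sequence (RNA or DNA text), length >= 8.
#' @return The 7-nt seed, in the alphabet of the input.
#' @export
extract_seed <- function(sequence) {
  if (any(nchar(sequence) < 8L)) stop("sequence shorter than 8 nt has no seed")
  substr(sequence, 2L, 8L)
}

#' Human-readable isomiR name
#'
#' Canonical tags keep the parent name; end modifications are appended in
#' the conventional style, e.g. `miR-191-5p DEL G` (3' deletion of G) or
#' `miR-140-3p 5' DEL U`; for both-end variants the 5' clause comes first.
#' Bases are rendered in the RNA alphabet.
#'
#' @param parent Parent mature miRNA name.
#' @param end5,end3 Modification descriptors as returned by
#'   [classify_offsets()].
#' @return Display name (character).
#' @export
name_isomir <- function(parent, end5, end3) {
  parts <- parent
  if (end5$kind != "none")
    parts <- c(parts, paste0("5' ", end5$kind, " ", as_rna(end5$bases)))
  if (end3$kind != "none")
    parts <- c(parts, paste(end3$kind, as_rna(end3$bases)))
  paste(parts, collapse = " ")
}

none_end <- list(kind = "none", n = 0L, bases = "")

ann_row <- function(tag_id, sequence, parent, category,
                    end5 = none_end, end3 = none_end, template = FALSE) {
  seed <- if (nchar(sequence) >= 8L) extract_seed(as_rna(sequence)) else NA_character_
  display <- if (category %in% c("canonical", "mammalian_canonical")) parent
  else if (startsWith(category, "isomir")) name_isomir(parent, end5, end3)
  else NA_character_
  data.frame(tag_id = tag_id, sequence = sequence, parent = parent,
             category = category,
             end5_kind = end5$kind, end5_n = end5$n, end5_bases = as_rna(end5$bases),
             end3_kind = end3$kind, end3_n = end3$n, end3_bases = as_rna(end3$bases),
             template = template, seed = seed, display_name = display,
             stringsAsFactors = FALSE)
}

#' Annotate a single tag against the reference cascade
#'
#' Cascade: (1) exact equality with a primary-species mature gives
#' `canonical`; (2) exact full-length occurrence inside a primary-species
#' hairpin at an interval overlapping a recorded mature locus gives a
#' template isomiR of that mature, classified by [classify_offsets()];
#' (3) exact equality with an other-species mature gives
#' `mammalian_canonical`; otherwise `unannotated`. A tag whose qualifying
#' hairpin intervals overlap loci of more than one distinct mature name is
#' `ambiguous` and excluded from isomiR statistics; multiple loci of the
#' same mature (multi-copy miRNAs) are not ambiguous, and the locus with the
#' smallest total end offset is used.
#'
#' @param tag_id Tag identifier.
#' @param sequence Tag sequence (DNA text).
#' @param reference A `mirna_reference` from [load_reference()].
#' @return One-row annotation data.frame (see [annotate_tags()]).
#' @export
annotate_tag <- function(tag_id, sequence, reference) {
  sequence <- as_dna(sequence)
  mat <- reference$mature
  # (1) canonical: exact match to a primary-species mature
  hit <- mat$name[mat$primary & mat$sequence == sequence]
  if (length(hit) > 1L)
    return(ann_row(tag_id, sequence, NA_character_, "ambiguous"))
  if (length(hit) == 1L)
    return(ann_row(tag_id, sequence, hit, "canonical", template = TRUE))
  # (2) template isomiR: substring of a primary hairpin overlapping a locus
  hps <- reference$hairpin[reference$hairpin$species == reference$species_primary, ,
                           drop = FALSE]
  cand <- list()
  for (j in seq_len(nrow(hps))) {
    m <- Biostrings::matchPattern(sequence, Biostrings::DNAString(hps$sequence[j]))
    if (!length(m)) next
    loc <- reference$locus[reference$locus$hairpin == hps$name[j], , drop = FALSE]
    for (k in seq_along(m)) {
      ts <- Biostrings::start(m)[k] - 1L; te <- Biostrings::end(m)[k]
      ov <- loc[loc$start < te & ts < loc$end, , drop = FALSE]
      if (nrow(ov)) {
        ov$tag_start <- ts; ov$tag_end <- te
        ov$hp_seq <- hps$sequence[j]
        cand[[length(cand) + 1L]] <- ov
      }
    }
  }
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    if (length(unique(cand$mature)) > 1L)
      return(ann_row(tag_id, sequence, NA_character_, "ambiguous"))
    cand$off <- abs(cand$tag_start - cand$start) + abs(cand$tag_end - cand$end)
    best <- cand[order(cand$off, cand$hairpin, cand$start)[1L], ]
    cl <- classify_offsets(c(best$tag_start, best$tag_end),
                           c(best$start, best$end), best$hp_seq)
    return(ann_row(tag_id, sequence, best$mature, cl$category,
                   cl$end5, cl$end3, template = TRUE))
  }
  # (3) other-species canonical
  hit <- mat$name[!mat$primary & mat$sequence == sequence]
  if (length(hit))
    return(ann_row(tag_id, sequence, hit[order(hit)][1L], "mammalian_canonical",
                   template = TRUE))
  ann_row(tag_id, sequence, NA_character_, "unannotated")
}

#' Annotate a set of unique tags
#'
#' @param tags A `unique_tags` data.frame ([collapse_reads()]) or any
#'   data.frame with `tag_id` and `sequence` columns.
#' @param reference A `mirna_reference`.
#' @param rescue_mature_fasta Optional FASTA of a newer mature set; tags
#'   left `unannotated` by the main cascade are re-tested for exact equality
#'   against it and, when hit, reported as `canonical` with the newer name.
#' @return Annotation data.frame, one row per tag: tag_id, sequence, parent,
#'   category, end5_kind/n/bases, end3_kind/n/bases, template, seed,
#'   display_name. Modification bases and seeds are rendered as RNA.
#' @export
annotate_tags <- function(tags, reference, rescue_mature_fasta = NULL) {
  ann <- do.call(rbind, lapply(seq_len(nrow(tags)), function(i)
    annotate_tag(tags$tag_id[i], tags$sequence[i], reference)))
  if (!is.null(rescue_mature_fasta)) {
    res <- Biostrings::readBStringSet(rescue_mature_fasta)
    rnames <- sub("\\s.*$", "", names(res))
    rseq <- as_dna(as.character(res))
    idx <- which(ann$category == "unannotated")
    for (i in idx) {
      hit <- rnames[rseq == ann$sequence[i]]
      if (length(hit) == 1L) {
        ann[i, ] <- ann_row(ann$tag_id[i], ann$sequence[i], hit,
                            "canonical", template = TRUE)
      }
    }
  }
  rownames(ann) <- NULL
  ann
}

#' Summarize template isomiR modifications
#'
#' Tallies the isomiR set (canonical, ambiguous, mammalian and unannotated
#' tags excluded) by modification site, kind and size, mirroring the usual
#' reporting: share of 3'-only / 5'-only / both-end variants, ADD vs DEL per
#' end, and modification-size spectrum (1-6 nt; larger offsets are counted
#' in row `">6"`).
#'
#' @param annotations Annotation data.frame from [annotate_tags()].
#' @return List of data.frames: `by_site` (site, n, percent over all
#'   isomiRs), `by_kind` (end, kind, n, percent over modifications at that
#'   end), `by_size` (end, kind, size, n, percent over that end's
#'   modifications of that kind).
#' @export
summarize_modifications <- function(annotations) {
  iso <- annotations[annotations$category %in%
                       c("isomir_3p_only", "isomir_5p_only", "isomir_both"), ,
                     drop = FALSE]
  if (!nrow(iso)) {
    empty <- data.frame()
    return(list(by_site = empty, by_kind = empty, by_size = empty))
  }
  site_levels <- c(isomir_3p_only = "3p_only", isomir_5p_only = "5p_only",
                   isomir_both = "both")
  site <- factor(site_levels[iso$category], levels = site_levels)
  n_site <- table(site)
  by_site <- data.frame(site = names(n_site), n = as.integer(n_site),
                        percent = 100 * as.integer(n_site) / nrow(iso),
                        stringsAsFactors = FALSE)

  ends <- rbind(
    data.frame(end = "3p", kind = iso$end3_kind, n = iso$end3_n),
    data.frame(end = "5p", kind = iso$end5_kind, n = iso$end5_n)
  )
  ends <- ends[ends$kind != "none", , drop = FALSE]
  by_kind <- do.call(rbind, lapply(split(ends, ends$end), function(e) {
    tab <- table(factor(e$kind, levels = c("ADD", "DEL")))
    data.frame(end = e$end[1], kind = names(tab), n = as.integer(tab),
               percent = 100 * as.integer(tab) / nrow(e),
               stringsAsFactors = FALSE)
  }))
  ends$size <- ifelse(ends$n <= 6L, as.character(ends$n), ">6")
  by_size <- do.call(rbind, lapply(split(ends, list(ends$end, ends$kind),
                                         drop = TRUE), function(e) {
    tab <- table(factor(e$size, levels = c(as.character(1:6), ">6")))
    data.frame(end = e$end[1], kind = e$kind[1], size = names(tab),
               n = as.integer(tab), percent = 100 * as.integer(tab) / nrow(e),
               stringsAsFactors = FALSE)
  }))
  rownames(by_kind) <- rownames(by_size) <- NULL
  list(by_site = by_site, by_kind = by_kind, by_size = by_size)
}

#' Group tags into seed families and sum normalized counts
#'
#' A seed family is the set of tags (canonical miRNA plus isomiRs) sharing
#' an identical 7-nt seed; family expression is the per-sample sum of the
#' members' normalized counts.
#'
#' @param annotations Annotation data.frame ([annotate_tags()]); rows with
#'   missing seeds are skipped.
#' @param normalized_counts Numeric matrix (tags x samples) of normalized
#'   counts, rows named by tag_id.
#' @return List with `families` (data.frame: seed, n_members, plus one sum
#'   column per sample) and `members` (named list seed -> tag_ids).
#' @export
build_seed_families <- function(annotations, normalized_counts) {
  ann <- annotations[!is.na(annotations$seed), , drop = FALSE]
  ann <- ann[ann$tag_id %in% rownames(normalized_counts), , drop = FALSE]
  members <- split(ann$tag_id, ann$seed)
  sums <- t(vapply(members, function(ids)
    colSums(normalized_counts[ids, , drop = FALSE]),
    numeric(ncol(normalized_counts))))
  fam <- data.frame(seed = names(members),
                    n_members = lengths(members),
                    sums, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(fam) <- NULL
  list(families = fam[order(-fam$n_members, fam$seed), ], members = members)
}
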