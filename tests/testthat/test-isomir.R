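ref <- toy_reference()
matA <- ref$mature$sequence[ref$mature$name == "ssc-miR-A"]
hpA <- ref$hairpin$sequence[ref$hairpin$name == "ssc-mir-A"]
locA <- ref$locus[ref$locus$mature == "ssc-miR-A", ]

test_that("classify_offsets derives end modifications from interval arithmetic", {
  m <- c(10L, 31L)
  # 3' deletion of the last base
  cl <- classify_offsets(c(10L, 30L), m, hpA)
  expect_equal(cl$category, "isomir_3p_only")
  expect_equal(cl$end3, list(kind = "DEL", n = 1L, bases = substr(hpA, 31, 31)))
  expect_equal(cl$end5$kind, "none")
  # 3' addition of the next hairpin base
  cl <- classify_offsets(c(10L, 32L), m, hpA)
  expect_equal(cl$end3, list(kind = "ADD", n = 1L, bases = substr(hpA, 32, 32)))
  # 5' deletion of the first base (U in RNA rendering)
  cl <- classify_offsets(c(11L, 31L), m, hpA)
  expect_equal(cl$category, "isomir_5p_only")
  expect_equal(cl$end5, list(kind = "DEL", n = 1L, bases = "T"))
  # both ends; zero offsets are canonical; non-overlap refused
  expect_equal(classify_offsets(c(9L, 30L), m, hpA)$category, "isomir_both")
  expect_equal(classify_offsets(m, m, hpA)$category, "canonical")
  expect_error(classify_offsets(c(0L, 5L), m, hpA), "overlap")
})

test_that("classification agrees with brute-force enumeration of hairpin substrings", {
  # enumerate every >= 17 nt substring of hpA overlapping the mature locus and
  # verify the template property: applying the classified offsets to the
  # mature interval reproduces the substring
  ms <- locA$start; me <- locA$end
  for (s in 0:(nchar(hpA) - 17)) {
    for (e in (s + 17):nchar(hpA)) {
      if (e <= ms || me <= s) next
      cl <- classify_offsets(c(s, e), c(ms, me), hpA)
      s2 <- ms + switch(cl$end5$kind, DEL = cl$end5$n, ADD = -cl$end5$n, 0L)
      e2 <- me + switch(cl$end3$kind, ADD = cl$end3$n, DEL = -cl$end3$n, 0L)
      expect_identical(c(s2, e2), c(s, e))
      expect_identical(substr(hpA, s2 + 1, e2), substr(hpA, s + 1, e))
    }
  }
})

test_that("extract_seed returns positions 2-8", {
  expect_equal(extract_seed("UACCACAGG"), "ACCACAG")
  expect_equal(extract_seed("ACCACAGGG"), "CCACAGG")
  expect_equal(extract_seed("AAAAAAAA"), "AAAAAAA")
  expect_error(extract_seed("AAAAAAA"), "shorter")
})

test_that("display names follow the field convention", {
  del_g <- list(kind = "DEL", n = 1L, bases = "G")
  del_u <- list(kind = "DEL", n = 1L, bases = "T")
  none <- list(kind = "none", n = 0L, bases = "")
  expect_equal(name_isomir("miR-191-5p", none, del_g), "miR-191-5p DEL G")
  expect_equal(name_isomir("miR-140-3p", del_u, none), "miR-140-3p 5' DEL U")
  expect_equal(name_isomir("miR-1", del_u, del_g), "miR-1 5' DEL U DEL G")
  expect_equal(name_isomir("miR-1", none, none), "miR-1")
})

test_that("annotation cascade: canonical, isomiR, ambiguous, mammalian, unannotated", {
  tagseq <- function(s, e) substr(hpA, s + 1, e)  # 0-based half-open
  ms <- locA$start; me <- locA$end
  a <- annotate_tag("t1", matA, ref)
  expect_equal(a$category, "canonical")
  expect_equal(a$parent, "ssc-miR-A")
  expect_equal(a$end5_kind, "none")
  expect_equal(a$display_name, "ssc-miR-A")

  a <- annotate_tag("t2", tagseq(ms, me - 1L), ref)  # 3' shifted by -1
  expect_equal(a$category, "isomir_3p_only")
  expect_equal(a$end3_kind, "DEL")
  expect_equal(a$end3_n, 1L)

  # substring of hpC overlapping both matC5 and matC3 loci
  hpC <- ref$hairpin$sequence[ref$hairpin$name == "ssc-mir-C"]
  amb <- substr(hpC, 14, 31)   # interval [13, 31) hits both loci
  expect_equal(annotate_tag("t3", amb, ref)$category, "ambiguous")

  hsa <- ref$mature$sequence[ref$mature$name == "hsa-miR-X"]
  a <- annotate_tag("t4", hsa, ref)
  expect_equal(a$category, "mammalian_canonical")
  expect_equal(a$parent, "hsa-miR-X")

  expect_equal(annotate_tag("t5", strrep("ACGTT", 4), ref)$category,
               "unannotated")
})

test_that("multi-copy matures are assigned, not ambiguous", {
  matB <- ref$mature$sequence[ref$mature$name == "ssc-miR-B"]
  a <- annotate_tag("t1", substr(matB, 1, nchar(matB) - 1), ref)
  expect_equal(a$category, "isomir_3p_only")
  expect_equal(a$parent, "ssc-miR-B")
})

test_that("seeds and template flag are carried on the annotation", {
  a <- annotate_tag("t1", matA, ref)
  expect_equal(a$seed, "ACCACAG")   # RNA rendering of positions 2-8
  expect_true(a$template)
  # 5' DEL shifts the seed window
  a5 <- annotate_tag("t2", substr(matA, 2, nchar(matA)), ref)
  expect_equal(a5$category, "isomir_5p_only")
  expect_equal(a5$seed, "CCACAGG")
  expect_equal(a5$display_name, "ssc-miR-A 5' DEL U")
})

test_that("rescue pass annotates canonical-less tags against a newer mature set", {
  novel <- strrep("TGCA", 5)
  expect_equal(annotate_tag("t1", novel, ref)$category, "unannotated")
  rescue <- write_fasta(c("ssc-miR-new" = novel))
  tags <- data.frame(tag_id = "t1", sequence = novel, stringsAsFactors = FALSE)
  ann <- annotate_tags(tags, ref, rescue_mature_fasta = rescue)
  expect_equal(ann$category, "canonical")
  expect_equal(ann$parent, "ssc-miR-new")
})

test_that("round-trip: annotation recovers generator truth on unambiguous tags", {
  cfg <- sim_config(rng_seed = 5, n_mirnas = 12)
  sim <- simulate_reference(cfg)
  reads <- simulate_reads(sim, 600, cfg)
  tru <- unique(reads$truth[, c("insert", "parent", "category",
                                "end5_kind", "end5_n", "end3_kind", "end3_n")])
  # drop inserts generated under two different labels (intrinsically ambiguous)
  tru <- tru[!tru$insert %in% tru$insert[duplicated(tru$insert)], ]
  tags <- data.frame(tag_id = paste0("t", seq_len(nrow(tru))),
                     sequence = tru$insert, stringsAsFactors = FALSE)
  ann <- annotate_tags(tags, sim$reference)
  ok <- ann$category != "ambiguous"
  expect_gt(mean(ok), 0.95)
  expected_cat <- ifelse(tru$category == "none", "canonical",
                         paste0("isomir_", tru$category))
  expect_equal(ann$category[ok], expected_cat[ok])
  expect_equal(ann$parent[ok], tru$parent[ok])
  expect_equal(ann$end5_kind[ok], tru$end5_kind[ok])
  expect_equal(ann$end5_n[ok], tru$end5_n[ok])
  expect_equal(ann$end3_kind[ok], tru$end3_kind[ok])
  expect_equal(ann$end3_n[ok], tru$end3_n[ok])
})

test_that("modification summary matches an independent counting oracle", {
  set.seed(9)
  cats <- sample(c("isomir_3p_only", "isomir_5p_only", "isomir_both",
                   "canonical", "ambiguous"), 300, TRUE)
  mk_end <- function(active) {
    kind <- ifelse(active, sample(c("ADD", "DEL"), 300, TRUE), "none")
    n <- ifelse(active, sample(1:6, 300, TRUE), 0L)
    list(kind = kind, n = as.integer(n))
  }
  e5 <- mk_end(cats %in% c("isomir_5p_only", "isomir_both"))
  e3 <- mk_end(cats %in% c("isomir_3p_only", "isomir_both"))
  ann <- data.frame(tag_id = paste0("t", 1:300), category = cats,
                    end5_kind = e5$kind, end5_n = e5$n,
                    end3_kind = e3$kind, end3_n = e3$n,
                    stringsAsFactors = FALSE)
  s <- summarize_modifications(ann)
  iso <- cats %in% c("isomir_3p_only", "isomir_5p_only", "isomir_both")
  expect_equal(sum(s$by_site$n), sum(iso))
  expect_equal(s$by_site$n[s$by_site$site == "3p_only"],
               sum(cats == "isomir_3p_only"))
  expect_equal(s$by_site$percent,
               100 * s$by_site$n / sum(iso))
  # ADD/DEL split on the 3' end, counted by hand
  n_add3 <- sum(e3$kind == "ADD" & iso)
  n_mod3 <- sum(e3$kind != "none" & iso)
  expect_equal(s$by_kind$n[s$by_kind$end == "3p" & s$by_kind$kind == "ADD"],
               n_add3)
  expect_equal(s$by_kind$percent[s$by_kind$end == "3p" & s$by_kind$kind == "ADD"],
               100 * n_add3 / n_mod3)
  # size spectrum sums back to the modification counts
  expect_equal(sum(s$by_size$n), sum(e3$kind != "none" & iso) +
                 sum(e5$kind != "none" & iso))
  expect_equal(nrow(summarize_modifications(ann[ann$category == "canonical", ])$by_site), 0L)
})

test_that("seed families group by identical seed and conserve mass", {
  tags <- data.frame(
    tag_id = c("t1", "t2", "t3", "t4"),
    sequence = c(matA,                                # canonical
                 paste0(matA, "A"),                   # 3' ADD, same seed
                 substr(matA, 1, nchar(matA) - 1),    # 3' DEL, same seed
                 substr(matA, 2, nchar(matA))),       # 5' DEL, shifted seed
    stringsAsFactors = FALSE)
  ann <- annotate_tags(tags, ref)
  cpm <- matrix(c(10, 20, 5, 40, 1, 2, 3, 4), 4, 2,
                dimnames = list(tags$tag_id, c("s1", "s2")))
  fam <- build_seed_families(ann, cpm)
  expect_equal(nrow(fam$families), 2L)
  f1 <- fam$families[fam$families$seed == "ACCACAG", ]
  expect_equal(f1$n_members, 3L)
  expect_equal(f1$s1, 10 + 20 + 5)
  expect_setequal(fam$members[["CCACAGG"]], "t4")
  # mass conservation over families
  expect_equal(sum(fam$families$s1) + 0, sum(cpm[, "s1"]))
  expect_equal(sum(fam$families$s2), sum(cpm[, "s2"]))
})
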