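#' Simulation configuration
#'
#' Ground-truthed generator settings for references, reads and count
#' matrices. Defaults emulate a typical small-RNA library: ~22-nt matures
#' embedded in ~80-nt hairpins, a modification mix in which 3'-only
#' variants dominate (about 69% of modified tags), deletions outnumbering
#' additions at both ends (66% at 3', 71% at 5') with 1-nt changes most
#' frequent, a 3' sequencing adapter appended to every insert, and
#' truncated-Gaussian per-base qualities high enough that only deliberately
#' planted reads fail a strict >20 Phred gate.
#'
#' @param rng_seed Integer seed; every generator is deterministic under it.
#' @param n_mirnas Number of simulated miRNAs (one mature per hairpin).
#' @param hairpin_len,mature_len Hairpin and mature lengths (nt).
#' @param mod_distribution Probabilities over modification sites
#'   (`none`, `3p_only`, `5p_only`, `both`); must sum to 1.
#' @param del_prob_3p,del_prob_5p Probability that a modified end is a
#'   deletion (rather than an addition).
#' @param size_distribution Probabilities of modification sizes 1-6 nt.
#' @param adapter 3' adapter ligated to every insert.
#' @param q_mean,q_sd,q_min Per-base quality model (truncated Gaussian).
#' @param low_quality_rate Fraction of reads planted with one base at or
#'   below Phred 20 (exercises the quality gate).
#' @param min_insert_len Smallest insert the generator will emit (sizes are
#'   resampled when a deletion would go below it).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(rng_seed = 1L,
                       n_mirnas = 50L,
                       hairpin_len = 80L,
                       mature_len = 22L,
                       mod_distribution = c(none = 0.30, "3p_only" = 0.48,
                                            "5p_only" = 0.07, both = 0.15),
                       del_prob_3p = 0.66,
                       del_prob_5p = 0.71,
                       size_distribution = c("1" = 0.50, "2" = 0.20,
                                             "3" = 0.12, "4" = 0.08,
                                             "5" = 0.06, "6" = 0.04),
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       q_mean = 36, q_sd = 3, q_min = 2,
                       low_quality_rate = 0.02,
                       min_insert_len = 17L) {
  stopifnot(abs(sum(mod_distribution) - 1) < 1e-9,
            abs(sum(size_distribution) - 1) < 1e-9,
            all(c("none", "3p_only", "5p_only", "both") %in%
                  names(mod_distribution)))
  structure(as.list(environment()), class = "sim_config")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

#' Simulate a miRBase-style reference with known loci
#'
#' Generates random hairpins, each with one embedded mature at a recorded
#' 0-based half-open locus, leaving >= 6 nt of flank on both sides so that
#' template additions up to 6 nt exist. Matures are resampled until their
#' seeds are pairwise distinct and each mature occurs exactly once in its
#' hairpin.
#'
#' @param config A [sim_config()].
#' @return List: `reference` (a `mirna_reference`, species prefix `sim`)
#'   and `truth` (the locus data.frame).
#' @export
simulate_reference <- function(config) {
  if (config$mature_len >= config$hairpin_len)
    stop("mature_len must be smaller than hairpin_len")
  set.seed(config$rng_seed)
  n <- config$n_mirnas
  hl <- config$hairpin_len; ml <- config$mature_len
  flank <- min(6L, (hl - ml) %/% 2L)
  seen_seeds <- character()
  hp <- character(n); mat <- character(n); st <- integer(n)
  for (i in seq_len(n)) {
    for (try in 1:200) {
      h <- rand_dna(hl)
      pos <- seq(flank, hl - ml - flank)
      s <- pos[sample.int(length(pos), 1L)]
      m <- substr(h, s + 1L, s + ml)
      seed <- substr(m, 2L, 8L)
      occ <- length(Biostrings::matchPattern(m, Biostrings::DNAString(h)))
      if (!(seed %in% seen_seeds) && occ == 1L) break
      if (try == 200L) stop("could not draw a unique mature; relax settings")
    }
    seen_seeds <- c(seen_seeds, seed)
    hp[i] <- h; mat[i] <- m; st[i] <- s
  }
  nm_m <- sprintf("sim-miR-%d", seq_len(n))
  nm_h <- sprintf("sim-mir-%d", seq_len(n))
  locus <- data.frame(mature = nm_m, hairpin = nm_h,
                      start = st, end = st + ml, stringsAsFactors = FALSE)
  ref <- structure(list(
    mature = data.frame(name = nm_m, sequence = mat, species = "sim",
                        primary = TRUE, stringsAsFactors = FALSE),
    hairpin = data.frame(name = nm_h, sequence = hp, species = "sim",
                         stringsAsFactors = FALSE),
    locus = locus, species_primary = "sim"), class = "mirna_reference")
  list(reference = ref, truth = locus)
}

#' Write a reference back to FASTA files
#'
#' @param reference A `mirna_reference`.
#' @param mature_fasta,hairpin_fasta Output paths.
#' @return Invisibly, the two paths.
#' @export
write_reference_fasta <- function(reference, mature_fasta, hairpin_fasta) {
  wr <- function(df, path) {
    writeLines(as.vector(rbind(paste0(">", df$name), df$sequence)), path)
  }
  wr(reference$mature, mature_fasta)
  wr(reference$hairpin, hairpin_fasta)
  invisible(c(mature_fasta, hairpin_fasta))
}

draw_mod <- function(kind_del_prob, size_probs) {
  kind <- if (runif(1) < kind_del_prob) "DEL" else "ADD"
  size <- sample(as.integer(names(size_probs)), 1L, prob = size_probs)
  list(kind = kind, n = size)
}

#' Simulate adapter-ligated small-RNA reads with per-read truth
#'
#' Each read draws a parent miRNA, a modification category / kind / size
#' from the configured distributions, builds the template variant from the
#' parent hairpin (so every insert is an exact hairpin substring), appends
#' the 3' adapter and draws a quality string. Sizes incompatible with the
#' hairpin bounds or the minimum insert length are resampled (bounded
#' retries, falling back to an unmodified read).
#'
#' @param sim Result of [simulate_reference()].
#' @param n_reads Number of reads.
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$rng_seed` for the read
#'   draw (so one reference can feed many libraries).
#' @return List: `records` (FASTQ-style records, see [read_fastq()]) and
#'   `truth` (data.frame: read_id, parent, category, end5_kind, end5_n,
#'   end3_kind, end3_n, insert, planted_lowq).
#' @export
simulate_reads <- function(sim, n_reads, config, seed = NULL) {
  set.seed(seed %||% config$rng_seed)
  ref <- sim$reference
  loc <- ref$locus
  hp_seq <- setNames(ref$hairpin$sequence, ref$hairpin$name)
  n_mir <- nrow(loc)
  cats <- sample(names(config$mod_distribution), n_reads, replace = TRUE,
                 prob = config$mod_distribution)
  parents <- sample.int(n_mir, n_reads, replace = TRUE)
  lowq <- runif(n_reads) < config$low_quality_rate

  rec <- vector("list", n_reads)
  tru <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    li <- loc[parents[i], ]
    h <- hp_seq[[li$hairpin]]
    cat_i <- cats[i]
    e5 <- list(kind = "none", n = 0L); e3 <- list(kind = "none", n = 0L)
    for (try in 1:20) {
      if (cat_i %in% c("5p_only", "both"))
        e5 <- draw_mod(config$del_prob_5p, config$size_distribution)
      if (cat_i %in% c("3p_only", "both"))
        e3 <- draw_mod(config$del_prob_3p, config$size_distribution)
      s <- li$start + switch(e5$kind, DEL = e5$n, ADD = -e5$n, 0L)
      e <- li$end + switch(e3$kind, ADD = e3$n, DEL = -e3$n, 0L)
      if (s >= 0L && e <= nchar(h) && (e - s) >= config$min_insert_len) break
      if (try == 20L) {  # fall back to the unmodified mature
        cat_i <- "none"
        e5 <- list(kind = "none", n = 0L); e3 <- list(kind = "none", n = 0L)
        s <- li$start; e <- li$end
      }
    }
    insert <- substr(h, s + 1L, e)
    full <- paste0(insert, config$adapter)
    q <- pmin(40L, pmax(config$q_min,
                        as.integer(round(rnorm(nchar(full),
                                               config$q_mean, config$q_sd)))))
    if (lowq[i]) q[sample.int(length(q), 1L)] <- sample(2:20, 1L)
    rec[[i]] <- list(id = paste0("r", i), sequence = full, quality = q)
    tru[[i]] <- data.frame(read_id = paste0("r", i), parent = li$mature,
                           category = cat_i,
                           end5_kind = e5$kind, end5_n = e5$n,
                           end3_kind = e3$kind, end3_n = e3$n,
                           insert = insert, planted_lowq = lowq[i],
                           stringsAsFactors = FALSE)
  }
  list(records = rec, truth = do.call(rbind, tru))
}

#' Simulate a group-structured negative-binomial count table
#'
#' Per-tag baseline means are drawn log-uniformly from `mu_range`; a
#' fraction `de_frac` of tags gets a planted log2 fold change (alternating
#' sign) applied in group `de_group`; counts are negative-binomial with
#' common dispersion `phi` (Poisson when `phi = 0`).
#'
#' @param group_sizes Named integer vector, group -> number of samples
#'   (>= 2 groups).
#' @param n_tags Number of tags.
#' @param mu_range Baseline mean-count range (default 20-2000).
#' @param phi Common NB dispersion (default 0.05).
#' @param de_frac Fraction of tags with planted differential expression.
#' @param de_lfc Magnitude of the planted log2 fold change.
#' @param de_group Group receiving the fold change (default: last group).
#' @param seed Integer seed.
#' @return List: `table` (a [count_table()]) and `truth` (data.frame:
#'   tag_id, mu, lfc).
#' @export
simulate_counts <- function(group_sizes, n_tags = 1000L,
                            mu_range = c(20, 2000), phi = 0.05,
                            de_frac = 0, de_lfc = 0,
                            de_group = NULL, seed = 1L) {
  if (length(group_sizes) < 2L) stop("need at least 2 groups")
  stopifnot(phi >= 0)
  set.seed(seed)
  de_group <- de_group %||% names(group_sizes)[length(group_sizes)]
  groups <- rep(names(group_sizes), group_sizes)
  sample_ids <- paste0(groups, "_s", unlist(lapply(group_sizes, seq_len)))
  mu <- exp(runif(n_tags, log(mu_range[1]), log(mu_range[2])))
  lfc <- numeric(n_tags)
  n_de <- round(de_frac * n_tags)
  if (n_de > 0) {
    idx <- sample.int(n_tags, n_de)
    lfc[idx] <- de_lfc * rep_len(c(1, -1), n_de)
  }
  cnt <- matrix(0L, n_tags, length(groups),
                dimnames = list(paste0("tag", seq_len(n_tags)), sample_ids))
  for (j in seq_along(groups)) {
    mu_j <- mu * 2^(lfc * (groups[j] == de_group))
    cnt[, j] <- if (phi == 0) rpois(n_tags, mu_j)
    else rnbinom(n_tags, size = 1 / phi, mu = mu_j)
  }
  ct <- count_table(cnt, setNames(groups, sample_ids))
  list(table = ct,
       truth = data.frame(tag_id = rownames(cnt), mu = mu, lfc = lfc,
                          stringsAsFactors = FALSE))
}
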