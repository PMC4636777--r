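#' Expression filter
#'
#' Keeps a tag iff in at least one group the number of samples with count
#' >= `min_reads` reaches that group's requirement: `min_samples` by
#' default, overridable per group via `group_exceptions` (e.g.
#' `c(CD12 = 3)` when one library of a 4-animal group failed).
#'
#' @param ct A [count_table()].
#' @param min_reads Per-sample read threshold (default 10).
#' @param min_samples Default number of qualifying samples (default 4).
#' @param group_exceptions Named integer vector of per-group overrides.
#' @return The filtered `count_table`.
#' @export
expression_filter <- function(ct, min_reads = 10L, min_samples = 4L,
                              group_exceptions = integer()) {
  stopifnot(min_reads >= 1)
  groups <- ct$groups
  req <- function(g) {
    r <- if (g %in% names(group_exceptions)) group_exceptions[[g]] else min_samples
    size <- sum(groups == g)
    if (r > size) stop("group ", g, " has ", size,
                       " samples but requires ", r)
    r
  }
  keep <- rep(FALSE, nrow(ct$counts))
  for (g in unique(groups)) {
    cols <- which(groups == g)
    n_ok <- rowSums(ct$counts[, cols, drop = FALSE] >= min_reads)
    keep <- keep | (n_ok >= req(g))
  }
  count_table(ct$counts[keep, , drop = FALSE], groups)
}

#' TMM normalization
#'
#' Computes per-sample scaling factors by the trimmed mean of M-values:
#' log2 tag-wise ratios (M) against a reference sample are trimmed (30% each
#' side on M, 5% each side on average log intensity A), averaged with
#' inverse-variance weights, and exponentiated; factors are rescaled so
#' their geometric mean is 1. The reference is the sample whose
#' upper-quartile count fraction is closest to the mean. Normalized counts
#' are counts per million after factor adjustment:
#' `count / (library_size * factor) * 1e6`.
#'
#' @param ct A [count_table()].
#' @param logratio_trim,abundance_trim Two-sided trim fractions on M and A
#'   (defaults 0.3 and 0.05).
#' @return List: `factors` (named numeric), `lib_sizes` (named numeric),
#'   `cpm` (normalized count matrix), `ref_sample`.
#' @export
tmm_normalize <- function(ct, logratio_trim = 0.3, abundance_trim = 0.05) {
  x <- ct$counts
  lib <- colSums(x)
  if (any(lib == 0)) stop("sample(s) with all-zero counts: ",
                          paste(colnames(x)[lib == 0], collapse = ", "))
  if (ncol(x) < 2L) stop("TMM needs at least 2 samples")
  uq <- apply(x, 2L, function(col) quantile(col, 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(x)), function(j) {
    tmm_pair_factor(x[, j], x[, ref], lib[j], lib[ref],
                    logratio_trim, abundance_trim)
  }, 0)
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(x)
  cpm <- sweep(x, 2L, lib * f, "/") * 1e6
  list(factors = f, lib_sizes = lib, cpm = cpm,
       ref_sample = colnames(x)[ref])
}

# One sample's TMM factor against the reference (weighted trimmed mean of
# M-values over tags expressed in both).
tmm_pair_factor <- function(obs, ref, n_obs, n_ref,
                            logratio_trim, abundance_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  p_o <- obs / n_obs; p_r <- ref / n_ref
  M <- log2(p_o / p_r)
  A <- (log2(p_o) + log2(p_r)) / 2
  # asymptotic delta-method variance of M, used as inverse weight
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; v <- v[fin]
  n <- length(M)
  if (!n) return(1)
  if (max(abs(M)) < 1e-6) return(1)
  loM <- floor(n * logratio_trim) + 1L; hiM <- n + 1L - loM
  loA <- floor(n * abundance_trim) + 1L; hiA <- n + 1L - loA
  keep <- rank(M, ties.method = "first") >= loM &
    rank(M, ties.method = "first") <= hiM &
    rank(A, ties.method = "first") >= loA &
    rank(A, ties.method = "first") <= hiA
  if (!any(keep)) return(1)
  2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
}

#' Method-of-moments common dispersion
#'
#' Pooled negative-binomial dispersion: within each group with >= 2
#' replicates, per-tag `max(0, (s^2 - m) / m^2)` on normalized counts, then
#' the mean over all tags and groups with positive mean.
#'
#' @param normalized Numeric matrix of normalized counts (tags x samples).
#' @param groups Named character vector sample -> group (covering columns).
#' @return Dispersion estimate `phi >= 0`; 0 with a warning when no group
#'   has >= 2 replicates.
#' @export
estimate_common_dispersion <- function(normalized, groups) {
  groups <- groups[colnames(normalized)]
  ests <- c()
  for (g in unique(groups)) {
    cols <- which(groups == g)
    if (length(cols) < 2L) next
    m <- rowMeans(normalized[, cols, drop = FALSE])
    s2 <- apply(normalized[, cols, drop = FALSE], 1L, var)
    ok <- m > 0
    ests <- c(ests, pmax(0, (s2[ok] - m[ok]) / m[ok]^2))
  }
  if (!length(ests)) {
    warning("no group with >= 2 replicates; dispersion set to 0")
    return(0)
  }
  mean(ests)
}

#' Two-group negative-binomial exact test
#'
#' Library sizes are first equalized: counts are scaled to the geometric
#' mean of the effective library sizes (library size x TMM factor) and
#' rounded. For each tag the two group sums are compared conditionally on
#' their total: under the null the total splits between groups in
#' proportion to their sample numbers, each group sum being a sum of
#' independent NB variables with common dispersion `phi` (binomial split
#' when `phi = 0`). The two-sided p-value sums the probabilities of all
#' splits at most as probable as the observed one. The fold change is
#' `log2((meanB + eps) / (meanA + eps))` on the CPM scale with a
#' half-count pseudo-count `eps`.
#'
#' @param ct A [count_table()].
#' @param group_a,group_b Group labels to contrast (fold change is B vs A).
#' @param phi Common NB dispersion (e.g. from
#'   [estimate_common_dispersion()]).
#' @param norm Optional result of [tmm_normalize()] on `ct` (recomputed if
#'   missing).
#' @return Data frame: tag_id, mean_a, mean_b (CPM), log2fc, p.
#' @export
nb_exact_test <- function(ct, group_a, group_b, phi = 0, norm = NULL) {
  stopifnot(phi >= 0)
  groups <- ct$groups
  ca <- which(groups == group_a); cb <- which(groups == group_b)
  if (!length(ca) || !length(cb)) stop("contrast group absent from table")
  if (is.null(norm)) norm <- tmm_normalize(ct)
  eff <- norm$lib_sizes * norm$factors
  N <- exp(mean(log(eff[c(ca, cb)])))
  adj <- round(sweep(ct$counts[, c(ca, cb), drop = FALSE], 2L,
                     N / eff[c(ca, cb)], "*"))
  na <- length(ca); nb <- length(cb)
  ia <- seq_len(na); ib <- na + seq_len(nb)
  sa <- rowSums(adj[, ia, drop = FALSE])
  sb <- rowSums(adj[, ib, drop = FALSE])
  p <- vapply(seq_along(sa), function(i)
    exact_split_pvalue(sa[i], sb[i], na, nb, phi), 0)
  mean_a <- rowMeans(norm$cpm[, ca, drop = FALSE])
  mean_b <- rowMeans(norm$cpm[, cb, drop = FALSE])
  eps <- 0.5 / N * 1e6
  data.frame(tag_id = rownames(ct$counts),
             mean_a = mean_a, mean_b = mean_b,
             log2fc = log2((mean_b + eps) / (mean_a + eps)),
             p = p, row.names = NULL, stringsAsFactors = FALSE)
}

# Conditional two-sided exact p for an observed split (sa, sb) of t = sa+sb
# between na and nb samples with common dispersion phi; probabilities of
# outcomes <= the observed outcome's probability are summed.
exact_split_pvalue <- function(sa, sb, na, nb, phi) {
  t <- sa + sb
  if (t == 0) return(1)
  a <- 0:t
  if (phi <= 0) {
    logp <- dbinom(a, t, na / (na + nb), log = TRUE)
  } else {
    mu <- t / (na + nb)   # per-sample mean under the null
    size_a <- na / phi; size_b <- nb / phi
    logp <- dnbinom(a, size = size_a, mu = na * mu, log = TRUE) +
      dnbinom(t - a, size = size_b, mu = nb * mu, log = TRUE)
    logp <- logp - log(sum(exp(logp - max(logp)))) - max(logp)
  }
  obs <- logp[sa + 1L]
  min(1, sum(exp(logp[logp <= obs + 1e-12])))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return FDR-adjusted values in the original order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1 | is.na(pvals)))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  if (m == 0L) return(numeric())
  o <- order(pvals)
  q <- pvals[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  q[order(o)]
}

#' Differential-expression call for one contrast
#'
#' Runs [tmm_normalize()], [estimate_common_dispersion()] (unless `phi`
#' given), [nb_exact_test()] and [bh_adjust()], then flags significance at
#' the usual thresholds |log2FC| >= 1 and FDR < 0.05.
#'
#' @param ct A (filtered) [count_table()].
#' @param group_a,group_b Contrast groups (fold change is B vs A).
#' @param min_abs_log2fc Fold-change cutoff (default 1).
#' @param max_fdr FDR cutoff (default 0.05).
#' @param phi Optional fixed dispersion; estimated when `NULL`.
#' @return Data frame: tag_id, mean_a, mean_b, log2fc, p, fdr, significant.
#' @export
de_test <- function(ct, group_a, group_b, min_abs_log2fc = 1,
                    max_fdr = 0.05, phi = NULL) {
  norm <- tmm_normalize(ct)
  if (is.null(phi)) {
    cols <- ct$groups %in% c(group_a, group_b)
    phi <- estimate_common_dispersion(norm$cpm[, cols, drop = FALSE],
                                      ct$groups[cols])
  }
  res <- nb_exact_test(ct, group_a, group_b, phi = phi, norm = norm)
  res$fdr <- bh_adjust(res$p)
  res$significant <- abs(res$log2fc) >= min_abs_log2fc & res$fdr < max_fdr
  attr(res, "phi") <- phi
  res
}

#' Venn region counts for 2-3 labelled sets
#'
#' @param de_lists Named list of 2 or 3 character vectors (e.g. significant
#'   tag ids per contrast).
#' @return Named integer vector of disjoint region counts; regions partition
#'   the union (e.g. `only_A`, `only_B`, `A_and_B` for two sets).
#' @export
venn_sets <- function(de_lists) {
  k <- length(de_lists)
  if (k < 2L || k > 3L) stop("venn_sets takes 2 or 3 sets")
  labs <- names(de_lists)
  if (is.null(labs) || any(labs == "")) stop("sets must be named")
  sets <- lapply(de_lists, unique)
  univ <- unique(unlist(sets))
  inset <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1L) inset <- matrix(inset, nrow = 1L)
  pattern <- apply(inset, 1L, function(r) paste(labs[r], collapse = "_and_"))
  regions <- unlist(lapply(seq_len(k), function(n)
    apply(utils::combn(labs, n), 2L, paste, collapse = "_and_")))
  cnt <- setNames(integer(length(regions)), regions)
  tab <- table(pattern)
  cnt[names(tab)] <- as.integer(tab)
  names(cnt)[match(labs, names(cnt))] <- paste0("only_", labs)
  cnt
}
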