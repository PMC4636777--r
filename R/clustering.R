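#' Group-mean expression profiles for clustering
#'
#' Builds the per-group mean log2(CPM + 1) profile matrix, optionally
#' mean-centering each row (standard when comparing expression patterns
#' rather than levels).
#'
#' @param cpm Normalized count matrix (tags x samples).
#' @param groups Named character vector sample -> group.
#' @param center Mean-center rows (default `TRUE`).
#' @return Numeric matrix, rows = tags, columns = groups.
#' @export
profile_matrix <- function(cpm, groups, center = TRUE) {
  groups <- groups[colnames(cpm)]
  lg <- log2(cpm + 1)
  prof <- vapply(unique(groups), function(g)
    rowMeans(lg[, groups == g, drop = FALSE]), numeric(nrow(lg)))
  prof <- matrix(prof, nrow = nrow(lg),
                 dimnames = list(rownames(cpm), unique(groups)))
  if (center) prof <- prof - rowMeans(prof)
  prof
}

#' Pearson correlation distance
#'
#' `d(x, y) = 1 - r(x, y)`, in \[0, 2\]. Rows with zero variance have no
#' defined correlation and are dropped with a warning.
#'
#' @param profiles Numeric matrix, one profile per row (>= 2 columns).
#' @return A symmetric distance matrix over the retained rows.
#' @export
pearson_distance <- function(profiles) {
  stopifnot(ncol(profiles) >= 2L)
  sds <- apply(profiles, 1L, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant profile(s) dropped: ",
            paste(head(rownames(profiles)[sds == 0], 5L), collapse = ", "))
    profiles <- profiles[sds > 0, , drop = FALSE]
  }
  d <- 1 - cor(t(profiles))
  d[d < 0] <- 0  # guard fp noise
  diag(d) <- 0
  d
}

#' Average-linkage hierarchical clustering of a distance matrix
#'
#' Thin wrapper around [stats::hclust()] returning the merge list, heights
#' and leaf order, plus a `cut` helper result when `k` is given.
#'
#' @param distances Symmetric distance matrix (e.g. [pearson_distance()]).
#' @param linkage Linkage method (default `"average"`).
#' @param k Optional number of clusters to cut into.
#' @return List: `hclust` (the stats::hclust object), `merges` (data.frame
#'   a, b, height; negative entries are leaves as in hclust), and
#'   `clusters` (named integer vector) when `k` is given.
#' @export
hcl_cluster <- function(distances, linkage = "average", k = NULL) {
  if (nrow(distances) < 2L) stop("need at least 2 profiles to cluster")
  hc <- hclust(as.dist(distances), method = linkage)
  out <- list(hclust = hc,
              merges = data.frame(a = hc$merge[, 1], b = hc$merge[, 2],
                                  height = hc$height))
  if (!is.null(k)) out$clusters <- cutree(hc, k = k)
  out
}

#' SOTA parameters
#'
#' @param max_clusters Target number of leaf cells (growth stops there).
#' @param max_epochs Training epochs per growth cycle (default 1000).
#' @param lr_winner,lr_parent,lr_sibling Learning rates for the winning
#'   cell, its parent and its sibling (defaults 0.01 / 0.005 / 0.001;
#'   winner >= parent >= sibling required).
#' @param variability_threshold Optional resource threshold: growth also
#'   stops when every leaf's resource (mean member distance) falls below it.
#' @param tol Relative-improvement convergence tolerance per cycle
#'   (default 1e-6).
#' @param rng_seed Seed for the (tiny) symmetry-breaking perturbation at
#'   cell splits.
#' @return List of class `sota_params`.
#' @export
sota_params <- function(max_clusters, max_epochs = 1000L,
                        lr_winner = 0.01, lr_parent = 0.005,
                        lr_sibling = 0.001,
                        variability_threshold = NULL,
                        tol = 1e-6, rng_seed = 1L) {
  stopifnot(lr_winner > 0, lr_winner <= 1,
            lr_winner >= lr_parent, lr_parent >= lr_sibling, lr_sibling > 0)
  structure(list(max_clusters = as.integer(max_clusters),
                 max_epochs = as.integer(max_epochs),
                 lr_winner = lr_winner, lr_parent = lr_parent,
                 lr_sibling = lr_sibling,
                 variability_threshold = variability_threshold,
                 tol = tol, rng_seed = as.integer(rng_seed)),
            class = "sota_params")
}

# correlation distance between one profile and each row of a centroid
# matrix; undefined correlations (constant vectors) count as distance 1
sota_dist <- function(x, centroids) {
  r <- suppressWarnings(as.vector(cor(x, t(centroids))))
  r[is.na(r)] <- 0
  1 - r
}

#' Self-Organizing Tree Algorithm clustering
#'
#' Divisive neural-tree clustering of expression profiles (Herrero &
#' Dopazo style). The tree starts as a root with two leaf cells; each
#' growth cycle trains the leaves over up to `max_epochs` epochs (every
#' profile adapts its winning leaf toward itself, and — when the winner's
#' sibling is a leaf — also the parent and sibling at lower rates), then
#' splits the leaf with the highest resource (mean correlation distance of
#' its members to the cell centroid) into two children seeded at the parent
#' centroid. Growth stops at `max_clusters` leaves or when all resources
#' fall below `variability_threshold`.
#'
#' @param profiles Numeric matrix, one profile per row.
#' @param params A [sota_params()] object.
#' @return List: `clusters` (named integer vector, one leaf id per
#'   profile), `centroids` (leaf centroid matrix), `resources` (per-leaf
#'   mean member distance), `tree` (data.frame of cells: id, parent,
#'   is_leaf).
#' @export
sota <- function(profiles, params) {
  n <- nrow(profiles)
  k <- params$max_clusters
  if (k > n) stop("more clusters requested (", k, ") than profiles (", n, ")")
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("p", seq_len(n))
  if (k == 1L) {
    cl <- setNames(rep(1L, n), rownames(profiles))
    cen <- matrix(colMeans(profiles), nrow = 1L)
    return(list(clusters = cl, centroids = cen,
                resources = mean(sota_dist_rows(profiles, colMeans(profiles))),
                tree = data.frame(id = 1L, parent = NA_integer_,
                                  is_leaf = TRUE)))
  }
  set.seed(params$rng_seed)
  p <- ncol(profiles)
  root_c <- colMeans(profiles)
  cells <- list(id = 1:3, parent = c(NA_integer_, 1L, 1L))
  centroid <- rbind(root_c,
                    root_c + rnorm(p, sd = 1e-6),
                    root_c + rnorm(p, sd = 1e-6))
  is_leaf <- c(FALSE, TRUE, TRUE)

  repeat {
    leaves <- which(is_leaf)
    # train current leaves
    prev_err <- Inf
    for (epoch in seq_len(params$max_epochs)) {
      err <- 0
      for (i in seq_len(n)) {
        x <- profiles[i, ]
        d <- sota_dist(x, centroid[leaves, , drop = FALSE])
        w <- leaves[which.min(d)]
        err <- err + min(d)
        par <- cells$parent[w]
        sib <- setdiff(which(cells$parent == par & cells$id != w), integer())
        centroid[w, ] <- centroid[w, ] + params$lr_winner * (x - centroid[w, ])
        if (length(sib) == 1L && is_leaf[sib]) {
          centroid[par, ] <- centroid[par, ] + params$lr_parent * (x - centroid[par, ])
          centroid[sib, ] <- centroid[sib, ] + params$lr_sibling * (x - centroid[sib, ])
        }
      }
      if (is.finite(prev_err) &&
          abs(prev_err - err) <= params$tol * max(prev_err, 1e-12)) break
      prev_err <- err
    }
    # assignment and per-leaf resource
    assign <- vapply(seq_len(n), function(i)
      leaves[which.min(sota_dist(profiles[i, ], centroid[leaves, , drop = FALSE]))],
      0L)
    resource <- vapply(leaves, function(l) {
      idx <- which(assign == l)
      if (!length(idx)) return(0)
      mean(vapply(idx, function(i)
        sota_dist(profiles[i, ], centroid[l, , drop = FALSE]), 0))
    }, 0)
    if (length(leaves) >= k) break
    if (!is.null(params$variability_threshold) &&
        all(resource < params$variability_threshold)) break
    # split the most variable leaf (ties: lowest id); only split populated cells
    splittable <- leaves[vapply(leaves, function(l) sum(assign == l) > 1L, TRUE)]
    if (!length(splittable)) break
    tgt <- splittable[which.max(resource[match(splittable, leaves)])]
    new_ids <- max(cells$id) + 1:2
    cells$id <- c(cells$id, new_ids)
    cells$parent <- c(cells$parent, tgt, tgt)
    centroid <- rbind(centroid,
                      centroid[tgt, ] + rnorm(p, sd = 1e-6),
                      centroid[tgt, ] + rnorm(p, sd = 1e-6))
    is_leaf[tgt] <- FALSE
    is_leaf <- c(is_leaf, TRUE, TRUE)
  }
  leaves <- which(is_leaf)
  assign <- vapply(seq_len(n), function(i)
    leaves[which.min(sota_dist(profiles[i, ], centroid[leaves, , drop = FALSE]))],
    0L)
  resource <- vapply(leaves, function(l) {
    idx <- which(assign == l)
    if (!length(idx)) return(0)
    mean(vapply(idx, function(i)
      sota_dist(profiles[i, ], centroid[l, , drop = FALSE]), 0))
  }, 0)
  cl <- setNames(match(assign, leaves), rownames(profiles))
  list(clusters = cl,
       centroids = centroid[leaves, , drop = FALSE],
       resources = setNames(resource, seq_along(leaves)),
       tree = data.frame(id = cells$id, parent = cells$parent,
                         is_leaf = is_leaf))
}

sota_dist_rows <- function(profiles, centroid) {
  vapply(seq_len(nrow(profiles)), function(i)
    sota_dist(profiles[i, ], matrix(centroid, nrow = 1L)), 0)
}
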