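#' Principal coordinate analysis
#'
#' Gower double-centering of -d^2/2 followed by eigendecomposition. Axes with
#' eigenvalue above `tol` (relative to the largest) are retained as
#' coordinates scaled by sqrt(eigenvalue); negative eigenvalues are reported,
#' not corrected.
#'
#' @param d a `dist` or square dissimilarity matrix.
#' @param tol relative eigenvalue tolerance for axis retention.
#' @return list with `coords` (samples x axes), `eigenvalues` (all, sorted
#'   decreasing) and `prop_explained` (per retained axis, relative to the sum
#'   of positive eigenvalues).
#' @export
pcoa <- function(d, tol = 1e-8) {
  d <- as_dist_matrix(d)
  m <- as.matrix(d)
  n <- nrow(m)
  a <- -0.5 * m^2
  g <- a - outer(rowMeans(a), colMeans(a), "+") + mean(a)
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  ev <- e$values
  cut <- tol * max(abs(ev), 1e-300)
  keep <- which(ev > cut)
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(ev[keep]), length(keep))
  rownames(coords) <- rownames(m)
  if (length(keep) > 0)
    colnames(coords) <- paste0("PCo", seq_along(keep))
  pos <- sum(ev[ev > cut])
  list(coords = coords, eigenvalues = ev,
       prop_explained = if (pos > 0) ev[keep] / pos else rep(0, length(keep)))
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 NMDS via iterative monotone regression, run from one
#' metric (PCoA) start plus `n_restarts` random starts; the lowest-stress
#' configuration wins.
#'
#' @param d a `dist` or square dissimilarity matrix.
#' @param k embedding dimension (default 2).
#' @param n_restarts number of random starts in addition to the PCoA start.
#' @param seed optional integer seed.
#' @param maxit maximum iterations per start.
#' @return list with `coords`, `stress` (fraction in [0, 1]), `n_restarts`,
#'   `converged` and `degenerate` flags.
#' @export
nmds <- function(d, k = 2, n_restarts = 10, seed = NULL, maxit = 500) {
  d <- as_dist_matrix(d)
  n <- attr(d, "Size")
  if (n <= k + 1) stop("need more samples than k + 1")
  if (max(d) - min(d) < 1e-12) {
    warning("all dissimilarities equal; returning degenerate zero-stress fit")
    coords <- matrix(0, n, k, dimnames = list(attr(d, "Labels"), NULL))
    return(list(coords = coords, stress = 0, n_restarts = n_restarts,
                converged = TRUE, degenerate = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  starts <- vector("list", n_restarts + 1)
  pc <- pcoa(d)$coords
  if (ncol(pc) < k)
    pc <- cbind(pc, matrix(rnorm(n * (k - ncol(pc)), sd = 1e-4), n))
  starts[[1]] <- pc[, seq_len(k), drop = FALSE]
  for (r in seq_len(n_restarts)) starts[[r + 1]] <- matrix(runif(n * k), n, k)
  best <- NULL
  for (init in starts) {
    fit <- vegan::monoMDS(d, y = init, k = k, model = "global",
                          maxit = maxit, smin = 1e-7, sratmax = 1 - 1e-7)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  coords <- best$points
  rownames(coords) <- attr(d, "Labels")
  list(coords = coords, stress = best$stress, n_restarts = n_restarts,
       converged = best$iters < maxit, degenerate = FALSE)
}

ss_within_groups <- function(d2m, groups) {
  ss <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    ss <- ss + sum(d2m[idx, idx]) / (2 * length(idx))
  }
  ss
}

#' PERMANOVA (one-way, free permutation of samples)
#'
#' Anderson's pseudo-F from the distance partition SS_total = sum d^2 / n and
#' within-group sums of squares; significance by free permutation of sample
#' labels: p = (1 + #{F* >= F}) / (1 + n_perm).
#'
#' @param d a `dist` or square dissimilarity matrix.
#' @param groups group labels aligned with the rows of `d`.
#' @param n_perm number of label permutations.
#' @param seed optional integer seed.
#' @param perms optional matrix of permutations (rows = permuted index
#'   vectors), e.g. for exhaustive enumeration; overrides `n_perm`.
#' @return list with `statistic` (pseudo-F), `r2`, `p_perm`, `n_perm`, `df1`,
#'   `df2`, `seed`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL, perms = NULL) {
  d <- as_dist_matrix(d)
  groups <- factor(groups)
  n <- attr(d, "Size")
  if (length(groups) != n) stop("groups length mismatch")
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) == 1))
    warning("group(s) with a single member")
  d2m <- as.matrix(d)^2
  df1 <- nlevels(groups) - 1L
  df2 <- n - nlevels(groups)
  ss_t <- sum(d2m) / (2 * n)
  f_of <- function(idx) {
    ss_w <- ss_within_groups(d2m, groups[idx])
    ((ss_t - ss_w) / df1) / (ss_w / df2)
  }
  f_obs <- f_of(seq_len(n))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(perms)) {
    perms <- t(replicate(n_perm, sample.int(n)))
  }
  f_perm <- apply(perms, 1, f_of)
  ss_w <- ss_within_groups(d2m, groups)
  list(statistic = f_obs, r2 = (ss_t - ss_w) / ss_t,
       p_perm = (1 + sum(f_perm >= f_obs)) / (1 + nrow(perms)),
       n_perm = nrow(perms), df1 = df1, df2 = df2, seed = seed)
}

#' Mantel test
#'
#' Pearson correlation over the off-diagonal pairs of two aligned
#' dissimilarity matrices; one-tailed (greater) significance by simultaneous
#' row/column permutation of the second matrix.
#'
#' @param d1,d2 `dist` objects (or square matrices) with identical labels and
#'   ordering.
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @param perms optional permutation matrix, as in [permanova()].
#' @return list with `statistic` (r), `p_perm`, `n_perm`, `seed`.
#' @export
mantel <- function(d1, d2, n_perm = 999, seed = NULL, perms = NULL) {
  d1 <- as_dist_matrix(d1); d2 <- as_dist_matrix(d2)
  if (attr(d1, "Size") != attr(d2, "Size"))
    stop("matrices differ in size")
  if (!identical(attr(d1, "Labels"), attr(d2, "Labels")))
    stop("matrices differ in labels/order")
  v1 <- as.vector(d1)
  m2 <- as.matrix(d2)
  n <- attr(d1, "Size")
  if (sd(v1) == 0 || sd(as.vector(d2)) == 0)
    stop("zero variance in a dissimilarity matrix")
  r_obs <- cor(v1, as.vector(d2))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(perms)) perms <- t(replicate(n_perm, sample.int(n)))
  lower <- lower.tri(m2)
  r_perm <- apply(perms, 1, function(idx) {
    cor(v1, m2[idx, idx][lower])
  })
  list(statistic = r_obs,
       p_perm = (1 + sum(r_perm >= r_obs)) / (1 + nrow(perms)),
       n_perm = nrow(perms), seed = seed)
}

#' Dominant-OTU matrix with Ward clustering orders
#'
#' Selects dominant OTUs (mean relative abundance at or above
#' `dominance_threshold` in at least one host species), then clusters both
#' OTUs (rows) and samples (columns) of the relative-abundance matrix by
#' Ward's method (Ward.D2 on Euclidean distances).
#'
#' @param tab an [otu_table()].
#' @param meta aligned metadata with a `species` column.
#' @param dominance_threshold mean relative-abundance cutoff (default 0.01).
#' @return list with `matrix` (OTUs x samples, relative abundances),
#'   `otu_order`, `sample_order`, and the two `hclust` objects.
#' @export
ward_cluster_heatmap_data <- function(tab, meta, dominance_threshold = 0.01) {
  validate_otu_table(tab)
  if (!identical(rownames(tab), meta$sample_id))
    stop("metadata not aligned with OTU table")
  rel <- unclass(tab) / rowSums(tab)
  sp_mean <- rowsum(rel, meta$species) / as.vector(table(meta$species))
  dominant <- colnames(rel)[apply(sp_mean, 2, max) >= dominance_threshold]
  if (length(dominant) == 0)
    stop("no OTU reaches mean relative abundance ", dominance_threshold,
         " in any species; lower the threshold")
  m <- t(rel[, dominant, drop = FALSE])  # OTUs x samples
  hr <- hclust(dist(m), method = "ward.D2")
  hc <- hclust(dist(t(m)), method = "ward.D2")
  list(matrix = m,
       otu_order = rownames(m)[hr$order],
       sample_order = colnames(m)[hc$order],
       otu_hclust = hr, sample_hclust = hc)
}
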