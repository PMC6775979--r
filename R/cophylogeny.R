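#' Sample-level cophenetic (patristic) distances from a host tree
#'
#' Expands tip-to-tip patristic distances to sample level: the entry for two
#' samples is the patristic distance between their host species (zero for
#' conspecifics).
#'
#' @param tree rooted host `phylo` with branch lengths.
#' @param species_map named character vector, sample id -> species code.
#' @return a `dist` over samples.
#' @export
cophenetic_distance <- function(tree, species_map) {
  unmapped <- setdiff(unique(species_map), tree$tip.label)
  if (length(unmapped) > 0)
    stop("species not in host tree: ", paste(unmapped, collapse = ", "))
  coph <- ape::cophenetic.phylo(tree)
  m <- coph[species_map, species_map, drop = FALSE]
  dimnames(m) <- list(names(species_map), names(species_map))
  as_dist_matrix(m)
}

#' Procrustes residual sum of squares
#'
#' Least-squares superimposition of configuration `Y` onto reference `X`
#' (translation, uniform scaling, orthogonal rotation/reflection); returns
#' the residual sum of squares m2 after the optimal transform.
#'
#' @param x reference configuration (rows = points).
#' @param y configuration fitted onto `x`; columns are zero-padded to a
#'   common width.
#' @return list with `m2`, `rotation`, `scale`, `translation` diagnostics.
#' @export
procrustes_m2 <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("row count mismatch")
  if (nrow(x) < 3) stop("need at least 3 rows")
  k <- max(ncol(x), ncol(y))
  if (ncol(x) < k) x <- cbind(x, matrix(0, nrow(x), k - ncol(x)))
  if (ncol(y) < k) y <- cbind(y, matrix(0, nrow(y), k - ncol(y)))
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- scale(y, center = TRUE, scale = FALSE)
  ssy <- sum(yc^2)
  if (ssy == 0) return(list(m2 = sum(xc^2), rotation = diag(k), scale = 0,
                            translation = attr(xc, "scaled:center")))
  sv <- svd(crossprod(yc, xc))
  rot <- sv$u %*% t(sv$v)
  s <- sum(sv$d) / ssy
  m2 <- sum(xc^2) - sum(sv$d)^2 / ssy
  list(m2 = max(m2, 0), rotation = rot, scale = s,
       translation = attr(xc, "scaled:center"))
}

#' PACo: Procrustean test of cophylogenetic signal
#'
#' Both distance matrices are PCoA-scaled; the microbiota configuration is
#' fitted onto the host-phylogeny configuration and the Procrustes residual
#' m2 is compared with a null built by permuting whole samples (rows) of the
#' microbiota configuration: p = (1 + #{m2* <= m2}) / (1 + n_perm).
#'
#' @param d_host sample-level host cophenetic `dist`
#'   (see [cophenetic_distance()]).
#' @param d_micro community dissimilarity `dist`, same labels and order.
#' @param n_perm number of permutations (the reference analysis uses 10,000).
#' @param seed optional integer seed.
#' @return list with `m2`, `p_perm`, `n_perm`, `seed`.
#' @export
paco_test <- function(d_host, d_micro, n_perm = 10000, seed = NULL) {
  d_host <- as_dist_matrix(d_host); d_micro <- as_dist_matrix(d_micro)
  if (!identical(attr(d_host, "Labels"), attr(d_micro, "Labels")))
    stop("matrices differ in labels/order")
  x <- pcoa(d_host)$coords
  y <- pcoa(d_micro)$coords
  # normalize both configurations to unit total sum of squares so that m2 is
  # invariant to the overall scale of either distance matrix
  x <- x / sqrt(sum(scale(x, scale = FALSE)^2))
  y <- y / sqrt(sum(scale(y, scale = FALSE)^2))
  m2_obs <- procrustes_m2(x, y)$m2
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(y)
  m2_perm <- numeric(n_perm)
  for (b in seq_len(n_perm))
    m2_perm[b] <- procrustes_m2(x, y[sample.int(n), , drop = FALSE])$m2
  list(m2 = m2_obs,
       p_perm = (1 + sum(m2_perm <= m2_obs)) / (1 + n_perm),
       n_perm = n_perm, seed = seed)
}

#' PACo over a posterior sample of host trees
#'
#' Runs [paco_test()] once per host tree (cophenetic distances recomputed per
#' tree) and pools: mean m2, median p. Per-tree values are retained.
#'
#' @param host_trees `multiPhylo` (or list of `phylo`).
#' @param species_map named character vector, sample id -> species code.
#' @param d_micro community dissimilarity `dist` over the same samples.
#' @param n_perm permutations per tree.
#' @param seed optional integer seed.
#' @return list with pooled `m2`, `p_perm`, plus `per_tree_m2`, `per_tree_p`.
#' @export
paco_over_posterior <- function(host_trees, species_map, d_micro,
                                n_perm = 999, seed = NULL) {
  if (inherits(host_trees, "phylo")) host_trees <- list(host_trees)
  if (length(host_trees) < 1) stop("need at least one host tree")
  if (!is.null(seed)) set.seed(seed)
  m2s <- ps <- numeric(length(host_trees))
  for (i in seq_along(host_trees)) {
    d_host <- cophenetic_distance(host_trees[[i]], species_map)
    res <- paco_test(d_host, d_micro, n_perm = n_perm, seed = NULL)
    m2s[i] <- res$m2; ps[i] <- res$p_perm
  }
  list(m2 = mean(m2s), p_perm = stats::median(ps), n_perm = n_perm,
       per_tree_m2 = m2s, per_tree_p = ps, seed = seed)
}
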