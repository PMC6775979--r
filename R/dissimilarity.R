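check_beta_input <- function(tab) {
  validate_otu_table(tab)
  tot <- rowSums(tab)
  if (any(tot == 0)) stop("zero-sum sample")
  if (length(unique(tot)) > 1)
    warning("samples differ in depth; consider rarefying first")
  invisible(tab)
}

#' Bray-Curtis dissimilarity
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i), bounded in [0, 1].
#'
#' @param tab an [otu_table()] (ideally rarefied to even depth; a warning is
#'   issued otherwise).
#' @return a `dist` over samples.
#' @export
bray_curtis <- function(tab) {
  check_beta_input(tab)
  as_dist_matrix(as.matrix(vegan::vegdist(unclass(tab), method = "bray")))
}

#' Binary Jaccard dissimilarity
#'
#' d = 1 - |A intersect B| / |A union B| on OTU presence sets.
#'
#' @inheritParams bray_curtis
#' @return a `dist` over samples.
#' @export
jaccard_binary <- function(tab) {
  check_beta_input(tab)
  as_dist_matrix(as.matrix(
    vegan::vegdist(unclass(tab), method = "jaccard", binary = TRUE)))
}

# Per-edge descendant read mass for every sample: one post-order pass.
# Returns n_edge x n_sample matrix; tree tips absent from the table carry 0.
edge_sample_mass <- function(tab, tree) {
  missing_tip <- setdiff(colnames(tab), tree$tip.label)
  if (length(missing_tip) > 0)
    stop("OTU(s) not in bacterial tree: ",
         paste(head(missing_tip, 5), collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (sum(tree$edge.length) <= 0)
    stop("tree total branch length must be > 0")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  ns <- nrow(tab)
  node_mass <- matrix(0, ntip + nnode, ns)
  idx <- match(tree$tip.label, colnames(tab))
  have <- !is.na(idx)
  node_mass[which(have), ] <- t(unclass(tab)[, idx[have], drop = FALSE])
  tr <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1]; chi <- tr$edge[k, 2]
    node_mass[par, ] <- node_mass[par, ] + node_mass[chi, ]
  }
  # edge k of tr leads to child node tr$edge[k, 2]
  list(mass = node_mass[tr$edge[, 2], , drop = FALSE],
       lengths = tr$edge.length, totals = rowSums(tab))
}

#' Unweighted UniFrac
#'
#' For each sample pair, the fraction of total branch length leading
#' exclusively to tips present in only one of the two samples, out of the
#' branch length leading to tips present in either. Uses the tree as rooted;
#' tips absent from the table carry no branch mass.
#'
#' @param tab an [otu_table()]; every OTU must be a tip of `tree`.
#' @param tree rooted `phylo` with branch lengths.
#' @return a `dist` over samples.
#' @export
unifrac_unweighted <- function(tab, tree) {
  check_beta_input(tab)
  em <- edge_sample_mass(tab, tree)
  pres <- em$mass > 0
  n <- nrow(tab)
  d <- matrix(0, n, n, dimnames = list(rownames(tab), rownames(tab)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    a <- pres[, i]; b <- pres[, j]
    union_len <- sum(em$lengths[a | b])
    if (union_len == 0) stop("pair with no branch support")
    d[i, j] <- d[j, i] <- sum(em$lengths[xor(a, b)]) / union_len
  }
  as_dist_matrix(d)
}

#' Weighted UniFrac
#'
#' raw = sum_b l_b |p_A(b) - p_B(b)| with p(b) the proportion of a sample's
#' reads descending from branch b. The normalized form (default) divides by
#' sum_b l_b (p_A(b) + p_B(b)), bounding the index in [0, 1].
#'
#' @inheritParams unifrac_unweighted
#' @param normalized divide by the abundance-weighted total branch length
#'   (default `TRUE`).
#' @return a `dist` over samples.
#' @export
unifrac_weighted <- function(tab, tree, normalized = TRUE) {
  check_beta_input(tab)
  em <- edge_sample_mass(tab, tree)
  p <- sweep(em$mass, 2, em$totals, "/")
  n <- nrow(tab)
  d <- matrix(0, n, n, dimnames = list(rownames(tab), rownames(tab)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    num <- sum(em$lengths * abs(p[, i] - p[, j]))
    if (normalized) {
      den <- sum(em$lengths * (p[, i] + p[, j]))
      d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
    } else d[i, j] <- d[j, i] <- num
  }
  as_dist_matrix(d)
}

#' All four community dissimilarity indices
#'
#' Convenience wrapper returning Bray-Curtis, binary Jaccard, and unweighted
#' plus (normalized) weighted UniFrac in one list.
#'
#' @inheritParams unifrac_unweighted
#' @return named list of `dist` objects.
#' @export
beta_diversity <- function(tab, tree) {
  list(bray = bray_curtis(tab),
       jaccard = jaccard_binary(tab),
       uunifrac = unifrac_unweighted(tab, tree),
       wunifrac = unifrac_weighted(tab, tree, normalized = TRUE))
}
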