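# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately take the slow, literal route so they share no
# code path with the package implementations they check.

# random OTU table over the tips of a random tree
random_unifrac_instance <- function(n_tips = 8, n_samples = 2) {
  tree <- ape::rtree(n_tips)
  counts <- t(vapply(seq_len(n_samples), function(i)
    rmultinom(1, 60, runif(n_tips)^3)[, 1], integer(n_tips)))
  dimnames(counts) <- list(paste0("s", seq_len(n_samples)), tree$tip.label)
  counts[rowSums(counts) == 0, 1] <- 1L
  list(tab = otu_table(counts), tree = tree)
}

# per-branch tip-descendant classification, one branch at a time
unifrac_oracle <- function(tab, tree, weighted = FALSE, normalized = TRUE) {
  n <- nrow(tab)
  labs <- rownames(tab)
  desc <- phangorn::Descendants(tree, tree$edge[, 2], "tips")
  tot <- rowSums(tab)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    num <- den <- 0
    for (k in seq_along(tree$edge.length)) {
      tips <- intersect(tree$tip.label[desc[[k]]], colnames(tab))
      ai <- sum(tab[i, tips])
      bj <- sum(tab[j, tips])
      l <- tree$edge.length[k]
      if (!weighted) {
        if ((ai > 0) != (bj > 0)) num <- num + l
        if (ai > 0 || bj > 0) den <- den + l
      } else {
        num <- num + l * abs(ai / tot[i] - bj / tot[j])
        den <- den + l * (ai / tot[i] + bj / tot[j])
      }
    }
    val <- if (weighted && !normalized) num else num / den
    d[i, j] <- d[j, i] <- val
  }
  d
}

# agglomerative Ward by explicit ESS recomputation over every candidate merge
ward_oracle_merges <- function(x) {
  ess <- function(idx) {
    if (length(idx) == 1) return(0)
    xc <- x[idx, , drop = FALSE]
    sum(sweep(xc, 2, colMeans(xc))^2)
  }
  clusters <- as.list(seq_len(nrow(x)))
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1))
      for (j in seq(i + 1, length(clusters))) {
        delta <- ess(c(clusters[[i]], clusters[[j]])) -
          ess(clusters[[i]]) - ess(clusters[[j]])
        if (is.null(best) || delta < best$delta)
          best <- list(i = i, j = j, delta = delta)
      }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges[[length(merges) + 1]] <- merged
    clusters[[best$i]] <- merged
    clusters[[best$j]] <- NULL
  }
  merges
}

# hclust merge table -> list of merged index sets, for comparison
hclust_merge_sets <- function(h) {
  sets <- list()
  out <- list()
  for (r in seq_len(nrow(h$merge))) {
    get <- function(v) if (v < 0) -v else sets[[v]]
    s <- sort(c(get(h$merge[r, 1]), get(h$merge[r, 2])))
    sets[[r]] <- s
    out[[r]] <- s
  }
  out
}

# Procrustes m2 by coarse-to-fine grid search over rotation angle (2-D),
# reflections included; optimal scale is closed-form given the rotation.
procrustes_grid_oracle <- function(x, y) {
  xc <- scale(as.matrix(x), scale = FALSE)
  yc <- scale(as.matrix(y), scale = FALSE)
  ssx <- sum(xc^2); ssy <- sum(yc^2)
  m2_at <- function(theta, refl) {
    r <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    if (refl) r <- r %*% diag(c(1, -1))
    num <- sum(xc * (yc %*% r))
    ssx - num^2 / ssy
  }
  lo <- 0; hi <- 2 * pi; best <- Inf
  for (round in 1:5) {
    thetas <- seq(lo, hi, length.out = 721)
    vals_f <- vapply(thetas, m2_at, 0, refl = FALSE)
    vals_t <- vapply(thetas, m2_at, 0, refl = TRUE)
    if (min(vals_f) <= min(vals_t)) {
      k <- which.min(vals_f); refl_best <- FALSE
    } else {
      k <- which.min(vals_t); refl_best <- TRUE
    }
    vals <- if (refl_best) vals_t else vals_f
    best <- min(best, vals[k])
    step <- thetas[2] - thetas[1]
    lo <- thetas[k] - 2 * step; hi <- thetas[k] + 2 * step
  }
  best
}

# all permutations of 1..n (n small), rows = permutations
all_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_perms(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# tiny aligned community fixture with metadata
tiny_community <- function(seed = 1, n = 12, n_otus = 15) {
  set.seed(seed)
  counts <- t(vapply(seq_len(n), function(i)
    rmultinom(1, 400, runif(n_otus)^2)[, 1], integer(n_otus)))
  dimnames(counts) <- list(sprintf("s%02d", seq_len(n)),
                           sprintf("o%02d", seq_len(n_otus)))
  counts[rowSums(counts) == 0, 1] <- 1L
  meta <- data.frame(sample_id = rownames(counts),
                     species = rep(c("A", "B", "C"), length.out = n),
                     locality_id = rep(c("L1", "L2"), length.out = n),
                     lat = runif(n, 48, 51), lon = runif(n, 12, 19))
  list(tab = otu_table(counts), meta = meta)
}
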