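test_that("PCoA reproduces Euclidean configurations and reports eigenvalues", {
  set.seed(2)
  pts <- matrix(rnorm(14), 7, 2,
                dimnames = list(paste0("s", 1:7), NULL))
  d <- as_dist_matrix(as.matrix(dist(pts)))
  pc <- pcoa(d)
  expect_equal(as.matrix(dist(pc$coords)), as.matrix(d), tolerance = 1e-8,
               ignore_attr = TRUE)
  # cross-check eigenvalues against the base R implementation
  cs <- cmdscale(d, k = 2, eig = TRUE)
  expect_equal(sort(pc$eigenvalues, decreasing = TRUE)[1:2],
               sort(cs$eig, decreasing = TRUE)[1:2], tolerance = 1e-8)
  # Euclidean input: no meaningfully negative eigenvalue
  expect_gt(min(pc$eigenvalues), -1e-8)

  # three collinear points at 0, 1, 2: single positive eigenvalue 2
  m <- as.matrix(dist(c(0, 1, 2)))
  dimnames(m) <- list(letters[1:3], letters[1:3])
  pc3 <- pcoa(as_dist_matrix(m))
  expect_equal(ncol(pc3$coords), 1)
  expect_equal(max(pc3$eigenvalues), 2, tolerance = 1e-10)
  expect_lt(max(abs(pc3$eigenvalues[-1])), 1e-10)

  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  pcz <- pcoa(as_dist_matrix(z))
  expect_true(all(abs(pcz$eigenvalues) < 1e-12))
})

test_that("NMDS recovers low-dimensional structure and improves with restarts", {
  set.seed(4)
  pts <- matrix(rnorm(30), 15, 2, dimnames = list(paste0("s", 1:15), NULL))
  d <- as_dist_matrix(as.matrix(dist(pts)))
  fit <- nmds(d, k = 2, n_restarts = 4, seed = 1)
  expect_lt(fit$stress, 0.01)
  expect_true(fit$converged)

  # more restarts never worsen the returned stress (same seed stream)
  s2 <- nmds(d, k = 2, n_restarts = 2, seed = 9)$stress
  s4 <- nmds(d, k = 2, n_restarts = 4, seed = 9)$stress
  expect_lte(s4, s2 + 1e-12)

  # rank-preserving monotone transform: essentially unchanged stress
  m <- as.matrix(d)^1.7
  dimnames(m) <- dimnames(as.matrix(d))
  s_t <- nmds(as_dist_matrix(m), k = 2, n_restarts = 4, seed = 1)$stress
  expect_lt(abs(s_t - fit$stress), 1e-3)

  z <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(z) <- 0
  expect_warning(fz <- nmds(as_dist_matrix(z), k = 2, seed = 1),
                 "degenerate")
  expect_true(fz$degenerate)
})

test_that("PERMANOVA p matches exhaustive enumeration and vegan agrees on F", {
  # two tight pairs far apart: F is maximal; exhaustive label permutations
  pts <- c(0, 0.1, 10, 10.1)
  m <- as.matrix(dist(pts))
  dimnames(m) <- list(paste0("s", 1:4), paste0("s", 1:4))
  d <- as_dist_matrix(m)
  g <- c("a", "a", "b", "b")
  # enumerate the 4!/(2!2!) = 6 distinct labelings; drop the identity one
  perms_full <- all_perms(4)
  labstr <- apply(perms_full, 1, function(p) paste(g[p], collapse = ""))
  distinct <- setdiff(unique(labstr), paste(g, collapse = ""))
  perms <- perms_full[match(distinct, labstr), , drop = FALSE]
  res <- permanova(d, g, perms = perms)
  # oracle: direct enumeration of the pseudo-F over the same permutations
  f_direct <- function(gg) {
    d2 <- m^2
    n <- 4
    sst <- sum(d2) / (2 * n)
    ssw <- 0
    for (lv in unique(gg)) {
      idx <- which(gg == lv)
      ssw <- ssw + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ((sst - ssw) / 1) / (ssw / 2)
  }
  f_obs <- f_direct(g)
  f_all <- apply(perms, 1, function(p) f_direct(g[p]))
  p_oracle <- (1 + sum(f_all >= f_obs)) / (1 + nrow(perms))
  expect_equal(res$p_perm, p_oracle)
  expect_equal(res$statistic, f_obs, tolerance = 1e-12)
  # only the group-swapped relabelling ties with the observed F
  expect_equal(p_oracle, 1 / 3, tolerance = 1e-12)

  # F and R2 agree with vegan::adonis2 on a random instance
  set.seed(5)
  tc <- tiny_community(5)
  d2 <- bray_curtis(tc$tab)
  grp <- tc$meta$species
  mine <- permanova(d2, grp, n_perm = 49, seed = 1)
  vg <- vegan::adonis2(d2 ~ grp, permutations = 49)
  expect_equal(mine$statistic, vg$F[1], tolerance = 1e-8)
  expect_equal(mine$r2, vg$R2[1], tolerance = 1e-8)

  expect_error(permanova(d2, rep("a", nrow(tc$meta))), "2 groups")
})

test_that("Mantel statistic and exhaustive p match enumeration and vegan", {
  set.seed(6)
  m1 <- as.matrix(dist(rnorm(4)))
  m2 <- as.matrix(dist(rnorm(4)))
  dimnames(m1) <- dimnames(m2) <- list(paste0("s", 1:4), paste0("s", 1:4))
  d1 <- as_dist_matrix(m1); d2 <- as_dist_matrix(m2)

  perms <- all_perms(4)
  perms <- perms[!apply(perms, 1, identical, 1:4), , drop = FALSE]
  res <- mantel(d1, d2, perms = perms)
  lower <- lower.tri(m1)
  r_obs <- cor(m1[lower], m2[lower])
  r_all <- apply(perms, 1, function(p) cor(m1[lower], m2[p, p][lower]))
  expect_equal(res$statistic, r_obs, tolerance = 1e-12)
  expect_equal(res$p_perm, (1 + sum(r_all >= r_obs)) / (1 + nrow(perms)))

  expect_equal(mantel(d1, d1, n_perm = 9, seed = 1)$statistic, 1)
  mrev <- max(m1) - m1; diag(mrev) <- 0
  dimnames(mrev) <- dimnames(m1)
  expect_equal(mantel(d1, as_dist_matrix(mrev), n_perm = 9,
                      seed = 1)$statistic, -1)

  vg <- vegan::mantel(d1, d2, permutations = 9)
  expect_equal(res$statistic, vg$statistic, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("Ward clustering of dominant OTUs matches the ESS oracle", {
  set.seed(8)
  for (rep in 1:5) {
    x <- matrix(rnorm(10), 5, 2)
    h <- hclust(dist(x), method = "ward.D2")
    expect_identical(hclust_merge_sets(h), ward_oracle_merges(x))
  }

  tc <- tiny_community(9)
  res <- ward_cluster_heatmap_data(tc$tab, tc$meta, dominance_threshold = 0)
  expect_equal(nrow(res$matrix), ncol(tc$tab))  # threshold 0 keeps all
  expect_setequal(res$sample_order, tc$meta$sample_id)

  # duplicate samples merge first
  counts <- unclass(tc$tab)
  counts[2, ] <- counts[1, ]
  tab2 <- otu_table(counts)
  res2 <- ward_cluster_heatmap_data(tab2, tc$meta, dominance_threshold = 0)
  expect_identical(sort(res2$sample_hclust$merge[1, ]), sort(c(-1L, -2L)))

  expect_error(ward_cluster_heatmap_data(tc$tab, tc$meta,
                                         dominance_threshold = 2),
               "lower the threshold")
})
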