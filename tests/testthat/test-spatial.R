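test_that("great-circle distances match closed-form values", {
  meta <- data.frame(sample_id = c("a", "b", "c"),
                     species = "AA", locality_id = "L1",
                     lat = c(0, 0, 0), lon = c(0, 90, 0))
  d <- as.matrix(geo_distances(meta))
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "b"], 6371 * pi / 2, tolerance = 1e-6)

  anti <- data.frame(sample_id = c("a", "b"), species = "AA",
                     locality_id = "L1", lat = c(0, 0), lon = c(0, 180))
  expect_equal(as.matrix(geo_distances(anti))["a", "b"], 6371 * pi,
               tolerance = 1e-6)

  bad <- meta; bad$lat[1] <- NA
  expect_error(geo_distances(bad), "missing coordinates")
})

test_that("PCNM reproduces the documented spatial eigenfunction structure", {
  # regular 1-D transect: truncation = spacing, leading axis ~ half-period wave
  x <- 0:9
  m <- as.matrix(dist(x))
  dimnames(m) <- list(paste0("p", x), paste0("p", x))
  pb <- pcnm(as_dist_matrix(m))
  expect_equal(pb$truncation, 1)
  # leading eigenfunction is sinusoidal along the transect
  wave <- sin(2 * pi * x / 9)
  expect_gt(abs(cor(pb$vectors[, 1], wave)), 0.9)
  expect_true(all(pb$eigenvalues > 0))
  expect_true(all(diff(pb$eigenvalues) <= 1e-12))
  # vectors orthogonal
  cp <- crossprod(pb$vectors)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)

  # cross-check eigenvalues against vegan's implementation
  vg <- vegan::pcnm(as_dist_matrix(m))
  nv <- min(length(pb$eigenvalues), sum(vg$values > 1e-8))
  expect_equal(pb$eigenvalues[seq_len(nv)], vg$values[seq_len(nv)],
               tolerance = 1e-6, ignore_attr = TRUE)

  # 3 equidistant points: at most 2 positive axes
  m3 <- matrix(1, 3, 3) - diag(3)
  dimnames(m3) <- list(letters[1:3], letters[1:3])
  expect_lte(ncol(pcnm(as_dist_matrix(m3))$vectors), 2)

  # truncation beyond the maximum distance: plain PCoA of the input
  pb2 <- pcnm(as_dist_matrix(m), truncation = 100)
  pc <- pcoa(as_dist_matrix(m))
  expect_equal(pb2$eigenvalues, pc$eigenvalues[seq_along(pb2$eigenvalues)],
               tolerance = 1e-10)

  same <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_error(pcnm(as_dist_matrix(same)), "identical")
})

test_that("db-RDA partitions variance like explicit least squares", {
  set.seed(10)
  n <- 10
  x1 <- rnorm(n); x2 <- rnorm(n)
  y2 <- cbind(2 * x1 + rnorm(n, sd = 0.1), -x1 + rnorm(n, sd = 0.1))
  m <- as.matrix(dist(y2))
  dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
  d <- as_dist_matrix(m)
  res <- dbrda(d, data.frame(x1 = x1, x2 = x2), n_perm = 199, seed = 1)

  # oracle: per-axis lm fits, marginal SS by model comparison
  y <- pcoa(d)$coords
  ss <- function(fit) sum(fitted(fit)^2)
  yc <- y  # pcoa coords are centred
  full <- lm(yc ~ x1 + x2)
  no1 <- lm(yc ~ x2)
  no2 <- lm(yc ~ x1)
  ss_full <- sum(fitted(full)^2)
  ss_res <- sum(resid(full)^2)
  f1 <- ((ss_full - sum(fitted(no1)^2)) / 1) / (ss_res / (n - 3))
  f2 <- ((ss_full - sum(fitted(no2)^2)) / 1) / (ss_res / (n - 3))
  expect_equal(res$table$F, c(f1, f2), tolerance = 1e-8)
  expect_equal(res$table$variance,
               c(ss_full - sum(fitted(no1)^2),
                 ss_full - sum(fitted(no2)^2)) / (n - 1), tolerance = 1e-8)
  # informative predictor detected; noise not
  expect_lte(res$table$p_perm[1], 0.005)
  expect_gt(res$table$p_perm[2], 0.05)

  # saturated design: residual variance 0
  # n - 1 independent numeric predictors saturate the centred response space
  sat_mm <- as.data.frame(matrix(rnorm(n * (n - 1)), n))
  res_sat <- dbrda(d, sat_mm, n_perm = 9, seed = 1)
  expect_lt(res_sat$residual$variance / res_sat$total_inertia, 1e-8)

  expect_error(dbrda(d, data.frame(a = x1, b = x1), n_perm = 9), "collinear")
})

test_that("adjusted R2 follows the Ezekiel formula", {
  expect_equal(adjusted_r2(0.5, 20, 3), 0.40625)
  expect_equal(adjusted_r2(0.37, 50, 0), 0.37)
  expect_equal(adjusted_r2(1, 20, 3), 1)
  expect_error(adjusted_r2(0.5, 5, 4), "degrees of freedom")
})

test_that("two-set variance partitioning satisfies its algebraic identities", {
  set.seed(12)
  n <- 24
  z1 <- rnorm(n); z2 <- rnorm(n)
  y2 <- cbind(z1 + rnorm(n, sd = 0.3), rnorm(n))
  m <- as.matrix(dist(y2))
  dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
  d <- as_dist_matrix(m)
  vp <- varpart2(d, data.frame(z1 = z1), data.frame(z2 = z2))
  expect_equal(vp$a + vp$b + vp$c + vp$d, 1, tolerance = 1e-12)
  expect_equal(vp$a + vp$b, vp$adj1, tolerance = 1e-12)
  expect_equal(vp$b + vp$c, vp$adj2, tolerance = 1e-12)
  # orthogonal informative/noise sets: pure fraction carries the signal
  expect_gt(vp$a, 0.2)
  expect_lt(abs(vp$b), 0.1)

  vps <- varpart2(d, data.frame(z1 = z1), data.frame(z1b = z1))
  expect_equal(vps$a, 0, tolerance = 1e-10)
  expect_equal(vps$c, 0, tolerance = 1e-10)
  expect_equal(vps$b, vps$adj1, tolerance = 1e-10)
})

test_that("forward selection keeps informative predictors and stops on null", {
  set.seed(13)
  n <- 20
  strong <- rnorm(n)
  y2 <- cbind(3 * strong + rnorm(n, sd = 0.2), rnorm(n, sd = 0.2))
  m <- as.matrix(dist(y2))
  dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
  d <- as_dist_matrix(m)
  cands <- data.frame(strong = strong, noise1 = rnorm(n), noise2 = rnorm(n))
  sel <- forward_select(d, cands, alpha = 0.05, n_perm = 199, seed = 1)
  expect_identical(sel, "strong")

  # alpha = 1 without the adjusted-R2 cap admits everything
  sel_all <- forward_select(d, cands, alpha = 1, n_perm = 19, seed = 1,
                            use_adjr2_cap = FALSE)
  expect_setequal(sel_all, names(cands))
  expect_identical(sel_all[1], "strong")

  # pure-noise candidates are mostly rejected
  empties <- vapply(1:10, function(s) {
    set.seed(100 + s)
    yn <- cbind(rnorm(n), rnorm(n))
    mn <- as.matrix(dist(yn))
    dimnames(mn) <- dimnames(m)
    length(forward_select(as_dist_matrix(mn),
                          data.frame(n1 = rnorm(n), n2 = rnorm(n)),
                          alpha = 0.05, n_perm = 99)) == 0
  }, logical(1))
  expect_gte(sum(empties), 7)
})
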