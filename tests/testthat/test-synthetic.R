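test_that("host-tree posterior emulation preserves topology and height", {
  cfg <- sim_config(n_otus = 20, n_host_trees = 20, seed = 3)
  hosts <- simulate_host_trees(cfg)
  expect_length(hosts$trees, 20)
  for (tr in hosts$trees) {
    expect_equal(max(ape::node.depth.edgelength(tr)), 1, tolerance = 1e-9)
    expect_equal(phangorn::RF.dist(tr, hosts$base), 0)
  }
  cfg0 <- sim_config(n_otus = 20, n_host_trees = 5, host_tree_jitter = 0,
                     seed = 3)
  h0 <- simulate_host_trees(cfg0)
  for (tr in h0$trees)
    expect_equal(tr$edge.length, h0$base$edge.length, tolerance = 1e-12)
})

test_that("sequence divergence tracks patristic distance on the OTU tree", {
  cfg <- sim_config(n_otus = 50, seed = 5, min_otu_divergence = 0)
  pool <- simulate_bacterial_pool(cfg)
  patr <- ape::cophenetic.phylo(pool$tree)
  x <- do.call(rbind, strsplit(as.character(pool$sequences), ""))
  # oracle: direct pairwise mismatch counting
  n <- nrow(x)
  pd <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    pd[i, j] <- pd[j, i] <- mean(x[i, ] != x[j, ])
  ids <- names(pool$sequences)
  lower <- lower.tri(pd)
  expect_gt(cor(patr[ids, ids][lower], pd[lower]), 0)

  cfg0 <- sim_config(n_otus = 10, seed = 5, mut_rate = 0)
  p0 <- simulate_bacterial_pool(cfg0)
  expect_length(unique(as.character(p0$sequences)), 1)
})

test_that("the enforced OTU divergence floor holds", {
  cfg <- sim_config(n_otus = 40, seed = 6)
  pool <- simulate_bacterial_pool(cfg)
  x <- do.call(rbind, strsplit(as.character(pool$sequences), ""))
  worst <- 0
  for (i in seq_len(nrow(x) - 1)) for (j in seq(i + 1, nrow(x)))
    worst <- max(worst, mean(x[i, ] == x[j, ]))
  expect_lte(worst, 1 - cfg$min_otu_divergence + 1e-12)
})

test_that("community tables satisfy depth construction and metadata contract", {
  cfg <- sim_config(n_otus = 40, seed = 4)
  hosts <- simulate_host_trees(cfg)
  pool <- simulate_bacterial_pool(cfg)
  comm <- simulate_community(cfg, hosts, pool)
  expect_equal(nrow(comm$tab), sum(cfg$samples_per_species))
  expect_true(all(rowSums(comm$tab) >= cfg$depth_min))
  expect_equal(unname(rowSums(comm$tab)),
               unname(comm$truth$depths[rownames(comm$tab)]))
  expect_identical(rownames(comm$tab), comm$meta$sample_id)
  expect_equal(sort(unique(comm$meta$species)), sort(unique(
    rep(c("AA", "LL", "SE", "PA", "FA", "PP", "RR"), 1))))
  # three species confounded with single localities, as in the field design
  per_sp <- tapply(comm$meta$locality_id, comm$meta$species,
                   function(l) length(unique(l)))
  expect_gte(sum(per_sp == 1), 3)
})

test_that("a structureless configuration collapses to shared multinomials", {
  cfg <- sim_config(n_otus = 40, seed = 8, phylosymbiosis_strength = 0,
                    spatial_strength = 0, noise_sd = 0)
  hosts <- simulate_host_trees(cfg)
  pool <- simulate_bacterial_pool(cfg)
  comm <- simulate_community(cfg, hosts, pool)
  b <- suppressWarnings(bray_curtis(comm$tab))
  expect_lt(mean(as.vector(b)), 0.15)  # sampling noise only
})

test_that("generation is deterministic given seed and config", {
  cfg <- sim_config(n_otus = 30, n_host_trees = 4, seed = 11)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(unclass(s1$tab), unclass(s2$tab))
  expect_identical(as.character(s1$pool$sequences),
                   as.character(s2$pool$sequences))
  expect_identical(s1$mm$data$y, s2$mm$data$y)
  expect_identical(ape::write.tree(s1$hosts$trees),
                   ape::write.tree(s2$hosts$trees))
})

test_that("trait designation hits the configured fractions and overlap", {
  cfg <- sim_config(n_otus = 250, seed = 9)
  pool <- simulate_bacterial_pool(cfg)
  tr <- simulate_trait_reference(cfg, pool)
  sets <- tr$truth_sets
  n_fdb <- length(sets$fdb)
  expect_equal(n_fdb, round(0.122 * 250))
  expect_equal(length(sets$bpb_any), round(0.245 * 250))
  ov <- length(intersect(sets$fdb, sets$bpb_any)) / n_fdb
  expect_lte(abs(ov - 0.92), 1.5 / n_fdb)  # one-OTU rounding

  expect_error(sim_config(frac_bpb = 0.05, frac_fdb = 0.4,
                          frac_overlap = 0.9), "inconsistent fractions")
})

test_that("mixed-model datasets follow the centered generating equation", {
  cfg <- sim_config(n_otus = 20, seed = 10)
  hosts <- simulate_host_trees(cfg)
  pool <- simulate_bacterial_pool(cfg)
  comm <- simulate_community(cfg, hosts, pool)
  mm <- simulate_mm_dataset(cfg, comm$meta, hosts$base,
                            beta_between = 0, beta_within = 0,
                            sigma_phylo = 0)
  # pure species + noise: y variance explained by species only
  an <- one_way_anova(mm$data$y, mm$data$species)
  expect_gt(an$r2, 0.1)
  dev_sums <- tapply(mm$data$x - tapply(mm$data$x, mm$data$species,
                                        mean)[mm$data$species],
                     mm$data$species, sum)
  expect_lt(max(abs(dev_sums)), 1e-10)
  expect_named(mm$truth, c("alpha", "beta_between", "beta_within",
                           "beta_within_by_species", "u", "a", "mu_x",
                           "sigma_species", "sigma_phylo", "sigma_resid"))
})

test_that("phylosymbiosis strength raises the Mantel correlation", {
  rs <- sapply(1:8, function(rep) {
    sapply(c(0, 2), function(sig) {
      cfg <- sim_config(n_otus = 40, seed = 100 + rep,
                        phylosymbiosis_strength = sig,
                        spatial_strength = 0.2)
      hosts <- simulate_host_trees(cfg)
      pool <- simulate_bacterial_pool(cfg)
      comm <- simulate_community(cfg, hosts, pool)
      d_host <- cophenetic_distance(
        hosts$base, setNames(comm$meta$species, comm$meta$sample_id))
      suppressWarnings(
        mantel(bray_curtis(comm$tab), d_host, n_perm = 9,
               seed = 1)$statistic)
    })
  })
  # sign test: stronger Brownian species effects -> larger Mantel r
  expect_gte(sum(rs[2, ] > rs[1, ]), 7)
})

test_that("simulated studies serialize to the documented plain-text layout", {
  cfg <- sim_config(n_otus = 25, n_host_trees = 3, seed = 12)
  st <- simulate_study(cfg)
  dir <- tempfile()
  write_simulation(st, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "otu_table.tsv", "metadata.csv", "rep_seqs.fasta",
    "bacterial_tree.nwk", "host_trees.nwk", "refs_fdb.fasta",
    "refs_bpbi.fasta", "truth_trait_sets.tsv")))))
  tab <- read_otu_table(file.path(dir, "otu_table.tsv"))
  expect_identical(unclass(tab), unclass(st$tab), ignore_attr = TRUE)
  trees <- read_newick(file.path(dir, "host_trees.nwk"))
  expect_length(trees, 3)
})
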