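#' Configuration for a synthetic feather-microbiota study
#'
#' Defaults mirror the reference study design: 7 passerine host species, 72
#' samples, up to 9 localities, minimum sequencing depth 2299 reads, and
#' trait fractions of 24.5\% BPB / 12.2\% FDB with 92\% of FDB also BPB.
#'
#' @param n_species number of host species (>= 3).
#' @param samples_per_species integer vector of per-species sample counts
#'   (recycled); default allocates 72 samples over 7 species.
#' @param n_localities number of sampling localities.
#' @param n_otus size of the bacterial OTU pool.
#' @param depth_min minimum sequencing depth per sample (reads).
#' @param depth_extra mean of the Poisson over-dispersion added to
#'   `depth_min`.
#' @param phylosymbiosis_strength sd of the Brownian species effects on the
#'   host tree (log-abundance scale).
#' @param spatial_strength sd of the Gaussian-process locality effects.
#' @param spatial_range range (km) of the squared-exponential spatial
#'   kernel.
#' @param noise_sd per-sample log-intensity noise sd.
#' @param base_intensity_sd sd of the per-OTU baseline log-abundance
#'   (0 gives uniform expected abundances).
#' @param seq_length OTU representative sequence length (bp).
#' @param mut_rate Jukes-Cantor substitution rate per unit branch length for
#'   sequence evolution along the bacterial tree.
#' @param min_otu_divergence minimum pairwise sequence divergence enforced
#'   between OTU representatives (default 0.055). OTUs are by definition
#'   clusters at 97\% identity, so representatives of distinct OTUs are more
#'   than 3\% diverged; the default sits past both species-level mapping
#'   thresholds (0.95, 0.97) so distinct OTUs never straddle them. Sequences
#'   of too-close tips receive extra substitutions until the floor holds.
#'   Set to 0 to disable.
#' @param frac_bpb,frac_fdb fractions of the OTU pool designated
#'   bacteriocin-producing / keratinolytic.
#' @param frac_overlap fraction of FDB OTUs that are simultaneously BPB.
#' @param ref_mutations substitutions introduced into each reference copy
#'   (0 = identity 1 references).
#' @param n_decoys number of decoy reference sequences far from every OTU.
#' @param host_tree_jitter lognormal sd of branch-length jitter emulating a
#'   Bayesian posterior of host trees.
#' @param n_host_trees number of jittered host trees.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_species = 7,
                       samples_per_species = c(11, 11, 10, 10, 10, 10, 10),
                       n_localities = 9,
                       n_otus = 500,
                       depth_min = 2299,
                       depth_extra = 300,
                       phylosymbiosis_strength = 1,
                       spatial_strength = 1,
                       spatial_range = 100,
                       noise_sd = 0.5,
                       base_intensity_sd = 1,
                       seq_length = 250,
                       mut_rate = 0.1,
                       min_otu_divergence = 0.055,
                       frac_bpb = 0.245,
                       frac_fdb = 0.122,
                       frac_overlap = 0.92,
                       ref_mutations = 0,
                       n_decoys = 5,
                       host_tree_jitter = 0.1,
                       n_host_trees = 100,
                       seed = 1) {
  cfg <- as.list(environment())
  if (cfg$n_species < 3) stop("n_species must be >= 3")
  if (cfg$depth_min < 1) stop("depth_min must be >= 1")
  fr <- c(cfg$frac_bpb, cfg$frac_fdb, cfg$frac_overlap)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$frac_overlap * cfg$frac_fdb > cfg$frac_bpb)
    stop("inconsistent fractions: frac_overlap * frac_fdb > frac_bpb")
  cfg$samples_per_species <-
    rep_len(cfg$samples_per_species, cfg$n_species)
  class(cfg) <- "sim_config"
  cfg
}

species_codes <- function(n) {
  base <- c("AA", "LL", "SE", "PA", "FA", "PP", "RR")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("S%02d", seq_len(n - length(base))))
}

scale_unit_height <- function(tree) {
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / h
  tree
}

#' Simulate a host-species tree and a jittered posterior sample
#'
#' One Yule (pure-birth) base tree scaled to unit height, plus
#' `n_host_trees` copies whose branch lengths are multiplied by independent
#' lognormal(0, `host_tree_jitter`) noise and rescaled to unit height
#' (topology preserved), emulating a Bayesian posterior.
#'
#' @param cfg a [sim_config()].
#' @return list with `base` (`phylo`) and `trees` (`multiPhylo`).
#' @export
simulate_host_trees <- function(cfg) {
  set.seed(cfg$seed)
  base <- ape::rphylo(cfg$n_species, birth = 1, death = 0)
  base$tip.label <- species_codes(cfg$n_species)
  base <- scale_unit_height(base)
  trees <- vector("list", cfg$n_host_trees)
  for (k in seq_len(cfg$n_host_trees)) {
    tr <- base
    if (cfg$host_tree_jitter > 0)
      tr$edge.length <- tr$edge.length *
        rlnorm(length(tr$edge.length), 0, cfg$host_tree_jitter)
    trees[[k]] <- scale_unit_height(tr)
  }
  class(trees) <- "multiPhylo"
  list(base = base, trees = trees)
}

#' Simulate the bacterial OTU pool: tree and representative sequences
#'
#' Yule tree with `n_otus` tips scaled to unit height; sequences evolve from
#' a random root sequence under Jukes-Cantor with rate `mut_rate` per unit
#' branch length, so sequence divergence grows with patristic distance.
#'
#' @param cfg a [sim_config()].
#' @return list with `tree` (`phylo`, tips `otu0001`, ...) and `sequences`
#'   (`DNAStringSet`).
#' @export
simulate_bacterial_pool <- function(cfg) {
  set.seed(cfg$seed + 1L)
  tree <- ape::rphylo(cfg$n_otus, birth = 1, death = 0)
  tree$tip.label <- sprintf("otu%04d", seq_len(cfg$n_otus))
  tree <- scale_unit_height(tree)
  if (cfg$mut_rate > 0) {
    sim <- phangorn::simSeq(tree, l = cfg$seq_length, type = "DNA",
                            rate = cfg$mut_rate)
    mat <- as.character(sim)  # taxa x sites
    chars <- toupper(apply(mat, 1, paste0, collapse = ""))
    chars <- chars[tree$tip.label]
    if (cfg$min_otu_divergence > 0)
      chars <- enforce_otu_divergence(chars, cfg$min_otu_divergence)
  } else {
    root <- paste0(sample(c("A", "C", "G", "T"), cfg$seq_length,
                          replace = TRUE), collapse = "")
    chars <- setNames(rep(root, cfg$n_otus), tree$tip.label)
  }
  seqs <- Biostrings::DNAStringSet(chars)
  names(seqs) <- tree$tip.label
  list(tree = tree, sequences = seqs)
}

# OTU representatives come from 97%-identity clustering, so two distinct
# OTUs are never near-identical. Enforce that on the simulated pool: while
# any pair agrees at more than (1 - min_div) of sites, add substitutions to
# one member at agreeing positions.
enforce_otu_divergence <- function(chars, min_div) {
  bases <- c("A", "C", "G", "T")
  X <- do.call(rbind, strsplit(chars, ""))
  n <- nrow(X); L <- ncol(X)
  max_match <- floor((1 - min_div) * L)
  match_counts <- function() {
    m <- matrix(0, n, n)
    for (b in bases) {
      ind <- (X == b) * 1
      m <- m + tcrossprod(ind)
    }
    m
  }
  m <- match_counts()
  diag(m) <- 0
  for (pass in seq_len(10000)) {
    viol <- which(m > max_match, arr.ind = TRUE)
    viol <- viol[viol[, 1] < viol[, 2], , drop = FALSE]
    if (nrow(viol) == 0) break
    j <- viol[1, 2]; i <- viol[1, 1]
    agree <- which(X[i, ] == X[j, ])
    need <- m[i, j] - max_match
    pos <- sample(agree, min(need, length(agree)))
    for (p in pos) X[j, p] <- sample(setdiff(bases, X[j, p]), 1)
    # refresh row/column j
    row_j <- numeric(n)
    for (b in bases) row_j <- row_j + ((X == b) %*% (X[j, ] == b))[, 1]
    m[j, ] <- m[, j] <- row_j
    diag(m) <- 0
  }
  setNames(apply(X, 1, paste0, collapse = ""), names(chars))
}

# Default species x locality design: mirrors the study's confounded layout -
# two warbler-like species and the flycatcher each restricted to a single
# site, the martin-like species alone at the last three sites, the rest
# spread over the middle sites.
default_locality_design <- function(n_species, n_localities) {
  design <- matrix(0, n_species, n_localities)
  mid <- setdiff(seq_len(n_localities), c(1, 2, n_localities - 2,
                                          n_localities - 1, n_localities))
  if (length(mid) == 0) mid <- seq_len(n_localities)
  for (s in seq_len(n_species)) {
    if (s %in% c(1, 2)) design[s, 1] <- 1
    else if (s == 5) design[s, 2] <- 1
    else if (s == n_species)
      design[s, seq(n_localities - 2, n_localities)] <- 1
    else design[s, mid] <- 1
  }
  design
}

#' Simulate the community: OTU table, metadata and ground truth
#'
#' Per-OTU species effects are Brownian on the base host tree
#' (phylosymbiosis); locality effects come from a Gaussian process with a
#' squared-exponential kernel over great-circle distances between localities
#' (spatial signal). Sample log-intensities (species + locality + noise,
#' plus a per-OTU baseline) map through a softmax to multinomial read
#' probabilities; depths are `depth_min` plus Poisson over-dispersion.
#'
#' @param cfg a [sim_config()].
#' @param hosts output of [simulate_host_trees()].
#' @param pool output of [simulate_bacterial_pool()].
#' @param locality_design optional binary species x locality matrix of
#'   allowed sites; default mirrors the study's partially confounded layout.
#' @return list with `tab` ([otu_table()]), `meta` (metadata data.frame) and
#'   `truth` (all generating effects and parameters).
#' @export
simulate_community <- function(cfg, hosts, pool, locality_design = NULL) {
  set.seed(cfg$seed + 2L)
  n_sp <- cfg$n_species
  codes <- species_codes(n_sp)
  if (is.null(locality_design))
    locality_design <- default_locality_design(n_sp, cfg$n_localities)
  # localities in a Czech-Republic-sized bounding box
  loc <- data.frame(
    locality_id = sprintf("L%02d", seq_len(cfg$n_localities)),
    lat = runif(cfg$n_localities, 48.6, 51.0),
    lon = runif(cfg$n_localities, 12.1, 18.9))
  n_otus <- cfg$n_otus
  base_intensity <- rnorm(n_otus, 0, cfg$base_intensity_sd)
  # Brownian species effects: chol of the host vcv
  vcv_host <- ape::vcv.phylo(hosts$base)[codes, codes]
  Ls <- chol(vcv_host + diag(1e-10, n_sp))
  species_eff <- cfg$phylosymbiosis_strength *
    t(Ls) %*% matrix(rnorm(n_sp * n_otus), n_sp)
  rownames(species_eff) <- codes
  # spatial GP over localities
  dloc <- geosphere::distm(cbind(loc$lon, loc$lat),
                           fun = function(a, b)
                             geosphere::distHaversine(a, b, r = 6371000)) /
    1000
  K <- cfg$spatial_strength^2 * exp(-dloc^2 / (2 * cfg$spatial_range^2))
  Lg <- chol(K + diag(1e-8, cfg$n_localities))
  locality_eff <- t(Lg) %*% matrix(rnorm(cfg$n_localities * n_otus),
                                   cfg$n_localities)
  rownames(locality_eff) <- loc$locality_id
  # allocate samples to species and localities
  sp_vec <- rep(codes, cfg$samples_per_species)
  n <- length(sp_vec)
  loc_vec <- character(n)
  for (s in seq_len(n_sp)) {
    idx <- which(sp_vec == codes[s])
    sites <- which(locality_design[s, ] > 0)
    loc_vec[idx] <- loc$locality_id[
      sites[rep_len(seq_along(sites), length(idx))]]
  }
  sample_ids <- sprintf("%s_%02d", sp_vec,
                        unlist(lapply(cfg$samples_per_species, seq_len)))
  meta <- data.frame(sample_id = sample_ids, species = sp_vec,
                     locality_id = loc_vec,
                     lat = loc$lat[match(loc_vec, loc$locality_id)],
                     lon = loc$lon[match(loc_vec, loc$locality_id)])
  ord <- order(meta$sample_id)
  meta <- meta[ord, , drop = FALSE]
  rownames(meta) <- NULL
  counts <- matrix(0L, n, n_otus,
                   dimnames = list(meta$sample_id, pool$tree$tip.label))
  depths <- cfg$depth_min + rpois(n, cfg$depth_extra)
  for (i in seq_len(n)) {
    eta <- base_intensity + species_eff[meta$species[i], ] +
      locality_eff[meta$locality_id[i], ] + rnorm(n_otus, 0, cfg$noise_sd)
    pr <- exp(eta - max(eta))
    counts[i, ] <- rmultinom(1, depths[i], pr / sum(pr))
  }
  truth <- list(base_intensity = base_intensity,
                species_effect = species_eff,
                locality_effect = locality_eff,
                localities = loc, depths = setNames(depths, meta$sample_id),
                locality_design = locality_design, config = cfg)
  list(tab = otu_table(counts), meta = meta, truth = truth)
}

#' Designate trait OTUs and emit reference sequences
#'
#' Marks `frac_fdb` of the pool as FDB and `frac_bpb` as BPB (split evenly
#' over classes I-III), with `frac_overlap` of FDB simultaneously BPB.
#' References are copies of the designated OTU sequences carrying
#' `ref_mutations` random substitutions each, plus `n_decoys` random decoy
#' sequences far from every OTU.
#'
#' @param cfg a [sim_config()].
#' @param pool output of [simulate_bacterial_pool()].
#' @return list with `reference` (a [trait_reference()]) and `truth_sets`
#'   (the designated OTU id sets per category, plus `bpb_any` and `fdb`).
#' @export
simulate_trait_reference <- function(cfg, pool) {
  set.seed(cfg$seed + 3L)
  n <- cfg$n_otus
  ids <- names(pool$sequences)
  n_fdb <- round(cfg$frac_fdb * n)
  n_bpb <- round(cfg$frac_bpb * n)
  n_shared <- round(cfg$frac_overlap * n_fdb)
  if (n_shared > n_bpb) stop("inconsistent fractions")
  fdb <- sample(ids, n_fdb)
  shared <- sample(fdb, n_shared)
  bpb_only <- sample(setdiff(ids, fdb), n_bpb - n_shared)
  bpb <- c(shared, bpb_only)
  classes <- split(bpb, rep_len(c("BPB-I", "BPB-II", "BPB-III"),
                                length(bpb)))
  mutate <- function(seq) {
    if (cfg$ref_mutations == 0) return(seq)
    s <- strsplit(seq, "")[[1]]
    pos <- sample(length(s), min(cfg$ref_mutations, length(s)))
    for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
    paste0(s, collapse = "")
  }
  ref_seqs <- character(0); cats <- list()
  add_refs <- function(otu_ids, cat, prefix) {
    for (id in otu_ids) {
      rid <- paste0(prefix, "_", id)
      if (is.null(cats[[rid]])) {
        ref_seqs[[rid]] <<- mutate(as.character(pool$sequences[[id]]))
        cats[[rid]] <<- cat
      } else cats[[rid]] <<- c(cats[[rid]], cat)
    }
  }
  for (cl in names(classes)) add_refs(classes[[cl]], cl,
                                      paste0("ref", sub("BPB-", "", cl)))
  add_refs(fdb, "FDB", "refFDB")
  for (k in seq_len(cfg$n_decoys)) {
    rid <- sprintf("decoy%02d", k)
    ref_seqs[[rid]] <- paste0(sample(c("A", "C", "G", "T"), cfg$seq_length,
                                     replace = TRUE), collapse = "")
    cats[[rid]] <- c("BPB-I", "BPB-II", "BPB-III", "FDB")
  }
  list(reference = trait_reference(unlist(ref_seqs), cats),
       truth_sets = c(classes, list(bpb_any = sort(bpb), fdb = sort(fdb))))
}

#' Simulate a dataset for the phylogenetic mixed model
#'
#' x is drawn with species-level means plus within-species scatter; the
#' response follows y = alpha + beta_between * mean_s(x) + beta_within *
#' (x - mean_s(x)) + u_s + a_s + e with independent species effects,
#' phylogenetic species effects (covariance from the base host tree) and
#' Gaussian noise. Optionally, species-specific within-species slopes are
#' added. All generating parameters are returned.
#'
#' @param cfg a [sim_config()].
#' @param meta metadata (provides sample ids and species).
#' @param host_tree base host tree for the phylogenetic covariance.
#' @param beta_between,beta_within generating slopes (defaults echo the
#'   magnitude of the reference interspecific association, -4.5, and a weak
#'   within-species slope).
#' @param alpha intercept.
#' @param sigma_species,sigma_phylo,sigma_resid random-effect and residual
#'   standard deviations.
#' @param x_mean,x_between_sd,x_within_sd distribution of the predictor.
#' @param beta_within_by_species optional named vector of species-specific
#'   deviations added to `beta_within` (injects an interaction).
#' @param seed optional seed override (defaults to `cfg$seed + 4`).
#' @return list with `data` (sample_id, species, x, y) and `truth`.
#' @export
simulate_mm_dataset <- function(cfg, meta, host_tree,
                                beta_between = -4.5, beta_within = -0.17,
                                alpha = 3,
                                sigma_species = 0.5, sigma_phylo = 0.3,
                                sigma_resid = 0.5,
                                x_mean = -1.5, x_between_sd = 0.5,
                                x_within_sd = 0.3,
                                beta_within_by_species = NULL,
                                seed = NULL) {
  set.seed(if (is.null(seed)) cfg$seed + 4L else seed)
  species <- factor(meta$species)
  codes <- levels(species)
  q <- length(codes)
  mu_x <- rnorm(q, x_mean, x_between_sd)
  names(mu_x) <- codes
  x <- mu_x[as.character(species)] + rnorm(nrow(meta), 0, x_within_sd)
  xb <- tapply(x, species, mean)[as.character(species)]
  xw <- x - xb
  slope_w <- rep(beta_within, nrow(meta))
  if (!is.null(beta_within_by_species))
    slope_w <- slope_w +
      beta_within_by_species[as.character(species)]
  u <- rnorm(q, 0, sigma_species); names(u) <- codes
  A <- phylo_cov(host_tree, codes)
  a <- as.vector(t(chol(A + diag(1e-10, q))) %*% rnorm(q)) * sigma_phylo
  names(a) <- codes
  y <- alpha + beta_between * xb + slope_w * xw +
    u[as.character(species)] + a[as.character(species)] +
    rnorm(nrow(meta), 0, sigma_resid)
  list(data = data.frame(sample_id = meta$sample_id,
                         species = as.character(species),
                         x = as.numeric(x), y = as.numeric(y)),
       truth = list(alpha = alpha, beta_between = beta_between,
                    beta_within = beta_within,
                    beta_within_by_species = beta_within_by_species,
                    u = u, a = a, mu_x = mu_x,
                    sigma_species = sigma_species,
                    sigma_phylo = sigma_phylo, sigma_resid = sigma_resid))
}

#' Simulate a complete study
#'
#' Runs all generator stages under one configuration; the result carries
#' every ground-truth object used.
#'
#' @param cfg a [sim_config()].
#' @return list with `hosts`, `pool`, `tab`, `meta`, `community_truth`,
#'   `reference`, `trait_truth`, `mm` and `cfg`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  hosts <- simulate_host_trees(cfg)
  pool <- simulate_bacterial_pool(cfg)
  comm <- simulate_community(cfg, hosts, pool)
  traits <- simulate_trait_reference(cfg, pool)
  mm <- simulate_mm_dataset(cfg, comm$meta, hosts$base)
  list(hosts = hosts, pool = pool, tab = comm$tab, meta = comm$meta,
       community_truth = comm$truth, reference = traits$reference,
       trait_truth = traits$truth_sets, mm = mm, cfg = cfg)
}

#' Write a simulated study to plain-text files
#'
#' Emits `otu_table.tsv`, `metadata.csv`, `rep_seqs.fasta`,
#' `bacterial_tree.nwk`, `host_trees.nwk`, one reference FASTA per trait
#' category, and `truth_trait_sets.tsv`, each tagged with the seed.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tag <- paste0("featherbiome simulate seed=", study$cfg$seed)
  write_otu_table(study$tab, file.path(dir, "otu_table.tsv"), comment = tag)
  write_metadata(study$meta, file.path(dir, "metadata.csv"), comment = tag)
  write_fasta(study$pool$sequences, file.path(dir, "rep_seqs.fasta"))
  ape::write.tree(study$pool$tree, file.path(dir, "bacterial_tree.nwk"))
  ape::write.tree(study$hosts$trees, file.path(dir, "host_trees.nwk"))
  ref <- study$reference
  for (cat in ref$category_levels) {
    ids <- names(Filter(function(cc) cat %in% cc, ref$categories))
    fn <- paste0("refs_", gsub("[^A-Za-z0-9]", "", tolower(cat)), ".fasta")
    write_fasta(ref$sequences[ids], file.path(dir, fn))
  }
  sets <- study$trait_truth
  df <- data.frame(
    category = rep(names(sets), lengths(sets)),
    otu_id = unlist(sets, use.names = FALSE))
  write.table(df, file.path(dir, "truth_trait_sets.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
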