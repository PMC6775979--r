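#' Within/between-species centering of a predictor
#'
#' Decomposes a predictor into species means (the between-species effect)
#' and per-observation deviations from the species mean (the within-species
#' effect). With `log_transform`, the natural log is taken first; zeros are
#' offset by half the smallest nonzero value before logging.
#'
#' @param x numeric predictor.
#' @param species species labels aligned with `x`.
#' @param log_transform take `log(x)` first (default `FALSE`).
#' @return data.frame with `species`, `x`, `x_between`, `x_within`.
#' @export
center_predictor <- function(x, species, log_transform = FALSE) {
  species <- factor(species)
  if (length(x) != length(species)) stop("length mismatch")
  if (log_transform) {
    if (any(x < 0)) stop("negative values cannot be log transformed")
    if (any(x == 0)) {
      nz <- min(x[x > 0])
      x <- x + nz / 2
    }
    x <- log(x)
  }
  mu <- tapply(x, species, mean)
  if (any(table(species) == 1))
    warning("species with a single observation: within deviation is 0")
  between <- as.numeric(mu[as.character(species)])
  out <- data.frame(species = species, x = x, x_between = between,
                    x_within = x - between)
  out
}

#' Phylogenetic correlation matrix among species
#'
#' A_ij is the branch length shared from the root to the most recent common
#' ancestor of species i and j, scaled so the diagonal is 1 (tree rescaled
#' to unit height; non-ultrametric trees are rescaled per-tip with a
#' warning).
#'
#' @param tree rooted `phylo`.
#' @param species species codes (must be tips); defaults to all tips.
#' @return correlation matrix with unit diagonal.
#' @export
phylo_cov <- function(tree, species = tree$tip.label) {
  missing <- setdiff(species, tree$tip.label)
  if (length(missing) > 0)
    stop("species not in tree: ", paste(missing, collapse = ", "))
  v <- ape::vcv.phylo(tree)
  depths <- diag(v)
  if (max(depths) - min(depths) > 1e-8 * max(depths))
    warning("non-ultrametric tree: rescaling by per-tip depth")
  a <- v / sqrt(outer(depths, depths))
  a[species, species, drop = FALSE]
}

#' Fit the Gaussian phylogenetic mixed model by Gibbs sampling
#'
#' y = X beta + Z u + Z a + e with independent species effects
#' u ~ N(0, sigma2_s I), phylogenetic species effects a ~ N(0, sigma2_p A)
#' and residuals e ~ N(0, sigma2_e I). All conditionals are conjugate
#' (multivariate normal for the location block; inverse-gamma for the three
#' variances). The fixed design is the within/between-centered predictor,
#' optionally with species-specific within-species slopes.
#'
#' @param y numeric response.
#' @param design a [center_predictor()] data.frame (columns `species`,
#'   `x_between`, `x_within`).
#' @param A phylogenetic correlation matrix over the species levels
#'   (see [phylo_cov()]).
#' @param interaction add species x within-deviation interaction slopes.
#' @param chain list with `iters`, `burnin`, `thin` (defaults 60000, 10000,
#'   25; reduce for simulation batteries).
#' @param prior list with inverse-gamma shape/rate `a`, `b` shared by all
#'   three variances (default 0.001, 0.001); per-component overrides
#'   `a_resid`/`b_resid`, `a_species`/`b_species`, `a_phylo`/`b_phylo` allow
#'   e.g. flooring the random-effect variances near zero.
#' @param seed optional integer seed.
#' @return object of class `mm_fit`: `fixed` summary table (posterior mean
#'   and 95\% credible interval), `variances`, `H2` summary, `DIC`,
#'   `draws` (retained samples), `ess` per fixed effect, `n`.
#' @export
fit_mm <- function(y, design, A, interaction = FALSE,
                   chain = list(iters = 60000, burnin = 10000, thin = 25),
                   prior = list(a = 0.001, b = 0.001), seed = NULL) {
  species <- factor(design$species)
  sp_levels <- levels(species)
  if (!all(sp_levels %in% rownames(A)))
    stop("A lacks species: ",
         paste(setdiff(sp_levels, rownames(A)), collapse = ", "))
  A <- A[sp_levels, sp_levels]
  q <- length(sp_levels)
  n <- length(y)
  X <- cbind(`(Intercept)` = 1, x_between = design$x_between,
             x_within = design$x_within)
  if (interaction) {
    Zi <- model.matrix(~ 0 + species)
    XI <- Zi[, -1, drop = FALSE] * design$x_within
    colnames(XI) <- paste0("within:", sp_levels[-1])
    X <- cbind(X, XI)
  }
  p <- ncol(X)
  if (n <= p + 2) stop("too few observations for the fixed design")
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("A is not positive semi-definite")
  Ainv <- solve(A + diag(1e-8, q))
  Z <- model.matrix(~ 0 + species)
  W <- cbind(X, Z, Z)
  WtW <- crossprod(W)
  Wty <- crossprod(W, y)
  idx_b <- seq_len(p); idx_u <- p + seq_len(q); idx_a <- p + q + seq_len(q)
  pick <- function(key, fallback) {
    if (!is.null(prior[[key]])) prior[[key]] else prior[[fallback]]
  }
  pr <- list(ae = pick("a_resid", "a"), be = pick("b_resid", "b"),
             as = pick("a_species", "a"), bs = pick("b_species", "b"),
             ap = pick("a_phylo", "a"), bp = pick("b_phylo", "b"))
  if (!is.null(seed)) set.seed(seed)
  s2s <- s2p <- s2e <- var(y)
  if (s2e == 0) s2e <- s2s <- s2p <- 1
  keep <- floor((chain$iters - chain$burnin) / chain$thin)
  draws <- matrix(NA_real_, keep, p + 3 + 1)
  colnames(draws) <- c(colnames(X), "sigma2_species", "sigma2_phylo",
                       "sigma2_resid", "deviance")
  theta_draws <- matrix(NA_real_, keep, p + 2 * q)
  beta_prior_prec <- 1e-8  # essentially flat on fixed effects
  k <- 0
  for (it in seq_len(chain$iters)) {
    P <- matrix(0, p + 2 * q, p + 2 * q)
    P[idx_b, idx_b] <- diag(beta_prior_prec, p)
    P[idx_u, idx_u] <- diag(1 / s2s, q)
    P[idx_a, idx_a] <- Ainv / s2p
    prec <- WtW / s2e + P
    ch <- tryCatch(chol(prec), error = function(e)
      stop("divergent chain at iteration ", it, ": ", conditionMessage(e)))
    mean_theta <- backsolve(ch, forwardsolve(t(ch), Wty / s2e))
    theta <- mean_theta + backsolve(ch, rnorm(p + 2 * q))
    u <- theta[idx_u]; a <- theta[idx_a]
    resid <- y - as.vector(W %*% theta)
    s2e <- 1 / rgamma(1, pr$ae + n / 2, pr$be + sum(resid^2) / 2)
    s2s <- 1 / rgamma(1, pr$as + q / 2, pr$bs + sum(u^2) / 2)
    s2p <- 1 / rgamma(1, pr$ap + q / 2,
                      pr$bp + as.numeric(crossprod(a, Ainv %*% a)) / 2)
    if (!all(is.finite(c(theta, s2e, s2s, s2p))))
      stop("divergent chain at iteration ", it)
    if (it > chain$burnin && (it - chain$burnin) %% chain$thin == 0) {
      k <- k + 1
      dev <- -2 * sum(dnorm(y, as.vector(W %*% theta), sqrt(s2e), log = TRUE))
      draws[k, ] <- c(theta[idx_b], s2s, s2p, s2e, dev)
      theta_draws[k, ] <- theta
    }
  }
  draws <- draws[seq_len(k), , drop = FALSE]
  theta_draws <- theta_draws[seq_len(k), , drop = FALSE]
  summarize_mm(draws, theta_draws, W, y, p, n)
}

summarize_mm <- function(draws, theta_draws, W, y, p, n) {
  fixed_names <- colnames(draws)[seq_len(p)]
  fixed <- t(apply(draws[, seq_len(p), drop = FALSE], 2, function(v)
    c(mean = mean(v), lower = unname(quantile(v, 0.025)),
      upper = unname(quantile(v, 0.975)))))
  variances <- colMeans(draws[, c("sigma2_species", "sigma2_phylo",
                                  "sigma2_resid"), drop = FALSE])
  h2_draws <- draws[, "sigma2_phylo"] /
    (draws[, "sigma2_phylo"] + draws[, "sigma2_species"] +
       draws[, "sigma2_resid"])
  dic <- NA_real_
  if (!is.null(W)) {
    theta_bar <- colMeans(theta_draws)
    s2e_bar <- mean(draws[, "sigma2_resid"])
    dev_bar <- -2 * sum(dnorm(y, as.vector(W %*% theta_bar),
                              sqrt(s2e_bar), log = TRUE))
    dic <- 2 * mean(draws[, "deviance"]) - dev_bar
  }
  ess <- apply(draws[, seq_len(p), drop = FALSE], 2, ess_ar1)
  structure(list(
    fixed = data.frame(effect = fixed_names, fixed),
    variances = as.list(variances),
    H2 = c(mean = mean(h2_draws), median = stats::median(h2_draws),
           lower = unname(quantile(h2_draws, 0.025)),
           upper = unname(quantile(h2_draws, 0.975))),
    DIC = dic, draws = draws, theta_draws = theta_draws,
    ess = ess, n = n, p = p,
    W = W, y = y), class = "mm_fit")
}

# crude lag-1 autocorrelation ESS; adequate for chain-health reporting
ess_ar1 <- function(v) {
  n <- length(v)
  if (n < 10 || sd(v) == 0) return(n)
  r1 <- cor(v[-1], v[-n])
  r1 <- min(max(r1, -0.999), 0.999)
  n * (1 - r1) / (1 + r1)
}

#' DIC difference between main-effect and interaction models
#'
#' Delta = DIC(interaction) - DIC(main); |Delta| < 2 is conventionally
#' read as model equivalence, negative values favour the interaction model.
#'
#' @param model_main,model_interaction `mm_fit` objects fitted to the same
#'   response.
#' @return the DIC difference.
#' @export
compare_dic <- function(model_main, model_interaction) {
  if (model_main$n != model_interaction$n)
    stop("models fitted to different numbers of observations")
  model_interaction$DIC - model_main$DIC
}

#' Pool mixed-model fits over a posterior sample of host trees
#'
#' Concatenates retained draws across per-tree fits with equal weight and
#' recomputes all posterior summaries on the pooled sample. The reported DIC
#' is the across-tree mean.
#'
#' @param fits list of `mm_fit` objects (same model, different trees).
#' @return an `mm_fit`-like pooled summary.
#' @export
pool_over_trees <- function(fits) {
  if (length(fits) < 1) stop("need at least one fit")
  p <- fits[[1]]$p
  draws <- do.call(rbind, lapply(fits, `[[`, "draws"))
  theta <- do.call(rbind, lapply(fits, `[[`, "theta_draws"))
  out <- summarize_mm(draws, theta, W = NULL, y = NULL, p = p,
                      n = fits[[1]]$n)
  out$DIC <- mean(vapply(fits, `[[`, numeric(1), "DIC"))
  out$n_trees <- length(fits)
  out
}
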