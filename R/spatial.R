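#' Great-circle distances among samples
#'
#' Haversine distances (Earth radius 6371 km) from metadata latitude and
#' longitude, in kilometres.
#'
#' @param meta metadata data.frame with `sample_id`, `lat`, `lon`.
#' @return a `dist` over samples, in km.
#' @export
geo_distances <- function(meta) {
  if (anyNA(meta$lat) || anyNA(meta$lon)) stop("missing coordinates")
  pts <- cbind(meta$lon, meta$lat)
  m <- geosphere::distm(pts,
                        fun = function(a, b)
                          geosphere::distHaversine(a, b, r = 6371000)) / 1000
  dimnames(m) <- list(meta$sample_id, meta$sample_id)
  as_dist_matrix(m)
}

#' Principal coordinates of neighbour matrices (spatial eigenfunctions)
#'
#' Truncates the geographic distance matrix at `truncation` (by default the
#' longest edge of its minimum spanning tree), replaces larger distances by
#' four times the truncation distance, and takes the positive-eigenvalue PCoA
#' axes of the result as spatial covariates.
#'
#' @param d_geo a `dist` of geographic distances (km).
#' @param truncation truncation distance in km, or `NULL` for the MST rule.
#' @return list with `vectors` (samples x axes, decreasing eigenvalue),
#'   `eigenvalues` (positive ones) and `truncation`.
#' @export
pcnm <- function(d_geo, truncation = NULL) {
  d_geo <- as_dist_matrix(d_geo)
  m <- as.matrix(d_geo)
  if (nrow(m) < 3) stop("need at least 3 locations")
  if (max(m) == 0) stop("all points identical")
  if (is.null(truncation)) {
    st <- vegan::spantree(d_geo)
    truncation <- max(st$dist)
  }
  if (truncation <= 0) stop("truncation must be positive")
  m[m > truncation] <- 4 * truncation
  pc <- pcoa(as_dist_matrix(m))
  k <- ncol(pc$coords)
  ev <- pc$eigenvalues[seq_len(k)]
  vec <- pc$coords
  colnames(vec) <- paste0("PCNM", seq_len(k))
  list(vectors = vec, eigenvalues = ev, truncation = truncation)
}

# Build a full-rank model matrix (no intercept column; response and
# predictors are centred instead). Errors name aliased columns.
build_design <- function(predictors, allow_aliased = FALSE) {
  if (is.null(dim(predictors)) ) predictors <- data.frame(x = predictors)
  predictors <- as.data.frame(predictors)
  mm <- model.matrix(~ ., data = predictors)
  assign <- attr(mm, "assign")[-1]
  mm <- mm[, -1, drop = FALSE]
  mm <- scale(mm, center = TRUE, scale = FALSE)
  qrx <- qr(mm)
  rank <- qrx$rank
  if (rank < ncol(mm) && !allow_aliased) {
    aliased <- colnames(mm)[qrx$pivot[seq(rank + 1, ncol(mm))]]
    stop("collinear predictor column(s): ", paste(aliased, collapse = ", "))
  }
  terms <- names(predictors)
  list(mm = mm, assign = assign, terms = terms, rank = rank)
}

hat_matrix <- function(x) {
  if (ncol(x) == 0) return(matrix(0, nrow(x), nrow(x)))
  qx <- qr(x)
  q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  tcrossprod(q)
}

#' Distance-based redundancy analysis with marginal permutation tests
#'
#' The response is the positive-eigenvalue PCoA embedding of `d`. Each term
#' of `predictors` is tested marginally (its sum of squares given all other
#' terms) with significance by Freedman-Lane permutation of the residuals of
#' the reduced model.
#'
#' @param d a `dist` or square dissimilarity matrix.
#' @param predictors data.frame of constraints (factors and/or numeric),
#'   rows aligned with `d`.
#' @param n_perm permutations for the marginal tests.
#' @param seed optional integer seed.
#' @return list with a per-term `table` (df, variance, F, p_perm), `residual`
#'   (variance, df), `r2`, `adj_r2`, `total_inertia` and `n`.
#' @export
dbrda <- function(d, predictors, n_perm = 999, seed = NULL) {
  d <- as_dist_matrix(d)
  y <- pcoa(d)$coords
  n <- nrow(y)
  des <- build_design(predictors)
  x <- des$mm
  if (nrow(x) != n) stop("predictor rows not aligned with d")
  if (!is.null(seed)) set.seed(seed)
  h_full <- hat_matrix(x)
  ss_tot <- sum(y^2)
  fit_full <- h_full %*% y
  ss_full <- sum(fit_full^2)
  ss_res <- ss_tot - ss_full
  df_res <- n - 1L - ncol(x)
  nt <- length(des$terms)
  tab <- data.frame(term = des$terms, df = NA_integer_,
                    variance = NA_real_, F = NA_real_, p_perm = NA_real_)
  for (t in seq_len(nt)) {
    cols <- which(des$assign == t)
    df_t <- length(cols)
    x_red <- x[, -cols, drop = FALSE]
    h_red <- hat_matrix(x_red)
    ss_red <- sum((h_red %*% y)^2)
    ss_term <- ss_full - ss_red
    tab$df[t] <- df_t
    tab$variance[t] <- ss_term / (n - 1)
    if (df_res < 1) next  # saturated model: no residual test possible
    f_obs <- (ss_term / df_t) / (ss_res / df_res)
    fit_red <- h_red %*% y
    res_red <- y - fit_red
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      y_star <- fit_red + res_red[sample.int(n), , drop = FALSE]
      ssf <- sum((h_full %*% y_star)^2)
      ssr <- sum((h_red %*% y_star)^2)
      sse <- sum(y_star^2) - ssf
      f_star <- ((ssf - ssr) / df_t) / (sse / df_res)
      if (f_star >= f_obs) exceed <- exceed + 1L
    }
    tab$F[t] <- f_obs
    tab$p_perm[t] <- (1 + exceed) / (1 + n_perm)
  }
  r2 <- ss_full / ss_tot
  list(table = tab,
       residual = list(variance = ss_res / (n - 1), df = df_res),
       r2 = r2,
       adj_r2 = if (df_res >= 1) adjusted_r2(r2, n, ncol(x)) else NA_real_,
       total_inertia = ss_tot / (n - 1), n = n)
}

# Constrained R2 of d ~ X without permutation testing (used by varpart and
# forward selection). Returns r2, adjusted r2 and the predictor rank.
dbrda_r2 <- function(y, predictors) {
  des <- build_design(predictors, allow_aliased = TRUE)
  h <- hat_matrix(des$mm)
  r2 <- sum((h %*% y)^2) / sum(y^2)
  list(r2 = r2, adj_r2 = adjusted_r2(r2, nrow(y), des$rank), m = des$rank)
}

#' Ezekiel-adjusted R-squared
#'
#' 1 - (1 - r2)(n - 1)/(n - m - 1), the proportion of variance explained
#' after adjusting for model complexity.
#'
#' @param r2 unadjusted R-squared.
#' @param n number of observations.
#' @param m number of predictor columns (model rank, intercept excluded).
#' @return adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n, m) {
  if (n - m - 1 < 1) stop("insufficient residual degrees of freedom")
  1 - (1 - r2) * (n - 1) / (n - m - 1)
}

#' Forward selection of db-RDA constraints
#'
#' Greedy forward selection: at each step the candidate with the smallest
#' marginal permutation p-value (given the already selected set) is added
#' (ties broken towards the larger gain in adjusted R2). Selection stops when
#' the best candidate's p exceeds `alpha` or when the selected set's adjusted
#' R2 would exceed that of the full candidate model (double stopping rule).
#'
#' @param d a `dist` or square dissimilarity matrix.
#' @param candidates data.frame of candidate predictors (each column one
#'   candidate term).
#' @param alpha entry threshold on the permutation p-value.
#' @param n_perm permutations per entry test.
#' @param seed optional integer seed.
#' @param use_adjr2_cap disable the adjusted-R2 stopping rule by setting
#'   `FALSE`.
#' @return character vector of selected column names (possibly empty).
#' @export
forward_select <- function(d, candidates, alpha = 0.05, n_perm = 199,
                           seed = NULL, use_adjr2_cap = TRUE) {
  d <- as_dist_matrix(d)
  y <- pcoa(d)$coords
  candidates <- as.data.frame(candidates)
  if (!is.null(seed)) set.seed(seed)
  adj_full <- dbrda_r2(y, candidates)$adj_r2
  selected <- character(0)
  remaining <- names(candidates)
  adj_cur <- 0
  n <- nrow(y)
  while (length(remaining) > 0) {
    ps <- adds <- setNames(numeric(length(remaining)), remaining)
    for (cand in remaining) {
      sub <- candidates[, c(selected, cand), drop = FALSE]
      res <- dbrda(d, sub, n_perm = n_perm)
      row <- match(cand, res$table$term)
      ps[cand] <- res$table$p_perm[row]
      adds[cand] <- res$adj_r2 - adj_cur
    }
    best_p <- min(ps)
    if (best_p > alpha) break
    tied <- names(ps)[ps == best_p]
    best <- tied[which.max(adds[tied])]
    new_adj <- adj_cur + adds[best]
    # the adjusted-R2 cap never blocks the first admitted variable: a single
    # informative predictor routinely beats the noise-diluted full model
    if (use_adjr2_cap && length(selected) > 0 && new_adj > adj_full) break
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    adj_cur <- new_adj
  }
  selected
}

#' Two-set variance partitioning on adjusted R-squared
#'
#' Partitions the constrained variation of `d` between two predictor sets
#' into pure fractions a and c, the shared fraction b, and the residual d,
#' all on the adjusted-R2 scale (pure fractions may be slightly negative).
#'
#' @param d a `dist` or square dissimilarity matrix.
#' @param set1,set2 data.frames of predictors, rows aligned with `d`.
#' @return list with fractions `a`, `b`, `c`, `d` and the three adjusted R2
#'   values (`adj1`, `adj2`, `adj12`).
#' @export
varpart2 <- function(d, set1, set2) {
  d <- as_dist_matrix(d)
  y <- pcoa(d)$coords
  set1 <- as.data.frame(set1); set2 <- as.data.frame(set2)
  if (ncol(set1) == 0 || ncol(set2) == 0) stop("both sets must be nonempty")
  adj1 <- dbrda_r2(y, set1)$adj_r2
  adj2 <- dbrda_r2(y, set2)$adj_r2
  adj12 <- dbrda_r2(y, cbind(set1, set2))$adj_r2
  list(a = adj12 - adj2, b = adj1 + adj2 - adj12, c = adj12 - adj1,
       d = 1 - adj12, adj1 = adj1, adj2 = adj2, adj12 = adj12)
}
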