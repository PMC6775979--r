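#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample's reads without replacement down to `depth`, the
#' standard normalisation before alpha-diversity comparison. A single draw is
#' taken (no averaging over repeated rarefactions); record the seed for
#' reproducibility.
#'
#' @param tab an [otu_table()].
#' @param depth target reads per sample; every sample must have at least this
#'   many reads.
#' @param seed optional integer seed.
#' @return rarefied [otu_table()] whose rows all sum to `depth`.
#' @export
rarefy <- function(tab, depth, seed = NULL) {
  validate_otu_table(tab)
  if (depth < 1) stop("depth must be >= 1")
  tot <- rowSums(tab)
  shallow <- rownames(tab)[tot < depth]
  if (length(shallow) > 0)
    stop("sample(s) shallower than rarefaction depth ", depth, ": ",
         paste(shallow, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  out <- tab
  for (i in seq_len(nrow(tab))) {
    if (tot[i] == depth) next
    reads <- rep.int(seq_len(ncol(tab)), tab[i, ])
    keep <- sample(reads, depth, replace = FALSE)
    out[i, ] <- tabulate(keep, nbins = ncol(tab))
  }
  otu_table(unclass(out))
}

#' Shannon diversity (natural log)
#'
#' H = -sum p_i log p_i over the nonzero proportions, in nats.
#'
#' @param counts non-negative count vector with positive total.
#' @return Shannon index in nats.
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) stop("negative count")
  tot <- sum(counts)
  if (tot == 0) stop("all-zero count vector")
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

#' Per-sample alpha diversity
#'
#' @param tab an [otu_table()] (typically rarefied).
#' @return data.frame with `sample_id`, `shannon` (nats) and `observed_otus`.
#' @export
alpha_diversity <- function(tab) {
  validate_otu_table(tab)
  data.frame(
    sample_id = rownames(tab),
    shannon = apply(tab, 1, shannon),
    observed_otus = rowSums(tab > 0),
    row.names = NULL
  )
}

#' One-way ANOVA with variance explained
#'
#' Classical fixed-effects one-way analysis of variance, reported with
#' R2 = SS_between / SS_total, as used for interspecific comparison of
#' alpha diversity.
#'
#' @param values numeric response.
#' @param groups factor (or coercible) of group labels.
#' @return list with `F`, `df1`, `df2`, `p`, `r2`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (length(values) != length(groups)) stop("length mismatch")
  df1 <- nlevels(groups) - 1L
  df2 <- length(values) - nlevels(groups)
  if (df2 < 1) stop("no residual degrees of freedom")
  tabl <- suppressWarnings(anova(aov(values ~ groups)))
  ssb <- tabl[["Sum Sq"]][1]
  ssw <- tabl[["Sum Sq"]][2]
  if (ssw <= .Machine$double.eps * (ssb + 1)) {
    warning("zero within-group variance; p reported as 0 limit")
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0,
                r2 = if (ssb > 0) 1 else 0))
  }
  list(F = tabl[["F value"]][1], df1 = df1, df2 = df2,
       p = tabl[["Pr(>F)"]][1], r2 = ssb / (ssb + ssw))
}
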