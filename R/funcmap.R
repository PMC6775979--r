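#' Labelled trait-reference sequence set
#'
#' Reference 16S sequences annotated with functional categories:
#' bacteriocin-producing classes (`BPB-I`, `BPB-II`, `BPB-III`) and
#' keratinolytic feather-damaging bacteria (`FDB`). A reference sequence may
#' carry several categories.
#'
#' @param sequences named character vector or `DNAStringSet` of reference
#'   sequences.
#' @param categories named list: reference id -> character vector of
#'   categories.
#' @return object of class `trait_reference`.
#' @export
trait_reference <- function(sequences, categories) {
  if (!inherits(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(sequences))) stop("reference sequences must be named")
  if (!all(names(categories) %in% names(sequences)))
    stop("category labels for unknown reference id(s)")
  cats <- unique(unlist(categories))
  if (length(cats) == 0) stop("no categories supplied")
  structure(list(sequences = sequences, categories = categories,
                 category_levels = sort(cats)),
            class = "trait_reference")
}

#' Percent identity from semi-global alignment
#'
#' Aligns two unambiguous DNA sequences with free terminal gaps on both ends
#' (match +1, mismatch -1, gap open -5, gap extend -2) and returns matches
#' divided by alignment columns, terminal-gap columns excluded; internal gaps
#' count as non-matches. If the best overlap covers less than half of the
#' shorter sequence the pair is treated as having no detectable similarity
#' (identity 0), preventing degenerate few-base terminal overlaps from
#' scoring as near-perfect hits.
#'
#' @param query,ref DNA strings over ACGT.
#' @return identity fraction in [0, 1].
#' @export
pairwise_identity <- function(query, ref) {
  q <- toupper(as.character(query)); r <- toupper(as.character(ref))
  if (nchar(q) == 0 || nchar(r) == 0) stop("empty sequence")
  if (grepl("[^ACGT]", q) || grepl("[^ACGT]", r))
    stop("ambiguity codes not supported; pre-filter sequences")
  identity_matrix(Biostrings::DNAStringSet(q),
                  Biostrings::DNAStringSet(r))[1, 1]
}

# Identity of every query against every reference (queries x refs), using
# overlap (free-end-gap) alignment; identity = matches / aligned columns.
# A best overlap covering less than half the shorter sequence is no hit
# (identity 0): without a coverage floor, dissimilar sequences score near 1
# on degenerate few-base terminal overlaps.
identity_matrix <- function(queries, refs, min_coverage = 0.5) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                     baseOnly = TRUE)
  out <- matrix(NA_real_, length(queries), length(refs),
                dimnames = list(names(queries), names(refs)))
  qw <- Biostrings::width(queries)
  for (j in seq_along(refs)) {
    aln <- Biostrings::pairwiseAlignment(
      queries, refs[[j]], type = "overlap", substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 2)
    ident <- Biostrings::pid(aln, type = "PID1") / 100
    cov <- Biostrings::nchar(aln) / pmin(qw, Biostrings::width(refs[j]))
    ident[is.nan(ident) | cov < min_coverage] <- 0
    out[, j] <- ident
  }
  out
}

#' Map OTU sequences to trait references by identity threshold
#'
#' For each OTU and category, the best hit is the reference with maximal
#' semi-global identity; the OTU is assigned to the category iff that
#' identity reaches `threshold`. Ties go to the lexicographically smallest
#' reference id.
#'
#' @param otus named character vector or `DNAStringSet` of OTU
#'   representative sequences.
#' @param ref a [trait_reference()].
#' @param threshold identity threshold (default 0.97, approximately
#'   species-level).
#' @param id_mat optional precomputed identity matrix (OTUs x references) to
#'   reuse across thresholds.
#' @return data.frame with one row per OTU x category: `otu_id`, `category`,
#'   `ref_id`, `identity`, `assigned`.
#' @export
map_otus <- function(otus, ref, threshold = 0.97, id_mat = NULL) {
  if (!inherits(otus, "DNAStringSet")) otus <- Biostrings::DNAStringSet(otus)
  if (is.null(names(otus))) stop("OTU sequences must be named")
  if (is.null(id_mat))
    id_mat <- identity_matrix(otus, ref$sequences)
  rows <- list()
  for (cat in ref$category_levels) {
    ref_ids <- sort(names(Filter(function(cc) cat %in% cc, ref$categories)))
    if (length(ref_ids) == 0) {
      warning("empty reference category ", cat, "; skipped")
      next
    }
    sub <- id_mat[, ref_ids, drop = FALSE]
    best_i <- apply(sub, 1, function(v) which(v == max(v))[1])
    best_id <- ref_ids[best_i]
    best_ident <- sub[cbind(seq_len(nrow(sub)), best_i)]
    rows[[cat]] <- data.frame(otu_id = names(otus), category = cat,
                              ref_id = best_id, identity = best_ident,
                              assigned = best_ident >= threshold)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  out
}

assigned_otus <- function(assignments, categories) {
  sub <- assignments[assignments$assigned &
                       assignments$category %in% categories, , drop = FALSE]
  unique(sub$otu_id)
}

#' Per-sample functional read and OTU proportions
#'
#' For every sample and category: the proportion of reads belonging to OTUs
#' assigned to the category. `BPB-any` is the union of the three bacteriocin
#' classes. OTU-count proportions (fraction of the table's OTUs assigned)
#' are reported alongside.
#'
#' @param tab an [otu_table()].
#' @param assignments output of [map_otus()].
#' @return list with `read_prop` (samples x categories matrix), `otu_prop`
#'   (named vector) and the `assignments` used.
#' @export
functional_profile <- function(tab, assignments) {
  validate_otu_table(tab)
  cats <- unique(assignments$category)
  bpb_cats <- grep("^BPB-", cats, value = TRUE)
  out_cats <- c(cats, if (length(bpb_cats) > 0) "BPB-any")
  tot <- rowSums(tab)
  read_prop <- matrix(0, nrow(tab), length(out_cats),
                      dimnames = list(rownames(tab), out_cats))
  otu_prop <- setNames(numeric(length(out_cats)), out_cats)
  for (cat in out_cats) {
    members <- if (cat == "BPB-any") assigned_otus(assignments, bpb_cats)
               else assigned_otus(assignments, cat)
    members <- intersect(members, colnames(tab))
    if (length(members) > 0)
      read_prop[, cat] <-
        rowSums(unclass(tab)[, members, drop = FALSE]) / tot
    otu_prop[cat] <- length(members) / ncol(tab)
  }
  list(read_prop = read_prop, otu_prop = otu_prop, assignments = assignments)
}

#' Overlap between BPB and FDB assignments
#'
#' Proportions of unique-BPB, unique-FDB and shared members, in both the
#' read-weighted convention (summed over all samples' reads) and the
#' OTU-count convention (relative to all OTUs in the table).
#'
#' @param tab an [otu_table()].
#' @param assignments output of [map_otus()] covering BPB classes and FDB.
#' @return data.frame with rows `read_weighted` and `otu_count`; columns
#'   `unique_bpb`, `shared`, `unique_fdb`, `shared_over_fdb`.
#' @export
category_overlap <- function(tab, assignments) {
  validate_otu_table(tab)
  cats <- unique(assignments$category)
  bpb <- intersect(assigned_otus(assignments,
                                 grep("^BPB-", cats, value = TRUE)),
                   colnames(tab))
  fdb <- intersect(assigned_otus(assignments, "FDB"), colnames(tab))
  shared <- intersect(bpb, fdb)
  conv <- function(weight) {
    tot <- sum(weight)
    w <- function(ids) if (length(ids) == 0) 0 else sum(weight[ids]) / tot
    sh <- w(shared); fd <- w(fdb)
    c(unique_bpb = w(setdiff(bpb, fdb)), shared = sh,
      unique_fdb = w(setdiff(fdb, bpb)),
      shared_over_fdb = if (fd > 0) sh / fd else NA_real_)
  }
  reads <- colSums(tab)
  otus <- setNames(rep(1, ncol(tab)), colnames(tab))
  out <- rbind(read_weighted = conv(reads), otu_count = conv(otus))
  as.data.frame(out)
}

#' Concordance of functional proportions across identity thresholds
#'
#' Re-maps at each threshold and correlates the per-sample read proportions
#' between the first two thresholds, per category (Pearson r). The reference
#' analysis checks 0.97 vs 0.95.
#'
#' @param otus OTU sequences (named, `DNAStringSet` or character).
#' @param ref a [trait_reference()].
#' @param tab an [otu_table()] whose columns match the OTU names.
#' @param thresholds two identity thresholds.
#' @return named numeric vector of Pearson r per category (NA with a warning
#'   where a proportion vector is constant).
#' @export
threshold_concordance <- function(otus, ref, tab,
                                  thresholds = c(0.97, 0.95)) {
  if (nrow(tab) < 3) stop("need at least 3 samples")
  if (length(thresholds) != 2) stop("supply exactly two thresholds")
  if (!inherits(otus, "DNAStringSet")) otus <- Biostrings::DNAStringSet(otus)
  id_mat <- identity_matrix(otus, ref$sequences)
  profs <- lapply(thresholds, function(th)
    functional_profile(tab, map_otus(otus, ref, th, id_mat = id_mat)))
  cats <- intersect(colnames(profs[[1]]$read_prop),
                    colnames(profs[[2]]$read_prop))
  out <- setNames(rep(NA_real_, length(cats)), cats)
  for (cat in cats) {
    a <- profs[[1]]$read_prop[, cat]; b <- profs[[2]]$read_prop[, cat]
    if (sd(a) == 0 || sd(b) == 0) {
      if (isTRUE(all.equal(a, b))) out[cat] <- 1
      else {
        warning("zero variance for category ", cat, "; r undefined")
        out[cat] <- NA_real_
      }
    } else out[cat] <- if (all(a == b)) 1 else cor(a, b)
  }
  out
}
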