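#' Construct and validate an OTU count table
#'
#' The central community object: a non-negative integer matrix of read counts
#' with samples as rows and OTUs as columns. Row and column labels must be
#' unique and every retained sample must contain at least one read.
#'
#' @param counts numeric matrix, samples x OTUs, integer-valued and >= 0.
#' @param sample_ids,otu_ids optional label vectors overriding dimnames.
#' @return the validated count matrix with class `"otu_table"`.
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      otu_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids) || is.null(otu_ids))
    stop("otu_table requires sample and OTU labels")
  rownames(counts) <- as.character(sample_ids)
  colnames(counts) <- as.character(otu_ids)
  validate_otu_table(counts)
  class(counts) <- c("otu_table", class(counts))
  counts
}

validate_otu_table <- function(counts) {
  if (!is.numeric(counts))
    stop("OTU table must be numeric")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "OTU table cell must be a non-negative integer (row '%s', column '%s')",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample id: ",
         rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU id: ",
         colnames(counts)[duplicated(colnames(counts))][1])
  if (any(rowSums(counts) == 0))
    stop("sample(s) with zero reads: ",
         paste(rownames(counts)[rowSums(counts) == 0], collapse = ", "))
  invisible(counts)
}

#' Read an OTU table from TSV
#'
#' Expects a header row of OTU ids with the first column holding sample ids.
#' Lines starting with `#` are treated as comments. Samples are returned
#' sorted by id so that permutation seeds downstream are reproducible.
#'
#' @param path file path.
#' @return an [otu_table()].
#' @export
read_otu_table <- function(path) {
  x <- read.delim(path, header = TRUE, check.names = FALSE,
                  comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(x) < 2) stop("OTU table needs at least one OTU column")
  ids <- as.character(x[[1]])
  m <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cell in OTU table")
  rownames(m) <- ids
  m <- m[order(rownames(m)), , drop = FALSE]
  otu_table(m)
}

#' Write an OTU table to TSV
#'
#' @param tab an [otu_table()] (or plain matrix with dimnames).
#' @param path output path.
#' @param comment optional comment string written as a leading `#` line
#'   (typically the generating command and seed).
#' @export
write_otu_table <- function(tab, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  df <- data.frame(sample_id = rownames(tab), unclass(tab),
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read one or many rooted trees from a newick file
#'
#' Multi-tree files hold one tree per line. Missing branch lengths are set to
#' zero with a warning (phylogeny-aware dissimilarities reject trees whose
#' branch lengths are all zero).
#'
#' @param path newick file.
#' @return an `ape` `phylo` for a single tree, or a `multiPhylo` list.
#' @export
read_newick <- function(path) {
  trees <- tryCatch(ape::read.tree(path),
                    error = function(e) stop("newick parse error in '", path,
                                             "': ", conditionMessage(e)))
  if (is.null(trees)) stop("newick parse error in '", path, "'")
  fix_one <- function(tr) {
    if (is.null(tr$edge.length)) {
      warning("tree without branch lengths: defaulting all lengths to 0")
      tr$edge.length <- rep(0, nrow(tr$edge))
    } else if (anyNA(tr$edge.length)) {
      warning("missing branch length(s): defaulting to 0")
      tr$edge.length[is.na(tr$edge.length)] <- 0
    }
    if (any(tr$edge.length < 0)) stop("negative branch length in '", path, "'")
    tr
  }
  if (inherits(trees, "multiPhylo")) {
    out <- lapply(trees, fix_one)
    class(out) <- "multiPhylo"
    out
  } else fix_one(trees)
}

#' Read sample metadata from CSV
#'
#' Columns: `sample_id`, `species`, `locality_id`, `lat`, `lon`. Rows come
#' back sorted by sample id; coordinates are validated against their ranges.
#'
#' @param path CSV file.
#' @return a data.frame.
#' @export
read_metadata <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "species", "locality_id", "lat", "lon")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$sample_id))
    stop("duplicate sample id in metadata")
  if (any(x$lat < -90 | x$lat > 90, na.rm = TRUE))
    stop("latitude outside [-90, 90]")
  if (any(x$lon < -180 | x$lon > 180, na.rm = TRUE))
    stop("longitude outside [-180, 180]")
  x[order(x$sample_id), , drop = FALSE]
}

#' @rdname read_metadata
#' @param meta metadata data.frame.
#' @param path output path.
#' @param comment optional leading `#` comment line.
#' @export
write_metadata <- function(meta, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(meta, con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate / coerce a square dissimilarity matrix
#'
#' Enforces the dissimilarity-matrix contract: symmetric, exactly zero
#' diagonal, non-negative, labelled.
#'
#' @param m square matrix (or `dist`).
#' @param tol symmetry tolerance.
#' @return a `stats::dist` object.
#' @export
as_dist_matrix <- function(m, tol = 1e-10) {
  if (inherits(m, "dist")) m <- as.matrix(m)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("dissimilarity matrix must be square")
  if (is.null(rownames(m))) stop("dissimilarity matrix must be labelled")
  if (max(abs(m - t(m))) > tol) stop("dissimilarity matrix not symmetric")
  if (any(abs(diag(m)) > tol)) stop("dissimilarity diagonal must be 0")
  if (any(m < 0)) stop("negative dissimilarity")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  as.dist(m)
}

#' Read / write a square dissimilarity matrix as TSV
#'
#' Serialized square, with labels in the header and first column.
#'
#' @param path TSV file.
#' @return a `dist` object.
#' @export
read_dist_matrix <- function(path) {
  x <- read.delim(path, header = TRUE, check.names = FALSE,
                  comment.char = "#", row.names = 1)
  as_dist_matrix(as.matrix(x))
}

#' @rdname read_dist_matrix
#' @param d `dist` object or square matrix.
#' @param comment optional leading `#` comment line.
#' @export
write_dist_matrix <- function(d, path, comment = NULL) {
  m <- as.matrix(d)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write DNA sequences in FASTA
#'
#' @param path FASTA file.
#' @return a `Biostrings::DNAStringSet`.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  if (any(Biostrings::width(s) == 0)) stop("empty sequence in '", path, "'")
  if (anyDuplicated(names(s))) stop("duplicate sequence id in '", path, "'")
  s
}

#' @rdname read_fasta
#' @param seqs named character vector or `DNAStringSet`.
#' @export
write_fasta <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Align an OTU table with its sample metadata
#'
#' Restricts both to the (sorted) intersection of sample ids, in identical
#' order. Dropped samples trigger a warning; an empty intersection is an
#' error.
#'
#' @param tab an [otu_table()].
#' @param meta metadata data.frame with a `sample_id` column.
#' @return list with elements `tab` and `meta`.
#' @export
align_table_metadata <- function(tab, meta) {
  common <- sort(intersect(rownames(tab), meta$sample_id))
  if (length(common) == 0)
    stop("no samples shared between OTU table and metadata")
  dropped <- c(setdiff(rownames(tab), common), setdiff(meta$sample_id, common))
  if (length(dropped) > 0)
    warning("dropping unmatched sample(s): ", paste(dropped, collapse = ", "))
  tab2 <- tab[common, , drop = FALSE]
  meta2 <- meta[match(common, meta$sample_id), , drop = FALSE]
  rownames(meta2) <- NULL
  list(tab = otu_table(unclass(tab2)), meta = meta2)
}
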