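#' @importFrom stats cophenetic cor lm median optimise pbeta qbeta quantile
#'   rbeta rlnorm rmultinom rnorm runif sd setNames coef pf pt complete.cases
#' @importFrom utils read.table write.table read.csv write.csv combn
NULL

METAL_ELEMENTS <- c("Cd", "Zn", "Fe", "Cu", "Pb")
SOIL_VARIABLES <- c("SOM", "AP", "SMC", "AK", "pH", "TN")
HABITAT_CATEGORIES <- c("urban", "suburban", "exurban", "rural")

#' Validate an OTU abundance table
#'
#' An OTU table is a base matrix of non-negative read counts with samples as
#' rows and OTUs as columns, both dimensions named. Validation enforces unique
#' identifiers and non-negative finite counts, and (by default) drops samples
#' and OTUs whose total count is zero, with a warning -- empty rows/columns
#' are a normal by-product of subsetting and carry no information for any
#' downstream statistic.
#'
#' @param x numeric matrix, samples x OTUs, with rownames (sample ids) and
#'   colnames (OTU ids).
#' @param drop_empty drop all-zero samples and OTUs (default `TRUE`); if
#'   `FALSE`, an all-zero sample is an error.
#' @return the validated (possibly reduced) matrix.
#' @export
validate_otu_table <- function(x, drop_empty = TRUE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("OTU table must be a numeric matrix (samples x OTUs)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("OTU table must have sample ids as rownames and OTU ids as colnames")
  if (anyDuplicated(rownames(x))) stop("duplicate sample ids in OTU table")
  if (anyDuplicated(colnames(x))) stop("duplicate OTU ids in OTU table")
  if (any(!is.finite(x))) stop("OTU table contains non-finite values")
  if (any(x < 0)) stop("OTU table contains negative counts")
  empty_otus <- colSums(x) == 0
  empty_samples <- rowSums(x) == 0
  if (drop_empty) {
    if (any(empty_otus)) {
      warning(sprintf("dropping %d all-zero OTU(s): %s", sum(empty_otus),
                      paste(utils::head(colnames(x)[empty_otus], 5), collapse = ", ")))
      x <- x[, !empty_otus, drop = FALSE]
    }
    if (any(empty_samples)) {
      warning(sprintf("dropping %d empty sample(s): %s", sum(empty_samples),
                      paste(utils::head(rownames(x)[empty_samples], 5), collapse = ", ")))
      x <- x[!empty_samples, , drop = FALSE]
    }
  } else if (any(empty_samples) || any(empty_otus)) {
    stop("OTU table contains all-zero samples or OTUs")
  }
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("OTU table needs at least 2 samples and 2 OTUs after validation")
  x
}

#' Read an OTU table from tab-separated text
#'
#' The caller states the orientation explicitly; no auto-detection is
#' attempted, because silently transposing a community matrix is the classic
#' OTU-table bug. The first column holds row identifiers.
#'
#' @param path path to a TSV file with a header row and one id column.
#' @param orientation `"samples_as_rows"` or `"otus_as_rows"`.
#' @param drop_empty passed to [validate_otu_table()].
#' @return validated samples x OTUs matrix.
#' @export
read_otu_table <- function(path,
                           orientation = c("samples_as_rows", "otus_as_rows"),
                           drop_empty = TRUE) {
  orientation <- match.arg(orientation)
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   comment.char = "", quote = "", stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate row ids in ", path)
  body <- df[, -1, drop = FALSE]
  if (!all(vapply(body, is.numeric, logical(1))))
    stop("non-numeric abundance cell(s) in ", path)
  m <- as.matrix(body)
  rownames(m) <- ids
  if (orientation == "otus_as_rows") m <- t(m)
  validate_otu_table(m, drop_empty = drop_empty)
}

#' Write an OTU table as tab-separated text
#'
#' Samples as rows; integer counts are written without decimals so that
#' write-then-read round-trips bit-exactly.
#'
#' @param x samples x OTUs matrix.
#' @param path output path.
#' @export
write_otu_table <- function(x, path) {
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from a newick file
#'
#' @param path newick file.
#' @param missing_lengths `"error"` to reject trees without branch lengths,
#'   `"zero"` to set missing lengths to 0.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path, missing_lengths = c("error", "zero")) {
  missing_lengths <- match.arg(missing_lengths)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("unparseable newick in ", path, ": ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("unparseable newick in ", path)
  if (anyDuplicated(tree$tip.label)) stop("tip label collision in ", path)
  if (is.null(tree$edge.length)) {
    if (missing_lengths == "error") stop("tree in ", path, " has no branch lengths")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (any(is.na(tree$edge.length))) {
    if (missing_lengths == "error") stop("tree in ", path, " has missing branch lengths")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in ", path)
  tree
}

#' Prune a phylogeny to a set of OTU ids
#'
#' @param tree `phylo` object.
#' @param otu_ids tip labels to keep; must all be tips of `tree`.
#' @return pruned `phylo`.
#' @export
prune_tree <- function(tree, otu_ids) {
  missing <- setdiff(otu_ids, tree$tip.label)
  if (length(missing))
    stop("OTUs absent from tree: ", paste(utils::head(missing, 5), collapse = ", "))
  ape::keep.tip(tree, otu_ids)
}

#' Read per-sample metadata from CSV
#'
#' Expected columns: `sample_id`, `category` (one of urban / suburban /
#' exurban / rural), `distance_km`, the soil variables SOM, AP, SMC, AK, pH,
#' TN, and -- when pollution indices will be requested -- the five metal
#' concentrations Cd, Zn, Fe, Cu, Pb (mg/kg).
#'
#' @param path CSV file with a header.
#' @param require_metals error if any of the five metal columns is missing
#'   (default `TRUE`).
#' @return data.frame, one row per sample.
#' @export
read_metadata <- function(path, require_metals = TRUE) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c("sample_id", "category", "distance_km")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (require_metals) {
    miss_m <- setdiff(METAL_ELEMENTS, names(df))
    if (length(miss_m))
      stop("metadata missing metal column(s): ", paste(miss_m, collapse = ", "))
  }
  bad <- setdiff(unique(df$category), HABITAT_CATEGORIES)
  if (length(bad)) stop("unknown category value(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  if (any(df$distance_km < 0)) stop("negative distance in metadata")
  df$category <- factor(df$category, levels = HABITAT_CATEGORIES)
  df
}

#' Align an OTU table with sample metadata
#'
#' Every downstream statistic assumes the table and metadata carry the same
#' samples in the same order; this join enforces that once, up front.
#'
#' @param table samples x OTUs matrix.
#' @param metadata data.frame with a `sample_id` column.
#' @return list with elements `table` and `metadata`, identically ordered.
#' @export
align_samples <- function(table, metadata) {
  common <- intersect(rownames(table), metadata$sample_id)
  if (length(common) < 2) stop("fewer than 2 samples shared by table and metadata")
  lost_t <- setdiff(rownames(table), common)
  lost_m <- setdiff(metadata$sample_id, common)
  if (length(lost_t) || length(lost_m))
    warning(sprintf("dropping %d table / %d metadata sample(s) absent from the join",
                    length(lost_t), length(lost_m)))
  table <- table[common, , drop = FALSE]
  metadata <- metadata[match(common, metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  list(table = table, metadata = metadata)
}
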