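#' Alpha diversity per sample
#'
#' Richness (number of OTUs with count > 0) and Shannon diversity (natural
#' log, via vegan's `diversity`).
#'
#' @param table samples x OTUs count matrix.
#' @return data.frame: `sample_id`, `richness`, `shannon`.
#' @export
alpha_diversity <- function(table) {
  data.frame(sample_id = rownames(table),
             richness = rowSums(table > 0),
             shannon = vegan::diversity(table, index = "shannon"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' BC(j,k) = sum |x_j - x_k| / sum (x_j + x_k) on within-sample relative
#' abundances, in [0, 1], symmetric, zero diagonal.
#'
#' @param table samples x OTUs count matrix with positive sample totals.
#' @return symmetric samples x samples matrix.
#' @export
bray_curtis <- function(table) {
  if (any(rowSums(table) == 0)) stop("sample with zero total count")
  rel <- table / rowSums(table)
  as.matrix(vegan::vegdist(rel, method = "bray"))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the matrices' upper triangles, with significance
#' from simultaneous row/column permutations of the second matrix (vegan's
#' `mantel`), one-tailed (greater) with the +1 permutation correction, so
#' the p-value is never exactly 0.
#'
#' @param D1,D2 symmetric zero-diagonal matrices (or `dist`) over the same
#'   samples.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list: `r`, `p_value`, `n_perm`, `tail`.
#' @export
mantel_test <- function(D1, D2, n_perm = 999, seed) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  if (!all(dim(D1) == dim(D2))) stop("distance matrices differ in size")
  if (sd(D1[upper.tri(D1)]) == 0 || sd(D2[upper.tri(D2)]) == 0)
    stop("constant distance matrix: Mantel r undefined")
  set.seed(seed)
  fit <- vegan::mantel(stats::as.dist(D1), stats::as.dist(D2),
                       method = "pearson", permutations = n_perm)
  list(r = unname(fit$statistic), p_value = fit$signif, n_perm = n_perm,
       tail = "greater")
}

#' Spearman rank correlation matrix with p-values
#'
#' rho for every column pair of `X` and `Y` using average ranks for ties,
#' with p-values from the t approximation
#' t = rho sqrt((n-2)/(1-rho^2)) on n-2 degrees of freedom. A constant
#' column yields `NA` (flagged, not an error) rather than aborting the batch.
#'
#' @param X,Y numeric matrices or data.frames with paired rows (n >= 4).
#' @return list of matrices `rho` and `p` (rows = columns of X, cols =
#'   columns of Y).
#' @export
spearman_matrix <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  if (n < 4) stop("need >= 4 paired observations")
  rho <- matrix(NA_real_, ncol(X), ncol(Y), dimnames = list(colnames(X), colnames(Y)))
  pval <- rho
  for (i in seq_len(ncol(X))) for (j in seq_len(ncol(Y))) {
    x <- X[, i]; y <- Y[, j]
    ok <- complete.cases(x, y)
    if (sum(ok) < 4 || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
    r <- cor(rank(x[ok]), rank(y[ok]), method = "pearson")
    m <- sum(ok)
    if (abs(r) >= 1) {
      rho[i, j] <- r; pval[i, j] <- 0
    } else {
      tstat <- r * sqrt((m - 2) / (1 - r^2))
      rho[i, j] <- r
      pval[i, j] <- 2 * pt(-abs(tstat), df = m - 2)
    }
  }
  list(rho = rho, p = pval)
}

#' Significance stars
#'
#' `***`, `**`, `*` at p < 0.001 / 0.01 / 0.05, the usual figure-legend
#' convention; empty string otherwise.
#'
#' @param p numeric p-value(s).
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

# map a per-sample covariate onto sample pairs
.pair_predictor <- function(values, sample_a, sample_b, pairing) {
  va <- values[sample_a]; vb <- values[sample_b]
  if (pairing == "pair_mean") (va + vb) / 2 else abs(va - vb)
}

#' Regress betaNTI on the Nemerow pollution index
#'
#' betaNTI is a pairwise quantity while Pn is per sample, so each sample
#' pair's predictor is either the mean of the two samples' Pn (default) or
#' their absolute difference. Ordinary least squares of betaNTI on the
#' predictor; degenerate pairs (undefined betaNTI) are excluded.
#'
#' @param bnti data.frame from [beta_nti()].
#' @param pollution data.frame from [pollution_indices()] (needs `sample_id`,
#'   `Pn`).
#' @param pairing `"pair_mean"` or `"pair_abs_difference"`.
#' @return list: `slope`, `intercept`, `r_squared`, `p_value`, `n`,
#'   `pairing`.
#' @export
bnti_vs_pollution <- function(bnti, pollution,
                              pairing = c("pair_mean", "pair_abs_difference")) {
  pairing <- match.arg(pairing)
  pn <- setNames(pollution$Pn, pollution$sample_id)
  missing <- setdiff(unique(c(bnti$sample_a, bnti$sample_b)), names(pn))
  if (length(missing)) stop("samples without pollution record: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  keep <- !bnti$degenerate & !is.na(bnti$bnti)
  x <- .pair_predictor(pn, bnti$sample_a[keep], bnti$sample_b[keep], pairing)
  y <- bnti$bnti[keep]
  if (length(y) < 3) stop("fewer than 3 usable sample pairs")
  if (sd(x) == 0) stop("constant predictor: slope undefined")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
                           lower.tail = FALSE)),
       n = length(y), pairing = pairing)
}

#' Spearman correlation between betaNTI and per-sample covariates
#'
#' Maps each covariate (e.g. heavy-metal concentration) onto sample pairs as
#' in [bnti_vs_pollution()] and correlates with betaNTI by Spearman rank
#' correlation.
#'
#' @param bnti data.frame from [beta_nti()].
#' @param metadata data.frame with `sample_id` and the covariate columns.
#' @param variables covariate column names (default the five metals).
#' @param pairing `"pair_mean"` or `"pair_abs_difference"`.
#' @return data.frame: `variable`, `rho`, `p_value`, `stars`.
#' @export
bnti_vs_covariates <- function(bnti, metadata, variables = METAL_ELEMENTS,
                               pairing = c("pair_mean", "pair_abs_difference")) {
  pairing <- match.arg(pairing)
  keep <- !bnti$degenerate & !is.na(bnti$bnti)
  y <- bnti$bnti[keep]
  out <- lapply(variables, function(v) {
    vals <- setNames(metadata[[v]], metadata$sample_id)
    x <- .pair_predictor(vals, bnti$sample_a[keep], bnti$sample_b[keep], pairing)
    sp <- spearman_matrix(cbind(x = x), cbind(y = y))
    data.frame(variable = v, rho = sp$rho[1, 1], p_value = sp$p[1, 1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$stars <- significance_stars(out$p_value)
  out
}

#' Shared and unique OTU partition across habitat categories
#'
#' An OTU belongs to a category if present (count > 0) in at least one of its
#' samples. Every OTU observed anywhere falls in exactly one Venn region --
#' the exact set of categories containing it -- so region counts partition
#' the observed OTUs.
#'
#' @param table samples x OTUs count matrix.
#' @param metadata data.frame with `sample_id` and `category`, covering the
#'   table's samples.
#' @return list: `regions` (named integer counts, names like
#'   `"urban&rural"`), `core_fraction` (share of OTUs present in every
#'   non-empty category), `total_otus`.
#' @export
shared_otu_partition <- function(table, metadata) {
  md <- metadata[match(rownames(table), metadata$sample_id), ]
  if (any(is.na(md$category))) stop("uncategorized sample(s) in table")
  cats <- HABITAT_CATEGORIES[HABITAT_CATEGORIES %in% unique(as.character(md$category))]
  empty <- setdiff(HABITAT_CATEGORIES, cats)
  if (length(empty))
    warning("empty categor(ies) ignored: ", paste(empty, collapse = ", "))
  membership <- sapply(cats, function(cc)
    colSums(table[md$category == cc, , drop = FALSE]) > 0)
  observed <- rowSums(membership) > 0
  keys <- apply(membership[observed, , drop = FALSE], 1, function(m)
    paste(cats[m], collapse = "&"))
  tab <- base::table(keys)
  regions <- setNames(as.integer(tab), names(tab))
  core_key <- paste(cats, collapse = "&")
  list(regions = regions,
       core_fraction = if (sum(observed) > 0)
         sum(keys == core_key) / sum(observed) else NA_real_,
       total_otus = sum(observed))
}
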