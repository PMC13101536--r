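#' Patristic distance matrix of a phylogeny
#'
#' Sum of branch lengths along the path between every pair of tips.
#'
#' @param tree `phylo` with branch lengths.
#' @return symmetric tips x tips matrix, zero diagonal.
#' @export
patristic_distances <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(is.na(tree$edge.length))) stop("tree has missing branch lengths")
  as.matrix(stats::cophenetic(tree))
}

# relative-abundance matrix used by the betaMNTD weighting: rows sum to 1;
# weighted = FALSE replaces abundances by 1/richness over present OTUs
.rel_weights <- function(table, weighted) {
  if (any(rowSums(table) == 0)) stop("empty sample in table")
  if (weighted) {
    table / rowSums(table)
  } else {
    pres <- table > 0
    pres / rowSums(pres)
  }
}

# core betaMNTD engine shared by the observed statistic and the null loop.
# For sample k, M[k, i] = min_{i' present in k} D[i, i'] for every OTU i;
# then term1[j, k] = sum_i F[j, i] M[k, i] is a single matrix product and
# betaMNTD = (term1 + t(term1)) / 2. `perm` relabels the distance matrix
# (tip-shuffling null) without copying it: D_perm[i, j] = D[perm[i], perm[j]],
# so min over columns perm[idx_k] followed by row reindexing by perm.
.bmntd_engine <- function(F_rel, D, present_idx, perm = NULL) {
  n_samples <- nrow(F_rel)
  n_otus <- ncol(F_rel)
  M <- matrix(0, n_samples, n_otus)
  for (k in seq_len(n_samples)) {
    cols <- present_idx[[k]]
    if (!is.null(perm)) cols <- perm[cols]
    v <- if (length(cols) == 1L) D[, cols] else
      do.call(pmin, lapply(cols, function(j) D[, j]))
    M[k, ] <- if (is.null(perm)) v else v[perm]
  }
  term1 <- F_rel %*% t(M)
  (term1 + t(term1)) / 2
}

#' Pairwise beta mean nearest taxon distance
#'
#' For samples j, k with relative abundances f, betaMNTD(j,k) is the mean,
#' weighted by f, of each taxon's patristic distance to its nearest taxon in
#' the other sample, averaged over both directions:
#' 0.5 * (sum_{i in j} f_ij min_{i' in k} d(i,i') +
#'        sum_{i' in k} f_i'k min_{i in j} d(i',i)).
#' A taxon present in both samples contributes 0 (its nearest taxon is
#' itself), so identical samples have betaMNTD 0.
#'
#' @param table samples x OTUs count matrix; OTU ids must all be rows of `D`.
#' @param D patristic distance matrix from [patristic_distances()].
#' @param weighted abundance-weighted (default) or presence/absence
#'   (`f = 1/richness`).
#' @return symmetric samples x samples matrix.
#' @export
beta_mntd <- function(table, D, weighted = TRUE) {
  missing <- setdiff(colnames(table), rownames(D))
  if (length(missing)) stop("OTUs absent from distance matrix: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  D <- D[colnames(table), colnames(table)]
  F_rel <- .rel_weights(table, weighted)
  present_idx <- lapply(seq_len(nrow(table)), function(j) which(table[j, ] > 0))
  out <- .bmntd_engine(F_rel, D, present_idx)
  dimnames(out) <- list(rownames(table), rownames(table))
  out
}

#' Naive reference implementation of betaMNTD
#'
#' Direct double loop over sample pairs and taxa, written independently of
#' the optimized engine so it can serve as a brute-force oracle in tests.
#'
#' @inheritParams beta_mntd
#' @export
beta_mntd_brute <- function(table, D, weighted = TRUE) {
  D <- D[colnames(table), colnames(table)]
  F_rel <- .rel_weights(table, weighted)
  n <- nrow(table)
  out <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j == k) next
    pj <- which(table[j, ] > 0)
    pk <- which(table[k, ] > 0)
    s1 <- 0
    for (i in pj) s1 <- s1 + F_rel[j, i] * min(D[i, pk])
    s2 <- 0
    for (i in pk) s2 <- s2 + F_rel[k, i] * min(D[i, pj])
    out[j, k] <- 0.5 * (s1 + s2)
  }
  out
}

#' Beta nearest taxon index (betaNTI)
#'
#' Standardized effect size of betaMNTD against a tip-shuffling null: for
#' each null iteration the tip labels of the patristic distance matrix are
#' permuted uniformly at random (equivalently, taxa are randomly relabeled on
#' the tree) and betaMNTD is recomputed for every sample pair. betaNTI is the
#' z-score (observed - null mean) / null sd. |betaNTI| <= 2 is read as
#' stochastic assembly (drift, dispersal), betaNTI > 2 or < -2 as
#' deterministic selection. Pairs whose null sd is 0 (e.g. under a star
#' phylogeny, where every shuffle gives identical distances) are flagged
#' degenerate and get `NA` betaNTI rather than an infinite z-score.
#'
#' @param table samples x OTUs count matrix.
#' @param tree `phylo` whose tips cover the table's OTUs (extra tips are
#'   pruned).
#' @param n_null number of null randomizations (>= 99; default 999).
#' @param weighted abundance weighting as in [beta_mntd()].
#' @param seed integer seed.
#' @return data.frame, one row per unordered sample pair: `sample_a`,
#'   `sample_b`, `bmntd_obs`, `null_mean`, `null_sd`, `bnti`, `degenerate`,
#'   `n_null`.
#' @export
beta_nti <- function(table, tree, n_null = 999, weighted = TRUE, seed) {
  if (n_null < 99) stop("n_null must be >= 99")
  tree <- prune_tree(tree, colnames(table))
  D <- patristic_distances(tree)[colnames(table), colnames(table)]
  F_rel <- .rel_weights(table, weighted)
  present_idx <- lapply(seq_len(nrow(table)), function(j) which(table[j, ] > 0))
  obs <- .bmntd_engine(F_rel, D, present_idx)
  n_samples <- nrow(table)
  n_otus <- ncol(table)
  ut <- upper.tri(obs)
  n_pairs <- sum(ut)
  set.seed(seed)
  null_sum <- numeric(n_pairs)
  null_sumsq <- numeric(n_pairs)
  for (it in seq_len(n_null)) {
    perm <- sample.int(n_otus)
    bm <- .bmntd_engine(F_rel, D, present_idx, perm = perm)[ut]
    null_sum <- null_sum + bm
    null_sumsq <- null_sumsq + bm^2
  }
  null_mean <- null_sum / n_null
  null_var <- pmax(null_sumsq / n_null - null_mean^2, 0) * n_null / (n_null - 1)
  null_sd <- sqrt(null_var)
  degenerate <- null_sd < 1e-12
  bnti <- ifelse(degenerate, NA_real_, (obs[ut] - null_mean) / null_sd)
  idx <- which(ut, arr.ind = TRUE)
  data.frame(sample_a = rownames(table)[idx[, 1]],
             sample_b = rownames(table)[idx[, 2]],
             bmntd_obs = obs[ut], null_mean = null_mean, null_sd = null_sd,
             bnti = bnti, degenerate = degenerate, n_null = n_null,
             stringsAsFactors = FALSE)
}

#' Deterministic vs stochastic assembly fractions
#'
#' Fractions of non-degenerate sample pairs whose betaNTI falls outside
#' (deterministic: |betaNTI| > 2) or inside (stochastic: |betaNTI| <= 2) the
#' +/-2 band; also reports the deterministic split into heterogeneous
#' (betaNTI > 2, variable selection) and homogeneous (betaNTI < -2,
#' homogeneous selection) components.
#'
#' @param results data.frame from [beta_nti()].
#' @param threshold z-score threshold (default 2).
#' @return named list: `deterministic`, `stochastic`, `variable_selection`,
#'   `homogeneous_selection`, `n_pairs` (non-degenerate pairs used).
#' @export
assembly_fractions <- function(results, threshold = 2) {
  z <- results$bnti[!results$degenerate & !is.na(results$bnti)]
  if (length(z) == 0) stop("all sample pairs degenerate; fractions undefined")
  list(deterministic = mean(abs(z) > threshold),
       stochastic = mean(abs(z) <= threshold),
       variable_selection = mean(z > threshold),
       homogeneous_selection = mean(z < -threshold),
       n_pairs = length(z))
}
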