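#' Levins' niche breadth
#'
#' For one OTU with abundance a_j across samples and P_j = a_j / sum(a),
#' B = 1 / sum(P_j^2). B ranges from 1 (all abundance in one sample; extreme
#' specialist) to the number of samples (perfectly even use of all habitats;
#' extreme generalist). Invariant to rescaling the vector by a positive
#' constant.
#'
#' @param abundances non-negative per-sample vector with positive sum.
#' @export
levins_breadth <- function(abundances) {
  if (any(abundances < 0)) stop("abundances must be non-negative")
  s <- sum(abundances)
  if (s == 0) stop("breadth undefined for an all-zero abundance vector")
  P <- abundances / s
  1 / sum(P^2)
}

# breadth of every OTU (column) of a samples x OTUs matrix; zero-total
# columns return NA rather than erroring, for use inside null loops
.breadth_cols <- function(x) {
  tot <- colSums(x)
  P2 <- colSums((x / rep(tot, each = nrow(x)))^2)
  B <- 1 / P2
  B[tot == 0] <- NA_real_
  B
}

#' Classify OTUs into habitat generalists, specialists and neutrals
#'
#' Computes Levins' breadth per OTU and compares it against a permutation
#' null distribution: OTUs whose breadth lies above the upper 95% bound of
#' their null distribution are generalists, below the lower bound
#' specialists, otherwise neutral (ties are neutral -- strict inequalities).
#'
#' The default null (`"quasiswap"`) randomizes the count matrix with fixed
#' row and column sums (vegan's `quasiswap_count` algorithm), the null behind
#' the established generalist/specialist permutation classification; each
#' OTU keeps its total abundance and each sample its depth while occurrence
#' structure is randomized. The `"across_otu"` alternative permutes the
#' assignment of abundance vectors to OTUs, so each OTU's null is the
#' breadth distribution of the observed vectors; it conditions on the
#' observed set of breadths rather than on the margins. Note that shuffling
#' one OTU's abundances across samples is *not* offered as a null: breadth
#' is a symmetric function of the vector, so that shuffle never changes B.
#'
#' @param table samples x OTUs count matrix (>= 3 samples).
#' @param n_perm number of null matrices (>= 100; default 1000).
#' @param alpha two-sided level for the null quantile bounds (default 0.05).
#' @param seed integer seed.
#' @param null_model `"quasiswap"` (fixed row/column sums) or `"across_otu"`.
#' @return data.frame: `otu_id`, `breadth`, `null_lower`, `null_upper`,
#'   `label` (generalist / specialist / neutral).
#' @export
classify_otus <- function(table, n_perm = 1000, alpha = 0.05, seed,
                          null_model = c("quasiswap", "across_otu")) {
  null_model <- match.arg(null_model)
  if (nrow(table) < 3) stop("need >= 3 samples to classify niches")
  if (n_perm < 100) stop("n_perm must be >= 100 (null quantiles unstable below)")
  if (any(colSums(table) == 0))
    stop("all-zero OTU column(s): validate_otu_table() the input first")
  B_obs <- .breadth_cols(table)
  n_otus <- ncol(table)
  null_B <- matrix(NA_real_, n_perm, n_otus)
  set.seed(seed)
  if (null_model == "quasiswap") {
    nm <- vegan::nullmodel(round(table), "quasiswap_count")
    sims <- stats::simulate(nm, nsim = n_perm)
    for (k in seq_len(n_perm)) null_B[k, ] <- .breadth_cols(sims[, , k])
  } else {
    for (k in seq_len(n_perm)) {
      perm <- sample.int(n_otus)
      null_B[k, ] <- B_obs[perm]
    }
  }
  lo <- apply(null_B, 2, quantile, probs = alpha / 2, na.rm = TRUE, type = 7)
  hi <- apply(null_B, 2, quantile, probs = 1 - alpha / 2, na.rm = TRUE, type = 7)
  label <- ifelse(B_obs > hi, "generalist",
                  ifelse(B_obs < lo, "specialist", "neutral"))
  data.frame(otu_id = colnames(table), breadth = B_obs,
             null_lower = lo, null_upper = hi, label = label,
             row.names = NULL, stringsAsFactors = FALSE)
}
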