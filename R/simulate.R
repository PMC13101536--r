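#' Derive a stage-specific sub-seed from a global seed
#'
#' Stable hash of the stage name mixed with the global seed, so that
#' reordering pipeline stages never changes any stage's random stream.
#' Always returns a positive integer below 2^31.
#'
#' @param stage character stage name.
#' @param seed global integer seed.
#' @export
derive_seed <- function(stage, seed) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 104729
  as.integer((abs(as.numeric(seed)) * 7919 + h * 31 + 17) %% 2147483587) + 1L
}

#' Simulate a Yule (pure-birth) phylogeny
#'
#' Ultrametric pure-birth tree with tips labeled `OTU_1 .. OTU_n`. Branch
#' lengths arise from exponential waiting times between birth events.
#'
#' @param n_otus number of tips (>= 2).
#' @param seed integer seed.
#' @param birth birth rate (default 1).
#' @return a `phylo` object.
#' @export
simulate_phylogeny <- function(n_otus, seed, birth = 1) {
  if (n_otus < 2) stop("n_otus must be >= 2")
  set.seed(seed)
  tree <- ape::rphylo(n_otus, birth = birth, death = 0)
  tree$tip.label <- paste0("OTU_", seq_len(n_otus))
  tree
}

#' Draw metacommunity relative abundances
#'
#' Long-tailed species-abundance distribution for the regional pool. The
#' log-series option draws per-OTU abundances from Fisher's log-series with
#' parameter `x` (P(k) proportional to x^k / k); the lognormal option draws
#' from a lognormal with log-sd `sdlog`. Returned abundances sum to 1.
#'
#' @param n_otus number of OTUs.
#' @param distribution `"logseries"` or `"lognormal"`.
#' @param x log-series parameter in (0,1); values near 1 give heavier tails.
#' @param sdlog lognormal log-scale sd.
#' @return numeric vector of length `n_otus` summing to 1.
#' @keywords internal
metacommunity_abundances <- function(n_otus,
                                     distribution = c("logseries", "lognormal"),
                                     x = 0.995, sdlog = 1.5) {
  distribution <- match.arg(distribution)
  if (distribution == "logseries") {
    kmax <- 100000L
    k <- seq_len(kmax)
    pmf <- x^k / k
    ab <- sample(k, n_otus, replace = TRUE, prob = pmf)
  } else {
    ab <- rlnorm(n_otus, meanlog = 0, sdlog = sdlog)
  }
  ab / sum(ab)
}

#' Specification for a neutral community simulation
#'
#' @param n_samples number of local communities.
#' @param n_otus number of OTUs in the metacommunity.
#' @param N reads per sample (local community size).
#' @param m migration (immigration) rate in (0, 1].
#' @param metacommunity `"logseries"` or `"lognormal"`.
#' @param seed integer seed (mandatory; generators are pure functions of the
#'   spec including the seed).
#' @param p optional explicit metacommunity relative abundances (sum to 1);
#'   overrides `metacommunity`.
#' @return a `neutral_sim_spec` list.
#' @export
neutral_sim_spec <- function(n_samples, n_otus, N, m,
                             metacommunity = "logseries", seed, p = NULL) {
  if (m <= 0 || m > 1) stop("m must be in (0, 1]")
  if (N <= 0) stop("N must be positive")
  if (!is.null(p)) {
    if (length(p) != n_otus || any(p <= 0))
      stop("p must be a positive vector of length n_otus")
    p <- p / sum(p)
  }
  structure(list(n_samples = n_samples, n_otus = n_otus, N = N, m = m,
                 metacommunity = metacommunity, seed = seed, p = p),
            class = "neutral_sim_spec")
}

# Shared sampler behind the neutral and selection generators: Sloan's
# stationary Beta for local relative abundance, an optional per-sample
# selection weight, then a multinomial read draw. weights = NULL is the
# neutral model; the selection generator passes its Gaussian niche weights,
# so selection_strength = 0 reduces exactly to the neutral code path.
.simulate_table <- function(spec, weights = NULL) {
  set.seed(spec$seed)
  p <- spec$p
  if (is.null(p))
    p <- metacommunity_abundances(spec$n_otus, spec$metacommunity)
  Nm <- spec$N * spec$m
  a <- Nm * p
  b <- Nm * (1 - p)
  if (any(a <= 0) || any(b <= 0)) stop("Beta parameters must be positive (check N, m, p)")
  n <- spec$n_samples
  counts <- matrix(0L, n, spec$n_otus,
                   dimnames = list(paste0("S", seq_len(n)),
                                   paste0("OTU_", seq_len(spec$n_otus))))
  for (j in seq_len(n)) {
    xj <- rbeta(spec$n_otus, a, b)
    if (!is.null(weights)) xj <- xj * weights[j, ]
    s <- sum(xj)
    if (s == 0) xj <- p else xj <- xj / s
    counts[j, ] <- rmultinom(1, size = spec$N, prob = xj)[, 1]
  }
  attr(counts, "metacommunity") <- p
  counts
}

#' Simulate a neutral OTU table under Sloan's model
#'
#' For each OTU i with metacommunity relative abundance p_i and each sample,
#' local relative abundance is drawn from the stationary Beta distribution
#' Beta(N m p_i, N m (1 - p_i)), renormalized within the sample, and reads
#' are drawn multinomially with total N. Drawing from the stationary
#' distribution (rather than running birth-death dynamics) matches the model
#' that [fit_ncm()] fits, making parameter recovery a clean test.
#'
#' @param spec a [neutral_sim_spec()].
#' @return samples x OTUs count matrix; the metacommunity abundances used are
#'   attached as `attr(, "metacommunity")`.
#' @export
simulate_neutral_table <- function(spec) {
  stopifnot(inherits(spec, "neutral_sim_spec"))
  .simulate_table(spec)
}

#' Specification for a selection-driven community simulation
#'
#' Extends [neutral_sim_spec()] with an environmental gradient, Gaussian
#' niches, and Brownian-motion trait evolution on a phylogeny so that
#' selection leaves a phylogenetic signal detectable by betaNTI (conserved
#' optima are what power nearest-taxon metrics).
#'
#' @inheritParams neutral_sim_spec
#' @param tree `phylo` over `OTU_1..OTU_n` on which optima evolve.
#' @param env_gradient per-sample environmental value E_j; default an evenly
#'   spaced gradient on `[0, 1]`.
#' @param sigma niche breadth (> 0) on the gradient's scale.
#' @param selection_strength selection intensity (>= 0); 0 reduces exactly to
#'   the neutral generator.
#' @param bm_rate Brownian-motion rate for trait evolution.
#' @return a `selection_sim_spec` list.
#' @export
selection_sim_spec <- function(n_samples, n_otus, N, m, tree,
                               metacommunity = "logseries", seed,
                               env_gradient = NULL, sigma = 0.1,
                               selection_strength = 1, bm_rate = 1, p = NULL) {
  base <- neutral_sim_spec(n_samples, n_otus, N, m, metacommunity, seed, p)
  if (sigma <= 0) stop("sigma must be > 0")
  if (selection_strength < 0) stop("selection_strength must be >= 0")
  if (is.null(env_gradient)) env_gradient <- seq(0, 1, length.out = n_samples)
  if (length(env_gradient) != n_samples) stop("env_gradient length must equal n_samples")
  spec <- c(base, list(tree = tree, env_gradient = env_gradient, sigma = sigma,
                       selection_strength = selection_strength, bm_rate = bm_rate))
  class(spec) <- c("selection_sim_spec", "neutral_sim_spec")
  spec
}

#' Simulate an OTU table under environmental selection
#'
#' OTU environmental optima evolve on the phylogeny by Brownian motion
#' (phylogenetically conserved niches), are affinely rescaled onto the range
#' of the sample gradient, and weight the neutral Sloan draw by a Gaussian
#' niche term exp(-s (E_j - mu_i)^2 / (2 sigma^2)) before the multinomial
#' read draw. With `selection_strength = 0` the weights are identically 1 and
#' the output equals [simulate_neutral_table()] exactly for the same spec.
#'
#' @param spec a [selection_sim_spec()].
#' @return list with `table` (samples x OTUs counts) and `optima` (named
#'   per-OTU true environmental optima, for test assertions).
#' @export
simulate_selected_table <- function(spec) {
  stopifnot(inherits(spec, "selection_sim_spec"))
  set.seed(derive_seed("optima", spec$seed))
  mu <- ape::rTraitCont(spec$tree, model = "BM", sigma = sqrt(spec$bm_rate))
  mu <- mu[paste0("OTU_", seq_len(spec$n_otus))]
  # map conserved traits onto the gradient's scale, preserving phylogenetic
  # correlation structure
  rng <- range(spec$env_gradient)
  if (diff(range(mu)) > 0)
    mu <- rng[1] + (mu - min(mu)) / diff(range(mu)) * diff(rng)
  w <- exp(-spec$selection_strength *
             outer(spec$env_gradient, mu, function(e, m) (e - m)^2) /
             (2 * spec$sigma^2))
  tab <- .simulate_table(spec, weights = w)
  list(table = tab, optima = mu)
}

# Synthetic per-element background concentrations (mg/kg), of the magnitude
# typical for uncontaminated temperate soils. These are generator defaults
# for simulation only; real analyses must supply measured background values.
DEFAULT_BACKGROUNDS <- c(Cd = 0.07, Zn = 60, Fe = 27000, Cu = 20, Pb = 20)

#' Simulate per-sample metadata with a pollution gradient
#'
#' Distances are uniform on 0-40 km from the urban center; habitat categories
#' are assigned by distance quartile (urban, suburban, exurban, rural from
#' nearest to farthest). Each metal concentration is
#' background * (1 + gradient term + lognormal noise), with the gradient term
#' increasing or decreasing with distance per `pollution_profile`. Soil
#' variables get mild distance correlations (SOM declining away from the
#' center, pH rising slightly) plus independent noise.
#'
#' @param n_samples number of samples (>= 4).
#' @param pollution_profile `"decreasing_with_distance"` (metal load highest
#'   at the urban center) or `"increasing_with_distance"`.
#' @param seed integer seed.
#' @param backgrounds named per-element background concentrations (mg/kg).
#' @param gradient_amplitude peak gradient term relative to background.
#' @param noise_sd lognormal noise sd on the log scale.
#' @return data.frame of per-sample metadata (categories, distance, soil
#'   variables, metal concentrations).
#' @export
simulate_metadata <- function(n_samples,
                              pollution_profile = c("decreasing_with_distance",
                                                    "increasing_with_distance"),
                              seed,
                              backgrounds = DEFAULT_BACKGROUNDS,
                              gradient_amplitude = 1.5,
                              noise_sd = 0.25) {
  pollution_profile <- match.arg(pollution_profile)
  if (n_samples < 4) stop("n_samples must be >= 4")
  set.seed(seed)
  dist_km <- sort(runif(n_samples, 0, 40))
  q <- quantile(dist_km, c(0.25, 0.5, 0.75))
  category <- cut(dist_km, breaks = c(-Inf, q, Inf), labels = HABITAT_CATEGORIES)
  g <- dist_km / 40
  if (pollution_profile == "decreasing_with_distance") g <- 1 - g
  md <- data.frame(sample_id = paste0("S", seq_len(n_samples)),
                   category = category, distance_km = dist_km,
                   stringsAsFactors = FALSE)
  for (el in names(backgrounds)) {
    noise <- rlnorm(n_samples, 0, noise_sd)
    md[[el]] <- backgrounds[[el]] * (1 + gradient_amplitude * g) * noise
  }
  som <- 25 - 8 * (dist_km / 40) + rnorm(n_samples, 0, 2)
  md$SOM <- pmax(som, 1)
  md$TN <- pmax(0.05 * md$SOM + rnorm(n_samples, 0.3, 0.15), 0.05)
  md$AP <- pmax(15 + 5 * (dist_km / 40) + rnorm(n_samples, 0, 3), 0.5)
  md$AK <- pmax(120 + rnorm(n_samples, 0, 25), 5)
  md$SMC <- pmin(pmax(18 + 3 * (dist_km / 40) + rnorm(n_samples, 0, 3), 2), 60)
  md$pH <- pmin(pmax(7.4 + 0.4 * (dist_km / 40) + rnorm(n_samples, 0, 0.25), 4), 9.5)
  md
}

#' Plant known generalists and specialists into an OTU table
#'
#' Overwrites randomly chosen OTU columns so their ground-truth niche class
#' is known: planted generalists get (near-)uniform abundance across all
#' samples; planted specialists get all their abundance in a single sample
#' (Levins breadth = 1). With `jitter = "none"` generalists are exactly
#' uniform (breadth = number of samples); the default `"multinomial"` adds
#' sampling noise around the uniform expectation -- real generalists are
#' evenly distributed, not literally constant, and a set of strictly
#' identical columns would make whole-community phylogenetic turnover
#' degenerate. Per-OTU totals are preserved up to rounding (jittered
#' generalists are topped up to 5 reads per sample on average so occupancy
#' stays essentially complete).
#'
#' @param table samples x OTUs count matrix.
#' @param n_generalists,n_specialists how many OTUs to overwrite.
#' @param seed integer seed choosing which OTUs are planted.
#' @param jitter `"multinomial"` (near-uniform) or `"none"` (exactly uniform).
#' @return list with `table` (modified matrix) and `labels` (data.frame of
#'   `otu_id`, `truth` in generalist/specialist/background).
#' @export
plant_generalists_specialists <- function(table, n_generalists, n_specialists,
                                          seed,
                                          jitter = c("multinomial", "none")) {
  jitter <- match.arg(jitter)
  n_otus <- ncol(table); n_samples <- nrow(table)
  if (n_generalists + n_specialists > n_otus)
    stop("cannot plant more OTUs than the table holds")
  set.seed(seed)
  chosen <- sample.int(n_otus, n_generalists + n_specialists)
  gen_idx <- chosen[seq_len(n_generalists)]
  spe_idx <- chosen[n_generalists + seq_len(n_specialists)]
  for (i in gen_idx) {
    if (jitter == "none") {
      table[, i] <- max(1, round(sum(table[, i]) / n_samples))
    } else {
      tot <- max(sum(table[, i]), 5 * n_samples)
      table[, i] <- rmultinom(1, tot, rep(1 / n_samples, n_samples))[, 1]
    }
  }
  for (i in spe_idx) {
    tot <- max(1, sum(table[, i]))
    table[, i] <- 0
    table[sample.int(n_samples, 1), i] <- tot
  }
  truth <- rep("background", n_otus)
  truth[gen_idx] <- "generalist"
  truth[spe_idx] <- "specialist"
  list(table = table,
       labels = data.frame(otu_id = colnames(table), truth = truth,
                           stringsAsFactors = FALSE))
}
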