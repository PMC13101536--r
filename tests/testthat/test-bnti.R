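test_that("patristic distances match path sums and a naive traversal oracle", {
  tr <- example_tree()
  D <- patristic_distances(tr)
  expect_equal(unname(D["A", "B"]), 2)
  expect_equal(unname(D["A", "C"]), 4)
  expect_true(all(diag(D) == 0))

  for (s in 1:20) {
    yt <- simulate_phylogeny(sample(5:15, 1), seed = s)
    expect_equal(patristic_distances(yt), naive_patristic(yt), tolerance = 1e-12)
  }
})

test_that("betaMNTD matches hand cases and the brute-force oracle exactly", {
  tr <- example_tree()
  D <- patristic_distances(tr)

  # identical samples: every taxon's nearest neighbor is itself
  same <- matrix(c(3, 1, 2, 3, 1, 2), 2, 3, byrow = TRUE,
                 dimnames = list(c("S1", "S2"), c("A", "B", "C")))
  expect_equal(unname(beta_mntd(same, D)[1, 2]), 0)

  # two single-OTU samples holding tips A and C: 0.5 * (4 + 4)
  single <- matrix(c(7, 0, 0, 0, 0, 5), 2, 3, byrow = TRUE,
                   dimnames = list(c("S1", "S2"), c("A", "B", "C")))
  expect_equal(unname(beta_mntd(single, D)[1, 2]), 4)

  # brute-force equality on random 8-sample x 12-OTU instances
  tree12 <- simulate_phylogeny(12, seed = 101)
  D12 <- patristic_distances(tree12)
  for (s in 1:5) {
    set.seed(200 + s)
    tab <- matrix(rpois(8 * 12, 3), 8, 12,
                  dimnames = list(paste0("S", 1:8), paste0("OTU_", 1:12)))
    tab[tab < 0] <- 0
    tab <- tab + (rowSums(tab) == 0)  # guard empty samples
    fast <- beta_mntd(tab, D12)
    brute <- beta_mntd_brute(tab, D12)
    expect_equal(fast[upper.tri(fast)], brute[upper.tri(brute)], tolerance = 1e-12)
    expect_equal(fast, t(fast))
    # unweighted mode agrees with its own brute force too
    expect_equal(beta_mntd(tab, D12, weighted = FALSE)[upper.tri(fast)],
                     beta_mntd_brute(tab, D12, weighted = FALSE)[upper.tri(fast)], tolerance = 1e-12)
  }
})

test_that("betaMNTD agrees with an independent reference implementation", {
  skip_if_not_installed("picante")
  tree <- simulate_phylogeny(25, seed = 7)
  spec <- neutral_sim_spec(10, 25, N = 300, m = 0.3, seed = 8)
  tab <- suppressWarnings(validate_otu_table(simulate_neutral_table(spec)))
  D <- patristic_distances(tree)
  ours <- beta_mntd(tab, D)
  ref <- as.matrix(picante::comdistnt(tab, D[colnames(tab), colnames(tab)],
                                      abundance.weighted = TRUE))
  expect_equal(ours[rownames(ref), colnames(ref)], ref, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("betaNTI flags the star-phylogeny degenerate null and stays deterministic", {
  # star tree: all pairwise tip distances equal, so the shuffle null is constant
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  tab <- matrix(c(3, 1, 0, 0,
                  0, 0, 2, 5,
                  1, 1, 1, 1), 3, 4, byrow = TRUE,
                dimnames = list(paste0("S", 1:3), c("A", "B", "C", "D")))
  res <- beta_nti(tab, star, n_null = 99, seed = 3)
  expect_true(all(res$degenerate))
  expect_true(all(is.na(res$bnti)))
  expect_error(assembly_fractions(res), "degenerate")

  tree <- simulate_phylogeny(30, seed = 51)
  spec <- neutral_sim_spec(8, 30, N = 400, m = 0.3, seed = 52)
  tab2 <- suppressWarnings(validate_otu_table(simulate_neutral_table(spec)))
  r1 <- beta_nti(tab2, tree, n_null = 99, seed = 6)
  r2 <- beta_nti(tab2, tree, n_null = 99, seed = 6)
  expect_identical(r1, r2)
  expect_error(beta_nti(tab2, tree, n_null = 50, seed = 1), "n_null")
})

test_that("the tip-shuffling null is centered when tree and table are independent", {
  tree <- simulate_phylogeny(60, seed = 61)
  spec <- neutral_sim_spec(12, 60, N = 1000, m = 0.2, seed = 62)
  tab <- suppressWarnings(validate_otu_table(simulate_neutral_table(spec)))
  res <- beta_nti(tab, tree, n_null = 299, seed = 63)
  expect_gte(nrow(res), 50)
  expect_lt(abs(mean(res$bnti, na.rm = TRUE)), 0.5)
})

test_that("assembly fractions partition non-degenerate pairs at the +/-2 thresholds", {
  mk <- function(z) data.frame(sample_a = "a", sample_b = "b", bmntd_obs = 1,
                               null_mean = 0, null_sd = 1, bnti = z,
                               degenerate = is.na(z), n_null = 99)
  all_zero <- do.call(rbind, lapply(rep(0, 4), mk))
  expect_equal(assembly_fractions(all_zero)$stochastic, 1)

  mixed <- do.call(rbind, lapply(c(3, -3, 0, 1), mk))
  fr <- assembly_fractions(mixed)
  expect_equal(fr$deterministic, 0.5)
  expect_equal(fr$variable_selection, 0.25)
  expect_equal(fr$homogeneous_selection, 0.25)
  expect_equal(fr$deterministic + fr$stochastic, 1)

  # exact threshold value counts as stochastic
  expect_equal(assembly_fractions(do.call(rbind, lapply(c(2, -2), mk)))$stochastic, 1)
})
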