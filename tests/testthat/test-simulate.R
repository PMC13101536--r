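test_that("Yule phylogenies are ultrametric, sized and deterministic", {
  for (n in c(2, 10, 100))
    expect_identical(length(simulate_phylogeny(n, seed = 1)$tip.label), as.integer(n))

  cherry <- simulate_phylogeny(2, seed = 4)
  depths <- ape::node.depth.edgelength(cherry)[1:2]
  expect_equal(depths[1], depths[2])
  expect_true(ape::is.ultrametric(simulate_phylogeny(30, seed = 9)))

  t1 <- simulate_phylogeny(50, seed = 7)
  t2 <- simulate_phylogeny(50, seed = 7)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("neutral tables respect the multinomial contract and the Beta mean", {
  spec <- neutral_sim_spec(20, 50, N = 500, m = 0.2, seed = 3)
  tab <- simulate_neutral_table(spec)
  expect_true(all(rowSums(tab) == 500))
  expect_true(all(tab >= 0))
  expect_identical(tab, simulate_neutral_table(spec))

  # m = 1, large N: per-sample relative abundances concentrate at p
  p <- rep(1 / 20, 20)
  conc <- simulate_neutral_table(
    neutral_sim_spec(10, 20, N = 50000, m = 1, seed = 5, p = p))
  rel <- conc / rowSums(conc)
  expect_lt(max(abs(rel - rep(p, each = 10))), 0.01)

  # over 200 samples, mean relative abundance of an OTU tracks p_i within 3 SE
  p2 <- c(0.4, 0.3, 0.2, 0.06, 0.04)
  big <- simulate_neutral_table(
    neutral_sim_spec(200, 5, N = 1000, m = 0.1, seed = 11, p = p2))
  rel2 <- big / rowSums(big)
  for (i in 1:3) {
    se <- sd(rel2[, i]) / sqrt(200)
    expect_lt(abs(mean(rel2[, i]) - p2[i]), 3 * se + 1e-12)
  }

  expect_error(neutral_sim_spec(10, 5, N = 100, m = 0, seed = 1), "m must")
})

test_that("selection reduces exactly to the neutral generator at strength 0", {
  tree <- simulate_phylogeny(40, seed = 2)
  s0 <- selection_sim_spec(10, 40, N = 500, m = 0.2, tree = tree, seed = 8,
                           selection_strength = 0)
  sn <- neutral_sim_spec(10, 40, N = 500, m = 0.2, seed = 8)
  out <- simulate_selected_table(s0)
  expect_identical(out$table[, ], simulate_neutral_table(sn)[, ])
  expect_identical(length(out$optima), 40L)
  expect_error(selection_sim_spec(10, 40, 500, 0.2, tree, seed = 1, sigma = 0),
               "sigma")
})

test_that("selection raises turnover between gradient extremes (Monte Carlo)", {
  tree <- simulate_phylogeny(40, seed = 13)
  extreme <- numeric(50); same <- numeric(50)
  for (r in 1:50) {
    sp <- selection_sim_spec(4, 40, N = 1000, m = 0.3, tree = tree,
                             seed = 1000 + r, env_gradient = c(0, 0, 1, 1),
                             sigma = 0.1, selection_strength = 1)
    tab <- simulate_selected_table(sp)$table
    bc <- bray_curtis(tab)
    extreme[r] <- bc[1, 3]   # opposite ends of the gradient
    same[r] <- bc[1, 2]      # identical environment
  }
  expect_gt(mean(extreme), mean(same))
})

test_that("metadata simulation produces the requested pollution structure", {
  md <- simulate_metadata(60, "decreasing_with_distance", seed = 17)
  expect_identical(nrow(md), 60L)
  expect_true(all(md[, c("Cd", "Zn", "Fe", "Cu", "Pb")] > 0))
  expect_lt(cor(md$distance_km, md$Cd, method = "spearman"), 0)
  expect_identical(md, simulate_metadata(60, "decreasing_with_distance", seed = 17))
  # four categories by distance quartile
  expect_identical(sort(unique(as.character(md$category))),
                   sort(c("urban", "suburban", "exurban", "rural")))
  up <- simulate_metadata(60, "increasing_with_distance", seed = 17)
  expect_gt(cor(up$distance_km, up$Cd, method = "spearman"), 0)
})

test_that("planted generalists and specialists have the promised breadths", {
  spec <- neutral_sim_spec(12, 30, N = 400, m = 0.2, seed = 19)
  tab <- suppressWarnings(validate_otu_table(simulate_neutral_table(spec)))
  pl <- plant_generalists_specialists(tab, 3, 3, seed = 20, jitter = "none")
  B <- apply(pl$table, 2, levins_breadth)
  expect_equal(unname(B[pl$labels$truth == "generalist"]), rep(12, 3))
  expect_equal(unname(B[pl$labels$truth == "specialist"]), rep(1, 3))
  expect_error(plant_generalists_specialists(tab, 20, 20, seed = 1), "more OTUs")

  # jittered planting stays near-uniform: breadth close to (but below) n
  pj <- plant_generalists_specialists(tab, 3, 0, seed = 21)
  Bj <- apply(pj$table, 2, levins_breadth)[pj$labels$truth == "generalist"]
  expect_true(all(Bj > 0.75 * 12 & Bj <= 12))
})
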