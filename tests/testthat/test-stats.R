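test_that("alpha diversity matches hand evaluations", {
  tab <- rbind(S1 = c(5, 5, 5, 5), S2 = c(9, 0, 0, 0), S3 = c(50, 25, 25, 0))
  colnames(tab) <- paste0("O", 1:4)
  div <- alpha_diversity(tab)
  expect_equal(div$shannon[1], log(4))
  expect_identical(div$richness[1], 4)
  expect_equal(div$shannon[2], 0)
  expect_identical(div$richness[2], 1)
  expect_equal(div$shannon[3], -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_true(all(div$shannon <= log(div$richness) + 1e-12))
})

test_that("Bray-Curtis is a [0,1] dissimilarity with the expected values", {
  tab <- rbind(S1 = c(1, 1, 0), S2 = c(0, 1, 1), S3 = c(1, 1, 0), S4 = c(0, 0, 2))
  colnames(tab) <- paste0("O", 1:3)
  bc <- bray_curtis(tab)
  expect_equal(bc["S1", "S3"], 0)          # identical composition
  expect_equal(bc["S1", "S4"], 1)          # disjoint
  expect_equal(bc["S1", "S2"], 0.5)        # (.5,.5,0) vs (0,.5,.5)
  expect_equal(bc, t(bc))
  expect_true(all(bc >= 0 & bc <= 1))
  expect_true(all(diag(bc) == 0))
})

test_that("Mantel test: perfect concordance, +1 correction and invariance", {
  set.seed(7)
  xy <- matrix(rnorm(20), 10, 2)
  D1 <- as.matrix(dist(xy))
  res <- mantel_test(D1, D1, n_perm = 199, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p_value, 1 / 200)

  # relabeling samples identically in both matrices leaves r unchanged
  perm <- sample(10)
  res2 <- mantel_test(D1[perm, perm], D1[perm, perm], n_perm = 99, seed = 2)
  expect_equal(res2$r, 1)

  expect_error(mantel_test(matrix(0, 3, 3), D1[1:3, 1:3], seed = 1), "size|constant")
})

test_that("Spearman matrix equals Pearson on midranks and flags constants", {
  set.seed(11)
  x <- rnorm(30)
  res <- spearman_matrix(cbind(x = x), cbind(cube = x^3, neg = -x))
  expect_equal(unname(res$rho[1, "cube"]), 1)
  expect_equal(unname(res$rho[1, "neg"]), -1)

  # oracle equivalence on tied data
  for (s in 1:10) {
    set.seed(500 + s)
    a <- sample(1:5, 25, replace = TRUE)
    b <- a + sample(0:3, 25, replace = TRUE)
    got <- spearman_matrix(cbind(a), cbind(b))
    expect_equal(unname(got$rho[1, 1]), cor(rank(a), rank(b)), tolerance = 1e-12)
    expect_equal(unname(got$rho[1, 1]), cor(a, b, method = "spearman"),
                 tolerance = 1e-12)
  }

  con <- spearman_matrix(cbind(k = rep(1, 30)), cbind(x = x))
  expect_true(is.na(con$rho[1, 1]))

  expect_identical(significance_stars(c(0.0005, 0.005, 0.03, 0.2, NA)),
                   c("***", "**", "*", "", ""))
})

test_that("betaNTI~Pn regression recovers noiseless fits and matches closed form", {
  mk_bnti <- function(z, a, b) data.frame(sample_a = a, sample_b = b,
                                          bmntd_obs = 1, null_mean = 0,
                                          null_sd = 1, bnti = z,
                                          degenerate = FALSE, n_null = 99)
  ids <- paste0("S", 1:8)
  pairs <- t(combn(ids, 2))
  pn <- data.frame(sample_id = ids, Pn = seq(0.5, 2.6, length.out = 8))
  pred <- (pn$Pn[match(pairs[, 1], ids)] + pn$Pn[match(pairs[, 2], ids)]) / 2
  bn <- mk_bnti(2 + 3 * pred, pairs[, 1], pairs[, 2])
  fit <- bnti_vs_pollution(bn, pn)
  expect_equal(fit$slope, 3, tolerance = 1e-10)
  expect_equal(fit$intercept, 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # closed-form normal equations oracle on random instances
  for (s in 1:20) {
    set.seed(600 + s)
    y <- rnorm(nrow(pairs)); x <- pred
    bn2 <- mk_bnti(y, pairs[, 1], pairs[, 2])
    fit2 <- bnti_vs_pollution(bn2, pn)
    slope_cf <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    expect_equal(fit2$slope, slope_cf, tolerance = 1e-10)
    expect_equal(fit2$intercept, mean(y) - slope_cf * mean(x), tolerance = 1e-10)
  }

  const <- data.frame(sample_id = ids, Pn = rep(1, 8))
  expect_error(bnti_vs_pollution(bn, const), "constant predictor")
  expect_error(bnti_vs_pollution(bn[1:2, ], pn), "3 usable")
})

test_that("Venn regions partition observed OTUs across categories", {
  tab <- rbind(S1 = c(1, 0, 1, 0, 1), S2 = c(1, 0, 0, 1, 0),
               S3 = c(1, 2, 0, 0, 0), S4 = c(1, 0, 0, 0, 0))
  colnames(tab) <- paste0("O", 1:5)
  md <- data.frame(sample_id = paste0("S", 1:4),
                   category = c("urban", "suburban", "exurban", "rural"))
  part <- shared_otu_partition(tab, md)
  expect_equal(sum(part$regions), part$total_otus)
  expect_identical(part$total_otus, 5L)
  # O1 present everywhere sits in the 4-way region
  expect_identical(unname(part$regions["urban&suburban&exurban&rural"]), 1L)
  expect_equal(part$core_fraction, 1 / 5)
  # disjoint planted OTUs land in singleton regions
  expect_identical(unname(part$regions["suburban"]), 1L)  # O4 only in S2
  expect_identical(unname(part$regions["exurban"]), 1L)   # O2 only in S3

  md_empty <- data.frame(sample_id = paste0("S", 1:4),
                         category = rep(c("urban", "rural"), 2))
  expect_warning(shared_otu_partition(tab, md_empty), "empty")
})
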