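test_that("noise-free degenerate simulation reproduces environment means exactly", {
  cfg <- design_config(n_sires = 4, dams_per_sire = 2, offspring_per_dam = 3,
                       missing_cell_rate = 0, seed = 1)
  tp <- true_params(G = matrix(0, 3, 3), sigma2_e = 0,
                    env_means = c(23.51, 12.96, 12.29), block_effects = 0)
  sim <- simulate_breeding_design(cfg, tp)
  expect_equal(sim$phenotypes$value,
               tp$env_means[as.integer(sim$phenotypes$environment)])
})

test_that("the default design produces a study-sized dataset", {
  sim <- simulate_breeding_design(design_config(seed = 3),
                                  default_trait_params())
  n <- nrow(sim$phenotypes)
  # 35 sire families x 3 dams x ~10 offspring: on the order of 1039 males
  expect_gte(n, 900)
  expect_lte(n, 1200)
  expect_setequal(levels(sim$phenotypes$environment), c("ripe", "unripe", "none"))
  # per-sire-family allocation skewed toward ripe and no-fruit diets
  by_env <- table(sim$phenotypes$environment)
  expect_gt(by_env[["ripe"]], by_env[["unripe"]])
  expect_gt(by_env[["none"]], by_env[["unripe"]])
})

test_that("paternal half-sib phenotypic covariance approximates V_A / 4", {
  # analytic oracle: cov(half sibs) = sigma2_a / 4 within an environment
  cfg <- design_config(n_sires = 200, dams_per_sire = 3, offspring_per_dam = 30,
                       env_weights = c(e1 = 1/3, e2 = 1/3, e3 = 1/3),
                       env_labels = c("e1", "e2", "e3"),
                       missing_cell_rate = 0, n_blocks = 1, seed = 42)
  tp <- true_params(G = diag(c(36.5, 1, 1.5)), sigma2_e = 54,
                    env_means = c(0, 0, 0), block_effects = 0)
  sim <- simulate_breeding_design(cfg, tp)
  d <- sim$phenotypes[sim$phenotypes$environment == "e1", ]
  d$y <- d$value - mean(d$value)
  per_sire <- vapply(split(d, d$sire), function(fam) {
    if (nrow(fam) < 2) return(NA_real_)
    # mean cross-product over half-sib pairs (different dams)
    prods <- outer(fam$y, fam$y)
    dams <- outer(fam$dam, fam$dam, "!=")
    if (!any(dams)) return(NA_real_)
    mean(prods[dams])
  }, numeric(1))
  per_sire <- per_sire[!is.na(per_sire)]
  est <- mean(per_sire)
  se <- stats::sd(per_sire) / sqrt(length(per_sire))
  expect_lt(abs(est - 36.5 / 4), 4 * se)
})

test_that("offspring breeding values covary with the sire's by G / 2", {
  cfg <- design_config(n_sires = 400, dams_per_sire = 1, offspring_per_dam = 1,
                       missing_cell_rate = 0, seed = 8)
  G <- genetic_cov_matrix(c(30, 8, 12), 0.5)
  tp <- true_params(G, sigma2_e = 10, env_means = c(0, 0, 0))
  sim <- simulate_breeding_design(cfg, tp)
  bv <- sim$breeding_values$value
  off <- sim$phenotypes$id
  sires <- sim$phenotypes$sire
  cc <- stats::cov(bv[off, ], bv[sires, ])
  # each entry has Monte Carlo error ~ sqrt(G_ii G_jj + cov^2)/sqrt(n)
  for (i in 1:3) for (j in 1:3) {
    se <- sqrt(G[i, i] * G[j, j] + (G[i, j] / 2)^2) / sqrt(400)
    expect_lt(abs(cc[i, j] - G[i, j] / 2), 4 * se)
  }
})

test_that("split-brood allocation follows the requested weights", {
  fams <- tibble::tibble(sire = "S1", dam = "D1", n = 50)
  a <- allocate_split_brood(fams, c(x = 1, y = 0, z = 0), seed = 1)
  expect_true(all(a$environment == "x"))

  fams <- tibble::tibble(sire = paste0("S", 1:100), dam = paste0("D", 1:100),
                         n = 30)
  a <- allocate_split_brood(fams, c(x = 1, y = 1, z = 1) / 3, seed = 2)
  counts <- table(a$environment)
  sd_bin <- sqrt(3000 * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - 1000) < 4 * sd_bin))

  a1 <- allocate_split_brood(fams, c(x = .5, y = .3, z = .2), seed = 7)
  a2 <- allocate_split_brood(fams, c(x = .5, y = .3, z = .2), seed = 7)
  expect_identical(a1, a2)

  expect_error(allocate_split_brood(tibble::tibble(sire = "a", dam = "b", n = -1),
                                    c(1, 1) / 2), "non-negative")
  expect_error(allocate_split_brood(fams, c(0, 0, 0)), "positive sum")
})

test_that("simulation is fully deterministic under a fixed seed", {
  s1 <- simulate_breeding_design(design_config(n_sires = 6, seed = 11),
                                 default_trait_params())
  s2 <- simulate_breeding_design(design_config(n_sires = 6, seed = 11),
                                 default_trait_params())
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$pedigree, s2$pedigree)
})

test_that("invalid simulation inputs are rejected", {
  expect_error(true_params(G = matrix(c(1, 2, 2, 1), 2), sigma2_e = 1,
                           env_means = c(0, 0)), "semidefinite")
  expect_error(true_params(G = diag(2), sigma2_e = -1, env_means = c(0, 0)),
               "sigma2_e")
  expect_error(design_config(missing_cell_rate = 1), "missing_cell_rate")
})

test_that("empirical phenotypic variance matches sigma2_a + sigma2_e", {
  cfg <- design_config(n_sires = 150, dams_per_sire = 3, offspring_per_dam = 12,
                       missing_cell_rate = 0, seed = 21)
  tp <- true_params(genetic_cov_matrix(c(36.5, 1, 1.5), 0.5), 54,
                    env_means = c(0, 0, 0))
  sim <- simulate_breeding_design(cfg, tp)
  for (i in 1:3) {
    ev <- levels(sim$phenotypes$environment)[i]
    y <- sim$phenotypes$value[sim$phenotypes$environment == ev]
    vp <- tp$G[i, i] + tp$sigma2_e
    # loose Monte Carlo band; family structure inflates the variance of var(y)
    expect_lt(abs(stats::var(y) - vp) / vp, 0.15)
  }
})
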