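test_that("restricted log-likelihood reduces to the iid closed form", {
  ped <- build_pedigree(tibble::tibble(id = c("a", "b"), sire = NA, dam = NA))
  d <- tibble::tibble(id = c("a", "b"), environment = "only",
                      y = c(1.3, 2.9))
  s2 <- 0.7
  ll <- restricted_log_likelihood(d, ped, "y",
                                  variance_components(matrix(0, 1, 1), s2))
  # REML of an iid normal sample: -(1/2)[n log s2 + log(n/s2) + SS/s2 + (n-1)log 2pi]
  n <- 2; ss <- sum((d$y - mean(d$y))^2)
  closed <- -0.5 * (n * log(s2) + log(n / s2) + ss / s2 + (n - 1) * log(2 * pi))
  expect_equal(ll, closed, tolerance = 1e-12)
})

test_that("restricted log-likelihood matches the dense first-principles oracle", {
  set.seed(31)
  for (rep in 1:4) {
    sim <- sim_small(seed = 100 + rep, n_sires = 5, dams = 2, per_dam = 2)
    G <- genetic_cov_matrix(stats::runif(3, 2, 30), stats::runif(1, -0.5, 0.9))
    s2 <- stats::runif(1, 5, 60)
    ll <- restricted_log_likelihood(sim$phenotypes, sim$pedigree, "value",
                                    variance_components(G, s2))
    llo <- oracle_reml_loglik(sim$phenotypes, sim$pedigree, "value", G, s2)
    expect_equal(ll, llo, tolerance = 1e-8)
  }
})

test_that("REML likelihood obeys the scaling identity", {
  sim <- sim_small(seed = 17)
  d <- sim$phenotypes
  G <- genetic_cov_matrix(c(10, 5, 8), 0.3); s2 <- 25
  ll1 <- restricted_log_likelihood(d, sim$pedigree, "value",
                                   variance_components(G, s2))
  d2 <- d; d2$value <- 2 * d$value
  ll2 <- restricted_log_likelihood(d2, sim$pedigree, "value",
                                   variance_components(4 * G, 4 * s2))
  n <- nrow(d)
  p <- 1 + 2 + 1  # intercept + env + block contrasts
  expect_equal(ll2, ll1 - (n - p) / 2 * log(4), tolerance = 1e-10)
})

test_that("a tiny single-environment fit agrees with a dense grid search", {
  cfg <- design_config(n_sires = 6, dams_per_sire = 2, offspring_per_dam = 3,
                       env_weights = c(only = 1), env_labels = "only",
                       missing_cell_rate = 0, n_blocks = 1, seed = 4)
  tp <- true_params(matrix(25, 1, 1), 30, env_means = 10)
  sim <- simulate_breeding_design(cfg, tp)
  fit <- reml_fit(sim$phenotypes, sim$pedigree, "value")
  va_grid <- seq(0.5, 80, by = 1)
  s2_grid <- seq(0.5, 80, by = 1)
  best <- c(ll = -Inf, va = NA, s2 = NA)
  for (va in va_grid) for (s2 in s2_grid) {
    ll <- restricted_log_likelihood(sim$phenotypes, sim$pedigree, "value",
                                    variance_components(matrix(va), s2))
    if (ll > best["ll"]) best <- c(ll = ll, va = va, s2 = s2)
  }
  expect_gte(fit$reml_loglik, best[["ll"]] - 1e-8)
  expect_lt(abs(fit$components$G[1, 1] - best[["va"]]), 1)
  expect_lt(abs(fit$components$sigma2_e - best[["s2"]]), 1)
})

test_that("EM warm-start iterations never decrease the restricted log-likelihood", {
  set.seed(52)
  for (rep in 1:5) {
    sim <- sim_small(seed = 200 + rep)
    fit <- reml_fit(sim$phenotypes, sim$pedigree, "value",
                    em_iters = 12, em_switch_tol = -Inf)
    em_traj <- fit$convergence$trajectory[seq_len(fit$convergence$em_iterations + 1)]
    expect_true(all(diff(em_traj) >= -1e-8))
    # the whole trajectory is monotone by construction of the accepted steps
    expect_true(all(diff(fit$convergence$trajectory) >= -1e-8))
  }
})

test_that("convergence diagnostics are sane and the AI matrix is PSD", {
  sim <- sim_small(seed = 33)
  fit <- reml_fit(sim$phenotypes, sim$pedigree, "value")
  expect_lt(fit$convergence$final_gradient_norm, 1e-4 + 1e-12)
  expect_true(is.finite(fit$reml_loglik))
  ev <- eigen(fit$vcov_components, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-6 * max(abs(ev)))
  evG <- eigen(fit$components$G, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(evG), -1e-8 * sum(diag(fit$components$G)))
})

test_that("data simulated without genetic variance drive estimates to the floor", {
  cfg <- design_config(n_sires = 30, dams_per_sire = 3, offspring_per_dam = 8,
                       missing_cell_rate = 0, seed = 61)
  tp <- true_params(matrix(0, 3, 3), sigma2_e = 54,
                    env_means = c(23.5, 13, 12.3))
  sim <- simulate_breeding_design(cfg, tp)
  fit <- reml_fit(sim$phenotypes, sim$pedigree, "value")
  vp <- fit$components$sigma2_e
  # estimates are small and statistically indistinguishable from zero
  expect_true(all(diag(fit$components$G) < 0.1 * vp))
  h2 <- heritability_by_environment(fit)
  expect_true(all(h2$h2 < 0.1))
  expect_true(all(h2$h2 - 2 * h2$se_h2 <= 0))
})

test_that("balanced single-environment REML agrees with the classical sire-model estimator", {
  cfg <- design_config(n_sires = 60, dams_per_sire = 16, offspring_per_dam = 1,
                       env_weights = c(only = 1), env_labels = "only",
                       missing_cell_rate = 0, n_blocks = 1, seed = 77)
  tp <- true_params(matrix(24, 1, 1), 40, env_means = 5)
  sim <- simulate_breeding_design(cfg, tp)
  fit <- reml_fit(sim$phenotypes, sim$pedigree, "value")
  # classical moment estimator: sigma2_a = 4 * between-sire component
  d <- sim$phenotypes
  an <- stats::anova(stats::aov(value ~ factor(sire), data = d))
  n0 <- 16  # paternal half sibs per sire, one offspring per dam
  sigma_s <- (an$`Mean Sq`[1] - an$`Mean Sq`[2]) / n0
  expect_lt(abs(fit$components$G[1, 1] - 4 * sigma_s), 8)
})

test_that("trait columns with missing values drop those individuals only", {
  sim <- sim_small(seed = 41)
  d <- sim$phenotypes
  d$value[1:5] <- NA
  fit <- reml_fit(d, sim$pedigree, "value")
  expect_equal(fit$model$n, nrow(d) - 5)
})

test_that("degenerate model inputs raise informative errors", {
  sim <- sim_small(seed = 3)
  d <- sim$phenotypes
  expect_error(restricted_log_likelihood(d, sim$pedigree, "value",
                                         variance_components(matrix(0), 1)),
               "environment level")
  d2 <- d; d2$id[2] <- d2$id[1]
  expect_error(reml_fit(d2, sim$pedigree, "value"), "exactly one record")
  d3 <- d; d3$id[1] <- "stranger"
  expect_error(reml_fit(d3, sim$pedigree, "value"), "absent from the pedigree")
  expect_error(reml_fit(dplyr::mutate(d, value = 1), sim$pedigree, "value"),
               "zero variance")
})

test_that("tidy and glance return the expected shapes", {
  sim <- sim_small(seed = 19)
  fit <- reml_fit(sim$phenotypes, sim$pedigree, "value")
  td <- tidy(fit)
  expect_equal(nrow(td), 7)  # vech(3x3 G) + residual
  expect_named(td, c("term", "estimate", "std.error"))
  expect_equal(td$estimate[1], fit$components$G[1, 1])
  gl <- glance(fit)
  expect_equal(gl$logLik, fit$reml_loglik)
  expect_true(gl$n > 0)
})
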