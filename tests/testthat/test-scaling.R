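test_that("log transform behaves on its edge cases", {
  expect_equal(log_transform(1), 0)
  expect_equal(log_transform(exp(1)), 1)
  expect_error(log_transform(c(2, 0, 3)), "row\\(s\\): 2")
  expect_error(log_transform(-1), "positive")
  expect_equal(log_transform(c(2, NA)), c(log(2), NA))
})

test_that("one-way ANOVA matches the regression F and a first-principles Tukey oracle", {
  set.seed(12)
  d <- tibble::tibble(
    g = rep(c("a", "b", "c"), times = c(12, 9, 15)),
    y = stats::rnorm(36, mean = rep(c(0, 1.2, 0.3), times = c(12, 9, 15)))
  )
  res <- one_way_anova_tukey(d, "y", "g")

  # regression route
  lm_fit <- stats::lm(y ~ g, data = d)
  fstat <- summary(lm_fit)$fstatistic
  expect_equal(res$F, unname(fstat[1]), tolerance = 1e-10)
  expect_equal(res$p,
               unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
               tolerance = 1e-10)

  # independent Tukey-Kramer route via stats::TukeyHSD
  th <- stats::TukeyHSD(stats::aov(y ~ g, data = d))$g
  key <- paste(res$tukey$group2, res$tukey$group1, sep = "-")
  expect_equal(res$tukey$p_adj, unname(th[key, "p adj"]), tolerance = 1e-6)
  expect_equal(res$tukey$diff, unname(th[key, "diff"]), tolerance = 1e-10)
})

test_that("identical observations give F = 0 and a single shared letter", {
  d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 3), y = 5)
  res <- one_way_anova_tukey(d, "y", "g")
  expect_equal(res$F, 0)
  expect_equal(unique(res$letters$letters), "a")
})

test_that("Tukey letters are invariant to shifts and group order", {
  set.seed(1)
  d <- tibble::tibble(
    g = rep(c("a", "b", "c"), each = 20),
    y = stats::rnorm(60, rep(c(0, 0, 3), each = 20))
  )
  r1 <- one_way_anova_tukey(d, "y", "g")
  d2 <- d; d2$y <- d2$y + 100
  r2 <- one_way_anova_tukey(d2, "y", "g")
  expect_equal(r1$letters, r2$letters)
  d3 <- d[sample(nrow(d)), ]
  r3 <- one_way_anova_tukey(d3, "y", "g")
  expect_equal(r1$letters, r3$letters)
  # a and b share a letter, c stands alone
  lt <- stats::setNames(r1$letters$letters, r1$letters$group)
  expect_equal(lt[["a"]], lt[["b"]])
  expect_false(lt[["c"]] %in% c(lt[["a"]], lt[["b"]]))
})

test_that("ANOVA rejects groups that are too small", {
  d <- tibble::tibble(g = c("a", "a", "b"), y = c(1, 2, 3))
  expect_error(one_way_anova_tukey(d, "y", "g"), ">= 2 observations")
  expect_error(one_way_anova_tukey(tibble::tibble(g = "a", y = 1), "y", "g"),
               "2 groups")
})

test_that("null one-way ANOVA rejects at about the nominal 5% rate", {
  set.seed(404)
  rej <- 0
  n_rep <- 1000
  for (i in seq_len(n_rep)) {
    d <- tibble::tibble(g = rep(c("a", "b", "c"), times = c(10, 6, 14)),
                        y = stats::rnorm(30))
    res <- one_way_anova_tukey(d, "y", "g")
    rej <- rej + (res$p < 0.05)
  }
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rej / n_rep - 0.05), 4 * se)
})

test_that("ANCOVA interaction screening keeps or drops the interaction at the threshold", {
  set.seed(9)
  n <- 60
  x <- stats::runif(3 * n, 1, 3)
  g <- rep(c("a", "b", "c"), each = n)

  # identical lines: interaction dropped, environment irrelevant
  y <- 2 + 1.5 * x + stats::rnorm(3 * n, sd = 0.3)
  d <- tibble::tibble(y = y, x = x, g = g)
  res <- ancova_scaling(d, "y", "x", "g")
  expect_false(res$interaction_retained)
  expect_gt(res$terms$p[res$terms$term == "g"], 0.001)

  # strongly different slopes: interaction retained
  y2 <- 2 + (1 + 2 * (g == "b") - 1.5 * (g == "c")) * x + stats::rnorm(3 * n, sd = 0.3)
  d2 <- tibble::tibble(y = y2, x = x, g = g)
  res2 <- ancova_scaling(d2, "y", "x", "g")
  expect_true(res2$interaction_retained)
  expect_lt(res2$screening_p, 0.2)
  expect_equal(nrow(res2$slopes), 3)

  # common slope, intercept offsets: dropped interaction, significant group,
  # adjusted means ordered like the generating offsets
  y3 <- 2 + 1.5 * x + 2 * (g == "b") + 4 * (g == "c") + stats::rnorm(3 * n, sd = 0.3)
  d3 <- tibble::tibble(y = y3, x = x, g = g)
  res3 <- ancova_scaling(d3, "y", "x", "g")
  expect_false(res3$interaction_retained)
  expect_lt(res3$terms$p[res3$terms$term == "g"], 1e-6)
  am <- stats::setNames(res3$adjusted_means$mean, res3$adjusted_means$group)
  expect_true(am[["a"]] < am[["b"]] && am[["b"]] < am[["c"]])

  # boundary behavior of the screening threshold
  expect_true(ancova_scaling(d, "y", "x", "g",
                             screening_threshold = 1)$interaction_retained)
  expect_false(ancova_scaling(d2, "y", "x", "g",
                              screening_threshold = 0)$interaction_retained)
})

test_that("ANCOVA errors on a constant covariate", {
  d <- tibble::tibble(y = stats::rnorm(30), x = 1,
                      g = rep(c("a", "b", "c"), 10))
  expect_error(ancova_scaling(d, "y", "x", "g"), "constant")
})

test_that("the scaling battery reproduces a known environment ordering", {
  # diet effects mirror the study pattern: body and femur ripe > unripe > none,
  # testis ripe > unripe ~ none
  cfg <- design_config(n_sires = 25, dams_per_sire = 3, offspring_per_dam = 10,
                       seed = 70)
  truth <- default_trait_params()
  sim <- simulate_breeding_design(cfg, truth)
  pos <- sim$phenotypes$body_mass_mg > 0 &
    sim$phenotypes$femur_area_mm2 > 0 & sim$phenotypes$testis_mass_mg > 0
  bat <- scaling_battery(sim$phenotypes[pos, ], )
  expect_s3_class(bat, "scaling_battery")
  expect_true(all(c("model", "term", "df", "F", "p") %in% names(bat$table)))
  # body ANOVA: ripe differs from both others
  lt <- stats::setNames(bat$anovas$body$letters$letters,
                        bat$anovas$body$letters$group)
  expect_false(lt[["ripe"]] == lt[["none"]])
  means <- stats::setNames(bat$anovas$body$group_means$mean,
                           bat$anovas$body$group_means$group)
  expect_true(means[["ripe"]] > means[["unripe"]] &&
                means[["unripe"]] > means[["none"]])
  # all five analyses present in the report
  expect_setequal(unique(bat$table$model),
                  c("anova_body", "anova_femur", "anova_testis",
                    "body_vs_femur", "body_vs_testis", "femur_vs_testis"))

  single <- sim$phenotypes[pos & sim$phenotypes$environment == "ripe", ]
  expect_error(scaling_battery(single), "2 groups")
})

test_that("tidy methods expose the term tables", {
  set.seed(3)
  d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 10),
                      y = stats::rnorm(30), x = stats::runif(30, 1, 2))
  expect_named(tidy(one_way_anova_tukey(d, "y", "g")),
               c("group1", "group2", "diff", "p_adj"))
  expect_named(tidy(ancova_scaling(d, "y", "x", "g")), c("term", "df", "F", "p"))
})
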