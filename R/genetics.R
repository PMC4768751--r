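#' Per-environment heritability with delta-method standard errors
#'
#' Narrow-sense heritability of each character state,
#' \eqn{h^2_i = \sigma^2_{aT_i} / (\sigma^2_{aT_i} + \sigma^2)}, with standard
#' errors from a first-order delta-method approximation using the asymptotic
#' covariance of the variance components (gradient
#' \eqn{(\sigma^2/d^2, -\sigma^2_{aT_i}/d^2)} on the pair
#' \eqn{(\sigma^2_{aT_i}, \sigma^2)}, \eqn{d} the phenotypic variance).
#'
#' A component at the boundary floor is reported as heritability 0 with
#' standard error 0.
#'
#' @param components A [variance_components()] (or an `animal_model_fit`, from
#'   which components and covariance are taken).
#' @param vcov Asymptotic covariance of `(vech(G), sigma2_e)`; required when
#'   `components` is not a fit and standard errors are wanted.
#' @param va_floor Boundary floor below which an additive variance is treated
#'   as zero.
#' @return A tibble with columns `environment`, `h2`, `se_h2`.
#' @export
heritability_by_environment <- function(components, vcov = NULL, va_floor = 0) {
  if (inherits(components, "animal_model_fit")) {
    fit <- components
    components <- fit$components
    if (is.null(vcov)) vcov <- fit$vcov_components
    va_floor <- max(va_floor, fit$va_floor)
  }
  stopifnot(inherits(components, "variance_components"))
  G <- components$G
  s2 <- components$sigma2_e
  k <- nrow(G)
  labels <- rownames(G)
  if (is.null(labels)) labels <- paste0("env", seq_len(k))
  didx <- vech_diag_idx(k)
  np <- k * (k + 1) / 2 + 1
  purrr::map_dfr(seq_len(k), function(i) {
    va <- G[i, i]
    den <- va + s2
    if (den <= 0) stop("sigma2_a + sigma2_e is zero for environment ",
                       labels[i], call. = FALSE)
    if (va <= va_floor) {
      return(tibble::tibble(environment = labels[i], h2 = 0, se_h2 = 0))
    }
    h2 <- va / den
    se <- NA_real_
    if (!is.null(vcov)) {
      grad <- c(s2 / den^2, -va / den^2)
      idx <- c(didx[i], np)
      se <- sqrt(max(drop(crossprod(grad, vcov[idx, idx] %*% grad)), 0))
    }
    tibble::tibble(environment = labels[i], h2 = h2, se_h2 = se)
  })
}

#' Mean-standardized evolvability measures
#'
#' Computes, from an additive genetic variance and a trait mean:
#' the coefficient of additive genetic variation in its standard form
#' \eqn{CV_A = \sqrt{V_A}/\bar X} (`cva_stated`, reported without the common
#' 100 multiplier); the variant \eqn{V_A/\bar X} (`cva_printed`), which some
#' published tables use in place of the standard form; and the
#' mean-standardized evolvability \eqn{I_A = V_A/\bar X^2}, the expected
#' proportional change in the trait after a unit strength of selection. Note
#' the algebraic identity `iA == cva_stated^2`; `cva_printed` does not satisfy
#' it and is not invariant to the trait's measurement scale.
#'
#' @param V_A Additive genetic variance(s), `>= 0` (trait-units squared).
#' @param mean Trait mean(s), `> 0` (trait units).
#' @return A tibble with columns `cva_stated`, `cva_printed`, `iA`.
#' @export
evolvability_measures <- function(V_A, mean) {
  if (any(mean <= 0)) stop("trait mean must be positive", call. = FALSE)
  if (any(V_A < 0)) stop("V_A must be non-negative", call. = FALSE)
  tibble::tibble(
    cva_stated = sqrt(V_A) / mean,
    cva_printed = V_A / mean,
    iA = V_A / mean^2
  )
}

#' Cross-environment additive genetic correlations
#'
#' \eqn{r_{ij} = \sigma_{aT_iT_j} / \sqrt{\sigma^2_{aT_i}\sigma^2_{aT_j}}},
#' clipped to `[-1, 1]`. Pairs involving an environment whose additive
#' variance sits at the boundary floor are reported as `NA`.
#'
#' @inheritParams heritability_by_environment
#' @return A symmetric correlation matrix with `NA` for undefined pairs.
#' @export
genetic_correlations <- function(components, va_floor = 0) {
  if (inherits(components, "animal_model_fit")) {
    va_floor <- max(va_floor, components$va_floor)
    components <- components$components
  }
  stopifnot(inherits(components, "variance_components"))
  G <- components$G
  d <- diag(G)
  ok <- d > va_floor
  R <- matrix(NA_real_, nrow(G), ncol(G), dimnames = dimnames(G))
  if (any(ok)) {
    sd_ok <- sqrt(d[ok])
    R[ok, ok] <- pmin(pmax(G[ok, ok, drop = FALSE] / tcrossprod(sd_ok), -1), 1)
  }
  diag(R)[ok] <- 1
  R
}

#' Per-environment genetic summary for a set of traits
#'
#' Assembles, for each trait and environment, the raw (untransformed) trait
#' mean, the additive genetic variance \eqn{V_A = \sigma^2_{aT_i}}, the
#' phenotypic variance \eqn{V_P = \sigma^2_{aT_i} + \sigma^2} (fixed effects
#' excluded), both coefficients of additive variation, heritability with its
#' delta-method standard error, and the evolvability \eqn{I_A}. Components at
#' the boundary floor are reported as `V_A = 0`.
#'
#' @param fits A named list of [reml_fit()] results (names are trait columns
#'   of `data`), or a single fit.
#' @param data The phenotype data frame the fits were computed from (used for
#'   the raw per-environment trait means).
#' @param env_col Environment column name.
#' @return A tibble of class `genetic_summary` with columns `trait`,
#'   `environment`, `mean`, `V_A`, `V_P`, `CVA_stated`, `CVA_printed`, `h2`,
#'   `SE_h2`, `I_A`.
#' @export
genetic_summary <- function(fits, data, env_col = "environment") {
  if (inherits(fits, "animal_model_fit")) {
    fits <- stats::setNames(list(fits), fits$trait)
  }
  stopifnot(all(vapply(fits, inherits, logical(1), "animal_model_fit")))
  out <- purrr::imap_dfr(fits, function(fit, trait) {
    G <- fit$components$G
    s2 <- fit$components$sigma2_e
    h2_tbl <- heritability_by_environment(fit)
    purrr::map_dfr(seq_along(fit$env_levels), function(i) {
      ev <- fit$env_levels[i]
      va <- if (fit$boundary[i]) 0 else G[i, i]
      sel <- as.character(data[[env_col]]) == ev & !is.na(data[[trait]])
      xbar <- mean(data[[trait]][sel])
      evo <- evolvability_measures(va, xbar)
      tibble::tibble(
        trait = trait, environment = ev, mean = xbar,
        V_A = va, V_P = va + s2,
        CVA_stated = evo$cva_stated, CVA_printed = evo$cva_printed,
        h2 = h2_tbl$h2[i], SE_h2 = h2_tbl$se_h2[i], I_A = evo$iA
      )
    })
  })
  class(out) <- c("genetic_summary", class(out))
  out
}

#' Round a genetic summary for reporting
#'
#' @param x A [genetic_summary()] tibble.
#' @param digits Decimal places for the rendered report (default 2).
#' @return The summary with numeric columns rounded; raw precision is kept in
#'   the unrounded object.
#' @export
format_genetic_summary <- function(x, digits = 2) {
  dplyr::mutate(x, dplyr::across(dplyr::where(is.numeric), ~ round(.x, digits)))
}

#' Published per-environment genetic estimates used as a worked example
#'
#' Per-environment trait means, additive genetic variance (V_A), phenotypic
#' variance (V_P), coefficient of additive variation, heritability with its
#' standard error, and evolvability (I_A), as published for a half-sib
#' split-brood study of body dry mass (mg), femur area (mm^2) and testis dry
#' mass (mg) in the leaf-footed cactus bug reared on cactus with ripe fruit,
#' unripe fruit, or no fruit. Used in worked examples and consistency checks
#' of the summary formulas (note that the published CVA column matches
#' `V_A / mean`, not the standard `sqrt(V_A) / mean`).
#'
#' @return A tibble with columns `trait`, `environment`, `mean`, `V_A`, `V_P`,
#'   `CVA`, `h2`, `SE_h2`, `I_A`.
#' @export
reference_genetic_summary <- function() {
  tibble::tribble(
    ~trait, ~environment, ~mean, ~V_A, ~V_P, ~CVA, ~h2, ~SE_h2, ~I_A,
    "body_mass_mg", "ripe", 23.51, 36.53, 90.68, 1.56, 0.40, 0.13, 0.07,
    "body_mass_mg", "unripe", 12.96, 0.97, 15.87, 0.07, 0.06, 0.11, 0.01,
    "body_mass_mg", "none", 12.29, 1.51, 20.63, 0.12, 0.07, 0.07, 0.01,
    "femur_area_mm2", "ripe", 7.14, 0.41, 3.09, 0.06, 0.13, 0.11, 0.01,
    "femur_area_mm2", "unripe", 6.17, 0.00, 1.78, 0.00, 0.00, 0.00, 0.00,
    "femur_area_mm2", "none", 4.86, 0.26, 2.12, 0.05, 0.12, 0.08, 0.01,
    "testis_mass_mg", "ripe", 0.20, 1.08, 5.08, 5.40, 0.21, 0.11, 27.00,
    "testis_mass_mg", "unripe", 0.13, 0.16, 1.79, 1.23, 0.09, 0.12, 9.50,
    "testis_mass_mg", "none", 0.13, 0.26, 2.49, 2.0, 0.11, 0.07, 15.40
  )
}
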