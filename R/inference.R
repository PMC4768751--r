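#' Approximate F-tests for the fixed effects of a fitted animal model
#'
#' Wald F statistic for each fixed-effect term (environment, dissector block):
#' \eqn{F = (L\hat b)'(L \, \mathrm{Var}(\hat b) \, L')^{-1}(L\hat b)/q} with
#' `q` estimable contrasts in the numerator and `n - rank(X)` denominator
#' degrees of freedom.
#'
#' @param fit An [reml_fit()] result.
#' @return A tibble with columns `term`, `df_num`, `df_den`, `F`, `p`.
#' @export
wald_f_tests <- function(fit) {
  stopifnot(inherits(fit, "animal_model_fit"))
  asgn <- fit$model$assign
  labels <- fit$model$term_labels
  terms <- setdiff(unique(asgn), 0)
  if (length(terms) == 0L) {
    stop("no testable fixed-effect term: every factor has a single level",
         call. = FALSE)
  }
  df_den <- fit$model$n - fit$model$rank
  out <- purrr::map_dfr(terms, function(tt) {
    cols <- which(asgn == tt)
    if (length(cols) == 0L) {
      stop("term `", labels[tt + 1L], "` has zero estimable contrasts", call. = FALSE)
    }
    b <- fit$fixed_effects$estimate[cols]
    Vb <- fit$model$bcov[cols, cols, drop = FALSE]
    Fst <- drop(crossprod(b, solve(Vb, b))) / length(cols)
    tibble::tibble(term = labels[tt + 1L],
                   df_num = length(cols), df_den = df_den,
                   F = Fst, p = stats::pf(Fst, length(cols), df_den,
                                          lower.tail = FALSE))
  })
  out
}

#' Predicted (adjusted) environment means from a fitted animal model
#'
#' Estimable linear combinations of the fixed effects at each environment
#' level, with dissector blocks averaged with equal weights.
#'
#' @param fit An [reml_fit()] result.
#' @return A tibble with columns `environment`, `mean`, `se`.
#' @export
predicted_environment_means <- function(fit) {
  stopifnot(inherits(fit, "animal_model_fit"))
  cn <- colnames(fit$model$X)
  envs <- fit$env_levels
  blocks <- fit$block_levels
  L <- matrix(0, length(envs), length(cn), dimnames = list(envs, cn))
  L[, "(Intercept)"] <- 1
  for (ev in envs) {
    col <- paste0("env", ev)
    if (col %in% cn) L[ev, col] <- 1
  }
  if (length(blocks) >= 2) {
    for (b in blocks) {
      col <- paste0("block", b)
      if (col %in% cn) L[, col] <- 1 / length(blocks)
    }
  }
  est <- drop(L %*% fit$fixed_effects$estimate)
  se <- sqrt(pmax(diag(L %*% fit$model$bcov %*% t(L)), 0))
  tibble::tibble(environment = envs, mean = unname(est), se = unname(se))
}
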