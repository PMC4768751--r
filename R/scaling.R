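#' Natural-log transform positive trait values
#'
#' @param values Numeric vector; missing values pass through, non-positive
#'   values are an error (their row indices are reported).
#' @return `log(values)`.
#' @export
log_transform <- function(values) {
  bad <- which(!is.na(values) & values <= 0)
  if (length(bad)) {
    stop("log transform needs positive values; offending row(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ...", call. = FALSE)
  }
  log(values)
}

# Compact letter display from pairwise "different / not different" decisions
# (insertion algorithm: start from one letter covering all groups, split on
# each significant pair, then drop redundant letters).
compact_letters <- function(groups, pair_tbl, alpha = 0.05) {
  sets <- list(groups)
  sig <- pair_tbl[pair_tbl$p_adj <= alpha, , drop = FALSE]
  if (nrow(sig)) {
    for (r in seq_len(nrow(sig))) {
      g1 <- sig$group1[r]; g2 <- sig$group2[r]
      for (s in seq_along(sets)) {
        if (g1 %in% sets[[s]] && g2 %in% sets[[s]]) {
          sets <- c(sets, list(setdiff(sets[[s]], g1)))
          sets[[s]] <- setdiff(sets[[s]], g2)
        }
      }
      keep <- rep(TRUE, length(sets))
      for (a in seq_along(sets)) {
        for (b in seq_along(sets)) {
          if (a != b && keep[b] && all(sets[[a]] %in% sets[[b]]) &&
              (length(sets[[a]]) < length(sets[[b]]) || a > b)) {
            keep[a] <- FALSE
          }
        }
      }
      sets <- sets[keep]
    }
  }
  lab <- letters[seq_along(sets)]
  out <- vapply(groups, function(g) {
    paste0(lab[vapply(sets, function(s) g %in% s, logical(1))], collapse = "")
  }, character(1))
  tibble::tibble(group = groups, letters = unname(out))
}

#' One-way ANOVA with Tukey-Kramer post hoc comparisons
#'
#' Standard one-way F test of a (typically log-transformed) trait across
#' environments, followed by all-pairs Tukey-Kramer comparisons on the
#' studentized-range distribution (the Kramer correction handles unequal
#' group sizes) and a compact letter display at `alpha`.
#'
#' @param data A data frame.
#' @param value Name of the response column.
#' @param group Name of the grouping column (>= 2 groups, each with >= 2
#'   observations).
#' @param alpha Significance level for the Tukey decisions.
#' @return An object of class `anova_tukey`: F statistic and degrees of
#'   freedom, p-value, group means, pairwise Tukey table, and letters.
#' @export
one_way_anova_tukey <- function(data, value, group, alpha = 0.05) {
  y <- data[[value]]
  g <- droplevels(factor(data[[group]]))
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- droplevels(g[ok])
  counts <- table(g)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(counts < 2)) {
    stop("every group needs >= 2 observations; too small: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  fit <- suppressWarnings(stats::aov(y ~ g))
  an <- suppressWarnings(stats::anova(fit))
  Fst <- an$`F value`[1]
  df1 <- an$Df[1]; df2 <- an$Df[2]
  p <- an$`Pr(>F)`[1]
  mse <- an$`Mean Sq`[2]
  if (stats::var(y) == 0) {
    # degenerate constant response: no variation to test
    Fst <- 0; p <- 1; mse <- 0
  }
  means <- tapply(y, g, mean)

  levs <- levels(g)
  pairs <- utils::combn(levs, 2)
  pair_tbl <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    diff <- means[[b]] - means[[a]]
    se <- sqrt(mse / 2 * (1 / counts[[a]] + 1 / counts[[b]]))
    q <- if (se > 0) abs(diff) / se else 0
    tibble::tibble(group1 = a, group2 = b, diff = diff,
                   p_adj = stats::ptukey(q, nlevels(g), df2, lower.tail = FALSE))
  })
  structure(list(
    F = Fst, df_num = df1, df_den = df2, p = p, alpha = alpha,
    group_means = tibble::tibble(group = levs, n = as.integer(counts[levs]),
                                 mean = as.numeric(means[levs])),
    tukey = pair_tbl,
    letters = compact_letters(levs, pair_tbl, alpha)
  ), class = "anova_tukey")
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat("One-way ANOVA: F(", x$df_num, ", ", x$df_den, ") = ",
      signif(x$F, 5), ", p = ", format.pval(x$p, digits = 3), "\n", sep = "")
  print(dplyr::left_join(x$group_means, x$letters, by = "group"))
  invisible(x)
}

#' Tidy an `anova_tukey` object
#' @param x An `anova_tukey`.
#' @param ... Unused.
#' @return A tibble with the pairwise Tukey-Kramer comparisons.
#' @export
tidy.anova_tukey <- function(x, ...) x$tukey

#' ANCOVA with interaction screening for allometric scaling
#'
#' Fits `response ~ covariate * group`; if the group-by-covariate interaction
#' has `p > screening_threshold` (default 0.20) it is removed and the
#' common-slope model is reported, otherwise the interaction is retained.
#' Main effects use Type II sums of squares. Adjusted group means are
#' evaluated at the grand covariate mean, with Tukey-adjusted pairwise
#' comparisons.
#'
#' @param data A data frame; `response` and `covariate` are typically
#'   log-transformed upstream.
#' @param response,covariate,group Column names.
#' @param screening_threshold Interaction-retention threshold on its p-value.
#' @param alpha Significance level for pairwise letters.
#' @return An object of class `ancova_scaling` with the per-term F table, the
#'   overall-model F, the interaction decision, slopes, and adjusted means.
#' @export
ancova_scaling <- function(data, response, covariate, group,
                           screening_threshold = 0.20, alpha = 0.05) {
  d <- data.frame(
    y = data[[response]],
    x = data[[covariate]],
    g = droplevels(factor(data[[group]]))
  )
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nlevels(droplevels(d$g)) < 2) stop("need at least 2 groups", call. = FALSE)
  d$g <- droplevels(d$g)
  if (stats::var(d$x) == 0) stop("covariate is constant", call. = FALSE)
  full <- stats::lm(y ~ x * g, data = d)
  if (any(!is.finite(stats::coef(full)))) {
    stop("covariate is collinear with the groups", call. = FALSE)
  }
  reduced <- stats::lm(y ~ x + g, data = d)
  screen <- stats::anova(reduced, full)
  p_int <- screen$`Pr(>F)`[2]
  retained <- !is.na(p_int) && p_int <= screening_threshold
  final <- if (retained) full else reduced

  a2 <- suppressMessages(car::Anova(final, type = 2))
  terms_tbl <- tibble::tibble(
    term = rownames(a2)[seq_len(nrow(a2) - 1L)],
    df = a2$Df[seq_len(nrow(a2) - 1L)],
    F = a2$`F value`[seq_len(nrow(a2) - 1L)],
    p = a2$`Pr(>F)`[seq_len(nrow(a2) - 1L)]
  )
  terms_tbl$term <- sub("^x:g$|^g:x$", paste0(group, " x ", covariate),
                        terms_tbl$term)
  terms_tbl$term[terms_tbl$term == "x"] <- covariate
  terms_tbl$term[terms_tbl$term == "g"] <- group

  fs <- summary(final)$fstatistic
  overall <- tibble::tibble(
    df = as.integer(fs[2]),
    F = unname(fs[1]),
    p = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  )

  emm <- suppressMessages(emmeans::emmeans(final, "g"))
  emm_tbl <- as.data.frame(emm)
  prs <- as.data.frame(suppressMessages(
    emmeans::contrast(emm, method = "pairwise", adjust = "tukey")))
  pair_tbl <- tibble::tibble(
    group1 = sub(" - .*$", "", prs$contrast),
    group2 = sub("^.* - ", "", prs$contrast),
    diff = -prs$estimate,
    p_adj = prs$p.value
  )
  slopes <- if (retained) {
    tr <- as.data.frame(suppressMessages(emmeans::emtrends(final, "g", var = "x")))
    tibble::tibble(group = as.character(tr$g), slope = tr$x.trend,
                   se = tr$SE)
  } else {
    sm <- summary(final)$coefficients
    tibble::tibble(group = "(common)", slope = sm["x", 1], se = sm["x", 2])
  }

  structure(list(
    response = response, covariate = covariate, group = group,
    interaction_retained = retained, screening_p = p_int,
    screening_threshold = screening_threshold,
    terms = terms_tbl, overall = overall,
    adjusted_means = tibble::tibble(group = as.character(emm_tbl$g),
                                    mean = emm_tbl$emmean, se = emm_tbl$SE),
    tukey_on_adjusted = pair_tbl,
    letters = compact_letters(levels(d$g), pair_tbl, alpha),
    slopes = slopes, model = final, n = nrow(d)
  ), class = "ancova_scaling")
}

#' @export
print.ancova_scaling <- function(x, ...) {
  cat("ANCOVA: ", x$response, " ~ ", x$covariate, " * ", x$group,
      " (interaction ", if (x$interaction_retained) "retained" else "dropped",
      ", screening p = ", signif(x$screening_p, 3), ")\n", sep = "")
  print(x$terms)
  cat("adjusted means at the grand covariate mean:\n")
  print(dplyr::left_join(x$adjusted_means, x$letters, by = "group"))
  invisible(x)
}

#' Tidy an `ancova_scaling` object
#' @param x An `ancova_scaling`.
#' @param ... Unused.
#' @return The per-term F table as a tibble.
#' @export
tidy.ancova_scaling <- function(x, ...) x$terms

#' Run the full trait-expression and allometry battery
#'
#' Log-transforms the three traits, runs a one-way ANOVA with Tukey-Kramer
#' comparisons per trait against environment, and the three allometric
#' ANCOVAs (femur ~ body, testis ~ body, testis ~ femur, each with
#' environment and the interaction-screening rule).
#'
#' @param data Phenotype data frame.
#' @param traits Named character vector of length 3:
#'   `c(body = ..., femur = ..., testis = ...)` column names.
#' @param env_col Environment column name.
#' @param screening_threshold Interaction-retention threshold.
#' @param alpha Significance level for Tukey decisions.
#' @return An object of class `scaling_battery` with elements `anovas`
#'   (named list of [one_way_anova_tukey()] results), `ancovas` (named list
#'   of [ancova_scaling()] results), and `table`, a long report with columns
#'   `model`, `term`, `df`, `F`, `p`.
#' @export
scaling_battery <- function(data,
                            traits = c(body = "body_mass_mg",
                                       femur = "femur_area_mm2",
                                       testis = "testis_mass_mg"),
                            env_col = "environment",
                            screening_threshold = 0.20, alpha = 0.05) {
  stopifnot(all(c("body", "femur", "testis") %in% names(traits)))
  missing_tr <- setdiff(unname(traits), names(data))
  if (length(missing_tr)) {
    stop("trait column(s) not found: ", paste(missing_tr, collapse = ", "),
         call. = FALSE)
  }
  logs <- data.frame(row.names = seq_len(nrow(data)))
  for (nm in names(traits)) logs[[nm]] <- log_transform(data[[traits[[nm]]]])
  logs$env <- data[[env_col]]

  anovas <- purrr::map(stats::setNames(names(traits), names(traits)),
                       function(nm) one_way_anova_tukey(logs, nm, "env", alpha))
  specs <- list(
    body_vs_femur = c(y = "femur", x = "body"),
    body_vs_testis = c(y = "testis", x = "body"),
    femur_vs_testis = c(y = "testis", x = "femur")
  )
  ancovas <- purrr::map(specs, function(sp) {
    ancova_scaling(logs, sp[["y"]], sp[["x"]], "env",
                   screening_threshold = screening_threshold, alpha = alpha)
  })

  anova_rows <- purrr::imap_dfr(anovas, function(a, nm) {
    tibble::tibble(model = paste0("anova_", nm), term = env_col,
                   df = a$df_num, F = a$F, p = a$p)
  })
  ancova_rows <- purrr::imap_dfr(ancovas, function(a, nm) {
    dplyr::bind_rows(
      tibble::tibble(model = nm, term = "(model)", df = a$overall$df,
                     F = a$overall$F, p = a$overall$p),
      dplyr::mutate(a$terms, model = nm, .before = 1)
    )
  })
  tbl <- dplyr::bind_rows(anova_rows, ancova_rows)
  structure(list(anovas = anovas, ancovas = ancovas, table = tbl,
                 data_log = tibble::as_tibble(logs)),
            class = "scaling_battery")
}

#' @export
print.scaling_battery <- function(x, ...) {
  cat("Trait-expression and allometry battery\n")
  print(x$table, n = Inf)
  invisible(x)
}

#' Tidy a `scaling_battery` object
#' @param x A `scaling_battery`.
#' @param ... Unused.
#' @return The long report table (`model`, `term`, `df`, `F`, `p`).
#' @export
tidy.scaling_battery <- function(x, ...) x$table
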