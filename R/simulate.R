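#' Design configuration for a half-sib split-brood simulation
#'
#' Describes the breeding design: a set of sires each mated to several
#' unrelated dams, broods split across developmental environments at random.
#' Defaults mirror a design of 35 paternal half-sib families with three dams
#' per sire and roughly 10 offspring per dam, allocated unevenly across the
#' three diets (per-sire-family medians near 11 ripe / 6 unripe / 14 no-fruit),
#' with an occasional empty sire-by-environment cell.
#'
#' @param n_sires Number of sires.
#' @param dams_per_sire Dams mated to each sire (each dam mates once).
#' @param offspring_per_dam Offspring per full-sib brood.
#' @param env_weights Named allocation proportions over environments; must be
#'   non-negative and are normalized to sum to 1.
#' @param env_labels Environment labels, in display order.
#' @param missing_cell_rate Probability that a sire-family-by-environment cell
#'   is emptied (its offspring reassigned to the remaining environments).
#' @param n_blocks Number of dissector blocks, assigned uniformly at random.
#' @param family_allocation If `TRUE`, whole broods are allocated to a single
#'   environment instead of splitting within broods (design exploration only).
#' @param seed Integer seed; if non-`NULL`, set before simulation.
#' @return A list of class `design_config`.
#' @export
design_config <- function(n_sires = 35,
                          dams_per_sire = 3,
                          offspring_per_dam = 10,
                          env_weights = c(ripe = 11, unripe = 6, none = 14) / 31,
                          env_labels = c("ripe", "unripe", "none"),
                          missing_cell_rate = 0.03,
                          n_blocks = 3,
                          family_allocation = FALSE,
                          seed = NULL) {
  stopifnot(n_sires >= 1, dams_per_sire >= 1, offspring_per_dam >= 1,
            n_blocks >= 1)
  if (length(env_weights) != length(env_labels)) {
    stop("env_weights must have one entry per environment label", call. = FALSE)
  }
  if (any(env_weights < 0) || sum(env_weights) <= 0) {
    stop("env_weights must be non-negative with a positive sum", call. = FALSE)
  }
  if (missing_cell_rate < 0 || missing_cell_rate >= 1) {
    stop("missing_cell_rate must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(n_sires = as.integer(n_sires),
         dams_per_sire = as.integer(dams_per_sire),
         offspring_per_dam = as.integer(offspring_per_dam),
         env_weights = stats::setNames(env_weights / sum(env_weights), env_labels),
         env_labels = env_labels,
         missing_cell_rate = missing_cell_rate,
         n_blocks = as.integer(n_blocks),
         family_allocation = isTRUE(family_allocation),
         seed = seed),
    class = "design_config"
  )
}

#' True simulation parameters for one trait
#'
#' The genetic architecture of a trait treated as correlated character states
#' across environments: an unstructured additive genetic covariance matrix `G`
#' (one state per environment), a common residual variance, environment means,
#' and fixed dissector-block effects.
#'
#' @param G Symmetric positive-semidefinite genetic covariance matrix
#'   (trait-units squared), one row/column per environment.
#' @param sigma2_e Residual variance (trait-units squared), `>= 0`.
#' @param env_means Environment means (overall mean plus environment effect).
#' @param block_effects Numeric vector of fixed dissector effects (one per
#'   block; recycled to the design's block count, default none).
#' @return A list of class `true_params`.
#' @export
true_params <- function(G, sigma2_e, env_means, block_effects = 0) {
  G <- as.matrix(G)
  if (!isSymmetric(unname(G), tol = 1e-8)) stop("G must be symmetric", call. = FALSE)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(sum(diag(G)), 1)) {
    stop("G must be positive semidefinite", call. = FALSE)
  }
  if (sigma2_e < 0) stop("sigma2_e must be >= 0", call. = FALSE)
  if (length(env_means) != nrow(G)) {
    stop("env_means must have one entry per environment", call. = FALSE)
  }
  structure(list(G = G, sigma2_e = sigma2_e,
                 env_means = env_means, block_effects = block_effects),
            class = "true_params")
}

#' Genetic covariance matrix from per-environment variances and a common
#' cross-environment genetic correlation
#'
#' @param va Vector of per-environment additive genetic variances.
#' @param r Common genetic correlation between environment pairs.
#' @return A symmetric PSD matrix `diag(sqrt(va)) %*% R %*% diag(sqrt(va))`.
#' @export
genetic_cov_matrix <- function(va, r = 0.5) {
  stopifnot(all(va >= 0), r >= -1, r <= 1)
  k <- length(va)
  R <- matrix(r, k, k); diag(R) <- 1
  sd <- sqrt(va)
  G <- R * tcrossprod(sd)
  (G + t(G)) / 2
}

#' Allocate split-brood offspring to environments
#'
#' Assigns each offspring independently to an environment by a multinomial
#' draw. When `missing_cell_rate > 0`, whole sire-by-environment cells are
#' emptied at random and their offspring reassigned among the sire's remaining
#' environments (a sire never loses all environments).
#'
#' @param families A data frame with columns `sire`, `dam`, `n` (brood size),
#'   or a numeric vector of brood sizes (treated as one dam per sire).
#' @param env_weights Non-negative allocation proportions (normalized).
#' @param missing_cell_rate Probability a sire-by-environment cell is emptied.
#' @param family_allocation Allocate whole broods instead of individuals.
#' @param seed Optional integer seed.
#' @return A tibble with one row per offspring: `sire`, `dam`, `environment`.
#' @export
allocate_split_brood <- function(families, env_weights,
                                 missing_cell_rate = 0,
                                 family_allocation = FALSE,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.numeric(families)) {
    families <- tibble::tibble(sire = paste0("S", seq_along(families)),
                               dam = paste0("D", seq_along(families)),
                               n = families)
  }
  stopifnot(all(c("sire", "dam", "n") %in% names(families)))
  if (any(families$n < 0)) stop("brood sizes must be non-negative", call. = FALSE)
  if (any(env_weights < 0) || sum(env_weights) <= 0) {
    stop("env_weights must be non-negative with a positive sum", call. = FALSE)
  }
  labs <- names(env_weights)
  if (is.null(labs)) labs <- paste0("env", seq_along(env_weights))
  w <- env_weights / sum(env_weights)
  out <- families[rep(seq_len(nrow(families)), families$n), c("sire", "dam")]
  out <- tibble::as_tibble(out)
  n <- nrow(out)
  if (n == 0L) return(dplyr::mutate(out, environment = character(0)))
  if (family_allocation) {
    fam <- paste(out$sire, out$dam)
    ufam <- unique(fam)
    env_by_fam <- stats::setNames(sample(labs, length(ufam), replace = TRUE, prob = w), ufam)
    out$environment <- unname(env_by_fam[fam])
  } else {
    out$environment <- sample(labs, n, replace = TRUE, prob = w)
  }
  if (missing_cell_rate > 0) {
    for (s in unique(out$sire)) {
      drop <- labs[stats::runif(length(labs)) < missing_cell_rate]
      if (length(drop) == 0L || length(drop) >= length(labs[w > 0])) next
      keep <- setdiff(labs[w > 0], drop)
      hit <- out$sire == s & out$environment %in% drop
      if (any(hit)) {
        wk <- w[keep] / sum(w[keep])
        out$environment[hit] <- sample(keep, sum(hit), replace = TRUE, prob = wk)
      }
    }
  }
  out
}

# PSD-safe matrix square root (for sampling from MVN(0, G) with G possibly
# singular, e.g. an environment with zero additive variance).
psd_sqrt <- function(G) {
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  e$vectors %*% (sqrt(lam) * t(e$vectors))
}

rmvn0 <- function(n, G) {
  k <- nrow(G)
  matrix(stats::rnorm(n * k), n, k) %*% psd_sqrt(G)
}

#' Simulate a half-sib split-brood dataset with known genetic architecture
#'
#' Draws founder breeding-value vectors (one character state per environment)
#' from MVN(0, G); each offspring inherits the parental average plus a
#' Mendelian-sampling deviation MVN(0, G/2). Offspring are assigned one
#' environment (split-brood allocation) and one dissector block, and the
#' observed phenotype is the environment mean plus the block effect plus the
#' breeding value expressed in that environment plus independent residual
#' noise.
#'
#' @param cfg A [design_config()].
#' @param truth A [true_params()] for a single trait, or a named list of
#'   `true_params` to simulate several traits on the same individuals (traits
#'   are genetically independent of each other).
#' @return A list with elements `pedigree` (a [build_pedigree()] object),
#'   `phenotypes` (tibble: `id`, `sire`, `dam`, `environment`, `block`, one
#'   column per trait), `truth`, and `breeding_values` (list of matrices, one
#'   per trait, pedigree individuals by environments).
#' @export
simulate_breeding_design <- function(cfg, truth) {
  stopifnot(inherits(cfg, "design_config"))
  single <- inherits(truth, "true_params")
  truths <- if (single) list(value = truth) else truth
  if (!all(vapply(truths, inherits, logical(1), "true_params"))) {
    stop("truth must be a true_params object or a named list of them", call. = FALSE)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  k <- length(cfg$env_labels)
  for (tp in truths) {
    if (nrow(tp$G) != k) stop("truth G dimension must match the number of environments", call. = FALSE)
  }

  sires <- paste0("S", seq_len(cfg$n_sires))
  dams <- paste0("D", outer(seq_len(cfg$dams_per_sire), seq_len(cfg$n_sires),
                            function(d, s) paste0(s, "_", d)))
  fam <- tibble::tibble(
    sire = rep(sires, each = cfg$dams_per_sire),
    dam = as.vector(dams),
    n = cfg$offspring_per_dam
  )
  alloc <- allocate_split_brood(fam, cfg$env_weights,
                                missing_cell_rate = cfg$missing_cell_rate,
                                family_allocation = cfg$family_allocation)
  n_off <- nrow(alloc)
  off_id <- paste0("O", seq_len(n_off))
  ped_tbl <- dplyr::bind_rows(
    tibble::tibble(id = sires, sire = NA_character_, dam = NA_character_),
    tibble::tibble(id = as.vector(dams), sire = NA_character_, dam = NA_character_),
    tibble::tibble(id = off_id, sire = alloc$sire, dam = alloc$dam)
  )
  ped <- build_pedigree(ped_tbl)

  env <- factor(alloc$environment, levels = cfg$env_labels)
  block <- factor(paste0("B", sample.int(cfg$n_blocks, n_off, replace = TRUE)),
                  levels = paste0("B", seq_len(cfg$n_blocks)))

  founders <- c(sires, as.vector(dams))
  pheno <- tibble::tibble(id = off_id, sire = alloc$sire, dam = alloc$dam,
                          environment = env, block = block)
  bv_list <- list()
  for (nm in names(truths)) {
    tp <- truths[[nm]]
    bv <- matrix(0, nrow(ped), k, dimnames = list(ped$id, cfg$env_labels))
    bv[founders, ] <- rmvn0(length(founders), tp$G)
    mend <- rmvn0(n_off, tp$G / 2)
    bv[off_id, ] <- 0.5 * (bv[alloc$sire, , drop = FALSE] +
                           bv[alloc$dam, , drop = FALSE]) + mend
    be <- rep_len(tp$block_effects, cfg$n_blocks)
    a_expr <- bv[cbind(match(off_id, rownames(bv)), as.integer(env))]
    y <- tp$env_means[as.integer(env)] + be[as.integer(block)] + a_expr +
      stats::rnorm(n_off, sd = sqrt(tp$sigma2_e))
    pheno[[nm]] <- y
    bv_list[[nm]] <- bv
  }
  # keep pedigree order consistent between outputs
  bv_list <- lapply(bv_list, function(m) m[ped$id, , drop = FALSE])
  list(pedigree = ped, phenotypes = pheno,
       truth = if (single) truths$value else truths,
       breeding_values = bv_list)
}

#' Default per-trait simulation parameters for the three-diet study design
#'
#' Returns `true_params` for body dry mass (mg), femur area (mm^2) and testis
#' dry mass (mg) on cactus diets with ripe fruit, unripe fruit, and no fruit.
#' Body mass and femur area use additive genetic variances on the scale of the
#' published per-environment estimates (body: 36.53/0.97/1.51 with residual
#' variance 54; femur: 0.41/0/0.26 with residual variance 2) and a
#' cross-environment genetic correlation of 0.5. Published testis-mass
#' variances are inconsistent with the printed means by an unstated unit
#' factor and would make a Gaussian simulation go negative, so the testis
#' defaults keep the printed means and heritabilities but scale the variances
#' to a coefficient of phenotypic variation near 25%.
#'
#' @param genetic_correlation Common cross-environment genetic correlation.
#' @return Named list of [true_params()]: `body_mass_mg`, `femur_area_mm2`,
#'   `testis_mass_mg`.
#' @export
default_trait_params <- function(genetic_correlation = 0.5) {
  r <- genetic_correlation
  testis_vp <- (0.25 * 0.20)^2           # SD = 25% of the ripe-diet mean
  testis_h2 <- c(0.21, 0.09, 0.11)
  testis_s2 <- testis_vp * (1 - testis_h2[1])
  list(
    body_mass_mg = true_params(
      G = genetic_cov_matrix(c(36.53, 0.97, 1.51), r),
      sigma2_e = 54,
      env_means = c(23.51, 12.96, 12.29),
      block_effects = c(-0.5, 0, 0.5)
    ),
    femur_area_mm2 = true_params(
      G = genetic_cov_matrix(c(0.41, 0, 0.26), r),
      sigma2_e = 2,
      env_means = c(7.14, 6.17, 4.86),
      block_effects = c(-0.05, 0, 0.05)
    ),
    testis_mass_mg = true_params(
      G = genetic_cov_matrix(testis_s2 * testis_h2 / (1 - testis_h2), r),
      sigma2_e = testis_s2,
      env_means = c(0.20, 0.13, 0.13),
      block_effects = c(-0.002, 0, 0.002)
    )
  )
}
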