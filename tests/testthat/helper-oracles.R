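# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive, first-principles implementations kept separate from the
# package's own code paths.

# Additive relationship by recursive coancestry: f(i,i) = (1 + f(s,d))/2,
# f(i,j) = (f(s,j) + f(d,j))/2 with i later in pedigree order than j;
# a(i,j) = 2 f(i,j), and an unknown parent contributes 0.
oracle_kinship <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- unname(idx[ped$sire])
  di <- unname(idx[ped$dam])
  memo <- matrix(NA_real_, n, n)
  f <- function(i, j) {
    if (i < j) { tmp <- i; i <- j; j <- tmp }
    if (!is.na(memo[i, j])) return(memo[i, j])
    val <- if (i == j) {
      fp <- if (!is.na(si[i]) && !is.na(di[i])) f(si[i], di[i]) else 0
      0.5 * (1 + fp)
    } else {
      # i is strictly later than j in topological order
      fs <- if (!is.na(si[i])) f(si[i], j) else 0
      fd <- if (!is.na(di[i])) f(di[i], j) else 0
      0.5 * (fs + fd)
    }
    memo[i, j] <<- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in seq_len(i)) A[i, j] <- A[j, i] <- 2 * f(i, j)
  A
}

# Random valid pedigree: founders plus layered generations with parents drawn
# from earlier layers (sires and dams kept disjoint to match the tabular
# method's assumptions about ordering only, not sex).
random_pedigree <- function(n, n_founders = max(4, n %/% 4)) {
  n_founders <- min(n_founders, n)
  id <- paste0("I", seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i <= n_founders) next
    pool <- seq_len(i - 1L)
    if (stats::runif(1) < 0.1) next  # occasional extra founder
    pick <- sample(pool, 2)
    sire[i] <- id[pick[1]]
    dam[i] <- id[pick[2]]
  }
  build_pedigree(tibble::tibble(id = id, sire = sire, dam = dam))
}

# Dense first-principles REML log-likelihood: explicit incidence matrix Z,
# Kronecker-product genetic covariance, generic determinant computations.
oracle_reml_loglik <- function(data, ped, trait, G, s2,
                               env_col = "environment", block_col = "block") {
  d <- data[!is.na(data[[trait]]), , drop = FALSE]
  q <- nrow(ped)
  k <- nrow(G)
  envi <- as.integer(factor(d[[env_col]]))
  ids <- match(as.character(d$id), ped$id)
  n <- nrow(d)
  Z <- matrix(0, n, q * k)
  for (mm in seq_len(n)) Z[mm, (envi[mm] - 1) * q + ids[mm]] <- 1
  A <- oracle_kinship(ped)
  V <- Z %*% kronecker(G, A) %*% t(Z) + s2 * diag(n)
  mf <- data.frame(env = factor(d[[env_col]]))
  terms <- if (nlevels(mf$env) >= 2) "env" else character(0)
  if (!is.null(block_col) && block_col %in% names(d)) {
    b <- droplevels(factor(d[[block_col]]))
    if (nlevels(b) >= 2) { mf$block <- b; terms <- c(terms, "block") }
  }
  X <- stats::model.matrix(stats::reformulate(if (length(terms)) terms else "1"), mf)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  y <- d[[trait]]
  p <- ncol(X)
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       t(y) %*% P %*% y + (n - p) * log(2 * pi)))
}

# small half-sib dataset for quick REML tests
sim_small <- function(seed, n_sires = 8, dams = 2, per_dam = 3,
                      va = c(20, 6, 9), r = 0.4, s2 = 30,
                      env_means = c(20, 12, 10), blocks = 2) {
  cfg <- design_config(n_sires = n_sires, dams_per_sire = dams,
                       offspring_per_dam = per_dam,
                       missing_cell_rate = 0, n_blocks = blocks, seed = seed)
  tp <- true_params(genetic_cov_matrix(va, r), s2, env_means,
                    block_effects = seq(-0.5, 0.5, length.out = blocks))
  simulate_breeding_design(cfg, tp)
}
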