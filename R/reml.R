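#' Variance components of the character-state animal model
#'
#' Container for the unstructured additive genetic covariance matrix across
#' environments (`G`, one character state per environment) and the common
#' residual variance.
#'
#' @param G Symmetric genetic covariance matrix (trait-units squared).
#' @param sigma2_e Residual variance (trait-units squared), `> 0`.
#' @return A list of class `variance_components`.
#' @export
variance_components <- function(G, sigma2_e) {
  G <- as.matrix(G)
  if (!isSymmetric(unname(G), tol = 1e-8)) stop("G must be symmetric", call. = FALSE)
  if (sigma2_e < 0) stop("sigma2_e must be non-negative", call. = FALSE)
  structure(list(G = (G + t(G)) / 2, sigma2_e = sigma2_e),
            class = "variance_components")
}

# half-vectorization (column-major lower triangle) and its inverse
vech <- function(G) G[lower.tri(G, diag = TRUE)]
unvech_lower <- function(v, k) {
  L <- matrix(0, k, k)
  L[lower.tri(L, diag = TRUE)] <- v
  L
}
unvech <- function(v, k) {
  G <- matrix(0, k, k)
  G[lower.tri(G, diag = TRUE)] <- v
  G + t(G) - diag(diag(G))
}
vech_names <- function(k, labels = NULL) {
  if (is.null(labels)) labels <- paste0("env", seq_len(k))
  idx <- which(lower.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  ifelse(idx[, 1] == idx[, 2],
         paste0("Va_", labels[idx[, 1]]),
         paste0("Cov_", labels[idx[, 2]], "_", labels[idx[, 1]]))
}
# vech positions of the diagonal entries of a k x k matrix
vech_diag_idx <- function(k) cumsum(c(1, rev(seq_len(k - 1) + 1)))[seq_len(k)]

# --- model frame preparation -------------------------------------------------

prep_animal_model <- function(data, pedigree, trait,
                              env_col = "environment", block_col = "block") {
  stopifnot(is.data.frame(data), inherits(pedigree, "pedigree"))
  for (col in c("id", env_col)) {
    if (!col %in% names(data)) stop("phenotype data lacks column `", col, "`", call. = FALSE)
  }
  if (!trait %in% names(data)) stop("trait column `", trait, "` not found", call. = FALSE)
  keep <- !is.na(data[[trait]])
  data <- data[keep, , drop = FALSE]
  if (nrow(data) < 2L) stop("need at least 2 phenotyped individuals", call. = FALSE)
  ids <- as.character(data$id)
  if (anyDuplicated(ids)) {
    stop("each individual must have exactly one record; duplicated id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  missing_ids <- setdiff(ids, pedigree$id)
  if (length(missing_ids)) {
    stop("phenotyped individual(s) absent from the pedigree: ",
         paste(utils::head(missing_ids, 5), collapse = ", "),
         if (length(missing_ids) > 5) " ...", call. = FALSE)
  }
  env <- data[[env_col]]
  env <- if (is.factor(env)) droplevels(env) else factor(env)
  k <- nlevels(env)
  block <- if (!is.null(block_col) && block_col %in% names(data)) {
    b <- data[[block_col]]
    if (is.factor(b)) droplevels(b) else factor(b)
  } else NULL

  terms <- character(0)
  if (k >= 2) terms <- c(terms, "env")
  if (!is.null(block) && nlevels(block) >= 2) terms <- c(terms, "block")
  mf <- data.frame(row.names = seq_along(ids))
  if ("env" %in% terms) mf$env <- env
  if ("block" %in% terms) mf$block <- block
  form <- stats::reformulate(if (length(terms)) terms else "1")
  X <- stats::model.matrix(form, mf)
  asgn <- attr(X, "assign")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep_col <- qrX$pivot[seq_len(qrX$rank)]
    message("dropping ", ncol(X) - qrX$rank, " aliased fixed-effect column(s)")
    X <- X[, keep_col, drop = FALSE]
    asgn <- asgn[keep_col]
  }
  term_labels <- c("(Intercept)", terms)

  A_full <- additive_relationship_matrix(pedigree)
  iobs <- match(ids, pedigree$id)
  Aobs <- A_full[iobs, iobs, drop = FALSE]

  list(y = as.numeric(data[[trait]]), X = X, assign = asgn,
       term_labels = term_labels, env = env, envi = as.integer(env), k = k,
       block = block, ids = ids, iobs = iobs, A_full = A_full, Aobs = Aobs,
       n = length(ids), trait = trait)
}

# --- likelihood machinery ----------------------------------------------------

# Evaluate the restricted log-likelihood and the matrices every update needs.
# V = Aobs * G[env_i, env_j] + sigma2_e * I (each individual observed in
# exactly one environment, so no explicit Kronecker assembly is required).
eval_reml_point <- function(m, G, s2) {
  V <- m$Aobs * G[m$envi, m$envi]
  diag(V) <- diag(V) + s2
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    stop("phenotypic covariance matrix V is singular (G = ",
         paste(signif(vech(G), 4), collapse = ", "),
         "; sigma2_e = ", signif(s2, 4), ")", call. = FALSE)
  }
  logdetV <- 2 * sum(log(diag(ch)))
  Vi <- chol2inv(ch)
  ViX <- Vi %*% m$X
  XtViX <- crossprod(m$X, ViX)
  chx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chx)) stop("X'V^{-1}X is singular", call. = FALSE)
  logdetX <- 2 * sum(log(diag(chx)))
  bcov <- chol2inv(chx)
  beta <- bcov %*% crossprod(ViX, m$y)
  P <- Vi - ViX %*% tcrossprod(bcov, ViX)
  r <- drop(P %*% m$y)
  yPy <- sum(m$y * r)
  p <- ncol(m$X)
  ll <- -0.5 * (logdetV + logdetX + yPy + (m$n - p) * log(2 * pi))
  if (!is.finite(ll)) {
    stop("restricted log-likelihood is not finite (V numerically singular)",
         call. = FALSE)
  }
  list(ll = ll, P = P, r = r, beta = drop(beta), bcov = bcov, yPy = yPy)
}

# per-environment indicator matrix (n x k)
env_indicator <- function(envi, k) {
  E <- matrix(0, length(envi), k)
  E[cbind(seq_along(envi), envi)] <- 1
  E
}

# Gradient and average-information matrix in theta = (vech(G), sigma2_e).
# For the (f,f') component the derivative of V is Aobs masked to the
# environment pair (both blocks when f != f').
reml_grad_ai <- function(m, st, E) {
  k <- m$k
  PA <- st$P * m$Aobs
  U <- crossprod(E, PA %*% E)                 # U[f,f'] = sum_{m in f, m' in f'} (P*A)
  trP <- sum(diag(st$P))
  H <- m$Aobs %*% (E * st$r)                  # H[m,f'] = sum_{m' in f'} A[m,m'] r[m']
  rE <- E * st$r
  Q <- crossprod(rE, H)                       # Q[f,f'] = sum_{m in f} r[m] H[m,f']

  np <- k * (k + 1) / 2 + 1
  grad <- numeric(np)
  W <- matrix(0, m$n, np)
  idx <- 0
  for (jj in seq_len(k)) {
    for (ii in jj:k) {
      idx <- idx + 1
      if (ii == jj) {
        grad[idx] <- -0.5 * (U[ii, ii] - Q[ii, ii])
        W[, idx] <- E[, ii] * H[, ii]
      } else {
        grad[idx] <- -0.5 * (2 * U[ii, jj] - 2 * Q[ii, jj])
        W[, idx] <- E[, ii] * H[, jj] + E[, jj] * H[, ii]
      }
    }
  }
  grad[np] <- -0.5 * (trP - sum(st$r^2))
  W[, np] <- st$r
  AI <- 0.5 * crossprod(W, st$P %*% W)
  list(grad = grad, AI = AI, U = U, trP = trP)
}

# EM-REML updates (guaranteed not to decrease the restricted log-likelihood):
#   G_new  = G + G (S'AS - U) G / q
#   s2_new = s2 + s2^2 (r'r - tr(P)) / n
# with S the full-pedigree aggregation of Py by individual and environment.
reml_em_update <- function(m, st, G, s2, E, ga) {
  q <- nrow(m$A_full)
  S <- matrix(0, q, m$k)
  S[cbind(m$iobs, m$envi)] <- st$r
  SAS <- crossprod(S, m$A_full %*% S)
  G_new <- G + G %*% (SAS - ga$U) %*% G / q
  s2_new <- s2 + s2^2 * (sum(st$r^2) - ga$trP) / m$n
  list(G = (G_new + t(G_new)) / 2, s2 = s2_new)
}

# Project (G, s2) back to the admissible region: clip G's eigenvalues at a
# small non-negative floor, keep diagonal entries and s2 above their floors.
# `active` records whether the projection moved the point materially (an
# estimate pinned to the PSD boundary or a variance floor).
project_components <- function(G, s2, va_floor, s2_floor) {
  G_in <- (G + t(G)) / 2
  e <- eigen(G_in, symmetric = TRUE)
  lam <- pmax(e$values, 1e-8 * max(sum(pmax(e$values, 0)), va_floor))
  G <- e$vectors %*% (lam * t(e$vectors))
  G <- (G + t(G)) / 2
  d <- diag(G)
  if (any(d < va_floor)) diag(G) <- pmax(d, va_floor)
  s2_out <- max(s2, s2_floor)
  scale <- max(abs(G_in), abs(s2), va_floor)
  active <- max(abs(G - G_in)) > 1e-7 * scale || (s2_out - s2) > 1e-7 * scale
  list(G = G, s2 = s2_out, active = active)
}

#' Restricted log-likelihood of the character-state animal model
#'
#' Evaluates the REML log-likelihood
#' \deqn{-\tfrac12\left[\log|V| + \log|X'V^{-1}X| + y'Py + (n-p)\log 2\pi\right]}
#' with \eqn{V = Z(A \otimes G)Z' + \sigma^2 I} and
#' \eqn{P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}}, where the fixed-effect
#' design X holds the intercept, environment, and dissector block.
#'
#' @param data Phenotype data frame: columns `id`, the environment and block
#'   columns, and the trait. One record per individual.
#' @param pedigree A [build_pedigree()] object covering every phenotyped id.
#' @param trait Name of the trait column.
#' @param components A [variance_components()] whose `G` dimension matches the
#'   number of environment levels present in `data`.
#' @param env_col,block_col Column names for environment and dissector block.
#'   A missing or single-level block column is tolerated (no block term).
#' @return The restricted log-likelihood (scalar).
#' @export
restricted_log_likelihood <- function(data, pedigree, trait, components,
                                      env_col = "environment",
                                      block_col = "block") {
  stopifnot(inherits(components, "variance_components"))
  m <- prep_animal_model(data, pedigree, trait, env_col, block_col)
  if (nrow(components$G) != m$k) {
    stop("G is ", nrow(components$G), "x", ncol(components$G),
         " but the data have ", m$k, " environment level(s)", call. = FALSE)
  }
  eval_reml_point(m, components$G, components$sigma2_e)$ll
}

#' Fit the character-state animal model by REML
#'
#' Maximizes the restricted log-likelihood of the model
#' \deqn{y = 1\mu + X_1\tau + X_2\beta + Za_{\times\tau} + e}
#' over the unstructured genetic covariance matrix `G` (one character state
#' per environment, individuals linked through the pedigree relationship
#' matrix A) and the residual variance, using EM-REML warm-start iterations
#' followed by average-information (AI) updates with step-halving. The
#' asymptotic covariance of the variance components is the inverse of the AI
#' matrix at the optimum; breeding values are the BLUPs from the fitted model.
#'
#' @inheritParams restricted_log_likelihood
#' @param start Optional [variance_components()] starting values.
#' @param max_iter Iteration cap (EM + AI combined).
#' @param em_iters Cap on EM warm-start iterations; the fit switches to AI
#'   updates earlier once EM improvement per iteration falls below
#'   `em_switch_tol`.
#' @param tol_loglik Convergence tolerance on the change in restricted
#'   log-likelihood.
#' @param tol_grad Convergence tolerance on the AI-scaled gradient norm
#'   (the Newton decrement `sqrt(g' AI^{-1} g)`, which is invariant to the
#'   trait's measurement scale; interior optima only -- boundary estimates
#'   are flagged instead).
#' @param em_switch_tol Absolute log-likelihood improvement per iteration
#'   below which the EM warm start hands over to AI updates.
#' @return An object of class `animal_model_fit`: variance components,
#'   restricted log-likelihood, asymptotic covariance of
#'   `(vech(G), sigma2_e)`, fixed effects, per-individual environment-specific
#'   BLUPs, convergence diagnostics, and boundary flags.
#' @export
reml_fit <- function(data, pedigree, trait,
                     env_col = "environment", block_col = "block",
                     start = NULL, max_iter = 500, em_iters = 20,
                     tol_loglik = 1e-8, tol_grad = 1e-4,
                     em_switch_tol = 1) {
  m <- prep_animal_model(data, pedigree, trait, env_col, block_col)
  k <- m$k
  E <- env_indicator(m$envi, k)
  vy <- stats::var(m$y)
  if (!is.finite(vy) || vy <= 0) stop("trait has zero variance", call. = FALSE)
  va_floor <- 1e-10 * vy
  s2_floor <- 1e-8 * vy

  if (!is.null(start)) {
    stopifnot(inherits(start, "variance_components"), nrow(start$G) == k)
    G <- start$G; s2 <- max(start$sigma2_e, s2_floor)
  } else {
    vg0 <- vy / 3
    G <- vg0 * (0.5 * diag(k) + 0.5)
    s2 <- vy / 2
  }
  pr <- project_components(G, s2, va_floor, s2_floor)
  G <- pr$G; s2 <- pr$s2

  st <- eval_reml_point(m, G, s2)
  traj <- st$ll
  phase <- "em"
  em_done <- 0
  gnorm <- Inf
  converged <- FALSE
  constrained <- FALSE
  stalled <- 0L
  iter <- 0

  while (iter < max_iter) {
    iter <- iter + 1
    ga <- reml_grad_ai(m, st, E)
    gnorm <- max(abs(ga$grad))

    if (phase == "em") {
      up <- reml_em_update(m, st, G, s2, E, ga)
      pr <- project_components(up$G, up$s2, va_floor, s2_floor)
      G_new <- pr$G; s2_new <- pr$s2
      constrained <- pr$active
      st_new <- eval_reml_point(m, G_new, s2_new)
      dll <- st_new$ll - st$ll
      em_done <- em_done + 1
      if (em_done >= em_iters || dll < em_switch_tol) {
        phase <- "ai"
      }
    } else {
      # AI update in Cholesky coordinates G = L L' (keeps G PSD and turns
      # boundary optima into interior stationary points)
      L <- psd_chol_lower(G)
      phi <- c(vech(L), log(s2))
      gc <- to_chol_coords(ga, L, s2)
      nl <- length(phi)
      try_phi <- function(cand) {
        L_cand <- unvech_lower(cand[seq_len(nl - 1)], k)
        G_cand <- tcrossprod(L_cand)
        s2_cand <- max(exp(cand[nl]), s2_floor)
        st_try <- tryCatch(eval_reml_point(m, G_cand, s2_cand),
                           error = function(e) NULL)
        if (is.null(st_try)) return(NULL)
        list(G = G_cand, s2 = s2_cand, st = st_try)
      }
      st_new <- NULL
      delta <- drop(pseudo_inverse(gc$AI, tol = 1e-5) %*% gc$grad)
      step <- 1
      for (h in seq_len(30)) {
        cand <- try_phi(phi + step * delta)
        if (!is.null(cand) && cand$st$ll >= st$ll - 1e-12) {
          G_new <- cand$G; s2_new <- cand$s2; st_new <- cand$st
          break
        }
        step <- step / 2
      }
      if (is.null(st_new)) {
        # AI step rejected even after halving; fall back to one EM update
        up <- reml_em_update(m, st, G, s2, E, ga)
        pr <- project_components(up$G, up$s2, va_floor, s2_floor)
        G_new <- pr$G; s2_new <- pr$s2
        st_new <- eval_reml_point(m, G_new, s2_new)
      }
      # offer the boundary-pinned version of the new point as well
      G_snap <- snap_to_boundary(G_new, va_floor)
      if (!is.null(G_snap)) {
        st_snap <- tryCatch(eval_reml_point(m, G_snap, s2_new),
                            error = function(e) NULL)
        if (!is.null(st_snap) && st_snap$ll >= st_new$ll - 1e-12) {
          G_new <- G_snap
          st_new <- st_snap
        }
      }
      dll <- st_new$ll - st$ll
    }

    G <- G_new; s2 <- s2_new; st <- st_new
    traj <- c(traj, st$ll)
    if (phase == "ai" && abs(dll) < tol_loglik) {
      stalled <- stalled + 1L
      ga <- reml_grad_ai(m, st, E)
      gc <- to_chol_coords(ga, psd_chol_lower(G), s2)
      gnorm <- newton_decrement(gc$grad, gc$AI)
      # a run of stagnant accepted steps with a near-threshold gradient means
      # the attainable remaining gain (~ gnorm^2 / 2) is below the
      # log-likelihood resolution; a stagnant run with a sizeable gradient is
      # a crawl that can still jump, so keep iterating
      if (gnorm < tol_grad || (stalled >= 5L && gnorm < 100 * tol_grad)) {
        # confirm: a line search along the lightly truncated AI direction can
        # still expose gain in a flat direction the working truncation hides
        esc <- escape_step(m, st, G, s2, gc, k, s2_floor, tol_loglik)
        if (!is.null(esc)) {
          G <- esc$G; s2 <- esc$s2; st <- esc$st
          traj <- c(traj, st$ll)
          stalled <- 0L
        } else {
          converged <- TRUE
          constrained <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) <=
            1e-6 * sum(diag(G))
          break
        }
      }
    } else if (phase == "ai") {
      stalled <- 0L
    }
  }
  if (!converged) {
    cond <- simpleError(paste0("REML did not converge within ", max_iter,
                               " iterations (last |grad| = ", signif(gnorm, 3), ")"))
    cond$trajectory <- traj
    stop(cond)
  }

  ga <- reml_grad_ai(m, st, E)
  gc_fin <- to_chol_coords(ga, psd_chol_lower(G), s2)
  gnorm <- newton_decrement(gc_fin$grad, gc_fin$AI)
  vcov_comp <- tryCatch(solve(ga$AI), error = function(e) pseudo_inverse(ga$AI))
  labels <- levels(m$env)
  nms <- c(vech_names(k, labels), "sigma2_e")
  dimnames(vcov_comp) <- list(nms, nms)
  dimnames(G) <- list(labels, labels)

  boundary <- stats::setNames(diag(G) <= va_floor * (1 + 1e-6), labels)

  # BLUPs for every pedigree individual in every environment: A S G
  q <- nrow(m$A_full)
  S <- matrix(0, q, k)
  S[cbind(m$iobs, m$envi)] <- st$r
  blup_mat <- m$A_full %*% S %*% G
  blups <- tibble::tibble(
    id = rep(rownames(m$A_full), times = k),
    environment = rep(labels, each = q),
    blup = as.vector(blup_mat)
  )

  fixed <- tibble::tibble(
    term = colnames(m$X),
    estimate = st$beta,
    std.error = sqrt(pmax(diag(st$bcov), 0))
  )

  structure(list(
    components = variance_components(G, s2),
    reml_loglik = st$ll,
    vcov_components = vcov_comp,
    fixed_effects = fixed,
    blups = blups,
    convergence = list(iterations = iter, final_gradient_norm = gnorm,
                       trajectory = traj, em_iterations = em_done,
                       constrained = constrained),
    boundary = boundary,
    va_floor = va_floor,
    trait = trait,
    env_levels = labels,
    block_levels = if (!is.null(m$block)) levels(m$block) else character(0),
    model = list(X = m$X, assign = m$assign, term_labels = m$term_labels,
                 bcov = st$bcov, n = m$n, rank = ncol(m$X), env = m$env,
                 y = m$y, ids = m$ids)
  ), class = "animal_model_fit")
}

# scale-invariant gradient norm: sqrt(g' AI^+ g). The pseudo-inverse discards
# near-null curvature directions; in Cholesky coordinates the gradient has no
# component along them (it is J' g and the null directions are J's null space).
newton_decrement <- function(g, AI) {
  sqrt(abs(sum(g * drop(pseudo_inverse(AI, tol = 1e-5) %*% g))))
}

# Jacobian d vech(G) / d vech(L) for G = L L', L lower triangular:
# dG_ij / dL_ab = delta_ia L_jb + delta_ja L_ib.
chol_jacobian <- function(L) {
  k <- nrow(L)
  idx <- which(lower.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  np <- nrow(idx)
  J <- matrix(0, np, np)
  for (cc in seq_len(np)) {
    a <- idx[cc, 1]; b <- idx[cc, 2]
    for (rr in seq_len(np)) {
      i <- idx[rr, 1]; j <- idx[rr, 2]
      J[rr, cc] <- (i == a) * L[j, b] + (j == a) * L[i, b]
    }
  }
  J
}

# Gradient and AI matrix in phi = (vech(L), log sigma2_e), from the
# raw-component gradient and AI via the chain rule. Both transformations put
# boundary optima (singular G, vanishing residual) at interior stationary
# points of the transformed coordinates.
to_chol_coords <- function(ga, L, s2) {
  np <- length(ga$grad)
  Jf <- diag(np)
  Jf[seq_len(np - 1), seq_len(np - 1)] <- chol_jacobian(L)
  Jf[np, np] <- s2
  list(grad = drop(crossprod(Jf, ga$grad)), AI = crossprod(Jf, ga$AI %*% Jf))
}

# Boundary "snap" candidate: eigenvalues (and diagonal variances) that are
# vanishing relative to the trace are pinned at their floor in one move,
# instead of letting the iteration approach the boundary asymptotically.
# Returns NULL when nothing is close enough to the boundary to snap.
snap_to_boundary <- function(G, va_floor, rel = 0.02) {
  tr <- sum(diag(G))
  if (tr <= 0) return(NULL)
  e <- eigen(G, symmetric = TRUE)
  small <- e$values < rel * tr
  d_small <- diag(G) < rel * tr
  if (!any(small) && !any(d_small)) return(NULL)
  lam <- ifelse(small, va_floor, e$values)
  G2 <- e$vectors %*% (lam * t(e$vectors))
  G2 <- (G2 + t(G2)) / 2
  if (any(d_small)) {
    G2[d_small, ] <- 0
    G2[, d_small] <- 0
    diag(G2)[d_small] <- va_floor
  }
  G2
}

# Convergence confirmation: line search along the lightly truncated AI
# direction. Returns an improved point, or NULL when no material gain exists.
escape_step <- function(m, st, G, s2, gc, k, s2_floor, tol_loglik) {
  delta <- drop(pseudo_inverse(gc$AI, tol = 1e-9) %*% gc$grad)
  L <- psd_chol_lower(G)
  phi <- c(vech(L), log(s2))
  nl <- length(phi)
  step <- 1
  for (h in seq_len(12)) {
    cand <- phi + step * delta
    L_cand <- unvech_lower(cand[seq_len(nl - 1)], k)
    G_cand <- tcrossprod(L_cand)
    s2_cand <- max(exp(cand[nl]), s2_floor)
    st_try <- tryCatch(eval_reml_point(m, G_cand, s2_cand),
                       error = function(e) NULL)
    if (!is.null(st_try) && st_try$ll > st$ll + 100 * tol_loglik) {
      return(list(G = G_cand, s2 = s2_cand, st = st_try))
    }
    step <- step / 2
  }
  NULL
}

# lower-triangular factor of a PSD matrix (eigen-based, tolerant of
# semidefiniteness): returns L with G ~ L L'
psd_chol_lower <- function(G) {
  k <- nrow(G)
  ch <- tryCatch(t(chol(G)), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  jitter <- 1e-10 * max(sum(diag(G)), 1)
  t(chol(G + jitter * diag(k)))
}

pseudo_inverse <- function(M, tol = sqrt(.Machine$double.eps)) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d)
  if (!any(pos)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, pos, drop = FALSE] %*% ((1 / s$d[pos]) * t(s$u[, pos, drop = FALSE]))
}

#' @export
print.animal_model_fit <- function(x, ...) {
  cat("Character-state animal model fit (REML)\n")
  cat("  trait:", x$trait, "  n =", x$model$n, "\n")
  cat("  restricted log-likelihood:", format(x$reml_loglik, digits = 8), "\n")
  cat("  iterations:", x$convergence$iterations,
      " |grad| =", signif(x$convergence$final_gradient_norm, 3), "\n")
  cat("  G (additive genetic covariance across environments):\n")
  print(round(x$components$G, 4))
  cat("  residual variance:", signif(x$components$sigma2_e, 6), "\n")
  if (any(x$boundary)) {
    cat("  note: variance component(s) at the boundary:",
        paste(names(x$boundary)[x$boundary], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a fitted animal model
#'
#' @param x An `animal_model_fit`.
#' @param ... Unused.
#' @return A tibble with one row per variance component (`vech(G)` then the
#'   residual), with delta-ready standard errors from the inverse AI matrix.
#' @export
tidy.animal_model_fit <- function(x, ...) {
  est <- c(vech(x$components$G), x$components$sigma2_e)
  tibble::tibble(
    term = rownames(x$vcov_components),
    estimate = est,
    std.error = sqrt(pmax(diag(x$vcov_components), 0))
  )
}

#' Glance at a fitted animal model
#'
#' @param x An `animal_model_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the restricted log-likelihood, iteration
#'   count, final gradient norm and sample size.
#' @export
glance.animal_model_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$reml_loglik,
    n = x$model$n,
    iterations = x$convergence$iterations,
    gradient_norm = x$convergence$final_gradient_norm,
    boundary = any(x$boundary)
  )
}
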