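# Haseman-Elston initialization: regress centered phenotype cross-products
# on the corresponding GRM entries (off-diagonal pairs). Method-of-moments;
# used only as a starting value for REML.
he_regression <- function(y, GA, GX, vp, floor_v) {
  yc <- y - mean(y)
  cp <- tcrossprod(yc)
  ut <- upper.tri(cp)
  X <- cbind(GA[ut], GX[ut])
  b <- tryCatch(solve(crossprod(X), crossprod(X, cp[ut])),
                error = function(e) NULL)
  if (is.null(b) || !all(is.finite(b))) return(rep(vp / 3, 3))
  sa <- min(max(b[1], floor_v), 0.99 * vp)
  sx <- min(max(b[2], floor_v), 0.99 * vp)
  if (sa + sx >= 0.99 * vp) {
    sc <- 0.9 * vp / (sa + sx)
    sa <- sa * sc; sx <- sx * sc
  }
  c(sa, sx, vp - sa - sx)
}

#' Two-variance-component REML (autosomal + X + residual)
#'
#' Fits, by restricted maximum likelihood, the partition model
#' \deqn{y = 1\mu + g_A + g_X + e,\quad
#'   g_A \sim N(0, G_A \sigma^2_A),\; g_X \sim N(0, G_X \sigma^2_X),\;
#'   e \sim N(0, I \sigma^2_e)}
#' so that phenotypic variance splits into an autosomal polygenic, an
#' X-linked polygenic, and a residual component.
#'
#' The optimizer is average-information (AI) REML with an
#' expectation-maximization (EM) first step and EM fallback whenever an AI
#' step leaves the parameter space or decreases the restricted likelihood.
#' Negative proposals are clamped to \code{1e-8 * var(y)}; a component
#' clamped on three consecutive iterations is fixed at the zero boundary and
#' removed from the update. Standard errors come from the inverse AI matrix
#' of the free components at convergence (zero for components fixed at the
#' boundary). The fit is flagged non-converged when the AI matrix is
#' numerically singular (non-identifiable designs, e.g. proportional GRMs).
#'
#' Dense algebra: one Cholesky of the n x n covariance per iteration;
#' intended for cohorts up to a few thousand samples.
#'
#' @param y numeric phenotype vector (yield deviations); if named, names
#'   must match the GRM sample ids.
#' @param G_A,G_X \code{grm_matrix} objects over the same samples in the
#'   same order (autosomal and X-linked SNP sets).
#' @param init starting values: \code{"he"} (default) initializes at a
#'   Haseman-Elston regression of phenotype cross-products on the GRM
#'   entries, a cheap method-of-moments estimate that typically lands close
#'   to the optimum; \code{"equal"} starts from equal thirds of the
#'   phenotypic variance; or a numeric vector
#'   \code{c(sigma2_a, sigma2_x, sigma2_e)}.
#' @param max_iter maximum iterations (default 200).
#' @param tol_loglik convergence tolerance on the change in restricted
#'   log-likelihood (default 1e-6).
#' @param tol_param convergence tolerance on parameter change relative to
#'   phenotypic variance (default 1e-8).
#' @param verbose print per-iteration progress.
#' @return object of class \code{variance_components}: \code{sigma2_a},
#'   \code{sigma2_x}, \code{sigma2_e}, their standard errors, \code{cov}
#'   (3x3 sampling covariance), \code{loglik}, \code{n_iter},
#'   \code{converged}, \code{n}, \code{fixed_at_zero}.
#' @export
fit_reml_two_components <- function(y, G_A, G_X, init = "he",
                                    max_iter = 200,
                                    tol_loglik = 1e-6, tol_param = 1e-8,
                                    verbose = FALSE) {
  stopifnot(inherits(G_A, "grm_matrix"), inherits(G_X, "grm_matrix"))
  if (!identical(G_A$samples, G_X$samples)) {
    stop("G_A and G_X cover different sample sets/orders")
  }
  n <- length(y)
  if (n != length(G_A$samples)) stop("y length does not match GRM dimension")
  if (n < 30) stop("need at least 30 samples for REML")
  if (!is.null(names(y)) && !identical(names(y), G_A$samples)) {
    stop("names(y) do not match GRM sample order")
  }
  Gs <- list(G_A$values, G_X$values, diag(n))
  vp <- stats::var(y)
  if (vp <= 0) stop("phenotype has zero variance")
  floor_v <- 1e-8 * vp

  if (is.numeric(init)) {
    stopifnot(length(init) == 3)
    theta <- pmax(init, floor_v)
  } else if (identical(init, "he")) {
    theta <- he_regression(y, Gs[[1]], Gs[[2]], vp, floor_v)
  } else {
    theta <- rep(vp / 3, 3)
  }
  fixed <- rep(FALSE, 3)
  clamp_streak <- rep(0L, 3)
  loglik_prev <- -Inf
  converged <- FALSE
  ai_singular <- FALSE
  it <- 0L

  quantities <- function(theta) {
    V <- theta[1] * Gs[[1]] + theta[2] * Gs[[2]] + diag(theta[3], n)
    R <- NULL
    ridge <- 0
    for (k in 0:8) {
      R <- tryCatch(chol(V + diag(ridge, n)), error = function(e) NULL)
      if (!is.null(R)) break
      ridge <- if (ridge == 0) 1e-10 * vp else ridge * 10
    }
    if (is.null(R)) stop("covariance matrix not positive definite after ",
                         "repeated ridge shrinkage")
    Vinv <- chol2inv(R)
    vi1 <- rowSums(Vinv)
    s <- sum(vi1)
    P <- Vinv - tcrossprod(vi1) / s
    Py <- as.vector(P %*% y)
    logdetV <- 2 * sum(log(diag(R)))
    loglik <- -0.5 * (logdetV + log(s) + sum(y * Py))
    trPG <- c(sum(P * Gs[[1]]), sum(P * Gs[[2]]), sum(diag(P)))
    w <- list(as.vector(Gs[[1]] %*% Py), as.vector(Gs[[2]] %*% Py), Py)
    yPGPy <- c(sum(Py * w[[1]]), sum(Py * w[[2]]), sum(Py * w[[3]]))
    grad <- -0.5 * (trPG - yPGPy)
    Pw <- lapply(w, function(wi) as.vector(P %*% wi))
    AI <- matrix(0, 3, 3)
    for (i in 1:3) for (j in i:3) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(w[[i]] * Pw[[j]])
    }
    list(loglik = loglik, grad = grad, AI = AI, trPG = trPG, yPGPy = yPGPy)
  }

  em_step <- function(theta, q) {
    th <- theta + theta^2 * (q$yPGPy - q$trPG) / n
    th
  }

  ll_trace <- numeric(0)
  step_trace <- character(0)
  q <- quantities(theta)
  for (it in seq_len(max_iter)) {
    free <- which(!fixed)
    used_em <- FALSE
    if (length(free) == 0) {
      proposal <- em_step(theta, q)
      used_em <- TRUE
    } else {
      AIf <- q$AI[free, free, drop = FALSE]
      delta <- tryCatch(solve(AIf, q$grad[free]), error = function(e) NULL)
      if (is.null(delta) || !all(is.finite(delta))) {
        ai_singular <- TRUE
        proposal <- em_step(theta, q)
        used_em <- TRUE
      } else {
        # negative proposals are clamped to the floor below, per component
        proposal <- theta
        proposal[free] <- theta[free] + delta
      }
    }
    proposal[fixed] <- 0
    clamped <- !fixed & proposal < floor_v
    proposal[clamped] <- floor_v
    clamp_streak <- ifelse(clamped, clamp_streak + 1L, 0L)
    newly_fixed <- clamp_streak >= 3L & !fixed
    if (any(newly_fixed)) {
      fixed[newly_fixed] <- TRUE
      proposal[newly_fixed] <- 0
    }
    q_new <- quantities(proposal)
    # a clamped component whose gradient points back into the interior is
    # not at a binding boundary: reset its streak
    reset <- clamped & q_new$grad > 0
    clamp_streak[reset] <- 0L
    if (!used_em && q_new$loglik < q$loglik - 1e-8) {
      # AI overshoot: redo this iteration with the guaranteed-ascent EM step
      proposal <- em_step(theta, q)
      proposal[fixed] <- 0
      proposal[!fixed & proposal < floor_v] <- floor_v
      q_new <- quantities(proposal)
      used_em <- TRUE
    }
    dl <- q_new$loglik - q$loglik
    dtheta <- max(abs(proposal - theta)) / vp
    theta <- proposal
    q <- q_new
    ll_trace <- c(ll_trace, q$loglik)
    step_trace <- c(step_trace, if (used_em) "EM" else "AI")
    if (verbose) {
      message(sprintf("iter %3d logL %.6f  theta %s%s", it, q$loglik,
                      paste(signif(theta, 6), collapse = " "),
                      if (used_em) "  [EM]" else ""))
    }
    if (abs(dl) < tol_loglik && dtheta < tol_param) {
      converged <- TRUE
      break
    }
  }

  free <- which(!fixed)
  se <- rep(0, 3)
  covm <- matrix(0, 3, 3)
  if (length(free)) {
    AIf <- q$AI[free, free, drop = FALSE]
    kap <- tryCatch(kappa(AIf, exact = TRUE), error = function(e) Inf)
    if (!is.finite(kap) || kap > 1e10) {
      ai_singular <- TRUE
    } else {
      Cf <- solve(AIf)
      covm[free, free] <- Cf
      se[free] <- sqrt(pmax(0, diag(Cf)))
    }
  }
  if (ai_singular) converged <- FALSE

  structure(list(sigma2_a = theta[1], sigma2_x = theta[2],
                 sigma2_e = theta[3],
                 se_sigma2_a = se[1], se_sigma2_x = se[2],
                 se_sigma2_e = se[3],
                 cov = covm, loglik = q$loglik, n_iter = it,
                 converged = converged, n = n,
                 fixed_at_zero = fixed,
                 trace = data.frame(iter = seq_along(ll_trace),
                                    loglik = ll_trace, step = step_trace)),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("variance_components (n =", x$n, ")\n")
  cat(sprintf("  sigma2_a = %.6g (se %.3g)\n", x$sigma2_a, x$se_sigma2_a))
  cat(sprintf("  sigma2_x = %.6g (se %.3g)\n", x$sigma2_x, x$se_sigma2_x))
  cat(sprintf("  sigma2_e = %.6g (se %.3g)\n", x$sigma2_e, x$se_sigma2_e))
  cat(sprintf("  logL = %.4f, %d iterations, converged: %s\n",
              x$loglik, x$n_iter, x$converged))
  invisible(x)
}

#' Heritability partition from variance components
#'
#' Converts fitted variance components into the heritability partition
#' \deqn{h^2 = \frac{\sigma^2_A + \sigma^2_X}{\sigma^2_A + \sigma^2_X +
#'   \sigma^2_e},\quad
#'   h^2_{AUT} = \frac{\sigma^2_A}{\cdot},\quad h^2_X = \frac{\sigma^2_X}{\cdot}}
#' with \code{h2 = h2_aut + h2_x} holding exactly by construction. Standard
#' errors of \code{h2_aut} and \code{h2_x} are obtained by the delta method
#' from the AI sampling covariance of the components.
#'
#' @param vc a \code{variance_components} object, or a numeric vector
#'   \code{c(sigma2_a, sigma2_x, sigma2_e)} (then SEs are \code{NA}).
#' @return list of class \code{heritability_partition}: \code{h2},
#'   \code{h2_aut}, \code{h2_x}, \code{se_h2_aut}, \code{se_h2_x}.
#' @export
heritability_from_components <- function(vc) {
  if (is.numeric(vc) && length(vc) == 3) {
    comp <- vc
    covm <- NULL
  } else {
    stopifnot(inherits(vc, "variance_components"))
    comp <- c(vc$sigma2_a, vc$sigma2_x, vc$sigma2_e)
    covm <- vc$cov
  }
  tot <- sum(comp)
  if (tot <= 0) stop("total variance must be positive")
  h2_aut <- comp[1] / tot
  h2_x <- comp[2] / tot
  se_h2_aut <- se_h2_x <- NA_real_
  if (!is.null(covm)) {
    # gradient of sigma_i / total w.r.t. (s_a, s_x, s_e)
    g_aut <- c(tot - comp[1], -comp[1], -comp[1]) / tot^2
    g_x <- c(-comp[2], tot - comp[2], -comp[2]) / tot^2
    se_h2_aut <- sqrt(max(0, as.numeric(t(g_aut) %*% covm %*% g_aut)))
    se_h2_x <- sqrt(max(0, as.numeric(t(g_x) %*% covm %*% g_x)))
  }
  structure(list(h2 = h2_aut + h2_x, h2_aut = h2_aut, h2_x = h2_x,
                 se_h2_aut = se_h2_aut, se_h2_x = se_h2_x),
            class = "heritability_partition")
}

#' @export
print.heritability_partition <- function(x, ...) {
  cat(sprintf("h2 = %.4f (h2_aut = %.4f +/- %.4f, h2_x = %.4f +/- %.4f)\n",
              x$h2, x$h2_aut, x$se_h2_aut, x$h2_x, x$se_h2_x))
  invisible(x)
}

# Profile restricted log-likelihood of the single-GRM model in the
# eigenbasis of G: V = sigma2_g (Lambda + delta I), delta = sigma2_e/sigma2_g.
# xt, yt are the rotated intercept and phenotype; lam the GRM eigenvalues.
reml_single_profile <- function(log_delta, xt, yt, lam) {
  d <- lam + exp(log_delta)
  xx <- sum(xt^2 / d)
  beta <- sum(xt * yt / d) / xx
  r <- yt - xt * beta
  n1 <- length(yt) - 1
  s2 <- sum(r^2 / d) / n1
  -0.5 * (n1 * log(s2) + sum(log(d)) + log(xx) + n1)
}

#' Single-component REML (polygenic null model)
#'
#' Fits \eqn{y = 1\mu + g + e}, \eqn{g \sim N(0, G \sigma^2_g)}, by REML
#' using one eigendecomposition of the GRM and a 1-D profile-likelihood
#' search over the variance ratio. This is the null model of the
#' mixed-linear-model association scan.
#'
#' @param y phenotype vector.
#' @param G a \code{grm_matrix}.
#' @return list: \code{sigma2_g}, \code{sigma2_e}, \code{loglik},
#'   \code{eigen} (the reusable eigendecomposition).
#' @export
fit_reml_single <- function(y, G) {
  stopifnot(inherits(G, "grm_matrix"))
  n <- length(y)
  if (n != length(G$samples)) stop("y length does not match GRM dimension")
  ed <- eigen(G$values, symmetric = TRUE)
  lam <- pmax(ed$values, 0)
  yt <- as.vector(crossprod(ed$vectors, y))
  xt <- as.vector(crossprod(ed$vectors, rep(1, n)))
  opt <- stats::optimize(reml_single_profile, interval = c(-12, 12),
                         xt = xt, yt = yt, lam = lam, maximum = TRUE,
                         tol = 1e-8)
  delta <- exp(opt$maximum)
  d <- lam + delta
  xx <- sum(xt^2 / d)
  beta <- sum(xt * yt / d) / xx
  r <- yt - xt * beta
  s2g <- sum(r^2 / d) / (n - 1)
  # boundary comparison: pure-noise model (sigma2_g -> 0)
  ols_var <- sum((y - mean(y))^2) / (n - 1)
  loglik_null <- -0.5 * ((n - 1) * log(ols_var) + log(n) + (n - 1))
  if (loglik_null > opt$objective) {
    return(list(sigma2_g = 0, sigma2_e = ols_var, loglik = loglik_null,
                eigen = ed))
  }
  list(sigma2_g = s2g, sigma2_e = s2g * delta, loglik = opt$objective,
       eigen = ed)
}
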