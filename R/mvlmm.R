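#' Fit a separate univariate linear mixed model for one outcome
#'
#' Maximum-likelihood fit of the single-outcome Laird-Ware model
#' y_ik = X_ik beta_k + Z_ik b_ik + e_ik with b_ik ~ N(0, D_kk) and
#' e_ik ~ N(0, sigma_k^2 I). Used to seed the multivariate EM and the
#' quasi-two-stage hazard initialisation. The fit is delegated to
#' \code{lme4::lmer} with \code{REML = FALSE}.
#'
#' @param dataset a \code{joint_dataset}
#' @param k outcome index (1..K)
#' @param tol optimizer tolerance
#' @return object of class \code{lmm_component}: \code{beta_k} (named),
#'   \code{D_kk}, \code{sigma2_k}
#' @export
fit_univariate_lmm <- function(dataset, k, tol = 1e-8) {
  sp <- dataset$specs[[k]]
  pieces <- lapply(dataset$subjects, function(s) {
    o <- s$outcomes[[k]]
    if (!length(o$y)) return(NULL)
    df <- as.data.frame(o$X)
    colnames(df) <- sp$fixed
    for (cn in setdiff(sp$random, sp$fixed)) df[[cn]] <- o$Z[, cn]
    df$.y <- o$y
    df$.id <- s$id
    df
  })
  df <- do.call(rbind, pieces)
  if (is.null(df) || nrow(df) < length(sp$fixed) + length(sp$random))
    stop("too few measurements to fit outcome '", sp$name, "'")
  if (length(sp$random) >= 2) {
    nper <- table(df$.id)
    if (max(nper) < 2)
      stop("variance components unidentifiable for outcome '", sp$name,
           "': no subject has repeated measurements")
  }
  bt <- function(x) paste0("`", x, "`")
  fml <- stats::as.formula(paste(
    ".y ~ 0 +", paste(bt(sp$fixed), collapse = " + "),
    "+ (0 +", paste(bt(sp$random), collapse = " + "), "| .id)"))
  qx <- qr(as.matrix(df[, sp$fixed, drop = FALSE]))
  if (qx$rank < length(sp$fixed))
    stop("singular fixed-effects design for outcome '", sp$name, "'")
  fit <- lme4::lmer(fml, data = df, REML = FALSE,
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore",
                      optCtrl = list(xtol_abs = tol, ftol_abs = tol)))
  beta_k <- lme4::fixef(fit)
  names(beta_k) <- sp$fixed
  vc <- lme4::VarCorr(fit)[[".id"]]
  D_kk <- matrix(as.numeric(vc), length(sp$random), length(sp$random))
  dimnames(D_kk) <- list(sp$random, sp$random)
  if (any(eigen(D_kk, symmetric = TRUE, only.values = TRUE)$values < 1e-10)) {
    warning("D estimate for outcome '", sp$name,
            "' at or near the boundary; eigenvalues floored", call. = FALSE)
    D_kk <- spd_floor(D_kk)
  }
  structure(list(beta_k = beta_k, D_kk = D_kk, sigma2_k = stats::sigma(fit)^2,
                 outcome = sp$name),
            class = "lmm_component")
}

#' Posterior moments of the random effects given the longitudinal data
#'
#' Under the multivariate linear mixed model, b_i | y_i is Gaussian with
#' covariance A_i = (Z_i' Sigma_i^-1 Z_i + D^-1)^-1 and mean
#' A_i Z_i' Sigma_i^-1 (y_i - X_i beta). For a subject with no measurements
#' the posterior equals the prior (mean 0, covariance D).
#'
#' @param subject one element of \code{assemble_designs(dataset)$subjects}
#' @param theta an \code{mjm_params} object (only beta, D, sigma2 are used)
#' @return list of class \code{re_posterior}: \code{mean}, \code{cov},
#'   \code{chol} (lower-triangular factor of \code{cov})
#' @export
posterior_re_moments <- function(subject, theta) {
  D <- theta$D
  Dinv <- tryCatch(chol2inv(chol(D)), error = function(e) stop("D not positive-definite"))
  out <- posterior_moments_one(subject, theta, Dinv, nrow(D))
  structure(out, class = "re_posterior")
}

## core posterior computation from the per-outcome crossproducts; Z'Sigma^-1 Z
## is block-diagonal because Z_i is block-diagonal and Sigma_i has a single
## variance per outcome block
posterior_moments_one <- function(subject, theta, Dinv, r) {
  if (length(subject$y) == 0L)
    return(list(mean = numeric(r), cov = theta$D, chol = t(chol(theta$D))))
  K <- length(subject$n_k)
  r_k <- vapply(subject$cross, function(cc) length(cc$Zty), integer(1))
  roff <- c(0L, cumsum(r_k))
  p_k <- vapply(subject$cross, function(cc) length(cc$Xty), integer(1))
  poff <- c(0L, cumsum(p_k))
  M <- Dinv
  rhs <- numeric(r)
  for (k in seq_len(K)) {
    if (subject$n_k[k] == 0L) next
    cc <- subject$cross[[k]]
    ridx <- roff[k] + seq_len(r_k[k])
    bk <- theta$beta[poff[k] + seq_len(p_k[k])]
    M[ridx, ridx] <- M[ridx, ridx] + cc$ZtZ / theta$sigma2[k]
    rhs[ridx] <- (cc$Zty - as.numeric(crossprod(cc$XtZ, bk))) / theta$sigma2[k]
  }
  M <- (M + t(M)) / 2
  ch_M <- tryCatch(chol(M), error = function(e)
    stop("posterior precision numerically singular (condition number ~ ",
         format(kappa(M, exact = FALSE), digits = 3), ")"))
  A <- chol2inv(ch_M)
  A <- (A + t(A)) / 2
  list(mean = as.numeric(A %*% rhs), cov = A, chol = t(chol(A)))
}

## posterior moments for every subject: means matrix, covariance and Cholesky
## cubes (used by the Monte Carlo E-step)
posterior_moments_all <- function(designs, theta) {
  r <- designs$r
  n <- length(designs$subjects)
  Dinv <- chol2inv(chol(theta$D))
  means <- matrix(0, n, r)
  covs <- chols <- array(0, c(r, r, n))
  for (i in seq_len(n)) {
    m <- posterior_moments_one(designs$subjects[[i]], theta, Dinv, r)
    means[i, ] <- m$mean
    covs[, , i] <- m$cov
    chols[, , i] <- m$chol
  }
  list(means = means, covs = covs, chols = chols)
}

#' Marginal log-likelihood of the longitudinal data
#'
#' Sum over subjects of log N(y_i; X_i beta, Sigma_i + Z_i D Z_i'), the
#' random effects integrated out. Subjects with no measurements contribute 0.
#'
#' @param dataset a \code{joint_dataset} or an \code{mjm_designs}
#' @param beta,D,sigma2 multivariate LMM parameters
#' @return log-likelihood (scalar)
#' @export
marginal_longitudinal_loglik <- function(dataset, beta, D, sigma2) {
  designs <- if (inherits(dataset, "mjm_designs")) dataset else assemble_designs(dataset)
  ll <- 0
  for (s in designs$subjects) {
    ni <- length(s$y)
    if (ni == 0L) next
    s2row <- rep(sigma2, s$n_k)
    V <- s$Z %*% D %*% t(s$Z)
    diag(V) <- diag(V) + s2row
    ch <- tryCatch(chol(V), error = function(e)
      stop("marginal covariance not positive-definite"))
    resid <- s$y - as.numeric(s$X %*% beta)
    u <- backsolve(ch, resid, transpose = TRUE)
    ll <- ll - 0.5 * ni * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(u^2)
  }
  ll
}

#' EM algorithm for the multivariate linear mixed model
#'
#' Finds maximum-likelihood estimates of (beta, D, sigma2) for the K-outcome
#' linear mixed model with a full (unstructured) random-effects covariance D
#' linking the outcomes. E-step: Gaussian posterior moments of b_i per
#' subject; M-step: generalized least squares for beta, expected residual
#' sums of squares for each sigma_k^2, and D = (1/n) sum_i E[b_i b_i'].
#' Initialised from separate univariate fits (block-diagonal D) unless
#' \code{init} is supplied. For K = 1 the problem is delegated to
#' \code{\link{fit_univariate_lmm}}.
#'
#' @param dataset a \code{joint_dataset}
#' @param init optional list of \code{lmm_component} (one per outcome)
#' @param tol absolute max-change convergence tolerance (the EM here is exact,
#'   so a stricter criterion than the MCEM stage is appropriate)
#' @param max_iter iteration cap (warning on hit)
#' @return object of class \code{mvlmm_fit}: \code{beta}, \code{D},
#'   \code{sigma2}, \code{loglik} (per-iteration marginal log-likelihoods),
#'   \code{converged}, \code{n_iter}
#' @export
mvlmm_em <- function(dataset, init = NULL, tol = 1e-6, max_iter = 500L) {
  designs <- assemble_designs(dataset)
  K <- designs$K
  if (K == 1L) {
    f <- if (is.null(init)) fit_univariate_lmm(dataset, 1L) else init[[1L]]
    beta <- f$beta_k
    names(beta) <- designs$beta_names
    ll <- marginal_longitudinal_loglik(designs, beta, f$D_kk, f$sigma2_k)
    return(structure(list(beta = beta, D = f$D_kk, sigma2 = f$sigma2_k,
                          loglik = ll, converged = TRUE, n_iter = 0L),
                     class = "mvlmm_fit"))
  }
  if (is.null(init))
    init <- lapply(seq_len(K), function(k) fit_univariate_lmm(dataset, k))
  beta <- unlist(lapply(init, function(f) f$beta_k))
  names(beta) <- designs$beta_names
  r <- designs$r
  D <- matrix(0, r, r)
  for (k in seq_len(K)) {
    idx <- designs$roff[k] + seq_len(designs$r_k[k])
    D[idx, idx] <- init[[k]]$D_kk
  }
  D <- spd_floor(D)
  sigma2 <- vapply(init, function(f) f$sigma2_k, numeric(1))

  subs <- designs$subjects
  n <- length(subs)
  nn <- vapply(seq_len(K), function(k)
    sum(vapply(subs, function(s) s$n_k[k], integer(1))), numeric(1))

  ll_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  theta_old <- c(beta, vech(D), sigma2)
  repeat {
    it <- it + 1L
    th <- list(beta = beta, D = D, sigma2 = sigma2)
    pm <- posterior_moments_all(designs, th)
    ## M-step: GLS for beta decouples per outcome because X_i is
    ## block-diagonal and Sigma_i has one variance per outcome block
    for (k in seq_len(K)) {
      ridx <- designs$roff[k] + seq_len(designs$r_k[k])
      rhs <- numeric(designs$p_k[k])
      for (i in seq_len(n)) {
        cc <- subs[[i]]$cross[[k]]
        rhs <- rhs + cc$Xty - as.numeric(cc$XtZ %*% pm$means[i, ridx])
      }
      beta[designs$poff[k] + seq_len(designs$p_k[k])] <-
        solve(designs$XtX_tot[[k]], rhs)
    }
    ## sigma2 from expected residual sums of squares; D from E[b b']
    Dnew <- matrix(0, r, r)
    ss <- numeric(K)
    for (i in seq_len(n)) {
      Ebb <- pm$covs[, , i] + tcrossprod(pm$means[i, ])
      Dnew <- Dnew + Ebb
      for (k in seq_len(K)) {
        if (subs[[i]]$n_k[k] == 0) next
        cc <- subs[[i]]$cross[[k]]
        ridx <- designs$roff[k] + seq_len(designs$r_k[k])
        bk <- beta[designs$poff[k] + seq_len(designs$p_k[k])]
        Ebk <- pm$means[i, ridx]
        ss[k] <- ss[k] + cc$yty - 2 * sum(bk * cc$Xty) - 2 * sum(Ebk * cc$Zty) +
          2 * as.numeric(bk %*% cc$XtZ %*% Ebk) +
          as.numeric(bk %*% cc$XtX %*% bk) +
          sum(cc$ZtZ * Ebb[ridx, ridx])
      }
    }
    sigma2 <- ss / nn
    D <- spd_floor(Dnew / n)
    ll_trace <- c(ll_trace, marginal_longitudinal_loglik(designs, beta, D, sigma2))
    theta_new <- c(beta, vech(D), sigma2)
    if (max(abs(theta_new - theta_old)) < tol) { converged <- TRUE; break }
    theta_old <- theta_new
    if (it >= max_iter) {
      warning("mvlmm_em: maximum iterations reached without convergence",
              call. = FALSE)
      break
    }
  }
  dimnames(D) <- list(designs$b_names, designs$b_names)
  structure(list(beta = beta, D = D, sigma2 = sigma2, loglik = ll_trace,
                 converged = converged, n_iter = it),
            class = "mvlmm_fit")
}
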