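#' Monte Carlo estimate of the observed-data log-likelihood
#'
#' Uses the marginal factorisation of the joint likelihood: the sum over
#' subjects of the marginal multivariate-normal log-density of y_i plus the
#' log of the Monte Carlo average of the survival density f(T_i, delta_i | b)
#' over antithetic draws b from the Gaussian posterior f(b_i | y_i; theta).
#' When gamma_v = gamma_y = 0 the survival factor does not depend on b and
#' the estimate is exact (zero MC variance).
#'
#' @param theta an \code{mjm_params} with a populated \code{lambda0}
#' @param dataset a \code{joint_dataset}
#' @param N even number of MC draws per subject
#' @param seed optional seed for the draws
#' @return scalar log-likelihood estimate
#' @export
observed_loglik <- function(theta, dataset, N = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (N %% 2 != 0) N <- N + 1L
  designs <- assemble_designs(dataset)
  sstr <- survival_structures(dataset, times = theta$lambda0$time)
  ## events must sit on hazard atoms
  for (s in sstr$subjects)
    if (s$status == 1 && is.na(s$Tatom))
      stop("event time ", s$time, " is not a baseline-hazard atom of theta")
  ex <- mcem_estep(designs, sstr, theta, N)
  marg <- marginal_longitudinal_loglik(designs, theta$beta, theta$D, theta$sigma2)
  marg + sum(ex$logmeanw)
}

## per-subject gamma profile scores with the Breslow estimator substituted
## before differentiation: profiling lambda0(gamma) centres each subject's
## contribution at the risk-set average covariate
##   s_i = delta_i (u_i(T_i) - ubar_{j(i)})
##         - sum_{t_j <= T_i} lambda0j (E[e^eta u_ij] - ubar_j E[e^eta])
## with ubar_j = sum_{l in R_j} E[e^eta u_lj] / sum_{l in R_j} E[e^eta].
## The total score equals the fixed-lambda0 score, but the per-subject outer
## products (and hence the empirical information) differ.
profile_gamma_scores <- function(expectations, sstr, theta_prof) {
  n <- length(sstr$subjects)
  K <- sstr$K
  q <- length(sstr$subjects[[1L]]$v)
  J <- sstr$J
  lam <- theta_prof$lambda0$haz
  Vmat <- if (q > 0) t(vapply(sstr$subjects, function(s) s$v, numeric(q))) else
    matrix(0, n, 0)
  delta <- vapply(sstr$subjects, function(s) s$status, numeric(1))
  EwT <- matrix(vapply(seq_len(n), function(i)
    as.numeric(sstr$subjects[[i]]$GT %*% expectations$Eb[i, ]), numeric(K)),
    nrow = n, byrow = TRUE)
  ## risk-set average covariates at each atom
  den_j <- colSums(expectations$Eexp)                        # J
  numv_j <- if (q > 0) crossprod(expectations$Eexp, Vmat) else
    matrix(0, J, 0)                                          # J x q
  numw_j <- matrix(0, J, K)
  for (i in seq_len(n))
    numw_j <- numw_j + matrix(expectations$EexpW[, , i], J, K)
  ubar <- cbind(numv_j, numw_j) / den_j                      # J x (q+K)
  Tat <- vapply(sstr$subjects, function(s)
    if (is.na(s$Tatom)) 1L else s$Tatom, integer(1))
  s_i <- matrix(0, n, q + K)
  for (i in seq_len(n)) {
    si <- numeric(q + K)
    if (delta[i] == 1)
      si <- c(if (q > 0) sstr$subjects[[i]]$v, EwT[i, ]) - ubar[Tat[i], ]
    ji <- sstr$subjects[[i]]$Ji
    if (ji > 0) {
      ee <- expectations$Eexp[i, seq_len(ji)]
      EuW <- matrix(expectations$EexpW[, , i], J, K)[seq_len(ji), , drop = FALSE]
      Eu <- cbind(if (q > 0) outer(ee, sstr$subjects[[i]]$v), EuW)
      si <- si - colSums(lam[seq_len(ji)] *
                           (Eu - ubar[seq_len(ji), , drop = FALSE] * ee))
    }
    s_i[i, ] <- si
  }
  colnames(s_i) <- sstr_gamma_names(sstr, q, K)
  s_i
}

## per-subject conditional expected complete-data profile scores for
## theta_{-lambda} = (beta, vech(D), sigma2, gamma), lambda0 profiled out by
## its Breslow estimator. Rows: subjects; columns ordered as theta_vector().
profile_scores <- function(fit, designs, sstr, expectations) {
  theta <- fit$theta_hat
  n <- length(designs$subjects)
  K <- designs$K
  r <- designs$r
  lam_hat <- mstep_baseline_hazard(expectations, sstr)
  theta_prof <- theta; theta_prof$lambda0 <- lam_hat
  s_gamma <- profile_gamma_scores(expectations, sstr, theta_prof)

  Dinv <- chol2inv(chol(theta$D))
  ltri <- which(lower.tri(diag(r), diag = TRUE), arr.ind = TRUE)
  ltri <- ltri[order(ltri[, 2L], ltri[, 1L]), , drop = FALSE]
  nD <- nrow(ltri)

  s_beta <- matrix(0, n, designs$p)
  s_sigma <- matrix(0, n, K)
  s_D <- matrix(0, n, nD)
  for (i in seq_len(n)) {
    s <- designs$subjects[[i]]
    Eb_i <- expectations$Eb[i, ]
    Ebb_i <- expectations$Ebb[, , i]
    ## D-score: d/dD of E[log N(b; 0, D)] for the unique elements of D
    M <- 0.5 * (Dinv %*% Ebb_i %*% Dinv - Dinv)
    s_D[i, ] <- vapply(seq_len(nD), function(e) {
      a <- ltri[e, 1L]; b <- ltri[e, 2L]
      if (a == b) M[a, a] else 2 * M[a, b]
    }, numeric(1))
    if (length(s$y) == 0L) next
    resid <- s$y - as.numeric(s$X %*% theta$beta) - as.numeric(s$Z %*% Eb_i)
    cov_i <- Ebb_i - tcrossprod(Eb_i)
    for (k in seq_len(K)) {
      if (s$n_k[k] == 0) next
      idx <- s$rows_k[[k]]
      Xk <- s$X[idx, designs$poff[k] + seq_len(designs$p_k[k]), drop = FALSE]
      Zk <- s$Z[idx, , drop = FALSE]
      s_beta[i, designs$poff[k] + seq_len(designs$p_k[k])] <-
        crossprod(Xk, resid[idx]) / theta$sigma2[k]
      ess <- sum(resid[idx]^2) + sum(Zk * (Zk %*% cov_i))
      s_sigma[i, k] <- -s$n_k[k] / (2 * theta$sigma2[k]) +
        ess / (2 * theta$sigma2[k]^2)
    }
  }
  S <- cbind(s_beta, s_D, s_sigma, s_gamma)
  colnames(S) <- fit$param_names
  S
}

#' Empirical-profile-information standard errors
#'
#' Approximates the information for theta_{-lambda} (the baseline hazard
#' profiled out via its Breslow estimator) by the observed empirical
#' information I_e = sum_i s_i s_i' - (1/n) S S', where s_i is the conditional
#' expectation of subject i's complete-data profile score at the maximiser.
#' The subtracted term would vanish exactly at the maximiser but is retained
#' because Monte Carlo error leaves the total score slightly nonzero. The
#' expectations are recomputed with a fresh, larger MC sample (default four
#' times the final fit size) to reduce MC contamination. Confidence intervals
#' are normal-approximation intervals. No standard errors are produced for
#' the baseline hazard.
#'
#' @param fit an \code{mjm_fit}
#' @param dataset the \code{joint_dataset} the model was fitted to
#' @param N MC sample size for the score expectations (default 4 x final fit N)
#' @param level confidence level
#' @return object of class \code{mjm_se}: \code{method}, named \code{se},
#'   \code{vcov}, \code{ci_lower}, \code{ci_upper}
#' @export
empirical_information_se <- function(fit, dataset, N = NULL, level = 0.95) {
  if (!fit$converged)
    warning("fit did not converge; standard errors may be unreliable",
            call. = FALSE)
  if (is.null(N)) N <- 4L * fit$final_N
  if (N %% 2 != 0) N <- N + 1L
  designs <- assemble_designs(dataset)
  sstr <- survival_structures(dataset)
  ex <- mcem_estep(designs, sstr, fit$theta_hat, N)
  Smat <- profile_scores(fit, designs, sstr, ex)
  Stot <- colSums(Smat)
  n <- nrow(Smat)
  I_e <- crossprod(Smat) - tcrossprod(Stot) / n
  ch <- tryCatch(chol(I_e), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- eigen(I_e, symmetric = TRUE, only.values = TRUE)$values
    stop("empirical information not positive-definite; eigenvalues: ",
         paste(format(ev[ev <= 0], digits = 3), collapse = ", "))
  }
  vcov <- chol2inv(ch)
  dimnames(vcov) <- dimnames(I_e) <- list(colnames(Smat), colnames(Smat))
  se <- sqrt(diag(vcov))
  est <- theta_vector(fit$theta_hat)
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(method = "empirical", se = se, vcov = vcov,
                 ci_lower = est - z * se, ci_upper = est + z * se,
                 level = level, N = N, score = Stot),
            class = "mjm_se")
}

## resample subjects with replacement, re-labelling ids 1..n
resample_dataset <- function(dataset, idx) {
  out <- dataset
  out$subjects <- dataset$subjects[idx]
  out$ids <- as.character(seq_along(idx))
  for (i in seq_along(idx)) out$subjects[[i]]$id <- out$ids[i]
  bal <- TRUE
  if (out$K > 1L) for (s in out$subjects) {
    t1 <- s$outcomes[[1L]]$times
    for (k in 2:out$K)
      if (length(t1) != length(s$outcomes[[k]]$times) ||
          (length(t1) && any(t1 != s$outcomes[[k]]$times))) bal <- FALSE
  }
  out$balanced <- bal
  out
}

#' Bootstrap standard errors for a fitted joint model
#'
#' Resamples subjects (not individual records) with replacement, re-labels
#' them, and refits the model on each bootstrap dataset using the original
#' maximum likelihood estimates as initial values. Standard errors are the
#' sample standard deviations of the replicate estimates; confidence
#' intervals use the empirical percentiles. Replicates that fail to converge
#' are dropped and counted.
#'
#' @param fit an \code{mjm_fit}
#' @param dataset the original \code{joint_dataset}
#' @param B number of bootstrap replicates (>= 2)
#' @param control MCEM control for the refits (default: the fit's control with
#'   \code{se_method = "none"})
#' @param level confidence level for percentile intervals
#' @param seed optional seed for the resampling / refits
#' @return object of class \code{mjm_se} with \code{B} and
#'   \code{B_effective} (converged replicates)
#' @export
bootstrap_se <- function(fit, dataset, B = 100L, control = NULL,
                         level = 0.95, seed = NULL) {
  if (B < 2) stop("B must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(control)) control <- fit$control
  control$se_method <- "none"
  n <- length(dataset$subjects)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * B)
  est <- matrix(NA_real_, B, length(fit$param_names),
                dimnames = list(NULL, fit$param_names))
  failed <- 0L
  for (b in seq_len(B)) {
    set.seed(seeds[b])
    idx <- sample.int(n, n, replace = TRUE)
    bd <- resample_dataset(dataset, idx)
    ctl <- control; ctl$seed <- seeds[B + b]
    rep_fit <- tryCatch(
      suppressWarnings(mcem_fit(bd, ctl, init = fit$theta_hat)),
      error = function(e) NULL)
    if (is.null(rep_fit) || !rep_fit$converged) { failed <- failed + 1L; next }
    est[b, ] <- theta_vector(rep_fit$theta_hat)
  }
  ok <- stats::complete.cases(est)
  if (!any(ok)) stop("all bootstrap replicates failed")
  est <- est[ok, , drop = FALSE]
  se <- apply(est, 2L, stats::sd)
  a <- (1 - level) / 2
  structure(list(method = "bootstrap", se = se,
                 ci_lower = apply(est, 2L, stats::quantile, probs = a),
                 ci_upper = apply(est, 2L, stats::quantile, probs = 1 - a),
                 level = level, B = B, B_effective = sum(ok),
                 failed = failed, estimates = est),
            class = "mjm_se")
}

#' @export
print.mjm_se <- function(x, digits = 4, ...) {
  cat("Joint model standard errors (", x$method, ")\n", sep = "")
  if (x$method == "bootstrap")
    cat("  based on", x$B_effective, "of", x$B, "replicates\n")
  tab <- data.frame(se = round(x$se, digits),
                    lower = round(x$ci_lower, digits),
                    upper = round(x$ci_upper, digits))
  print(tab)
  invisible(x)
}

#' Information criteria for a fitted joint model
#'
#' AIC = -2 l + 2 p and BIC = -2 l + p log(n) with p the dimension of
#' theta_{-lambda} (the profiled nonparametric baseline hazard is not
#' counted) and n the number of subjects.
#'
#' @param fit an \code{mjm_fit}
#' @return named vector with elements \code{AIC} and \code{BIC}
#' @export
aic_bic <- function(fit) {
  p <- length(theta_vector(fit$theta_hat))
  ll <- fit$loglik
  c(AIC = -2 * ll + 2 * p, BIC = -2 * ll + p * log(fit$n))
}

#' @export
confint.mjm_fit <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$se)) stop("fit has no standard errors; see empirical_information_se")
  est <- theta_vector(object$theta_hat)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(lower = est - z * object$se, upper = est + z * object$se)
  rownames(ci) <- object$param_names
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Write the estimate / SE / CI table as CSV
#'
#' @param fit an \code{mjm_fit} with standard errors
#' @param file output path
#' @return invisibly, the table written
#' @export
write_se_table <- function(fit, file) {
  est <- theta_vector(fit$theta_hat)
  tab <- data.frame(parameter = fit$param_names, estimate = unname(est),
                    se = if (is.null(fit$se)) NA_real_ else unname(fit$se),
                    lower = if (is.null(fit$ci_lower)) NA_real_ else unname(fit$ci_lower),
                    upper = if (is.null(fit$ci_upper)) NA_real_ else unname(fit$ci_upper),
                    method = if (is.null(fit$se)) "none" else "empirical")
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(tab)
}
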