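#' Joint model parameter set
#'
#' Container for the full parameter vector theta of the joint model: the
#' stacked fixed effects beta, the random-effects covariance D (r x r,
#' symmetric positive-definite, block D_kl structure implied by the
#' outcome-major stacking), the residual variances sigma2 (one per outcome),
#' the baseline hazard coefficients gamma_v, the association parameters
#' gamma_y (one per outcome), and the nonparametric baseline hazard lambda0
#' (a step function with an increment at each distinct observed failure time).
#'
#' @param beta numeric vector, outcome-major stacking of (beta_1, ..., beta_K)
#' @param D r x r SPD matrix
#' @param sigma2 K positive residual variances
#' @param gamma_v q-vector of baseline hazard covariate coefficients
#' @param gamma_y K-vector of association parameters
#' @param lambda0 data.frame with columns \code{time} (strictly increasing
#'   distinct failure times) and \code{haz} (positive increments); may have
#'   zero rows before the first Breslow update
#' @return object of class \code{mjm_params}
#' @export
mjm_params <- function(beta, D, sigma2, gamma_v = numeric(0), gamma_y,
                       lambda0 = data.frame(time = numeric(0), haz = numeric(0))) {
  D <- as.matrix(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("D must be symmetric")
  if (any(eigen(D, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("D must be positive-definite")
  if (any(sigma2 <= 0)) stop("sigma2 must be positive")
  if (nrow(lambda0) > 1 && any(diff(lambda0$time) <= 0))
    stop("lambda0 times must be strictly increasing")
  structure(list(beta = beta, D = (D + t(D)) / 2, sigma2 = sigma2,
                 gamma_v = as.numeric(gamma_v), gamma_y = as.numeric(gamma_y),
                 lambda0 = lambda0),
            class = "mjm_params")
}

## half-vectorisation, column-major lower triangle (fixed convention)
vech <- function(M) M[lower.tri(M, diag = TRUE)]

vech_names <- function(r) {
  idx <- which(lower.tri(diag(r), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
  paste0("D[", idx[, 1L], ",", idx[, 2L], "]")
}

## theta_{-lambda}: the parameter vector monitored for convergence and
## reported with standard errors (baseline hazard excluded)
theta_vector <- function(theta, designs = NULL) {
  bn <- if (!is.null(designs)) designs$beta_names else
    if (!is.null(names(theta$beta))) names(theta$beta) else
      paste0("beta", seq_along(theta$beta))
  vn <- if (!is.null(designs) && length(designs$surv_covariates))
    designs$surv_covariates else if (length(theta$gamma_v))
      paste0("v", seq_along(theta$gamma_v)) else character(0)
  out <- c(theta$beta, vech(theta$D), theta$sigma2, theta$gamma_v, theta$gamma_y)
  names(out) <- c(paste0("beta:", bn), vech_names(nrow(theta$D)),
                  paste0("sigma2_", seq_along(theta$sigma2)),
                  if (length(vn)) paste0("gamma_v:", vn),
                  paste0("gamma_y_", seq_along(theta$gamma_y)))
  out
}

#' @export
print.mjm_params <- function(x, digits = 4, ...) {
  cat("Joint model parameters\n")
  cat("beta:\n"); print(round(x$beta, digits))
  cat("D:\n"); print(round(x$D, digits))
  cat("sigma2:", round(x$sigma2, digits), "\n")
  if (length(x$gamma_v)) cat("gamma_v:", round(x$gamma_v, digits), "\n")
  cat("gamma_y:", round(x$gamma_y, digits), "\n")
  cat("baseline hazard:", nrow(x$lambda0), "increments\n")
  invisible(x)
}

## symmetrise and floor eigenvalues so the covariance stays SPD under MC noise
spd_floor <- function(M, floor = 1e-10, warn = FALSE) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  if (any(e$values < floor)) {
    if (warn) warning("covariance iterate floored to remain positive-definite",
                      call. = FALSE)
    e$values <- pmax(e$values, floor)
    M <- e$vectors %*% (e$values * t(e$vectors))
    M <- (M + t(M)) / 2
  }
  M
}

#' Control settings for the MCEM algorithm
#'
#' Tolerances, Monte Carlo sample sizes and update choices for
#' \code{\link{mcem_fit}}. Defaults follow the values found to work well in
#' practice: relative-difference stopping with eps0 = 0.005 (denominator
#' offset eps1 = 0.001), absolute tolerance eps2 = 0.005, Monte Carlo growth
#' divisor delta = 3, initial MC size and burn-in both 100 K (K = number of
#' outcomes), and three consecutive passes of the stopping rule required
#' before convergence is declared.
#'
#' @param tol_rel eps0, relative-difference tolerance
#' @param tol_denom eps1, denominator offset in the relative difference
#' @param tol_abs eps2, absolute-difference tolerance
#' @param criterion "hybrid" (default), "rel" or "abs". The hybrid rule
#'   checks parameters with magnitude below 0.01 by absolute difference and
#'   the rest by relative difference: the relative rule alone is unstable for
#'   parameters near zero under Monte Carlo error (a covariance entry whose
#'   true value is 0 would essentially never pass it)
#' @param N0 initial (even) Monte Carlo sample size; default 100 * K, resolved
#'   at fit time
#' @param burnin number of iterations run at fixed N0 before the dynamic MC
#'   size rule activates; default 100 * K
#' @param delta MC growth divisor: N grows by floor(N / delta) when the
#'   coefficient of variation of the relative difference increases
#' @param N_max optional cap on the dynamic MC size (default Inf); bounds the
#'   compute of slow-converging fits without altering the fitted model
#' @param consecutive required consecutive stopping-rule passes
#' @param max_iter iteration cap
#' @param gamma_update "NR" (one-step Newton-Raphson, step 1) or "GN"
#'   (Gauss-Newton-like with empirical information, step 0.5)
#' @param seed RNG seed for reproducible fits (NULL: use current RNG state)
#' @param se_method "empirical", "bootstrap" or "none"
#' @return object of class \code{mjm_control}
#' @export
mcem_control <- function(tol_rel = 0.005, tol_denom = 0.001, tol_abs = 0.005,
                         criterion = c("hybrid", "rel", "abs"),
                         N0 = NULL, burnin = NULL, delta = 3L, N_max = Inf,
                         consecutive = 3L, max_iter = 500L,
                         gamma_update = c("NR", "GN"), seed = NULL,
                         se_method = c("empirical", "bootstrap", "none")) {
  criterion <- match.arg(criterion)
  gamma_update <- match.arg(gamma_update)
  se_method <- match.arg(se_method)
  stopifnot(tol_rel > 0, tol_denom > 0, tol_abs > 0,
            delta >= 1, consecutive >= 1, max_iter >= 1)
  if (!is.null(N0)) {
    stopifnot(N0 >= 2)
    if (N0 %% 2 != 0) stop("N0 must be even (antithetic pairing)")
  }
  structure(list(tol_rel = tol_rel, tol_denom = tol_denom, tol_abs = tol_abs,
                 criterion = criterion, N0 = N0, burnin = burnin,
                 delta = as.integer(delta), N_max = N_max,
                 consecutive = as.integer(consecutive),
                 max_iter = as.integer(max_iter), gamma_update = gamma_update,
                 seed = seed, se_method = se_method),
            class = "mjm_control")
}

## resolve data-dependent defaults (N0 and burn-in scale with K)
resolve_control <- function(control, K) {
  if (is.null(control$N0)) control$N0 <- 100L * K
  if (is.null(control$burnin)) control$burnin <- 100L * K
  control
}
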