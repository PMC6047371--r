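#' Survival structures for the hazard sub-model
#'
#' Precomputes, once per fit, everything the E- and M-steps need about the
#' event process: the ordered distinct failure times (the atoms of the
#' nonparametric baseline hazard), the failure counts d_j, and for each
#' subject the random-effect design maps G_i(t_j) (K x r matrices with
#' z_ik'(t_j) in the k-th row's outcome-k block) at every atom t_j <= T_i and
#' at the subject's own time T_i.
#'
#' @param dataset a \code{joint_dataset}
#' @param times optional atom times (default: the distinct observed failure
#'   times of the dataset)
#' @return object of class \code{mjm_survstr}
#' @export
survival_structures <- function(dataset, times = NULL) {
  designs_dims <- list(
    r_k = vapply(dataset$specs, function(s) length(s$random), integer(1)))
  r_k <- designs_dims$r_k
  r <- sum(r_k); roff <- c(0L, cumsum(r_k))
  K <- dataset$K
  n <- length(dataset$subjects)
  Tvec <- vapply(dataset$subjects, function(s) s$surv$time, numeric(1))
  dvec <- vapply(dataset$subjects, function(s) s$surv$status, integer(1))
  ev <- Tvec[dvec == 1]
  ft <- if (is.null(times)) sort(unique(ev)) else sort(unique(times))
  d <- vapply(ft, function(t) sum(ev == t), numeric(1))
  J <- length(ft)

  ## the evaluation convention (time column -> t, everything else
  ## subject-constant) makes z_ik(t) affine in t, so G_i(t) = Gc_i + t Gm_i
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    Gcon <- Gslp <- matrix(0, K, r)
    for (k in seq_len(K)) {
      z0 <- z_at_time(dataset, i, k, 0)
      z1 <- z_at_time(dataset, i, k, 1)
      Gcon[k, roff[k] + seq_len(r_k[k])] <- z0
      Gslp[k, roff[k] + seq_len(r_k[k])] <- z1 - z0
    }
    Ji <- sum(ft <= Tvec[i])
    G <- if (Ji > 0)
      array(Gcon, c(K, r, Ji)) +
        array(Gslp, c(K, r, Ji)) * rep(ft[seq_len(Ji)], each = K * r)
    else array(0, c(K, r, 0))
    Tatom <- if (dvec[i] == 1) match(Tvec[i], ft) else NA_integer_
    subjects[[i]] <- list(id = dataset$subjects[[i]]$id,
                          time = Tvec[i], status = dvec[i],
                          v = dataset$subjects[[i]]$surv$v,
                          Ji = Ji, G = G, Gc = Gcon, Gm = Gslp,
                          GT = Gcon + Tvec[i] * Gslp,
                          Tatom = Tatom,
                          G_at = local({
                            a <- Gcon; b <- Gslp
                            function(t) a + t * b
                          }))
  }
  structure(list(failure_times = ft, d = d, J = J, K = K, r = r,
                 subjects = subjects),
            class = "mjm_survstr")
}

#' Antithetic draws from the posterior of the random effects
#'
#' Samples N/2 standard normal r-vectors Omega and emits the antithetic pairs
#' mean + C Omega and mean - C Omega (rows 2j-1 and 2j), where C is the
#' lower-triangular Cholesky factor of the posterior covariance. Pair averages
#' equal the posterior mean exactly, and the negative correlation within pairs
#' reduces the Monte Carlo variance of the E-step expectations.
#'
#' @param moments an \code{re_posterior} (from
#'   \code{\link{posterior_re_moments}})
#' @param N even number of draws
#' @return object of class \code{mc_draws}: \code{draws} (N x r matrix),
#'   \code{log_weights} (NULL until survival weights are attached)
#' @export
draw_antithetic <- function(moments, N) {
  if (N %% 2 != 0) stop("N must be even for antithetic pairing")
  r <- length(moments$mean)
  Om <- matrix(stats::rnorm(N / 2 * r), N / 2, r)
  shift <- Om %*% t(moments$chol)
  draws <- matrix(0, N, r)
  draws[seq(1, N, by = 2), ] <- rep(moments$mean, each = N / 2) + shift
  draws[seq(2, N, by = 2), ] <- rep(moments$mean, each = N / 2) - shift
  structure(list(draws = draws, log_weights = NULL), class = "mc_draws")
}

#' Log survival weight f(T_i, delta_i | b; theta)
#'
#' The log conditional density of the observed event datum given the random
#' effects: delta_i [log lambda0(T_i) + v_i'gamma_v + W_2i(T_i, b)] minus the
#' cumulative hazard, which for the nonparametric baseline is the step-sum
#' over hazard atoms t_j <= T_i of lambda0j exp(v_i'gamma_v + W_2i(t_j, b)).
#'
#' @param b r-vector of random effects
#' @param subject one element of \code{survival_structures(...)$subjects}
#' @param theta an \code{mjm_params} (lambda0 atoms must contain T_i when
#'   delta_i = 1)
#' @return scalar log weight
#' @export
survival_log_weight <- function(b, subject, theta) {
  lam <- theta$lambda0
  vg <- if (length(theta$gamma_v)) sum(subject$v * theta$gamma_v) else 0
  w2 <- function(t) sum(theta$gamma_y * (subject$G_at(t) %*% b))
  keep <- which(lam$time <= subject$time)
  cumhaz <- 0
  for (j in keep)
    cumhaz <- cumhaz + lam$haz[j] * exp(vg + w2(lam$time[j]))
  lw <- -cumhaz
  if (subject$status == 1) {
    j0 <- match(subject$time, lam$time)
    if (is.na(j0))
      stop("event time ", subject$time, " is not a baseline-hazard atom")
    lw <- lw + log(lam$haz[j0]) + vg + w2(subject$time)
  }
  lw
}

#' Self-normalised Monte Carlo conditional expectation
#'
#' Computes E[h(b) | T, delta, y] ~= sum_m h(b_m) w_m / sum_m w_m where the
#' weights are exp(log w_m - max log w) (max-shifted for numerical safety).
#' NULL log-weights are treated as constant (plain Monte Carlo average).
#'
#' @param h function of one draw (r-vector), returning a scalar, vector or
#'   matrix
#' @param draws an \code{mc_draws} whose \code{log_weights} were filled in
#'   (e.g. via \code{\link{survival_log_weight}})
#' @return the weighted expectation, with the shape returned by \code{h}
#' @export
conditional_expectation <- function(h, draws) {
  B <- draws$draws
  N <- nrow(B)
  lw <- draws$log_weights
  if (is.null(lw)) lw <- numeric(N)
  mx <- max(lw)
  if (!is.finite(mx)) stop("degenerate survival weights: all log-weights are -Inf")
  w <- exp(lw - mx)
  vals <- lapply(seq_len(N), function(m) h(B[m, ]))
  out <- Reduce(`+`, Map(`*`, vals, w))
  out / sum(w)
}

## full Monte Carlo E-step (C++ core). Returns the expectations container used
## by every M-step: per-subject E[b], E[bb'], log mean weight, and the
## hazard-atom moment matrices. Fresh antithetic draws are generated on every
## call from the R RNG stream (bit-identical to composing draw_antithetic over
## subjects under the same seed).
mcem_estep <- function(designs, sstr, theta, N, keep_draws = FALSE) {
  n <- length(designs$subjects)
  K <- sstr$K
  J <- sstr$J
  if (N %% 2 != 0) stop("N must be even (antithetic pairing)")
  pm <- posterior_moments_all(designs, theta)
  vgam <- vapply(sstr$subjects, function(s)
    if (length(theta$gamma_v)) sum(s$v * theta$gamma_v) else 0, numeric(1))
  delta <- vapply(sstr$subjects, function(s) s$status, integer(1))
  lam_by_atom <- theta$lambda0$haz
  if (length(lam_by_atom) != J || (J > 0 && any(theta$lambda0$time != sstr$failure_times)))
    stop("theta$lambda0 atoms do not match the survival structures")
  loglamT <- vapply(sstr$subjects, function(s)
    if (s$status == 1) log(lam_by_atom[s$Tatom]) else 0, numeric(1))
  Hc <- matrix(vapply(sstr$subjects, function(s)
    as.numeric(crossprod(s$Gc, theta$gamma_y)), numeric(sstr$r)),
    nrow = n, byrow = TRUE)
  Hm <- matrix(vapply(sstr$subjects, function(s)
    as.numeric(crossprod(s$Gm, theta$gamma_y)), numeric(sstr$r)),
    nrow = n, byrow = TRUE)
  hT <- matrix(vapply(sstr$subjects, function(s)
    as.numeric(crossprod(s$GT, theta$gamma_y)), numeric(sstr$r)),
    nrow = n, byrow = TRUE)
  Gc <- array(0, c(K, sstr$r, n)); Gm <- array(0, c(K, sstr$r, n))
  for (i in seq_len(n)) {
    Gc[, , i] <- sstr$subjects[[i]]$Gc
    Gm[, , i] <- sstr$subjects[[i]]$Gm
  }
  Ji <- vapply(sstr$subjects, function(s) s$Ji, integer(1))
  out <- mjm_estep_cpp(pm$means, pm$chols, as.integer(N), vgam, delta,
                       loglamT, hT, Hc, Hm, Gc, Gm,
                       if (J > 0) sstr$failure_times else numeric(0),
                       if (J > 0) lam_by_atom else numeric(0),
                       Ji, J, K, keep_draws)
  structure(list(logmeanw = as.numeric(out$logmeanw),
                 Eb = out$Eb, Ebb = out$Ebb,
                 Eexp = out$Eexp, EexpW = out$EexpW, EexpWW = out$EexpWW,
                 moments = pm, draws = if (keep_draws) out$draws, N = N),
            class = "mjm_estep")
}

#' Closed-form M-step updates for beta, sigma2 and D
#'
#' beta is updated by generalized least squares on the residuals
#' y_i - Z_i E[b_i] (the block-diagonal designs decouple the update per
#' outcome); each sigma_k^2 by the expected residual sum of squares of
#' outcome k's rows; D by the average of E[b_i b_i'], symmetrised and floored
#' to stay positive-definite under Monte Carlo noise.
#'
#' @param designs \code{mjm_designs}
#' @param expectations an E-step result (\code{mjm_estep})
#' @param theta current parameters (provides the Sigma_i weighting for beta)
#' @return list with \code{beta}, \code{sigma2}, \code{D}
#' @export
mstep_beta_sigma_D <- function(designs, expectations, theta) {
  K <- designs$K
  n <- length(designs$subjects)
  beta <- numeric(designs$p)
  ## per-outcome GLS (Sigma_i is a single variance within each outcome block,
  ## so the sigma_k^2 factor cancels within the block)
  for (k in seq_len(K)) {
    ridx <- designs$roff[k] + seq_len(designs$r_k[k])
    rhs <- numeric(designs$p_k[k])
    for (i in seq_len(n)) {
      cc <- designs$subjects[[i]]$cross[[k]]
      rhs <- rhs + cc$Xty - as.numeric(cc$XtZ %*% expectations$Eb[i, ridx])
    }
    beta[designs$poff[k] + seq_len(designs$p_k[k])] <-
      tryCatch(solve(designs$XtX_tot[[k]], rhs),
               error = function(e) stop("singular GLS system for outcome ", k))
  }
  names(beta) <- designs$beta_names
  Dnew <- matrix(0, designs$r, designs$r)
  ss <- numeric(K); nn <- numeric(K)
  for (i in seq_len(n)) {
    s <- designs$subjects[[i]]
    Ebb_i <- expectations$Ebb[, , i]
    Dnew <- Dnew + Ebb_i
    for (k in seq_len(K)) {
      if (s$n_k[k] == 0) next
      cc <- s$cross[[k]]
      ridx <- designs$roff[k] + seq_len(designs$r_k[k])
      bk <- beta[designs$poff[k] + seq_len(designs$p_k[k])]
      Ebk <- expectations$Eb[i, ridx]
      ss[k] <- ss[k] + cc$yty - 2 * sum(bk * cc$Xty) - 2 * sum(Ebk * cc$Zty) +
        2 * as.numeric(bk %*% cc$XtZ %*% Ebk) +
        as.numeric(bk %*% cc$XtX %*% bk) +
        sum(cc$ZtZ * Ebb_i[ridx, ridx])
      nn[k] <- nn[k] + s$n_k[k]
    }
  }
  sigma2 <- ss / nn
  D <- spd_floor(Dnew / n)
  list(beta = beta, sigma2 = sigma2, D = D)
}

#' Breslow M-step for the baseline hazard
#'
#' lambda0j = d_j / sum over subjects at risk at t_j of
#' E[exp(v_i'gamma_v + W_2i(t_j, b_i))], with d_j the number of failures at
#' atom t_j. The expectations are the survival-weighted conditional moments
#' from the E-step.
#'
#' @param expectations an \code{mjm_estep}
#' @param sstr the \code{mjm_survstr} the expectations were computed under
#' @return data.frame with columns \code{time} and \code{haz}
#' @export
mstep_baseline_hazard <- function(expectations, sstr) {
  if (sstr$J == 0) return(data.frame(time = numeric(0), haz = numeric(0)))
  denom <- colSums(expectations$Eexp)  # zero entries lie outside the risk set
  if (any(denom <= 0)) stop("empty risk set at a failure time")
  data.frame(time = sstr$failure_times, haz = sstr$d / denom)
}

#' Score and information for the hazard coefficients gamma
#'
#' Assembles S(gamma) = sum_i s_i and, for \code{method = "NR"}, the observed
#' information (the derivative of the negative score at fixed baseline
#' hazard), or for \code{method = "GN"} the empirical information
#' I_e = sum_i s_i s_i' - (1/n) S S'. The per-subject score is
#' s_i = delta_i (v_i, E[w_i(T_i, b)])' - sum_{t_j <= T_i} lambda0j
#' E[exp(eta_ij) (v_i, w_ij)'] with w_ij the K-vector of association
#' covariates at t_j.
#'
#' @param expectations an \code{mjm_estep}
#' @param sstr the matching \code{mjm_survstr}
#' @param theta current parameters; \code{theta$lambda0} supplies the hazard
#'   increments used in the sums (typically the fresh Breslow update)
#' @param method "NR" or "GN"
#' @return list with \code{score}, \code{info}, and the n x (q+K) matrix
#'   \code{s_i} of per-subject scores
#' @export
gamma_score_information <- function(expectations, sstr, theta,
                                    method = c("NR", "GN")) {
  method <- match.arg(method)
  n <- length(sstr$subjects)
  K <- sstr$K
  q <- length(sstr$subjects[[1L]]$v)
  J <- sstr$J
  lam <- theta$lambda0$haz
  if (length(lam) != J) stop("lambda0 length does not match failure times")
  Vmat <- if (q > 0) t(vapply(sstr$subjects, function(s) s$v, numeric(q))) else
    matrix(0, n, 0)
  delta <- vapply(sstr$subjects, function(s) s$status, numeric(1))
  ## observed part: delta_i * (v_i, G_i(T_i) E[b_i])
  EwT <- matrix(vapply(seq_len(n), function(i)
    as.numeric(sstr$subjects[[i]]$GT %*% expectations$Eb[i, ]), numeric(K)),
    nrow = n, byrow = TRUE)
  ## integrated part, per subject
  cumE <- as.numeric(expectations$Eexp %*% lam)          # n
  Wp <- matrix(vapply(seq_len(n), function(i)
    as.numeric(crossprod(matrix(expectations$EexpW[, , i], J, K), lam)),
    numeric(K)), nrow = n, byrow = TRUE)                 # n x K
  s_i <- cbind(Vmat * (delta - cumE), EwT * delta - Wp)
  colnames(s_i) <- c(sstr_gamma_names(sstr, q, K))
  score <- colSums(s_i)
  if (method == "GN") {
    info <- crossprod(s_i) - tcrossprod(score) / n
  } else {
    qq <- crossprod(Vmat * cumE, Vmat)
    qK <- crossprod(Vmat, Wp)
    KK <- matrix(0, K, K)
    for (i in seq_len(n))
      KK <- KK + matrix(crossprod(matrix(expectations$EexpWW[, , i], J, K * K), lam), K, K)
    info <- rbind(cbind(qq, qK), cbind(t(qK), KK))
  }
  dimnames(info) <- list(colnames(s_i), colnames(s_i))
  list(score = score, info = info, s_i = s_i)
}

sstr_gamma_names <- function(sstr, q, K) {
  c(if (q > 0) paste0("gamma_v", seq_len(q)), paste0("gamma_y", seq_len(K)))
}

#' One-step gamma update
#'
#' gamma' = gamma + kappa * info^-1 score with kappa = 1 for the
#' Newton-Raphson update and a nominal step-size of 0.5 for the
#' Gauss-Newton-like update (compensating for the empirical-information
#' approximation).
#'
#' @param gamma current coefficient vector (gamma_v, gamma_y)
#' @param score,info from \code{\link{gamma_score_information}}
#' @param method "NR" or "GN"
#' @return updated gamma vector
#' @export
gamma_onestep_update <- function(gamma, score, info, method = c("NR", "GN")) {
  method <- match.arg(method)
  kappa <- if (method == "NR") 1 else 0.5
  step <- tryCatch(solve(info, score), error = function(e)
    stop("singular gamma information; consider the GN update or a ridge"))
  out <- gamma + kappa * step
  if (any(!is.finite(out))) stop("non-finite gamma update")
  out
}

## convergence state -----------------------------------------------------------

new_convergence_state <- function() {
  structure(list(history = list(), delta_rel = numeric(0),
                 delta_abs = numeric(0), passes = 0L, converged = FALSE,
                 N_history = integer(0)),
            class = "mjm_convergence")
}

push_theta <- function(state, theta_vec) {
  state$history[[length(state$history) + 1L]] <- theta_vec
  state
}

#' Stopping-rule check for the MCEM iterations
#'
#' From the last two parameter vectors in the state's history computes the
#' relative difference Delta_rel = max |theta' - theta| / (|theta| + eps1)
#' and the absolute difference Delta_abs = max |theta' - theta|, applies the
#' selected criterion ("rel", "abs", or "hybrid": absolute for components
#' with magnitude below 0.01, relative otherwise), and updates the
#' consecutive-pass counter, which resets to zero on any failed check.
#' Convergence is declared after \code{control$consecutive} successive passes.
#' Baseline-hazard components are excluded (the history holds theta_{-lambda}).
#'
#' @param state an \code{mjm_convergence} with at least two history entries
#'   (see \code{push_theta} used internally by \code{\link{mcem_fit}})
#' @param control an \code{mjm_control}
#' @return the updated state, with \code{converged}, the appended
#'   \code{delta_rel} and \code{delta_abs} histories and the pass counter
#' @export
convergence_check <- function(state, control) {
  h <- state$history
  m <- length(h)
  if (m < 2L) stop("need at least two iterations of history")
  old <- h[[m - 1L]]; new <- h[[m]]
  adiff <- abs(new - old)
  rdiff <- adiff / (abs(old) + control$tol_denom)
  d_rel <- max(rdiff); d_abs <- max(adiff)
  pass <- switch(control$criterion,
    rel = d_rel < control$tol_rel,
    abs = d_abs < control$tol_abs,
    hybrid = {
      small <- abs(old) < 0.01
      all(adiff[small] < control$tol_abs) && all(rdiff[!small] < control$tol_rel)
    })
  state$passes <- if (pass) state$passes + 1L else 0L
  state$converged <- state$passes >= control$consecutive
  state$delta_rel <- c(state$delta_rel, d_rel)
  state$delta_abs <- c(state$delta_abs, d_abs)
  state
}

#' Dynamic Monte Carlo sample size rule
#'
#' Compares the coefficient of variation of the last three relative
#' differences with that of the previous (overlapping) window; if it has
#' increased -- the parameter changes are being swamped by Monte Carlo error --
#' the MC size grows to N + floor(N / delta), rounded up to an even number for
#' antithetic pairing. The rule is inactive during burn-in.
#'
#' @param state an \code{mjm_convergence} with at least four entries of
#'   relative-difference history
#' @param N current MC size
#' @param control an \code{mjm_control}
#' @param iteration current iteration number (to honour the burn-in)
#' @return the (possibly increased) MC size
#' @export
adapt_mc_size <- function(state, N, control, iteration = Inf) {
  if (iteration <= control$burnin) return(N)
  dr <- state$delta_rel
  if (length(dr) < 4L) return(N)
  cv <- function(x) {
    m <- mean(x)
    if (m == 0) 0 else stats::sd(x) / m
  }
  m <- length(dr)
  cv_new <- cv(dr[(m - 2):m])
  cv_old <- cv(dr[(m - 3):(m - 1)])
  if (cv_new > cv_old) {
    N <- N + N %/% control$delta
    if (N %% 2 != 0) N <- N + 1L
  }
  nmax <- control$N_max
  if (!is.null(nmax) && is.finite(nmax) && N > nmax) {
    N <- as.integer(nmax)
    if (N %% 2 != 0) N <- N + 1L
  }
  as.integer(N)
}

## initial lambda0: Breslow increments with the random effects fixed at their
## BLUP-style posterior means under the longitudinal parameters
initial_lambda0 <- function(designs, sstr, theta) {
  if (sstr$J == 0) return(data.frame(time = numeric(0), haz = numeric(0)))
  n <- length(designs$subjects)
  bhat <- t(vapply(designs$subjects, function(s)
    posterior_re_moments(s, theta)$mean, numeric(designs$r)))
  denom <- numeric(sstr$J)
  for (i in seq_len(n)) {
    s <- sstr$subjects[[i]]
    if (s$Ji == 0) next
    vg <- if (length(theta$gamma_v)) sum(s$v * theta$gamma_v) else 0
    for (j in seq_len(s$Ji)) {
      w2 <- sum(theta$gamma_y * (s$G[, , j] %*% bhat[i, ]))
      denom[j] <- denom[j] + exp(vg + w2)
    }
  }
  data.frame(time = sstr$failure_times, haz = sstr$d / denom)
}

#' Fit the multivariate joint model by Monte Carlo EM
#'
#' Full fitting routine: initial values from separate linear mixed fits, the
#' multivariate-LMM EM, and a quasi-two-stage Cox model; then MCEM iterations
#' alternating an antithetic Monte Carlo E-step with closed-form M-steps for
#' (beta, sigma2, D), a Breslow update for the baseline hazard and a one-step
#' Newton-Raphson (or Gauss-Newton-like) update for the hazard coefficients,
#' under the relative/absolute stopping rules with dynamic MC size. After
#' convergence the observed-data log-likelihood is evaluated and, when
#' requested, empirical-profile-information standard errors are attached.
#'
#' @param dataset a \code{joint_dataset} with at least one event
#' @param control an \code{\link{mcem_control}}
#' @param init optional \code{mjm_params} initial values (its lambda0 may be
#'   empty; a Breslow-style initial hazard is then computed)
#' @return object of class \code{mjm_fit}
#' @export
mcem_fit <- function(dataset, control = mcem_control(), init = NULL) {
  validate_dataset(dataset)
  control <- resolve_control(control, dataset$K)
  if (!is.null(control$seed)) set.seed(control$seed)
  designs <- assemble_designs(dataset)
  sstr <- survival_structures(dataset)
  K <- dataset$K
  q <- designs$q

  if (is.null(init)) {
    sep <- lapply(seq_len(K), function(k) fit_univariate_lmm(dataset, k))
    ## initial values only: partial convergence of the inner EM is fine
    mv <- suppressWarnings(mvlmm_em(dataset, init = sep))
    ts <- two_stage_initial_values(dataset, sep)
    theta <- mjm_params(beta = mv$beta, D = mv$D, sigma2 = mv$sigma2,
                        gamma_v = ts$gamma_v0, gamma_y = ts$gamma_y0)
  } else theta <- init
  if (nrow(theta$lambda0) != sstr$J ||
      (sstr$J > 0 && any(theta$lambda0$time != sstr$failure_times)))
    theta$lambda0 <- initial_lambda0(designs, sstr, theta)
  theta0 <- theta

  N <- as.integer(control$N0)
  state <- new_convergence_state()
  state <- push_theta(state, theta_vector(theta, designs))
  trace <- list()
  converged <- FALSE
  it <- 0L
  while (it < control$max_iter) {
    it <- it + 1L
    ex <- mcem_estep(designs, sstr, theta, N)
    ms <- mstep_beta_sigma_D(designs, ex, theta)
    lam_new <- mstep_baseline_hazard(ex, sstr)
    theta_new <- theta
    theta_new$beta <- ms$beta; theta_new$sigma2 <- ms$sigma2; theta_new$D <- ms$D
    theta_new$lambda0 <- lam_new
    gi <- gamma_score_information(ex, sstr, theta_new, control$gamma_update)
    gam <- gamma_onestep_update(c(theta$gamma_v, theta$gamma_y),
                                gi$score, gi$info, control$gamma_update)
    theta_new$gamma_v <- gam[seq_len(q)]
    theta_new$gamma_y <- gam[q + seq_len(K)]
    theta <- theta_new
    tv <- theta_vector(theta, designs)
    state <- push_theta(state, tv)
    state <- convergence_check(state, control)
    state$N_history <- c(state$N_history, N)
    trace[[it]] <- c(iteration = it, tv,
                     delta_rel = state$delta_rel[it], N = N)
    if (state$converged && it > control$burnin) { converged <- TRUE; break }
    N <- adapt_mc_size(state, N, control, iteration = it)
  }
  if (!converged)
    warning("MCEM did not converge within max_iter = ", control$max_iter,
            call. = FALSE)
  trace <- as.data.frame(do.call(rbind, trace))
  ll <- observed_loglik(theta, dataset, N = N)

  fit <- structure(list(theta_hat = theta, theta0 = theta0,
                        se = NULL, vcov = NULL,
                        loglik = ll, trace = trace, converged = converged,
                        n_iter = it, final_N = N, control = control,
                        n = length(dataset$subjects), K = K, q = q,
                        p = designs$p, r = designs$r,
                        param_names = names(theta_vector(theta, designs))),
                   class = "mjm_fit")
  if (control$se_method == "empirical") {
    se <- tryCatch(empirical_information_se(fit, dataset),
                   error = function(e) {
                     warning("empirical SE computation failed: ",
                             conditionMessage(e), call. = FALSE)
                     NULL
                   })
    if (!is.null(se)) {
      fit$se <- se$se; fit$vcov <- se$vcov
      fit$ci_lower <- se$ci_lower; fit$ci_upper <- se$ci_upper
    }
  }
  fit
}

#' @export
print.mjm_fit <- function(x, digits = 4, ...) {
  cat("Multivariate joint model fit (MCEM)\n")
  cat("  subjects:", x$n, " outcomes:", x$K, "\n")
  cat("  converged:", x$converged, "after", x$n_iter,
      "iterations (final MC size", x$final_N, ")\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8), "\n")
  est <- theta_vector(x$theta_hat)
  tab <- data.frame(estimate = round(est, digits))
  if (!is.null(x$se)) {
    tab$se <- round(x$se, digits)
    tab$lower <- round(x$ci_lower, digits)
    tab$upper <- round(x$ci_upper, digits)
  }
  rownames(tab) <- x$param_names
  print(tab)
  invisible(x)
}

#' @export
logLik.mjm_fit <- function(object, ...) {
  structure(object$loglik, df = length(theta_vector(object$theta_hat)),
            nobs = object$n, class = "logLik")
}
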