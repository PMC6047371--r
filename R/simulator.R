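#' Simulation scenario for joint longitudinal-survival data
#'
#' Defines the data-generating mechanism used in the simulation study: K
#' longitudinal outcomes with random intercepts and slopes on a fixed visit
#' schedule, two baseline covariates (x1 ~ N(0,1), x2 ~ Bin(1, 0.5)) shared
#' by both sub-models, Gompertz event times whose log-hazard is linear in
#' time and depends on the random effects through the association parameters,
#' independent exponential censoring, and administrative censoring at a
#' truncation time. Defaults reproduce the bivariate reference scenario:
#' n = 200, visits 0..5, Gompertz shape -3.5 and scale exp(0.25), censoring
#' rate 0.05, truncation 5.1, random-intercept correlation -0.5 between the
#' outcomes.
#'
#' @param n number of subjects
#' @param K number of longitudinal outcomes
#' @param visit_times scheduled measurement times
#' @param beta K x 4 matrix of fixed effects (intercept, slope, x1, x2) per
#'   outcome
#' @param D 2K x 2K SPD random-effects covariance, ordered
#'   (intercept_1, slope_1, intercept_2, slope_2, ...)
#' @param sigma2 K residual variances
#' @param theta0,theta1 Gompertz log-scale and shape of the baseline hazard
#'   exp(theta0 + theta1 t)
#' @param gamma_v length-2 hazard coefficients for (x1, x2)
#' @param gamma_y K association parameters
#' @param censor_rate exponential censoring rate (0 disables)
#' @param admin_censor administrative truncation time
#' @param admin_after subjects whose event and censoring times both exceed
#'   this value are administratively censored at \code{admin_censor}
#' @param re_dist "normal" or "t" (multivariate t, scaled so that the
#'   covariance -- not the scale matrix -- equals D)
#' @param df degrees of freedom for the t variant
#' @return object of class \code{sim_scenario}
#' @export
sim_scenario <- function(n = 200L, K = 2L, visit_times = 0:5,
                         beta = rbind(c(0, 1, 1, 1), c(0, -1, 0, 0.5)),
                         D = default_sim_D(),
                         sigma2 = c(0.25, 0.25),
                         theta0 = 0.25, theta1 = -3.5,
                         gamma_v = c(0, 1), gamma_y = c(-0.5, 1),
                         censor_rate = 0.05, admin_censor = 5.1,
                         admin_after = 5, re_dist = c("normal", "t"), df = 5) {
  re_dist <- match.arg(re_dist)
  beta <- matrix(beta, nrow = K)
  stopifnot(n >= 1, K >= 1, ncol(beta) == 4, length(sigma2) == K,
            length(gamma_y) == K, length(gamma_v) == 2,
            nrow(D) == 2 * K, censor_rate >= 0,
            !is.unsorted(visit_times))
  if (any(eigen(D, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("D must be positive-definite")
  if (re_dist == "t" && df <= 2) stop("df must exceed 2 for a finite covariance")
  structure(list(n = as.integer(n), K = as.integer(K),
                 visit_times = as.numeric(visit_times), beta = beta,
                 D = D, sigma2 = sigma2, theta0 = theta0, theta1 = theta1,
                 gamma_v = gamma_v, gamma_y = gamma_y,
                 censor_rate = censor_rate, admin_censor = admin_censor,
                 admin_after = admin_after, re_dist = re_dist, df = df),
            class = "sim_scenario")
}

## reference random-effects covariance: intercept variances 0.25, slope
## variances 0.04, intercept-intercept covariance -0.125 (correlation -0.5)
default_sim_D <- function() {
  D <- diag(c(0.25, 0.04, 0.25, 0.04))
  D[3, 1] <- D[1, 3] <- -0.125
  D
}

#' Invert the cumulative hazard of a log-linear hazard
#'
#' Solves integral_0^T exp(a + b s) ds = u in closed form: T = u exp(-a) when
#' b = 0, else T = log(1 + b u exp(-a)) / b. For b < 0 the cumulative hazard
#' is bounded; when u exceeds the bound the event never occurs and +Inf is
#' returned. With u = -log(U), U ~ Uniform(0,1), this generates Gompertz
#' event times (inverse-transform sampling for time-to-event models with
#' log-linear hazards).
#'
#' @param a log-hazard intercept
#' @param b log-hazard slope
#' @param u nonnegative target cumulative hazard
#' @return event time (possibly +Inf); vectorised over \code{u}
#' @export
invert_loglinear_hazard <- function(a, b, u) {
  if (any(u < 0)) stop("u must be nonnegative")
  if (abs(b) < 1e-12) return(u * exp(-a))
  arg <- 1 + b * u * exp(-a)
  out <- ifelse(arg > 0, log(pmax(arg, .Machine$double.xmin)) / b, Inf)
  out[u == 0] <- 0
  out
}

## random effects draw: rows ~ N(0, D) or scaled multivariate t with cov D
draw_random_effects <- function(n, D, re_dist, df) {
  r <- nrow(D)
  L <- t(chol(D))
  Zm <- matrix(stats::rnorm(n * r), n, r) %*% t(L)
  if (re_dist == "normal") return(Zm)
  Zm <- Zm * sqrt((df - 2) / df)       # scale matrix = D (df-2)/df => cov = D
  Zm / sqrt(stats::rchisq(n, df) / df)
}

#' Simulate a joint dataset
#'
#' Generates one dataset under a \code{\link{sim_scenario}}: random effects,
#' covariates, Gompertz event times via \code{\link{invert_loglinear_hazard}},
#' exponential and administrative censoring, and longitudinal responses at
#' the scheduled visits not exceeding the observed time. Uses the current
#' RNG state; call \code{set.seed} beforehand for reproducibility.
#'
#' @param scenario a \code{sim_scenario}
#' @return a \code{joint_dataset} (outcomes named "y1", ..., "yK"; fixed
#'   design columns intercept, time, x1, x2; random columns intercept, time)
#' @export
simulate_joint <- function(scenario) {
  sc <- scenario
  n <- sc$n; K <- sc$K
  x1 <- stats::rnorm(n)
  x2 <- stats::rbinom(n, 1L, 0.5)
  b <- draw_random_effects(n, sc$D, sc$re_dist, sc$df)
  b0 <- b[, 2 * seq_len(K) - 1, drop = FALSE]  # intercept effects (n x K)
  b1 <- b[, 2 * seq_len(K), drop = FALSE]      # slope effects (n x K)
  a_i <- sc$theta0 + sc$gamma_v[1] * x1 + sc$gamma_v[2] * x2 +
    as.numeric(b0 %*% sc$gamma_y)
  slope_i <- sc$theta1 + as.numeric(b1 %*% sc$gamma_y)
  u <- -log(stats::runif(n))
  Tstar <- vapply(seq_len(n), function(i)
    invert_loglinear_hazard(a_i[i], slope_i[i], u[i]), numeric(1))
  Ci <- if (sc$censor_rate > 0) stats::rexp(n, sc$censor_rate) else rep(Inf, n)
  Tobs <- pmin(Tstar, Ci)
  status <- as.integer(Tstar <= Ci)
  admin <- pmin(Tstar, Ci) > sc$admin_after
  Tobs[admin] <- sc$admin_censor
  status[admin] <- 0L
  if (any(!is.finite(Tobs)))
    stop("infinite observed times: with a decreasing hazard some events never ",
         "occur; enable exponential or administrative censoring")

  longs <- vector("list", K)
  specs <- vector("list", K)
  for (k in seq_len(K)) {
    rows <- lapply(seq_len(n), function(i) {
      tj <- sc$visit_times[sc$visit_times <= Tobs[i]]
      if (!length(tj)) return(NULL)
      y <- (sc$beta[k, 1] + b0[i, k]) + (sc$beta[k, 2] + b1[i, k]) * tj +
        sc$beta[k, 3] * x1[i] + sc$beta[k, 4] * x2[i] +
        stats::rnorm(length(tj), 0, sqrt(sc$sigma2[k]))
      data.frame(id = i, time = tj, intercept = 1, x1 = x1[i], x2 = x2[i],
                 y = y)
    })
    df <- do.call(rbind, rows)
    names(df)[names(df) == "y"] <- paste0("y", k)
    longs[[k]] <- df
    specs[[k]] <- outcome_spec(paste0("y", k),
                               fixed = c("intercept", "time", "x1", "x2"),
                               random = c("intercept", "time"))
  }
  surv <- data.frame(id = seq_len(n), time = Tobs, status = status,
                     x1 = x1, x2 = x2)
  load_joint_dataset(longs, surv, specs, id_col = "id",
                     surv_covariates = c("x1", "x2"))
}

## true theta_{-lambda} vector of a scenario, in theta_vector() order
scenario_truth <- function(scenario) {
  sc <- scenario
  beta <- as.numeric(t(sc$beta))
  names(beta) <- paste0("beta:", unlist(lapply(seq_len(sc$K), function(k)
    paste0("y", k, ":", c("intercept", "time", "x1", "x2")))))
  out <- c(beta, vech(sc$D), sc$sigma2, sc$gamma_v, sc$gamma_y)
  names(out) <- c(names(beta), vech_names(nrow(sc$D)),
                  paste0("sigma2_", seq_len(sc$K)),
                  paste0("gamma_v:", c("x1", "x2")),
                  paste0("gamma_y_", seq_len(sc$K)))
  out
}

#' Run a simulation study
#'
#' Repeatedly simulates a dataset under the scenario, fits the joint model by
#' MCEM with empirical-information standard errors, and aggregates the
#' replicate estimates into the usual simulation-study summary: mean
#' estimate, bias, empirical SE (SD of estimates), mean SE, MSE and coverage
#' of 95% confidence intervals for every component of theta_{-lambda}.
#' Replicates that fail to converge are dropped and counted. Per-replicate
#' seeds are derived from \code{seed} so the study is reproducible.
#'
#' @param scenario a \code{sim_scenario}
#' @param reps number of replicates (>= 2)
#' @param control an \code{mcem_control} for the fits
#' @param seed base seed
#' @param level confidence level used for the coverage column
#' @return object of class \code{sim_study}: the summary data.frame plus
#'   attributes \code{estimates}, \code{n_failed}, \code{reps}
#' @export
run_simulation_study <- function(scenario, reps, control = mcem_control(),
                                 seed = 1L, level = 0.95) {
  stopifnot(reps >= 2)
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * reps), ncol = 2L)
  truth <- scenario_truth(scenario)
  P <- length(truth)
  est <- matrix(NA_real_, reps, P, dimnames = list(NULL, names(truth)))
  ses <- cover <- est
  failed <- 0L
  for (rp in seq_len(reps)) {
    set.seed(seeds[rp, 1L])
    dat <- simulate_joint(scenario)
    ctl <- control; ctl$seed <- seeds[rp, 2L]; ctl$se_method <- "empirical"
    fit <- tryCatch(suppressWarnings(mcem_fit(dat, ctl)),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { failed <- failed + 1L; next }
    est[rp, ] <- theta_vector(fit$theta_hat)
    if (!is.null(fit$se)) {
      ses[rp, ] <- fit$se
      cover[rp, ] <- as.numeric(fit$ci_lower <= truth & truth <= fit$ci_upper)
    }
  }
  if (failed > reps / 2) stop("more than half of the replicates failed")
  ok <- stats::complete.cases(est)
  est <- est[ok, , drop = FALSE]
  ses <- ses[ok, , drop = FALSE]
  cover <- cover[ok, , drop = FALSE]
  summ <- data.frame(
    parameter = names(truth),
    true = unname(truth),
    mean = colMeans(est),
    emp_se = apply(est, 2L, stats::sd),
    mean_se = colMeans(ses),
    bias = colMeans(est) - unname(truth),
    mse = colMeans((est - rep(truth, each = nrow(est)))^2),
    coverage = colMeans(cover),
    row.names = NULL)
  structure(summ, class = c("sim_study", "data.frame"),
            estimates = est, ses = ses, n_failed = failed, reps = reps,
            level = level)
}

#' @export
print.sim_study <- function(x, digits = 4, ...) {
  cat("Simulation study:", attr(x, "reps") - attr(x, "n_failed"), "of",
      attr(x, "reps"), "replicates converged\n")
  y <- as.data.frame(x)
  y[, -1] <- round(y[, -1], digits)
  print(y)
  invisible(x)
}
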