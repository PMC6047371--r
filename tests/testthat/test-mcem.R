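test_that("antithetic draws: exact pair means, N=2 case, covariance consistency", {
  m <- structure(list(mean = c(1, -2),
                      cov = matrix(c(0.5, 0.2, 0.2, 0.4), 2),
                      chol = t(chol(matrix(c(0.5, 0.2, 0.2, 0.4), 2)))),
                 class = "re_posterior")
  set.seed(2)
  dr <- draw_antithetic(m, 10L)
  pairs_mean <- (dr$draws[seq(1, 9, 2), ] + dr$draws[seq(2, 10, 2), ]) / 2
  expect_equal(pairs_mean, matrix(rep(m$mean, each = 5), 5), tolerance = 1e-12)

  dr2 <- draw_antithetic(m, 2L)
  expect_equal(nrow(dr2$draws), 2L)
  expect_equal(colMeans(dr2$draws), m$mean)
  expect_error(draw_antithetic(m, 3L), "even")

  set.seed(3)
  big <- draw_antithetic(m, 1e5L)
  expect_lt(norm(cov(big$draws) - m$cov, "F") / norm(m$cov, "F"), 0.05)
})

test_that("survival log-weight: empty hazard, plug-in value, refinement to Gompertz", {
  dat <- small_sim_dataset(n = 10, seed = 71)
  sstr <- survival_structures(dat)
  theta <- mjm_params(beta = rep(0, 8), D = diag(4) * 0.1, sigma2 = c(1, 1),
                      gamma_v = c(0, 0), gamma_y = c(0, 0),
                      lambda0 = data.frame(time = numeric(0), haz = numeric(0)))
  ## censored subject, empty hazard -> 0
  cens <- which(vapply(sstr$subjects, function(s) s$status == 0, logical(1)))[1]
  expect_equal(survival_log_weight(rep(0, 4), sstr$subjects[[cens]], theta), 0)

  ## single failure atom, gamma = 0, lambda = 0.2 -> log(0.2) - 0.2
  ev <- which(vapply(sstr$subjects, function(s) s$status == 1, logical(1)))[1]
  s <- sstr$subjects[[ev]]
  th1 <- theta
  th1$lambda0 <- data.frame(time = s$time, haz = 0.2)
  expect_equal(survival_log_weight(rep(0, 4), s, th1), log(0.2) - 0.2)
  ## event time must be an atom
  th_bad <- theta
  th_bad$lambda0 <- data.frame(time = s$time + 1, haz = 0.2)
  expect_error(survival_log_weight(rep(0, 4), s, th_bad), "atom")

  ## refining the hazard steps approximates the continuous Gompertz integral
  th0 <- 0.25; th1g <- -3.5
  Tcens <- 2.0
  s0 <- s; s0$status <- 0L; s0$time <- Tcens
  errs <- vapply(c(50, 500, 5000), function(m) {
    grid <- seq(Tcens / m, Tcens, length.out = m)
    haz <- exp(th0 + th1g * (grid - Tcens / (2 * m))) * (Tcens / m)
    th <- theta
    th$lambda0 <- data.frame(time = grid, haz = haz)
    lw <- survival_log_weight(rep(0, 4), s0, th)
    Lam <- exp(th0) * (exp(th1g * Tcens) - 1) / th1g
    abs(lw + Lam)
  }, numeric(1))
  expect_lt(errs[3], 1e-4)
  expect_true(all(diff(errs) < 0))
})

test_that("conditional expectation: normalisation, constant weights, quadrature oracle", {
  set.seed(5)
  dr <- draw_antithetic(structure(list(mean = c(0, 0), cov = diag(2),
                                       chol = diag(2)), class = "re_posterior"),
                        1000L)
  ## constant h under arbitrary weights
  dr$log_weights <- rnorm(1000)
  expect_equal(conditional_expectation(function(b) 3.7, dr), 3.7)
  ## NULL weights: plain MC mean
  dr0 <- dr; dr0$log_weights <- NULL
  expect_equal(conditional_expectation(identity, dr0), colMeans(dr$draws))
  ## all -Inf -> error
  drbad <- dr; drbad$log_weights <- rep(-Inf, 1000)
  expect_error(conditional_expectation(identity, drbad), "degenerate")

  ## quadrature oracle on an r=2 single-outcome instance with survival weights
  dat <- small_sim_dataset(n = 8, K = 1, beta = matrix(c(0, 1, 1, 1), 1),
                           D = matrix(c(0.25, -0.05, -0.05, 0.04), 2),
                           sigma2 = 0.25, gamma_v = c(0.3, 0.5), gamma_y = 0.8,
                           censor_rate = 0, admin_after = 3, admin_censor = 3.1,
                           theta0 = 0.6, seed = 103)
  designs <- assemble_designs(dat)
  sstr <- survival_structures(dat)
  theta <- mjm_params(beta = c(0.1, 0.9, 1.1, 0.9),
                      D = matrix(c(0.3, -0.04, -0.04, 0.05), 2),
                      sigma2 = 0.3, gamma_v = c(0.2, 0.4), gamma_y = 0.6,
                      lambda0 = data.frame(time = sstr$failure_times,
                                           haz = rep(0.1, sstr$J)))
  i <- which(vapply(sstr$subjects, function(s) s$Ji > 0, logical(1)))[1]
  post <- posterior_re_moments(designs$subjects[[i]], theta)
  set.seed(9)
  dr <- draw_antithetic(post, 20000L)
  dr$log_weights <- apply(dr$draws, 1, survival_log_weight,
                          subject = sstr$subjects[[i]], theta = theta)
  or <- quad_posterior_oracle(designs$subjects[[i]], sstr$subjects[[i]], theta)
  Eb_mc <- conditional_expectation(identity, dr)
  expect_equal(Eb_mc, or$mean, tolerance = 1e-2)
})

test_that("C++ E-step equals the composition of the exported operations", {
  dat <- small_sim_dataset(n = 10, seed = 81)
  designs <- assemble_designs(dat)
  sstr <- survival_structures(dat)
  sc <- sim_scenario()
  theta <- mjm_params(as.numeric(t(sc$beta)), sc$D, sc$sigma2,
                      sc$gamma_v, sc$gamma_y)
  theta$lambda0 <- multijm:::initial_lambda0(designs, sstr, theta)
  N <- 500L
  set.seed(123)
  ex <- multijm:::mcem_estep(designs, sstr, theta, N)
  set.seed(123)  # same RNG stream: the C++ draw order mirrors the R path
  for (i in seq_along(designs$subjects)) {
    post <- posterior_re_moments(designs$subjects[[i]], theta)
    dr <- draw_antithetic(post, N)
    dr$log_weights <- apply(dr$draws, 1, survival_log_weight,
                            subject = sstr$subjects[[i]], theta = theta)
    expect_equal(conditional_expectation(identity, dr), ex$Eb[i, ],
                 tolerance = 1e-12)
    expect_equal(conditional_expectation(tcrossprod, dr), ex$Ebb[, , i],
                 tolerance = 1e-12)
  }
})

test_that("Breslow baseline M-step: hand-computed increments and homogeneity", {
  ## gamma = 0, W2 = 0: three subjects, events at 1 and 2, censored at 3
  ## -> Nelson-Aalen increments 1/3 and 1/2
  long <- data.frame(id = 1:3, time = 0, one = 1, y1 = c(0.1, -0.2, 0.3))
  surv <- data.frame(id = 1:3, time = c(1, 2, 3), status = c(1, 1, 0))
  spec <- outcome_spec("y1", fixed = "one", random = "one")
  dat <- load_joint_dataset(list(long), surv, list(spec))
  designs <- assemble_designs(dat)
  sstr <- survival_structures(dat)
  theta <- mjm_params(beta = 0, D = matrix(1), sigma2 = 1, gamma_y = 0,
                      lambda0 = data.frame(time = c(1, 2), haz = c(1, 1)))
  set.seed(4)
  ex <- multijm:::mcem_estep(designs, sstr, theta, 200L)
  lam <- mstep_baseline_hazard(ex, sstr)
  expect_equal(lam$haz, c(1 / 3, 1 / 2))
  expect_equal(lam$time, c(1, 2))

  ## homogeneity: doubling every E[exp(eta)] halves every increment
  ex2 <- ex; ex2$Eexp <- 2 * ex$Eexp
  expect_equal(mstep_baseline_hazard(ex2, sstr)$haz, lam$haz / 2)

  ## Breslow self-consistency: sum of increments times denominators = events
  denom <- colSums(ex$Eexp)
  expect_equal(sum(lam$haz * denom), 2)
})

test_that("gamma score and NR information match a frozen-draw oracle", {
  dat <- small_sim_dataset(n = 15, seed = 91)
  designs <- assemble_designs(dat)
  sstr <- survival_structures(dat)
  sc <- sim_scenario()
  theta <- mjm_params(as.numeric(t(sc$beta)), sc$D, sc$sigma2,
                      sc$gamma_v, sc$gamma_y)
  theta$lambda0 <- multijm:::initial_lambda0(designs, sstr, theta)
  N <- 400L
  set.seed(6)
  ex <- multijm:::mcem_estep(designs, sstr, theta, N, keep_draws = TRUE)
  gi <- gamma_score_information(ex, sstr, theta, "NR")

  ## oracle: S(gamma) from the frozen draws with weights frozen at theta
  S_or <- function(gam) {
    gv <- gam[1:2]; gy <- gam[3:4]
    S <- numeric(4)
    for (i in seq_along(sstr$subjects)) {
      s <- sstr$subjects[[i]]
      B <- ex$draws[[i]]
      lw <- apply(B, 1, survival_log_weight, subject = s, theta = theta)
      w <- exp(lw - max(lw)); w <- w / sum(w)
      if (s$status == 1)
        S <- S + c(s$v, as.numeric(s$GT %*% (t(B) %*% w)))
      if (s$Ji > 0) for (j in seq_len(s$Ji)) {
        wj <- B %*% t(s$G[, , j])
        eta <- exp(sum(s$v * gv) + wj %*% gy)
        S <- S - theta$lambda0$haz[j] *
          c(s$v * sum(w * eta), colSums(as.numeric(w * eta) * wj))
      }
    }
    S
  }
  g0 <- c(theta$gamma_v, theta$gamma_y)
  expect_equal(unname(gi$score), S_or(g0), tolerance = 1e-8)
  h <- 1e-5
  Ifd <- matrix(0, 4, 4)
  for (j in 1:4) {
    e <- rep(0, 4); e[j] <- h
    Ifd[, j] <- -(S_or(g0 + e) - S_or(g0 - e)) / (2 * h)
  }
  expect_equal(unname(gi$info), Ifd, tolerance = 1e-3)

  ## GN identity: identical per-subject scores give a zero empirical information
  n <- 6
  s_equal <- matrix(rep(c(1, -2, 0.5, 3), n), n, byrow = TRUE)
  Ie <- crossprod(s_equal) - tcrossprod(colSums(s_equal)) / n
  expect_equal(Ie, matrix(0, 4, 4), tolerance = 1e-10)
})

test_that("one-step gamma update arithmetic and exact Newton on a quadratic", {
  expect_equal(gamma_onestep_update(0, 2, matrix(4), "NR"), 0.5)
  expect_equal(gamma_onestep_update(0, 2, matrix(4), "GN"), 0.25)
  expect_equal(gamma_onestep_update(c(1, 2), c(0, 0), diag(2), "NR"), c(1, 2))
  ## quadratic log-likelihood with maximizer gstar: one NR step lands on it
  H <- matrix(c(3, 1, 1, 2), 2)
  gstar <- c(0.4, -1.2)
  for (start in list(c(0, 0), c(5, -5))) {
    sc0 <- H %*% (gstar - start)
    expect_equal(as.numeric(gamma_onestep_update(start, sc0, H, "NR")), gstar)
  }
  expect_error(gamma_onestep_update(0, 1, matrix(0), "NR"), "singular")
})

test_that("convergence check: arithmetic, criterion choice, counter semantics", {
  ctl <- mcem_control(tol_rel = 0.005, tol_denom = 0.001, tol_abs = 0.005,
                      criterion = "rel", consecutive = 3)
  st <- multijm:::new_convergence_state()
  st <- multijm:::push_theta(st, c(a = 1, b = 0.001))
  st <- multijm:::push_theta(st, c(a = 1.004, b = 0.0011))
  st <- convergence_check(st, ctl)
  ## Delta_rel = max(0.004/1.001, 0.0001/0.002) = 0.05 -> fail at 0.005
  expect_equal(st$delta_rel[1], 0.05, tolerance = 1e-10)
  expect_false(st$converged)
  expect_equal(st$passes, 0L)

  ## identical thetas pass with Delta = 0; three passes converge
  st2 <- multijm:::new_convergence_state()
  st2 <- multijm:::push_theta(st2, c(1, 2))
  for (z in 1:3) {
    st2 <- multijm:::push_theta(st2, c(1, 2))
    st2 <- convergence_check(st2, ctl)
  }
  expect_true(st2$converged)
  expect_equal(st2$delta_rel, rep(0, 3))

  ## two passes then a fail resets the counter
  st3 <- multijm:::new_convergence_state()
  st3 <- multijm:::push_theta(st3, c(1, 2))
  for (v in list(c(1, 2), c(1, 2), c(1.5, 2))) {
    st3 <- multijm:::push_theta(st3, v)
    st3 <- convergence_check(st3, ctl)
  }
  expect_false(st3$converged)
  expect_equal(st3$passes, 0L)

  ## hybrid: near-zero parameter checked by absolute difference
  ctlh <- mcem_control(criterion = "hybrid", tol_rel = 0.005, tol_abs = 0.005)
  sth <- multijm:::new_convergence_state()
  sth <- multijm:::push_theta(sth, c(big = 1, tiny = 0.001))
  sth <- multijm:::push_theta(sth, c(big = 1.001, tiny = 0.0012))
  sth <- convergence_check(sth, ctlh)
  expect_equal(sth$passes, 1L)  # tiny move 2e-4 < 0.005 abs; big rel 0.001 < 0.005
})

test_that("dynamic MC size rule: growth, stasis, burn-in, even rounding, cap", {
  ctl <- mcem_control(delta = 3, burnin = 10)
  st <- multijm:::new_convergence_state()
  ## constant history: cv = 0, unchanged
  st$delta_rel <- c(0.1, 0.1, 0.1, 0.1)
  expect_equal(adapt_mc_size(st, 100L, ctl, iteration = 50), 100L)
  ## increasing cv: N = 100 -> 133 -> 134 after even rounding
  st$delta_rel <- c(0.1, 0.1, 0.1, 0.3)
  expect_equal(adapt_mc_size(st, 100L, ctl, iteration = 50), 134L)
  ## inactive during burn-in
  expect_equal(adapt_mc_size(st, 100L, ctl, iteration = 5), 100L)
  ## too little history
  st$delta_rel <- c(0.1, 0.2)
  expect_equal(adapt_mc_size(st, 100L, ctl, iteration = 50), 100L)
  ## zero mean treated as cv 0
  st$delta_rel <- c(0, 0, 0, 0)
  expect_equal(adapt_mc_size(st, 100L, ctl, iteration = 50), 100L)
  ## cap
  ctl2 <- mcem_control(delta = 3, burnin = 10, N_max = 120)
  st$delta_rel <- c(0.1, 0.1, 0.1, 0.3)
  expect_equal(adapt_mc_size(st, 100L, ctl2, iteration = 50), 120L)
})

test_that("antithetic pairing reduces MC variance for a linear functional", {
  dat <- small_sim_dataset(n = 5, seed = 105)
  designs <- assemble_designs(dat)
  theta <- mjm_params(rep(0, 8), diag(4) * 0.2, c(0.3, 0.3), c(0, 0), c(0, 0))
  post <- posterior_re_moments(designs$subjects[[1]], theta)
  N <- 50L
  set.seed(12)
  anti <- replicate(200, mean(draw_antithetic(post, N)$draws %*% c(1, 1, 1, 1)))
  iid <- replicate(200, mean((matrix(rnorm(N * 4), N) %*% t(post$chol) +
                                rep(post$mean, each = N)) %*% c(1, 1, 1, 1)))
  expect_lt(var(anti), var(iid))
  expect_lt(var(anti), 1e-20)  # linear functionals cancel exactly in pairs
})

test_that("EM with exact (quadrature) expectations is monotone on an r=2 toy", {
  dat <- small_sim_dataset(n = 12, K = 1, beta = matrix(c(0, 1, 1, 1), 1),
                           D = matrix(c(0.25, -0.05, -0.05, 0.04), 2),
                           sigma2 = 0.25, gamma_v = c(0.3, 0.5), gamma_y = 0.8,
                           theta0 = 0.8, censor_rate = 0.05, seed = 107)
  designs <- assemble_designs(dat)
  sstr <- survival_structures(dat)
  theta <- mjm_params(beta = c(0.2, 0.8, 0.8, 1.2),
                      D = matrix(c(0.4, 0, 0, 0.06), 2),
                      sigma2 = 0.35, gamma_v = c(0, 0), gamma_y = 0.3)
  theta$lambda0 <- multijm:::initial_lambda0(designs, sstr, theta)

  ## one vectorised grid pass per subject: posterior-only weights w0, the
  ## survival log-density on the grid, and the atom-wise exp(eta) matrix.
  ## K = 1 with random intercept+slope: W2(t, b) = gamma_y (b0 + b1 t).
  ft <- sstr$failure_times
  grid_pass <- function(theta) {
    g <- theta$gamma_y
    lapply(seq_along(designs$subjects), function(i) {
      post <- posterior_re_moments(designs$subjects[[i]], theta)
      ng <- 71; width <- 7
      g1 <- seq(post$mean[1] - width * sqrt(post$cov[1, 1]),
                post$mean[1] + width * sqrt(post$cov[1, 1]), length.out = ng)
      g2 <- seq(post$mean[2] - width * sqrt(post$cov[2, 2]),
                post$mean[2] + width * sqrt(post$cov[2, 2]), length.out = ng)
      gr <- unname(as.matrix(expand.grid(g1, g2)))
      dev <- sweep(gr, 2, post$mean)
      Pinv <- solve(post$cov)
      w0 <- exp(-0.5 * rowSums((dev %*% Pinv) * dev))
      w0 <- w0 / sum(w0)
      s <- sstr$subjects[[i]]
      vg <- sum(s$v * theta$gamma_v)
      em <- if (s$Ji > 0)
        exp(vg + g * gr[, 1]) * exp(outer(g * gr[, 2], ft[seq_len(s$Ji)]))
      else matrix(0, nrow(gr), 0)
      cum <- if (s$Ji > 0)
        as.numeric(em %*% theta$lambda0$haz[seq_len(s$Ji)]) else 0
      lsurv <- -cum
      if (s$status == 1)
        lsurv <- lsurv + log(theta$lambda0$haz[s$Tatom]) + vg +
          g * (gr[, 1] + gr[, 2] * s$time)
      list(gr = gr, w0 = w0, em = em, lsurv = lsurv)
    })
  }
  quad_estep <- function(gp) {
    n <- length(gp)
    Eb <- matrix(0, n, 2); Ebb <- array(0, c(2, 2, n))
    Eexp <- matrix(0, n, sstr$J)
    for (i in seq_len(n)) {
      w <- gp[[i]]$w0 * exp(gp[[i]]$lsurv - max(gp[[i]]$lsurv))
      w <- w / sum(w)
      Eb[i, ] <- colSums(gp[[i]]$gr * w)
      Ebb[, , i] <- t(gp[[i]]$gr) %*% (gp[[i]]$gr * w)
      if (ncol(gp[[i]]$em) > 0)
        Eexp[i, seq_len(ncol(gp[[i]]$em))] <- colSums(gp[[i]]$em * w)
    }
    list(Eb = Eb, Ebb = Ebb, Eexp = Eexp)
  }
  quad_ll <- function(theta, gp) {
    marginal_longitudinal_loglik(designs, theta$beta, theta$D, theta$sigma2) +
      sum(vapply(gp, function(p) log(sum(p$w0 * exp(p$lsurv))), numeric(1)))
  }
  lls <- numeric(6)
  for (it in 1:6) {
    gp <- grid_pass(theta)
    ex <- quad_estep(gp)
    ms <- mstep_beta_sigma_D(designs, ex, theta)
    th2 <- theta
    th2$beta <- ms$beta; th2$sigma2 <- ms$sigma2; th2$D <- ms$D
    th2$lambda0 <- mstep_baseline_hazard(ex, sstr)
    ## gamma held fixed: the (beta, sigma2, D, lambda0) M-steps are exact
    ## maximizers, so the EM ascent property must hold exactly
    theta <- th2
    lls[it] <- quad_ll(theta, grid_pass(theta))
  }
  expect_true(all(diff(lls) > -1e-8))
})

test_that("mcem_fit is reproducible and respects K-scaled defaults", {
  dat <- small_sim_dataset(n = 40, seed = 111)
  ctl <- test_control(seed = 77, N0 = 60L, burnin = 20L, max_iter = 60L)
  fit1 <- suppressWarnings(mcem_fit(dat, ctl))
  fit2 <- suppressWarnings(mcem_fit(dat, ctl))
  expect_identical(fit1$trace, fit2$trace)  # bit-identical trace
  expect_identical(theta_hat1 <- multijm:::theta_vector(fit1$theta_hat),
                   multijm:::theta_vector(fit2$theta_hat))
  expect_equal(fit1$loglik, fit2$loglik)

  ## defaults resolve to 100 K for K = 2
  ctl0 <- multijm:::resolve_control(mcem_control(), K = 2L)
  expect_equal(ctl0$N0, 200L)
  expect_equal(ctl0$burnin, 200L)

  ## trace bookkeeping
  expect_equal(nrow(fit1$trace), fit1$n_iter)
  expect_true(all(fit1$trace$N %% 2 == 0))
})

test_that("without true association the longitudinal fit tracks the marginal LMM", {
  ## K = 1 with gamma_y truth 0: the survival weights carry little
  ## information, so longitudinal estimates track fit_univariate_lmm
  dat <- small_sim_dataset(n = 80, K = 1, beta = matrix(c(0, 1, 1, 1), 1),
                           D = matrix(c(0.25, -0.05, -0.05, 0.04), 2),
                           sigma2 = 0.25, gamma_v = c(0, 1), gamma_y = 0,
                           seed = 115)
  u <- fit_univariate_lmm(dat, 1)
  ctl <- test_control(seed = 5, N0 = 100L, burnin = 30L, max_iter = 80L)
  fit <- suppressWarnings(mcem_fit(dat, ctl))
  ## longitudinal parameters should sit near the marginal LMM estimates
  expect_equal(unname(fit$theta_hat$beta), unname(u$beta_k), tolerance = 0.05)
  expect_equal(fit$theta_hat$sigma2, u$sigma2_k, tolerance = 0.05)
})
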