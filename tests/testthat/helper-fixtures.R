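## shared fixture builders and independent oracles for the test suite

## tiny hand-built joint dataset: 3 subjects, K = 2, shared visit grid
tiny_tables <- function() {
  long1 <- data.frame(
    id = c(1, 1, 2, 2, 3),
    time = c(0, 1, 0, 1, 0),
    intercept = 1,
    xc = c(0.5, 0.5, -1, -1, 0.2),
    y1 = c(1.0, 1.5, -0.5, 0.0, 0.8))
  long2 <- data.frame(
    id = c(1, 1, 2, 2, 3),
    time = c(0, 1, 0, 1, 0),
    intercept = 1,
    xc = c(0.5, 0.5, -1, -1, 0.2),
    y2 = c(2.0, 2.2, 1.1, 1.3, 1.9))
  surv <- data.frame(id = 1:3, time = c(1.5, 2.5, 0.7),
                     status = c(1, 0, 1), xs = c(0.1, -0.3, 0.8))
  list(long1 = long1, long2 = long2, surv = surv)
}

tiny_specs <- function() {
  list(outcome_spec("y1", fixed = c("intercept", "time", "xc"),
                    random = c("intercept", "time")),
       outcome_spec("y2", fixed = c("intercept", "xc"),
                    random = "intercept"))
}

tiny_dataset <- function() {
  tb <- tiny_tables()
  load_joint_dataset(list(tb$long1, tb$long2), tb$surv, tiny_specs(),
                     surv_covariates = "xs")
}

## small simulated dataset under the reference scenario
small_sim_dataset <- function(n = 60, seed = 101, ...) {
  sc <- sim_scenario(n = n, ...)
  set.seed(seed)
  simulate_joint(sc)
}

## independent dense-grid posterior oracle for r = 2 subjects:
## moments of f(b | y, T, delta) on a grid, survival factor included
quad_posterior_oracle <- function(subject_design, subject_surv, theta,
                                  ng = 151, width = 7) {
  post <- posterior_re_moments(subject_design, theta)
  g1 <- seq(post$mean[1] - width * sqrt(post$cov[1, 1]),
            post$mean[1] + width * sqrt(post$cov[1, 1]), length.out = ng)
  g2 <- seq(post$mean[2] - width * sqrt(post$cov[2, 2]),
            post$mean[2] + width * sqrt(post$cov[2, 2]), length.out = ng)
  gr <- unname(as.matrix(expand.grid(g1, g2)))
  dev <- sweep(gr, 2, post$mean)
  Pinv <- solve(post$cov)
  lpost <- -0.5 * rowSums((dev %*% Pinv) * dev)
  lsurv <- apply(gr, 1, function(b) survival_log_weight(b, subject_surv, theta))
  lw <- lpost + lsurv
  w <- exp(lw - max(lw)); w <- w / sum(w)
  list(mean = colSums(gr * w), cov = t(gr) %*% (gr * w) -
         tcrossprod(colSums(gr * w)),
       Ebb = t(gr) %*% (gr * w),
       grid = gr, weights = w,
       ## MC-free value of E[exp(v'gv + W2(t, b))] at a time t
       Eexp_at = function(t) {
         vg <- if (length(theta$gamma_v)) sum(subject_surv$v * theta$gamma_v) else 0
         eta <- apply(gr, 1, function(b)
           vg + sum(theta$gamma_y * (subject_surv$G_at(t) %*% b)))
         sum(w * exp(eta))
       })
}

## brute-force Breslow partial log-likelihood for a single binary/continuous
## covariate (time-fixed), written independently of any Cox code
breslow_partial_loglik <- function(gamma, times, status, x) {
  ll <- 0
  for (j in which(status == 1)) {
    risk <- times >= times[j]
    ll <- ll + gamma * x[j] - log(sum(exp(gamma * x[risk])))
  }
  ll
}

## default reduced MCEM control for fast test fits
test_control <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(N0 = 100L, burnin = 50L, tol_rel = 0.02, tol_abs = 0.01,
                   max_iter = 150L, seed = seed, se_method = "none")
  defaults[names(args)] <- args
  do.call(mcem_control, defaults)
}
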