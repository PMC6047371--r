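#' Cox proportional hazards fit by Breslow partial likelihood
#'
#' Newton-Raphson maximisation of the partial likelihood with Breslow's
#' approximation for ties, supporting piecewise-constant time-varying
#' covariates through counting-process (start, stop] rows. The numerical
#' optimisation is delegated to \code{survival::coxph} with
#' \code{ties = "breslow"}; this wrapper adds the error contracts needed by
#' the joint-model initialisation (degenerate covariates, separation).
#'
#' @param times observed times (stop times when \code{start} is given)
#' @param status 0/1 event indicators
#' @param covariates numeric matrix of covariate rows (one per row of
#'   \code{times})
#' @param start optional vector of interval start times (counting-process
#'   format for time-varying covariates)
#' @return object of class \code{cox_fit}: \code{gamma}, \code{loglik},
#'   \code{iterations}
#' @export
coxph_partial_fit <- function(times, status, covariates, start = NULL) {
  covariates <- as.matrix(covariates)
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  if (sum(status) == 0) stop("no events: partial likelihood is flat")
  if (!all(is.finite(covariates))) stop("non-finite covariates")
  ## a covariate constant across all rows cancels from the partial likelihood:
  ## the score is identically zero and the information singular
  degen <- apply(covariates, 2L, function(x) max(x) - min(x) == 0)
  if (any(degen))
    stop("degenerate covariate (constant across subjects): ",
         paste(colnames(covariates)[degen], collapse = ", "))
  df <- as.data.frame(covariates)
  if (is.null(start)) {
    df$.time <- times; df$.status <- status
    fml <- stats::as.formula(paste(
      "survival::Surv(.time, .status) ~",
      paste(paste0("`", colnames(covariates), "`"), collapse = " + ")))
  } else {
    df$.start <- start; df$.stop <- times; df$.status <- status
    fml <- stats::as.formula(paste(
      "survival::Surv(.start, .stop, .status) ~",
      paste(paste0("`", colnames(covariates), "`"), collapse = " + ")))
  }
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  gam <- stats::coef(fit)
  if (any(!is.finite(gam)) || any(abs(gam) > 20))
    stop("separation: partial likelihood is monotone in a coefficient")
  names(gam) <- colnames(covariates)
  structure(list(gamma = gam,
                 loglik = fit$loglik[length(fit$loglik)],
                 iterations = fit$iter),
            class = "cox_fit")
}

## BLUPs (posterior means of b_ik) from the separate univariate fits,
## one n x r_k matrix per outcome
separate_blups <- function(dataset, lmm_fits) {
  K <- dataset$K
  lapply(seq_len(K), function(k) {
    f <- lmm_fits[[k]]
    rk <- length(dataset$specs[[k]]$random)
    Dinv <- chol2inv(chol(f$D_kk))
    t(vapply(dataset$subjects, function(s) {
      o <- s$outcomes[[k]]
      if (!length(o$y)) return(numeric(rk))
      M <- crossprod(o$Z) / f$sigma2_k + Dinv
      as.numeric(solve(M, crossprod(o$Z, o$y - o$X %*% f$beta_k) / f$sigma2_k))
    }, numeric(rk)))
  })
}

## random-effect design vector z_ik(t) for subject i, outcome k, at time t:
## a random covariate equal to the time column evaluates to t; anything else
## must be constant within the subject (or globally, for subjects without
## rows on this outcome)
z_at_time <- function(dataset, i, k, t) {
  sp <- dataset$specs[[k]]
  o <- dataset$subjects[[i]]$outcomes[[k]]
  vapply(seq_along(sp$random), function(c) {
    cn <- sp$random[c]
    if (cn == sp$time) return(t)
    if (nrow(o$Z) > 0) {
      vals <- o$Z[, c]
      if (any(vals != vals[1L]))
        stop("random covariate '", cn, "' varies within subject ",
             dataset$subjects[[i]]$id,
             " and cannot be evaluated at event times")
      return(vals[1L])
    }
    gc <- dataset$z_const[[k]][c]
    if (is.na(gc))
      stop("cannot evaluate random covariate '", cn, "' for subject ",
           dataset$subjects[[i]]$id, " (no measurements and not globally constant)")
    gc
  }, numeric(1))
}

#' Quasi-two-stage initial values for the hazard coefficients
#'
#' When visit times are balanced across outcomes, the BLUP-estimated latent
#' trajectories W_1i^(k)(t) = z_ik'(t) b-hat_ik from the separate univariate
#' fits are included as piecewise-constant time-varying covariates (evaluated
#' at each distinct failure time, left-continuous) in a Cox regression
#' alongside the baseline covariates; the fitted coefficients seed
#' (gamma_v, gamma_y). For unbalanced data a baseline-covariate-only Cox model
#' is fitted and gamma_y is initialised at zero.
#'
#' @param dataset a \code{joint_dataset}
#' @param lmm_fits list of \code{lmm_component}, one per outcome
#' @return list with \code{gamma_v0} and \code{gamma_y0}
#' @export
two_stage_initial_values <- function(dataset, lmm_fits) {
  K <- dataset$K
  n <- length(dataset$subjects)
  Tvec <- vapply(dataset$subjects, function(s) s$surv$time, numeric(1))
  dvec <- vapply(dataset$subjects, function(s) s$surv$status, integer(1))
  q <- dataset$q
  Vmat <- if (q > 0)
    t(vapply(dataset$subjects, function(s) s$surv$v, numeric(q))) else
      matrix(0, n, 0)
  colnames(Vmat) <- dataset$surv_covariates

  baseline_only <- function() {
    gv <- if (q > 0) coxph_partial_fit(Tvec, dvec, Vmat)$gamma else numeric(0)
    list(gamma_v0 = gv, gamma_y0 = rep(0, K))
  }
  if (!dataset$balanced) return(baseline_only())

  blups <- separate_blups(dataset, lmm_fits)
  ft <- sort(unique(Tvec[dvec == 1]))
  rows <- vector("list", n)
  wnames <- paste0("W1_", vapply(dataset$specs, function(s) s$name, character(1)))
  for (i in seq_len(n)) {
    cuts <- c(0, ft[ft < Tvec[i]], Tvec[i])
    cuts <- unique(cuts)
    m <- length(cuts) - 1L
    ## the BLUP trajectory is affine in t under the evaluation convention
    W <- matrix(0, m, K)
    for (k in seq_len(K)) {
      w0 <- sum(z_at_time(dataset, i, k, 0) * blups[[k]][i, ])
      w1 <- sum(z_at_time(dataset, i, k, 1) * blups[[k]][i, ])
      W[, k] <- w0 + (w1 - w0) * cuts[-1L]
    }
    colnames(W) <- wnames
    st <- integer(m); st[m] <- dvec[i]
    rows[[i]] <- data.frame(.start = cuts[-length(cuts)], .stop = cuts[-1L],
                            .status = st,
                            Vmat[rep(i, m), , drop = FALSE], W,
                            check.names = FALSE)
  }
  cp <- do.call(rbind, rows)
  fit <- tryCatch(
    coxph_partial_fit(cp$.stop, cp$.status,
                      as.matrix(cp[, c(colnames(Vmat), wnames), drop = FALSE]),
                      start = cp$.start),
    error = function(e) {
      if (grepl("separation", conditionMessage(e))) {
        warning("two-stage Cox fit separated; falling back to gamma_y0 = 0",
                call. = FALSE)
        NULL
      } else stop(e)
    })
  if (is.null(fit)) return(baseline_only())
  list(gamma_v0 = fit$gamma[seq_len(q)],
       gamma_y0 = unname(fit$gamma[q + seq_len(K)]))
}
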