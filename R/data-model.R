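#' Specify one longitudinal outcome
#'
#' Describes how the columns of a long-format table map onto one longitudinal
#' sub-model: the response, the measurement-time column, and the columns that
#' form the fixed-effects design \code{x_ik} and the random-effects design
#' \code{z_ik}. Intercepts are explicit constant-1 columns supplied by the
#' caller; no formula language is interpreted.
#'
#' Random-effect covariates must be evaluable at arbitrary event times for the
#' hazard sub-model: a random covariate is either the time column itself
#' (evaluates to \code{t}) or constant within each subject (intercepts,
#' baseline covariates).
#'
#' @param name outcome label (also the response column name in its long table)
#' @param fixed character vector of fixed-effect column names (length p_k >= 1)
#' @param random character vector of random-effect column names (length r_k >= 1)
#' @param time name of the measurement-time column
#' @return an object of class \code{outcome_spec}
#' @export
outcome_spec <- function(name, fixed, random, time = "time") {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(fixed), length(fixed) >= 1L,
            is.character(random), length(random) >= 1L,
            is.character(time), length(time) == 1L)
  structure(list(name = name, fixed = fixed, random = random, time = time),
            class = "outcome_spec")
}

#' @export
print.outcome_spec <- function(x, ...) {
  cat("Outcome spec:", x$name, "\n")
  cat("  fixed  (p =", length(x$fixed), "):", paste(x$fixed, collapse = ", "), "\n")
  cat("  random (r =", length(x$random), "):", paste(x$random, collapse = ", "), "\n")
  cat("  time column:", x$time, "\n")
  invisible(x)
}

read_table_source <- function(src, delim = ",") {
  if (is.data.frame(src)) return(as.data.frame(src))
  if (is.character(src) && length(src) == 1L) {
    if (!file.exists(src)) stop("file not found: ", src)
    return(utils::read.table(src, header = TRUE, sep = delim,
                             stringsAsFactors = FALSE, check.names = FALSE))
  }
  stop("table source must be a data.frame or a file path")
}

## subject-constant evaluation value for a random covariate column; NA when the
## column is not globally constant (then subjects lacking rows cannot be scored)
global_constant <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) && all(v == v[1L])) v[1L] else NA_real_
}

#' Construct a joint dataset from long tables and a survival table
#'
#' Builds the per-subject data structure used by all model-fitting functions:
#' for each subject, per-outcome measurement times, responses and design
#' matrices, plus one survival record (observed time, event indicator,
#' baseline covariates).
#'
#' @param long_tables list of length K: each a data.frame or a delimited-text
#'   file path in long format, containing the id column, the outcome's time
#'   column, the response column (named as in the spec) and all design columns
#' @param survival_table data.frame or file path with columns \code{id_col},
#'   \code{time}, \code{status} (0/1) and any baseline covariates
#' @param specs list of \code{\link{outcome_spec}} objects, one per outcome
#' @param id_col name of the subject identifier column (all tables)
#' @param surv_covariates character vector naming the baseline covariate
#'   columns of the survival table that enter the hazard (may be empty)
#' @param delim field delimiter for file-path sources
#' @return an object of class \code{joint_dataset}
#' @export
load_joint_dataset <- function(long_tables, survival_table, specs,
                               id_col = "id", surv_covariates = character(),
                               delim = ",") {
  if (inherits(specs, "outcome_spec")) specs <- list(specs)
  K <- length(specs)
  if (is.data.frame(long_tables)) long_tables <- list(long_tables)
  if (length(long_tables) == 1L && K > 1L)
    long_tables <- rep(long_tables, K)  # shared table, balanced design
  stopifnot(length(long_tables) == K, K >= 1L)

  surv <- read_table_source(survival_table, delim)
  for (col in c(id_col, "time", "status"))
    if (!col %in% names(surv)) stop("survival table lacks column '", col, "'")
  for (col in surv_covariates)
    if (!col %in% names(surv)) stop("survival covariate column missing: '", col, "'")
  if (anyDuplicated(surv[[id_col]]))
    stop("duplicate ids in survival table")
  if (!is.numeric(surv$time) || any(surv$time < 0))
    stop("survival times must be numeric and nonnegative")
  if (!all(surv$status %in% c(0, 1)))
    stop("status must be 0/1")

  ids <- as.character(surv[[id_col]])
  n <- length(ids)
  longs <- vector("list", K)
  n_dropped <- 0L
  for (k in seq_len(K)) {
    sp <- specs[[k]]
    df <- read_table_source(long_tables[[k]], delim)
    need <- unique(c(id_col, sp$time, sp$name, sp$fixed, sp$random))
    for (col in need)
      if (!col %in% names(df)) stop("long table for outcome '", sp$name,
                                    "' lacks column '", col, "'")
    unknown <- setdiff(unique(as.character(df[[id_col]])), ids)
    if (length(unknown))
      stop("id '", unknown[1L], "' in long table for outcome '", sp$name,
           "' is absent from the survival table")
    if (!is.numeric(df[[sp$name]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(df[[sp$name]])))) &
                     !is.na(df[[sp$name]]))
      stop("non-numeric response for outcome '", sp$name, "' at row ",
           if (length(bad)) bad[1L] else 1L)
    }
    if (!is.numeric(df[[sp$time]]) || any(df[[sp$time]] < 0, na.rm = TRUE))
      stop("times for outcome '", sp$name, "' must be numeric and nonnegative")
    ## drop rows with missing response
    miss_y <- is.na(df[[sp$name]])
    ## drop rows with missing covariates (no imputation)
    covcols <- unique(c(sp$fixed, sp$random))
    miss_x <- rowSums(is.na(df[, covcols, drop = FALSE])) > 0
    drop <- miss_y | miss_x
    if (any(drop)) {
      n_dropped <- n_dropped + sum(drop)
      warning(sum(drop), " row(s) with missing response/covariates dropped for outcome '",
              sp$name, "'", call. = FALSE)
      df <- df[!drop, , drop = FALSE]
    }
    dup <- duplicated(df[, c(id_col, sp$time)])
    if (any(dup))
      stop("duplicate (id, time) rows within outcome '", sp$name, "' (e.g. id ",
           df[[id_col]][which(dup)[1L]], ", time ", df[[sp$time]][which(dup)[1L]], ")")
    longs[[k]] <- df
  }

  z_const <- lapply(seq_len(K), function(k) {
    sp <- specs[[k]]
    vapply(sp$random, function(cn) {
      if (cn == sp$time) NA_real_ else global_constant(longs[[k]][[cn]])
    }, numeric(1))
  })

  split_by_id <- lapply(longs, function(df)
    split(seq_len(nrow(df)), factor(as.character(df[[id_col]]), levels = ids)))
  subjects <- vector("list", n)
  balanced <- TRUE
  for (i in seq_len(n)) {
    outc <- vector("list", K)
    for (k in seq_len(K)) {
      sp <- specs[[k]]
      df <- longs[[k]]
      rows <- df[split_by_id[[k]][[i]], , drop = FALSE]
      rows <- rows[order(rows[[sp$time]]), , drop = FALSE]
      outc[[k]] <- list(
        times = as.numeric(rows[[sp$time]]),
        y = as.numeric(rows[[sp$name]]),
        X = as.matrix(rows[, sp$fixed, drop = FALSE]),
        Z = as.matrix(rows[, sp$random, drop = FALSE]))
      storage.mode(outc[[k]]$X) <- "double"
      storage.mode(outc[[k]]$Z) <- "double"
    }
    if (K > 1L) {
      t1 <- outc[[1L]]$times
      for (k in 2:K)
        if (!identical(length(t1), length(outc[[k]]$times)) ||
            (length(t1) && any(t1 != outc[[k]]$times))) balanced <- FALSE
    }
    subjects[[i]] <- list(
      id = ids[i],
      outcomes = outc,
      surv = list(time = surv$time[i], status = as.integer(surv$status[i]),
                  v = as.numeric(surv[i, surv_covariates, drop = TRUE])))
  }

  structure(list(subjects = subjects, K = K, specs = specs,
                 ids = ids, id_col = id_col,
                 surv_covariates = surv_covariates, q = length(surv_covariates),
                 z_const = z_const, balanced = balanced,
                 n_dropped = n_dropped),
            class = "joint_dataset")
}

#' @export
print.joint_dataset <- function(x, ...) {
  n <- length(x$subjects)
  ev <- sum(vapply(x$subjects, function(s) s$surv$status, integer(1)))
  cat("Joint dataset:", n, "subjects,", x$K, "longitudinal outcome(s),",
      ev, "events\n")
  for (k in seq_len(x$K)) {
    m <- sum(vapply(x$subjects, function(s) length(s$outcomes[[k]]$y), integer(1)))
    cat("  ", x$specs[[k]]$name, ": ", m, " measurements\n", sep = "")
  }
  cat("  balanced visit times:", x$balanced, "\n")
  invisible(x)
}

#' Write a joint dataset back to long-format tables
#'
#' Inverse of \code{\link{load_joint_dataset}}: returns (and optionally writes
#' as CSV) one long table per outcome and the survival table. Reloading the
#' written tables reproduces the dataset exactly.
#'
#' @param dataset a \code{joint_dataset}
#' @param dir optional directory; when given, CSV files are written there
#' @return invisibly, a list with elements \code{long} (list of data.frames)
#'   and \code{survival}
#' @export
write_joint_dataset <- function(dataset, dir = NULL) {
  K <- dataset$K
  longs <- vector("list", K)
  for (k in seq_len(K)) {
    sp <- dataset$specs[[k]]
    covcols <- unique(c(sp$fixed, sp$random))
    covcols <- setdiff(covcols, sp$time)
    pieces <- lapply(dataset$subjects, function(s) {
      o <- s$outcomes[[k]]
      if (!length(o$times)) return(NULL)
      df <- data.frame(id = rep(s$id, length(o$times)), check.names = FALSE)
      names(df) <- dataset$id_col
      df[[sp$time]] <- o$times
      df[[sp$name]] <- o$y
      for (cn in covcols) {
        if (cn %in% colnames(o$X)) df[[cn]] <- o$X[, cn]
        else df[[cn]] <- o$Z[, cn]
      }
      df
    })
    longs[[k]] <- do.call(rbind, pieces)
    rownames(longs[[k]]) <- NULL
  }
  sv <- data.frame(id = dataset$ids,
                   time = vapply(dataset$subjects, function(s) s$surv$time, numeric(1)),
                   status = vapply(dataset$subjects, function(s) s$surv$status, integer(1)),
                   check.names = FALSE)
  names(sv)[1L] <- dataset$id_col
  if (dataset$q > 0) {
    V <- t(vapply(dataset$subjects, function(s) s$surv$v, numeric(dataset$q)))
    colnames(V) <- dataset$surv_covariates
    sv <- cbind(sv, V)
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (k in seq_len(K))
      utils::write.csv(longs[[k]],
                       file.path(dir, paste0("long_", dataset$specs[[k]]$name, ".csv")),
                       row.names = FALSE)
    utils::write.csv(sv, file.path(dir, "survival.csv"), row.names = FALSE)
  }
  invisible(list(long = longs, survival = sv))
}

#' Assemble per-subject block design matrices
#'
#' For each subject forms the stacked response \code{y_i} and the
#' block-diagonal designs \code{X_i} (direct sum of the per-outcome fixed
#' designs) and \code{Z_i} (direct sum of the random designs), in outcome-major
#' order (all rows of outcome 1, then outcome 2, ...). This ordering matches
#' the stacking of the fixed-effect vector beta and the random effects b.
#'
#' @param dataset a \code{joint_dataset}
#' @return an object of class \code{mjm_designs}: a list with per-subject
#'   elements (\code{y}, \code{X}, \code{Z}, row counts \code{n_k}) and the
#'   dimension bookkeeping (\code{p_k}, \code{r_k}, parameter names)
#' @export
assemble_designs <- function(dataset) {
  K <- dataset$K
  p_k <- vapply(dataset$specs, function(s) length(s$fixed), integer(1))
  r_k <- vapply(dataset$specs, function(s) length(s$random), integer(1))
  p <- sum(p_k); r <- sum(r_k)
  poff <- c(0L, cumsum(p_k)); roff <- c(0L, cumsum(r_k))
  subjects <- lapply(dataset$subjects, function(s) {
    n_k <- vapply(s$outcomes, function(o) length(o$y), integer(1))
    ntot <- sum(n_k)
    X <- matrix(0, ntot, p); Z <- matrix(0, ntot, r)
    y <- numeric(ntot)
    row0 <- 0L
    for (k in seq_len(K)) {
      if (n_k[k] > 0L) {
        idx <- row0 + seq_len(n_k[k])
        X[idx, poff[k] + seq_len(p_k[k])] <- s$outcomes[[k]]$X
        Z[idx, roff[k] + seq_len(r_k[k])] <- s$outcomes[[k]]$Z
        y[idx] <- s$outcomes[[k]]$y
      }
      row0 <- row0 + n_k[k]
    }
    ## per-outcome crossproducts: everything the EM iterations need without
    ## touching row-level matrices again
    cross <- lapply(seq_len(K), function(k) {
      if (n_k[k] == 0L)
        return(list(XtX = matrix(0, p_k[k], p_k[k]),
                    XtZ = matrix(0, p_k[k], r_k[k]),
                    Xty = numeric(p_k[k]),
                    ZtZ = matrix(0, r_k[k], r_k[k]),
                    Zty = numeric(r_k[k]), yty = 0))
      Xk <- s$outcomes[[k]]$X; Zk <- s$outcomes[[k]]$Z; yk <- s$outcomes[[k]]$y
      list(XtX = crossprod(Xk), XtZ = crossprod(Xk, Zk),
           Xty = as.numeric(crossprod(Xk, yk)),
           ZtZ = crossprod(Zk), Zty = as.numeric(crossprod(Zk, yk)),
           yty = sum(yk^2))
    })
    list(id = s$id, y = y, X = X, Z = Z, n_k = n_k,
         rows_k = split(seq_len(ntot), rep(seq_len(K), n_k)),
         cross = cross, surv = s$surv)
  })
  beta_names <- unlist(lapply(seq_len(K), function(k)
    paste0(dataset$specs[[k]]$name, ":", dataset$specs[[k]]$fixed)))
  b_names <- unlist(lapply(seq_len(K), function(k)
    paste0(dataset$specs[[k]]$name, ":", dataset$specs[[k]]$random)))
  XtX_tot <- lapply(seq_len(K), function(k)
    Reduce(`+`, lapply(subjects, function(s) s$cross[[k]]$XtX)))
  structure(list(subjects = subjects, K = K, p_k = p_k, r_k = r_k,
                 p = p, r = r, poff = poff, roff = roff,
                 beta_names = beta_names, b_names = b_names,
                 XtX_tot = XtX_tot,
                 q = dataset$q, surv_covariates = dataset$surv_covariates),
            class = "mjm_designs")
}

#' Validate a joint dataset
#'
#' Produces a summary report (counts of subjects, events and measurements) and
#' a list of warnings: measurements recorded after the subject's observed
#' time, and subjects with no measurements at all. A dataset with zero events
#' is an error because the baseline hazard is then unidentifiable.
#'
#' @param dataset a \code{joint_dataset}
#' @return an object of class \code{mjm_validation}; convert with
#'   \code{\link[jsonlite]{toJSON}} or via \code{as_json = TRUE}
#' @param as_json return a JSON string instead of the list
#' @export
validate_dataset <- function(dataset, as_json = FALSE) {
  n <- length(dataset$subjects)
  events <- sum(vapply(dataset$subjects, function(s) s$surv$status, integer(1)))
  if (events == 0L)
    stop("no events in dataset: baseline hazard is unidentifiable")
  meas <- vapply(seq_len(dataset$K), function(k)
    sum(vapply(dataset$subjects, function(s) length(s$outcomes[[k]]$y), integer(1))),
    integer(1))
  names(meas) <- vapply(dataset$specs, function(s) s$name, character(1))
  after <- sum(vapply(dataset$subjects, function(s)
    sum(vapply(s$outcomes, function(o) sum(o$times > s$surv$time), integer(1))),
    integer(1)))
  zero_meas <- sum(vapply(dataset$subjects, function(s)
    all(vapply(s$outcomes, function(o) length(o$y) == 0L, logical(1))), logical(1)))
  warnings <- character()
  if (after > 0)
    warnings <- c(warnings, paste0(after, " measurement(s) recorded after the observed event/censoring time"))
  if (zero_meas > 0)
    warnings <- c(warnings, paste0(zero_meas, " subject(s) with zero measurements"))
  rep <- structure(list(subjects = n, events = events,
                        measurements = as.list(meas),
                        measurements_after_followup = after,
                        subjects_without_measurements = zero_meas,
                        warnings = warnings),
                   class = "mjm_validation")
  if (as_json)
    return(jsonlite::toJSON(unclass(rep), auto_unbox = TRUE, pretty = TRUE))
  rep
}

#' @export
print.mjm_validation <- function(x, ...) {
  cat("Joint dataset validation\n")
  cat("  subjects:", x$subjects, " events:", x$events, "\n")
  for (nm in names(x$measurements))
    cat("  measurements (", nm, "): ", x$measurements[[nm]], "\n", sep = "")
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  } else cat("  warnings: none\n")
  invisible(x)
}
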