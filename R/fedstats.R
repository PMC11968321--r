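## Aggregate statistics: contingency tables under cell suppression,
## univariate summaries via sufficient statistics, and the federated GLM.
## The GLM is fitted by exchanging per-site score vectors U = X'(y - mu) and
## Fisher information matrices I = X'WX at canonical links; pooling these
## across sites and taking Newton steps is algebraically the same IRLS that
## a single analysis of the physically pooled data would perform, so the
## federated fit equals the pooled fit to numerical precision while only
## p-dimensional summaries ever leave a site.

## ---------------------------------------------------------------------------
## Contingency tables

#' Cross-tabulate categorical variables at one site
#'
#' Tabulates complete cases of 1–3 categorical variables, after the levels
#' filter on each variable, and applies the cell-count rule. A table failing
#' the rule is returned *suppressed*: the payload carries the flag and the
#' dimension names but no counts.
#'
#' @param session A node session.
#' @param vars 1–3 categorical variable names.
#' @param s Disclosure settings.
#' @param source Source table symbol (default the node's dataset).
#' @return An object of class `contingency_table` with fields `dims`,
#'   `levels`, `counts` (absent when suppressed), `suppressed`,
#'   `n_missing`, `site`.
#' @export
site_contingency <- function(session, vars, s = effective_settings(session),
                             source = session$node$dataset_name) {
  if (length(vars) < 1L || length(vars) > 3L) stop_sdc("DIM_TOO_HIGH")
  tab <- resolve_source(session, source, vars = vars)
  cols <- tab[, vars, drop = FALSE]
  for (v in vars) {
    if (is.numeric(cols[[v]])) stop_sdc("TYPE_MISMATCH")
    cols[[v]] <- as.factor(cols[[v]])
    dec <- check_levels(nlevels(cols[[v]]), nrow(cols), s)
    if (!dec$allowed) stop_sdc("LEVELS_BLOCKED")
  }
  cc <- stats::complete.cases(cols)
  counts <- table(cols[cc, , drop = FALSE], dnn = vars)
  dec <- check_table(unclass(counts), s)
  out <- list(dims = vars, levels = dimnames(counts),
              suppressed = !dec$allowed, n_missing = sum(!cc),
              site = session$site)
  if (dec$allowed) out$counts <- unclass(counts)
  structure(out, class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table %s: %s%s>\n",
              x$site %||% "pooled", paste(x$dims, collapse = " x "),
              if (x$suppressed) ", SUPPRESSED" else ""))
  if (!x$suppressed) print(x$counts)
  invisible(x)
}

#' Pool per-site contingency tables
#'
#' Element-wise sum of counts over sites. Pooling is refused outright if any
#' site's table is suppressed: summing the remaining sites would let an
#' analyst recover the suppressed site's counts by subtracting a pooled
#' table obtained elsewhere (a difference attack).
#'
#' @param tables List of `contingency_table` objects with identical
#'   dimensions and level sets.
#' @return A pooled `contingency_table`.
#' @export
pool_tables <- function(tables) {
  stopifnot(length(tables) >= 1L)
  if (any(vapply(tables, function(t) isTRUE(t$suppressed), logical(1)))) {
    stop_sdc("POOL_BLOCKED")
  }
  ref <- tables[[1]]
  for (t in tables[-1]) {
    if (!identical(t$dims, ref$dims) || !identical(t$levels, ref$levels)) {
      stop_sdc("BAD_ARGUMENT")
    }
  }
  counts <- Reduce(`+`, lapply(tables, `[[`, "counts"))
  structure(list(dims = ref$dims, levels = ref$levels, suppressed = FALSE,
                 n_missing = sum(vapply(tables, `[[`, numeric(1), "n_missing")),
                 site = NULL, counts = counts),
            class = "contingency_table")
}

## ---------------------------------------------------------------------------
## Univariate summaries via sufficient statistics

#' Sufficient statistics for a numeric variable at one site
#'
#' Returns `{N, sum, sum_sq, n_missing}` — enough to pool means and
#' variances exactly, and nothing individual-level. A variable with fewer
#' complete observations than the subset threshold is refused (a tiny
#' summary is as disclosive as a tiny subset).
#'
#' @param session A node session.
#' @param var Numeric variable name; may be `NULL` when `source` itself
#'   resolves to a numeric workspace vector.
#' @param s Disclosure settings.
#' @param source Source symbol.
#' @return An object of class `summary_share`.
#' @export
site_summary <- function(session, var = NULL,
                         s = effective_settings(session),
                         source = session$node$dataset_name) {
  obj <- resolve_source(session, source,
                        vars = if (!is.null(var)) var else NULL)
  x <- if (is.data.frame(obj)) {
    if (is.null(var)) stop_sdc("BAD_ARGUMENT")
    obj[[var]]
  } else obj
  if (!is.numeric(x)) stop_sdc("TYPE_MISMATCH")
  miss <- sum(is.na(x))
  x <- x[!is.na(x)]
  if (length(x) < s$subset_threshold) stop_sdc("SUMMARY_TOO_SMALL")
  structure(list(N = length(x), sum = sum(x), sum_sq = sum(x^2),
                 n_missing = miss, site = session$site),
            class = "summary_share")
}

#' Pool per-site summary shares
#'
#' Pooled mean is the ratio of summed sums to total N; pooled variance uses
#' the one-pass identity `(sum_sq - N * mean^2) / (N - 1)` on the pooled
#' sufficient statistics.
#'
#' @param shares List of `summary_share` objects.
#' @return A list `{mean, variance, N, n_missing}`.
#' @export
pool_summaries <- function(shares) {
  stopifnot(length(shares) >= 1L)
  N <- sum(vapply(shares, `[[`, numeric(1), "N"))
  sm <- sum(vapply(shares, `[[`, numeric(1), "sum"))
  sq <- sum(vapply(shares, `[[`, numeric(1), "sum_sq"))
  miss <- sum(vapply(shares, `[[`, numeric(1), "n_missing"))
  mean <- sm / N
  variance <- if (N > 1) (sq - N * mean^2) / (N - 1) else NA_real_
  list(mean = mean, variance = variance, N = N, n_missing = miss)
}

## ---------------------------------------------------------------------------
## Federated GLM

#' Specify a generalized linear model
#'
#' Canonical-link families only: gaussian (identity), binomial (logit),
#' poisson (log).
#'
#' @param outcome Outcome variable name.
#' @param covariates Character vector of covariate names (numeric variables).
#' @param family `"gaussian"`, `"binomial"` or `"poisson"`.
#' @param intercept Include an intercept? Default `TRUE`.
#' @return An object of class `model_spec` with parameter count `p`.
#' @export
model_spec <- function(outcome, covariates,
                       family = c("gaussian", "binomial", "poisson"),
                       intercept = TRUE) {
  family <- match.arg(family)
  if (outcome %in% covariates) stop_sdc("BAD_ARGUMENT")
  structure(list(outcome = outcome, covariates = covariates,
                 family = family, intercept = isTRUE(intercept),
                 p = length(covariates) + as.integer(isTRUE(intercept))),
            class = "model_spec")
}

#' Parse a `"y ~ x1 + x2"` formula string into a model spec
#'
#' Plain additive formulas only; `-1` or `0` drops the intercept.
#' Interactions and transformations are out of scope.
#'
#' @param formula_string Formula as a string.
#' @param family Family name.
#' @return A [model_spec()].
#' @export
model_spec_from_formula <- function(formula_string, family) {
  parts <- strsplit(formula_string, "~", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop_sdc("BAD_ARGUMENT")
  outcome <- trimws(parts[1])
  rhs <- trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
  intercept <- TRUE
  drop <- rhs %in% c("-1", "0")
  if (any(rhs == "1") && length(rhs) == 1L) rhs <- character(0)
  intercept <- !any(drop)
  rhs <- setdiff(rhs[!drop], "1")
  if (!nzchar(outcome) || any(!nzchar(rhs))) stop_sdc("BAD_ARGUMENT")
  model_spec(outcome, rhs, family, intercept)
}

# Canonical-link family kernels: mean, IRLS weight, unit deviance sum.
family_funs <- function(family) {
  switch(family,
    gaussian = list(
      linkinv = function(eta) eta,
      weight  = function(mu) rep(1, length(mu)),
      deviance = function(y, mu) sum((y - mu)^2)),
    binomial = list(
      linkinv = function(eta) 1 / (1 + exp(-eta)),
      weight  = function(mu) mu * (1 - mu),
      deviance = function(y, mu) {
        t1 <- ifelse(y > 0, y * log(y / mu), 0)
        t2 <- ifelse(y < 1, (1 - y) * log((1 - y) / (1 - mu)), 0)
        2 * sum(t1 + t2)
      }),
    poisson = list(
      linkinv = function(eta) exp(eta),
      weight  = function(mu) mu,
      deviance = function(y, mu) {
        2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
      }),
    stop_sdc("BAD_ARGUMENT"))
}

#' Per-site GLM share: score vector and information matrix
#'
#' At the current estimate `beta`, with `eta = X beta` and
#' `mu = linkinv(eta)`, computes the score `U = X'(y - mu)`, the Fisher
#' information `I = X' diag(w) X` with the canonical weights (gaussian: 1;
#' binomial: `mu(1-mu)`; poisson: `mu`), and the family deviance. These are
#' the only quantities a site contributes to a federated fit.
#'
#' @param X N x p design matrix.
#' @param y Response vector of length N.
#' @param beta Current coefficient estimate of length p.
#' @param family Family name.
#' @return An object of class `glm_share` with fields `U`, `I`, `deviance`,
#'   `N`.
#' @export
glm_share <- function(X, y, beta, family) {
  X <- as.matrix(X)
  if (nrow(X) != length(y) || ncol(X) != length(beta)) stop_sdc("BAD_ARGUMENT")
  ff <- family_funs(family)
  eta <- drop(X %*% beta)
  mu <- ff$linkinv(eta)
  w <- ff$weight(mu)
  structure(list(U = drop(crossprod(X, y - mu)),
                 I = crossprod(X, X * w),
                 deviance = ff$deviance(y, mu),
                 N = nrow(X)),
            class = "glm_share")
}

# Build (X, y) for a model spec from a session's data, complete cases only.
model_matrix_at_site <- function(session, spec, source) {
  vars <- c(spec$outcome, spec$covariates)
  tab <- resolve_source(session, source, vars = vars)
  if (!is.data.frame(tab)) stop_sdc("TYPE_MISMATCH")
  cols <- tab[, vars, drop = FALSE]
  for (v in vars) {
    if (!is.numeric(cols[[v]])) stop_sdc("TYPE_MISMATCH")
  }
  cc <- stats::complete.cases(cols)
  cols <- cols[cc, , drop = FALSE]
  X <- as.matrix(cols[, spec$covariates, drop = FALSE])
  if (spec$intercept) X <- cbind(`(Intercept)` = 1, X)
  list(X = X, y = cols[[spec$outcome]])
}

# Server-side glm share with the per-site dimension filter applied.
site_glm_share <- function(session, spec, beta,
                           s = effective_settings(session),
                           source = session$node$dataset_name) {
  my <- model_matrix_at_site(session, spec, source)
  dec <- check_glm_dimension(spec$p, nrow(my$X), s)
  if (!dec$allowed) stop_sdc("GLM_DIM_BLOCKED")
  glm_share(my$X, my$y, beta, spec$family)
}

#' Fit a generalized linear model across sites without moving data
#'
#' Drives the federated IRLS loop: starting from `beta = 0`, each iteration
#' broadcasts the current estimate, collects per-site score vectors and
#' information matrices, and takes the Newton step
#' `beta <- beta + (sum I)^{-1} (sum U)` until the relative change in total
#' deviance falls below `tol` or `max_iter` is reached. Because the summed
#' shares equal the full-data score and information, the result is the same
#' fit a single pooled analysis would produce. The model-dimension filter
#' must pass at every site against that site's own sample size.
#'
#' The result contains coefficients, standard errors, the covariance matrix,
#' deviance, sample size, and the iteration trace — and deliberately no
#' fitted values, residuals, or linear predictors, which are individual
#' level. Standard errors for the gaussian family use the moment dispersion
#' estimate `deviance / (N - p)`; binomial and poisson use dispersion 1.
#'
#' @param conn A [connect()] connection (or plain list of sessions).
#' @param spec A [model_spec()], or a formula string when `family` is given.
#' @param family Family name (only when `spec` is a formula string).
#' @param tol Relative deviance-change convergence tolerance (default 1e-8).
#' @param max_iter Maximum IRLS iterations (default 25).
#' @param source Source table symbol at each site.
#' @return An object of class `glm_result`.
#' @export
federated_glm <- function(conn, spec, family = NULL, tol = 1e-8,
                          max_iter = 25L, source = NULL) {
  sessions <- if (inherits(conn, "ds_connection")) conn$sessions else conn
  if (is.character(spec)) spec <- model_spec_from_formula(spec, family)
  p <- spec$p

  request_shares <- function(beta) {
    lapply(sessions, function(sess) {
      src <- source %||% sess$node$dataset_name
      r <- ds_request(user = sess$user, fun = "glmShareDS",
                      kind = "aggregate",
                      args = c(list(src,
                                    ds_arg_string(format_spec(spec), "long"),
                                    ds_arg_string(spec$family, "short")),
                               lapply(beta, function(b) list(type = "number",
                                                             value = b))))
      out <- dispatch(sess, r)
      if (inherits(out, "fedsdc_error")) stop(out)
      out
    })
  }

  beta <- rep(0, p)
  dev_old <- Inf
  trace <- list()
  converged <- FALSE
  iterations <- 0L
  shares <- NULL
  for (it in seq_len(max_iter)) {
    iterations <- it
    shares <- request_shares(beta)
    U <- Reduce(`+`, lapply(shares, `[[`, "U"))
    I <- Reduce(`+`, lapply(shares, `[[`, "I"))
    dev <- sum(vapply(shares, `[[`, numeric(1), "deviance"))
    trace[[it]] <- list(iteration = it, beta = beta, deviance = dev)
    step <- tryCatch(solve(I, U), error = function(e) stop_sdc("SINGULAR_INFORMATION"))
    if (is.finite(dev) && abs(dev - dev_old) / (abs(dev) + 0.1) < tol) {
      converged <- TRUE
      break
    }
    beta <- beta + step
    dev_old <- dev
  }

  I_tot <- Reduce(`+`, lapply(shares, `[[`, "I"))
  N_tot <- sum(vapply(shares, `[[`, numeric(1), "N"))
  dev <- sum(vapply(shares, `[[`, numeric(1), "deviance"))
  vcov <- tryCatch(solve(I_tot), error = function(e) stop_sdc("SINGULAR_INFORMATION"))
  if (spec$family == "gaussian") vcov <- vcov * dev / (N_tot - p)
  dimnames(vcov) <- list(coef_names(spec), coef_names(spec))
  structure(list(beta = stats::setNames(beta, coef_names(spec)),
                 se = stats::setNames(sqrt(diag(vcov)), coef_names(spec)),
                 vcov = vcov, deviance = dev, N_total = N_tot,
                 iterations = iterations, converged = converged,
                 family = spec$family, trace = trace),
            class = "glm_result")
}

coef_names <- function(spec) {
  c(if (spec$intercept) "(Intercept)", spec$covariates)
}

format_spec <- function(spec) {
  rhs <- paste(c(if (!spec$intercept) "-1", spec$covariates), collapse = " + ")
  paste(spec$outcome, "~", if (nzchar(rhs)) rhs else "1")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("<federated glm: %s, N = %d, deviance = %.4f, %d iteration(s)%s>\n",
              x$family, x$N_total, x$deviance, x$iterations,
              if (x$converged) "" else ", NOT CONVERGED"))
  print(cbind(estimate = x$beta, std.error = x$se))
  invisible(x)
}
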