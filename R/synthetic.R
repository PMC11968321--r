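## Synthetic multi-site data with known generative parameters, plus the
## pseudonymization helpers recommended for snapshot preparation. The
## generator produces horizontally partitioned cohorts whose pooled
## re-analysis has a known truth, which is what the federated-versus-pooled
## equivalence and parameter-recovery checks rest on. Site heterogeneity is
## intercept-shift only, so the pooled coefficient vector stays the
## estimand.

#' Specify a synthetic multi-site dataset
#'
#' @param sites List of `list(name, n)` per site.
#' @param covariates List of covariate specs:
#'   `list(name, kind = "normal", mu, sd)`,
#'   `list(name, kind = "bernoulli", p)`, or
#'   `list(name, kind = "categorical", levels, probs)`.
#' @param outcome `list(name, family, beta, sigma)`: `family` is
#'   `"gaussian"` (residual sd `sigma`), `"binomial"` or `"poisson"`;
#'   `beta` is the intercept followed by one coefficient per covariate
#'   (categorical covariates contribute through their integer level codes).
#' @param site_shift Optional numeric vector of per-site intercept offsets
#'   (default all zero).
#' @param missing Optional `list(vars, rate)`: the named covariates have a
#'   `rate` fraction of values (at least one per site) set missing
#'   completely at random, emulating item non-response.
#' @param seed Master seed; per-site RNG streams are derived from it, so
#'   adding a site never perturbs the others' data.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(sites, covariates, outcome, site_shift = NULL,
                           missing = NULL, seed = 1L) {
  if (is.null(site_shift)) site_shift <- rep(0, length(sites))
  stopifnot(length(site_shift) == length(sites),
            length(outcome$beta) == length(covariates) + 1L)
  for (st in sites) stopifnot(st$n >= 1L)
  for (cv in covariates) {
    if (identical(cv$kind, "categorical")) {
      stopifnot(length(cv$probs) == length(cv$levels),
                all(cv$probs >= 0), abs(sum(cv$probs) - 1) < 1e-8)
    }
  }
  structure(list(sites = sites, covariates = covariates, outcome = outcome,
                 site_shift = site_shift, missing = missing,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Default three-site logistic study specification
#'
#' The stock study design used throughout the package's own checks: three
#' sites, a standard-normal continuous exposure and a Bernoulli(0.4) binary
#' covariate, logistic outcome with coefficients `(0, 1, -0.5)`
#' (intercept, continuous, binary) and no site shifts.
#'
#' @param n_per_site Integer vector of site sizes (default `c(200, 200,
#'   200)`).
#' @param family Outcome family (default `"binomial"`).
#' @param beta Coefficient vector (intercept first; default `c(0, 1,
#'   -0.5)`).
#' @param sigma Gaussian residual sd (default 1; ignored otherwise).
#' @param site_shift Per-site intercept offsets (default zeros).
#' @param seed Master seed.
#' @return A [synthetic_spec()].
#' @export
default_study_spec <- function(n_per_site = c(200L, 200L, 200L),
                               family = "binomial", beta = c(0, 1, -0.5),
                               sigma = 1, site_shift = NULL, seed = 1L) {
  synthetic_spec(
    sites = lapply(seq_along(n_per_site), function(i) {
      list(name = paste0("site", i), n = n_per_site[i])
    }),
    covariates = list(list(name = "x1", kind = "normal", mu = 0, sd = 1),
                      list(name = "x2", kind = "bernoulli", p = 0.4)),
    outcome = list(name = "y", family = family, beta = beta, sigma = sigma),
    site_shift = site_shift, seed = seed
  )
}

draw_covariate <- function(cv, n) {
  switch(cv$kind,
    normal = stats::rnorm(n, cv$mu, cv$sd),
    bernoulli = stats::rbinom(n, 1L, cv$p),
    categorical = factor(sample(cv$levels, n, replace = TRUE,
                                prob = cv$probs), levels = cv$levels),
    stop_sdc("BAD_ARGUMENT"))
}

covariate_numeric <- function(x) {
  if (is.factor(x)) as.numeric(x) else as.numeric(x)
}

#' Generate horizontally partitioned multi-site datasets
#'
#' Per site: covariates drawn independently per the spec, linear predictor
#' `eta = beta0 + site_shift + sum(beta_j * x_j)`, and outcome drawn from
#' the family (gaussian with mean `eta` and sd `sigma`; binomial with
#' probability `plogis(eta)`; poisson with rate `exp(eta)`). Each site uses
#' its own RNG stream derived from the master seed, so generation is fully
#' reproducible and sites are mutually independent.
#'
#' @param spec A [synthetic_spec()].
#' @return Named list of data frames, one per site.
#' @export
generate_multisite <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  out <- list()
  for (i in seq_along(spec$sites)) {
    st <- spec$sites[[i]]
    out[[st$name]] <- with_seed(derive_seed(spec$seed, i), {
      n <- st$n
      covs <- lapply(spec$covariates, draw_covariate, n = n)
      names(covs) <- vapply(spec$covariates, `[[`, character(1), "name")
      eta <- rep(spec$outcome$beta[1] + spec$site_shift[i], n)
      for (j in seq_along(covs)) {
        eta <- eta + spec$outcome$beta[j + 1L] * covariate_numeric(covs[[j]])
      }
      y <- switch(spec$outcome$family,
        gaussian = stats::rnorm(n, eta, spec$outcome$sigma %||% 1),
        binomial = stats::rbinom(n, 1L, stats::plogis(eta)),
        poisson = stats::rpois(n, exp(eta)),
        stop_sdc("BAD_ARGUMENT"))
      df <- as.data.frame(covs, optional = TRUE)
      df[[spec$outcome$name]] <- y
      if (!is.null(spec$missing)) {
        for (v in spec$missing$vars) {
          m <- max(1L, stats::rbinom(1L, n, spec$missing$rate))
          df[[v]][sample.int(n, m)] <- NA
        }
      }
      df
    })
  }
  out
}

#' Pseudonymize an identifier column with a keyed hash
#'
#' Replaces each identifier with a fixed-length hexadecimal pseudonym
#' computed by a keyed hash, so linkage within a study is deterministic
#' (same id, same key, same pseudonym) while different keys yield unrelated
#' pseudonyms. The linkage map (pseudonym back to original) is returned as a
#' separate object and is never stored alongside the table; it is the
#' custodian's job to keep it apart.
#'
#' @param table A data frame.
#' @param id_column Name of the identifier column.
#' @param key Secret key (non-empty string).
#' @return `list(table, linkage)`: the pseudonymized table and a named
#'   character vector mapping pseudonym to original id.
#' @export
pseudonymize <- function(table, id_column, key) {
  if (!id_column %in% names(table)) stop_sdc("BAD_ARGUMENT")
  if (!is_scalar(key, is.character) || !nzchar(key)) stop_sdc("BAD_ARGUMENT")
  ids <- as.character(table[[id_column]])
  pseud <- keyed_hash(ids, key)
  linkage <- stats::setNames(ids, pseud)
  linkage <- linkage[!duplicated(names(linkage))]
  table[[id_column]] <- pseud
  list(table = table, linkage = linkage)
}

#' Coarsen dates to month or year granularity
#'
#' Reduces the granularity of a date column (e.g. date of birth kept only as
#' month and year) as recommended for snapshot preparation.
#'
#' @param dates Character vector of ISO dates (`"YYYY-MM-DD"`) or `Date`s.
#' @param granularity `"month"` (keep `"YYYY-MM"`) or `"year"` (keep
#'   `"YYYY"`).
#' @return Character vector of coarsened values.
#' @export
coarsen_date <- function(dates, granularity = c("month", "year")) {
  granularity <- match.arg(granularity)
  d <- as.Date(as.character(dates), format = "%Y-%m-%d")
  if (anyNA(d)) stop_sdc("BAD_ARGUMENT")
  format(d, if (granularity == "month") "%Y-%m" else "%Y")
}
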