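## An end-to-end analyst workflow over in-memory nodes: generate data, build
## nodes, connect, and run the standard sequence
## tabulate -> summary -> glm -> obfuscate, collecting every client-bound
## payload. The collected payloads back the payload-hygiene check: nothing
## the client receives may contain a vector as long as any site's row count,
## because such a vector could carry raw individual-level values.

#' Demo study specification
#'
#' Three sites of 120, 80 and 100 participants; a standard-normal exposure
#' `x1`, a Bernoulli(0.4) indicator `x2`, a three-level categorical `grp`
#' (not in the outcome model), and a logistic outcome `y` with coefficients
#' `(0, 1, -0.5)` on `(intercept, x1, x2)`. `x1` and `grp` carry about 3%
#' item non-response, as real cohort snapshots do.
#'
#' @param seed Master seed.
#' @return A [synthetic_spec()].
#' @export
demo_study_spec <- function(seed = 1L) {
  synthetic_spec(
    sites = list(list(name = "alpha", n = 120L),
                 list(name = "beta",  n = 80L),
                 list(name = "gamma", n = 100L)),
    covariates = list(
      list(name = "x1", kind = "normal", mu = 0, sd = 1),
      list(name = "x2", kind = "bernoulli", p = 0.4),
      list(name = "grp", kind = "categorical", levels = c("a", "b", "c"),
           probs = c(0.35, 0.35, 0.30))),
    outcome = list(name = "y", family = "binomial", beta = c(0, 1, -0.5, 0)),
    missing = list(vars = c("x1", "grp"), rate = 0.03),
    seed = seed
  )
}

#' Build connected demo nodes in memory
#'
#' @param seed Master seed for the generated study.
#' @param settings Site disclosure settings (defaults for every site).
#' @return A list with the connection (`conn`), the node list (`nodes`),
#'   per-site row counts (`site_n`) and the generating spec.
#' @export
build_demo_connection <- function(seed = 1L, settings = default_settings()) {
  spec <- demo_study_spec(seed)
  datasets <- generate_multisite(spec)
  nodes <- lapply(names(datasets), function(nm) {
    new_node(name = nm, data = datasets[[nm]],
             accounts = list(list(user = "analyst",
                                  token = paste0("token-", nm))),
             custodian = paste0("custodian-", nm), settings = settings)
  })
  names(nodes) <- names(datasets)
  conn <- connect(lapply(nodes, function(nd) {
    list(node = nd, user = "analyst", token = paste0("token-", nd$name))
  }))
  list(conn = conn, nodes = nodes,
       site_n = vapply(datasets, nrow, integer(1)), spec = spec)
}

#' Run the full demo workflow and collect every client-bound payload
#'
#' Executes, through the client: a 1-dimensional contingency table on
#' `grp`, a univariate summary of `x1`, the federated logistic regression
#' `y ~ x1 + x2`, k-nearest-neighbour obfuscation of `(x1, y)` and
#' Gaussian-noise obfuscation of `x1`. Everything the client receives is
#' collected under a descriptive name for downstream inspection.
#'
#' @param seed Master seed.
#' @return A list: `payloads` (named list of all client-bound objects),
#'   `site_n` (per-site row counts), `glm` (the federated fit), `pooled`
#'   (pooled table and summary).
#' @export
run_demo <- function(seed = 1L) {
  demo <- build_demo_connection(seed)
  conn <- demo$conn
  payloads <- list()
  keep <- function(name, x) payloads[[name]] <<- x

  tab <- aggregate_all(conn, ds_request("analyst", "tableDS", "aggregate",
                                        args = list("D", "grp")))
  keep("table_per_site", tab$per_site)
  keep("table_pooled", tab$pooled)

  sm <- aggregate_all(conn, ds_request("analyst", "summaryDS", "aggregate",
                                       args = list("D", "x1")))
  keep("summary_per_site", sm$per_site)
  keep("summary_pooled", sm$pooled)

  fit <- federated_glm(conn, "y ~ x1 + x2", family = "binomial")
  keep("glm_result", fit)

  knn <- aggregate_all(conn, ds_request("analyst", "scatterKnnDS", "aggregate",
                                        args = list("D", "x1", "y",
                                                    list(type = "number",
                                                         value = 5))))
  keep("knn_per_site", knn$per_site)

  noise <- aggregate_all(conn, ds_request("analyst", "scatterNoiseDS",
                                          "aggregate",
                                          args = list("D", "x1",
                                                      list(type = "number",
                                                           value = 0.25))))
  keep("noise_per_site", noise$per_site)

  st <- show_settings(conn)
  keep("settings", st)

  list(payloads = payloads, site_n = demo$site_n, glm = fit,
       pooled = list(table = tab$pooled, summary = sm$pooled))
}

#' Scan client-bound payloads for site-length vectors
#'
#' Recursively walks a payload structure and reports every atomic vector or
#' matrix dimension whose length equals one of the site row counts — the
#' signature of raw column values having leaked into a client-bound object.
#'
#' @param x Any payload structure.
#' @param site_n Integer vector of site row counts.
#' @param path Internal (position label for reports).
#' @return Character vector of offending positions (empty when clean).
#' @export
scan_payload_hygiene <- function(x, site_n, path = "payload") {
  hits <- character(0)
  if (is.environment(x)) return(hits)
  if (is.atomic(x) && !is.null(x)) {
    if (length(x) %in% site_n) hits <- c(hits, sprintf("%s (length %d)", path, length(x)))
    if (!is.null(dim(x)) && any(dim(x) %in% site_n)) {
      hits <- c(hits, sprintf("%s (dim %s)", path, paste(dim(x), collapse = "x")))
    }
    return(hits)
  }
  if (is.list(x)) {
    nms <- names(x)
    for (i in seq_along(x)) {
      lbl <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
      hits <- c(hits, scan_payload_hygiene(x[[i]], site_n,
                                           paste(path, lbl, sep = "$")))
    }
  }
  hits
}
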