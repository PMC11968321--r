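## The analyst-facing client: connects to several data-holding nodes,
## broadcasts requests, surfaces per-site outcomes with site attribution,
## and pools non-disclosive statistics when every site succeeded.

#' Connect to a set of data-holding nodes
#'
#' All-or-nothing: if any login fails, no sessions are retained and the
#' failing site is named. Duplicate site names are a configuration error.
#'
#' @param configs List of `list(node, user, token)` entries, one per site.
#' @return An object of class `ds_connection` holding one session per site.
#' @export
connect <- function(configs) {
  stopifnot(length(configs) >= 1L)
  sites <- vapply(configs, function(cf) cf$node$name, character(1))
  if (anyDuplicated(sites)) stop_sdc("CONFIG_ERROR")
  sessions <- list()
  for (cf in configs) {
    sess <- tryCatch(login(cf$node, cf$user, cf$token),
                     fedsdc_error = function(e) e)
    if (inherits(sess, "fedsdc_error")) {
      cond <- sdc_error("AUTH_FAILED")
      cond$site <- cf$node$name
      stop(cond)
    }
    sessions[[cf$node$name]] <- sess
  }
  structure(list(sessions = sessions, sites = sites),
            class = "ds_connection")
}

#' @export
print.ds_connection <- function(x, ...) {
  cat(sprintf("<ds_connection: %d site(s): %s>\n", length(x$sites),
              paste(x$sites, collapse = ", ")))
  invisible(x)
}

#' Broadcast an aggregate request and pool the results
#'
#' Dispatches the request to every connected site. The per-site map contains
#' each site's payload or typed error verbatim (error text comes from the
#' fixed catalogue, with site attribution). Pooling is attempted only when
#' every site returned successfully: contingency tables via [pool_tables()],
#' summary shares via [pool_summaries()]; other payload types are returned
#' per site only.
#'
#' @param conn A [connect()] connection.
#' @param r An aggregate [ds_request()].
#' @return A list with `per_site` (map site -> payload/error) and `pooled`
#'   (combined result, or `NULL` when unavailable).
#' @export
aggregate_all <- function(conn, r) {
  if (r$kind != "aggregate") stop_sdc("BAD_ARGUMENT")
  per_site <- lapply(conn$sessions, function(sess) dispatch(sess, r))
  names(per_site) <- conn$sites
  ok <- !vapply(per_site, inherits, logical(1), "fedsdc_error")
  pooled <- NULL
  if (all(ok)) {
    first <- per_site[[1]]
    pooled <- if (inherits(first, "contingency_table")) {
      tryCatch(pool_tables(per_site), fedsdc_error = function(e) e)
    } else if (inherits(first, "summary_share")) {
      pool_summaries(per_site)
    } else NULL
  }
  list(per_site = per_site, pooled = pooled)
}

#' Broadcast an assign request
#'
#' @param conn A [connect()] connection.
#' @param r An assign [ds_request()].
#' @return Map site -> status message or typed error; never values.
#' @export
assign_all <- function(conn, r) {
  if (r$kind != "assign") stop_sdc("BAD_ARGUMENT")
  out <- lapply(conn$sessions, function(sess) dispatch(sess, r))
  names(out) <- conn$sites
  out
}

#' Read each site's active disclosure settings
#'
#' Returns value copies: the analyst can inspect every threshold but
#' mutating the returned objects has no effect on node behaviour.
#'
#' @param conn A [connect()] connection.
#' @return Map site -> `disclosure_settings`.
#' @export
show_settings <- function(conn) {
  out <- lapply(conn$sessions, effective_settings)
  names(out) <- conn$sites
  out
}
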