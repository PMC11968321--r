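## The simulated server-side. A node holds an immutable snapshot dataset,
## authenticates tokens, projects user-specific data views, and dispatches
## validated requests through the full invocation flow:
## authenticate -> parse -> semantic checks -> pre-execution disclosure
## controls -> execute -> post-execution output check. Every dispatch appends
## exactly one audit event, whatever the outcome.

#' Create a data-holding node
#'
#' @param name Site identifier.
#' @param data A data frame: the site's snapshot. Snapshots are read-only;
#'   assign requests create derived objects in per-session workspaces and
#'   never mutate the source.
#' @param accounts List of user accounts, each
#'   `list(user, token, views, profile)`. `views` is a named list mapping
#'   dataset name to the character vector of permitted variables; `profile`
#'   (optional) may carry disclosure-settings overrides (config key names)
#'   that are applied only where at least as strict as the site values.
#' @param custodian Custodian credential for this site (controls log export).
#' @param settings Site-level [default_settings()] object or custodian
#'   overrides already applied via [settings_from_config()].
#' @param dataset_name Symbol under which the snapshot is served (default
#'   `"D"`).
#' @param column_types Optional named character vector overriding inferred
#'   column types (`"numeric"` or `"categorical"`).
#' @param clock Injectable clock for the audit log.
#' @return An object of class `ds_node`.
#' @export
new_node <- function(name, data, accounts, custodian,
                     settings = default_settings(), dataset_name = "D",
                     column_types = NULL, clock = Sys.time) {
  stopifnot(is.data.frame(data))
  v <- validate_settings(settings)
  if (!v$accepted) stop_sdc("CONFIG_ERROR")
  if (!is_scalar(custodian, is.character) || !nzchar(custodian)) {
    stop_sdc("CONFIG_ERROR")
  }
  data <- coerce_columns(data, column_types)

  acct <- list()
  for (a in accounts) {
    if (!nzchar(a$token %||% "")) stop_sdc("CONFIG_ERROR")
    views <- a$views %||% stats::setNames(list(names(data)), dataset_name)
    for (dn in names(views)) {
      if (dn != dataset_name || !all(views[[dn]] %in% names(data))) {
        stop_sdc("CONFIG_ERROR")
      }
    }
    acct[[a$user]] <- list(user = a$user,
                           token_hash = keyed_hash(a$token, "token"),
                           views = views, profile = a$profile %||% NULL)
  }

  node <- new.env(parent = emptyenv())
  node$name <- name
  node$dataset_name <- dataset_name
  node$data <- data
  node$accounts <- acct
  node$custodian_hash <- keyed_hash(custodian, "token")
  node$settings <- settings
  node$registry <- function_registry()
  node$log <- audit_log(clock)
  node$session_counter <- 0L
  class(node) <- "ds_node"
  node
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# All-numeric columns become numeric; everything else is categorical
# (factor). Explicit overrides win.
coerce_columns <- function(data, column_types = NULL) {
  for (nm in names(data)) {
    override <- column_types[[nm]]
    if (identical(override, "numeric")) {
      data[[nm]] <- as.numeric(data[[nm]])
    } else if (identical(override, "categorical")) {
      data[[nm]] <- as.factor(data[[nm]])
    } else if (!is.numeric(data[[nm]])) {
      data[[nm]] <- as.factor(data[[nm]])
    }
  }
  data
}

#' @export
print.ds_node <- function(x, ...) {
  cat(sprintf("<ds_node %s: %d rows, %d columns, %d accounts>\n",
              x$name, nrow(x$data), ncol(x$data), length(x$accounts)))
  invisible(x)
}

#' Authenticate against a node
#'
#' Unknown user and wrong token produce the same `AUTH_FAILED` condition, so
#' the login interface cannot be used to enumerate accounts. Each login
#' creates an independent, initially empty workspace.
#'
#' @param node A [new_node()].
#' @param user,token Credentials.
#' @return An object of class `ds_session`.
#' @export
login <- function(node, user, token) {
  acct <- node$accounts[[user]]
  if (is.null(acct) || !is_scalar(token, is.character) ||
      !identical(keyed_hash(token, "token"), acct$token_hash)) {
    stop_sdc("AUTH_FAILED")
  }
  node$session_counter <- node$session_counter + 1L
  s <- new.env(parent = emptyenv())
  s$user <- user
  s$site <- node$name
  s$node <- node
  s$id <- sprintf("%s-%s-%d", node$name, user, node$session_counter)
  s$workspace <- new.env(parent = emptyenv())
  class(s) <- "ds_session"
  s
}

#' Effective disclosure settings for a session
#'
#' Site-level values, with the user's profile overrides applied only where
#' they are at least as strict as the site's own value (a profile can narrow
#' access, never widen it).
#'
#' @param session A [login()] session.
#' @return A `disclosure_settings` object.
#' @export
effective_settings <- function(session) {
  node <- session$node
  s <- node$settings
  prof <- node$accounts[[session$user]]$profile
  if (is.null(prof)) return(s)
  cand <- settings_from_config(prof)
  stricter <- list(
    tab_threshold = `>=`, subset_threshold = `>=`, glm_ratio = `<=`,
    string_max = `<=`, string_short_max = `<=`, levels_density = `<=`,
    levels_max = `<=`, knn_min = `>=`, noise_min_fraction = `>=`
  )
  for (f in names(stricter)) {
    if (stricter[[f]](cand[[f]], s[[f]])) s[[f]] <- cand[[f]]
  }
  # privacy level: adopt the profile's level only if its blocked set covers
  # the site's (never unblocks anything)
  if (all(blocked_functions(s$privacy_level) %in%
          blocked_functions(cand$privacy_level))) {
    s$privacy_level <- cand$privacy_level
  }
  s
}

#' Project the user's data view of a dataset
#'
#' Access is need-to-know: the projection contains only the variables the
#' user's view permits, with row order preserved.
#'
#' @param session A session.
#' @param dataset Dataset symbol (the node's `dataset_name`).
#' @param vars Optional variables the caller intends to touch; naming one
#'   outside the view raises `VARIABLE_DENIED`.
#' @return A data frame projection.
#' @export
resolve_view <- function(session, dataset, vars = NULL) {
  node <- session$node
  views <- node$accounts[[session$user]]$views
  if (!dataset %in% names(views) || !identical(dataset, node$dataset_name)) {
    stop_sdc("VIEW_DENIED")
  }
  permitted <- views[[dataset]]
  if (!is.null(vars) && !all(vars %in% permitted)) stop_sdc("VARIABLE_DENIED")
  node$data[, permitted, drop = FALSE]
}

# Resolve a source symbol: session workspace first, then the data view.
resolve_source <- function(session, symbol, vars = NULL) {
  if (exists(symbol, envir = session$workspace, inherits = FALSE)) {
    obj <- get(symbol, envir = session$workspace, inherits = FALSE)
    if (is.data.frame(obj) && !is.null(vars) && !all(vars %in% names(obj))) {
      stop_sdc("VARIABLE_DENIED")
    }
    return(obj)
  }
  resolve_view(session, symbol, vars)
}

#' Non-disclosive status message for an assign request
#'
#' Carries only an ok flag, the stored object's class, and whether its
#' dimensions are internally consistent; never any values.
#' @noRd
status_message <- function(ok, class = NA_character_, dims_ok = NA) {
  structure(list(ok = ok, class = class, dims_ok = dims_ok),
            class = "status_message")
}

#' @export
print.status_message <- function(x, ...) {
  cat(sprintf("<status: %s, class=%s, dims_ok=%s>\n",
              if (isTRUE(x$ok)) "ok" else "failed", x$class, x$dims_ok))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Subset predicates: `var op constant`, combinable with & (tighter) and |.

.comp_re <- "^\\s*([A-Za-z._][A-Za-z0-9._]*)\\s*(<=|>=|==|!=|<|>)\\s*('[^']*'|\"[^\"]*\"|[-+]?[A-Za-z0-9._]+)\\s*$"

eval_comparison <- function(tab, comp) {
  m <- regmatches(comp, regexec(.comp_re, comp))[[1]]
  if (length(m) != 4L) stop_sdc("BAD_PREDICATE")
  var <- m[2]; op <- m[3]; lit <- m[4]
  if (!var %in% names(tab)) stop_sdc("UNKNOWN_SYMBOL")
  col <- tab[[var]]
  if (grepl("^['\"]", lit)) lit <- substr(lit, 2, nchar(lit) - 1L)
  num <- suppressWarnings(as.numeric(lit))
  if (is.numeric(col)) {
    if (is.na(num)) stop_sdc("BAD_PREDICATE")
    res <- do.call(op, list(col, num))
  } else {
    if (!op %in% c("==", "!=")) stop_sdc("BAD_PREDICATE")
    res <- do.call(op, list(as.character(col), lit))
  }
  res & !is.na(res)  # missing values never satisfy a predicate
}

eval_predicate <- function(tab, predicate) {
  if (!is_scalar(predicate, is.character) || !nzchar(trimws(predicate))) {
    stop_sdc("BAD_PREDICATE")
  }
  or_terms <- strsplit(predicate, "|", fixed = TRUE)[[1]]
  keep <- rep(FALSE, nrow(tab))
  for (term in or_terms) {
    and_terms <- strsplit(term, "&", fixed = TRUE)[[1]]
    part <- rep(TRUE, nrow(tab))
    for (comp in and_terms) part <- part & eval_comparison(tab, comp)
    keep <- keep | part
  }
  keep
}

#' Create a subset under the subset-size disclosure filter
#'
#' Evaluates a predicate (comparisons of one variable against a constant,
#' combinable with `&` and `|`) over the source table and stores the subset
#' under `target` iff the resulting row count meets the subset threshold.
#' The exact size is recorded in the custodian-side audit metadata but is
#' never revealed to the analyst on failure: the refusal states only that
#' the threshold was not met.
#'
#' @param session A session.
#' @param source Source table symbol (workspace object or data view).
#' @param predicate Predicate string, e.g. `"age > 40 & bmi <= 30"`.
#' @param target Workspace symbol for the subset.
#' @param s Disclosure settings (defaults to the session's effective
#'   settings).
#' @return A status message (ok, class, dims validity); the subset size is
#'   not part of it.
#' @export
assign_subset <- function(session, source, predicate, target,
                          s = effective_settings(session)) {
  tab <- resolve_source(session, source)
  if (!is.data.frame(tab)) stop_sdc("TYPE_MISMATCH")
  keep <- eval_predicate(tab, predicate)
  sub <- tab[keep, , drop = FALSE]
  dec <- check_subset_size(nrow(sub), s)
  if (!dec$allowed) stop_sdc("SUBSET_TOO_SMALL")
  assign(target, sub, envir = session$workspace)
  status_message(TRUE, class = "data.frame", dims_ok = TRUE)
}

## ---------------------------------------------------------------------------
## Dispatch: the single entry point for analyst requests.

#' Dispatch a request through the full invocation flow
#'
#' Runs the complete server-side pipeline: syntactic validation against the
#' registry and active privacy level, semantic checks (symbols exist, types
#' match), pre-execution disclosure controls, execution, and post-execution
#' output checks. Aggregate requests return a non-disclosive payload; assign
#' requests store their result in the session workspace and return a status
#' message carrying no values. Every stage failure is returned as a typed
#' error value whose message comes from a fixed catalogue. Exactly one audit
#' event is appended per dispatch, whatever the outcome.
#'
#' @param session A [login()] session.
#' @param r A [ds_request()].
#' @return An aggregate payload, a status message, or a typed error object
#'   (class `fedsdc_error`); never an unhandled failure.
#' @export
dispatch <- function(session, r) {
  node <- session$node
  s <- effective_settings(session)
  meta <- list()
  outcome <- "executed"

  result <- tryCatch({
    verdict <- parse_and_validate(r, node$registry, s)
    if (!verdict$accepted) {
      codes <- vapply(verdict$reasons, `[[`, character(1), "code")
      stop_sdc(codes[[1]])
    }
    entry <- node$registry[node$registry$name == r$fun, ]
    if (!entry$implemented) stop_sdc("NOT_IMPLEMENTED")
    exec <- execute_request(session, r, s)
    meta <- exec$meta
    exec$payload
  },
  fedsdc_error = function(e) {
    outcome <<- paste0(if (e$code %in% c("SUBSET_TOO_SMALL", "TABLE_SUPPRESSED",
                                         "LEVELS_BLOCKED", "GLM_DIM_BLOCKED",
                                         "KNN_BLOCKED", "NOISE_BLOCKED",
                                         "SUMMARY_TOO_SMALL",
                                         "BLOCKED_BY_PRIVACY_LEVEL"))
                         "blocked:" else "error:", e$code)
    e
  },
  error = function(e) {
    outcome <<- "error:INTERNAL"
    sdc_error("BAD_ARGUMENT")
  })

  if (outcome == "executed" && !inherits(result, "fedsdc_error")) {
    meta <- c(meta, list(source = request_source(r), target = r$target))
  }
  audit_record(node$log, user = session$user, site = node$name,
               fun = r$fun, kind = r$kind, outcome = outcome,
               args = r$args, session_id = session$id, meta = meta)
  result
}

# The source symbol of a request is by convention its first symbol argument.
request_source <- function(r) {
  for (a in r$args) if (identical(a$type, "symbol")) return(a$value)
  NA_character_
}

arg_values <- function(r, type) {
  vals <- lapply(Filter(function(a) identical(a$type, type), r$args),
                 `[[`, "value")
  unlist(vals, use.names = FALSE)
}

# Execute an already-validated request. Returns list(payload, meta).
execute_request <- function(session, r, s) {
  syms <- arg_values(r, "symbol")
  switch(r$fun,
    tableDS = {
      if (length(syms) < 2L) stop_sdc("BAD_ARGUMENT")
      tbl <- site_contingency(session, syms[-1], s, source = syms[1])
      list(payload = tbl,
           meta = list(table_dims = tbl$dims,
                       suppressed = tbl$suppressed))
    },
    summaryDS = {
      sh <- site_summary(session, var = if (length(syms) > 1L) syms[2] else NULL,
                         s, source = syms[1])
      list(payload = sh, meta = list(n = sh$N))
    },
    levelsDS = {
      if (length(syms) < 2L) stop_sdc("BAD_ARGUMENT")
      tab <- resolve_source(session, syms[1], vars = syms[2])
      col <- tab[[syms[2]]]
      if (is.numeric(col)) stop_sdc("TYPE_MISMATCH")
      lev <- levels(as.factor(col))
      dec <- check_levels(length(lev), length(col), s)
      if (!dec$allowed) stop_sdc("LEVELS_BLOCKED")
      list(payload = list(variable = syms[2], levels = lev),
           meta = list(n_levels = length(lev)))
    },
    glmShareDS = {
      strs <- arg_values(r, "string")
      if (length(syms) < 1L || length(strs) < 2L) stop_sdc("BAD_ARGUMENT")
      spec <- model_spec_from_formula(strs[1], strs[2])
      beta <- arg_values(r, "number")
      if (length(beta) == 0L) beta <- rep(0, spec$p)
      sh <- site_glm_share(session, spec, beta, s, source = syms[1])
      list(payload = sh, meta = list(p = spec$p, n = sh$N))
    },
    scatterKnnDS = {
      nums <- arg_values(r, "number")
      if (length(syms) < 2L || length(nums) < 1L) stop_sdc("BAD_ARGUMENT")
      vars <- syms[-1]
      tab <- resolve_source(session, syms[1], vars = vars)
      pts <- as.matrix(tab[stats::complete.cases(tab[, vars, drop = FALSE]),
                           vars, drop = FALSE])
      if (!is.numeric(pts)) stop_sdc("TYPE_MISMATCH")
      obf <- knn_centroid_obfuscate(pts, k = as.integer(nums[1]), s = s)
      list(payload = obf, meta = list(k = as.integer(nums[1]), n = nrow(pts)))
    },
    scatterNoiseDS = {
      nums <- arg_values(r, "number")
      if (length(syms) < 2L || length(nums) < 1L) stop_sdc("BAD_ARGUMENT")
      tab <- resolve_source(session, syms[1], vars = syms[2])
      x <- tab[[syms[2]]]
      if (!is.numeric(x)) stop_sdc("TYPE_MISMATCH")
      x <- x[!is.na(x)]
      # analyst-chosen seeds enable noise-subtraction attacks: honour one
      # only when the active level does not block seed control
      seed_allowed <- !"setSeedDS" %in% blocked_functions(s$privacy_level)
      analyst_seed <- if (length(nums) > 1L) nums[2] else NULL
      seed <- if (seed_allowed && !is.null(analyst_seed)) analyst_seed
              else sample.int(2147483646L, 1L)
      obf <- gaussian_noise_obfuscate(x, noise_fraction = nums[1],
                                      seed = seed, s = s)
      list(payload = obf,
           meta = list(n = length(x), seed = seed,
                       analyst_seed_used = seed_allowed && !is.null(analyst_seed)))
    },
    setSeedDS = {
      nums <- arg_values(r, "number")
      if (length(nums) < 1L) stop_sdc("BAD_ARGUMENT")
      assign(".seed", as.integer(nums[1]), envir = session$workspace)
      list(payload = list(ok = TRUE), meta = list())
    },
    subsetDS = {
      strs <- arg_values(r, "string")
      if (length(syms) < 1L || length(strs) < 1L) stop_sdc("BAD_ARGUMENT")
      tab <- resolve_source(session, syms[1])
      if (!is.data.frame(tab)) stop_sdc("TYPE_MISMATCH")
      keep <- eval_predicate(tab, strs[1])
      sub <- tab[keep, , drop = FALSE]
      dec <- check_subset_size(nrow(sub), s)
      if (!dec$allowed) stop_sdc("SUBSET_TOO_SMALL")
      assign(r$target, sub, envir = session$workspace)
      list(payload = status_message(TRUE, "data.frame", TRUE),
           meta = list(subset_size = nrow(sub), parent_size = nrow(tab)))
    },
    asNumericDS = ,
    asFactorDS = {
      if (length(syms) < 2L) stop_sdc("BAD_ARGUMENT")
      tab <- resolve_source(session, syms[1], vars = syms[2])
      col <- tab[[syms[2]]]
      out <- if (r$fun == "asNumericDS") {
        suppressWarnings(as.numeric(as.character(col)))
      } else as.factor(col)
      assign(r$target, out, envir = session$workspace)
      list(payload = status_message(TRUE, class(out)[1],
                                    dims_ok = length(out) == length(col)),
           meta = list())
    },
    stop_sdc("NOT_IMPLEMENTED")
  )
}
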