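#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Run code with a temporarily seeded RNG, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed; stays below 2^31
#' @noRd
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483629
}

#' Keyed MD5 hash of a character vector, fixed-length lowercase hex
#'
#' Hashes `key || ":" || x` per element via [tools::md5sum()] on a scratch
#' file. Used for token storage and pseudonymization; the key never appears
#' in the output.
#' @noRd
keyed_hash <- function(x, key) {
  stopifnot(is.character(key), length(key) == 1L, nzchar(key))
  vapply(as.character(x), function(v) {
    f <- tempfile()
    on.exit(unlink(f), add = TRUE)
    writeBin(charToRaw(paste0(key, ":", v)), f)
    unname(tools::md5sum(f))
  }, character(1), USE.NAMES = FALSE)
}

#' Short digest of a request's arguments for the audit trail
#' @noRd
args_digest <- function(args) {
  flat <- vapply(args, function(a) paste(a$type, a$value, sep = "="), character(1))
  substr(keyed_hash(paste(flat, collapse = "|"), "audit"), 1, 12)
}

#' Typed condition used for every server-side refusal
#'
#' Message text comes from a fixed catalogue keyed by `code`: no data values
#' are ever interpolated, so an error message cannot leak microdata.
#' @noRd
sdc_error <- function(code, class = "fedsdc_error") {
  msg <- error_catalogue[[code]]
  if (is.null(msg)) msg <- "request refused"
  structure(
    class = c(code, class, "error", "condition"),
    list(message = msg, call = NULL, code = code)
  )
}

error_catalogue <- list(
  AUTH_FAILED          = "authentication failed",
  VIEW_DENIED          = "no data view grants access to the requested dataset",
  VARIABLE_DENIED      = "a requested variable is outside the permitted data view",
  UNKNOWN_FUNCTION     = "the requested function is not in the server registry",
  BLOCKED_BY_PRIVACY_LEVEL = "the requested function is blocked by the active privacy control level",
  KIND_MISMATCH        = "the request kind does not match the registered function kind",
  NOT_IMPLEMENTED      = "the requested function is registered but not executable",
  STRING_TOO_LONG      = "a string argument exceeds the permitted length",
  FORBIDDEN_CHARACTER  = "a string argument contains a character outside the permitted set",
  MISSING_TARGET       = "an assign request must name a target symbol",
  UNEXPECTED_TARGET    = "an aggregate request must not name a target symbol",
  UNKNOWN_SYMBOL       = "a named server-side object does not exist",
  TYPE_MISMATCH        = "a server-side object has an incompatible type for this request",
  BAD_PREDICATE        = "the subset predicate is not in the supported comparison grammar",
  SUBSET_TOO_SMALL     = "the requested subset does not meet the minimum row threshold",
  SUMMARY_TOO_SMALL    = "the variable has too few complete observations for a summary",
  TABLE_SUPPRESSED     = "the contingency table was suppressed by the cell-count rule",
  LEVELS_BLOCKED       = "the number of category levels exceeds the permitted bounds",
  GLM_DIM_BLOCKED      = "the model dimension filter blocked the regression request",
  SINGULAR_INFORMATION = "the pooled information matrix is singular",
  NOT_CONVERGED        = "the iterative fit did not converge within the iteration limit",
  KNN_BLOCKED          = "the neighbour count is below the permitted minimum",
  KNN_INFEASIBLE       = "the neighbour count exceeds the number of points",
  NOISE_BLOCKED        = "the noise variance fraction is below the permitted minimum",
  POOL_BLOCKED         = "pooling is blocked because at least one site withheld its share",
  ACCESS_DENIED        = "only the data custodian may perform this operation",
  CONFIG_ERROR         = "the site or connection configuration is invalid",
  DIM_TOO_HIGH         = "contingency tables support at most three dimensions",
  BAD_ARGUMENT         = "a request argument is malformed"
)

#' Stop with a typed, catalogue-backed condition
#' @noRd
stop_sdc <- function(code) stop(sdc_error(code))

#' Is `x` a single non-missing value of the given predicate?
#' @noRd
is_scalar <- function(x, pred) length(x) == 1L && !is.na(x) && pred(x)

is_count  <- function(x) is_scalar(x, function(v) is.numeric(v) && v >= 0 && v == floor(v))
is_pos_count <- function(x) is_count(x) && x >= 1
is_unit_open <- function(x) is_scalar(x, is.numeric) && x > 0 && x < 1
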