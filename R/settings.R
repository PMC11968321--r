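## Disclosure-control settings, privacy control levels, and the server-side
## function registry. Every filter decision in the package is governed by the
## parameter vector defined here; custodians may override values site by site,
## analysts may read but never write them.

#' Default disclosure-control settings
#'
#' Returns the parameter vector that governs every disclosure filter on a
#' data-holding node. Field semantics:
#'
#' * `tab_threshold` — minimum count permitted in a *non-empty* contingency
#'   cell (config key `nfilter.tab`). A table containing a smaller positive
#'   cell is suppressed. A value of 1 disables the rule; 0 is also accepted
#'   (the field is a non-negative integer).
#' * `subset_threshold` — minimum number of rows a derived subset may have
#'   (`nfilter.subset`; positive integer).
#' * `glm_ratio` — maximum number of regression parameters as a fraction of a
#'   site's sample size (`nfilter.glm`; in (0,1)).
#' * `string_max`, `string_short_max` — maximum length of long (formula /
#'   predicate) and short (name) string arguments (`nfilter.string`,
#'   `nfilter.stringShort`).
#' * `levels_density`, `levels_max` — bounds on how many unique levels of a
#'   categorical variable may be returned: more than `levels_density * N`
#'   levels, or more than `levels_max` levels, blocks the request
#'   (`nfilter.levels.density`, `nfilter.levels.max`).
#' * `knn_min` — minimum neighbourhood size for k-nearest-neighbour centroid
#'   obfuscation (`nfilter.kNN`).
#' * `noise_min_fraction` — minimum variance of obfuscating Gaussian noise as
#'   a fraction of the variable's sample variance (`nfilter.noise`).
#' * `privacy_level` — one of `"permissive"`, `"non-permissive"`,
#'   `"avocado"`, `"banana"`; selects a predefined set of blocked server-side
#'   functions (see [blocked_functions()]).
#'
#' @return An object of class `disclosure_settings`.
#' @examples
#' s <- default_settings()
#' s$tab_threshold   # 3
#' s$privacy_level   # "banana"
#' @export
default_settings <- function() {
  structure(list(
    tab_threshold      = 3L,
    subset_threshold   = 3L,
    glm_ratio          = 0.33,
    string_max         = 80L,
    string_short_max   = 20L,
    levels_density     = 0.33,
    levels_max         = 40L,
    knn_min            = 3L,
    noise_min_fraction = 0.25,
    privacy_level      = "banana"
  ), class = "disclosure_settings")
}

#' @export
print.disclosure_settings <- function(x, ...) {
  cat("<disclosure_settings>\n")
  for (nm in names(unclass(x))) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

PRIVACY_LEVELS <- c("permissive", "non-permissive", "avocado", "banana")

# Blocked-function lists per privacy control level. The avocado list blocks
# functions usable for subsetting/difference attacks; the banana list blocks
# functions usable for inference attacks (seeded random draws, sequence
# generation); non-permissive blocks both families plus repDS.
.blocked_lists <- list(
  "permissive" = character(0),
  "banana" = c("cDS", "dmtC2SDS", "rBinomDS", "rNormDS", "rPoisDS",
               "rUnifDS", "seqDS", "setSeedDS"),
  "avocado" = c("BooleDS", "cbindDS", "dataFrameDS", "dataFrameSortDS",
                "dataFrameSubsetDS1", "dataFrameSubsetDS2", "levelsDS",
                "rbindDS", "recodeLevelsDS", "recodeValuesDS", "reShapeDS",
                "subsetByClassDS", "subsetDS", "vectorDS"),
  "non-permissive" = c("BooleDS", "cbindDS", "cDS", "dataFrameDS",
                       "dataFrameSortDS", "dataFrameSubsetDS1",
                       "dataFrameSubsetDS2", "dmtC2SDS", "levelsDS",
                       "rbindDS", "rBinomDS", "recodeLevelsDS",
                       "recodeValuesDS", "repDS", "reShapeDS", "rNormDS",
                       "rPoisDS", "rUnifDS", "seqDS", "setSeedDS",
                       "subsetByClassDS", "subsetDS", "vectorDS")
)

#' Functions blocked under a privacy control level
#'
#' @param level One of `"permissive"`, `"non-permissive"`, `"avocado"`,
#'   `"banana"`.
#' @return Character vector of blocked server-side function names
#'   (empty for `"permissive"`).
#' @examples
#' blocked_functions("permissive")  # character(0)
#' "setSeedDS" %in% blocked_functions("banana")
#' @export
blocked_functions <- function(level) {
  if (!is_scalar(level, is.character) || !level %in% PRIVACY_LEVELS) {
    stop_sdc("BAD_ARGUMENT")
  }
  .blocked_lists[[level]]
}

#' Server-side function registry
#'
#' Maps each server-side function name to its kind (`assign` or `aggregate`)
#' and whether this package implements it. Every name appearing in any
#' privacy-level blocked list is registered (as an executable function or a
#' stub), so a block is always resolvable against the registry.
#'
#' @return A data frame with columns `name`, `kind`, `implemented`.
#' @export
function_registry <- function() {
  reg <- rbind(
    # executable functions provided by this package
    data.frame(name = "tableDS",        kind = "aggregate", implemented = TRUE),
    data.frame(name = "summaryDS",      kind = "aggregate", implemented = TRUE),
    data.frame(name = "glmShareDS",     kind = "aggregate", implemented = TRUE),
    data.frame(name = "levelsDS",       kind = "aggregate", implemented = TRUE),
    data.frame(name = "scatterKnnDS",   kind = "aggregate", implemented = TRUE),
    data.frame(name = "scatterNoiseDS", kind = "aggregate", implemented = TRUE),
    data.frame(name = "setSeedDS",      kind = "aggregate", implemented = TRUE),
    data.frame(name = "subsetDS",       kind = "assign",    implemented = TRUE),
    data.frame(name = "asNumericDS",    kind = "assign",    implemented = TRUE),
    data.frame(name = "asFactorDS",     kind = "assign",    implemented = TRUE),
    # registered stubs: resolvable (and blockable) but not executable here
    data.frame(name = c("BooleDS", "cbindDS", "cDS", "dataFrameDS",
                        "dataFrameSortDS", "dataFrameSubsetDS1",
                        "dataFrameSubsetDS2", "dmtC2SDS", "rbindDS",
                        "rBinomDS", "recodeLevelsDS", "recodeValuesDS",
                        "repDS", "reShapeDS", "rNormDS", "rPoisDS",
                        "rUnifDS", "seqDS", "subsetByClassDS", "vectorDS"),
               kind = c("aggregate", "assign", "assign", "assign",
                        "assign", "assign",
                        "assign", "aggregate", "assign",
                        "assign", "assign", "assign",
                        "assign", "assign", "assign", "assign",
                        "assign", "assign", "assign", "aggregate"),
               implemented = FALSE)
  )
  rownames(reg) <- NULL
  reg
}

#' Validate a disclosure-settings object
#'
#' Checks every field against its permitted domain: `tab_threshold` may be
#' any non-negative integer; `subset_threshold`, `string_max`,
#' `string_short_max`, `levels_max` and `knn_min` must be positive integers;
#' `glm_ratio` and `levels_density` must lie strictly in (0, 1);
#' `noise_min_fraction` must be positive; `privacy_level` must be a known
#' mode. All violations are reported, not just the first.
#'
#' @param s A `disclosure_settings` object (or plain named list).
#' @return A list with `accepted` (logical) and `violations` (character
#'   vector of offending field names, empty when accepted).
#' @export
validate_settings <- function(s) {
  bad <- character(0)
  chk <- function(field, ok) if (!isTRUE(ok)) bad <<- c(bad, field)
  chk("tab_threshold",      is_count(s$tab_threshold))
  chk("subset_threshold",   is_pos_count(s$subset_threshold))
  chk("glm_ratio",          is_unit_open(s$glm_ratio))
  chk("string_max",         is_pos_count(s$string_max))
  chk("string_short_max",   is_pos_count(s$string_short_max))
  chk("levels_density",     is_unit_open(s$levels_density))
  chk("levels_max",         is_pos_count(s$levels_max))
  chk("knn_min",            is_pos_count(s$knn_min))
  chk("noise_min_fraction", is_scalar(s$noise_min_fraction, is.numeric) &&
                            s$noise_min_fraction > 0)
  chk("privacy_level",      is_scalar(s$privacy_level, is.character) &&
                            s$privacy_level %in% PRIVACY_LEVELS)
  list(accepted = length(bad) == 0L, violations = bad)
}

# Mapping between settings fields and the config-file key names understood in
# the `disclosure:` block of a site configuration.
.settings_keys <- c(
  tab_threshold      = "nfilter.tab",
  subset_threshold   = "nfilter.subset",
  glm_ratio          = "nfilter.glm",
  string_max         = "nfilter.string",
  string_short_max   = "nfilter.stringShort",
  levels_density     = "nfilter.levels.density",
  levels_max         = "nfilter.levels.max",
  knn_min            = "nfilter.kNN",
  noise_min_fraction = "nfilter.noise",
  privacy_level      = "datashield.privacyControlLevel"
)

#' Serialize settings to the config-file key set
#'
#' @param s A `disclosure_settings` object.
#' @return A named list using the `nfilter.*` /
#'   `datashield.privacyControlLevel` key names.
#' @seealso [settings_from_config()]
#' @export
settings_to_config <- function(s) {
  out <- lapply(names(.settings_keys), function(f) s[[f]])
  names(out) <- unname(.settings_keys)
  out
}

#' Build settings from a config-file `disclosure:` block
#'
#' Starts from [default_settings()] and applies custodian overrides. Unknown
#' keys or overrides that fail [validate_settings()] are configuration errors
#' and abort (a node never silently falls back to defaults).
#'
#' @param overrides Named list using the `nfilter.*` key names; may be `NULL`
#'   or empty for pure defaults.
#' @return A validated `disclosure_settings` object.
#' @export
settings_from_config <- function(overrides = NULL) {
  s <- default_settings()
  if (length(overrides)) {
    if (is.null(names(overrides)) || !all(names(overrides) %in% .settings_keys)) {
      stop_sdc("CONFIG_ERROR")
    }
    for (key in names(overrides)) {
      field <- names(.settings_keys)[.settings_keys == key]
      value <- overrides[[key]]
      s[[field]] <- if (field %in% c("glm_ratio", "levels_density",
                                     "noise_min_fraction")) {
        as.numeric(value)
      } else if (field == "privacy_level") {
        as.character(value)
      } else {
        as.integer(value)
      }
    }
  }
  v <- validate_settings(s)
  if (!v$accepted) stop_sdc("CONFIG_ERROR")
  s
}
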