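## Site and connection configuration files (YAML or JSON). A site config
## declares the snapshot CSV, the accounts with their data views, the
## custodian credential, and a `disclosure:` block of custodian overrides
## using the canonical parameter key names. Invalid overrides abort node
## construction: a node never starts on silently-degraded settings.

read_config_file <- function(path) {
  if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Build a data-holding node from a site configuration file
#'
#' Expected keys: `site` (name), `data` (CSV path, header row, column types
#' inferred as all-numeric -> numeric else categorical, with optional
#' `column_types` overrides), `custodian` (credential), `accounts` (list of
#' `{user, token, views, profile}`), and an optional `disclosure:` block
#' with `nfilter.*` / `datashield.privacyControlLevel` overrides.
#'
#' @param path Path to a YAML or JSON site config.
#' @param base_dir Directory against which a relative `data` path is
#'   resolved (defaults to the config's directory).
#' @return A [new_node()].
#' @export
node_from_config <- function(path, base_dir = dirname(path)) {
  cfg <- read_config_file(path)
  for (field in c("site", "data", "custodian", "accounts")) {
    if (is.null(cfg[[field]])) stop_sdc("CONFIG_ERROR")
  }
  data_path <- cfg$data
  if (!file.exists(data_path)) data_path <- file.path(base_dir, cfg$data)
  if (!file.exists(data_path)) stop_sdc("CONFIG_ERROR")
  data <- utils::read.csv(data_path, stringsAsFactors = FALSE)
  settings <- settings_from_config(cfg$disclosure)
  accounts <- lapply(cfg$accounts, function(a) {
    list(user = a$user, token = a$token,
         views = lapply(a$views, unlist), profile = a$profile)
  })
  new_node(name = cfg$site, data = data, accounts = accounts,
           custodian = cfg$custodian, settings = settings,
           dataset_name = cfg$dataset_name %||% "D",
           column_types = cfg$column_types)
}

#' Write example site data and configuration files
#'
#' Generates the stock demo study ([demo_study_spec()]), writes one CSV per
#' site, one site config (YAML) per site, a connection config listing all
#' sites, and a JSON sidecar recording the generating spec and seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed for the generated data.
#' @return Invisibly, a list with the connection-config path and per-site
#'   config paths.
#' @export
write_example_configs <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- demo_study_spec(seed)
  datasets <- generate_multisite(spec)
  site_cfgs <- character(0)
  conn <- list()
  for (nm in names(datasets)) {
    csv <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(datasets[[nm]], csv, row.names = FALSE)
    cfg <- list(
      site = nm,
      data = basename(csv),
      dataset_name = "D",
      custodian = paste0("custodian-", nm),
      accounts = list(list(
        user = "analyst", token = paste0("token-", nm),
        views = list(D = as.list(names(datasets[[nm]]))))),
      disclosure = list(`datashield.privacyControlLevel` = "banana")
    )
    cfg_path <- file.path(dir, paste0(nm, ".yaml"))
    yaml::write_yaml(cfg, cfg_path)
    site_cfgs <- c(site_cfgs, cfg_path)
    conn[[length(conn) + 1L]] <- list(site = nm, config = basename(cfg_path),
                                      user = "analyst",
                                      token = paste0("token-", nm))
  }
  conn_path <- file.path(dir, "connection.yaml")
  yaml::write_yaml(list(sites = conn), conn_path)
  jsonlite::write_json(
    list(seed = spec$seed,
         sites = spec$sites,
         beta = spec$outcome$beta,
         family = spec$outcome$family),
    file.path(dir, "spec.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(connection = conn_path, sites = site_cfgs))
}

#' Open a connection from a connection configuration file
#'
#' The file lists `sites:` entries `{site, config, user, token}`; each
#' site's node is built via [node_from_config()] and logged into.
#'
#' @param path Path to the connection config (YAML or JSON).
#' @return A [connect()] connection.
#' @export
connect_from_config <- function(path) {
  cfg <- read_config_file(path)
  if (is.null(cfg$sites)) stop_sdc("CONFIG_ERROR")
  base <- dirname(path)
  configs <- lapply(cfg$sites, function(e) {
    cfg_path <- e$config
    if (!file.exists(cfg_path)) cfg_path <- file.path(base, e$config)
    list(node = node_from_config(cfg_path), user = e$user, token = e$token)
  })
  connect(configs)
}
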