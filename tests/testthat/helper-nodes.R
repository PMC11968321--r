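# Shared builders: all fixtures are constructed in code at test time.

fixed_clock <- function() as.POSIXct("2026-01-01 12:00:00", tz = "UTC")

# Settings with field overrides, for boundary cases.
within_list <- function(s, ...) {
  mods <- list(...)
  for (nm in names(mods)) s[[nm]] <- mods[[nm]]
  s
}

# A small mixed-type site: numeric age/bmi, categorical smoker/town.
tiny_data <- function(n = 10) {
  data.frame(
    age = c(34, 45, 52, 29, 61, 41, 38, 55, 47, 33)[seq_len(n)],
    bmi = c(22, 27, 31, 24, 29, 26, 23, 33, 28, 25)[seq_len(n)],
    smoker = factor(c("no", "yes", "yes", "no", "no",
                      "yes", "no", "no", "yes", "no")[seq_len(n)]),
    town = factor(rep(c("north", "south"), length.out = n))
  )
}

tiny_node <- function(data = tiny_data(), settings = default_settings(),
                      accounts = NULL, name = "siteA") {
  if (is.null(accounts)) {
    accounts <- list(list(user = "ana", token = "tok-ana"))
  }
  new_node(name, data, accounts = accounts, custodian = "cust-secret",
           settings = settings, clock = fixed_clock)
}

tiny_session <- function(...) {
  nd <- tiny_node(...)
  login(nd, "ana", "tok-ana")
}

# Connection over generated multi-site data for a synthetic spec.
study_connection <- function(spec, settings = default_settings()) {
  dats <- generate_multisite(spec)
  nodes <- lapply(names(dats), function(nm) {
    new_node(nm, dats[[nm]],
             accounts = list(list(user = "ana", token = paste0("t-", nm))),
             custodian = paste0("c-", nm), settings = settings,
             clock = fixed_clock)
  })
  connect(lapply(nodes, function(nd) {
    list(node = nd, user = "ana", token = paste0("t-", nd$name))
  }))
}

# Deterministic analyst workload; see fedsdc::simulate_workload().
run_workload <- function(seed, attack) simulate_workload(seed, attack)
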