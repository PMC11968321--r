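test_that("the log is append-only with strictly increasing sequence numbers", {
  log <- audit_log(clock = fixed_clock)
  expect_identical(audit_length(log), 0L)
  audit_record(log, "u", "s", "tableDS", "aggregate", "executed")
  expect_identical(audit_length(log), 1L)
  audit_record(log, "u", "s", "summaryDS", "aggregate", "executed")
  seqs <- vapply(audit_events(log), `[[`, integer(1), "seq")
  expect_identical(seqs, c(1L, 2L))

  # events read out are copies: editing them does not touch the log
  ev <- audit_events(log)
  ev[[1]]$outcome <- "tampered"
  expect_identical(audit_events(log)[[1]]$outcome, "executed")
})

test_that("log export is custodian-only and round-trips through NDJSON", {
  nd <- tiny_node()
  sess <- login(nd, "ana", "tok-ana")
  dispatch(sess, ds_request("ana", "tableDS", "aggregate",
                            args = list("D", "smoker")))
  expect_error(export_log(nd, "tok-ana"), class = "ACCESS_DENIED")
  ev <- export_log(nd, "cust-secret")
  expect_length(ev, 1L)

  nd2 <- tiny_node()
  expect_identical(export_log(nd2, "cust-secret"), list())

  txt <- export_log(nd, "cust-secret", format = "ndjson")
  back <- read_log_ndjson(txt)
  expect_length(back, 1L)
  expect_identical(back[[1]]$fun, "tableDS")
  expect_identical(back[[1]]$meta$source, "D")
})

test_that("a one-row-difference pair of queried subsets raises one alert", {
  events <- run_workload(seed = 1, attack = TRUE)
  alerts <- detect_difference_attacks(events)
  expect_length(alerts, 1L)
  expect_identical(alerts[[1]]$type, "difference_attack")
  expect_length(alerts[[1]]$events, 4L)
  expect_identical(alerts[[1]]$events,
                   sort(vapply(events, `[[`, integer(1), "seq")))
})

test_that("subsets with larger gaps or unqueried subsets raise no alert", {
  expect_length(detect_difference_attacks(run_workload(2, attack = FALSE)), 0)
  expect_length(detect_difference_attacks(list()), 0)

  # one-row difference but no aggregate follow-up: not an attack signature
  nd <- new_node("w", data.frame(v = as.numeric(1:40)),
                 accounts = list(list(user = "u", token = "t")),
                 custodian = "c", clock = fixed_clock)
  sess <- login(nd, "u", "t")
  for (m in c(10L, 11L)) {
    dispatch(sess, ds_request("u", "subsetDS", "assign",
                              args = list("D", ds_arg_string(
                                paste("v <=", m), "long")),
                              target = paste0("s", m)))
  }
  expect_length(detect_difference_attacks(audit_events(nd$log)), 0)
})

test_that("the difference detector is sound and complete over seeded workloads", {
  benign_alerts <- vapply(1:30, function(sd_) {
    length(detect_difference_attacks(run_workload(sd_, attack = FALSE)))
  }, integer(1))
  attack_alerts <- vapply(1:30, function(sd_) {
    length(detect_difference_attacks(run_workload(sd_, attack = TRUE)))
  }, integer(1))
  expect_identical(sum(benign_alerts), 0L)
  expect_true(all(attack_alerts >= 1L))
})

test_that("seed-setting before noise obfuscation is flagged, even when blocked", {
  nd <- tiny_node()  # banana: setSeedDS blocked
  sess <- login(nd, "ana", "tok-ana")
  out <- dispatch(sess, ds_request("ana", "setSeedDS", "aggregate",
                                   args = list(list(type = "number", value = 7))))
  expect_s3_class(out, "fedsdc_error")
  dispatch(sess, ds_request("ana", "scatterNoiseDS", "aggregate",
                            args = list("D", "age",
                                        list(type = "number", value = 0.3))))
  alerts <- detect_seed_abuse(audit_events(nd$log))
  expect_length(alerts, 1L)
  expect_identical(alerts[[1]]$events, c(1L, 2L))

  # an executed seed request under permissive is still an advisory alert
  perm <- within_list(default_settings(), privacy_level = "permissive")
  nd2 <- tiny_node(settings = perm)
  sess2 <- login(nd2, "ana", "tok-ana")
  dispatch(sess2, ds_request("ana", "setSeedDS", "aggregate",
                             args = list(list(type = "number", value = 7))))
  dispatch(sess2, ds_request("ana", "scatterNoiseDS", "aggregate",
                             args = list("D", "age",
                                         list(type = "number", value = 0.3))))
  expect_length(detect_seed_abuse(audit_events(nd2$log)), 1L)

  # noise alone is clean
  nd3 <- tiny_node()
  sess3 <- login(nd3, "ana", "tok-ana")
  dispatch(sess3, ds_request("ana", "scatterNoiseDS", "aggregate",
                             args = list("D", "age",
                                         list(type = "number", value = 0.3))))
  expect_length(detect_seed_abuse(audit_events(nd3$log)), 0)
})

test_that("a single-request disclosure leaves no multi-step signature", {
  # one lone aggregate request: indistinguishable from valid analysis in the
  # log, so the detectors (correctly) stay silent
  nd <- tiny_node()
  sess <- login(nd, "ana", "tok-ana")
  dispatch(sess, ds_request("ana", "summaryDS", "aggregate",
                            args = list("D", "age")))
  expect_length(scan_log(audit_events(nd$log)), 0)
})
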