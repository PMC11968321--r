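test_that("login authenticates without revealing which credential failed", {
  nd <- tiny_node()
  sess <- login(nd, "ana", "tok-ana")
  expect_s3_class(sess, "ds_session")
  expect_length(ls(sess$workspace), 0)

  err_user <- tryCatch(login(nd, "nobody", "tok-ana"), error = identity)
  err_tok <- tryCatch(login(nd, "ana", "wrong"), error = identity)
  expect_s3_class(err_user, "AUTH_FAILED")
  expect_s3_class(err_tok, "AUTH_FAILED")
  expect_identical(conditionMessage(err_user), conditionMessage(err_tok))
})

test_that("two logins by the same user have independent workspaces", {
  nd <- tiny_node()
  s1 <- login(nd, "ana", "tok-ana")
  s2 <- login(nd, "ana", "tok-ana")
  st <- dispatch(s1, ds_request("ana", "subsetDS", "assign",
                                args = list("D", ds_arg_string("age > 30", "long")),
                                target = "adults"))
  expect_true(st$ok)
  expect_true(exists("adults", envir = s1$workspace))
  expect_false(exists("adults", envir = s2$workspace))
})

test_that("data views project only permitted variables, preserving rows", {
  nd <- tiny_node(accounts = list(list(
    user = "ana", token = "tok-ana",
    views = list(D = c("age", "bmi")))))
  sess <- login(nd, "ana", "tok-ana")
  proj <- resolve_view(sess, "D")
  expect_identical(names(proj), c("age", "bmi"))
  expect_identical(nrow(proj), nrow(tiny_data()))
  expect_identical(proj$age, tiny_data()$age)
  expect_error(resolve_view(sess, "D", vars = "smoker"),
               class = "VARIABLE_DENIED")
  expect_error(resolve_view(sess, "E"), class = "VIEW_DENIED")
  # dispatch surfaces the denial as a typed error value
  out <- dispatch(sess, ds_request("ana", "summaryDS", "aggregate",
                                   args = list("D", "smoker")))
  expect_s3_class(out, "VARIABLE_DENIED")
})

test_that("subset creation enforces the row threshold without leaking the size", {
  sess <- tiny_session()
  # predicate keeping 2 of 10 rows is refused under the default threshold
  err <- tryCatch(assign_subset(sess, "D", "age > 52", "older"),
                  error = identity)
  expect_s3_class(err, "SUBSET_TOO_SMALL")
  expect_false(grepl("[0-9]", conditionMessage(err)))
  # exactly at the threshold passes
  st <- assign_subset(sess, "D", "age >= 52", "older")
  expect_true(st$ok)
  expect_identical(nrow(get("older", envir = sess$workspace)), 3L)
  # empty subsets are refused too
  expect_error(assign_subset(sess, "D", "age > 100", "none"),
               class = "SUBSET_TOO_SMALL")
})

test_that("predicates combine comparisons with & and | and ignore missing rows", {
  d <- tiny_data()
  d$age[1] <- NA
  sess <- tiny_session(data = d)
  st <- assign_subset(sess, "D", "age > 40 & bmi <= 31", "mid")
  expect_true(st$ok)
  got <- get("mid", envir = sess$workspace)
  expect_identical(nrow(got), sum(d$age > 40 & d$bmi <= 31, na.rm = TRUE))

  st2 <- assign_subset(sess, "D", "smoker == yes | age < 35", "some")
  expect_true(st2$ok)
  got2 <- get("some", envir = sess$workspace)
  keep <- (!is.na(d$age) & d$age < 35) | d$smoker == "yes"
  expect_identical(nrow(got2), sum(keep))

  expect_error(assign_subset(sess, "D", "smoker < yes", "x"),
               class = "BAD_PREDICATE")
  expect_error(assign_subset(sess, "D", "height > 1", "x"),
               class = "UNKNOWN_SYMBOL")
  expect_error(assign_subset(sess, "D", "age >", "x"),
               class = "BAD_PREDICATE")
})

test_that("assign status messages carry class and shape but never values", {
  sess <- tiny_session()
  st <- dispatch(sess, ds_request("ana", "asNumericDS", "assign",
                                  args = list("D", "smoker"), target = "smk"))
  expect_true(st$ok)
  expect_identical(sort(names(unclass(st))), sort(c("ok", "class", "dims_ok")))
  expect_true(all(vapply(unclass(st), length, integer(1)) == 1L))
  expect_error(get("smk", envir = sess$workspace), NA)
})

test_that("snapshots are immutable: assigns derive, never mutate", {
  nd <- tiny_node()
  before <- nd$data
  sess <- login(nd, "ana", "tok-ana")
  dispatch(sess, ds_request("ana", "subsetDS", "assign",
                            args = list("D", ds_arg_string("age > 30", "long")),
                            target = "adults"))
  dispatch(sess, ds_request("ana", "asFactorDS", "assign",
                            args = list("D", "town"), target = "tf"))
  expect_identical(nd$data, before)
})

test_that("dispatch is total and always appends exactly one audit event", {
  nd <- tiny_node()
  sess <- login(nd, "ana", "tok-ana")
  requests <- list(
    ds_request("ana", "tableDS", "aggregate", args = list("D", "smoker")),
    ds_request("ana", "noSuchDS", "aggregate"),
    ds_request("ana", "setSeedDS", "aggregate",
               args = list(list(type = "number", value = 1))),  # blocked
    ds_request("ana", "subsetDS", "assign",
               args = list("D", ds_arg_string("age > 100", "long")),
               target = "none"),                                 # too small
    ds_request("ana", "summaryDS", "aggregate", args = list("ghost", "v")),
    ds_request("ana", "rNormDS", "assign", args = list(), target = "z"),
    ds_request("ana", "tableDS", "aggregate", args = list())     # malformed
  )
  for (i in seq_along(requests)) {
    before <- audit_length(nd$log)
    expect_no_error(out <- dispatch(sess, requests[[i]]))
    expect_identical(audit_length(nd$log), before + 1L,
                     label = sprintf("request %d", i))
  }
  seqs <- vapply(audit_events(nd$log), `[[`, integer(1), "seq")
  expect_identical(seqs, seq_along(seqs))
})

test_that("profile overrides tighten but never loosen site settings", {
  prof <- list(`nfilter.tab` = 5, `nfilter.subset` = 1,
               `datashield.privacyControlLevel` = "non-permissive")
  nd <- tiny_node(accounts = list(list(user = "ana", token = "tok-ana",
                                       profile = prof)))
  sess <- login(nd, "ana", "tok-ana")
  eff <- effective_settings(sess)
  expect_identical(eff$tab_threshold, 5L)       # stricter: applied
  expect_identical(eff$subset_threshold, 3L)    # looser: ignored
  expect_identical(eff$privacy_level, "non-permissive")  # superset: applied
})
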