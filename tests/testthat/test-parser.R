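s0 <- default_settings()

test_that("string-length filter honours the long/short slots at their boundaries", {
  long80 <- strrep("a", 80)
  expect_true(check_string(long80, "long", s0)$allowed)
  expect_false(check_string(paste0(long80, "a"), "long", s0)$allowed)
  expect_true(check_string("", "long", s0)$allowed)
  expect_true(check_string("", "short", s0)$allowed)
  expect_true(check_string(strrep("b", 20), "short", s0)$allowed)
  expect_false(check_string(strrep("b", 21), "short", s0)$allowed)
})

test_that("charset filter admits predicates and rejects injection characters", {
  expect_true(check_charset("age > 40 & bmi <= 30")$allowed)
  expect_true(check_charset("y ~ x1 + x2")$allowed)
  expect_true(check_charset("")$allowed)
  bad <- check_charset("x; delete_all()")
  expect_false(bad$allowed)
  expect_match(bad$detail, ";", fixed = TRUE)
  for (ch in c("`", "$", "@", "#", "\\", "{", "[")) {
    expect_false(check_charset(paste0("x", ch))$allowed, label = ch)
  }
})

test_that("blocked functions are rejected under the active privacy level only", {
  reg <- function_registry()
  r <- ds_request("ana", "setSeedDS", "aggregate",
                  args = list(list(type = "number", value = 42)))
  v <- parse_and_validate(r, reg, s0)  # banana blocks setSeedDS
  expect_false(v$accepted)
  expect_true("BLOCKED_BY_PRIVACY_LEVEL" %in%
                vapply(v$reasons, `[[`, character(1), "code"))

  s_perm <- s0; s_perm$privacy_level <- "permissive"
  expect_true(parse_and_validate(r, reg, s_perm)$accepted)

  sub <- ds_request("ana", "subsetDS", "assign",
                    args = list("D", ds_arg_string("age > 40", "long")),
                    target = "old")
  s_avo <- s0; s_avo$privacy_level <- "avocado"
  expect_false(parse_and_validate(sub, reg, s_avo)$accepted)
  expect_true(parse_and_validate(sub, reg, s0)$accepted)  # banana allows it
})

test_that("all failures are reported together, with kind and target checks", {
  reg <- function_registry()
  r <- ds_request("ana", "setSeedDS", "assign",  # wrong kind, blocked, bad arg
                  args = list(ds_arg_string(paste0(strrep("x", 81), ";"), "long")),
                  target = "t")
  v <- parse_and_validate(r, reg, s0)
  codes <- vapply(v$reasons, `[[`, character(1), "code")
  expect_setequal(codes, c("BLOCKED_BY_PRIVACY_LEVEL", "KIND_MISMATCH",
                           "STRING_TOO_LONG", "FORBIDDEN_CHARACTER"))

  expect_false(parse_and_validate(
    ds_request("ana", "tableDS", "aggregate", args = list("D", "smoker"),
               target = "t"), reg, s0)$accepted)
  expect_false(parse_and_validate(
    ds_request("ana", "subsetDS", "assign",
               args = list("D", ds_arg_string("age > 1", "long"))),
    reg, s0)$accepted)
  expect_false(parse_and_validate(
    ds_request("ana", "noSuchDS", "aggregate"), reg, s0)$accepted)
})

test_that("verdicts are deterministic and monotone across privacy levels", {
  reg <- function_registry()
  s_non <- s0; s_non$privacy_level <- "non-permissive"
  s_perm <- s0; s_perm$privacy_level <- "permissive"
  set.seed(11)
  for (i in 1:40) {
    fun <- sample(reg$name, 1)
    kind <- reg$kind[reg$name == fun]
    r <- ds_request("ana", fun, kind,
                    args = list(sample(c("D", "age"), 1)),
                    target = if (kind == "assign") "t" else NULL)
    v1 <- parse_and_validate(r, reg, s_non)
    v2 <- parse_and_validate(r, reg, s_non)
    expect_identical(v1, v2)
    if (v1$accepted) {
      expect_true(parse_and_validate(r, reg, s_perm)$accepted)
    }
  }
})

test_that("arbitrary string content never crashes validation", {
  reg <- function_registry()
  set.seed(99)
  for (i in 1:100) {
    len <- sample(0:200, 1)
    v <- if (len == 0) "" else {
      rawToChar(as.raw(sample(c(9L, 10L, 13L, 32:126), len, replace = TRUE)))
    }
    r <- ds_request("ana", "subsetDS", "assign",
                    args = list("D", ds_arg_string(v, "long")), target = "t")
    expect_no_error(parse_and_validate(r, reg, s0))
  }
})

test_that("requests round-trip through their JSON envelope", {
  r <- ds_request("ana", "subsetDS", "assign",
                  args = list("D", ds_arg_string("age > 40", "long"),
                              list(type = "number", value = 3)),
                  target = "old")
  back <- request_from_json(request_to_json(r))
  expect_identical(back$fun, r$fun)
  expect_identical(back$kind, r$kind)
  expect_identical(back$target, r$target)
  expect_identical(back$args[[2]]$value, "age > 40")
  # aggregate request with no target survives too
  r2 <- ds_request("ana", "tableDS", "aggregate", args = list("D", "smoker"))
  expect_null(request_from_json(request_to_json(r2))$target)
})
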