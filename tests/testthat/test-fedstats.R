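test_that("contingency tables are returned or suppressed by the cell rule", {
  sess <- tiny_session()
  tab <- site_contingency(sess, "smoker")   # counts 6/4, all >= 3
  expect_false(tab$suppressed)
  expect_identical(sum(tab$counts), 10L)

  tab2 <- site_contingency(sess, c("smoker", "town"))  # a cell of 1 exists
  expect_true(tab2$suppressed)
  expect_null(tab2$counts)

  s1 <- default_settings(); s1$tab_threshold <- 1L
  tab3 <- site_contingency(sess, c("smoker", "town"), s = s1)
  expect_false(tab3$suppressed)

  expect_error(site_contingency(sess, "age"), class = "TYPE_MISMATCH")
  expect_error(site_contingency(sess, character(0)), class = "DIM_TOO_HIGH")
})

test_that("pooling sums counts and refuses any suppressed share", {
  sess <- tiny_session()
  a <- site_contingency(sess, "smoker")
  b <- site_contingency(sess, "smoker")
  pooled <- pool_tables(list(a, b))
  expect_identical(as.vector(pooled$counts), as.vector(a$counts) * 2L)
  expect_identical(sum(pooled$counts), 20L)
  expect_identical(pool_tables(list(a))$counts, a$counts)

  supp <- site_contingency(sess, c("smoker", "town"))
  expect_error(pool_tables(list(a, supp)), class = "POOL_BLOCKED")
})

test_that("summary shares pool to the concatenated mean and variance", {
  mk <- function(vals, name) {
    nd <- new_node(name, data.frame(v = vals),
                   accounts = list(list(user = "u", token = "t")),
                   custodian = "c", clock = fixed_clock)
    site_summary(login(nd, "u", "t"), "v")
  }
  a <- mk(c(1, 2, 3), "A")
  b <- mk(c(4, 5, 6), "B")
  pooled <- pool_summaries(list(a, b))
  expect_equal(pooled$mean, 3.5)
  expect_equal(pooled$variance, var(1:6))  # 3.5
  expect_identical(pooled$N, 6)

  expect_error(mk(c(1, 2), "C"), class = "SUMMARY_TOO_SMALL")

  # random shares match the concatenation oracle
  set.seed(4)
  xs <- list(rnorm(17, 5, 2), rnorm(9, -1, 3), rnorm(30))
  shares <- lapply(seq_along(xs), function(i) mk(xs[[i]], paste0("S", i)))
  pooled <- pool_summaries(shares)
  expect_equal(pooled$mean, mean(unlist(xs)))
  expect_equal(pooled$variance, var(unlist(xs)))
})

test_that("glm shares match hand-computed score and information", {
  # binomial at beta = 0: mu = 1/2, so U = X'(y - 1/2), I = X'X / 4
  X <- cbind(1, c(0, 1, 2, 3))
  y <- c(0, 0, 1, 1)
  sh <- glm_share(X, y, c(0, 0), "binomial")
  expect_equal(sh$U, drop(crossprod(X, y - 0.5)), ignore_attr = TRUE)
  expect_equal(sh$I, 0.25 * crossprod(X), ignore_attr = TRUE)

  # gaussian information is X'X whatever beta
  sh1 <- glm_share(X, y, c(0, 0), "gaussian")
  sh2 <- glm_share(X, y, c(3, -2), "gaussian")
  expect_equal(sh1$I, crossprod(X), ignore_attr = TRUE)
  expect_equal(sh2$I, sh1$I)

  # poisson toy: intercept only, y = 1:4, beta = 0 -> U = 6, I = 4
  shp <- glm_share(matrix(1, 4, 1), 1:4, 0, "poisson")
  expect_equal(drop(shp$U), 6)
  expect_equal(drop(shp$I), 4)
  expect_identical(shp$N, 4L)

  expect_error(glm_share(X, y, c(0, 0, 0), "binomial"),
               class = "BAD_ARGUMENT")
})

test_that("single-site gaussian fit equals the closed-form least squares", {
  set.seed(21)
  spec <- default_study_spec(n_per_site = 60L, family = "gaussian",
                             beta = c(1, 2, -1), seed = 21)
  conn <- study_connection(spec)
  fit <- federated_glm(conn, "y ~ x1 + x2", family = "gaussian")
  d <- generate_multisite(spec)[[1]]
  X <- cbind(1, d$x1, d$x2)
  beta_hat <- solve(crossprod(X), crossprod(X, d$y))
  expect_equal(unname(fit$beta), drop(beta_hat), tolerance = 1e-10)
  expect_true(fit$converged)
})

test_that("federated fits equal pooled fits for every family", {
  for (fam in c("gaussian", "binomial", "poisson")) {
    beta <- if (fam == "poisson") c(0.2, 0.4, -0.3) else c(0, 1, -0.5)
    spec <- default_study_spec(n_per_site = c(70L, 50L, 80L), family = fam,
                               beta = beta, seed = 31)
    conn <- study_connection(spec)
    fit <- federated_glm(conn, "y ~ x1 + x2", family = fam)
    dat <- do.call(rbind, generate_multisite(spec))
    oracle <- glm(y ~ x1 + x2, family = fam, data = dat,
                  control = glm.control(epsilon = 1e-12))
    expect_lt(max(abs(unname(fit$beta) - unname(coef(oracle)))), 1e-6)
    expect_lt(max(abs(unname(fit$se) -
                        unname(summary(oracle)$coefficients[, 2]))), 1e-6)
  }
})

test_that("estimates are invariant to how the data are partitioned", {
  base <- default_study_spec(n_per_site = 200L, family = "binomial", seed = 5)
  one <- generate_multisite(base)[[1]]
  fit_for <- function(chunks) {
    nodes <- lapply(seq_along(chunks), function(i) {
      new_node(paste0("p", i), chunks[[i]],
               accounts = list(list(user = "u", token = "t")),
               custodian = "c", clock = fixed_clock)
    })
    conn <- connect(lapply(nodes, function(nd) list(node = nd, user = "u",
                                                    token = "t")))
    federated_glm(conn, "y ~ x1 + x2", family = "binomial")
  }
  split_rows <- function(df, k) {
    idx <- cut(seq_len(nrow(df)), k, labels = FALSE)
    lapply(seq_len(k), function(i) df[idx == i, , drop = FALSE])
  }
  f1 <- fit_for(list(one))
  f2 <- fit_for(split_rows(one, 2))
  f5 <- fit_for(split_rows(one, 5))
  expect_lt(max(abs(f1$beta - f2$beta)), 1e-8)
  expect_lt(max(abs(f1$beta - f5$beta)), 1e-8)
  expect_lt(max(abs(f1$se - f5$se)), 1e-8)
})

test_that("the dimension filter blocks per site and names only the rule", {
  small <- data.frame(x1 = rnorm(12), x2 = rnorm(12), x3 = rnorm(12),
                      x4 = rnorm(12), y = rnorm(12))
  nd <- new_node("tiny", small,
                 accounts = list(list(user = "u", token = "t")),
                 custodian = "c", clock = fixed_clock)
  conn <- connect(list(list(node = nd, user = "u", token = "t")))
  err <- tryCatch(
    federated_glm(conn, "y ~ x1 + x2 + x3 + x4", family = "gaussian"),
    error = identity)
  expect_s3_class(err, "GLM_DIM_BLOCKED")
  expect_false(grepl("12", conditionMessage(err)))
  # p = 3 on N = 12 passes (3 <= 3.96)
  expect_no_error(federated_glm(conn, "y ~ x1 + x2", family = "gaussian"))
})

test_that("glm results carry no observation-length fields", {
  spec <- default_study_spec(n_per_site = c(40L, 40L), seed = 9)
  conn <- study_connection(spec)
  fit <- federated_glm(conn, "y ~ x1 + x2", family = "binomial")
  expect_false("fitted.values" %in% names(fit))
  expect_false("residuals" %in% names(fit))
  expect_length(scan_payload_hygiene(fit, c(40L, 40L)), 0)
  sess <- conn$sessions[[1]]
  tab <- site_contingency(tiny_session(), "smoker")
  expect_length(scan_payload_hygiene(tab, 10L), 0)
})
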