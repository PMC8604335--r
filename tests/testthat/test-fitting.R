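test_that("estimation-space transforms round-trip", {
  pr <- mabc_priors()
  expect_equal(transform_params(c(a_self = 0.5), pr), c(a_self = 0))
  expect_equal(transform_params(c(beta0 = 1), pr), c(beta0 = 0))
  expect_equal(transform_params(c(tau = -1.3), pr), c(tau = -1.3))
  set.seed(40)
  for (i in 1:1000) {
    p <- mabc_params(a_self = runif(1, 1e-4, 1 - 1e-4),
                     a_other = runif(1, 1e-4, 1 - 1e-4),
                     bias_pos = rnorm(1, 0, 3), bias_neg = rnorm(1, 0, 3),
                     beta0 = exp(rnorm(1, 0, 2)), tau = rnorm(1, 0, 3),
                     theta = runif(1), beta_con = exp(rnorm(1, 0, 2)))
    v <- transform_params(p, pr)
    expect_equal(untransform_params(v, pr), p, tolerance = 1e-12)
  }
})

test_that("prior hyperparameters can be overridden per parameter", {
  pr <- mabc_priors(mean = c(beta0 = log(2)), variance = c(tau = 1))
  expect_equal(pr["beta0", "mean"], log(2))
  expect_equal(pr["tau", "variance"], 1)
  expect_equal(pr["a_self", "variance"], 4)
  expect_error(mabc_priors(variance = c(tau = -1)))
})

test_that("Laplace evidence matches the conjugate Gaussian closed form", {
  # y_i ~ N(m, s2) with known s2 and prior m ~ N(mu0, v0): the marginal
  # likelihood is available in closed form
  set.seed(50)
  y <- rnorm(20, 1.3, 1)
  s2 <- 1; mu0 <- 0; v0 <- 4; n <- length(y)
  logjoint <- function(m) sum(dnorm(y, m, sqrt(s2), log = TRUE)) +
    dnorm(m, mu0, sqrt(v0), log = TRUE)
  vpost <- 1 / (n / s2 + 1 / v0)
  mpost <- vpost * (sum(y) / s2 + mu0 / v0)
  # analytic evidence: y ~ N(mu0 * 1, s2 I + v0 J)
  S <- diag(s2, n) + v0
  analytic <- -0.5 * (n * log(2 * pi) +
                        determinant(S, logarithm = TRUE)$modulus[1] +
                        mahalanobis(matrix(y, 1), rep(mu0, n), S))
  h <- n / s2 + 1 / v0            # exact curvature of the quadratic
  lme <- laplace_lme(logjoint(mpost), matrix(h, 1, 1))
  expect_equal(as.numeric(lme), as.numeric(analytic), tolerance = 1e-6)
  # 1-D quadratic identity: peak + 0.5 log(2 pi / h)
  expect_equal(as.numeric(lme), logjoint(mpost) + 0.5 * log(2 * pi / h),
               tolerance = 1e-12)
  # additivity: shifting the log joint by c shifts the evidence by c
  expect_equal(as.numeric(laplace_lme(logjoint(mpost) + 7.5, matrix(h, 1, 1))),
               as.numeric(lme) + 7.5, tolerance = 1e-12)
})

test_that("non-positive-definite curvature is ridged with a flag", {
  lme <- laplace_lme(-10, matrix(c(0, 0, 0, 1), 2, 2))
  expect_true(attr(lme, "ridged"))
  expect_true(is.finite(lme))
})

test_that("a one-parameter sub-model MAP matches a dense grid oracle", {
  truth <- mabc_params(a_self = 0.35, a_other = 0.3, bias_pos = 0.2,
                       bias_neg = -0.2, beta0 = 2, tau = 0.5, theta = 0.2,
                       beta_con = 2)
  s <- simulate_subject(task_config(), truth, seed = 71)
  pins <- truth[setdiff(names(truth), "a_self")]
  spec1 <- mabc_spec("mabc_full", pin = pins, label = "custom")
  expect_identical(spec1$free, "a_self")
  pr <- mabc_priors()
  f <- mabc_fit(s, spec1, pr, n_restarts = 3, seed = 1)
  # dense grid over the logit space
  grid <- seq(-4, 4, by = 0.005)
  objective <- vapply(grid, function(v) {
    a <- 1 / (1 + exp(-v))
    mabc_loglik(s, replace(truth, "a_self", a), spec1) +
      dnorm(v, 0, 2, log = TRUE)
  }, numeric(1))
  v_star <- grid[which.max(objective)]
  expect_lt(abs(unname(coef(f, "transformed")) - v_star), 0.01)
  expect_gte(f$log_joint + 1e-8, max(objective))
})

test_that("the flat model needs no optimization and has exact evidence", {
  s <- cached_subject_session()
  f <- mabc_fit(s, "flat")
  n <- nrow(s$trials) + sum(s$trials$probe == "causality")
  expect_equal(f$lme, n * log(0.5))
  expect_length(coef(f), 0)
  expect_true(f$converged)
})

test_that("MAP recovers generating parameters from a long session", {
  cfg <- task_config(trials_per_task = 1000, n_self_blocks = 40,
                     n_other_blocks = 40)
  truth <- mabc_params(a_self = 0.3, a_other = 0.35, bias_pos = 0.3,
                       bias_neg = -0.25, beta0 = 2, tau = 0.7, theta = 0.2,
                       beta_con = 2)
  s <- simulate_subject(cfg, truth, seed = 101)
  f <- mabc_fit(s, "mabc_full", n_restarts = 3, seed = 2)
  est <- coef(f)
  expect_lt(abs(est[["a_self"]] - 0.3), 0.1)
  expect_lt(abs(est[["a_other"]] - 0.35), 0.15)
  expect_lt(abs(est[["theta"]] - 0.2), 0.1)
  expect_lt(abs(est[["beta0"]] - 2), 1)
  expect_gt(est[["tau"]], 0)
  expect_gt(est[["bias_pos"]], est[["bias_neg"]])
})

test_that("log-joint of the full model dominates a nested restriction", {
  s <- cached_subject_session()
  pr <- mabc_priors()
  f_nb <- mabc_fit(s, "mabc_nobias", pr, n_restarts = 3, seed = 5)
  # evaluate the full model's log joint at the restricted optimum
  # (biases at 0): the optimized full log joint cannot fall below it
  full <- mabc_spec("mabc_full")
  rest_full <- mabc_params()
  rest_full[names(coef(f_nb))] <- coef(f_nb)
  rest_full[c("bias_pos", "bias_neg")] <- 0
  v <- transform_params(rest_full, pr)
  lj_restricted <- mabc_loglik(s, rest_full, full) +
    sum(dnorm(v[full$free], 0, 2, log = TRUE))
  f_full <- mabc_fit(s, "mabc_full", pr, n_restarts = 4, seed = 6)
  expect_gte(f_full$log_joint + 1e-6, lj_restricted)
})

test_that("fit objects expose the standard modelling methods", {
  s <- cached_subject_session()
  f <- mabc_fit(s, "mabc_full", n_restarts = 2, seed = 3)
  expect_s3_class(f, "mabc_fit")
  expect_named(coef(f), mabc_spec("mabc_full")$free)
  ll <- logLik(f)
  expect_identical(attr(ll, "df"), 8L)
  expect_equal(as.numeric(ll), f$loglik)
  V <- vcov(f)
  expect_true(all(diag(V) > 0))
  expect_output(print(f), "mabc_full")
  expect_output(print(summary(f)), "log model evidence")
  tr <- predict(f, type = "trace")
  expect_identical(nrow(tr), nrow(s$trials))
  r <- residuals(f)
  expect_true(all(abs(r) <= 1))
  sims <- simulate(f, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "mabc_session")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
})

test_that("population fitting is order-invariant and matches single fits", {
  p <- mabc_params(a_self = 0.3, a_other = 0.3, bias_pos = 0.3,
                   bias_neg = -0.3, beta0 = 2, tau = 0.7, theta = 0.2,
                   beta_con = 2)
  sessions <- lapply(1:3, function(i)
    simulate_subject(task_config(), p, seed = 200 + i))
  fp <- fit_population(sessions, c("mabc_full", "flat"), n_restarts = 2,
                       seed = 9)
  expect_identical(dim(fp$lme), c(3L, 2L))
  expect_true(all(is.finite(fp$lme)))
  # permuting the subjects permutes the rows only
  fp2 <- fit_population(sessions[c(2, 1, 3)], c("mabc_full", "flat"),
                        n_restarts = 2, seed = 9)
  expect_equal(unname(fp2$lme[2, "flat"]), unname(fp$lme[1, "flat"]))
  # flat column is deterministic: matches an individual fit exactly
  f1 <- mabc_fit(sessions[[1]], "flat")
  expect_equal(unname(fp$lme[1, "flat"]), f1$lme)
  # degenerate 1 x 1 batch
  fp1 <- fit_population(sessions[1], "flat", seed = 1)
  expect_identical(dim(fp1$lme), c(1L, 1L))
})

test_that("the Rescorla-Wagner fit recovers the partner's learning rate", {
  set.seed(301)
  sessions <- lapply(1:10, function(i)
    simulate_session(task_config(), policy_random(),
                     seed = sample.int(1e6, 1)))
  fit <- fit_partner_rw(sessions)
  expect_lt(abs(fit$learning_rate - 0.3), 0.1)
  expect_lt(abs(fit$inv_temp - 1.5), 0.75)
})
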