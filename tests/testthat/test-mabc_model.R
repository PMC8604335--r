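test_that("contingency learning follows the delta rule", {
  tab <- contingency_table()
  tab <- update_contingency(tab, "self", "left", 1, 0.3)
  expect_equal(tab["self", "left"], 0.65)
  expect_equal(tab["self", "right"], 0.5)
  expect_equal(tab["other", "left"], 0.5)
  # zero prediction error: no movement
  tab2 <- contingency_table()
  tab2["other", "right"] <- 1
  expect_equal(update_contingency(tab2, "other", "right", 1, 0.7), tab2)
  # repeated rewards converge monotonically to 1
  p <- numeric(30); tab3 <- contingency_table()
  for (i in 1:30) {
    tab3 <- update_contingency(tab3, "self", "left", 1, 0.3)
    p[i] <- tab3["self", "left"]
  }
  expect_true(all(diff(p) > 0))
  expect_gt(p[30], 0.999)
  # mirrored option keeps the two cells complementary
  tab4 <- update_contingency(contingency_table(), "self", "left", 1, 0.3,
                             mirrored = TRUE)
  expect_equal(tab4["self", "right"], 1 - tab4["self", "left"])
})

test_that("likelihoods read the learned table with the complement rule", {
  tab <- contingency_table()
  tab["self", "left"] <- 0.8
  expect_equal(compute_likelihoods(tab, "left", "right", 1),
               c(likelihood_self = 0.8, likelihood_other = 0.5))
  expect_equal(compute_likelihoods(tab, "left", "right", 0),
               c(likelihood_self = 0.2, likelihood_other = 0.5))
  expect_equal(compute_likelihoods(contingency_table(), "right", "left", 1),
               c(likelihood_self = 0.5, likelihood_other = 0.5))
})

test_that("the biased posterior follows Bayes rule with likelihood weighting", {
  expect_equal(posterior_update(0.5, 0.7, 0.7, 1), 0.5)
  # 0.4 / (0.4 + 0.1)
  expect_equal(posterior_update(0.5, 0.8, 0.2, 1), 0.8)
  # equal evidence, reward bias log 2: 0.5/(0.5 + 0.25) scaled -> 2/3
  expect_equal(posterior_update(0.5, 0.5, 0.5, 1, bias_pos = log(2)), 2 / 3)
  # extreme bias drives the posterior to the clipping bound
  expect_equal(posterior_update(0.5, 0.5, 0.5, 1, bias_pos = 800), 1 - 1e-6)
  expect_equal(posterior_update(0.5, 0.5, 0.5, 0, bias_neg = -800), 1e-6)
  # loss selects the negative bias
  expect_equal(posterior_update(0.5, 0.5, 0.5, 0, bias_pos = 5, bias_neg = 0),
               0.5)
  # single-agent variant replaces the other-likelihood by chance
  expect_equal(posterior_update(0.5, 0.8, 0.9, 1, use_other_likelihood = FALSE),
               0.8 * 0.5 / (0.8 * 0.5 + 0.5 * 0.5))
  expect_error(posterior_update(NaN, 0.5, 0.5, 1), "non-finite")
})

test_that("posterior is monotone in self-likelihood and bias", {
  set.seed(10)
  for (i in 1:50) {
    prior <- runif(1, 0.05, 0.95)
    lo <- runif(1, 0.05, 0.95)
    ls <- sort(runif(2, 0.05, 0.95))
    expect_lt(posterior_update(prior, ls[1], lo, 1),
              posterior_update(prior, ls[2], lo, 1))
    b <- sort(rnorm(2, 0, 1))
    expect_lt(posterior_update(prior, ls[1], lo, 1, bias_pos = b[1]),
              posterior_update(prior, ls[1], lo, 1, bias_pos = b[2]))
  }
})

test_that("prediction drifts toward 0.5 by theta", {
  expect_equal(predict_next(0.9, 1), 0.5)
  expect_equal(predict_next(0.123, 1), 0.5)
  expect_equal(predict_next(0.9, 0), 0.9)
  expect_equal(predict_next(0.9, 0.2), 0.82)
})

test_that("controllability modulates the inverse temperature via the odds", {
  expect_equal(trial_inverse_temperature(0.8, 2, 0), 2)
  expect_equal(trial_inverse_temperature(0.5, 2, 3.7), 2)
  expect_equal(trial_inverse_temperature(0.8, 1, 1), 4)
  # tau < 0 reverses the modulation
  expect_lt(trial_inverse_temperature(0.8, 1, -1), 1)
})

test_that("choice and report policies are logistic with the right limits", {
  expect_equal(choice_prob(0.3, 0.8, 0), 0.5)
  expect_equal(choice_prob(0.7, 0.7, 25), 0.5)
  expect_equal(choice_prob(0.2, 0.8, 4), 1 / (1 + exp(-2.4)))
  expect_equal(causality_report_prob(0.5, 3), 0.5)
  expect_equal(causality_report_prob(0.9, 0), 0.5)
  expect_equal(causality_report_prob(0.9, 2), 1 / (1 + exp(-1.6)))
  # log-odds form agrees at the indifference point and orders the same way
  expect_equal(causality_report_prob(0.5, 2, form = "log_odds"), 0.5)
  expect_gt(causality_report_prob(0.8, 2, form = "log_odds"),
            causality_report_prob(0.6, 2, form = "log_odds"))
})

test_that("log-controllability ratio is the clipped log odds", {
  expect_equal(lcr(0.5), 0)
  expect_equal(lcr(0.8), log(4))
  for (p in c(0.1, 0.35, 0.62, 0.9))
    expect_equal(lcr(p), -lcr(1 - p))
})

test_that("the N-agent posterior generalizes the two-agent update", {
  # uniform everything stays uniform
  expect_equal(generalized_posterior(rep(1 / 3, 3), rep(0.4, 3)),
               rep(1 / 3, 3))
  # hand-normalized three-agent case
  expect_equal(generalized_posterior(rep(1 / 3, 3), c(0.8, 0.1, 0.1)),
               c(0.8, 0.1, 0.1))
  # reduction to the pairwise update across random draws
  set.seed(20)
  for (i in 1:25) {
    prior <- runif(1, 0.05, 0.95)
    ls <- runif(1, 0.05, 0.95); lo <- runif(1, 0.05, 0.95)
    o <- rbinom(1, 1, 0.5)
    bp <- rnorm(1); bn <- rnorm(1)
    g <- generalized_posterior(c(prior, 1 - prior), c(ls, lo), bp, bn, o)
    expect_equal(g[1], posterior_update(prior, ls, lo, o, bp, bn),
                 tolerance = 1e-12)
    expect_equal(sum(g), 1)
  }
  expect_error(generalized_posterior(c(0.5, 0.5), c(0.1, 0.2, 0.3)), "length")
})

test_that("model trace matches an independent sequential-Bayes oracle", {
  pars <- toy_pars()
  # three hand-picked trials including a causality probe
  s <- make_toy_session(action_self = c("left", "right", "left"),
                        action_other = c("right", "right", "left"),
                        outcome = c(1, 0, 1),
                        probe = c("none", "none", "causality"),
                        probe_response = c(NA, NA, "self"))
  tr <- mabc_trace(s, do.call(mabc_params, pars))
  orc <- oracle_sequential_bayes(
    a_self = c(0, 1, 0), a_other = c(1, 1, 0), outcome = c(1, 0, 1),
    probe = c(0, 0, 1), resp_self = c(0, 0, 1), pars = pars)
  expect_equal(tr$posterior_self, orc$posterior, tolerance = 1e-10)
  expect_equal(tr$prior_pred_self, orc$prediction, tolerance = 1e-10)
  expect_equal(attr(tr, "loglik"), orc$loglik, tolerance = 1e-10)
  # and on a longer simulated stretch
  s2 <- cached_subject_session()
  tr2 <- mabc_trace(s2, do.call(mabc_params, pars))
  enc <- list(a_self = as.integer(s2$trials$action_self == "right"),
              a_other = as.integer(s2$trials$action_other == "right"),
              outcome = s2$trials$outcome,
              probe = as.integer(s2$trials$probe == "causality"),
              resp = as.integer(!is.na(s2$trials$probe_response) &
                                  s2$trials$probe_response == "self"))
  orc2 <- oracle_sequential_bayes(enc$a_self, enc$a_other, enc$outcome,
                                  enc$probe, enc$resp, pars)
  expect_equal(tr2$posterior_self, orc2$posterior, tolerance = 1e-10)
  expect_equal(attr(tr2, "loglik"), orc2$loglik, tolerance = 1e-10)
})

test_that("compiled and reference likelihoods agree across variants", {
  s <- cached_subject_session()
  set.seed(33)
  for (lab in c("mabc_full", "mabc_nobias", "mabc_notau", "single_agent",
                "flat")) {
    spec <- mabc_spec(lab)
    for (i in 1:5) {
      p <- mabc_params(a_self = runif(1, 0.05, 0.95),
                       a_other = runif(1, 0.05, 0.95),
                       bias_pos = rnorm(1), bias_neg = rnorm(1),
                       beta0 = exp(rnorm(1)), tau = rnorm(1),
                       theta = runif(1), beta_con = exp(rnorm(1)))
      expect_equal(mabc_loglik(s, p, spec),
                   as.numeric(mabc_loglik(s, p, spec, engine = "r")),
                   tolerance = 1e-12)
    }
  }
  # log-odds report form too
  spec_lo <- mabc_spec("mabc_full", report_form = "log_odds")
  p <- mabc_params(beta0 = 1.5, tau = 0.5, theta = 0.2)
  expect_equal(mabc_loglik(s, p, spec_lo),
               as.numeric(mabc_loglik(s, p, spec_lo, engine = "r")),
               tolerance = 1e-12)
})

test_that("variant nesting: zero bias reproduces the no-bias model exactly", {
  s <- cached_subject_session()
  p <- mabc_params(a_self = 0.25, a_other = 0.35, bias_pos = 0, bias_neg = 0,
                   beta0 = 1.2, tau = 0.4, theta = 0.15, beta_con = 1.8)
  expect_identical(mabc_loglik(s, p, mabc_spec("mabc_full")),
                   mabc_loglik(s, p, mabc_spec("mabc_nobias")))
  tr_full <- mabc_trace(s, p, mabc_spec("mabc_full"))
  tr_nb <- mabc_trace(s, p, mabc_spec("mabc_nobias"))
  expect_identical(tr_full$posterior_self, tr_nb$posterior_self)
})

test_that("the flat variant is pure chance responding", {
  s <- cached_subject_session()
  n_choices <- nrow(s$trials)
  n_probes <- sum(s$trials$probe == "causality")
  expect_equal(mabc_loglik(s, mabc_params(), mabc_spec("flat")),
               (n_choices + n_probes) * log(0.5))
})

test_that("limit identities hold along the whole trace", {
  s <- cached_subject_session()
  # theta = 1: predictions pinned at 0.5
  tr <- mabc_trace(s, mabc_params(theta = 1, beta0 = 1.5, tau = 1))
  expect_true(all(tr$prior_pred_self == 0.5))
  expect_true(all(tr$beta_trial == 1.5))
  # tau = 0: inverse temperature constant at the baseline
  tr2 <- mabc_trace(s, mabc_params(tau = 0, beta0 = 2.5, theta = 0.2))
  expect_true(all(tr2$beta_trial == 2.5))
  # posterior always inside the clipping bounds
  tr3 <- mabc_trace(s, mabc_params(bias_pos = 3, bias_neg = -3, theta = 0.01))
  expect_true(all(tr3$posterior_self >= 1e-6 & tr3$posterior_self <= 1 - 1e-6))
})

test_that("generative subjects are reproducible and track true controllability", {
  p <- mabc_params(a_self = 0.3, a_other = 0.3, bias_pos = 0.2,
                   bias_neg = -0.2, beta0 = 2, tau = 0.7, theta = 0.2,
                   beta_con = 2)
  s1 <- simulate_subject(task_config(), p, seed = 9)
  s2 <- simulate_subject(task_config(), p, seed = 9)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$generator_params, s2$generator_params)
  # on average the inferred controllability is higher in self blocks
  set.seed(61)
  gap <- vapply(1:15, function(i) {
    s <- simulate_subject(task_config(), p, seed = sample.int(1e6, 1))
    tr <- mabc_trace(s, p)
    mean(tr$posterior_self[s$trials$true_controller == "self"]) -
      mean(tr$posterior_self[s$trials$true_controller == "other"])
  }, numeric(1))
  expect_gt(mean(gap), 0.05)
})

test_that("the generating parameters beat a permuted-outcome session", {
  p <- mabc_params(a_self = 0.3, a_other = 0.3, bias_pos = 0.2,
                   bias_neg = -0.2, beta0 = 2, tau = 0.7, theta = 0.2,
                   beta_con = 2)
  s <- simulate_subject(task_config(), p, seed = 14)
  ll <- mabc_loglik(s, p)
  set.seed(15)
  perm <- s
  perm$trials$outcome <- sample(perm$trials$outcome)
  expect_gt(ll, mabc_loglik(perm, p))
})
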