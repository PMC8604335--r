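# Independent oracles used by the tests. These are deliberately written
# from the model equations directly, not by calling package internals,
# so that agreement with the package is an actual cross-check.

# Sequential-Bayes calculator: given per-trial actions (0 left / 1 right)
# and outcomes, walks the recursion with plain dictionaries and explicit
# normalization, returning posterior and prediction traces and the joint
# log-likelihood of the recorded choices/reports.
oracle_sequential_bayes <- function(a_self, a_other, outcome,
                                    probe, resp_self, pars,
                                    use_other = TRUE, eps = 1e-6) {
  clamp <- function(z) min(max(z, eps), 1 - eps)
  P <- list(self = c(left = 0.5, right = 0.5),
            other = c(left = 0.5, right = 0.5))
  act <- function(i) if (i == 1) "right" else "left"
  pred <- 0.5
  n <- length(a_self)
  post_trace <- pred_trace <- numeric(n)
  ll <- 0
  for (k in seq_len(n)) {
    # choice term under the prediction entering trial k
    vl <- P$self[["left"]]; vr <- P$self[["right"]]
    pc <- clamp(pred)
    beta_k <- pars$beta0 * (pc / (1 - pc))^pars$tau
    p_right <- if (vr == vl) 0.5 else 1 / (1 + exp(-beta_k * (vr - vl)))
    p_right <- min(max(p_right, 1e-12), 1 - 1e-12)
    ll <- ll + log(if (a_self[k] == 1) p_right else 1 - p_right)
    # learning
    o <- outcome[k]
    P$self[[act(a_self[k])]] <- P$self[[act(a_self[k])]] +
      pars$a_self * (o - P$self[[act(a_self[k])]])
    P$other[[act(a_other[k])]] <- P$other[[act(a_other[k])]] +
      pars$a_other * (o - P$other[[act(a_other[k])]])
    # likelihood of the observed outcome under each hypothesis
    lik_s <- if (o == 1) P$self[[act(a_self[k])]] else 1 - P$self[[act(a_self[k])]]
    lik_o <- if (o == 1) P$other[[act(a_other[k])]] else 1 - P$other[[act(a_other[k])]]
    lik_s <- clamp(lik_s)
    lik_o <- if (use_other) clamp(lik_o) else 0.5
    # biased Bayes step, explicitly normalized over both hypotheses
    w <- exp(if (o == 1) pars$bias_pos else pars$bias_neg)
    joint <- c(self = w * lik_s * clamp(pred), other = lik_o * (1 - clamp(pred)))
    post <- clamp(joint[["self"]] / sum(joint))
    if (probe[k] == 1) {
      p_rep <- 1 / (1 + exp(-pars$beta_con * (2 * post - 1)))
      p_rep <- min(max(p_rep, 1e-12), 1 - 1e-12)
      ll <- ll + log(if (resp_self[k] == 1) p_rep else 1 - p_rep)
    }
    post_trace[k] <- post
    pred_trace[k] <- pred
    pred <- (1 - pars$theta) * post + pars$theta / 2
  }
  list(posterior = post_trace, prediction = pred_trace, loglik = ll)
}

# Long-hand variational fixed point for the Dirichlet model-frequency
# posterior, written subject-by-subject with explicit softmax.
oracle_rfx_alpha <- function(lme, alpha0 = 1, tol = 1e-10, max_iter = 5000) {
  n <- nrow(lme); K <- ncol(lme)
  a0 <- rep(alpha0, length.out = K)
  a <- a0 + n / K
  for (it in seq_len(max_iter)) {
    counts <- numeric(K)
    for (s in seq_len(n)) {
      u <- lme[s, ] + digamma(a) - digamma(sum(a))
      u <- u - max(u)
      g <- exp(u) / sum(exp(u))
      counts <- counts + g
    }
    a_new <- a0 + counts
    if (max(abs(a_new - a)) < tol) return(a_new)
    a <- a_new
  }
  a
}

# Assemble a session object from raw per-trial vectors (single task by
# default), for hand-constructed scenarios.
make_toy_session <- function(action_self, action_other, outcome,
                             probe = NULL, probe_response = NULL,
                             true_controller = NULL, task_id = NULL) {
  n <- length(action_self)
  if (is.null(probe)) probe <- rep("none", n)
  if (is.null(probe_response)) probe_response <- rep(NA_character_, n)
  if (is.null(true_controller)) true_controller <- rep("self", n)
  if (is.null(task_id)) task_id <- rep(1L, n)
  mabc_session(data.frame(
    trial = seq_len(n), task_id = task_id,
    true_controller = true_controller,
    action_self = action_self, action_other = action_other,
    outcome = as.integer(outcome), probe = probe,
    probe_response = probe_response, stringsAsFactors = FALSE))
}

# Default parameter list for oracle comparisons.
toy_pars <- function(...) {
  p <- list(a_self = 0.3, a_other = 0.4, bias_pos = 0.5, bias_neg = -0.4,
            beta0 = 1.5, tau = 0.8, theta = 0.2, beta_con = 2)
  mod <- list(...)
  p[names(mod)] <- mod
  p
}

# A reasonably informative simulated subject reused across tests.
cached_subject_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_subject(
        task_config(),
        mabc_params(a_self = 0.3, a_other = 0.3, bias_pos = 0.3,
                    bias_neg = -0.3, beta0 = 2, tau = 0.7, theta = 0.2,
                    beta_con = 2),
        seed = 42)
    cache
  }
})
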