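#' Model variants of the controllability-inference family
#'
#' A model variant is defined by four switches on the full multi-agent
#' Bayesian controllability (MABC) model:
#' \describe{
#'   \item{use_other_likelihood}{integrate the partner's action-outcome
#'     likelihood (off: the other-likelihood is fixed at the chance value
#'     0.5, i.e. single-agent inference from own evidence only);}
#'   \item{use_bias}{valence-dependent inferential biases
#'     (\code{bias_pos}, \code{bias_neg}) multiplying the self-likelihood
#'     (off: both pinned at 0);}
#'   \item{use_tau}{controllability-dependent modulation of the softmax
#'     inverse temperature (off: \code{tau} pinned at 0);}
#'   \item{use_drift}{drift of the next-trial controllability prediction
#'     toward 0.5 (off: \code{theta} pinned at 0).}
#' }
#' Named variants: \code{"mabc_full"} (all switches on),
#' \code{"mabc_nobias"}, \code{"mabc_notau"}, \code{"single_agent"}
#' (other-likelihood off), and \code{"flat"} (all switches off with
#' \code{beta0} and \code{beta_con} additionally pinned at 0, i.e. pure
#' chance responding with no free parameters).
#'
#' @param model a named variant label, or \code{NULL} to set switches
#'   directly.
#' @param use_other_likelihood,use_bias,use_tau,use_drift logical switches
#'   (ignored when \code{model} is a named variant).
#' @param mirrored_update also update the unchosen option's contingency to
#'   the complement of the chosen option's (off by default; the standard
#'   delta rule touches only the observed cell).
#' @param report_form argument passed to the causality-report logistic:
#'   \code{"difference"} uses the posterior difference \code{2p - 1},
#'   \code{"log_odds"} uses the log-controllability ratio.
#' @param pin optional named numeric vector of additional parameters to
#'   hold fixed at the given natural-space values (they drop out of the
#'   free-parameter set when fitting).
#' @param label display label.
#' @return an object of class \code{"mabc_spec"}.
#' @examples
#' mabc_spec("mabc_full")
#' mabc_spec("single_agent")$free
#' @export
mabc_spec <- function(model = "mabc_full",
                      use_other_likelihood = TRUE, use_bias = TRUE,
                      use_tau = TRUE, use_drift = TRUE,
                      mirrored_update = FALSE,
                      report_form = c("difference", "log_odds"),
                      pin = NULL, label = NULL) {
  report_form <- match.arg(report_form)
  if (!is.null(model)) {
    model <- match.arg(model, c("mabc_full", "mabc_nobias", "mabc_notau",
                                "single_agent", "flat", "custom"))
    if (model != "custom") {
      use_other_likelihood <- model != "single_agent" && model != "flat"
      use_bias  <- model %in% c("mabc_full", "mabc_notau", "single_agent")
      use_tau   <- model %in% c("mabc_full", "mabc_nobias", "single_agent")
      use_drift <- model != "flat"
      if (is.null(label)) label <- model
    }
  }
  if (is.null(label)) label <- "custom"
  pinned <- c(
    if (!use_bias) c(bias_pos = 0, bias_neg = 0),
    if (!use_tau) c(tau = 0),
    if (!use_drift) c(theta = 0),
    if (!use_other_likelihood) c(a_other = 0.5),
    if (identical(label, "flat")) c(a_self = 0.5, beta0 = 0, beta_con = 0))
  if (!is.null(pin)) {
    stopifnot(all(names(pin) %in% .mabc_par_names))
    pinned <- c(pinned, pin[setdiff(names(pin), names(pinned))])
  }
  free <- setdiff(.mabc_par_names, names(pinned))
  structure(list(use_other_likelihood = use_other_likelihood,
                 use_bias = use_bias, use_tau = use_tau,
                 use_drift = use_drift,
                 mirrored_update = isTRUE(mirrored_update),
                 report_form = report_form,
                 pinned = pinned, free = free, label = label),
            class = "mabc_spec")
}

#' @export
print.mabc_spec <- function(x, ...) {
  cat("MABC model variant '", x$label, "'\n", sep = "")
  cat("  switches: other_likelihood=", x$use_other_likelihood,
      " bias=", x$use_bias, " tau=", x$use_tau, " drift=", x$use_drift,
      "\n  free parameters: ", paste(x$free, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Construct a full MABC parameter vector
#'
#' @param a_self,a_other contingency learning rates in (0,1) for own and
#'   partner action-outcome tables.
#' @param bias_pos,bias_neg log-scale multipliers on the self-likelihood
#'   after reward / loss outcomes.
#' @param beta0 baseline softmax inverse temperature (>= 0).
#' @param tau exponent coupling the predicted controllability odds to the
#'   inverse temperature ("value utilization").
#' @param theta drift of the next-trial prediction toward 0.5, in [0,1].
#' @param beta_con inverse temperature of the causality-report logistic
#'   (>= 0).
#' @return a named numeric vector in the canonical parameter order.
#' @export
mabc_params <- function(a_self = 0.3, a_other = 0.3, bias_pos = 0,
                        bias_neg = 0, beta0 = 1, tau = 0, theta = 0.1,
                        beta_con = 2) {
  p <- c(a_self = a_self, a_other = a_other, bias_pos = bias_pos,
         bias_neg = bias_neg, beta0 = beta0, tau = tau, theta = theta,
         beta_con = beta_con)
  .validate_params(p)
  p
}

.validate_params <- function(p) {
  if (!all(.mabc_par_names %in% names(p)))
    stop("parameter vector must contain: ",
         paste(.mabc_par_names, collapse = ", "))
  if (any(!is.finite(p))) stop("non-finite parameter value")
  if (p[["a_self"]] <= 0 || p[["a_self"]] >= 1)
    stop("a_self must lie in (0,1)")
  if (p[["a_other"]] <= 0 || p[["a_other"]] >= 1)
    stop("a_other must lie in (0,1)")
  if (p[["theta"]] < 0 || p[["theta"]] > 1) stop("theta must lie in [0,1]")
  if (p[["beta0"]] < 0) stop("beta0 must be non-negative")
  if (p[["beta_con"]] < 0) stop("beta_con must be non-negative")
  invisible(p)
}

# fill a spec's pinned values into a (possibly partial) parameter vector
.complete_params <- function(params, spec) {
  full <- mabc_params()          # template with defaults
  full[names(params)] <- params
  if (length(spec$pinned)) full[names(spec$pinned)] <- spec$pinned
  full[.mabc_par_names]
}

#' Delta-rule update of a learned action-outcome contingency table
#'
#' The table holds the learned reward probabilities
#' \code{p(outcome = reward | controller frame, action)} for both frames
#' (self, other) and both actions. Only the observed (frame, action) cell
#' moves: \code{p <- p + rate * (outcome - p)}.
#'
#' @param table a 2 x 2 numeric matrix, rows \code{c("self","other")},
#'   columns \code{c("left","right")}; see \code{\link{contingency_table}}.
#' @param frame \code{"self"} or \code{"other"}: whose action-outcome
#'   contingency is being learned.
#' @param action the observed action of that agent.
#' @param outcome 0 (loss) or 1 (reward).
#' @param rate learning rate in (0,1).
#' @param mirrored if \code{TRUE}, the unchosen action's cell is set to
#'   the complement of the updated chosen cell.
#' @return the updated table.
#' @export
update_contingency <- function(table, frame, action, outcome, rate,
                               mirrored = FALSE) {
  stopifnot(outcome %in% c(0, 1), rate > 0, rate < 1)
  p <- table[frame, action]
  p <- p + rate * (outcome - p)
  table[frame, action] <- p
  if (mirrored) {
    other_a <- setdiff(c("left", "right"), action)
    table[frame, other_a] <- 1 - p
  }
  table
}

#' Fresh contingency table
#'
#' All four reward probabilities start at the uninformative 0.5.
#'
#' @param init initial value for every cell.
#' @return a 2 x 2 matrix with dimnames frames x actions.
#' @export
contingency_table <- function(init = 0.5) {
  matrix(init, 2, 2, dimnames = list(c("self", "other"), c("left", "right")))
}

#' Outcome likelihoods under the self- and other-controller hypotheses
#'
#' Reads the learned reward probabilities for the observed actions; the
#' likelihood of a loss is the complement of the learned reward
#' probability. Within a trial these are read from the table after that
#' trial's contingency update.
#'
#' @param table a contingency table (see \code{\link{contingency_table}}).
#' @param action_self,action_other observed actions.
#' @param outcome 0 or 1.
#' @return named vector \code{c(likelihood_self, likelihood_other)}.
#' @export
compute_likelihoods <- function(table, action_self, action_other, outcome) {
  ls <- table["self", action_self]
  lo <- table["other", action_other]
  if (outcome == 0) { ls <- 1 - ls; lo <- 1 - lo }
  c(likelihood_self = unname(ls), likelihood_other = unname(lo))
}

#' Biased Bayesian update of the controllability posterior
#'
#' Combines the predicted controllability (prior) with the self- and
#' other-likelihoods. After reward the self-likelihood is weighted by
#' \code{exp(bias_pos)}, after loss by \code{exp(bias_neg)}; positive
#' biases inflate perceived self-control. When the other-likelihood is
#' switched off the chance value 0.5 stands in for it.
#'
#' @param prior_pred_self predicted probability that self is in control.
#' @param l_self,l_other outcome likelihoods under the two hypotheses.
#' @param outcome 0 or 1 (selects which bias applies).
#' @param bias_pos,bias_neg log-scale self-likelihood weights.
#' @param use_other_likelihood if \code{FALSE}, \code{l_other} is replaced
#'   by 0.5.
#' @param eps clipping bound applied to inputs and the result.
#' @return posterior probability that self is in control, clipped to
#'   \code{[eps, 1 - eps]}.
#' @export
posterior_update <- function(prior_pred_self, l_self, l_other, outcome,
                             bias_pos = 0, bias_neg = 0,
                             use_other_likelihood = TRUE, eps = 1e-6) {
  if (!all(is.finite(c(prior_pred_self, l_self, l_other))))
    stop("non-finite input to posterior update")
  p <- .clip(prior_pred_self, eps)
  ls <- .clip(l_self, eps)
  lo <- if (use_other_likelihood) .clip(l_other, eps) else 0.5
  w <- exp(if (outcome == 1) bias_pos else bias_neg)
  num <- w * ls * p
  if (!is.finite(num)) return(1 - eps)  # bias -> +Inf limit
  .clip(num / (num + lo * (1 - p)), eps)
}

#' Drifted prediction of next-trial controllability
#'
#' \code{prediction = (1 - theta) * posterior + 0.5 * theta}: the drift
#' parameter pulls the prediction toward the uninformative 0.5. At
#' \code{theta = 1} the previous inference is ignored entirely.
#'
#' @param posterior_self posterior controllability of the current trial.
#' @param theta drift parameter in [0,1].
#' @return the predicted controllability for the next trial.
#' @export
predict_next <- function(posterior_self, theta) {
  stopifnot(theta >= 0, theta <= 1)
  (1 - theta) * posterior_self + 0.5 * theta
}

#' Action values from the learned self contingency
#'
#' The learned reward probability of each option under the
#' self-in-control hypothesis serves as its value.
#'
#' @param table a contingency table.
#' @return named vector \code{c(left, right)}.
#' @export
action_values <- function(table) {
  c(left = unname(table["self", "left"]), right = unname(table["self", "right"]))
}

#' Controllability-modulated inverse temperature
#'
#' \code{beta = beta0 * (p / (1 - p))^tau} where \code{p} is the predicted
#' controllability: positive \code{tau} sharpens value-based choice when
#' the subject expects to be in control.
#'
#' @param prior_pred_self predicted controllability, clipped internally.
#' @param beta0 baseline inverse temperature.
#' @param tau modulation exponent.
#' @param eps clipping bound for the odds ratio.
#' @return the trial inverse temperature.
#' @export
trial_inverse_temperature <- function(prior_pred_self, beta0, tau, eps = 1e-6) {
  p <- .clip(prior_pred_self, eps)
  beta0 * (p / (1 - p))^tau
}

#' Softmax choice probability
#'
#' @param v_left,v_right action values.
#' @param beta inverse temperature.
#' @return \code{p(choose right) = 1 / (1 + exp(-beta * (v_right - v_left)))}.
#' @export
choice_prob <- function(v_left, v_right, beta) {
  d <- v_right - v_left
  if (d == 0) return(0.5)
  .inv_logit(beta * d)
}

#' Causality-report probability
#'
#' The probability of answering "self" on a causality probe is a logistic
#' in the posterior controllability: with the (default) difference form
#' the argument is \code{2 * posterior - 1} (the posterior difference
#' p(self) - p(other)); with the log-odds form it is the
#' log-controllability ratio.
#'
#' @param posterior_self posterior controllability.
#' @param beta_con report inverse temperature.
#' @param form \code{"difference"} or \code{"log_odds"}.
#' @param eps clipping bound used by the log-odds form.
#' @return probability of reporting "self".
#' @export
causality_report_prob <- function(posterior_self, beta_con,
                                  form = c("difference", "log_odds"),
                                  eps = 1e-6) {
  form <- match.arg(form)
  x <- if (form == "difference") 2 * posterior_self - 1
       else lcr(posterior_self, eps)
  .inv_logit(beta_con * x)
}

#' Log-controllability ratio
#'
#' \code{LCR = log(p / (1 - p))}: positive when self is the inferred
#' controller.
#'
#' @param posterior_self posterior controllability.
#' @param eps clipping bound before the log.
#' @return the log odds of self-control.
#' @export
lcr <- function(posterior_self, eps = 1e-6) {
  p <- .clip(posterior_self, eps)
  log(p / (1 - p))
}

#' Generalized N-agent controllability posterior
#'
#' With one self entry (first component) and N-1 other agents, the
#' posterior over "who is in control" is proportional to
#' \code{w_i * likelihood_i * prior_i}, where the self entry carries the
#' valence-dependent bias weight \code{exp(bias)} and all others weight 1.
#' The two-agent case reduces exactly to \code{\link{posterior_update}}.
#'
#' @param prior probability vector summing to 1 (self first).
#' @param likelihood outcome likelihood of each agent's hypothesis.
#' @param bias_pos,bias_neg self-likelihood log-weights.
#' @param outcome 0 or 1 (selects which bias applies).
#' @param eps clipping bound.
#' @return the normalized posterior vector.
#' @export
generalized_posterior <- function(prior, likelihood, bias_pos = 0,
                                  bias_neg = 0, outcome = 1, eps = 1e-6) {
  if (length(prior) != length(likelihood))
    stop("prior and likelihood must have the same length")
  if (abs(sum(prior) - 1) > 1e-8) stop("prior must sum to 1")
  w <- rep(1, length(prior))
  w[1] <- exp(if (outcome == 1) bias_pos else bias_neg)
  num <- w * .clip(likelihood, eps) * .clip(prior, eps)
  num / sum(num)
}

# integer encoding of a session's trials for the likelihood engines
.encode_session <- function(session) {
  tr <- session$trials
  list(a_self = as.integer(tr$action_self == "right"),
       a_other = as.integer(tr$action_other == "right"),
       outcome = as.integer(tr$outcome),
       is_probe = as.integer(tr$probe == "causality"),
       resp_self = ifelse(tr$probe == "causality",
                          as.integer(tr$probe_response == "self"), -1L))
}

#' Joint log-likelihood of a session under an MABC variant
#'
#' Iterates the recorded trials in the model's event order: softmax
#' likelihood of the recorded choice under the current prediction, then
#' the contingency updates from the recorded actions and outcome, the
#' likelihood computation from the updated table, the biased posterior,
#' the report likelihood on causality probes, and the drifted prediction
#' for the next trial. Returns the summed log-likelihood of choices and
#' causality reports.
#'
#' @param session a \code{"mabc_session"}.
#' @param params full or partial named parameter vector (pinned entries
#'   of the variant override it).
#' @param spec a \code{\link{mabc_spec}}.
#' @param engine \code{"cpp"} (compiled, default) or \code{"r"}
#'   (reference implementation; also returns the trial-by-trial trace).
#' @return for \code{engine = "cpp"} a single number; for
#'   \code{engine = "r"} the number with the belief trace data frame as
#'   attribute \code{"trace"}.
#' @export
mabc_loglik <- function(session, params, spec = mabc_spec("mabc_full"),
                        engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  p <- .complete_params(params, spec)
  .validate_params(p)
  enc <- .encode_session(session)
  if (engine == "cpp") {
    mabc_loglik_cpp(enc$a_self, enc$a_other, enc$outcome, enc$is_probe,
                    enc$resp_self, p, spec$use_other_likelihood,
                    spec$mirrored_update,
                    spec$report_form == "log_odds")
  } else {
    tr <- mabc_trace(session, p, spec)
    ll <- attr(tr, "loglik")
    attr(ll, "trace") <- tr
    ll
  }
}

#' Trial-by-trial belief trace of an MABC variant
#'
#' Pure-R reference implementation of the model recursion. Returns, per
#' trial, the predicted controllability, the two likelihoods, the biased
#' posterior, the log-controllability ratio, the action values and trial
#' inverse temperature used for the choice, the choice probability of
#' "right", and the report probability of "self" (NA off probe trials).
#'
#' @param session a \code{"mabc_session"}.
#' @param params named parameter vector.
#' @param spec a \code{\link{mabc_spec}}.
#' @param eps clipping bound.
#' @return a data frame, one row per trial, with the total joint
#'   log-likelihood of the recorded choices and reports in attribute
#'   \code{"loglik"}.
#' @export
mabc_trace <- function(session, params, spec = mabc_spec("mabc_full"),
                       eps = 1e-6) {
  p <- .complete_params(params, spec)
  .validate_params(p)
  tr <- session$trials
  n <- nrow(tr)
  tab <- contingency_table()
  prior <- 0.5
  out <- data.frame(trial = tr$trial,
                    prior_pred_self = NA_real_, likelihood_self = NA_real_,
                    likelihood_other = NA_real_, posterior_self = NA_real_,
                    lcr = NA_real_, value_left = NA_real_,
                    value_right = NA_real_, beta_trial = NA_real_,
                    p_choose_right = NA_real_, p_report_self = NA_real_)
  ll <- 0
  for (k in seq_len(n)) {
    v <- action_values(tab)
    beta <- trial_inverse_temperature(prior, p[["beta0"]], p[["tau"]], eps)
    if (!is.finite(beta)) beta <- 1e10
    pr <- choice_prob(v[["left"]], v[["right"]], beta)
    pr_c <- .clip(pr, 1e-12)
    ll <- ll + if (tr$action_self[k] == "right") log(pr_c) else log(1 - pr_c)
    o <- tr$outcome[k]
    tab <- update_contingency(tab, "self", tr$action_self[k], o,
                              p[["a_self"]], spec$mirrored_update)
    tab <- update_contingency(tab, "other", tr$action_other[k], o,
                              p[["a_other"]], spec$mirrored_update)
    lik <- compute_likelihoods(tab, tr$action_self[k], tr$action_other[k], o)
    post <- posterior_update(prior, lik[["likelihood_self"]],
                             lik[["likelihood_other"]], o,
                             p[["bias_pos"]], p[["bias_neg"]],
                             spec$use_other_likelihood, eps)
    p_rep <- NA_real_
    if (tr$probe[k] == "causality") {
      p_rep <- causality_report_prob(post, p[["beta_con"]], spec$report_form, eps)
      p_rep_c <- .clip(p_rep, 1e-12)
      ll <- ll + if (tr$probe_response[k] == "self") log(p_rep_c)
                 else log(1 - p_rep_c)
    }
    out[k, -1] <- c(prior, lik[["likelihood_self"]], lik[["likelihood_other"]],
                    post, lcr(post, eps), v[["left"]], v[["right"]], beta,
                    pr, p_rep)
    prior <- predict_next(post, p[["theta"]])
  }
  attr(out, "loglik") <- ll
  out
}

#' MABC generative subject policy
#'
#' A subject that runs the MABC recursion forward: chooses by the
#' controllability-modulated softmax over learned action values and
#' answers causality probes by sampling the report logistic on the
#' current posterior.
#'
#' @param params named parameter vector (see \code{\link{mabc_params}}).
#' @param spec a \code{\link{mabc_spec}}.
#' @param eps clipping bound.
#' @return a policy object usable with \code{\link{simulate_session}};
#'   the generating parameters are attached as attribute \code{"params"}.
#' @export
policy_mabc <- function(params, spec = mabc_spec("mabc_full"), eps = 1e-6) {
  p <- .complete_params(params, spec)
  .validate_params(p)
  env <- new.env(parent = emptyenv())
  reset <- function() {
    env$tab <- contingency_table()
    env$prior <- 0.5
    env$post <- 0.5
    invisible(NULL)
  }
  act <- function() {
    v <- c(env$tab["self", "left"], env$tab["self", "right"])
    beta <- trial_inverse_temperature(env$prior, p[["beta0"]], p[["tau"]], eps)
    if (!is.finite(beta)) beta <- 1e10
    pr <- choice_prob(v[1], v[2], beta)
    if (runif(1) < pr) "right" else "left"
  }
  observe <- function(action_self, action_other, outcome) {
    env$tab <- update_contingency(env$tab, "self", action_self, outcome,
                                  p[["a_self"]], spec$mirrored_update)
    env$tab <- update_contingency(env$tab, "other", action_other, outcome,
                                  p[["a_other"]], spec$mirrored_update)
    lik <- compute_likelihoods(env$tab, action_self, action_other, outcome)
    env$post <- posterior_update(env$prior, lik[["likelihood_self"]],
                                 lik[["likelihood_other"]], outcome,
                                 p[["bias_pos"]], p[["bias_neg"]],
                                 spec$use_other_likelihood, eps)
    env$prior <- predict_next(env$post, p[["theta"]])
    invisible(NULL)
  }
  probe_answer <- function() {
    pr <- causality_report_prob(env$post, p[["beta_con"]], spec$report_form, eps)
    if (runif(1) < pr) "self" else "other"
  }
  reset()
  structure(list(reset = reset, act = act, observe = observe,
                 probe_answer = probe_answer),
            class = "mabc_policy", params = p, spec = spec)
}

#' Simulate a session from a generative MABC subject
#'
#' Convenience wrapper closing the loop between the task simulator and
#' the model: the subject behaves according to the MABC variant with the
#' given parameters, playing against the default Rescorla-Wagner partner.
#'
#' @param config a \code{\link{task_config}}.
#' @param params named parameter vector.
#' @param spec a \code{\link{mabc_spec}}.
#' @param seed integer seed (reproducible bit-for-bit).
#' @param partner a \code{\link{partner_agent}}.
#' @return a \code{"mabc_session"} with the generating parameters stored
#'   in \code{$generator_params}.
#' @export
simulate_subject <- function(config, params, spec = mabc_spec("mabc_full"),
                             seed = NULL, partner = partner_agent()) {
  simulate_session(config, policy_mabc(params, spec), partner, seed)
}
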