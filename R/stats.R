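#' Per-trial correlation index (CIx)
#'
#' CIx at trial k summarizes whether the agent's action-outcome pairs of
#' trials k-1 and k are consistent with a correlated action-outcome
#' relationship: 1 if the same action yielded the same outcome or
#' different actions yielded different outcomes; 0 if the same action
#' yielded different outcomes or different actions yielded the same
#' outcome. The first trial of each task has no preceding trial and is
#' \code{NA}. The definition depends only on same/different patterns, so
#' it is invariant to swapping the action labels globally.
#'
#' @param session a \code{"mabc_session"}.
#' @param agent \code{"self"} or \code{"other"}: whose actions to index.
#' @return an integer vector (0/1/NA) over trials.
#' @export
compute_cix <- function(session, agent = c("self", "other")) {
  agent <- match.arg(agent)
  tr <- session$trials
  a <- if (agent == "self") tr$action_self else tr$action_other
  o <- tr$outcome
  n <- nrow(tr)
  same_a <- a[-1] == a[-n]
  same_o <- o[-1] == o[-n]
  cix <- c(NA_integer_, as.integer(same_a == same_o))
  cix[match(unique(tr$task_id), tr$task_id)] <- NA_integer_
  cix
}

.probe_idx <- function(session) {
  which(session$trials$probe == "causality" &
          !is.na(session$trials$probe_response))
}

#' Accuracy of causality reports against the true controller
#'
#' @param session a \code{"mabc_session"} with at least one answered
#'   causality probe.
#' @return the fraction of causality probes whose answer matches the true
#'   controller on that trial.
#' @export
controllability_accuracy <- function(session) {
  idx <- .probe_idx(session)
  if (!length(idx)) stop("no answered causality probes in session")
  mean(session$trials$probe_response[idx] ==
         session$trials$true_controller[idx])
}

#' Illusion of control
#'
#' The proportion of causality probes falling in other-controllable
#' blocks that were nevertheless answered "self".
#'
#' @param session a \code{"mabc_session"}.
#' @return a proportion.
#' @export
illusion_of_control <- function(session) {
  idx <- .probe_idx(session)
  idx <- idx[session$trials$true_controller[idx] == "other"]
  if (!length(idx)) stop("no answered causality probes in other-controllable blocks")
  mean(session$trials$probe_response[idx] == "self")
}

#' Optimal-choice proportions in self-controllable blocks
#'
#' The optimal choice is defined only while the subject truly controls
#' the outcome. Reports the overall proportion, the proportions
#' conditioned on the most recent preceding causality-probe answer within
#' the same task ("self" vs "other"), and the proportions in the first
#' and second half of each self-controllable block (the middle trial of
#' an odd-length block goes to the first half).
#'
#' @param session a \code{"mabc_session"} with a schedule (simulated).
#' @return a named list of proportions (\code{NA} where the conditioning
#'   cell is empty): \code{overall}, \code{after_self_report},
#'   \code{after_other_report}, \code{first_half}, \code{second_half}.
#' @export
optimal_choice_stats <- function(session) {
  tr <- session$trials
  sch <- session$schedule
  if (is.null(sch)) stop("optimal_choice_stats needs a session with a schedule")
  self_tr <- which(tr$true_controller == "self")
  if (!length(self_tr)) stop("no self-controllable trials")
  opt <- tr$action_self == sch$optimal_action
  prop <- function(idx) if (length(idx)) mean(opt[idx]) else NA_real_

  # conditioning on the most recent preceding probe answer (same task)
  last_resp <- rep(NA_character_, nrow(tr))
  cur <- NA_character_; cur_task <- NA_integer_
  for (k in seq_len(nrow(tr))) {
    if (!identical(cur_task, tr$task_id[k])) { cur <- NA_character_; cur_task <- tr$task_id[k] }
    last_resp[k] <- cur
    if (tr$probe[k] == "causality" && !is.na(tr$probe_response[k]))
      cur <- tr$probe_response[k]
  }
  # half split within each self block
  halves <- rep(NA_character_, nrow(tr))
  for (b in unique(sch$block[self_tr])) {
    idx <- which(sch$block == b)
    n1 <- ceiling(length(idx) / 2)
    halves[idx[seq_len(n1)]] <- "first"
    halves[idx[-seq_len(n1)]] <- "second"
  }
  list(overall = prop(self_tr),
       after_self_report = prop(self_tr[!is.na(last_resp[self_tr]) &
                                          last_resp[self_tr] == "self"]),
       after_other_report = prop(self_tr[!is.na(last_resp[self_tr]) &
                                           last_resp[self_tr] == "other"]),
       first_half = prop(self_tr[halves[self_tr] == "first"]),
       second_half = prop(self_tr[halves[self_tr] == "second"]))
}

#' Partial correlation controlling for one covariate
#'
#' Pearson correlation of the residuals of \code{x} and \code{y} after
#' linear regression on the covariate, with the p-value from the t
#' distribution on n - 3 degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @param covariate numeric (or coercible) vector of the same length.
#' @return a list with \code{r}, \code{p}, \code{n}.
#' @export
partial_corr <- function(x, y, covariate) {
  n <- length(x)
  stopifnot(length(y) == n, length(covariate) == n, n >= 4)
  covariate <- as.numeric(covariate)
  rx <- residuals(lm(x ~ covariate))
  ry <- residuals(lm(y ~ covariate))
  if (sd(rx) <= 1e-10 * max(sd(x), 1) || sd(ry) <= 1e-10 * max(sd(y), 1))
    stop("degenerate input: residuals are constant")
  r <- cor(rx, ry)
  df <- n - 3
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), df), n = n)
}

#' @importFrom stats sd
NULL
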