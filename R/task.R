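#' Configuration of the changing-controllability task
#'
#' Describes the two-person two-armed bandit task in which exactly one
#' player (the "controller") determines the shared outcome at any time.
#' The controller alternates between the subject (self) and the partner
#' (other) in blocks of 20--30 trials; only the controller has an optimal
#' option, which pays reward with probability \code{p_reward_optimal}.
#' Causality probes ("who caused the outcome?") are interleaved every
#' 2--3 trials in task 2; task 1 carries mood probes in the same slots
#' (recorded as placeholders).
#'
#' @param n_tasks number of task sessions (default 2).
#' @param trials_per_task trials per task session (default 100).
#' @param block_len_min,block_len_max admissible block lengths (default 20, 30).
#' @param n_self_blocks,n_other_blocks number of self-/other-controllable
#'   blocks over the whole run (default 4 each).
#' @param p_reward_optimal reward probability of the controller's optimal
#'   option (default 0.8); the other option rewards with its complement.
#' @param probe_gaps set of admissible gaps (in trials) between probes
#'   (default \code{c(2, 3)}).
#' @param first_block_self logical; does the run start with a
#'   self-controllable block (default \code{TRUE})?
#' @return an object of class \code{"mabc_task_config"}.
#' @examples
#' cfg <- task_config()
#' cfg$trials_per_task * cfg$n_tasks  # 200 trials
#' @export
task_config <- function(n_tasks = 2L, trials_per_task = 100L,
                        block_len_min = 20L, block_len_max = 30L,
                        n_self_blocks = 4L, n_other_blocks = 4L,
                        p_reward_optimal = 0.8,
                        probe_gaps = c(2L, 3L),
                        first_block_self = TRUE) {
  n_tasks <- as.integer(n_tasks)
  trials_per_task <- as.integer(trials_per_task)
  block_len_min <- as.integer(block_len_min)
  block_len_max <- as.integer(block_len_max)
  n_self_blocks <- as.integer(n_self_blocks)
  n_other_blocks <- as.integer(n_other_blocks)
  probe_gaps <- as.integer(probe_gaps)
  if (p_reward_optimal <= 0 || p_reward_optimal >= 1)
    stop("p_reward_optimal must lie strictly between 0 and 1")
  if (block_len_min < 1L || block_len_max < block_len_min)
    stop("block length bounds must satisfy 1 <= min <= max")
  n_blocks <- n_self_blocks + n_other_blocks
  total <- n_tasks * trials_per_task
  if (total < n_blocks * block_len_min || total > n_blocks * block_len_max)
    stop("infeasible schedule: ", n_blocks, " blocks of length [",
         block_len_min, ", ", block_len_max, "] cannot sum to ", total,
         " trials")
  # strict alternation constrains the block counts
  d <- abs(n_self_blocks - n_other_blocks)
  if (d > 1L || (d == 1L && first_block_self != (n_self_blocks > n_other_blocks)))
    stop("block counts incompatible with strict alternation")
  if (any(probe_gaps < 1L)) stop("probe gaps must be positive")
  structure(list(n_tasks = n_tasks, trials_per_task = trials_per_task,
                 block_len_min = block_len_min, block_len_max = block_len_max,
                 n_self_blocks = n_self_blocks, n_other_blocks = n_other_blocks,
                 p_reward_optimal = p_reward_optimal,
                 probe_gaps = probe_gaps,
                 first_block_self = isTRUE(first_block_self)),
            class = "mabc_task_config")
}

#' Read a task configuration from a YAML file
#'
#' The YAML keys mirror the arguments of \code{\link{task_config}} exactly;
#' missing keys take their defaults.
#'
#' @param path path to a YAML file.
#' @return an object of class \code{"mabc_task_config"}.
#' @export
read_task_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(task_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown task config fields: ", paste(bad, collapse = ", "))
  do.call(task_config, vals)
}

#' Generate a controllability schedule
#'
#' Draws alternating self-/other-controllable blocks whose lengths are
#' i.i.d. uniform on \code{[block_len_min, block_len_max]}, conditioned by
#' rejection on summing exactly to the total trial count. Each block is
#' assigned a uniformly drawn optimal option for its controller; the
#' optimal option may differ between blocks of the same controller.
#' Uses the current R random number generator state.
#'
#' @param config a \code{\link{task_config}} object.
#' @param max_tries maximum rejection-sampler attempts before failing.
#' @return an object of class \code{"mabc_schedule"}: a list with
#'   \code{controller} (character vector "self"/"other" per trial),
#'   \code{optimal_action} (the subject's optimal option, \code{NA} in
#'   other-controllable blocks), \code{controller_optimal} (the acting
#'   controller's optimal option, always defined), \code{block} (block
#'   index per trial), \code{block_boundaries} (first trial of each
#'   block), \code{block_lengths}, and \code{probes} (a data frame of
#'   probe trials and types).
#' @examples
#' set.seed(1)
#' sch <- generate_schedule(task_config())
#' table(sch$controller)
#' @export
generate_schedule <- function(config, max_tries = 100000L) {
  stopifnot(inherits(config, "mabc_task_config"))
  n_blocks <- config$n_self_blocks + config$n_other_blocks
  total <- config$n_tasks * config$trials_per_task
  lens <- NULL
  if (config$block_len_min == config$block_len_max) {
    if (n_blocks * config$block_len_min != total)
      stop("infeasible schedule with forced block length")
    lens <- rep(config$block_len_min, n_blocks)
  } else {
    for (i in seq_len(max_tries)) {
      cand <- sample(config$block_len_min:config$block_len_max, n_blocks,
                     replace = TRUE)
      if (sum(cand) == total) { lens <- cand; break }
    }
    if (is.null(lens))
      stop("rejection sampler failed to find a feasible block composition")
  }
  first <- if (config$first_block_self) "self" else "other"
  second <- if (config$first_block_self) "other" else "self"
  ctrl_blocks <- rep(c(first, second), length.out = n_blocks)
  controller <- rep(ctrl_blocks, lens)
  block <- rep(seq_len(n_blocks), lens)
  # per-block optimal option for the block's controller
  block_opt <- sample(c("left", "right"), n_blocks, replace = TRUE)
  controller_optimal <- rep(block_opt, lens)
  optimal_action <- ifelse(controller == "self", controller_optimal, NA_character_)
  boundaries <- cumsum(c(1L, lens[-n_blocks]))

  # probe slots: i.i.d. gaps within each task, mood in task 1, causality after
  probes <- do.call(rbind, lapply(seq_len(config$n_tasks), function(t) {
    gaps <- integer(0)
    pos <- 0L
    repeat {
      g <- if (length(config$probe_gaps) == 1L) config$probe_gaps else
        sample(config$probe_gaps, 1L)
      pos <- pos + g
      if (pos > config$trials_per_task) break
      gaps <- c(gaps, pos)
    }
    if (!length(gaps)) return(NULL)
    data.frame(trial = gaps + (t - 1L) * config$trials_per_task,
               task_id = t,
               type = if (t == 1L) "mood" else "causality",
               stringsAsFactors = FALSE)
  }))
  structure(list(controller = controller,
                 optimal_action = optimal_action,
                 controller_optimal = controller_optimal,
                 block = block,
                 block_boundaries = boundaries,
                 block_lengths = lens,
                 probes = probes,
                 config = config),
            class = "mabc_schedule")
}

#' @export
print.mabc_schedule <- function(x, ...) {
  cat("Controllability schedule:", length(x$controller), "trials,",
      length(x$block_lengths), "blocks\n")
  cat("  block lengths:", paste(x$block_lengths, collapse = " "), "\n")
  cat("  controllers:  ",
      paste(rep(c(x$controller[1],
                  setdiff(c("self", "other"), x$controller[1])),
                length.out = length(x$block_lengths)), collapse = " "), "\n")
  invisible(x)
}

#' Rescorla-Wagner partner agent
#'
#' The artificial partner learns the action-outcome contingency with a
#' fixed-rate delta rule and chooses by a softmax on its two action
#' values. Defaults match the study's agent (learning rate 0.3, inverse
#' temperature 1.5); action values start at the uninformative 0.5.
#'
#' @param learning_rate delta-rule learning rate in (0,1).
#' @param inv_temp softmax inverse temperature (non-negative).
#' @param q_init initial action values, \code{c(left, right)}.
#' @return an object of class \code{"rw_agent"}.
#' @export
partner_agent <- function(learning_rate = 0.3, inv_temp = 1.5,
                          q_init = c(0.5, 0.5)) {
  stopifnot(learning_rate > 0, learning_rate < 1, inv_temp >= 0,
            length(q_init) == 2)
  structure(list(learning_rate = learning_rate, inv_temp = inv_temp,
                 q = as.numeric(q_init)),
            class = "rw_agent")
}

#' One softmax choice of the partner agent
#'
#' @param state an \code{\link{partner_agent}} object.
#' @return \code{"left"} or \code{"right"}, drawn with
#'   \code{p(right) = 1 / (1 + exp(-inv_temp * (q_right - q_left)))}.
#' @export
partner_step <- function(state) {
  p_right <- .inv_logit(state$inv_temp * (state$q[2] - state$q[1]))
  if (runif(1) < p_right) "right" else "left"
}

#' Delta-rule update of the partner agent
#'
#' Only the chosen action's value moves: \code{q <- q + lr * (outcome - q)}.
#'
#' @param state an \code{\link{partner_agent}} object.
#' @param action \code{"left"} or \code{"right"}.
#' @param outcome 0 (loss) or 1 (reward).
#' @return the updated agent state.
#' @export
partner_update <- function(state, action, outcome) {
  stopifnot(outcome %in% c(0, 1))
  i <- match(action, c("left", "right"))
  if (is.na(i)) stop("invalid action: ", action)
  state$q[i] <- state$q[i] + state$learning_rate * (outcome - state$q[i])
  state
}

#' Draw outcomes from the task's reward engine
#'
#' Only the controller's action matters: reward arrives with probability
#' \code{p_reward_optimal} when the controller picked the block's optimal
#' option and with its complement otherwise. Vectorized over trials.
#'
#' @param schedule a \code{\link{generate_schedule}} object.
#' @param trial trial index (1-based), possibly a vector.
#' @param action_controller the controller's action on each trial.
#' @return integer vector of outcomes (1 reward, 0 loss).
#' @export
draw_outcome <- function(schedule, trial, action_controller) {
  stopifnot(inherits(schedule, "mabc_schedule"))
  if (any(trial < 1L | trial > length(schedule$controller)))
    stop("trial index outside schedule")
  p_opt <- schedule$config$p_reward_optimal
  p <- ifelse(action_controller == schedule$controller_optimal[trial],
              p_opt, 1 - p_opt)
  rbinom(length(trial), 1L, p)
}

#' Random subject policy
#'
#' Chooses left/right with fixed probability and answers causality probes
#' uniformly at random. Useful as a null subject for the simulator.
#'
#' @param p_right probability of choosing "right".
#' @param p_report_self probability of answering "self" on a probe.
#' @return a policy object usable with \code{\link{simulate_session}}.
#' @export
policy_random <- function(p_right = 0.5, p_report_self = 0.5) {
  structure(list(
    reset = function() invisible(NULL),
    act = function() if (runif(1) < p_right) "right" else "left",
    observe = function(action_self, action_other, outcome) invisible(NULL),
    probe_answer = function() if (runif(1) < p_report_self) "self" else "other"
  ), class = "mabc_policy")
}

#' Simulate one full session of the task
#'
#' Runs the subject policy against the Rescorla-Wagner partner on a
#' freshly drawn schedule. The partner acts and learns on every trial
#' whether or not it is in control; outcomes depend only on the
#' controller's action. Probe trials are answered by the subject policy
#' (causality probes) or recorded as placeholders (mood probes).
#'
#' @param config a \code{\link{task_config}}.
#' @param subject a policy object (see \code{\link{policy_random}},
#'   \code{\link{policy_mabc}}): a list with functions \code{reset()},
#'   \code{act()}, \code{observe(action_self, action_other, outcome)} and
#'   \code{probe_answer()}.
#' @param partner a \code{\link{partner_agent}}.
#' @param seed integer seed; the session is bit-for-bit reproducible
#'   given (config, policies, seed).
#' @param schedule optionally a pre-generated \code{\link{generate_schedule}}
#'   object (drawn fresh when \code{NULL}).
#' @return an object of class \code{"mabc_session"}: a list with
#'   \code{trials} (data frame with columns \code{trial}, \code{task_id},
#'   \code{true_controller}, \code{action_self}, \code{action_other},
#'   \code{outcome}, \code{probe}, \code{probe_response}),
#'   \code{schedule}, \code{config}, \code{generator_params}, \code{seed}.
#' @examples
#' s <- simulate_session(task_config(), policy_random(), seed = 1)
#' nrow(s$trials)
#' @export
simulate_session <- function(config, subject, partner = partner_agent(),
                             seed = NULL, schedule = NULL) {
  stopifnot(inherits(config, "mabc_task_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(schedule)) schedule <- generate_schedule(config)
  n <- length(schedule$controller)
  subject$reset()
  probe_type <- rep("none", n)
  if (!is.null(schedule$probes))
    probe_type[schedule$probes$trial] <- schedule$probes$type
  q <- partner$q
  lr <- partner$learning_rate
  it <- partner$inv_temp
  action_self <- character(n); action_other <- character(n)
  outcome <- integer(n); probe_response <- rep(NA_character_, n)
  p_opt <- config$p_reward_optimal
  for (k in seq_len(n)) {
    a_s <- subject$act()
    if (!identical(a_s, "left") && !identical(a_s, "right"))
      stop("subject policy returned invalid action at trial ", k)
    p_right <- 1 / (1 + exp(-it * (q[2] - q[1])))
    a_o <- if (runif(1) < p_right) "right" else "left"
    a_ctrl <- if (schedule$controller[k] == "self") a_s else a_o
    p <- if (a_ctrl == schedule$controller_optimal[k]) p_opt else 1 - p_opt
    o <- rbinom(1L, 1L, p)
    i <- if (a_o == "right") 2L else 1L
    q[i] <- q[i] + lr * (o - q[i])
    subject$observe(a_s, a_o, o)
    if (probe_type[k] == "causality") {
      r <- subject$probe_answer()
      if (!r %in% c("self", "other"))
        stop("subject policy returned invalid probe answer at trial ", k)
      probe_response[k] <- r
    }
    action_self[k] <- a_s; action_other[k] <- a_o; outcome[k] <- o
  }
  trials <- data.frame(
    trial = seq_len(n),
    task_id = rep(seq_len(config$n_tasks), each = config$trials_per_task),
    true_controller = schedule$controller,
    action_self = action_self,
    action_other = action_other,
    outcome = outcome,
    probe = probe_type,
    probe_response = probe_response,
    stringsAsFactors = FALSE)
  structure(list(trials = trials, schedule = schedule, config = config,
                 generator_params = attr(subject, "params"),
                 partner_params = c(learning_rate = lr, inv_temp = it),
                 seed = seed),
            class = "mabc_session")
}

#' @export
print.mabc_session <- function(x, ...) {
  cat("Session log:", nrow(x$trials), "trials,",
      sum(x$trials$probe == "causality"), "causality probes,",
      sum(x$trials$probe == "mood"), "mood probes\n")
  cat("  reward rate:", round(mean(x$trials$outcome), 3), "\n")
  invisible(x)
}

.session_vocab <- list(
  true_controller = c("self", "other"),
  action_self = c("left", "right"),
  action_other = c("left", "right"),
  probe = c("none", "causality", "mood"),
  probe_response = c("self", "other", NA_character_))

#' Write a session trial log to CSV
#'
#' One row per trial with 1-based trial indices and the controlled
#' vocabularies used throughout the package.
#'
#' @param session a \code{"mabc_session"} object.
#' @param path output file path.
#' @export
write_session <- function(session, path) {
  write.csv(session$trials, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Construct a session from a trial table
#'
#' Validates the controlled vocabularies and trial index of a hand-built
#' (or externally produced) per-trial table and wraps it as a session
#' object usable with the likelihood and statistics functions.
#'
#' @param trials data frame with columns \code{trial}, \code{task_id},
#'   \code{true_controller}, \code{action_self}, \code{action_other},
#'   \code{outcome}, \code{probe}, \code{probe_response}.
#' @param schedule optional \code{\link{generate_schedule}} object.
#' @param config optional \code{\link{task_config}}.
#' @return an object of class \code{"mabc_session"}.
#' @export
mabc_session <- function(trials, schedule = NULL, config = NULL) {
  need <- c("trial", "task_id", "true_controller", "action_self",
            "action_other", "outcome", "probe", "probe_response")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!identical(as.integer(trials$trial), seq_len(nrow(trials))))
    stop("trial index must be the contiguous sequence 1..n")
  for (col in names(.session_vocab)) {
    bad <- !trials[[col]] %in% .session_vocab[[col]]
    if (any(bad))
      stop("invalid value in column ", col, " at trial ",
           trials$trial[which(bad)[1]], ": ", trials[[col]][which(bad)[1]])
  }
  if (!all(trials$outcome %in% c(0L, 1L))) stop("outcome must be 0 or 1")
  structure(list(trials = trials, schedule = schedule, config = config,
                 generator_params = NULL, seed = NULL),
            class = "mabc_session")
}

#' Read a session trial log from CSV
#'
#' Validates the controlled vocabularies and that the trial index is a
#' contiguous 1-based sequence. The returned object carries no schedule
#' (the true controller column is retained per trial).
#'
#' @param path CSV path as written by \code{\link{write_session}}.
#' @param config optional \code{\link{task_config}} to attach.
#' @return an object of class \code{"mabc_session"}.
#' @export
read_session <- function(path, config = NULL) {
  tr <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(probe_response = "character"))
  mabc_session(tr, config = config)
}
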