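#' Sample natural-space parameters from the priors
#'
#' Draws each free parameter of a variant from its transformed-space
#' Gaussian prior and maps it back to natural space; pinned parameters
#' take their pinned values.
#'
#' @param n number of parameter vectors.
#' @param spec a \code{\link{mabc_spec}}.
#' @param priors a \code{\link{mabc_priors}}.
#' @return a matrix (n x 8) of full natural-space parameter vectors.
#' @export
sample_params <- function(n, spec = mabc_spec("mabc_full"),
                          priors = mabc_priors()) {
  base <- .complete_params(mabc_params(), spec)
  out <- matrix(rep(base, each = n), n, length(base),
                dimnames = list(NULL, .mabc_par_names))
  for (nm in spec$free) {
    v <- rnorm(n, priors[nm, "mean"], sqrt(priors[nm, "variance"]))
    out[, nm] <- .untransform_one(v, priors[nm, "transform"])
  }
  out
}

#' Behaviorally plausible generative parameter distribution
#'
#' An informative counterpart of \code{\link{mabc_priors}} used to
#' generate recovery cohorts: transformed-space Gaussians centred on
#' values representative of fitted human subjects (learning rates near
#' 0.3, a positive reward bias and negative loss bias, clear value
#' utilization, moderate choice and report temperatures) with moderate
#' between-subject spread. Sampling simulated cohorts from this
#' distribution keeps their behavior informative about the generating
#' variant; the diffuse default prior would often produce degenerate
#' subjects (for example a report temperature near zero) whose data
#' cannot distinguish the variants at all.
#'
#' @return an object of class \code{"mabc_priors"}.
#' @export
cohort_priors <- function() {
  mabc_priors(
    mean = c(a_self = .logit(0.3), a_other = .logit(0.3),
             bias_pos = 0.23, bias_neg = -0.26,
             beta0 = log(2), tau = 0.74, theta = .logit(0.2),
             beta_con = log(2)),
    variance = c(a_self = 0.25, a_other = 0.25, bias_pos = 0.25,
                 bias_neg = 0.25, beta0 = 0.1, tau = 0.1, theta = 0.25,
                 beta_con = 0.1))
}

#' Parameter-recovery experiment
#'
#' Samples subject parameters from the priors, simulates one session per
#' subject, refits the generating variant by MAP, and reports the
#' Pearson correlation between true and recovered values of every free
#' parameter (in the estimation space, where the prior is Gaussian).
#'
#' @param n_subjects number of simulated subjects (>= 10).
#' @param config a \code{\link{task_config}}.
#' @param model variant label or \code{\link{mabc_spec}}.
#' @param priors a \code{\link{mabc_priors}}.
#' @param seed master seed (drives parameter draws, sessions, and fits).
#' @param n_restarts optimizer restarts per fit.
#' @return an object of class \code{"mabc_recovery"}: a list with
#'   \code{true} and \code{recovered} matrices (transformed space),
#'   \code{true_natural}, \code{recovered_natural}, and a
#'   \code{correlations} data frame (parameter, r, p).
#' @export
parameter_recovery <- function(n_subjects = 200, config = task_config(),
                               model = "mabc_full", priors = mabc_priors(),
                               seed = 1, n_restarts = 2) {
  stopifnot(n_subjects >= 10)
  spec <- if (inherits(model, "mabc_spec")) model else mabc_spec(model)
  set.seed(seed)
  true_nat <- sample_params(n_subjects, spec, priors)
  session_seeds <- sample.int(2^31 - 2, n_subjects)
  free <- spec$free
  rec_nat <- matrix(NA_real_, n_subjects, length(free),
                    dimnames = list(NULL, free))
  for (i in seq_len(n_subjects)) {
    s <- simulate_subject(config, true_nat[i, ], spec,
                          seed = session_seeds[i])
    f <- mabc_fit(s, spec, priors, n_restarts = n_restarts,
                  seed = (seed * 7901L + i) %% 2147483647L)
    if (!is.null(f$coefficients)) rec_nat[i, ] <- f$coefficients[free]
  }
  tru <- vapply(free, function(nm)
    .transform_one(true_nat[, nm], priors[nm, "transform"]),
    numeric(n_subjects))
  rec <- vapply(free, function(nm)
    .transform_one(rec_nat[, nm], priors[nm, "transform"]),
    numeric(n_subjects))
  cors <- do.call(rbind, lapply(free, function(nm) {
    ok <- is.finite(tru[, nm]) & is.finite(rec[, nm])
    ct <- cor.test(tru[ok, nm], rec[ok, nm])
    data.frame(parameter = nm, r = unname(ct$estimate),
               p = ct$p.value, n = sum(ok), stringsAsFactors = FALSE)
  }))
  structure(list(true = tru, recovered = rec,
                 true_natural = true_nat[, free, drop = FALSE],
                 recovered_natural = rec_nat,
                 correlations = cors, seed = seed,
                 n_subjects = n_subjects, model = spec$label),
            class = "mabc_recovery")
}

#' @export
print.mabc_recovery <- function(x, digits = 3, ...) {
  cat("Parameter recovery, variant '", x$model, "', ", x$n_subjects,
      " simulated subjects\n", sep = "")
  print(transform(x$correlations, r = round(r, digits),
                  p = signif(p, digits)))
  invisible(x)
}

#' Model-recovery experiment
#'
#' For each generating variant, simulates a cohort (parameters drawn from
#' the priors), fits every candidate variant to every subject, runs
#' random-effects Bayesian model selection on the resulting log model
#' evidences, and records which variant wins (highest protected
#' exceedance probability).
#'
#' @param models character vector of variant labels (>= 2).
#' @param n_subjects_per_model cohort size per generating variant.
#' @param config a \code{\link{task_config}}.
#' @param priors a \code{\link{mabc_priors}} used for fitting.
#' @param gen_priors distribution from which the generating cohorts'
#'   parameters are sampled (default \code{\link{cohort_priors}()}).
#' @param seed master seed.
#' @param n_restarts optimizer restarts per fit.
#' @param n_samples Monte Carlo samples for the exceedance probabilities.
#' @return an object of class \code{"mabc_model_recovery"}: a list with
#'   \code{confusion} (generator x winner indicator matrix, rows sum to
#'   1), \code{pep} (generator x candidate protected exceedance
#'   probabilities), and \code{bms} (one \code{"mabc_bms"} per cohort).
#' @export
model_recovery <- function(models = c("mabc_full", "flat", "single_agent"),
                           n_subjects_per_model = 20,
                           config = task_config(), priors = mabc_priors(),
                           gen_priors = cohort_priors(),
                           seed = 1, n_restarts = 2, n_samples = 1e5) {
  stopifnot(length(models) >= 2)
  K <- length(models)
  confusion <- matrix(0, K, K, dimnames = list(generator = models,
                                               winner = models))
  pep <- matrix(NA_real_, K, K, dimnames = list(generator = models,
                                                candidate = models))
  bms_list <- vector("list", K)
  names(bms_list) <- models
  for (gi in seq_len(K)) {
    gspec <- mabc_spec(models[gi])
    set.seed(seed * 131L + gi)
    pars <- sample_params(n_subjects_per_model, gspec, gen_priors)
    seeds <- sample.int(2^31 - 2, n_subjects_per_model)
    sessions <- lapply(seq_len(n_subjects_per_model), function(i)
      simulate_subject(config, pars[i, ], gspec, seed = seeds[i]))
    fp <- fit_population(sessions, models, priors, n_restarts = n_restarts,
                         seed = seed * 977L + gi)
    bms <- rfx_bms(fp$lme, n_samples = n_samples, seed = seed * 17L + gi)
    win <- which.max(bms$pep)
    confusion[gi, win] <- 1
    pep[gi, ] <- bms$pep
    bms_list[[gi]] <- bms
  }
  structure(list(confusion = confusion, pep = pep, bms = bms_list,
                 n_subjects_per_model = n_subjects_per_model, seed = seed),
            class = "mabc_model_recovery")
}

#' @export
print.mabc_model_recovery <- function(x, digits = 3, ...) {
  cat("Model recovery,", x$n_subjects_per_model,
      "subjects per generating variant\nProtected exceedance probabilities:\n")
  print(round(x$pep, digits))
  invisible(x)
}

#' @importFrom stats cor.test
NULL
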