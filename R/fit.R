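#' Prior specification for MAP estimation
#'
#' Each parameter is estimated in a transformed space in which its prior
#' is Gaussian: unit-interval parameters (\code{a_self}, \code{a_other},
#' \code{theta}) in logit space, positive parameters (\code{beta0},
#' \code{beta_con}) in log space, and the unconstrained parameters
#' (\code{bias_pos}, \code{bias_neg}, \code{tau}) in identity space.
#' The default hyperparameters are weakly informative transformed-space
#' Gaussians with mean 0 and variance 4 for every parameter; both can be
#' overridden per parameter.
#'
#' @param mean named numeric vector of transformed-space prior means
#'   (entries override the default 0).
#' @param variance named numeric vector of transformed-space prior
#'   variances (entries override the default 4).
#' @return an object of class \code{"mabc_priors"}: a data frame with one
#'   row per parameter and columns \code{transform}, \code{mean},
#'   \code{variance}.
#' @examples
#' mabc_priors()
#' mabc_priors(mean = c(beta0 = log(2)), variance = c(tau = 1))
#' @export
mabc_priors <- function(mean = NULL, variance = NULL) {
  out <- data.frame(
    parameter = .mabc_par_names,
    transform = c("logit", "logit", "identity", "identity",
                  "log", "identity", "logit", "log"),
    mean = 0, variance = 4,
    stringsAsFactors = FALSE)
  rownames(out) <- out$parameter
  if (!is.null(mean)) {
    stopifnot(all(names(mean) %in% .mabc_par_names))
    out[names(mean), "mean"] <- mean
  }
  if (!is.null(variance)) {
    stopifnot(all(names(variance) %in% .mabc_par_names), all(variance > 0))
    out[names(variance), "variance"] <- variance
  }
  class(out) <- c("mabc_priors", "data.frame")
  out
}

.transform_one <- function(x, kind) {
  switch(kind,
         logit = .logit(x),
         log = log(x),
         identity = x,
         stop("unknown transform: ", kind))
}

.untransform_one <- function(v, kind) {
  switch(kind,
         logit = .inv_logit(v),
         # cap to keep the optimizer's excursions finite
         log = exp(pmin(v, 50)),
         identity = v,
         stop("unknown transform: ", kind))
}

#' Map natural-space parameters to estimation space and back
#'
#' @param params named natural-space parameter vector.
#' @param priors a \code{\link{mabc_priors}} object.
#' @param which parameter names to include (default: all in
#'   \code{params}).
#' @return a named vector in the other space.
#' @export
transform_params <- function(params, priors = mabc_priors(),
                             which = names(params)) {
  vapply(which, function(nm) .transform_one(params[[nm]],
                                            priors[nm, "transform"]),
         numeric(1))
}

#' @rdname transform_params
#' @param v named transformed-space vector.
#' @export
untransform_params <- function(v, priors = mabc_priors(),
                               which = names(v)) {
  vapply(which, function(nm) .untransform_one(v[[nm]],
                                              priors[nm, "transform"]),
         numeric(1))
}

# negative log joint (data + transformed-space Gaussian prior) over the
# free parameters of a spec; enc is a pre-encoded session
.make_objective <- function(enc, spec, priors, pinned_full) {
  free <- spec$free
  kinds <- priors[free, "transform"]
  mu <- priors[free, "mean"]
  sd <- sqrt(priors[free, "variance"])
  use_other <- spec$use_other_likelihood
  mirrored <- spec$mirrored_update
  log_odds <- spec$report_form == "log_odds"
  idx <- match(free, .mabc_par_names)
  base <- pinned_full
  function(v) {
    nat <- numeric(length(v))
    for (i in seq_along(v)) nat[i] <- .untransform_one(v[i], kinds[i])
    par <- base
    par[idx] <- nat
    ll <- mabc_loglik_cpp(enc$a_self, enc$a_other, enc$outcome, enc$is_probe,
                          enc$resp_self, par, use_other, mirrored, log_odds)
    lp <- sum(dnorm(v, mu, sd, log = TRUE))
    if (!is.finite(ll)) return(1e12)
    -(ll + lp)
  }
}

# symmetric finite-difference Hessian of f at x (relative step)
.fd_hessian <- function(f, x, rel_step = 1e-4) {
  d <- length(x)
  h <- rel_step * pmax(1, abs(x))
  H <- matrix(0, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(d), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

#' Laplace-approximate log model evidence
#'
#' \code{LME = log-joint(MAP) + (d/2) log(2 pi) - 0.5 log det(H)} where
#' \code{H} is the curvature (negative Hessian of the log joint) at the
#' MAP in the estimation space. A non-positive-definite curvature is
#' regularized by an added ridge (with a warning recorded by
#' \code{\link{mabc_fit}}).
#'
#' @param log_joint value of the log joint at the MAP.
#' @param hessian curvature matrix (negative log-joint Hessian) at the
#'   MAP; may be a 0 x 0 matrix for a model without free parameters.
#' @param ridge ridge added to the diagonal when the Cholesky
#'   factorization fails.
#' @return the scalar LME, with attribute \code{"ridged"} flagging
#'   whether the ridge was needed.
#' @export
laplace_lme <- function(log_joint, hessian, ridge = 1e-6) {
  d <- nrow(hessian)
  if (is.null(d) || d == 0)
    return(structure(log_joint, ridged = FALSE))
  ch <- tryCatch(chol(hessian), error = function(e) NULL)
  ridged <- FALSE
  if (is.null(ch)) {
    ch <- tryCatch(chol(hessian + diag(ridge, d)), error = function(e) NULL)
    ridged <- TRUE
    if (is.null(ch)) stop("curvature matrix singular even after ridge; ",
                          "model evidence undefined")
  }
  logdet <- 2 * sum(log(diag(ch)))
  structure(log_joint + d / 2 * log(2 * pi) - 0.5 * logdet, ridged = ridged)
}

#' Fit an MABC variant to a session by MAP with Laplace model evidence
#'
#' Maximizes the log joint (session log-likelihood plus transformed-space
#' Gaussian prior) over the variant's free parameters with a quasi-Newton
#' optimizer (BFGS), restarted from the prior mean plus seeded Gaussian
#' jitter. The curvature at the optimum (finite differences) yields the
#' Laplace approximation of the log model evidence.
#'
#' @param session a \code{"mabc_session"} (simulated or read from CSV).
#' @param model variant label or a \code{\link{mabc_spec}} object.
#' @param priors a \code{\link{mabc_priors}} object.
#' @param n_restarts number of optimizer starts (>= 1).
#' @param seed integer seed controlling the restart jitter.
#' @param jitter_sd standard deviation of the restart jitter in the
#'   estimation space.
#' @param control control list passed to \code{\link[stats]{optim}}.
#' @return an object of class \code{"mabc_fit"} with components
#'   \code{coefficients} (natural space), \code{coefficients_transformed},
#'   \code{log_joint}, \code{loglik} (data log-likelihood at the MAP),
#'   \code{lme}, \code{hessian}, \code{converged}, \code{ridged},
#'   \code{n_restarts_used}, \code{spec}, \code{priors}, \code{session}.
#'   Methods: \code{print}, \code{summary}, \code{coef}, \code{logLik},
#'   \code{vcov}, \code{predict}, \code{simulate}, \code{residuals},
#'   \code{plot}.
#' @examples
#' \donttest{
#' s <- simulate_subject(task_config(), mabc_params(bias_pos = 0.3,
#'   tau = 0.7, beta0 = 2, theta = 0.2), seed = 1)
#' f <- mabc_fit(s, "mabc_full", n_restarts = 2, seed = 1)
#' coef(f)
#' }
#' @export
mabc_fit <- function(session, model = "mabc_full", priors = mabc_priors(),
                     n_restarts = 10, seed = NULL, jitter_sd = 1,
                     control = list(maxit = 500)) {
  spec <- if (inherits(model, "mabc_spec")) model else mabc_spec(model)
  stopifnot(n_restarts >= 1)
  if (!is.null(seed)) set.seed(seed)
  enc <- .encode_session(session)
  pinned_full <- .complete_params(mabc_params(), spec)
  free <- spec$free
  d <- length(free)
  nll <- .make_objective(enc, spec, priors, pinned_full)

  if (d == 0) {
    lj <- -nll(numeric(0))
    H <- matrix(0, 0, 0)
    lme <- laplace_lme(lj, H)
    fit <- list(coefficients = untransform_params(
                  setNames(numeric(0), character(0)), priors),
                coefficients_transformed = setNames(numeric(0), character(0)),
                log_joint = lj, loglik = lj, lme = as.numeric(lme),
                hessian = H, converged = TRUE, ridged = FALSE,
                n_restarts_used = 0L, spec = spec, priors = priors,
                session = session)
    class(fit) <- "mabc_fit"
    return(fit)
  }

  mu <- priors[free, "mean"]
  best <- NULL
  n_used <- 0L
  any_conv <- FALSE
  for (r in seq_len(n_restarts)) {
    start <- if (r == 1) mu else mu + rnorm(d, 0, jitter_sd)
    res <- tryCatch(optim(start, nll, method = "BFGS", control = control),
                    error = function(e) NULL)
    if (is.null(res)) next
    n_used <- n_used + 1L
    if (res$convergence == 0) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    return(structure(list(converged = FALSE, spec = spec, priors = priors,
                          session = session, lme = NA_real_,
                          n_restarts_used = n_used),
                     class = "mabc_fit"))
  v <- setNames(best$par, free)
  lj <- -best$value
  H <- .fd_hessian(nll, best$par)          # curvature of the negative
  H <- (H + t(H)) / 2                      # log joint = -log-joint Hessian
  lme <- laplace_lme(lj, H)
  nat <- untransform_params(v, priors)
  full_nat <- pinned_full
  full_nat[free] <- nat
  ll_data <- mabc_loglik(session, full_nat, spec)
  fit <- list(coefficients = nat, coefficients_transformed = v,
              log_joint = lj, loglik = ll_data, lme = as.numeric(lme),
              hessian = H, converged = any_conv,
              ridged = isTRUE(attr(lme, "ridged")),
              n_restarts_used = n_used, spec = spec, priors = priors,
              session = session)
  class(fit) <- "mabc_fit"
  fit
}

#' @export
print.mabc_fit <- function(x, digits = 3, ...) {
  cat("MABC model fit, variant '", x$spec$label, "'\n", sep = "")
  if (!isTRUE(x$converged) && is.null(x$coefficients)) {
    cat("  all optimizer restarts failed\n")
    return(invisible(x))
  }
  if (length(x$coefficients)) {
    cat("  MAP parameters (natural space):\n")
    print(round(x$coefficients, digits))
  } else cat("  no free parameters\n")
  cat("  log-likelihood:", round(x$loglik, digits),
      "  log model evidence:", round(x$lme, digits), "\n")
  invisible(x)
}

#' @export
coef.mabc_fit <- function(object, space = c("natural", "transformed"), ...) {
  if (match.arg(space) == "natural") object$coefficients
  else object$coefficients_transformed
}

#' @export
logLik.mabc_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = nrow(object$session$trials), class = "logLik")
}

#' @export
vcov.mabc_fit <- function(object, ...) {
  if (!length(object$coefficients)) return(matrix(0, 0, 0))
  V <- solve(object$hessian)
  dimnames(V) <- list(names(object$coefficients), names(object$coefficients))
  V
}

#' @export
summary.mabc_fit <- function(object, ...) {
  se <- if (length(object$coefficients)) {
    sqrt(pmax(diag(solve(object$hessian)), 0))
  } else numeric(0)
  out <- list(fit = object,
              table = data.frame(
                estimate = object$coefficients,
                transformed = object$coefficients_transformed,
                se_transformed = se))
  class(out) <- "summary.mabc_fit"
  out
}

#' @export
print.summary.mabc_fit <- function(x, digits = 3, ...) {
  f <- x$fit
  cat("MABC model fit, variant '", f$spec$label, "'\n", sep = "")
  cat(nrow(f$session$trials), "trials,",
      sum(f$session$trials$probe == "causality"), "causality probes\n\n")
  if (nrow(x$table)) print(round(x$table, digits)) else
    cat("no free parameters\n")
  cat("\nlog-joint at MAP:", round(f$log_joint, digits),
      "\ndata log-likelihood:", round(f$loglik, digits),
      "\nLaplace log model evidence:", round(f$lme, digits), "\n")
  if (f$ridged) cat("note: curvature regularized by ridge\n")
  if (!f$converged) cat("warning: optimizer did not report convergence\n")
  invisible(x)
}

#' @export
predict.mabc_fit <- function(object, newdata = NULL,
                             type = c("trace", "choice", "report"), ...) {
  type <- match.arg(type)
  session <- if (is.null(newdata)) object$session else newdata
  full <- .complete_params(mabc_params(), object$spec)
  full[names(object$coefficients)] <- object$coefficients
  tr <- mabc_trace(session, full, object$spec)
  switch(type, trace = tr, choice = tr$p_choose_right,
         report = tr$p_report_self)
}

#' @export
simulate.mabc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  full <- .complete_params(mabc_params(), object$spec)
  full[names(object$coefficients)] <- object$coefficients
  seeds <- sample.int(2^31 - 2, nsim)
  lapply(seeds, function(s)
    simulate_subject(object$session$config, full, object$spec, seed = s))
}

#' @export
residuals.mabc_fit <- function(object, ...) {
  tr <- predict(object, type = "trace")
  as.integer(object$session$trials$action_self == "right") - tr$p_choose_right
}

#' @export
plot.mabc_fit <- function(x, ...) {
  tr <- predict(x, type = "trace")
  n <- nrow(tr)
  truth <- as.integer(x$session$trials$true_controller == "self")
  plot(seq_len(n), tr$posterior_self, type = "l", col = "steelblue",
       ylim = c(0, 1), xlab = "trial",
       ylab = "inferred p(self in control)", ...)
  lines(seq_len(n), truth, col = "grey40", lty = 2)
  probes <- which(x$session$trials$probe == "causality")
  if (length(probes))
    points(probes,
           ifelse(x$session$trials$probe_response[probes] == "self", 1, 0),
           pch = 4, col = "firebrick")
  legend("topright", c("posterior", "true controller", "report"),
         col = c("steelblue", "grey40", "firebrick"),
         lty = c(1, 2, NA), pch = c(NA, NA, 4), cex = 0.8, bg = "white")
  invisible(x)
}

#' Fit several model variants to a cohort of sessions
#'
#' Runs \code{\link{mabc_fit}} for every (session, variant) pair and
#' collects the Laplace log model evidences into the subjects-by-models
#' matrix consumed by \code{\link{rfx_bms}}. Per-fit seeds are derived
#' deterministically from \code{seed} and the pair's indices, so results
#' do not depend on execution order.
#'
#' @param sessions list of \code{"mabc_session"} objects.
#' @param models character vector of variant labels or list of
#'   \code{\link{mabc_spec}} objects.
#' @param priors a \code{\link{mabc_priors}}.
#' @param n_restarts optimizer restarts per fit.
#' @param seed integer master seed.
#' @return a list with \code{lme} (matrix, subjects x models) and
#'   \code{fits} (list of lists of \code{"mabc_fit"}).
#' @export
fit_population <- function(sessions, models, priors = mabc_priors(),
                           n_restarts = 10, seed = 1) {
  stopifnot(length(sessions) >= 1, length(models) >= 1)
  specs <- lapply(models, function(m)
    if (inherits(m, "mabc_spec")) m else mabc_spec(m))
  labels <- vapply(specs, `[[`, character(1), "label")
  n <- length(sessions); K <- length(specs)
  lme <- matrix(NA_real_, n, K,
                dimnames = list(names(sessions) %||% paste0("s", seq_len(n)),
                                labels))
  fits <- vector("list", n)
  for (i in seq_len(n)) {
    fits[[i]] <- vector("list", K)
    for (k in seq_len(K)) {
      f <- mabc_fit(sessions[[i]], specs[[k]], priors,
                    n_restarts = n_restarts,
                    seed = (seed * 1000003L + i * 1009L + k) %% 2147483647L)
      lme[i, k] <- f$lme
      fits[[i]][[k]] <- f
    }
    names(fits[[i]]) <- labels
  }
  list(lme = lme, fits = fits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Maximum-likelihood fit of a Rescorla-Wagner softmax agent
#'
#' Recovers the partner agent's learning rate and inverse temperature
#' from its recorded choices and the shared outcomes, by maximizing the
#' softmax choice likelihood in (logit, log) space. Action values reset
#' to \code{q0} at each session start.
#'
#' @param sessions a list of \code{"mabc_session"} objects, or a single
#'   session.
#' @param q0 initial action value.
#' @param n_restarts optimizer restarts.
#' @param seed seed for restart jitter.
#' @return a list with \code{learning_rate}, \code{inv_temp},
#'   \code{loglik}, \code{convergence}.
#' @export
fit_partner_rw <- function(sessions, q0 = 0.5, n_restarts = 5, seed = 1) {
  if (inherits(sessions, "mabc_session")) sessions <- list(sessions)
  action <- unlist(lapply(sessions, function(s)
    as.integer(s$trials$action_other == "right")))
  outcome <- unlist(lapply(sessions, function(s) as.integer(s$trials$outcome)))
  start <- unlist(lapply(sessions, function(s)
    c(1L, rep(0L, nrow(s$trials) - 1L))))
  nll <- function(v) {
    lr <- .inv_logit(v[1]); it <- exp(min(v[2], 30))
    -rw_loglik_cpp(action, outcome, start, lr, it, q0)
  }
  set.seed(seed)
  best <- NULL
  conv <- 1L
  for (r in seq_len(n_restarts)) {
    s0 <- if (r == 1) c(0, 0) else rnorm(2, 0, 1)
    res <- tryCatch(optim(s0, nll, method = "BFGS"), error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) { best <- res; conv <- res$convergence }
  }
  if (is.null(best)) stop("RW fit failed on all restarts")
  list(learning_rate = .inv_logit(best$par[1]),
       inv_temp = exp(best$par[2]),
       loglik = -best$value, convergence = conv)
}
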