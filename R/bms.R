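#' Random-effects Bayesian model selection
#'
#' Treats the model used by each subject as a draw from a multinomial
#' with Dirichlet-distributed frequencies, estimated from the
#' subjects-by-models matrix of log model evidences by the standard
#' variational fixed point: responsibilities
#' \code{g_nk ~ exp(lme_nk + psi(alpha_k) - psi(sum alpha))} and
#' \code{alpha_k = alpha0_k + sum_n g_nk}, iterated to convergence.
#' Exceedance probabilities are computed by Monte Carlo from the
#' Dirichlet posterior; the Bayesian omnibus risk (the posterior
#' probability that all model frequencies are equal) protects them.
#'
#' @param lme numeric matrix of log model evidences, subjects in rows,
#'   models in columns (finite entries).
#' @param alpha0 Dirichlet prior concentration (scalar or one per model;
#'   default 1, uniform).
#' @param n_samples Monte Carlo sample size for the exceedance
#'   probabilities.
#' @param seed seed for the Monte Carlo draw.
#' @param tol convergence tolerance on \code{max |delta alpha|}.
#' @param max_iter iteration cap (error if exceeded).
#' @return an object of class \code{"mabc_bms"}: a list with
#'   \code{alpha}, \code{expected_freq}, \code{ep}, \code{bor},
#'   \code{pep}, \code{g} (responsibilities), \code{F1}, \code{F0},
#'   \code{n_iterations}, \code{n_samples}, \code{seed}.
#' @examples
#' lme <- cbind(m1 = rnorm(10, 0), m2 = rnorm(10, -3))
#' rfx_bms(lme, n_samples = 1e4)
#' @export
rfx_bms <- function(lme, alpha0 = 1, n_samples = 1e6, seed = 1,
                    tol = 1e-6, max_iter = 10000L) {
  lme <- as.matrix(lme)
  if (any(!is.finite(lme))) stop("log model evidence matrix must be finite")
  n <- nrow(lme); K <- ncol(lme)
  if (length(alpha0) == 1) alpha0 <- rep(alpha0, K)
  stopifnot(length(alpha0) == K, all(alpha0 > 0))
  alpha <- alpha0 + n / K
  g <- matrix(1 / K, n, K)
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter) stop("RFX-BMS fixed point failed to converge in ",
                            max_iter, " iterations")
    lg <- sweep(lme, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lg <- lg - apply(lg, 1, max)
    g <- exp(lg)
    g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  ef <- alpha / sum(alpha)
  ep <- exceedance_prob(alpha, n_samples = n_samples, seed = seed)
  bp <- bor_and_pep(lme, alpha = alpha, alpha0 = alpha0, g = g, ep = ep)
  structure(list(alpha = setNames(alpha, colnames(lme)),
                 expected_freq = setNames(ef, colnames(lme)),
                 ep = setNames(ep, colnames(lme)),
                 bor = bp$bor,
                 pep = setNames(bp$pep, colnames(lme)),
                 g = g, F1 = bp$F1, F0 = bp$F0,
                 n_iterations = it, n_samples = n_samples, seed = seed),
            class = "mabc_bms")
}

#' @export
print.mabc_bms <- function(x, digits = 3, ...) {
  cat("Random-effects Bayesian model selection (", length(x$alpha),
      " models, ", x$n_iterations, " iterations)\n", sep = "")
  print(round(rbind(alpha = x$alpha, expected_freq = x$expected_freq,
                    ep = x$ep, pep = x$pep), digits))
  cat("Bayesian omnibus risk:", signif(x$bor, digits), "\n")
  invisible(x)
}

#' Monte-Carlo exceedance probabilities of a Dirichlet posterior
#'
#' Fraction of Dirichlet draws in which each component is the largest
#' (ties, a measure-zero event, go to the first index).
#'
#' @param alpha Dirichlet concentration vector.
#' @param n_samples number of Monte Carlo draws.
#' @param seed RNG seed.
#' @return a probability vector summing to 1.
#' @export
exceedance_prob <- function(alpha, n_samples = 1e6, seed = 1) {
  stopifnot(all(alpha > 0))
  K <- length(alpha)
  if (K == 1) return(1)
  set.seed(seed)
  # Dirichlet draws via normalized gammas; only the argmax matters, and
  # normalization does not change it
  x <- matrix(rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
              n_samples, K)
  win <- max.col(x, ties.method = "first")
  tabulate(win, K) / n_samples
}

#' Bayesian omnibus risk and protected exceedance probabilities
#'
#' The omnibus risk compares the variational free energy \code{F1} of the
#' random-effects model against the evidence \code{F0} of the null in
#' which every model is equally likely in every subject:
#' \code{BOR = 1 / (1 + exp(F1 - F0))}. Protected exceedance
#' probabilities shrink the EPs toward uniform by the omnibus risk:
#' \code{pep_k = ep_k (1 - BOR) + BOR / K}.
#'
#' @param lme log model evidence matrix (subjects x models).
#' @param bms optionally a converged \code{"mabc_bms"} (its alpha,
#'   responsibilities and EPs are reused).
#' @param alpha,alpha0,g,ep internal pieces, supplied by
#'   \code{\link{rfx_bms}} when \code{bms} is missing.
#' @return a list with \code{bor}, \code{pep}, \code{F1}, \code{F0}.
#' @export
bor_and_pep <- function(lme, bms = NULL, alpha = NULL, alpha0 = NULL,
                        g = NULL, ep = NULL) {
  lme <- as.matrix(lme)
  K <- ncol(lme)
  if (!is.null(bms)) {
    alpha <- bms$alpha; g <- bms$g; ep <- bms$ep
    alpha0 <- alpha - colSums(g)
  }
  # variational free energy of the random-effects model at convergence:
  # expected log-likelihood + Dirichlet and multinomial entropy terms
  lgB <- function(a) sum(lgamma(a)) - lgamma(sum(a))
  elog <- digamma(alpha) - digamma(sum(alpha))
  F1 <- sum(g * lme) +
    sum((alpha0 - alpha + colSums(g)) * elog) +
    lgB(alpha) - lgB(alpha0) -
    sum(g * log(pmax(g, 1e-300)))
  # null model: every subject uses each model with probability 1/K
  F0 <- sum(apply(lme, 1, .logsumexp) - log(K))
  bor <- 1 / (1 + exp(F1 - F0))
  list(bor = bor, pep = ep * (1 - bor) + bor / K, F1 = F1, F0 = F0)
}
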