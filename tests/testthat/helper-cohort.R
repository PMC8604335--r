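# Cohort generator for behavioral-signature checks: parameters centred
# on values representative of fitted human subjects (moderate learning
# rates, positive reward bias / negative loss bias, clear value
# utilization), with between-subject spread in the bias parameters.
simulate_signature_cohort <- function(n_subjects, seed) {
  set.seed(seed)
  bias_pos <- rnorm(n_subjects, 0.23, 0.5)
  bias_neg <- rnorm(n_subjects, -0.26, 0.5)
  seeds <- sample.int(2^31 - 2, n_subjects)
  sessions <- lapply(seq_len(n_subjects), function(i)
    simulate_subject(task_config(),
                     mabc_params(a_self = 0.3, a_other = 0.3,
                                 bias_pos = bias_pos[i],
                                 bias_neg = bias_neg[i],
                                 beta0 = 2, tau = 0.74, theta = 0.2,
                                 beta_con = 2),
                     seed = seeds[i]))
  list(sessions = sessions, bias_pos = bias_pos, bias_neg = bias_neg)
}
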