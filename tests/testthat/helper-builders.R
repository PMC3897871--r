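# Shared fixture builders (available to every test file).

# With lambda = 1, theta irrelevant, sigma_o = 0 and mu0 = 0, an arm's
# belief mean equals its last observed reward, so pre-choice means can be
# staged through the reward sequence.
staging_params <- function(beta = 0.2)
  model_params(lambda_hat = 1, theta_hat = 0, sigma_d_hat = 0,
               sigma_o_hat = 0, mu0_pre = 0, var0_pre = 1, beta = beta)

# Random ROI activity long table: n subjects, alternating groups, iid
# standard-normal estimates plus an optional explore shift.
make_roi_df <- function(n = 10, rois = c("vmPFC", "dACC"), seed = 1,
                        explore_shift = 0) {
  set.seed(seed)
  ids <- sprintf("s%02d", seq_len(n))
  grp <- rep(c("gA", "gB"), length.out = n)
  do.call(rbind, lapply(rois, function(r)
    data.frame(subject = rep(ids, 2), group = rep(grp, 2), roi = r,
               condition = rep(c("explore", "exploit"), each = n),
               estimate = rnorm(2 * n) +
                 rep(c(explore_shift, 0), each = n))))
}
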