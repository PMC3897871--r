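# Independently coded reference implementations used as oracles. These walk
# the definitions step by step with none of the package's vectorized or
# compiled code paths.

# Stepwise Kalman walk + softmax likelihood, one trial at a time.
naive_session_nll <- function(session, params, n_arms = 4L) {
  m <- rep(params$mu0_pre, n_arms)
  v <- rep(params$var0_pre, n_arms)
  nll <- 0
  ord <- order(session$trial)
  for (i in ord) {
    if (!session$missed[i]) {
      z <- params$beta * m
      p <- exp(z - max(z)) / sum(exp(z - max(z)))
      nll <- nll - log(p[session$choice[i]])
      c_ <- session$choice[i]
      denom <- v[c_] + params$sigma_o_hat^2
      k <- if (denom < 1e-12) 1 else v[c_] / denom
      m[c_] <- m[c_] + k * (session$reward[i] - m[c_])
      v[c_] <- (1 - k) * v[c_]
    }
    m <- params$lambda_hat * m + (1 - params$lambda_hat) * params$theta_hat
    v <- params$lambda_hat^2 * v + params$sigma_d_hat^2
  }
  nll
}

# Unweighted-means sums of squares for the 2x2 mixed design, computed from
# cell means the textbook way (harmonic-mean cell size for the unbalanced
# case). Returns F statistics in the order condition, group, interaction.
oracle_mixed_anova <- function(data) {
  conds <- sort(unique(as.character(data$condition)))
  wide <- reshape(data.frame(subject = as.character(data$subject),
                             group = as.character(data$group),
                             condition = as.character(data$condition),
                             value = data$value),
                  idvar = c("subject", "group"), timevar = "condition",
                  direction = "wide")
  y <- as.matrix(wide[, paste0("value.", conds)])
  g <- factor(wide$group)
  gl <- levels(g)
  n_g <- table(g)
  n <- nrow(y)
  nh <- 2 / sum(1 / n_g)                       # harmonic mean group size

  cell <- rbind(colMeans(y[g == gl[1], , drop = FALSE]),
                colMeans(y[g == gl[2], , drop = FALSE]))  # groups x conds
  m_c <- colMeans(cell)                        # unweighted condition means
  m_g <- rowMeans(cell)
  m_gg <- mean(cell)

  # condition and interaction SS from unweighted cell means
  ss_cond <- nh * 2 * sum((m_c - m_gg)^2)
  resid_cell <- cell - outer(m_g, rep(1, 2)) -
    outer(rep(1, 2), m_c) + m_gg
  ss_int <- nh * sum(resid_cell^2)
  # condition-by-subject error from the within-subject residuals
  subj_mean <- rowMeans(y)
  sse_w <- 0
  for (i in seq_len(n)) {
    gi <- as.integer(g[i])
    sse_w <- sse_w + sum((y[i, ] - subj_mean[i] - cell[gi, ] + m_g[gi])^2)
  }
  mse_w <- sse_w / (n - 2)

  # group effect on subject means (weighted one-way ANOVA; x2 for cell scale)
  ss_group <- 2 * sum(n_g * (tapply(subj_mean, g, mean) - mean(subj_mean))^2)
  sse_b <- 2 * sum((subj_mean - tapply(subj_mean, g, mean)[g])^2)

  c(condition = ss_cond / mse_w,
    group = ss_group / (sse_b / (n - 2)),
    interaction = ss_int / mse_w)
}

# OLS through the normal equations, with classical standard errors.
oracle_ols <- function(X, y) {
  XtX <- crossprod(X)
  b <- solve(XtX, crossprod(X, y))
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(s2 * solve(XtX)))
  list(coef = drop(b), se = se,
       r2 = 1 - sum(res^2) / sum((y - mean(y))^2))
}

# Pooled-variance two-sample t statistic from the textbook formula.
oracle_pooled_t <- function(x, y) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}

# A tiny hand-built session: explicit trial log, no simulator involved.
make_session <- function(choices, rewards, rts = NULL, missed = NULL,
                         subject = "s1", group = NA_character_) {
  n <- length(choices)
  if (is.null(missed)) missed <- rep(FALSE, n)
  if (is.null(rts)) rts <- ifelse(missed, NA_real_, 0.4)
  session_record(trial = seq_len(n), run = rep(1L, n),
                 choice = ifelse(missed, NA_integer_, choices),
                 reward = ifelse(missed, 0, rewards), rt = rts,
                 missed = missed, subject = subject, group = group)
}

# Random long-format 2x2 mixed-design dataset.
random_mixed_data <- function(nA, nB) {
  n <- nA + nB
  subj <- sprintf("s%02d", seq_len(n))
  grp <- rep(c("g1", "g2"), c(nA, nB))
  data.frame(subject = rep(subj, 2), group = rep(grp, 2),
             condition = rep(c("c1", "c2"), each = n),
             value = rnorm(2 * n, mean = rep(c(0, 0.5), each = n)))
}
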