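make_mediation_data <- function(n_rep = 6, seed = 1, a = 1, b = 0.5,
                                c_dir = 0.5, sd_c = 2, sd_p = 2) {
  grid <- generate_protocol(widths = c(0.1, 0.2, 0.4), rates = c(10, 20),
                            seed = seed)
  df <- do.call(rbind, replicate(n_rep, as.data.frame(grid),
                                 simplify = FALSE))
  N_true <- eval_surface(vns_truth()$surface$pupil, df$amplitude_ma,
                         df$width_ms, df$rate_hz)
  set.seed(seed + 1000)
  df$response_calcium <- a * N_true + rnorm(nrow(df), 0, sd_c)
  df$response_pupil <- c_dir * N_true + b * df$response_calcium +
    rnorm(nrow(df), 0, sd_p)
  df$N_true <- N_true
  df
}

test_that("cross-validated engagement matches the truth on noiseless data", {
  # noiseless responses generated from the separable (full) surface, so
  # the per-fold full-model fit can represent them exactly
  full_truth <- list(kind = "full", s = 10, a1 = 0.4, b1 = 2, a2 = 0.3,
                     b2 = 2, a3 = 9, b3 = 2)
  df <- make_mediation_data(sd_c = 0, sd_p = 0, b = 0, c_dir = 1, a = 1)
  df$N_true <- eval_surface(full_truth, df$amplitude_ma, df$width_ms,
                            df$rate_hz)
  df$response_pupil <- df$N_true    # exactly the surface
  cv <- predict_engagement_cv(df, folds = 10, seed = 2)
  expect_equal(cv$engagement, df$N_true[cv$index], tolerance = 1e-3)
  # every trial predicted by a model that excluded it
  expect_equal(sort(unique(cv$fold)), 1:10)
  for (k in 1:10) {
    expect_equal(cv$provenance[[k]]$n_train,
                 length(cv$engagement) - sum(cv$fold == k))
  }
})

test_that("engagement correlates with responses and passes the honesty check", {
  df <- make_mediation_data(seed = 3)
  cv <- predict_engagement_cv(df, folds = 20, seed = 3)
  expect_gt(cor(cv$engagement, df$response_pupil[cv$index]), 0.3)

  # shuffled labels: out-of-fold correlation collapses to ~0 (averaged
  # over shuffles; a single shuffle can retain a spurious cell-level
  # pattern that all folds share)
  rs <- vapply(1:4, function(i) {
    df_sh <- df
    set.seed(i)
    df_sh$response_pupil <- sample(df_sh$response_pupil)
    cv_sh <- predict_engagement_cv(df_sh, folds = 20, seed = 3)
    r <- suppressWarnings(cor(cv_sh$engagement,
                              df_sh$response_pupil[cv_sh$index]))
    if (is.na(r)) 0 else r    # constant null prediction is maximally honest
  }, numeric(1))
  expect_lt(mean(abs(rs)), 0.2)

  # leave-one-out runs and preserves the exclusion invariant
  small <- df[seq_len(40), ]
  cv_loo <- predict_engagement_cv(small, folds = 40, seed = 5)
  expect_equal(length(unique(cv_loo$fold)), 40)
})

test_that("mediation fits recover exact chains and the OLS identity", {
  # C = 2N (plus the small jitter the collinearity guard requires),
  # P = 3C exactly: full mediation through C
  set.seed(5)
  N <- rnorm(100, 5, 2)
  C <- 2 * N + rnorm(100, 0, 0.2)
  P <- 3 * C
  m <- mediation_fit(P, C, N)
  expect_equal(m$a, 2, tolerance = 0.02)
  expect_equal(m$b, 3, tolerance = 1e-8)
  expect_equal(m$c, 6, tolerance = 0.05)
  expect_equal(m$c_prime, 0, tolerance = 1e-6)
  expect_equal(m$proportion_mediated, 1, tolerance = 1e-6)
  # exact collinearity is refused
  expect_error(mediation_fit(3 * 2 * N, 2 * N, N), "collinear")

  # independent mediator: no indirect path
  set.seed(6)
  C2 <- rnorm(200)
  N2 <- rnorm(200)
  P2 <- 1.5 * N2 + rnorm(200, 0, 0.1)
  m2 <- mediation_fit(P2, C2, N2)
  expect_lt(abs(m2$a), 0.2)
  expect_lt(abs(m2$indirect), 0.05)
  expect_equal(m2$c_prime, m2$c, tolerance = 0.05)

  # identity c = c' + a*b to numerical precision on noisy data
  df <- make_mediation_data(seed = 7)
  cv <- predict_engagement_cv(df, seed = 7)
  m3 <- mediation_fit(df$response_pupil, df$response_calcium, cv)
  expect_equal(m3$c, m3$c_prime + m3$a * m3$b, tolerance = 1e-8)

  expect_error(mediation_fit(P, C, rep(1, 100)), "constant")
  expect_error(mediation_fit(P, N + 1e-12 * rnorm(100), N), "collinear")
})

test_that("path coefficients are recovered within 2 SE on generated data", {
  df <- make_mediation_data(seed = 8, a = 1, b = 0.5, c_dir = 0.5)
  cv <- predict_engagement_cv(df, seed = 8)
  m <- mediation_fit(df$response_pupil, df$response_calcium, cv)
  expect_lt(abs(m$a - 1), 2.5 * m$se["a"])
  expect_lt(abs(m$b - 0.5), 2.5 * m$se["b"])
  expect_lt(abs(m$c_prime - 0.5), 2.5 * m$se["c_prime"])
  expect_lt(abs(m$proportion_mediated - 0.5), 0.15)
})

test_that("bootstrap mediation is seeded, calibrated and sign-consistent", {
  df <- make_mediation_data(seed = 9)
  cv <- predict_engagement_cv(df, seed = 9)
  P <- df$response_pupil[cv$index]
  C <- df$response_calcium[cv$index]
  b1 <- bootstrap_mediation(P, C, cv$engagement, n_boot = 300, seed = 10)
  b2 <- bootstrap_mediation(P, C, cv$engagement, n_boot = 300, seed = 10)
  expect_identical(b1$draws, b2$draws)
  # strong effect: indirect draws essentially never negative
  expect_lt(b1$sign_fraction["indirect"], 0.01)

  # null mediator: the indirect sign fraction is 1/2 on average over
  # datasets (any single dataset centres its bootstrap on that dataset's
  # chance estimate of a*b, so only the average is calibrated)
  fr <- vapply(1:8, function(i) {
    set.seed(100 + i)
    C0 <- rnorm(length(P))
    b0 <- bootstrap_mediation(P, C0, cv$engagement, n_boot = 150,
                              seed = 12)
    unname(b0$sign_fraction["indirect"])
  }, numeric(1))
  expect_gt(mean(fr), 0.3)
  expect_lt(mean(fr), 0.7)
})

test_that("partial residual correlation isolates shared noise", {
  # shared noise beyond N: positive partial correlation
  set.seed(13)
  N <- rnorm(300, 5, 2)
  shared <- rnorm(300)
  C <- N + shared + rnorm(300, 0, 0.5)
  P <- 0.5 * N + 0.8 * shared + rnorm(300, 0, 0.5)
  pr <- partial_residual_correlation(P, C, N)
  expect_gt(pr$r, 0.3)
  expect_lt(pr$p, 0.001)
  # residualization: residuals orthogonal to N
  expect_lt(abs(cor(pr$residuals$pupil, N)), 1e-10)
  expect_lt(abs(cor(pr$residuals$calcium, N)), 1e-10)

  # conditionally independent: |r| below 2/sqrt(n)
  C2 <- N + rnorm(300)
  P2 <- 0.5 * N + rnorm(300)
  pr2 <- partial_residual_correlation(P2, C2, N)
  expect_lt(abs(pr2$r), 2 / sqrt(300))
})
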