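test_that("sequential polynomial regression detects the true order", {
  set.seed(51)
  x <- runif(200, -2, 2)
  y_lin <- 2 + 3 * x + rnorm(200, 0, 0.3)
  r_lin <- sequential_poly_regression(y_lin, x)
  expect_equal(r_lin$selected_order, 1L)
  expect_gt(r_lin$p[2], 0.05)

  # inverted-U detector: quadratic truth
  y_quad <- (x - mean(x))^2 + rnorm(200, 0, 0.2)
  r_quad <- sequential_poly_regression(y_quad, x)
  expect_equal(r_quad$selected_order, 2L)
  expect_equal(r_quad$selected_order_bic, 2L)

  expect_error(sequential_poly_regression(y_lin, rep(1, 200)), "constant")
})

test_that("orthogonalized F statistics match R's sequential anova", {
  # oracle: anova(lm(...)) uses the same full-model denominator convention
  for (s in 1:20) {
    set.seed(s)
    x <- rnorm(60)
    y <- 1 + 0.5 * x + 0.2 * x^2 + rnorm(60)
    r <- sequential_poly_regression(y, x)
    oracle <- anova(lm(y ~ x + I(x^2)))
    expect_equal(r$F, oracle$`F value`[1:2], tolerance = 1e-8)
    expect_equal(r$p, oracle$`Pr(>F)`[1:2], tolerance = 1e-8)
  }
})

test_that("orthogonalized fit spans the same space as the raw polynomial", {
  set.seed(52)
  x <- rnorm(80)
  y <- 2 - x + 0.3 * x^2 + rnorm(80)
  r <- sequential_poly_regression(y, x)
  expect_lt(max(abs(crossprod(r$Q) - diag(3))), 1e-10)
  fitted_q <- r$Q %*% crossprod(r$Q, y)
  fitted_raw <- fitted(lm(y ~ x + I(x^2)))
  expect_equal(as.numeric(fitted_q), as.numeric(fitted_raw),
               tolerance = 1e-10)
})

test_that("BH-FDR matches a brute-force step-up oracle exactly", {
  # independent oracle: direct implementation of the step-up definition
  bh_oracle <- function(p, q) {
    m <- length(p)
    ord <- order(p)
    k <- which(p[ord] <= q * seq_len(m) / m)
    reject <- rep(FALSE, m)
    if (length(k)) reject[ord[seq_len(max(k))]] <- TRUE
    reject
  }
  set.seed(53)
  for (i in 1:1000) {
    p <- runif(sample(3:30, 1))^sample(1:3, 1)
    expect_identical(bh_fdr(p, 0.05)$reject, bh_oracle(p, 0.05))
  }

  expect_equal(bh_fdr(rep(1, 5))$reject, rep(FALSE, 5))
  one <- bh_fdr(0.01, 0.05)
  expect_true(one$reject)
  expect_equal(one$p_adjusted, 0.01)
  withna <- bh_fdr(c(0.01, NA, 0.5))
  expect_true(is.na(withna$reject[2]))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("cluster permutation test recovers planted effects, rejects specks", {
  p <- stim_trains(seq(30, by = 40, length.out = 12), rep(0.7, 12),
                   rep(0.4, 12), rep(20, 12))
  st <- generate_image_stack(p, vns_truth(), shape = c(32, 32), seed = 61,
                             noise_sd = 0.8)
  resp <- pixel_trial_responses(st)
  cm <- cluster_permutation_map(resp, c(32, 32), n_perm = 500, seed = 62)
  truth_mask <- as.vector(st$mask)
  found <- as.vector(cm$sig_mask)
  jaccard <- sum(found & truth_mask) / sum(found | truth_mask)
  expect_gt(jaccard, 0.8)

  # single-pixel effect: killed by the cluster-mass correction
  set.seed(63)
  null_resp <- matrix(rnorm(12 * 32 * 32), 12)
  null_resp[, 500] <- null_resp[, 500] + 3
  cm1 <- cluster_permutation_map(null_resp, c(32, 32), n_perm = 500,
                                 seed = 64)
  expect_false(cm1$sig_mask[500])

  expect_error(cluster_permutation_map(null_resp[1:5, ], c(32, 32)),
               "at least 8")
})

test_that("cluster labels are 4-connected components with valid p-values", {
  # two diagonal pixels must not join into one cluster
  tmap <- numeric(25)
  tmap[c(7, 13)] <- 10       # (2,2) and (3,3) in a 5x5: diagonal touch
  lab <- vnspupil:::label_clusters_cpp(tmap, 5L, 5L, 2)
  expect_equal(length(lab$mass), 2)
  expect_equal(lab$size, c(1L, 1L))
  # opposite signs split even when adjacent
  tmap2 <- numeric(25)
  tmap2[c(7, 8)] <- c(10, -10)
  lab2 <- vnspupil:::label_clusters_cpp(tmap2, 5L, 5L, 2)
  expect_equal(length(lab2$mass), 2)
  expect_equal(sort(lab2$mass), c(-10, 10))

  set.seed(65)
  resp <- matrix(rnorm(10 * 64), 10)
  cm <- cluster_permutation_map(resp, c(8, 8), n_perm = 200, seed = 66)
  if (nrow(cm$clusters)) {
    expect_true(all(cm$clusters$p >= 1 / 201 & cm$clusters$p <= 1))
  }
})

test_that("phase-locked power isolates a train-rate tone", {
  rate <- 50
  rel <- seq(-20, 40 - 1 / rate, by = 1 / rate)
  n_tr <- 12
  set.seed(71)
  mk <- function(tone_hz, amp) {
    ep <- matrix(rnorm(n_tr * length(rel), 0, 1), n_tr)
    tone <- amp * sin(2 * pi * tone_hz * rel)
    for (i in seq_len(n_tr)) {
      ep[i, rel >= 0 & rel < 10] <- ep[i, rel >= 0 & rel < 10] +
        tone[rel >= 0 & rel < 10]
    }
    attr(ep, "time") <- rel
    attr(ep, "rate") <- rate
    ep
  }
  sp <- phase_locked_power(mk(10, 2), train_rate_hz = 10)
  expect_gt(sp$scalar, 50)
  # neighbouring frequencies stay near baseline
  far <- abs(sp$freq - 10) > 3 & sp$freq > 2
  tsel <- sp$time >= 0 & sp$time < 10
  expect_lt(mean(abs(rowMeans(sp$pct_change[far, tsel, drop = FALSE]))), 25)
  # spectral peak within one bin of the tone
  band <- rowMeans(sp$pct_change[, tsel, drop = FALSE])
  expect_lt(abs(sp$freq[which.max(band)] - 10), 1.01)

  # stationary noise: scalar consistent with zero
  sp0 <- phase_locked_power(mk(10, 0), train_rate_hz = 10)
  expect_lt(abs(sp0$scalar), 30)

  expect_error(phase_locked_power(mk(10, 1), train_rate_hz = 30), "Nyquist")
})

test_that("grounded sessions show train-rate power, ungrounded do not", {
  p <- stim_trains(seq(45, by = 55, length.out = 8), rep(0.5, 8),
                   rep(0.2, 8), rep(10, 8))
  cfg <- vns_config()
  run <- function(grounded) {
    s <- generate_session(p, vns_truth(), seed = 72,
                          meta = list(grounded = grounded),
                          native_rates = list(pupil = 50, eyelid = 50,
                                              eye = 50))
    cond <- condition_session(s, cfg)
    ep <- epoch_signal(cond$eye_x, s$events, c(-10, 20))
    phase_locked_power(ep, 10)$scalar
  }
  expect_gt(run(TRUE), 100)
  expect_lt(abs(run(FALSE)), 50)
})
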