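test_that("the canonical HRF has the expected shape", {
  expect_equal(canonical_hrf(0), 0)
  tg <- seq(0, 32, by = 0.01)
  h <- canonical_hrf(tg)
  expect_equal(tg[which.max(h)], 5, tolerance = 0.2 / 5)
  expect_equal(max(h), 1)
  # undershoot after ~10 s, tail decays to zero
  expect_lt(min(h), 0)
  expect_lt(max(abs(canonical_hrf(seq(30, 32, by = 0.1)))), 1e-3)
  expect_error(canonical_hrf(-1), "non-negative")
})

test_that("design matrices localise blocks, stay well-conditioned, and drop dead columns", {
  ev <- data.frame(onset = 60, duration = 12, trial_type = "stim")
  X <- build_design_matrix(ev, TR = 2, n_scans = 90, drift_order = 0)
  x <- X[, "stim"]
  t_scan <- (0:89) * 2
  inwin <- t_scan >= 60 - 5 & t_scan <= 72 + 30
  expect_gt(sum(abs(x[inwin])) / sum(abs(x)), 0.99)
  # non-overlapping condition blocks give near-orthogonal regressors
  run <- protocol_retinotopy(seed = 3)
  Xr <- build_design_matrix(run$blocks, 2, run$timing$TRs)
  conds <- attr(Xr, "conditions")
  cc <- stats::cor(Xr[, conds])
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.3)
  # full rank with conditions + motion + drift + intercept
  set.seed(1)
  mo <- matrix(rnorm(run$timing$TRs * 6), ncol = 6)
  Xm <- build_design_matrix(run$blocks, 2, run$timing$TRs, motion = mo)
  expect_equal(qr(Xm)$rank, ncol(Xm))
  expect_equal(ncol(Xm), 7 + 6 + 2 + 1)
  # zero-variance motion columns are dropped with a warning
  mo0 <- mo; mo0[, 3] <- 1
  expect_warning(build_design_matrix(run$blocks, 2, run$timing$TRs,
                                     motion = mo0), "zero-variance")
  # duplicated condition labels make the design rank deficient
  ev2 <- rbind(ev, data.frame(onset = 60, duration = 12, trial_type = "copy"))
  expect_error(build_design_matrix(ev2, 2, 90, drift_order = 0),
               "rank deficient")
  expect_error(build_design_matrix(
    data.frame(onset = 500, duration = 12, trial_type = "x"), 2, 90),
    "beyond")
})

test_that("the GLM recovers planted amplitudes exactly without noise", {
  run <- protocol_retinotopy(seed = 11)
  amp <- synth_retinotopic_population(40, margin = 0.8, extra_conditions = 2)
  bold <- synth_bold(sim_spec(amp, sigma = 0, phi = 0, drift_order = 0,
                              seed = 1), run)
  X <- build_design_matrix(run$blocks, 2, run$timing$TRs, drift_order = 0)
  fit <- fit_glm(bold, X)
  expect_lt(max(abs(coef(fit)[, colnames(bold$design)] - amp)), 1e-8)
  expect_equal(unname(fit$betas[, "intercept"]), rep(100, 40))
  expect_true(all(fit$rho == 0))
})

test_that("AR(1) prewhitening leaves beta estimates unbiased within 2%", {
  run <- protocol_retinotopy(seed = 11)
  amp <- synth_retinotopic_population(500, margin = 1, base_amp = 0.5,
                                      extra_conditions = 2)
  bold <- synth_bold(sim_spec(amp, sigma = 2, phi = 0.4, drift_order = 2,
                              seed = 7), run)
  X <- build_design_matrix(run$blocks, 2, run$timing$TRs)
  fit <- fit_glm(bold, X)
  est <- coef(fit)[, colnames(bold$design)]
  bias <- colMeans(est - amp)
  expect_lt(max(abs(bias[1:5])) / 1.5, 0.02)   # preferred-band amplitude 1.5
  # the AR coefficient is recovered in the right range
  expect_gt(stats::median(fit$rho), 0.2)
  expect_lt(stats::median(fit$rho), 0.5)
})

test_that("breaking the temporal alignment nulls the betas", {
  run <- protocol_retinotopy(seed = 11)
  amp <- synth_retinotopic_population(100, margin = 1, extra_conditions = 2)
  bold <- synth_bold(sim_spec(amp, sigma = 1, phi = 0, drift_order = 0,
                              seed = 9), run)
  set.seed(10)
  perm <- sample(ncol(bold$data))
  X <- build_design_matrix(run$blocks, 2, run$timing$TRs, drift_order = 0)
  fit <- fit_glm(bold$data[, perm], X)
  tvals <- abs(contrast_tmap(fit, stats::setNames(1, "ecc3"))$t)
  expect_lt(stats::median(tvals, na.rm = TRUE), 1)
})

test_that("contrast t-maps negate with the contrast and hold their size", {
  fx <- fix_retinotopy_bold()
  ct <- c(ecc5 = 1, ecc1 = -1)
  tpos <- contrast_tmap(fx$fit, ct)
  tneg <- contrast_tmap(fx$fit, -ct)
  expect_equal(tpos$t, -tneg$t)
  expect_error(contrast_tmap(fx$fit, c(ecc1 = 0)), "zero")
  expect_error(contrast_tmap(fx$fit, c(nope = 1)), "unknown")
  # null simulation: type-I rate at p < 0.01 within [0.005, 0.02]
  run <- fx$run
  X <- build_design_matrix(run$blocks, 2, run$timing$TRs, drift_order = 0)
  null_amp <- matrix(0, 4000, 7)
  nb <- synth_bold(sim_spec(null_amp, sigma = 1, phi = 0.3, drift_order = 0,
                            seed = 33), run)
  nf <- fit_glm(nb, X)
  tn <- contrast_tmap(nf, stats::setNames(c(1, -1), c("ecc5", "ecc1")))
  pv <- 2 * stats::pt(-abs(tn$t), tn$df)
  rate <- mean(pv < 0.01, na.rm = TRUE)
  expect_gt(rate, 0.005); expect_lt(rate, 0.02)
  # planted effects exceed the threshold at high power
  eff_amp <- matrix(0, 200, 7); eff_amp[, 5] <- 3   # ecc5 column (sorted order)
  eb <- synth_bold(sim_spec(eff_amp, sigma = 1, phi = 0.3, drift_order = 0,
                            seed = 34), run)
  ef <- fit_glm(eb, X)
  te <- contrast_tmap(ef, stats::setNames(c(1, -1), c("ecc5", "ecc1")))
  expect_gt(mean(te$t > stats::qt(0.9999, te$df), na.rm = TRUE), 0.9)
})

test_that("conjunction masks equal the brute-force intersection of pairwise masks", {
  run <- protocol_retinotopy(seed = 11)
  amp <- synth_retinotopic_population(300, margin = 2, base_amp = 0.3,
                                      extra_conditions = 2)
  bold <- synth_bold(sim_spec(amp, sigma = 1, phi = 0.3, seed = 41), run)
  X <- build_design_matrix(run$blocks, 2, run$timing$TRs)
  fit <- fit_glm(bold, X)
  others <- paste0("ecc", 1:4)
  cj <- conjunction_mask(fit, "ecc5", others, alpha = 0.01)
  tcrit <- stats::qt(0.99, fit$df)
  pieces <- lapply(others, function(oth)
    contrast_tmap(fit, stats::setNames(c(1, -1), c("ecc5", oth)))$t > tcrit)
  brute <- Reduce(`&`, pieces)
  brute[is.na(brute)] <- FALSE
  expect_identical(as.vector(cj), as.vector(brute))
  # conjunction is a subset of every pairwise mask
  for (pc in pieces) expect_true(all(!cj | (pc & !is.na(pc))))
  # voxels preferring the far-periphery band with a wide margin are caught
  pref5 <- attr(amp, "preferred") == 5
  expect_gt(mean(cj[pref5]), 0.8)
  expect_lt(mean(cj[!pref5]), 0.05)
})

test_that("a voxel beating only 3 of 4 comparisons is excluded", {
  # noiseless construction: amplitudes decide membership exactly
  run <- protocol_retinotopy(seed = 11)
  amp <- matrix(0.2, 2, 7)
  amp[1, 5] <- 2            # beats all others (ecc5 in sorted order)
  amp[2, 5] <- 2; amp[2, 4] <- 2.5   # loses to ecc4
  bold <- synth_bold(sim_spec(amp, sigma = 0.05, phi = 0, drift_order = 0,
                              seed = 12), run)
  X <- build_design_matrix(run$blocks, 2, run$timing$TRs, drift_order = 0)
  fit <- fit_glm(bold, X)
  cj <- conjunction_mask(fit, "ecc5", paste0("ecc", 1:4), alpha = 1e-4)
  expect_true(cj[1]); expect_false(cj[2])
})

test_that("the preference map takes the winner and the top-two margin", {
  pm <- preference_map(rbind(c(1, 2, 5, 3, 1)))
  expect_equal(pm$index, 3)
  expect_equal(pm$strength, 2)
  # permutation equivariance of the condition axis
  m <- matrix(rnorm(200), 40, 5)
  perm <- c(4, 1, 5, 3, 2)
  pm0 <- preference_map(m); pmp <- preference_map(m[, perm])
  expect_equal(perm[pmp$index], pm0$index)
  expect_equal(pmp$strength, pm0$strength)
  # ties: lowest index wins with zero strength
  pt <- preference_map(rbind(c(2, 2, 2)))
  expect_equal(pt$index, 1)
  expect_equal(pt$strength, 0)
  expect_error(preference_map(matrix(1, 3, 1)), "two conditions")
})

test_that("tSNR is mean over SD, scale-invariant, flagging constants", {
  set.seed(5)
  z <- as.vector(scale(rnorm(100)))
  y <- rbind(100 + 10 * z, 7 * (100 + 10 * z), rep(3, 100))
  ts <- compute_tsnr(y)
  expect_equal(ts[1], 10)
  expect_equal(ts[2], 10)         # scale invariance
  expect_equal(ts[3], Inf)
  expect_equal(attr(ts, "n_constant"), 1)
  expect_error(compute_tsnr(matrix(1, 2, 1)), "two time points")
  # white-noise series: tSNR ~ mu/sigma within sampling error
  set.seed(6)
  w <- matrix(rnorm(200 * 300, 50, 5), 200)
  expect_equal(stats::median(compute_tsnr(w)), 10, tolerance = 0.05)
})

test_that("ROI overlap subtraction reports exact fractions", {
  a <- c(TRUE, TRUE, TRUE, FALSE); b <- c(FALSE, FALSE, FALSE, TRUE)
  d <- subtract_overlap(a, b)
  expect_equal(as.vector(d), a)
  expect_equal(attr(d, "overlap_fraction"), 0)
  i <- subtract_overlap(a, a)
  expect_equal(sum(i), 0)
  expect_equal(attr(i, "overlap_fraction"), 1)
  set.seed(3)
  ra <- runif(500) < 0.4; rb <- runif(500) < 0.3
  rd <- subtract_overlap(ra, rb)
  expect_equal(attr(rd, "overlap_fraction"), sum(ra & rb) / sum(ra))
  expect_equal(as.vector(rd), ra & !rb)
  expect_error(subtract_overlap(ra, rb[1:10]), "match")
})

test_that("the ROI ANOVA recovers planted effects with exact eta-squared", {
  # planted main effect of size, no content effect, no noise beyond cells
  d <- expand.grid(subject = 1:10, size = c("fullfield", "postcard"),
                   content = c("intact", "scrambled"))
  set.seed(8)
  d$beta <- 1 + 2 * (d$size == "fullfield") + rnorm(40, sd = 0.3)
  out <- roi_anova(d)
  expect_equal(out$effect, c("size", "content", "interaction"))
  expect_gt(out$F[1], 50)
  expect_lt(out$p[1], 0.01)
  # eta squared equals the analytic SS ratio computed independently
  ss <- function(x) sum((x - mean(x))^2)
  g <- interaction(d$size, d$content)
  ss_size <- ss(tapply(d$beta, d$size, mean)[as.character(d$size)])
  expect_equal(out$etaSq[1], ss_size / ss(d$beta), tolerance = 0.01)
  # the effect-free null gives uniform p-values
  set.seed(9)
  pvals <- replicate(400, {
    d$beta <- rnorm(40)
    roi_anova(d)$p[1]
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
  expect_error(roi_anova(within(d, beta <- 0)), "zero-variance")
  expect_error(roi_anova(d[-1, ]), "unbalanced")
})
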