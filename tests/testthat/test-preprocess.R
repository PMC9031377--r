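test_that("average_traces is the pointwise mean with grid checking", {
  tr <- synth_return_loss(right_model(), 21)
  expect_identical(average_traces(list(tr))$values, tr$values)
  neg <- return_loss_trace(tr$frequencies, -tr$values)
  expect_equal(average_traces(list(tr, neg))$values, rep(0, 21))
  other <- synth_return_loss(right_model(), 22)
  expect_error(average_traces(list(tr, other)), "incompatible")
  # 200 noisy sweeps: the mean recovers the clean curve within a bound
  # frozen from the law of large numbers (sd 0.5/sqrt(200) ~ 0.035,
  # max over 21 samples stays well under 0.2 dB)
  sw <- simulate_acquisitions(tr, noise_model(0.5, M = 200L, seed = 42))
  expect_lt(max(abs(average_traces(sw)$values - tr$values)), 0.2)
})

test_that("flatten_and_debias zeroes both endpoints exactly", {
  for (ft in c(2.45e9, 2.55e9, 2.7e9)) {
    tr <- synth_return_loss(right_model(ft), 101)
    bar <- flatten_and_debias(tr)
    expect_identical(bar$values[1L], 0)
    expect_identical(bar$values[101L], 0)
    expect_true(all(bar$values >= 0))
    # peak height ~ amplitude (offset and right-tail level removed)
    expect_equal(max(bar$values), 18, tolerance = 0.05)
  }
})

test_that("flatten_and_debias flattens left of the crossing only", {
  tr <- synth_return_loss(right_model(2.55e9), 201)
  bar <- flatten_and_debias(tr)
  ft <- attr(bar, "f_tilde")
  left <- bar$frequencies <= ft
  expect_true(all(bar$values[left] == 0))
  expect_true(all(bar$values[!left] >= 0))
  # a trace already flat at the RL(fmax) level is only debiased
  flat <- return_loss_trace(tr$frequencies,
                            pmax(tr$values, tr$values[201L]))
  flat_bar <- flatten_and_debias(flat)
  expect_equal(flat_bar$values, pmax(tr$values, tr$values[201L]) -
                 tr$values[201L], tolerance = 1e-12)
})

test_that("symmetric model: flattening point mirrors fmax about ftrue", {
  # symmetric Gaussian, ftrue on grid: RL(f) = RL(fmax) at exactly
  # 2*ftrue - fmax, which lies on the grid for this configuration
  m <- sym_model(ftrue = 2.6e9, sigma = 0.1e9)
  tr <- synth_return_loss(m, 201)           # step 5 MHz, 2.2 GHz on grid
  bar <- flatten_and_debias(tr)
  expect_equal(attr(bar, "f_tilde"), 2 * 2.6e9 - 3e9)
})

test_that("flatten_and_debias instructs mirroring when orientation fails", {
  tr <- synth_return_loss(synthetic_model(ftrue = 2.25e9), 101)
  expect_error(flatten_and_debias(tr), "mirror")
})

test_that("alpha_band finds the analytic crossings on a dense grid", {
  m <- right_model(2.6e9)
  tr <- synth_return_loss(m, 1001)          # step 1 MHz
  bar <- flatten_and_debias(tr)
  band <- alpha_band(bar, 0.1)
  # analytic inversion of each Gaussian flank at the 10% level; the
  # residual right-tail baseline (< 1e-6 dB here) moves the crossing by
  # far less than one grid step, confirmed by the brute-force scan below
  want_lo <- 2.6e9 - 0.07e9 * sqrt(2 * log(10))
  want_hi <- 2.6e9 + 0.10e9 * sqrt(2 * log(10))
  expect_lt(abs(band$f_tilde_min - want_lo), 2 * tr$step)
  expect_lt(abs(band$f_tilde_max - want_hi), 2 * tr$step)
  # brute-force oracle: outermost samples with normalised value >= alpha
  rel <- bar$values / max(bar$values)
  inside <- range(which(rel >= 0.1))
  expect_equal(band$idx, c(inside[1L] - 1L, inside[2L] + 1L))
})

test_that("alpha_band limits: collapse near 1, symmetry, monotonicity", {
  bar <- flatten_and_debias(synth_return_loss(right_model(2.55e9), 101))
  peak <- which.max(bar$values)
  tight <- alpha_band(bar, 0.999)
  expect_equal(tight$idx, c(peak - 1L, peak + 1L))
  # symmetric model: band symmetric about ftrue within one grid step
  sbar <- flatten_and_debias(synth_return_loss(sym_model(2.5e9), 201))
  sband <- alpha_band(sbar, 0.3)
  expect_lt(abs((sband$f_tilde_max - 2.5e9) - (2.5e9 - sband$f_tilde_min)),
            1.5 * sbar$step)
  # larger alpha never widens the band
  widths <- vapply(c(0.05, 0.2, 0.5, 0.8, 0.95), function(a) {
    b <- alpha_band(bar, a)
    b$f_tilde_max - b$f_tilde_min
  }, numeric(1))
  expect_true(all(diff(widths) <= 0))
  expect_error(alpha_band(bar, 1), "alpha")
  expect_error(alpha_band(bar, 0), "alpha")
})

test_that("beta_support matches a brute-force scan of the sinc kernel", {
  tr <- return_loss_trace(seq(2e9, 3e9, length.out = 51), rep(1, 51))
  sig <- idtft(tr, 513)
  sup <- beta_support(sig, 0.5)
  # brute force: walk outward from the peak to the first |rl| <= beta*max
  rel <- sig$magnitude / max(sig$magnitude)
  peak <- which.max(rel)
  lo <- max(which(rel[1:peak] <= 0.5))
  hi <- peak - 1L + min(which(rel[peak:513] <= 0.5))
  expect_equal(sup$idx, c(lo, hi))
  expect_equal(sup$n_tilde_t, hi - lo + 1L)
  # main-lobe half-magnitude full width of the band kernel is 1.2068/B;
  # boundary samples sit at most one time step outside each crossing
  width <- sup$t_tilde_max - sup$t_tilde_min
  expect_gte(width, 1.2068 / 1e9)
  expect_lte(width, 1.2068 / 1e9 + 2.1 * sig$step)
})

test_that("beta_support limits: collapse, full-window, monotonicity", {
  bar <- flatten_and_debias(synth_return_loss(right_model(2.55e9), 101))
  sig <- idtft(bar, 512)
  peak <- which.max(sig$magnitude)
  # beta above every non-peak value: support collapses to the samples
  # adjacent to the magnitude peak
  rel <- sig$magnitude / max(sig$magnitude)
  tight <- beta_support(sig, (max(rel[-peak]) + 1) / 2)
  expect_equal(tight$idx, c(peak - 1L, peak + 1L))
  # beta below the window-edge magnitude: support is the whole window
  # (this is exactly the iterative algorithm's stopping condition)
  edge_rel <- min(sig$magnitude) / max(sig$magnitude)
  if (edge_rel > 0.011) {
    full <- beta_support(sig, 0.01)
    expect_equal(full$idx, c(1L, 512L))
  }
  widths <- vapply(c(0.05, 0.2, 0.5, 0.9), function(b) {
    s <- beta_support(sig, b)
    s$t_tilde_max - s$t_tilde_min
  }, numeric(1))
  expect_true(all(diff(widths) <= 0))
  zero <- time_signal(seq(-1e-9, 1e-9, length.out = 16), complex(16))
  expect_error(beta_support(zero, 0.5), "degenerate")
})
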