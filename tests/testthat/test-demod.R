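test_that("a constant 40 Hz tone demodulates to its amplitude and phase", {
  ep <- tone_epochs(function(t, k) 2 * cos(2 * pi * 40 * t + pi / 4))
  dm <- complex_demodulate(ep)
  mid <- dm$t > 1 & dm$t < 5
  amp <- 2 * Mod(dm$z[1, mid])
  expect_true(all(amp > 1.98 & amp < 2.02))
  expect_true(all(abs(Arg(dm$z[1, mid]) - pi / 4) < 0.02))
  # zero in, zero out
  ep0 <- tone_epochs(function(t, k) rep(0, length(t)))
  expect_equal(Mod(complex_demodulate(ep0)$z), matrix(0, 1, 1750))
})

test_that("out-of-band tones are rejected by the narrow bandpass", {
  ep <- tone_epochs(function(t, k) cos(2 * pi * 39 * t))
  dm <- complex_demodulate(ep)
  mid <- dm$t > 1 & dm$t < 5
  expect_lt(max(2 * Mod(dm$z[1, mid])), 0.1)
})

test_that("demodulated envelope matches a slow MCGF envelope within 5 percent", {
  prm <- list(A = 1, d = 1, mu = 2, sigma = 0.6, alpha = 0.05)
  ep <- tone_epochs(function(t, k)
    ifelse(t >= 0, mcgf_eval(t, prm), 0) * cos(2 * pi * 40 * t))
  dm <- complex_demodulate(ep)
  env <- ifelse(dm$t >= 0, mcgf_eval(dm$t, prm), 0)
  inwin <- dm$t >= 0.5 & dm$t <= 5.5
  expect_lt(max(abs(2 * Mod(dm$z[1, inwin]) - env[inwin])), 0.05 * max(env))
})

test_that("AM is the trial-mean modulus minus its baseline mean", {
  fs <- fix_fs
  n <- 7 * fs
  # analytic complex epochs: K trials with constant envelopes a_k / 2
  a_k <- c(1, 2, 4)
  z <- (a_k / 2) %o% rep(1 + 0i, n)
  am <- amplitude_modulation(demod_from_z(z))
  # constant envelope everywhere: baseline self-subtracts to zero
  expect_lt(max(abs(am$am)), 1e-12)
  expect_equal(am$am_baseline, mean(a_k))
  # envelope zero in baseline, a_k during stimulation
  t <- demod_from_z(z)$t
  z2 <- (a_k / 2) %o% as.numeric(t >= 0)
  am2 <- amplitude_modulation(demod_from_z(z2))
  expect_equal(am2$am_baseline, 0)
  expect_equal(unique(am2$am[t >= 0]), mean(a_k))   # closed-form trial mean
  expect_true(all(am2$am + am2$am_baseline >= 0))   # pre-baseline AM >= 0
})

test_that("ITPC attains its analytic values in degenerate phase configurations", {
  fs <- fix_fs
  n <- 7 * fs
  # identical phases: resultant length is exactly 1
  z <- matrix(exp(1i * 0.7), nrow = 40, ncol = n) * (1:40)
  pr <- itpc(demod_from_z(z))
  expect_true(all(abs(pr$itpc + pr$itpc_baseline - 1) < 1e-12))
  # antiphase pair: resultant length 0
  z2 <- rbind(rep(1 + 0i, n), rep(exp(1i * pi), n))
  pr2 <- itpc(demod_from_z(z2))
  expect_true(all(abs(pr2$itpc + pr2$itpc_baseline) < 1e-12))
  expect_error(itpc(demod_from_z(z2[1, , drop = FALSE])), "2 trials")
})

test_that("uniform-phase ITPC matches the Rayleigh expectation", {
  # Monte-Carlo oracle: K = 40 unit phasors with iid uniform phases;
  # E[resultant length] ~ sqrt(pi / (4 K))
  set.seed(99)
  K <- 40
  reps <- 1e4
  r <- replicate(reps, Mod(mean(exp(1i * runif(K, 0, 2 * pi)))))
  expect_equal(mean(r), sqrt(pi / (4 * K)),
               tolerance = 2 * sd(r) / sqrt(reps) / sqrt(pi / (4 * K)))
})

test_that("pre-baseline ITPC is always inside [0, 1] and AM non-negative", {
  set.seed(7)
  for (i in 1:100) {
    K <- sample(2:10, 1)
    n <- 300
    z <- matrix(complex(real = rnorm(K * n), imaginary = rnorm(K * n)), K)
    dm <- demod_from_z(z, fs = 100, t_start = -1)
    pr <- itpc(dm, baseline_window = c(-0.5, -0.25))
    raw_itpc <- pr$itpc + pr$itpc_baseline
    expect_true(all(raw_itpc >= 0 & raw_itpc <= 1 + 1e-12, na.rm = TRUE))
    am <- amplitude_modulation(dm, baseline_window = c(-0.5, -0.25))
    expect_true(all(am$am + am$am_baseline >= 0))
  }
})

test_that("band power equals a^2/2 for a sine and is robust to out-of-band noise", {
  ep <- tone_epochs(function(t, k) 3 * sin(2 * pi * 40 * t))
  expect_equal(assr_bandpower(ep), 9 / 2, tolerance = 0.02 * 9 / 2)
  ep2 <- tone_epochs(function(t, k) 6 * sin(2 * pi * 40 * t))
  expect_equal(assr_bandpower(ep2) / assr_bandpower(ep), 4, tolerance = 1e-6)
  # independent out-of-band interference barely moves the estimate
  set.seed(3)
  ep3 <- tone_epochs(function(t, k)
    3 * sin(2 * pi * 40 * t) + 2 * sin(2 * pi * 10 * t) + 0.5 * rnorm(length(t)),
    n_trials = 5)
  expect_equal(assr_bandpower(ep3), 9 / 2, tolerance = 0.05 * 9 / 2)
})

test_that("ERSP is the trial-mean squared modulus with its invariances", {
  set.seed(5)
  X1 <- array(complex(real = rnorm(40), imaginary = rnorm(40)), c(1, 4, 10))
  expect_equal(ersp(X1), Mod(X1[1, , ])^2)
  # identical trials leave the map unchanged
  Xr <- array(0i, c(5, 4, 10)); for (k in 1:5) Xr[k, , ] <- X1[1, , ]
  expect_equal(ersp(Xr), ersp(X1))
  # sign-flipped trials give the same map
  X2 <- array(0i, c(2, 4, 10)); X2[1, , ] <- X1[1, , ]; X2[2, , ] <- -X1[1, , ]
  expect_equal(ersp(X2), ersp(X1))
  expect_true(all(ersp(Xr) >= 0))
  expect_error(ersp(array(0i, c(0, 4, 10))), "non-empty")
})

test_that("integrated 40 Hz ERSP row tracks band power by a constant factor", {
  # the documented constant links the Hann-windowed STFT row to the
  # rectangular-window band power; it must not depend on signal amplitude
  ratio_for <- function(a) {
    ep <- tone_epochs(function(t, k) a * sin(2 * pi * 40 * t), n_trials = 2)
    tf <- stft_component(ep)
    row40 <- which.min(abs(tf$f - 40))
    instim <- tf$t > 0 & tf$t < 6
    sum(ersp(tf)[row40, instim]) / assr_bandpower(ep)
  }
  expect_equal(ratio_for(1), ratio_for(3), tolerance = 1e-6)
})

test_that("topographies localize sources and permute with channels", {
  t <- seq(-1, 6 - 1 / 250, by = 1 / 250)
  arr <- array(0, c(2, 3, length(t)))
  arr[, 2, ] <- rep(sin(2 * pi * 40 * t), each = 2)
  ep <- epoched_data(arr, 250, t, c("a", "b", "c"))
  topo <- topography_40hz(ep)
  expect_equal(names(which.max(topo$value)), "b")
  expect_gt(topo$value["b"], 1e6 * max(topo$value[c("a", "c")]))
  # permuting channels permutes values
  perm <- c(3, 1, 2)
  ep2 <- ep; ep2$data <- ep$data[, perm, ]; ep2$channel_labels <- ep$channel_labels[perm]
  topo2 <- topography_40hz(ep2)
  expect_equal(unname(topo2$value), unname(topo$value[perm]))
})

test_that("focal spatial profiles concentrate band power more than diffuse ones", {
  tl <- make_session_timeline(10, 6, 5)
  gini <- function(x) {
    x <- sort(x); n <- length(x)
    sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
  }
  topo_of <- function(profile) {
    cfg <- synth_config(spatial_profile = profile, seed = 11,
                        noise_scale = 0.5)
    topography_40hz(simulate_assr_epochs(cfg, tl))$value
  }
  expect_gt(gini(topo_of("focal_temporal")),
            gini(topo_of("diffuse_frontocentral")))
})
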