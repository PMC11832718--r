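test_that("generalized eigendecomposition matches analytic and brute-force results", {
  # analytic 2x2 case
  dec <- ress_decompose(diag(c(4, 1)), diag(2), shrinkage = 0)
  expect_equal(dec$values, c(4, 1))
  expect_equal(abs(dec$vectors[, 1]), c(1, 0))
  # S = R and S = 2R give flat spectra
  set.seed(13)
  M <- crossprod(matrix(rnorm(25), 5))
  expect_equal(ress_decompose(M, M, shrinkage = 0)$values, rep(1, 5))
  expect_equal(ress_decompose(2 * M, M, shrinkage = 0)$values, rep(2, 5))
  # brute-force oracle: eigenvalues of solve(R) %*% S (Eq. form), random PD pairs
  for (i in 1:20) {
    n <- sample(2:6, 1)
    S <- crossprod(matrix(rnorm(n * n), n)) + diag(n) * 0.1
    R <- crossprod(matrix(rnorm(n * n), n)) + diag(n) * 0.1
    dec <- ress_decompose(S, R, shrinkage = 0)
    brute <- sort(Re(eigen(solve(R) %*% S)$values), decreasing = TRUE)
    expect_equal(dec$values, brute, tolerance = 1e-8)
    # definition check: S v = lambda R v
    resid <- S %*% dec$vectors - R %*% dec$vectors %*% diag(dec$values, n)
    expect_lt(max(abs(resid)), 1e-6 * max(abs(S)))
  }
})

test_that("eigenvectors are unit-norm with a fixed sign and not forced orthogonal", {
  set.seed(17)
  n <- 5
  S <- crossprod(matrix(rnorm(n * n), n)) + diag(n) * 0.1
  R <- crossprod(matrix(rnorm(n * n), n)) + diag(n) * 0.1
  dec <- ress_decompose(S, R, shrinkage = 0)
  expect_equal(colSums(dec$vectors^2), rep(1, n))
  for (j in 1:n) {
    v <- dec$vectors[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  # generalized eigenvectors are generally non-orthogonal
  G <- crossprod(dec$vectors)
  expect_gt(max(abs(G[upper.tri(G)])), 1e-6)
})

test_that("narrowband covariances localize a single-channel 40 Hz source", {
  t <- seq(-1, 6 - 1 / 250, by = 1 / 250)
  arr <- array(0, dim = c(3, 3, length(t)))
  for (k in 1:3) arr[k, 1, ] <- sin(2 * pi * 40 * t)
  ep <- epoched_data(arr, 250, t, c("a", "b", "c"))
  cv <- narrowband_covariances(ep)
  expect_gt(cv$S[1, 1], 100 * max(abs(cv$S[-1, -1])))
  # zero signal gives zero matrices
  ep0 <- epoched_data(array(0, dim = c(2, 2, length(t))), 250, t, c("a", "b"))
  cv0 <- narrowband_covariances(ep0)
  expect_equal(cv0$S, matrix(0, 2, 2))
  expect_equal(cv0$R, matrix(0, 2, 2))
})

test_that("spectrally flat noise gives S approximately equal to R", {
  set.seed(23)
  t <- seq(-1, 6 - 1 / 250, by = 1 / 250)
  arr <- array(rnorm(100 * 2 * length(t)), dim = c(100, 2, length(t)))
  ep <- epoched_data(arr, 250, t, c("a", "b"))
  cv <- narrowband_covariances(ep)
  # same white process at all frequencies: relative difference within
  # Monte-Carlo error over 100 trials
  expect_lt(abs(cv$S[1, 1] - cv$R[1, 1]) / cv$R[1, 1], 0.2)
  expect_lt(abs(cv$S[2, 2] - cv$R[2, 2]) / cv$R[2, 2], 0.2)
})

test_that("projection is the stated linear combination", {
  set.seed(29)
  arr <- array(rnorm(2 * 3 * 100), dim = c(2, 3, 100))
  t <- seq(-0.2, 0.2 - 1 / 250, by = 1 / 250)
  ep <- epoched_data(arr, 250, t, c("a", "b", "c"),
                     window = c(-0.2, 0.2), baseline_window = c(-0.2, -0.1))
  e1 <- project_component(ep, c(1, 0, 0))
  expect_equal(e1$data[1, 1, ], arr[1, 1, ])
  w <- c(0.5, -1, 2)
  p1 <- project_component(ep, w)
  p2 <- project_component(ep, 3 * w)
  expect_equal(p2$data, 3 * p1$data)
  expect_error(project_component(ep, c(1, 2)), "channel count")
})

test_that("SNR spectrum behaves as a power ratio with a noiseless cap", {
  t <- seq(-1, 6 - 1 / 250, by = 1 / 250)
  pure <- epoched_data(array(sin(2 * pi * 40 * t), c(1, 1, length(t))),
                       250, t, "x")
  s <- snr_spectrum(pure)
  expect_true(isTRUE(attr(s, "capped")))
  # white noise only: SNR near 1
  set.seed(31)
  noise <- epoched_data(array(rnorm(100 * length(t)), c(100, 1, length(t))),
                        250, t, "x")
  sn <- snr_spectrum(noise)
  expect_false(isTRUE(attr(sn, "capped")))
  expect_lt(abs(as.numeric(sn) - 1), 1)
  # doubling the tone amplitude quadruples SNR against a fixed noise floor
  set.seed(37)
  nz <- matrix(rnorm(20 * length(t)), 20)
  mk <- function(a) {
    arr <- array(0, c(20, 1, length(t)))
    for (k in 1:20) arr[k, 1, ] <- a * sin(2 * pi * 40 * t) + 0.5 * nz[k, ]
    as.numeric(snr_spectrum(epoched_data(arr, 250, t, "x")))
  }
  expect_equal(mk(2) / mk(1), 4, tolerance = 0.15)
})

test_that("RESS recovers a planted source and beats the best single channel", {
  tl <- make_session_timeline(40, 6, 5)
  # planted source: known mixing vector, broadband noise at source level
  cfg <- synth_config(seed = 101, phase_jitter_sd = 0, noise_scale = 1)
  ep <- simulate_assr_epochs(cfg, tl)
  rr <- ress(ep)
  expect_equal(length(rr$eigenvalues), 14)
  expect_true(all(diff(rr$eigenvalues) <= 1e-9))
  # the component's 40 Hz content must track the planted source closely
  env <- ifelse(ep$t >= 0, mcgf_eval(ep$t, cfg$carrier_env_params), 0)
  src <- env * cos(2 * pi * 40 * ep$t)
  instim <- ep$t > 0.5 & ep$t < 5.5
  cors <- sapply(seq_len(n_epochs(ep)), function(k) {
    comp <- gaussian_narrowband(rr$component$data[k, 1, ], ep$fs, 40, 1)
    abs(cor(comp[instim], src[instim]))
  })
  expect_gt(median(cors), 0.95)
  # component SNR at least as high as every single channel's
  ch_snr <- sapply(seq_len(n_channels(ep)), function(ch) {
    w <- numeric(14); w[ch] <- 1
    as.numeric(snr_spectrum(project_component(ep, w)))
  })
  expect_gte(as.numeric(rr$snr), max(ch_snr))
})

test_that("scaling all epochs leaves the RESS eigenvalue spectrum unchanged", {
  tl <- make_session_timeline(5, 6, 5)
  cfg <- synth_config(channel_labels = c("Cz", "T7", "P7"), seed = 7)
  ep <- simulate_assr_epochs(cfg, tl)
  r1 <- ress(ep)
  ep2 <- ep; ep2$data <- 3 * ep2$data
  r2 <- ress(ep2)
  expect_equal(r2$eigenvalues, r1$eigenvalues, tolerance = 1e-8)
  # component shape is invariant (weights are unit norm)
  expect_equal(r2$component$data, 3 * r1$component$data, tolerance = 1e-6)
})
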