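w3 <- window_spec(3, 4)

test_that("windowed correlations satisfy Cauchy-Schwarz with equality for
           identical and globally phase-shifted pairs", {
  s <- iid_speckle(c(32, 32, 32), 1)
  wc <- windowed_correlations(s, s, w3, step_mm = 1)
  expect_lt(max(abs(Mod(wc$R01)^2 - wc$R00 * wc$R11) /
                  (wc$R00 * wc$R11)), 1e-10)
  ph <- s * exp(1i * 1.234)
  wcp <- windowed_correlations(s, ph, w3, step_mm = 1)
  expect_lt(max(abs(Mod(wcp$R01)^2 - wcp$R00 * wcp$R11) /
                  (wcp$R00 * wcp$R11)), 1e-10)
  # general inputs: inequality
  t <- iid_speckle(c(32, 32, 32), 2)
  wci <- windowed_correlations(s, t, w3, step_mm = 1)
  expect_true(all(Mod(wci$R01)^2 <= wci$R00 * wci$R11 * (1 + 1e-10)))
  expect_error(windowed_correlations(s, t[1:10, , ], w3, 1), "dimensions")
})

test_that("windowed correlations agree with the direct-summation oracle", {
  s <- iid_speckle(c(40, 40, 40), 3)
  t <- iid_speckle(c(40, 40, 40), 4)
  wc <- windowed_correlations(s, t, w3, step_mm = 1,
                              edge_correction = FALSE)
  k <- echodecorr:::gauss_kernel1d(3, 4)
  set.seed(5)
  at <- cbind(sample(40, 50, TRUE), sample(40, 50, TRUE),
              sample(40, 50, TRUE))
  oracle <- direct_windowed(s, t, k, at)
  expect_lt(max(Mod(oracle - wc$R01[at]) / Mod(oracle)), 1e-6)
  # the edge correction divides every window sum by the local weight mass
  wcn <- windowed_correlations(s, t, w3, step_mm = 1)
  mass <- direct_windowed(array(1 + 0i, dim(s)), array(1 + 0i, dim(s)),
                          k, at)
  expect_lt(max(Mod(oracle / Re(mass) - wcn$R01[at]) /
                  Mod(oracle / Re(mass))), 1e-6)
})

test_that("independent-speckle correlation ratio matches window power", {
  s <- iid_speckle(c(48, 48, 48), 6)
  t <- iid_speckle(c(48, 48, 48), 7)
  wc <- windowed_correlations(s, t, w3, step_mm = 1)
  k <- echodecorr:::gauss_kernel1d(3, 4)
  interior <- 14:35
  ratio <- mean((Mod(wc$R01)^2 / (wc$R00 * wc$R11))[interior, interior,
                                                    interior])
  expect_equal(ratio, sum(k^2)^3, tolerance = 0.2)
})

test_that("identical pairs give exactly zero decorrelation", {
  s <- iid_speckle(c(32, 32, 32), 8)
  wc <- windowed_correlations(s, s, w3, step_mm = 1)
  m <- instantaneous_decorrelation(wc$R01, wc$R00, wc$R11, tau_ms = 50)
  expect_lt(max(abs(m$delta)), 1e-12)
})

test_that("homogeneous pairs recover (1 - rho^2) / tau within 10%", {
  d <- c(64, 64, 64)
  s0 <- iid_speckle(d, 11)
  ind <- iid_speckle(d, 12)
  for (rho2 in c(0, 0.5, 0.9)) {
    s1 <- sqrt(rho2) * s0 + sqrt(1 - rho2) * ind
    wc <- windowed_correlations(s0, s1, w3, step_mm = 1)
    m <- instantaneous_decorrelation(wc$R01, wc$R00, wc$R11, tau_ms = 50)
    expect_equal(mean(m$delta), (1 - rho2) / 50, tolerance = 0.1)
  }
})

test_that("decorrelation maps respect the [0, 2/tau] bound and the window
           normalization cancels", {
  s <- iid_speckle(c(32, 32, 32), 13)
  t <- iid_speckle(c(32, 32, 32), 14)
  wc <- windowed_correlations(s, t, w3, step_mm = 1)
  m <- instantaneous_decorrelation(wc$R01, wc$R00, wc$R11, tau_ms = 50)
  expect_true(all(m$delta >= -1e-12 & m$delta <= 2 / 50 + 1e-12))
  # scaling all window weights by a constant changes nothing
  m2 <- instantaneous_decorrelation(wc$R01 * 7, wc$R00 * 7, wc$R11 * 7,
                                    tau_ms = 50)
  expect_equal(m$delta, m2$delta, tolerance = 1e-12)
  expect_error(instantaneous_decorrelation(wc$R01, wc$R00 * 0, wc$R11 * 0,
                                           50), "degenerate")
  expect_error(instantaneous_decorrelation(wc$R01, wc$R00, wc$R11, 50,
                                           array(FALSE, dim(s))), "valid")
})

test_that("cumulative map is the order-independent voxelwise maximum", {
  grid <- cartesian_grid(10, 1)
  set.seed(15)
  insts <- lapply(1:5, function(i) {
    d <- array(runif(11^3, 0, 0.04), rep(11, 3))
    v <- array(runif(11^3) > 0.1, rep(11, 3))
    d[!v] <- NA
    structure(list(delta = d, validity = v, tau_ms = 50,
                   acquisition_index = i), class = "decorr_map")
  })
  cum <- empty_cumulative(grid)
  cum1 <- update_cumulative(cum, insts[[1]])
  expect_equal(cum1$delta, insts[[1]]$delta)
  # inst of zeros never lowers the map
  zero <- insts[[1]]
  zero$delta[zero$validity] <- 0
  expect_equal(update_cumulative(cum1, zero)$delta, cum1$delta)
  # any order, same final map; equals brute-force stack max
  run <- function(ord) {
    c <- empty_cumulative(grid)
    for (i in ord) c <- update_cumulative(c, insts[[i]])
    c$delta
  }
  stack <- simplify2array(lapply(insts, `[[`, "delta"))
  brute <- apply(stack, 1:3, function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  expect_equal(run(1:5), brute)
  expect_equal(run(5:1), brute)
  expect_equal(run(c(3, 1, 5, 2, 4)), brute)
})

test_that("cumulative ROI series is monotone across a simulated trial", {
  ds <- small_trial(seed = 23)
  rec <- run_trial(ds, control_config(), "uncontrolled")
  expect_true(all(diff(rec$series$statistic) > -1e-12))
})

test_that("B-mode envelope is log-magnitude clipped to the dynamic range", {
  x <- array(1 + 0i, c(4, 4, 4))
  expect_true(all(bmode_envelope(x) == 0))
  x[1] <- 10 + 0i
  env <- bmode_envelope(x)
  expect_equal(max(env), 20)
  expect_equal(env[2], 0)
  y <- array(10^seq(-6, 2, length.out = 64), c(4, 4, 4))
  env <- bmode_envelope(y)
  expect_equal(diff(range(env)), 65)
  z <- array(c(0, 1, 1, 1), c(2, 2, 1))
  expect_equal(min(bmode_envelope(z)), -65)   # zeros at the floor
  expect_error(bmode_envelope(array(0i, c(2, 2))), "all-zero")
})

test_that("uniform-coherence pairs recover (1 - rho^2)/tau through the full
           scan-convert + window pipeline at 30 dB SNR", {
  geom <- small_geometry()
  grid <- small_grid()
  roi <- sphere_mask(grid, c(0, 0, 0), 20)$mask
  base <- make_speckle_volume(geom, c(0.3, 1.7), seed = 50)
  sv <- echodecorr:::psf_sigma_vox(geom, c(0.3, 1.7))
  for (rho2 in c(0.1, 0.5, 0.9)) {
    p <- make_echo_pair(base, sqrt(rho2), tau_ms = 50, noise_snr_db = 30,
                        seed = 51, psf_sigma_vox = sv)
    m <- pair_decorrelation(p, geom, grid)
    sel <- roi & m$validity
    expect_equal(mean(m$delta[sel]), (1 - rho2) / 50, tolerance = 0.15)
  }
})

test_that("full-trial lesion-interior decorrelation tracks the synthetic
           within-pair coherence to 15% at 30 dB SNR", {
  ds <- small_trial(seed = 31, noise_snr_db = 30)
  grid <- ds$grid
  # interior of the final lesion, clear of the transition band
  interior <- sphere_mask(grid, c(0, 0, 0), 10)$mask
  k <- echodecorr:::gauss_kernel1d(3, 4)
  kern <- list(k, k, k)
  errs <- c()
  for (n in seq_along(ds$pairs)) {
    rp <- ds$pair_coherence[[n]]
    rc <- scan_convert(array(complex(real = rp), dim(rp)),
                       ds$geometry, grid, ds$apex_mm)
    # first-order model of the windowed estimator: the window sees the
    # smoothed coherence field, so delta ~ (1 - (w * rho)^2) / tau
    wmass <- pmax(Re(echodecorr:::conv_separable(rc$validity + 0, kern)),
                  1e-12)
    sm <- Re(echodecorr:::conv_separable(rc$field, kern)) / wmass
    exp_map <- (1 - sm^2) / ds$config$tau_ms
    inst <- pair_decorrelation(ds$pairs[[n]], ds$geometry, grid, ds$apex_mm)
    sel <- interior & inst$validity
    expected <- mean(exp_map[sel])
    # compare only where modeled decorrelation is substantial (a quarter of
    # the 2/tau ceiling); below that the first-order model is noise-limited
    if (expected > 0.005) {
      errs <- c(errs, abs(mean(inst$delta[sel]) - expected) / expected)
    }
  }
  expect_gte(length(errs), 3)
  expect_true(all(errs < 0.15))
})
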