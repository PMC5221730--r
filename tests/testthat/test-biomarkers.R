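test_that("trapezoid fixtures recover closed-form biomarkers", {
  tr <- generate_synthetic_ap("trapezoid", rmp = -80, peak = 20,
                              plateau_ms = 100, fall_ms = 200, dt = 0.1)
  truth <- attr(tr, "truth")
  bm <- compute_ap_biomarkers(tr)
  tol <- 0.05 # dt/2
  expect_equal(bm$apa, truth$apa, tolerance = 1e-6)
  expect_equal(bm$rmp, truth$rmp, tolerance = 1e-6)
  expect_lt(abs(bm$apd20 - truth$apd20), tol)
  expect_lt(abs(bm$apd50 - truth$apd50), tol)
  expect_lt(abs(bm$apd90 - truth$apd90), tol)
  expect_lt(abs(bm$v20 - truth$v20), 1e-6)
})

test_that("biomarkers are invariant to voltage offset and time shift", {
  tr <- generate_synthetic_ap("trapezoid")
  up <- tr; up$V <- up$V + 10
  attr(up, "stim_times") <- attr(tr, "stim_times")
  a <- compute_ap_biomarkers(tr); b <- compute_ap_biomarkers(up)
  expect_equal(b$apd90, a$apd90)
  expect_equal(b$apd50, a$apd50)
  expect_equal(b$apa, a$apa)
  expect_equal(b$rmp, a$rmp + 10)
  expect_equal(b$v20, a$v20 + 10)

  sh <- tr; sh$time <- sh$time + 137
  attr(sh, "stim_times") <- attr(tr, "stim_times") + 137
  cc <- compute_ap_biomarkers(sh)
  expect_equal(cc$apd90, a$apd90)
  expect_equal(cc$rmp, a$rmp)
})

test_that("exponential repolarization matches its closed form", {
  tr <- generate_synthetic_ap("exponential", tau_ms = 80, dt = 0.05)
  truth <- attr(tr, "truth")
  bm <- compute_ap_biomarkers(tr)
  expect_lt(abs(bm$apd90 - truth$apd90), 0.1)
  expect_lt(abs(bm$apd50 - truth$apd50), 0.1)
  expect_lt(abs(bm$apd20 - truth$apd20), 0.1)
  expect_lt(abs(bm$v20 - truth$v20), 0.05)
})

test_that("model-trace biomarkers agree with a dense threshold-scan oracle", {
  tr <- fx_baseline_trace()
  bm <- compute_ap_biomarkers(tr, c(2000, 3000))
  # oracle: brute-force scan of the sampled points
  keep <- tr$time >= 2000 & tr$time <= 3000
  t <- tr$time[keep]; V <- tr$V[keep]
  rmp <- V[max(which(t <= 2000))]
  apa <- max(V) - rmp
  pk <- which.max(V)
  for (x in c(20, 50, 90)) {
    thr <- rmp + (1 - x / 100) * apa
    below <- which(V <= thr & seq_along(V) > pk)[1]
    # sampled-grid crossing agrees within one sample of the interpolated value
    ref <- t[below] - bm$t_takeoff
    expect_lt(abs(bm[[paste0("apd", x)]] - ref), attr(tr, "sample_dt") + 1e-9)
  }
  expect_equal(bm$apa, apa, tolerance = 1e-12)
  # APD ordering invariant
  expect_true(bm$apd20 <= bm$apd50 && bm$apd50 <= bm$apd90)
})

test_that("non-excited and non-repolarized traces are flagged", {
  flat <- tibble::tibble(time = seq(0, 500, 0.5), V = -80)
  class(flat) <- c("voltage_trace", class(flat))
  attr(flat, "stim_times") <- 50
  bm <- compute_ap_biomarkers(flat)
  expect_false(bm$excited)
  expect_true(is.na(bm$apd90))

  # plateau that never repolarizes inside the window
  tr <- generate_synthetic_ap(plateau_ms = 600, fall_ms = 200, post_ms = 0)
  w <- tr[tr$time <= 500, ]
  attr(w, "stim_times") <- attr(tr, "stim_times")
  class(w) <- c("voltage_trace", class(w))
  bm2 <- compute_ap_biomarkers(w)
  expect_true(bm2$excited)
  expect_false(bm2$repolarized)
  expect_true(is.na(bm2$apd90))
})

test_that("rate ratios divide elementwise by the 1 Hz values", {
  bm <- tibble::tibble(frequency = c(1, 2, 4),
                       apd50 = c(100, 100, 80), apd90 = c(200, 200, 150))
  rr <- compute_rate_ratios(bm)
  expect_equal(rr$apd50_ratio_2hz, 1)
  expect_equal(rr$apd90_ratio_2hz, 1)
  expect_equal(rr$apd90_ratio_4hz, 0.75)
  expect_equal(rr$apd50_ratio_4hz, 0.8)

  expect_error(compute_rate_ratios(bm[bm$frequency != 1, ]), "1 Hz")
  bad <- bm; bad$apd90[1] <- 0
  expect_error(compute_rate_ratios(bad), "positive")
})

test_that("ordering invariant holds across random synthetic shapes", {
  for (seed in 1:25) {
    set.seed(seed)
    tr <- generate_synthetic_ap("trapezoid",
                                rmp = runif(1, -90, -70),
                                peak = runif(1, 0, 40),
                                plateau_ms = runif(1, 10, 150),
                                fall_ms = runif(1, 50, 300),
                                noise_sd = 0)
    bm <- compute_ap_biomarkers(tr)
    expect_true(bm$apd20 <= bm$apd50 && bm$apd50 <= bm$apd90)
    expect_true(bm$rmp < bm$v20 && bm$v20 <= bm$rmp + bm$apa + 1e-9)
  }
})
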