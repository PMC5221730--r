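test_that("acceptance envelopes contain their center and tighten with spread", {
  center <- baseline_phenotype()
  wide <- generate_biomarker_ranges(center, spread = 0.3)
  tight <- generate_biomarker_ranges(center, spread = 0.01)
  expect_true(all(wide$min < wide$center & wide$center < wide$max))
  expect_true(all(tight$min >= wide$min & tight$max <= wide$max))
  # degenerate-envelope limit: half-widths shrink towards zero
  expect_lt(max(tight$max - tight$min), 0.05 * max(wide$max - wide$min))
  expect_error(generate_biomarker_ranges(center, spread = 0), "spread")
  expect_error(generate_biomarker_ranges(center, spread = -1), "spread")
})

test_that("envelope generation is deterministic given the seed", {
  center <- baseline_phenotype()
  a <- generate_biomarker_ranges(center, 0.3)
  b <- generate_biomarker_ranges(center, 0.3)
  expect_identical(a, b)
  j1 <- generate_biomarker_ranges(center, 0.3, jitter = 0.2, seed = 5)
  j2 <- generate_biomarker_ranges(center, 0.3, jitter = 0.2, seed = 5)
  j3 <- generate_biomarker_ranges(center, 0.3, jitter = 0.2, seed = 6)
  expect_identical(j1, j2)
  expect_false(identical(j1, j3))
  expect_error(generate_biomarker_ranges(center, 0.3, jitter = 0.2), "seed")
})

test_that("synthetic traces are reproducible and noise averages out", {
  a <- generate_synthetic_ap(noise_sd = 1, seed = 42)
  b <- generate_synthetic_ap(noise_sd = 1, seed = 42)
  expect_identical(a$V, b$V)

  truth <- attr(generate_synthetic_ap(), "truth")
  apd90 <- vapply(1:100, function(s)
    compute_ap_biomarkers(generate_synthetic_ap(noise_sd = 1, seed = s))$apd90,
    numeric(1))
  expect_lt(abs(mean(apd90) - truth$apd90), 2)
})

test_that("ranges round-trip through CSV", {
  r <- default_biomarker_ranges()
  f <- withr::local_tempfile(fileext = ".csv")
  write_ranges_csv(r, f)
  r2 <- read_ranges_csv(f)
  expect_equal(r2$min, r$min, tolerance = 1e-12)
  expect_s3_class(r2, "biomarker_ranges")
})
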