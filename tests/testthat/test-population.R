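test_that("latin hypercube samples occupy every stratum exactly once", {
  for (n in c(1, 8, 64)) {
    s <- latin_hypercube_sample(n, seed = 3)
    m <- as.matrix(s[, conductance_names()])
    expect_equal(dim(m), c(n, 11))
    expect_true(all(m >= 0 & m <= 3))
    # brute-force stratum occupancy
    for (j in seq_len(ncol(m))) {
      occ <- tabulate(findInterval(m[, j], seq(0, 3, length.out = n + 1),
                                   rightmost.closed = TRUE), nbins = n)
      expect_identical(occ, rep(1L, n))
    }
  }
  expect_error(latin_hypercube_sample(0), "at least 1")
})

test_that("sampling is reproducible under a fixed seed", {
  a <- latin_hypercube_sample(16, seed = 9)
  b <- latin_hypercube_sample(16, seed = 9)
  c <- latin_hypercube_sample(16, seed = 10)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("candidate evaluation is a pure function of the scale vector", {
  s <- setNames(c(1.2, 0.8, 1, 1, 1, 1, 1.5, 1, 1, 1, 1), conductance_names())
  a <- evaluate_candidate(s, beats = 6)
  b <- evaluate_candidate(s, beats = 6)
  expect_identical(a, b)
  expect_true(a$excited)
  expect_true(is.na(a$failure))
})

test_that("calibration accepts the baseline and validates the envelope", {
  base_row <- evaluate_candidate(setNames(rep(1, 11), conductance_names()),
                                 beats = 20, dt = 0.025)
  tbl <- dplyr::bind_cols(tibble::tibble(model_id = 1L,
                                         !!!setNames(rep(1, 11),
                                                     conductance_names())),
                          base_row)
  ranges <- default_biomarker_ranges(spread = 0.25, beats = 20, dt = 0.025)
  pop <- calibrate_population(tbl, ranges)
  expect_true(pop$accepted[1])

  bad <- ranges; bad$min[3] <- bad$max[3] + 1
  expect_error(calibrate_population(tbl, bad), "min must be below max")
  expect_error(calibrate_population(tbl[, 1:5], ranges), "lacks biomarker")
})

test_that("widening the envelope never loses accepted models", {
  ev <- fx_evaluated()
  counts <- vapply(c(0.1, 0.2, 0.3, 0.5, 0.8), function(sp) {
    pop <- calibrate_population(ev, default_biomarker_ranges(spread = sp))
    sum(pop$accepted)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("non-excitable candidates are rejected with a recorded reason", {
  ev <- fx_evaluated()
  pop <- calibrate_population(ev, default_biomarker_ranges())
  expect_true(all(!pop$accepted | is.na(pop$rejection_reason)))
  expect_true(all(pop$accepted | !is.na(pop$rejection_reason)))

  no_na <- evaluate_candidate(setNames(c(0, rep(1, 10)), conductance_names()),
                              beats = 6)
  row <- dplyr::bind_cols(tibble::tibble(model_id = 1L,
                                         !!!setNames(c(0, rep(1, 10)),
                                                     conductance_names())),
                          no_na)
  pop2 <- calibrate_population(row, default_biomarker_ranges())
  expect_false(pop2$accepted[1])
  expect_true(pop2$rejection_reason[1] %in%
                c("not_excited", "apa", "apd20", "apd50", "apd90", "v20"))
})
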