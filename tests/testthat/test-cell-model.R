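test_that("conductance scaling is multiplicative, named and validated", {
  base <- af_cell_params()
  ident <- scale_conductances(base, setNames(rep(1, 11), conductance_names()))
  expect_identical(ident$g, base$g)

  half_cal <- scale_conductances(base, c(gCaL = 0.5))
  expect_equal(half_cal$g[["gCaL"]], base$g[["gCaL"]] * 0.5)
  expect_identical(half_cal$g[names(base$g) != "gCaL"],
                   base$g[names(base$g) != "gCaL"])
  # base untouched
  expect_equal(base$g[["gCaL"]], afpop:::crn_nominal()[["gCaL"]] * 0.3)

  expect_error(scale_conductances(base, c(gFoo = 1)), "unknown conductance")
  expect_error(scale_conductances(base, c(gNa = -0.1)), "non-negative")
  expect_error(scale_conductances(base, c(gNa = 3.5)), "\\[0, 3\\]")
})

test_that("chronic-AF remodeling shortens the action potential", {
  tr_af <- fx_baseline_trace()
  tr_ctl <- simulate_cell(af_cell_params(remodeling = "none"),
                          pacing_protocol(1, beats = 3))
  bm_af <- compute_ap_biomarkers(tr_af, c(2000, 3000))
  bm_ctl <- compute_ap_biomarkers(tr_ctl, c(2000, 3000))
  expect_true(bm_af$apd90 < 0.6 * bm_ctl$apd90)
  expect_gt(bm_ctl$apd90, 250) # published non-remodeled APD90 is ~300 ms
  expect_lt(bm_af$apd90, 200)
})

test_that("derivatives vanish at the relaxed steady state and validate input", {
  ss <- cell_steady_state(af_cell_params())
  d <- cell_derivatives(ss, af_cell_params(), stim = 0)
  expect_lt(abs(d[["V"]]), 1e-3)

  bad <- ss; bad[["m"]] <- 1.2
  expect_error(cell_derivatives(bad), "outside \\[0, 1\\]")
  bad2 <- ss; bad2[["Cai"]] <- -1e-5
  expect_error(cell_derivatives(bad2), "concentration")
  bad3 <- ss; bad3[["V"]] <- NaN
  expect_error(cell_derivatives(bad3), "non-finite")
})

test_that("stimulus enters the voltage derivative additively", {
  ss <- cell_steady_state(af_cell_params())
  d0 <- cell_derivatives(ss, stim = 0)
  d1 <- cell_derivatives(ss, stim = 7)
  d2 <- cell_derivatives(ss, stim = 14)
  expect_equal(d1[["V"]] - d0[["V"]], 7)
  expect_equal(d2[["V"]] - d1[["V"]], 7)
  expect_identical(d1[-1], d0[-1])
})

test_that("pacing simulation is deterministic and respects the protocol", {
  pr <- pacing_protocol(2, beats = 2)
  a <- simulate_cell(af_cell_params(), pr)
  b <- simulate_cell(af_cell_params(), pr)
  expect_identical(a$V, b$V)
  expect_identical(attr(a, "final_state"), attr(b, "final_state"))

  quiet <- simulate_cell(af_cell_params(),
                         pacing_protocol(1, beats = 2, amplitude = 0))
  expect_lt(max(abs(quiet$V - quiet$V[1])), 1)

  expect_error(pacing_protocol(0), "positive")
  expect_error(pacing_protocol(4, pulse_ms = 300), "1000 ms")
  expect_error(simulate_cell(af_cell_params(), pacing_protocol(1, beats = 5),
                             duration = 2000), "cover")
})

test_that("last-beat APD90 is converged in dt to under 1 ms", {
  bm <- lapply(c(0.02, 0.01), function(dt) {
    tr <- simulate_cell(af_cell_params(), pacing_protocol(1, beats = 3),
                        dt = dt)
    compute_ap_biomarkers(tr, c(2000, 3000))
  })
  expect_lt(abs(bm[[1]]$apd90 - bm[[2]]$apd90), 1)
})

test_that("baseline AF phenotype lies in the human-atrial window and adapts to rate", {
  ph <- baseline_phenotype()
  expect_gt(ph$rmp, -90); expect_lt(ph$rmp, -70)
  expect_gt(ph$apd90, 80); expect_lt(ph$apd90, 250)
  expect_gt(ph$apa, 90)
  # restitution direction: APD90 shortens from 1 Hz to 4 Hz
  expect_lt(ph$apd90_ratio_4hz, 1)
})

test_that("removing the sodium current abolishes the regenerative upstroke", {
  p0 <- af_cell_params(scale = c(gNa = 0))
  tr <- simulate_cell(p0, pacing_protocol(1, beats = 3))
  expect_lt(max(tr$V), 0) # no overshoot
  bm <- compute_ap_biomarkers(tr, c(2000, 3000))
  ranges <- default_biomarker_ranges()
  apa_min <- ranges$min[ranges$biomarker == "apa"]
  expect_true(!bm$excited || bm$apa < apa_min)
})

test_that("parameter sets serialize to JSON and back", {
  skip_if_not_installed("jsonlite")
  p <- af_cell_params(scale = c(gNa = 1.5, gK1 = 0.7))
  f <- withr::local_tempfile(fileext = ".json")
  write_params_json(p, f)
  q <- read_params_json(f)
  expect_equal(unname(q$g), unname(p$g))
  expect_equal(q$remodeling, p$remodeling)
})
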