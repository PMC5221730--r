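test_that("zero diffusion reproduces the single-cell trajectory exactly", {
  p <- af_cell_params()
  mesh <- build_mesh("strip", size = 0.5, dx = 0.05)
  traj <- afpop:::beat_state_trajectory(p, 300)
  st <- traj[, 40] # mid-plateau state of a paced beat
  mv <- run_tissue(mesh, p, matrix(st, 21, nrow(mesh$points)),
                   duration = 150, D = 0, dt = 0.025, frame_dt = 1)
  ref <- afpop:::crn_cell_run(afpop:::param_vector(p), st, 0.025, 150,
                              numeric(0), 2, 0, 1, FALSE)
  for (node in c(1, 5, 11))
    expect_lt(max(abs(mv$V[node, ] - ref$V)), 1e-9)
})

test_that("uniform tissue stays uniform under diffusion (zero-flux)", {
  p <- af_cell_params()
  mesh <- build_mesh("sheet", size = 1, dx = 0.05)
  rest <- unname(cell_steady_state(p))
  mv <- run_tissue(mesh, p, rest, duration = 20, D = 6e-4, dt = 0.025)
  spreads <- apply(mv$V, 2, function(v) diff(range(v)))
  expect_lt(max(spreads), 1e-9)
})

test_that("a conductance block changes nothing before its onset", {
  p <- af_cell_params()
  mesh <- build_mesh("strip", size = 1, dx = 0.05)
  stim <- list(list(nodes = 1:3, start = 2, dur = 2,
                    amp = 2 * diastolic_threshold()))
  run <- function(block) run_tissue(mesh, p, unname(cell_steady_state(p)),
                                    duration = 120, D = 6e-4, dt = 0.025,
                                    stims = stim, block = block)
  free <- run(NULL)
  blocked <- run(block_spec("gCaL", 0.5, onset = 60))
  pre <- blocked$time < 60
  expect_identical(blocked$V[, pre], free$V[, pre])
  expect_false(identical(blocked$V[, !pre], free$V[, !pre]))
  expect_true(blocked$interventions$applied)

  late <- run(block_spec("gCaL", 0.5, onset = 500))
  expect_identical(late$V, free$V)
  expect_false(late$interventions$applied)

  null_block <- run(block_spec("gCaL", 1, onset = 0))
  expect_identical(null_block$V, free$V)
})

test_that("block specifications are validated", {
  expect_error(block_spec("gFoo", 0.5), "unknown block target")
  expect_error(block_spec("gCaL", 1.5), "\\[0, 1\\]")
  expect_error(block_spec("gCaL", -0.1), "\\[0, 1\\]")
})

test_that("unstable diffusion steps are refused", {
  p <- af_cell_params()
  mesh <- build_mesh("strip", size = 1, dx = 0.01)
  expect_error(run_tissue(mesh, p, unname(cell_steady_state(p)),
                          duration = 10, D = 1.2e-3, dt = 0.05),
               "unstable")
})

test_that("planar waves propagate with a measurable conduction velocity", {
  cv <- measure_cv(af_cell_params(), D = 1.2e-3, dx = 0.05, dt = 0.025)
  expect_gt(cv, 15)
  expect_lt(cv, 90)
})

test_that("phase-seed initiation spawns a rotor on the sheet", {
  p <- af_cell_params()
  mesh <- build_mesh("sheet", size = 2.5, dx = 0.05)
  init <- initiate_reentry(mesh, p, "phase_seed")
  expect_equal(dim(init), c(21L, nrow(mesh$points)))
  mv <- run_tissue(mesh, p, init, duration = 400, D = 6e-4, dt = 0.04,
                   frame_dt = 2)
  ps <- detect_singularities(compute_phase(mv))
  at200 <- ps[ps$time >= 150 & ps$time <= 250, ]
  expect_gt(nrow(at200), 0)
  expect_true(all(abs(at200$charge) == 1))
})

test_that("an all-resting sheet has no phase singularities", {
  p <- af_cell_params()
  mesh <- build_mesh("sheet", size = 1.5, dx = 0.05)
  mv <- run_tissue(mesh, p, unname(cell_steady_state(p)), duration = 300,
                   D = 6e-4, dt = 0.04, frame_dt = 2)
  ph <- compute_phase(mv)
  expect_true(all(ph$undefined))
  expect_equal(nrow(detect_singularities(ph)), 0L)
})
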