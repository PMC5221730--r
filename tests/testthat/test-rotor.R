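# synthetic voltage movie from an explicit space-time function
synthetic_movie <- function(mesh, f, times) {
  V <- vapply(times, function(t)
    vapply(seq_len(nrow(mesh$points)),
           function(i) f(mesh$points[i, ], t), numeric(1)),
    numeric(nrow(mesh$points)))
  structure(list(V = V, time = times, mesh = mesh, frame_dt = diff(times[1:2]),
                 interventions = NULL), class = "voltage_movie")
}

test_that("the analytic-signal phase of a cosine advances one turn per period", {
  mesh <- build_mesh("strip", size = 0.1, dx = 0.05)
  times <- seq(0, 2000, by = 2)
  f <- 5 / 1000 # 5 Hz in 1/ms
  mv <- synthetic_movie(mesh, function(p, t) cos(2 * pi * f * t), times)
  ph <- compute_phase(mv)
  up <- afpop:::wrap_phase(diff(ph$phase[1, ]))
  total <- sum(up)
  periods <- (max(ph$time) - min(ph$time)) * f
  expect_lt(abs(abs(total) / (2 * pi) - periods) / periods, 0.02)
})

test_that("degenerate and sign-flipped signals are handled", {
  mesh <- build_mesh("strip", size = 0.15, dx = 0.05)
  times <- seq(0, 1000, by = 2)
  mv <- synthetic_movie(mesh, function(p, t)
    if (p[1] == 0) -70 else cos(2 * pi * 0.006 * t), times)
  ph <- compute_phase(mv)
  expect_true(ph$undefined[1])
  expect_true(all(is.na(ph$phase[1, ])))
  neg <- mv; neg$V <- -mv$V
  phn <- compute_phase(neg)
  d <- afpop:::wrap_phase(phn$phase[3, ] - ph$phase[3, ] - pi)
  expect_lt(max(abs(d)), 1e-8)
})

test_that("an analytic spiral field yields one centered +1 singularity", {
  mesh <- build_mesh("sheet", size = 2, dx = 0.05)
  ctr <- c(1.013, 0.987) # off-node center
  phase <- atan2(mesh$points[, 2] - ctr[2], mesh$points[, 1] - ctr[1])
  ps <- detect_singularities(matrix(phase, ncol = 1), mesh)
  expect_equal(nrow(ps), 1L)
  expect_equal(ps$charge, 1L)
  expect_lt(sqrt((ps$x - ctr[1])^2 + (ps$y - ctr[2])^2), mesh$spacing)

  uniform <- detect_singularities(matrix(1, nrow(mesh$points), 1), mesh)
  expect_equal(nrow(uniform), 0L)
})

test_that("topological charge sums to zero on closed spheres", {
  mesh <- build_mesh("sphere", radius = 2, subdivisions = 3)
  # azimuthal winding: singular pair at the poles
  ps <- detect_singularities(matrix(atan2(mesh$points[, 2], mesh$points[, 1]),
                                    ncol = 1), mesh)
  expect_gt(nrow(ps), 0)
  expect_equal(sum(ps$charge), 0L)
  # random smooth fields from low-order spherical modes
  for (seed in 1:20) {
    set.seed(seed)
    p <- mesh$points / 2
    z <- complex(real = 0, imaginary = 0)
    for (k in 1:3)
      z <- z + runif(1, 0.2, 1) * exp(1i * (runif(1, -3, 3) * p[, 1] +
                                            runif(1, -3, 3) * p[, 2] +
                                            runif(1, -3, 3) * p[, 3]))
    ps <- detect_singularities(matrix(Arg(z), ncol = 1), mesh)
    if (nrow(ps)) expect_equal(sum(ps$charge), 0L)
  }
})

test_that("face-loop detection agrees with the brute-force winding oracle", {
  mesh <- build_mesh("sheet", size = 1, dx = 0.05)
  for (seed in 1:25) {
    phase <- random_smooth_phase(mesh, seed)
    ps <- detect_singularities(matrix(phase, ncol = 1), mesh)
    w <- oracle_winding(phase, mesh)
    hits <- which(w != 0)
    expect_identical(unname(sort(ps$face)), sort(hits))
    if (nrow(ps))
      expect_identical(ps$charge[order(ps$face)], w[hits])
  }
})

test_that("core tracking follows trajectories without identity switches", {
  mesh <- build_mesh("sheet", size = 2, dx = 0.05)
  # stationary core
  stat <- tibble::tibble(frame = 1:50, time = (1:50) * 2, face = 1L,
                         x = 1, y = 1, z = 0, charge = 1L)
  tr <- track_cores(stat, mesh)
  expect_equal(length(unique(tr$id)), 1L)
  expect_equal(nrow(tr), 50L)

  # core moving along a circle
  th <- seq(0, 4 * pi, length.out = 120)
  circ <- tibble::tibble(frame = seq_along(th), time = 2 * seq_along(th),
                         face = 1L, x = 1 + 0.4 * cos(th),
                         y = 1 + 0.4 * sin(th), z = 0, charge = 1L)
  tr2 <- track_cores(circ, mesh)
  expect_equal(length(unique(tr2$id)), 1L)

  # annihilating pair: both trajectories end at the collision frame
  tt <- 1:40
  pair <- dplyr::bind_rows(
    tibble::tibble(frame = tt, time = 2 * tt, face = 1L,
                   x = 1 - 0.02 * (40 - tt), y = 1, z = 0, charge = 1L),
    tibble::tibble(frame = tt, time = 2 * tt, face = 2L,
                   x = 1 + 0.02 * (40 - tt), y = 1, z = 0, charge = -1L))
  tr3 <- track_cores(pair, mesh)
  ends <- dplyr::summarise(dplyr::group_by(tr3, id), last = max(frame))
  expect_equal(nrow(ends), 2L)
  expect_true(all(ends$last == 40))
})

test_that("meandering area matches hull geometry", {
  expect_equal(meandering_area(cbind(1, 1, 0)[rep(1, 10), ]), 0)
  expect_equal(meandering_area(rbind(c(0, 0, 0), c(1, 1, 0))), 0)
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  circ <- cbind(0.5 * cos(th), 0.5 * sin(th), 0)
  expect_equal(meandering_area(circ), pi * 0.25, tolerance = 0.05)
  # collinear points
  expect_equal(meandering_area(cbind(1:5, 1:5, 0)), 0)
})

test_that("tangent-plane projection preserves small hull areas on spheres", {
  mesh <- build_mesh("sphere", radius = 2.5, subdivisions = 2)
  th <- seq(0, 2 * pi, length.out = 33)[-33]
  r <- 0.3
  # small circle around the +x pole, pushed onto the sphere
  pts <- cbind(sqrt(2.5^2 - r^2), r * cos(th), r * sin(th))
  expect_equal(meandering_area(pts, mesh), pi * r^2, tolerance = 0.02)
})

test_that("dominant frequency recovers a known pulse rate", {
  mesh <- build_mesh("strip", size = 0.25, dx = 0.05)
  times <- seq(0, 1998, by = 2)
  mv <- synthetic_movie(mesh, function(p, t)
    -80 + 100 * (t %% 200 < 30), times) # 5 Hz pulse train
  df <- dominant_frequency(mv)
  expect_lt(abs(df$df - 5), df$resolution)
  expect_true(all(abs(df$map - 5) < df$resolution))

  flat <- synthetic_movie(mesh, function(p, t) -80, times)
  expect_true(is.na(dominant_frequency(flat)$df))

  rev <- mv; rev$V <- mv$V[, rev(seq_len(ncol(mv$V)))]
  expect_equal(dominant_frequency(rev)$map, df$map)
})

test_that("termination is detected with its mechanism", {
  mesh <- build_mesh("strip", size = 0.25, dx = 0.05)
  times <- seq(0, 1998, by = 2)
  relax <- synthetic_movie(mesh, function(p, t)
    if (t < 1000) -80 + 100 * (t %% 150 < 25) else -80, times)
  term <- detect_termination(relax, tibble::tibble(id = integer(),
                                                   frame = integer(),
                                                   time = numeric(),
                                                   x = numeric(), y = numeric(),
                                                   z = numeric(),
                                                   charge = integer()))
  expect_false(term$sustained)
  # quiescence begins right after the last suprathreshold pulse (ends ~925)
  expect_gte(term$t_term, 920)
  expect_lte(term$t_term, 1000)

  active <- synthetic_movie(mesh, function(p, t) -80 + 100 * (t %% 150 < 25),
                            times)
  expect_true(detect_termination(active, tibble::tibble())$sustained)

  # annihilating opposite-charge pair near each other at death
  tt <- 1:100
  tracks <- dplyr::bind_rows(
    tibble::tibble(id = 1L, frame = tt, time = relax$time[tt],
                   x = 0.1, y = 0, z = 0, charge = 1L),
    tibble::tibble(id = 2L, frame = tt, time = relax$time[tt],
                   x = 0.15, y = 0, z = 0, charge = -1L))
  term2 <- detect_termination(relax, tracks)
  expect_false(term2$sustained)
  expect_equal(term2$mechanism, "core_collision")
})
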