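#' Phase map of a voltage movie
#'
#' Computes the instantaneous activation phase of every node, by default as
#' the argument of the analytic signal (FFT-based Hilbert transform) of the
#' mean-subtracted voltage. A time-delay embedding alternative
#' (`atan2(V(t) - m, V(t - delay) - m)`) is provided. Nodes with (near-)
#' constant voltage have undefined phase and are flagged `NA`.
#'
#' @param movie A `voltage_movie`.
#' @param method `"hilbert"` (default) or `"delay"`.
#' @param delay_ms Embedding delay for `method = "delay"`.
#' @return A `phase_movie`: list with `phase` (nodes x frames, in
#'   `(-pi, pi]`), `time`, `mesh`, `undefined` (logical per node).
#' @export
compute_phase <- function(movie, method = c("hilbert", "delay"),
                          delay_ms = 10) {
  method <- match.arg(method)
  V <- movie$V
  time <- movie$time
  if (method == "hilbert") {
    # trim leading frames so the FFT length is 5-smooth (mixed-radix FFT
    # cost explodes for near-prime lengths)
    nt0 <- ncol(V)
    smooth5 <- function(n) {
      while (n > 1) { for (f in c(2, 3, 5)) while (n %% f == 0) n <- n / f
        if (n > 1) return(FALSE) else break }
      TRUE
    }
    nt <- nt0
    while (nt > 16 && !smooth5(nt)) nt <- nt - 1
    if (nt < nt0) {
      V <- V[, (nt0 - nt + 1):nt0, drop = FALSE]
      time <- time[(nt0 - nt + 1):nt0]
    }
  }
  m <- rowMeans(V)
  x <- V - m
  undefined <- apply(x, 1, function(r) sd(r) < 1e-4)
  if (method == "hilbert") {
    nt <- ncol(x)
    h <- numeric(nt)
    if (nt %% 2 == 0) {
      h[1] <- 1; h[nt / 2 + 1] <- 1; h[2:(nt / 2)] <- 2
    } else {
      h[1] <- 1; h[2:((nt + 1) / 2)] <- 2
    }
    X <- t(mvfft(t(x)))          # node-wise FFT over time
    A <- t(mvfft(t(X * rep(h, each = nrow(x))), inverse = TRUE)) / nt
    ph <- atan2(Im(A), Re(A))
  } else {
    d <- max(1L, round(delay_ms / movie$frame_dt))
    xd <- cbind(x[, rep(1L, d), drop = FALSE], x[, seq_len(ncol(x) - d),
                                                 drop = FALSE])
    ph <- atan2(x, xd)
  }
  ph[ph <= -pi] <- pi
  ph[undefined, ] <- NA_real_
  structure(list(phase = ph, time = time, mesh = movie$mesh,
                 undefined = undefined), class = "phase_movie")
}

wrap_phase <- function(d) d - 2 * pi * round(d / (2 * pi))

#' Detect phase singularities
#'
#' Scans every mesh face of every frame and reports a phase singularity
#' where the oriented sum of wrapped phase differences around the face
#' boundary equals +-2 pi (topological charge +-1). Position is the face
#' centroid.
#'
#' @param phase A `phase_movie` (or a plain nodes x frames phase matrix with
#'   `mesh` supplied).
#' @param mesh Mesh, required when `phase` is a bare matrix.
#' @param frames Optional integer subset of frame indices to scan.
#' @return Tibble with `frame`, `time`, `face`, `x`, `y`, `z`, `charge`.
#' @export
detect_singularities <- function(phase, mesh = NULL, frames = NULL) {
  if (inherits(phase, "phase_movie")) {
    mesh <- phase$mesh; time <- phase$time; P <- phase$phase
  } else {
    if (is.null(mesh)) abort("mesh is required for a bare phase matrix")
    P <- phase; time <- seq_len(ncol(P)) - 1
  }
  f <- mesh$faces
  if (is.null(f)) abort("mesh has no faces (strip meshes are 1D)")
  if (is.null(frames)) frames <- seq_len(ncol(P))
  k <- ncol(f)
  cent <- matrix(0, nrow(f), 3)
  for (s in seq_len(k)) cent <- cent + mesh$points[f[, s], , drop = FALSE] / k

  out <- vector("list", length(frames))
  chunk <- 250L
  for (c0 in seq(1, length(frames), by = chunk)) {
    sel <- frames[c0:min(c0 + chunk - 1L, length(frames))]
    S <- matrix(0, nrow(f), length(sel))
    bad <- matrix(FALSE, nrow(f), length(sel))
    Ps <- P[, sel, drop = FALSE]
    for (s in seq_len(k)) {
      a <- f[, s]; b <- f[, if (s == k) 1L else s + 1L]
      d <- Ps[b, , drop = FALSE] - Ps[a, , drop = FALSE]
      bad <- bad | !is.finite(d)
      d[!is.finite(d)] <- 0
      S <- S + wrap_phase(d)
    }
    q <- round(S / (2 * pi))
    q[bad] <- 0L
    hit <- which(q != 0, arr.ind = TRUE)
    if (nrow(hit)) {
      out[[c0]] <- tibble(frame = sel[hit[, 2]], time = time[sel[hit[, 2]]],
                          face = unname(hit[, 1]),
                          x = cent[hit[, 1], 1], y = cent[hit[, 1], 2],
                          z = cent[hit[, 1], 3],
                          charge = as.integer(q[hit]))
    }
  }
  res <- dplyr::bind_rows(out)
  if (!nrow(res))
    res <- tibble(frame = integer(), time = numeric(), face = integer(),
                  x = numeric(), y = numeric(), z = numeric(),
                  charge = integer())
  dplyr::arrange(res, .data$frame, .data$face)
}

#' Track phase-singularity cores over time
#'
#' Greedy nearest-neighbour association of singularities between
#' consecutive frames, gated by a maximum jump distance and matching
#' topological charge; unmatched singularities open or close trajectories.
#'
#' @param ps Singularity tibble from [detect_singularities()].
#' @param mesh Mesh (used for the default jump gate of 4 node spacings).
#' @param max_jump Maximum allowed inter-frame displacement (cm).
#' @return Tibble with `id`, `frame`, `time`, `x`, `y`, `z`, `charge`,
#'   ordered by trajectory and time.
#' @export
track_cores <- function(ps, mesh = NULL, max_jump = NULL) {
  if (is.null(max_jump)) {
    if (is.null(mesh)) abort("either mesh or max_jump must be given")
    max_jump <- 4 * mesh$spacing
  }
  if (!nrow(ps))
    return(tibble(id = integer(), frame = integer(), time = numeric(),
                  x = numeric(), y = numeric(), z = numeric(),
                  charge = integer()))
  frames <- sort(unique(ps$frame))
  next_id <- 0L
  open <- list() # id, pos, charge, frame
  rows <- vector("list", length(frames))
  prev_frame <- -Inf
  for (fi in seq_along(frames)) {
    fr <- frames[fi]
    cur <- ps[ps$frame == fr, , drop = FALSE]
    m <- nrow(cur)
    assigned <- rep(NA_integer_, m)
    if (length(open) && fr - prev_frame <= 1.5) {
      op <- do.call(rbind, lapply(open, function(o) c(o$pos, o$charge)))
      dmat <- sqrt(outer(op[, 1], cur$x, "-")^2 +
                   outer(op[, 2], cur$y, "-")^2 +
                   outer(op[, 3], cur$z, "-")^2)
      dmat[op[, 4] != rep(cur$charge, each = nrow(op))] <- Inf
      dmat[dmat > max_jump] <- Inf
      repeat {
        if (all(!is.finite(dmat))) break
        w <- which.min(dmat)
        i <- (w - 1) %% nrow(dmat) + 1; j <- (w - 1) %/% nrow(dmat) + 1
        assigned[j] <- i
        dmat[i, ] <- Inf; dmat[, j] <- Inf
      }
    }
    new_open <- list()
    ids <- integer(m)
    for (j in seq_len(m)) {
      if (!is.na(assigned[j])) {
        ids[j] <- open[[assigned[j]]]$id
      } else {
        next_id <- next_id + 1L
        ids[j] <- next_id
      }
      new_open[[j]] <- list(id = ids[j],
                            pos = c(cur$x[j], cur$y[j], cur$z[j]),
                            charge = cur$charge[j], frame = fr)
    }
    open <- new_open
    prev_frame <- fr
    rows[[fi]] <- dplyr::mutate(cur, id = ids)
  }
  dplyr::arrange(dplyr::bind_rows(rows)[, c("id", "frame", "time", "x", "y",
                                            "z", "charge")],
                 .data$id, .data$frame)
}

#' Rotor-meandering area of a core trajectory
#'
#' Area (cm^2) of the convex hull of the visited core positions; on
#' spherical meshes positions are first projected onto the tangent plane at
#' the trajectory centroid. Fewer than 3 non-collinear points give 0.
#'
#' @param traj Trajectory tibble (columns `x`, `y`, `z`) or an `n x 3`
#'   matrix.
#' @param mesh Optional mesh (tangent-plane projection used for spheres).
#' @return Area in cm^2.
#' @export
meandering_area <- function(traj, mesh = NULL) {
  p <- if (is.data.frame(traj)) cbind(traj$x, traj$y, traj$z) else as.matrix(traj)
  if (nrow(p) < 3) return(0)
  if (!is.null(mesh) && mesh$kind == "sphere") {
    ctr <- colMeans(p)
    nrm <- ctr / sqrt(sum(ctr^2))
    e1 <- c(-nrm[2], nrm[1], 0)
    if (sqrt(sum(e1^2)) < 1e-8) e1 <- c(1, 0, 0)
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
            nrm[3] * e1[1] - nrm[1] * e1[3],
            nrm[1] * e1[2] - nrm[2] * e1[1])
    q <- cbind((p - rep(ctr, each = nrow(p))) %*% e1,
               (p - rep(ctr, each = nrow(p))) %*% e2)
  } else {
    q <- p[, 1:2, drop = FALSE]
  }
  q <- unique(q)
  if (nrow(q) < 3) return(0)
  h <- grDevices::chull(q[, 1], q[, 2])
  if (length(h) < 3) return(0)
  hx <- q[h, 1]; hy <- q[h, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

# RM over a set of trajectories: hull area of the dominant (longest-lived)
# trajectory; with several comparably long-lived rotors, the maximum.
meandering_from_tracks <- function(tracks, mesh, life_frac = 0.5) {
  if (!nrow(tracks)) return(0)
  life <- dplyr::summarise(dplyr::group_by(tracks, .data$id),
                           life = max(.data$time) - min(.data$time))
  keep <- life$id[life$life >= life_frac * max(life$life)]
  max(vapply(keep, function(k)
    meandering_area(tracks[tracks$id == k, , drop = FALSE], mesh),
    numeric(1)))
}

#' Dominant frequency of a voltage movie
#'
#' Per-node dominant frequency: the frequency of the highest peak of a
#' Welch-averaged periodogram (Hann window, 50% segment overlap, parabolic
#' peak interpolation) within `band`. The scalar movie DF is the modal
#' per-node value (median within the most populated resolution bin), robust
#' to local conduction block; `aggregate = "max"` is available.
#'
#' @param movie A `voltage_movie`.
#' @param band Search band in Hz.
#' @param nseg Number of Welch segments.
#' @param aggregate `"mode"` (default) or `"max"`.
#' @param window Optional time window (ms) to analyze.
#' @return List with scalar `df` (Hz, `NA` if undefined), per-node `map`,
#'   and the spectral `resolution` (Hz).
#' @export
dominant_frequency <- function(movie, band = c(1, 20), nseg = 2,
                               aggregate = c("mode", "max"), window = NULL) {
  aggregate <- match.arg(aggregate)
  V <- movie$V
  tt <- movie$time
  if (!is.null(window)) {
    keep <- tt >= window[1] & tt <= window[2]
    V <- V[, keep, drop = FALSE]; tt <- tt[keep]
  }
  fs <- 1000 / movie$frame_dt
  nt <- ncol(V)
  L <- floor(2 * nt / (nseg + 1))
  if (L < 16) abort("movie too short for spectral analysis")
  starts <- unique(round(seq(1, nt - L + 1, length.out = nseg)))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1)) # Hann
  nfft <- 2^ceiling(log2(L))
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  inband <- which(freqs >= band[1] & freqs <= band[2])
  x <- V - rowMeans(V)
  psd <- 0
  keep <- seq_len(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[, s:(s + L - 1), drop = FALSE] * rep(win, each = nrow(x))
    seg <- cbind(seg, matrix(0, nrow(x), nfft - L))
    X <- mvfft(t(seg))[keep, , drop = FALSE]
    psd <- psd + t(Re(X)^2 + Im(X)^2)
  }
  inband <- inband[inband <= length(keep)]
  flat <- apply(x, 1, function(r) sd(r) < 1e-4)
  map <- rep(NA_real_, nrow(V))
  pb <- psd[, inband, drop = FALSE]
  pk <- max.col(pb, ties.method = "first")
  for (j in which(!flat)) {
    i <- inband[pk[j]]
    # parabolic interpolation of the log-power peak
    if (i > 1 && i < ncol(psd)) {
      y1 <- log(psd[j, i - 1] + 1e-300); y2 <- log(psd[j, i] + 1e-300)
      y3 <- log(psd[j, i + 1] + 1e-300)
      den <- y1 - 2 * y2 + y3
      delta <- if (abs(den) > 1e-12) 0.5 * (y1 - y3) / den else 0
      delta <- max(min(delta, 0.5), -0.5)
      map[j] <- freqs[i] + delta * fs / nfft
    } else map[j] <- freqs[i]
  }
  resolution <- fs / L
  df <- NA_real_
  vals <- map[is.finite(map)]
  if (length(vals)) {
    if (aggregate == "max") {
      df <- max(vals)
    } else {
      bins <- round(vals / resolution)
      tab <- table(bins)
      modal <- as.numeric(names(tab)[which.max(tab)])
      df <- median(vals[bins == modal])
    }
  }
  list(df = df, map = map, resolution = resolution)
}

#' Detect termination of reentrant activity
#'
#' The movie is terminated when, for a contiguous `quiet_ms` window, no
#' phase singularity exists and no node is above the activation threshold.
#' If the last two surviving opposite-charge trajectories died close to each
#' other (within `gate` and 2 frames), the mechanism is tagged
#' `"core_collision"`.
#'
#' @param movie A `voltage_movie`.
#' @param tracks Trajectory tibble from [track_cores()] (may be empty).
#' @param threshold Activation threshold (mV).
#' @param quiet_ms Required quiescent window (ms).
#' @param gate Collision gate distance (cm); default 4 node spacings.
#' @return One-row tibble: `sustained`, `t_term` (ms or `NA`), `mechanism`
#'   (`"core_collision"`, `"other"` or `NA`).
#' @export
detect_termination <- function(movie, tracks, threshold = -40,
                               quiet_ms = 300, gate = NULL) {
  if (is.null(gate)) gate <- 4 * movie$mesh$spacing
  vmax <- apply(movie$V, 2, max)
  has_ps <- if (nrow(tracks)) movie$time %in% unique(tracks$time)
            else rep(FALSE, length(movie$time))
  quiet <- vmax <= threshold & !has_ps
  need <- ceiling(quiet_ms / movie$frame_dt)
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= need)
  if (!length(hit))
    return(tibble(sustained = TRUE, t_term = NA_real_,
                  mechanism = NA_character_))
  t_term <- movie$time[starts[hit[1]]]
  mech <- "other"
  if (nrow(tracks)) {
    deaths <- dplyr::slice_tail(dplyr::group_by(
      dplyr::arrange(tracks, .data$id, .data$frame), .data$id), n = 1)
    deaths <- dplyr::ungroup(deaths)
    deaths <- deaths[deaths$time <= t_term, , drop = FALSE]
    if (nrow(deaths) >= 2) {
      deaths <- dplyr::arrange(deaths, dplyr::desc(.data$time))
      a <- deaths[1, ]; b <- deaths[2, ]
      d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
      if (a$charge != b$charge && d <= gate &&
          abs(a$frame - b$frame) <= 2) mech <- "core_collision"
    }
  }
  tibble(sustained = FALSE, t_term = t_term, mechanism = mech)
}

#' Reentry biomarkers of one tissue simulation
#'
#' Full rotor analysis of a voltage movie: phase mapping, singularity
#' detection and tracking, dominant frequency, rotor-meandering area and
#' termination classification.
#'
#' @param movie A `voltage_movie`.
#' @param band DF search band (Hz).
#' @param quiet_ms Termination quiescence window (ms).
#' @param min_spectrum_ms Minimum analyzable window for DF (ms).
#' @return One-row tibble: `df` (Hz), `rm` (cm^2), `sustained`, `t_term`,
#'   `mechanism`, `n_trajectories`.
#' @export
reentry_biomarkers <- function(movie, band = c(1, 20), quiet_ms = 300,
                               min_spectrum_ms = 250) {
  ph <- compute_phase(movie)
  ps <- detect_singularities(ph)
  tracks <- track_cores(ps, movie$mesh)
  term <- detect_termination(movie, tracks, quiet_ms = quiet_ms)
  # sustained activity without any detectable singularity = reentry anchored
  # around the domain boundary (a bounded-sheet mode): there is no core, so
  # its meandering is undefined rather than zero
  rm_area <- if (term$sustained && !nrow(tracks)) NA_real_
             else meandering_from_tracks(tracks, movie$mesh)
  df_window <- if (term$sustained) NULL else c(0, term$t_term)
  df <- NA_real_
  span <- if (is.null(df_window)) max(movie$time) else term$t_term
  if (span >= min_spectrum_ms)
    df <- dominant_frequency(movie, band = band, window = df_window)$df
  dplyr::bind_cols(tibble(df = df, rm = rm_area,
                          n_trajectories = length(unique(tracks$id))), term)
}
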