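#' Build a tissue mesh
#'
#' Constructs the spatial discretization for monodomain simulation: a square
#' sheet (regular grid, 5-point Laplacian, no-flux boundaries), a 1D strip
#' (for conduction-velocity measurements), or a closed spherical surface
#' (icosahedron subdivision, cotangent-weight Laplacian normalized by
#' barycentric vertex area). Every Laplacian row sums to zero, so a uniform
#' voltage field diffuses to exactly zero flux.
#'
#' @param kind `"sheet"`, `"strip"` or `"sphere"`.
#' @param size Sheet edge length or strip length in cm.
#' @param dx Grid spacing in cm (sheet/strip).
#' @param radius Sphere radius in cm (default 2.5, surface about 79 cm^2, of
#'   the order of the human atrial surface).
#' @param subdivisions Icosphere subdivision level; level `k` has
#'   `10 * 4^k + 2` vertices. Level 4 gives about 0.08-cm spacing at the
#'   default radius; use 5-6 for production-resolution spheres.
#' @return An `af_mesh`: list with `points` (n x 3, cm), `faces` (quads for
#'   grids, triangles for spheres), `L` (sparse Laplacian, 1/cm^2), `area`
#'   (per-node, cm^2), `kind`, `spacing`, and grid dims `nx`, `ny`.
#' @export
build_mesh <- function(kind = c("sheet", "strip", "sphere"), size = 3,
                       dx = 0.05, radius = 2.5, subdivisions = 4) {
  kind <- match.arg(kind)
  switch(kind,
         sheet = grid_mesh(size, size, dx),
         strip = grid_mesh(size, 0, dx),
         sphere = sphere_mesh(radius, subdivisions))
}

grid_mesh <- function(lx, ly, dx) {
  if (dx <= 0 || lx <= 0) abort("degenerate mesh size")
  nx <- round(lx / dx) + 1L
  ny <- max(round(ly / dx) + 1L, 1L)
  idx <- function(i, j) (j - 1L) * nx + i # column-major over rows of x
  pts <- cbind(x = rep((seq_len(nx) - 1) * dx, ny),
               y = rep((seq_len(ny) - 1) * dx, each = nx), z = 0)
  n <- nx * ny
  # 5-point Laplacian with mirror (no-flux) boundaries: off-diagonal 1/dx^2
  # per existing neighbor, diagonal minus the row sum
  ii <- jj <- integer(0)
  add <- function(a, b) { ii <<- c(ii, a); jj <<- c(jj, b) }
  i <- seq_len(nx); j <- seq_len(ny)
  # horizontal edges
  if (nx > 1) {
    a <- as.vector(outer(i[-nx], j, idx)); b <- as.vector(outer(i[-1], j, idx))
    add(a, b); add(b, a)
  }
  if (ny > 1) {
    a <- as.vector(outer(i, j[-ny], idx)); b <- as.vector(outer(i, j[-1], idx))
    add(a, b); add(b, a)
  }
  w <- rep(1 / dx^2, length(ii))
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = w, dims = c(n, n))
  Matrix::diag(L) <- -Matrix::rowSums(L)
  faces <- NULL
  if (nx > 1 && ny > 1) {
    fi <- as.vector(outer(i[-nx], j[-ny], idx))
    faces <- cbind(fi, fi + 1L, fi + 1L + nx, fi + nx) # counterclockwise quad
  }
  structure(list(points = pts, faces = faces, L = L,
                 area = rep(dx^2, n), kind = if (ny == 1) "strip" else "sheet",
                 spacing = dx, nx = nx, ny = ny),
            class = "af_mesh")
}

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(v = v, f = f)
}

sphere_mesh <- function(radius, subdivisions) {
  if (radius <= 0) abort("degenerate sphere radius")
  ico <- icosahedron()
  v <- ico$v; f <- ico$f
  for (lev in seq_len(subdivisions)) {
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mids <- new.env(parent = emptyenv())
    nv <- nrow(v)
    vlist <- list(v)
    midpoint <- function(a, b) {
      k <- edge_key(a, b)
      hit <- mids[[k]]
      if (!is.null(hit)) return(hit)
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      nv <<- nv + 1L
      vlist[[length(vlist) + 1L]] <<- m
      mids[[k]] <- nv
      nv
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(t - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  v <- v * radius
  n <- nrow(v)
  # cotangent weights and barycentric vertex areas
  tri_area <- function(p1, p2, p3) {
    cr <- cbind((p2[, 2] - p1[, 2]) * (p3[, 3] - p1[, 3]) -
                (p2[, 3] - p1[, 3]) * (p3[, 2] - p1[, 2]),
                (p2[, 3] - p1[, 3]) * (p3[, 1] - p1[, 1]) -
                (p2[, 1] - p1[, 1]) * (p3[, 3] - p1[, 3]),
                (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
                (p2[, 2] - p1[, 2]) * (p3[, 1] - p1[, 1]))
    0.5 * sqrt(rowSums(cr^2))
  }
  cot_at <- function(p0, pa, pb) {
    u <- pa - p0; w <- pb - p0
    dot <- rowSums(u * w)
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    dot / pmax(sqrt(rowSums(cr^2)), 1e-12)
  }
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  at <- tri_area(p1, p2, p3)
  acc <- rowsum(rep(at / 3, 3), c(f[, 1], f[, 2], f[, 3]))
  area <- numeric(n)
  area[as.integer(rownames(acc))] <- acc[, 1]
  c1 <- cot_at(p1, p2, p3); c2 <- cot_at(p2, p3, p1); c3 <- cot_at(p3, p1, p2)
  ii <- c(f[, 2], f[, 3], f[, 3], f[, 1], f[, 1], f[, 2])
  jj <- c(f[, 3], f[, 2], f[, 1], f[, 3], f[, 2], f[, 1])
  ww <- c(c1, c1, c2, c2, c3, c3) / 2
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
  L <- Matrix::Diagonal(x = 1 / area) %*% (W - Matrix::Diagonal(x = Matrix::rowSums(W)))
  edge_len <- sqrt(rowSums((p1 - p2)^2))
  structure(list(points = v, faces = f, L = methods::as(L, "generalMatrix"),
                 area = area, kind = "sphere", spacing = mean(edge_len),
                 nx = NA_integer_, ny = NA_integer_),
            class = "af_mesh")
}

#' Euler characteristic of a mesh
#'
#' `V - E + F` over unique undirected edges; 2 for a closed sphere.
#'
#' @param mesh An `af_mesh`.
#' @return Integer.
#' @export
mesh_euler_characteristic <- function(mesh) {
  f <- mesh$faces
  k <- ncol(f)
  e <- do.call(rbind, lapply(seq_len(k), function(s) {
    a <- f[, s]; b <- f[, if (s == k) 1L else s + 1L]
    cbind(pmin(a, b), pmax(a, b))
  }))
  nrow(mesh$points) - nrow(unique(e)) + nrow(f)
}

#' @export
print.af_mesh <- function(x, ...) {
  cat(sprintf("<af_mesh> %s: %d nodes, %d faces, spacing %.3f cm, area %.1f cm^2\n",
              x$kind, nrow(x$points), if (is.null(x$faces)) 0L else nrow(x$faces),
              x$spacing, sum(x$area)))
  invisible(x)
}

#' Export a mesh as ASCII PLY
#'
#' @param mesh An `af_mesh`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nf <- if (is.null(mesh$faces)) 0L else nrow(mesh$faces)
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$points)),
               "property float x", "property float y", "property float z",
               paste("element face", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$points, 1, function(p) paste(p, collapse = " ")), con)
  if (nf)
    writeLines(apply(mesh$faces - 1L, 1, function(f)
      paste(c(length(f), f), collapse = " ")), con)
  invisible(path)
}
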