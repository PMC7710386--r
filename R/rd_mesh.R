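#' @useDynLib patternblend, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

new_cell_mesh <- function(coordinates, laplacian, geometry,
                          axis = NULL, extra = list()) {
  structure(c(list(coordinates = coordinates, laplacian = laplacian,
                   geometry = geometry, axis = axis,
                   n = nrow(coordinates)), extra),
            class = "cell_mesh")
}

#' @export
print.cell_mesh <- function(x, ...) {
  cat(sprintf("<cell_mesh: %s, %d cells%s>\n", x$geometry, x$n,
              if (!is.null(x$axis)) ", with blend axis" else ""))
  invisible(x)
}

#' Rectangular grid mesh
#'
#' Builds a 2D grid of cells with unit spacing and the standard 5-point
#' Laplacian stencil; with `periodic = TRUE` both directions wrap.
#' Row sums of the Laplacian are zero, so constant fields diffuse to zero
#' flux exactly.
#'
#' @param width,height Grid dimensions in cells (each at least 8).
#' @param periodic Wrap both directions into a torus?
#' @return A `cell_mesh` with `geometry = "grid"`. Cells are ordered
#'   column-major: cell `(i, j)` (row `i`, column `j`) has index
#'   `i + (j - 1) * height`.
#' @export
make_grid_mesh <- function(width, height, periodic = TRUE) {
  if (width < 8 || height < 8)
    stop("grid must be at least 8x8 cells")
  n <- width * height
  row <- rep(seq_len(height), times = width)
  col <- rep(seq_len(width), each = height)
  idx <- function(r, cc) (r - 1L) + (cc - 1L) * height + 1L
  shift <- function(x, d, m) {
    y <- x + d
    if (periodic) ((y - 1L) %% m) + 1L else y
  }
  ii <- integer(0); jj <- integer(0)
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    r2 <- shift(row, d[1L], height)
    c2 <- shift(col, d[2L], width)
    ok <- r2 >= 1L & r2 <= height & c2 >= 1L & c2 <= width
    ii <- c(ii, idx(row, col)[ok])
    jj <- c(jj, idx(r2, c2)[ok])
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  L <- W - Matrix::Diagonal(n, Matrix::rowSums(W))
  new_cell_mesh(cbind(x = col, y = row, z = 0), L, "grid",
                extra = list(nx = width, ny = height, periodic = periodic))
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  th <- golden * (seq_len(n) - 1)
  cbind(x = r * cos(th), y = r * sin(th), z = z)
}

# Symmetrized inverse-distance k-NN graph Laplacian (unscaled).
point_cloud_graph <- function(pts, k = 6) {
  nn <- .knn_brute(pts, as.integer(k))
  n <- nrow(pts)
  w <- 1 / nn$dist
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn$idx),
                            x = as.vector(w), dims = c(n, n))
  W <- (A + Matrix::t(A)) / 2
  L <- W - Matrix::Diagonal(n, Matrix::rowSums(W))
  list(L = L, h = mean(nn$dist[, 1]), nn = nn)
}

# Rayleigh-quotient estimate of the operator magnitude on a unit sphere:
# coordinate functions are Laplace-Beltrami eigenfunctions with eigenvalue
# -2/R^2, so q = mean_x -(x' L x)/(x' x) estimates 2 * alpha_raw (R = 1).
sphere_rayleigh <- function(L, pts) {
  ctr <- sweep(pts, 2, colMeans(pts))
  mean(vapply(1:3, function(d) {
    x <- ctr[, d]
    -sum(x * as.numeric(L %*% x)) / sum(x^2)
  }, numeric(1)))
}

# Geometric calibration constant gamma(k) such that the raw inverse-distance
# k-NN Laplacian approximates (gamma / h^2) * LaplaceBeltrami for
# quasi-uniform samplings with mean nearest-neighbour spacing h.
# Computed once on a reference Fibonacci sphere and cached.
.pb_cache <- new.env(parent = emptyenv())
laplacian_gamma <- function(k = 6, n_ref = 2000) {
  key <- sprintf("gamma_%d_%d", k, n_ref)
  if (!is.null(.pb_cache[[key]])) return(.pb_cache[[key]])
  pts <- fibonacci_sphere(n_ref)
  g <- point_cloud_graph(pts, k)
  gam <- sphere_rayleigh(g$L, pts) / 2 * g$h^2
  .pb_cache[[key]] <- gam
  gam
}

#' Quasi-uniform sphere mesh
#'
#' Places `n_cells` points on the unit sphere with a Fibonacci lattice and
#' builds a symmetrized inverse-distance k-nearest-neighbour graph
#' Laplacian. The operator is scaled so that it matches the grid Laplacian's
#' convention of unit cell spacing: applied to the coordinate functions
#' (the first spherical harmonics) it reproduces the analytic eigenvalue
#' `2 / R^2` of a sphere whose radius is measured in mean cell spacings.
#'
#' @param n_cells Number of cells (at least 100).
#' @param k Neighbours per cell for the graph Laplacian.
#' @return A `cell_mesh` with `geometry = "sphere"`.
#' @export
make_sphere_mesh <- function(n_cells, k = 6) {
  if (n_cells < 100) stop("n_cells must be at least 100")
  pts <- fibonacci_sphere(n_cells)
  g <- point_cloud_graph(pts, k)
  q <- sphere_rayleigh(g$L, pts)        # approx 2 * alpha_raw (R = 1)
  R_h <- 1 / g$h                        # sphere radius in cell spacings
  scale <- (2 / R_h^2) / q
  new_cell_mesh(pts, g$L * scale, "sphere",
                extra = list(k = k, h = g$h, nn_dist = g$nn$dist))
}

metaball_field <- function(pts, centers) {
  d2a <- rowSums(sweep(pts, 2, centers[1, ])^2)
  d2b <- rowSums(sweep(pts, 2, centers[2, ])^2)
  1 / d2a + 1 / d2b
}

metaball_grad <- function(pts, centers) {
  g <- matrix(0, nrow(pts), 3)
  for (m in 1:2) {
    dd <- sweep(pts, 2, centers[m, ])
    d2 <- rowSums(dd^2)
    g <- g - 2 * dd / d2^2
  }
  g
}

#' Fused-blob ("metaball") mesh for in silico hybridization
#'
#' Two overlapping balls of radius `radius` whose centres are `separation`
#' apart define an implicit metaball surface (`sum 1/d_i^2 = 1/radius^2`).
#' Cells are seeded on the two spheres (each side of the symmetry plane),
#' Newton-projected onto the isosurface, and connected by the same
#' calibrated k-NN graph Laplacian as [make_sphere_mesh()]. Each cell gets
#' an `axis` coordinate in `[0, 1]` by projection onto the line joining the
#' two centres; the blend gradient of [assign_hybrid_gradient()] runs along
#' it.
#'
#' @param n_cells Approximate total number of cells (at least 200).
#' @param separation Distance between ball centres; must be below
#'   `2 * sqrt(2) * radius` so the surface stays connected.
#' @param radius Ball radius.
#' @param k Neighbours per cell.
#' @return A `cell_mesh` with `geometry = "metaball"` and an `axis` field.
#' @export
make_metaball_mesh <- function(n_cells = 2000, separation = 2.2,
                               radius = 1, k = 6) {
  if (n_cells < 200) stop("n_cells must be at least 200")
  if (separation >= 2 * sqrt(2) * radius)
    stop("balls too far apart: metaball surface is disconnected")
  centers <- rbind(c(-separation / 2, 0, 0), c(separation / 2, 0, 0))
  iso <- 1 / radius^2
  half <- ceiling(n_cells / 2)
  seed_a <- sweep(fibonacci_sphere(half) * radius, 2, centers[1, ], `+`)
  seed_b <- sweep(fibonacci_sphere(half) * radius, 2, centers[2, ], `+`)
  pts <- rbind(seed_a[seed_a[, 1] <= 0, , drop = FALSE],
               seed_b[seed_b[, 1] > 0, , drop = FALSE])
  for (it in 1:30) {
    fv <- metaball_field(pts, centers) - iso
    gr <- metaball_grad(pts, centers)
    g2 <- rowSums(gr^2)
    pts <- pts - gr * (fv / g2)
    if (max(abs(fv)) < 1e-12) break
  }
  g <- point_cloud_graph(pts, k)
  gam <- laplacian_gamma(k)
  scale <- g$h^4 / gam        # unit-mean-spacing convention, see vignette
  ax <- (pts[, 1] - min(pts[, 1])) / diff(range(pts[, 1]))
  mesh <- new_cell_mesh(pts, g$L * scale, "metaball", axis = ax,
                        extra = list(k = k, h = g$h))
  if (mesh_components(mesh) != 1L)
    stop("metaball neighbour graph is disconnected; increase n_cells")
  mesh
}

# number of connected components of the neighbour graph
mesh_components <- function(mesh) {
  n <- mesh$n
  adj <- mesh$laplacian
  Matrix::diag(adj) <- 0
  adjT <- methods::as(abs(adj) > 0, "TsparseMatrix")
  nb <- split(adjT@j + 1L, adjT@i + 1L)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cid
      nbv <- nb[[as.character(v)]]
      if (!is.null(nbv)) stack <- c(stack, nbv[comp[nbv] == 0L])
    }
  }
  cid
}
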