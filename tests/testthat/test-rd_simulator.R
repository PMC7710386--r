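test_that("grid mesh has the 5-point stencil and zero row sums", {
  m <- make_grid_mesh(64, 64, periodic = TRUE)
  expect_equal(m$n, 4096)
  deg <- -Matrix::diag(m$laplacian)
  expect_true(all(deg == 4))
  const <- rep(3.7, m$n)
  expect_equal(max(abs(m$laplacian %*% const)), 0, tolerance = 1e-12)

  m2 <- make_grid_mesh(8, 8, periodic = FALSE)
  deg2 <- -Matrix::diag(m2$laplacian)
  expect_equal(sum(deg2 == 2), 4)   # the four corners
  expect_error(make_grid_mesh(4, 64), "at least 8x8")
})

test_that("sphere mesh is quasi-uniform with a conservative Laplacian", {
  m <- make_sphere_mesh(25000)
  expect_equal(m$n, 25000)
  nn1 <- m$nn_dist[, 1]
  expect_lt(stats::sd(nn1) / mean(nn1), 0.2)
  const <- rep(-1.5, m$n)
  expect_lt(max(abs(m$laplacian %*% const)), 1e-10)
  # every cell is connected to at least k neighbours after symmetrization
  adj <- m$laplacian
  Matrix::diag(adj) <- 0
  deg <- Matrix::rowSums(adj != 0)
  expect_true(all(deg >= m$k))
  expect_error(make_sphere_mesh(50), "at least 100")
})

test_that("sphere Laplacian is calibrated to the coordinate eigenfunctions", {
  # x, y, z are Laplace-Beltrami eigenfunctions with eigenvalue -2/R^2;
  # after scaling to unit mean spacing the operator must reproduce it
  m <- make_sphere_mesh(4000)
  h <- m$h
  lam_target <- 2 * h^2              # 2 / (1/h)^2
  x <- m$coordinates[, 1]
  lam_est <- -sum(x * as.numeric(m$laplacian %*% x)) / sum(x^2)
  expect_equal(lam_est, lam_target, tolerance = 0.1)
})

test_that("metaball mesh is connected with a normalized blend axis", {
  m <- make_metaball_mesh(1200, separation = 2.2, radius = 1)
  expect_identical(m$geometry, "metaball")
  expect_equal(range(m$axis), c(0, 1))
  const <- rep(2, m$n)
  expect_lt(max(abs(m$laplacian %*% const)), 1e-10)
  expect_error(make_metaball_mesh(1200, separation = 3.5, radius = 1),
               "disconnected")
})

test_that("reaction kinetics clip synthesis before decay", {
  # at the origin only the constant production term survives
  k <- reaction(0, 0, kinetic_params(C = 0.02))
  expect_equal(k$du, 0.02)
  expect_equal(k$dv, 0)
  # saturated synthesis: clip at synUmax, then subtract decay D*u
  k2 <- reaction(10, 10, kinetic_params(B = 0.08, C = 0))
  expect_equal(k2$du, 0.23 - 0.03 * 10)
  # at the interior fixed point both kinetics vanish
  kp <- kinetic_params(C = 0.02)
  fp <- fixed_point(kp)
  k3 <- reaction(fp[["u"]], fp[["v"]], kp)
  expect_equal(k3$du, 0, tolerance = 1e-12)
  expect_equal(k3$dv, 0, tolerance = 1e-12)
})

test_that("fixed point solver handles clipped branches", {
  # all-saturated regime: with B > 0 there is no negative feedback and
  # both synthesis terms pin at their upper clips
  kp <- kinetic_params(B = 0.08, C = 0.02)
  fp <- fixed_point(kp)
  expect_equal(fp[["u"]], kp$synUmax / kp$D)
  expect_equal(fp[["v"]], kp$synVmax / kp$G)
  k <- reaction(fp[["u"]], fp[["v"]], kp)
  expect_equal(abs(k$du) + abs(k$dv), 0, tolerance = 1e-12)
})

test_that("diffusion-off integration converges to the analytic rest state", {
  mesh <- make_grid_mesh(8, 8, periodic = TRUE)
  kp <- kinetic_params(C = 0.02)
  st <- simulate(mesh, kp, diff = diffusion_params(0, 0),
                 n_steps = 6000, dt = 0.01, seed = 7)
  fp <- fixed_point(kp)
  expect_lt(max(abs(st$u - fp[["u"]])), 1e-6)
  expect_lt(max(abs(st$v - fp[["v"]])), 1e-6)
})

test_that("simulation is deterministic given a seed and reports blow-up", {
  mesh <- make_grid_mesh(16, 16, periodic = TRUE)
  a <- simulate(mesh, kinetic_params(), n_steps = 200, seed = 42)
  b <- simulate(mesh, kinetic_params(), n_steps = 200, seed = 42)
  expect_identical(a$u, b$u)
  expect_identical(a$v, b$v)
  c <- simulate(mesh, kinetic_params(), n_steps = 200, seed = 43)
  expect_false(identical(a$u, c$u))
  expect_error(
    simulate(mesh, kinetic_params(), n_steps = 500, dt = 10, seed = 1),
    "blow-up at step")
})

test_that("uniform state is Turing-unstable only with fast inhibitor", {
  mesh <- make_grid_mesh(64, 64, periodic = TRUE)
  st <- simulate(mesh, kinetic_params(), n_steps = 2000, seed = 1)
  expect_gt(stats::sd(st$u), 10 * 0.1)     # pattern formed
  st_eq <- simulate(mesh, kinetic_params(),
                    diff = diffusion_params(Du = 0.5, Dv = 0.5),
                    n_steps = 2000, seed = 1)
  expect_lt(stats::sd(st_eq$u), 0.1)       # noise decayed, no pattern
})

test_that("hybrid gradient interpolates exactly between endpoints", {
  mesh <- make_metaball_mesh(600)
  end_a <- kinetic_params(C = -0.05)
  end_b <- kinetic_params(C = 0.05)
  pf <- assign_hybrid_gradient(mesh, end_a, end_b, profile = "linear")
  i0 <- which(mesh$axis == 0); i1 <- which(mesh$axis == 1)
  expect_equal(pf$C[i0], end_a$C)
  expect_equal(pf$C[i1], end_b$C)
  imid <- which.min(abs(mesh$axis - 0.5))
  expect_equal(pf$C[imid], 0, tolerance = 0.01)
  # monotone along the axis, for both profiles
  for (prof in c("linear", "sigmoid")) {
    pf2 <- assign_hybrid_gradient(mesh, end_a, end_b, profile = prof)
    ord <- order(mesh$axis)
    expect_true(all(diff(pf2$C[ord]) >= -1e-12))
  }
  expect_error(
    assign_hybrid_gradient(make_grid_mesh(8, 8), end_a, end_b),
    "axis")
})

test_that("field binarization thresholds pigment sensibly", {
  mesh <- make_grid_mesh(8, 8)
  st <- structure(list(u = seq(0, 1, length.out = 64), v = rep(0, 64),
                       t = 0, step_count = 0, mesh = mesh),
                  class = "field_state")
  expect_true(all(binarize_field(st, threshold = -1)))
  pig <- binarize_field(st, threshold = stats::median(st$u))
  expect_equal(mean(pig), 0.5, tolerance = 1 / 64)
  flat <- structure(list(u = rep(1, 64)), class = "field_state")
  expect_error(binarize_field(flat), "flat")
})
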