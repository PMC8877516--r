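test_that("grids are cubic, odd, and hold the solute with margin", {
  p <- pb_parameters()
  s <- make_charged_sphere(1, 1)
  g <- build_grid(s, p, fill_fraction = 0.5)
  expect_true(g$dims[1] %% 2 == 1)
  expect_gte(g$dims[1], 9)
  box <- (g$dims[1] - 1) * g$spacing
  expect_lte(2 / box, 0.5)                      # solute extent / box extent
  s2 <- random_structure(15, seed = 2)
  g1 <- build_grid(s2, pb_parameters(grid_spacing = 1.0))
  g05 <- build_grid(s2, pb_parameters(grid_spacing = 0.5))
  expect_equal(g05$dims[1] / g1$dims[1], 2, tolerance = 0.1)
  # every atom at least 2 nodes inside
  lo <- g1$origin + 2 * g1$spacing
  hi <- g1$origin + (g1$dims - 3) * g1$spacing
  expect_true(all(sweep(coords(s2), 2, lo) > 0))
  expect_true(all(sweep(coords(s2), 2, hi) < 0))
  expect_error(build_grid(s2, pb_parameters(grid_spacing = 0.02)),
               "memory ceiling")
})

test_that("charge spreading conserves total charge exactly", {
  p <- pb_parameters()
  for (seed in 1:4) {
    s <- random_structure(25, seed = seed)
    maps <- map_dielectric(s, build_grid(s, p), p)
    expect_equal(sum(maps$charge_grid), total_charge(s), tolerance = 1e-9)
  }
  s0 <- random_structure(10, seed = 5)
  s0$atoms$charge <- 0
  maps0 <- map_dielectric(s0, build_grid(s0, p), p)
  expect_true(all(maps0$charge_grid == 0))
})

test_that("ion exclusion and salt-free limits shape the kappa map", {
  s <- make_charged_sphere(2, 1)
  p0 <- pb_parameters(ionic_strength = 0)
  maps0 <- map_dielectric(s, build_grid(s, p0), p0)
  expect_true(all(maps0$kappa_sq == 0))
  ps <- pb_parameters(ionic_strength = 0.15)
  g <- build_grid(s, ps)
  maps <- map_dielectric(s, g, ps)
  # node at the center (inside radius + probe) excluded; far corner not
  ctr <- (g$dims + 1) %/% 2
  expect_equal(maps$kappa_sq[ctr[1], ctr[2], ctr[3]], 0)
  expect_equal(maps$kappa_sq[2, 2, 2], 1 / debye_length(0.15)^2,
               tolerance = 1e-12)
  far <- translate_structure(s, rep(1e3, 3))
  expect_error(map_dielectric(far, g, ps), "outside the grid")
})

test_that("boundary values follow the screened monopole + dipole expansion", {
  p <- uniform_pb()
  # neutral, zero-dipole solute -> all zeros
  s0 <- make_two_charge_system(0, 0, 10)
  m0 <- merge_structures(s0$a, s0$b)
  g0 <- build_grid(m0, p)
  expect_true(all(boundary_potential(m0, g0, p) == 0))
  # single +1 charge, no salt: C/(eps r) on the faces
  s1 <- make_charged_sphere(1, 1)
  g1 <- build_grid(s1, p, fill_fraction = 0.3)
  b1 <- boundary_potential(s1, g1, p)
  C <- coulomb_const(p$temperature)
  ax <- g1$origin[1] + (seq_len(g1$dims[1]) - 1) * g1$spacing
  mid <- (g1$dims[1] + 1) %/% 2
  r_face <- abs(ax[1])
  expect_equal(b1[1, mid, mid], C / (80 * r_face), tolerance = 1e-9)
  # point dipole: +/-1 at 2 A vs the ideal-dipole formula at >= 20 A
  md <- structure3d(data.frame(
    elety = "Q", resid = "ION", chain = "A", resno = 1:2,
    x = c(0, 2), y = 0, z = 0, charge = c(1, -1), radius = 0.9, mass = 1))
  gd <- build_grid(md, p, dims = 101)
  bd <- boundary_potential(md, gd, p)
  mc <- mass_center(md)
  axd <- lapply(1:3, function(d) gd$origin[d] +
                  (seq_len(gd$dims[d]) - 1) * gd$spacing)
  i_mid <- (gd$dims[1] + 1) %/% 2
  pt <- c(axd[[1]][1], axd[[2]][i_mid], axd[[3]][i_mid])
  rvec <- pt - mc
  r <- sqrt(sum(rvec^2))
  expect_gte(r, 20)
  dip <- c(-2, 0, 0)  # q * d pointing from - to + charge
  exact <- C * sum(dip * rvec) / (80 * r^3)
  expect_equal(bd[1, i_mid, i_mid], exact, tolerance = abs(exact) * 0.05)
})

test_that("zero sources and zero boundary give the zero potential", {
  s <- make_charged_sphere(1, 0)
  p <- pb_parameters(boundary = "zero", ionic_strength = 0)
  pg <- solve_structure(s, p, dims = 17)
  expect_true(all(pg$phi == 0))
  expect_true(pg$converged)
})

test_that("the solver reproduces the Coulomb field of a point charge", {
  p <- uniform_pb(boundary = "debye-monopole")
  pg <- solve_structure(make_charged_sphere(1, 1), p, dims = 49)
  C <- coulomb_const(p$temperature)
  r <- seq(5, 23, 2)
  rel <- potential_at(pg, cbind(r, 0, 0)) / (C / (80 * r)) - 1
  expect_lt(max(abs(rel)), 0.05)
})

test_that("salt screens the potential at the Debye-Hueckel rate", {
  ps <- uniform_pb(ionic_strength = 0.15, boundary = "debye-monopole")
  pg <- solve_structure(make_charged_sphere(1, 1), ps, dims = 49)
  lam <- debye_length(0.15)
  r1 <- 6; r2 <- 14
  ratio <- potential_at(pg, c(r2, 0, 0)) / potential_at(pg, c(r1, 0, 0))
  expect_equal(ratio, exp(-(r2 - r1) / lam) * r1 / r2, tolerance = 0.10)
  # pointwise |phi| decreases when salt is added
  p0 <- uniform_pb(ionic_strength = 0, boundary = "debye-monopole")
  pg0 <- solve_structure(make_charged_sphere(1, 1), p0, dims = 49)
  pts <- cbind(seq(4, 20, 2), 0, 0)
  expect_true(all(potential_at(pg, pts) < potential_at(pg0, pts)))
})

test_that("the Born-sphere exterior matches the analytic solution", {
  p <- pb_parameters(eps_in = 2, eps_out = 80, ionic_strength = 0,
                     boundary = "debye-monopole")
  pg <- solve_structure(make_charged_sphere(2, 1), p, dims = 49)
  C <- coulomb_const(p$temperature)
  r <- seq(4, 20, 2)
  rel <- potential_at(pg, cbind(r, 0, 0)) / (C / (80 * r)) - 1
  expect_lt(max(abs(rel)), 0.10)
})

test_that("linear-mode solutions superpose and antisymmetrize", {
  p <- uniform_pb(ionic_strength = 0.15, tolerance = 1e-9)
  sys <- make_two_charge_system(0.7, -0.4, 8)
  both <- merge_structures(sys$a, sys$b)
  g <- build_grid(both, p, dims = 33)
  with_charges <- function(q) {
    s <- both
    s$atoms$charge <- q
    solve_pbe(map_dielectric(s, g, p), boundary_potential(s, g, p), p)
  }
  pg12 <- with_charges(c(0.7, -0.4))
  pg1 <- with_charges(c(0.7, 0))
  pg2 <- with_charges(c(0, -0.4))
  expect_lt(max(abs(pg1$phi + pg2$phi - pg12$phi)), 1e-6)
  pgneg <- with_charges(c(-0.7, 0.4))
  expect_lt(max(abs(pgneg$phi + pg12$phi)), 1e-10)
})

test_that("halving the spacing reduces the Coulomb benchmark error", {
  C <- coulomb_const()
  err_at <- function(h) {
    p <- uniform_pb(boundary = "debye-monopole")
    p$grid_spacing <- h
    pg <- solve_structure(make_charged_sphere(1, 1), p,
                          dims = round(24 / h) + 1)
    r <- c(3, 4, 5)
    max(abs(potential_at(pg, cbind(r, 0, 0)) / (C / (80 * r)) - 1))
  }
  expect_lt(err_at(0.5), err_at(1.0))
})

test_that("the nonlinear mode agrees with the linear one at weak potentials", {
  p_lin <- uniform_pb(ionic_strength = 0.15, boundary = "debye-monopole")
  p_nl <- p_lin
  p_nl$linearized <- FALSE
  s <- make_charged_sphere(1, 0.02)
  pg_lin <- solve_structure(s, p_lin, dims = 33)
  pg_nl <- solve_structure(s, p_nl, dims = 33)
  # outer fixed-point loop converges to 10x the inner tolerance
  expect_lt(max(abs(pg_lin$phi - pg_nl$phi)), 1e-3)
})

test_that("non-convergence is reported, not hidden", {
  p <- uniform_pb()
  p$max_iterations <- 2L
  expect_warning(pg <- solve_structure(make_charged_sphere(1, 1), p,
                                       dims = 33),
                 "stopped")
  expect_false(pg$converged)
})

test_that("trilinear interpolation is exact on nodes and linear fields", {
  spec <- structure(list(origin = c(-5, -5, -5), spacing = 1,
                         dims = c(11L, 11L, 11L)), class = "grid_spec")
  ax <- lapply(1:3, function(d) spec$origin[d] + 0:10)
  lin <- outer(outer(2 * ax[[1]], 3 * ax[[2]], `+`), 5 * ax[[3]], `+`) + 1
  pg <- structure(list(spec = spec, phi = lin, converged = TRUE,
                       iterations = 0L, max_update = 0),
                  class = "potential_grid")
  expect_equal(potential_at(pg, c(-2, 0, 3)), lin[4, 6, 9])
  set.seed(3)
  pts <- matrix(runif(30, -4.5, 4.5), 10, 3)
  exact <- 2 * pts[, 1] + 3 * pts[, 2] + 5 * pts[, 3] + 1
  expect_equal(potential_at(pg, pts), exact, tolerance = 1e-12)
  expect_error(potential_at(pg, c(50, 0, 0)), "outside")
  # interpolated values stay within the cell's min/max
  set.seed(4)
  rnd <- structure(list(spec = spec, phi = array(rnorm(11^3), c(11, 11, 11)),
                        converged = TRUE, iterations = 0L, max_update = 0),
                   class = "potential_grid")
  for (k in 1:20) {
    pt <- runif(3, -4.5, 4.5)
    i0 <- floor(pt - spec$origin) + 1
    cell <- rnd$phi[i0[1]:(i0[1] + 1), i0[2]:(i0[2] + 1), i0[3]:(i0[3] + 1)]
    v <- potential_at(rnd, pt)
    expect_gte(v, min(cell) - 1e-12)
    expect_lte(v, max(cell) + 1e-12)
  }
})

test_that("OpenDX grids round-trip and reject malformed input", {
  p <- uniform_pb()
  pg <- solve_structure(make_charged_sphere(1, 1), p, dims = 17)
  f <- withr::local_tempfile(fileext = ".dx")
  export_grid(pg, f)
  pg2 <- import_grid(f)
  expect_equal(pg2$spec$dims, pg$spec$dims)
  expect_equal(pg2$spec$origin, pg$spec$origin, tolerance = 1e-6)
  expect_equal(pg2$spec$spacing, pg$spec$spacing, tolerance = 1e-9)
  expect_lt(max(abs(pg2$phi - pg$phi)), 1e-6)
  # hand-written 3x3x3 zero grid
  f3 <- withr::local_tempfile(fileext = ".dx")
  writeLines(c(
    "object 1 class gridpositions counts 3 3 3",
    "origin 0 0 0", "delta 1 0 0", "delta 0 1 0", "delta 0 0 1",
    "object 2 class gridconnections counts 3 3 3",
    "object 3 class array type double rank 0 items 27 data follows",
    rep("0 0 0", 9)), f3)
  z <- import_grid(f3)
  expect_true(all(z$phi == 0))
  expect_equal(z$spec$dims, c(3L, 3L, 3L))
  # item count inconsistent with dims
  bad <- readLines(f3)
  bad[7] <- sub("items 27", "items 26", bad[7])
  fb <- withr::local_tempfile(fileext = ".dx")
  writeLines(bad, fb)
  expect_error(import_grid(fb), "item count")
  expect_error(import_grid(withr::local_tempfile(fileext = ".dx",
                                                 lines = "not a dx")),
               "malformed DX")
})
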