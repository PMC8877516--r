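test_that("surface samples lie on the union-of-spheres boundary", {
  one <- make_charged_sphere(2.5, 1)
  pts <- sample_surface(one, 200, seed = 3)
  d <- sqrt(rowSums(pts^2))
  expect_lt(max(abs(d - 2.5)), 1e-6)
  expect_gt(nrow(pts), 180)
  expect_lt(nrow(pts), 221)
  # two overlapping atoms: no sample strictly inside either sphere
  two <- structure3d(data.frame(
    elety = "Q", resid = "ION", chain = "A", resno = 1:2,
    x = c(0, 2), y = 0, z = 0, charge = 0, radius = 1.5, mass = 1))
  pts2 <- sample_surface(two, 300, seed = 4)
  d1 <- sqrt(rowSums(pts2^2))
  d2 <- sqrt((pts2[, 1] - 2)^2 + pts2[, 2]^2 + pts2[, 3]^2)
  expect_true(all(d1 >= 1.5 - 1e-6))
  expect_true(all(d2 >= 1.5 - 1e-6))
  expect_identical(pts2, sample_surface(two, 300, seed = 4))  # seeded
})

test_that("surface-potential summaries reflect the solute charge sign", {
  spec <- structure(list(origin = c(-8, -8, -8), spacing = 1,
                         dims = c(17L, 17L, 17L)), class = "grid_spec")
  zero <- structure(list(spec = spec, phi = array(0, c(17, 17, 17)),
                         converged = TRUE, iterations = 0L, max_update = 0),
                    class = "potential_grid")
  s <- make_charged_sphere(2, -1)
  sp0 <- map_surface_potential(sample_surface(s, 100, seed = 1), zero)
  expect_equal(sp0$mean, 0)
  expect_equal(sp0$fraction_positive, 0)
  pneg <- pb_parameters(ionic_strength = 0)
  pg <- solve_structure(s, pneg, dims = 33)
  spn <- map_surface_potential(sample_surface(s, 100, seed = 1), pg)
  expect_lt(spn$mean, 0)
  expect_equal(spn$fraction_positive, 0)
})

test_that("a negative tail makes the mean surface potential more negative", {
  tp <- tail_sim_params(n_residues = 10, per_residue_charge = -0.5, seed = 2)
  dimer <- make_toy_dimer_with_tail(8, tp)
  bare <- drop_tail(dimer)
  p <- pb_parameters()
  pg_w <- solve_structure(dimer, p)
  pg_o <- solve_structure(bare, p)
  m_w <- map_surface_potential(sample_surface(dimer, 200, seed = 3), pg_w)$mean
  m_o <- map_surface_potential(sample_surface(bare, 200, seed = 3), pg_o)$mean
  expect_lt(m_w, m_o)
})

test_that("field lines of a point charge run radially outward", {
  p <- uniform_pb(boundary = "debye-monopole")
  pg <- solve_structure(make_charged_sphere(1, 1), p, dims = 49)
  set.seed(6)
  seeds <- matrix(rnorm(24), 8, 3)
  seeds <- seeds / sqrt(rowSums(seeds^2)) * 10
  for (i in seq_len(nrow(seeds))) {
    ln <- trace_field_line(pg, seeds[i, ], "downhill", step = 0.5,
                           max_steps = 100)
    v <- ln$vertices
    dirs <- diff(v)
    radial <- v[-nrow(v), ] / sqrt(rowSums(v[-nrow(v), ]^2))
    cosang <- rowSums(dirs * radial) / sqrt(rowSums(dirs^2))
    expect_gt(min(cosang), cos(5 * pi / 180))
  }
})

test_that("uniform potential terminates tracing immediately", {
  spec <- structure(list(origin = c(-8, -8, -8), spacing = 1,
                         dims = c(17L, 17L, 17L)), class = "grid_spec")
  flat <- structure(list(spec = spec, phi = array(2, c(17, 17, 17)),
                         converged = TRUE, iterations = 0L, max_update = 0),
                    class = "potential_grid")
  ln <- trace_field_line(flat, c(0, 0, 0), "downhill")
  expect_equal(ln$termination, "low-field")
  expect_equal(nrow(ln$vertices), 1)
})

test_that("a dipole's axis line connects the two charges", {
  sys <- make_two_charge_system(+1, -1, 20)
  m <- merge_structures(sys$a, sys$b)
  p <- uniform_pb()
  pg <- solve_structure(m, p, fill_fraction = 0.5)
  ln <- trace_field_line(pg, c(10, 0.3, 0), "downhill", step = 0.5,
                         max_steps = 500, mask = solute_mask(m))
  expect_equal(ln$termination, "solute")
  # downhill from the midpoint runs into the negative charge
  endpt <- ln$vertices[nrow(ln$vertices), ]
  expect_true(solute_mask(sys$b, pad = 1.4)(endpt))
  ln_up <- trace_field_line(pg, c(10, 0.3, 0), "uphill", step = 0.5,
                            max_steps = 500, mask = solute_mask(m))
  expect_true(solute_mask(sys$a, pad = 1.4)(ln_up$vertices[
    nrow(ln_up$vertices), ]))
})

test_that("field lines ignore constant potential offsets", {
  p <- uniform_pb(boundary = "debye-monopole")
  pg <- solve_structure(make_charged_sphere(1, 1), p, dims = 33)
  pg_shift <- pg
  pg_shift$phi <- pg$phi + 5
  l1 <- trace_field_line(pg, c(8, 1, 0), "downhill", step = 0.5,
                         max_steps = 50)
  l2 <- trace_field_line(pg_shift, c(8, 1, 0), "downhill", step = 0.5,
                         max_steps = 50)
  expect_equal(l1$vertices, l2$vertices, tolerance = 1e-9)
})

test_that("line lengths of a point-charge field preserve seed ordering", {
  p <- uniform_pb(boundary = "debye-monopole")
  pg <- solve_structure(make_charged_sphere(1, 1), p, dims = 49)
  radii <- c(6, 10, 14)
  lens <- vapply(radii, function(r) {
    ln <- trace_field_line(pg, c(r / sqrt(2), r / sqrt(2), 0), "downhill",
                           step = 0.5, max_steps = 200)
    sum(sqrt(rowSums(diff(ln$vertices)^2)))
  }, numeric(1))
  # downhill lines run outward to the boundary: farther seeds have less
  # distance left to cover, so line lengths strictly mirror seed radius
  expect_true(all(diff(lens) < 0))
})

test_that("zone reports count through and connecting lines", {
  sys <- make_two_charge_system(+1, -1, 20)
  empty <- zone_line_density(list(), list(lo = c(0, -5, -5), hi = c(20, 5, 5)),
                             sys$a, sys$b)
  expect_equal(empty$n_lines_through, 0L)
  expect_equal(empty$n_connecting, 0L)
  fake <- structure(list(
    vertices = cbind(seq(1, 19, 0.5), 0, 0),
    seed = c(1, 0, 0), termination = "solute"), class = "field_line")
  rep1 <- zone_line_density(list(fake), list(lo = c(0, -5, -5),
                                             hi = c(20, 5, 5)),
                            sys$a, sys$b)
  expect_equal(rep1$n_lines_through, 1L)
  expect_equal(rep1$n_connecting, 1L)
  outside <- zone_line_density(list(fake), list(lo = c(50, 0, 0),
                                                hi = c(60, 5, 5)),
                               sys$a, sys$b)
  expect_equal(outside$n_lines_through, 0L)
})

test_that("a charged tail recruits more partner-connecting field lines", {
  tp <- tail_sim_params(n_residues = 10, per_residue_charge = -0.5, seed = 9)
  dimer <- make_toy_dimer_with_tail(8, tp)
  bare <- drop_tail(dimer)
  partner <- pbforce:::.toy_partner(dimer)
  p <- pb_parameters()
  comb_w <- merge_structures(dimer, partner)
  comb_o <- merge_structures(bare, partner)
  pg_w <- solve_structure(comb_w, p, fill_fraction = 0.5)
  pg_o <- solve_structure(comb_o, p, fill_fraction = 0.5)
  n_w <- count_connecting_lines(
    trace_field_lines(pg_w, partner, n_seeds = 40, seed = 5,
                      mask = solute_mask(comb_w)), partner, dimer)
  n_o <- count_connecting_lines(
    trace_field_lines(pg_o, partner, n_seeds = 40, seed = 5,
                      mask = solute_mask(comb_o)), partner, bare)
  expect_gte(n_w, n_o)
})

test_that("field lines are written as parseable polylines", {
  p <- uniform_pb(boundary = "debye-monopole")
  pg <- solve_structure(make_charged_sphere(1, 1), p, dims = 33)
  lines <- list(trace_field_line(pg, c(6, 0, 0), "downhill", step = 0.5,
                                 max_steps = 20))
  f <- withr::local_tempfile(fileext = ".txt")
  write_field_lines(lines, f)
  txt <- readLines(f)
  hdr <- strsplit(txt[1], " ")[[1]]
  expect_equal(hdr[1], "LINE")
  expect_equal(as.integer(hdr[3]), nrow(lines[[1]]$vertices))
  expect_equal(length(txt), 1 + nrow(lines[[1]]$vertices))
})
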