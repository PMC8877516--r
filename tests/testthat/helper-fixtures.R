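# Shared fixture builders; everything is generated in code so the suite
# has no binary dependencies.

# uniform-dielectric parameters: turn the solver into a pure Coulomb /
# Debye-Hueckel machine for analytic benchmarks
uniform_pb <- function(ionic_strength = 0, boundary = "dipolar", ...)
  pb_parameters(eps_in = 80, eps_out = 80, ionic_strength = ionic_strength,
                boundary = boundary, ...)

# small random structure with charges, radii and masses
random_structure <- function(n = 20, seed = 1, spread = 10) {
  set.seed(seed)
  structure3d(data.frame(
    elety = "CA", resid = "GLY", chain = "A", resno = seq_len(n),
    x = runif(n, -spread, spread), y = runif(n, -spread, spread),
    z = runif(n, -spread, spread),
    charge = round(runif(n, -1, 1), 2), radius = runif(n, 1, 2),
    mass = runif(n, 1, 20)))
}

# random rigid motion: rotation matrix (QR of a Gaussian) + translation
random_rigid <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, sd = 20))
}

apply_rigid <- function(pts, rt) sweep(pts %*% t(rt$R), 2, rt$t, `+`)

# a tiny PQR file written by hand (the fixture generator for parser tests)
write_tiny_pqr <- function(path, charges = c(-1, 0, 1)) {
  lines <- sprintf(
    "ATOM  %5d  CA  %s A%4d    %8.3f%8.3f%8.3f %7.4f %6.4f",
    seq_along(charges), c("GLU", "GLY", "LYS")[seq_along(charges)],
    seq_along(charges), 3.8 * (seq_along(charges) - 1), 0, 0,
    charges, 1.9)
  writeLines(c(lines, "END"), path)
  path
}
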