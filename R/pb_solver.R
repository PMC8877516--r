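#' Poisson-Boltzmann solver parameters
#'
#' Defaults follow the standard DelPhi-style parameterization for
#' protein electrostatics: protein dielectric 2, water 80, 1.4 A solvent
#' probe for the ion-exclusion layer, 1.0 A grid spacing, 0.15 M salt and
#' a dipolar (screened monopole + dipole) boundary condition. Potentials
#' are in kT/e at the configured temperature.
#'
#' @param eps_in solute relative dielectric.
#' @param eps_out solvent relative dielectric.
#' @param probe_radius A; inflates atom spheres for the ion-exclusion map.
#' @param grid_spacing A per grid interval.
#' @param ionic_strength mol/L of 1:1 salt.
#' @param temperature K.
#' @param boundary `"dipolar"` (screened monopole + dipole at the mass
#'   center), `"debye-monopole"` (monopole only) or `"zero"`.
#' @param linearized solve the linearized PBE (sinh x ~ x); the nonlinear
#'   form is available via `linearized = FALSE`.
#' @param tolerance convergence threshold on the max potential update,
#'   kT/e.
#' @param max_iterations SOR iteration cap.
#' @export
pb_parameters <- function(eps_in = 2.0, eps_out = 80.0, probe_radius = 1.4,
                          grid_spacing = 1.0, ionic_strength = 0.15,
                          temperature = 298.15,
                          boundary = c("dipolar", "zero", "debye-monopole"),
                          linearized = TRUE, tolerance = 1e-4,
                          max_iterations = 5000L) {
  boundary <- match.arg(boundary)
  stopifnot(eps_in > 0, eps_out > 0, grid_spacing > 0, probe_radius >= 0,
            ionic_strength >= 0, temperature > 0, tolerance > 0,
            max_iterations >= 1)
  structure(list(eps_in = eps_in, eps_out = eps_out,
                 probe_radius = probe_radius, grid_spacing = grid_spacing,
                 ionic_strength = ionic_strength, temperature = temperature,
                 boundary = boundary, linearized = isTRUE(linearized),
                 tolerance = tolerance,
                 max_iterations = as.integer(max_iterations)),
            class = "pb_parameters")
}

.max_grid_nodes <- 2.7e7

#' Build a cubic grid around a structure
#'
#' The box is cubic at the requested spacing, sized so the solute
#' (including atom radii) occupies at most `fill_fraction` of the edge;
#' dims are odd so a center node exists, at least 9, with a >= 2 node
#' margin around every atom.
#'
#' @param s a `structure3d`.
#' @param p a [pb_parameters()].
#' @param fill_fraction solute extent / box extent (default 0.6).
#' @param dims optional explicit per-axis node count (scalar, made odd);
#'   overrides `fill_fraction` when larger than the minimum box.
#' @return a `grid_spec`: list(origin, spacing, dims).
#' @export
build_grid <- function(s, p, fill_fraction = 0.6, dims = NULL) {
  if (n_atoms(s) == 0) stop("cannot grid an empty structure")
  stopifnot(fill_fraction > 0, fill_fraction < 1)
  h <- p$grid_spacing
  xyz <- coords(s)
  r <- s$atoms$radius
  lo <- apply(xyz - r, 2, min)
  hi <- apply(xyz + r, 2, max)
  extent <- max(hi - lo)
  ctr <- (lo + hi) / 2
  L_min <- max(extent / fill_fraction, extent + 4 * h)
  n <- if (is.null(dims)) 2L * ceiling(L_min / (2 * h)) + 1L
       else max(2L * ceiling(L_min / (2 * h)) + 1L,
                as.integer(dims) %/% 2L * 2L + 1L)
  n <- max(n, 9L)
  if (as.double(n)^3 > .max_grid_nodes)
    stop(sprintf(
      "grid of %d^3 nodes exceeds the memory ceiling; try spacing >= %.2f A",
      n, h * n / (.max_grid_nodes^(1 / 3))))
  origin <- ctr - (n - 1) * h / 2
  structure(list(origin = as.numeric(origin), spacing = h,
                 dims = rep(as.integer(n), 3)),
            class = "grid_spec")
}

grid_axes <- function(g)
  lapply(1:3, function(d) g$origin[d] + (seq_len(g$dims[d]) - 1) * g$spacing)

#' Map dielectric, ion-accessibility and charge onto a grid
#'
#' Union-of-spheres assignment: edge midpoints inside any atom sphere get
#' `eps_in`, else `eps_out`; nodes inside any probe-inflated sphere get
#' kappa^2 = 0 (ion exclusion), else 1/lambda_D^2; atom charges are
#' spread to the 8 surrounding nodes by trilinear weights (exactly
#' conserving total charge).
#'
#' @param s a `structure3d` (all radii > 0).
#' @param g a `grid_spec` from [build_grid()].
#' @param p a [pb_parameters()].
#' @return `dielectric_maps`: eps edge arrays, kappa_sq node array (1/A^2),
#'   charge_grid node array (e), plus the grid spec.
#' @export
map_dielectric <- function(s, g, p) {
  if (any(s$atoms$radius <= 0)) stop("all atoms need radius > 0")
  h <- g$spacing
  nd <- g$dims
  ax <- grid_axes(g)
  xyz <- coords(s)
  rad <- s$atoms$radius
  lam <- debye_length(p$ionic_strength, p$eps_out, p$temperature)
  kap0 <- if (is.finite(lam)) 1 / lam^2 else 0
  epsx <- array(p$eps_out, nd); epsy <- array(p$eps_out, nd)
  epsz <- array(p$eps_out, nd)
  kappa_sq <- array(kap0, nd)
  qgrid <- array(0, nd)

  mark_sphere <- function(arr, ctr, r, off, value) {
    # off: per-axis half-spacing shift of the probed points (edge midpoints)
    rng <- lapply(1:3, function(d) {
      i <- which(ax[[d]] + off[d] >= ctr[d] - r &
                 ax[[d]] + off[d] <= ctr[d] + r)
      i
    })
    if (any(lengths(rng) == 0)) return(arr)
    dx2 <- (ax[[1]][rng[[1]]] + off[1] - ctr[1])^2
    dy2 <- (ax[[2]][rng[[2]]] + off[2] - ctr[2])^2
    dz2 <- (ax[[3]][rng[[3]]] + off[3] - ctr[3])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    sub <- arr[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    sub[d2 <= r^2] <- value
    arr[rng[[1]], rng[[2]], rng[[3]]] <- sub
    arr
  }

  for (i in seq_len(nrow(xyz))) {
    ctr <- xyz[i, ]
    if (any(ctr < g$origin) || any(ctr > g$origin + (nd - 1) * h))
      stop("atom ", i, " lies outside the grid")
    epsx <- mark_sphere(epsx, ctr, rad[i], c(h / 2, 0, 0), p$eps_in)
    epsy <- mark_sphere(epsy, ctr, rad[i], c(0, h / 2, 0), p$eps_in)
    epsz <- mark_sphere(epsz, ctr, rad[i], c(0, 0, h / 2), p$eps_in)
    if (kap0 > 0)
      kappa_sq <- mark_sphere(kappa_sq, ctr, rad[i] + p$probe_radius,
                              c(0, 0, 0), 0)
    q <- s$atoms$charge[i]
    if (q != 0) {
      fi <- (ctr - g$origin) / h
      i0 <- pmin(pmax(floor(fi), 0), nd - 2)
      w <- fi - i0
      for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
        wt <- prod(ifelse(c(cx, cy, cz) == 1, w, 1 - w))
        ii <- i0 + c(cx, cy, cz) + 1
        qgrid[ii[1], ii[2], ii[3]] <- qgrid[ii[1], ii[2], ii[3]] + q * wt
      }
    }
  }
  structure(list(spec = g, eps_edges = list(x = epsx, y = epsy, z = epsz),
                 kappa_sq = kappa_sq, charge_grid = qgrid),
            class = "dielectric_maps")
}

#' Analytic boundary potential (Dirichlet values)
#'
#' Each boundary-face node receives the screened potential of the
#' solute's total monopole and (for `boundary = "dipolar"`) dipole, both
#' placed at the mass center, evaluated in the solvent dielectric with
#' Debye screening at the configured ionic strength.
#'
#' @param s a `structure3d`.
#' @param g a `grid_spec`.
#' @param p a [pb_parameters()].
#' @return 3-D array over the grid with the 6 faces filled (interior 0),
#'   ready to seed the solver.
#' @export
boundary_potential <- function(s, g, p) {
  nd <- g$dims
  phi <- array(0, nd)
  if (p$boundary == "zero") return(phi)
  C <- coulomb_const(p$temperature)
  lam <- debye_length(p$ionic_strength, p$eps_out, p$temperature)
  kappa <- if (is.finite(lam)) 1 / lam else 0
  mc <- mass_center(s)
  q_tot <- total_charge(s)
  dip <- as.numeric(crossprod(sweep(coords(s), 2, mc), s$atoms$charge))
  use_dip <- p$boundary == "dipolar"
  ax <- grid_axes(g)

  face_value <- function(pts) {
    dx <- sweep(pts, 2, mc)
    r <- sqrt(rowSums(dx^2))
    r <- pmax(r, g$spacing)
    scr <- exp(-kappa * r)
    v <- C * q_tot * scr / (p$eps_out * r)
    if (use_dip && any(dip != 0)) {
      pr <- dx %*% dip
      v <- v + C * as.numeric(pr) * (1 + kappa * r) * scr / (p$eps_out * r^3)
    }
    v
  }

  fill_face <- function(phi, d, side) {
    idx <- if (side == 1) 1L else nd[d]
    others <- setdiff(1:3, d)
    gg <- expand.grid(ax[[others[1]]], ax[[others[2]]])
    pts <- matrix(0, nrow(gg), 3)
    pts[, d] <- ax[[d]][idx]
    pts[, others[1]] <- gg[, 1]
    pts[, others[2]] <- gg[, 2]
    vals <- array(face_value(pts),
                  dim = c(nd[others[1]], nd[others[2]]))
    if (d == 1) phi[idx, , ] <- vals
    else if (d == 2) phi[, idx, ] <- vals
    else phi[, , idx] <- vals
    phi
  }
  for (d in 1:3) for (side in 1:2) phi <- fill_face(phi, d, side)
  phi
}

.sor_omega <- function(n) min(1.9, max(1.0, 2 / (1 + sin(pi / n))))

#' Solve the finite-difference Poisson-Boltzmann equation
#'
#' 7-point-stencil discretization of
#' div(eps grad phi) - eps_out kappa^2 phi = -4 pi C rho
#' (potential in kT/e, lengths in A, charges in e), solved by red-black
#' successive over-relaxation with an auto-tuned relaxation factor.
#' In linearized mode (default) the screening term is linear in phi; the
#' nonlinear sinh form is solved by damped fixed-point outer iterations
#' around the linear kernel.
#'
#' @param maps a `dielectric_maps` from [map_dielectric()].
#' @param boundary Dirichlet boundary array from [boundary_potential()]
#'   (or a compatible all-zero array).
#' @param p a [pb_parameters()].
#' @return a `potential_grid`: list(spec, phi (3-D array, kT/e),
#'   converged, iterations, max_update).
#' @export
solve_pbe <- function(maps, boundary, p) {
  stopifnot(inherits(maps, "dielectric_maps"))
  g <- maps$spec
  nd <- g$dims
  stopifnot(all(dim(boundary) == nd))
  h <- g$spacing
  C <- coulomb_const(p$temperature)
  src <- 4 * pi * C * maps$charge_grid / h
  kap_lin <- p$eps_out * maps$kappa_sq * h^2
  omega <- .sor_omega(max(nd))
  phi <- boundary

  run_linear <- function(phi_init, kap) {
    work <- phi_init + 0  # the kernel updates its argument in place
    res <- .sor_solve(work, maps$eps_edges$x, maps$eps_edges$y,
                      maps$eps_edges$z, kap, src,
                      as.integer(nd), omega, p$tolerance,
                      p$max_iterations)
    list(phi = work, res = res)
  }

  if (p$linearized || all(maps$kappa_sq == 0)) {
    out <- run_linear(phi, kap_lin)
    phi <- out$phi; res <- out$res
  } else {
    # nonlinear: kappa term uses sinh(phi)/phi of the previous iterate
    res <- NULL
    for (outer_it in seq_len(30)) {
      ratio <- ifelse(abs(phi) < 1e-8, 1,
                      pmin(sinh(pmin(abs(phi), 30)) / pmax(abs(phi), 1e-8),
                           1e4))
      out <- run_linear(phi, kap_lin * array(ratio, nd))
      delta <- max(abs(out$phi - phi))
      phi <- 0.5 * phi + 0.5 * out$phi
      res <- out$res
      if (delta < 10 * p$tolerance) break
    }
  }
  if (!res$converged)
    warning(sprintf(
      "PB solver stopped at %d iterations with max update %.3g kT/e",
      res$iterations, res$max_update))
  structure(list(spec = g, phi = phi, converged = res$converged,
                 iterations = res$iterations, max_update = res$max_update),
            class = "potential_grid")
}

#' @export
print.potential_grid <- function(x, ...) {
  cat(sprintf(
    "potential_grid: %dx%dx%d @ %.2f A, range [%.3g, %.3g] kT/e, %s in %d it\n",
    x$spec$dims[1], x$spec$dims[2], x$spec$dims[3], x$spec$spacing,
    min(x$phi), max(x$phi),
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' One-call PB solve for a structure
#'
#' Convenience wrapper: [build_grid()] + [map_dielectric()] +
#' [boundary_potential()] + [solve_pbe()].
#'
#' @inheritParams build_grid
#' @export
solve_structure <- function(s, p = pb_parameters(), fill_fraction = 0.6,
                            dims = NULL) {
  g <- build_grid(s, p, fill_fraction, dims)
  maps <- map_dielectric(s, g, p)
  bnd <- boundary_potential(s, g, p)
  solve_pbe(maps, bnd, p)
}

#' Trilinear interpolation of the potential
#'
#' @param pg a `potential_grid`.
#' @param points 3-vector or n x 3 matrix (A); every point must be at
#'   least one node inside the grid boundary.
#' @return numeric vector, kT/e.
#' @export
potential_at <- function(pg, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  g <- pg$spec
  h <- g$spacing
  nd <- g$dims
  fi <- sweep(points, 2, g$origin) / h
  if (any(fi < 0) || any(sweep(fi, 2, nd - 1) > 0))
    stop("query point outside the potential grid")
  i0 <- pmin(pmax(floor(fi), 0), matrix(nd - 2, nrow(fi), 3, byrow = TRUE))
  w <- fi - i0
  out <- numeric(nrow(points))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wt <- (if (cx) w[, 1] else 1 - w[, 1]) *
          (if (cy) w[, 2] else 1 - w[, 2]) *
          (if (cz) w[, 3] else 1 - w[, 3])
    lin <- (i0[, 1] + cx) + nd[1] * (i0[, 2] + cy) +
           nd[1] * nd[2] * (i0[, 3] + cz) + 1
    out <- out + wt * pg$phi[lin]
  }
  out
}

#' Electric field by central differences of the interpolated potential
#'
#' E = -grad phi, in kT/(e A). Points must sit at least two nodes inside
#' the grid so the difference stencil stays in bounds.
#'
#' @param pg a `potential_grid`.
#' @param points 3-vector or n x 3 matrix.
#' @param delta finite-difference step (A); defaults to the grid spacing.
#' @return n x 3 matrix.
#' @export
field_at <- function(pg, points, delta = NULL) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (is.null(delta)) delta <- pg$spec$spacing
  n <- nrow(points)
  stacked <- points[rep(seq_len(n), 6), , drop = FALSE]
  for (d in 1:3) {
    stacked[(2 * d - 2) * n + seq_len(n), d] <-
      stacked[(2 * d - 2) * n + seq_len(n), d] + delta
    stacked[(2 * d - 1) * n + seq_len(n), d] <-
      stacked[(2 * d - 1) * n + seq_len(n), d] - delta
  }
  v <- potential_at(pg, stacked)
  E <- matrix(0, n, 3)
  for (d in 1:3)
    E[, d] <- -(v[(2 * d - 2) * n + seq_len(n)] -
                v[(2 * d - 1) * n + seq_len(n)]) / (2 * delta)
  E
}
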