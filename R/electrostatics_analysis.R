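#' Surface-potential and field-line characterization of solved grids
#'
#' These tools quantify what surface-potential renderings and field-line
#' visualizations show qualitatively: how charged patches (for instance a
#' net-negative disordered tail) shape the potential on a molecular
#' surface and the topology of field lines between binding partners.
#'
#' @name electrostatics-analysis
NULL

#' Quasi-uniform samples on a union-of-spheres surface
#'
#' Random points are drawn on each atom sphere (count proportional to its
#' surface area) and rejected when strictly inside a neighbouring atom,
#' leaving samples on the union-of-spheres boundary. Deterministic given
#' the seed; the returned count lands within ~10% of `n_points` (top-up
#' rounds compensate rejection).
#'
#' @param s a `structure3d`.
#' @param n_points requested sample count.
#' @param seed integer.
#' @return m x 3 matrix of surface points (A).
#' @export
sample_surface <- function(s, n_points = 500L, seed = 1L) {
  if (n_atoms(s) == 0) stop("cannot sample an empty structure")
  xyz <- coords(s)
  rad <- s$atoms$radius
  area <- rad^2
  draw <- function(n_target) {
    n_at <- pmax(0L, as.integer(round(n_target * area / sum(area))))
    short <- n_target - sum(n_at)
    if (short > 0) {
      add <- sample.int(length(area), short, replace = TRUE,
                        prob = area / sum(area))
      for (a in add) n_at[a] <- n_at[a] + 1L
    }
    pts <- vector("list", length(n_at))
    for (i in seq_along(n_at)) {
      if (n_at[i] == 0) next
      u <- .random_unit_vectors(n_at[i])
      cand <- sweep(u * rad[i], 2, xyz[i, ], `+`)
      keep <- rep(TRUE, nrow(cand))
      for (j in seq_len(nrow(xyz))) {
        if (j == i) next
        d2 <- (cand[, 1] - xyz[j, 1])^2 + (cand[, 2] - xyz[j, 2])^2 +
              (cand[, 3] - xyz[j, 3])^2
        keep <- keep & d2 >= (rad[j] - 1e-9)^2
      }
      pts[[i]] <- cand[keep, , drop = FALSE]
    }
    do.call(rbind, pts)
  }
  local_seed(seed, {
    out <- draw(n_points)
    tries <- 0
    while (nrow(out) < 0.9 * n_points && tries < 10) {
      out <- rbind(out, draw(n_points - nrow(out)))
      tries <- tries + 1
    }
    out <- out[seq_len(min(nrow(out), ceiling(1.1 * n_points))), ,
               drop = FALSE]
  })
  colnames(out) <- c("x", "y", "z")
  out
}

#' Map potentials onto surface samples and summarize
#'
#' Interpolates the solved potential at each surface point and reports
#' the summary statistics used to compare binding faces: mean potential,
#' fraction of positive points, and the fraction beyond +/-3 kT/e (the
#' conventional saturation of surface-potential color scales).
#'
#' @param points m x 3 matrix from [sample_surface()].
#' @param pg a `potential_grid`.
#' @return list: `points`, `potentials` (kT/e), `mean`,
#'   `fraction_positive`, `fraction_saturated`.
#' @export
map_surface_potential <- function(points, pg) {
  phi <- potential_at(pg, points)
  list(points = points, potentials = phi,
       mean = mean(phi),
       fraction_positive = mean(phi > 0),
       fraction_saturated = mean(abs(phi) > 3.0))
}

#' Union-of-spheres membership test
#'
#' @param s a `structure3d`.
#' @param pad extra radius added to every atom (A).
#' @return function(points) -> logical vector (inside/outside).
#' @export
solute_mask <- function(s, pad = 0) {
  xyz <- coords(s)
  rad <- s$atoms$radius + pad
  function(points) {
    if (is.null(dim(points))) points <- matrix(points, ncol = 3)
    inside <- rep(FALSE, nrow(points))
    for (j in seq_len(nrow(xyz))) {
      d2 <- (points[, 1] - xyz[j, 1])^2 + (points[, 2] - xyz[j, 2])^2 +
            (points[, 3] - xyz[j, 3])^2
      inside <- inside | d2 <= rad[j]^2
    }
    inside
  }
}

#' Trace one electric field line
#'
#' 4th-order Runge-Kutta integration along the unit vector of
#' E = -grad(phi) (central differences on the interpolated grid).
#' `direction = "downhill"` follows +E (the path of a positive test
#' charge), `"uphill"` follows -E. Terminates on grid exit
#' (`"boundary"`), solute entry (`"solute"`), field collapse below
#' `min_field` (`"low-field"`), or `max_steps`.
#'
#' @param pg a `potential_grid`.
#' @param seed_point 3-vector, inside the grid and outside the solute.
#' @param direction `"downhill"` or `"uphill"`.
#' @param step integration step, A.
#' @param max_steps cap on vertices.
#' @param mask optional [solute_mask()] closure.
#' @param min_field termination threshold, kT/(e A).
#' @return a `field_line`: list(vertices, seed, termination).
#' @export
trace_field_line <- function(pg, seed_point,
                             direction = c("downhill", "uphill"),
                             step = 0.5, max_steps = 2000L, mask = NULL,
                             min_field = 1e-6) {
  direction <- match.arg(direction)
  sgn <- if (direction == "downhill") 1 else -1
  g <- pg$spec
  lo <- g$origin + 2 * g$spacing
  hi <- g$origin + (g$dims - 3) * g$spacing
  in_core <- function(x) all(x >= lo) && all(x <= hi)
  if (!in_core(seed_point)) stop("seed point outside the usable grid")
  if (!is.null(mask) && mask(seed_point)[1])
    stop("seed point lies inside the solute")
  unit_E <- function(x) {
    E <- sgn * as.numeric(field_at(pg, x))
    nE <- sqrt(sum(E^2))
    list(u = if (nE > 0) E / nE else c(0, 0, 0), mag = nE)
  }
  verts <- matrix(NA_real_, max_steps + 1, 3)
  verts[1, ] <- seed_point
  x <- seed_point
  termination <- "max-steps"
  nv <- 1L
  for (st in seq_len(max_steps)) {
    f1 <- unit_E(x)
    if (f1$mag < min_field) { termination <- "low-field"; break }
    k1 <- f1$u
    x2 <- x + step / 2 * k1; if (!in_core(x2)) { termination <- "boundary"; break }
    k2 <- unit_E(x2)$u
    x3 <- x + step / 2 * k2; if (!in_core(x3)) { termination <- "boundary"; break }
    k3 <- unit_E(x3)$u
    x4 <- x + step * k3;     if (!in_core(x4)) { termination <- "boundary"; break }
    k4 <- unit_E(x4)$u
    xn <- x + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!in_core(xn)) { termination <- "boundary"; break }
    nv <- nv + 1L
    verts[nv, ] <- xn
    x <- xn
    if (!is.null(mask) && mask(xn)[1]) { termination <- "solute"; break }
  }
  structure(list(vertices = verts[seq_len(nv), , drop = FALSE],
                 seed = seed_point, termination = termination),
            class = "field_line")
}

#' Trace field lines seeded on a structure's surface
#'
#' Seeds are surface samples of `seed_structure` pushed outward by one
#' grid spacing along the local sphere normal; both downhill and uphill
#' traces are launched from every seed so that lines can run from one
#' body to another across the seeding surface.
#'
#' @param pg a `potential_grid`.
#' @param seed_structure structure whose surface is seeded.
#' @param n_seeds number of seed points.
#' @param seed RNG seed for surface sampling.
#' @param mask combined solute mask used for termination (default: mask
#'   of `seed_structure`).
#' @inheritParams trace_field_line
#' @return list of `field_line` objects.
#' @export
trace_field_lines <- function(pg, seed_structure, n_seeds = 100L, seed = 1L,
                              step = 0.5, max_steps = 2000L, mask = NULL) {
  pts <- sample_surface(seed_structure, n_seeds, seed = seed)
  xyz <- coords(seed_structure)
  if (is.null(mask)) mask <- solute_mask(seed_structure)
  h <- pg$spec$spacing
  lo <- pg$spec$origin + 2 * h
  hi <- pg$spec$origin + (pg$spec$dims - 3) * h
  lines <- list()
  for (i in seq_len(nrow(pts))) {
    p0 <- pts[i, ]
    d2 <- (xyz[, 1] - p0[1])^2 + (xyz[, 2] - p0[2])^2 + (xyz[, 3] - p0[3])^2
    nearest <- which.min(d2)
    nrm <- p0 - xyz[nearest, ]
    nrm <- nrm / max(sqrt(sum(nrm^2)), 1e-12)
    sp <- p0 + h * nrm
    if (any(sp < lo) || any(sp > hi) || mask(sp)[1]) next
    for (dir in c("downhill", "uphill")) {
      ln <- trace_field_line(pg, sp, dir, step = step,
                             max_steps = max_steps, mask = mask)
      lines[[length(lines) + 1]] <- ln
    }
  }
  lines
}

#' Field-line density and connectivity inside a zone
#'
#' Counts the lines with at least one vertex inside an axis-aligned box
#' (an "interfacial zone"), and the subset whose two endpoints touch the
#' two named structures — the computable version of "the field lines in
#' this region connect body A to body B". An endpoint "touches" a
#' structure when it lies within `touch_pad` of its union-of-spheres.
#'
#' @param lines list of `field_line` objects.
#' @param zone list(lo = 3-vector, hi = 3-vector), A.
#' @param structure_a,structure_b `structure3d` objects.
#' @param touch_pad A (default 1.4, a solvent probe).
#' @return list: `n_lines_through`, `n_connecting`.
#' @export
zone_line_density <- function(lines, zone, structure_a, structure_b,
                              touch_pad = 1.4) {
  stopifnot(all(zone$hi > zone$lo))
  mask_a <- solute_mask(structure_a, pad = touch_pad)
  mask_b <- solute_mask(structure_b, pad = touch_pad)
  n_through <- 0L; n_connect <- 0L
  for (ln in lines) {
    v <- ln$vertices
    inz <- v[, 1] >= zone$lo[1] & v[, 1] <= zone$hi[1] &
           v[, 2] >= zone$lo[2] & v[, 2] <= zone$hi[2] &
           v[, 3] >= zone$lo[3] & v[, 3] <= zone$hi[3]
    if (!any(inz)) next
    n_through <- n_through + 1L
    ends <- v[c(1, nrow(v)), , drop = FALSE]
    ta <- mask_a(ends); tb <- mask_b(ends)
    if ((ta[1] && tb[2]) || (ta[2] && tb[1]))
      n_connect <- n_connect + 1L
  }
  list(n_lines_through = n_through, n_connecting = n_connect)
}

#' Count lines connecting two structures (whole-domain)
#' @inheritParams zone_line_density
#' @export
count_connecting_lines <- function(lines, structure_a, structure_b,
                                   touch_pad = 1.4) {
  mask_a <- solute_mask(structure_a, pad = touch_pad)
  mask_b <- solute_mask(structure_b, pad = touch_pad)
  n <- 0L
  for (ln in lines) {
    ends <- ln$vertices[c(1, nrow(ln$vertices)), , drop = FALSE]
    ta <- mask_a(ends); tb <- mask_b(ends)
    if ((ta[1] && tb[2]) || (ta[2] && tb[1])) n <- n + 1L
  }
  n
}

#' Write field lines as a plain multi-polyline text file
#'
#' One `LINE <id> <n_vertices> <termination>` header per line followed by
#' `x y z` rows.
#'
#' @param lines list of `field_line` objects.
#' @param path output path.
#' @export
write_field_lines <- function(lines, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(lines)) {
    v <- lines[[i]]$vertices
    writeLines(sprintf("LINE %d %d %s", i, nrow(v),
                       lines[[i]]$termination), con)
    writeLines(sprintf("%.4f %.4f %.4f", v[, 1], v[, 2], v[, 3]), con)
  }
  invisible(path)
}
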