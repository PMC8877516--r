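#' Parameters of the synthetic anchored-tail trajectory generator
#'
#' The generator emulates the ensemble behaviour of an anchored, highly
#' charged disordered tail: each tail bead fluctuates about its mean
#' position with isotropic Gaussian noise whose per-axis standard
#' deviation grows linearly from the anchor (g(i) = i / n_residues, so
#' the tip moves most). When `restraint_on` is TRUE — emulating a bound
#' binding partner that grips the tail — every tail bead's amplitude is
#' scaled by `restraint_factor` in (0, 1). Frames are i.i.d. by default,
#' which makes the stationary distribution exactly known; an optional
#' AR(1) mode (`ar1_phi` > 0) adds temporal correlation while keeping the
#' same stationary per-axis SD.
#'
#' @param n_residues number of tail beads (tubulin E-hooks have 15-16).
#' @param anchor_point 3-vector, A; where the tail attaches.
#' @param per_residue_charge e per bead (E-hook-like tails are ~-0.5 e
#'   per residue on average).
#' @param fluctuation_sigma stationary per-axis SD of the terminal bead, A.
#' @param restraint_on logical; emulates the bound state.
#' @param restraint_factor multiplier in (0,1) applied when restrained.
#' @param n_frames frames to generate (>= 2).
#' @param ar1_phi AR(1) coefficient in [0,1); 0 = i.i.d. frames.
#' @param seed integer seed; generation is bit-reproducible.
#' @export
tail_sim_params <- function(n_residues = 16L, anchor_point = c(0, 0, 0),
                            per_residue_charge = -0.5,
                            fluctuation_sigma = 2.0,
                            restraint_on = FALSE, restraint_factor = 0.5,
                            n_frames = 4000L, ar1_phi = 0, seed = 1L) {
  stopifnot(n_residues >= 0, length(anchor_point) == 3,
            fluctuation_sigma > 0, n_frames >= 2,
            restraint_factor > 0, restraint_factor < 1,
            ar1_phi >= 0, ar1_phi < 1)
  structure(list(n_residues = as.integer(n_residues),
                 anchor_point = as.numeric(anchor_point),
                 per_residue_charge = per_residue_charge,
                 fluctuation_sigma = fluctuation_sigma,
                 restraint_on = isTRUE(restraint_on),
                 restraint_factor = restraint_factor,
                 n_frames = as.integer(n_frames),
                 ar1_phi = ar1_phi, seed = as.integer(seed)),
            class = "tail_sim_params")
}

#' Two point charges on the x-axis
#'
#' The workhorse of the analytic benchmarks: two single-atom structures
#' (radius 1 A, unit mass) at the given center separation, for which the
#' (screened) Coulomb law gives closed-form potentials and forces.
#'
#' @param q1,q2 charges in e.
#' @param separation center-center distance, A; must exceed the sum of
#'   the two radii.
#' @return list of two `structure3d` objects (`$a` at the origin, `$b`
#'   at (separation, 0, 0)).
#' @export
make_two_charge_system <- function(q1, q2, separation) {
  radius <- 1.0
  if (separation <= 2 * radius)
    stop("separation ", separation, " A would overlap the two 1 A spheres")
  one <- function(q, x, ch) structure3d(data.frame(
    elety = "Q", resid = "ION", chain = ch, resno = 1,
    x = x, y = 0, z = 0, charge = q, radius = radius, mass = 1),
    title = sprintf("point charge %+g e", q))
  list(a = one(q1, 0, "A"), b = one(q2, separation, "B"))
}

#' A charged sphere (Born-ion style geometry)
#'
#' A central atom of the given radius carrying the whole charge, plus
#' optional zero-charge surface atoms that pad out the cavity. Serves as
#' geometry for Born/Debye-Hueckel analytic benchmarks.
#'
#' @param radius A.
#' @param total_charge e, on the central atom.
#' @param n_surface_atoms zero-charge decoration atoms on the sphere.
#' @param seed integer; deterministic placement.
#' @export
make_charged_sphere <- function(radius, total_charge, n_surface_atoms = 0L,
                                seed = 1L) {
  stopifnot(radius > 0, n_surface_atoms >= 0)
  atoms <- data.frame(elety = "Q", resid = "SPH", chain = "A", resno = 1,
                      x = 0, y = 0, z = 0, charge = total_charge,
                      radius = radius, mass = 1)
  if (n_surface_atoms > 0) {
    pts <- local_seed(seed, .random_unit_vectors(n_surface_atoms)) * radius
    atoms <- rbind(atoms, data.frame(
      elety = "S", resid = "SPH", chain = "A",
      resno = 1 + seq_len(n_surface_atoms),
      x = pts[, 1], y = pts[, 2], z = pts[, 3],
      charge = 0, radius = radius / 4, mass = 1))
  }
  structure3d(atoms, title = sprintf("charged sphere %+g e", total_charge))
}

.random_unit_vectors <- function(n) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

#' Toy rigid body with an anchored charged tail
#'
#' Emulates the topology of a tubulin-like body carrying a disordered,
#' net-negative C-terminal tail. The body is a compact cluster of beads
#' with alternating +/-0.25 e charges (chain "B", near net-neutral); the
#' tail (chain "T") grows from the +x face of the body as a seeded
#' self-avoiding random walk with a mild outward bias — the compact-coil
#' geometry of a disordered chain, not a rigid rod — one bead per
#' residue, each carrying `per_residue_charge`, so the tail net charge
#' is `n_residues * per_residue_charge`.
#'
#' @param body_atoms number of body beads (>= 1).
#' @param tail_params a [tail_sim_params()]; its `n_residues`,
#'   `per_residue_charge` and `seed` shape the geometry.
#' @param bead_radius A.
#' @param bond_length tail bead spacing, A.
#' @return a `structure3d`; tail beads have `resid == "GLU"`.
#' @export
make_toy_dimer_with_tail <- function(body_atoms, tail_params,
                                     bead_radius = 1.9, bond_length = 3.8) {
  stopifnot(body_atoms >= 1, inherits(tail_params, "tail_sim_params"))
  p <- tail_params
  # body: beads on a compact cubic lattice centred at the origin
  side <- ceiling(body_atoms^(1 / 3))
  g <- expand.grid(x = seq_len(side), y = seq_len(side), z = seq_len(side))
  g <- g[seq_len(body_atoms), , drop = FALSE] * 4.0
  g <- sweep(g, 2, colMeans(g))
  qb <- rep_len(c(0.25, -0.25), body_atoms)
  if (body_atoms %% 2 == 1) qb[body_atoms] <- 0  # keep the body neutral
  body <- data.frame(elety = "CB", resid = "BDY", chain = "B",
                     resno = seq_len(body_atoms),
                     x = g$x, y = g$y, z = g$z,
                     charge = qb, radius = bead_radius, mass = 1)
  atoms <- body
  if (p$n_residues > 0) {
    anchor <- c(max(body$x) + bond_length, 0, 0)
    pts <- matrix(NA_real_, p$n_residues, 3)
    pts[1, ] <- anchor
    existing <- as.matrix(body[, c("x", "y", "z")])
    local_seed(p$seed, {
      prev <- anchor
      for (i in seq_len(p$n_residues)[-1]) {
        for (try in 1:100) {
          dir <- stats::rnorm(3) + c(0.5, 0, 0)  # gentle outward bias
          dir <- dir / sqrt(sum(dir^2))
          cand <- prev + bond_length * dir
          obst <- rbind(existing, pts[seq_len(i - 1), , drop = FALSE])
          d2 <- (obst[, 1] - cand[1])^2 + (obst[, 2] - cand[2])^2 +
                (obst[, 3] - cand[3])^2
          if (min(d2) >= 3.0^2) { pts[i, ] <- cand; prev <- cand; break }
        }
        if (anyNA(pts[i, ]))
          stop("toy tail walk failed at bead ", i)
      }
    })
    tail <- data.frame(elety = "CA", resid = "GLU", chain = "T",
                       resno = seq_len(p$n_residues),
                       x = pts[, 1], y = pts[, 2], z = pts[, 3],
                       charge = p$per_residue_charge,
                       radius = bead_radius,
                       mass = unname(.residue_masses["GLU"]))
    atoms <- rbind(atoms, tail)
  }
  structure3d(atoms, title = "toy dimer with tail")
}

#' Remove the tail chain from a toy dimer
#' @param s a `structure3d` built by [make_toy_dimer_with_tail()].
#' @param tail_chain chain id of the tail.
#' @export
drop_tail <- function(s, tail_chain = "T") {
  s$atoms <- s$atoms[s$atoms$chain != tail_chain, , drop = FALSE]
  rownames(s$atoms) <- NULL
  s
}

#' Simulate a tail trajectory with known stationary statistics
#'
#' Body beads stay fixed at their structure positions. Tail bead i
#' (chain `tail_chain`, beads ordered by resno from anchor to tip) moves
#' per frame as mean position + isotropic Gaussian noise with per-axis SD
#' `fluctuation_sigma * (i / n) * (restraint_factor if restraint_on)`.
#' Because the stationary distribution is exact, flexibility estimators
#' can be checked against the closed form sqrt(3) * sd_axis.
#'
#' @param s a `structure3d` containing the tail chain.
#' @param p a [tail_sim_params()].
#' @param tail_chain chain id of the mobile tail.
#' @return a [trajectory_ensemble()].
#' @export
simulate_tail_trajectory <- function(s, p, tail_chain = "T") {
  stopifnot(inherits(p, "tail_sim_params"))
  idx_tail <- which(s$atoms$chain == tail_chain)
  if (!length(idx_tail)) stop("structure has no tail chain '", tail_chain, "'")
  idx_tail <- idx_tail[order(s$atoms$resno[idx_tail])]
  n_tail <- length(idx_tail)
  nf <- p$n_frames
  na <- n_atoms(s)
  x0 <- coords(s)
  coord <- array(rep(x0, each = nf), dim = c(nf, na, 3))
  sd_bead <- p$fluctuation_sigma * (seq_len(n_tail) / n_tail)
  if (p$restraint_on) sd_bead <- sd_bead * p$restraint_factor
  phi <- p$ar1_phi
  local_seed(p$seed, {
    for (b in seq_len(n_tail)) {
      ai <- idx_tail[b]
      if (phi == 0) {
        dev <- matrix(stats::rnorm(nf * 3, sd = sd_bead[b]), nf, 3)
      } else {
        # AR(1) with stationary per-axis SD sd_bead[b]
        innov <- matrix(stats::rnorm(nf * 3, sd = sd_bead[b] * sqrt(1 - phi^2)),
                        nf, 3)
        dev <- matrix(0, nf, 3)
        dev[1, ] <- stats::rnorm(3, sd = sd_bead[b])
        for (f in 2:nf) dev[f, ] <- phi * dev[f - 1, ] + innov[f, ]
      }
      coord[, ai, ] <- coord[, ai, ] + dev
    }
  })
  trajectory_ensemble(coord, s$atoms)
}
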