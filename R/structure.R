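#' Molecular structure container
#'
#' A `structure3d` is an ordered atom table plus a title. It is the common
#' currency of the whole pipeline: structure preparation, charge
#' assignment, dielectric mapping, surface sampling and force evaluation
#' all consume it. Columns of `$atoms`:
#' \describe{
#'   \item{elety}{atom name, e.g. "CA"}
#'   \item{resid}{3-letter residue name}
#'   \item{resno}{1-based residue index (PDB convention)}
#'   \item{chain}{chain identifier}
#'   \item{x,y,z}{coordinates in Angstrom, as read (never recentred)}
#'   \item{charge}{partial charge in elementary charges e}
#'   \item{radius}{atomic radius in Angstrom (> 0 for dielectric mapping)}
#'   \item{mass}{atomic mass units}
#' }
#'
#' @param atoms data.frame with at least x, y, z; missing charge/radius/mass
#'   columns are filled with defaults (0 e, 1.5 A, element-guessed mass).
#' @param title free-text title.
#' @return an object of class `structure3d`.
#' @export
structure3d <- function(atoms, title = "") {
  atoms <- as.data.frame(atoms)
  stopifnot(all(c("x", "y", "z") %in% names(atoms)))
  defaults <- list(elety = "CA", resid = "UNK", chain = "A")
  for (nm in names(defaults))
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  if (is.null(atoms$resno))  atoms$resno  <- seq_len(nrow(atoms))
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$radius)) atoms$radius <- 1.5
  if (is.null(atoms$mass))   atoms$mass   <- .guess_mass(atoms$elety)
  keep <- c("elety", "resid", "chain", "resno",
            "x", "y", "z", "charge", "radius", "mass")
  atoms <- atoms[, keep]
  rownames(atoms) <- NULL
  if (nrow(atoms) && !all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in structure")
  out <- list(atoms = atoms, title = as.character(title))
  class(out) <- "structure3d"
  out
}

# average masses by element symbol; atom names lead with the element for
# the standard biomolecular set handled here
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974)

.guess_mass <- function(elety) {
  first <- substr(gsub("[^A-Za-z].*$", "", toupper(elety)), 1, 1)
  m <- .element_masses[first]
  m[is.na(m)] <- 12.011
  unname(m)
}

# average amino-acid residue masses (Da), used for coarse C-alpha beads
# where one bead stands for a whole residue
.residue_masses <- c(
  ALA =  71.08, ARG = 156.19, ASN = 114.10, ASP = 115.09, CYS = 103.14,
  GLN = 128.13, GLU = 129.12, GLY =  57.05, HIS = 137.14, ILE = 113.16,
  LEU = 113.16, LYS = 128.17, MET = 131.19, PHE = 147.18, PRO =  97.12,
  SER =  87.08, THR = 101.10, TRP = 186.21, TYR = 163.18, VAL =  99.13)

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("structure3d: %d atoms, %d chains, total charge %+.3f e\n",
              n_atoms(x), length(unique(x$atoms$chain)), total_charge(x)))
  if (nzchar(x$title)) cat(" title:", x$title, "\n")
  invisible(x)
}

#' Number of atoms in a structure
#' @param s a `structure3d`.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Total charge of a structure in e
#' @param s a `structure3d`.
#' @export
total_charge <- function(s) sum(s$atoms$charge)

#' Atom coordinates as an n x 3 matrix
#' @param s a `structure3d`.
#' @export
coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

#' Read a structure from PDB or PQR
#'
#' Parsing is delegated to \pkg{bio3d}; for multi-model PDB files the first
#' model is returned. PQR files populate the charge and radius columns from
#' the file; PDB files get zero charges and a uniform default radius until
#' [assign_charges()] or a PQR round-trip supplies real values.
#'
#' @param path file path.
#' @param format `"pdb"`, `"pqr"`, or `"auto"` (by file extension).
#' @param default_radius radius (A) given to atoms of PDB files.
#' @return a `structure3d`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "pqr"),
                           default_radius = 1.7) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("pdb", "pqr", "ent"))
      stop("cannot infer format from extension '", ext,
           "'; pass format = \"pdb\" or \"pqr\"")
    format <- if (ext == "pqr") "pqr" else "pdb"
  }
  raw <- if (format == "pqr") bio3d::read.pqr(path)
         else suppressWarnings(bio3d::read.pdb(path, multi = FALSE))
  at <- raw$atom
  atoms <- data.frame(
    elety = at$elety, resid = at$resid,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno, x = at$x, y = at$y, z = at$z,
    charge = if (format == "pqr") at$o else 0,
    radius = if (format == "pqr") at$b else default_radius,
    stringsAsFactors = FALSE)
  if (anyNA(atoms$charge) || anyNA(atoms$radius))
    stop("malformed ", toupper(format), " record: missing charge/radius at ",
         "atom row ", which(is.na(atoms$charge) | is.na(atoms$radius))[1])
  structure3d(atoms, title = basename(path))
}

#' Write a structure as PQR (or PDB)
#'
#' @param s a `structure3d`.
#' @param path output path.
#' @param format `"pqr"` (charges + radii, the pipeline's native format)
#'   or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, format = c("pqr", "pdb")) {
  format <- match.arg(format)
  a <- s$atoms
  pdbobj <- .as_bio3d(s)
  if (format == "pqr") bio3d::write.pqr(pdbobj, file = path)
  else bio3d::write.pdb(pdbobj, file = path)
  invisible(path)
}

.as_bio3d <- function(s) {
  a <- s$atoms
  n <- nrow(a)
  xyz <- as.numeric(t(coords(s)))
  atom <- data.frame(
    type = rep("ATOM", n), eleno = seq_len(n), elety = a$elety,
    alt = NA_character_, resid = a$resid, chain = a$chain, resno = a$resno,
    insert = NA_character_, x = a$x, y = a$y, z = a$z,
    o = a$charge, b = a$radius, segid = NA_character_,
    elesy = substr(a$elety, 1, 1), charge = NA_character_,
    stringsAsFactors = FALSE)
  out <- list(atom = atom, xyz = bio3d::as.xyz(matrix(xyz, nrow = 1)),
              calpha = a$elety == "CA")
  class(out) <- c("pdb", "sse")
  out
}

.water_names <- c("HOH", "WAT", "TIP", "TIP3", "TIP4", "SPC", "SOL")

#' Remove water molecules
#'
#' Drops all residues named HOH/WAT/TIP(3/4)/SPC/SOL; idempotent on
#' water-free input, every other atom untouched.
#'
#' @param s a `structure3d`.
#' @export
strip_waters <- function(s) {
  keep <- !(toupper(s$atoms$resid) %in% .water_names)
  s$atoms <- s$atoms[keep, , drop = FALSE]
  rownames(s$atoms) <- NULL
  s
}

#' Charge assignment scheme
#'
#' `"formal"` mode assigns whole formal charges at pH 7: -1 e to Asp and
#' Glu, +1 e to Lys and Arg, 0 elsewhere, each placed on the residue's
#' C-alpha (coarse placement below the 1 A grid resolution of the solver).
#' `"pqr-supplied"` leaves file charges untouched.
#'
#' @param mode `"formal"` or `"pqr-supplied"`.
#' @param ph pH of the assignment (only 7 is implemented; recorded for
#'   provenance).
#' @export
charge_scheme <- function(mode = c("formal", "pqr-supplied"), ph = 7) {
  mode <- match.arg(mode)
  structure(list(mode = mode, ph = ph), class = "charge_scheme")
}

.formal_charges <- c(ASP = -1, GLU = -1, LYS = +1, ARG = +1)

#' Assign per-residue formal charges
#'
#' In formal mode the total structure charge equals
#' (#Lys + #Arg) - (#Asp + #Glu); every non-placement atom gets charge 0.
#' Unknown residue names draw a warning and charge 0.
#'
#' @param s a `structure3d`.
#' @param scheme a [charge_scheme()].
#' @export
assign_charges <- function(s, scheme = charge_scheme("formal")) {
  stopifnot(inherits(scheme, "charge_scheme"))
  if (scheme$mode == "pqr-supplied") return(s)
  a <- s$atoms
  a$charge <- 0
  key <- paste(a$chain, a$resno)
  known <- c(names(.residue_masses), .water_names)
  for (k in unique(key)) {
    idx <- which(key == k)
    rn <- toupper(a$resid[idx[1]])
    if (!rn %in% known) {
      warning("unknown residue '", rn, "' in formal mode; assigned 0 e")
      next
    }
    q <- .formal_charges[rn]
    if (is.na(q)) next
    place <- idx[match("CA", a$elety[idx])]
    if (is.na(place)) place <- idx[1]
    a$charge[place] <- q
  }
  s$atoms <- a
  s
}

#' Graft a coarse C-terminal tail onto a chain
#'
#' Appends one C-alpha bead per sequence letter, grown from the chain's
#' last C-alpha as a self-avoiding random walk with fixed 3.8 A virtual
#' bonds. Used to model disordered C-terminal tails (e.g. the tubulin
#' E-hooks) that experimental structures do not resolve; it produces an
#' extended flexible conformation, not a physical model of the real tail.
#'
#' @param s a `structure3d`.
#' @param chain chain id to extend.
#' @param sequence 1-letter amino-acid string (e.g. "GVDSVEGEGEEEGEEY").
#' @param seed integer; the walk is bit-reproducible given the seed.
#' @param bond_length virtual C-alpha--C-alpha bond, A.
#' @param clash_cutoff minimum distance of a new bead to every existing
#'   atom, A.
#' @param max_retries direction re-draws allowed per residue before a
#'   build error.
#' @param bead_radius radius (A) given to the new beads.
#' @return the extended `structure3d`; new beads carry charge 0 until
#'   [assign_charges()].
#' @export
build_cterminal_tail <- function(s, chain, sequence, seed = 1L,
                                 bond_length = 3.8, clash_cutoff = 3.0,
                                 max_retries = 100L, bead_radius = 1.9) {
  sequence <- gsub("\\s", "", sequence)
  if (!nzchar(sequence)) return(s)
  if (!chain %in% s$atoms$chain) stop("no such chain: ", chain)
  res3 <- bio3d::aa123(strsplit(toupper(sequence), "")[[1]])
  if (anyNA(res3)) stop("unrecognized residue letter in sequence")
  ach <- s$atoms[s$atoms$chain == chain, ]
  last <- ach[which.max(ach$resno), ]
  ca <- ach[ach$resno == last$resno & ach$elety == "CA", ]
  anchor <- if (nrow(ca)) as.numeric(ca[1, c("x", "y", "z")])
            else as.numeric(last[c("x", "y", "z")])
  existing <- coords(s)
  new_pts <- matrix(NA_real_, length(res3), 3)
  prev <- anchor
  local_seed(seed, {
    for (i in seq_along(res3)) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        cand <- prev + bond_length * dir
        pts <- rbind(existing, new_pts[seq_len(i - 1), , drop = FALSE])
        d2 <- (pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2 +
              (pts[, 3] - cand[3])^2
        if (!length(d2) || min(d2) >= clash_cutoff^2) {
          new_pts[i, ] <- cand
          prev <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("tail build failed: cannot place residue ", i,
             " without clashes after ", max_retries, " retries")
    }
  })
  tail_atoms <- data.frame(
    elety = "CA", resid = res3, chain = chain,
    resno = last$resno + seq_along(res3),
    x = new_pts[, 1], y = new_pts[, 2], z = new_pts[, 3],
    charge = 0, radius = bead_radius,
    mass = unname(.residue_masses[res3]),
    stringsAsFactors = FALSE)
  s$atoms <- rbind(s$atoms, tail_atoms)
  rownames(s$atoms) <- NULL
  s
}

#' Merge two structures
#'
#' Chain ids of `b` colliding with chains of `a` are suffix-renamed
#' (deterministic, lossless). A clash report — the number of
#' inter-structure atom pairs closer than `clash_cutoff` — is attached as
#' attribute `"n_clashes"`.
#'
#' @param a,b `structure3d` objects.
#' @param clash_cutoff A.
#' @export
merge_structures <- function(a, b, clash_cutoff = 3.0) {
  if (n_atoms(b) == 0) out_atoms <- a$atoms
  else {
    bat <- b$atoms
    collide <- intersect(unique(a$atoms$chain), unique(bat$chain))
    for (ch in collide) {
      new <- paste0(ch, "2")
      while (new %in% c(a$atoms$chain, bat$chain)) new <- paste0(new, "2")
      bat$chain[bat$chain == ch] <- new
    }
    out_atoms <- rbind(a$atoms, bat)
  }
  out <- structure3d(out_atoms,
                     title = paste(a$title, b$title, sep = " + "))
  n_cl <- 0L
  if (n_atoms(a) && n_atoms(b)) {
    xa <- coords(a); xb <- coords(b)
    for (i in seq_len(nrow(xa))) {
      d2 <- (xb[, 1] - xa[i, 1])^2 + (xb[, 2] - xa[i, 2])^2 +
            (xb[, 3] - xa[i, 3])^2
      n_cl <- n_cl + sum(d2 < clash_cutoff^2)
    }
  }
  attr(out, "n_clashes") <- n_cl
  out
}

#' Mass-weighted center of a structure
#'
#' @param s a `structure3d` with at least one atom and positive masses.
#' @return 3-vector, Angstrom.
#' @export
mass_center <- function(s) {
  if (n_atoms(s) == 0) stop("mass_center of an empty structure")
  m <- s$atoms$mass
  if (any(m <= 0)) stop("non-positive atom mass")
  as.numeric(crossprod(coords(s), m) / sum(m))
}

#' Rigidly translate a structure
#' @param s a `structure3d`.
#' @param shift 3-vector, Angstrom.
#' @export
translate_structure <- function(s, shift) {
  stopifnot(length(shift) == 3, all(is.finite(shift)))
  s$atoms$x <- s$atoms$x + shift[1]
  s$atoms$y <- s$atoms$y + shift[2]
  s$atoms$z <- s$atoms$z + shift[3]
  s
}

# run `expr` under a fixed RNG seed, restoring the caller's RNG state
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}
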