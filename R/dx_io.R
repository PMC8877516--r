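#' OpenDX scalar-grid export/import
#'
#' Reads and writes the "regular positions, regular connections" OpenDX
#' scalar format used throughout the continuum-electrostatics ecosystem
#' (DelPhi/APBS potential maps). Data ordering follows the OpenDX
#' convention: the z index varies fastest.
#'
#' @param pg a `potential_grid`.
#' @param path file path (conventionally `.dx`).
#' @return `export_grid`: `path`, invisibly; `import_grid`: a
#'   `potential_grid` (with `converged = NA`-free metadata re-marked as
#'   converged, since a stored grid carries no residual).
#' @rdname dx_io
#' @export
export_grid <- function(pg, path) {
  g <- pg$spec
  nd <- g$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar grid: electrostatic potential (kT/e)",
    sprintf("object 1 class gridpositions counts %d %d %d",
            nd[1], nd[2], nd[3]),
    sprintf("origin %.6e %.6e %.6e", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.6e %.6e %.6e", g$spacing, 0, 0),
    sprintf("delta %.6e %.6e %.6e", 0, g$spacing, 0),
    sprintf("delta %.6e %.6e %.6e", 0, 0, g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            nd[1], nd[2], nd[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(nd))), con)
  # OpenDX: value index runs z fastest, x slowest
  vals <- as.vector(aperm(pg$phi, c(3, 2, 1)))
  pad <- (-length(vals)) %% 3
  vv <- c(vals, rep(NA_real_, pad))
  m <- matrix(vv, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r)
    paste(sprintf("%.8e", r[!is.na(r)]), collapse = " "))
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' @rdname dx_io
#' @export
import_grid <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  gp <- grep("class gridpositions counts", lines, value = TRUE)
  if (!length(gp)) stop("malformed DX: no gridpositions object")
  nd <- as.integer(strsplit(trimws(sub(".*counts", "", gp[1])), "\\s+")[[1]])
  if (length(nd) != 3 || anyNA(nd)) stop("malformed DX: bad counts")
  ol <- grep("^origin", lines, value = TRUE)
  if (!length(ol)) stop("malformed DX: no origin")
  origin <- as.numeric(strsplit(trimws(sub("^origin", "", ol[1])), "\\s+")[[1]])
  dl <- grep("^delta", lines, value = TRUE)
  if (length(dl) < 3) stop("malformed DX: need 3 delta lines")
  deltas <- t(vapply(dl[1:3], function(x)
    as.numeric(strsplit(trimws(sub("^delta", "", x)), "\\s+")[[1]]),
    numeric(3)))
  deltas <- unname(deltas)
  spacing <- deltas[1, 1]
  if (abs(deltas[2, 2] - spacing) > 1e-9 ||
      abs(deltas[3, 3] - spacing) > 1e-9)
    stop("only uniform axis-aligned DX grids are supported")
  di <- grep("data follows", lines)
  if (!length(di)) stop("malformed DX: no data section")
  items <- as.integer(sub(".*items\\s+(\\d+)\\s+data.*", "\\1", lines[di[1]]))
  if (items != prod(nd))
    stop("malformed DX: item count ", items, " != product of dims ",
         prod(nd))
  body <- lines[(di[1] + 1):length(lines)]
  body <- body[!grepl("attribute|object|component", body)]
  vals <- as.numeric(unlist(strsplit(trimws(body), "\\s+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != items) stop("malformed DX: expected ", items,
                                  " values, found ", length(vals))
  phi <- aperm(array(vals, dim = rev(nd)), c(3, 2, 1))
  spec <- structure(list(origin = origin, spacing = spacing, dims = nd),
                    class = "grid_spec")
  structure(list(spec = spec, phi = phi, converged = TRUE,
                 iterations = 0L, max_update = 0),
            class = "potential_grid")
}
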