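#' Flexibility statistics of tracked atoms over a trajectory ensemble
#'
#' The flexibility index of a tracked point is the root of the mean
#' squared Euclidean distance of its per-frame positions from their
#' centroid:
#'
#'   sigma^2 = sum_i ((x - xi)^2 + (y - yi)^2 + (z - zi)^2) / n
#'
#' with (x, y, z) the centroid. Note this is the RMS distance from the
#' centroid — the mean distance is not subtracted — and the divisor is n,
#' not n - 1. For an isotropic Gaussian point cloud with per-axis SD s,
#' the expected index is sqrt(3) * s.
#'
#' @name flexibility
NULL

#' Centroid of a point cloud
#' @param pc n x 3 matrix of positions (A).
#' @return 3-vector.
#' @export
centroid <- function(pc) {
  pc <- .as_cloud(pc)
  colMeans(pc)
}

.as_cloud <- function(pc) {
  pc <- as.matrix(pc)
  if (!nrow(pc)) stop("empty point cloud")
  if (ncol(pc) != 3) stop("point cloud must be n x 3")
  if (!all(is.finite(pc))) stop("non-finite point in cloud")
  pc
}

#' Flexibility index of a point cloud
#'
#' @param pc n x 3 matrix: per-frame positions of one tracked atom.
#' @return list with `sigma` (A), `centroid` (3-vector) and `n`.
#' @export
#' @examples
#' flexibility_index(rbind(c(0, 0, 0), c(2, 0, 0)))$sigma  # 1.0
flexibility_index <- function(pc) {
  pc <- .as_cloud(pc)
  ctr <- colMeans(pc)
  d2 <- (pc[, 1] - ctr[1])^2 + (pc[, 2] - ctr[2])^2 + (pc[, 3] - ctr[3])^2
  list(sigma = sqrt(mean(d2)), centroid = ctr, n = nrow(pc))
}

#' Per-frame displacement from the first frame
#'
#' Distance of each point from the frame-0 (first) position; element 1 is
#' always 0.
#'
#' @param pc n x 3 matrix.
#' @return numeric vector of length n, Angstrom.
#' @export
displacement_series <- function(pc) {
  pc <- .as_cloud(pc)
  sqrt((pc[, 1] - pc[1, 1])^2 + (pc[, 2] - pc[1, 2])^2 +
       (pc[, 3] - pc[1, 3])^2)
}

#' Correlation between two displacement series
#'
#' Pearson correlation of the two per-frame distance series, with a 95%
#' confidence interval by the Fisher z-transform (as provided by
#' [stats::cor.test()]).
#'
#' @param a,b equal-length numeric series (length >= 3, nonzero variance).
#' @return list with `r`, `ci_low`, `ci_high`, `n`.
#' @export
movement_correlation <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance displacement series")
  ct <- stats::cor.test(a, b, method = "pearson", conf.level = 0.95)
  list(r = unname(ct$estimate), ci_low = ct$conf.int[1],
       ci_high = ct$conf.int[2], n = length(a))
}

#' Flexibility table for a set of tracked atoms
#'
#' Convenience wrapper: tracks each requested atom through the trajectory
#' and tabulates its flexibility index.
#'
#' @param traj a [trajectory_ensemble()].
#' @param tracks data.frame with columns chain, resno, elety.
#' @return data.frame: chain, resno, elety, n, sigma.
#' @export
flexibility_table <- function(traj, tracks) {
  stopifnot(all(c("chain", "resno", "elety") %in% names(tracks)))
  res <- lapply(seq_len(nrow(tracks)), function(i) {
    pc <- track_atom(traj, tracks$chain[i], tracks$resno[i], tracks$elety[i])
    fx <- flexibility_index(pc)
    data.frame(chain = tracks$chain[i], resno = tracks$resno[i],
               elety = tracks$elety[i], n = fx$n, sigma = fx$sigma)
  })
  do.call(rbind, res)
}
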