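# --- small vector helpers ---------------------------------------------------

vec_norm <- function(v) sqrt(sum(v * v))

unit_vector <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("degenerate direction vector (zero norm)")
  v / n
}

#' Rotate vectors about an axis (Rodrigues' formula)
#'
#' @param v numeric vector of length 3, or an n x 3 matrix of row vectors.
#' @param axis rotation axis (need not be unit length).
#' @param angle rotation angle in radians (right-handed about `axis`).
#' @return rotated vector(s), same shape as `v`.
#' @export
rotate_about_axis <- function(v, axis, angle) {
  k <- unit_vector(axis)
  single <- is.null(dim(v))
  m <- if (single) matrix(v, nrow = 1) else v
  cs <- cos(angle); sn <- sin(angle)
  kx <- m[, 1] * k[1] + m[, 2] * k[2] + m[, 3] * k[3]
  cross <- cbind(k[2] * m[, 3] - k[3] * m[, 2],
                 k[3] * m[, 1] - k[1] * m[, 3],
                 k[1] * m[, 2] - k[2] * m[, 1])
  out <- m * cs + cross * sn + outer(kx * (1 - cs), k)
  if (single) drop(out) else out
}

#' Deterministic unit normal orthogonal to a direction
#'
#' Returns the unit vector orthogonal to `dir` closest to the +x axis
#' (Gram-Schmidt); falls back to +y when `dir` is parallel to x. Used as the
#' zero-angle reference for needle bending planes.
#' @keywords internal
reference_normal <- function(dir) {
  d <- unit_vector(dir)
  for (e in list(c(1, 0, 0), c(0, 1, 0))) {
    r <- e - sum(e * d) * d
    if (vec_norm(r) > 1e-8) return(unit_vector(r))
  }
  stop("cannot build reference normal")  # unreachable for unit dir
}

#' Resample a polyline at a fixed arc-length step
#'
#' @param pts n x 3 matrix of polyline vertices (mm).
#' @param step_mm sampling step, must be <= 1 mm for distance queries.
#' @return m x 3 matrix including both endpoints.
#' @export
resample_polyline <- function(pts, step_mm = 1) {
  pts <- rbind(pts)
  if (nrow(pts) == 1) return(pts)
  seg <- diff(pts)
  len <- sqrt(rowSums(seg^2))
  keep <- len > 1e-12
  if (!any(keep)) return(pts[1, , drop = FALSE])
  pts <- pts[c(TRUE, keep), , drop = FALSE]
  len <- len[keep]
  s <- c(0, cumsum(len))
  total <- s[length(s)]
  t_out <- seq(0, total, by = step_mm)
  if (total - t_out[length(t_out)] > 1e-9) t_out <- c(t_out, total)
  idx <- findInterval(t_out, s, rightmost.closed = TRUE)
  idx[idx >= length(s)] <- length(s) - 1
  frac <- (t_out - s[idx]) / len[idx]
  pts[idx, , drop = FALSE] + (pts[idx + 1, , drop = FALSE] - pts[idx, , drop = FALSE]) * frac
}

# Minimum pairwise distance between two point sets, chunked to bound memory.
# Returns the global minimum; optionally the per-row (P) minima.
min_cross_distance <- function(P, Q, per_point = FALSE, chunk = 4096L) {
  P <- rbind(P); Q <- rbind(Q)
  p2 <- rowSums(P^2)
  if (per_point) {
    q2 <- rowSums(Q^2)
    best <- rep(Inf, nrow(P))
    p_chunk <- max(1L, floor(4e6 / nrow(Q)))
    for (ps in seq(1L, nrow(P), by = p_chunk)) {
      pi_ <- ps:min(ps + p_chunk - 1L, nrow(P))
      Pc <- P[pi_, , drop = FALSE]
      acc <- rep(Inf, length(pi_))
      for (qs in seq(1L, nrow(Q), by = chunk)) {
        qi <- qs:min(qs + chunk - 1L, nrow(Q))
        Qc <- Q[qi, , drop = FALSE]
        d2 <- outer(p2[pi_], q2[qi], "+") - 2 * tcrossprod(Pc, Qc)
        acc <- pmin(acc, row_mins(d2))
      }
      best[pi_] <- acc
    }
    return(sqrt(pmax(best, 0)))
  }
  best <- Inf
  for (start in seq(1L, nrow(Q), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(Q))
    Qc <- Q[idx, , drop = FALSE]
    d2 <- outer(p2, rowSums(Qc^2), "+") - 2 * tcrossprod(P, Qc)
    best <- min(best, min(d2))
  }
  sqrt(max(best, 0))
}

# Row minima of a matrix without extra copies (base-R stand-in).
row_mins <- function(m) {
  out <- m[, 1]
  if (ncol(m) > 1) for (j in 2:ncol(m)) out <- pmin(out, m[, j])
  out
}

# Distance from points to an axis-aligned box [lo, hi] (0 inside).
dist_to_aabb <- function(P, lo, hi) {
  P <- rbind(P)
  dx <- pmax(lo[1] - P[, 1], 0, P[, 1] - hi[1])
  dy <- pmax(lo[2] - P[, 2], 0, P[, 2] - hi[2])
  dz <- pmax(lo[3] - P[, 3], 0, P[, 3] - hi[3])
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Exact distance from a point to a segment (analytic)
#'
#' Independent closed-form helper used by tests as an oracle and by entry
#' preprocessing for clearance estimates.
#' @param p point (length 3).
#' @param a,b segment endpoints.
#' @export
point_segment_distance <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / max(sum(ab * ab), 1e-300)
  t <- min(max(t, 0), 1)
  vec_norm(p - (a + t * ab))
}

# Run `expr` under a local RNG seed, restoring global RNG state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
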