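## Shared geometry and small numeric helpers.

#' Optimal rigid superposition of two matched point sets
#'
#' Computes the least-squares rigid transform (rotation + translation) that
#' maps \code{coordsB} onto \code{coordsA} using the Kabsch singular value
#' decomposition, together with the resulting root-mean-square deviation.
#'
#' @param coordsA n x 3 numeric matrix of reference coordinates (Angstrom).
#' @param coordsB n x 3 numeric matrix of coordinates to superpose; row i of
#'   \code{coordsB} is matched to row i of \code{coordsA}.
#' @return A list with \code{rotation} (3 x 3 matrix), \code{translation}
#'   (length-3 vector) such that \code{coordsB \%*\% rotation + translation}
#'   best fits \code{coordsA}, and \code{rmsd} in Angstrom.
#' @examples
#' a <- matrix(rnorm(30), ncol = 3)
#' fit <- kabsch_superpose(a, a)
#' fit$rmsd  # 0
#' @export
kabsch_superpose <- function(coordsA, coordsB) {
  coordsA <- as.matrix(coordsA); coordsB <- as.matrix(coordsB)
  if (nrow(coordsA) != nrow(coordsB) || ncol(coordsA) != 3L || ncol(coordsB) != 3L)
    stop("coordsA and coordsB must be matched n x 3 matrices")
  if (nrow(coordsA) < 3L)
    stop("at least 3 matched points are required for a rigid superposition")
  ca <- colMeans(coordsA); cb <- colMeans(coordsB)
  A <- sweep(coordsA, 2, ca); B <- sweep(coordsB, 2, cb)
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  R <- t(R)  # so that B %*% R aligns onto A
  fitted <- B %*% R
  rmsd <- sqrt(mean(rowSums((fitted - A)^2)))
  translation <- ca - as.vector(cb %*% R)
  list(rotation = R, translation = translation, rmsd = rmsd)
}

## Apply a rigid transform stored as list(rotation, translation).
apply_transform <- function(coords, transform) {
  sweep(as.matrix(coords) %*% transform$rotation, 2, -transform$translation)
}

## Random rotation matrix (uniform over SO(3)) from the current RNG stream.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

## Squared / plain Euclidean cross-distances between two n x 3 matrices.
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

## Evaluate expr under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

## Any unit vector orthogonal to v.
orthogonal_vector <- function(v) {
  v <- unit_vector(v)
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- ref - sum(ref * v) * v
  unit_vector(w)
}

vec_angle <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}
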