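#' Rigid-body transform
#'
#' A rotation plus translation, applied as `x %*% t(R) + t`.
#'
#' @param R 3x3 rotation matrix (orthogonal, det +1).
#' @param t Length-3 translation vector (Angstrom).
#' @return An object of class `lf_transform`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  stopifnot(all(dim(R) == c(3, 3)), length(t) == 3)
  if (abs(det(R) - 1) > 1e-6 || max(abs(crossprod(R) - diag(3))) > 1e-6)
    abort("R must be a proper rotation matrix")
  structure(list(R = R, t = as.numeric(t)), class = "lf_transform")
}

#' @export
print.lf_transform <- function(x, ...) {
  cat("<lf_transform>\n")
  print(round(x$R, 4))
  cat("t =", paste(round(x$t, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param coords n x 3 matrix.
#' @param tf An `lf_transform`.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(coords, tf) {
  coords <- rbind(coords) # tolerate a bare length-3 vector
  sweep(coords %*% t(tf$R), 2, -tf$t)
}

#' Compose two rigid transforms (apply `a` after `b`)
#' @param a,b `lf_transform` objects.
#' @return `lf_transform` equal to x -> a(b(x)).
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)
}

#' Invert a rigid transform
#' @param tf An `lf_transform`.
#' @return The inverse `lf_transform`.
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$R), as.numeric(-t(tf$R) %*% tf$t))
}

#' Rotation matrix from a rotation vector (Rodrigues)
#'
#' @param w Length-3 rotation vector; direction = axis, norm = angle (rad).
#' @return 3x3 rotation matrix.
#' @export
rotation_from_vector <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  k <- w / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# uniform random rotation (Shoemake quaternion method); consumes 3 uniforms
random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  quat_to_matrix(q)
}

quat_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Least-squares superposition of `mobile` onto `fixed` (Horn's quaternion
# method). Returns the lf_transform minimizing RMSD.
superpose_transform <- function(mobile, fixed) {
  mobile <- as.matrix(mobile); fixed <- as.matrix(fixed)
  if (nrow(mobile) < 3)
    abort("superposition needs at least 3 points")
  if (nrow(mobile) != nrow(fixed))
    abort("point sets must have equal size")
  mc <- colMeans(mobile); fc <- colMeans(fixed)
  A <- sweep(mobile, 2, mc); B <- sweep(fixed, 2, fc)
  S <- t(A) %*% B
  if (!all(is.finite(S)) || qr(A)$rank < 2)
    abort("degenerate coordinates: superposition is singular")
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],       S[3,1]-S[1,3],       S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],       S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]
  ), 4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  R <- quat_to_matrix(q)
  rigid_transform(R, fc - as.numeric(R %*% mc))
}
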