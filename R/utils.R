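# Shared small helpers: units, rotations, seeded evaluation.

# Boltzmann constant in kcal/(mol K); all energies kcal/mol, lengths Angstrom,
# times ps throughout the package.
.kB <- 0.0019872041

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about the z axis
#'
#' @param angle_deg rotation angle in degrees (counter-clockwise looking down
#'   the +z axis).
#' @return 3x3 rotation matrix.
#' @export
rot_z <- function(angle_deg) {
  a <- deg2rad(angle_deg)
  matrix(c(cos(a), sin(a), 0,
           -sin(a), cos(a), 0,
           0, 0, 1), 3, 3)
}

#' Rotation matrix about an arbitrary axis (Rodrigues formula)
#'
#' @param axis 3-vector, need not be normalized.
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rot_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- deg2rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL evaluates code with the ambient RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Orthonormal frame completing a unit vector u: returns 3x3 with columns
# (u, v, w). Deterministic.
complete_frame <- function(u) {
  u <- u / sqrt(sum(u^2))
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  v <- crossprod_3(u, ref)
  v <- v / sqrt(sum(v^2))
  w <- crossprod_3(u, v)
  cbind(u, v, w, deparse.level = 0)
}

crossprod_3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Sweep a 3-vector off every row of an n x 3 matrix.
sweep_rows <- function(x, v) {
  x - matrix(v, nrow(x), 3, byrow = TRUE)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
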