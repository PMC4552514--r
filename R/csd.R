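# Spherical-spline surface Laplacian (current source density).
#
# Scalp potentials are interpolated with spherical splines and the surface
# Laplacian of the spline is evaluated at the electrodes, yielding
# reference-free current source density in uV/m^2. The construction is the
# classical one: spline kernels g() and Laplacian kernels h() are Legendre
# series in the cosine of the inter-electrode angle.

legendre_series <- function(x, coef) {
  # sum_n coef[n] * P_n(x), n = 1..length(coef), via the three-term recurrence
  p_prev <- rep(1, length(x))   # P_0
  p_cur <- x                    # P_1
  acc <- coef[1] * p_cur
  for (n in 2:length(coef)) {
    p_next <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
    acc <- acc + coef[n] * p_next
    p_prev <- p_cur
    p_cur <- p_next
  }
  acc
}

#' Current source density transform matrix
#'
#' Precomputes the linear operator mapping scalp potentials (uV) to
#' spherical-spline surface Laplacian estimates (uV/m^2) for a montage.
#'
#' @param positions data.frame with `label`, `x`, `y`, `z` on the unit
#'   sphere.
#' @param m Spline stiffness (flexibility) order.
#' @param lambda Ridge regularization added to the spline system.
#' @param n_legendre Number of Legendre terms in the kernel series.
#' @param head_radius Physical head radius in metres used to scale the unit
#'   sphere (sets the uV/m^2 units).
#' @return A channels-by-channels matrix `M` such that `M %*% data` is the
#'   CSD-referenced data.
#' @export
csd_matrix <- function(positions, m = 4, lambda = 1e-5, n_legendre = 50,
                       head_radius = 0.1) {
  xyz <- as.matrix(positions[, c("x", "y", "z")])
  xyz <- xyz / sqrt(rowSums(xyz^2))
  cosang <- tcrossprod(xyz)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1

  n <- seq_len(n_legendre)
  gcoef <- (2 * n + 1) / (n * (n + 1))^m / (4 * pi)
  hcoef <- -(2 * n + 1) / (n * (n + 1))^(m - 1) / (4 * pi)

  cvec <- as.vector(cosang)
  G <- matrix(legendre_series(cvec, gcoef), nrow(xyz))
  H <- matrix(legendre_series(cvec, hcoef), nrow(xyz))

  Gs <- G + diag(lambda, nrow(G))
  Ginv <- solve(Gs)
  ones <- rep(1, nrow(G))
  gi1 <- Ginv %*% ones
  denom <- sum(gi1)
  # spline weights c = A v with the sum-to-zero constraint folded in
  A <- Ginv - (gi1 %*% t(gi1)) / denom
  # Laplacian on a sphere of radius r scales as 1/r^2; sign flipped so that
  # a focal positive source yields a positive CSD peak.
  -(H %*% A) / head_radius^2
}

#' Apply the current source density reference
#'
#' Transforms an ocular-corrected recording to reference-free current
#' source density (spherical-spline surface Laplacian). A spatially uniform
#' potential maps to (numerically) zero.
#'
#' @param rec An `eeg_recording` at stage `"ocular_corrected"`.
#' @param m,lambda,n_legendre,head_radius See [csd_matrix()].
#' @return The CSD-referenced recording (uV/m^2), stage `"csd"`.
#' @export
apply_csd <- function(rec, m = 4, lambda = 1e-5, n_legendre = 50,
                      head_radius = 0.1) {
  check_stage(rec, "ocular_corrected", "apply_csd")
  if (anyNA(rec$positions[, c("x", "y", "z")])) {
    stop("all channels need electrode positions for the CSD transform",
         call. = FALSE)
  }
  M <- csd_matrix(rec$positions, m = m, lambda = lambda,
                  n_legendre = n_legendre, head_radius = head_radius)
  rec$data <- M %*% rec$data
  rownames(rec$data) <- rec$labels
  set_stage(rec, "csd")
}
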