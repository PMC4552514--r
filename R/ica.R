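# ICA-based ocular artifact correction.
#
# Blinks are near rank-one: a stereotyped low-frequency time course with a
# fixed frontally dominant scalp pattern, so independent component analysis
# isolates them in one component. We use a deflationary fixed-point ICA
# (logcosh contrast) on whitened data: components are extracted one at a
# time, and extraction stops when a component fails to converge, which is
# the expected outcome once the identifiable (non-Gaussian) part of the
# signal is exhausted -- directions within a Gaussian subspace carry no
# contrast and are unidentifiable in principle. On blink-free Gaussian-like
# data this extracts nothing and the correction is an exact no-op. For long
# recordings the unmixing vectors are estimated on a decimated subset of
# time points and applied to the full data.

fastica_deflate <- function(X, seed, tol = 1e-6, max_iter = 100,
                            restarts = 2L, max_components = 8L) {
  # X: channels x time, rows centered. Returns list(unmix, n_iter, K).
  if (!all(is.finite(X))) {
    stop("ICA input contains non-finite values", call. = FALSE)
  }
  cv <- tcrossprod(X) / ncol(X)
  eg <- eigen(cv, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-12
  if (sum(keep) < 2L) {
    stop("degenerate input: fewer than 2 non-null spatial dimensions",
         call. = FALSE)
  }
  K <- diag(1 / sqrt(eg$values[keep]), sum(keep)) %*%
    t(eg$vectors[, keep, drop = FALSE])
  Z <- K %*% X
  k <- nrow(Z)
  nT <- ncol(Z)
  if (is.null(max_components)) max_components <- k
  seeds <- derive_seeds(seed, max_components * restarts)
  W <- matrix(0, 0, k)
  iters <- integer(0)
  for (j in seq_len(max_components)) {
    found <- FALSE
    for (r in seq_len(restarts)) {
      w <- with_seed(seeds[(j - 1L) * restarts + r], stats::rnorm(k))
      if (nrow(W)) w <- drop(w - t(W) %*% (W %*% w))
      w <- w / sqrt(sum(w^2))
      for (it in seq_len(max_iter)) {
        wz <- drop(w %*% Z)
        g <- tanh(wz)
        w1 <- drop(Z %*% g) / nT - mean(1 - g^2) * w
        if (nrow(W)) w1 <- w1 - t(W) %*% (W %*% w1)
        nrm <- sqrt(sum(w1^2))
        if (!is.finite(nrm) || nrm < 1e-12) break
        w1 <- w1 / nrm
        delta <- abs(abs(sum(w1 * w)) - 1)
        w <- drop(w1)
        if (delta < tol) {
          found <- TRUE
          break
        }
      }
      if (found) {
        W <- rbind(W, w)
        iters <- c(iters, it)
        break
      }
    }
    if (!found) break  # contrast exhausted: remaining subspace ~ Gaussian
  }
  list(unmix = if (nrow(W)) W %*% K else matrix(0, 0, nrow(X)),
       n_iter = iters, K = K)
}

#' Remove ocular artifacts by independent component analysis
#'
#' Decomposes the filtered recording with a deflationary fixed-point ICA
#' and zeroes components identified as ocular. Because the montage carries
#' no dedicated EOG leads, a frontal proxy signal (mean of the two most
#' anterior channels) stands in for the ocular reference. A component is
#' flagged when (a) the absolute correlation of its time course with the
#' frontal proxy exceeds `threshold` and (b) its scalp pattern is
#' frontally dominant, loading on both anterior-most channels and much
#' more on frontal than on parietal sites. The joint-loading requirement
#' keeps single-channel noise components (which can correlate ~0.7 with a
#' two-channel mean) from being flagged on blink-free data. When no
#' component is extracted or flagged the recording passes through
#' unchanged.
#'
#' @param rec An `eeg_recording` at stage `"filtered"` with >= 8 channels.
#' @param seed Seed for the ICA initializations.
#' @param threshold Absolute correlation threshold against the frontal
#'   proxy.
#' @param max_points Maximum number of time points used to estimate the
#'   unmixing vectors (the correction itself is applied to all samples).
#' @param tol,max_iter Per-component convergence tolerance and iteration
#'   cap of the fixed-point iteration.
#' @return List with `recording` (stage `"ocular_corrected"`) and `report`,
#'   a data.frame of per-component detection criteria (zero rows when
#'   nothing was extracted).
#' @export
remove_ocular <- function(rec, seed = 1L, threshold = 0.7,
                          max_points = 25000L, tol = 1e-6,
                          max_iter = 100) {
  check_stage(rec, "filtered", "remove_ocular")
  if (nrow(rec$data) < 8L) {
    stop("ocular correction needs at least 8 channels", call. = FALSE)
  }
  X <- rec$data
  mu <- rowMeans(X)
  Xc <- X - mu

  step <- max(1L, ceiling(ncol(Xc) / max_points))
  fit <- fastica_deflate(Xc[, seq(1L, ncol(Xc), by = step), drop = FALSE],
                         seed = seed, tol = tol, max_iter = max_iter)
  k <- nrow(fit$unmix)
  rec_out <- rec
  if (k == 0L) {
    report <- data.frame(component = integer(), proxy_correlation = numeric(),
                         frontal_topography = logical(), flagged = logical())
    attr(report, "ica_iterations") <- integer()
    return(list(recording = set_stage(rec_out, "ocular_corrected"),
                report = report))
  }
  S <- fit$unmix %*% Xc                 # component time courses, full data
  # spatial patterns by least squares of the data on the sources
  A <- t(solve(tcrossprod(S), S %*% t(Xc)))

  front_order <- order(rec$positions$y, decreasing = TRUE)
  fp <- front_order[1:2]
  proxy <- colMeans(X[fp, , drop = FALSE])
  frontal <- rec$positions$y > 0.55
  parietal <- rec$positions$y < -0.2

  cors <- abs(apply(S, 1, function(s) suppressWarnings(stats::cor(s, proxy))))
  cors[is.na(cors)] <- 0
  topo_ok <- logical(k)
  for (j in seq_len(k)) {
    a <- abs(A[, j])
    pair_ok <- min(a[fp]) > 0.5 * max(a)
    grad_ok <- mean(a[frontal]) > 2 * mean(a[parietal])
    topo_ok[j] <- pair_ok && grad_ok
  }
  flagged <- cors > threshold & topo_ok

  # Subtract flagged components only where they are active (smoothly gated
  # around their high-amplitude excursions). Continuous subtraction would
  # inject the component's pattern-estimation noise into every sample,
  # which the downstream surface Laplacian amplifies; away from blinks the
  # data are left untouched.
  if (any(flagged)) {
    for (j in which(flagged)) {
      s <- S[j, ]
      act <- abs(s) > 5 * stats::mad(s)
      if (!any(act)) next
      # dilate and ramp with zero padding so excursions at the recording
      # edges (including tails wrapped there by the circular zero-phase
      # filters) stay fully inside the gate
      padded_ma <- function(v, w) {
        out <- stats::filter(c(numeric(w), v, numeric(w)), rep(1, w * 2 + 1),
                             sides = 2)
        out[(w + 1):(w + length(v))]
      }
      r <- max(1L, round(0.3 * rec$fs))
      act <- as.numeric(padded_ma(as.numeric(act), r) > 0)
      wlen <- max(1L, round(0.05 * rec$fs))
      gate <- padded_ma(act, wlen) / (2 * wlen + 1)
      sg <- s * as.numeric(gate)
      # re-estimate the scalp pattern from the active (high-SNR) samples,
      # where the artifact dominates and the pattern is best determined
      a <- drop(Xc %*% sg) / sum(sg^2)
      Xc <- Xc - a %o% sg
    }
  }
  rec_out$data <- Xc + mu
  rownames(rec_out$data) <- rec_out$labels
  report <- data.frame(component = seq_len(k),
                       proxy_correlation = cors,
                       frontal_topography = topo_ok,
                       flagged = flagged,
                       stringsAsFactors = FALSE)
  attr(report, "ica_iterations") <- fit$n_iter
  list(recording = set_stage(rec_out, "ocular_corrected"), report = report)
}

# Moore-Penrose pseudo-inverse via SVD (tiny helper; avoids pulling in a
# dependency for one call).
MASS_ginv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*%
    diag(1 / s$d[pos], sum(pos)) %*% t(s$u[, pos, drop = FALSE])
}
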