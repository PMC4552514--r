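#' Standard 10-20 montage on the unit sphere
#'
#' Returns unit-sphere electrode positions for a 10-20/10-10 subset suitable
#' for frontal/parietal pool analyses. Coordinates follow the usual head
#' frame: x to the right preauricular point, y to the nasion, z to the
#' vertex. Anchor electrodes use the classical 10-20 spherical placement;
#' intermediate 10% electrodes (FC/CP rows) are constructed as normalized
#' spherical midpoints of their 10-20 neighbours.
#'
#' @param labels Optional character vector restricting (and ordering) the
#'   returned channels. Defaults to the 19-channel set used by the synthetic
#'   generator: the 12 pooled analysis channels plus fronto-polar, midline
#'   and occipital support channels.
#' @return A data.frame with columns `label`, `x`, `y`, `z` (unit sphere).
#' @examples
#' head(montage_1020())
#' @export
montage_1020 <- function(labels = NULL) {
  nm <- function(p, q) {
    v <- (p + q) / 2
    v / sqrt(sum(v^2))
  }
  a <- list(
    Fpz = c(0, 1, 0),
    Fp1 = c(-0.309, 0.951, 0),
    Fp2 = c(0.309, 0.951, 0),
    F7  = c(-0.809, 0.588, 0),
    F8  = c(0.809, 0.588, 0),
    T7  = c(-1, 0, 0),
    T8  = c(1, 0, 0),
    P7  = c(-0.809, -0.588, 0),
    P8  = c(0.809, -0.588, 0),
    O1  = c(-0.309, -0.951, 0),
    O2  = c(0.309, -0.951, 0),
    Oz  = c(0, -1, 0),
    Fz  = c(0, 0.7071, 0.7071),
    Cz  = c(0, 0, 1),
    Pz  = c(0, -0.7071, 0.7071),
    C3  = c(-0.7071, 0, 0.7071),
    C4  = c(0.7071, 0, 0.7071),
    F3  = c(-0.5450, 0.6731, 0.5000),
    F4  = c(0.5450, 0.6731, 0.5000),
    P3  = c(-0.5450, -0.6731, 0.5000),
    P4  = c(0.5450, -0.6731, 0.5000)
  )
  # 10% rows by spherical interpolation between the 10-20 anchors
  a$F5 <- nm(a$F3, a$F7); a$F6 <- nm(a$F4, a$F8)
  a$F1 <- nm(a$F3, a$Fz); a$F2 <- nm(a$F4, a$Fz)
  a$C5 <- nm(a$C3, a$T7); a$C6 <- nm(a$C4, a$T8)
  a$C1 <- nm(a$C3, a$Cz); a$C2 <- nm(a$C4, a$Cz)
  a$P5 <- nm(a$P3, a$P7); a$P6 <- nm(a$P4, a$P8)
  a$P1 <- nm(a$P3, a$Pz); a$P2 <- nm(a$P4, a$Pz)
  a$FC5 <- nm(a$F5, a$C5); a$FC6 <- nm(a$F6, a$C6)
  a$FC1 <- nm(a$F1, a$C1); a$FC2 <- nm(a$F2, a$C2)
  a$CP5 <- nm(a$C5, a$P5); a$CP6 <- nm(a$C6, a$P6)
  a$CP1 <- nm(a$C1, a$P1); a$CP2 <- nm(a$C2, a$P2)

  tab <- do.call(rbind, a)
  out <- data.frame(label = rownames(tab), x = tab[, 1], y = tab[, 2],
                    z = tab[, 3], row.names = NULL,
                    stringsAsFactors = FALSE)
  if (is.null(labels)) {
    labels <- c("Fp1", "Fp2", "F3", "F4", "Fz",
                "FC5", "FC1", "FC2", "FC6", "Cz",
                "CP5", "CP1", "CP2", "CP6",
                "P3", "P4", "Pz", "O1", "O2")
  }
  missing <- setdiff(labels, out$label)
  if (length(missing)) {
    stop("unknown channel label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out[match(labels, out$label), , drop = FALSE]
}

#' Electrode pools for regional analysis
#'
#' The four analysis pools: frontal-left (FL), frontal-right (FR),
#' parietal-left (PL) and parietal-right (PR), each an ordered triplet of
#' 10-10 channels. Border channels between the regions are not pooled.
#'
#' @return Named list of character triplets.
#' @examples
#' pool_spec()$FL
#' @export
pool_spec <- function() {
  list(FL = c("FC5", "F3", "FC1"),
       FR = c("FC6", "F4", "FC2"),
       PL = c("CP5", "P3", "CP1"),
       PR = c("CP6", "P4", "CP2"))
}

#' Pool couplings considered for coherence analysis
#'
#' @return Character matrix with one row per pool pair (FL-FR, FL-PL, FL-PR,
#'   FR-PL, FR-PR, PL-PR).
#' @export
pool_couplings <- function() {
  m <- rbind(c("FL", "FR"), c("FL", "PL"), c("FL", "PR"),
             c("FR", "PL"), c("FR", "PR"), c("PL", "PR"))
  colnames(m) <- c("a", "b")
  m
}

#' All channels referenced by the analysis pools
#' @return Character vector of the 12 pooled channels.
#' @export
pool_channels <- function() unname(unlist(pool_spec()))

check_pools_in_montage <- function(labels) {
  missing <- setdiff(pool_channels(), labels)
  if (length(missing)) {
    stop("montage is missing pooled analysis channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
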