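# Dose-volume histogram, homogeneity index, flux uniformity index.

#' Dose-volume histogram metrics
#'
#' Builds the cumulative DVH of a structure and the percentile doses D_x,
#' defined so that at least x% of the structure volume receives a dose of
#' D_x or more. Percentiles are computed by linear interpolation between
#' the sorted voxel doses (`stats::quantile()` type 7 at probability
#' `1 - x/100`), and the homogeneity index is `HI = (D2 - D98) / D50`
#' (0 for a perfectly uniform dose).
#'
#' @param dose Numeric vector of voxel doses (Gy-eq), or a dose array.
#' @param mask Optional logical array selecting the structure's voxels when
#'   `dose` is an array.
#' @param curve_points Number of dose levels in the exported cumulative
#'   curve (default 200).
#' @return An object of class `dvh_metrics`: `D2`, `D5`, `D50`, `D98`,
#'   `Dmax`, `Dmin`, `Dmean`, `HI`, `n_voxels`, and `curve` (data frame
#'   `dose_gy_eq`, `fractional_volume` = fraction of volume receiving at
#'   least that dose, non-increasing from 1 to 0).
#' @examples
#' m <- dvh(c(10, 30))
#' m$D50   # 20 by linear interpolation
#' @export
dvh <- function(dose, mask = NULL, curve_points = 200) {
  if (!is.null(mask)) {
    if (!identical(dim(dose), dim(mask))) {
      stop("dose and mask dimensions do not match")
    }
    dose <- dose[mask]
  }
  dose <- as.numeric(dose)
  if (length(dose) == 0) stop("structure mask is empty")
  if (any(!is.finite(dose))) stop("dose contains non-finite values")
  Dx <- function(x) unname(stats::quantile(dose, probs = 1 - x / 100,
                                           type = 7, names = FALSE))
  D2 <- Dx(2); D5 <- Dx(5); D50 <- Dx(50); D98 <- Dx(98)
  levels <- seq(0, max(dose), length.out = curve_points)
  frac <- vapply(levels, function(d) mean(dose >= d), numeric(1))
  structure(list(D2 = D2, D5 = D5, D50 = D50, D98 = D98,
                 Dmax = max(dose), Dmin = min(dose), Dmean = mean(dose),
                 HI = if (D50 > 0) homogeneity_index(D2, D98, D50) else NA_real_,
                 n_voxels = length(dose),
                 curve = data.frame(dose_gy_eq = levels,
                                    fractional_volume = frac)),
            class = "dvh_metrics")
}

#' @export
print.dvh_metrics <- function(x, ...) {
  cat(sprintf("DVH over %d voxels: Dmin %.3g, D98 %.3g, D50 %.3g, D2 %.3g, Dmax %.3g Gy-eq; HI %.3g\n",
              x$n_voxels, x$Dmin, x$D98, x$D50, x$D2, x$Dmax, x$HI))
  invisible(x)
}

#' Homogeneity index
#'
#' `HI = (D2 - D98) / D50`, where D_x is the dose received by at least x%
#' of the tumor volume. The ideal value is 0.
#'
#' @param D2,D98,D50 Percentile doses (Gy-eq); `D50` must be positive.
#' @return The homogeneity index (dimensionless).
#' @examples
#' homogeneity_index(30, 10, 20)   # 1
#' @export
homogeneity_index <- function(D2, D98, D50) {
  if (any(D50 <= 0)) stop("D50 must be positive")
  (D2 - D98) / D50
}

#' Thermal neutron flux uniformity index
#'
#' Mean absolute percent deviation of the flux from its mean over the
#' seven evaluation points spanning the central 10-cm-diameter region:
#' `u = sum_i |100 (1 - phi_i / phi_av)| / 7` with
#' `phi_av = mean(phi_1..phi_7)`. u is 0 iff all fluxes are equal and is
#' invariant under uniform rescaling.
#'
#' @param phi Positive fluxes at the evaluation points: either exactly the
#'   7 uniformity-set values, or all 10 layout values (points 1-7 are then
#'   used).
#' @return The uniformity index u (percent scale).
#' @examples
#' uniformity_index(c(1, 1, 1, 1, 1, 1, 2))   # 150/7
#' @export
uniformity_index <- function(phi) {
  if (length(phi) == 10) phi <- phi[1:7]
  if (length(phi) != 7) {
    stop("phi must hold the 7 uniformity-set fluxes (or all 10 layout points)")
  }
  if (any(!is.finite(phi)) || any(phi <= 0)) {
    stop("all fluxes must be positive")
  }
  phi_av <- mean(phi)
  sum(abs(100 * (1 - phi / phi_av))) / 7
}

#' Percent improvement of a metric
#'
#' `100 * (before - after) / before`: positive when the metric (a
#' uniformity or homogeneity index, where smaller is better) decreased.
#' The raw value is returned; the `"reported"` attribute carries the
#' nearest-integer percentage used in summaries.
#'
#' @param before,after Metric values; `before` must be positive.
#' @return Numeric raw percent improvement with attribute `reported`.
#' @examples
#' improvement_percent(0.84, 0.54)   # 35.71..., reported 36
#' @export
improvement_percent <- function(before, after) {
  if (!is.finite(before) || before <= 0) stop("'before' must be positive")
  raw <- 100 * (before - after) / before
  attr(raw, "reported") <- as.integer(round(raw))
  raw
}
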