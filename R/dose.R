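# RBE/CBE-weighted equivalent dose, field combination and prescription.
#
# The BNCT absorbed dose is the sum of four components: the boron dose from
# 10B(n,alpha)7Li capture of thermal neutrons (proportional to thermal flux
# and the tissue boron concentration), the nitrogen dose from 14N(n,p)
# capture (proportional to thermal flux), the hydrogen recoil dose from
# fast/epithermal neutrons, and the gamma dose. Each component is weighted
# by its RBE (hydrogen 2.4, nitrogen 2.9, gamma 1.0) or, for boron, by the
# compound biological effectiveness (CBE: tumor 3.8, skin 2.5, brain 1.34)
# to give the equivalent dose in Gy-eq.

#' Tissue radiobiology model
#'
#' Boron concentrations are expressed through the blood boron concentration
#' (ppm) and per-tissue concentration ratios: T/B for tumor (default 3.5),
#' S/B for skin and a separate brain/blood ratio (both default 1.0).
#'
#' The kerma coefficients convert flux components to absorbed dose rate
#' (Gy per minute per unit flux); they are engine parameters with defaults
#' of plausible relative magnitude (boron dominating the tumor dose), not
#' measured nuclear data.
#'
#' @param blood_boron_ppm Blood boron concentration in ppm (default 24).
#' @param tumor_blood_ratio Tumor-to-blood boron ratio, T/B (default 3.5).
#' @param skin_blood_ratio Skin-to-blood boron ratio, S/B (default 1.0).
#' @param brain_blood_ratio Brain-to-blood boron ratio (default 1.0).
#' @param rbe_hydrogen,rbe_nitrogen,rbe_gamma RBE weights (2.4, 2.9, 1.0).
#' @param cbe_boron Named CBE weights of the boron component for tumor,
#'   skin and brain (3.8, 2.5, 1.34).
#' @param kerma Flux-to-absorbed-dose-rate coefficients: `boron_per_ppm`
#'   (per ppm of tissue boron, times thermal flux), `nitrogen` (times
#'   thermal flux), `hydrogen` (times fast flux), `gamma` (times the gamma
#'   field).
#' @return An object of class `tissue_model`.
#' @export
tissue_model <- function(blood_boron_ppm = 24,
                         tumor_blood_ratio = 3.5,
                         skin_blood_ratio = 1.0,
                         brain_blood_ratio = 1.0,
                         rbe_hydrogen = 2.4,
                         rbe_nitrogen = 2.9,
                         rbe_gamma = 1.0,
                         cbe_boron = c(tumor = 3.8, skin = 2.5, brain = 1.34),
                         kerma = list(boron_per_ppm = 8e-4,
                                      nitrogen = 6e-3,
                                      hydrogen = 8e-3,
                                      gamma = 5e-2)) {
  ratios <- c(blood_boron_ppm, tumor_blood_ratio, skin_blood_ratio,
              brain_blood_ratio)
  if (any(!is.finite(ratios)) || any(ratios <= 0)) {
    stop("boron concentration and all tissue/blood ratios must be > 0")
  }
  if (!all(c("tumor", "skin", "brain") %in% names(cbe_boron))) {
    stop("cbe_boron must name tumor, skin and brain weights")
  }
  if (any(unlist(kerma) < 0)) stop("kerma coefficients must be >= 0")
  structure(list(blood_boron_ppm = blood_boron_ppm,
                 tumor_blood_ratio = tumor_blood_ratio,
                 skin_blood_ratio = skin_blood_ratio,
                 brain_blood_ratio = brain_blood_ratio,
                 rbe_hydrogen = rbe_hydrogen,
                 rbe_nitrogen = rbe_nitrogen,
                 rbe_gamma = rbe_gamma,
                 cbe_boron = cbe_boron,
                 kerma = kerma),
            class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat("Tissue radiobiology model\n")
  cat("  blood boron :", x$blood_boron_ppm, "ppm;  T/B =",
      x$tumor_blood_ratio, ", S/B =", x$skin_blood_ratio,
      ", brain/B =", x$brain_blood_ratio, "\n")
  cat("  RBE         : H", x$rbe_hydrogen, ", N", x$rbe_nitrogen,
      ", gamma", x$rbe_gamma, "\n")
  cat("  CBE (boron) :", paste(names(x$cbe_boron), x$cbe_boron,
                               sep = " ", collapse = ", "), "\n")
  invisible(x)
}

# per-tissue boron concentration ratio and CBE, indexed by tissue code + 1
.tissue_coeffs <- function(tissues) {
  # order: air, skin, brain, tumor (codes 0:3)
  list(
    conc_ratio = c(0, tissues$skin_blood_ratio, tissues$brain_blood_ratio,
                   tissues$tumor_blood_ratio),
    cbe = c(0, tissues$cbe_boron[["skin"]], tissues$cbe_boron[["brain"]],
            tissues$cbe_boron[["tumor"]]),
    alive = c(0, 1, 1, 1)
  )
}

#' Combine weighted dose components for one tissue
#'
#' Applies the RBE/CBE weighting to unweighted component absorbed doses
#' (or dose rates): `cbe_boron[tissue] * boron + rbe_N * nitrogen +
#' rbe_H * hydrogen + rbe_gamma * gamma`.
#'
#' @param boron,nitrogen,hydrogen,gamma Component absorbed doses (Gy),
#'   vectorized.
#' @param tissue `"tumor"`, `"skin"` or `"brain"`.
#' @param tissues A [tissue_model()].
#' @return Equivalent dose (Gy-eq).
#' @examples
#' weight_components(1, 1, 1, 1, "tumor")   # 3.8 + 2.9 + 2.4 + 1.0 = 10.1
#' @export
weight_components <- function(boron, nitrogen, hydrogen, gamma, tissue,
                              tissues = tissue_model()) {
  stopifnot(inherits(tissues, "tissue_model"))
  if (!tissue %in% names(tissues$cbe_boron)) {
    stop("unknown tissue label: ", tissue)
  }
  tissues$cbe_boron[[tissue]] * boron + tissues$rbe_nitrogen * nitrogen +
    tissues$rbe_hydrogen * hydrogen + tissues$rbe_gamma * gamma
}

#' Equivalent dose-rate map from a flux map
#'
#' Converts flux components to weighted dose-rate components per voxel,
#' using each voxel's own tissue label for the boron concentration and CBE
#' weight. Air voxels receive zero dose. The stored components are already
#' weighted, so they sum to the total at every voxel.
#'
#' @param flux A [flux_map()] object.
#' @param tissues A [tissue_model()].
#' @param phantom The [make_head_phantom()] object the flux was computed on.
#' @return An object of class `dose_rate_map`: `total` (Gy-eq/min per unit
#'   beam intensity) and weighted `components` (boron, nitrogen, hydrogen,
#'   gamma arrays).
#' @export
equivalent_dose_rate <- function(flux, tissues, phantom) {
  stopifnot(inherits(flux, "flux_map"), inherits(tissues, "tissue_model"),
            inherits(phantom, "phantom"))
  if (!identical(unname(flux$dim), unname(phantom$dim))) {
    stop("flux map and phantom grids do not match")
  }
  codes <- as.vector(phantom$tissue)
  if (any(!codes %in% 0:3)) stop("phantom contains an unknown tissue label")
  cf <- .tissue_coeffs(tissues)
  idx <- codes + 1L
  k <- tissues$kerma
  dims <- unname(phantom$dim)

  boron_un <- k$boron_per_ppm * tissues$blood_boron_ppm *
    cf$conc_ratio[idx] * as.vector(flux$thermal)
  comp <- list(
    boron = cf$cbe[idx] * boron_un,  # zero in air (cbe = conc_ratio = 0)
    nitrogen = tissues$rbe_nitrogen * k$nitrogen * cf$alive[idx] *
      as.vector(flux$thermal),
    hydrogen = tissues$rbe_hydrogen * k$hydrogen * cf$alive[idx] *
      as.vector(flux$fast),
    gamma = tissues$rbe_gamma * k$gamma * cf$alive[idx] *
      as.vector(flux$gamma_rate)
  )
  total <- comp$boron + comp$nitrogen + comp$hydrogen + comp$gamma
  comp <- lapply(comp, array, dim = dims)
  structure(list(total = array(total, dim = dims), components = comp,
                 dim = dims, voxel_size = phantom$voxel_size,
                 units = "Gy-eq/min per unit beam intensity"),
            class = "dose_rate_map")
}

#' Combine two fields at an irradiation time ratio
#'
#' The intensity-modulated field delivered by irradiating field A and
#' field B for times in ratio 1:r is the time-weighted mean
#' `(F_A + r * F_B) / (1 + r)`; with r = 5 this is the combination
#' `(F_A + 5 F_B) / 6`.
#'
#' @param field_a,field_b Numeric vectors/arrays, [flux_map()]s, or
#'   [equivalent_dose_rate()] maps on the same grid.
#' @param ratio Integer r of the time ratio 1:r; the standard planning grid
#'   is r in 2, 3, 4, 5.
#' @param allow_any Allow any integer ratio >= 1 (default `FALSE`:
#'   restricted to the standard grid).
#' @return The combined object, same class as the inputs.
#' @export
combine_fields <- function(field_a, field_b, ratio, allow_any = FALSE) {
  if (!is.numeric(ratio) || length(ratio) != 1 ||
      abs(ratio - round(ratio)) > 1e-9) {
    stop("ratio must be a single integer (time ratio 1:r)")
  }
  r <- round(ratio)
  if (!allow_any && !r %in% 2:5) {
    stop("ratio must be one of 2, 3, 4, 5 (use allow_any = TRUE to override)")
  }
  if (allow_any && r < 1) stop("ratio must be >= 1")
  mix <- function(a, b) (a + r * b) / (1 + r)
  if (is.numeric(field_a) && is.numeric(field_b)) {
    if (!identical(dim(field_a), dim(field_b)) ||
        length(field_a) != length(field_b)) {
      stop("field grids do not match")
    }
    return(mix(field_a, field_b))
  }
  if (inherits(field_a, "flux_map") && inherits(field_b, "flux_map")) {
    if (!identical(unname(field_a$dim), unname(field_b$dim))) {
      stop("field grids do not match")
    }
    out <- field_a
    for (nm in c("thermal", "fast", "gamma_rate")) {
      out[[nm]] <- mix(field_a[[nm]], field_b[[nm]])
    }
    out$provenance <- list(
      pattern_id = sprintf("(%s + %d x %s)/%d",
                           field_a$provenance$pattern_id, r,
                           field_b$provenance$pattern_id, 1 + r),
      beam = field_a$provenance$beam)
    return(out)
  }
  if (inherits(field_a, "dose_rate_map") && inherits(field_b, "dose_rate_map")) {
    if (!identical(unname(field_a$dim), unname(field_b$dim))) {
      stop("field grids do not match")
    }
    out <- field_a
    out$total <- mix(field_a$total, field_b$total)
    out$components <- Map(mix, field_a$components, field_b$components)
    return(out)
  }
  stop("field_a and field_b must both be numeric, flux_map or dose_rate_map")
}

#' Prescribe the irradiation time from normal tissue limits
#'
#' The deliverable time is set by the tolerance dose of the limiting
#' normal tissue: skin 12 Gy-eq or brain 15 Gy-eq, whichever is reached
#' first. If both limits are reached simultaneously the plan is labeled
#' skin-limited (documented tie-break).
#'
#' @param rate_skin_max Maximum skin equivalent dose rate (Gy-eq/min).
#' @param rate_brain_max Maximum brain equivalent dose rate (Gy-eq/min).
#' @param skin_limit,brain_limit Tolerance doses (Gy-eq), defaults 12, 15.
#' @return An object of class `prescription`: `time_min`,
#'   `limiting_tissue`, and the limits.
#' @export
prescribe <- function(rate_skin_max, rate_brain_max,
                      skin_limit = 12, brain_limit = 15) {
  if (rate_skin_max < 0 || rate_brain_max < 0) {
    stop("dose rates must be non-negative")
  }
  if (rate_skin_max == 0 && rate_brain_max == 0) {
    stop("both normal tissue dose rates are zero: no finite prescription")
  }
  t_skin <- if (rate_skin_max > 0) skin_limit / rate_skin_max else Inf
  t_brain <- if (rate_brain_max > 0) brain_limit / rate_brain_max else Inf
  limiting <- if (t_skin <= t_brain) "skin" else "brain"
  structure(list(time_min = min(t_skin, t_brain),
                 limiting_tissue = limiting,
                 skin_limit = skin_limit, brain_limit = brain_limit,
                 rate_skin_max = rate_skin_max,
                 rate_brain_max = rate_brain_max),
            class = "prescription")
}

#' @export
print.prescription <- function(x, ...) {
  cat(sprintf("Prescription: %.2f min, %s-limited (skin %.3g/%g, brain %.3g/%g Gy-eq)\n",
              x$time_min, x$limiting_tissue,
              x$rate_skin_max * x$time_min, x$skin_limit,
              x$rate_brain_max * x$time_min, x$brain_limit))
  invisible(x)
}

#' Full dose maps and prescription for a two-field plan
#'
#' Computes the equivalent dose-rate maps of both fields, combines them at
#' the time ratio 1:`ratio`, prescribes the total time so the limiting
#' normal tissue saturates its tolerance dose, and returns absolute dose
#' maps. With `pattern_b = NULL` an IF-A-only (single field) plan is
#' produced.
#'
#' @param pattern_a,pattern_b [modulator_pattern()]s for the two fields;
#'   `pattern_b = NULL` for a single-field plan.
#' @param ratio Time ratio integer r (1:r); ignored for single-field plans.
#' @param phantom A [make_head_phantom()] object.
#' @param beam A [beam_model()].
#' @param tissues A [tissue_model()].
#' @param grid An [build_aperture_grid()] object.
#' @return An object of class `bnct_plan`: the prescription, total time and
#'   per-field times (min), the absolute equivalent dose array `dose`
#'   (Gy-eq), per-tissue dose maxima, tumor DVH metrics and the candidate
#'   identifiers.
#' @export
plan_doses <- function(pattern_a, pattern_b = NULL, ratio = NULL, phantom,
                       beam, tissues, grid = build_aperture_grid()) {
  stopifnot(inherits(pattern_a, "modulator_pattern"))
  rate_a <- equivalent_dose_rate(
    flux_map(aperture_emission(beam, pattern_a, grid), phantom, beam),
    tissues, phantom)
  if (is.null(pattern_b)) {
    combined <- rate_a
    r <- NA_integer_
  } else {
    stopifnot(inherits(pattern_b, "modulator_pattern"))
    rate_b <- equivalent_dose_rate(
      flux_map(aperture_emission(beam, pattern_b, grid), phantom, beam),
      tissues, phantom)
    combined <- combine_fields(rate_a, rate_b, ratio, allow_any = TRUE)
    r <- round(ratio)
  }
  skin <- tissue_mask(phantom, "skin")
  brain <- tissue_mask(phantom, "brain")
  tumor <- tissue_mask(phantom, "tumor")
  rx <- prescribe(max(combined$total[skin]), max(combined$total[brain]))
  T_total <- rx$time_min
  dose <- combined$total * T_total
  dvh_t <- dvh(dose[tumor])
  structure(list(
    pattern_a = pattern_a$id,
    pattern_b = if (is.null(pattern_b)) NA_character_ else pattern_b$id,
    ratio = r,
    prescription = rx,
    time_min = T_total,
    time_a_min = if (is.na(r)) T_total else T_total / (1 + r),
    time_b_min = if (is.na(r)) 0 else T_total * r / (1 + r),
    dose = dose,
    dose_rate = combined,
    skin_max = max(dose[skin]),
    brain_max = max(dose[brain]),
    d_min_tumor = min(dose[tumor]),
    tumor_dvh = dvh_t,
    HI = dvh_t$HI
  ), class = "bnct_plan")
}

#' @export
print.bnct_plan <- function(x, ...) {
  cat("BNCT plan:", x$pattern_a,
      if (!is.na(x$pattern_b)) paste0("+ ", x$pattern_b, " (1:", x$ratio, ")")
      else "(single field)", "\n")
  cat(sprintf("  time %.1f min (%s-limited);  skin max %.3f, brain max %.3f Gy-eq\n",
              x$time_min, x$prescription$limiting_tissue, x$skin_max,
              x$brain_max))
  cat(sprintf("  tumor: D_min %.2f Gy-eq, HI %.3f (D2 %.2f / D50 %.2f / D98 %.2f)\n",
              x$d_min_tumor, x$HI, x$tumor_dvh$D2, x$tumor_dvh$D50,
              x$tumor_dvh$D98))
  invisible(x)
}
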