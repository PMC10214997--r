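# Kernel-superposition transport engine.
#
# The engine is a deterministic stand-in for Monte Carlo neutron transport:
# each aperture cell emits thermal neutrons, residual epithermal ("fast")
# neutrons and gammas in proportion to the incident epithermal beam at its
# radius and its modulator material stack, and each component propagates
# into the phantom with a separable kernel -- a Gaussian lateral spread
# about the cell center times a depth profile with a surface-buildup factor:
#
#   flux(x, y, z) = sum_cells em_c * exp(-d_c(x,y)^2 / (2 sigma^2))
#                              * (1 - beta exp(-z / z0)) * exp(-z / lambda)
#
# The model is linear in the emissions, so all pattern fluxes are sums of
# cached single-cell kernels. Engine coefficients are calibration artifacts
# chosen to reproduce the qualitative flux shapes of the two fields (IF-A
# center-peaked with roughly half the flux 5 cm off-axis; IF-B edge-peaked);
# they are not measured nuclear data.

#' Construct the parameterized beam + transport model
#'
#' @param epithermal_intensity Overall beam intensity scale (flux per unit
#'   time in arbitrary units; doses scale linearly with it).
#' @param profile_sigma_cm Width (cm) of the Gaussian radial intensity
#'   profile of the beam on the aperture plane; the profile is monotone
#'   non-increasing in radius.
#' @param gamma_fraction Gamma emission per unit incident epithermal
#'   intensity (dimensionless).
#' @param materials Per-material transfer coefficients (1/cm): PE converts
#'   epithermal to thermal neutrons with `thermal_yield_per_cm` and
#'   self-attenuates (`self_attenuation`, `fast_attenuation`,
#'   `gamma_attenuation`); LiF-PE additionally absorbs thermal neutrons
#'   (`thermal_attenuation`) through its 6Li content.
#' @param kernels Per-component tissue kernels: lateral Gaussian spread
#'   `sigma_cm`, depth attenuation length `lambda_cm`, and surface buildup
#'   (`buildup_beta` in \[0, 1), `buildup_z0_cm`).
#' @return An object of class `beam_model`.
#' @export
beam_model <- function(epithermal_intensity = 0.45,
                       profile_sigma_cm = 4.25,
                       gamma_fraction = 0.05,
                       materials = list(
                         pe = list(thermal_yield_per_cm = 0.6,
                                   self_attenuation = 0.10,
                                   fast_attenuation = 0.50,
                                   gamma_attenuation = 0.06),
                         lif_pe = list(thermal_attenuation = 1.4,
                                       fast_attenuation = 0.60,
                                       gamma_attenuation = 0.06)),
                       kernels = list(
                         thermal = list(sigma_cm = 1.4, lambda_cm = 3.0,
                                        buildup_beta = 0.65, buildup_z0_cm = 1.2),
                         fast = list(sigma_cm = 1.0, lambda_cm = 6.0,
                                     buildup_beta = 0, buildup_z0_cm = 1.0),
                         gamma = list(sigma_cm = 3.0, lambda_cm = 15.0,
                                      buildup_beta = 0, buildup_z0_cm = 1.0))) {
  atten <- c(materials$pe$self_attenuation, materials$pe$fast_attenuation,
             materials$pe$gamma_attenuation, materials$lif_pe$thermal_attenuation,
             materials$lif_pe$fast_attenuation, materials$lif_pe$gamma_attenuation)
  if (any(!is.finite(atten)) || any(atten <= 0)) {
    stop("all material attenuation coefficients must be positive")
  }
  if (epithermal_intensity < 0) stop("epithermal_intensity must be >= 0")
  if (profile_sigma_cm <= 0) stop("profile_sigma_cm must be > 0")
  for (k in kernels) {
    if (k$sigma_cm <= 0 || k$lambda_cm <= 0) {
      stop("kernel sigma_cm and lambda_cm must be > 0")
    }
    if (k$buildup_beta < 0 || k$buildup_beta >= 1) {
      stop("buildup_beta must lie in [0, 1)")
    }
  }
  structure(list(epithermal_intensity = epithermal_intensity,
                 profile_sigma_cm = profile_sigma_cm,
                 gamma_fraction = gamma_fraction,
                 materials = materials, kernels = kernels),
            class = "beam_model")
}

#' @export
print.beam_model <- function(x, ...) {
  cat("Kernel transport beam model\n")
  cat("  intensity scale :", x$epithermal_intensity, "\n")
  cat("  radial profile  : Gaussian, sigma =", x$profile_sigma_cm, "cm\n")
  for (nm in names(x$kernels)) {
    k <- x$kernels[[nm]]
    cat(sprintf("  %-7s kernel  : sigma %.2f cm, lambda %.2f cm, buildup %.2f\n",
                nm, k$sigma_cm, k$lambda_cm, k$buildup_beta))
  }
  invisible(x)
}

#' Radial beam intensity profile on the aperture plane
#'
#' @param beam A [beam_model()].
#' @param r Radius (cm), vectorized.
#' @return Relative intensity, monotone non-increasing in `r` with value 1
#'   on the axis.
#' @export
radial_profile <- function(beam, r) {
  stopifnot(inherits(beam, "beam_model"))
  exp(-r^2 / (2 * beam$profile_sigma_cm^2))
}

#' Tessellate the aperture into emitting cells
#'
#' The 36 central 1x1 cells plus the PE annulus between the central block
#' and the disk edge on the same 1-cm lattice, with partial cells weighted
#' by the fraction of their area covered by the disk (midpoint subsampling).
#'
#' @param grid An [build_aperture_grid()] object.
#' @return Data frame of cells: `x`, `y` (center, cm), `area` (cm^2),
#'   `central` flag, `core` flag, `site` (peripheral number or `NA`).
#' @export
aperture_cells <- function(grid) {
  stopifnot(inherits(grid, "aperture_grid"))
  central <- data.frame(x = grid$cells$x, y = grid$cells$y, area = 1,
                        central = TRUE, core = grid$cells$core,
                        site = grid$cells$site)
  R <- grid$disk_diameter / 2
  half <- ceiling(R) - 0.5
  ctr <- seq(-half, half, by = 1)
  ann <- expand.grid(x = ctr, y = ctr)
  in_block <- abs(ann$x) < 3 & abs(ann$y) < 3
  ann <- ann[!in_block, , drop = FALSE]
  sub <- seq(-0.5 + 1 / 22, 0.5 - 1 / 22, length.out = 11)
  off <- expand.grid(dx = sub, dy = sub)
  cover <- vapply(seq_len(nrow(ann)), function(i) {
    mean((ann$x[i] + off$dx)^2 + (ann$y[i] + off$dy)^2 <= R^2)
  }, numeric(1))
  ann <- ann[cover > 0, , drop = FALSE]
  annulus <- data.frame(x = ann$x, y = ann$y, area = cover[cover > 0],
                        central = FALSE, core = FALSE, site = NA_integer_)
  out <- rbind(central, annulus)
  rownames(out) <- NULL
  out
}

# material transfer: emissions of one cell per unit incident intensity
.cell_transfer <- function(beam, material, thickness) {
  pe <- beam$materials$pe
  lif <- beam$materials$lif_pe
  t <- thickness
  switch(material,
    "PE" = c(
      thermal = pe$thermal_yield_per_cm * t * exp(-pe$self_attenuation * t),
      fast = exp(-pe$fast_attenuation * t),
      gamma = beam$gamma_fraction * exp(-pe$gamma_attenuation * t)),
    "LiF-PE" = c(
      thermal = pe$thermal_yield_per_cm * t * exp(-pe$self_attenuation * t) *
        exp(-lif$thermal_attenuation * t),
      fast = exp(-lif$fast_attenuation * t),
      gamma = beam$gamma_fraction * exp(-lif$gamma_attenuation * t)),
    stop("unknown modulator material: ", material)
  )
}

#' Per-cell emissions of a beam through a modulator pattern
#'
#' Each cell's emission is the radial beam profile at its center times its
#' area times the material transfer of its block stack: PE converts
#' epithermal neutrons to thermal with the stated yield per cm and
#' attenuates; LiF-PE attenuates the thermal yield exponentially with its
#' thickness. Annulus cells are PE at the IF-A disk thickness.
#'
#' @param beam A [beam_model()].
#' @param pattern A [modulator_pattern()].
#' @param grid An [build_aperture_grid()] object.
#' @return An object of class `cell_emission`: the [aperture_cells()] table
#'   with `material`, `thickness`, and `thermal`, `fast`, `gamma` emission
#'   columns (per unit time).
#' @export
aperture_emission <- function(beam, pattern, grid = build_aperture_grid()) {
  stopifnot(inherits(beam, "beam_model"),
            inherits(pattern, "modulator_pattern"))
  cells <- aperture_cells(grid)
  is_lif <- cells$central &
    ((cells$core & pattern$core_lif) |
       (!cells$core & cells$site %in% pattern$lif_sites))
  cells$material <- ifelse(is_lif, "LiF-PE", "PE")
  cells$thickness <- ifelse(is_lif, pattern$lif_thickness, pattern$pe_thickness)

  inc <- beam$epithermal_intensity *
    radial_profile(beam, sqrt(cells$x^2 + cells$y^2)) * cells$area
  tr <- t(vapply(seq_len(nrow(cells)),
                 function(i) .cell_transfer(beam, cells$material[i],
                                            cells$thickness[i]),
                 numeric(3)))
  cells$thermal <- inc * tr[, "thermal"]
  cells$fast <- inc * tr[, "fast"]
  cells$gamma <- inc * tr[, "gamma"]
  structure(cells, class = c("cell_emission", "data.frame"),
            pattern_id = pattern$id,
            disk_diameter = grid$disk_diameter)
}

# depth profile of one kernel component at depths z
.depth_profile <- function(kernel, z) {
  (1 - kernel$buildup_beta * exp(-z / kernel$buildup_z0_cm)) *
    exp(-z / kernel$lambda_cm)
}

# lateral kernel matrix: n_lateral_voxels x n_cells Gaussian weights
.lateral_kernel_matrix <- function(kernel, cells, phantom) {
  xy <- expand.grid(x = phantom$x, y = phantom$y)  # x fastest: matches array
  d2 <- outer(xy$x, cells$x, "-")^2 + outer(xy$y, cells$y, "-")^2
  exp(-d2 / (2 * kernel$sigma_cm^2))
}

#' Flux map by kernel superposition
#'
#' Propagates per-cell emissions into the phantom. For each component the
#' lateral Gaussian sum and the depth profile are separable, so the map is
#' an outer product of a lateral field (one kernel pass over all cells) and
#' a depth vector. The map is linear in the emissions; flux is zero in air
#' voxels.
#'
#' @param emission An [aperture_emission()] object.
#' @param phantom A [make_head_phantom()] object.
#' @param beam The [beam_model()] that produced `emission`.
#' @return An object of class `flux_map`: 3-D arrays `thermal`, `fast`,
#'   `gamma_rate` (per unit time, per unit beam intensity scale), plus grid
#'   metadata and provenance.
#' @export
flux_map <- function(emission, phantom, beam) {
  stopifnot(inherits(emission, "cell_emission"),
            inherits(phantom, "phantom"),
            inherits(beam, "beam_model"))
  dims <- unname(phantom$dim)
  air <- tissue_mask(phantom, "air")
  comps <- list(thermal = "thermal", fast = "fast", gamma_rate = "gamma")
  out <- list()
  for (nm in names(comps)) {
    col <- comps[[nm]]
    kern <- beam$kernels[[if (col == "gamma") "gamma" else col]]
    K <- .lateral_kernel_matrix(kern, emission, phantom)
    lat <- as.vector(K %*% emission[[col]])
    depth <- .depth_profile(kern, phantom$z)
    arr <- array(outer(lat, depth), dim = dims)
    arr[air] <- 0
    out[[nm]] <- arr
  }
  structure(list(thermal = out$thermal, fast = out$fast,
                 gamma_rate = out$gamma_rate,
                 voxel_size = phantom$voxel_size, dim = dims,
                 x = phantom$x, y = phantom$y, z = phantom$z,
                 provenance = list(pattern_id = attr(emission, "pattern_id"),
                                   beam = .beam_signature(beam))),
            class = "flux_map")
}

.beam_signature <- function(beam) {
  paste(format(unlist(beam, use.names = TRUE), digits = 17), collapse = ";")
}

#' @export
print.flux_map <- function(x, ...) {
  cat("Flux map (", paste(x$dim, collapse = " x "), "voxels of",
      x$voxel_size, "cm )\n")
  cat("  pattern:", x$provenance$pattern_id, "\n")
  cat(sprintf("  thermal max %.4g, fast max %.4g, gamma max %.4g\n",
              max(x$thermal), max(x$fast), max(x$gamma_rate)))
  invisible(x)
}

#' Brute-force dense-sum flux oracle
#'
#' Computes the same kernel model as [flux_map()] by looping over every
#' voxel and summing the full per-cell kernel expression directly, with no
#' separability or caching. Intended as an independent test oracle at
#' coarse resolution; it is orders of magnitude slower than [flux_map()].
#'
#' @inheritParams flux_map
#' @return A `flux_map` object.
#' @export
dense_flux_oracle <- function(emission, phantom, beam) {
  stopifnot(inherits(emission, "cell_emission"),
            inherits(phantom, "phantom"))
  dims <- unname(phantom$dim)
  air <- tissue_mask(phantom, "air")
  comp_cols <- c(thermal = "thermal", fast = "fast", gamma_rate = "gamma")
  arrs <- lapply(comp_cols, function(col) array(0, dim = dims))
  for (ix in seq_len(dims[1])) for (iy in seq_len(dims[2])) {
    d2 <- (phantom$x[ix] - emission$x)^2 + (phantom$y[iy] - emission$y)^2
    for (iz in seq_len(dims[3])) {
      z <- phantom$z[iz]
      for (nm in names(comp_cols)) {
        kern <- beam$kernels[[if (nm == "gamma_rate") "gamma" else nm]]
        val <- sum(emission[[comp_cols[[nm]]]] *
                     exp(-d2 / (2 * kern$sigma_cm^2)) *
                     (1 - kern$buildup_beta * exp(-z / kern$buildup_z0_cm)) *
                     exp(-z / kern$lambda_cm))
        arrs[[nm]][ix, iy, iz] <- val
      }
    }
  }
  for (nm in names(arrs)) arrs[[nm]][air] <- 0
  structure(c(arrs,
              list(voxel_size = phantom$voxel_size, dim = dims,
                   x = phantom$x, y = phantom$y, z = phantom$z,
                   provenance = list(pattern_id = attr(emission, "pattern_id"),
                                     beam = "dense-oracle"))),
            class = "flux_map")
}

# trilinear interpolation of a 3-D array on voxel-center coordinates,
# clamped at the grid boundary
.interp3 <- function(arr, xs, ys, zs, px, py, pz) {
  bracket <- function(grid, p) {
    n <- length(grid)
    i0 <- findInterval(p, grid, all.inside = TRUE)
    w <- (p - grid[i0]) / (grid[i0 + 1] - grid[i0])
    w <- pmin(pmax(w, 0), 1)
    list(i0 = i0, w = w)
  }
  bx <- bracket(xs, px); by <- bracket(ys, py); bz <- bracket(zs, pz)
  val <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx == 0) 1 - bx$w else bx$w
    wy <- if (dy == 0) 1 - by$w else by$w
    wz <- if (dz == 0) 1 - bz$w else bz$w
    val <- val + wx * wy * wz *
      arr[cbind(bx$i0 + dx, by$i0 + dy, bz$i0 + dz)]
  }
  val
}

#' Flux at the surface evaluation points
#'
#' Trilinear interpolation of a flux component at the layout's points on
#' the phantom surface (z = 0, clamped to the first voxel layer).
#'
#' @param map A [flux_map()] object.
#' @param layout An [make_evaluation_layout()] object.
#' @param component Which field to sample (default `"thermal"`).
#' @return Named numeric vector of length 10, ordered by point index.
#' @export
flux_at_points <- function(map, layout, component = c("thermal", "fast",
                                                      "gamma_rate")) {
  stopifnot(inherits(map, "flux_map"), inherits(layout, "evaluation_layout"))
  component <- match.arg(component)
  pts <- layout$points
  eps <- 1e-9
  if (any(pts$x < min(map$x) - eps | pts$x > max(map$x) + eps |
          pts$y < min(map$y) - eps | pts$y > max(map$y) + eps)) {
    stop("evaluation point outside the flux grid")
  }
  vals <- .interp3(map[[component]], map$x, map$y, map$z,
                   pts$x, pts$y, rep(0, nrow(pts)))
  names(vals) <- pts$index
  vals
}
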