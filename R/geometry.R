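# Collimator aperture grid and phantom geometry.
#
# Coordinate conventions (used throughout the package):
#   * beam axis = z, pointing into the phantom; z = 0 is the skin surface,
#     depth increases with z (cm)
#   * grid rows run along the anterior-posterior (AP) axis = y, with row 1
#     anterior (y > 0); grid columns run left -> right along x
#   * the left-right mirror is x -> -x, i.e. column c -> 7 - c
# All lengths are in cm; voxel indexing is 1-based with half-open voxel
# intervals and cell-center coordinates.

#' Build the collimator aperture grid
#'
#' The collimator opening is a disk (default diameter 15 cm) whose central
#' 6 x 6 cm region is divided into 36 cells of 1 x 1 cm in which intensity
#' modulator blocks (polyethylene, PE, or lithium-fluoride-loaded
#' polyethylene, LiF-PE) can be placed. The central 2 x 2 cells form the
#' *core* (always shielded in the second irradiation field); the remaining
#' 32 cells are the numbered peripheral sites.
#'
#' Peripheral sites are numbered row-major (anterior row first, left to
#' right within a row), skipping the four core cells. Under this rule the
#' *inner ring* -- the 12 cells edge- or corner-adjacent to the core -- is
#' exactly sites 8, 9, 10, 11, 14, 15, 18, 19, 22, 23, 24, 25, and the
#' *perimeter* of the central block is the remaining 20 sites.
#'
#' @param disk_diameter Collimator opening diameter in cm (default 15, the
#'   largest aperture in clinical use). Must be at least 6 so the central
#'   block fits inside the disk.
#' @return An object of class `aperture_grid`: a list with the cell table
#'   (`cells`: row, col, x, y, core flag, site number), the site index sets
#'   `inner_ring` and `perimeter`, the six left-right mirror pairs of the
#'   inner ring (`inner_pairs`), and the ten perimeter mirror pairs in
#'   cyclic order along the half-perimeter path starting at the
#'   anterior-center pair (`perimeter_pairs`).
#' @examples
#' grid <- build_aperture_grid()
#' grid$inner_ring
#' @export
build_aperture_grid <- function(disk_diameter = 15) {
  if (!is.numeric(disk_diameter) || length(disk_diameter) != 1 ||
      !is.finite(disk_diameter)) {
    stop("disk_diameter must be a single finite number (cm)")
  }
  if (disk_diameter < 6) {
    stop("disk_diameter (", disk_diameter,
         " cm) is smaller than the 6-cm central modulator block")
  }
  cell_size <- 1
  n <- 6
  cells <- expand.grid(col = seq_len(n), row = seq_len(n))
  cells <- cells[order(cells$row, cells$col), c("row", "col")]
  cells$x <- cells$col - (n + 1) / 2      # col 1 -> -2.5 (left)
  cells$y <- (n + 1) / 2 - cells$row      # row 1 -> +2.5 (anterior)
  cells$core <- cells$row %in% c(3, 4) & cells$col %in% c(3, 4)
  cells$site <- NA_integer_
  cells$site[!cells$core] <- seq_len(sum(!cells$core))
  rownames(cells) <- NULL

  # inner ring: peripheral cells within Chebyshev distance 1 of a core cell
  core_xy <- cells[cells$core, c("x", "y")]
  cheb <- vapply(seq_len(nrow(cells)), function(i) {
    min(pmax(abs(cells$x[i] - core_xy$x), abs(cells$y[i] - core_xy$y)))
  }, numeric(1))
  inner_ring <- sort(cells$site[!cells$core & cheb <= 1 + 1e-9])
  perimeter <- sort(setdiff(cells$site[!cells$core], inner_ring))

  mirror_site <- function(s) {
    i <- match(s, cells$site)
    m <- cells$site[cells$row == cells$row[i] & cells$col == 7 - cells$col[i]]
    m
  }
  pair_up <- function(sites) {
    pairs <- lapply(sites, function(s) sort(c(s, mirror_site(s))))
    unique(pairs)
  }
  inner_pairs <- pair_up(inner_ring)
  # order inner pairs by their smaller member for a stable enumeration order
  inner_pairs <- inner_pairs[order(vapply(inner_pairs, min, numeric(1)))]

  # perimeter pairs in cyclic order along the half-perimeter: anterior-center
  # pair first, then sweeping through the left side to the posterior-center
  # pair.  The representative of a pair is its left (x < 0) cell; the angle
  # from the anterior direction orders the sweep.
  per_pairs <- pair_up(perimeter)
  rep_angle <- vapply(per_pairs, function(p) {
    i <- match(p, cells$site)
    xs <- cells$x[i]; ys <- cells$y[i]
    k <- which.min(xs)
    atan2(-xs[k], ys[k])
  }, numeric(1))
  perimeter_pairs <- per_pairs[order(rep_angle)]

  structure(list(
    disk_diameter = disk_diameter,
    cell_size = cell_size,
    n_central = n * n,
    cells = cells,
    inner_ring = inner_ring,
    perimeter = perimeter,
    inner_pairs = inner_pairs,
    perimeter_pairs = perimeter_pairs
  ), class = "aperture_grid")
}

#' @export
print.aperture_grid <- function(x, ...) {
  cat("Collimator aperture grid\n")
  cat("  disk diameter :", x$disk_diameter, "cm\n")
  cat("  central block : 6 x 6 cells of", x$cell_size, "cm (4 core + 32 sites)\n")
  cat("  inner ring    :", paste(x$inner_ring, collapse = ", "), "\n")
  cat("  perimeter     :", paste(x$perimeter, collapse = ", "), "\n")
  invisible(x)
}

#' Mirror a set of peripheral sites left-right
#'
#' Applies the left-right mirror of the aperture frame (column `c -> 7 - c`)
#' to a set of peripheral site numbers.
#'
#' @param grid An [build_aperture_grid()] object.
#' @param sites Integer vector of peripheral site numbers (1-32).
#' @return The mirrored site numbers, sorted.
#' @export
mirror_sites <- function(grid, sites) {
  stopifnot(inherits(grid, "aperture_grid"))
  if (length(sites) == 0) return(integer(0))
  i <- match(sites, grid$cells$site)
  if (anyNA(i)) stop("unknown peripheral site: ",
                     paste(sites[is.na(i)], collapse = ", "))
  out <- vapply(i, function(j) {
    grid$cells$site[grid$cells$row == grid$cells$row[j] &
                      grid$cells$col == 7 - grid$cells$col[j]]
  }, integer(1))
  sort(out)
}

# tissue label codes used in phantom arrays
.tissue_legend <- c(air = 0L, skin = 1L, brain = 2L, tumor = 3L)

#' Build a voxelized head phantom for one of the three study tumor cases
#'
#' The head is modeled as a layered slab facing the collimator: the tumor
#' occupies its footprint from the skin surface down to its thickness, a
#' contiguous skin layer covers the rest of the beam-facing surface and is
#' displaced beneath the tumor inside the footprint, and brain tissue fills
#' the remaining depth. The three cases are:
#'
#' * `wide_disk` -- a shallow, widely spreading tumor: disk footprint of
#'   100 mm diameter, 10 mm thick, centered on the beam axis;
#' * `small_rect` -- a small tumor typical of accelerator BNCT practice:
#'   40 x 40 mm footprint, 20 mm thick;
#' * `asymmetric` -- a left-right asymmetric footprint (left half-disk of
#'   50 mm radius joined to a right half-disk of 35 mm radius), 10 mm thick.
#'
#' @param case_id One of `"wide_disk"`, `"small_rect"`, `"asymmetric"`.
#' @param voxel_size Cubic voxel edge in cm (default 0.5). Must divide the
#'   tumor footprint dimensions and thickness.
#' @param lateral_extent Lateral side length of the phantom in cm
#'   (default 20); must give an integer number of voxels.
#' @param depth Phantom depth in cm (default 10).
#' @param skin_thickness Skin layer thickness in cm (default 0.5); rounded
#'   up to a whole number of voxel layers.
#' @return An object of class `phantom`: voxel size, dimensions, voxel
#'   center coordinate vectors `x`, `y`, `z`, the integer `tissue` array
#'   (legend in `attr(tissue, "legend")`), and the tumor specification.
#' @examples
#' ph <- make_head_phantom("wide_disk", voxel_size = 0.5)
#' table(ph$tissue)
#' @export
make_head_phantom <- function(case_id = c("wide_disk", "small_rect", "asymmetric"),
                              voxel_size = 0.5,
                              lateral_extent = 20,
                              depth = 10,
                              skin_thickness = 0.5) {
  case_id <- match.arg(case_id)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0) {
    stop("voxel_size must be a single positive length (cm)")
  }
  spec <- switch(case_id,
    wide_disk = list(shape = "disk", diameter = 10, thickness = 1,
                     area = pi * 5^2),
    small_rect = list(shape = "rect", side = 4, thickness = 2, area = 16),
    asymmetric = list(shape = "half_disks", r_left = 5, r_right = 3.5,
                      thickness = 1,
                      area = pi * (5^2 + 3.5^2) / 2)
  )
  divides <- function(len) abs(len / voxel_size - round(len / voxel_size)) < 1e-9
  dims_to_check <- switch(case_id,
    wide_disk = c(spec$diameter, spec$thickness),
    small_rect = c(spec$side, spec$thickness),
    asymmetric = c(2 * spec$r_left, 2 * spec$r_right, spec$thickness))
  if (!all(vapply(dims_to_check, divides, logical(1)))) {
    stop("voxel_size must divide the tumor footprint dimensions for case '",
         case_id, "'")
  }
  if (!divides(lateral_extent) || !divides(depth)) {
    stop("voxel_size must divide lateral_extent and depth")
  }

  nx <- as.integer(round(lateral_extent / voxel_size))
  ny <- nx
  nz <- as.integer(round(depth / voxel_size))
  x <- (seq_len(nx) - (nx + 1) / 2) * voxel_size
  y <- ((ny + 1) / 2 - seq_len(ny)) * voxel_size   # y decreasing with row? keep increasing:
  y <- sort(y)                                     # voxel-center y, increasing
  z <- (seq_len(nz) - 0.5) * voxel_size

  xy <- expand.grid(x = x, y = y)                  # x varies fastest
  footprint <- switch(spec$shape,
    disk = sqrt(xy$x^2 + xy$y^2) <= spec$diameter / 2 + 1e-9,
    rect = abs(xy$x) <= spec$side / 2 & abs(xy$y) <= spec$side / 2,
    half_disks = {
      r <- sqrt(xy$x^2 + xy$y^2)
      (xy$x < 0 & r <= spec$r_left + 1e-9) |
        (xy$x >= 0 & r <= spec$r_right + 1e-9)
    })
  footprint <- matrix(footprint, nrow = nx, ncol = ny)

  n_tumor_layers <- as.integer(round(spec$thickness / voxel_size))
  n_skin_layers <- max(1L, as.integer(ceiling(skin_thickness / voxel_size - 1e-9)))

  tissue <- array(.tissue_legend[["brain"]], dim = c(nx, ny, nz))
  for (k in seq_len(n_skin_layers)) {
    tissue[, , k][!footprint] <- .tissue_legend[["skin"]]
  }
  for (k in seq_len(n_tumor_layers)) {
    tissue[, , k][footprint] <- .tissue_legend[["tumor"]]
  }
  for (k in n_tumor_layers + seq_len(n_skin_layers)) {
    if (k <= nz) tissue[, , k][footprint] <- .tissue_legend[["skin"]]
  }
  attr(tissue, "legend") <- .tissue_legend

  structure(list(
    case_id = case_id,
    voxel_size = voxel_size,
    dim = c(nx = nx, ny = ny, nz = nz),
    x = x, y = y, z = z,
    tissue = tissue,
    footprint = footprint,
    tumor_spec = spec,
    skin_thickness = n_skin_layers * voxel_size
  ), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat("Voxelized head phantom -- case:", x$case_id, "\n")
  cat("  voxel size :", x$voxel_size, "cm;  grid:",
      paste(x$dim, collapse = " x "), "\n")
  tt <- table(factor(x$tissue, levels = .tissue_legend,
                     labels = names(.tissue_legend)))
  cat("  voxels     :", paste(names(tt), tt, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Logical mask of a tissue in a phantom
#'
#' @param phantom A [make_head_phantom()] object.
#' @param tissue One of `"air"`, `"skin"`, `"brain"`, `"tumor"`.
#' @return Logical array with the phantom's dimensions.
#' @export
tissue_mask <- function(phantom, tissue) {
  stopifnot(inherits(phantom, "phantom"))
  code <- .tissue_legend[tissue]
  if (anyNA(code)) stop("unknown tissue label: ", tissue)
  phantom$tissue == code
}

#' Gold-foil evaluation point layout on the phantom surface
#'
#' Ten surface points where thermal neutron flux is evaluated, mirroring a
#' gold-foil activation layout: point 1 at the irradiation field center,
#' points 2-4 at 2.5 cm and points 5-7 at 5.0 cm offsets along the
#' anterior, posterior and left-lateral directions, and points 8-10 at
#' 7.5 cm offsets along the same three directions. The right side is
#' omitted by the left-right symmetry of head and beam. Points 1-7 (the
#' `uniformity_set`) span the central 10-cm-diameter region and enter the
#' flux uniformity index.
#'
#' @param phantom A [make_head_phantom()] object whose surface extends at
#'   least 7.5 cm from the beam axis in the anterior, posterior and left
#'   directions.
#' @return An object of class `evaluation_layout` with the point table
#'   (`points`: index, x, y, offset_cm, direction) and `uniformity_set`.
#' @export
make_evaluation_layout <- function(phantom) {
  stopifnot(inherits(phantom, "phantom"))
  need <- 7.5
  if (max(phantom$y) < need || -min(phantom$y) < need || -min(phantom$x) < need) {
    stop("phantom surface must extend at least 7.5 cm from the center in ",
         "the anterior, posterior and left directions")
  }
  dirs <- data.frame(direction = c("anterior", "posterior", "left"),
                     ux = c(0, 0, -1), uy = c(1, -1, 0))
  offs <- c(2.5, 5.0, 7.5)
  pts <- data.frame(index = 1L, x = 0, y = 0, offset_cm = 0,
                    direction = "center")
  idx <- 2L
  for (o in offs) {
    for (d in seq_len(nrow(dirs))) {
      pts <- rbind(pts, data.frame(index = idx, x = o * dirs$ux[d],
                                   y = o * dirs$uy[d], offset_cm = o,
                                   direction = dirs$direction[d]))
      idx <- idx + 1L
    }
  }
  rownames(pts) <- NULL
  structure(list(points = pts, uniformity_set = 1:7),
            class = "evaluation_layout")
}

#' @export
print.evaluation_layout <- function(x, ...) {
  cat("Surface evaluation layout: 10 points (uniformity set = 1-7)\n")
  print(x$points, ...)
  invisible(x)
}
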