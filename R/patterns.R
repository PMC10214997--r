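# Intensity modulator patterns and the shape catalog.
#
# The first irradiation field (IF-A) uses a uniform 2-cm polyethylene (PE)
# disk. The second field (IF-B) shields the field center with LiF-PE blocks:
# the 2x2 core is always LiF-PE and peripheral 1x1 sites may be LiF-PE
# (at the pattern's single block thickness) or PE (2 cm). The annular region
# between the central 6x6 block and the disk edge is always PE.

#' Construct an intensity modulator pattern
#'
#' @param lif_sites Integer vector of peripheral sites (1-32) filled with
#'   LiF-PE. Empty for IF-A.
#' @param core_lif Logical; is the central 2x2 core LiF-PE? `TRUE` for every
#'   IF-B pattern, `FALSE` for IF-A.
#' @param lif_thickness LiF-PE block thickness in cm (one of 2, 3, 4, 5).
#' @param pe_thickness PE thickness in cm (fixed at 2).
#' @param label Field label, `"IF-A"` or `"IF-B"`.
#' @param id Optional stable pattern identifier.
#' @return An object of class `modulator_pattern`.
#' @seealso [if_a_pattern()], [shape_to_pattern()]
#' @export
modulator_pattern <- function(lif_sites = integer(0), core_lif = TRUE,
                              lif_thickness = 5, pe_thickness = 2,
                              label = if (core_lif) "IF-B" else "IF-A",
                              id = NULL) {
  lif_sites <- sort(unique(as.integer(lif_sites)))
  if (length(lif_sites) && (min(lif_sites) < 1 || max(lif_sites) > 32)) {
    stop("unknown peripheral site index: ",
         paste(lif_sites[lif_sites < 1 | lif_sites > 32], collapse = ", "))
  }
  if (!core_lif && length(lif_sites)) {
    stop("a pattern with LiF-PE peripheral sites must also shield the core")
  }
  if (!is.numeric(lif_thickness) || length(lif_thickness) != 1 ||
      lif_thickness <= 0) {
    stop("lif_thickness must be a single positive length (cm)")
  }
  structure(list(
    label = label,
    lif_sites = lif_sites,
    core_lif = isTRUE(core_lif),
    lif_thickness = lif_thickness,
    pe_thickness = pe_thickness,
    annulus_material = "PE",
    id = id %||% (if (isTRUE(core_lif)) "IF-B" else "IF-A")
  ), class = "modulator_pattern")
}

#' The uniform PE disk pattern of irradiation field A
#'
#' @param pe_thickness PE disk thickness in cm (fixed at 2 in the standard
#'   setup).
#' @return A `modulator_pattern` with no LiF-PE anywhere.
#' @export
if_a_pattern <- function(pe_thickness = 2) {
  modulator_pattern(integer(0), core_lif = FALSE, lif_thickness = 5,
                    pe_thickness = pe_thickness, label = "IF-A", id = "IF-A")
}

#' @export
print.modulator_pattern <- function(x, ...) {
  cat("Modulator pattern", x$id, sprintf("(%s)\n", x$label))
  if (x$core_lif) {
    cat("  core 2x2    : LiF-PE,", x$lif_thickness, "cm\n")
    cat("  LiF-PE sites:",
        if (length(x$lif_sites)) paste(x$lif_sites, collapse = ", ") else "none",
        "\n")
  } else {
    cat("  uniform PE disk,", x$pe_thickness, "cm\n")
  }
  invisible(x)
}

#' Per-cell material assignment of a pattern
#'
#' Expands a pattern into the material and thickness of each of the 36
#' central cells.
#'
#' @param grid An [build_aperture_grid()] object.
#' @param pattern A [modulator_pattern()].
#' @return The grid's cell table with `material` (`"PE"` or `"LiF-PE"`) and
#'   `thickness` (cm) columns appended.
#' @export
pattern_cell_materials <- function(grid, pattern) {
  stopifnot(inherits(grid, "aperture_grid"),
            inherits(pattern, "modulator_pattern"))
  cells <- grid$cells
  is_lif <- (cells$core & pattern$core_lif) |
    (!cells$core & cells$site %in% pattern$lif_sites)
  cells$material <- ifelse(is_lif, "LiF-PE", "PE")
  cells$thickness <- ifelse(is_lif, pattern$lif_thickness, pattern$pe_thickness)
  cells
}

# shape: a thickness-independent cell subset (peripheral LiF-PE sites; the
# core is implicit in every IF-B shape)
new_shape <- function(id, criterion, sites) {
  list(id = id, criterion = criterion, sites = sort(unique(as.integer(sites))))
}

#' Enumerate Criterion-1 modulator shapes
#'
#' Criterion 1 grows the shielded region outward from the 2x2 core into the
#' inner ring only. The 12 inner-ring sites are folded into their 6
#' left-right mirror pairs -- (8,11), (9,10), (14,15), (18,19), (22,25),
#' (23,24) -- and every subset of pairs (2^6 = 64 subsets, including the
#' core-only shape) is a shape, reflecting the left-right symmetry of head
#' and beam. Enumeration order is binary counting over the pairs, so two
#' runs produce identical catalogs.
#'
#' @param grid An [build_aperture_grid()] object.
#' @return List of 64 shapes (id, criterion `"C1"`, peripheral LiF-PE sites).
#' @export
enumerate_criterion1 <- function(grid) {
  stopifnot(inherits(grid, "aperture_grid"))
  pairs <- grid$inner_pairs
  np <- length(pairs)
  shapes <- vector("list", 2^np)
  for (b in 0:(2^np - 1)) {
    take <- which(bitwAnd(b, bitwShiftL(1L, seq_len(np) - 1L)) != 0L)
    sites <- if (length(take)) unlist(pairs[take]) else integer(0)
    shapes[[b + 1]] <- new_shape(sprintf("C1-%02d", b), "C1", sites)
  }
  shapes
}

#' Enumerate Criterion-2 modulator shapes
#'
#' Criterion 2 starts from the base shape in which the core and the full
#' inner ring are LiF-PE, and grows along the perimeter of the central
#' block. The 20 perimeter sites are folded into 10 mirror pairs ordered
#' cyclically along the half-perimeter path (anterior-center pair, then
#' sweeping through the left-lateral pairs to the posterior-center pair,
#' wrapping around). The shapes are the base plus every cyclic contiguous
#' arc of 1 to 4 pairs (10 starting positions each, 40 shapes), plus one
#' further step of the same growth sequence -- the arc of 5 pairs starting
#' at the anterior-center pair: 41 in total. The all-perimeter pattern is
#' not a Criterion-2 shape; it is the separate all-filled catalog entry
#' ([full_shape()]).
#'
#' @param grid An [build_aperture_grid()] object.
#' @return List of 41 shapes (criterion `"C2"`); every shape contains the
#'   full inner ring.
#' @export
enumerate_criterion2 <- function(grid) {
  stopifnot(inherits(grid, "aperture_grid"))
  base <- grid$inner_ring
  pairs <- grid$perimeter_pairs
  np <- length(pairs)
  shapes <- list()
  k <- 0L
  for (len in 1:4) {
    for (start in seq_len(np)) {
      arc <- ((start - 1L) + seq_len(len) - 1L) %% np + 1L
      k <- k + 1L
      shapes[[k]] <- new_shape(sprintf("C2-%02d", k), "C2",
                               c(base, unlist(pairs[arc])))
    }
  }
  shapes[[k + 1L]] <- new_shape(sprintf("C2-%02d", k + 1L), "C2",
                                c(base, unlist(pairs[1:5])))
  shapes
}

#' The all-shielded shape
#'
#' All 36 central cells (core plus every peripheral site) are LiF-PE.
#'
#' @param grid An [build_aperture_grid()] object.
#' @return A single shape with criterion `"FULL"`.
#' @export
full_shape <- function(grid) {
  stopifnot(inherits(grid, "aperture_grid"))
  new_shape("FULL", "FULL", grid$cells$site[!grid$cells$core])
}

#' Build the modulator shape/thickness catalog
#'
#' Collects the 64 Criterion-1 shapes, 41 Criterion-2 shapes and the
#' all-shielded shape (106 shapes), and crosses them with the LiF-PE block
#' thicknesses (default 2, 3, 4 and 5 cm) into 424 source configurations.
#' Catalog order is deterministic and part of the public contract: C1 in
#' binary-counting order, then C2 arcs by length and starting pair, then
#' FULL; thicknesses in the given order within each shape.
#'
#' @param grid An [build_aperture_grid()] object.
#' @param thicknesses Positive, distinct LiF-PE thicknesses in cm.
#' @return An object of class `pattern_catalog`: `shapes` (named list),
#'   `configs` (data frame: config_id, shape_id, criterion, thickness_cm,
#'   n_lif_sites) and `thicknesses`.
#' @examples
#' cat424 <- build_catalog(build_aperture_grid())
#' nrow(cat424$configs)   # 424
#' @export
build_catalog <- function(grid, thicknesses = c(2, 3, 4, 5)) {
  stopifnot(inherits(grid, "aperture_grid"))
  if (length(thicknesses) == 0) stop("thicknesses must be non-empty")
  if (any(!is.finite(thicknesses)) || any(thicknesses <= 0)) {
    stop("thicknesses must be positive lengths (cm)")
  }
  if (anyDuplicated(thicknesses)) stop("duplicate thickness in thicknesses")

  shapes <- c(enumerate_criterion1(grid), enumerate_criterion2(grid),
              list(full_shape(grid)))
  names(shapes) <- vapply(shapes, `[[`, character(1), "id")
  configs <- do.call(rbind, lapply(shapes, function(s) {
    data.frame(config_id = sprintf("%s_t%g", s$id, thicknesses),
               shape_id = s$id, criterion = s$criterion,
               thickness_cm = thicknesses,
               n_lif_sites = length(s$sites))
  }))
  rownames(configs) <- NULL
  structure(list(shapes = shapes, configs = configs,
                 thicknesses = thicknesses, grid = grid),
            class = "pattern_catalog")
}

#' @export
print.pattern_catalog <- function(x, ...) {
  crit <- table(vapply(x$shapes, `[[`, character(1), "criterion"))
  cat("Modulator pattern catalog\n")
  cat("  shapes  :", length(x$shapes),
      sprintf("(%s)\n", paste(names(crit), crit, sep = "=", collapse = ", ")))
  cat("  configs :", nrow(x$configs), "at thicknesses",
      paste(x$thicknesses, collapse = ", "), "cm\n")
  invisible(x)
}

#' Realize a catalog shape as an IF-B modulator pattern
#'
#' @param shape A shape from a [build_catalog()] catalog.
#' @param thickness LiF-PE block thickness in cm.
#' @return A [modulator_pattern()] in which the shape's sites and the core
#'   are LiF-PE at `thickness` and all other central cells are 2-cm PE.
#' @export
shape_to_pattern <- function(shape, thickness) {
  if (!is.list(shape) || is.null(shape$sites) || is.null(shape$id)) {
    stop("shape must be a catalog shape (id, criterion, sites)")
  }
  modulator_pattern(shape$sites, core_lif = TRUE, lif_thickness = thickness,
                    id = sprintf("%s_t%g", shape$id, thickness))
}

#' Write a pattern catalog to JSON
#'
#' One record per configuration: `id`, `criterion`, `lif_cells` (peripheral
#' site numbers), `thickness_cm`.
#'
#' @param catalog A [build_catalog()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog_json <- function(catalog, path) {
  stopifnot(inherits(catalog, "pattern_catalog"))
  recs <- lapply(seq_len(nrow(catalog$configs)), function(i) {
    row <- catalog$configs[i, ]
    s <- catalog$shapes[[row$shape_id]]
    list(id = row$config_id, criterion = row$criterion,
         lif_cells = s$sites, thickness_cm = row$thickness_cm)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
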