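# shared fixtures: built once per test run, in code
fix_grid <- build_aperture_grid()
fix_beam <- beam_model()
fix_tissues <- tissue_model()

# coarse 1-cm phantom for transport-level tests (16 x 16 x 8 voxels)
coarse_phantom <- function(case = "wide_disk") {
  make_head_phantom(case, voxel_size = 1, lateral_extent = 16, depth = 8,
                    skin_thickness = 1)
}

# the measured IF-B pattern: full inner ring plus the posterior-center
# perimeter pair, 5-cm LiF-PE
edge_shape <- function(grid = fix_grid) {
  list(id = "inner-ring+29-30", criterion = "C2",
       sites = sort(c(grid$inner_ring, 29L, 30L)))
}

mirror_flux_x <- function(arr) arr[dim(arr)[1]:1, , , drop = FALSE]
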