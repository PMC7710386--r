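#' Per-region metrics along the blend axis
#'
#' Splits a simulated blend-axis grid into an `end_a` region (axis below
#' `bounds[1]`), a central hybrid region, and an `end_b` region (axis above
#' `bounds[2]`), binarizes the field with one global threshold, and
#' quantifies each region with [quantify()].
#'
#' @param state A `field_state` from a grid mesh carrying a blend axis.
#' @param bounds Axis cut points (default thirds).
#' @param min_area Speck filter passed to [quantify()].
#' @return A data.frame with one row per region: `region`,
#'   `pigmented_fraction`, `lightness`, `pcs`, `n_elements`.
#' @export
blend_region_metrics <- function(state, bounds = c(1 / 3, 2 / 3),
                                 min_area = 9) {
  mesh <- state$mesh
  if (mesh$geometry != "grid" || is.null(mesh$axis))
    stop("region metrics need a grid mesh with a blend axis")
  pig <- binarize_field(state)
  img <- field_to_matrix(mesh, pig)
  ax_col <- mesh$axis[seq(1, mesh$n, by = mesh$ny)]
  regions <- list(end_a = ax_col < bounds[1],
                  center = ax_col >= bounds[1] & ax_col <= bounds[2],
                  end_b = ax_col > bounds[2])
  do.call(rbind, lapply(names(regions), function(nm) {
    sub <- img[, regions[[nm]], drop = FALSE]
    q <- quantify(binary_pattern(sub), min_area = min_area)
    data.frame(region = nm, pigmented_fraction = mean(sub),
               lightness = q$lightness, pcs = q$pcs,
               n_elements = q$n_elements)
  }))
}

#' In silico hybridization on a grid surrogate
#'
#' Simulates the blend between two kinetic endpoints along the x axis of a
#' non-periodic grid (the raster stand-in for the fused-blob surface, which
#' lets the pattern metrics run directly on the simulated image) and
#' returns the per-region metrics.
#'
#' @param c_a,c_b Endpoint values of the kinetic offset `C` (defaults: the
#'   calibrated dark-spot / light-spot endpoints).
#' @param nx,ny Grid size; the blend runs along `nx`.
#' @param seed Simulation seed.
#' @param profile,steepness Blend profile, see [assign_hybrid_gradient()].
#' @param n_steps,dt Integration settings.
#' @param base Base [kinetic_params()] shared by both endpoints.
#' @return A `field_state` with the graded parameter field attached.
#' @export
simulate_blend_grid <- function(c_a = c_dark_spots(), c_b = c_light_spots(),
                                nx = 192, ny = 64, seed = NULL,
                                profile = "linear", steepness = 8,
                                n_steps = 2000, dt = 0.01,
                                base = kinetic_params()) {
  mesh <- with_blend_axis(make_grid_mesh(nx, ny, periodic = FALSE))
  end_a <- base; end_a$C <- c_a
  end_b <- base; end_b$C <- c_b
  pf <- assign_hybrid_gradient(mesh, end_a, end_b, profile = profile,
                               steepness = steepness)
  simulate(mesh, pf, n_steps = n_steps, dt = dt, seed = seed)
}

#' Replicated blending experiment
#'
#' Runs [simulate_blend_grid()] over a set of seeds and scores, per seed,
#' the two signatures of pattern blending: the central hybrid region is
#' *intermediate* in lightness (strictly between the endpoint regions) and
#' *transgressive* in pattern complexity (PCS at least as large as both
#' endpoint regions).
#'
#' @param seeds Integer vector of simulation seeds.
#' @param ... Passed to [simulate_blend_grid()].
#' @return A data.frame with one row per seed: region metrics (wide),
#'   `intermediate_lightness`, `transgressive_pcs`, `blended`.
#' @export
blending_experiment <- function(seeds = 1:20, ...) {
  rows <- lapply(seeds, function(s) {
    st <- simulate_blend_grid(seed = s, ...)
    m <- blend_region_metrics(st)
    li <- m$lightness[m$region == "center"]
    la <- m$lightness[m$region == "end_a"]
    lb <- m$lightness[m$region == "end_b"]
    pc <- m$pcs[m$region == "center"]
    inter <- li > min(la, lb) & li < max(la, lb)
    trans <- pc >= max(m$pcs[m$region != "center"])
    data.frame(seed = s,
               lightness_a = la, lightness_center = li, lightness_b = lb,
               pcs_a = m$pcs[m$region == "end_a"], pcs_center = pc,
               pcs_b = m$pcs[m$region == "end_b"],
               intermediate_lightness = inter, transgressive_pcs = trans,
               blended = inter & trans)
  })
  do.call(rbind, rows)
}
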