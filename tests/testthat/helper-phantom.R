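# Shared fixtures: compact phantom configurations used across tests.

# straight tube with the default piecewise CSA profile
straight_spec <- function(...) {
  phantom_spec(arc_radius_mm = Inf, ...)
}

# constant-CSA tube (all profile knots equal)
const_spec <- function(csa = 50, length_mm = 40, ...) {
  phantom_spec(csa_tail = csa, csa_body = csa, csa_peak = csa,
               csa_tip = csa, length_mm = length_mm,
               tail_len = 8, body_len = 14, head_rise_len = 8,
               arc_radius_mm = Inf, ...)
}

# compact 1-mm grid large enough for the default 45-mm phantom
small_t1_grid <- function() make_grid(c(52, 56, 48), c(1, 1, 1))

# smooth Gaussian blob volume for interpolation tests
blob_volume <- function(dims = c(32, 32, 32), sigma = 6) {
  g <- make_grid(dims, c(1, 1, 1))
  w <- hippoaxis:::grid_world_coords(g)
  image_volume(array(exp(-rowSums(w^2) / (2 * sigma^2)), dims), g$affine)
}

# native-space CSA profile of a phantom subject generated at identity pose:
# distance map on the subject's own AP-aligned grid
native_csa_profile <- function(seg, tiv = 1450, tiv_ref = 1450) {
  dmap <- build_distance_map(seg)
  tab <- slice_distance_table(dmap, seg)
  csa_profile(seg, tab, tiv = tiv, tiv_ref = tiv_ref)
}
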