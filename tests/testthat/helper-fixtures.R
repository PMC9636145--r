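# Shared fixtures, built lazily once per session.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# 7-pixel cluster of 40 um pixels in the default homogeneous medium
cluster7 <- function() fixture("cluster7", function() {
  lay <- build_hex_array(40, 120)
  rm_ <- cross_resistance_matrix(lay, medium())
  list(layout = lay, rmat = rm_, params = pixel_params(lay, rm_))
})

# 43-pixel array: the smallest scale at which the far-field proxy behaves
# like the full implant (sufficient inter-pixel coupling)
array_ff <- function() fixture("array_ff", function() {
  lay <- build_hex_array(40, 280)
  rm_ <- cross_resistance_matrix(lay, medium())
  list(layout = lay, rmat = rm_, params = pixel_params(lay, rm_))
})

# mid-sized array for contrast-style checks (interior rows exist)
array_mid <- function() fixture("array_mid", function() {
  lay <- build_hex_array(40, 600)
  rm_ <- cross_resistance_matrix(lay, tissue_medium())
  list(layout = lay, rmat = rm_, params = pixel_params(lay, rm_))
})

# hand-built two-electrode "layout" with the ring pushed far away, for
# isolated pairwise couplings
pair_layout <- function(d_um = 40, a_um = 9, ring_at = 20000) {
  structure(list(
    pixel_width = d_um, row_pitch = d_um * cos(pi / 6),
    centers = cbind(x = c(-d_um / 2, d_um / 2), y = c(0, 0)),
    row_index = c(0L, 0L), electrode_radius = a_um,
    array_diameter = 2 * ring_at, return_inner = ring_at - 50,
    return_outer = ring_at, device_thickness = 30), class = "pv_layout")
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}

superpose_at_test <- function(rmat, pts, z, I) {
  pvpix:::superpose_at(pts, z, I, rmat)
}
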