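# shared phantoms, profiles and closed-form oracles for the test suite

ref_model <- nucleated_cell_model()
ref_grid <- reference_grid()
ref_pitch <- unname(pixel_pitch(ref_grid)[["dx"]])   # 15/255 um

# row/column through the body centre on the 255-px grid (y = x = 0 exactly)
center_row <- 128L
center_col <- 128L

single_sphere_model <- function(radius = 6, index = 1.37) {
  cell_model(sphere_component(c(0, 0, 0), radius, index),
             medium_index = 1.33, wavelength = 0.6328)
}

signed_profile <- function(map, line, axis = NULL) {
  if (is.null(axis)) {
    axis <- if (line$type == "column") "y" else "x"
  }
  extract_profile(forward_diff_gradient(map, axis), line)
}

# closed-form second lateral derivative along y = 0 of the reference model;
# each component contributes -C * R^2 / (R^2 - u^2)^(3/2) inside its disc
ref_d2phi_dx2 <- function(x) {
  v <- 0
  if (x^2 < 36) {
    v <- v - (4 * pi / 0.6328) * 0.04 * 36 / (36 - x^2)^1.5
  }
  if ((x - 3)^2 < 6.25) {
    v <- v - (4 * pi / 0.6328) * 0.08 * 6.25 / (6.25 - (x - 3)^2)^1.5
  }
  v
}

ref_boundaries_x <- c(-6, 0.5, 5.5, 6)   # body rim and nucleus rim at y = 0
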