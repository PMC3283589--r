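# shared fixtures and independent oracles, built in code at test time

# clockwise unit squares/rectangles as raw vertex matrices
square_cw <- function(half = 1) {
  cbind(c(-half, half, half, -half), c(half, half, -half, -half))
}

# frozen study fixtures used by the acceptance suite and integration tests:
# a rectangle with an erased corner, and a two-structure stiffness-sweep phantom
missing_corner_phantom <- function() {
  make_rectangle_phantom(phantom_spec(obj_width = 40, obj_height = 36,
                                      noise_sd = 0,
                                      missing_corners = c(br = 4)))
}

sweep_phantom <- function() {
  make_vertebra_phantom(phantom_spec(obj_width = 20, obj_height = 20,
                                     concavity = 2.5, corner_radius = 2,
                                     neighbor_gap = 2, noise_sd = 0))
}

# independent circular 3-tap convolution, written as an explicit loop
oracle_smooth <- function(radii, kernel, iterations = 1L) {
  n <- length(radii)
  for (it in seq_len(iterations)) {
    out <- numeric(n)
    for (r in seq_len(n)) {
      prev <- if (r == 1L) n else r - 1L
      nxt <- if (r == n) 1L else r + 1L
      out[r] <- kernel[1L] * radii[prev] + kernel[2L] * radii[r] +
        kernel[3L] * radii[nxt]
    }
    radii <- out
  }
  radii
}
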