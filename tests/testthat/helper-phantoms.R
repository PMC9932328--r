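# Shared small fixtures, built in code at test time.

tiny_tube <- function(lumen_mm = 4, wall_mm = 1, spacing = 0.5,
                      length_mm = 14, noise_sd = 0, seed = 1) {
  spec <- straight_tube_spec(lumen_mm = lumen_mm, wall_mm = wall_mm,
                             length_mm = length_mm)
  make_airway_phantom(spec, spacing = spacing, noise_sd = noise_sd,
                      seed = seed)
}

small_lobe_geometry <- function() lobe_block_geometry(shape = c(24, 24, 30))

# a minimal hand-built tree: trachea -> two mains -> one child each
toy_tree <- function() {
  airway_tree(tibble::tibble(
    id = c("t", "m1", "m2", "c1", "c2"),
    parent = c(NA, "t", "t", "m1", "m2"),
    centerline = list(
      rbind(c(0, 0, 0), c(0, 0, -10)),
      rbind(c(0, 0, -10), c(8, 0, -14)),
      rbind(c(0, 0, -10), c(-8, 0, -14)),
      rbind(c(8, 0, -14), c(12, 0, -20)),
      rbind(c(-8, 0, -14), c(-12, 0, -20))
    )
  ))
}
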