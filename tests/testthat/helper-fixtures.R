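# Shared fixtures, built in code at test time.

# white-noise vessel-likelihood image with a centred optic-disc annotation:
# the standard geometry fixture (profiles are noise-like, as on real data)
noise_posterior <- function(seed = 1, side = 400, d_od = 100) {
  set.seed(seed)
  px <- matrix(as.integer(sample(0:255, side * side, replace = TRUE)),
               side, side)
  structure(list(pixels = px,
                 od = od_annotation((side - 1) / 2, (side - 1) / 2, d_od),
                 fit = "fixture"),
            class = "vessel_posterior")
}

# small synthetic fundus (fast default for pipeline tests)
small_fundus <- function(seed = 1, side = 200, d_od = 50, ...) {
  gen_synthetic_fundus(fundus_synth_params(image_size = side,
                                           od_diameter = d_od,
                                           seed = seed, ...))
}

# 90 degree grid rotation about the frame centre (exact for square images)
rot90_image <- function(m) t(m)[, nrow(m):1]
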