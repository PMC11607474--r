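# Fixtures built in code: spherical phantoms and small random survival
# datasets for oracle cross-checks.

make_sphere_phantom <- function(centers_mm, radii_mm, peaks,
                                spacing = c(1, 1, 1), grid = NULL,
                                background = 0.5, noise_sd = 0, seed = 1L) {
  centers_mm <- matrix(centers_mm, ncol = 3)
  if (is.null(grid)) {
    grid <- ceiling((apply(centers_mm, 2, max) + max(radii_mm) + 10) / spacing)
  }
  lesions <- lapply(seq_len(nrow(centers_mm)), function(i) {
    r <- if (length(radii_mm) == nrow(centers_mm)) radii_mm[i] else radii_mm
    p <- if (length(peaks) == nrow(centers_mm)) peaks[i] else peaks
    list(center_mm = centers_mm[i, ], radii_mm = rep(r, 3)[1:3], peak_suv = p)
  })
  generate_phantom(phantom_spec(grid, spacing, background_suv = background,
                                noise_sd = noise_sd, lesions = lesions,
                                seed = seed))
}

# random right-censored dataset with optional binary covariate effect
random_surv_data <- function(n, beta = 0, seed = 1L) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  t_event <- rweibull(n, shape = 1.1, scale = 40 * exp(-beta * x / 1.1))
  cens <- runif(n, 5, 80)
  # round times to force ties so the tie corrections are exercised
  time <- pmax(0.5, round(pmin(t_event, cens) * 2) / 2)
  list(time = time, event = as.integer(t_event <= cens), x = x)
}
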