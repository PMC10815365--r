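# Shared fixtures and independent oracles, built in code at test time.

# random CIELAB colour away from the degenerate denominator
random_color <- function() {
  repeat {
    c <- color_cie(runif(1, 5, 95), runif(1, -40, 40), runif(1, -40, 40))
    den <- 5.645 * c$L + c$a - 3.012 * c$b
    if (abs(den) > 1) return(c)
  }
}

# brute-force Savitzky-Golay second derivative: per point, least-squares
# polynomial over the window (one-sided at the edges), differentiated twice
# analytically and evaluated at that point's wavelength
sg_oracle <- function(values, wavelengths, window, order) {
  n <- length(values)
  k <- (window - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- if (i <= k) 1:window
           else if (i > n - k) (n - window + 1):n
           else (i - k):(i + k)
    basis <- outer(wavelengths[idx] - wavelengths[i], 0:order, "^")
    cf <- stats::lm.fit(basis, values[idx])$coefficients
    out[i] <- 2 * cf[[3]]
  }
  out
}

# tiny spectrum on a short uniform grid
small_spectrum <- function(values, start = 285, step = 3,
                           kind = "reflectance_percent", id = "s1") {
  g <- wavelength_grid(start, step, length(values))
  new_spectrum(values, g, kind, id)
}

# low-dimensional regression problem with planted linear structure
planted_linear <- function(n = 40, p = 3, noise = 0, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- seq_len(p)
  y <- as.numeric(X %*% beta) + rnorm(n, 0, noise)
  list(X = X, y = y, beta = beta)
}

small_cfg <- function(seed = 7, noise_scale = 1) {
  trajectory_config(seed = seed, noise_scale = noise_scale)
}
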