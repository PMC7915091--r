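# Shared fixture builders: everything is generated in code at test time.

# A compact three-line base spectrum for fast unit tests.
small_base <- function(n_cols = 300) {
  make_base_spectrum(
    n_cols,
    data.frame(col = c(80, 150, 230), height = c(1000, 800, 900), width = 3)
  )
}

small_estimates <- function() c(80, 150, 230)

# Detection window narrow enough for the small frames.
small_params <- function(...) detection_params(window_halfwidth = 12, ...)

# A quick small frame spec; noise on by default.
small_spec <- function(n_rows = 200, n_cols = 300, seed = 1, ...) {
  frame_spec(n_rows = n_rows, n_cols = n_cols, seed = seed, ...)
}

# Noise-free variant for exactness checks.
clean_spec <- function(n_rows = 200, n_cols = 300, seed = 1) {
  frame_spec(n_rows = n_rows, n_cols = n_cols, seed = seed,
             gain_sigma = 0, noise_amplitude = 0)
}

# Sample points exactly on a circular arc around center column a, center row
# b, radius r; the line lies at a - sgn * sqrt(r^2 - (y-b)^2).
arc_points <- function(rows, a, b, r, sgn = 1) {
  data.frame(row = rows, col = a - sgn * sqrt(r^2 - (rows - b)^2))
}
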