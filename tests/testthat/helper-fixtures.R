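# Small in-code fixtures shared across test files.

tiny_meta <- function(nr = 3, nc = 3) {
  grid_meta(nr, nc, cell_size = 0.5, origin_x = 100, origin_y = 40)
}

tiny_times <- function(n = 12, start_year = 2001, start_month = 1) {
  ser <- (start_year * 12 + start_month - 1) + seq_len(n) - 1
  data.frame(year = ser %/% 12, month = ser %% 12 + 1)
}

# cube from a function f(time_index, month) giving one matrix per step,
# or from a constant
tiny_cube <- function(n = 12, nr = 3, nc = 3, fill = 1, units = "",
                      start_year = 2001) {
  tt <- tiny_times(n, start_year)
  v <- array(NA_real_, c(n, nr, nc))
  for (i in seq_len(n)) {
    v[i, , ] <- if (is.function(fill)) fill(i, tt$month[i]) else fill
  }
  grid_cube(v, tiny_meta(nr, nc), tt, units)
}

# all-grassland land cover
grass_map <- function(nr = 3, nc = 3) {
  land_cover_map(matrix(3L, nr, nc), tiny_meta(nr, nc))
}

# a small complete synthetic scenario (kept small for speed)
small_scenario <- function(seed = 11, ...) {
  generate_synthetic(synth_config(n_rows = 6, n_cols = 6, seed = seed, ...))
}
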