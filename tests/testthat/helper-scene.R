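# Shared small fixtures, built once per test run.

# Compact scene for module tests: fewer pixels/samples than the default
# study conditions, same curve preset.
tiny_scene_config <- function(seed = 42, n_per_class = 20, ...) {
  scene_config(grid = c(40, 40), n_per_class = n_per_class, seed = seed, ...)
}

test_scene <- generate_scene(tiny_scene_config())
test_series <- suppressMessages(
  fill_gaps_linear(median_composite(test_scene$stack,
                                    range(test_scene$stack$dates),
                                    period_days = 10)))

# A small deterministic stack built directly from numbers (no generator).
make_stack <- function(nrow = 4, ncol = 4, bands = c("B4", "B8"),
                       dates = as.Date("2021-06-01") + c(0, 10, 20),
                       fill = NULL, seed = 1) {
  d <- c(nrow, ncol, length(bands), length(dates))
  values <- if (is.null(fill)) {
    withr::with_seed(seed, array(runif(prod(d)), d))
  } else {
    array(fill, d)
  }
  reflectance_stack(values, dates, bands, geo_meta(1000, 2000, 10))
}
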