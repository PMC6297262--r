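# Shared fixtures: a 64 x 64 x 32 test-scale phantom (0.2 x 0.2 x 1 mm) and
# light registration parameters. Built once per test run.

test_geometry <- function() phantom_geometry(c(64L, 64L, 32L), c(0.2, 0.2, 1.0))

base_phantom_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_base_phantom(test_geometry())
    cache
  }
})

light_reg <- function() reg_params(iterations = c(25, 15, 10))

# world-mm centre of a named ROI (right-hemisphere copy) in the default layout
roi_center <- function(name, geom = test_geometry()) {
  lay <- default_roi_layout()
  row <- lay[lay$name == name, ]
  ctr <- geom$origin + (geom$dim - 1) / 2 * geom$spacing
  ctr + c(row$x, row$y, row$z)
}
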