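## Fixtures are generated in code and cached so several test files can share
## one rendering or one benchmark run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, make) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, make(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

## Grayscale disc test image (values as plain matrix).
disc_image <- function(H, W, r0, c0, radius, inside = 60, outside = 200) {
  d2 <- outer((seq_len(H) - r0)^2, (seq_len(W) - c0)^2, "+")
  m <- matrix(outside, H, W)
  m[d2 <= radius^2] <- inside
  m
}

## Edge set of a gray matrix through the package's own stages (smoothing
## before gradients, as in the detection chain).
edges_of <- function(m, keep_fraction = 0.2) {
  g <- weighted_smooth(gray_image(m), filter_mask(5L))
  field <- compute_gradients(g)
  threshold_edges(field, auto_threshold(field, keep_fraction))
}

## A clean default scene, rendered once.
clean_scene <- function() cached("clean_scene", function() {
  spec <- scene_spec(seed = 42L)
  c(render_scene(spec), list(spec = spec))
})

## A scene without a polar body.
no_pb_scene <- function() cached("no_pb_scene", function() {
  spec <- scene_spec(polar_body = list(present = FALSE), seed = 43L)
  c(render_scene(spec), list(spec = spec))
})

## Shared acceptance benchmarks (seeds fixed once for the test suite).
acceptance_clean_mix <- function() cached("acc_clean_mix", function() {
  run_benchmark(clean_mix_suite(30L, base_seed = 101L))
})

acceptance_category <- function(category, seed) {
  cached(paste0("acc_", category), function() {
    run_benchmark(generate_suite(category, 20L, base_seed = seed))
  })
}
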