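# Shared fixtures, built lazily and cached across test files so expensive
# phantom generation and classifier training happen once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small paired case with default contrast, both images
fixture_case <- function() fixture("case", function() {
  generate_case(default_sim_params("ALPPS"), seed = 42L)
})

# training cohort (default contrast) and trained classifier
fixture_model <- function() fixture("model", function() {
  tr <- generate_cohort(n = 8, technique_split = c(4L, 4L), seed = 500L)
  train_functional_classifier(tr$cases)
})

# zero-contrast training cohort and classifier (null phantoms)
fixture_null_model <- function() fixture("null_model", function() {
  spd <- list(ALPPS = default_sim_params("ALPPS", contrast = 0),
              PVE = default_sim_params("PVE", contrast = 0))
  tr <- generate_cohort(n = 6, technique_split = c(3L, 3L),
                        sim_params_dist = spd, seed = 700L)
  train_functional_classifier(tr$cases)
})

# constant-intensity cube fixture for degenerate-texture conventions
fixture_constant_region <- function(side = 6, value = 50) {
  list(arr = array(value, dim = rep(side, 3)),
       mask = array(TRUE, dim = rep(side, 3)))
}
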