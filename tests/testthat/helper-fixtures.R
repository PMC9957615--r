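# Shared fixtures, generated in code at test time.

tiny_landscape <- function(seed = 42, ncols = 5, nrows = 5,
                           n_livestock_groups = 2, n_days = 30,
                           n_patches = 4, elevation_range = c(150, 280), ...) {
  # gentle relief: on a handful of 50 m cells the full 100-1200 m range would
  # put every slope beyond the livestock accessibility cutoffs
  generate_landscape(
    landscape_config(
      seed = seed, ncols = ncols, nrows = nrows,
      n_livestock_groups = n_livestock_groups, n_patches = n_patches,
      elevation_range = elevation_range, ...
    ),
    n_days = n_days
  )
}

# A minimal registry with one external, one static model and one change model,
# used by the engine tests that do not need the full pasture system.
toy_registry <- function(change_value = -1) {
  r <- model_registry()
  r <- declare_external(r, concept("toy.input", units = "1"))
  r <- register_component(r, component_model(
    id = "toy.double", namespace = "temperature", output = "toy.double",
    inputs = "toy.input",
    compute = function(ins, t, ctx) 2 * ins[["toy.input"]]
  ))
  r <- declare_external(r, concept("toy.stock", units = "g/m2"))
  r <- register_component(r, component_model(
    id = "toy.change_in_stock", namespace = "temperature",
    output = "toy.change_in_stock", inputs = character(0),
    compute = function(ins, t, ctx) {
      matrix(change_value, ctx$grid$nrows, ctx$grid$ncols)
    },
    is_change_model = TRUE, of_concept = "toy.stock"
  ))
  r
}

one_cell_context <- function(n_days = 1) {
  context(
    grid_spec(1, 1, cell_size = 50),
    timeline("2018-01-01", as.Date("2018-01-01") + n_days - 1)
  )
}
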