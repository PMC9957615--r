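test_that("registration enforces unique ids and per-namespace outputs", {
  r <- toy_registry()
  expect_s3_class(r, "pal_registry")
  # duplicate id
  expect_error(register_component(r, component_model(
    id = "toy.double", namespace = "radiation", output = "toy.other",
    inputs = character(0), compute = function(ins, t, ctx) 0
  )), class = "pal_registration_error")
  # duplicate (output, namespace)
  expect_error(register_component(r, component_model(
    id = "toy.double.bis", namespace = "temperature", output = "toy.double",
    inputs = character(0), compute = function(ins, t, ctx) 0
  )), class = "pal_registration_error")
  # same output in another namespace is allowed; scoping decides later
  r2 <- register_component(r, component_model(
    id = "toy.double.radiation", namespace = "radiation", output = "toy.double",
    inputs = character(0), compute = function(ins, t, ctx) 99
  ))
  expect_equal(length(lookup_components(r2, "toy.double")), 2)
})

test_that("scoping prefers the consumer's namespace, then lexicographic id", {
  r <- toy_registry()
  r <- register_component(r, component_model(
    id = "a.other", namespace = "radiation", output = "toy.double",
    inputs = character(0), compute = function(ins, t, ctx) 99
  ))
  # consumer in radiation namespace gets the radiation provider
  got <- lookup_components(r, "toy.double", scope = list(namespace = "radiation"))
  expect_equal(got[[1]]$id, "a.other")
  # no namespace match: lexicographic tie-break
  got2 <- lookup_components(r, "toy.double", scope = list(namespace = "nitrogen"))
  expect_equal(got2[[1]]$id, "a.other")  # "a.other" < "toy.double"
})

test_that("resolution builds the radiation chain and is deterministic", {
  reg <- pal_default_registry()
  ctx <- one_cell_context()
  df <- resolve("radiation.limiting_factor", reg, ctx)
  ids <- names(df$nodes)
  expect_true("radiation.over_vegetation" %in% ids)
  expect_true("radiation.at_surface" %in% ids)
  expect_true("external:climate.rg" %in% ids)
  df2 <- resolve("radiation.limiting_factor", reg, ctx)
  expect_identical(names(df$nodes), names(df2$nodes))
  expect_identical(df$order, df2$order)
})

test_that("an external concept resolves to a single-node dataflow", {
  reg <- pal_default_registry()
  df <- resolve("terrain.slope", reg, one_cell_context())
  expect_equal(length(df$nodes), 1)
  expect_equal(df$nodes[[1]]$type, "external")
})

test_that("unresolvable concepts and cycles raise typed errors", {
  reg <- pal_default_registry()
  err <- expect_error(resolve("no.such_concept", reg, one_cell_context()),
                      class = "pal_resolution_error")
  expect_match(conditionMessage(err), "no.such_concept")

  r <- model_registry()
  r <- register_component(r, component_model(
    id = "cyc.a", namespace = "nitrogen", output = "cyc.a", inputs = "cyc.b",
    compute = function(ins, t, ctx) 0
  ))
  r <- register_component(r, component_model(
    id = "cyc.b", namespace = "nitrogen", output = "cyc.b", inputs = "cyc.a",
    compute = function(ins, t, ctx) 0
  ))
  err2 <- expect_error(resolve("cyc.a", r, one_cell_context()),
                       class = "pal_cycle_error")
  expect_match(conditionMessage(err2), "cyc")
})

test_that("change models are inserted only on multi-step timelines", {
  r <- toy_registry()
  df1 <- resolve("toy.stock", r, one_cell_context(1))
  expect_false("toy.change_in_stock" %in% names(df1$nodes))
  expect_equal(length(df1$state_concepts), 0)

  df5 <- resolve("toy.stock", r, one_cell_context(5))
  expect_true("toy.change_in_stock" %in% names(df5$nodes))
  expect_equal(df5$state_concepts, "toy.stock")
})

test_that("the Euler update integrates a constant change model", {
  r <- toy_registry(change_value = -1)
  ctx <- one_cell_context(5)
  df <- resolve("toy.stock", r, ctx)
  store <- execute(df, ctx, inputs = list("toy.stock" = 10))
  # X(0)=10, dX=-1 each step: X at steps 1..5 is 10,9,8,7,6
  expect_equal(vapply(1:5, function(t) get_field(store, "toy.stock", t, FALSE)[1, 1],
                      numeric(1)),
               c(10, 9, 8, 7, 6))
})

test_that("a concept is constant over time iff its change model returns zero", {
  ctx <- one_cell_context(8)
  for (cv in c(0, 0.5)) {
    r <- toy_registry(change_value = cv)
    store <- execute(resolve("toy.stock", r, ctx), ctx, list("toy.stock" = 3))
    traj <- vapply(1:8, function(t) get_field(store, "toy.stock", t, FALSE)[1, 1],
                   numeric(1))
    if (cv == 0) expect_true(all(traj == 3)) else expect_true(all(diff(traj) == cv))
  }
})

test_that("missing external inputs and unwritten reads are hard errors", {
  r <- toy_registry()
  ctx <- one_cell_context(3)
  df <- resolve("toy.stock", r, ctx)
  expect_error(execute(df, ctx, inputs = list()), class = "pal_execution_error")
  dfd <- resolve("toy.double", r, ctx)
  err <- expect_error(execute(dfd, ctx, inputs = list()),
                      class = "pal_execution_error")
  expect_match(conditionMessage(err), "toy.input")
})

test_that("non-finite component output raises a numerical error naming the cell", {
  r <- model_registry()
  r <- declare_external(r, "bad.x")
  r <- register_component(r, component_model(
    id = "bad.inv", namespace = "nitrogen", output = "bad.inv", inputs = "bad.x",
    compute = function(ins, t, ctx) 1 / ins[["bad.x"]]
  ))
  ctx <- one_cell_context(1)
  df <- resolve("bad.inv", r, ctx)
  err <- expect_error(execute(df, ctx, list("bad.x" = 0)),
                      class = "pal_numerical_error")
  expect_match(conditionMessage(err), "bad.inv")
  expect_match(conditionMessage(err), "\\(1,1\\)")
})

test_that("execution mediates units and grids of external fields on the fly", {
  reg <- pal_default_registry()
  ctx <- context(grid_spec(2, 2, cell_size = 50), timeline("2018-01-01", "2018-01-01"))
  df <- resolve("vegetation.living_biomass", reg, ctx)
  # biomass supplied in kg/ha on a finer grid: 1000 kg/ha -> 100 g/m2
  fine <- grid_spec(4, 4, cell_size = 25)
  f <- raster_field(matrix(1000, 4, 4), fine, units = "kg/ha")
  store <- execute(df, ctx, list("vegetation.living_biomass" = f))
  expect_equal(get_field(store, "vegetation.living_biomass", 1, FALSE),
               matrix(100, 2, 2))
})

test_that("DOT export is well-formed and covers the resolved graph", {
  reg <- pal_default_registry()
  ctx <- one_cell_context()
  df <- resolve("radiation.limiting_factor", reg, ctx)
  dot <- export_dataflow(df)
  expect_match(dot, "^digraph")
  expect_equal(sum(gregexpr("{", dot, fixed = TRUE)[[1]] > 0),
               sum(gregexpr("}", dot, fixed = TRUE)[[1]] > 0))
  # one node statement per resolved node
  expect_equal(length(gregexpr("pal_provenance", dot)[[1]]), length(df$nodes))
  # single-node dataflow: one node, no edges
  d1 <- export_dataflow(resolve("terrain.slope", reg, ctx))
  expect_equal(length(gregexpr("pal_provenance", d1)[[1]]), 1)
  expect_false(grepl("->", d1))
})

test_that("reports carry the six canonical sections and true statistics", {
  reg <- pal_default_registry()
  ctx <- context(grid_spec(3, 3, cell_size = 50), timeline("2018-06-01", "2018-06-01"))
  df <- resolve("radiation.over_vegetation", reg, ctx)
  com <- raster_field(matrix(c(1, 1, 2, 2, 3, 3, 1, 2, 3), 3, 3), ctx$grid,
                      kind = "categorical")
  com2 <- raster_field(matrix(c(1, 1, 2, 5, 3, 3, 1, 2, 3), 3, 3), ctx$grid,
                       kind = "categorical")
  store <- execute(df, ctx, list(
    "climate.rg" = 10, "terrain.exposure" = 1,
    "vegetation.type" = com, "vegetation.overstory_type" = com2
  ))
  rpt <- generate_report(store, df)
  for (h in c("# Introduction", "# Methods", "# Results", "# Discussion",
              "# Conclusion", "# References")) {
    expect_match(rpt, h, fixed = TRUE)
  }
  # exactly one results subsection for a single queried concept
  expect_equal(length(gregexpr("\n## ", rpt)[[1]]), 1)
  # statistics equal an independent zonal computation over the full grid
  f <- get_field(store, "radiation.over_vegetation")
  st <- zonal_statistics(f, raster_field(1, ctx$grid, kind = "categorical"))
  expect_match(rpt, sprintf("mean %.6g", st$mean[1]), fixed = TRUE)
  expect_match(rpt, sprintf("min %.6g", st$min[1]), fixed = TRUE)
})

test_that("state store enforces write-once and read-after-write", {
  r <- toy_registry()
  ctx <- one_cell_context(2)
  df <- resolve("toy.stock", r, ctx)
  store <- execute(df, ctx, list("toy.stock" = 1))
  expect_error(get_field(store, "not.there"), class = "pal_execution_error")
})
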