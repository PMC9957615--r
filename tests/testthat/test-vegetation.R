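test_that("potential growth is exactly the triple product", {
  expect_equal(potential_growth(2, 0.5, 1), 1)
  expect_equal(potential_growth(4, 0.8, 0), 0)
  expect_equal(potential_growth(5, 0.115113, 0.9), 5 * 0.115113 * 0.9)
  set.seed(7)
  xf <- runif(1000, 0.1, 8)
  ftrh <- runif(1000)
  ph <- runif(1000)
  expect_identical(potential_growth(xf, ftrh, ph), xf * ftrh * ph)
})

test_that("actual growth scales potential by the nitrogen factor", {
  expect_equal(actual_growth(3.2, 1), 3.2)
  expect_equal(actual_growth(3.2, 0), 0)
  # back-solved magnitude check: 5.29 potential at FN ~ 0.2987 gives ~1.58
  expect_equal(actual_growth(5.29, 0.2987), 1.58, tolerance = 1e-3)
  p <- runif(100, 0, 6); f <- runif(100)
  expect_true(all(actual_growth(p, f) <= p))
})

test_that("senescence and litterfall are first-order and bounded by their pools", {
  expect_equal(senescence_flux(100, 0.01, 1), 0)
  expect_equal(senescence_flux(100, 0.01, 0), 1)
  expect_equal(senescence_flux(0, 0.5, 0.2), 0)
  expect_equal(litterfall_flux(0, 0.02), 0)
  expect_equal(litterfall_flux(50, 0.02), 1)
  expect_equal(litterfall_flux(80, 1), 80)
  agb <- runif(50, 0, 400)
  expect_true(all(senescence_flux(agb, 0.03, runif(50)) <= agb))
  expect_true(all(litterfall_flux(agb, runif(50)) <= agb))
})

test_that("harvest removes the stated fraction and composes", {
  st <- list(agb_living = 200, agb_dead = 10, litter = 5)
  h0 <- apply_harvest(st, 0)
  expect_equal(h0$state, st); expect_equal(h0$flux, 0)
  h <- apply_harvest(st, 0.5)
  expect_equal(h$state$agb_living, 100); expect_equal(h$flux, 100)
  h2 <- apply_harvest(h$state, 0.5)
  expect_equal(h2$state$agb_living, 50)  # 25% of the original remains
})

test_that("pool updates conserve mass and clamp at zero with rescaled outflows", {
  st <- list(agb_living = 10, agb_dead = 5, litter = 2)
  r0 <- update_vegetation(st, list())
  expect_equal(r0$state, st)

  r <- update_vegetation(st, list(actual_growth = 2, senescence = 1),
                         ingestion_living = 0.5)
  expect_equal(r$state$agb_living, 10.5)
  expect_equal(r$state$agb_dead, 6)

  # demanded outflows exceed the pool: realized outflows sum to pool + inflow
  r2 <- update_vegetation(list(agb_living = 1, agb_dead = 0, litter = 0),
                          list(actual_growth = 0.2, senescence = 3, harvest = 2),
                          ingestion_living = 1)
  expect_equal(r2$state$agb_living, 0, tolerance = 1e-12)
  out <- r2$realized
  expect_equal(out$senescence + out$harvest + out$ingestion_living, 1.2,
               tolerance = 1e-12)
  # proportionality of the rescale
  expect_equal(out$senescence / out$harvest, 3 / 2, tolerance = 1e-12)

  # mass balance closes under random fluxes
  set.seed(8)
  for (k in 1:100) {
    st <- list(agb_living = runif(1, 0, 50), agb_dead = runif(1, 0, 30),
               litter = runif(1, 0, 30))
    fl <- list(actual_growth = runif(1, 0, 5), senescence = runif(1, 0, 40),
               harvest = runif(1, 0, 40), litterfall = runif(1, 0, 40),
               decomposition = runif(1, 0, 40))
    res <- update_vegetation(st, fl, runif(1, 0, 20), runif(1, 0, 20))
    before <- st$agb_living + st$agb_dead + st$litter
    after <- res$state$agb_living + res$state$agb_dead + res$state$litter
    rl <- res$realized
    expect_equal(after - before,
                 rl$actual_growth - rl$harvest - rl$ingestion_living -
                   rl$ingestion_dead - rl$decomposition,
                 tolerance = 1e-9)
    expect_true(all(unlist(res$state) >= 0))
  }
})

test_that("with no limitation and no losses, biomass grows linearly at xf", {
  vp <- default_vegetation_params(1)
  xf <- vp$xf[1]
  st <- list(agb_living = 100, agb_dead = 0, litter = 0)
  traj <- numeric(10)
  for (t in 1:10) {
    g <- potential_growth(xf, 1, 1)
    st <- update_vegetation(st, list(actual_growth = actual_growth(g, 1)))$state
    traj[t] <- st$agb_living
  }
  expect_equal(traj, 100 + xf * (1:10))
})
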