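test_that("soil mass and FD stock follow the unit algebra", {
  expect_equal(soil_mass(1.0, 10), 1000)
  expect_equal(soil_mass(1.2, 15), 1800)
  expect_equal(fd_stock(10, 1.5, 15), 22.5)
  expect_equal(fd_stock(0, 1.5, 15), 0)
  set.seed(3)
  bd <- runif(20, 0.8, 1.8); d <- runif(20, 5, 100); cc <- runif(20, 0, 30)
  expect_equal(fd_stock(cc, bd, d), soil_mass(bd, d) * cc / 1000)
  expect_equal(soil_mass(bd, 2 * d), 2 * soil_mass(bd, d))
})

test_that("reference masses average t0 replicate layer masses per treatment", {
  ps <- as_profile_set(rbind(
    make_profile_df(0, 15, 1.2, 10, plot = "a"),
    make_profile_df(0, 15, 1.0, 12, plot = "b")))
  refs <- reference_masses(ps)
  expect_equal(refs$ref_mass_Mg_ha, mean(c(1800, 1500)))
  single <- reference_masses(as_profile_set(make_profile_df(
    c(0, 15), c(15, 30), c(1.2, 1.4), c(10, 6))))
  expect_equal(single$ref_mass_Mg_ha, c(1800, 2100))
  expect_equal(single$cum_ref_mass_Mg_ha, c(1800, 3900))
  expect_error(reference_masses(ps, t0_label = "t9"), "t9")
})

test_that("all three methods agree when sampled masses equal the references", {
  ps <- make_profile_set(n_plots = 3, jitter = 0)  # identical replicates
  st <- stocks_pipeline(ps)
  expect_equal(nrow(st), 3 * 2 * 3 * 3)  # plots x times x layers x methods
  wide <- split(st$stock_MgC_ha, st$method)
  expect_equal(wide$ESM_classical, wide$FD, tolerance = 1e-9)
  expect_equal(wide$ESM_spline, wide$FD, tolerance = 1e-9)
  # cumulative columns are prefix sums within a profile/method
  one <- st[st$plot == "p1" & st$time == "t0" & st$method == "FD", ]
  expect_equal(one$cum_stock_MgC_ha, cumsum(one$stock_MgC_ha))
  expect_equal(one$cum_mass_Mg_ha, cumsum(one$soil_mass_Mg_ha))
})

test_that("spline ESM recovers the smooth underlying mass-stock relation", {
  set.seed(11)
  for (k in 1:10) {
    p <- random_smooth_profile()
    cum_mass <- cumsum(soil_mass(p$bd, p$bottom - p$top))
    cum_stock <- cumsum(fd_stock(p$conc, p$bd, p$bottom - p$top))
    query <- cum_mass * runif(4, 0.92, 0.98)
    got <- esm_spline_cum(cum_mass, cum_stock, query)$cum_stock
    want <- fine_cum_stock_cont(p$bfun, p$cfun, max(p$bottom), query)
    expect_lt(max(abs(got - want) / want), 0.005)
  }
})

test_that("spline ESM stays within 1% of a step-concentration column", {
  # against piecewise-constant layers the true mass-stock curve is kinked at
  # every boundary, which caps what any smooth interpolant can achieve
  top <- c(0, 15, 30, 60); bottom <- c(15, 30, 60, 100)
  bd <- c(1.25, 1.35, 1.45, 1.55); conc <- c(10, 8, 6, 4.5)
  cum_mass <- cumsum(soil_mass(bd, bottom - top))
  cum_stock <- cumsum(fd_stock(conc, bd, bottom - top))
  query <- 0.95 * cum_mass
  got <- esm_spline_cum(cum_mass, cum_stock, query)$cum_stock
  want <- fine_cum_stock(top, bottom, bd, conc, query)
  expect_lt(max(abs(got - want) / want), 0.01)
})

test_that("spline ESM reproduces knots exactly and controls extrapolation", {
  cum_mass <- c(1800, 3900, 8400)
  cum_stock <- c(18, 30, 39)
  at_knots <- esm_spline_cum(cum_mass, cum_stock, cum_mass)
  expect_equal(at_knots$cum_stock, cum_stock, tolerance = 1e-12)
  expect_false(any(at_knots$extrapolated))
  expect_error(esm_spline_cum(cum_mass, cum_stock, 9000), "extrapolate")
  ext <- esm_spline_cum(cum_mass, cum_stock, 9000, extrapolate = TRUE)
  expect_true(ext$extrapolated)
  # continuation beyond the last knot is linear: zero second differences
  far <- esm_spline_cum(cum_mass, cum_stock, c(8800, 9200, 9600),
                        extrapolate = TRUE)$cum_stock
  expect_equal(diff(far, differences = 2), 0, tolerance = 1e-9)
})

test_that("classical ESM applies the surplus/deficit corrections", {
  # one-layer surplus: ESM = FD - surplus * conc / 1000
  out <- esm_classical_cum(cum_mass = c(2000, 4000),
                           cum_stock = c(20, 32), conc = c(10, 6),
                           ref_cum_mass = c(1800, 4000))
  expect_equal(out$cum_stock[1], 20 - 200 * 10 / 1000)
  expect_equal(out$cum_stock[2], 32)
  # deficit borrows at the deeper layer's concentration
  out2 <- esm_classical_cum(cum_mass = c(2000, 4000),
                            cum_stock = c(20, 32), conc = c(10, 6),
                            ref_cum_mass = c(2100, 4000))
  expect_equal(out2$cum_stock[1], 20 + 100 * 6 / 1000)
  expect_error(esm_classical_cum(c(2000, 4000), c(20, 32), c(10, 6),
                                 c(2000, 4200)),
               "deepest")
  ext <- esm_classical_cum(c(2000, 4000), c(20, 32), c(10, 6),
                           c(2000, 4200), extrapolate = TRUE)
  expect_equal(ext$cum_stock[2], 32 + 200 * 6 / 1000)
  expect_true(ext$extrapolated[2])
})

test_that("classical and spline ESM agree closely on smooth profiles", {
  set.seed(23)
  ps <- make_profile_set(n_plots = 4, bd = c(1.25, 1.4, 1.5, 1.6),
                         conc = c(11, 7, 4, 2),
                         top = c(0, 15, 30, 60), bottom = c(15, 30, 60, 100),
                         bd_mult = 0.95, conc_mult = 1.1, jitter = 0.02)
  st <- stocks_pipeline(ps, extrapolate = TRUE)
  sp <- st$cum_stock_MgC_ha[st$method == "ESM_spline"]
  cl <- st$cum_stock_MgC_ha[st$method == "ESM_classical"]
  expect_true(all(abs(sp - cl) / cl < 0.02))
})

test_that("stocks scale with concentration and vanish with no change", {
  ps <- make_profile_set(n_plots = 2, jitter = 0.03, seed = 5)
  st <- stocks_pipeline(ps, extrapolate = TRUE)
  ps3 <- ps; ps3$c_g_kg <- 3 * ps3$c_g_kg
  st3 <- stocks_pipeline(as_profile_set(as.data.frame(ps3)),
                         extrapolate = TRUE)
  expect_equal(st3$stock_MgC_ha, 3 * st$stock_MgC_ha, tolerance = 1e-9)
  # t0 == t1 => zero change under every method
  chg <- sapply(split(st, list(st$plot, st$method)), function(s)
    sum(s$stock_MgC_ha[s$time == "t1"]) - sum(s$stock_MgC_ha[s$time == "t0"]))
  expect_equal(unname(chg), rep(0, length(chg)), tolerance = 1e-9)
})

test_that("mass-preserving compaction moves FD but not ESM stocks", {
  top <- c(0, 15, 30, 60); bottom <- c(15, 30, 60, 100)
  bd <- c(1.25, 1.40, 1.50, 1.60); conc <- c(11, 7, 4, 2)
  t1 <- compact_oracle(top, bottom, bd, conc, c(1.15, 1.08, 1.02, 1.0))
  ps <- as_profile_set(rbind(
    make_profile_df(top, bottom, bd, conc),
    make_profile_df(top, bottom, t1$bd, t1$conc, time = "t1")))
  st <- stocks_pipeline(ps)
  tot <- function(m, tm) sum(st$stock_MgC_ha[st$method == m & st$time == tm])
  fd_change <- tot("FD", "t1") - tot("FD", "t0")
  expect_gt(fd_change, 0.5)  # compaction inflates the fixed-depth stock
  for (m in c("ESM_spline", "ESM_classical")) {
    expect_lt(abs(tot(m, "t1") - tot(m, "t0")), 0.01 * tot(m, "t0"))
  }
  # FD error is concentrated at the surface
  surf <- st[st$layer_top_cm == 0 & st$method == "FD", ]
  fd_surf <- surf$stock_MgC_ha[surf$time == "t1"] -
    surf$stock_MgC_ha[surf$time == "t0"]
  expect_gt(abs(fd_surf), 1)
})

test_that("uniform-concentration compaction gives exactly zero classical ESM change", {
  top <- c(0, 15, 30); bottom <- c(15, 30, 60)
  bd <- c(1.2, 1.4, 1.5); conc <- rep(8, 3)
  t1 <- compact_oracle(top, bottom, bd, conc, c(1.2, 1.1, 1.0))
  ps <- as_profile_set(rbind(
    make_profile_df(top, bottom, bd, conc),
    make_profile_df(top, bottom, t1$bd, t1$conc, time = "t1")))
  st <- stocks_pipeline(ps, methods = c("FD", "ESM_classical"))
  cl <- st[st$method == "ESM_classical", ]
  expect_equal(cl$stock_MgC_ha[cl$time == "t1"],
               cl$stock_MgC_ha[cl$time == "t0"], tolerance = 1e-12)
})
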