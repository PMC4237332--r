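simple_site <- function() kba_site("S1", "IBA", "C1", rect_ring(0, 0, 10, 10))

test_that("kba_protection_percent uses union semantics and date filters", {
  site <- simple_site()
  inside <- protected_area("P1", "C1", rect_ring(-1, -1, 11, 11), 1980L)
  expect_equal(kba_protection_percent(site, list(inside)), 100)

  half_a <- protected_area("P2", "C1", rect_ring(0, 0, 5, 10), 1980L)
  half_b <- protected_area("P3", "C1", rect_ring(0, 0, 5, 10), 1990L)
  expect_equal(kba_protection_percent(site, list(half_a, half_b)), 50)

  late <- protected_area("P4", "C1", rect_ring(0, 0, 10, 10), 2000L)
  expect_equal(kba_protection_percent(site, list(late), year = 1999), 0)
  expect_equal(kba_protection_percent(site, list(late), year = 2000), 100)
})

test_that("rectangle overlap math matches a Monte-Carlo oracle", {
  set.seed(17)
  for (i in 1:5) {
    site <- simple_site()
    pas <- lapply(1:4, function(k) {
      x0 <- runif(1, -2, 8); y0 <- runif(1, -2, 8)
      protected_area(sprintf("P%d", k), "C1",
                     rect_ring(x0, y0, x0 + runif(1, 1, 6),
                               y0 + runif(1, 1, 6)), 1970L)
    })
    exact <- kba_protection_percent(site, pas)
    mc <- mc_protection_percent(site, pas, seed = 100 + i)
    expect_lt(abs(exact - mc), 1)
  }
})

test_that("general polygons fall back to sampling and stay close to exact", {
  # a triangle site with one rectangular PA: exact answer by construction
  tri <- kba_site("T1", "AZE", "C1",
                  cbind(c(0, 10, 0), c(0, 0, 10)))
  pa <- protected_area("P1", "C1", rect_ring(0, 0, 10, 5), 1980L)
  # covered region is the trapezoid below y=5: area 37.5 of 50
  got <- kba_protection_percent(tri, list(pa))
  expect_lt(abs(got - 75), 1)
})

test_that("mean_protection averages a unit's sites", {
  s1 <- kba_site("S1", "IBA", "C1", rect_ring(0, 0, 10, 10))
  s2 <- kba_site("S2", "IBA", "C1", rect_ring(20, 0, 30, 10))
  pa <- protected_area("P1", "C1", rect_ring(-1, -1, 11, 11), 1980L)
  expect_equal(mean_protection("C1", list(s1, s2), list(pa)), 50)
  expect_error(mean_protection("C9", list(s1, s2), list(pa)),
               class = "psrb_no_sites_error")
})

test_that("date imputation samples same-country known years", {
  dated <- protected_area("A", "C1", rect_ring(0, 0, 1, 1), 1990L)
  undated <- protected_area("B", "C1", rect_ring(1, 0, 2, 1))
  out <- impute_establishment_dates(list(dated, undated), seed = 1L)
  expect_equal(out[[2]]$establishment_year, 1990L)
  expect_equal(out[[1]]$establishment_year, 1990L)  # dated untouched

  # all dates known: identity
  out2 <- impute_establishment_dates(list(dated), seed = 1L)
  expect_identical(out2[[1]], dated)

  # two-point pool: empirical frequencies approach 1/2
  pool <- list(protected_area("A", "C1", rect_ring(0, 0, 1, 1), 1960L),
               protected_area("B", "C1", rect_ring(1, 0, 2, 1), 2000L))
  draws <- vapply(1:1000, function(s) {
    u <- protected_area("C", "C1", rect_ring(2, 0, 3, 1))
    impute_establishment_dates(c(pool, list(u)), seed = s)[[3]]$establishment_year
  }, integer(1))
  expect_lt(abs(mean(draws == 1960L) - 0.5), 0.05)

  # country without dated PAs falls back to the global pool, with a message
  lone <- protected_area("D", "C2", rect_ring(3, 0, 4, 1))
  expect_message(out3 <- impute_establishment_dates(c(pool, list(lone)),
                                                    seed = 2L),
                 "global date pool")
  expect_false(is.na(out3[[3]]$establishment_year))

  nothing <- list(protected_area("E", "C3", rect_ring(0, 0, 1, 1)))
  expect_error(impute_establishment_dates(nothing),
               class = "psrb_no_known_dates_error")
})

test_that("bootstrap series: determinism, degeneracy, monotonicity, order", {
  scn <- gen_scenario(tiny_config(seed = 11L, missing_date_fraction = 0.4))
  units <- scn$landscape$units
  a <- bootstrap_protection_series("U1", scn$sites$kbas, scn$sites$pas,
                                   n_boot = 40L, seed = 5L)
  b <- bootstrap_protection_series("U1", scn$sites$kbas, scn$sites$pas,
                                   n_boot = 40L, seed = 5L)
  expect_identical(as.data.frame(a), as.data.frame(b))

  # PA input order must not matter
  perm <- rev(scn$sites$pas)
  c2 <- bootstrap_protection_series("U1", scn$sites$kbas, perm,
                                    n_boot = 40L, seed = 5L)
  expect_equal(a$mean_pct, c2$mean_pct)
  expect_equal(a$ci_low, c2$ci_low)

  # every replicate is monotone non-decreasing in year, and in [0, 100]
  reps <- attr(a, "replicates")
  expect_true(all(reps >= 0 & reps <= 100 + 1e-9))
  expect_true(all(apply(reps, 1L, function(x) all(diff(x) >= -1e-9))))
  expect_true(all(a$ci_low <= a$mean_pct + 1e-12) &&
                all(a$mean_pct <= a$ci_high + 1e-12))

  # zero missing dates: the band collapses for every year
  full <- gen_sites(tiny_config(seed = 11L, missing_date_fraction = 0))
  z <- bootstrap_protection_series("U1", full$kbas, full$pas,
                                   n_boot = 25L, seed = 5L)
  expect_equal(z$ci_low, z$mean_pct)
  expect_equal(z$ci_high, z$mean_pct)

  # n_boot = 1 collapses onto the single replicate
  one <- bootstrap_protection_series("U1", scn$sites$kbas, scn$sites$pas,
                                     n_boot = 1L, seed = 5L)
  expect_equal(one$ci_low, one$mean_pct)
  expect_equal(one$ci_high, one$mean_pct)
})

test_that("protection_annual_rate is the 1980-2010 slope", {
  scn <- gen_sites(tiny_config(seed = 12L, missing_date_fraction = 0))
  ser <- bootstrap_protection_series("U1", scn$kbas, scn$pas,
                                     n_boot = 1L, seed = 1L)
  expect_equal(protection_annual_rate(ser),
               (ser$mean_pct[ser$year == 2010] -
                  ser$mean_pct[ser$year == 1980]) / 30)

  flat <- ser
  flat$mean_pct <- rep(40, nrow(flat))
  expect_equal(protection_annual_rate(flat), 0)

  synth <- ser
  synth$mean_pct[synth$year == 1980] <- 20
  synth$mean_pct[synth$year == 2010] <- 80
  expect_equal(protection_annual_rate(synth), 2)
  synth$mean_pct[synth$year == 1980] <- 37.1
  synth$mean_pct[synth$year == 2010] <- 100
  expect_equal(protection_annual_rate(synth), (100 - 37.1) / 30)
})

test_that("regions pool their member countries' sites", {
  scn <- gen_scenario(tiny_config(seed = 14L))
  units <- scn$landscape$units
  reg_sites <- sites_in_unit(scn$sites$kbas, units[["R1"]], units)
  expect_equal(length(reg_sites), length(scn$sites$kbas))
  expect_error(sites_in_unit(scn$sites$kbas, units[["R1"]]),
               class = "psrb_unit_input_error")
})
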