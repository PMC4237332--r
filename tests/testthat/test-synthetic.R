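test_that("generators are pure functions of (seed, config)", {
  a <- gen_scenario(tiny_config(seed = 3L))
  b <- gen_scenario(tiny_config(seed = 3L))
  expect_identical(a$landscape$grids, b$landscape$grids)
  expect_identical(a$species$assessments, b$species$assessments)
  expect_identical(a$sites, b$sites)
  expect_identical(a$survey$responses, b$survey$responses)

  c2 <- gen_scenario(tiny_config(seed = 4L))
  expect_false(identical(a$landscape$grids$cover2000$values,
                         c2$landscape$grids$cover2000$values))
})

test_that("zero loss rate yields an all-zero loss grid", {
  ls <- gen_landscape(tiny_config(true_annual_loss_rate = 0))
  expect_true(all(ls$grids$loss$values == 0))
})

test_that("generated D8 grids drain every cell to a sink (path oracle)", {
  ls <- gen_landscape(scenario_config(seed = 2L, grid_shape = c(10L, 10L)))
  v <- ls$grids$ddir$values
  codes <- c(1, 2, 4, 8, 16, 32, 64, 128)
  drow <- c(0, 1, 1, 1, 0, -1, -1, -1)
  dcol <- c(1, 1, 0, -1, -1, -1, 0, 1)
  for (r in 1:10) for (cc in 1:10) {
    cr <- r; c0 <- cc
    for (step in 1:100) {
      if (v[cr, c0] == 0) break
      k <- match(v[cr, c0], codes)
      cr <- cr + drow[k]; c0 <- c0 + dcol[k]
    }
    expect_equal(v[cr, c0], 0)
  }
})

test_that("species ground truth behaves at the boundaries", {
  no_change <- gen_species_table(tiny_config(category_change_prob = 0))
  gt <- no_change$ground_truth
  expect_equal(gt$rli_first, gt$rli_last)
  expect_true(all(no_change$assessments$change_from == ""))

  # planted-change count matches an independent re-draw of the generator
  cfg <- scenario_config(seed = 7L, n_units = 2L, grid_shape = c(12L, 12L),
                         n_species_per_taxon = c(mammal = 7L, bird = 7L,
                                                 amphibian = 6L),
                         category_change_prob = 0.3)
  n1 <- sum(nzchar(gen_species_table(cfg)$assessments$change_from))
  n2 <- sum(nzchar(gen_species_table(cfg)$assessments$change_from))
  expect_identical(n1, n2)
  expect_gt(n1, 0L)
})

test_that("genuine changes are one-step and internally consistent", {
  tab <- gen_species_table(tiny_config(category_change_prob = 0.5))$assessments
  ladder <- c("LC", "NT", "VU", "EN", "CR", "EW", "EX")
  ch <- tab[nzchar(tab$change_from), ]
  expect_gt(nrow(ch), 0L)
  expect_true(all(ch$change_to == ch$last_category))
  expect_true(all(abs(match(ch$change_from, ladder) -
                        match(ch$change_to, ladder)) == 1L))
  # driver units are a subset of the species' membership
  for (i in seq_len(nrow(ch)))
    expect_true(all(strsplit(ch$driver_units[i], ";")[[1]] %in%
                      strsplit(ch$units[i], ";")[[1]]))
})

test_that("site generation honours missing_date_fraction and stores truth", {
  s0 <- gen_sites(tiny_config(missing_date_fraction = 0))
  expect_false(any(is.na(vapply(s0$pas, function(p) p$establishment_year,
                                integer(1)))))

  s3 <- gen_sites(tiny_config(missing_date_fraction = 0.5))
  est <- vapply(s3$pas, function(p) p$establishment_year, integer(1))
  expect_equal(sum(is.na(est)), floor(0.5 * 8))
  gt <- s3$ground_truth$pa_years
  expect_false(any(is.na(gt$year)))
  expect_equal(gt$withheld, is.na(est))
})

test_that("KBA rectangles of one country never overlap", {
  s <- gen_sites(tiny_config(seed = 9L, n_kba = 6L))
  boxes <- lapply(s$kbas, function(k) geom_bbox(k$geometry))
  ctry <- vapply(s$kbas, function(k) k$country_id, character(1))
  for (i in seq_along(boxes)) for (j in seq_along(boxes)) {
    if (i >= j || ctry[i] != ctry[j]) next
    b1 <- boxes[[i]]; b2 <- boxes[[j]]
    overlap <- max(0, min(b1[3], b2[3]) - max(b1[1], b2[1])) *
      max(0, min(b1[4], b2[4]) - max(b1[2], b2[2]))
    expect_equal(overlap, 0)
  }
})

test_that("survey generator matches its probability vector at large n", {
  cfg <- scenario_config(seed = 5L, n_units = 1L, survey_n = 1000L,
                         survey_probs = c(0.5, 0.25, 0.25, 0))
  resp <- gen_survey(cfg)$responses
  freq <- prop.table(table(factor(resp$status,
                                  levels = c("Monitored", "LimitedMonitoring",
                                             "NotMonitored", "Unknown"))))
  expect_true(all(abs(as.numeric(freq) - c(0.5, 0.25, 0.25, 0)) < 0.05))

  all_mon <- gen_survey(scenario_config(seed = 1L, n_units = 1L,
                                        survey_n = 5L,
                                        survey_probs = c(1, 0, 0, 0)))
  expect_true(all(all_mon$responses$status == "Monitored"))
})

test_that("a scenario round-trips through the file writers losslessly", {
  scn <- gen_scenario(tiny_config(seed = 6L))
  dir <- withr::local_tempdir()
  write_scenario(scn, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- read_scenario(dir)
  for (nm in names(scn$landscape$grids))
    expect_identical(back$grids[[nm]]$values,
                     scn$landscape$grids[[nm]]$values)
  expect_equal(back$assessments, scn$species$assessments)
  expect_equal(back$responses, scn$survey$responses)
  expect_equal(length(back$pas), length(scn$sites$pas))
  expect_equal(vapply(back$pas, function(p) p$establishment_year, integer(1)),
               vapply(scn$sites$pas, function(p) p$establishment_year,
                      integer(1)))
})
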