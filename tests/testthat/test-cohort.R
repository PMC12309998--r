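test_that("noise-free simulation reproduces the deterministic expectations", {
  spec <- small_spec(Vg = 0, Vge = 0, cv_r = 0, priming_sd = 0)
  sim <- simulate_cohort(spec, derive = FALSE)
  joined <- dplyr::left_join(
    sim$table, expected_cell_means(spec),
    by = c("genotype", "row_type", "trait", "treatment"))
  expect_equal(joined$value, joined$expectation, tolerance = 1e-12)
  expect_true(is_balanced(sim$table))
  expect_equal(nrow(sim$table), 6 * 3 * 4 * 2)
})

test_that("identical (spec, seed) pairs give identical tables", {
  spec <- small_spec(Vg = 0.05, Vge = 0.02, cv_r = 0.1, priming_sd = 0.3)
  a <- simulate_cohort(spec, seed = 11)$table
  b <- simulate_cohort(spec, seed = 11)$table
  expect_identical(a, b)
  c <- simulate_cohort(spec, seed = 12)$table
  expect_false(isTRUE(all.equal(a$value, c$value)))
})

test_that("empirical cell means converge to expectations (3 SE)", {
  # many replicates of one cell; log-scale effects are mean-one
  spec <- small_spec(n = 3, n_reps = 4, Vg = 0.05, Vge = 0.02, cv_r = 0.1)
  sims <- lapply(1:400, function(s) {
    tab <- simulate_cohort(spec, seed = s, derive = FALSE)$table
    tab$value[tab$genotype == "S01" & tab$treatment == "Ds" &
                tab$trait == "MSW"]
  })
  vals <- unlist(sims)
  exp_tbl <- expected_cell_means(spec)
  mu <- exp_tbl$expectation[exp_tbl$genotype == "S01" &
                              exp_tbl$treatment == "Ds" &
                              exp_tbl$trait == "MSW"]
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - mu), 3 * se)
})

test_that("planted near-zero main-ear retention shows up as ~5% of control", {
  spec <- small_spec(sus_main_retention = 0.05)
  # raw expected change% of a susceptible genotype = multiplier x
  # row-normalised modifier; with one archetype per row-type position the
  # normalisation is within row type
  ex <- expected_cell_means(spec)
  sus <- spec$genotypes$genotype[spec$genotypes$archetype == "susceptible"]
  ch <- ex |>
    dplyr::filter(.data$trait == "MSW", .data$genotype %in% sus) |>
    tidyr::pivot_wider(names_from = "treatment",
                       values_from = "expectation") |>
    dplyr::mutate(change = 100 * .data$Ds / .data$C)
  # retention 0.05 vs block mean ~0.45: raw change ~ 50% x 0.05/0.45
  expect_true(all(ch$change < 12))
  sim <- simulate_cohort(spec, derive = FALSE)
  chm <- change_percent_matrix(sim$table, "Ds")
  got <- chm$change_pct[chm$trait == "MSW" & chm$genotype %in% sus]
  expect_equal(got, ch$change, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("cohort specs round-trip through YAML", {
  spec <- default_study_spec(seed = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_spec(spec, path)
  back <- read_cohort_spec(path)
  expect_equal(back$genotypes, spec$genotypes)
  expect_equal(back$n_reps, spec$n_reps)
  expect_equal(back$variance, spec$variance)
  expect_equal(back$seed, spec$seed)
  expect_equal(expected_cell_means(back), expected_cell_means(spec),
               tolerance = 1e-12)
  # and simulation from the round-tripped spec is identical
  expect_identical(simulate_cohort(back)$table, simulate_cohort(spec)$table)
})

test_that("default study spec encodes the published panel conditions", {
  spec <- default_study_spec()
  expect_equal(nrow(spec$genotypes), 28L)
  expect_equal(sum(spec$genotypes$row_type == "2R"), 13L)
  counts <- table(spec$genotypes$archetype)
  expect_equal(unname(counts[c("main_ear_preserver", "side_ear_compensator",
                               "susceptible")]), c(14L, 6L, 8L),
               ignore_attr = TRUE)

  b <- spec$baselines
  expect_equal(b$baseline[b$trait == "GY" & b$row_type == "2R"], 4.7)
  te <- spec$treatment_effects
  gy2_ds <- te$multiplier[te$trait == "GY" & te$row_type == "2R" &
                            te$treatment == "Ds"]
  expect_equal(gy2_ds, 2.45 / 4.7, tolerance = 1e-12)
  expect_equal(4.7 * gy2_ds, 2.45, tolerance = 1e-12)
  gy6_ds <- te$multiplier[te$trait == "GY" & te$row_type == "6R" &
                            te$treatment == "Ds"]
  expect_equal(gy6_ds, 1 - 0.4752, tolerance = 1e-12)

  # panel-level expected stress intensity for GY sits in the design window
  ex <- expected_cell_means(spec)
  gy <- ex[ex$trait == "GY", ]
  yp <- mean(gy$expectation[gy$treatment == "C"])
  ys <- mean((gy$expectation[gy$treatment == "Ds"] +
                gy$expectation[gy$treatment == "Dd"]) / 2)
  expect_gt(1 - ys / yp, 0.46)
  expect_lt(1 - ys / yp, 0.49)
})

test_that("spec validation catches inconsistent inputs", {
  spec <- small_spec()
  g <- spec$genotypes; g$archetype[1] <- "hero"
  expect_error(cohort_spec(g, 4, spec$baselines, spec$treatment_effects),
               class = "droughtphen_spec_error")
  b <- spec$baselines; b$baseline[1] <- -1
  expect_error(cohort_spec(spec$genotypes, 4, b, spec$treatment_effects),
               class = "droughtphen_spec_error")
  te <- spec$treatment_effects[-1, ]
  expect_error(expected_cell_means(
    cohort_spec(spec$genotypes, 4, spec$baselines, te)),
    class = "droughtphen_spec_error")
})
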