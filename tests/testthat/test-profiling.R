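test_that("change percent matrix is stress/control x 100", {
  tbl <- toy_table()
  chm <- change_percent_matrix(tbl, "Ds")
  expect_s3_class(chm, "change_matrix")
  # toy table: stress factor 0.5 of control for every genotype
  expect_equal(chm$change_pct, rep(50, 2), ignore_attr = TRUE)
  same <- tbl
  same$value[same$treatment == "Ds"] <- same$value[same$treatment == "C"]
  expect_equal(change_percent_matrix(same, "Ds")$change_pct, rep(100, 2))
  # published two-row example
  expect_equal(100 * 2.45 / 4.7, 52.13, tolerance = 1e-3)
  expect_error(change_percent_matrix(tbl, "C"),
               class = "droughtphen_argument_error")
  # invariant under uniform rescaling of a trait
  scaled <- tbl; scaled$value <- scaled$value * 13
  expect_equal(change_percent_matrix(scaled, "Ds")$change_pct,
               chm$change_pct)
  # zero control mean goes missing with a warning
  z <- tbl; z$value[z$treatment == "C" & z$genotype == "A"] <- 0
  expect_warning(chz <- change_percent_matrix(z, "Ds"), "zero control")
  expect_true(is.na(chz$change_pct[chz$genotype == "A"]))
})

test_that("noise-free cohort change matrix equals the planted multipliers", {
  spec <- small_spec()
  sim <- simulate_cohort(spec, derive = FALSE)
  chm <- change_percent_matrix(sim$table, "Ds")
  ex <- expected_cell_means(spec) |>
    tidyr::pivot_wider(names_from = "treatment", values_from = "expectation")
  joined <- dplyr::left_join(chm, ex, by = c("genotype", "trait"))
  expect_equal(joined$change_pct, 100 * joined$Ds / joined$C,
               tolerance = 1e-10)
})

test_that("clustering recovers noise-free archetype blocks exactly", {
  sim <- simulate_cohort(small_spec(n = 12), derive = FALSE)
  chm <- change_percent_matrix(sim$table, "Ds")
  cl <- cluster_axis(chm, "genotypes", k = 3)
  truth <- sim$truth$genotypes
  m <- dplyr::left_join(cl$labels, truth, by = c(item = "genotype"))
  expect_equal(rand_index(m$cluster, m$archetype), 1.0)
  if (requireNamespace("mclust", quietly = TRUE)) {
    expect_equal(mclust::adjustedRandIndex(m$cluster, m$archetype), 1.0)
  }
  # group numbering: most affected group gets the highest number
  gy <- dplyr::left_join(chm[chm$trait == "GY", ], cl$labels,
                         by = c(genotype = "item"))
  mean_by_cl <- tapply(gy$change_pct, gy$cluster, mean)
  expect_true(all(diff(mean_by_cl[order(as.integer(names(mean_by_cl)))]) <= 0))
})

test_that("clustering is column-order invariant; duplicates merge at 0; k bounds", {
  sim <- simulate_cohort(small_spec(n = 9, Vg = 0.05, Vge = 0.02,
                                    cv_r = 0.1), derive = FALSE)
  chm <- change_percent_matrix(sim$table, "Ds")
  cl1 <- cluster_axis(chm, "genotypes", k = 3)
  perm <- chm[order(rev(seq_len(nrow(chm)))), ]
  cl2 <- cluster_axis(perm, "genotypes", k = 3)
  m <- dplyr::inner_join(cl1$labels, cl2$labels, by = "item")
  expect_equal(rand_index(m$cluster.x, m$cluster.y), 1.0)
  expect_equal(cl1$labels$cluster[order(cl1$labels$item)],
               cl2$labels$cluster[order(cl2$labels$item)])

  # duplicated genotype columns merge at height zero
  dup <- chm[chm$genotype == "S01", ]
  dup$genotype <- "S01copy"
  chm2 <- dplyr::bind_rows(chm, dup)
  cl3 <- cluster_axis(chm2, "genotypes", k = 3)
  expect_equal(min(cl3$hclust$height), 0)
  lab <- setNames(cl3$labels$cluster, cl3$labels$item)
  expect_equal(lab[["S01"]], lab[["S01copy"]])

  # k = 1 puts everything in one group and profiles are identically 100
  cl_one <- cluster_axis(chm, "genotypes", k = 1)
  expect_equal(unique(cl_one$labels$cluster), 1L)
  prof <- group_profile(chm, cl_one$labels)
  expect_equal(prof$profile, rep(100, nrow(prof)), tolerance = 1e-12)

  expect_error(cluster_axis(chm, "genotypes", k = 99),
               class = "droughtphen_argument_error")
  # trait-axis clustering runs and labels every trait
  clt <- cluster_axis(chm, "traits", k = 2)
  expect_setequal(clt$labels$item, unique(chm$trait))
})

test_that("group profiles are proportions of the grand mean change", {
  chm <- structure(tibble::new_tibble(tibble::tibble(
    trait = "GY", genotype = c("a", "b", "c", "d"),
    row_type = "2R", change_pct = c(50, 50, 150, 150)),
    class = "change_matrix"), treatment = "Ds")
  labels <- tibble::tibble(item = c("a", "b", "c", "d"),
                           cluster = c(1L, 1L, 2L, 2L))
  prof <- group_profile(chm, labels)
  expect_equal(prof$profile, c(50, 150))
  expect_equal(prof$group_change_pct, c(50, 150))
  expect_equal(unique(prof$grand_change_pct), 100)
  expect_error(group_profile(chm, labels[1:2, ]),
               class = "droughtphen_argument_error")
})

test_that("separation letters distinguish separated groups and share under ties", {
  set.seed(31)
  vals <- c(rnorm(6, 0, 0.01), rnorm(6, 10, 0.01), rnorm(6, 20, 0.01))
  labs <- rep(1:3, each = 6)
  lt <- group_separation_letters(vals, labs)
  expect_equal(length(unique(lt)), 3L)
  # identical distributions share a letter
  same <- rep(c(1.0, 1.1, 0.9, 1.05, 0.95), 2)
  lt2 <- group_separation_letters(same, rep(1:2, each = 5))
  expect_equal(unname(lt2[1]), unname(lt2[2]))
  # degenerate all-equal input shares "a"
  lt3 <- group_separation_letters(rep(2, 8), rep(1:2, each = 4))
  expect_equal(unname(lt3), c("a", "a"))
  expect_error(group_separation_letters(1:4, c(1, 1, 1, 2)),
               class = "droughtphen_argument_error")
})

test_that("ANOVA partition sums to 100 and isolates pure effects", {
  spec <- small_spec(n = 6)
  sim <- simulate_cohort(spec, derive = FALSE)
  # noise-free data with archetype structure: treatment + genotype +
  # interaction explain everything, residual 0
  part <- suppressWarnings(anova_ss_partition(sim$table, "MSW"))
  expect_equal(sum(part$ss_pct), 100, tolerance = 1e-9)
  expect_equal(part$ss_pct[part$term == "residual"], 0, tolerance = 1e-9)

  # y depending only on treatment: treatment SS% = 100
  tbl <- toy_table()
  tbl$value <- c(C = 1, Ds = 2, Dd = 3)[tbl$treatment]
  part2 <- suppressWarnings(anova_ss_partition(tbl, "GY"))
  expect_equal(part2$ss_pct[part2$term == "treatment"], 100,
               tolerance = 1e-9)
  expect_equal(sum(part2$ss_pct[part2$term != "treatment"]), 0,
               tolerance = 1e-9)

  # strong genotype effects dominate a weak treatment effect
  spec_g <- additive_spec(n = 10, Vg = 4, Vge = 0, Vr = 0.25, seed = 2)
  sim_g <- simulate_cohort(spec_g, derive = FALSE)
  part3 <- anova_ss_partition(sim_g$table, "GY")
  expect_gt(part3$ss_pct[part3$term == "genotype"],
            part3$ss_pct[part3$term == "treatment"])

  # unbalanced input is refused
  drop_one <- sim$table[-which(sim$table$trait == "MSW")[1], ]
  expect_error(anova_ss_partition(drop_one, "MSW"),
               class = "droughtphen_balance_error")
})

test_that("rand index counts pairwise agreements", {
  expect_equal(rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y")), 1)
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), 1 / 3)
  expect_equal(rand_index(1:4, rep(1, 4)), 0)
})
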