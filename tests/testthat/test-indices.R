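test_that("index formulas match hand arithmetic", {
  expect_equal(stress_intensity(2, 4), 0.5)
  expect_equal(stress_intensity(4, 4), 0)
  expect_error(stress_intensity(2, 0), class = "droughtphen_domain_error")

  expect_equal(dsi(4, 2, 0.5), 1.0)
  expect_equal(dsi(4, 3, 0.5), 0.5)
  expect_equal(dsi(4, 4, 0.5), 0.0)
  expect_warning(out <- dsi(4, 2, 0), "SI is 0")
  expect_true(is.na(out))

  expect_equal(sti(4, 4, 4), 1.0)
  expect_equal(sti(4, 2, 4), 0.5)
  expect_equal(sti(4, 0, 4), 0.0)

  expect_equal(ysi(4, 2), 0.5)
  expect_equal(tol(4, 2), 2)
  expect_equal(ysi(4, 4), 1)
  expect_equal(tol(4, 4), 0)
})

test_that("TOL = Yp * (1 - YSI) on random inputs", {
  set.seed(101)
  Yp <- runif(200, 0.5, 10)
  Ys <- runif(200, 0, 1) * Yp
  expect_equal(tol(Yp, Ys), Yp * (1 - ysi(Yp, Ys)), tolerance = 1e-12)
})

test_that("stress mean averages the two stress treatments equally", {
  tbl <- toy_table()
  ys <- stress_mean(tbl, "GY")
  # genotype A: control 4, Ds 2, Dd 1.6 (replicate offsets cancel)
  expect_equal(ys$Yp[ys$genotype == "A"], 4)
  expect_equal(ys$Ys[ys$genotype == "A"], (2 + 1.6) / 2)
  # published two-row example: Ds 2.45 g, Dd 2.2 g
  expect_equal((2.45 + 2.2) / 2, 2.325)
  # identical stress treatments collapse to themselves
  same <- tbl
  same$value[same$treatment == "Dd"] <- same$value[same$treatment == "Ds"]
  ys2 <- stress_mean(same, "GY")
  expect_equal(ys2$Ys, stress_mean(same, "GY", "Ds")$Ys)
  # missing treatment errors with guidance
  expect_error(stress_mean(tbl[tbl$treatment != "Dd", ], "GY"),
               "single-treatment", class = "droughtphen_config_error")
  expect_silent(stress_mean(tbl[tbl$treatment != "Dd", ], "GY", "Ds"))
})

test_that("DSI is exactly 1 for a genotype at panel-average relative loss", {
  # panel built so genotype P's Ys/Yp equals grand_Ys/grand_Yp
  Yp <- c(P = 4, Q = 2, R = 6)
  ratio_others <- c(Q = 0.3, R = 0.7)
  # choose P's ratio x so that (4x + 0.6 + 4.2) / 12 = x
  x <- (2 * 0.3 + 6 * 0.7) / (sum(Yp) - 4)
  Ys <- c(P = 4 * x, Q = 0.6, R = 4.2)
  SI <- stress_intensity(mean(Ys), mean(Yp))
  expect_equal(dsi(Yp[["P"]], Ys[["P"]], SI), 1.0, tolerance = 1e-12)
})

test_that("indices are monotone in Ys with panel fixed", {
  SI <- 0.5; Yp <- 4; grand_Yp <- 5
  Ys <- seq(0.1, 3.9, length.out = 25)
  expect_true(all(diff(dsi(Yp, Ys, SI)) < 0))
  expect_true(all(diff(tol(Yp, Ys)) < 0))
  expect_true(all(diff(sti(Yp, Ys, grand_Yp)) > 0))
  expect_true(all(diff(ysi(Yp, Ys)) > 0))
})

test_that("ratio indices are scale invariant; TOL scales linearly", {
  tbl <- toy_table()
  idx1 <- stress_indices(tbl)
  scaled <- tbl
  scaled$value <- scaled$value * 3.7
  idx2 <- stress_indices(scaled)
  idx2 <- idx2[match(idx1$genotype, idx2$genotype), ]
  for (col in c("SI", "DSI", "STI", "YSI")) {
    expect_equal(idx2[[col]], idx1[[col]], tolerance = 1e-12)
  }
  expect_equal(idx2$TOL, 3.7 * idx1$TOL, tolerance = 1e-12)
})

test_that("classification applies the published joint thresholds", {
  base <- tibble::tibble(
    genotype = sprintf("g%d", 1:8),
    DSI = c(0.3, 1.8, 1.0, 0.9, 1.1, 0.8, 1.2, 0.9),
    YSI = c(0.80, 0.20, 0.5, 0.5, 0.5, 0.6, 0.4, 0.5),
    STI = c(1.2, 0.10, 0.6, 0.7, 0.6, 0.8, 0.4, 0.6),
    TOL = c(0.2, 5.0, 2, 2.2, 2.4, 1.9, 2.6, 2.1))
  out <- classify_tolerance(base)
  expect_equal(out$class[1], "most_tolerant")
  expect_equal(out$class[2], "most_susceptible")
  expect_true(all(out$class[3:8] == "intermediate"))
  # DSI boundary resolves to the sensitive side (strict inequality)
  expect_equal(out$dsi_class[out$DSI == 1.0], "sensitive")
  # missing index leaves a genotype unclassified
  base$STI[4] <- NA
  expect_equal(classify_tolerance(base)$class[4], "unclassified")
})

test_that("consensus rank averages per-index ranks deterministically", {
  res <- tibble::tibble(
    genotype = c("b", "a", "c"),
    DSI = c(0.2, 1.5, 0.8), STI = c(1.5, 0.2, 0.8),
    YSI = c(0.9, 0.2, 0.6), TOL = c(0.3, 3.0, 1.2))
  out <- consensus_rank(res)
  expect_equal(out$genotype, c("b", "c", "a"))
  expect_equal(out$consensus_rank, 1:3)

  # identical genotypes take adjacent ranks in name order
  dup <- res
  dup$genotype <- c("z", "z2", "c")
  dup[2, -1] <- dup[1, -1]
  out2 <- consensus_rank(dup)
  expect_equal(out2$genotype[out2$consensus_rank <= 2], c("z", "z2"))

  # brute-force oracle on a random panel
  set.seed(7)
  pan <- tibble::tibble(
    genotype = sprintf("g%02d", 1:12),
    DSI = runif(12), STI = runif(12), YSI = runif(12), TOL = runif(12))
  out3 <- consensus_rank(pan)
  score <- (rank(pan$DSI) + rank(pan$TOL) + rank(-pan$STI) +
              rank(-pan$YSI)) / 4
  expect_equal(out3$genotype,
               pan$genotype[order(score, pan$genotype)])
  expect_error(consensus_rank(pan[1, ]),
               class = "droughtphen_domain_error")
})

test_that("stress_indices agrees with a manual recomputation on a cohort", {
  sim <- simulate_cohort(default_study_spec(seed = 5))
  idx <- stress_indices(sim$table)
  cm <- oracle_cell_means(sim$table, "GY")
  w <- tidyr::pivot_wider(tibble::as_tibble(cm), names_from = "treatment",
                          values_from = "value")
  Yp <- w$C; Ys <- (w$Ds + w$Dd) / 2
  SI <- 1 - mean(Ys) / mean(Yp)
  m <- match(w$genotype, idx$genotype)
  expect_equal(idx$SI[1], SI, tolerance = 1e-12)
  expect_equal(idx$DSI[m], (1 - Ys / Yp) / SI, tolerance = 1e-12)
  expect_equal(idx$STI[m], Ys * Yp / mean(Yp)^2, tolerance = 1e-12)
})
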