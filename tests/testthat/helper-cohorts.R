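# Shared fixture builders; all data is generated in code.

# Minimal deterministic two-genotype table: 2 genotypes x 3 treatments x
# 4 replicates x 1 trait = 24 records.
toy_table <- function(trait = "GY") {
  grid <- expand.grid(
    genotype = c("A", "B"), treatment = c("C", "Ds", "Dd"),
    replicate = 1:4, stringsAsFactors = FALSE)
  grid$row_type <- ifelse(grid$genotype == "A", "2R", "6R")
  grid$trait <- trait
  # value = base (4 for A, 6 for B) * treatment factor + replicate offset
  fac <- c(C = 1, Ds = 0.5, Dd = 0.4)
  base <- c(A = 4, B = 6)
  grid$value <- base[grid$genotype] * fac[grid$treatment] +
    0.1 * (grid$replicate - 2.5)
  tibble::as_tibble(grid[c("genotype", "row_type", "treatment", "replicate",
                           "trait", "value")])
}

# Small spec for fast simulator tests: n genotypes, two traits with
# archetype structure on one of them.
small_spec <- function(n = 6, n_reps = 4, Vg = 0, Vge = 0, cv_r = 0,
                       priming_sd = 0, seed = 1,
                       sus_main_retention = 0.08) {
  stopifnot(n >= 3)
  arch <- rep(c("main_ear_preserver", "side_ear_compensator",
                "susceptible"), length.out = n)
  genotypes <- tibble::tibble(
    genotype = sprintf("S%02d", seq_len(n)),
    row_type = rep(c("2R", "6R"), length.out = n),
    archetype = arch)
  baselines <- tidyr::crossing(
    tibble::tibble(trait = c("GY", "MSW")), row_type = c("2R", "6R"))
  baselines$baseline <- ifelse(baselines$trait == "GY", 4, 1.5)
  te <- tidyr::crossing(trait = c("GY", "MSW"), row_type = c("2R", "6R"),
                        treatment = c("Ds", "Dd"))
  te$multiplier <- ifelse(te$treatment == "Ds", 0.5, 0.45)
  ar <- tidyr::crossing(trait = "MSW", treatment = c("Ds", "Dd"),
                        tibble::tibble(
                          archetype = c("main_ear_preserver",
                                        "side_ear_compensator",
                                        "susceptible"),
                          retention = c(0.8, 0.5, sus_main_retention)))
  cohort_spec(genotypes = genotypes, n_reps = n_reps, baselines = baselines,
              treatment_effects = te, archetype_retention = ar,
              variance = list(scale = "log", Vg = Vg, Vge = Vge,
                              cv_r = cv_r),
              priming = list(sd = priming_sd, traits = "GY"), seed = seed)
}

# One-trait additive-scale spec used for variance-component recovery.
additive_spec <- function(n = 28, n_reps = 4, Vg = 1, Vge = 0.5, Vr = 0.25,
                          baseline = 10, seed = 1) {
  genotypes <- tibble::tibble(
    genotype = sprintf("S%02d", seq_len(n)),
    row_type = rep(c("2R", "6R"), length.out = n),
    archetype = rep("main_ear_preserver", n))
  baselines <- tidyr::crossing(trait = "GY", row_type = c("2R", "6R"))
  baselines$baseline <- baseline
  te <- tidyr::crossing(trait = "GY", row_type = c("2R", "6R"),
                        treatment = c("Ds", "Dd"))
  te$multiplier <- 1
  cohort_spec(genotypes = genotypes, n_reps = n_reps, baselines = baselines,
              treatment_effects = te,
              variance = list(scale = "additive", Vg = Vg, Vge = Vge,
                              Vr = Vr),
              priming = list(sd = 0, traits = character()), seed = seed)
}

# Independent brute-force cell means over records (oracle for cell_means).
oracle_cell_means <- function(table, trait) {
  sub <- table[table$trait == trait, ]
  agg <- aggregate(value ~ genotype + treatment, data = as.data.frame(sub),
                   FUN = mean)
  agg[order(agg$genotype, agg$treatment), ]
}

# Henderson mixed-model equations for the balanced two-way model with
# treatment fixed, genotype and genotype:treatment random. Returns the
# predicted genotype means mu + u_g (oracle for blup_genotype_means).
mme_blup_means <- function(table, trait, Vg, Vge, Vr) {
  sub <- as.data.frame(table[table$trait == trait, ])
  g <- factor(sub$genotype); t_ <- factor(sub$treatment)
  y <- sub$value
  X <- stats::model.matrix(~t_)
  Zg <- stats::model.matrix(~g - 1)
  Zge <- stats::model.matrix(~g:t_ - 1)
  lam_g <- Vr / Vg
  lam_ge <- Vr / Vge
  C <- rbind(
    cbind(crossprod(X), crossprod(X, Zg), crossprod(X, Zge)),
    cbind(crossprod(Zg, X), crossprod(Zg) + diag(lam_g, ncol(Zg)),
          crossprod(Zg, Zge)),
    cbind(crossprod(Zge, X), crossprod(Zge, Zg),
          crossprod(Zge) + diag(lam_ge, ncol(Zge))))
  rhs <- c(crossprod(X, y), crossprod(Zg, y), crossprod(Zge, y))
  sol <- solve(C, rhs)
  beta <- sol[seq_len(ncol(X))]
  u_g <- sol[ncol(X) + seq_len(ncol(Zg))]
  # intercept parameterisation: mean over treatments of the fixed part
  mu <- beta[1] + mean(c(0, beta[-1]))
  data.frame(genotype = levels(g), pred = mu + u_g)
}
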