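test_that("same seed reproduces the cohort, different seeds differ", {
  cfg <- sim_config(n_case = 60, n_control = 60)
  a <- simulate_cohort(cfg, seed = 101)
  b <- simulate_cohort(cfg, seed = 101)
  d <- simulate_cohort(cfg, seed = 102)
  expect_identical(a$geno, b$geno)
  expect_identical(a$info, b$info)
  expect_false(identical(a$geno, d$geno))

  t1 <- suppressWarnings(simulate_from_published_tables(seed = 9))
  t2 <- suppressWarnings(simulate_from_published_tables(seed = 9))
  expect_identical(t1$geno, t2$geno)
})

test_that("control genotype frequencies converge to the configured values", {
  freqs <- c(L1 = 0.2, L2 = 0.5, L3 = 0.7)
  cfg <- sim_config(n_case = 10, n_control = 100000, control_freqs = freqs,
                    covariates = NULL)
  co <- simulate_cohort(cfg, seed = 55)
  ctrl <- co$geno[co$info$status == "control", ]
  for (l in names(freqs))
    expect_equal(mean(ctrl[, l]) / 2, unname(freqs[l]), tolerance = 0.01)
})

test_that("null model produces no case-control frequency differences", {
  cfg <- sim_config(n_case = 5000, n_control = 5000,
                    control_freqs = c(L1 = 0.3, L2 = 0.5), covariates = NULL)
  co <- simulate_cohort(cfg, seed = 31)
  for (l in c("L1", "L2")) {
    pc <- allele_frequency(genotype_counts(co, l, "case"))
    p0 <- allele_frequency(genotype_counts(co, l, "control"))
    # 3 binomial MC standard errors on the difference
    se <- sqrt(pc * (1 - pc) / (2 * 5000) + p0 * (1 - p0) / (2 * 5000))
    expect_lt(abs(pc - p0), 3 * se + 1e-12)
  }
})

test_that("a configured per-allele effect is recovered by logistic refit", {
  cfg <- sim_config(n_case = 4000, n_control = 4000,
                    control_freqs = c(L1 = 0.3, L2 = 0.4),
                    or = c(L1 = 2.0, L2 = 1.0), covariates = NULL)
  co <- simulate_cohort(cfg, seed = 61)
  y <- as.numeric(co$info$status == "case")
  fit <- fit_logistic(y, cbind(g = co$geno[, "L1"]))
  expect_equal(unname(coef(fit)["g"]), log(2), tolerance = 0.1)
})

test_that("published-table simulation honours group sizes and frequencies", {
  co <- suppressWarnings(simulate_from_published_tables(seed = 44))
  v <- validate_cohort(co)
  expect_equal(v$n_cases, 137)
  expect_equal(v$n_controls, 150)
  expect_length(v$errors, 0)

  # degenerate frequencies give constant genotypes
  f <- data.frame(locus_id = "L1", group = c("case", "control"),
                  risk_freq = c(0, 0), g0 = c(1, 1), g1 = c(0, 0), g2 = c(0, 0))
  loci <- locus_set("L1", "A", "B", "B")
  co2 <- simulate_from_published_tables(f, n_case = 10, n_control = 10,
                                        seed = 1, loci = loci)
  expect_true(all(co2$geno == 0))

  # frequencies beyond the slack are rejected
  f_bad <- data.frame(locus_id = "L1", group = c("case", "control"),
                      risk_freq = c(0, 0), g0 = c(0.5, 1), g1 = c(0.4, 0),
                      g2 = c(0, 0))
  expect_error(simulate_from_published_tables(f_bad, 10, 10, seed = 1, loci = loci),
               "config error")
})

test_that("a D' = 1 haplotype block is recovered by the EM", {
  block <- list(loci = c("L1", "L2"),
                freq = c(`00` = 0.55, `11` = 0.45))
  cfg <- sim_config(n_case = 1000, n_control = 1000,
                    control_freqs = c(L1 = 0.45, L2 = 0.45, L3 = 0.2),
                    hap_blocks = list(block), covariates = NULL)
  co <- simulate_cohort(cfg, seed = 71)
  fit <- em_haplotypes(co, c("L1", "L2"))
  f <- setNames(fit$freq, fit$haplotype)
  expect_lt(abs(f[["BB"]] - 0.45), 0.02)
  expect_lt(abs(f[["AA"]] - 0.55), 0.02)
  expect_lt(f[["AB"]] + f[["BA"]], 0.02)
  expect_equal(ld_stats(fit)$D_prime, 1, tolerance = 0.02)
})

test_that("covariates follow the group-specific generators", {
  cfg <- sim_config(n_case = 2000, n_control = 2000)
  co <- simulate_cohort(cfg, seed = 81)
  pub <- ra_published_covariates()
  age_case <- mean(co$info$age[co$info$status == "case"])
  age_ctrl <- mean(co$info$age[co$info$status == "control"])
  expect_equal(age_case, pub$case$age_mean, tolerance = 1)
  expect_equal(age_ctrl, pub$control$age_mean, tolerance = 1)
  p_male_case <- mean(co$info$sex[co$info$status == "case"] == "male")
  expect_equal(p_male_case, pub$case$p_male, tolerance = 0.05)
})

test_that("infeasible acceptance rates raise a simulation error", {
  cfg <- sim_config(n_case = 50, n_control = 10,
                    control_freqs = c(L1 = 0.5), covariates = NULL,
                    target_acceptance = 1e-6)
  expect_error(simulate_cohort(cfg, seed = 2, max_attempts = 3L),
               "simulation error")
})
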