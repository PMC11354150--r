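test_that("genotype counts tabulate non-missing dosages per group", {
  co <- tiny_cohort()
  ct <- genotype_counts(co, "L1", "case")
  expect_equal(c(ct$n0, ct$n1, ct$n2, ct$n), c(1, 1, 1, 3))
  ct_all <- genotype_counts(co, "L2", "all")
  expect_equal(ct_all$n, 4)  # one missing genotype excluded
  expect_error(genotype_counts(co, "nope"), "unknown locus")

  # all-missing locus
  loci <- two_loci()
  co2 <- cohort(loci, c("S1", "S2"), c("case", "control"),
                rbind(c(NA, 0), c(NA, 1)))
  expect_equal(genotype_counts(co2, "L1")$n, 0)
})

test_that("allele frequency reproduces the published frequency rows", {
  # genotype-frequency triples in risk-dosage order (g0, g1, g2)
  expect_equal(allele_frequency(c(0.21, 0.50, 0.29)), 0.54)  # TRAF1 patients, A
  expect_equal(allele_frequency(c(0.28, 0.32, 0.40)), 0.56)  # ACE patients, D
  expect_equal(allele_frequency(c(0.40, 0.48, 0.12)), 0.36)  # VDR TaqI patients, G
  expect_equal(allele_frequency(c(0.77, 0.22, 0.01)), 0.12)  # PTPN22 controls, T
  expect_equal(allele_frequency(c(10, 0, 0)), 0)
  expect_error(allele_frequency(c(0, 0, 0)), "undefined")
})

test_that("HWE chi-square matches the hand-expanded statistic", {
  expect_equal(hwe_chi_square(c(25, 50, 25))$statistic, 0)
  expect_equal(hwe_chi_square(c(25, 50, 25))$p_value, 1)

  # hand expansion for (38, 44, 55): q = 154/274, expected (26.28, 67.45, 43.28)
  q <- (44 + 110) / 274
  expected <- 137 * c((1 - q)^2, 2 * q * (1 - q), q^2)
  stat <- sum((c(38, 44, 55) - expected)^2 / expected)
  res <- hwe_chi_square(c(38, 44, 55))
  expect_equal(res$statistic, stat)
  expect_equal(round(stat, 2), 16.55)
  expect_equal(res$p_value, pchisq(stat, 1, lower.tail = FALSE))

  # complete heterozygote deficit
  expect_lt(hwe_chi_square(c(10, 0, 10))$p_value, 1e-4)
  # monomorphic: degenerate
  expect_equal(hwe_chi_square(c(12, 0, 0))$p_value, 1)
})

test_that("HWE chi-square statistic is invariant under allele-label swap", {
  set.seed(11)
  for (i in 1:25) {
    x <- rmultinom(1, 80, prob = runif(3))[, 1]
    if (sum(x[2:3]) == 0 || sum(x[1:2]) == 0) next
    expect_equal(hwe_chi_square(x)$statistic, hwe_chi_square(rev(x))$statistic)
  }
})

test_that("exact HWE test equals the enumeration oracle", {
  # frozen: (2,1,2) -> sum of P(n_ab = 1) and P(n_ab = 5) = 23/63
  expect_equal(hwe_exact(c(2, 1, 2))$p_value, 23 / 63, tolerance = 1e-12)
  expect_equal(hwe_exact(c(5, 0, 0))$p_value, 1)

  set.seed(7)
  for (i in 1:30) {
    x <- rmultinom(1, sample(10:200, 1), prob = runif(3))[, 1]
    expect_equal(hwe_exact(x)$p_value, hwe_exact_oracle(x[1], x[2], x[3]),
                 tolerance = 1e-9)
  }
})

test_that("exact and chi-square tests agree and are valid under the null", {
  set.seed(31)
  n_sim <- 500
  p_exact <- numeric(n_sim); p_chi <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    g <- rbinom(100, 2, 0.4)
    x <- c(sum(g == 0), sum(g == 1), sum(g == 2))
    p_exact[i] <- hwe_exact(x)$p_value
    p_chi[i] <- hwe_chi_square(x)$p_value
  }
  expect_gt(cor(p_exact, p_chi), 0.9)
  # super-uniform: rejection rate at 5% does not exceed nominal + MC slack
  expect_lt(mean(p_exact < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("count reconstruction inverts published rounded rows", {
  cand <- reconstruct_counts(c(0.59, 0.35, 0.06), 137)  # PTPN22 patients
  expect_length(cand, 1)
  expect_equal(c(cand[[1]]$n0, cand[[1]]$n1, cand[[1]]$n2), c(81, 48, 8))

  cand <- reconstruct_counts(c(0.11, 0.54, 0.35), 150)  # TRAF1 controls
  expect_length(cand, 2)
  triples <- lapply(cand, function(x) c(x$n0, x$n1, x$n2))
  has <- function(t) any(vapply(triples, function(x) all(x == t), logical(1)))
  expect_true(has(c(16, 81, 53)) && has(c(17, 81, 52)))

  cand <- reconstruct_counts(c(1, 0, 0), 5)
  expect_length(cand, 1)
  expect_equal(cand[[1]]$n0, 5)
})

test_that("rows admitting candidates have an allele-frequency-consistent one", {
  f <- ra_published_freqs()
  feasible <- 0
  for (i in seq_len(nrow(f))) {
    n <- if (f$group[i] == "case") 137 else 150
    cand <- reconstruct_counts(c(f$g0[i], f$g1[i], f$g2[i]), n)
    if (!length(cand)) next  # printed row sums away from 1; no integer triple fits
    feasible <- feasible + 1
    af <- vapply(cand, allele_frequency, numeric(1))
    expect_true(any(round_half_away(af, 2) == f$risk_freq[i]),
                label = sprintf("%s/%s has a consistent candidate",
                                f$locus_id[i], f$group[i]))
  }
  expect_gte(feasible, 19)
})

test_that("locus summary flags HWE departures and feeds the TSV writer", {
  co <- suppressWarnings(simulate_from_published_tables(seed = 5))
  ls <- locus_summary(co)
  expect_equal(nrow(ls), 22)
  expect_true(all(abs(ls$f0 + ls$f1 + ls$f2 - 1) < 1e-12))
  expect_true(all(ls$hwe_p >= 0 & ls$hwe_p <= 1, na.rm = TRUE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_locus_summary(ls, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 22)
})
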