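make_two_locus_cohort <- function(genotypes, status = NULL) {
  n <- nrow(genotypes)
  if (is.null(status)) status <- rep(c("case", "control"), length.out = n)
  cohort(two_loci(), paste0("S", seq_len(n)), status, genotypes)
}

test_that("EM resolves the classic coupling example to h(AB) = h(ab) = 0.5", {
  # 4x double-homozygote risk, 2x double heterozygote, 4x double-homozygote ref
  geno <- rbind(matrix(2L, 4, 2), matrix(1L, 2, 2), matrix(0L, 4, 2))
  fit <- em_haplotypes(make_two_locus_cohort(geno), c("L1", "L2"))
  expect_true(fit$converged)
  f <- setNames(fit$freq, fit$haplotype)
  expect_equal(unname(f["GT"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(f["AC"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(f["GC"] + f["AT"]), 0, tolerance = 1e-6)
})

test_that("unambiguous phase converges immediately", {
  # single double homozygote: h = 1 for its haplotype
  fit <- em_haplotypes(make_two_locus_cohort(matrix(2L, 1, 2), "case"), c("L1", "L2"))
  expect_equal(max(fit$freq), 1, tolerance = 1e-9)

  # phase-known cohort (no multi-heterozygote): equals direct counting
  geno <- rbind(c(0, 0), c(2, 2), c(2, 0), c(1, 0), c(0, 2), c(2, 1))
  fit <- em_haplotypes(make_two_locus_cohort(geno), c("L1", "L2"))
  # direct haplotype counting: each individual contributes 2 resolvable haplotypes
  counts <- c(AC = 2 + 1, AT = 2, GC = 2 + 1 + 1, GT = 2 + 1)
  expect_equal(setNames(fit$freq, fit$haplotype)[names(counts)],
               counts / 12, tolerance = 1e-9)
})

test_that("EM equals exhaustive grid-search likelihood maximization", {
  set.seed(17)
  n_checked <- 0
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    geno <- matrix(sample(0:2, 2 * n, replace = TRUE, prob = c(0.3, 0.4, 0.3)),
                   n, 2)
    # both loci must be polymorphic for the margins to be informative
    if (length(unique(geno[, 1])) == 1 || length(unique(geno[, 2])) == 1) next
    co <- make_two_locus_cohort(geno)
    fit <- em_haplotypes(co, c("L1", "L2"))
    oracle <- em_grid_oracle(co, c("L1", "L2"))
    expect_lt(max(abs(fit$freq - unname(oracle))), 1e-3 + 1e-9)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 20)
})

test_that("missing genotypes are excluded and empty input errors", {
  geno <- rbind(c(1, NA), c(NA, 1), c(2, 2))
  fit <- em_haplotypes(make_two_locus_cohort(geno), c("L1", "L2"))
  expect_equal(fit$n, 1)
  geno_all_na <- matrix(NA_integer_, 2, 2)
  expect_error(em_haplotypes(make_two_locus_cohort(geno_all_na), c("L1", "L2")),
               "no complete observations")
})

test_that("LD statistics match the hand formulas", {
  # h(AB)=0.5, h(Ab)=0.1, h(aB)=0.2, h(ab)=0.2
  ld <- ld_stats(c(0.5, 0.1, 0.2, 0.2), n = 100)
  expect_equal(ld$D, 0.08)
  expect_equal(ld$D_prime, 0.08 / 0.18)
  expect_equal(ld$r2, 0.0064 / (0.6 * 0.4 * 0.7 * 0.3))

  # independent haplotypes: D = 0
  p <- 0.6; q <- 0.3
  ld0 <- ld_stats(c(p * q, p * (1 - q), (1 - p) * q, (1 - p) * (1 - q)), n = 50)
  expect_equal(ld0$D, 0)
  expect_equal(ld0$D_prime, 0)
  expect_equal(ld0$r2, 0)

  # complete LD
  ld1 <- ld_stats(c(0.7, 0, 0, 0.3), n = 50)
  expect_equal(ld1$D_prime, 1)
  expect_equal(ld1$r2, 1)

  expect_error(ld_stats(c(1, 0, 0, 0), 10), "monomorphic")
})

test_that("D-prime and r2 are invariant under allele relabelling", {
  set.seed(5)
  for (i in 1:20) {
    h <- rexp(4); h <- h / sum(h)  # (AB, Ab, aB, ab)
    ld <- ld_stats(h, n = 100)
    # swap alleles at locus 1: (aB, ab, AB, Ab)
    ld_sw1 <- ld_stats(h[c(3, 4, 1, 2)], n = 100)
    # swap alleles at locus 2
    ld_sw2 <- ld_stats(h[c(2, 1, 4, 3)], n = 100)
    expect_equal(ld$D_prime, ld_sw1$D_prime, tolerance = 1e-12)
    expect_equal(ld$r2, ld_sw1$r2, tolerance = 1e-12)
    expect_equal(ld$D_prime, ld_sw2$D_prime, tolerance = 1e-12)
    expect_equal(ld$r2, ld_sw2$r2, tolerance = 1e-12)
  }
})

test_that("haplotype association recovers a dosage effect and drops absent haplotypes", {
  # phase-known data: both loci monomorphic-coupled so haplotypes are countable
  set.seed(23)
  n <- 1200
  # draw haplotype pairs directly: AB risk haplotype with OR 3 per copy
  hfreq <- c(GT = 0.15, GC = 0.25, AT = 0.25, AC = 0.35)
  h1 <- sample(names(hfreq), n, replace = TRUE, prob = hfreq)
  h2 <- sample(names(hfreq), n, replace = TRUE, prob = hfreq)
  dose_gt <- (h1 == "GT") + (h2 == "GT")
  p_case <- plogis(-1.5 + log(3) * dose_gt)
  status <- ifelse(runif(n) < p_case, "case", "control")
  g1 <- (substr(h1, 1, 1) == "G") + (substr(h2, 1, 1) == "G")
  g2 <- (substr(h1, 2, 2) == "T") + (substr(h2, 2, 2) == "T")
  co <- cohort(two_loci(), paste0("S", 1:n), status, cbind(g1, g2))
  ha <- haplotype_association(co, c("L1", "L2"))
  gt_row <- ha[ha$haplotype == "GT", ]
  expect_gt(gt_row$or, 1.8)
  expect_lt(gt_row$p_value, 0.01)

  # absent haplotype never appears in the output
  geno <- rbind(matrix(2L, 6, 2), matrix(0L, 6, 2),
                cbind(rep(2L, 6), rep(1L, 6)))
  co2 <- make_two_locus_cohort(geno)
  ha2 <- haplotype_association(co2, c("L1", "L2"), freq_floor = 0)
  expect_false("AT" %in% ha2$haplotype)
})

test_that("null haplotype data give ORs near 1", {
  set.seed(77)
  n <- 800
  geno <- cbind(rbinom(n, 2, 0.5), rbinom(n, 2, 0.4))
  co <- make_two_locus_cohort(geno, sample(c("case", "control"), n, replace = TRUE))
  ha <- haplotype_association(co, c("L1", "L2"))
  non_ref <- ha[!is.na(ha$p_value), ]
  expect_true(all(non_ref$or > 0.6 & non_ref$or < 1.7))
})
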