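# Shared fixtures: small deterministic cohorts built in code.

two_loci <- function() {
  locus_set(c("L1", "L2"), allele_a = c("A", "C"), allele_b = c("G", "T"),
            risk_allele = c("G", "T"), rsid = c("rs1", "rs2"))
}

# a tiny fully specified cohort: 3 cases, 2 controls, 2 loci
tiny_cohort <- function() {
  cohort(two_loci(),
         sample_id = paste0("S", 1:5),
         status = c("case", "case", "case", "control", "control"),
         geno = rbind(c(0, 2), c(1, 1), c(2, 0), c(0, 1), c(1, NA)),
         age = c(50, 61, 47, 55, 58),
         sex = c("female", "male", "female", "female", "male"),
         diet = c("mixed", "vegetarian", "mixed", "mostly_meat", "mixed"),
         alcohol = c("0", "1-6", "0", "14+", "7-13"),
         smoking = c("never", "ever", "never", "never", "ever"))
}

# random cohort for property tests; missingness optional
random_cohort <- function(seed, n = 20, n_loci = 3, miss_rate = 0.1) {
  set.seed(seed)
  loci <- locus_set(paste0("L", seq_len(n_loci)),
                    allele_a = rep("A", n_loci), allele_b = rep("B", n_loci),
                    risk_allele = rep("B", n_loci))
  geno <- matrix(sample(0:2, n * n_loci, replace = TRUE), n, n_loci)
  if (miss_rate > 0)
    geno[sample(length(geno), ceiling(miss_rate * length(geno)))] <- NA
  cohort(loci,
         sample_id = paste0("S", seq_len(n)),
         status = sample(c("case", "control"), n, replace = TRUE,
                         prob = c(0.5, 0.5)),
         geno = geno,
         age = sample(30:80, n, replace = TRUE),
         sex = sample(c("male", "female"), n, replace = TRUE),
         diet = sample(c("vegetarian", "mixed", "mostly_meat"), n, replace = TRUE),
         alcohol = sample(c("0", "1-6", "7-13", "14+"), n, replace = TRUE),
         smoking = sample(c("never", "ever"), n, replace = TRUE))
}

# published risk-allele frequency vectors, named by locus
published_risk_freqs <- function(group) {
  f <- ra_published_freqs()
  stats::setNames(f$risk_freq[f$group == group], f$locus_id[f$group == group])
}

# independent enumeration oracle for the exact HWE test: multinomial
# probabilities computed directly from factorials over all genotype triples
# with the observed allele counts
hwe_exact_oracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nb <- n1 + 2 * n2
  na <- 2 * n - nb
  probs <- c()
  labels <- c()
  for (nab in 0:min(na, nb)) {
    if ((nb - nab) %% 2 != 0) next
    naa <- (na - nab) / 2
    nbb <- (nb - nab) / 2
    if (naa < 0 || nbb < 0 || naa != round(naa)) next
    p <- exp(lfactorial(n) - lfactorial(naa) - lfactorial(nab) - lfactorial(nbb) +
               nab * log(2) + lfactorial(na) + lfactorial(nb) - lfactorial(2 * n))
    probs <- c(probs, p)
    labels <- c(labels, nab)
  }
  p_obs <- probs[labels == n1]
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

# 1-parameter grid-search likelihood oracle for 2-locus EM: the MLE keeps
# haplotype margins at the observed allele frequencies, leaving h(BB) free
em_grid_oracle <- function(cohort, loci, step = 1e-3) {
  j <- match(loci, cohort$loci$locus_id)
  geno <- cohort$geno[, j, drop = FALSE]
  geno <- geno[stats::complete.cases(geno), , drop = FALSE]
  p1 <- mean(geno[, 1]) / 2   # risk-allele freq locus 1
  p2 <- mean(geno[, 2]) / 2
  loglik <- function(h11) {
    h10 <- p1 - h11; h01 <- p2 - h11; h00 <- 1 - p1 - p2 + h11
    h <- c(h00, h01, h10, h11)  # index by bits (g1, g2)
    if (any(h < -1e-12)) return(-Inf)
    h <- pmax(h, 0)
    hp <- function(b1, b2) h[b1 * 2 + b2 + 1]
    ll <- 0
    for (i in seq_len(nrow(geno))) {
      g <- geno[i, ]
      pr <- 0
      for (a1 in 0:1) for (a2 in 0:1) for (b1 in 0:1) for (b2 in 0:1)
        if (a1 + b1 == g[1] && a2 + b2 == g[2])
          pr <- pr + hp(a1, a2) * hp(b1, b2)
      ll <- ll + log(max(pr, 1e-300))
    }
    ll
  }
  lo <- max(0, p1 + p2 - 1)
  hi <- min(p1, p2)
  grid <- seq(lo, hi, by = step)
  lls <- vapply(grid, loglik, numeric(1))
  h11 <- grid[which.max(lls)]
  c(`00` = 1 - p1 - p2 + h11, `01` = p2 - h11, `10` = p1 - h11, `11` = h11)
}
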