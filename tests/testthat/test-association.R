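test_that("contingency odds ratio, Woolf interval and Haldane correction", {
  # equal odds
  res <- contingency_or(rbind(c(20, 80), c(20, 80)))
  expect_equal(res$or, 1)

  # hand Woolf computation
  res <- contingency_or(rbind(c(40, 97), c(17, 133)))
  expect_equal(res$or, 5320 / 1649)
  se <- sqrt(1 / 40 + 1 / 97 + 1 / 17 + 1 / 133)
  expect_equal(res$lower, exp(log(5320 / 1649) - qnorm(0.975) * se))
  expect_equal(round(res$or, 2), 3.23)
  expect_equal(round(res$lower, 2), 1.73)
  expect_equal(round(res$upper, 2), 6.03)

  # zero cell: 0.5 added everywhere, flagged
  res <- contingency_or(rbind(c(0, 10), c(5, 5)))
  expect_true(res$haldane)
  expect_equal(res$or, (0.5 * 5.5) / (10.5 * 5.5))

  # zero margin is undefined
  expect_error(contingency_or(rbind(c(0, 10), c(0, 5))), "margin")
})

test_that("inheritance models collapse genotype counts correctly", {
  ca <- counts(45, 73, 19); co <- counts(74, 69, 7)
  rec <- model_tables(ca, co, "recessive")
  expect_equal(unname(rec), rbind(c(19, 118), c(7, 143)))
  dom <- model_tables(ca, co, "dominant")
  expect_equal(unname(dom), rbind(c(92, 45), c(76, 74)))
  all2 <- model_tables(ca, co, "allelic_2x2")
  expect_equal(unname(all2), rbind(c(111, 163), c(83, 217)))
  cod <- model_tables(ca, co, "codominant")
  expect_equal(unname(cod), rbind(c(45, 73, 19), c(74, 69, 7)))
})

test_that("logistic IRLS matches closed forms and glm, and flags separation", {
  # independence: slope ~ 0
  y <- rep(c(1, 0), each = 100)
  x <- rep(c(1, 0, 1, 0), each = 50)
  fit <- fit_logistic(y, cbind(x = x))
  expect_equal(unname(coef(fit)["x"]), 0, tolerance = 1e-10)

  # saturated 2x2: slope equals the sample log-odds difference to 10 sig digits
  y <- c(rep(1, 137), rep(0, 150))
  x <- c(rep(1, 40), rep(0, 97), rep(1, 17), rep(0, 133))
  fit <- fit_logistic(y, cbind(exposed = x))
  expect_equal(unname(coef(fit)["exposed"]), log(5320 / 1649), tolerance = 1e-11)

  # independent cross-check against glm on a multi-regressor design
  set.seed(42)
  n <- 300
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  yy <- rbinom(n, 1, plogis(-0.3 + 0.8 * x1 - 0.5 * x2))
  ours <- fit_logistic(yy, cbind(x1 = x1, x2 = x2))
  ref <- glm(yy ~ x1 + x2, family = binomial())
  expect_equal(unname(coef(ours)), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(diag(vcov(ours))), unname(diag(vcov(ref))), tolerance = 1e-6)
  expect_equal(as.numeric(logLik(ours)), as.numeric(logLik(ref)), tolerance = 1e-9)

  # perfect separation
  ys <- c(0, 0, 0, 1, 1, 1)
  xs <- c(-3, -2, -1, 1, 2, 3)
  expect_warning(fs <- fit_logistic(ys, cbind(x = xs)), "separation")
  expect_true(fs$separation)
  expect_false(fs$converged)

  expect_error(fit_logistic(rep(1, 5), cbind(x = rnorm(5))), "classes")
  expect_error(fit_logistic(c(0, 1, 0), cbind(k = rep(2, 3))), "constant")
})

test_that("likelihood-ratio test is computed against the correct null", {
  set.seed(9)
  y <- rbinom(200, 1, 0.5)
  x <- rnorm(200)
  full <- fit_logistic(y, cbind(x = x))
  n1 <- sum(y); n0 <- 200 - n1
  null_ll <- n1 * log(n1 / 200) + n0 * log(n0 / 200)
  lrt <- lr_test(full, list(loglik = null_ll, coefficients = 0))
  ref <- glm(y ~ x, family = binomial())
  expect_equal(lrt$statistic, ref$null.deviance - ref$deviance, tolerance = 1e-7)
  expect_equal(lrt$df, 1)
})

test_that("association scan: crude equals covariate-free call, OR group-swap inverts", {
  co <- suppressWarnings(simulate_from_published_tables(seed = 21))
  crude <- suppressWarnings(association_scan(co, covariates = NULL))
  # covariate-free call duplicates crude into the adjusted columns exactly
  expect_identical(crude$crude_or, crude$adj_or)
  expect_identical(crude$crude_p, crude$adj_p)

  # swapping case/control labels inverts every OR
  co_sw <- co
  co_sw$info$status <- factor(ifelse(co$info$status == "case", "control", "case"),
                              levels = c("control", "case"))
  crude_sw <- suppressWarnings(association_scan(co_sw, covariates = NULL))
  ok <- !is.na(crude$crude_or)
  expect_equal(crude_sw$crude_or[ok], 1 / crude$crude_or[ok], tolerance = 1e-8)
})

test_that("dominant and recessive ORs coincide without heterozygotes", {
  loci <- two_loci()
  set.seed(3)
  g1 <- sample(c(0L, 2L), 120, replace = TRUE, prob = c(0.6, 0.4))
  g2 <- sample(0:2, 120, replace = TRUE)
  st <- rep(c("case", "control"), 60)
  co <- cohort(loci, paste0("S", 1:120), st, cbind(g1, g2))
  scan <- suppressWarnings(
    association_scan(co, models = c("dominant", "recessive"), covariates = NULL))
  d <- scan[scan$locus_id == "L1" & scan$model == "dominant", ]
  r <- scan[scan$locus_id == "L1" & scan$model == "recessive", ]
  expect_equal(d$crude_or, r$crude_or)
})

test_that("adjusted scan adjusts: covariates enter the null and wholly-missing ones drop", {
  cfg <- sim_config(n_case = 150, n_control = 150)
  co <- simulate_cohort(cfg, seed = 88)
  expect_warning(
    scan <- association_scan(co, models = "log_additive",
                             covariates = c("sex", "age", "smoking")),
    "smoking")
  expect_setequal(attr(scan, "covariates"), c("sex_male", "age"))
  expect_true(all(scan$adj_or > 0))
  expect_true(all(scan$adj_lower <= scan$adj_or & scan$adj_or <= scan$adj_upper))
})

test_that("Bonferroni threshold and display rounding", {
  b <- bonferroni(0.05, 11)
  expect_equal(b$threshold, 0.05 / 11)
  expect_equal(b$display, "0.0045")
  expect_equal(bonferroni(0.05, 1)$threshold, 0.05)
  expect_equal(bonferroni(0.01, 5)$threshold, 0.002)
  expect_error(bonferroni(0.05, 0), "m")
  expect_error(bonferroni(1.2, 3), "alpha")
})

test_that("covariate comparison reproduces the hand Pearson chi-square", {
  # published sex split: cases 37 M / 100 F, controls 64 M / 84 F
  loci <- two_loci()
  n <- 137 + 148
  sex <- c(rep(c("male", "female"), c(37, 100)), rep(c("male", "female"), c(64, 84)))
  st <- rep(c("case", "control"), c(137, 148))
  co <- cohort(loci, paste0("S", 1:n), st,
               matrix(0L, n, 2), sex = sex,
               age = c(rnorm(137, 49, 10), rnorm(148, 59, 10)))
  tab <- covariate_table(co)
  sex_row <- tab[tab$variable == "sex", ]
  # hand Pearson over the 2x2: sum (obs - exp)^2 / exp
  obs <- c(37, 100, 64, 84)
  exp_ <- c(137 * 101, 137 * 184, 148 * 101, 148 * 184) / 285
  expect_equal(sex_row$statistic, sum((obs - exp_)^2 / exp_), tolerance = 1e-12)
  expect_equal(round(sex_row$statistic, 1), 8.2)
  expect_equal(sex_row$df, 1)
  # cross-check against chisq.test directly
  ref <- chisq.test(rbind(c(37, 100), c(64, 84)), correct = FALSE)
  expect_equal(sex_row$statistic, unname(ref$statistic))

  # identical distributions -> p = 1 / t = 0
  co2 <- cohort(loci, paste0("S", 1:4), c("case", "case", "control", "control"),
                matrix(0L, 4, 2), sex = c("male", "female", "male", "female"),
                age = c(50, 50, 50, 50))
  tab2 <- covariate_table(co2)
  expect_equal(tab2$p_value[tab2$variable == "sex"], 1)
  expect_equal(tab2$statistic[tab2$variable == "age"], 0)
  # single-level covariate is skipped with a note
  expect_match(tab2$note[tab2$variable == "diet"], "skipped")
})
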