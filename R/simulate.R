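#' Simulation configuration for synthetic case-control cohorts
#'
#' Describes the generative model behind [simulate_cohort()]: control
#' risk-allele frequencies per locus, per-allele disease odds ratios,
#' optional haplotype blocks (loci drawn jointly from given haplotype
#' frequencies instead of independently), group-specific covariate
#' distributions, and optional covariate-disease log-odds. Defaults
#' reproduce the study conditions of the 11-locus RA panel: 137 cases,
#' 150 controls, control allele frequencies from the published frequency
#' table, adjusted per-allele odds ratios as effects, and the published
#' covariate distributions.
#'
#' @param n_case,n_control group sizes.
#' @param control_freqs named control risk-allele frequencies, in (0, 1).
#' @param or named per-allele odds ratios (> 0); default all 1 (no effect).
#' @param hap_blocks optional list of blocks, each a list with `loci`
#'   (2-3 locus ids among `names(control_freqs)`) and `freq` (named vector
#'   of haplotype frequencies over risk-allele dosage bit strings such as
#'   `"01"`, summing to 1).
#' @param covariates group-specific covariate generators as returned by
#'   [ra_published_covariates()], or `NULL` to skip covariates.
#' @param covariate_logodds optional named log-odds for covariate effects
#'   on disease (`sex_male`, `age`, `diet_vegetarian`, `diet_mostly_meat`,
#'   `alcohol`); default none.
#' @param target_acceptance mean acceptance probability the disease-model
#'   intercept is solved for (default 0.25).
#' @return a list of class `"raprs_sim_config"`.
#' @export
sim_config <- function(n_case = 137, n_control = 150,
                       control_freqs = NULL, or = NULL, hap_blocks = NULL,
                       covariates = ra_published_covariates(),
                       covariate_logodds = NULL,
                       target_acceptance = 0.25) {
  if (is.null(control_freqs)) {
    pub <- ra_published_freqs()
    control_freqs <- stats::setNames(pub$risk_freq[pub$group == "control"],
                                     pub$locus_id[pub$group == "control"])
  }
  if (is.null(names(control_freqs))) stop_data("control_freqs must be named")
  if (any(control_freqs <= 0 | control_freqs >= 1))
    stop_data("control frequencies must lie in (0, 1)")
  if (is.null(or)) or <- stats::setNames(rep(1, length(control_freqs)),
                                         names(control_freqs))
  if (any(or <= 0)) stop_data("odds ratios must be positive")
  miss <- setdiff(names(control_freqs), names(or))
  if (length(miss)) stop_data("no odds ratio for locus '%s'", miss[1])
  if (!is.null(hap_blocks)) {
    for (b in hap_blocks) {
      stopifnot(all(b$loci %in% names(control_freqs)),
                length(b$loci) %in% 2:3)
      if (abs(sum(b$freq) - 1) > 1e-6)
        stop_data("haplotype block frequencies must sum to 1")
      if (any(nchar(names(b$freq)) != length(b$loci)))
        stop_data("haplotype labels must be dosage bit strings over the block loci")
    }
  }
  structure(list(n_case = n_case, n_control = n_control,
                 control_freqs = control_freqs, or = or[names(control_freqs)],
                 hap_blocks = hap_blocks, covariates = covariates,
                 covariate_logodds = covariate_logodds,
                 target_acceptance = target_acceptance),
            class = "raprs_sim_config")
}

# draw one group's genotype matrix from HWE at `freqs`, haplotype blocks
# overriding the independent draw for their loci
.draw_genotypes <- function(n, freqs, hap_blocks) {
  L <- length(freqs)
  geno <- matrix(0L, n, L, dimnames = list(NULL, names(freqs)))
  for (j in seq_len(L))
    geno[, j] <- stats::rbinom(n, 2L, freqs[j])
  if (!is.null(hap_blocks)) {
    for (b in hap_blocks) {
      labels <- names(b$freq)
      h1 <- sample(labels, n, replace = TRUE, prob = b$freq)
      h2 <- sample(labels, n, replace = TRUE, prob = b$freq)
      for (k in seq_along(b$loci)) {
        bit <- function(lab) as.integer(substr(lab, k, k))
        geno[, b$loci[k]] <- vapply(h1, bit, integer(1)) +
          vapply(h2, bit, integer(1))
      }
    }
  }
  geno
}

.draw_covariates <- function(n, gen) {
  if (is.null(gen)) return(NULL)
  list(age = round(stats::rnorm(n, gen$age_mean, gen$age_sd), 1),
       sex = ifelse(stats::runif(n) < gen$p_male, "male", "female"),
       diet = sample(names(gen$diet), n, replace = TRUE, prob = gen$diet),
       alcohol = sample(names(gen$alcohol), n, replace = TRUE, prob = gen$alcohol))
}

# linear predictor of the disease model (without intercept)
.sim_linpred <- function(geno, cov, config) {
  eta <- drop(geno %*% log(config$or))
  cl <- config$covariate_logodds
  if (!is.null(cl) && !is.null(cov)) {
    if (!is.null(cl[["sex_male"]])) eta <- eta + cl[["sex_male"]] * (cov$sex == "male")
    if (!is.null(cl[["age"]])) eta <- eta + cl[["age"]] * cov$age
    if (!is.null(cl[["diet_vegetarian"]]))
      eta <- eta + cl[["diet_vegetarian"]] * (cov$diet == "vegetarian")
    if (!is.null(cl[["diet_mostly_meat"]]))
      eta <- eta + cl[["diet_mostly_meat"]] * (cov$diet == "mostly_meat")
    if (!is.null(cl[["alcohol"]]))
      eta <- eta + cl[["alcohol"]] * (match(cov$alcohol, ALCOHOL_LEVELS) - 1)
  }
  eta
}

#' Simulate a case-control cohort under a logistic disease model
#'
#' Controls are drawn genotype-wise from Hardy-Weinberg proportions at the
#' control allele frequencies (or jointly from configured haplotype
#' blocks); covariates come from the group-specific generators. Cases are
#' produced by rejection sampling: candidates are drawn from the control
#' model and accepted with probability exp(b0 + sum_l ln(OR_l) g_l +
#' covariate terms), capped at 1, with the intercept b0 solved numerically
#' for the target mean acceptance. Tilting the control distribution by the
#' disease odds is exactly the case distribution a logistic disease model
#' implies given the control frequencies, so a case-control logistic refit
#' recovers ln(OR_l) without rare-disease approximation. Fully reproducible
#' given `seed`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; all randomness flows from it.
#' @param loci optional [locus_set()] supplying allele labels; defaults to
#'   [ra_loci()] when the configured loci match, else synthetic A/B labels.
#' @param max_attempts rejection-sampling cap, as a multiple of the number
#'   of cases still needed per round (default 2000 rounds of batches).
#' @return a [cohort()].
#' @export
simulate_cohort <- function(config, seed = NULL, loci = NULL,
                            max_attempts = 2000L) {
  stopifnot(inherits(config, "raprs_sim_config"))
  ids <- names(config$control_freqs)
  if (is.null(loci)) {
    panel <- ra_loci()
    loci <- if (all(ids %in% panel$locus_id))
      structure(panel[match(ids, panel$locus_id), ],
                class = c("locus_set", "data.frame"))
    else locus_set(ids, allele_a = "A", allele_b = "B", risk_allele = "B")
  }
  with_seed(seed, {
    # controls
    g0 <- .draw_genotypes(config$n_control, config$control_freqs, config$hap_blocks)
    c0 <- .draw_covariates(config$n_control, config$covariates$control)

    # Cases follow f(g | case) proportional to f(g | control) * exp(eta):
    # under a logistic disease model the case distribution is the control
    # distribution tilted by the odds, so accepting control-model draws with
    # probability exp(b0 + eta) reproduces the configured odds ratios
    # exactly. b0 is solved for the target mean acceptance on a Monte Carlo
    # pool and capped so the acceptance probability stays below 1.
    pool_n <- 4000L
    gp <- .draw_genotypes(pool_n, config$control_freqs, config$hap_blocks)
    cp <- .draw_covariates(pool_n, config$covariates$case)
    eta_pool <- .sim_linpred(gp, cp, config)
    b0 <- min(log(config$target_acceptance) - log(mean(exp(eta_pool))),
              -max(eta_pool))

    # cases by rejection
    got <- 0L
    g1 <- matrix(0L, 0, length(ids)); c1 <- NULL
    attempts <- 0L
    while (got < config$n_case) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop_data("simulation error: acceptance too low after %d batches", attempts)
      need <- config$n_case - got
      batch <- max(need * 4L, 50L)
      gb <- .draw_genotypes(batch, config$control_freqs, config$hap_blocks)
      cb <- .draw_covariates(batch, config$covariates$case)
      acc <- stats::runif(batch) < pmin(1, exp(b0 + .sim_linpred(gb, cb, config)))
      take <- which(acc)[seq_len(min(need, sum(acc)))]
      if (length(take)) {
        g1 <- rbind(g1, gb[take, , drop = FALSE])
        if (!is.null(cb))
          c1 <- Map(c, c1 %||% lapply(cb, function(x) x[0]),
                    lapply(cb, function(x) x[take]))
        got <- got + length(take)
      }
    }

    n <- config$n_case + config$n_control
    covs <- if (is.null(c0)) NULL else Map(c, c1, c0)
    cohort(loci,
           sample_id = sprintf("S%04d", seq_len(n)),
           status = rep(c("case", "control"), c(config$n_case, config$n_control)),
           geno = rbind(g1, g0)[, loci$locus_id, drop = FALSE],
           age = covs$age, sex = covs$sex, diet = covs$diet,
           alcohol = covs$alcohol)
  })
}

#' Simulate a cohort directly from published group frequencies
#'
#' Draws each group's genotypes locus-wise from that group's published
#' genotype frequencies — no disease model, no linkage. This is the fixture
#' behind the PRS mean-difference identity: the simulated group allele
#' frequencies are centred on the published ones. Genotype-frequency rows
#' that do not sum to 1 within `slack` (printed rounding) are renormalised
#' with a warning; beyond the slack they are a configuration error.
#'
#' @param freqs data.frame like [ra_published_freqs()]: columns `locus_id`,
#'   `group`, `g0`, `g1`, `g2`.
#' @param n_case,n_control group sizes (defaults 137 / 150).
#' @param seed integer seed.
#' @param loci optional [locus_set()]; defaults as in [simulate_cohort()].
#' @param slack tolerated deviation of a frequency row's sum from 1
#'   (default 0.02).
#' @return a [cohort()] (no covariates).
#' @export
simulate_from_published_tables <- function(freqs = ra_published_freqs(),
                                           n_case = 137, n_control = 150,
                                           seed = NULL, loci = NULL,
                                           slack = 0.03) {
  ids <- unique(freqs$locus_id)
  if (is.null(loci)) {
    panel <- ra_loci()
    loci <- if (all(ids %in% panel$locus_id))
      structure(panel[match(ids, panel$locus_id), ],
                class = c("locus_set", "data.frame"))
    else locus_set(ids, allele_a = "A", allele_b = "B", risk_allele = "B")
  }
  draw_group <- function(group, n) {
    geno <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
    for (id in ids) {
      row <- freqs[freqs$locus_id == id & freqs$group == group, ]
      if (nrow(row) != 1) stop_data("config error: no unique row for %s/%s", id, group)
      p <- c(row$g0, row$g1, row$g2)
      if (abs(sum(p) - 1) > slack + 1e-9)
        stop_data("config error: genotype frequencies for %s/%s sum to %.3f",
                  id, group, sum(p))
      if (abs(sum(p) - 1) > 1e-9) {
        warning(sprintf("genotype frequencies for %s/%s renormalised (sum %.2f)",
                        id, group, sum(p)), call. = FALSE)
        p <- p / sum(p)
      }
      geno[, id] <- sample(0:2, n, replace = TRUE, prob = p)
    }
    geno
  }
  with_seed(seed, {
    g1 <- draw_group("case", n_case)
    g0 <- draw_group("control", n_control)
    cohort(loci,
           sample_id = sprintf("S%04d", seq_len(n_case + n_control)),
           status = rep(c("case", "control"), c(n_case, n_control)),
           geno = rbind(g1, g0)[, loci$locus_id, drop = FALSE])
  })
}
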