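MODEL_NAMES <- c("codominant", "dominant", "recessive", "log_additive", "allelic_2x2")

#' Odds ratio from a 2x2 contingency table
#'
#' Rows are case/control, columns exposed/unexposed. OR = ad/bc with the
#' Woolf 95% interval exp(ln OR +/- z sqrt(1/a + 1/b + 1/c + 1/d)). When any
#' cell is zero the Haldane-Anscombe correction (0.5 added to every cell) is
#' applied to the OR and interval and the result is flagged; the p-value is
#' the Pearson chi-square test (no continuity correction) on the original
#' table.
#'
#' @param table 2x2 numeric matrix of counts `rbind(case = c(exposed,
#'   unexposed), control = c(exposed, unexposed))`.
#' @param level confidence level (default 0.95).
#' @return object of class `"raprs_or"`: list with `or`, `lower`, `upper`,
#'   `p_value`, `haldane`, `table`.
#' @export
contingency_or <- function(table, level = 0.95) {
  tab <- as.matrix(table)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop_data("odds ratio undefined: a margin of the 2x2 table is zero")
  haldane <- any(tab == 0)
  w <- if (haldane) tab + 0.5 else tab
  or <- (w[1, 1] * w[2, 2]) / (w[1, 2] * w[2, 1])
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(sum(1 / w))
  p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  structure(list(or = or, lower = exp(log(or) - z * se),
                 upper = exp(log(or) + z * se),
                 p_value = p, haldane = haldane, table = tab),
            class = "raprs_or")
}

#' @export
print.raprs_or <- function(x, ...) {
  cat(sprintf("OR = %.3f (95%% CI %.3f-%.3f), p = %.4g%s\n",
              x$or, x$lower, x$upper, x$p_value,
              if (x$haldane) " [Haldane-Anscombe corrected]" else ""))
  invisible(x)
}

#' Collapse genotype counts under an inheritance model
#'
#' Builds the contingency table an inheritance model implies from
#' case/control genotype-count triples: dominant collapses carriers
#' (g >= 1) against non-carriers, recessive collapses risk homozygotes
#' (g = 2) against the rest, `allelic_2x2` doubles to allele counts
#' (n1 + 2 n2 risk alleles per group), and codominant keeps the full 2x3.
#' In 2x2 tables the exposed column comes first.
#'
#' @param case_counts,control_counts [counts()] objects or numeric triples.
#' @param model one of `"codominant"`, `"dominant"`, `"recessive"`,
#'   `"allelic_2x2"`.
#' @return integer matrix with rows `case`, `control`.
#' @export
model_tables <- function(case_counts, control_counts,
                         model = c("codominant", "dominant", "recessive", "allelic_2x2")) {
  model <- match.arg(model)
  tri <- function(x) if (inherits(x, "genotype_counts")) c(x$n0, x$n1, x$n2) else as.numeric(x)
  ca <- tri(case_counts); co <- tri(control_counts)
  out <- switch(model,
    codominant = rbind(case = ca, control = co),
    dominant   = rbind(case = c(ca[2] + ca[3], ca[1]),
                       control = c(co[2] + co[3], co[1])),
    recessive  = rbind(case = c(ca[3], ca[1] + ca[2]),
                       control = c(co[3], co[1] + co[2])),
    allelic_2x2 = rbind(case = c(ca[2] + 2 * ca[3], 2 * ca[1] + ca[2]),
                        control = c(co[2] + 2 * co[3], 2 * co[1] + co[2]))
  )
  colnames(out) <- switch(model,
    codominant = c("g0", "g1", "g2"),
    dominant = c("carrier", "non_carrier"),
    recessive = c("homozygote", "other"),
    allelic_2x2 = c("risk_allele", "other_allele"))
  out
}

# genotype regressor columns for a model, from a dosage vector
.model_design <- function(g, model) {
  switch(model,
    codominant = cbind(het = as.numeric(g == 1), hom = as.numeric(g == 2)),
    dominant = cbind(carrier = as.numeric(g >= 1)),
    recessive = cbind(homozygote = as.numeric(g == 2)),
    log_additive = cbind(dosage = as.numeric(g)))
}

# covariate design matrix; wholly-missing covariates dropped with a warning
.covariate_design <- function(cohort, covariates) {
  info <- cohort$info
  cols <- list()
  for (cv in covariates) {
    add <- switch(cv,
      sex = list(sex_male = as.numeric(info$sex == "male")),
      age = list(age = info$age),
      diet = list(diet_vegetarian = as.numeric(info$diet == "vegetarian"),
                  diet_mostly_meat = as.numeric(info$diet == "mostly_meat")),
      alcohol = list(alcohol = as.numeric(info$alcohol) - 1),
      smoking = list(smoking_ever = ifelse(info$smoking == "unknown", NA,
                                           as.numeric(info$smoking == "ever"))),
      stop_data("unknown covariate '%s'", cv))
    if (all(vapply(add, function(v) all(is.na(v)), logical(1)))) {
      warning(sprintf("covariate '%s' is wholly missing and was dropped", cv),
              call. = FALSE)
      next
    }
    cols <- c(cols, add)
  }
  if (!length(cols)) return(NULL)
  do.call(cbind, cols)
}

#' Genetic association scan over all loci and inheritance models
#'
#' For every locus and requested inheritance model, computes the crude
#' association (contingency-table odds ratio for dominant/recessive/allelic
#' models, logistic fit on dosage or genotype indicators for log-additive
#' and codominant) and, when covariates are supplied, the adjusted
#' association from a logistic model including the covariates. Adjusted
#' p-values are likelihood-ratio tests of the genotype term(s) against the
#' covariate-only null; crude logistic p-values are LRTs against the
#' intercept-only null. Wald intervals accompany model-based odds ratios.
#' Individuals are excluded locus-wise when genotype, status or (for the
#' adjusted fit) a covariate is missing. When `covariates` is empty the
#' adjusted columns repeat the crude results. The allele-level 2x2 model
#' has no covariate-adjusted counterpart and reports crude results only.
#'
#' @param cohort a [cohort()].
#' @param models subset of `"codominant"`, `"dominant"`, `"recessive"`,
#'   `"log_additive"`, `"allelic_2x2"`.
#' @param covariates character vector among `"sex"`, `"age"`, `"diet"`,
#'   `"alcohol"`, `"smoking"` (coded: male indicator, age in years, two diet
#'   indicators with mixed as reference, alcohol band score 0-3, ever-smoker
#'   indicator); `NULL` for crude-only.
#' @param alpha family-wise significance level.
#' @param m number of comparisons for Bonferroni (default: loci scanned).
#' @return data.frame of class `"raprs_assoc"`: one row per locus x model x
#'   non-reference level with crude and adjusted OR, 95% CI, p-values and
#'   significance flags; metadata in attributes.
#' @export
association_scan <- function(cohort,
                             models = c("codominant", "dominant", "recessive",
                                        "log_additive", "allelic_2x2"),
                             covariates = c("sex", "age", "diet", "alcohol", "smoking"),
                             alpha = 0.05, m = NULL) {
  models <- match.arg(models, MODEL_NAMES, several.ok = TRUE)
  m <- m %||% nrow(cohort$loci)
  bonf <- bonferroni(alpha, m)
  status_ok <- !is.na(cohort$info$status)
  y_all <- as.numeric(cohort$info$status == "case")
  cov_design <- if (length(covariates)) .covariate_design(cohort, covariates) else NULL

  rows <- list()
  for (j in seq_len(nrow(cohort$loci))) {
    locus <- cohort$loci[j, ]
    g_all <- cohort$geno[, j]
    for (model in models) {
      keep <- status_ok & !is.na(g_all)
      g <- g_all[keep]; y <- y_all[keep]
      lv <- .level_labels(locus, model)

      crude <- .crude_association(g, y, model)
      if (is.null(cov_design)) {
        adj <- crude
      } else if (model == "allelic_2x2") {
        adj <- NULL
      } else {
        keep_a <- keep & stats::complete.cases(cov_design)
        adj <- .logistic_association(g_all[keep_a], y_all[keep_a], model,
                                     cov_design[keep_a, , drop = FALSE])
      }
      n_lv <- length(lv$levels)
      blank <- rep(NA_real_, n_lv)
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = locus$locus_id, model = model,
        level = lv$levels, reference = lv$reference,
        crude_or = crude$or, crude_lower = crude$lower, crude_upper = crude$upper,
        crude_p = crude$p,
        adj_or = if (is.null(adj)) blank else adj$or,
        adj_lower = if (is.null(adj)) blank else adj$lower,
        adj_upper = if (is.null(adj)) blank else adj$upper,
        adj_p = if (is.null(adj)) blank else adj$p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  p_eff <- ifelse(is.na(out$adj_p), out$crude_p, out$adj_p)
  out$significant_raw <- !is.na(out$crude_p) & out$crude_p <= alpha
  out$significant_bonferroni <- !is.na(p_eff) & p_eff <= bonf$threshold
  attr(out, "alpha") <- alpha
  attr(out, "bonferroni") <- bonf
  attr(out, "covariates") <- if (is.null(cov_design)) character() else colnames(cov_design)
  attr(out, "conventions") <- paste(
    "p-values: likelihood-ratio tests of the genotype term(s); Wald CIs for",
    "model-based ORs; Woolf CIs and Pearson chi-square p for contingency ORs.")
  class(out) <- c("raprs_assoc", "data.frame")
  out
}

.level_labels <- function(locus, model) {
  other <- ifelse(locus$risk_allele == locus$allele_a, locus$allele_b, locus$allele_a)
  r <- locus$risk_allele
  gl <- c(paste0(other, other), paste0(other, r), paste0(r, r))
  switch(model,
    codominant = list(levels = gl[2:3], reference = gl[1]),
    dominant = list(levels = paste(gl[2], gl[3], sep = "-"), reference = gl[1]),
    recessive = list(levels = gl[3], reference = paste(gl[1], gl[2], sep = "-")),
    log_additive = list(levels = r, reference = other),
    allelic_2x2 = list(levels = r, reference = other))
}

.crude_association <- function(g, y, model) {
  ca <- counts(sum(g == 0 & y == 1), sum(g == 1 & y == 1), sum(g == 2 & y == 1))
  co <- counts(sum(g == 0 & y == 0), sum(g == 1 & y == 0), sum(g == 2 & y == 0))
  if (model %in% c("dominant", "recessive", "allelic_2x2")) {
    tab <- model_tables(ca, co, model)
    res <- tryCatch(contingency_or(tab), error = function(e) NULL)
    if (is.null(res))
      return(list(or = NA_real_, lower = NA_real_, upper = NA_real_, p = NA_real_))
    list(or = res$or, lower = res$lower, upper = res$upper, p = res$p_value)
  } else {
    .logistic_association(g, y, model, covariates = NULL)
  }
}

.logistic_association <- function(g, y, model, covariates = NULL) {
  xg <- .model_design(g, model)
  n_lv <- ncol(xg)
  keep_g <- apply(xg, 2, function(col) stats::var(col) > 0)
  blank <- list(or = rep(NA_real_, n_lv), lower = rep(NA_real_, n_lv),
                upper = rep(NA_real_, n_lv), p = rep(NA_real_, n_lv))
  if (!any(keep_g) || length(unique(y)) < 2) return(blank)
  if (!is.null(covariates)) {
    keep_c <- apply(covariates, 2, function(col) stats::var(col) > 0)
    covariates <- if (any(keep_c)) covariates[, keep_c, drop = FALSE] else NULL
  }
  xg_fit <- xg[, keep_g, drop = FALSE]
  x_full <- if (is.null(covariates)) xg_fit else cbind(xg_fit, covariates)
  full <- suppressWarnings(fit_logistic(y, x_full))
  null <- if (is.null(covariates)) {
    n1 <- sum(y); n0 <- length(y) - n1
    list(loglik = n1 * log(n1 / length(y)) + n0 * log(n0 / length(y)),
         coefficients = c(`(Intercept)` = 0))
  } else suppressWarnings(fit_logistic(y, covariates))
  lrt <- lr_test(full, null)
  k <- seq_len(ncol(xg_fit)) + 1L  # genotype coefficients follow the intercept
  z <- stats::qnorm(0.975)
  b <- full$coefficients[k]
  se <- sqrt(diag(full$vcov))[k]
  out <- blank
  out$or[keep_g] <- exp(b)
  out$lower[keep_g] <- exp(b - z * se)
  out$upper[keep_g] <- exp(b + z * se)
  out$p <- rep(lrt$p_value, n_lv)
  out
}

#' @export
print.raprs_assoc <- function(x, ...) {
  bonf <- attr(x, "bonferroni")
  cat(sprintf("Association scan: %d loci, models: %s\n",
              length(unique(x$locus_id)), paste(unique(x$model), collapse = ", ")))
  cat(sprintf("Bonferroni threshold: %s (alpha = %g, m = %d)\n",
              bonf$display, bonf$alpha, bonf$m))
  cv <- attr(x, "covariates")
  cat("Adjusted for:", if (length(cv)) paste(cv, collapse = ", ") else "(nothing)", "\n\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' @export
summary.raprs_assoc <- function(object, ...) {
  hits <- object[object$significant_bonferroni, c("locus_id", "model", "level"), drop = FALSE]
  cat(sprintf("%d of %d tests significant after Bonferroni correction\n",
              nrow(hits), nrow(object)))
  if (nrow(hits)) print.data.frame(hits, row.names = FALSE)
  invisible(hits)
}

#' Bonferroni multiple-testing threshold
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return object of class `"raprs_bonferroni"`: list with `alpha`, `m`,
#'   `threshold` (= alpha/m) and `display` (threshold rounded
#'   half-away-from-zero to 4 decimals, as printed in results tables).
#' @export
#' @examples
#' bonferroni(0.05, 11)$display  # "0.0045"
bonferroni <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_data("alpha must be in (0, 1)")
  if (!is.numeric(m) || m < 1) stop_data("m must be a positive integer")
  thr <- alpha / m
  structure(list(alpha = alpha, m = as.integer(m), threshold = thr,
                 display = sprintf("%.4f", round_half_away(thr, 4))),
            class = "raprs_bonferroni")
}

#' @export
print.raprs_bonferroni <- function(x, ...) {
  cat(sprintf("Bonferroni: alpha = %g over m = %d comparisons -> threshold %s\n",
              x$alpha, x$m, x$display))
  invisible(x)
}

#' Case-control comparison of covariates
#'
#' Compares every covariate between cases and controls: unpaired
#' pooled-variance t-test for age, Pearson chi-square (no continuity
#' correction) for categorical covariates. Covariates with a single
#' observed level are skipped with a note.
#'
#' @param cohort a [cohort()].
#' @return data.frame of class `"raprs_covariate_table"`: `variable`,
#'   `test`, `statistic`, `df`, `p_value`, `note`.
#' @export
covariate_table <- function(cohort) {
  info <- cohort$info[!is.na(cohort$info$status), ]
  is_case <- info$status == "case"
  rows <- list()
  add <- function(variable, test, statistic, df, p_value, note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, test = test, statistic = statistic, df = df,
      p_value = p_value, note = note, stringsAsFactors = FALSE)
  }
  if (sum(!is.na(info$age[is_case])) >= 2 && sum(!is.na(info$age[!is_case])) >= 2) {
    a1 <- info$age[is_case]; a0 <- info$age[!is_case]
    tt <- tryCatch(stats::t.test(a1, a0, var.equal = TRUE), error = function(e) NULL)
    if (is.null(tt)) {
      # zero pooled variance: identical constant groups have t = 0 by convention
      df <- sum(!is.na(a1)) + sum(!is.na(a0)) - 2
      if (isTRUE(all.equal(mean(a1, na.rm = TRUE), mean(a0, na.rm = TRUE))))
        add("age", "t", 0, df, 1)
      else add("age", "t", NA_real_, df, NA_real_, "degenerate: zero variance")
    } else add("age", "t", unname(tt$statistic), unname(tt$parameter), tt$p.value)
  }
  for (cv in c("sex", "diet", "alcohol", "smoking")) {
    v <- droplevels(info[[cv]][!is.na(info[[cv]])])
    tab <- table(info$status[!is.na(info[[cv]])], v)
    if (nlevels(v) < 2 || nrow(tab) < 2 || any(rowSums(tab) == 0)) {
      add(cv, "chi_square", NA_real_, NA_real_, NA_real_,
          "skipped: fewer than two observed levels")
      next
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    add(cv, "chi_square", unname(ct$statistic), unname(ct$parameter), ct$p.value)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("raprs_covariate_table", "data.frame")
  out
}
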