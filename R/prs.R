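#' Per-locus weights for a polygenic risk score
#'
#' Weight schemes for [compute_prs()]: `"unit"` (unweighted score, every
#' locus weight 1), `"crude"` / `"adjusted"` (the published per-allele
#' odds ratios of the 11-locus RA panel, raw ORs as multipliers), or
#' `"external"` with caller-supplied weights. Raw odds ratios, not
#' log-odds, are the multipliers: the weighted score is the dosage sum with
#' each locus multiplied by its allelic OR.
#'
#' @param cohort a [cohort()].
#' @param scheme `"unit"`, `"crude"`, `"adjusted"` or `"external"`.
#' @param weights named numeric vector (locus_id -> weight), required for
#'   `"external"`; must cover every scored locus with positive weights.
#' @return object of class `"raprs_weights"`: named weight vector with a
#'   `source` attribute.
#' @export
prs_weights <- function(cohort, scheme = c("unit", "crude", "adjusted", "external"),
                        weights = NULL) {
  scheme <- match.arg(scheme)
  ids <- cohort$loci$locus_id
  w <- switch(scheme,
    unit = stats::setNames(rep(1, length(ids)), ids),
    crude = ,
    adjusted = {
      pub <- ra_published_or()
      idx <- match(ids, pub$locus_id)
      if (anyNA(idx))
        stop_data("no published %s OR for locus '%s'; use scheme = \"external\"",
                  scheme, ids[is.na(idx)][1])
      col <- if (scheme == "crude") "crude_or" else "adjusted_or"
      stats::setNames(pub[[col]][idx], ids)
    },
    external = {
      if (is.null(weights) || is.null(names(weights)))
        stop_data("external scheme needs a named weights vector")
      miss <- setdiff(ids, names(weights))
      if (length(miss))
        stop_data("no weight for locus '%s'", miss[1])
      weights[ids]
    })
  if (any(!is.finite(w)) || any(w <= 0)) stop_data("weights must be positive")
  structure(w, source = scheme, class = "raprs_weights")
}

#' Polygenic risk score
#'
#' The per-individual score S = sum over loci of w_l * g_l, where g_l is
#' the risk-allele dosage (0, 1, 2). With unit weights this is the plain
#' risk-allele count (range 0 to 2 x number of loci). Individuals missing
#' a genotype at any scored locus are excluded from the score and listed.
#'
#' @param cohort a [cohort()].
#' @param scheme weight scheme passed to [prs_weights()], or a ready-made
#'   `"raprs_weights"` vector.
#' @param weights external weights when `scheme = "external"`.
#' @return object of class `"raprs_prs"`: list with `score` (named vector
#'   over scored individuals), `status` (matching factor), `weights`,
#'   `excluded` (sample ids dropped for missingness), `n_loci`.
#' @export
compute_prs <- function(cohort, scheme = "unit", weights = NULL) {
  w <- if (inherits(scheme, "raprs_weights")) scheme
       else prs_weights(cohort, scheme, weights)
  geno <- cohort$geno
  complete <- stats::complete.cases(geno)
  score <- drop(geno[complete, , drop = FALSE] %*% unclass(w)[colnames(geno)])
  names(score) <- cohort$info$sample_id[complete]
  structure(list(score = score,
                 status = cohort$info$status[complete],
                 weights = w,
                 excluded = cohort$info$sample_id[!complete],
                 n_loci = ncol(geno)),
            class = "raprs_prs")
}

#' @export
print.raprs_prs <- function(x, ...) {
  cat(sprintf("Polygenic risk score (%s weights, %d loci): %d individuals scored",
              attr(x$weights, "source"), x$n_loci, length(x$score)))
  if (length(x$excluded))
    cat(sprintf(", %d excluded for missing genotypes", length(x$excluded)))
  cat("\n")
  by_grp <- tapply(x$score, x$status, mean)
  cat(sprintf("Mean score: cases %.3f, controls %.3f\n",
              by_grp[["case"]], by_grp[["control"]]))
  invisible(x)
}

#' Case-control comparison of polygenic risk scores
#'
#' Independent two-sample t-test with pooled variance: df = n_case +
#' n_control - 2. The sign of t follows the case-minus-control mean
#' difference.
#'
#' @param prs a [compute_prs()] result, or a numeric score vector.
#' @param status group factor (`"case"`/`"control"`), taken from `prs` when
#'   it is a `"raprs_prs"` object.
#' @return object of class `"raprs_prs_test"`: list with `mean_case`,
#'   `mean_control`, `mean_difference`, `pooled_sd`, `t`, `df`, `p_value`,
#'   `n_case`, `n_control`.
#' @export
compare_groups <- function(prs, status = NULL) {
  if (inherits(prs, "raprs_prs")) {
    score <- prs$score
    status <- prs$status
  } else score <- as.numeric(prs)
  ok <- !is.na(status) & !is.na(score)
  score <- score[ok]; status <- status[ok]
  x1 <- score[status == "case"]
  x0 <- score[status == "control"]
  if (length(x1) < 2 || length(x0) < 2)
    stop_data("need at least 2 members per group")
  sp2 <- ((length(x1) - 1) * stats::var(x1) + (length(x0) - 1) * stats::var(x0)) /
    (length(x1) + length(x0) - 2)
  if (sp2 <= 0) stop_data("t statistic undefined: zero pooled variance")
  tt <- stats::t.test(x1, x0, var.equal = TRUE)
  structure(list(mean_case = mean(x1), mean_control = mean(x0),
                 mean_difference = mean(x1) - mean(x0),
                 pooled_sd = sqrt(sp2),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 n_case = length(x1), n_control = length(x0)),
            class = "raprs_prs_test")
}

#' @export
print.raprs_prs_test <- function(x, ...) {
  cat(sprintf("PRS comparison: mean difference = %.3f (cases %.3f, controls %.3f)\n",
              x$mean_difference, x$mean_case, x$mean_control))
  cat(sprintf("t(%d) = %.3f, p = %.4g (pooled sd %.3f)\n",
              x$df, x$t, x$p_value, x$pooled_sd))
  invisible(x)
}

#' Closed-form expected PRS mean difference from allele frequencies
#'
#' Under dosage scoring, the group mean of S is 2 * sum_l w_l * p_l with
#' p_l the group's risk-allele frequency (mean dosage at a locus is twice
#' the allele frequency). The expected case-minus-control mean difference
#' is therefore 2 * sum_l w_l * (p_case,l - p_control,l) — computable from
#' a published allele-frequency table alone, with no individual-level data.
#'
#' @param case_freqs,control_freqs named risk-allele frequency vectors
#'   (locus_id -> frequency); names must match.
#' @param weights named weight vector (default: unit weights).
#' @return expected mean difference (numeric scalar).
#' @export
#' @examples
#' freqs <- ra_published_freqs()
#' pc <- setNames(freqs$risk_freq[freqs$group == "case"],
#'                freqs$locus_id[freqs$group == "case"])
#' p0 <- setNames(freqs$risk_freq[freqs$group == "control"],
#'                freqs$locus_id[freqs$group == "control"])
#' prs_mean_diff_identity(pc, p0)  # 1.48
prs_mean_diff_identity <- function(case_freqs, control_freqs, weights = NULL) {
  if (is.null(names(case_freqs)) || is.null(names(control_freqs)))
    stop_data("frequency vectors must be named by locus_id")
  if (!setequal(names(case_freqs), names(control_freqs)))
    stop_data("case and control frequency vectors cover different loci")
  control_freqs <- control_freqs[names(case_freqs)]
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(case_freqs)),
                                                   names(case_freqs))
  miss <- setdiff(names(case_freqs), names(weights))
  if (length(miss)) stop_data("no weight for locus '%s'", miss[1])
  weights <- weights[names(case_freqs)]
  2 * sum(unclass(weights) * (case_freqs - control_freqs))
}

#' Per-group PRS distribution report
#'
#' Histograms of the score per group on a common grid (empty bins kept as
#' zeros), optionally rendered to a PNG. The plot draws both group
#' histograms with their mean markers.
#'
#' @param prs a [compute_prs()] result.
#' @param path optional PNG output path; when `NULL` the current graphics
#'   device is used.
#' @param breaks number of bins on the common grid (default 20).
#' @return invisibly, a list with `breaks`, `case` and `control` bin counts
#'   and group means.
#' @export
prs_distribution_report <- function(prs, path = NULL, breaks = 20) {
  stopifnot(inherits(prs, "raprs_prs"))
  score <- prs$score; status <- prs$status
  rng <- range(score)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  brk <- seq(rng[1], rng[2], length.out = breaks + 1)
  h1 <- graphics::hist(score[status == "case"], breaks = brk, plot = FALSE)
  h0 <- graphics::hist(score[status == "control"], breaks = brk, plot = FALSE)
  out <- list(breaks = brk, case = h1$counts, control = h0$counts,
              mean_case = mean(score[status == "case"]),
              mean_control = mean(score[status == "control"]))
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 500)
    on.exit(grDevices::dev.off())
  }
  ylim <- c(0, max(h1$counts, h0$counts))
  graphics::plot(h0, col = grDevices::adjustcolor("steelblue", 0.5),
                 ylim = ylim, main = "Polygenic risk score by group",
                 xlab = sprintf("score (%s weights)", attr(prs$weights, "source")))
  graphics::plot(h1, col = grDevices::adjustcolor("firebrick", 0.5), add = TRUE)
  graphics::abline(v = out$mean_control, col = "steelblue", lwd = 2, lty = 2)
  graphics::abline(v = out$mean_case, col = "firebrick", lwd = 2, lty = 2)
  graphics::legend("topright", legend = c("controls", "cases"),
                   fill = grDevices::adjustcolor(c("steelblue", "firebrick"), 0.5))
  invisible(out)
}

#' @export
plot.raprs_prs <- function(x, ...) prs_distribution_report(x, ...)
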