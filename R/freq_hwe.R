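#' Per-group genotype counts at a locus
#'
#' Tabulates non-missing risk-allele dosages at one locus within cases,
#' controls, or everyone. `n0`/`n1`/`n2` count individuals carrying 0, 1, 2
#' copies of the risk allele.
#'
#' @param cohort a [cohort()].
#' @param locus_id locus label.
#' @param group `"case"`, `"control"` or `"all"`.
#' @return object of class `"genotype_counts"`: list with `n0`, `n1`, `n2`,
#'   `n`, `locus_id`, `group`.
#' @export
genotype_counts <- function(cohort, locus_id, group = c("all", "case", "control")) {
  group <- match.arg(group)
  j <- match(locus_id, cohort$loci$locus_id)
  if (is.na(j)) stop_data("unknown locus '%s'", locus_id)
  g <- cohort$geno[, j]
  if (group != "all") g <- g[!is.na(cohort$info$status) & cohort$info$status == group]
  g <- g[!is.na(g)]
  counts(sum(g == 0L), sum(g == 1L), sum(g == 2L),
         locus_id = locus_id, group = group)
}

#' Construct a genotype-count triple
#'
#' @param n0,n1,n2 non-negative integer counts of individuals with dosage
#'   0, 1 and 2 of the counted allele.
#' @param locus_id,group optional labels.
#' @return object of class `"genotype_counts"`.
#' @export
counts <- function(n0, n1, n2, locus_id = NA_character_, group = NA_character_) {
  n0 <- as.integer(n0); n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (any(c(n0, n1, n2) < 0)) stop_data("genotype counts must be non-negative")
  structure(list(n0 = n0, n1 = n1, n2 = n2, n = n0 + n1 + n2,
                 locus_id = locus_id, group = group),
            class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("Genotype counts%s%s: g0=%d g1=%d g2=%d (n=%d)\n",
              if (!is.na(x$locus_id)) paste0(" ", x$locus_id) else "",
              if (!is.na(x$group)) paste0(" [", x$group, "]") else "",
              x$n0, x$n1, x$n2, x$n))
  invisible(x)
}

#' Allele frequency from genotype counts
#'
#' Frequency of the counted (dosage) allele: (n1 + 2 n2) / (2n). With
#' genotype *frequencies* instead of counts the same arithmetic applies,
#' which is how published rounded genotype-frequency rows are converted to
#' allele frequencies.
#'
#' @param x a [counts()] object, or a numeric triple of genotype counts or
#'   frequencies (g0, g1, g2).
#' @return frequency of the counted allele in `[0, 1]`.
#' @export
#' @examples
#' allele_frequency(c(0.29, 0.50, 0.21))  # 0.54
allele_frequency <- function(x) {
  if (inherits(x, "genotype_counts")) x <- c(x$n0, x$n1, x$n2)
  x <- as.numeric(x)
  stopifnot(length(x) == 3, all(x >= 0))
  tot <- sum(x)
  if (tot <= 0) stop_data("allele frequency undefined: no observations")
  (x[2] + 2 * x[3]) / (2 * tot)
}

#' Chi-square test of Hardy-Weinberg equilibrium
#'
#' Pearson goodness-of-fit of the three genotype classes against p^2, 2pq,
#' q^2 at the estimated allele frequency, on 1 df. A monomorphic locus is
#' degenerate: statistic 0, p = 1.
#'
#' @param x a [counts()] object or numeric genotype-count triple.
#' @return object of class `"hwe_test"`: list with `method = "chi_square"`,
#'   `statistic`, `p_value`.
#' @export
hwe_chi_square <- function(x) {
  if (inherits(x, "genotype_counts")) x <- c(x$n0, x$n1, x$n2)
  x <- as.numeric(x)
  n <- sum(x)
  if (n <= 0) stop_data("HWE test undefined: no observations")
  q <- (x[2] + 2 * x[3]) / (2 * n)  # counted-allele frequency
  if (q == 0 || q == 1)
    return(structure(list(method = "chi_square", statistic = 0, p_value = 1),
                     class = "hwe_test"))
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  stat <- sum((x - expected)^2 / expected)
  structure(list(method = "chi_square", statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE)),
            class = "hwe_test")
}

# log-probability of each possible heterozygote count given minor-allele
# copies nb among n diploids (conditional HWE distribution)
.hwe_het_dist <- function(n, nb) {
  nab <- seq(nb %% 2, min(nb, 2 * n - nb), by = 2)
  naa <- (2 * n - nb - nab) / 2
  nbb <- (nb - nab) / 2
  lp <- lgamma(n + 1) - lgamma(naa + 1) - lgamma(nab + 1) - lgamma(nbb + 1) +
    nab * log(2) + lgamma(nb + 1) + lgamma(2 * n - nb + 1) - lgamma(2 * n + 1)
  list(nab = nab, prob = exp(lp))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed allele counts, heterozygote
#' counts are distributed over the same-parity lattice with the classical
#' hypergeometric-type HWE probabilities; the p-value sums the
#' probabilities of all heterozygote counts no more probable than the one
#' observed. Preferred over the chi-square test when rare-homozygote
#' expected counts are small.
#'
#' @param x a [counts()] object or numeric genotype-count triple.
#' @return object of class `"hwe_test"`: list with `method = "exact"`,
#'   `statistic` (`NA`), `p_value`.
#' @export
hwe_exact <- function(x) {
  if (inherits(x, "genotype_counts")) x <- c(x$n0, x$n1, x$n2)
  x <- as.integer(round(as.numeric(x)))
  n <- sum(x)
  if (n <= 0) stop_data("HWE test undefined: no observations")
  nb <- x[2] + 2L * x[3]
  if (nb == 0L || nb == 2L * n)
    return(structure(list(method = "exact", statistic = NA_real_, p_value = 1),
                     class = "hwe_test"))
  d <- .hwe_het_dist(n, nb)
  p_obs <- d$prob[d$nab == x[2]]
  p <- min(1, sum(d$prob[d$prob <= p_obs * (1 + 1e-12)]))
  structure(list(method = "exact", statistic = NA_real_, p_value = p),
            class = "hwe_test")
}

#' @export
print.hwe_test <- function(x, ...) {
  if (x$method == "chi_square")
    cat(sprintf("HWE chi-square test: X2 = %.4g, p = %.4g\n", x$statistic, x$p_value))
  else
    cat(sprintf("HWE exact test: p = %.4g\n", x$p_value))
  invisible(x)
}

#' Reconstruct integer genotype counts from rounded frequencies
#'
#' Inverts a published rounded genotype-frequency row: returns every
#' integer triple (n0, n1, n2) summing to `n` whose frequencies round
#' (half away from zero) to the printed values at the stated precision,
#' ordered by L2 distance to `n * freqs`. Ambiguity is surfaced as multiple
#' candidates, never silently resolved; an empty list means no triple is
#' consistent with the printed row.
#'
#' @param freqs printed genotype frequencies (g0, g1, g2).
#' @param n group size.
#' @param decimals printed precision (default 2).
#' @return list of [counts()] objects (possibly empty).
#' @export
reconstruct_counts <- function(freqs, n, decimals = 2) {
  stopifnot(length(freqs) == 3, all(freqs >= 0), all(freqs <= 1), n > 0)
  out <- list()
  dist <- numeric()
  target <- n * freqs
  for (a in 0:n) {
    if (abs(round_half_away(a / n, decimals) - freqs[1]) > 1e-9) next
    for (b in 0:(n - a)) {
      cc <- n - a - b
      if (abs(round_half_away(b / n, decimals) - freqs[2]) > 1e-9) next
      if (abs(round_half_away(cc / n, decimals) - freqs[3]) > 1e-9) next
      out[[length(out) + 1L]] <- counts(a, b, cc)
      dist[length(out)] <- sum((c(a, b, cc) - target)^2)
    }
  }
  out[order(dist)]
}

#' Per-locus, per-group frequency and HWE summary
#'
#' The per-locus summary table of a case-control study: genotype counts and
#' frequencies, allele frequency of the risk allele, and an HWE p-value per
#' group (exact test by default).
#'
#' @param cohort a [cohort()].
#' @param hwe_method `"exact"` (default) or `"chi_square"`.
#' @return data.frame of class `"raprs_locus_summary"` with one row per
#'   locus x group.
#' @export
locus_summary <- function(cohort, hwe_method = c("exact", "chi_square")) {
  hwe_method <- match.arg(hwe_method)
  hwe_fun <- if (hwe_method == "exact") hwe_exact else hwe_chi_square
  rows <- list()
  for (locus in cohort$loci$locus_id) {
    for (grp in c("case", "control")) {
      ct <- genotype_counts(cohort, locus, grp)
      freq <- if (ct$n > 0) allele_frequency(ct) else NA_real_
      hwe_p <- if (ct$n > 0 && (ct$n1 + ct$n2) > 0 && (ct$n0 + ct$n1) > 0)
        hwe_fun(ct)$p_value else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = locus, group = grp,
        n = ct$n, n0 = ct$n0, n1 = ct$n1, n2 = ct$n2,
        f0 = ct$n0 / ct$n, f1 = ct$n1 / ct$n, f2 = ct$n2 / ct$n,
        risk_freq = freq, hwe_p = hwe_p,
        hwe_flag = !is.na(hwe_p) && hwe_p <= 0.05,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "hwe_method") <- hwe_method
  class(out) <- c("raprs_locus_summary", "data.frame")
  out
}

#' Write a locus summary as TSV
#'
#' @param x a [locus_summary()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_locus_summary <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
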