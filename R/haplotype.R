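# Internal: haplotype bookkeeping for a 2-3 locus subset.
# Haplotypes are enumerated as bit vectors (bit 1 = risk allele) and labelled
# with allele letters; individuals with any missing genotype are excluded.
.hap_setup <- function(cohort, loci) {
  j <- match(loci, cohort$loci$locus_id)
  if (anyNA(j)) stop_data("unknown locus '%s'", loci[is.na(j)][1])
  L <- length(j)
  if (L < 2 || L > 3) stop_data("haplotype analysis supports 2 or 3 loci, got %d", L)
  geno <- cohort$geno[, j, drop = FALSE]
  complete <- stats::complete.cases(geno)
  bits <- as.matrix(expand.grid(rep(list(0:1), L))[, L:1, drop = FALSE])  # lexicographic
  chars <- sapply(seq_len(L), function(k) {
    locus <- cohort$loci[j[k], ]
    other <- ifelse(locus$risk_allele == locus$allele_a, locus$allele_b, locus$allele_a)
    c(other, locus$risk_allele)
  })
  labels <- apply(bits, 1, function(b)
    paste(sapply(seq_len(L), function(k) chars[b[k] + 1, k]), collapse = ""))
  hap_index <- function(b) sum(b * 2^((L - 1):0)) + 1L

  pattern_pairs <- function(g) {
    het <- which(g == 1)
    base <- ifelse(g == 2, 1L, 0L)
    H <- length(het)
    assigns <- as.matrix(expand.grid(rep(list(0:1), max(H, 0))))
    if (H == 0) assigns <- matrix(0L, 1, 0)
    i1 <- integer(nrow(assigns)); i2 <- integer(nrow(assigns))
    for (r in seq_len(nrow(assigns))) {
      b1 <- base; b2 <- base
      if (H > 0) {
        b1[het] <- as.integer(assigns[r, ])
        b2[het] <- 1L - as.integer(assigns[r, ])
      }
      i1[r] <- hap_index(b1); i2[r] <- hap_index(b2)
    }
    cbind(i1, i2)  # ordered pairs
  }

  gsub_rows <- geno[complete, , drop = FALSE]
  if (nrow(gsub_rows) == 0)
    return(list(loci = loci, L = L, labels = labels, bits = bits,
                patterns = list(), n = 0L, complete = complete,
                key = character(), uniq_key = character()))
  key <- apply(gsub_rows, 1, paste, collapse = "/")
  tab <- table(key)
  uniq <- do.call(rbind, strsplit(names(tab), "/", fixed = TRUE))
  storage.mode(uniq) <- "integer"
  patterns <- lapply(seq_len(nrow(uniq)), function(r)
    list(mult = as.integer(tab[r]), pairs = pattern_pairs(uniq[r, ])))
  list(loci = loci, L = L, labels = labels, bits = bits,
       patterns = patterns, n = sum(complete), complete = complete,
       key = key, uniq_key = names(tab))
}

.hap_loglik <- function(f, patterns) {
  sum(vapply(patterns, function(p) {
    pr <- sum(f[p$pairs[, 1]] * f[p$pairs[, 2]])
    p$mult * log(max(pr, 1e-300))
  }, numeric(1)))
}

#' EM haplotype frequency estimation from unphased genotypes
#'
#' Standard two-to-three-locus EM: the E-step distributes each
#' multi-heterozygote's probability over its compatible phase pairs in
#' proportion to products of current haplotype frequencies; the M-step
#' re-estimates frequencies from the expected haplotype counts. The
#' log-likelihood is checked to be non-decreasing at every iteration.
#' Initialisation is the uniform haplotype distribution (deterministic);
#' seeded random restarts can be requested to guard against local maxima.
#' Individuals missing any genotype at the chosen loci are excluded.
#'
#' @param cohort a [cohort()].
#' @param loci 2 or 3 locus ids.
#' @param tol convergence threshold on the max absolute frequency change
#'   (default 1e-8).
#' @param max_iter iteration cap (default 1000).
#' @param n_restarts extra random restarts (default 0).
#' @param seed seed for the restarts.
#' @return object of class `"raprs_haplotypes"`: data.frame-like list with
#'   `haplotype` labels, `freq`, plus `loglik`, `n_iter`, `converged`, `n`
#'   (individuals used) and the locus ids.
#' @export
em_haplotypes <- function(cohort, loci, tol = 1e-8, max_iter = 1000L,
                          n_restarts = 0L, seed = NULL) {
  setup <- .hap_setup(cohort, loci)
  if (setup$n == 0) stop_data("no complete observations at loci %s",
                              paste(loci, collapse = ", "))
  K <- length(setup$labels)

  run_em <- function(f) {
    ll <- .hap_loglik(f, setup$patterns)
    iter <- 0L
    converged <- FALSE
    while (iter < max_iter) {
      iter <- iter + 1L
      cnt <- numeric(K)
      for (p in setup$patterns) {
        w <- f[p$pairs[, 1]] * f[p$pairs[, 2]]
        s <- sum(w)
        if (s <= 0) next
        w <- p$mult * w / s
        for (r in seq_along(w)) {
          cnt[p$pairs[r, 1]] <- cnt[p$pairs[r, 1]] + w[r]
          cnt[p$pairs[r, 2]] <- cnt[p$pairs[r, 2]] + w[r]
        }
      }
      f_new <- cnt / (2 * setup$n)
      ll_new <- .hap_loglik(f_new, setup$patterns)
      if (ll_new < ll - 1e-8)
        stop_data("EM log-likelihood decreased (%.10g -> %.10g)", ll, ll_new)
      delta <- max(abs(f_new - f))
      f <- f_new; ll <- ll_new
      if (delta < tol) { converged <- TRUE; break }
    }
    list(f = f, loglik = ll, n_iter = iter, converged = converged)
  }

  best <- run_em(rep(1 / K, K))
  if (n_restarts > 0) {
    starts <- with_seed(seed, replicate(n_restarts, {
      g <- stats::rexp(K); g / sum(g)
    }, simplify = FALSE))
    for (f0 in starts) {
      cand <- run_em(f0)
      if (cand$loglik > best$loglik + 1e-10) best <- cand
    }
  }
  structure(list(loci = setup$loci, haplotype = setup$labels, freq = best$f,
                 bits = setup$bits, loglik = best$loglik,
                 n_iter = best$n_iter, converged = best$converged,
                 n = setup$n),
            class = "raprs_haplotypes")
}

#' @export
print.raprs_haplotypes <- function(x, ...) {
  cat(sprintf("EM haplotype frequencies at %s (n = %d, %d iterations%s)\n",
              paste(x$loci, collapse = "-"), x$n, x$n_iter,
              if (x$converged) "" else ", NOT converged"))
  df <- data.frame(haplotype = x$haplotype, freq = round(x$freq, 4))
  print.data.frame(df[order(-df$freq), ], row.names = FALSE)
  cat(sprintf("log-likelihood: %.4f\n", x$loglik))
  invisible(x)
}

#' Pairwise linkage-disequilibrium statistics
#'
#' From two-locus haplotype frequencies: D = h_AB - p_A p_B (A and B the
#' risk alleles at the two loci), D' = |D| / D_max with D_max =
#' min(p_A q_B, q_A p_B) for D > 0 and min(p_A p_B, q_A q_B) otherwise,
#' r2 = D^2 / (p_A q_A p_B q_B), and a chi-square test of D = 0 with
#' statistic 2 n r2 on 1 df. D' and r2 are invariant to allele relabelling.
#'
#' @param x a 2-locus [em_haplotypes()] fit, or a numeric vector of four
#'   haplotype frequencies in the order (AB, Ab, aB, ab).
#' @param n number of individuals (diploid) behind the estimate; taken from
#'   the fit when available.
#' @return object of class `"raprs_ld"`: list with `D`, `D_prime`, `r2`,
#'   `chi_square`, `p_value`.
#' @export
ld_stats <- function(x, n = NULL) {
  if (inherits(x, "raprs_haplotypes")) {
    if (length(x$loci) != 2) stop_data("ld_stats needs exactly 2 loci")
    n <- n %||% x$n
    h_ab <- x$freq[x$bits[, 1] == 1 & x$bits[, 2] == 1]
    p_a <- sum(x$freq[x$bits[, 1] == 1])
    p_b <- sum(x$freq[x$bits[, 2] == 1])
  } else {
    stopifnot(length(x) == 4)
    if (abs(sum(x) - 1) > 1e-6) stop_data("haplotype frequencies must sum to 1")
    h_ab <- x[1]
    p_a <- x[1] + x[2]
    p_b <- x[1] + x[3]
  }
  if (p_a <= 0 || p_a >= 1 || p_b <= 0 || p_b >= 1)
    stop_data("LD undefined: a locus is monomorphic")
  D <- h_ab - p_a * p_b
  d_max <- if (D > 0) min(p_a * (1 - p_b), (1 - p_a) * p_b)
           else min(p_a * p_b, (1 - p_a) * (1 - p_b))
  d_prime <- if (D == 0) 0 else abs(D) / d_max
  r2 <- D^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
  chi <- if (is.null(n)) NA_real_ else 2 * n * r2
  structure(list(D = D, D_prime = d_prime, r2 = r2, chi_square = chi,
                 p_value = if (is.na(chi)) NA_real_
                           else stats::pchisq(chi, 1, lower.tail = FALSE)),
            class = "raprs_ld")
}

#' @export
print.raprs_ld <- function(x, ...) {
  cat(sprintf("LD: D = %.4f, D' = %.3f, r2 = %.3f, p = %.3g\n",
              x$D, x$D_prime, x$r2, x$p_value))
  invisible(x)
}

# Internal: expected per-individual haplotype dosages under an EM fit
# (posterior phase weights). Rows with missing genotypes are NA.
.expected_dosage <- function(cohort, fit) {
  setup <- .hap_setup(cohort, fit$loci)
  K <- length(fit$freq)
  pat_dos <- lapply(setup$patterns, function(p) {
    w <- fit$freq[p$pairs[, 1]] * fit$freq[p$pairs[, 2]]
    s <- sum(w)
    d <- numeric(K)
    if (s > 0) {
      w <- w / s
      for (r in seq_along(w)) {
        d[p$pairs[r, 1]] <- d[p$pairs[r, 1]] + w[r]
        d[p$pairs[r, 2]] <- d[p$pairs[r, 2]] + w[r]
      }
    }
    d
  })
  names(pat_dos) <- setup$uniq_key
  out <- matrix(NA_real_, n_individuals(cohort), K,
                dimnames = list(cohort$info$sample_id, fit$haplotype))
  rows <- which(setup$complete)
  for (i in seq_along(rows)) out[rows[i], ] <- pat_dos[[setup$key[i]]]
  out
}

#' Haplotype association by expected-dosage logistic regression
#'
#' Haplotypes are estimated by [em_haplotypes()] on cases and controls
#' pooled; each individual then receives the expected dosage of every
#' haplotype given its genotypes (posterior phase weights). Disease status
#' is regressed on the dosages of all non-reference haplotypes jointly,
#' optionally covariate-adjusted; the reference is the most frequent
#' haplotype (ties broken lexicographically, with a warning). Haplotypes
#' below `freq_floor` are pooled into a `"rare"` dosage column; haplotypes
#' with estimated frequency zero are dropped from the output.
#'
#' @param cohort a [cohort()].
#' @param loci 2 or 3 locus ids.
#' @param covariates covariate names as in [association_scan()], or `NULL`.
#' @param freq_floor pooling threshold for rare haplotypes (default 0.01).
#' @param ... passed to [em_haplotypes()].
#' @return object of class `"raprs_hap_assoc"`: data.frame with `haplotype`,
#'   `freq`, `or`, `lower`, `upper`, `p_value` (reference row has OR 1 and
#'   `NA` interval); the EM fit in attribute `"em_fit"`.
#' @export
haplotype_association <- function(cohort, loci, covariates = NULL,
                                  freq_floor = 0.01, ...) {
  fit <- em_haplotypes(cohort, loci, ...)
  if (!fit$converged) stop_data("EM did not converge; cannot test association")
  dosage <- .expected_dosage(cohort, fit)

  present <- fit$freq > 1e-12
  labels <- fit$haplotype[present]
  freqs <- fit$freq[present]
  dosage <- dosage[, present, drop = FALSE]

  rare <- freqs < freq_floor
  if (any(rare)) {
    pooled <- rowSums(dosage[, rare, drop = FALSE])
    dosage <- cbind(dosage[, !rare, drop = FALSE], rare = pooled)
    labels <- c(labels[!rare], "rare")
    freqs <- c(freqs[!rare], sum(freqs[rare]))
  }

  top <- which(freqs == max(freqs))
  if (length(top) > 1) {
    warning("reference haplotype tie broken lexicographically", call. = FALSE)
    top <- top[order(labels[top])][1]
  }
  ref <- labels[top]

  y_all <- as.numeric(cohort$info$status == "case")
  keep <- !is.na(cohort$info$status) & stats::complete.cases(dosage)
  cov_design <- if (length(covariates)) .covariate_design(cohort, covariates) else NULL
  if (!is.null(cov_design)) keep <- keep & stats::complete.cases(cov_design)

  xg <- dosage[keep, labels != ref, drop = FALSE]
  x_full <- if (is.null(cov_design)) xg else cbind(xg, cov_design[keep, , drop = FALSE])
  full <- suppressWarnings(fit_logistic(y_all[keep], x_full))
  z <- stats::qnorm(0.975)

  out <- data.frame(haplotype = labels, freq = freqs,
                    or = NA_real_, lower = NA_real_, upper = NA_real_,
                    p_value = NA_real_, stringsAsFactors = FALSE)
  out$or[labels == ref] <- 1
  for (h in setdiff(labels, ref)) {
    b <- full$coefficients[h]
    se <- sqrt(full$vcov[h, h])
    i <- which(labels == h)
    out$or[i] <- exp(b)
    out$lower[i] <- exp(b - z * se)
    out$upper[i] <- exp(b + z * se)
    # drop-one LRT for this haplotype's dosage term
    x_red <- x_full[, colnames(x_full) != h, drop = FALSE]
    red <- if (ncol(x_red)) suppressWarnings(fit_logistic(y_all[keep], x_red))
           else {
             yk <- y_all[keep]; n1 <- sum(yk); n0 <- length(yk) - n1
             list(loglik = n1 * log(n1 / length(yk)) + n0 * log(n0 / length(yk)),
                  coefficients = 0)
           }
    out$p_value[i] <- lr_test(full, red)$p_value
  }
  out <- out[order(-out$freq), ]
  rownames(out) <- NULL
  attr(out, "reference") <- ref
  attr(out, "em_fit") <- fit
  attr(out, "n_used") <- sum(keep)
  class(out) <- c("raprs_hap_assoc", "data.frame")
  out
}

#' @export
print.raprs_hap_assoc <- function(x, ...) {
  cat(sprintf("Haplotype association at %s (reference: %s, n = %d)\n",
              paste(attr(x, "em_fit")$loci, collapse = "-"),
              attr(x, "reference"), attr(x, "n_used")))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
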