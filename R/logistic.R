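#' Maximum-likelihood logistic regression via IRLS
#'
#' Fits a binomial logit model by iteratively reweighted least squares.
#' Convergence is declared when the score (gradient) max-norm drops below
#' `tol_score` or the relative log-likelihood change drops below `tol_ll`;
#' fitting stops after `max_iter` iterations regardless. Complete or
#' quasi-complete separation is detected as a coefficient exceeding 15 on
#' the log-odds scale; a warning is emitted, the fit is flagged
#' non-converged, and the (diverging) estimates are still returned so
#' callers can report the degeneracy.
#'
#' This is the machinery behind every adjusted odds ratio in the package;
#' Wald intervals come from the inverse observed information.
#'
#' @param y binary outcome vector (0/1 or logical; 1 = case).
#' @param x design matrix of regressors. An intercept column is prepended
#'   unless `intercept = FALSE`.
#' @param intercept prepend an intercept column (default TRUE).
#' @param tol_score,tol_ll,max_iter convergence controls.
#' @return object of class `"raprs_logit"`: coefficients, covariance matrix
#'   (`vcov`), `loglik`, `n_iter`, `converged`, `separation`, `n`.
#' @export
fit_logistic <- function(y, x, intercept = TRUE,
                         tol_score = 1e-8, tol_ll = 1e-10, max_iter = 100L) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_data("outcome must be binary 0/1")
  if (length(unique(y)) < 2) stop_data("need both outcome classes present")
  x <- as.matrix(x)
  if (intercept) {
    x <- cbind(`(Intercept)` = 1, x)
  }
  if (is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)) - intercept)
  n <- length(y)
  if (nrow(x) != n) stop_data("design matrix has %d rows for %d outcomes", nrow(x), n)
  nonconst <- apply(x, 2, function(col) stats::var(col) > 0)
  if (intercept && any(!nonconst[-1]))
    stop_data("constant non-intercept column: %s",
              paste(colnames(x)[-1][!nonconst[-1]], collapse = ", "))

  beta <- numeric(ncol(x))
  log1pexp <- function(e) ifelse(e > 30, e, log1p(exp(pmin(e, 30))))
  loglik <- function(b) {
    eta <- drop(x %*% b)
    sum(y * eta - log1pexp(eta))
  }
  ll <- loglik(beta)
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    score <- drop(crossprod(x, y - mu))
    info <- crossprod(x * w, x)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) { separation <- TRUE; break }
    # step-halving guards against overshoot on ill-conditioned designs
    new_beta <- beta + step
    new_ll <- loglik(new_beta)
    h <- 0L
    while (new_ll < ll - 1e-12 && h < 20L) {
      step <- step / 2
      new_beta <- beta + step
      new_ll <- loglik(new_beta)
      h <- h + 1L
    }
    beta <- new_beta
    rel <- abs(new_ll - ll) / (abs(ll) + 1e-10)
    ll <- new_ll
    if (max(abs(drop(crossprod(x, y - stats::plogis(drop(x %*% beta)))))) < tol_score ||
        rel < tol_ll) {
      converged <- TRUE
      break
    }
    if (any(abs(beta) > 15)) { separation <- TRUE; break }
  }
  if (separation) {
    warning("possible complete or quasi-complete separation; estimates unreliable",
            call. = FALSE)
    converged <- FALSE
  }
  eta <- drop(x %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(x * w, x)
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, ncol(x), ncol(x)))
  dimnames(vc) <- list(colnames(x), colnames(x))
  names(beta) <- colnames(x)
  structure(list(coefficients = beta, vcov = vc, loglik = ll,
                 n_iter = iter, converged = converged, separation = separation,
                 n = n),
            class = "raprs_logit")
}

#' @export
coef.raprs_logit <- function(object, ...) object$coefficients

#' @export
vcov.raprs_logit <- function(object, ...) object$vcov

#' @export
logLik.raprs_logit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients), class = "logLik")
}

#' @export
print.raprs_logit <- function(x, ...) {
  cat(sprintf("Logistic fit (IRLS): n = %d, logLik = %.4f, %d iterations%s\n",
              x$n, x$loglik, x$n_iter,
              if (x$separation) " [separation flagged]"
              else if (!x$converged) " [not converged]" else ""))
  se <- sqrt(diag(x$vcov))
  print(cbind(estimate = x$coefficients, se = se, OR = exp(x$coefficients)))
  invisible(x)
}

#' @export
predict.raprs_logit <- function(object, newdata, type = c("link", "response"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  if (ncol(x) == length(object$coefficients) - 1) x <- cbind(1, x)
  eta <- drop(x %*% object$coefficients)
  if (type == "response") stats::plogis(eta) else eta
}

#' Wald odds ratios from a logistic fit
#'
#' @param fit a [fit_logistic()] result.
#' @param level confidence level (default 0.95).
#' @return data.frame with `term`, `or`, `lower`, `upper`, `p_wald`
#'   (intercept excluded).
#' @export
wald_or <- function(fit, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  b <- fit$coefficients
  se <- sqrt(diag(fit$vcov))
  keep <- names(b) != "(Intercept)"
  data.frame(term = names(b)[keep],
             or = exp(b[keep]),
             lower = exp(b[keep] - z * se[keep]),
             upper = exp(b[keep] + z * se[keep]),
             p_wald = 2 * stats::pnorm(-abs(b[keep] / se[keep])),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Likelihood-ratio test between nested logistic fits
#'
#' @param full,null [fit_logistic()] results, `null` nested in `full`.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
lr_test <- function(full, null) {
  stat <- max(0, 2 * (full$loglik - null$loglik))
  df <- length(full$coefficients) - length(null$coefficients)
  if (df < 1) stop_data("models are not nested (df = %d)", df)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}
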