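#' Design rows for the outcome regression
#'
#' One row per patient: the net five-year outcome (NC reference), the
#' high-risk indicator (low risk reference), the female indicator (male
#' reference) and age in decades (age at index / 10). Model 1 uses all
#' three predictors; Model 2 the risk category only.
#'
#' @param members cohort table.
#' @param outcomes data.frame from [net_outcomes_all()].
#' @param risk data.frame from [risk_score()].
#' @return data.frame with `outcome` (factor NC/IN/DI), `risk_high`,
#'   `sex_female`, `age_decades`.
#' @export
build_design <- function(members, outcomes, risk) {
  i <- match(members$patient_id, outcomes$patient_id)
  j <- match(members$patient_id, risk$patient_id)
  data.frame(patient_id = members$patient_id,
             outcome = factor(outcomes$net_state[i], levels = c("NC", "IN", "DI")),
             risk_high = as.integer(risk$category[j] == "high"),
             sex_female = as.integer(members$sex == "female"),
             age_decades = members$age_at_index / 10,
             stringsAsFactors = FALSE)
}

#' Multinomial logistic regression by Newton-Raphson
#'
#' Maximum-likelihood multinomial logit with the first factor level as the
#' reference outcome. Fitting uses full Newton-Raphson on the multinomial
#' log-likelihood with step halving; standard errors come from the
#' observed information matrix, so confidence intervals are Wald
#' intervals. Outcome levels with no observations are dropped from the
#' equations. Rank-deficient designs (duplicated or collinear predictors)
#' and quasi-separation (a coefficient diverging) are reported as errors
#' naming the offending predictor.
#'
#' @param y factor outcome (reference = first level).
#' @param X numeric model matrix (no intercept column; one is added).
#' @param weights optional non-negative case weights (grouped data).
#' @param tol relative log-likelihood convergence tolerance (default
#'   1e-10).
#' @param maxit maximum Newton iterations (default 100).
#' @return object of class `mlogit_nr` with coefficients (one column per
#'   non-reference outcome), `vcov`, log-likelihoods of the fitted and
#'   null models and the iteration count. Methods: `print`, `summary`,
#'   `coef`, `vcov`, `confint`, `logLik`, [or_table()].
#' @export
fit_mlogit <- function(y, X, weights = NULL, tol = 1e-10, maxit = 100) {
  y <- droplevels(as.factor(y))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(weights)) weights <- rep(1, length(y))
  stopifnot(length(y) == nrow(X), length(weights) == length(y))
  Xd <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xd * sqrt(weights))
  if (qrX$rank < ncol(Xd)) {
    bad <- colnames(Xd)[qrX$pivot[(qrX$rank + 1):ncol(Xd)]]
    stop("design is rank deficient (collinear predictor: ",
         paste(bad, collapse = ", "), ")")
  }
  K <- nlevels(y)
  if (K < 2) stop("outcome needs at least two observed categories")
  lev <- levels(y)
  p <- ncol(Xd); nk <- K - 1
  Y <- matrix(0, length(y), nk)
  for (k in seq_len(nk)) Y[, k] <- as.numeric(y == lev[k + 1])

  beta <- matrix(0, p, nk, dimnames = list(colnames(Xd), lev[-1]))
  ll_of <- function(b) {
    eta <- Xd %*% b
    den <- 1 + rowSums(exp(eta))
    sum(weights * (rowSums(Y * eta) - log(den)))
  }
  ll <- ll_of(beta)
  ll0 <- ll
  for (it in seq_len(maxit)) {
    eta <- Xd %*% beta
    mu <- exp(eta) / (1 + rowSums(exp(eta)))
    grad <- as.numeric(t(Xd) %*% ((Y - mu) * weights))
    H <- matrix(0, p * nk, p * nk)
    for (k in seq_len(nk)) for (l in seq_len(nk)) {
      wkl <- weights * (mu[, k] * ((k == l) - mu[, l]))
      H[((k - 1) * p + 1):(k * p), ((l - 1) * p + 1):(l * p)] <-
        t(Xd) %*% (Xd * wkl)
    }
    step <- tryCatch(solve(H, grad), error = function(e)
      stop("observed information is singular (separation or collinearity)"))
    stepm <- matrix(step, p, nk)
    lam <- 1
    repeat {
      cand <- beta + lam * stepm
      ll_new <- ll_of(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) { ll_new <- ll; cand <- beta; break }
    }
    beta <- cand
    if (max(abs(beta)) > 15)
      stop("separation detected: coefficient for '",
           rownames(beta)[which.max(apply(abs(beta), 1, max))],
           "' is diverging")
    if (abs(ll_new - ll) < tol * (abs(ll) + 1)) { ll <- ll_new; break }
    ll <- ll_new
  }
  eta <- Xd %*% beta
  mu <- exp(eta) / (1 + rowSums(exp(eta)))
  H <- matrix(0, p * nk, p * nk)
  for (k in seq_len(nk)) for (l in seq_len(nk)) {
    wkl <- weights * (mu[, k] * ((k == l) - mu[, l]))
    H[((k - 1) * p + 1):(k * p), ((l - 1) * p + 1):(l * p)] <-
      t(Xd) %*% (Xd * wkl)
  }
  V <- solve(H)
  nm <- as.vector(outer(rownames(beta), colnames(beta), paste, sep = ":"))
  dimnames(V) <- list(nm, nm)

  # intercept-only log-likelihood for the null comparison
  tab <- tapply(weights, y, sum); tab[is.na(tab)] <- 0
  pr <- tab / sum(tab)
  ll_null <- sum(tab[pr > 0] * log(pr[pr > 0]))

  structure(list(coefficients = beta, vcov = V, loglik = ll,
                 loglik_null = ll_null, iterations = it,
                 levels = lev, n = sum(weights)),
            class = "mlogit_nr")
}

#' @export
coef.mlogit_nr <- function(object, ...) object$coefficients

#' @export
vcov.mlogit_nr <- function(object, ...) object$vcov

#' @export
logLik.mlogit_nr <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients), class = "logLik")
}

#' @export
confint.mlogit_nr <- function(object, parm, level = 0.95, ...) {
  b <- as.vector(object$coefficients)
  se <- sqrt(diag(object$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(b - z * se, b + z * se)
  dimnames(out) <- list(rownames(object$vcov),
                        sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                   1 - (1 - level) / 2)))
  out
}

#' Odds-ratio table with Wald confidence intervals
#'
#' Exponentiated coefficients per non-reference outcome, with two-sided
#' Wald 95% intervals and a significance flag at the 0.05 level.
#'
#' @param fit an `mlogit_nr` fit.
#' @param level confidence level (default 0.95).
#' @return data.frame with `outcome`, `term`, `or`, `ci_low`, `ci_high`,
#'   `p_value`, `significant`.
#' @export
or_table <- function(fit, level = 0.95) {
  b <- fit$coefficients
  se <- matrix(sqrt(diag(fit$vcov)), nrow(b), ncol(b))
  z <- stats::qnorm(1 - (1 - level) / 2)
  pv <- 2 * stats::pnorm(-abs(b / se))
  out <- do.call(rbind, lapply(seq_len(ncol(b)), function(k)
    data.frame(outcome = colnames(b)[k], term = rownames(b),
               or = exp(b[, k]),
               ci_low = exp(b[, k] - z * se[, k]),
               ci_high = exp(b[, k] + z * se[, k]),
               p_value = pv[, k],
               significant = pv[, k] < 0.05,
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' @export
print.mlogit_nr <- function(x, digits = 3, ...) {
  cat(sprintf("Multinomial logit (reference outcome '%s', n = %g, %d iterations)\n",
              x$levels[1], x$n, x$iterations))
  print(round(x$coefficients, digits))
  cat(sprintf("log-likelihood %.3f (null %.3f)\n", x$loglik, x$loglik_null))
  invisible(x)
}

#' @export
summary.mlogit_nr <- function(object, ...) {
  out <- list(or = or_table(object), loglik = object$loglik,
              loglik_null = object$loglik_null, n = object$n)
  class(out) <- "summary.mlogit_nr"
  out
}

#' @export
print.summary.mlogit_nr <- function(x, ...) {
  cat(sprintf("Odds ratios (Wald 95%% CI), n = %g\n", x$n))
  print(x$or, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Fit the five-year outcome models
#'
#' Model 1 regresses the net five-year outcome on risk category, sex and
#' age per decade; Model 2 on risk category alone.
#'
#' @param design data.frame from [build_design()].
#' @param model 1 or 2.
#' @return an `mlogit_nr` fit.
#' @export
fit_outcome_model <- function(design, model = 1) {
  stopifnot(model %in% 1:2)
  cols <- if (model == 1) c("risk_high", "sex_female", "age_decades")
          else "risk_high"
  fit_mlogit(design$outcome, as.matrix(design[, cols, drop = FALSE]))
}
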