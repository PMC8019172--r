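#' Conditional log-likelihood of matched case-control sets
#'
#' Each matched set contributes the log of the conditional probability
#' that, among its members, the actual case is the one with the
#' outcome:
#' \deqn{\ell(\beta) = \sum_s \log \frac{\exp(\beta^\top x_{\mathrm{case}(s)})}
#'   {\sum_{j \in s} \exp(\beta^\top x_j)}.}
#' Sets in which all members share the same covariate values contribute
#' a constant (they are non-informative).
#'
#' @param beta Numeric coefficient vector of length `ncol(x)`.
#' @param x Numeric covariate matrix, one row per set member.
#' @param case Logical vector, `TRUE` for the single case of each set.
#' @param set Vector of set identifiers, one per row of `x`.
#' @return The conditional log-likelihood (a single number).
#' @export
conditional_loglik <- function(beta, x, case, set) {
  x <- as.matrix(x)
  if (length(set) == 0) stop("no matched sets supplied")
  ok <- tapply(case, set, sum)
  if (any(ok != 1)) stop("every matched set must contain exactly one case")
  eta <- drop(x %*% beta)
  # log-sum-exp per set, stabilised
  mx <- tapply(eta, set, max)[as.character(set)]
  lse <- log(tapply(exp(eta - mx), set, sum))
  sum(eta[case]) - sum(tapply(eta, set, max) + lse)
}

#' Conditional logistic regression for 1:m matched sets
#'
#' Fits the conditional logistic model by Newton-Raphson on the
#' set-conditional log-likelihood, the standard analysis for matched
#' case-control data: conditioning on set membership removes all
#' set-level confounding (everything the sets were matched on). The
#' exposure odds ratio is `exp(coef)`, with Wald 95% confidence limits
#' `exp(coef +/- 1.96 se)` from the inverse observed information.
#'
#' @param formula Model formula, e.g. `is_case ~ exposed`; the left
#'   side is the case indicator, the right side the exposure and any
#'   additional within-set covariates (no intercept is used — it is
#'   absorbed by the conditioning).
#' @param data Data frame with one row per set member.
#' @param set Name of the column identifying matched sets (default
#'   `"set_id"`).
#' @param max_iter,tol Newton-Raphson controls: iteration cap and
#'   convergence threshold on the gradient norm.
#' @return An object of class `clr_fit` with components `coefficients`,
#'   `se`, `vcov`, `or`, `ci_low`, `ci_high` (95% Wald, OR scale),
#'   `loglik`, `converged`, `n_sets`, `n_informative_sets`, `iter`.
#'   Methods: `print`, `summary`, `coef`, `vcov`, `confint`, `logLik`.
#' @examples
#' d <- data.frame(set_id = rep(1:9, each = 2),
#'                 is_case = rep(c(TRUE, FALSE), 9),
#'                 exposed = c(rbind(rep(1:0, c(6, 3)), rep(0:1, c(6, 3)))))
#' fit <- clr_fit(is_case ~ exposed, d)
#' fit  # discordant-pair OR 6/3 = 2
#' @export
clr_fit <- function(formula, data, set = "set_id",
                    max_iter = 50L, tol = 1e-8) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- as.logical(mf[[1]])
  x <- stats::model.matrix(stats::terms(formula), mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  if (!set %in% names(data)) stop("set column '", set, "' not found")
  sid <- as.character(data[[set]])

  n_case <- tapply(y, sid, sum)
  if (any(n_case != 1))
    stop("every matched set must contain exactly one case")
  # informative sets: some within-set covariate variation
  informative <- tapply(seq_along(sid), sid, function(i) {
    nrow(unique(x[i, , drop = FALSE])) > 1
  })
  n_sets <- length(n_case)
  keep <- sid %in% names(informative)[informative]
  n_inf <- sum(informative)
  p <- ncol(x)
  fit <- list(coefficients = setNames(rep(NA_real_, p), colnames(x)),
              se = setNames(rep(NA_real_, p), colnames(x)),
              vcov = matrix(NA_real_, p, p,
                            dimnames = list(colnames(x), colnames(x))),
              loglik = NA_real_, converged = FALSE,
              n_sets = n_sets, n_informative_sets = n_inf, iter = 0L,
              formula = formula)
  class(fit) <- "clr_fit"
  if (n_inf == 0) {
    warning("no informative matched sets; nothing to estimate")
    return(fit)
  }
  xk <- x[keep, , drop = FALSE]
  yk <- y[keep]
  sk <- sid[keep]
  idx <- split(seq_along(sk), sk)

  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(xk %*% beta)
    grad <- rep(0, p)
    info <- matrix(0, p, p)
    for (i in idx) {
      e <- eta[i]
      w <- exp(e - max(e))
      w <- w / sum(w)
      xi <- xk[i, , drop = FALSE]
      mu <- drop(crossprod(xi, w))
      grad <- grad + xi[yk[i], ] - mu
      info <- info + crossprod(xi * sqrt(w)) - tcrossprod(mu)
    }
    if (sqrt(sum(grad^2)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(info, grad), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    # step-halving if the likelihood would not improve
    ll0 <- conditional_loglik(beta, xk, yk, sk)
    h <- 1
    repeat {
      cand <- beta + h * step
      if (conditional_loglik(cand, xk, yk, sk) >= ll0 - 1e-12 ||
          h < 1e-4) break
      h <- h / 2
    }
    beta <- beta + h * step
    if (any(abs(beta) > 15)) break  # separation: likelihood has no maximum
  }
  fit$iter <- it
  fit$converged <- converged
  fit$loglik <- conditional_loglik(beta, xk, yk, sk)
  if (!converged) {
    warning("conditional logistic regression did not converge ",
            "(possible separation); estimates withheld")
    return(fit)
  }
  eta <- drop(xk %*% beta)
  info <- matrix(0, p, p)
  for (i in idx) {
    e <- eta[i]
    w <- exp(e - max(e)); w <- w / sum(w)
    xi <- xk[i, , drop = FALSE]
    mu <- drop(crossprod(xi, w))
    info <- info + crossprod(xi * sqrt(w)) - tcrossprod(mu)
  }
  vc <- solve(info)
  fit$coefficients <- setNames(beta, colnames(x))
  fit$vcov <- vc
  fit$se <- setNames(sqrt(diag(vc)), colnames(x))
  fit
}

#' @export
coef.clr_fit <- function(object, ...) object$coefficients

#' @export
vcov.clr_fit <- function(object, ...) object$vcov

#' @export
logLik.clr_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' @export
confint.clr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- object$coefficients
  lo <- est - z * object$se
  hi <- est + z * object$se
  out <- cbind(lo, hi)
  colnames(out) <- paste(format(100 * c((1 - level) / 2,
                                        1 - (1 - level) / 2)), "%")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Odds ratios with Wald confidence limits
#'
#' @param object A `clr_fit`.
#' @param level Confidence level (default 0.95).
#' @return Data frame with columns `or`, `ci_low`, `ci_high`, one row
#'   per coefficient.
#' @export
odds_ratios <- function(object, level = 0.95) {
  ci <- confint(object, level = level)
  data.frame(or = exp(object$coefficients),
             ci_low = exp(ci[, 1]), ci_high = exp(ci[, 2]),
             row.names = names(object$coefficients))
}

#' @export
print.clr_fit <- function(x, ...) {
  cat("Conditional logistic regression (matched sets)\n")
  cat(sprintf("  sets: %d (%d informative)   converged: %s\n",
              x$n_sets, x$n_informative_sets, x$converged))
  if (x$converged) {
    orr <- odds_ratios(x)
    for (i in seq_along(x$coefficients))
      cat(sprintf("  %-12s beta = %7.4f  OR = %.3f  95%% CI [%.3f, %.3f]\n",
                  names(x$coefficients)[i], x$coefficients[i],
                  orr$or[i], orr$ci_low[i], orr$ci_high[i]))
  }
  invisible(x)
}

#' @export
summary.clr_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(fit = object, coefficients = tab),
            class = "summary.clr_fit")
}

#' @export
print.summary.clr_fit <- function(x, ...) {
  print(x$fit)
  if (x$fit$converged) {
    cat("\n")
    stats::printCoefmat(x$coefficients)
  }
  invisible(x)
}
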