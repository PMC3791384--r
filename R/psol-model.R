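# The solitariness discriminant: a binary logistic regression on the eleven
# arena parameters. Outcome coding is fixed project-wide: 1 = solitary,
# 0 = gregarious, so P-sol = plogis(eta) is the probability that an
# individual behaves as a member of the solitary phase.
#
# The fitter is Newton scoring (iteratively reweighted least squares) with
# Wald inference from the inverse observed information. Feature units are
# fixed (cm, s, counts) because the coefficients are unit-dependent.

.code_outcome <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    bad <- setdiff(unique(y), c("solitary", "gregarious"))
    if (length(bad))
      .lp_stop(paste("outcome labels must be 'solitary'/'gregarious'; got:",
                     paste(bad, collapse = ", ")), "lp_contract_error")
    y <- as.integer(y == "solitary")
  }
  if (!all(y %in% c(0, 1)))
    .lp_stop("outcome must be binary 0/1 (1 = solitary)", "lp_contract_error")
  as.numeric(y)
}

.loglik_logistic <- function(eta, y) {
  # log(1 + e^eta) computed stably for large |eta|
  lse <- ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
  sum(y * eta - lse)
}

#' Fit a logistic solitariness model by maximum likelihood
#'
#' Newton scoring (IRLS) with convergence declared when the log-likelihood
#' improves by less than `tol` (default 1e-8), up to `max_iter` iterations.
#' Standard errors come from the inverse observed information; each
#' coefficient gets a Wald statistic `(beta/se)^2` referred to chi-square
#' with 1 df.
#'
#' Complete or quasi-complete separation is detected when any coefficient
#' exceeds `beta_cap` on the standardized scale (`|beta| * sd(x)`), and
#' raises an error naming the culprit variables; a singular information
#' matrix raises a collinearity error.
#'
#' @param x Numeric matrix or data frame of covariates (columns named), or
#'   `NULL` for an intercept-only fit.
#' @param y Binary outcome: 0/1 numeric (1 = solitary) or a character/factor
#'   with levels `"solitary"`/`"gregarious"`.
#' @param tol Log-likelihood convergence tolerance.
#' @param max_iter Maximum IRLS iterations.
#' @param beta_cap Separation-detection threshold on standardized
#'   coefficients.
#' @return An object of class `"psol_logit"`; see [summary.psol_logit()].
#' @seealso [psol_logit()] for the formula interface, [forward_stepwise()]
#'   for variable selection.
#' @export
fit_logistic <- function(x, y, tol = 1e-8, max_iter = 50, beta_cap = 50) {
  y <- .code_outcome(y)
  n <- length(y)
  if (is.null(x) || (!is.null(dim(x)) && ncol(x) == 0L)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    x <- as.matrix(x)
    if (is.null(colnames(x)))
      colnames(x) <- paste0("X", seq_len(ncol(x)))
    if (nrow(x) != n)
      .lp_stop("covariate rows must match outcome length", "lp_contract_error")
    X <- cbind("(Intercept)" = 1, x)
  }
  k <- ncol(X) - 1L
  if (n <= k + 1L)
    .lp_stop("need more observations than coefficients", "lp_contract_error")
  if (length(unique(y)) < 2L)
    .lp_stop("outcome must contain both classes", "lp_contract_error")
  sdx <- if (k > 0) apply(X[, -1, drop = FALSE], 2, stats::sd) else numeric(0)

  beta <- numeric(ncol(X))
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    info <- crossprod(X, X * w)
    delta <- tryCatch(solve(info, crossprod(X, y - mu)),
                      error = function(e)
                        .lp_stop("singular information matrix: collinear covariates",
                                 "lp_collinearity_error"))
    beta <- beta + drop(delta)
    if (k > 0) {
      bstd <- abs(beta[-1]) * ifelse(sdx > 0, sdx, 1)
      if (any(bstd > beta_cap))
        .lp_stop(paste("complete or quasi-complete separation detected for:",
                       paste(colnames(X)[-1][bstd > beta_cap], collapse = ", ")),
                 "lp_separation_error")
    }
    ll <- .loglik_logistic(drop(X %*% beta), y)
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  vc <- solve(crossprod(X, X * w))
  se <- sqrt(diag(vc))
  wald <- (beta / se)^2
  structure(
    list(coefficients = stats::setNames(beta, colnames(X)),
         se = stats::setNames(se, colnames(X)),
         wald = stats::setNames(wald, colnames(X)),
         df = stats::setNames(rep(1L, length(beta)), colnames(X)),
         p.values = stats::setNames(stats::pchisq(wald, 1, lower.tail = FALSE),
                                    colnames(X)),
         exp_beta = stats::setNames(exp(beta), colnames(X)),
         vcov = vc,
         loglik = .loglik_logistic(eta, y), n = n,
         variables = colnames(X)[-1],
         fitted = mu, y = y,
         converged = converged, iterations = iter,
         path = NULL, call = sys.call()),
    class = "psol_logit")
}

#' Formula interface to the solitariness model
#'
#' @param formula Model formula, e.g. `phase ~ TDM + FOM + AI`. The response
#'   may be 0/1 (1 = solitary) or a `"solitary"`/`"gregarious"` label.
#' @param data Data frame holding the behavioral parameters, typically from
#'   [extract_features_cohort()].
#' @param ... Passed to [fit_logistic()].
#' @return A `"psol_logit"` model.
#' @examples
#' \donttest{
#' g <- arena_geometry()
#' cohort <- simulate_cohort(sim_config(n_per_group = 30, seed = 1), g)
#' feats <- extract_features_cohort(cohort, g)
#' m <- psol_logit(phase ~ FOM + AI, data = feats)
#' summary(m)
#' }
#' @export
psol_logit <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  m <- fit_logistic(if (ncol(X)) X else NULL, y, ...)
  m$call <- match.call()
  m
}

#' The published reference discriminant for fourth-stadium nymphs
#'
#' The fixed-coefficient logistic discriminant commonly used to place
#' fourth-stadium nymphs on the P-sol scale, retaining total distance moved
#' (TDM, cm), frequency of movement (FOM, count) and the attraction index
#' (AI, s), all with negative coefficients: active, stimulus-attracted
#' animals score gregarious (P-sol near 0), inactive repulsed ones score
#' solitary (P-sol near 1).
#'
#' Wald statistics are recomputed as `(beta/se)^2` from the published
#' rounded coefficients and standard errors; they therefore differ slightly
#' from originally reported test statistics, which were computed from
#' unrounded estimates. The log-likelihood of the original 200-animal fit is
#' not recoverable and is stored as `NA`.
#'
#' @return A `"psol_logit"` model object with fixed coefficients.
#' @examples
#' m <- psol_reference_model()
#' round(m$exp_beta, 3)
#' # an inactive animal with no zone preference scores strongly solitary:
#' predict(m, data.frame(TDM = 0, FOM = 0, AI = 0), type = "response")
#' @export
psol_reference_model <- function() {
  nm <- c("(Intercept)", "TDM", "FOM", "AI")
  beta <- stats::setNames(c(2.361, -0.016, -0.172, -0.005), nm)
  se <- stats::setNames(c(0.353, 0.004, 0.073, 0.001), nm)
  wald <- (beta / se)^2
  structure(
    list(coefficients = beta, se = se, wald = wald,
         df = stats::setNames(rep(1L, 4L), nm),
         p.values = stats::setNames(stats::pchisq(wald, 1, lower.tail = FALSE), nm),
         exp_beta = exp(beta), vcov = NULL,
         loglik = NA_real_, n = 200L,
         variables = c("TDM", "FOM", "AI"),
         fitted = NULL, y = NULL, converged = TRUE, iterations = 0L,
         path = NULL, call = quote(psol_reference_model())),
    class = "psol_logit")
}

#' @export
print.psol_logit <- function(x, ...) {
  cat("Logistic solitariness model (P-sol; 1 = solitary, 0 = gregarious)\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("n = %d, variables: %s\n", x$n,
              if (length(x$variables)) paste(x$variables, collapse = ", ")
              else "(intercept only)"))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Summarize a fitted solitariness model
#'
#' @param object A `"psol_logit"` model.
#' @param ... Unused.
#' @return An object of class `"summary.psol_logit"` whose `coefficients`
#'   table has columns beta, SE, Wald, df, p and Exp(beta), listing the
#'   retained variables first and the constant last.
#' @export
summary.psol_logit <- function(object, ...) {
  ord <- c(object$variables, "(Intercept)")
  tab <- cbind(beta = object$coefficients[ord], SE = object$se[ord],
               Wald = object$wald[ord], df = object$df[ord],
               p = object$p.values[ord], `Exp(beta)` = object$exp_beta[ord])
  rownames(tab)[rownames(tab) == "(Intercept)"] <- "Constant"
  structure(list(call = object$call, coefficients = tab,
                 loglik = object$loglik, n = object$n,
                 converged = object$converged, iterations = object$iterations,
                 path = object$path),
            class = "summary.psol_logit")
}

#' @export
print.summary.psol_logit <- function(x, digits = 4, ...) {
  cat("Logistic solitariness model (P-sol)\nCall: ", deparse(x$call), "\n\n",
      sep = "")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE, cs.ind = 1:2, tst.ind = 3,
                      zap.ind = 4)
  if (is.finite(x$loglik))
    cat(sprintf("\nlog-likelihood %.4f on n = %d (%s in %d iterations)\n",
                x$loglik, x$n,
                if (x$converged) "converged" else "NOT converged",
                x$iterations))
  if (!is.null(x$path)) {
    cat("\nForward stepwise path:\n")
    print(x$path, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.psol_logit <- function(object, ...) object$coefficients

#' @export
vcov.psol_logit <- function(object, ...) object$vcov

#' @export
logLik.psol_logit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' Predict the linear predictor or P-sol for new animals
#'
#' @param object A `"psol_logit"` model.
#' @param newdata Data frame containing every model variable on the original
#'   untransformed scale (cm, s, counts).
#' @param type `"response"` for P-sol probabilities, `"link"` for the linear
#'   predictor eta.
#' @param ... Unused.
#' @return Numeric vector, one value per row of `newdata`.
#' @export
predict.psol_logit <- function(object, newdata,
                               type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (missing(newdata)) {
    if (is.null(object$fitted))
      .lp_stop("model has no training data; supply `newdata`", "lp_contract_error")
    return(if (type == "response") object$fitted
           else stats::qlogis(object$fitted))
  }
  miss <- setdiff(object$variables, names(newdata))
  if (length(miss))
    .lp_stop(paste("newdata is missing model variables:",
                   paste(miss, collapse = ", ")), "lp_contract_error")
  X <- as.matrix(newdata[, object$variables, drop = FALSE])
  eta <- drop(object$coefficients["(Intercept)"] +
                X %*% object$coefficients[object$variables])
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
residuals.psol_logit <- function(object, type = c("deviance", "pearson"), ...) {
  type <- match.arg(type)
  if (is.null(object$y))
    .lp_stop("model has no training data", "lp_contract_error")
  mu <- object$fitted
  if (type == "pearson") return((object$y - mu) / sqrt(mu * (1 - mu)))
  d <- -2 * (object$y * log(mu) + (1 - object$y) * log(1 - mu))
  sign(object$y - mu) * sqrt(pmax(d, 0))
}

#' @export
simulate.psol_logit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$fitted))
    .lp_stop("model has no training data to simulate from", "lp_contract_error")
  if (!is.null(seed)) set.seed(seed)
  as.data.frame(replicate(nsim, stats::rbinom(length(object$fitted), 1,
                                              object$fitted)))
}

#' Score animals on the P-sol scale
#'
#' @param model A `"psol_logit"` model.
#' @param features Data frame with one row per subject containing at least
#'   the model variables; a `subject_id` column is carried through.
#' @return Data frame with columns `subject_id`, `eta`, `psol`.
#' @export
score_psol <- function(model, features) {
  if (!nrow(features))
    .lp_stop("empty feature table", "lp_contract_error")
  eta <- predict(model, features, type = "link")
  data.frame(
    subject_id = if ("subject_id" %in% names(features)) features$subject_id
                 else paste0("subj_", seq_len(nrow(features))),
    eta = eta, psol = stats::plogis(eta),
    stringsAsFactors = FALSE)
}

#' Forward stepwise selection of the solitariness model
#'
#' Starts from the intercept-only model and, at each step, adds the
#' candidate variable with the smallest likelihood-ratio p-value, provided
#' it is below `p_enter`; selection stops when no candidate qualifies.
#' Ties are broken by the larger likelihood improvement, then by candidate
#' order. There is no removal step. Candidates whose trial fit fails with a
#' separation or collinearity error are ineligible at that step (their
#' likelihood-ratio inference is undefined); any such exclusions are noted
#' in the selection path.
#'
#' @param data Data frame of candidate covariates plus the outcome column.
#' @param outcome Name of the outcome column (0/1 with 1 = solitary, or
#'   `"solitary"`/`"gregarious"` labels). Default `"phase"`.
#' @param candidates Character vector of candidate variable names; defaults
#'   to the eleven behavioral parameters present in `data`.
#' @param p_enter Likelihood-ratio entry threshold (default 0.05).
#' @param ... Passed to [fit_logistic()].
#' @return The final refitted `"psol_logit"` model, with the selection path
#'   in `$path` (step, variable added, log-likelihood, LR p-value).
#' @export
forward_stepwise <- function(data, outcome = "phase",
                             candidates = intersect(FEATURE_NAMES, names(data)),
                             p_enter = 0.05, ...) {
  if (!outcome %in% names(data))
    .lp_stop(sprintf("outcome column '%s' not found", outcome),
             "lp_contract_error")
  y <- .code_outcome(data[[outcome]])
  selected <- character(0)
  current <- fit_logistic(NULL, y, ...)
  path <- data.frame(step = integer(0), added = character(0),
                     loglik = numeric(0), lr_p = numeric(0),
                     stringsAsFactors = FALSE)
  remaining <- candidates
  step_no <- 0L
  while (length(remaining)) {
    trials <- lapply(remaining, function(v) {
      tryCatch({
        m <- fit_logistic(data[, c(selected, v), drop = FALSE], y, ...)
        lr <- 2 * (m$loglik - current$loglik)
        list(model = m, p = stats::pchisq(max(lr, 0), 1, lower.tail = FALSE),
             loglik = m$loglik, ok = TRUE)
      }, locustphase_error = function(e) list(ok = FALSE, message = conditionMessage(e)))
    })
    ok <- vapply(trials, `[[`, logical(1), "ok")
    if (!any(ok)) break
    ps <- vapply(trials[ok], `[[`, numeric(1), "p")
    lls <- vapply(trials[ok], `[[`, numeric(1), "loglik")
    # smallest p; ties by larger loglik, then candidate order
    best <- order(ps, -lls)[1]
    if (ps[best] >= p_enter) break
    step_no <- step_no + 1L
    pick <- which(ok)[best]
    selected <- c(selected, remaining[pick])
    current <- trials[[pick]]$model
    path <- rbind(path, data.frame(step = step_no, added = remaining[pick],
                                   loglik = current$loglik, lr_p = ps[best],
                                   stringsAsFactors = FALSE))
    remaining <- remaining[-pick]
  }
  current$path <- path
  current$call <- match.call()
  current
}
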