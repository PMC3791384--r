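test_that("the reference discriminant carries the published coefficients coherently", {
  m <- psol_reference_model()
  expect_identical(m$variables, c("TDM", "FOM", "AI"))
  expect_equal(unname(coef(m)), c(2.361, -0.016, -0.172, -0.005))
  # Exp(beta) is exp of the stored coefficients, to machine accuracy
  expect_equal(m$exp_beta, exp(coef(m)), tolerance = 1e-12)
  # Wald = (beta/se)^2 with 1 df
  expect_equal(unname(m$wald), unname((coef(m) / m$se)^2))
  expect_true(all(m$df == 1))
})

test_that("P-sol scoring evaluates the logistic link on untransformed features", {
  m <- psol_reference_model()
  # eta = 0 gives exactly 0.5 (TDM chosen to cancel the constant)
  expect_equal(predict(m, data.frame(TDM = 2.361 / 0.016, FOM = 0, AI = 0),
                       type = "response"), 0.5)
  # an animal that never moves and shows no preference scores solitary
  p0 <- predict(m, data.frame(TDM = 0, FOM = 0, AI = 0), type = "response")
  expect_equal(p0, exp(2.361) / (1 + exp(2.361)))
  expect_equal(p0, 0.9138, tolerance = 1e-4)
  # an active, attracted animal scores gregarious
  act <- data.frame(TDM = 1000, FOM = 20, AI = 300)
  expect_equal(predict(m, act, type = "link"), -18.579)
  expect_lt(predict(m, act, type = "response"), 1e-8)
  # P-sol is decreasing in each retained variable
  base <- data.frame(TDM = 100, FOM = 5, AI = 50)
  for (v in c("TDM", "FOM", "AI")) {
    up <- base; up[[v]] <- up[[v]] + 10
    expect_lt(predict(m, up, type = "response"),
              predict(m, base, type = "response"))
  }
  expect_error(predict(m, data.frame(TDM = 1, FOM = 2)),
               class = "lp_contract_error")
  sc <- score_psol(m, data.frame(subject_id = "a", TDM = 0, FOM = 0, AI = 0))
  expect_equal(sc$psol, plogis(sc$eta))
})

test_that("intercept-only fits recover the logit of the class rate", {
  expect_equal(unname(coef(fit_logistic(NULL, rep(c(0, 1), 25)))), 0,
               tolerance = 1e-8)
  y <- c(rep(1, 40), rep(0, 10))
  expect_equal(unname(coef(fit_logistic(NULL, y))), log(4), tolerance = 1e-8)
})

test_that("IRLS agrees with glm on multivariate fits", {
  set.seed(101)
  n <- 200
  X <- cbind(TDM = rnorm(n, 300, 150), FOM = rnorm(n, 30, 10),
             AI = rnorm(n, 0, 100))
  y <- rbinom(n, 1, plogis(1 - 0.004 * X[, 1] - 0.05 * X[, 2] - 0.004 * X[, 3]))
  m <- fit_logistic(X, y)
  ref <- glm(y ~ X, family = binomial())
  expect_equal(unname(coef(m)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(m$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)
  expect_equal(m$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_true(m$converged)
  # fit -> score round trip reproduces the fitted probabilities
  expect_equal(predict(m, as.data.frame(X), type = "response"),
               unname(m$fitted), tolerance = 1e-10)
  # outcome labels code solitary as 1
  lab <- ifelse(y == 1, "solitary", "gregarious")
  expect_equal(coef(fit_logistic(X, lab)), coef(m))
})

test_that("rescaling a covariate rescales its coefficient and not the fit", {
  set.seed(55)
  x <- matrix(rnorm(150), ncol = 1, dimnames = list(NULL, "AI"))
  y <- rbinom(150, 1, plogis(0.4 - 0.8 * x))
  m1 <- fit_logistic(x, y)
  m2 <- fit_logistic(x * 10, y)
  expect_equal(coef(m2)[["AI"]], coef(m1)[["AI"]] / 10, tolerance = 1e-6)
  expect_equal(m2$fitted, m1$fitted, tolerance = 1e-8)
})

test_that("separation and collinearity are reported as such", {
  # quasi-separation with a tiny class gap forces the standardized
  # coefficient past the cap before the likelihood can level off
  x <- matrix(c(1, 2, 3, 4, 4.0001, 5, 6, 7) * 100, ncol = 1,
              dimnames = list(NULL, "TDM"))
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  expect_error(fit_logistic(x, y), "TDM", class = "lp_separation_error")
  X2 <- cbind(a = rnorm(30), b = 0)
  X2 <- cbind(X2, c = X2[, "a"] * 2)
  expect_error(fit_logistic(X2, rbinom(30, 1, 0.5)),
               class = "lp_collinearity_error")
  expect_error(fit_logistic(NULL, rep(1, 20)), class = "lp_contract_error")
  expect_error(fit_logistic(matrix(rnorm(4), 2), c(0, 1)),
               class = "lp_contract_error")
})

test_that("the maximum-likelihood solution matches a direct-optimization oracle", {
  set.seed(77)
  for (i in 1:6) {
    n <- sample(8:12, 1)
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(0.3 * x))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    m <- tryCatch(fit_logistic(matrix(x, dimnames = list(NULL, "v")), y),
                  locustphase_error = function(e) NULL)
    if (is.null(m)) next
    expect_equal(unname(coef(m)), oracle_logit1(x, y), tolerance = 1e-4)
  }
})

test_that("forward stepwise recovers a single informative signal", {
  set.seed(202)
  n <- 200
  d <- data.frame(TDM = rnorm(n, 300, 100), FOM = rnorm(n, 30, 10),
                  AI = rnorm(n, 0, 100), MDTSG = rnorm(n, 12, 3))
  d$phase <- rbinom(n, 1, plogis(-0.015 * d$AI))  # only AI informative
  m <- forward_stepwise(d, outcome = "phase",
                        candidates = c("TDM", "FOM", "AI", "MDTSG"))
  expect_identical(m$path$added[1], "AI")
  expect_lt(coef(m)[["AI"]], 0)
  expect_true(all(m$path$lr_p < 0.05))
})

test_that("forward stepwise holds its type-I entry level on pure noise", {
  set.seed(303)
  n_rep <- 200
  picked <- integer(n_rep)
  for (r in seq_len(n_rep)) {
    d <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60),
                    phase = rbinom(60, 1, 0.5))
    m <- forward_stepwise(d, outcome = "phase", candidates = c("a", "b", "c"))
    picked[r] <- length(m$variables)
  }
  # per-candidate entry rate ~ 5%; 3 candidates, binomial error over 200 reps
  rate <- sum(picked) / (n_rep * 3)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.10)
})

test_that("an empty candidate set yields the intercept-only model", {
  d <- data.frame(phase = rep(c(0, 1), 20))
  m <- forward_stepwise(d, outcome = "phase", candidates = character(0))
  expect_length(m$variables, 0)
  expect_equal(unname(coef(m)), 0, tolerance = 1e-8)
})

test_that("models serialize to JSON and back without losing the fit", {
  set.seed(9)
  d <- data.frame(TDM = rnorm(80, 300, 100), AI = rnorm(80, 0, 100))
  d$phase <- rbinom(80, 1, plogis(1 - 0.01 * d$TDM - 0.01 * d$AI))
  m <- psol_logit(phase ~ TDM + AI, data = d)
  path <- withr::local_tempfile(fileext = ".json")
  write_psol_model(m, path)
  back <- read_psol_model(path)
  expect_equal(coef(back), coef(m))
  expect_equal(back$se, m$se)
  expect_equal(predict(back, d, type = "response"),
               predict(m, d, type = "response"))
})
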