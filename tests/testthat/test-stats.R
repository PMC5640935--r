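test_that("logistic regression reproduces the closed-form 2x2 log-OR", {
  # cells (a, b, c, d) = (exposed cases, unexposed cases,
  # exposed controls, unexposed controls)
  set.seed(30)
  for (i in 1:20) {
    cells <- sample(5:40, 4)
    dd <- data.frame(
      y = rep(c(1, 1, 0, 0), cells),
      x = rep(c(1, 0, 1, 0), cells)
    )
    fit <- fit_logistic(dd, y ~ x)
    expect_true(fit$converged)
    expect_equal(unname(fit$coefficients["x"]),
                 log(cells[1] * cells[4] / (cells[2] * cells[3])),
                 tolerance = 1e-8)
  }
})

test_that("logistic IRLS agrees with independent likelihood maximisation", {
  set.seed(31)
  for (i in 1:10) {
    n <- 60
    dd <- data.frame(x = stats::rnorm(n))
    dd$y <- stats::rbinom(n, 1, stats::plogis(0.3 + 0.8 * dd$x))
    if (length(unique(dd$y)) < 2) next
    fit <- fit_logistic(dd, y ~ x)
    # brute-force likelihood oracle: direct Bernoulli likelihood,
    # generic optimiser
    nll <- function(b) {
      p <- 1 / (1 + exp(-(b[1] + b[2] * dd$x)))
      -sum(dd$y * log(p) + (1 - dd$y) * log(1 - p))
    }
    o <- stats::optim(c(0, 0), nll, method = "BFGS",
                      control = list(reltol = 1e-14))
    expect_equal(unname(fit$coefficients), o$par, tolerance = 1e-4)
    # cross-check against the standard GLM fit, coefficients and SEs
    g <- stats::glm(y ~ x, binomial, dd)
    expect_equal(unname(fit$coefficients), unname(stats::coef(g)),
                 tolerance = 1e-6)
    expect_equal(unname(fit$se),
                 unname(sqrt(diag(stats::vcov(g)))), tolerance = 1e-4)
  }
})

test_that("a covariate independent of the outcome estimates near zero", {
  set.seed(32)
  dd <- data.frame(y = stats::rbinom(1e4, 1, 0.4),
                   x = stats::rnorm(1e4))
  fit <- fit_logistic(dd, y ~ x)
  expect_lt(abs(fit$coefficients["x"]), 3 * fit$se["x"])
})

test_that("separation and singularity are flagged, not silently returned", {
  dd <- data.frame(y = rep(c(0, 1), each = 10),
                   x = rep(c(0, 1), each = 10))
  fit <- fit_logistic(dd, y ~ x)
  expect_false(fit$converged)
  expect_true(fit$separation)
  expect_warning(wald_or_ci(fit), "converge")

  dd$z <- 2 * dd$x
  expect_error(fit_logistic(dd, y ~ x + z), "z")
  expect_error(fit_logistic(data.frame(y = rep(1, 5), x = 1:5), y ~ x),
               "both classes")
})

test_that("conditional logistic matches the discordant-pair closed form", {
  # 10 case-exposed-only and 5 control-exposed-only discordant pairs,
  # plus concordant padding: OR = 10/5 = 2
  dd <- data.frame(
    stratum = rep(1:19, each = 2),
    is_case = rep(c(1, 0), 19),
    x = c(rep(c(1, 0), 10), rep(c(0, 1), 5), rep(c(1, 1), 4))
  )
  fit <- fit_conditional_logistic(dd, is_case ~ x)
  expect_equal(unname(exp(fit$coefficients["x"])), 2, tolerance = 1e-6)
  expect_equal(fit$n_informative, 15)

  # concordant-only strata are rejected as uninformative
  conc <- data.frame(stratum = rep(1:4, each = 2),
                     is_case = rep(c(1, 0), 4), x = rep(c(1, 1), 4))
  expect_error(fit_conditional_logistic(conc, is_case ~ x),
               "uninformative")
  # stratum structure is validated
  bad <- data.frame(stratum = c(1, 1), is_case = c(1, 1), x = c(1, 0))
  expect_error(fit_conditional_logistic(bad, is_case ~ x),
               "exactly one case")
})

test_that("conditional fit agrees with a conditional-likelihood grid
           oracle on random 1:3 sets", {
  set.seed(33)
  for (i in 1:10) {
    n_sets <- 25
    dd <- data.frame(
      stratum = rep(seq_len(n_sets), each = 4),
      is_case = rep(c(1, 0, 0, 0), n_sets),
      x = stats::rnorm(4 * n_sets)
    )
    fit <- fit_conditional_logistic(dd, is_case ~ x)
    oracle <- stats::optimize(
      function(b) -oracle_cond_loglik(b, dd$x, dd$is_case, dd$stratum),
      interval = c(-8, 8), tol = 1e-10)$minimum
    expect_equal(unname(fit$coefficients["x"]), oracle,
                 tolerance = 1e-4)
  }
})

test_that("1:1 conditional fit equals the paired-difference logistic fit", {
  set.seed(34)
  for (i in 1:10) {
    n <- 40
    x_case <- stats::rnorm(n, 0.3)
    x_ctrl <- stats::rnorm(n)
    dd <- data.frame(
      stratum = rep(seq_len(n), each = 2),
      is_case = rep(c(1, 0), n),
      x = as.vector(rbind(x_case, x_ctrl))
    )
    fit <- fit_conditional_logistic(dd, is_case ~ x)
    expect_equal(unname(fit$coefficients["x"]),
                 oracle_pairdiff_beta(x_case - x_ctrl),
                 tolerance = 1e-10)
  }
})

test_that("conditional fit agrees with the survival package on shared data", {
  skip_if_not_installed("survival")
  set.seed(35)
  n <- 60
  dd <- data.frame(
    stratum = rep(seq_len(n), each = 2),
    is_case = rep(c(1, 0), n),
    x = stats::rnorm(2 * n),
    z = stats::rbinom(2 * n, 1, 0.4)
  )
  fit <- fit_conditional_logistic(dd, is_case ~ x + z)
  ref <- survival::coxph(
    survival::Surv(rep(1, nrow(dd)), is_case) ~ x + z +
      survival::strata(stratum),
    data = dd, method = "exact")
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(stats::vcov(ref)))),
               tolerance = 1e-5)
})

test_that("Wald intervals use the exact normal quantile", {
  fit <- structure(
    list(coefficients = c(x = 0), se = c(x = 1), vcov = matrix(1),
         loglik = 0, iterations = 1, converged = TRUE,
         separation = FALSE, method = "logistic (IRLS)", n = 10,
         n_strata = NA, n_informative = NA),
    class = "organo_fit")
  ci <- wald_or_ci(fit)
  expect_equal(ci$or, 1)
  expect_equal(ci$conf.low, exp(-stats::qnorm(0.975)), tolerance = 1e-10)
  expect_equal(ci$conf.high, exp(stats::qnorm(0.975)), tolerance = 1e-10)
  expect_equal(round(ci$conf.low, 3), 0.141)
  expect_equal(round(ci$conf.high, 2), 7.10)
  # degenerate SE collapses the interval and is flagged
  fit$se <- c(x = 0)
  ci0 <- wald_or_ci(fit)
  expect_true(ci0$degenerate)
  expect_equal(ci0$conf.low, ci0$or)

  # level argument against an independent quantile computation
  fit$se <- c(x = 0.5)
  ci90 <- wald_or_ci(fit, level = 0.90)
  expect_equal(ci90$conf.high, exp(0.5 * stats::qnorm(0.95)),
               tolerance = 1e-12)
})

test_that("chi-square reproduces printed case-series statistics", {
  er <- rbind(Positive = c(57, 69, 77), Negative = c(48, 37, 21))
  out <- pearson_chi_square(er)
  expect_equal(round(out$statistic, 1), 13.3)
  expect_equal(out$df, 2)

  # identical columns give exactly zero
  same <- cbind(a = c(10, 20), b = c(10, 20))
  expect_equal(pearson_chi_square(same)$statistic, 0)

  # direct-formula oracle on random tables
  set.seed(36)
  for (i in 1:20) {
    tab <- matrix(sample(1:30, 12, replace = TRUE), 3, 4)
    got <- pearson_chi_square(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(got$statistic, sum((tab - E)^2 / E), tolerance = 1e-10)
    expect_equal(got$p_value,
                 stats::pchisq(got$statistic, 6, lower.tail = FALSE))
  }
  # empty rows dropped with warning
  expect_warning(
    out <- pearson_chi_square(rbind(c(5, 6), c(0, 0), c(7, 8))),
    "empty")
  expect_equal(out$df, 1)
})

test_that("Mann-Whitney U handles exact, tied and degenerate cases", {
  # enumeration example: complete separation of 3 vs 3
  h <- mann_whitney_u(1:3, 4:6)
  expect_equal(h$statistic, 0)
  expect_equal(h$p_value, 0.1)

  # identical multisets: U = n1 n2 / 2
  h <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(h$statistic, 4.5)

  # all values tied across both samples
  h <- mann_whitney_u(rep(2, 5), rep(2, 7))
  expect_equal(h$p_value, 1)
  expect_match(h$note, "degenerate")

  # tie-corrected approximation vs a permutation oracle
  set.seed(37)
  x <- sample(1:6, 25, replace = TRUE)
  y <- sample(2:7, 30, replace = TRUE)
  h <- mann_whitney_u(x, y)
  pooled <- c(x, y)
  obs <- abs(h$statistic - length(x) * length(y) / 2)
  perm <- replicate(1e4, {
    idx <- sample(length(pooled), length(x))
    u <- sum(rank(pooled)[idx]) - length(x) * (length(x) + 1) / 2
    abs(u - length(x) * length(y) / 2)
  })
  p_perm <- mean(perm >= obs)
  mc_sd <- sqrt(p_perm * (1 - p_perm) / 1e4)
  expect_lt(abs(h$p_value - p_perm), 4 * mc_sd + 0.01)
})

test_that("Wilcoxon signed-rank handles exact, tied and degenerate cases", {
  # all positive, n = 6: W = 21, exact p = 2/64
  h <- wilcoxon_signed_rank(c(0.5, 1, 2, 3, 4, 5))
  expect_equal(h$statistic, 21)
  expect_equal(h$p_value, 2 / 64)

  # antisymmetric differences: W at the null centre, p = 1
  h <- wilcoxon_signed_rank(c(2, -2))
  expect_equal(h$p_value, 1)

  # zeros dropped, all-zero degenerate
  h <- wilcoxon_signed_rank(c(0, 0, 0))
  expect_equal(h$p_value, 1)
  expect_match(h$note, "degenerate")

  # sign-flip permutation oracle with ties present
  set.seed(38)
  d <- sample(c(-3:-1, 1:4), 30, replace = TRUE)
  h <- wilcoxon_signed_rank(d)
  r <- rank(abs(d))
  mu <- sum(r) / 2
  obs <- abs(sum(r[d > 0]) - mu)
  perm <- replicate(1e4, {
    sgn <- sample(c(TRUE, FALSE), length(d), replace = TRUE)
    abs(sum(r[sgn]) - mu)
  })
  p_perm <- mean(perm >= obs)
  mc_sd <- sqrt(p_perm * (1 - p_perm) / 1e4)
  expect_lt(abs(h$p_value - p_perm), 4 * mc_sd + 0.01)

  # exact distribution agrees with the base-R reference for clean input
  h <- wilcoxon_signed_rank(c(1.2, -0.7, 2.5, 3.1, -0.2, 1.9, 4.4))
  ref <- stats::wilcox.test(c(1.2, -0.7, 2.5, 3.1, -0.2, 1.9, 4.4))
  expect_equal(h$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("BH adjustment implements the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  # hand application with distinct ranks
  expect_equal(bh_adjust(c(0.001, 0.02, 0.9)),
               c(0.003, 0.03, 0.9))
  # cross-check against the reference implementation, and order
  # preservation
  set.seed(39)
  p <- stats::runif(200)^2
  expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  o <- order(p)
  expect_true(all(diff(bh_adjust(p)[o]) >= -1e-15))
})

test_that("AUC obeys the rank formula and the U identity", {
  expect_equal(roc_auc(c(1, 2, 10, 11), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(3, 10), rep(c(0, 1), 5))$auc, 0.5)
  set.seed(40)
  for (i in 1:50) {
    scores <- sample(1:8, 30, replace = TRUE)  # heavy ties
    labels <- sample(c(0, 1), 30, replace = TRUE, prob = c(.6, .4))
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    u <- mann_whitney_u(scores[labels == 1],
                        scores[labels == 0])$statistic
    expect_identical(r$u, u)
    expect_identical(r$auc, r$u / (r$n_pos * r$n_neg))
  }
  # ROC curve ends at (1, 1) and is monotone
  r <- roc_auc(stats::rnorm(50), stats::rbinom(50, 1, 0.5))
  expect_equal(r$points$fpr[nrow(r$points)], 1)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_error(roc_auc(1:5, rep(1, 5)), "both label classes")
})

test_that("quartile analysis bins by control thresholds and detects
           monotone risk", {
  set.seed(41)
  n <- 120
  score_ctrl <- stats::rnorm(n)
  score_case <- stats::rnorm(n, 1)  # strong positive shift
  dd <- data.frame(
    stratum = rep(seq_len(n), each = 2),
    is_case = rep(c(1, 0), n),
    score = as.vector(rbind(score_case, score_ctrl))
  )
  out <- quartile_or_analysis(dd)
  # thresholds equal independently computed control percentiles
  expect_equal(unname(out$thresholds),
               unname(stats::quantile(score_ctrl, c(.25, .5, .75))))
  or <- out$table$or
  names(or) <- out$table$term
  expect_gt(or[["Q4"]], or[["Q2"]])
  expect_gt(or[["Q4"]], 1)

  # null scores: quartile ORs compatible with 1
  set.seed(42)
  dd0 <- data.frame(
    stratum = rep(1:200, each = 2),
    is_case = rep(c(1, 0), 200),
    score = stats::rnorm(400)
  )
  out0 <- quartile_or_analysis(dd0)
  tab <- out0$table[out0$table$term != "Q1", ]
  expect_gte(sum(tab$conf.low < 1 & tab$conf.high > 1), 2)
  expect_true(all(tab$or > 0.5 & tab$or < 2))
  expect_error(quartile_or_analysis(
    data.frame(stratum = 1:4, is_case = rep(c(1, 0), 2),
               score = 1:4)),
    "at least 8")
})

test_that("tidy and glance summarise fits in broom shape", {
  set.seed(43)
  dd <- data.frame(x = stats::rnorm(80))
  dd$y <- stats::rbinom(80, 1, stats::plogis(dd$x))
  fit <- fit_logistic(dd, y ~ x)
  td <- tidy(fit)
  expect_equal(names(td),
               c("term", "estimate", "std.error", "statistic", "p.value",
                 "conf.low", "conf.high"))
  expect_equal(nrow(td), 2)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$nobs, 80)
  expect_s3_class(tidy(mann_whitney_u(1:5, 2:9)), "tbl_df")
})
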