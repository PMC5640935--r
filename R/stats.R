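#' @importFrom rlang .data
#' @importFrom stats pchisq pnorm qnorm quantile
NULL

new_organo_fit <- function(coefficients, se, vcov, loglik, iterations,
                           converged, separation, method, n,
                           n_strata = NA_integer_,
                           n_informative = NA_integer_) {
  structure(
    list(coefficients = coefficients, se = se, vcov = vcov,
         loglik = loglik, iterations = iterations, converged = converged,
         separation = separation, method = method, n = n,
         n_strata = n_strata, n_informative = n_informative),
    class = "organo_fit"
  )
}

check_separation <- function(beta, X, has_intercept) {
  idx <- seq_along(beta)
  if (has_intercept) idx <- idx[-1]
  if (length(idx) == 0) return(FALSE)
  sds <- apply(X[, idx, drop = FALSE], 2, stats::sd)
  sds[sds == 0] <- 1
  any(abs(beta[idx] * sds) > 15)
}

check_singular <- function(X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is singular; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
}

#' Unconditional logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic regression fitted from scratch: Newton
#' scoring (IRLS) with an intercept, standard errors from the inverse
#' observed information. Iteration stops when the largest score component
#' falls below 1e-8 or the relative log-likelihood change falls below
#' 1e-10 (at most 50 iterations). Complete or quasi-complete separation is
#' detected as a coefficient exceeding 15 on the standardized-covariate
#' scale and reported via `converged = FALSE` with a separation flag.
#'
#' @param data Data frame holding the outcome and covariates.
#' @param formula Model formula, e.g. `case ~ score + er`; the outcome
#'   must be 0/1 with both classes present.
#' @return An object of class `organo_fit`; see [tidy.organo_fit()] and
#'   [wald_or_ci()].
#' @export
fit_logistic <- function(data, formula) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  stopifnot(all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) {
    stop("outcome must include both classes", call. = FALSE)
  }
  X <- stats::model.matrix(formula, mf)
  check_singular(X)
  has_int <- "(Intercept)" %in% colnames(X)

  beta <- rep(0, ncol(X))
  ll_old <- -Inf
  separation <- FALSE
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    ll <- sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
    score <- drop(crossprod(X, y - p))
    w <- p * (1 - p)
    info <- crossprod(X * w, X)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) break
    # iterate to machine precision; declare convergence on the score /
    # likelihood criteria
    if (max(abs(score)) < 1e-8 ||
        (is.finite(ll_old) && abs(ll - ll_old) <
           1e-10 * (abs(ll_old) + 1e-10))) {
      converged <- TRUE
      if (max(abs(step)) < 1e-12) break
    }
    beta <- beta + step
    ll_old <- ll
    if (check_separation(beta, X, has_int)) {
      separation <- TRUE
      break
    }
    if (iter >= 50) break
  }
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  info <- crossprod(X * (p * (1 - p)), X)
  vc <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  dimnames(vc) <- list(colnames(X), colnames(X))
  new_organo_fit(
    coefficients = stats::setNames(beta, colnames(X)),
    se = stats::setNames(sqrt(diag(vc)), colnames(X)),
    vcov = vc,
    loglik = sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))),
    iterations = iter,
    converged = converged && !separation,
    separation = separation,
    method = "logistic (IRLS)",
    n = length(y)
  )
}

clogit_parts <- function(beta, X, y, stratum) {
  eta <- drop(X %*% beta)
  ll <- 0
  score <- rep(0, ncol(X))
  info <- matrix(0, ncol(X), ncol(X))
  for (s in split(seq_along(y), stratum)) {
    e <- eta[s]
    m <- max(e)
    w <- exp(e - m)
    p <- w / sum(w)
    xs <- X[s, , drop = FALSE]
    xbar <- drop(crossprod(xs, p))
    case <- s[y[s] == 1]
    ll <- ll + (eta[case] - m) - log(sum(w))
    score <- score + X[case, ] - xbar
    info <- info + crossprod(xs * p, xs) - tcrossprod(xbar)
  }
  list(ll = ll, score = score, info = info)
}

#' Conditional logistic regression on matched sets
#'
#' Maximizes the conditional likelihood
#' `prod_s exp(beta' x_case) / sum_{j in s} exp(beta' x_j)` over matched
#' sets (one case and one or more controls per stratum) by Newton-Raphson
#' — the estimator used for individually matched case-control data, where
#' per-set nuisance intercepts are eliminated by conditioning. Strata with
#' no within-stratum covariate variation contribute nothing and are
#' counted as uninformative; separation is flagged as in
#' [fit_logistic()]. For 1:1 matching this is identical to an
#' intercept-free logistic fit on within-pair covariate differences.
#'
#' @param data Data frame with outcome, covariates and a stratum column.
#' @param formula Model formula without intercept semantics, e.g.
#'   `case ~ score`; the outcome must be 0/1.
#' @param strata Name of the column identifying matched sets.
#' @return An object of class `organo_fit`.
#' @export
fit_conditional_logistic <- function(data, formula, strata = "stratum") {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  stopifnot(all(y %in% c(0, 1)))
  X <- stats::model.matrix(formula, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  stratum <- data[[strata]]
  if (is.null(stratum)) {
    stop("stratum column not found: ", strata, call. = FALSE)
  }
  n_case <- tapply(y, stratum, sum)
  n_tot <- tapply(y, stratum, length)
  if (any(n_case != 1) || any(n_tot < 2)) {
    stop("each stratum needs exactly one case and at least one control",
         call. = FALSE)
  }
  informative <- vapply(
    split(seq_along(y), stratum),
    function(s) nrow(unique(X[s, , drop = FALSE])) > 1,
    logical(1)
  )
  if (!any(informative)) {
    stop("all strata are uninformative (no within-stratum covariate ",
         "variation)", call. = FALSE)
  }
  keep <- stratum %in% names(informative)[informative]
  Xk <- X[keep, , drop = FALSE]
  check_singular(Xk)
  yk <- y[keep]
  sk <- stratum[keep]

  beta <- rep(0, ncol(X))
  ll_old <- -Inf
  separation <- FALSE
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    parts <- clogit_parts(beta, Xk, yk, sk)
    step <- tryCatch(solve(parts$info, parts$score),
                     error = function(e) NULL)
    if (is.null(step)) break
    if (max(abs(parts$score)) < 1e-8 ||
        (is.finite(ll_old) && abs(parts$ll - ll_old) <
           1e-10 * (abs(ll_old) + 1e-10))) {
      converged <- TRUE
      if (max(abs(step)) < 1e-12) break
    }
    beta <- beta + step
    ll_old <- parts$ll
    if (check_separation(beta, Xk, has_intercept = FALSE)) {
      separation <- TRUE
      break
    }
    if (iter >= 50) break
  }
  parts <- clogit_parts(beta, Xk, yk, sk)
  vc <- tryCatch(solve(parts$info), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  dimnames(vc) <- list(colnames(X), colnames(X))
  new_organo_fit(
    coefficients = stats::setNames(beta, colnames(X)),
    se = stats::setNames(sqrt(diag(vc)), colnames(X)),
    vcov = vc,
    loglik = parts$ll,
    iterations = iter,
    converged = converged && !separation,
    separation = separation,
    method = "conditional logistic (Newton-Raphson)",
    n = length(y),
    n_strata = length(n_case),
    n_informative = sum(informative)
  )
}

#' Wald odds ratios with confidence intervals
#'
#' `OR = exp(beta)` with `CI = exp(beta +/- z * SE)`. A zero standard
#' error collapses the interval to the point estimate and is flagged.
#'
#' @param fit An `organo_fit` object.
#' @param level Confidence level (default 0.95).
#' @return Tibble `term`, `or`, `conf.low`, `conf.high`, `p.value`,
#'   `degenerate`.
#' @export
wald_or_ci <- function(fit, level = 0.95) {
  if (!isTRUE(fit$converged)) {
    warning("fit did not converge", if (fit$separation) " (separation)",
            "; estimates are not reportable", call. = FALSE)
  }
  z <- qnorm(1 - (1 - level) / 2)
  b <- fit$coefficients
  se <- fit$se
  tibble::tibble(
    term = names(b),
    or = unname(exp(b)),
    conf.low = unname(exp(b - z * se)),
    conf.high = unname(exp(b + z * se)),
    p.value = unname(2 * pnorm(-abs(b / se))),
    degenerate = unname(se == 0)
  )
}

#' @export
print.organo_fit <- function(x, ...) {
  cat(x$method, "fit:", x$n, "observations")
  if (!is.na(x$n_strata)) {
    cat(",", x$n_strata, "strata (", x$n_informative, "informative )")
  }
  cat("\nconverged:", x$converged,
      if (x$separation) "[separation detected]", "\n")
  print(wald_or_ci(x))
  invisible(x)
}

#' Tidy a fitted logistic model
#'
#' @param x An `organo_fit` object.
#' @param conf.level Confidence level for Wald intervals.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (log odds ratio), `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high` (log scale).
#' @export
tidy.organo_fit <- function(x, conf.level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf.level) / 2)
  b <- x$coefficients
  tibble::tibble(
    term = names(b),
    estimate = unname(b),
    std.error = unname(x$se),
    statistic = unname(b / x$se),
    p.value = unname(2 * pnorm(-abs(b / x$se))),
    conf.low = unname(b - z * x$se),
    conf.high = unname(b + z * x$se)
  )
}

#' @rdname tidy.organo_fit
#' @export
glance.organo_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, nobs = x$n, n_strata = x$n_strata,
    n_informative = x$n_informative, iterations = x$iterations,
    converged = x$converged, separation = x$separation
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

new_organo_htest <- function(statistic, p_value, method, ...) {
  structure(c(list(statistic = statistic, p_value = p_value,
                   method = method), list(...)),
            class = "organo_htest")
}

#' @export
print.organo_htest <- function(x, ...) {
  cat(x$method, "\nstatistic =", x$statistic, ", p =",
      format.pval(x$p_value), "\n")
  invisible(x)
}

#' @export
tidy.organo_htest <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    p.value = x$p_value,
    method = x$method,
    direction = if (is.null(x$direction)) NA_character_ else x$direction,
    note = if (is.null(x$note)) NA_character_ else x$note
  )
}

#' Pearson chi-square test on a contingency table
#'
#' `X^2 = sum (O - E)^2 / E` with expected counts from the product of
#' margins, no continuity correction; degrees of freedom
#' `(r - 1)(c - 1)`; p-value from the upper chi-square tail. Empty rows
#' and columns are dropped with a warning.
#'
#' @param x Matrix or data frame of counts (a data frame's first column
#'   is treated as row labels when non-numeric).
#' @return An `organo_htest` with fields `statistic`, `df`, `p_value`,
#'   `expected`.
#' @export
pearson_chi_square <- function(x) {
  if (is.data.frame(x)) {
    if (!is.numeric(x[[1]])) {
      rn <- as.character(x[[1]])
      x <- as.matrix(x[, -1, drop = FALSE])
      rownames(x) <- rn
    } else {
      x <- as.matrix(x)
    }
  }
  storage.mode(x) <- "double"
  empty_r <- rowSums(x) == 0
  empty_c <- colSums(x) == 0
  if (any(empty_r) || any(empty_c)) {
    warning("dropping ", sum(empty_r), " empty row(s) and ",
            sum(empty_c), " empty column(s)", call. = FALSE)
    x <- x[!empty_r, !empty_c, drop = FALSE]
  }
  stopifnot(nrow(x) >= 2, ncol(x) >= 2)
  E <- outer(rowSums(x), colSums(x)) / sum(x)
  stat <- sum((x - E)^2 / E)
  df <- (nrow(x) - 1) * (ncol(x) - 1)
  new_organo_htest(
    statistic = stat, p_value = pchisq(stat, df, lower.tail = FALSE),
    method = "Pearson chi-square", df = df, expected = E
  )
}

#' Mann-Whitney U test (unpaired, two-sided)
#'
#' The U statistic is computed from midranks of the pooled sample (U for
#' the `x` side). The p-value is exact by complete enumeration of
#' `choose(n, n_x)` group assignments when `n_x + n_y <= 12` and there
#' are no ties, and otherwise uses the normal approximation with
#' tie-corrected variance and a 0.5 continuity correction.
#'
#' @param x,y Numeric samples.
#' @return An `organo_htest` with `statistic` (U of `x`), `p_value`,
#'   `direction` (`"x_greater"`/`"x_less"`/`"none"`) and `note`.
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1)

  if (all(ties == length(pooled))) {
    return(new_organo_htest(statistic = u, p_value = 1,
                            method = "Mann-Whitney U", direction = "none",
                            note = "degenerate: all values tied"))
  }
  if (n1 + n2 <= 12 && !has_ties) {
    combos <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(us <= u), mean(us >= u)))
    note <- "exact enumeration"
  } else {
    N <- n1 + n2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      return(new_organo_htest(statistic = u, p_value = 1,
                              method = "Mann-Whitney U",
                              direction = "none",
                              note = "degenerate: zero variance"))
    }
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-max(z, 0)))
    note <- paste0("normal approximation",
                   if (has_ties) ", tie-corrected",
                   ", continuity-corrected")
  }
  new_organo_htest(
    statistic = u, p_value = p, method = "Mann-Whitney U",
    direction = if (u > mu) "x_greater" else if (u < mu) "x_less"
                else "none",
    note = note
  )
}

signed_rank_counts <- function(n) {
  # number of rank subsets with each possible sum 0..n(n+1)/2
  counts <- c(1, rep(0, n * (n + 1) / 2))
  for (r in seq_len(n)) {
    shifted <- c(rep(0, r), counts[seq_len(length(counts) - r)])
    counts <- counts + shifted
  }
  counts
}

#' Wilcoxon signed-rank test for matched pairs (two-sided)
#'
#' Zero differences are dropped; W is the sum of ranks of the positive
#' differences among ranks of `|d|`. The p-value is exact (rank-sum
#' distribution by dynamic programming over sign assignments) for up to
#' 25 nonzero differences without ties in `|d|`, and otherwise uses the
#' normal approximation with tie correction and a 0.5 continuity
#' correction.
#'
#' @param differences Numeric vector of within-pair differences.
#' @return An `organo_htest` with `statistic` (W), `p_value`, `direction`
#'   and `note`.
#' @export
wilcoxon_signed_rank <- function(differences) {
  d <- differences[differences != 0]
  n_zero <- length(differences) - length(d)
  if (length(d) == 0) {
    return(new_organo_htest(statistic = NA_real_, p_value = 1,
                            method = "Wilcoxon signed-rank",
                            direction = "none",
                            note = "degenerate: all differences zero"))
  }
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  has_ties <- anyDuplicated(abs(d)) > 0
  if (n <= 25 && !has_ties) {
    counts <- signed_rank_counts(n)
    tot <- 2^n
    cdf_le <- sum(counts[seq_len(w + 1)]) / tot
    cdf_ge <- sum(counts[(w + 1):length(counts)]) / tot
    p <- min(1, 2 * min(cdf_le, cdf_ge))
    note <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (sigma2 <= 0) {
      return(new_organo_htest(statistic = w, p_value = 1,
                              method = "Wilcoxon signed-rank",
                              direction = "none",
                              note = "degenerate: zero variance"))
    }
    z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-max(z, 0)))
    note <- paste0("normal approximation",
                   if (has_ties) ", tie-corrected",
                   ", continuity-corrected")
  }
  if (n_zero > 0) note <- paste0(note, "; ", n_zero, " zero(s) dropped")
  new_organo_htest(
    statistic = w, p_value = p, method = "Wilcoxon signed-rank",
    direction = if (w > mu) "positive" else if (w < mu) "negative"
                else "none",
    note = note
  )
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `p_(i) -> min_{j >= i} (m p_(j) / j)`, capped at 1, returned in input
#' order.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  m <- length(pvals)
  if (m <= 1) return(pvals)
  o <- order(pvals, decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m:1) * pvals[o]))
  adj[order(o)]
}

#' ROC curve and AUC by the rank formula
#'
#' AUC equals the Mann-Whitney U of the positive class divided by
#' `n_pos * n_neg`, so ties count one half; the identity
#' `AUC * n_pos * n_neg = U` holds exactly on every input. The full ROC
#' point list is returned for plotting.
#'
#' @param scores Numeric classifier scores (higher = more case-like).
#' @param labels Binary labels (logical or 0/1); both classes required.
#' @return Object of class `organo_roc`: list with `auc`, `u` (the rank
#'   U statistic of the positive class, so `auc == u / (n_pos * n_neg)`
#'   by construction), `points` (tibble `threshold`, `fpr`, `tpr`),
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) {
    stop("both label classes must be present", call. = FALSE)
  }
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)
  u <- sum(r[labels == 1]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  thr <- unique(scores[ord])
  grp <- factor(match(scores[ord], thr), levels = seq_along(thr))
  tp <- cumsum(tapply(labels[ord] == 1, grp, sum))
  fp <- cumsum(tapply(labels[ord] == 0, grp, sum))
  points <- tibble::tibble(
    threshold = c(Inf, thr),
    fpr = c(0, unname(fp) / n0),
    tpr = c(0, unname(tp) / n1)
  )
  structure(list(auc = auc, u = u, points = points, n_pos = n1,
                 n_neg = n0),
            class = "organo_roc")
}

#' @export
print.organo_roc <- function(x, ...) {
  cat("ROC:", x$n_pos, "positives,", x$n_neg, "negatives; AUC =",
      round(x$auc, 4), "\n")
  invisible(x)
}

#' Quartile odds-ratio analysis of a module score
#'
#' Bins every subject by the quartile thresholds of the *control* scores
#' (25th/50th/75th linear-interpolation percentiles), codes quartiles 2-4
#' as indicators against the first quartile, and fits a conditional
#' logistic model on the matched sets. Quartile contrasts without
#' discordant information surface through the fit's convergence and
#' separation flags.
#'
#' @param data Data frame with columns `stratum`, `is_case` (0/1) and
#'   `score`.
#' @return List of class `organo_quartile`: `thresholds` (named numeric),
#'   `fit` (`organo_fit`), `table` (tidy OR tibble with a reference row).
#' @export
quartile_or_analysis <- function(data) {
  stopifnot(all(c("stratum", "is_case", "score") %in% names(data)))
  controls <- data$score[data$is_case == 0]
  if (length(controls) < 8) {
    stop("need at least 8 controls to define quartile thresholds",
         call. = FALSE)
  }
  thr <- quantile(controls, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  q <- cut(data$score, breaks = c(-Inf, thr, Inf),
           labels = c("Q1", "Q2", "Q3", "Q4"), right = TRUE)
  dd <- dplyr::mutate(
    tibble::as_tibble(data),
    Q2 = as.integer(q == "Q2"),
    Q3 = as.integer(q == "Q3"),
    Q4 = as.integer(q == "Q4")
  )
  fit <- fit_conditional_logistic(dd, is_case ~ Q2 + Q3 + Q4,
                                  strata = "stratum")
  tab <- dplyr::bind_rows(
    tibble::tibble(term = "Q1", or = 1, conf.low = NA_real_,
                   conf.high = NA_real_, p.value = NA_real_,
                   degenerate = FALSE),
    wald_or_ci(fit)
  )
  structure(list(thresholds = stats::setNames(thr, c("q25", "q50", "q75")),
                 fit = fit, table = tab),
            class = "organo_quartile")
}

#' @export
print.organo_quartile <- function(x, ...) {
  cat("Quartile OR analysis (thresholds:",
      paste(round(x$thresholds, 3), collapse = ", "), ")\n")
  print(x$table)
  invisible(x)
}
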