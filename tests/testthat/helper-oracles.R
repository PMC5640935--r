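# Independent oracles used across tests. These deliberately re-derive
# results by the most literal route available (exhaustive scans, direct
# formulas, permutation) and stay independent of the package internals.

# Literal first-pattern classifier: scan all bone/visceral event pairs.
oracle_classify <- function(times, categories, window) {
  keep <- categories %in% c("bone", "visceral")
  times <- times[keep]
  categories <- categories[keep]
  tb <- suppressWarnings(min(times[categories == "bone"]))
  tv <- suppressWarnings(min(times[categories == "visceral"]))
  if (!is.finite(tb) && !is.finite(tv)) return("none")
  if (is.finite(tb) && is.finite(tv)) {
    if (abs(tb - tv) <= window) return("bone_and_visceral")
    return(if (tb < tv) "bone_only" else "visceral_only")
  }
  if (is.finite(tb)) "bone_only" else "visceral_only"
}

random_timeline <- function() {
  n <- sample(0:5, 1)
  tibble::tibble(
    patient_id = "p",
    site = sample(names(organ_site_categories), n, replace = TRUE),
    days_since_diagnosis = round(stats::runif(n, 0, 2000), 1)
  )
}

# Direct conditional log-likelihood for a single covariate.
oracle_cond_loglik <- function(beta, x, y, stratum) {
  ll <- 0
  for (s in split(seq_along(y), stratum)) {
    num <- exp(beta * x[s][y[s] == 1])
    ll <- ll + log(num / sum(exp(beta * x[s])))
  }
  ll
}

# Intercept-free logistic fit on within-pair covariate differences
# (independent Newton iteration written out longhand).
oracle_pairdiff_beta <- function(d) {
  beta <- 0
  for (i in 1:100) {
    p <- 1 / (1 + exp(-beta * d))
    score <- sum(d * (1 - p))
    info <- sum(d^2 * p * (1 - p))
    step <- score / info
    beta <- beta + step
    if (abs(step) < 1e-14) break
  }
  beta
}

# Tiny cohort shared by several risk-set tests.
toy_cohort <- function() {
  tibble::tibble(
    patient_id = c("a", "b", "c", "d", "e"),
    diagnosis_date = c(0, 0, 100, 200, 900),
    exit_date = c(1000, 400, 800, 950, 1500),
    event_date = c(600, NA, NA, 700, NA),
    pattern = factor(
      c("bone_and_visceral", "none", "none", "visceral_only", "none"),
      levels = levels(classify_patterns(
        data.frame(patient_id = 1, site = "bone",
                   days_since_diagnosis = 1))$pattern)
    )
  )
}
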