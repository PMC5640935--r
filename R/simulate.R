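#' Simulation configuration for a synthetic metastasis cohort
#'
#' Defines the generative model used throughout the package's validation:
#' patients accrue uniformly over a calendar window; each carries an ER
#' status and standard-normal latent gene-module scores; first bone and
#' first visceral metastases arise from independent exponential
#' cause-specific hazards whose log is linear in covariates and scores;
#' after the earlier event the other site's hazard is multiplied by a
#' coupling factor (values > 1 induce metasynchronous bone-and-visceral
#' spread); follow-up ends at the earlier of a random dropout and the
#' administrative end of study. Member genes of each module co-vary with
#' that module's latent score in a genes-by-samples log-expression matrix.
#'
#' Default rates are calibrated so that roughly a third of patients develop
#' distant metastasis during follow-up, visceral-only first events outnumber
#' bone-only ones, and roughly a quarter of metastasizing patients have
#' metasynchronous bone-and-visceral spread — the regime of the archival
#' breast-cancer cohorts this design emulates. ER prevalence defaults to
#' 0.68.
#'
#' @param n_patients Number of patients.
#' @param accrual_start,accrual_end Calendar day window of diagnosis dates
#'   (default a 30-year accrual window).
#' @param admin_end Administrative end of follow-up (calendar day).
#' @param n_genes Total genes in the expression matrix (0 skips expression).
#' @param modules Tibble with columns `module`, `gene`, `weight` (+1/-1)
#'   defining module memberships and expression directions. Member genes
#'   must be among `gene_ids()`-style ids `g0001..` within `n_genes`.
#' @param tau Named numeric: per-module expression effect size (log-units
#'   of expression per unit latent score).
#' @param noise_sd Residual SD of log expression.
#' @param er_positive_prob Probability a patient is ER-positive.
#' @param lambda0_bone,lambda0_visc Baseline cause-specific hazards
#'   (events/day) of first bone and first visceral metastasis.
#' @param beta_bone,beta_visc Named numeric log hazard ratios per unit of
#'   the named covariate column (e.g. `c(score_M1 = log(2), er = 0.1)`).
#' @param coupling Multiplier applied to the other site's hazard after the
#'   first metastasis (rho; > 1 induces metasynchronicity).
#' @param dropout_rate Censoring hazard (per day); 0 disables dropout.
#' @param score_correlation Optional correlation matrix for the latent
#'   module scores (default independent).
#' @param window_days Metasynchronicity window passed to the classifier.
#' @param seed Optional integer seed applied at the start of
#'   [generate_cohort()].
#'
#' @return A list of class `organo_sim_config`.
#' @export
sim_config <- function(n_patients = 2000,
                       accrual_start = 0,
                       accrual_end = 10957,
                       admin_end = 12784,
                       n_genes = 1000,
                       modules = default_modules(),
                       tau = c(M1 = 1),
                       noise_sd = 1,
                       er_positive_prob = 0.68,
                       lambda0_bone = 2.6e-05,
                       lambda0_visc = 4.6e-05,
                       beta_bone = c(score_M1 = 0),
                       beta_visc = c(score_M1 = 0),
                       coupling = 50,
                       dropout_rate = 5e-05,
                       score_correlation = NULL,
                       window_days = 183,
                       seed = NULL) {
  stopifnot(
    n_patients >= 1,
    accrual_end >= accrual_start, admin_end >= accrual_end,
    n_genes >= 0, noise_sd > 0,
    er_positive_prob >= 0, er_positive_prob <= 1,
    lambda0_bone >= 0, lambda0_visc >= 0,
    coupling >= 0, dropout_rate >= 0, window_days > 0
  )
  modules <- tibble::as_tibble(modules)
  if (nrow(modules) > 0) {
    stopifnot(all(c("module", "gene", "weight") %in% names(modules)),
              all(modules$weight %in% c(-1, 1)))
    dup <- modules |>
      dplyr::distinct(.data$module, .data$gene, .data$weight) |>
      dplyr::count(.data$module, .data$gene) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup) > 0) {
      stop("conflicting weights for gene(s) ",
           paste(unique(dup$gene), collapse = ", "),
           " within a module", call. = FALSE)
    }
    if (!all(unique(modules$module) %in% names(tau))) {
      stop("every module needs an effect size in `tau`", call. = FALSE)
    }
    if (n_genes > 0 && !all(modules$gene %in% gene_ids(n_genes))) {
      stop("module member genes must lie within the simulated gene pool",
           call. = FALSE)
    }
  }
  structure(
    list(n_patients = n_patients, accrual_start = accrual_start,
         accrual_end = accrual_end, admin_end = admin_end,
         n_genes = n_genes, modules = modules, tau = tau,
         noise_sd = noise_sd, er_positive_prob = er_positive_prob,
         lambda0_bone = lambda0_bone, lambda0_visc = lambda0_visc,
         beta_bone = beta_bone, beta_visc = beta_visc,
         coupling = coupling, dropout_rate = dropout_rate,
         score_correlation = score_correlation,
         window_days = window_days, seed = seed),
    class = "organo_sim_config"
  )
}

#' Simulated gene identifiers
#'
#' @param n Number of genes.
#' @return Character vector `g0001`, `g0002`, ...
#' @export
gene_ids <- function(n) {
  if (n == 0) return(character(0))
  sprintf("g%04d", seq_len(n))
}

#' Default simulated module: 20 genes, 15 up and 5 down
#'
#' @return Tibble with columns `module`, `gene`, `weight`.
#' @export
default_modules <- function() {
  tibble::tibble(
    module = "M1",
    gene = gene_ids(20),
    weight = rep(c(1, -1), c(15, 5))
  )
}

#' Generate patient covariates and latent module scores
#'
#' ER status is Bernoulli with the configured prevalence; latent module
#' scores are standard normal, independent across modules unless a
#' correlation matrix is supplied.
#'
#' @param cfg An [sim_config()] object.
#' @return Tibble with `patient_id`, `er` (0/1) and one `score_<module>`
#'   column per module.
#' @export
generate_covariates <- function(cfg) {
  n <- cfg$n_patients
  mods <- unique(cfg$modules$module)
  if (length(mods) == 0) mods <- names(cfg$tau)
  k <- length(mods)
  z <- matrix(stats::rnorm(n * k), n, k)
  if (!is.null(cfg$score_correlation)) {
    R <- cfg$score_correlation
    stopifnot(nrow(R) == k, ncol(R) == k)
    z <- z %*% chol(R)
  }
  colnames(z) <- paste0("score_", mods)
  out <- tibble::tibble(
    patient_id = sprintf("pt%05d", seq_len(n)),
    er = stats::rbinom(n, 1, cfg$er_positive_prob)
  )
  dplyr::bind_cols(out, tibble::as_tibble(z))
}

#' Generate a log-expression matrix tied to latent module scores
#'
#' Member gene g of module j gets `weight_g * tau_j * s_j` plus Gaussian
#' noise; genes in no module are pure noise. Genes belonging to several
#' modules accumulate each module's contribution.
#'
#' @inheritParams generate_covariates
#' @param covariates Output of [generate_covariates()].
#' @return Numeric matrix, genes x samples, log-scale units, with gene ids
#'   as rownames and patient ids as colnames.
#' @export
generate_expression <- function(cfg, covariates) {
  genes <- gene_ids(cfg$n_genes)
  n <- nrow(covariates)
  x <- matrix(stats::rnorm(length(genes) * n, sd = cfg$noise_sd),
              length(genes), n,
              dimnames = list(genes, covariates$patient_id))
  if (nrow(cfg$modules) > 0) {
    for (m in unique(cfg$modules$module)) {
      mem <- cfg$modules[cfg$modules$module == m, ]
      s <- covariates[[paste0("score_", m)]]
      x[mem$gene, ] <- x[mem$gene, , drop = FALSE] +
        outer(mem$weight * cfg$tau[[m]], s)
    }
  }
  x
}

#' Expand a gene-level matrix into multiple probes per gene
#'
#' Duplicates each gene into `k` probes with independent extra noise, so
#' probe-resolution logic (keep the most variable probe per gene) can be
#' exercised on synthetic data.
#'
#' @param expr Genes x samples matrix.
#' @param k Probes per gene.
#' @param extra_noise_sd Extra per-probe noise SDs, length `k` (probes
#'   differ in noisiness).
#' @return List with `expr` (probes x samples matrix, probe ids
#'   `<gene>_p1`, ...) and `annotation` (tibble `probe_id`, `gene_id`).
#' @export
expand_to_probes <- function(expr, k = 2, extra_noise_sd = seq_len(k) - 1) {
  stopifnot(k >= 1, length(extra_noise_sd) == k)
  probes <- as.vector(t(outer(rownames(expr), paste0("_p", seq_len(k)),
                              paste0)))
  out <- matrix(NA_real_, length(probes), ncol(expr),
                dimnames = list(probes, colnames(expr)))
  for (j in seq_len(k)) {
    idx <- seq(j, length(probes), by = k)
    out[idx, ] <- expr +
      matrix(stats::rnorm(length(expr), sd = extra_noise_sd[j]),
             nrow(expr), ncol(expr))
  }
  list(
    expr = out,
    annotation = tibble::tibble(
      probe_id = probes,
      gene_id = rep(rownames(expr), each = k)
    )
  )
}

#' Simulate organ-site event times and follow-up
#'
#' First-bone and first-visceral times are drawn from exponential
#' cause-specific hazards `lambda0_site * exp(sum beta_site * z)`; after
#' the earlier of the two the other site's time is redrawn from its hazard
#' multiplied by the coupling factor (valid by memorylessness). Follow-up
#' ends at the earlier of an exponential dropout and the administrative
#' end; events after the end of follow-up are discarded.
#'
#' @inheritParams generate_expression
#' @return List with `events` (tibble `patient_id`, `site`,
#'   `days_since_diagnosis`, using concrete organ-site codes) and
#'   `followup` (tibble `patient_id`, `diagnosis_date`, `exit_date`), plus
#'   `truth` (tibble of uncensored event times per patient).
#' @export
simulate_event_times <- function(cfg, covariates) {
  n <- nrow(covariates)
  eta <- function(beta) {
    e <- rep(0, n)
    for (nm in names(beta)) {
      if (beta[[nm]] == 0) next
      if (!nm %in% names(covariates)) {
        stop("hazard covariate not found: ", nm, call. = FALSE)
      }
      e <- e + beta[[nm]] * covariates[[nm]]
    }
    e
  }
  rate_b <- cfg$lambda0_bone * exp(eta(cfg$beta_bone))
  rate_v <- cfg$lambda0_visc * exp(eta(cfg$beta_visc))
  rexp_rate <- function(rate) {
    t <- rep(Inf, n)
    pos <- rate > 0
    t[pos] <- stats::rexp(sum(pos), rate[pos])
    t
  }
  tb <- rexp_rate(rate_b)
  tv <- rexp_rate(rate_v)
  bone_first <- tb <= tv
  t1 <- pmin(tb, tv)
  # redraw the later site's time with the coupled (post-first) hazard
  other_rate <- ifelse(bone_first, rate_v, rate_b) * cfg$coupling
  t2 <- t1 + rexp_rate(other_rate)
  tb_final <- ifelse(bone_first, tb, t2)
  tv_final <- ifelse(bone_first, t2, tv)

  diagnosis <- floor(stats::runif(n, cfg$accrual_start,
                                  cfg$accrual_end + 1))
  admin_cens <- cfg$admin_end - diagnosis
  drop_cens <- if (cfg$dropout_rate > 0) {
    stats::rexp(n, cfg$dropout_rate)
  } else {
    rep(Inf, n)
  }
  cens <- pmin(admin_cens, drop_cens)

  bone_sites <- names(organ_site_categories)[organ_site_categories == "bone"]
  visc_sites <- names(organ_site_categories)[
    organ_site_categories == "visceral"]
  mk <- function(t, sites) {
    keep <- which(t <= cens)
    tibble::tibble(
      patient_id = covariates$patient_id[keep],
      site = sample(sites, length(keep), replace = TRUE),
      days_since_diagnosis = t[keep]
    )
  }
  events <- dplyr::bind_rows(mk(tb_final, bone_sites),
                             mk(tv_final, visc_sites)) |>
    dplyr::arrange(.data$patient_id, .data$days_since_diagnosis)

  list(
    events = events,
    followup = tibble::tibble(
      patient_id = covariates$patient_id,
      diagnosis_date = diagnosis,
      exit_date = diagnosis + cens
    ),
    truth = tibble::tibble(
      patient_id = covariates$patient_id,
      t_bone_true = tb_final,
      t_visc_true = tv_final,
      t_first_true = t1,
      censor_time = cens
    )
  )
}

#' Generate a complete synthetic cohort with ground truth
#'
#' Composes [generate_covariates()], [generate_expression()] and
#' [simulate_event_times()], then classifies every patient's observed
#' timeline with [classify_patterns()] — the classifier under test, not
#' the generator, assigns patterns. The returned `truth` element (latent
#' scores, uncensored times, true log hazard ratios) exists only for
#' validation and is never consumed by analysis stages.
#'
#' @inheritParams generate_covariates
#' @return List with `cohort` (tibble: `patient_id`, `diagnosis_date`,
#'   `exit_date`, `er`, `pattern`, `t_first`, `t_other_site`,
#'   `event_date`), `events`, `expression` (matrix or `NULL` when
#'   `n_genes = 0`), `truth` and `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "organo_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  covariates <- generate_covariates(cfg)
  expression <- if (cfg$n_genes > 0) {
    generate_expression(cfg, covariates)
  }
  sim <- simulate_event_times(cfg, covariates)
  labels <- classify_patterns(sim$events, window_days = cfg$window_days,
                              patients = covariates$patient_id)
  cohort <- sim$followup |>
    dplyr::left_join(labels, by = "patient_id") |>
    dplyr::mutate(er = covariates$er,
                  event_date = .data$diagnosis_date + .data$t_first)
  truth <- dplyr::left_join(sim$truth, covariates, by = "patient_id")
  list(cohort = cohort, events = sim$events, expression = expression,
       truth = truth, config = cfg)
}
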