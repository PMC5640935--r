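#' Study configuration for the end-to-end case-control analysis
#'
#' Bundles either a simulation config or paths/objects holding a cohort
#' and expression data, the case-control design (series, cases per
#' series, controls per case), the gene-module panel to score, and the
#' seed governing every random draw.
#'
#' @param sim An [sim_config()] object (simulated input), or `NULL` when
#'   `cohort`/`events`/`expression` are supplied directly.
#' @param cohort,events,expression Pre-built inputs (see
#'   [generate_cohort()] for shapes); ignored when `sim` is given.
#' @param series Which case-control series to build (subset of
#'   `c("V", "BV", "B")`).
#' @param n_cases Cases sampled per series (default all eligible).
#' @param m Controls drawn per case before 1:1 reduction (default 3).
#' @param modules Module panel tibble (`module`, `gene`, `weight`);
#'   defaults to the simulation's modules.
#' @param discover Run the module-derivation stage on the BV series?
#' @param discovery_reference `"never_metastasizing"` (controls with no
#'   distant event during follow-up) or `"all_controls"`.
#' @param er_stratum ER stratum for discovery (default `"positive"`).
#' @param fdr_threshold FDR threshold for module derivation.
#' @param seed Mandatory integer seed.
#' @return List of class `organo_study_config`.
#' @export
study_config <- function(sim = NULL, cohort = NULL, events = NULL,
                         expression = NULL,
                         series = c("V", "BV", "B"),
                         n_cases = Inf, m = 3, modules = NULL,
                         discover = FALSE,
                         discovery_reference = c("never_metastasizing",
                                                 "all_controls"),
                         er_stratum = "positive",
                         fdr_threshold = 0.2,
                         seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(sim) == is.null(cohort)) {
    stop("supply exactly one of `sim` or `cohort`(+events/expression)",
         call. = FALSE)
  }
  series <- match.arg(series, several.ok = TRUE)
  structure(
    list(sim = sim, cohort = cohort, events = events,
         expression = expression, series = series, n_cases = n_cases,
         m = m, modules = modules,
         discover = discover,
         discovery_reference = match.arg(discovery_reference),
         er_stratum = er_stratum, fdr_threshold = fdr_threshold,
         seed = as.integer(seed)),
    class = "organo_study_config"
  )
}

fit_series_module <- function(pairs, scaled_scores) {
  sc <- stats::setNames(scaled_scores$score, scaled_scores$sample_id)
  dd <- tibble::tibble(
    stratum = rep(seq_len(nrow(pairs)), 2),
    is_case = rep(c(1, 0), each = nrow(pairs)),
    score = c(sc[pairs$case_id], sc[pairs$control_id])
  )
  dd <- dd[stats::complete.cases(dd), , drop = FALSE]
  ok <- names(which(table(dd$stratum) == 2))
  dd <- dd[dd$stratum %in% ok, , drop = FALSE]
  cond <- fit_conditional_logistic(dd, is_case ~ score, strata = "stratum")
  unc <- fit_logistic(dd, is_case ~ score)
  list(conditional = cond, unconditional = unc, n_pairs = length(ok))
}

#' Run the full organotropism case-control study
#'
#' Executes the whole pipeline under one seed: simulate (or ingest) the
#' cohort, classify first-metastasis patterns, build risk-set-sampled
#' case-control series reduced to 1:1 pairs, score the module panel,
#' scale scores within each series so 95% of values lie in `[-1, 1]`,
#' fit conditional and unconditional logistic models per module per
#' series, adjust p-values across the module panel within each
#' series-by-model block, and (optionally) run ER-stratified module
#' discovery on the BV series. All randomness flows through `set.seed` on
#' the configured seed, so two runs of one config are identical.
#'
#' @param cfg An [study_config()] object.
#' @return List of class `organo_study_report`: `or_table` (per series,
#'   module and model family: log-OR, SE, OR with CI, raw and
#'   panel-adjusted p), `pairs`, `sets`, `pattern_counts`, `discovery`
#'   (or `NULL`), `provenance` (seed, config hash, package version).
#' @export
run_full_study <- function(cfg) {
  stopifnot(inherits(cfg, "organo_study_config"))
  set.seed(cfg$seed)
  if (!is.null(cfg$sim)) {
    sim <- cfg$sim
    sim$seed <- NULL
    data <- generate_cohort(sim)
    cohort <- data$cohort
    expression <- data$expression
    modules <- cfg$modules
    if (is.null(modules)) modules <- sim$modules
  } else {
    cohort <- cfg$cohort
    expression <- cfg$expression
    modules <- cfg$modules
    if (is.null(modules)) stop("module panel required", call. = FALSE)
  }
  if (!"pattern" %in% names(cohort)) {
    stop("cohort must be classified (pattern column)", call. = FALSE)
  }

  sets <- purrr::map(cfg$series, function(s) {
    build_case_control_series(cohort, series = s, n_cases = cfg$n_cases,
                              m = cfg$m)
  }) |> dplyr::bind_rows()
  pairs <- reduce_to_pairs(sets)

  raw_scores <- purrr::map(split(modules, modules$module),
                           \(m) weighted_sum_score(expression, m))

  or_table <- purrr::map_dfr(cfg$series, function(s) {
    pp <- pairs[pairs$series == s, , drop = FALSE]
    members <- unique(c(pp$case_id, pp$control_id))
    purrr::map_dfr(names(raw_scores), function(mn) {
      sc <- raw_scores[[mn]]
      ref <- sc$score[sc$sample_id %in% members]
      scaled <- sc
      scaled$score <- as.numeric(scale_scores_95(sc$score, reference = ref))
      fits <- fit_series_module(pp, scaled)
      purrr::map_dfr(
        c("conditional", "unconditional"),
        function(fam) {
          fit <- fits[[fam]]
          td <- tidy.organo_fit(fit)
          td <- td[td$term == "score", , drop = FALSE]
          tibble::tibble(
            series = s, module = mn, model = fam,
            n_pairs = fits$n_pairs,
            estimate = td$estimate, std.error = td$std.error,
            or = exp(td$estimate),
            conf.low = exp(td$conf.low), conf.high = exp(td$conf.high),
            p.value = td$p.value,
            converged = fit$converged
          )
        }
      )
    })
  })
  or_table <- or_table |>
    dplyr::group_by(.data$series, .data$model) |>
    dplyr::mutate(adj.p.value = bh_adjust(.data$p.value)) |>
    dplyr::ungroup()

  discovery <- NULL
  if (cfg$discover) {
    discovery <- run_discovery(cohort, expression,
                               pairs[pairs$series == "BV", , drop = FALSE],
                               reference = cfg$discovery_reference,
                               er_stratum = cfg$er_stratum,
                               fdr_threshold = cfg$fdr_threshold)
  }

  structure(
    list(
      or_table = or_table,
      pairs = pairs,
      sets = sets,
      pattern_counts = dplyr::count(cohort, .data$pattern),
      discovery = discovery,
      provenance = list(
        seed = cfg$seed,
        config_hash = rlang::hash(cfg),
        package_version = as.character(utils::packageVersion("organotrope"))
      )
    ),
    class = "organo_study_report"
  )
}

run_discovery <- function(cohort, expression, bv_pairs, reference,
                          er_stratum, fdr_threshold) {
  er <- cohort[, c("patient_id", "er")]
  pp <- er_concordant_pairs(bv_pairs, er, stratum = er_stratum)
  cases <- unique(pp$case_id)
  ctrls <- unique(setdiff(pp$control_id, cases))
  if (reference == "never_metastasizing") {
    never <- cohort$patient_id[cohort$pattern == "none"]
    ctrls <- intersect(ctrls, never)
  }
  if (length(cases) < 3 || length(ctrls) < 3) {
    stop("too few discovery samples after ER filtering", call. = FALSE)
  }
  diff_tab <- per_gene_differential(expression, cases, ctrls)
  module <- derive_module(diff_tab, fdr_threshold = fdr_threshold)
  evaluation <- if (nrow(module) > 0) {
    evaluate_module(expression, module, cases, ctrls,
                    resubstitution = TRUE)
  }
  list(differential = diff_tab, module = module, evaluation = evaluation,
       n_cases = length(cases), n_reference = length(ctrls))
}

#' @export
print.organo_study_report <- function(x, ...) {
  cat("Organotropism case-control study report\n")
  cat("  seed:", x$provenance$seed, " config:",
      x$provenance$config_hash, "\n")
  cat("  pairs per series:\n")
  print(dplyr::count(x$pairs, .data$series))
  cat("  OR table (panel-adjusted):\n")
  print(x$or_table)
  if (!is.null(x$discovery)) {
    cat("  derived module:", nrow(x$discovery$module), "genes; ",
        "resubstitution AUC",
        round(x$discovery$evaluation$auc, 3), "\n")
  }
  invisible(x)
}

#' Per-subtype odds ratios against a declared baseline
#'
#' Dummy-codes a categorical subtype against the declared baseline level
#' and fits both conditional (matched pairs) and unconditional logistic
#' models, as done when comparing IHC, PAM50-style or IntClust-style
#' subtypes between cases and their matched controls.
#'
#' @param pairs Tibble with `case_id`, `control_id` (one series).
#' @param subtypes Data frame with `patient_id` and `subtype`.
#' @param baseline Baseline subtype level (must be present).
#' @return Tibble: `model`, `term` (subtype level), `or`, `conf.low`,
#'   `conf.high`, `p.value`; baseline rows carry OR 1 by construction.
#' @export
subtype_or_table <- function(pairs, subtypes, baseline) {
  lab <- stats::setNames(as.character(subtypes$subtype),
                         subtypes$patient_id)
  levs <- unique(lab)
  if (!baseline %in% levs) {
    stop("baseline level absent: ", baseline, call. = FALSE)
  }
  dd <- tibble::tibble(
    stratum = rep(seq_len(nrow(pairs)), 2),
    is_case = rep(c(1, 0), each = nrow(pairs)),
    subtype = factor(c(lab[pairs$case_id], lab[pairs$control_id]),
                     levels = c(baseline, setdiff(levs, baseline)))
  )
  dd <- dd[!is.na(dd$subtype), , drop = FALSE]
  ok <- names(which(table(dd$stratum) == 2))
  dd <- dd[dd$stratum %in% ok, , drop = FALSE]
  cond <- fit_conditional_logistic(dd, is_case ~ subtype,
                                   strata = "stratum")
  unc <- fit_logistic(dd, is_case ~ subtype)
  base_row <- function(model) {
    tibble::tibble(model = model, term = baseline, or = 1,
                   conf.low = NA_real_, conf.high = NA_real_,
                   p.value = NA_real_, degenerate = FALSE)
  }
  fmt <- function(fit, model) {
    w <- wald_or_ci(fit)
    w <- w[w$term != "(Intercept)", , drop = FALSE]
    w$term <- sub("^subtype", "", w$term)
    dplyr::bind_rows(base_row(model),
                     dplyr::mutate(w, model = model, .before = 1))
  }
  dplyr::bind_rows(fmt(cond, "conditional"), fmt(unc, "unconditional"))
}

#' Cross-tabulate first-metastasis patterns against subtypes
#'
#' Counts, row- and column-normalized proportions, and a Pearson
#' chi-square test of association between pattern and subtype.
#'
#' @param cohort Classified cohort tibble (needs `patient_id`,
#'   `pattern`).
#' @param subtypes Data frame with `patient_id` and `subtype`.
#' @return List of class `organo_crosstab`: `counts`, `row_prop`,
#'   `col_prop`, `test` (`organo_htest`).
#' @export
pattern_subtype_crosstab <- function(cohort, subtypes) {
  dd <- dplyr::inner_join(cohort[, c("patient_id", "pattern")],
                          subtypes, by = "patient_id")
  counts <- table(pattern = dd$pattern, subtype = dd$subtype)
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  structure(
    list(
      counts = counts,
      row_prop = prop.table(counts, 1),
      col_prop = prop.table(counts, 2),
      test = pearson_chi_square(unclass(counts))
    ),
    class = "organo_crosstab"
  )
}

#' @export
print.organo_crosstab <- function(x, ...) {
  print(x$counts)
  cat("chi-square =", round(x$test$statistic, 2), ", df =", x$test$df,
      ", p =", format.pval(x$test$p_value), "\n")
  invisible(x)
}
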