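#' Restrict matched pairs to an ER-concordant stratum
#'
#' To control for interactions between ER status and metastatic pattern,
#' module derivation is run within an ER stratum: pairs whose case and
#' control differ in IHC-defined ER status are removed, and the surviving
#' concordant pairs are filtered to the requested stratum. Pairs with an
#' unknown ER status on either side are dropped with a warning.
#'
#' @param pairs Tibble with `case_id` and `control_id` columns (e.g. from
#'   [reduce_to_pairs()]).
#' @param er_status Data frame with columns `patient_id` and `er`
#'   (1 = positive, 0 = negative, `NA` = unknown).
#' @param stratum `"positive"` or `"negative"`.
#' @return The filtered pairs tibble.
#' @export
er_concordant_pairs <- function(pairs, er_status,
                                stratum = c("positive", "negative")) {
  stratum <- match.arg(stratum)
  want <- if (stratum == "positive") 1 else 0
  er <- stats::setNames(er_status$er, er_status$patient_id)
  e_case <- er[pairs$case_id]
  e_ctrl <- er[pairs$control_id]
  unknown <- is.na(e_case) | is.na(e_ctrl)
  if (any(unknown)) {
    warning(sum(unknown), " pair(s) with unknown ER status dropped",
            call. = FALSE)
  }
  keep <- !unknown & e_case == e_ctrl & e_case == want
  out <- pairs[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("no ER-concordant ", stratum, " pairs remain", call. = FALSE)
  }
  out
}

#' Per-gene rank-test screening between two sample groups
#'
#' For every gene, an unpaired two-sided Mann-Whitney U test between the
#' case and reference groups, with Benjamini-Hochberg adjustment across
#' all tested genes. Direction is the sign of the case-minus-reference
#' difference in medians (means break median ties). Genes constant across
#' all tested samples are skipped and listed in the `skipped` attribute.
#'
#' For more than a dozen samples per group the U statistic and the
#' tie-corrected, continuity-corrected normal p-value are computed in a
#' vectorized pass identical in value to [mann_whitney_u()]; small groups
#' fall back to the exact per-gene test.
#'
#' @param expr Expression matrix or data frame.
#' @param group_case,group_ref Sample id vectors (>= 3 each).
#' @return Tibble `gene`, `u`, `p`, `adj_p`, `direction` (`up`/`down`).
#' @export
per_gene_differential <- function(expr, group_case, group_ref) {
  expr <- as_expr_matrix(expr)
  stopifnot(length(group_case) >= 3, length(group_ref) >= 3)
  miss <- setdiff(c(group_case, group_ref), colnames(expr))
  if (length(miss) > 0) {
    stop("sample id(s) not in expression data: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  x <- expr[, c(group_case, group_ref), drop = FALSE]
  n1 <- length(group_case)
  n2 <- length(group_ref)
  N <- n1 + n2
  constant <- apply(x, 1, function(v) length(unique(v)) == 1)
  if (any(constant)) {
    message(sum(constant), " constant gene(s) skipped")
  }
  xs <- x[!constant, , drop = FALSE]

  if (N > 12) {
    r <- t(apply(xs, 1, rank))
    u <- rowSums(r[, seq_len(n1), drop = FALSE]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    tie_term <- numeric(nrow(xs))
    tied_rows <- which(apply(xs, 1, anyDuplicated) > 0)
    for (i in tied_rows) {
      tt <- table(r[i, ])
      tie_term[i] <- sum(tt^3 - tt)
    }
    tie_term <- tie_term / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    p <- pmin(1, 2 * pnorm(-pmax(z, 0)))
  } else {
    res <- apply(xs, 1, function(v) {
      h <- mann_whitney_u(v[seq_len(n1)], v[n1 + seq_len(n2)])
      c(h$statistic, h$p_value)
    })
    u <- res[1, ]
    p <- res[2, ]
  }
  med_diff <- apply(xs[, seq_len(n1), drop = FALSE], 1, stats::median) -
    apply(xs[, n1 + seq_len(n2), drop = FALSE], 1, stats::median)
  mean_diff <- rowMeans(xs[, seq_len(n1), drop = FALSE]) -
    rowMeans(xs[, n1 + seq_len(n2), drop = FALSE])
  direction <- ifelse(med_diff > 0, "up",
                      ifelse(med_diff < 0, "down",
                             ifelse(mean_diff >= 0, "up", "down")))
  out <- tibble::tibble(
    gene = rownames(xs),
    u = unname(u),
    p = unname(p),
    adj_p = bh_adjust(unname(p)),
    direction = unname(direction)
  )
  attr(out, "skipped") <- rownames(x)[constant]
  out
}

#' Build a gene module from screening results
#'
#' Selects genes whose BH-adjusted p falls below the FDR threshold
#' (default 0.2) and assigns weight +1 to up- and -1 to down-regulated
#' genes. An empty module is legal and flagged with a message.
#'
#' @param results Tibble from [per_gene_differential()].
#' @param fdr_threshold FDR threshold in (0, 1), default 0.2.
#' @param name Module name.
#' @return Tibble `module`, `gene`, `weight`.
#' @export
derive_module <- function(results, fdr_threshold = 0.2, name = "BV") {
  stopifnot(fdr_threshold > 0, fdr_threshold <= 1)
  sel <- results[results$adj_p < fdr_threshold, , drop = FALSE]
  if (nrow(sel) == 0) {
    message("no genes pass FDR < ", fdr_threshold, "; empty module")
  }
  tibble::tibble(
    module = name,
    gene = sel$gene,
    weight = ifelse(sel$direction == "up", 1, -1)
  )
}

#' Evaluate a gene module as a classifier of group membership
#'
#' Scores samples with the directional weighted sum and computes the ROC
#' curve and AUC for case-versus-reference discrimination, together with
#' per-group score summaries for density plots. When the evaluation
#' samples are the derivation samples the result is labelled
#' `resubstitution` (optimistically biased).
#'
#' @param expr Expression matrix or data frame.
#' @param module Tibble `gene`/`weight`.
#' @param group_case,group_ref Sample id vectors.
#' @param resubstitution Set `TRUE` when evaluating on the derivation
#'   samples.
#' @return List of class `organo_module_eval`: `auc`, `roc`
#'   (`organo_roc`), `scores` (tibble `sample_id`, `score`, `group`),
#'   `summary` (per-group median/IQR), `resubstitution`.
#' @export
evaluate_module <- function(expr, module, group_case, group_ref,
                            resubstitution = FALSE) {
  stopifnot(nrow(module) > 0)
  expr <- as_expr_matrix(expr)
  sc <- weighted_sum_score(expr[, c(group_case, group_ref), drop = FALSE],
                           module)
  sc$group <- rep(c("case", "reference"),
                  c(length(group_case), length(group_ref)))
  roc <- roc_auc(sc$score, sc$group == "case")
  summ <- sc |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$score),
      q25 = quantile(.data$score, 0.25),
      q75 = quantile(.data$score, 0.75),
      .groups = "drop"
    )
  structure(list(auc = roc$auc, roc = roc, scores = sc, summary = summ,
                 resubstitution = resubstitution),
            class = "organo_module_eval")
}

#' @export
print.organo_module_eval <- function(x, ...) {
  cat("Module evaluation: AUC =", round(x$auc, 3),
      if (x$resubstitution) "(resubstitution; optimistically biased)",
      "\n")
  print(x$summary)
  invisible(x)
}
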