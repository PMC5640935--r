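#' Coerce expression input to a genes-by-samples matrix
#'
#' Accepts a numeric matrix (gene ids as rownames) or a data frame whose
#' first column holds gene/probe ids and whose remaining columns are
#' samples.
#'
#' @param expr Matrix or data frame.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
as_expr_matrix <- function(expr) {
  if (is.matrix(expr)) {
    stopifnot(!is.null(rownames(expr)), !is.null(colnames(expr)))
    if (anyDuplicated(colnames(expr))) {
      stop("duplicate sample ids in expression matrix", call. = FALSE)
    }
    return(expr)
  }
  ids <- as.character(expr[[1]])
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) {
    stop("duplicate sample ids in expression matrix", call. = FALSE)
  }
  storage.mode(m) <- "double"
  m
}

#' Read and write direction-suffixed GMT gene modules
#'
#' The GMT dialect used here appends `|+` or `|-` to each gene token to
#' carry the direction of expression in the signature; a bare token means
#' `+`. Standard tab-separated GMT layout otherwise: module name,
#' description, then gene tokens.
#'
#' @param path File path.
#' @return `read_gmt()`: tibble with columns `module`, `gene`, `weight`
#'   (+1/-1).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  purrr::map_dfr(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("malformed GMT line (need name, description, >=1 gene): ", l,
           call. = FALSE)
    }
    tokens <- parts[-(1:2)]
    weight <- ifelse(grepl("\\|-$", tokens), -1, 1)
    gene <- sub("\\|[+-]$", "", tokens)
    tibble::tibble(module = parts[1], gene = gene, weight = weight)
  })
}

#' @rdname read_gmt
#' @param modules Tibble with columns `module`, `gene`, `weight`.
#' @export
write_gmt <- function(modules, path) {
  lines <- modules |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(
      line = paste(c(.data$module[1], "na",
                     paste0(.data$gene,
                            ifelse(.data$weight < 0, "|-", "|+"))),
                   collapse = "\t"),
      .groups = "drop"
    )
  readr::write_lines(lines$line, path)
  invisible(path)
}

#' Resolve module genes to probes by maximal variability
#'
#' When several probes map to one gene, keeps the probe with the largest
#' sample standard deviation in `expr`; ties are broken by the
#' lexicographically smallest probe id (and reported). Genes with no probe
#' in `expr` are dropped and reported via the `dropped_genes` attribute.
#'
#' @param module Tibble `module`/`gene`/`weight` (a single module).
#' @param annotation Tibble `probe_id`, `gene_id` (many probes to one gene).
#' @param expr Probe-level expression matrix or data frame.
#' @return Module tibble whose `gene` column now holds probe ids, with
#'   attributes `dropped_genes` and `sd_ties`.
#' @export
resolve_module_probes <- function(module, annotation, expr) {
  expr <- as_expr_matrix(expr)
  if (anyDuplicated(annotation$probe_id)) {
    stop("a probe may map to at most one gene", call. = FALSE)
  }
  ann <- annotation[annotation$probe_id %in% rownames(expr), , drop = FALSE]
  sds <- apply(expr[ann$probe_id, , drop = FALSE], 1, stats::sd)
  ann <- ann |>
    dplyr::mutate(sd = unname(sds)) |>
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$sd), .data$probe_id)
  ties <- ann |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::filter(dplyr::n() > 1, .data$sd[1] == .data$sd[2]) |>
    dplyr::ungroup()
  best <- ann |> dplyr::distinct(.data$gene_id, .keep_all = TRUE)
  out <- module |>
    dplyr::inner_join(best, by = c(gene = "gene_id")) |>
    dplyr::transmute(module = .data$module, gene = .data$probe_id,
                     weight = .data$weight)
  dropped <- setdiff(module$gene, best$gene_id)
  if (nrow(out) == 0) {
    stop("module ", module$module[1], " has no mappable genes in the ",
         "expression data", call. = FALSE)
  }
  if (length(dropped) > 0) {
    warning("module ", module$module[1], ": ", length(dropped),
            " gene(s) without probes dropped", call. = FALSE)
  }
  if (nrow(ties) > 0) {
    message("SD ties broken lexicographically for gene(s): ",
            paste(unique(ties$gene_id), collapse = ", "))
  }
  attr(out, "dropped_genes") <- dropped
  attr(out, "sd_ties") <- unique(ties$gene_id)
  out
}

#' Directional weighted-sum module score
#'
#' Per sample, the sum of member-gene expression values weighted +1 or -1
#' by the direction of expression in the signature. Genes absent from the
#' matrix are skipped and counted in the `n_missing` attribute; a module
#' with no present gene is an error.
#'
#' @param expr Expression matrix or data frame (log scale).
#' @param module Tibble `gene`/`weight` for one module.
#' @return Tibble `sample_id`, `score`, with attribute `n_missing`.
#' @examples
#' m <- matrix(c(5, 3), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' weighted_sum_score(m, data.frame(gene = c("a", "b"), weight = c(1, -1)))
#' @export
weighted_sum_score <- function(expr, module) {
  expr <- as_expr_matrix(expr)
  present <- module$gene %in% rownames(expr)
  if (!any(present)) {
    stop("no module genes present in the expression data", call. = FALSE)
  }
  mod <- module[present, , drop = FALSE]
  s <- drop(crossprod(expr[mod$gene, , drop = FALSE], mod$weight))
  out <- tibble::tibble(sample_id = colnames(expr), score = unname(s))
  attr(out, "n_missing") <- sum(!present)
  out
}

#' Scale scores so 95 percent of a reference series lies in [-1, 1]
#'
#' Affine map `x -> (x - c) / h` where `c` is the midpoint and `h` the
#' half-width of the reference's central 95% interval (2.5th and 97.5th
#' linear-interpolation quantiles). Applied within each case-control
#' series so module scores are on a comparable scale and per-unit odds
#' ratios span the series' observed range.
#'
#' @param x Numeric scores to scale.
#' @param reference Numeric values defining the scaling (defaults to `x`);
#'   needs at least 20 values.
#' @return Scaled numeric vector with attributes `center` and `halfwidth`.
#' @export
scale_scores_95 <- function(x, reference = x) {
  reference <- reference[!is.na(reference)]
  if (length(reference) < 20) {
    stop("need at least 20 reference values to scale", call. = FALSE)
  }
  q <- stats::quantile(reference, c(0.025, 0.975), names = FALSE, type = 7)
  h <- (q[2] - q[1]) / 2
  if (h == 0) {
    stop("reference series is (nearly) constant; cannot scale",
         call. = FALSE)
  }
  ctr <- (q[1] + q[2]) / 2
  out <- (x - ctr) / h
  attr(out, "center") <- ctr
  attr(out, "halfwidth") <- h
  out
}

#' Nearest-centroid subtype assignment by Spearman correlation
#'
#' Genes are median-centred across samples on the shared gene set; each
#' sample is assigned the centroid with the highest Spearman rank
#' correlation. Rank-based, so any per-sample monotone transform of the
#' expression values leaves assignments unchanged.
#'
#' @param expr Expression matrix or data frame.
#' @param centroids Matrix or data frame of centroid profiles (genes x
#'   subtypes; first column = gene ids when a data frame).
#' @return Tibble `sample_id`, `subtype`, plus one correlation column per
#'   centroid (`cor_<subtype>`).
#' @export
assign_nearest_centroid <- function(expr, centroids) {
  expr <- as_expr_matrix(expr)
  cen <- as_expr_matrix(centroids)
  shared <- intersect(rownames(expr), rownames(cen))
  if (length(shared) < 3) {
    stop("need at least 3 genes shared between expression and centroids",
         call. = FALSE)
  }
  e <- expr[shared, , drop = FALSE]
  e <- e - apply(e, 1, stats::median)
  cc <- stats::cor(e, cen[shared, , drop = FALSE], method = "spearman")
  lab <- colnames(cc)[max.col(cc, ties.method = "first")]
  out <- tibble::tibble(sample_id = rownames(cc), subtype = lab)
  cors <- tibble::as_tibble(cc)
  names(cors) <- paste0("cor_", names(cors))
  dplyr::bind_cols(out, cors)
}

#' NanoString-style count normalization
#'
#' Per sample: (1) background correction by the mean-plus-2-SD of the
#' negative-control probes, truncated at zero; (2) content normalization
#' to the housekeeping geometric mean — each sample is multiplied by
#' (grand mean of per-sample housekeeping geometric means) / (its own
#' housekeeping geometric mean); (3) log2(count + 1); (4) per-sample
#' standardization by subtracting the sample's mean log2 endogenous value
#' (the log-domain equivalent of dividing by the geometric mean). Samples
#' whose housekeeping geometric mean is zero after background correction
#' are excluded and reported.
#'
#' @param counts Data frame: first column probe id, second column probe
#'   class (`endogenous`, `negative`, `housekeeping`), remaining columns
#'   raw counts per sample. A matrix plus a `probe_class` vector is also
#'   accepted.
#' @param probe_class Optional character vector when `counts` is a matrix.
#' @return Normalized log2 expression matrix over endogenous probes, with
#'   attribute `excluded_samples`.
#' @export
nanostring_normalize <- function(counts, probe_class = NULL) {
  if (is.null(probe_class)) {
    probe_class <- as.character(counts[[2]])
    m <- as_expr_matrix(counts[, -2, drop = FALSE])
  } else {
    m <- as_expr_matrix(counts)
  }
  stopifnot(length(probe_class) == nrow(m), all(m >= 0))
  cls <- probe_class
  bad_cls <- setdiff(unique(cls), c("endogenous", "negative", "housekeeping"))
  if (length(bad_cls) > 0) {
    stop("unknown probe class(es): ", paste(bad_cls, collapse = ", "),
         call. = FALSE)
  }
  if (!any(cls == "negative") || !any(cls == "housekeeping")) {
    stop("need at least one negative and one housekeeping probe",
         call. = FALSE)
  }
  all_samples <- colnames(m)
  neg <- m[cls == "negative", , drop = FALSE]
  bg <- colMeans(neg) + 2 * apply(neg, 2, stats::sd)
  bg[is.na(bg)] <- colMeans(neg)[is.na(bg)]  # single negative probe: sd NA
  m <- pmax(sweep(m, 2, bg), 0)

  hk <- m[cls == "housekeeping", , drop = FALSE]
  geo <- exp(colMeans(log(hk)))  # 0 when any housekeeping count is 0
  geo[!is.finite(geo)] <- 0
  bad <- geo == 0
  if (any(bad)) {
    warning("excluding sample(s) with zero housekeeping geometric mean: ",
            paste(colnames(m)[bad], collapse = ", "), call. = FALSE)
  }
  keep <- !bad
  m <- m[, keep, drop = FALSE]
  geo <- geo[keep]
  f <- mean(geo) / geo
  m <- sweep(m, 2, f, `*`)

  endo <- log2(m[cls == "endogenous", , drop = FALSE] + 1)
  endo <- sweep(endo, 2, colMeans(endo))
  attr(endo, "excluded_samples") <- all_samples[bad]
  endo
}

#' Standardized weighted-sum score within ER-positive samples
#'
#' Each module gene is mean-centred and SD-scaled across the ER-positive
#' samples before the directional weighted sum, as used for
#' NanoString-validated module scoring. Genes with zero SD across the
#' ER-positive samples are excluded with a warning.
#'
#' @param expr Expression matrix or data frame.
#' @param module Tibble `gene`/`weight`.
#' @param er_positive Character vector of ER-positive sample ids (>= 2).
#' @return Tibble `sample_id`, `score` over the ER-positive samples.
#' @export
bv_nanostring_score <- function(expr, module, er_positive) {
  expr <- as_expr_matrix(expr)
  er_positive <- intersect(er_positive, colnames(expr))
  if (length(er_positive) < 2) {
    stop("need at least 2 ER-positive samples", call. = FALSE)
  }
  present <- module$gene %in% rownames(expr)
  if (!any(present)) {
    stop("no module genes present in the expression data", call. = FALSE)
  }
  mod <- module[present, , drop = FALSE]
  e <- expr[mod$gene, er_positive, drop = FALSE]
  sds <- apply(e, 1, stats::sd)
  if (any(sds == 0)) {
    warning("excluding constant gene(s): ",
            paste(mod$gene[sds == 0], collapse = ", "), call. = FALSE)
    mod <- mod[sds > 0, , drop = FALSE]
    e <- e[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- (e - rowMeans(e)) / sds
  weighted_sum_score(z, mod)
}
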