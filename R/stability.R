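#' @title Per-gene expression-stability statistics
#' @description The four statistics in common use for screening candidate
#'   reference genes: the comparative delta-Ct method (mean pairwise SD of Ct
#'   differences), the geNorm M value with iterative elimination, the
#'   NormFinder model-based stability value, and BestKeeper descriptive
#'   statistics. Each returns a `stability_table`: a data frame with columns
#'   `gene`, `value`, `rank` and attributes `method` and `subset`.
#' @name stability
NULL

new_stability_table <- function(method, genes, values, subset = "all",
                                ranks = NULL) {
  if (is.null(ranks)) ranks <- competition_ranks(stats::setNames(values, genes))
  out <- data.frame(gene = genes, value = as.numeric(values),
                    rank = as.integer(ranks), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, method = method, subset = subset,
            class = c("stability_table", "data.frame"))
}

#' @export
print.stability_table <- function(x, ...) {
  cat(sprintf("<stability_table> method=%s subset=%s\n",
              attr(x, "method"), attr(x, "subset")))
  NextMethod()
}

.collapsed_ct <- function(m, caller) {
  stopifnot(inherits(m, "ct_matrix"))
  if (dim(m$ct)[3L] != 1L)
    stop(caller, ": collapse replicates first", call. = FALSE)
  ct <- matrix(m$ct[, , 1L], nrow = length(m$genes),
               dimnames = list(m$genes, m$samples))
  if (anyNA(ct)) {
    idx <- which(is.na(ct), arr.ind = TRUE)
    stop(caller, ": missing Ct cell(s): ",
         paste0(m$genes[idx[, 1L]], "/", m$samples[idx[, 2L]],
                collapse = ", "), call. = FALSE)
  }
  ct
}

#' Comparative delta-Ct stability
#'
#' For every ordered gene pair (j, k) the per-sample Ct difference
#' `Ct_j - Ct_k` is formed; the dispersion of a pair is the sample standard
#' deviation of that difference across samples. The stability of gene j is
#' the mean dispersion over all partners k != j — a gene whose Ct tracks
#' every other gene up to a constant is maximally stable. Because shared
#' per-sample effects (loading, cDNA input) cancel in the difference, the
#' statistic is invariant to them.
#'
#' @param m a [ct_matrix()], replicates collapsed, no missing cells;
#'   at least 2 genes and 2 samples.
#' @param subset label stored on the result.
#' @return A `stability_table` (cycles; lower = more stable).
#' @export
deltact_stability <- function(m, subset = "all") {
  ct <- .collapsed_ct(m, "deltact_stability")
  if (nrow(ct) < 2L) stop("need at least 2 genes", call. = FALSE)
  if (ncol(ct) < 2L) stop("need at least 2 samples", call. = FALSE)
  n <- nrow(ct)
  pair_sd <- matrix(0, n, n)
  for (j in seq_len(n - 1L)) for (k in (j + 1L):n) {
    s <- stats::sd(ct[j, ] - ct[k, ])
    pair_sd[j, k] <- pair_sd[k, j] <- s
  }
  vals <- rowSums(pair_sd) / (n - 1L)
  new_stability_table("delta_ct", m$genes, vals, subset)
}

#' geNorm M values
#'
#' The gene-stability measure M of the geNorm approach: for genes j, k the
#' pairwise variation `V_jk` is the standard deviation across samples of
#' `log2(q_j / q_k)`, and `M_j` is the mean of `V_jk` over all k != j.
#' Computed on the full gene set with no elimination; see [genorm_ranking()]
#' for the iterative procedure.
#'
#' @param q a [to_relative_quantity()] result; >= 2 genes, >= 2 samples,
#'   all quantities positive.
#' @return Named numeric vector of M values (lower = more stable).
#' @export
genorm_m_values <- function(q) {
  stopifnot(inherits(q, "quantity_matrix"))
  .genorm_m(.log2_quantities(q))
}

.log2_quantities <- function(q) {
  if (any(!is.finite(q$q) | q$q <= 0))
    stop("quantities must be positive and finite", call. = FALSE)
  log2(q$q)
}

.genorm_m <- function(y) {
  n <- nrow(y)
  if (n < 2L) stop("need at least 2 genes", call. = FALSE)
  if (ncol(y) < 2L) stop("need at least 2 samples", call. = FALSE)
  v <- matrix(0, n, n)
  for (j in seq_len(n - 1L)) for (k in (j + 1L):n) {
    s <- stats::sd(y[j, ] - y[k, ])  # sd of log2 ratio
    v[j, k] <- v[k, j] <- s
  }
  stats::setNames(rowSums(v) / (n - 1L), rownames(y))
}

#' geNorm ranking by iterative elimination
#'
#' Repeatedly computes M on the surviving gene set and removes the single
#' gene with the largest M (ties broken deterministically by removing the
#' later gene in input order, with a message) until two genes remain. The
#' value reported for each gene is its M at the step of its elimination; the
#' two survivors cannot be ranked against each other by this procedure, so
#' both receive rank 1 and their shared last-step M, and the next-best gene
#' receives rank 3.
#'
#' @param q a [to_relative_quantity()] result with >= 3 genes.
#' @param subset label stored on the result.
#' @return A `stability_table` ordered as the input genes.
#' @export
genorm_ranking <- function(q, subset = "all") {
  stopifnot(inherits(q, "quantity_matrix"))
  y <- .log2_quantities(q)
  n <- nrow(y)
  if (n < 3L)
    stop("genorm_ranking needs >= 3 genes; use genorm_m_values for 2",
         call. = FALSE)
  surviving <- q$genes
  value <- stats::setNames(numeric(n), q$genes)
  rank <- stats::setNames(integer(n), q$genes)
  while (length(surviving) > 2L) {
    m_val <- .genorm_m(y[surviving, , drop = FALSE])
    worst_val <- max(m_val)
    worst <- which(m_val == worst_val)
    if (length(worst) > 1L)
      message("genorm_ranking: tie at M = ", format(worst_val),
              " broken by input order")
    drop_gene <- surviving[max(worst)]
    value[drop_gene] <- worst_val
    rank[drop_gene] <- length(surviving)
    surviving <- setdiff(surviving, drop_gene)
  }
  m_final <- .genorm_m(y[surviving, , drop = FALSE])
  value[surviving] <- m_final[surviving]
  rank[surviving] <- 1L
  new_stability_table("genorm", q$genes, value, subset, ranks = rank)
}

#' geNorm pairwise variation V(n/n+1)
#'
#' Quantifies the benefit of adding an (n+1)-th reference gene: with genes
#' ordered by a geNorm ranking, `NF_n(s)` is the geometric mean of the n best
#' genes' quantities in sample s, and `V(n/n+1)` is the standard deviation
#' over samples of `log2(NF_n / NF_{n+1})`. Small V means the extra gene
#' hardly changes the normalization factor. The classical rule of thumb takes
#' V < 0.15 as sufficient, but the cutoff is the user's decision; this
#' function only reports the series.
#'
#' @param q a [to_relative_quantity()] result.
#' @param ranking a `stability_table` from [genorm_ranking()] on the same
#'   genes; `NULL` (default) computes it.
#' @param max_n largest n to report (default: gene count - 1).
#' @return Data frame with columns `n` and `v`: rows n = 2 .. max_n.
#' @export
genorm_pairwise_variation <- function(q, ranking = NULL, max_n = NULL) {
  stopifnot(inherits(q, "quantity_matrix"))
  n_genes <- length(q$genes)
  if (is.null(max_n)) max_n <- n_genes - 1L
  if (max_n >= n_genes)
    stop("max_n must be smaller than the gene count", call. = FALSE)
  if (max_n < 2L) stop("max_n must be at least 2", call. = FALSE)
  if (is.null(ranking)) ranking <- genorm_ranking(q)
  stopifnot(inherits(ranking, "stability_table"))
  ord <- ranking$gene[order(ranking$rank,
                            match(ranking$gene, q$genes))]
  y <- .log2_quantities(q)[ord, , drop = FALSE]
  # log2 NF_n per sample = mean of the n best genes' log2 quantities
  v <- vapply(2:max_n, function(n) {
    nf_n <- colMeans(y[seq_len(n), , drop = FALSE])
    nf_n1 <- colMeans(y[seq_len(n + 1L), , drop = FALSE])
    stats::sd(nf_n - nf_n1)
  }, numeric(1))
  data.frame(n = 2:max_n, v = v)
}

#' NormFinder stability values
#'
#' Model-based stability on `y = log2 Q`. Ungrouped: the additive model
#' `y_gs = gene_g + sample_s + e_gs` is fitted by double centering, and the
#' per-gene error variance is estimated from the residual sums of squares
#' with the across-gene bias correction of the model
#' (`sigma2_g = G/(G-2) * (S_g - sum(S)/(G(G-1)))`, `S_g = RSS_g/(n-1)`,
#' floored at 0); the stability value is its square root. Grouped: within
#' each group the same intragroup variance `gamma2` is estimated; the
#' intergroup bias `d_gk` of gene g in group k is the doubly-centered
#' gene-by-group mean, shrunk by its sampling variance
#' (`d~^2 = max(0, d^2 - gamma2/n_k)`); the stability value combines bias and
#' imprecision as the mean over groups of `|d~| + sqrt(gamma2/n_k)`.
#'
#' @param q a [to_relative_quantity()] result; >= 3 genes.
#' @param groups `NULL` for the ungrouped variant, or a named character
#'   vector (sample -> group); defaults to the matrix's own labels when
#'   `use_groups = TRUE`. Every group needs >= 2 samples.
#' @param use_groups if `TRUE` and `groups` is `NULL`, use `q$groups`.
#' @param subset label stored on the result.
#' @return A `stability_table` (dimensionless SVs; lower = more stable).
#' @export
normfinder_stability <- function(q, groups = NULL, use_groups = !is.null(groups),
                                 subset = "all") {
  stopifnot(inherits(q, "quantity_matrix"))
  y <- .log2_quantities(q)
  if (nrow(y) < 3L) stop("need at least 3 genes", call. = FALSE)
  if (use_groups && is.null(groups)) groups <- q$groups
  if (!use_groups) groups <- NULL
  if (is.null(groups)) {
    sv <- sqrt(.normfinder_var(y))
  } else {
    groups <- groups[q$samples]
    if (anyNA(groups))
      stop("group labels missing for some samples", call. = FALSE)
    tab <- table(groups)
    if (any(tab < 2L))
      stop("singleton group(s): ",
           paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
    sv <- .normfinder_grouped(y, as.character(groups))
  }
  new_stability_table("normfinder", q$genes, sv, subset)
}

# Unbiased per-gene error variance under the doubly-centered additive model.
# With G genes, E[RSS_g/(n-1)] = ((G-1)/G)^2 sigma2_g + sum_{h!=g} sigma2_h/G^2,
# which inverts to the correction below; estimates are floored at 0.
.normfinder_var <- function(y) {
  g <- nrow(y)
  n <- ncol(y)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  r <- y - rowMeans(y)
  r <- sweep(r, 2L, colMeans(r))
  s <- rowSums(r^2) / (n - 1L)
  pmax(0, g / (g - 2) * (s - sum(s) / (g * (g - 1))))
}

.normfinder_grouped <- function(y, groups) {
  g <- nrow(y)
  glev <- unique(groups)
  n_k <- vapply(glev, function(k) sum(groups == k), integer(1))
  # intragroup variance per gene x group
  gamma2 <- sapply(glev, function(k)
    .normfinder_var(y[, groups == k, drop = FALSE]))
  gamma2 <- matrix(gamma2, nrow = g, dimnames = list(rownames(y), glev))
  # gene-by-group means centered for gene and group (sample) effects
  ybar <- sapply(glev, function(k) rowMeans(y[, groups == k, drop = FALSE]))
  ybar <- matrix(ybar, nrow = g, dimnames = list(rownames(y), glev))
  d <- ybar - rowMeans(ybar)
  d <- sweep(d, 2L, colMeans(d))
  var_d <- sweep(gamma2, 2L, n_k, "/")
  d_shrunk <- sqrt(pmax(0, d^2 - var_d))
  rho <- d_shrunk + sqrt(var_d)
  stats::setNames(rowMeans(rho), rownames(y))
}

#' BestKeeper descriptive statistics
#'
#' Per gene, on raw Ct values across samples: the standard deviation about
#' the arithmetic mean, the coefficient of variation (`100 * SD / mean`, in
#' percent of the mean Ct), and the geometric mean Ct. Per sample, the
#' BestKeeper index: the geometric mean Ct over all candidate genes. Per
#' gene, the Pearson correlation of its Ct with the index; for a gene with
#' zero variance the correlation is undefined and reported `NA` with a
#' warning.
#'
#' @param m a [ct_matrix()], replicates collapsed, no missing cells,
#'   >= 2 samples.
#' @return An object of class `bestkeeper_stats`: list with `per_gene`
#'   (data frame `gene`, `geo_mean_ct`, `mean_ct`, `sd_ct`, `cv_pct`,
#'   `r_vs_index`) and `index` (named per-sample vector).
#' @export
bestkeeper_stats <- function(m) {
  ct <- .collapsed_ct(m, "bestkeeper_stats")
  if (ncol(ct) < 2L) stop("need at least 2 samples", call. = FALSE)
  index <- exp(colMeans(log(ct)))
  sd_ct <- apply(ct, 1L, stats::sd)
  mean_ct <- rowMeans(ct)
  degenerate <- sd_ct == 0 | stats::sd(index) == 0
  if (any(degenerate))
    warning("correlation with the BestKeeper index undefined for: ",
            paste(m$genes[degenerate], collapse = ", "), call. = FALSE)
  r <- ifelse(degenerate, NA_real_,
              apply(ct, 1L, function(v)
                if (stats::sd(v) == 0 || stats::sd(index) == 0) NA_real_
                else stats::cor(v, index)))
  per_gene <- data.frame(gene = m$genes,
                         geo_mean_ct = exp(rowMeans(log(ct))),
                         mean_ct = mean_ct, sd_ct = sd_ct,
                         cv_pct = 100 * sd_ct / mean_ct,
                         r_vs_index = r, stringsAsFactors = FALSE)
  rownames(per_gene) <- NULL
  structure(list(per_gene = per_gene, index = index),
            class = "bestkeeper_stats")
}

#' @export
print.bestkeeper_stats <- function(x, ...) {
  cat("<bestkeeper_stats>\n")
  print(x$per_gene)
  invisible(x)
}

#' BestKeeper ranking
#'
#' Ranks genes by ascending Ct standard deviation (the default) or by
#' ascending coefficient of variation. The two orders can differ when genes
#' have similar SDs at different expression levels.
#'
#' @param stats a [bestkeeper_stats()] result.
#' @param criterion `"sd"` (default) or `"cv"`.
#' @param subset label stored on the result.
#' @return A `stability_table` (cycles for `"sd"`, percent for `"cv"`).
#' @export
bestkeeper_ranking <- function(stats, criterion = c("sd", "cv"),
                               subset = "all") {
  stopifnot(inherits(stats, "bestkeeper_stats"))
  criterion <- match.arg(criterion)
  vals <- if (criterion == "sd") stats$per_gene$sd_ct else stats$per_gene$cv_pct
  new_stability_table("bestkeeper", stats$per_gene$gene, vals, subset)
}
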