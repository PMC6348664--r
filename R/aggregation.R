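#' Competition ("1224") ranks
#'
#' Tied values share the minimum rank and the next distinct value's rank
#' skips by the tie count, the convention used when ranking candidate genes
#' within each stability method.
#'
#' @param values named numeric vector (gene -> value), no missing values.
#' @param lower_is_better if `TRUE` (default) the smallest value ranks 1.
#' @return Named integer vector of ranks.
#' @examples
#' competition_ranks(c(a = 0.20, b = 0.20, c = 0.31))  # 1, 1, 3
#' @export
competition_ranks <- function(values, lower_is_better = TRUE) {
  if (anyNA(values))
    stop("missing stability value for gene(s): ",
         paste(names(values)[is.na(values)], collapse = ", "), call. = FALSE)
  v <- as.numeric(values)
  if (!lower_is_better) v <- -v
  stats::setNames(as.integer(rank(v, ties.method = "min")), names(values))
}

# Round half away from zero, the display convention of published comprehensive
# rankings (base round() rounds half to even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Geometric-mean comprehensive ranking
#'
#' The RefFinder-style consensus: each gene's comprehensive stability score
#' is the geometric mean of its integer ranks across methods,
#' \deqn{G_g = (\prod_m r_{gm})^{1/M},}
#' and a lower geometric mean indicates higher stability. Display values are
#' rounded half-up to 2 decimals; the final ordering uses the unrounded
#' scores with competition ranks.
#'
#' @param rank_matrix gene x method matrix of positive integer ranks, with
#'   gene rownames; every gene must be ranked by every method.
#' @param subset label stored on the result.
#' @return An object of class `comprehensive_ranking`: data frame with
#'   columns `gene`, `geomean` (2-decimal display value) and `final_rank`,
#'   plus attributes `subset`, `methods` and `rank_matrix`; `geomean_exact`
#'   carries the unrounded scores.
#' @examples
#' rk <- cbind(delta_ct = c(1, 2), genorm = c(1, 2))
#' rownames(rk) <- c("RPL4", "ACT")
#' geometric_mean_ranks(rk)
#' @export
geometric_mean_ranks <- function(rank_matrix, subset = "all") {
  rank_matrix <- as.matrix(rank_matrix)
  if (is.null(rownames(rank_matrix)))
    stop("rank_matrix needs gene rownames", call. = FALSE)
  if (ncol(rank_matrix) < 1L) stop("need at least one method", call. = FALSE)
  if (anyNA(rank_matrix))
    stop("unranked gene/method cell(s): ",
         paste(rownames(rank_matrix)[rowSums(is.na(rank_matrix)) > 0],
               collapse = ", "), call. = FALSE)
  if (any(rank_matrix <= 0))
    stop("ranks must be positive", call. = FALSE)
  gm <- exp(rowMeans(log(rank_matrix)))
  final <- competition_ranks(gm)
  out <- data.frame(gene = rownames(rank_matrix),
                    geomean = round_half_up(gm, 2),
                    final_rank = as.integer(final),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, subset = subset,
            methods = colnames(rank_matrix),
            rank_matrix = rank_matrix,
            geomean_exact = stats::setNames(gm, rownames(rank_matrix)),
            class = c("comprehensive_ranking", "data.frame"))
}

#' @export
print.comprehensive_ranking <- function(x, ...) {
  cat(sprintf("<comprehensive_ranking> subset=%s methods=%s\n",
              attr(x, "subset"), paste(attr(x, "methods"), collapse = "+")))
  NextMethod()
}

#' Comprehensive ranking from per-method stability tables
#'
#' Assembles the gene x method rank matrix from stability tables computed on
#' one sample subset — by convention in the order delta-Ct, BestKeeper,
#' NormFinder, geNorm — and aggregates with [geometric_mean_ranks()].
#'
#' @param tables list of `stability_table`s sharing gene set and subset.
#' @return A `comprehensive_ranking`.
#' @export
comprehensive_report <- function(tables) {
  if (!length(tables)) stop("no stability tables given", call. = FALSE)
  stopifnot(all(vapply(tables, inherits, logical(1), "stability_table")))
  genes <- tables[[1L]]$gene
  subsets <- unique(vapply(tables, attr, character(1), "subset"))
  if (length(subsets) > 1L)
    stop("tables span several subsets: ", paste(subsets, collapse = ", "),
         call. = FALSE)
  for (t in tables) {
    extra <- setdiff(t$gene, genes)
    miss <- setdiff(genes, t$gene)
    if (length(extra) || length(miss))
      stop("mismatched gene sets (method ", attr(t, "method"),
           "): only in this table: ",
           paste(extra, collapse = ", "), "; missing: ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  methods <- vapply(tables, attr, character(1), "method")
  canonical <- c("delta_ct", "bestkeeper", "normfinder", "genorm")
  ord <- order(match(methods, canonical))
  tables <- tables[ord]
  methods <- methods[ord]
  rk <- vapply(tables, function(t)
    t$rank[match(genes, t$gene)], integer(length(genes)))
  rk <- matrix(rk, nrow = length(genes),
               dimnames = list(genes, methods))
  geometric_mean_ranks(rk, subset = subsets)
}
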