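#' Ct matrix: genes x samples x replicates quantification-cycle values
#'
#' The universal input of the stability pipeline. Ct (= Cq) values are stored
#' on the raw cycle scale in a 3-axis numeric array; all transforms (replicate
#' collapse, relative quantities) are explicit operations. Missing wells are
#' `NA`; values that are present must be finite and strictly positive.
#'
#' @param ct numeric array gene x sample x replicate, or a gene x sample
#'   matrix (treated as replicate count 1).
#' @param genes character vector of unique gene identifiers (rows).
#' @param samples character vector of unique sample identifiers (columns).
#' @param groups optional named character vector mapping sample -> group label.
#' @return An object of class `ct_matrix`.
#' @examples
#' ct <- array(20 + rnorm(12, sd = 0.2), dim = c(2, 3, 2))
#' m <- ct_matrix(ct, genes = c("RPL4", "ACT"), samples = c("s1", "s2", "s3"))
#' dim(m)
#' @export
ct_matrix <- function(ct, genes, samples, groups = NULL) {
  if (is.matrix(ct)) ct <- array(ct, dim = c(dim(ct), 1L))
  if (!is.array(ct) || length(dim(ct)) != 3L)
    stop("`ct` must be a gene x sample x replicate array", call. = FALSE)
  genes <- as.character(genes)
  samples <- as.character(samples)
  if (dim(ct)[1L] != length(genes) || dim(ct)[2L] != length(samples))
    stop(sprintf("ct array is %d x %d but %d genes and %d samples were given",
                 dim(ct)[1L], dim(ct)[2L], length(genes), length(samples)),
         call. = FALSE)
  if (anyDuplicated(genes))
    stop("duplicate gene id: ", paste(unique(genes[duplicated(genes)]),
                                      collapse = ", "), call. = FALSE)
  if (anyDuplicated(samples))
    stop("duplicate sample id: ", paste(unique(samples[duplicated(samples)]),
                                        collapse = ", "), call. = FALSE)
  if (dim(ct)[3L] < 1L) stop("replicate count must be >= 1", call. = FALSE)
  bad <- !is.na(ct) & (!is.finite(ct) | ct <= 0)
  if (any(bad))
    stop("Ct values must be finite and > 0 where present; ",
         sum(bad), " offending cell(s)", call. = FALSE)
  storage.mode(ct) <- "double"
  dimnames(ct) <- list(genes, samples, NULL)
  if (!is.null(groups)) {
    groups <- vapply(groups, as.character, character(1))
    missing_g <- setdiff(samples, names(groups))
    if (length(missing_g))
      stop("group labels missing for sample(s): ",
           paste(missing_g, collapse = ", "), call. = FALSE)
    groups <- groups[samples]
  }
  structure(list(ct = ct, genes = genes, samples = samples, groups = groups),
            class = "ct_matrix")
}

#' @export
dim.ct_matrix <- function(x) dim(x$ct)

#' @export
print.ct_matrix <- function(x, ...) {
  d <- dim(x$ct)
  cat(sprintf("<ct_matrix> %d gene(s) x %d sample(s) x %d replicate(s)\n",
              d[1L], d[2L], d[3L]))
  cat("  genes:   ", paste(utils::head(x$genes, 8L), collapse = ", "),
      if (d[1L] > 8L) ", ..." else "", "\n", sep = "")
  cat("  samples: ", paste(utils::head(x$samples, 8L), collapse = ", "),
      if (d[2L] > 8L) ", ..." else "", "\n", sep = "")
  if (!is.null(x$groups))
    cat("  groups:  ", paste(unique(x$groups), collapse = ", "), "\n", sep = "")
  nmiss <- sum(is.na(x$ct))
  if (nmiss) cat("  missing cells: ", nmiss, "\n", sep = "")
  invisible(x)
}

#' Number of missing Ct wells
#' @param m a [ct_matrix()].
#' @return integer count of `NA` cells.
#' @export
n_missing <- function(m) {
  stopifnot(inherits(m, "ct_matrix"))
  sum(is.na(m$ct))
}

#' Collapse technical replicates
#'
#' Reduces the replicate axis to length 1 by averaging the non-missing
#' replicate Ct values of every gene x sample well. The mean is taken on the
#' cycle scale (the convention of the stability tools this package mirrors);
#' `median` is offered for robustness against a single aberrant well.
#'
#' @param m a [ct_matrix()].
#' @param how `"mean"` (default) or `"median"`.
#' @return A `ct_matrix` with one replicate. Wells whose replicates are all
#'   missing stay missing, with a warning listing them.
#' @examples
#' m <- ct_matrix(array(c(20, 20.4), dim = c(1, 1, 2)), "g1", "s1")
#' collapse_replicates(m)$ct[1, 1, 1]  # 20.2
#' @export
collapse_replicates <- function(m, how = c("mean", "median")) {
  stopifnot(inherits(m, "ct_matrix"))
  how <- match.arg(how)
  f <- if (how == "mean") function(v) mean(v, na.rm = TRUE)
       else function(v) stats::median(v, na.rm = TRUE)
  collapsed <- apply(m$ct, c(1L, 2L), function(v) {
    if (all(is.na(v))) NA_real_ else f(v)
  })
  if (anyNA(collapsed)) {
    idx <- which(is.na(collapsed), arr.ind = TRUE)
    cells <- paste0(m$genes[idx[, 1L]], "/", m$samples[idx[, 2L]])
    warning("all replicates missing for cell(s): ",
            paste(cells, collapse = ", "), call. = FALSE)
  }
  ct_matrix(collapsed, m$genes, m$samples, m$groups)
}

#' Select a sample subset
#'
#' Restricts a Ct matrix to the samples of one experimental set (e.g. fruit
#' developmental stages) in the order the subset lists them. Genes are
#' unchanged.
#'
#' @param m a [ct_matrix()].
#' @param spec a [subset_spec()], or a character vector of sample ids.
#' @return A `ct_matrix` over `spec$samples`.
#' @export
subset_samples <- function(m, spec) {
  stopifnot(inherits(m, "ct_matrix"))
  if (is.character(spec)) spec <- subset_spec("subset", spec)
  stopifnot(inherits(spec, "subset_spec"))
  unknown <- setdiff(spec$samples, m$samples)
  if (length(unknown))
    stop("subset '", spec$name, "' names unknown sample(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  ct <- m$ct[, spec$samples, , drop = FALSE]
  ct_matrix(ct, m$genes, spec$samples,
            if (is.null(m$groups)) NULL else m$groups[spec$samples])
}

#' Define a named sample subset
#'
#' @param name subset label (e.g. `"Fruits"`).
#' @param samples non-empty character vector of member sample ids.
#' @return An object of class `subset_spec`.
#' @export
subset_spec <- function(name, samples) {
  samples <- as.character(samples)
  if (!length(samples)) stop("subset '", name, "' is empty", call. = FALSE)
  if (anyDuplicated(samples))
    stop("subset '", name, "' repeats sample(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  structure(list(name = as.character(name), samples = samples),
            class = "subset_spec")
}

#' Per-gene five-number summary of collapsed Ct values
#'
#' The descriptive view behind the usual candidate-gene boxplots: for each
#' gene the minimum, lower quartile, median, upper quartile and maximum of
#' its collapsed Ct values across samples, plus the mean and the number of
#' non-missing observations. Quartiles use the default quantile definition
#' (type 7).
#'
#' @param m a [ct_matrix()] with replicates already collapsed.
#' @return A data frame with one row per gene and columns `gene`, `n`,
#'   `min`, `q1`, `median`, `q3`, `max`, `mean`.
#' @export
summarize_expression <- function(m) {
  stopifnot(inherits(m, "ct_matrix"))
  if (dim(m$ct)[3L] != 1L)
    stop("collapse replicates before summarizing (see collapse_replicates)",
         call. = FALSE)
  rows <- lapply(seq_along(m$genes), function(g) {
    v <- m$ct[g, , 1L]
    v <- v[!is.na(v)]
    if (!length(v))
      stop("gene '", m$genes[g], "' has no observations", call. = FALSE)
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(gene = m$genes[g], n = length(v), min = q[1L], q1 = q[2L],
               median = q[3L], q3 = q[4L], max = q[5L], mean = mean(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
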