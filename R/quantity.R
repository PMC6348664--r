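#' Relative quantities from Ct values
#'
#' Converts Ct values to linear-scale relative quantities with the usual
#' min-Ct calibration: for gene g in sample s,
#' \deqn{Q_{gs} = E_g^{\min_s Ct_{gs} - Ct_{gs}},}
#' where `E_g` is the per-cycle amplification factor of gene g (2.0 = 100%
#' efficiency, perfect doubling). Each gene's best-expressed sample gets
#' quantity exactly 1.
#'
#' @param m a [ct_matrix()] with replicates collapsed and no missing cells.
#' @param efficiencies per-gene amplification factors: a single number applied
#'   to every gene, or a named numeric vector (gene -> factor). Factors must
#'   exceed 1. Default 2 (100% efficiency). Percentages from a standard curve
#'   convert as `1 + pct/100`.
#' @return An object of class `quantity_matrix` with fields `q` (gene x
#'   sample matrix), `genes`, `samples`, `groups`, `efficiencies`.
#' @examples
#' m <- ct_matrix(matrix(c(20, 21, 22), 1), "g", c("a", "b", "c"))
#' to_relative_quantity(m)$q  # 1, 0.5, 0.25
#' @export
to_relative_quantity <- function(m, efficiencies = 2) {
  stopifnot(inherits(m, "ct_matrix"))
  if (dim(m$ct)[3L] != 1L)
    stop("collapse replicates before computing quantities", call. = FALSE)
  ct <- m$ct[, , 1L, drop = TRUE]
  ct <- matrix(ct, nrow = length(m$genes), ncol = length(m$samples),
               dimnames = list(m$genes, m$samples))
  if (anyNA(ct)) {
    idx <- which(is.na(ct), arr.ind = TRUE)
    stop("missing Ct cell(s): ",
         paste0(m$genes[idx[, 1L]], "/", m$samples[idx[, 2L]],
                collapse = ", "), call. = FALSE)
  }
  eff <- .resolve_efficiencies(efficiencies, m$genes)
  q <- eff ^ (apply(ct, 1L, min) - ct)  # eff and row-min recycle per gene
  structure(list(q = q, genes = m$genes, samples = m$samples,
                 groups = m$groups, efficiencies = eff),
            class = "quantity_matrix")
}

.resolve_efficiencies <- function(efficiencies, genes) {
  if (length(efficiencies) == 1L && is.null(names(efficiencies)))
    efficiencies <- stats::setNames(rep(as.numeric(efficiencies),
                                        length(genes)), genes)
  miss <- setdiff(genes, names(efficiencies))
  if (length(miss))
    stop("no efficiency for gene(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  eff <- as.numeric(efficiencies[genes])
  if (any(!is.finite(eff) | eff <= 1))
    stop("amplification factors must be finite and > 1 ",
         "(2.0 means 100% efficiency)", call. = FALSE)
  stats::setNames(eff, genes)
}

#' @export
print.quantity_matrix <- function(x, ...) {
  cat(sprintf("<quantity_matrix> %d gene(s) x %d sample(s)\n",
              length(x$genes), length(x$samples)))
  cat("  efficiencies: ",
      paste(sprintf("%s=%.3g", utils::head(x$genes, 6L),
                    utils::head(x$efficiencies, 6L)), collapse = ", "),
      if (length(x$genes) > 6L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Convert efficiency percentages to amplification factors
#'
#' @param pct efficiency in percent (100 = perfect doubling).
#' @return Per-cycle amplification factor `1 + pct/100`.
#' @export
efficiency_factor <- function(pct) 1 + pct / 100
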