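#' Fit a dilution-series standard curve
#'
#' Ordinary least squares of mean Ct on log10 relative template amount. For
#' a valid series the slope is negative, and the amplification efficiency in
#' percent is
#' \deqn{E(\%) = (10^{-1/slope} - 1) \times 100,}
#' so a slope of \eqn{-1/\log_{10} 2 \approx -3.3219} means perfect doubling
#' (100%). A non-negative slope is flagged invalid and no efficiency is
#' reported.
#'
#' @param log10_amount log10 relative template amounts (>= 3 distinct
#'   dilution levels).
#' @param ct mean Ct at each dilution.
#' @return An object of class `standard_curve`: list with `points`,
#'   `slope` (cycles per log10 dilution), `intercept`, `r_squared`,
#'   `efficiency_pct`, `valid`.
#' @examples
#' sc <- fit_standard_curve(0:-4, 18 + (0:4) / log10(2))
#' sc$efficiency_pct  # 100
#' @export
fit_standard_curve <- function(log10_amount, ct) {
  if (length(log10_amount) != length(ct))
    stop("log10_amount and ct differ in length", call. = FALSE)
  keep <- !is.na(log10_amount) & !is.na(ct)
  log10_amount <- log10_amount[keep]
  ct <- ct[keep]
  if (length(unique(log10_amount)) < 3L)
    stop("need at least 3 distinct dilution levels", call. = FALSE)
  fit <- stats::lm(ct ~ log10_amount)
  slope <- unname(stats::coef(fit)[2L])
  tss <- sum((ct - mean(ct))^2)  # direct R^2: robust to an exact fit
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  valid <- is.finite(slope) && slope < 0
  structure(list(points = data.frame(log10_amount = log10_amount, ct = ct),
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 efficiency_pct = if (valid) slope_to_efficiency(slope)
                                  else NA_real_,
                 valid = valid),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve>\n")
  cat(sprintf("  slope %.4f cycles/log10, intercept %.2f, R^2 %.4f\n",
              x$slope, x$intercept, x$r_squared))
  if (x$valid)
    cat(sprintf("  efficiency %.2f%% (amplification factor %.4f)\n",
                x$efficiency_pct, efficiency_factor(x$efficiency_pct)))
  else cat("  INVALID: non-negative slope, efficiency not reported\n")
  invisible(x)
}

#' Convert between standard-curve slope and efficiency percentage
#'
#' `slope_to_efficiency` applies `E(%) = (10^(-1/slope) - 1) * 100`;
#' `efficiency_to_slope` is its exact inverse
#' `slope = -1 / log10(1 + E/100)`.
#'
#' @param slope standard-curve slope (cycles per log10 dilution, negative).
#' @param pct efficiency in percent.
#' @return The corresponding efficiency percentage / slope.
#' @export
slope_to_efficiency <- function(slope) (10^(-1 / slope) - 1) * 100

#' @rdname slope_to_efficiency
#' @export
efficiency_to_slope <- function(pct) -1 / log10(1 + pct / 100)

#' Multi-reference-gene normalization factor
#'
#' Per sample, the geometric mean of the relative quantities of the chosen
#' reference genes (min-Ct calibrated, efficiency corrected). Dividing a
#' target gene's relative quantity by this factor removes shared per-sample
#' effects such as cDNA input.
#'
#' @param m a [ct_matrix()], replicates collapsed, no missing cells for the
#'   reference genes.
#' @param rg_set non-empty character vector of reference genes in `m`.
#' @param efficiencies as in [to_relative_quantity()].
#' @return Named per-sample numeric vector of normalization factors.
#' @export
normalization_factor <- function(m, rg_set, efficiencies = 2) {
  stopifnot(inherits(m, "ct_matrix"))
  rg_set <- as.character(rg_set)
  if (!length(rg_set)) stop("rg_set is empty", call. = FALSE)
  unknown <- setdiff(rg_set, m$genes)
  if (length(unknown))
    stop("rg_set names unknown gene(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  q <- to_relative_quantity(subset_genes(m, rg_set), efficiencies)
  exp(colMeans(log(q$q)))
}

# gene-axis projection, internal companion of subset_samples()
subset_genes <- function(m, genes) {
  stopifnot(inherits(m, "ct_matrix"))
  unknown <- setdiff(genes, m$genes)
  if (length(unknown))
    stop("unknown gene(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  ct_matrix(m$ct[genes, , , drop = FALSE], genes, m$samples, m$groups)
}

#' Normalized relative expression of a target gene
#'
#' Efficiency-corrected ratio: each biological replicate's relative quantity
#' `E^(min Ct - Ct)` is divided by the sample's normalization factor; per
#' sample the mean and standard deviation over biological replicates are
#' reported. With `efficiency = 2` and a single reference gene this is the
#' classic 2^(-ddCt) computation up to the choice of calibrator; passing
#' `calibrator` rescales so that sample's mean expression is 1.
#'
#' @param target_ct numeric matrix sample x biological replicate of target
#'   Ct values (a vector is one replicate), with sample rownames or names
#'   matching `nf`.
#' @param nf named per-sample normalization factors from
#'   [normalization_factor()].
#' @param efficiency amplification factor of the target gene (default 2).
#' @param calibrator optional sample id whose mean expression is scaled to 1.
#' @return An object of class `normalized_expression`: data frame `sample`,
#'   `mean_expression`, `sd_expression`, `n_replicates`.
#' @export
relative_expression <- function(target_ct, nf, efficiency = 2,
                                calibrator = NULL) {
  if (is.vector(target_ct))
    target_ct <- matrix(target_ct, ncol = 1L,
                        dimnames = list(names(target_ct), NULL))
  if (is.null(rownames(target_ct)))
    stop("target_ct needs sample names", call. = FALSE)
  if (!setequal(rownames(target_ct), names(nf)))
    stop("samples of target and normalization factor differ: ",
         paste(union(setdiff(rownames(target_ct), names(nf)),
                     setdiff(names(nf), rownames(target_ct))),
               collapse = ", "), call. = FALSE)
  if (!is.finite(efficiency) || efficiency <= 1)
    stop("efficiency factor must be > 1", call. = FALSE)
  nf <- nf[rownames(target_ct)]
  q <- efficiency ^ (min(target_ct, na.rm = TRUE) - target_ct)
  expr <- q / nf  # nf recycles down columns (per sample)
  mean_e <- apply(expr, 1L, mean, na.rm = TRUE)
  sd_e <- apply(expr, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) NA_real_ else stats::sd(v)
  })
  scale <- 1
  if (!is.null(calibrator)) {
    if (!calibrator %in% rownames(target_ct))
      stop("calibrator sample '", calibrator, "' not found", call. = FALSE)
    scale <- mean_e[calibrator]
  }
  out <- data.frame(sample = rownames(target_ct),
                    mean_expression = mean_e / scale,
                    sd_expression = sd_e / scale,
                    n_replicates = apply(target_ct, 1L,
                                         function(v) sum(!is.na(v))),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("normalized_expression", "data.frame"))
}
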