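#' Published per-method stability ranks for an 11-gene loquat panel
#'
#' The package bundles the per-method stability ranks reported in a
#' published RT-qPCR reference-gene survey of loquat (*Eriobotrya
#' japonica*): 11 candidate genes evaluated by the delta-Ct, BestKeeper,
#' NormFinder and geNorm methods over five sample sets (fruit stages, floral
#' tissues, ovules and seeds, vegetative tissues, and all 23 samples).
#' Feeding these ranks through [geometric_mean_ranks()] reproduces that
#' survey's comprehensive ranking, which makes the table a convenient
#' worked example and regression anchor for the aggregation arithmetic.
#'
#' One printed cell of the source table is internally inconsistent (the
#' floral-tissue BestKeeper rank of *UGPase* does not match its printed
#' comprehensive score); the ranks are reproduced as printed.
#'
#' @return Named list of gene x method integer rank matrices, one per sample
#'   set, methods in the order `delta_ct`, `bestkeeper`, `normfinder`,
#'   `genorm`.
#' @examples
#' rk <- loquat_panel_ranks()
#' geometric_mean_ranks(rk[["All samples"]], subset = "All samples")
#' @export
loquat_panel_ranks <- function() {
  path <- system.file("extdata", "loquat_panel_ranks.csv",
                      package = "rgstab", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  methods <- c("delta_ct", "bestkeeper", "normfinder", "genorm")
  out <- lapply(unique(df$subset), function(s) {
    block <- df[df$subset == s, , drop = FALSE]
    rk <- as.matrix(block[, methods])
    storage.mode(rk) <- "integer"
    rownames(rk) <- block$gene
    rk
  })
  stats::setNames(out, unique(df$subset))
}

#' Published amplification efficiencies for the 11-gene loquat panel
#'
#' Standard-curve amplification efficiencies (percent) and regression
#' coefficients reported for the same published loquat panel as
#' [loquat_panel_ranks()]. Convert to per-cycle factors for
#' [to_relative_quantity()] with [efficiency_factor()] or load them
#' directly with [read_efficiencies()].
#'
#' @return Data frame with columns `gene`, `efficiency_pct`, `r_squared`.
#' @export
loquat_panel_efficiencies <- function() {
  path <- system.file("extdata", "loquat_panel_efficiencies.csv",
                      package = "rgstab", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
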