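#' Run all four stability methods on one sample subset
#'
#' Collapses replicates if needed, computes the delta-Ct, BestKeeper,
#' NormFinder and geNorm stability tables, aggregates them into the
#' comprehensive ranking, and summarizes expression.
#'
#' @param m a [ct_matrix()] already restricted to the subset's samples.
#' @param subset_name label attached to every table.
#' @param efficiencies as in [to_relative_quantity()].
#' @param normfinder_groups use the grouped NormFinder variant on `m$groups`
#'   (default `FALSE`; the ungrouped variant is the conservative default
#'   because grouped and ungrouped stability values differ).
#' @param bestkeeper_criterion `"sd"` or `"cv"`.
#' @param collapse replicate-collapse rule, `"mean"` or `"median"`.
#' @return List with `tables` (the four `stability_table`s, canonical order
#'   delta-Ct, BestKeeper, NormFinder, geNorm), `comprehensive`, `summary`.
#' @export
evaluate_subset <- function(m, subset_name = "all", efficiencies = 2,
                            normfinder_groups = FALSE,
                            bestkeeper_criterion = "sd",
                            collapse = "mean") {
  stopifnot(inherits(m, "ct_matrix"))
  if (dim(m$ct)[3L] > 1L) m <- collapse_replicates(m, collapse)
  q <- to_relative_quantity(m, efficiencies)
  tables <- list(
    delta_ct = deltact_stability(m, subset = subset_name),
    bestkeeper = bestkeeper_ranking(bestkeeper_stats(m),
                                    criterion = bestkeeper_criterion,
                                    subset = subset_name),
    normfinder = normfinder_stability(q, use_groups = normfinder_groups,
                                      subset = subset_name),
    genorm = genorm_ranking(q, subset = subset_name))
  list(tables = tables,
       comprehensive = comprehensive_report(unname(tables)),
       summary = summarize_expression(m))
}

#' Pipeline configuration
#'
#' @param input path of a Ct table readable by [read_ct_table()], or `NULL`
#'   to analyse a generated dataset from the default [synthetic_config()].
#' @param subsets named list of [subset_spec()]s, or a YAML path for
#'   [read_subsets()], or `NULL` for [default_subsets()] (requires the
#'   default sample sheet). An `All samples` subset covering every sample is
#'   always added if absent.
#' @param efficiencies per-gene amplification factors: number, named vector,
#'   or path of a CSV with columns `gene` and one of `efficiency_pct` /
#'   `factor`.
#' @param normfinder_groups,bestkeeper_criterion,collapse method switches,
#'   see [evaluate_subset()].
#' @param out_dir directory for the report bundle; `NULL` to skip writing.
#' @param seed seed used when `input` is `NULL`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, subsets = NULL, efficiencies = 2,
                            normfinder_groups = FALSE,
                            bestkeeper_criterion = "sd", collapse = "mean",
                            out_dir = NULL, seed = 1) {
  if (!is.null(input) && !file.exists(input))
    stop("input file not found: ", input, call. = FALSE)
  if (is.character(subsets) && length(subsets) == 1L) {
    if (!file.exists(subsets))
      stop("subset file not found: ", subsets, call. = FALSE)
    subsets <- read_subsets(subsets)
  }
  if (is.character(efficiencies) && length(efficiencies) == 1L) {
    if (!file.exists(efficiencies))
      stop("efficiency file not found: ", efficiencies, call. = FALSE)
    efficiencies <- read_efficiencies(efficiencies)
  }
  structure(list(input = input, subsets = subsets,
                 efficiencies = efficiencies,
                 normfinder_groups = isTRUE(normfinder_groups),
                 bestkeeper_criterion = match.arg(bestkeeper_criterion,
                                                  c("sd", "cv")),
                 collapse = match.arg(collapse, c("mean", "median")),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read per-gene amplification efficiencies from CSV
#'
#' @param path CSV with a `gene` column and either `efficiency_pct`
#'   (percent, 100 = doubling) or `factor` (per-cycle amplification factor).
#' @return Named numeric vector of amplification factors.
#' @export
read_efficiencies <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"gene" %in% names(df))
    stop("efficiency file needs a 'gene' column", call. = FALSE)
  f <- if ("factor" %in% names(df)) as.numeric(df$factor)
       else if ("efficiency_pct" %in% names(df))
         efficiency_factor(as.numeric(df$efficiency_pct))
       else stop("efficiency file needs 'efficiency_pct' or 'factor'",
                 call. = FALSE)
  stats::setNames(f, df$gene)
}

#' Run the full stability-evaluation pipeline
#'
#' Reads (or generates) a Ct dataset, evaluates every configured sample
#' subset with all four stability methods, aggregates each subset into a
#' comprehensive ranking, and optionally writes a report bundle: per subset
#' a long-format table (`<subset>_stability.csv`: method, subset, gene,
#' value, rank), the comprehensive ranking (`<subset>_comprehensive.csv`),
#' the expression summary (`<subset>_summary.csv`) and a human-readable
#' table (`<subset>_report.txt`) with one `value (rank)` cell per gene and
#' method; plus `run_log.txt` recording every defaulted analysis switch.
#' Identical config and input give a byte-identical bundle.
#'
#' @param config a [pipeline_config()].
#' @return List of per-subset results (as [evaluate_subset()]) plus
#'   attributes `config` and `files`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))
  if (is.null(config$input)) {
    m <- generate_ct_dataset(synthetic_config(), seed = config$seed)$ct
    say("input: default synthetic dataset (seed %d)", config$seed)
  } else {
    m <- read_ct_table(config$input)
    say("input: %s", config$input)
  }
  subsets <- config$subsets
  if (is.null(subsets)) {
    subsets <- default_subsets()
    if (all(unlist(lapply(subsets, `[[`, "samples")) %in% m$samples)) {
      say("subsets: default five-set design")
    } else {
      subsets <- list()
      say("subsets: none configured; evaluating all samples as one set")
    }
  }
  if (!any(vapply(subsets, function(s)
    setequal(s$samples, m$samples), logical(1))))
    subsets <- c(subsets,
                 list("All samples" = subset_spec("All samples", m$samples)))
  eff <- config$efficiencies
  say("efficiencies: %s",
      if (length(eff) == 1L && is.null(names(eff)))
        sprintf("uniform factor %.3f", eff)
      else sprintf("per-gene factors for %d gene(s)", length(eff)))
  say("replicate collapse: %s", config$collapse)
  say("normfinder grouping: %s",
      if (config$normfinder_groups) "grouped" else "ungrouped")
  say("bestkeeper criterion: %s", config$bestkeeper_criterion)
  results <- lapply(subsets, function(sp) {
    say("evaluating subset '%s' (%d samples)", sp$name, length(sp$samples))
    evaluate_subset(subset_samples(m, sp), subset_name = sp$name,
                    efficiencies = eff,
                    normfinder_groups = config$normfinder_groups,
                    bestkeeper_criterion = config$bestkeeper_criterion,
                    collapse = config$collapse)
  })
  names(results) <- vapply(subsets, `[[`, character(1), "name")
  files <- character()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(results))
      files <- c(files, .write_subset_bundle(results[[nm]], nm,
                                             config$out_dir))
    log_path <- file.path(config$out_dir, "run_log.txt")
    writeLines(log_lines, log_path)
    files <- c(files, log_path)
  }
  structure(results, config = config, files = files, log = log_lines)
}

.slug <- function(x) gsub("[^a-z0-9]+", "_", tolower(x))

.write_subset_bundle <- function(res, subset_name, out_dir) {
  slug <- .slug(subset_name)
  long <- do.call(rbind, lapply(res$tables, function(t)
    data.frame(method = attr(t, "method"), subset = attr(t, "subset"),
               gene = t$gene, value = t$value, rank = t$rank,
               stringsAsFactors = FALSE)))
  rownames(long) <- NULL
  paths <- file.path(out_dir, paste0(slug, c("_stability.csv",
                                             "_comprehensive.csv",
                                             "_summary.csv", "_report.txt")))
  utils::write.csv(long, paths[1L], row.names = FALSE, quote = FALSE)
  comp <- as.data.frame(res$comprehensive)
  utils::write.csv(comp, paths[2L], row.names = FALSE, quote = FALSE)
  utils::write.csv(res$summary, paths[3L], row.names = FALSE, quote = FALSE)
  writeLines(format_report_table(res, subset_name), paths[4L])
  paths
}

#' Format a subset's results as a value-(rank) text table
#'
#' One row per method plus the comprehensive row, one column per gene, each
#' cell `value (rank)` — the layout used in published candidate-gene
#' stability reports.
#'
#' @param res an [evaluate_subset()] result.
#' @param subset_name heading label.
#' @return Character vector of report lines.
#' @export
format_report_table <- function(res, subset_name = "all") {
  genes <- res$tables[[1L]]$gene
  method_label <- c(delta_ct = "Delta CT", bestkeeper = "BestKeeper",
                    normfinder = "NormFinder", genorm = "geNorm")
  rows <- lapply(res$tables, function(t) {
    v <- sprintf("%.2f (%d)", round_half_up(t$value, 2),
                 t$rank)[match(genes, t$gene)]
    c(method_label[[attr(t, "method")]], v)
  })
  comp <- res$comprehensive
  rows <- c(rows, list(c("Comprehensive",
                         sprintf("%.2f (%d)", comp$geomean,
                                 comp$final_rank)[match(genes, comp$gene)])))
  cells <- rbind(c("Method", genes), do.call(rbind, rows))
  widths <- apply(nchar(cells), 2L, max)
  lines <- apply(cells, 1L, function(r)
    paste(mapply(formatC, r, width = widths, flag = "-"), collapse = "  "))
  c(sprintf("== %s ==", subset_name), trimws(lines, "right"))
}
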