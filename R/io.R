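#' Read a Ct table from delimited text
#'
#' Two layouts are accepted. Wide: a `gene` column followed by one column per
#' sample-replicate named `<sample>_<replicate>` (a bare `<sample>` column is
#' read as replicate 1). Long: columns `gene`, `sample`, `replicate`, `ct`,
#' and optionally `group`. Cells that are empty or `NA` are recorded as
#' missing, never dropped. The delimiter is inferred from the file extension
#' (`.csv` comma, otherwise tab) unless given.
#'
#' @param path file to read.
#' @param format `"auto"` (default), `"wide"` or `"long"`.
#' @param sep field delimiter; `NULL` to infer from the extension.
#' @param groups optional group labels: a named character vector
#'   (sample -> group) or the path of a YAML sidecar mapping sample ids to
#'   group labels. A `group` column in long format takes effect without this.
#' @return A [ct_matrix()].
#' @export
read_ct_table <- function(path, format = c("auto", "wide", "long"),
                          sep = NULL, groups = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""), comment.char = "#")
  if (!nrow(df)) stop("no data rows in ", path, call. = FALSE)
  if (is.character(groups) && length(groups) == 1L && file.exists(groups))
    groups <- unlist(yaml::read_yaml(groups))
  if (format == "auto") {
    format <- if (all(c("gene", "sample", "ct") %in% names(df))) "long"
              else "wide"
  }
  m <- if (format == "long") .ct_from_long(df, path) else .ct_from_wide(df, path)
  if (!is.null(groups)) m <- ct_matrix(m$ct, m$genes, m$samples, groups)
  m
}

.check_numeric_ct <- function(values, raw, where) {
  bad <- which(!is.na(raw) & is.na(values))
  if (length(bad))
    stop("non-numeric Ct cell at ", where(bad[1L]), call. = FALSE)
}

.ct_from_wide <- function(df, path) {
  if (!"gene" %in% names(df))
    stop("malformed header in ", path, ": a 'gene' column is required",
         call. = FALSE)
  value_cols <- setdiff(names(df), "gene")
  if (!length(value_cols))
    stop("malformed header in ", path, ": no sample columns", call. = FALSE)
  samp <- sub("_[0-9]+$", "", value_cols)
  rep_id <- ifelse(grepl("_[0-9]+$", value_cols),
                   as.integer(sub("^.*_", "", value_cols)), 1L)
  samples <- unique(samp)
  n_rep <- max(rep_id)
  genes <- as.character(df$gene)
  ct <- array(NA_real_, dim = c(length(genes), length(samples), n_rep))
  for (j in seq_along(value_cols)) {
    raw <- df[[value_cols[j]]]
    v <- suppressWarnings(as.numeric(raw))
    .check_numeric_ct(v, raw, function(i)
      sprintf("row %d, column '%s' (value '%s')", i, value_cols[j], raw[i]))
    ct[, match(samp[j], samples), rep_id[j]] <- v
  }
  ct_matrix(ct, genes, samples)
}

.ct_from_long <- function(df, path) {
  need <- c("gene", "sample", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed header in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  genes <- unique(as.character(df$gene))
  samples <- unique(as.character(df$sample))
  reps <- sort(unique(as.integer(df$replicate)))
  raw <- df$ct
  v <- suppressWarnings(as.numeric(raw))
  .check_numeric_ct(v, raw, function(i)
    sprintf("row %d, column 'ct' (value '%s')", i, raw[i]))
  ct <- array(NA_real_, dim = c(length(genes), length(samples), length(reps)))
  idx <- cbind(match(as.character(df$gene), genes),
               match(as.character(df$sample), samples),
               match(as.integer(df$replicate), reps))
  ct[idx] <- v
  groups <- NULL
  if ("group" %in% names(df)) {
    g <- tapply(as.character(df$group), as.character(df$sample),
                function(x) unique(x)[1L])
    groups <- as.character(g[samples])
    names(groups) <- samples
  }
  ct_matrix(ct, genes, samples, groups)
}

#' Write a Ct matrix to delimited text
#'
#' Inverse of [read_ct_table()]. Wide output names replicate columns
#' `<sample>_<replicate>`; long output has columns
#' `gene,sample,replicate,ct` plus `group` when labels are present.
#'
#' @param m a [ct_matrix()].
#' @param path destination file; `.csv` writes commas, anything else tabs.
#' @param format `"wide"` (default) or `"long"`.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(m, path, format = c("wide", "long")) {
  stopifnot(inherits(m, "ct_matrix"))
  format <- match.arg(format)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- dim(m$ct)
  if (format == "wide") {
    cols <- list(gene = m$genes)
    for (s in seq_len(d[2L])) for (r in seq_len(d[3L]))
      cols[[if (d[3L] == 1L) m$samples[s]
            else paste0(m$samples[s], "_", r)]] <- m$ct[, s, r]
    df <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    grid <- expand.grid(g = seq_len(d[1L]), s = seq_len(d[2L]),
                        r = seq_len(d[3L]))
    df <- data.frame(gene = m$genes[grid$g], sample = m$samples[grid$s],
                     replicate = grid$r, ct = m$ct[as.matrix(grid)],
                     stringsAsFactors = FALSE)
    if (!is.null(m$groups)) df$group <- m$groups[df$sample]
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sample-subset definitions from YAML
#'
#' The file maps subset names to lists of sample ids:
#' \preformatted{
#' Fruits: [Fr1, Fr2, Fr3]
#' All samples: [Fr1, Fr2, Fr3, Rt]
#' }
#'
#' @param path YAML file.
#' @return A named list of [subset_spec()] objects.
#' @export
read_subsets <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!length(raw)) stop("no subsets defined in ", path, call. = FALSE)
  specs <- lapply(names(raw), function(nm)
    subset_spec(nm, unlist(raw[[nm]])))
  names(specs) <- names(raw)
  specs
}

#' Default five-subset design of the bundled multi-tissue sample sheet
#'
#' Returns the subset layout used by the synthetic default dataset: five
#' fruit developmental stages, seven floral tissues, six ovule/seed stages,
#' five vegetative tissues, and their union. The sample names are a synthetic
#' stand-in for a typical multi-tissue RT-qPCR survey of a fruit tree.
#'
#' @return Named list of [subset_spec()]s: `Fruits`, `Floral tissues`,
#'   `Ovules and seeds`, `Vegetative tissues`, `All samples`.
#' @export
default_subsets <- function() {
  sets <- list(
    "Fruits" = paste0("Fr", 1:5),
    "Floral tissues" = c("If", "Pe", "An", "St", "Fi", "Se", "Fl"),
    "Ovules and seeds" = c("Ov1", "Ov2", "Ov3", "Sd1", "Sd2", "Sd3"),
    "Vegetative tissues" = c("Rt", "Yst", "Mst", "Ml", "Ca"))
  sets[["All samples"]] <- unname(unlist(sets))
  lapply(stats::setNames(names(sets), names(sets)),
         function(nm) subset_spec(nm, sets[[nm]]))
}
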