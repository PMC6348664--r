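#' Configuration for the synthetic Ct-data generator
#'
#' Describes a simulated RT-qPCR candidate-panel experiment. The generative
#' model on the cycle scale is
#' \deqn{Ct_{gsr} = baseline_g + shift_{gs} + load_s + noise_{gsr},}
#' where `shift ~ N(0, instability_sd_g)` is the gene's tissue-dependent
#' expression shift (drawn per gene x group when group labels exist, so an
#' "unstable" gene moves coherently within a tissue class, else per gene x
#' sample), `load ~ N(0, loading_sd)` is the per-sample loading/cDNA-input
#' effect shared by all genes, and `noise ~ N(0, tech_sd)` is technical
#' replicate noise. A gene with `instability_sd = 0` is a perfect reference
#' gene up to technical noise.
#'
#' Defaults mirror a typical multi-tissue candidate-gene survey of a fruit
#' tree: an 11-gene panel measured over 23 samples in five subsets (fruit
#' stages, floral tissues, ovules/seeds, vegetative tissues, all) with 4
#' technical replicates, baseline Ct spread over 17-25 cycles, loading SD
#' 1.0 cycles, technical SD 0.15 cycles, and per-gene instability SDs
#' spanning stable (0.15) to clearly unstable (1.2).
#'
#' @param n_genes,n_samples,n_replicates panel dimensions.
#' @param genes,samples identifiers; defaulted when dimensions match the
#'   bundled 11 x 23 design, else auto-named.
#' @param groups optional named character vector sample -> group; defaults
#'   to the five-subset tissue classes for the bundled design.
#' @param baseline_ct per-gene baseline cycles (recycled).
#' @param instability_sd per-gene tissue-shift SD, cycles (recycled).
#' @param loading_sd shared per-sample effect SD, cycles.
#' @param tech_sd technical replicate SD, cycles.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 11, n_samples = 23, n_replicates = 4,
                             genes = NULL, samples = NULL, groups = NULL,
                             baseline_ct = NULL, instability_sd = NULL,
                             loading_sd = 1.0, tech_sd = 0.15) {
  n_genes <- as.integer(n_genes)
  n_samples <- as.integer(n_samples)
  n_replicates <- as.integer(n_replicates)
  if (n_genes < 1L || n_samples < 1L || n_replicates < 1L)
    stop("dimensions must be at least 1", call. = FALSE)
  default_design <- is.null(genes) && is.null(samples) &&
    n_genes == 11L && n_samples == 23L
  if (is.null(genes))
    genes <- if (default_design) default_panel_genes()
             else sprintf("gene%02d", seq_len(n_genes))
  if (is.null(samples)) {
    if (default_design) {
      subs <- default_subsets()
      samples <- subs[["All samples"]]$samples
      if (is.null(groups)) {
        tissue <- setdiff(names(subs), "All samples")
        groups <- stats::setNames(rep(tissue, vapply(
          tissue, function(t) length(subs[[t]]$samples), integer(1))),
          unlist(lapply(tissue, function(t) subs[[t]]$samples)))
        groups <- groups[samples]
      }
    } else samples <- sprintf("s%02d", seq_len(n_samples))
  }
  if (length(genes) != n_genes || length(samples) != n_samples)
    stop("gene/sample names disagree with the declared dimensions",
         call. = FALSE)
  if (is.null(baseline_ct))
    baseline_ct <- seq(17, 25, length.out = n_genes)
  if (is.null(instability_sd))
    instability_sd <- rep_len(c(0.15, 0.2, 0.25, 0.3, 0.35, 0.4, 0.5,
                                0.7, 0.9, 1.0, 1.2), n_genes)
  baseline_ct <- rep_len(as.numeric(baseline_ct), n_genes)
  instability_sd <- rep_len(as.numeric(instability_sd), n_genes)
  if (any(instability_sd < 0) || loading_sd < 0 || tech_sd < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  if (any(baseline_ct <= 0)) stop("baseline Ct must be > 0", call. = FALSE)
  structure(list(n_genes = n_genes, n_samples = n_samples,
                 n_replicates = n_replicates, genes = as.character(genes),
                 samples = as.character(samples), groups = groups,
                 baseline_ct = stats::setNames(baseline_ct, genes),
                 instability_sd = stats::setNames(instability_sd, genes),
                 loading_sd = loading_sd, tech_sd = tech_sd),
            class = "synthetic_config")
}

#' Default 11-gene candidate panel
#'
#' The classic plant candidate reference genes used by the bundled example
#' data and the default generator design.
#' @return Character vector of 11 gene symbols.
#' @export
default_panel_genes <- function() {
  c("RPL4", "RPL18", "HIS3", "TUA3", "SAMDC", "TIP41", "UGPase",
    "18S", "GAPDH", "PIP2", "ACT")
}

#' Generate a synthetic Ct dataset with known ground truth
#'
#' Draws a Ct dataset from the model described in [synthetic_config()],
#' fully reproducible from `seed`. The returned ground truth carries the
#' realized loading effects, tissue shifts and the true per-gene instability
#' SDs, so parameter-recovery experiments can compare a method's inferred
#' stability order with the truth.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed fixing the full output.
#' @return List with `ct` (a [ct_matrix()]) and `truth` (class
#'   `ground_truth`: `instability_sd`, `true_order` — genes sorted most to
#'   least stable, ties in input order — `loading`, `shifts`,
#'   `target_profile` once spiked).
#' @export
generate_ct_dataset <- function(config = synthetic_config(), seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  g <- config$n_genes; s <- config$n_samples; r <- config$n_replicates
  load_s <- stats::rnorm(s, 0, config$loading_sd)
  if (!is.null(config$groups)) {
    grp <- as.character(config$groups[config$samples])
    lev <- unique(grp)
    shift_grp <- matrix(stats::rnorm(g * length(lev)), g, length(lev)) *
      config$instability_sd
    shifts <- shift_grp[, match(grp, lev), drop = FALSE]
  } else {
    shifts <- matrix(stats::rnorm(g * s), g, s) * config$instability_sd
  }
  dimnames(shifts) <- list(config$genes, config$samples)
  noise <- array(stats::rnorm(g * s * r, 0, config$tech_sd), dim = c(g, s, r))
  ct <- array(config$baseline_ct, dim = c(g, s, r)) +
    array(shifts, dim = c(g, s, r)) +
    array(rep(load_s, each = g), dim = c(g, s, r)) + noise
  truth <- structure(
    list(instability_sd = config$instability_sd,
         true_order = config$genes[order(config$instability_sd)],
         loading = stats::setNames(load_s, config$samples),
         shifts = shifts, target_profile = NULL),
    class = "ground_truth")
  list(ct = ct_matrix(ct, config$genes, config$samples, config$groups),
       truth = truth)
}

#' Spike a target gene with a programmed expression profile
#'
#' Appends a gene whose true log2 expression follows `profile` (higher
#' expression = proportionally lower Ct), subject to the same per-sample
#' loading effects recorded in the ground truth and fresh technical noise.
#' Used to validate normalization end-to-end: dividing the spiked gene's
#' quantities by a normalization factor built from stable reference genes
#' must recover the programmed profile.
#'
#' @param m a [ct_matrix()] from [generate_ct_dataset()].
#' @param truth the matching `ground_truth`.
#' @param profile per-sample true log2 expression (named or in sample order).
#' @param name gene name of the spiked target (must be new).
#' @param baseline_ct target baseline cycles at profile 0.
#' @param tech_sd technical noise SD of the target, cycles.
#' @param seed seed for the target's technical noise.
#' @return List with `ct` (matrix including the target) and updated `truth`
#'   (`target_profile` filled in).
#' @export
spike_target <- function(m, truth, profile, name = "target",
                         baseline_ct = 24, tech_sd = 0.15, seed = 1) {
  stopifnot(inherits(m, "ct_matrix"), inherits(truth, "ground_truth"))
  if (name %in% m$genes)
    stop("gene '", name, "' already exists", call. = FALSE)
  if (!is.null(names(profile))) {
    miss <- setdiff(m$samples, names(profile))
    if (length(miss))
      stop("profile missing sample(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    profile <- profile[m$samples]
  } else if (length(profile) != length(m$samples)) {
    stop("profile length differs from sample count", call. = FALSE)
  }
  d <- dim(m$ct)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(as.integer(seed))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  noise <- matrix(stats::rnorm(d[2L] * d[3L], 0, tech_sd), d[2L], d[3L])
  target <- baseline_ct - as.numeric(profile) +
    truth$loading[m$samples] + noise  # recycles per sample down rows
  ct <- array(NA_real_, dim = c(d[1L] + 1L, d[2L], d[3L]))
  ct[seq_len(d[1L]), , ] <- m$ct
  ct[d[1L] + 1L, , ] <- target
  truth$target_profile <- stats::setNames(as.numeric(profile), m$samples)
  list(ct = ct_matrix(ct, c(m$genes, name), m$samples, m$groups),
       truth = truth)
}
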