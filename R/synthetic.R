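#' Configuration for the synthetic irradiation-study generator
#'
#' The defaults emulate the design of a seven-dose, five-donor blood
#' irradiation study: dose levels 0, 0.005, 0.01, 0.025, 0.05, 0.1 and 0.5 Gy
#' with 18, 16, 18, 18, 17 and 16 samples respectively (121 samples in
#' total). Gene expression is per-gene Gaussian on the log scale; member
#' genes of designated "responsive" pathways receive coordinated
#' dose-dependent mean shifts. Low-responsive pathways shift only at
#' low-class doses (0 < d <= 0.1 Gy, shift curve reaching its full size at
#' 0.1 Gy) and high-responsive pathways only at high-class doses, so the two
#' contrasts have distinct planted signal.
#'
#' @param n_genes Number of genes (default 10875, the probe count of the
#'   emulated study after detection filtering).
#' @param n_pathways Number of pathways (default 343, the number of KEGG
#'   maps with measured genes in the emulated study).
#' @param pathway_size_range Integer min/max pathway sizes, uniform draw
#'   (default 20-60 genes, typical of measured KEGG gene sets).
#' @param gene_overlap_allowed May pathways share genes? If `FALSE`, the sum
#'   of drawn sizes must not exceed `n_genes`.
#' @param dose_levels_gy Ordered dose levels in Gy.
#' @param samples_per_dose Sample counts aligned 1:1 with `dose_levels_gy`.
#' @param low_responsive Pathway ids shifted at low doses; `NULL` picks the
#'   first `n_low_responsive` generated pathways.
#' @param high_responsive Pathway ids shifted at high doses; `NULL` picks the
#'   next `n_high_responsive` pathways (disjoint from the low set).
#' @param n_low_responsive,n_high_responsive Counts used when the explicit id
#'   sets are `NULL`.
#' @param effect_size Mean shift at full effect, in units of the gene's
#'   baseline sd.
#' @param effect_curve Shape of the dose-effect curve `c(d)` with `c(0) = 0`,
#'   monotone non-decreasing, and `c` = 1 at the largest dose of the
#'   responsive class: `"saturating"` (default) `c(d) = d / (d + d_half)`
#'   rescaled, `"linear"`, or `"step"`.
#' @param d_half Half-saturation dose (Gy) for the saturating curve.
#' @param noise_sd Multiplier on the per-gene baseline sd.
#' @param baseline_mean_mu,baseline_mean_sd Per-gene baseline means are drawn
#'   `Normal(baseline_mean_mu, baseline_mean_sd)`.
#' @param baseline_sd_range Per-gene baseline sds are drawn uniformly in this
#'   range.
#' @param n_donors Number of donors (assigned cyclically within dose groups).
#' @param donor_effect_sd Sd of additive per-donor intercepts; 0 (default)
#'   disables donor effects.
#' @param na_fraction Fraction of cells set to not-detected (`NA`); 0 by
#'   default, 0.01 is a typical setting to exercise the detection filter.
#' @param seed Integer seed; all generation is reproducible given the config.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 10875,
                             n_pathways = 343,
                             pathway_size_range = c(20L, 60L),
                             gene_overlap_allowed = TRUE,
                             dose_levels_gy = c(0, 0.005, 0.01, 0.025, 0.05, 0.1, 0.5),
                             samples_per_dose = c(18L, 16L, 18L, 18L, 17L, 18L, 16L),
                             low_responsive = NULL,
                             high_responsive = NULL,
                             n_low_responsive = 3L,
                             n_high_responsive = 3L,
                             effect_size = 0.8,
                             effect_curve = c("saturating", "linear", "step"),
                             d_half = 0.05,
                             noise_sd = 1,
                             baseline_mean_mu = 7,
                             baseline_mean_sd = 2,
                             baseline_sd_range = c(0.3, 1.0),
                             n_donors = 5L,
                             donor_effect_sd = 0,
                             na_fraction = 0,
                             seed = 1L) {
  effect_curve <- match.arg(effect_curve)
  if (length(samples_per_dose) != length(dose_levels_gy))
    stop("samples_per_dose must align 1:1 with dose_levels_gy")
  if (any(dose_levels_gy < 0)) stop("dose levels must be >= 0 Gy")
  if (any(samples_per_dose < 1)) stop("each dose level needs >= 1 sample")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (na_fraction < 0 || na_fraction >= 1) stop("na_fraction must be in [0, 1)")
  structure(list(
    n_genes = as.integer(n_genes), n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    gene_overlap_allowed = isTRUE(gene_overlap_allowed),
    dose_levels_gy = dose_levels_gy,
    samples_per_dose = as.integer(samples_per_dose),
    low_responsive = low_responsive, high_responsive = high_responsive,
    n_low_responsive = as.integer(n_low_responsive),
    n_high_responsive = as.integer(n_high_responsive),
    effect_size = effect_size, effect_curve = effect_curve, d_half = d_half,
    noise_sd = noise_sd,
    baseline_mean_mu = baseline_mean_mu, baseline_mean_sd = baseline_mean_sd,
    baseline_sd_range = baseline_sd_range,
    n_donors = as.integer(n_donors), donor_effect_sd = donor_effect_sd,
    na_fraction = na_fraction, seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate a synthetic gene-set collection
#'
#' Draws `n_pathways` member sets with sizes uniform in
#' `pathway_size_range`. Without overlap, genes are partitioned; with overlap
#' (default) each pathway samples its members independently.
#'
#' @param cfg A [synthetic_config()].
#' @return A `gene_set_collection`; reproducible under `cfg$seed`.
#' @export
generate_gene_sets <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  withr::with_seed(cfg$seed, {
    size_choices <- seq(cfg$pathway_size_range[1L], cfg$pathway_size_range[2L])
    sizes <- size_choices[sample.int(length(size_choices), cfg$n_pathways,
                                     replace = TRUE)]
    if (!cfg$gene_overlap_allowed && sum(sizes) > cfg$n_genes) {
      stop("cannot draw ", cfg$n_pathways, " disjoint pathways totalling ",
           sum(sizes), " genes from ", cfg$n_genes, " genes")
    }
    ids <- sprintf("pw%03d", seq_len(cfg$n_pathways))
    if (cfg$gene_overlap_allowed) {
      members <- lapply(sizes, function(s) sample(genes, s))
    } else {
      pool <- sample(genes, sum(sizes))
      ends <- cumsum(sizes)
      starts <- c(1L, utils::head(ends, -1L) + 1L)
      members <- Map(function(a, b) pool[a:b], starts, ends)
    }
    names(members) <- ids
    gene_set_collection(members)
  })
}

# dose-effect curve, normalized so c(d_max_class) = 1 within the responsive
# dose class; c(0) = 0 and monotone non-decreasing
effect_curve_value <- function(d, d_max, shape, d_half) {
  if (d_max <= 0) return(rep(0, length(d)))
  v <- switch(shape,
    linear = d / d_max,
    saturating = (d / (d + d_half)) / (d_max / (d_max + d_half)),
    step = as.numeric(d > 0)
  )
  v[d <= 0] <- 0
  v
}

#' Generate a synthetic dose-structured expression study
#'
#' Baseline expression of gene k is `Normal(mu_k, sigma_k)` with per-gene
#' parameters drawn once. Member genes of responsive pathways get a mean
#' shift of `effect_size * sigma_k * c(dose)` at the doses of their
#' responsive class (low-responsive at low doses, high-responsive at high
#' doses). A gene in several responsive pathways of the same class is
#' shifted once, not additively.
#'
#' @param cfg A [synthetic_config()].
#' @param gs A `gene_set_collection`, e.g. from [generate_gene_sets()].
#' @return List with `expression` (genes x samples matrix), `annotation`
#'   (data frame: sample_id, donor_id, dose_gy, dose_class) and `truth`
#'   (list: `low_responsive`, `high_responsive` pathway ids, and `shift`, the
#'   genes x dose-levels matrix of planted mean shifts).
#' @export
generate_dataset <- function(cfg, gs) {
  stopifnot(inherits(cfg, "synthetic_config"))
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  low_ids <- cfg$low_responsive
  high_ids <- cfg$high_responsive
  if (is.null(low_ids))
    low_ids <- utils::head(names(gs), cfg$n_low_responsive)
  if (is.null(high_ids))
    high_ids <- utils::head(setdiff(names(gs), low_ids), cfg$n_high_responsive)
  unknown <- setdiff(c(low_ids, high_ids), names(gs))
  if (length(unknown))
    stop("responsive pathway id(s) not in collection: ",
         paste(unknown, collapse = ", "))

  doses <- rep(cfg$dose_levels_gy, cfg$samples_per_dose)
  n <- length(doses)
  ann <- data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    donor_id = sprintf("donor%d", rep_len(seq_len(cfg$n_donors), n)),
    dose_gy = doses,
    stringsAsFactors = FALSE
  )
  ann <- assign_dose_class(ann)

  cls <- as.character(ann$dose_class)
  low_doses <- cfg$dose_levels_gy[cfg$dose_levels_gy > 0 & cfg$dose_levels_gy <= 0.1]
  high_doses <- cfg$dose_levels_gy[cfg$dose_levels_gy > 0.1]
  low_genes <- genes %in% unique(unlist(gs[low_ids], use.names = FALSE))
  high_genes <- genes %in% unique(unlist(gs[high_ids], use.names = FALSE))

  withr::with_seed(cfg$seed + 1L, {
    mu <- stats::rnorm(cfg$n_genes, cfg$baseline_mean_mu, cfg$baseline_mean_sd)
    sigma <- stats::runif(cfg$n_genes, cfg$baseline_sd_range[1L],
                          cfg$baseline_sd_range[2L]) * cfg$noise_sd
    vals <- mu + sigma * matrix(stats::rnorm(cfg$n_genes * n), cfg$n_genes, n)

    # planted shifts: shift[g, d] in expression units at dose level d
    shift <- matrix(0, cfg$n_genes, length(cfg$dose_levels_gy),
                    dimnames = list(genes, as.character(cfg$dose_levels_gy)))
    for (j in seq_along(cfg$dose_levels_gy)) {
      d <- cfg$dose_levels_gy[j]
      if (d > 0 && d <= 0.1 && length(low_doses)) {
        cv <- effect_curve_value(d, max(low_doses), cfg$effect_curve, cfg$d_half)
        shift[low_genes, j] <- cfg$effect_size * sigma[low_genes] * cv
      }
      if (d > 0.1 && length(high_doses)) {
        cv <- effect_curve_value(d, max(high_doses), cfg$effect_curve, cfg$d_half)
        shift[high_genes, j] <- cfg$effect_size * sigma[high_genes] * cv
      }
    }
    dose_idx <- match(doses, cfg$dose_levels_gy)
    vals <- vals + shift[, dose_idx, drop = FALSE]

    if (cfg$donor_effect_sd > 0) {
      donor_fx <- stats::rnorm(cfg$n_donors, 0, cfg$donor_effect_sd)
      vals <- vals + matrix(donor_fx[rep_len(seq_len(cfg$n_donors), n)],
                            cfg$n_genes, n, byrow = TRUE)
    }
    if (cfg$na_fraction > 0) {
      nd <- which(stats::runif(length(vals)) < cfg$na_fraction)
      vals[nd] <- NA_real_
    }
    dimnames(vals) <- list(genes, ann$sample_id)
    list(
      expression = vals,
      annotation = ann,
      truth = list(low_responsive = low_ids, high_responsive = high_ids,
                   shift = shift)
    )
  })
}

#' Write a complete synthetic study directory
#'
#' Emits `expression.tsv`, `annotations.tsv`, `pathways.gmt`, `truth.json`
#' and a `manifest.json` holding the generating configuration.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_synthetic_study <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gs <- generate_gene_sets(cfg)
  ds <- generate_dataset(cfg, gs)
  write_expression_matrix(ds$expression, file.path(dir, "expression.tsv"))
  write_sample_annotation(ds$annotation, file.path(dir, "annotations.tsv"))
  write_gmt(gs, file.path(dir, "pathways.gmt"))
  jsonlite::write_json(
    list(low_responsive = ds$truth$low_responsive,
         high_responsive = ds$truth$high_responsive),
    file.path(dir, "truth.json"))
  jsonlite::write_json(unclass(cfg)[!vapply(cfg, is.null, TRUE)],
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
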