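# Dose-structure experiments: per-dose contrasts against the zero-dose
# reference, progressive low-dose inclusion, ranked-list intersection
# curves, the pooled low-dose joint analysis, and dose profiles of a fitted
# model. All return long-format plot-ready data frames.

# run the full LLR scoring chain for an explicit two-group contrast
contrast_analysis <- function(m, samples_ref, samples_alt, gs,
                              labels = c("REF", "ALT"),
                              subset = c("alt", "all"),
                              sigma_floor = 1e-6) {
  subset <- match.arg(subset)
  model <- fit_gaussians_groups(m, samples_ref, samples_alt, labels,
                                sigma_floor)
  pooled <- m[, c(samples_ref, samples_alt), drop = FALSE]
  llr <- compute_llr(model, pooled)
  llr <- normalize_llr(llr, model)
  # class orientation by explicit membership: alt-group entries negated
  llr[, samples_alt] <- -llr[, samples_alt, drop = FALSE]
  attr(llr, "class_oriented") <- TRUE
  subset_ids <- if (subset == "alt") samples_alt else colnames(llr)
  tab <- aggregated_differential_score(llr, gs, subset_ids, sigma_floor)
  rank_pathways(tab)
}

#' Per-dose pathway scoring against the zero-dose reference
#'
#' For every non-zero dose level, fits a zero-vs-that-dose contrast and
#' computes every pathway's aggregated differential activity score over that
#' dose group's samples.
#'
#' @param m Expression matrix.
#' @param ann Sample annotation data frame.
#' @param gs A `gene_set_collection` (restricted internally).
#' @param doses Non-zero dose levels to score; default all present in `ann`.
#' @return Long data frame: `dose_gy`, `pathway_id`, `name`,
#'   `aggregated_score`, `pathway_t`, `rank`, `n_samples`.
#' @export
per_dose_scores <- function(m, ann, gs, doses = NULL) {
  gs <- restrict_gene_sets(gs, m)
  zero <- intersect(ann$sample_id[ann$dose_gy == 0], colnames(m))
  present <- sort(unique(ann$dose_gy[ann$dose_gy > 0]))
  if (is.null(doses)) doses <- present
  missing_d <- setdiff(doses, present)
  if (length(missing_d))
    stop("dose(s) absent from annotations: ",
         paste(missing_d, collapse = ", "))
  out <- lapply(doses, function(d) {
    alt <- intersect(ann$sample_id[ann$dose_gy == d], colnames(m))
    tab <- contrast_analysis(m, zero, alt, gs,
                             labels = c("ZERO", paste0(d, "Gy")))
    data.frame(dose_gy = d, tab[, c("pathway_id", "name", "aggregated_score",
                                    "pathway_t", "rank", "n_samples")],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Progressive inclusion of low-dose groups
#'
#' Re-runs the zero-vs-low contrast on growing unions of low-dose groups.
#' Step i pools the first i low-dose groups in the requested dose order
#' (ascending starts at the smallest dose; descending at the largest low
#' dose); the final step of either order uses the identical full union.
#'
#' @inheritParams per_dose_scores
#' @param order `"ascending"` or `"descending"`.
#' @return Long data frame: `step`, `doses_included` (slash-separated),
#'   `n_samples`, `pathway_id`, `name`, `aggregated_score`, `pathway_t`,
#'   `rank`.
#' @export
progressive_inclusion <- function(m, ann, gs,
                                  order = c("ascending", "descending")) {
  order <- match.arg(order)
  gs <- restrict_gene_sets(gs, m)
  zero <- intersect(ann$sample_id[ann$dose_class == "ZERO"], colnames(m))
  low_doses <- sort(unique(ann$dose_gy[ann$dose_class == "LOW"]),
                    decreasing = (order == "descending"))
  if (length(low_doses) == 0L) stop("no low-dose samples present")
  out <- lapply(seq_along(low_doses), function(i) {
    dset <- low_doses[seq_len(i)]
    alt <- intersect(ann$sample_id[ann$dose_gy %in% dset], colnames(m))
    tab <- contrast_analysis(m, zero, alt, gs, labels = c("ZERO", "LOW"))
    data.frame(step = i, doses_included = paste(sort(dset), collapse = "/"),
               n_samples = length(alt),
               tab[, c("pathway_id", "name", "aggregated_score",
                       "pathway_t", "rank")],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Top-k intersection curve of ranked pathway lists
#'
#' `count(k)` is the size of the intersection of the top-k prefixes of all
#' supplied ranked lists. Counts are non-decreasing in k and never exceed k.
#'
#' @param lists A list of two or more ranked id vectors (best first), ranked
#'   tables from [rank_pathways()], or analysis results carrying `$table`.
#' @param k_max Largest prefix length; must not exceed the shortest list.
#' @return Data frame: `k`, `count`.
#' @export
topk_intersection <- function(lists, k_max) {
  ids <- lapply(lists, function(x) {
    if (is.character(x)) x else ranked_ids(x)
  })
  if (length(ids) < 2L) stop("need >= 2 ranked lists")
  if (any(vapply(ids, anyDuplicated, 0L) > 0L))
    stop("ranked lists must not contain duplicate ids")
  shortest <- min(lengths(ids))
  if (k_max > shortest)
    stop("k_max (", k_max, ") exceeds shortest list length (", shortest, ")")
  counts <- vapply(seq_len(k_max), function(k) {
    length(Reduce(intersect, lapply(ids, utils::head, k)))
  }, 0L)
  data.frame(k = seq_len(k_max), count = counts)
}

#' Low-dose joint analysis
#'
#' Pools every LOW-class sample into a single contrast against the ZERO
#' group and returns the standard ranked table — identical to
#' [llr_pathway_analysis()] with contrast `c("ZERO", "LOW")`.
#'
#' @inheritParams per_dose_scores
#' @return The ranked analysis list from [llr_pathway_analysis()].
#' @export
low_dose_joint_analysis <- function(m, ann, gs) {
  llr_pathway_analysis(m, ann, gs, contrast = c("ZERO", "LOW"))
}

#' Dose profiles of pathway activity under a fixed contrast model
#'
#' Fits the model on the stated contrast (default zero-vs-low), then applies
#' it unchanged — normalized LLRs summed over member genes, no class
#' orientation — to the samples of every dose level, giving per-dose
#' distributions of the accumulated LLR activity `S_j` for the requested
#' pathways.
#'
#' @inheritParams per_dose_scores
#' @param pathway_ids Pathways to profile.
#' @param model_contrast Dose-class pair the model is fitted on.
#' @return List with `samples` (long data frame: `pathway_id`, `sample_id`,
#'   `dose_gy`, `activity`) and `summary` (per pathway per dose: mean,
#'   median, n).
#' @export
dose_profile <- function(m, ann, gs, pathway_ids,
                         model_contrast = c("ZERO", "LOW")) {
  gs <- restrict_gene_sets(gs, m)
  unknown <- setdiff(pathway_ids, names(gs))
  if (length(unknown))
    stop("unknown pathway id(s): ", paste(unknown, collapse = ", "))
  model <- fit_gene_gaussians(m, ann, model_contrast)
  keep <- intersect(ann$sample_id, colnames(m))
  llr <- normalize_llr(compute_llr(model, m[, keep, drop = FALSE]), model)
  S <- pathway_activity_scores(llr, gs[pathway_ids])
  long <- data.frame(
    pathway_id = rep(pathway_ids, each = length(keep)),
    sample_id = rep(keep, times = length(pathway_ids)),
    dose_gy = rep(ann$dose_gy[match(keep, ann$sample_id)],
                  times = length(pathway_ids)),
    activity = as.vector(t(S)),
    stringsAsFactors = FALSE
  )
  summ <- do.call(rbind, lapply(split(long, long[c("pathway_id", "dose_gy")]),
    function(g) data.frame(pathway_id = g$pathway_id[1L],
                           dose_gy = g$dose_gy[1L],
                           mean = mean(g$activity),
                           median = stats::median(g$activity),
                           n = nrow(g), stringsAsFactors = FALSE)))
  summ <- summ[order(summ$pathway_id, summ$dose_gy), , drop = FALSE]
  rownames(summ) <- NULL
  list(samples = long, summary = summ)
}
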