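#' Fit per-gene two-phenotype Gaussian models and LLR normalization constants
#'
#' For each gene, class-conditional Gaussian densities are estimated by the
#' sample mean and the population (ddof = 0) standard deviation of the
#' class's samples; the expectation-style normalization constants
#' `E[L_k]` and `sqrt(E[(L_k - E L_k)^2])` are population moments of the raw
#' LLR over the pooled contrast samples (the same samples used for the
#' fits). Standard deviations below `sigma_floor` are floored to keep
#' degenerate (near-constant) genes finite.
#'
#' @param m Expression matrix, genes in rows.
#' @param ann Sample annotation data frame with `sample_id` and `dose_class`.
#' @param contrast Length-2 character vector of dose classes, e.g.
#'   `c("ZERO", "LOW")`; the first is phenotype 1 (LLR numerator).
#' @param sigma_floor Lower bound for all standard deviations.
#' @return A `gene_llr_model`: list with `table` (per-gene parameters),
#'   `classes`, `samples1`, `samples2`, `sigma_floor`.
#' @export
fit_gene_gaussians <- function(m, ann, contrast, sigma_floor = 1e-6) {
  stopifnot(length(contrast) == 2L)
  s1 <- intersect(ann$sample_id[ann$dose_class == contrast[1L]], colnames(m))
  s2 <- intersect(ann$sample_id[ann$dose_class == contrast[2L]], colnames(m))
  fit_gaussians_groups(m, s1, s2, contrast, sigma_floor)
}

# group-level worker: explicit sample-id sets, arbitrary class labels
fit_gaussians_groups <- function(m, samples1, samples2, classes,
                                 sigma_floor = 1e-6) {
  if (length(samples1) < 2L || length(samples2) < 2L)
    stop("each contrast class needs >= 2 samples (got ",
         length(samples1), " and ", length(samples2), ")")
  x1 <- m[, samples1, drop = FALSE]
  x2 <- m[, samples2, drop = FALSE]
  pop_fit <- function(x) {
    mu <- rowMeans(x, na.rm = TRUE)
    sd <- sqrt(rowMeans((x - mu)^2, na.rm = TRUE))
    list(mu = mu, sd = pmax(sd, sigma_floor))
  }
  f1 <- pop_fit(x1)
  f2 <- pop_fit(x2)
  tab <- data.frame(gene_id = rownames(m),
                    mu1 = f1$mu, sd1 = f1$sd, mu2 = f2$mu, sd2 = f2$sd,
                    stringsAsFactors = FALSE, row.names = NULL)
  model <- structure(list(table = tab, classes = classes,
                          samples1 = samples1, samples2 = samples2,
                          sigma_floor = sigma_floor),
                     class = "gene_llr_model")
  # normalization constants: moments of the raw LLR under the equal-prior
  # two-phenotype mixture (each class's samples weighted equally, matching
  # the equal-prior likelihood ratio), estimated on the fitting samples
  pooled <- m[, c(samples1, samples2), drop = FALSE]
  L <- compute_llr(model, pooled)
  L1 <- L[, samples1, drop = FALSE]
  L2 <- L[, samples2, drop = FALSE]
  nm <- (rowMeans(L1, na.rm = TRUE) + rowMeans(L2, na.rm = TRUE)) / 2
  ns <- sqrt((rowMeans((L1 - nm)^2, na.rm = TRUE) +
                rowMeans((L2 - nm)^2, na.rm = TRUE)) / 2)
  model$table$norm_mean <- nm
  model$table$norm_sd <- pmax(ns, sigma_floor)
  model$table$norm_sd_floored <- ns < sigma_floor | is.na(ns)
  model
}

#' @export
print.gene_llr_model <- function(x, ...) {
  cat("gene_llr_model:", nrow(x$table), "genes;",
      x$classes[1L], "(", length(x$samples1), "samples ) vs",
      x$classes[2L], "(", length(x$samples2), "samples )\n")
  invisible(x)
}

#' Per-gene log-likelihood ratios
#'
#' Entry (k, j) is `ln f1_k(x_jk) - ln f2_k(x_jk)` with the fitted Gaussian
#' class-conditional densities; natural logarithm. Positive values favor
#' phenotype 1. Genes of `m` absent from the model are omitted with a
#' warning; model genes absent from `m` are an error.
#'
#' @param model A `gene_llr_model`.
#' @param m Expression matrix (any samples; genes must cover the model's).
#' @return Genes x samples matrix of raw LLRs with attributes
#'   `normalized = FALSE`, `class_oriented = FALSE`.
#' @export
compute_llr <- function(model, m) {
  tab <- model$table
  missing_genes <- setdiff(tab$gene_id, rownames(m))
  if (length(missing_genes))
    stop("model gene(s) absent from matrix: ",
         paste(utils::head(missing_genes, 5L), collapse = ", "))
  extra <- setdiff(rownames(m), tab$gene_id)
  if (length(extra))
    warning(length(extra), " gene(s) in matrix not in model; omitted")
  x <- m[tab$gene_id, , drop = FALSE]
  L <- (log(tab$sd2) - log(tab$sd1)) -
    (x - tab$mu1)^2 / (2 * tab$sd1^2) +
    (x - tab$mu2)^2 / (2 * tab$sd2^2)
  dimnames(L) <- list(tab$gene_id, colnames(m))
  attr(L, "normalized") <- FALSE
  attr(L, "class_oriented") <- FALSE
  L
}

#' Normalize LLRs by their expectation-style moments
#'
#' Per gene: subtract `E[L_k]`, divide by `sqrt(E[(L_k - E L_k)^2])`
#' (population-style second moment, computed at fit time from the pooled
#' contrast samples). On the fitting samples every gene row of the output
#' has mean 0 and mean square 1.
#'
#' @param llr Raw LLR matrix from [compute_llr()].
#' @param model The fitting `gene_llr_model`.
#' @return Normalized LLR matrix (`normalized = TRUE`).
#' @export
normalize_llr <- function(llr, model) {
  if (isTRUE(attr(llr, "normalized"))) stop("LLR matrix already normalized")
  tab <- model$table
  idx <- match(rownames(llr), tab$gene_id)
  if (anyNA(idx)) stop("LLR rows not covered by model")
  if (any(tab$norm_sd_floored[idx]))
    warning(sum(tab$norm_sd_floored[idx]),
            " gene(s) had LLR sd below the floor; floor applied")
  out <- (llr - tab$norm_mean[idx]) / tab$norm_sd[idx]
  attr(out, "normalized") <- TRUE
  attr(out, "class_oriented") <- attr(llr, "class_oriented")
  out
}

#' Orient LLRs by class membership
#'
#' Entries of phenotype-2 samples are negated, so that evidence for each
#' sample's own class is positive in both groups (the class-oriented ratio
#' `p1/p2` for class-1 samples and `p2/p1` for class-2 samples). Applying
#' the operation twice restores the input.
#'
#' @param llr LLR matrix (raw or normalized).
#' @param ann Sample annotation data frame.
#' @param contrast Length-2 character vector of dose classes.
#' @return The oriented matrix (`class_oriented` toggled).
#' @export
orient_llr_by_class <- function(llr, ann, contrast) {
  cls <- ann$dose_class[match(colnames(llr), ann$sample_id)]
  in1 <- cls == contrast[1L]
  in2 <- cls == contrast[2L]
  if (any(is.na(cls)) || any(!(in1 | in2)))
    stop("sample(s) without a class in the contrast")
  out <- llr
  out[, in2] <- -out[, in2, drop = FALSE]
  attr(out, "normalized") <- attr(llr, "normalized")
  attr(out, "class_oriented") <- !isTRUE(attr(llr, "class_oriented"))
  out
}

#' Per-sample pathway activity scores
#'
#' The activity of pathway j in sample s is the sum of the pathway's member
#' genes' LLR entries for that sample (`NA` entries are dropped from the
#' sum).
#'
#' @param llr LLR matrix (typically normalized and class-oriented).
#' @param gs A `gene_set_collection` restricted to the LLR genes.
#' @return Pathways x samples matrix of activity scores `S_j`.
#' @export
pathway_activity_scores <- function(llr, gs) {
  genes <- rownames(llr)
  rows <- lapply(gs, function(members) {
    colSums(llr[intersect(members, genes), , drop = FALSE], na.rm = TRUE)
  })
  S <- matrix(unlist(rows, use.names = FALSE), nrow = length(gs),
              ncol = ncol(llr), byrow = TRUE,
              dimnames = list(names(gs), colnames(llr)))
  S
}

#' Aggregated differential pathway activity scores
#'
#' For every pathway: each member gene's LLR values over `sample_subset` are
#' tested against a null mean of 0 with a one-sample t statistic
#' (`t = mean / (sd / sqrt(n))`, sample sd); the aggregated score is the
#' mean of the absolute member-gene t statistics. The pathway-level reading
#' — a one-sample t of the summed activity `S_j` over the same subset — is
#' reported alongside.
#'
#' @param llr LLR matrix (normalized, class-oriented).
#' @param gs A `gene_set_collection`.
#' @param sample_subset Sample ids over which the t statistics are taken;
#'   defaults to all columns of `llr`.
#' @param sigma_floor Floor for a zero member-gene sd (with a warning).
#' @return Data frame: `pathway_id`, `name`, `n_members`, `n_samples`,
#'   `aggregated_score`, `pathway_t`. Per-gene t statistics are attached as
#'   the `gene_t` attribute (named list).
#' @export
aggregated_differential_score <- function(llr, gs,
                                          sample_subset = colnames(llr),
                                          sigma_floor = 1e-6) {
  sample_subset <- as.character(sample_subset)
  bad <- setdiff(sample_subset, colnames(llr))
  if (length(bad)) stop("subset sample(s) not in LLR matrix: ",
                        paste(utils::head(bad, 5L), collapse = ", "))
  if (length(sample_subset) < 2L) stop("sample subset must have >= 2 samples")
  X <- llr[, sample_subset, drop = FALSE]

  n_floored <- 0L
  one_sample_t <- function(v) {
    v <- v[!is.na(v)]
    n <- length(v)
    if (n < 2L) return(NA_real_)
    s <- stats::sd(v)
    if (s < sigma_floor) {
      n_floored <<- n_floored + 1L
      s <- sigma_floor
    }
    mean(v) / (s / sqrt(n))
  }
  gene_t_all <- apply(X, 1L, one_sample_t)
  S <- pathway_activity_scores(X, gs)

  genes <- rownames(X)
  gene_t <- lapply(gs, function(members) gene_t_all[intersect(members, genes)])
  agg <- vapply(gene_t, function(t) mean(abs(t), na.rm = TRUE), 0)
  pt_ <- apply(S[, , drop = FALSE], 1L, one_sample_t)

  dn <- attr(gs, "display_name")
  tab <- data.frame(
    pathway_id = names(gs),
    name = if (is.null(dn)) names(gs) else unname(dn[names(gs)]),
    n_members = vapply(gs, function(g) length(intersect(g, genes)), 0L),
    n_samples = length(sample_subset),
    aggregated_score = unname(agg),
    pathway_t = unname(pt_),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (n_floored > 0L)
    warning(n_floored, " zero-sd statistic(s) over the subset; sd floor applied")
  attr(tab, "gene_t") <- gene_t
  tab
}

#' Rank pathways by differential activity
#'
#' Sorts descending by score (default: the aggregated per-gene reading),
#' breaking ties by pathway id. Two-sided p-values for the pathway-level t
#' come from the Student t distribution with `n_samples - 1` degrees of
#' freedom; Benjamini-Hochberg adjusted p-values are added.
#'
#' @param tab Output of [aggregated_differential_score()].
#' @param by `"aggregated_score"` (default) or `"pathway_t"` (ranked by its
#'   absolute value).
#' @return The table sorted with `p_value`, `p_adj` and `rank` columns.
#' @export
rank_pathways <- function(tab, by = c("aggregated_score", "pathway_t")) {
  by <- match.arg(by)
  key <- if (by == "aggregated_score") tab$aggregated_score else abs(tab$pathway_t)
  tab$p_value <- 2 * stats::pt(-abs(tab$pathway_t), df = tab$n_samples - 1L)
  tab$p_adj <- stats::p.adjust(tab$p_value, method = "BH")
  ord <- order(-key, tab$pathway_id)
  out <- tab[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "gene_t") <- attr(tab, "gene_t")[out$pathway_id]
  attr(out, "ranked_by") <- by
  out
}

#' One-shot LLR pathway analysis for a two-class contrast
#'
#' Fits the per-gene Gaussians, computes normalized class-oriented LLRs,
#' aggregates differential activity over the phenotype-2 (non-reference)
#' samples, and ranks the pathways.
#'
#' @param m Expression matrix.
#' @param ann Sample annotation data frame.
#' @param gs A `gene_set_collection` (restricted internally to `m`'s genes).
#' @param contrast Length-2 dose-class vector, reference first, e.g.
#'   `c("ZERO", "LOW")`.
#' @param subset Which samples the t statistics are taken over: `"class2"`
#'   (default; the irradiated group) or `"all"` contrast samples.
#' @param rank_by Passed to [rank_pathways()].
#' @param sigma_floor Sd floor for fits and t statistics.
#' @return List: `table` (ranked), `model`, `llr` (normalized, oriented),
#'   `scores` (pathway x sample activity matrix over contrast samples).
#' @export
llr_pathway_analysis <- function(m, ann, gs, contrast = c("ZERO", "LOW"),
                                 subset = c("class2", "all"),
                                 rank_by = "aggregated_score",
                                 sigma_floor = 1e-6) {
  subset <- match.arg(subset)
  gs <- restrict_gene_sets(gs, m)
  model <- fit_gene_gaussians(m, ann, contrast, sigma_floor)
  pooled <- m[, c(model$samples1, model$samples2), drop = FALSE]
  llr <- compute_llr(model, pooled)
  llr <- normalize_llr(llr, model)
  llr <- orient_llr_by_class(llr, ann, contrast)
  subset_ids <- if (subset == "class2") model$samples2 else colnames(llr)
  tab <- aggregated_differential_score(llr, gs, subset_ids, sigma_floor)
  tab <- rank_pathways(tab, by = rank_by)
  list(table = tab, model = model, llr = llr,
       scores = pathway_activity_scores(llr, gs))
}

#' Ranked pathway ids of a score table
#' @param tab A ranked table from [rank_pathways()] (or a list containing one
#'   under `$table`).
#' @return Character vector of pathway ids, best first.
#' @export
ranked_ids <- function(tab) {
  if (is.list(tab) && !is.data.frame(tab) && !is.null(tab$table)) tab <- tab$table
  tab$pathway_id
}
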