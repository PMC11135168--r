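# End-to-end driver: ties preprocessing, the two contrasts (zero-vs-low and
# zero-vs-high), the dose-structure experiments and (optionally) the VAE
# stage into one reproducible run writing TSV tables plus a JSON manifest.

#' Validate and normalize a run configuration
#'
#' A configuration names either real input files (`expression`,
#' `annotations`, `gmt`) or a synthetic config (`synthetic`), never both.
#' Missing optional fields are filled with defaults.
#'
#' @param cfg A list. Fields: `expression`/`annotations`/`gmt` (paths) or
#'   `synthetic` (a [synthetic_config()]); `out_dir` (required);
#'   `dose_threshold` (default 0.1); `methods` (subset of `c("llr","vega")`,
#'   default both); `contrasts` (default `c("zero_vs_low", "zero_vs_high")`);
#'   `seed` (default 1); `undetected_frac` (default 0.75); `vega` (a
#'   [vega_config()], default constructed from `seed`); `profile_top_n`
#'   (default 5).
#' @return The normalized configuration list.
#' @export
validate_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a list")
  has_files <- !is.null(cfg$expression) || !is.null(cfg$annotations) ||
    !is.null(cfg$gmt)
  has_synth <- !is.null(cfg$synthetic)
  if (has_files && has_synth)
    stop("give either input file paths or a synthetic config, not both")
  if (!has_files && !has_synth)
    stop("config lacks inputs: either expression/annotations/gmt paths ",
         "or a synthetic config")
  if (has_files) {
    miss <- c("expression", "annotations", "gmt")[
      vapply(c("expression", "annotations", "gmt"),
             function(f) is.null(cfg[[f]]), TRUE)]
    if (length(miss)) stop("config lacks field(s): ",
                           paste(miss, collapse = ", "))
    for (f in c("expression", "annotations", "gmt"))
      if (!file.exists(cfg[[f]])) stop("input file not found: ", cfg[[f]])
  } else if (!inherits(cfg$synthetic, "synthetic_config")) {
    stop("cfg$synthetic must be a synthetic_config")
  }
  if (is.null(cfg$out_dir)) stop("config lacks field(s): out_dir")
  cfg$dose_threshold <- cfg$dose_threshold %||% 0.1
  if (cfg$dose_threshold <= 0) stop("dose_threshold must be positive")
  cfg$methods <- cfg$methods %||% c("llr", "vega")
  if (!all(cfg$methods %in% c("llr", "vega")))
    stop("methods must be a subset of c(\"llr\", \"vega\")")
  cfg$contrasts <- cfg$contrasts %||% c("zero_vs_low", "zero_vs_high")
  if (!all(cfg$contrasts %in% c("zero_vs_low", "zero_vs_high")))
    stop("contrasts must be among zero_vs_low, zero_vs_high")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$undetected_frac <- cfg$undetected_frac %||% 0.75
  cfg$profile_top_n <- cfg$profile_top_n %||% 5L
  if (is.null(cfg$vega)) cfg$vega <- vega_config(seed = cfg$seed)
  if (!inherits(cfg$vega, "vega_config")) stop("cfg$vega must be a vega_config")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# pathdose run seed: ", seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Loads (or simulates) the study, applies the detection filter and gene-set
#' restriction, and for each requested contrast runs the LLR pathway ranking
#' and/or the VAE differential-activity test; also emits the per-dose score
#' table, progressive-inclusion tables (both orders), top-k intersection
#' curves, dose profiles of the top low-dose pathways, UMAP embeddings of the
#' latent space, and a JSON run manifest. Identical config and seed give
#' identical outputs.
#'
#' @param cfg A configuration list (passed through [validate_config()]).
#' @return Invisibly, a list with the output directory, the loaded data and
#'   the per-contrast result objects.
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(cfg$synthetic)) {
    gs <- generate_gene_sets(cfg$synthetic)
    ds <- generate_dataset(cfg$synthetic, gs)
    m <- ds$expression
    ann <- ds$annotation
  } else {
    m <- read_expression_matrix(cfg$expression)
    ann <- read_sample_annotation(cfg$annotations, cfg$dose_threshold)
    gs <- read_gmt(cfg$gmt)
  }
  ann <- assign_dose_class(ann, cfg$dose_threshold)
  m <- filter_undetected_genes(m, cfg$undetected_frac)
  gs <- restrict_gene_sets(gs, m)

  contrast_classes <- list(zero_vs_low = c("ZERO", "LOW"),
                           zero_vs_high = c("ZERO", "HIGH"))
  results <- list()

  for (cn in cfg$contrasts) {
    classes <- contrast_classes[[cn]]
    if ("llr" %in% cfg$methods) {
      res <- llr_pathway_analysis(m, ann, gs, classes)
      write_tsv(res$table[, c("pathway_id", "name", "n_members",
                              "aggregated_score", "pathway_t", "p_value",
                              "p_adj", "rank")],
                file.path(cfg$out_dir, paste0("llr_ranking_", cn, ".tsv")),
                cfg$seed)
      results[[cn]]$llr <- res
    }
    if ("vega" %in% cfg$methods) {
      keep <- ann$sample_id[ann$dose_class %in% classes]
      sub <- m[, intersect(colnames(m), keep), drop = FALSE]
      sub <- sub[stats::complete.cases(sub), , drop = FALSE]
      mask <- build_mask(restrict_gene_sets(gs, sub), rownames(sub))
      model <- train_vega(sub, mask, cfg$vega)
      da <- differential_activity(model, sub, ann, classes,
                                  seed = cfg$seed)
      write_tsv(da, file.path(cfg$out_dir, paste0("vega_bf_", cn, ".tsv")),
                cfg$seed)
      latent <- vega_encode(model, sub)
      emb <- umap_embed(latent, seed = cfg$seed)
      emb$dose_gy <- ann$dose_gy[match(emb$sample_id, ann$sample_id)]
      emb$dose_class <- as.character(
        ann$dose_class[match(emb$sample_id, ann$sample_id)])
      write_tsv(emb, file.path(cfg$out_dir, paste0("vega_umap_", cn, ".tsv")),
                cfg$seed)
      results[[cn]]$vega <- list(model = model, bf = da, umap = emb)
    }
  }

  if ("llr" %in% cfg$methods) {
    pd <- per_dose_scores(m, ann, gs)
    write_tsv(pd, file.path(cfg$out_dir, "per_dose_scores.tsv"), cfg$seed)
    results$per_dose <- pd
    if (any(ann$dose_class == "LOW")) {
      for (ord in c("ascending", "descending")) {
        pi_ <- progressive_inclusion(m, ann, gs, ord)
        write_tsv(pi_, file.path(cfg$out_dir,
                                 paste0("progressive_", ord, ".tsv")),
                  cfg$seed)
        results[[paste0("progressive_", ord)]] <- pi_
      }
      joint <- low_dose_joint_analysis(m, ann, gs)
      results$joint <- joint
      # per-dose ranked lists + joint list, intersected pairwise with joint
      dose_lists <- split(pd, pd$dose_gy)
      dose_lists <- lapply(dose_lists, function(g) g$pathway_id[order(g$rank)])
      k_max <- min(50L, min(lengths(dose_lists)))
      if (length(dose_lists) >= 2L) {
        ic_all <- topk_intersection(dose_lists, k_max)
        ic_all$comparison <- "all_doses"
        ic_joint <- do.call(rbind, lapply(names(dose_lists), function(d) {
          cur <- topk_intersection(list(dose_lists[[d]], ranked_ids(joint)),
                                   k_max)
          cur$comparison <- paste0(d, "_vs_joint")
          cur
        }))
        write_tsv(rbind(ic_all, ic_joint),
                  file.path(cfg$out_dir, "intersection_curves.tsv"), cfg$seed)
        results$intersections <- rbind(ic_all, ic_joint)
      }
      top_ids <- utils::head(ranked_ids(joint), cfg$profile_top_n)
      prof <- dose_profile(m, ann, gs, top_ids)
      write_tsv(prof$samples, file.path(cfg$out_dir, "dose_profiles.tsv"),
                cfg$seed)
      write_tsv(prof$summary,
                file.path(cfg$out_dir, "dose_profiles_summary.tsv"), cfg$seed)
      results$profiles <- prof
    }
  }

  manifest <- list(
    seed = cfg$seed,
    methods = cfg$methods,
    contrasts = cfg$contrasts,
    dose_threshold = cfg$dose_threshold,
    undetected_frac = cfg$undetected_frac,
    n_genes = nrow(m), n_samples = ncol(m), n_pathways = length(gs),
    package_version = as.character(utils::packageVersion("pathdose")),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(out_dir = cfg$out_dir, expression = m, annotation = ann,
                 gene_sets = gs, results = results))
}
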