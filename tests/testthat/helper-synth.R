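# small synthetic studies used across tests; full-size Table-1 dose design
# but few genes/pathways so each call stays fast

tiny_config <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(n_genes = 300L, n_pathways = 12L,
                   pathway_size_range = c(8L, 20L),
                   n_low_responsive = 2L, n_high_responsive = 2L,
                   effect_size = 1, seed = seed)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

tiny_study <- function(seed = 1L, ...) {
  cfg <- tiny_config(seed, ...)
  gs <- generate_gene_sets(cfg)
  ds <- generate_dataset(cfg, gs)
  c(ds, list(gene_sets = gs, config = cfg))
}

# hand-constructed single-gene LLR model (class densities given directly)
manual_model <- function(mu1, sd1, mu2, sd2, norm_mean = 0, norm_sd = 1,
                         gene_id = "g1") {
  structure(list(
    table = data.frame(gene_id = gene_id, mu1 = mu1, sd1 = sd1,
                       mu2 = mu2, sd2 = sd2, norm_mean = norm_mean,
                       norm_sd = norm_sd, norm_sd_floored = FALSE,
                       stringsAsFactors = FALSE),
    classes = c("A", "B"), samples1 = character(), samples2 = character(),
    sigma_floor = 1e-6), class = "gene_llr_model")
}

# annotation for an explicit dose vector
make_ann <- function(dose_gy, ids = sprintf("s%03d", seq_along(dose_gy))) {
  assign_dose_class(data.frame(sample_id = ids,
                               donor_id = "donor1",
                               dose_gy = dose_gy,
                               stringsAsFactors = FALSE))
}
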