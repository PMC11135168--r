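test_that("the decoder mask mirrors membership plus one dense node", {
  gs <- gene_set_collection(list(pA = c("A", "B"), pB = c("B", "C")))
  mask <- build_mask(gs, c("A", "B", "C"))
  expect_identical(dim(mask), c(3L, 3L))
  expect_identical(unname(mask["pA", ]), c(1, 1, 0))
  expect_identical(unname(mask["pB", ]), c(0, 1, 1))
  expect_identical(unname(mask["UNANNOTATED", ]), c(1, 1, 1))
  # one pathway covering all genes -> dense first row
  full <- build_mask(gene_set_collection(list(p = c("A", "B", "C"))),
                     c("A", "B", "C"))
  expect_identical(unname(full[1, ]), c(1, 1, 1))
  expect_error(build_mask(gene_set_collection(list()), "A"), "empty")
  expect_error(build_mask(gene_set_collection(list(p = "Z")), c("A", "B")),
               "restrict")
})

test_that("analytic gradients match finite differences", {
  set.seed(1)
  G <- 6L; h <- 4L; D <- 3L; n <- 5L
  mask <- matrix(rbinom(D * G, 1, 0.5), D, G)
  mask[D, ] <- 1
  X <- matrix(rnorm(n * G), n, G)
  eps <- matrix(rnorm(n * D), n, D)
  params <- list(W1 = matrix(rnorm(G * h, 0, 0.3), G, h),
                 b1 = rnorm(h, 0, 0.1),
                 W2 = matrix(rnorm(h * D, 0, 0.3), h, D),
                 b2 = rnorm(D, 0, 0.1),
                 W3 = matrix(rnorm(h * D, 0, 0.1), h, D),
                 b3 = rep(-1, D),
                 Wd = matrix(rnorm(D * G, 0, 0.3), D, G) * mask,
                 bd = rnorm(G, 0, 0.1))
  lg <- pathdose:::vega_loss_grad(params, X, eps, mask, beta = 0.7)
  d <- 1e-5
  for (nm in names(params)) {
    for (i in seq_len(min(length(params[[nm]]), 8L))) {
      if (nm == "Wd" && mask[i] == 0) next
      up <- params; up[[nm]][i] <- up[[nm]][i] + d
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - d
      num <- (pathdose:::vega_loss_grad(up, X, eps, mask, beta = 0.7)$loss -
                pathdose:::vega_loss_grad(dn, X, eps, mask, beta = 0.7)$loss) /
        (2 * d)
      expect_equal(lg$grads[[nm]][i], num, tolerance = 1e-5)
    }
  }
})

test_that("the monitored closed-form loss equals the Monte-Carlo expectation", {
  set.seed(2)
  G <- 8L; D <- 3L; n <- 40L
  mask <- matrix(1, D, G)
  X <- matrix(rnorm(n * G), n, G)
  params <- list(W1 = matrix(rnorm(G * 5, 0, 0.3), G, 5), b1 = rep(0, 5),
                 W2 = matrix(rnorm(5 * D, 0, 0.3), 5, D), b2 = rep(0, D),
                 W3 = matrix(rnorm(5 * D, 0, 0.1), 5, D), b3 = rep(-1, D),
                 Wd = matrix(rnorm(D * G, 0, 0.3), D, G), bd = rep(0, G))
  mc <- mean(replicate(3000, {
    eps <- matrix(rnorm(n * D), n, D)
    pathdose:::vega_loss_grad(params, X, eps, mask)$loss
  }))
  exact <- pathdose:::vega_expected_loss(params, X)
  expect_equal(mc, exact, tolerance = 0.01)
})

test_that("training is deterministic, decreases the loss, and enforces the mask", {
  ds <- tiny_study(seed = 3L, n_genes = 120L, n_pathways = 6L)
  keep <- ds$annotation$dose_class %in% c("ZERO", "LOW")
  m <- ds$expression[, ds$annotation$sample_id[keep]]
  gs <- restrict_gene_sets(ds$gene_sets, m)
  mask <- build_mask(gs, rownames(m))
  cfg <- vega_config(encoder_hidden = 32L, max_epochs = 60L,
                     learning_rate = 1e-3, seed = 7L,
                     kl_warmup_epochs = 20L)
  fit1 <- train_vega(m, mask, cfg)
  fit2 <- train_vega(m, mask, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$params, fit2$params)
  expect_lt(utils::tail(fit1$history, 1), fit1$history[1])
  expect_identical(max(abs(fit1$params$Wd * (1 - mask))), 0)
  # serialize round trip keeps the zero pattern exactly
  path <- withr::local_tempfile(fileext = ".rds")
  save_vega(fit1, path)
  back <- load_vega(path)
  expect_identical(back$params$Wd, fit1$params$Wd)
  expect_identical(max(abs(back$params$Wd * (1 - mask))), 0)
})

test_that("early stopping waits out the patience window on a flat loss", {
  ds <- tiny_study(seed = 3L, n_genes = 60L, n_pathways = 4L,
                   pathway_size_range = c(5L, 10L))
  m <- ds$expression[, 1:40]
  mask <- build_mask(restrict_gene_sets(ds$gene_sets, m), rownames(m))
  # a vanishing learning rate freezes the parameters: the monitored loss is
  # exactly constant, so training must stop after 1 + patience epochs
  cfg <- vega_config(encoder_hidden = 16L, max_epochs = 200L,
                     learning_rate = 1e-300, early_stop_patience = 10L,
                     seed = 1L, kl_warmup_epochs = 0L)
  fit <- train_vega(m, mask, cfg)
  expect_identical(fit$n_epochs, 11L)
})

test_that("encoding is shape-stable, deterministic, and separates planted groups", {
  ds <- tiny_study(seed = 17L, n_genes = 150L, n_pathways = 6L,
                   pathway_size_range = c(25L, 35L), n_low_responsive = 1L,
                   effect_size = 4, donor_effect_sd = 0.3)
  ann <- ds$annotation
  keep <- ann$dose_class %in% c("ZERO", "LOW")
  m <- ds$expression[, ann$sample_id[keep]]
  mask <- build_mask(restrict_gene_sets(ds$gene_sets, m), rownames(m))
  cfg <- vega_config(encoder_hidden = 64L, max_epochs = 800L,
                     learning_rate = 3e-3, seed = 2L,
                     kl_warmup_epochs = 100L, early_stop_patience = 50L)
  fit <- train_vega(m, mask, cfg)
  z <- vega_encode(fit, m)
  expect_identical(dim(z), c(ncol(m), nrow(mask)))
  expect_identical(vega_encode(fit, m), z)
  zs <- vega_encode(fit, m, mode = "sample", seed = 9L)
  expect_identical(vega_encode(fit, m, mode = "sample", seed = 9L), zs)
  expect_false(identical(zs, vega_encode(fit, m, mode = "sample", seed = 10L)))
  # linear separability of the dose classes in the latent means
  y <- as.integer(ann$dose_class[match(colnames(m), ann$sample_id)] == "LOW")
  glm_fit <- suppressWarnings(stats::glm(y ~ z, family = stats::binomial()))
  acc <- mean((stats::fitted(glm_fit) > 0.5) == y)
  expect_gte(acc, 0.9)
  expect_error(vega_encode(fit, m[rev(rownames(m)), ]), "gene order")
})

test_that("Bayes factors are calibrated under the null and antisymmetric", {
  set.seed(23)
  genes <- sprintf("g%03d", 1:80)
  half <- matrix(rnorm(80 * 30, 7, 1), nrow = 80,
                 dimnames = list(genes, sprintf("a%02d", 1:30)))
  m <- cbind(half, half)                       # class 2 is a copy of class 1
  colnames(m) <- c(sprintf("a%02d", 1:30), sprintf("b%02d", 1:30))
  ann <- make_ann(rep(c(0, 0.5), each = 30), colnames(m))
  gs <- gene_set_collection(list(p1 = genes[1:20], p2 = genes[21:50]))
  mask <- build_mask(gs, genes)
  cfg <- vega_config(encoder_hidden = 32L, max_epochs = 40L,
                     learning_rate = 1e-3, seed = 4L, kl_warmup_epochs = 10L)
  fit <- train_vega(m, mask, cfg)
  da <- differential_activity(fit, m, ann, c("ZERO", "HIGH"), seed = 6L)
  expect_true(all(abs(da$bayes_factor) < 0.2))
  expect_false(any(da$significant))
  rev_da <- differential_activity(fit, m, ann, c("HIGH", "ZERO"), seed = 7L)
  merged <- merge(da, rev_da, by = "pathway_id")
  expect_true(all(abs(merged$bayes_factor.x + merged$bayes_factor.y) < 0.1))
  expect_error(differential_activity(fit, m, ann, c("ZERO", "HIGH"),
                                     n_mc_pairs = 10L), "1000")
  expect_error(differential_activity(fit, m, ann, c("ZERO", "LOW")), "sample")
})

test_that("a strongly shifted planted pathway reaches the significance threshold", {
  ds <- tiny_study(seed = 101L, n_genes = 150L, n_pathways = 6L,
                   pathway_size_range = c(25L, 35L), n_low_responsive = 1L,
                   effect_size = 4, donor_effect_sd = 0.3)
  ann <- ds$annotation
  keep <- ann$dose_class %in% c("ZERO", "LOW")
  m <- ds$expression[, ann$sample_id[keep]]
  mask <- build_mask(restrict_gene_sets(ds$gene_sets, m), rownames(m))
  cfg <- vega_config(encoder_hidden = 64L, max_epochs = 1500L,
                     learning_rate = 3e-3, seed = 11L,
                     kl_warmup_epochs = 100L, early_stop_patience = 50L)
  fit <- train_vega(m, mask, cfg)
  da <- differential_activity(fit, m, ann, c("ZERO", "LOW"), seed = 3L)
  planted_bf <- abs(da$bayes_factor[da$pathway_id == ds$truth$low_responsive])
  expect_gte(planted_bf, bf_significance_threshold())
  expect_identical(da$pathway_id[1], ds$truth$low_responsive)
})

test_that("UMAP embeddings are reproducible and respect group structure", {
  set.seed(31)
  z <- rbind(matrix(rnorm(30 * 5, 0), 30, 5), matrix(rnorm(30 * 5, 4), 30, 5))
  rownames(z) <- sprintf("s%02d", 1:60)
  emb <- umap_embed(z, seed = 5L)
  expect_identical(dim(emb), c(60L, 3L))
  expect_identical(names(emb), c("sample_id", "umap1", "umap2"))
  expect_identical(umap_embed(z, seed = 5L), emb)
  if (requireNamespace("cluster", quietly = TRUE)) {
    lab <- rep(1:2, each = 30)
    sil <- cluster::silhouette(lab, stats::dist(cbind(emb$umap1, emb$umap2)))
    expect_gt(mean(sil[, "sil_width"]), 0)
  }
  tiny <- z[1:6, ]
  expect_warning(emb2 <- umap_embed(tiny, seed = 1L, n_neighbors = 15L),
                 "reduced")
  expect_identical(nrow(emb2), 6L)
  expect_error(umap_embed(z[1:2, ]), ">= 3")
})
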