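test_that("class Gaussians use population moments and guard degenerate genes", {
  m <- matrix(c(0, 2, 5, 5,      # gene g1: class A [0,2], class B [5,5]
                1, 3, 2, 4),     # gene g2
              nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  ann <- make_ann(c(0, 0, 0.05, 0.05), paste0("s", 1:4))
  model <- fit_gene_gaussians(m, ann, c("ZERO", "LOW"))
  tab <- model$table
  expect_equal(tab$mu1[tab$gene_id == "g1"], 1)
  expect_equal(tab$sd1[tab$gene_id == "g1"], 1)   # population sd of [0,2]
  # constant class -> sd floored, downstream stays finite
  expect_equal(tab$sd2[tab$gene_id == "g1"], model$sigma_floor)
  llr <- compute_llr(model, m)
  norm <- normalize_llr(llr, model)
  expect_false(anyNA(norm))
  expect_true(all(is.finite(norm)))
  # too-small classes rejected
  expect_error(fit_gene_gaussians(m, make_ann(c(0, 0.05, 0.05, 0.05),
                                              paste0("s", 1:4)),
                                  c("ZERO", "LOW")), ">= 2")
})

test_that("identical class distributions give near-zero normalization means", {
  set.seed(11)
  n <- 5000
  m <- matrix(rnorm(2 * n, 5, 1), nrow = 1,
              dimnames = list("g1", sprintf("s%05d", 1:(2 * n))))
  ann <- make_ann(rep(c(0, 0.05), each = n), colnames(m))
  model <- fit_gene_gaussians(m, ann, c("ZERO", "LOW"))
  expect_lt(abs(model$table$norm_mean), 0.05)
})

test_that("log-likelihood ratios match Gaussian density evaluation", {
  model <- manual_model(mu1 = 0, sd1 = 1, mu2 = 1, sd2 = 1)
  xs <- c(0.5, 0, -1, 2, 0.3)
  m <- matrix(xs, nrow = 1,
              dimnames = list("g1", sprintf("s%d", seq_along(xs))))
  L <- compute_llr(model, m)
  # midpoint symmetry and the closed form (1 - 2x)/2
  expect_equal(L[1, 1], 0)
  expect_equal(L[1, 2], 0.5)
  oracle <- dnorm(xs, 0, 1, log = TRUE) - dnorm(xs, 1, 1, log = TRUE)
  expect_equal(as.numeric(L), oracle)
  # identical densities -> all zero
  same <- manual_model(2, 0.7, 2, 0.7)
  expect_true(all(compute_llr(same, m) == 0))
  # unequal sds against the density oracle
  uneq <- manual_model(0, 0.5, 1, 2)
  expect_equal(as.numeric(compute_llr(uneq, m)),
               dnorm(xs, 0, 0.5, log = TRUE) - dnorm(xs, 1, 2, log = TRUE))
  # model genes must be present; extra matrix genes are dropped with warning
  expect_error(compute_llr(model, matrix(1, 1, 1, dimnames = list("gX", "s1"))),
               "absent")
  m2 <- rbind(m, gZ = rep(0, ncol(m)))
  expect_warning(L2 <- compute_llr(model, m2), "omitted")
  expect_identical(rownames(L2), "g1")
})

test_that("normalization applies the stored moments and refuses double application", {
  model <- manual_model(0, 1, 1, 1, norm_mean = 2, norm_sd = sqrt(2 / 3))
  llr <- matrix(c(1, 2, 3), nrow = 1,
                dimnames = list("g1", c("s1", "s2", "s3")))
  attr(llr, "normalized") <- FALSE
  out <- normalize_llr(llr, model)
  expect_equal(as.numeric(out), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_error(normalize_llr(out, model), "already")
})

test_that("training-sample moments are exactly zero mean and unit mean square", {
  set.seed(3)
  m <- matrix(rnorm(40 * 36, 7, 1), nrow = 40,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:36)))
  ann <- make_ann(rep(c(0, 0.05), each = 18), colnames(m))  # balanced design
  model <- fit_gene_gaussians(m, ann, c("ZERO", "LOW"))
  norm <- normalize_llr(compute_llr(model, m), model)
  expect_lt(max(abs(rowMeans(norm))), 1e-10)
  expect_lt(max(abs(rowMeans(norm^2) - 1)), 1e-10)
})

test_that("class orientation negates phenotype-2 entries and is an involution", {
  llr <- matrix(c(0.7, -0.2, 0.7, 1.1), nrow = 1,
                dimnames = list("g1", paste0("s", 1:4)))
  ann <- make_ann(c(0, 0, 0.05, 0.05), paste0("s", 1:4))
  o <- orient_llr_by_class(llr, ann, c("ZERO", "LOW"))
  expect_equal(as.numeric(o), c(0.7, -0.2, -0.7, -1.1))
  expect_true(attr(o, "class_oriented"))
  back <- orient_llr_by_class(o, ann, c("ZERO", "LOW"))
  expect_equal(as.numeric(back), as.numeric(llr))
  expect_false(attr(back, "class_oriented"))
  ann_bad <- make_ann(c(0, 0, 0.05, 0.5), paste0("s", 1:4))
  expect_error(orient_llr_by_class(llr, ann_bad, c("ZERO", "LOW")), "class")
})

test_that("pathway activity sums member-gene LLRs", {
  llr <- matrix(c(0.5, -0.5, 1.3, rep(0.1, 20)), ncol = 1,
                dimnames = list(c("g1", "g2", "g3", sprintf("h%02d", 1:20)),
                                "s1"))
  gs <- gene_set_collection(list(cancel = c("g1", "g2"), single = "g3",
                                 twenty = sprintf("h%02d", 1:20)))
  S <- pathway_activity_scores(llr, gs)
  expect_equal(S["cancel", "s1"], 0)
  expect_equal(S["single", "s1"], 1.3)
  # oracle: explicit loop
  acc <- 0
  for (g in sprintf("h%02d", 1:20)) acc <- acc + llr[g, "s1"]
  expect_equal(S["twenty", "s1"], acc)
  expect_equal(S["twenty", "s1"], 2.0)
})

test_that("aggregated scores average absolute one-sample t statistics", {
  v <- c(1, 2, 3)
  m0 <- 4 / sqrt(3)
  llr <- matrix(c(v,
                  m0 - 1, m0, m0 + 1,       # t exactly +4
                  -(m0 - 1), -m0, -(m0 + 1) # t exactly -4
                  ), nrow = 3, byrow = TRUE,
                dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3")))
  gs <- gene_set_collection(list(p1 = "g1", pm = c("g2", "g3")))
  # pm's two member rows cancel in S_j, so the pathway-level t triggers the
  # documented sd-floor warning; the per-gene statistics are what we check
  tab <- suppressWarnings(aggregated_differential_score(llr, gs))
  # textbook formula and t.test as independent oracle
  expect_equal(tab$aggregated_score[tab$pathway_id == "p1"], 3.4641,
               tolerance = 1e-3)
  expect_equal(tab$aggregated_score[tab$pathway_id == "p1"],
               unname(stats::t.test(v)$statistic))
  expect_equal(tab$aggregated_score[tab$pathway_id == "pm"], 4)
  # all-zero LLRs -> zero score (sd floor warning)
  zero <- matrix(0, 1, 3, dimnames = list("g1", paste0("s", 1:3)))
  expect_warning(tz <- aggregated_differential_score(
    zero, gene_set_collection(list(p = "g1"))), "floor")
  expect_equal(tz$aggregated_score, 0)
})

test_that("ranking sorts by score with documented tie-breaks and adds p-values", {
  tab <- data.frame(pathway_id = c("A", "B", "C"), name = c("A", "B", "C"),
                    n_members = 3L, n_samples = 10L,
                    aggregated_score = c(2, 3, 1),
                    pathway_t = c(1, 2, 0), stringsAsFactors = FALSE)
  r <- rank_pathways(tab)
  expect_identical(r$pathway_id, c("B", "A", "C"))
  expect_identical(r$rank, 1:3)
  expect_equal(r$p_value[r$pathway_id == "C"], 1)  # t = 0 -> p = 1
  expect_equal(r$p_value[r$pathway_id == "A"],
               2 * stats::pt(-1, df = 9))
  expect_identical(r$p_adj, stats::p.adjust(r$p_value, "BH"))
  tie <- tab
  tie$aggregated_score <- c(1, 1, 0)
  expect_identical(rank_pathways(tie)$pathway_id[1:2], c("A", "B"))
})

test_that("un-normalized summed LLRs decide like an equal-prior naive Bayes classifier", {
  set.seed(77)
  for (rep in 1:20) {
    n_genes <- 5L
    m <- matrix(rnorm(n_genes * 10, sample(5:9, 1), runif(1, 0.5, 2)),
                nrow = n_genes,
                dimnames = list(sprintf("g%d", 1:n_genes),
                                sprintf("s%d", 1:10)))
    ann <- make_ann(rep(c(0, 0.5), each = 5), colnames(m))
    model <- fit_gene_gaussians(m, ann, c("ZERO", "HIGH"))
    S <- pathway_activity_scores(
      compute_llr(model, m),
      gene_set_collection(list(all = rownames(m))))
    # oracle: explicit naive Bayes with equal priors
    tab <- model$table
    nb <- vapply(seq_len(ncol(m)), function(j) {
      l1 <- sum(dnorm(m[, j], tab$mu1, tab$sd1, log = TRUE))
      l2 <- sum(dnorm(m[, j], tab$mu2, tab$sd2, log = TRUE))
      ifelse(l1 > l2, 1, -1)
    }, 0)
    expect_identical(sign(as.numeric(S)), nb)
  }
})

test_that("normalized LLRs are invariant to rescaling a gene's measurement units", {
  set.seed(5)
  m <- matrix(rnorm(36, 7, 1), nrow = 1,
              dimnames = list("g1", sprintf("s%02d", 1:36)))
  ann <- make_ann(rep(c(0, 0.05), each = 18), colnames(m))
  model <- fit_gene_gaussians(m, ann, c("ZERO", "LOW"))
  norm <- normalize_llr(compute_llr(model, m), model)
  scaled <- m * 3.7
  model_s <- fit_gene_gaussians(scaled, ann, c("ZERO", "LOW"))
  norm_s <- normalize_llr(compute_llr(model_s, scaled), model_s)
  expect_equal(as.numeric(norm_s), as.numeric(norm), tolerance = 1e-8)
})

test_that("permuting class labels equalizes responsive and other pathways' scores", {
  ds <- tiny_study(seed = 42L, n_genes = 200L, n_pathways = 10L,
                   effect_size = 0.8)
  ann <- ds$annotation
  contrast_samples <- ann$sample_id[ann$dose_class %in% c("ZERO", "LOW")]
  resp <- numeric(0)
  other <- numeric(0)
  set.seed(8)
  for (p in 1:50) {
    perm_ann <- ann[ann$sample_id %in% contrast_samples, ]
    perm_ann$dose_class <- sample(perm_ann$dose_class)
    res <- llr_pathway_analysis(ds$expression[, perm_ann$sample_id],
                                perm_ann, ds$gene_sets, c("ZERO", "LOW"))
    tab <- res$table
    is_resp <- tab$pathway_id %in% ds$truth$low_responsive
    resp <- c(resp, tab$aggregated_score[is_resp])
    other <- c(other, tab$aggregated_score[!is_resp])
  }
  ks <- suppressWarnings(stats::ks.test(resp, other))
  expect_gt(ks$p.value, 0.01)
})
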