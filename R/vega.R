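# Pathway-constrained variational autoencoder with a masked linear decoder.
#
# The encoder is a two-layer fully connected network (ReLU hidden layer,
# separate linear heads for the latent posterior mean and log-variance); the
# decoder is a single linear layer whose weight matrix is hard-masked by the
# gene-pathway membership pattern, so each latent variable reconstructs only
# its own pathway's genes and is interpretable as that pathway's activity.
# One extra, fully connected latent node absorbs variability not captured by
# the annotated pathways. Training maximizes the evidence lower bound
# (unit-variance Gaussian reconstruction + KL against a standard normal
# prior) with Adam; the implementation is plain R matrix algebra with
# hand-derived gradients.

#' VEGA-style model configuration
#'
#' @param encoder_hidden Width of the encoder's hidden layer (default 800).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param max_epochs Training epoch cap (default 200).
#' @param early_stop_patience Stop when the monitored loss has not improved
#'   for this many consecutive epochs (default 10).
#' @param batch_size Minibatch size (default 32).
#' @param seed Integer seed controlling initialization, shuffling and the
#'   reparameterization noise.
#' @param n_mc_pairs Monte-Carlo sample pairs for the Bayes-factor test
#'   (default 10000).
#' @param validation_fraction Fraction of samples held out to monitor early
#'   stopping; 0 (default) monitors the training loss.
#' @param kl_warmup_epochs The KL term's weight is annealed linearly from 0
#'   to 1 over this many epochs (the usual warm-up of this model family,
#'   preventing posterior collapse on small sample sizes); default 50.
#'   Early stopping starts counting only after the warm-up.
#' @return A `vega_config` list.
#' @export
vega_config <- function(encoder_hidden = 800L, learning_rate = 1e-4,
                        max_epochs = 200L, early_stop_patience = 10L,
                        batch_size = 32L, seed = 1L, n_mc_pairs = 10000L,
                        validation_fraction = 0, kl_warmup_epochs = 50L) {
  stopifnot(encoder_hidden >= 1, learning_rate > 0, max_epochs >= 1,
            early_stop_patience >= 1, batch_size >= 1,
            validation_fraction >= 0, validation_fraction < 1,
            kl_warmup_epochs >= 0)
  structure(list(encoder_hidden = as.integer(encoder_hidden),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 n_mc_pairs = as.integer(n_mc_pairs),
                 validation_fraction = validation_fraction,
                 kl_warmup_epochs = as.integer(kl_warmup_epochs)),
            class = "vega_config")
}

#' Significance threshold for log Bayes factors
#'
#' The natural-log magnitude corresponding to an evidence ratio of
#' `bf_ratio`; with the conventional ratio of 10 this is `ln(10)`, about
#' 2.3, the threshold used by [differential_activity()].
#'
#' @param bf_ratio Evidence ratio (default 10).
#' @return `log(bf_ratio)`.
#' @export
bf_significance_threshold <- function(bf_ratio = 10) log(bf_ratio)

#' Build the masked-decoder wiring from gene-set membership
#'
#' Row p, column g of the mask is 1 iff gene g belongs to pathway p; pathway
#' rows are ordered by sorted pathway id. A final all-ones row adds one
#' fully connected latent node for unannotated variability, so the latent
#' dimension is `n_pathways + 1`.
#'
#' @param gs A non-empty `gene_set_collection`, restricted to `gene_index`.
#' @param gene_index Ordered gene ids (the expression matrix's row order).
#' @return Binary matrix `(n_pathways + 1) x n_genes`; the extra row is
#'   named `"UNANNOTATED"`.
#' @export
build_mask <- function(gs, gene_index) {
  if (length(gs) == 0L) stop("gene-set collection is empty")
  ids <- sort(names(gs))
  mask <- matrix(0, nrow = length(ids) + 1L, ncol = length(gene_index),
                 dimnames = list(c(ids, "UNANNOTATED"), gene_index))
  for (p in ids) {
    members <- intersect(gs[[p]], gene_index)
    if (length(members) == 0L)
      stop("pathway ", p, " has no gene in gene_index; ",
           "restrict the collection first")
    mask[p, members] <- 1
  }
  mask[length(ids) + 1L, ] <- 1
  mask
}

# forward pass; X is samples x genes
vega_forward <- function(params, X) {
  A1 <- X %*% params$W1 + matrix(params$b1, nrow(X), length(params$b1),
                                 byrow = TRUE)
  H <- pmax(A1, 0)
  mu <- H %*% params$W2 + matrix(params$b2, nrow(X), length(params$b2),
                                 byrow = TRUE)
  lv <- H %*% params$W3 + matrix(params$b3, nrow(X), length(params$b3),
                                 byrow = TRUE)
  lv <- pmax(pmin(lv, 10), -10)
  list(A1 = A1, H = H, mu = mu, lv = lv)
}

# loss and gradients for one minibatch with given reparameterization noise;
# returns mean per-sample negative ELBO (KL weighted by beta) and gradients
vega_loss_grad <- function(params, X, eps, mask, beta = 1) {
  n <- nrow(X)
  fw <- vega_forward(params, X)
  sd_ <- exp(0.5 * fw$lv)
  z <- fw$mu + eps * sd_
  Xhat <- z %*% params$Wd + matrix(params$bd, n, length(params$bd),
                                   byrow = TRUE)
  resid <- Xhat - X
  recon <- 0.5 * sum(resid^2) / n
  kl <- -0.5 * sum(1 + fw$lv - fw$mu^2 - exp(fw$lv)) / n
  loss <- recon + beta * kl

  dXhat <- resid / n
  gWd <- crossprod(z, dXhat) * mask
  gbd <- colSums(dXhat)
  dz <- dXhat %*% t(params$Wd)
  dmu <- dz + beta * fw$mu / n
  inside <- abs(fw$lv) < 10           # clamp pass-through region
  dlv <- (dz * eps * 0.5 * sd_ - beta * 0.5 * (1 - exp(fw$lv)) / n) * inside
  gW2 <- crossprod(fw$H, dmu); gb2 <- colSums(dmu)
  gW3 <- crossprod(fw$H, dlv); gb3 <- colSums(dlv)
  dH <- (dmu %*% t(params$W2) + dlv %*% t(params$W3)) * (fw$A1 > 0)
  gW1 <- crossprod(X, dH); gb1 <- colSums(dH)

  list(loss = loss, recon = recon, kl = kl,
       grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    W3 = gW3, b3 = gb3, Wd = gWd, bd = gbd))
}

# exact expected per-sample negative ELBO: because the decoder is linear the
# expectation over the reparameterization noise is available in closed form
# (residual at the posterior mean + posterior-variance-weighted decoder row
# norms), so the monitored loss carries no Monte-Carlo noise
vega_expected_loss <- function(params, X, beta = 1) {
  n <- nrow(X)
  fw <- vega_forward(params, X)
  var_ <- exp(fw$lv)
  mu_hat <- fw$mu %*% params$Wd +
    matrix(params$bd, n, length(params$bd), byrow = TRUE)
  wrow2 <- rowSums(params$Wd^2)
  recon <- 0.5 * (sum((mu_hat - X)^2) + sum(var_ %*% wrow2)) / n
  kl <- -0.5 * sum(1 + fw$lv - fw$mu^2 - var_) / n
  recon + beta * kl
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + epsilon)
  }
  list(params = params, state = state)
}

#' Train a pathway-constrained VAE
#'
#' Optimizes the negative ELBO (unit-variance Gaussian reconstruction plus
#' KL to a standard normal latent prior) with Adam at the configured
#' learning rate, for at most `max_epochs` epochs, stopping early when the
#' monitored loss has not improved for `early_stop_patience` consecutive
#' epochs. Masked decoder entries are forced to exactly zero after every
#' update. Fully reproducible under `cfg$seed`.
#'
#' The monitored epoch loss is the exact expected objective (closed form,
#' available because the decoder is linear), so early stopping is not
#' confounded by Monte-Carlo noise.
#'
#' @param m Expression matrix, genes in rows (no `NA`s).
#' @param mask Decoder mask from [build_mask()]; column order must match
#'   `rownames(m)`.
#' @param cfg A [vega_config()].
#' @param scale_genes Center and scale every gene to mean 0, sd 1 before
#'   training (default `TRUE`; the transform is stored in the model and
#'   re-applied at encoding time). With the unit-variance reconstruction
#'   likelihood, standardization puts all genes on the likelihood's noise
#'   scale so that coordinated pathway variation — not whichever genes
#'   happen to have the largest raw variance — is what the latent space
#'   captures.
#' @return A `vega_model`: list with `params`, `mask`, `gene_ids`,
#'   `pathway_ids` (mask row names), `config`, `history` (per-epoch monitored
#'   loss), `n_epochs`, `gene_center`, `gene_scale`.
#' @export
train_vega <- function(m, mask, cfg = vega_config(), scale_genes = TRUE) {
  stopifnot(inherits(cfg, "vega_config"))
  if (!identical(colnames(mask), rownames(m)))
    stop("mask columns must match the expression matrix's gene order")
  if (anyNA(m)) stop("expression matrix contains NA; impute or filter first")
  if (scale_genes) {
    gene_center <- rowMeans(m)
    gene_scale <- pmax(sqrt(rowMeans((m - gene_center)^2)), 1e-6)
    m <- (m - gene_center) / gene_scale
  } else {
    gene_center <- rep(0, nrow(m))
    gene_scale <- rep(1, nrow(m))
  }
  X_all <- t(m)                      # samples x genes
  n_all <- nrow(X_all)
  if (n_all < 2L) stop("need >= 2 samples")
  G <- ncol(X_all)
  D <- nrow(mask)
  h <- cfg$encoder_hidden

  withr::with_seed(cfg$seed, {
    val_idx <- integer(0)
    if (cfg$validation_fraction > 0) {
      n_val <- max(1L, floor(cfg$validation_fraction * n_all))
      if (n_val >= n_all - 1L) stop("validation fraction leaves < 2 training samples")
      val_idx <- sample(n_all, n_val)
    }
    train_idx <- setdiff(seq_len(n_all), val_idx)
    X <- X_all[train_idx, , drop = FALSE]
    n <- nrow(X)

    params <- list(
      W1 = matrix(stats::rnorm(G * h, 0, sqrt(2 / G)), G, h),
      b1 = rep(0, h),
      W2 = matrix(stats::rnorm(h * D, 0, sqrt(1 / h)), h, D),
      b2 = rep(0, D),
      W3 = matrix(stats::rnorm(h * D, 0, 0.01), h, D),
      b3 = rep(-2, D),               # start with small posterior variances
      Wd = matrix(stats::rnorm(D * G, 0, 0.01), D, G) * mask,
      bd = colMeans(X)
    )
    state <- list(m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0))

    history <- numeric(0)
    best <- Inf
    wait <- 0L
    t_step <- 0L
    warmup <- cfg$kl_warmup_epochs
    for (epoch in seq_len(cfg$max_epochs)) {
      beta <- if (warmup > 0L) min(1, epoch / warmup) else 1
      ord <- sample(n)
      starts <- seq(1L, n, by = cfg$batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        eps <- matrix(stats::rnorm(length(idx) * D), length(idx), D)
        lg <- vega_loss_grad(params, Xb, eps, mask, beta)
        if (!is.finite(lg$loss))
          stop("non-finite loss at epoch ", epoch)
        t_step <- t_step + 1L
        upd <- adam_step(params, lg$grads, state, cfg$learning_rate, t_step)
        params <- upd$params
        state <- upd$state
        params$Wd <- params$Wd * mask          # hard mask after every update
        ep_loss <- ep_loss + lg$loss * length(idx)
      }
      monitored <- if (length(val_idx)) {
        vega_expected_loss(params, X_all[val_idx, , drop = FALSE], beta)
      } else {
        vega_expected_loss(params, X, beta)
      }
      history <- c(history, monitored)
      # patience counting starts once the KL weight has reached 1, so the
      # monitored losses being compared share the same objective
      if (epoch > warmup) {
        if (monitored < best) {
          best <- monitored
          wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= cfg$early_stop_patience) break
        }
      }
    }

    structure(list(params = params, mask = mask,
                   gene_ids = rownames(m), pathway_ids = rownames(mask),
                   config = cfg, history = history,
                   n_epochs = length(history),
                   gene_center = gene_center, gene_scale = gene_scale),
              class = "vega_model")
  })
}

#' @export
print.vega_model <- function(x, ...) {
  cat("vega_model:", length(x$gene_ids), "genes,",
      length(x$pathway_ids) - 1L, "pathways (+1 unannotated node),",
      x$n_epochs, "epochs trained; final loss",
      format(utils::tail(x$history, 1L), digits = 6), "\n")
  invisible(x)
}

#' Encode samples into the pathway latent space
#'
#' @param model A trained `vega_model`.
#' @param m Expression matrix with the training gene order.
#' @param mode `"mean"` (posterior means; deterministic) or `"sample"` (one
#'   reparameterized draw per sample).
#' @param seed Seed for `mode = "sample"`.
#' @return Samples x latent matrix; columns named by pathway id (last column
#'   `"UNANNOTATED"`).
#' @export
vega_encode <- function(model, m, mode = c("mean", "sample"), seed = 1L) {
  mode <- match.arg(mode)
  if (!identical(rownames(m), model$gene_ids))
    stop("gene order differs from the training matrix")
  m <- (m - model$gene_center) / model$gene_scale
  fw <- vega_forward(model$params, t(m))
  out <- if (mode == "mean") {
    fw$mu
  } else {
    withr::with_seed(seed, {
      fw$mu + matrix(stats::rnorm(length(fw$mu)), nrow(fw$mu)) *
        exp(0.5 * fw$lv)
    })
  }
  dimnames(out) <- list(colnames(m), model$pathway_ids)
  out
}

# posterior parameters for a set of samples
vega_posterior <- function(model, m) {
  m <- (m - model$gene_center) / model$gene_scale
  fw <- vega_forward(model$params, t(m))
  list(mu = fw$mu, sd = exp(0.5 * fw$lv))
}

#' Monte-Carlo Bayes-factor differential pathway activity
#'
#' For each pathway, draws `n_mc_pairs` pairs of latent values — one from
#' the posterior of a random class-1 sample, one from a random class-2
#' sample — and estimates `P`, the probability that the class-1 value
#' exceeds the class-2 value. The Bayes factor is `ln(P / (1 - P))` (`P`
#' clamped to `[1/(n+1), n/(n+1)]` to keep it finite); `|BF| >= ln(10)`
#' (about 2.3) marks significant differential activity.
#'
#' @param model A trained `vega_model`.
#' @param m Expression matrix (training gene order).
#' @param ann Sample annotation data frame.
#' @param contrast Length-2 dose-class vector (class 1 first).
#' @param n_mc_pairs Monte-Carlo pairs (>= 1000).
#' @param seed Seed for the Monte-Carlo draws.
#' @return Data frame sorted by `|bayes_factor|`: `pathway_id`, `P`,
#'   `bayes_factor`, `significant`, `rank` (the unannotated node is
#'   excluded).
#' @export
differential_activity <- function(model, m, ann, contrast,
                                  n_mc_pairs = model$config$n_mc_pairs,
                                  seed = 1L) {
  if (n_mc_pairs < 1000L) stop("n_mc_pairs must be >= 1000")
  s1 <- intersect(ann$sample_id[ann$dose_class == contrast[1L]], colnames(m))
  s2 <- intersect(ann$sample_id[ann$dose_class == contrast[2L]], colnames(m))
  if (length(s1) == 0L || length(s2) == 0L)
    stop("both contrast classes need >= 1 sample")
  p1 <- vega_posterior(model, m[, s1, drop = FALSE])
  p2 <- vega_posterior(model, m[, s2, drop = FALSE])
  D <- ncol(p1$mu)
  withr::with_seed(seed, {
    ia <- sample.int(length(s1), n_mc_pairs, replace = TRUE)
    ib <- sample.int(length(s2), n_mc_pairs, replace = TRUE)
    za <- p1$mu[ia, , drop = FALSE] +
      matrix(stats::rnorm(n_mc_pairs * D), n_mc_pairs, D) *
      p1$sd[ia, , drop = FALSE]
    zb <- p2$mu[ib, , drop = FALSE] +
      matrix(stats::rnorm(n_mc_pairs * D), n_mc_pairs, D) *
      p2$sd[ib, , drop = FALSE]
    P <- colMeans(za > zb)
  })
  P <- pmin(pmax(P, 1 / (n_mc_pairs + 1)), n_mc_pairs / (n_mc_pairs + 1))
  bf <- log(P / (1 - P))
  keep <- model$pathway_ids != "UNANNOTATED"
  out <- data.frame(pathway_id = model$pathway_ids[keep],
                    P = P[keep], bayes_factor = bf[keep],
                    significant = abs(bf[keep]) >= log(10),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$bayes_factor), out$pathway_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Two-dimensional UMAP embedding of a latent matrix
#'
#' @param latent Samples x latent matrix (e.g. from [vega_encode()]).
#' @param seed Seed; the embedding is reproducible given it.
#' @param n_neighbors UMAP neighborhood size, auto-reduced (with a warning)
#'   when there are too few samples.
#' @return Data frame: `sample_id`, `umap1`, `umap2`.
#' @export
umap_embed <- function(latent, seed = 1L, n_neighbors = 15L) {
  n <- nrow(latent)
  if (n < 3L) stop("need >= 3 samples for an embedding")
  if (n_neighbors > n - 1L) {
    warning("n_neighbors reduced to ", n - 1L, " (only ", n, " samples)")
    n_neighbors <- n - 1L
  }
  coords <- withr::with_seed(seed, {
    uwot::umap(latent, n_neighbors = n_neighbors, n_threads = 1,
               n_sgd_threads = 0, batch = TRUE)
  })
  data.frame(sample_id = rownames(latent),
             umap1 = coords[, 1L], umap2 = coords[, 2L],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Serialize / restore a trained model
#'
#' The archive holds the configuration, gene and pathway order, mask and
#' weights; the masked zero pattern survives the round trip exactly.
#'
#' @param model A `vega_model`.
#' @param path File path.
#' @return `save_vega`: the path, invisibly. `load_vega`: the model.
#' @export
save_vega <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_vega
#' @export
load_vega <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "vega_model"))
  model
}
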