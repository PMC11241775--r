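# Conditional generator / discriminator pair on 250-dimensional molecular
# latent vectors.
#
# Generator: 50-d category embedding ++ noise -> 2-layer FCN (hidden 128,
# Tanh) -> 64x64x3 quasi-image -> 4 conv units (3x3 conv, LeakyReLU 0.2,
# BatchNorm; units 1-2 downsample 2x) -> 16x16x30 features -> 2-layer FCN
# (middle 500) -> latent of length 250.
#
# Discriminator: latent 250 -> 2-layer FCN (hidden 512) -> 64x64x3
# quasi-image -> 4 conv units with dropout 0.25 (units 1-3 downsample 2x)
# plus a residual connection into the last unit -> 8x8x128 features ->
# two heads: sigmoid real/fake confidence and softmax class probabilities.

GEN_CHANNELS <- c(3L, 16L, 30L, 30L, 30L)
DISC_CHANNELS <- c(3L, 16L, 32L, 64L, 128L)

#' Build the conditional generator network
#'
#' @param n_categories Number of attribute categories (>= 2).
#' @param noise_dim Noise vector length (default 50, symmetric with the
#'   category embedding).
#' @param latent_dim Output latent length (default 250).
#' @param seed Integer seed for the weight initialization.
#' @return An object of class \code{acgan_generator}.
#' @export
build_generator <- function(n_categories, noise_dim = 50L, latent_dim = 250L, seed = 1L) {
  if (!is.numeric(n_categories) || n_categories < 2) stop("BadConfig: n_categories >= 2 required")
  set.seed(as.integer(seed))
  ch <- GEN_CHANNELS
  geoms <- list()
  H <- 64L
  strides <- c(2L, 2L, 1L, 1L)
  for (u in 1:4) {
    ci <- conv_index(H, H, strides[u])
    geoms[[u]] <- list(H = H, W = H, C = ch[u], sidx = ci$sidx,
                       outH = ci$outH, outW = ci$outW, stride = strides[u])
    H <- ci$outH
  }
  params <- list(
    emb = matrix(rnorm(n_categories * 50L, sd = 0.1), n_categories, 50L),
    fc1 = nn_init_dense(50L + noise_dim, 128L, "tanh"),
    fc2 = nn_init_dense(128L, 64L * 64L * 3L, "tanh"),
    conv1 = nn_init_conv(ch[1], ch[2]), bn1 = nn_init_bn(ch[2]),
    conv2 = nn_init_conv(ch[2], ch[3]), bn2 = nn_init_bn(ch[3]),
    conv3 = nn_init_conv(ch[3], ch[4]), bn3 = nn_init_bn(ch[4]),
    conv4 = nn_init_conv(ch[4], ch[5]), bn4 = nn_init_bn(ch[5]),
    fc3 = nn_init_dense(16L * 16L * ch[5], 500L, "tanh"),
    fc4 = nn_init_dense(500L, latent_dim, "linear")
  )
  structure(list(n_categories = as.integer(n_categories),
                 noise_dim = as.integer(noise_dim),
                 latent_dim = as.integer(latent_dim),
                 params = params, geoms = geoms, seed = as.integer(seed),
                 opt = list()),
            class = "acgan_generator")
}

#' @export
print.acgan_generator <- function(x, ...) {
  cat(sprintf("<acgan_generator: %d categories, noise %d, latent %d>\n",
              x$n_categories, x$noise_dim, x$latent_dim))
  invisible(x)
}

gen_forward <- function(G, categories, noise, train = FALSE, return_features = FALSE) {
  p <- G$params
  N <- length(categories)
  stopifnot(nrow(noise) == N, ncol(noise) == G$noise_dim)
  if (any(categories < 1L | categories > G$n_categories)) stop("BadCategory")
  x0 <- cbind(p$emb[categories, , drop = FALSE], noise)
  h1 <- dense_forward(p$fc1, x0); a1 <- tanh_forward(h1)
  h2 <- dense_forward(p$fc2, a1$out); a2 <- tanh_forward(h2)
  x <- t(a2$out)                      # per-sample (h, w, c) layout
  caches <- list(x0 = x0, a1 = a1, a2 = a2)
  feat <- NULL
  for (u in 1:4) {
    cf <- conv_forward(list(geom = G$geoms[[u]]), p[[paste0("conv", u)]], x, N,
                       input_pm = (u == 1L))
    lr <- lrelu_forward(cf$out)
    bn <- bn_forward(p[[paste0("bn", u)]], lr$out, train)
    caches[[paste0("u", u)]] <- list(cf = cf, lr = lr, bn = bn)
    x <- bn$out
  }
  P <- 16L * 16L
  if (return_features) feat <- array(x, c(P, N, GEN_CHANNELS[5]))
  xf <- flatten_cmat(x, P, GEN_CHANNELS[5], N)
  h3 <- dense_forward(p$fc3, xf); a3 <- tanh_forward(h3)
  z <- dense_forward(p$fc4, a3$out)
  caches$xf <- xf; caches$a3 <- a3; caches$categories <- categories
  list(z = z, cache = caches, features = feat)
}

gen_backward <- function(G, cache, dz) {
  p <- G$params
  N <- length(cache$categories)
  g <- list()
  b4 <- dense_backward(p$fc4, cache$a3$out, dz)
  g$fc4 <- b4$grads
  d <- tanh_backward(cache$a3, b4$dx)
  b3 <- dense_backward(p$fc3, cache$xf, d)
  g$fc3 <- b3$grads
  d <- unflatten_grad(b3$dx, 16L * 16L, GEN_CHANNELS[5], N)
  for (u in 4:1) {
    uc <- cache[[paste0("u", u)]]
    bb <- bn_backward(p[[paste0("bn", u)]], uc$bn, d)
    g[[paste0("bn", u)]] <- bb$grads
    d <- lrelu_backward(uc$lr, bb$dx)
    cb <- conv_backward(list(geom = G$geoms[[u]]), p[[paste0("conv", u)]], uc$cf, d, N)
    g[[paste0("conv", u)]] <- cb$grads
    d <- cb$dx
  }
  d <- tanh_backward(cache$a2, t(d))
  b2 <- dense_backward(p$fc2, cache$a1$out, d)
  g$fc2 <- b2$grads
  d <- tanh_backward(cache$a1, b2$dx)
  b1 <- dense_backward(p$fc1, cache$x0, d)
  g$fc1 <- b1$grads
  demb <- matrix(0, G$n_categories, 50L)
  dsum <- rowsum(b1$dx[, 1:50, drop = FALSE], cache$categories)
  demb[as.integer(rownames(dsum)), ] <- dsum
  g$emb <- demb
  g
}

#' Build the auxiliary-classifier discriminator network
#'
#' @param n_categories Number of attribute categories (>= 2).
#' @param latent_dim Input latent length (default 250).
#' @param seed Integer seed for the weight initialization.
#' @return An object of class \code{acgan_discriminator}.
#' @export
build_discriminator <- function(n_categories, latent_dim = 250L, seed = 1L) {
  if (!is.numeric(n_categories) || n_categories < 2) stop("BadConfig: n_categories >= 2 required")
  set.seed(as.integer(seed))
  ch <- DISC_CHANNELS
  geoms <- list()
  H <- 64L
  strides <- c(2L, 2L, 2L, 1L)
  for (u in 1:4) {
    ci <- conv_index(H, H, strides[u])
    geoms[[u]] <- list(H = H, W = H, C = ch[u], sidx = ci$sidx,
                       outH = ci$outH, outW = ci$outW, stride = strides[u])
    H <- ci$outH
  }
  params <- list(
    fc1 = nn_init_dense(latent_dim, 512L, "lrelu"),
    fc2 = nn_init_dense(512L, 64L * 64L * 3L, "lrelu"),
    conv1 = nn_init_conv(ch[1], ch[2]), bn1 = nn_init_bn(ch[2]),
    conv2 = nn_init_conv(ch[2], ch[3]), bn2 = nn_init_bn(ch[3]),
    conv3 = nn_init_conv(ch[3], ch[4]), bn3 = nn_init_bn(ch[4]),
    conv4 = nn_init_conv(ch[4], ch[5]), bn4 = nn_init_bn(ch[5]),
    skip = nn_init_dense(ch[4], ch[5], "linear"),   # 1x1 conv residual projection
    headT1 = nn_init_dense(8L * 8L * ch[5], 128L, "lrelu"),
    headT2 = nn_init_dense(128L, 1L, "linear"),
    headC1 = nn_init_dense(8L * 8L * ch[5], 128L, "lrelu"),
    headC2 = nn_init_dense(128L, as.integer(n_categories), "linear")
  )
  structure(list(n_categories = as.integer(n_categories),
                 latent_dim = as.integer(latent_dim),
                 dropout = 0.25, params = params, geoms = geoms,
                 seed = as.integer(seed), opt = list()),
            class = "acgan_discriminator")
}

#' @export
print.acgan_discriminator <- function(x, ...) {
  cat(sprintf("<acgan_discriminator: %d categories, latent %d>\n",
              x$n_categories, x$latent_dim))
  invisible(x)
}

disc_forward <- function(D, z, train = FALSE, return_features = FALSE) {
  p <- D$params
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  N <- nrow(z)
  h1 <- dense_forward(p$fc1, z); a1 <- lrelu_forward(h1)
  h2 <- dense_forward(p$fc2, a1$out); a2 <- lrelu_forward(h2)
  x <- t(a2$out)                      # per-sample (h, w, c) layout
  caches <- list(z = z, a1 = a1, a2 = a2)
  for (u in 1:4) {
    cf <- conv_forward(list(geom = D$geoms[[u]]), p[[paste0("conv", u)]], x, N,
                       input_pm = (u == 1L))
    lr <- lrelu_forward(cf$out)
    bn <- bn_forward(p[[paste0("bn", u)]], lr$out, train)
    dr <- dropout_forward(bn$out, D$dropout, train)
    caches[[paste0("u", u)]] <- list(cf = cf, lr = lr, bn = bn, dr = dr, xin = x)
    if (u == 3L) caches$res_in <- dr$out
    x <- dr$out
  }
  skip <- dense_forward(p$skip, caches$res_in)
  x <- x + skip
  P <- 8L * 8L
  feat <- if (return_features) array(x, c(P, N, DISC_CHANNELS[5])) else NULL
  xf <- flatten_cmat(x, P, DISC_CHANNELS[5], N)
  t1 <- dense_forward(p$headT1, xf); at <- lrelu_forward(t1)
  conf_logit <- dense_forward(p$headT2, at$out)[, 1]
  c1 <- dense_forward(p$headC1, xf); ac <- lrelu_forward(c1)
  class_logit <- dense_forward(p$headC2, ac$out)
  probs <- softmax_rows(class_logit)
  caches$xf <- xf; caches$at <- at; caches$ac <- ac
  list(confidence = sigmoid(conf_logit), class_probs = probs,
       conf_logit = conf_logit, class_logit = class_logit,
       cache = caches, features = feat)
}

# dconf: gradient of loss wrt conf_logit (length N); dclass: wrt class
# logits (N x k).  Returns parameter grads and the input-latent gradient.
disc_backward <- function(D, cache, dconf, dclass) {
  p <- D$params
  N <- nrow(cache$z)
  g <- list()
  bt2 <- dense_backward(p$headT2, cache$at$out, matrix(dconf, ncol = 1))
  g$headT2 <- bt2$grads
  dt <- lrelu_backward(cache$at, bt2$dx)
  bt1 <- dense_backward(p$headT1, cache$xf, dt)
  g$headT1 <- bt1$grads
  bc2 <- dense_backward(p$headC2, cache$ac$out, dclass)
  g$headC2 <- bc2$grads
  dc <- lrelu_backward(cache$ac, bc2$dx)
  bc1 <- dense_backward(p$headC1, cache$xf, dc)
  g$headC1 <- bc1$grads
  d <- unflatten_grad(bt1$dx + bc1$dx, 8L * 8L, DISC_CHANNELS[5], N)
  bsk <- dense_backward(p$skip, cache$res_in, d)
  g$skip <- bsk$grads
  dres <- bsk$dx
  for (u in 4:1) {
    uc <- cache[[paste0("u", u)]]
    d <- dropout_backward(uc$dr, d)
    bb <- bn_backward(p[[paste0("bn", u)]], uc$bn, d)
    g[[paste0("bn", u)]] <- bb$grads
    d <- lrelu_backward(uc$lr, bb$dx)
    cb <- conv_backward(list(geom = D$geoms[[u]]), p[[paste0("conv", u)]], uc$cf, d, N)
    g[[paste0("conv", u)]] <- cb$grads
    d <- cb$dx
    if (u == 4L) d <- d + dres   # residual skip joins unit-3 output
  }
  d <- lrelu_backward(cache$a2, t(d))
  b2 <- dense_backward(p$fc2, cache$a1$out, d)
  g$fc2 <- b2$grads
  d <- lrelu_backward(cache$a1, b2$dx)
  b1 <- dense_backward(p$fc1, cache$z, d)
  g$fc1 <- b1$grads
  list(grads = g, dz = b1$dx)
}

#' Score latent vectors with the discriminator
#'
#' @param D An \code{acgan_discriminator}.
#' @param z Latent matrix (n x latent_dim).
#' @param chunk Batch size for memory-bounded evaluation.
#' @return List with \code{confidence} in [0,1] and \code{class_probs}
#'   (rows sum to 1).
#' @export
discriminate <- function(D, z, chunk = 256L) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (nrow(z) <= chunk) {
    out <- disc_forward(D, z, train = FALSE)
    return(list(confidence = out$confidence, class_probs = out$class_probs))
  }
  parts <- split(seq_len(nrow(z)), ceiling(seq_len(nrow(z)) / chunk))
  outs <- lapply(parts, function(ix) disc_forward(D, z[ix, , drop = FALSE], train = FALSE))
  list(confidence = unlist(lapply(outs, `[[`, "confidence"), use.names = FALSE),
       class_probs = do.call(rbind, lapply(outs, `[[`, "class_probs")))
}

# evaluation-mode generator pass in memory-bounded chunks
gen_sample <- function(G, categories, noise, chunk = 256L) {
  n <- length(categories)
  if (n <= chunk) return(gen_forward(G, categories, noise, train = FALSE)$z)
  parts <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  do.call(rbind, lapply(parts, function(ix) {
    gen_forward(G, categories[ix], noise[ix, , drop = FALSE], train = FALSE)$z
  }))
}

#' Generate labelled fake latent vectors
#'
#' Draws seeded standard-normal noise, conditions the generator on the
#' requested categories and returns fake-flagged latents.
#'
#' @param G An \code{acgan_generator}.
#' @param categories Integer vector of requested category labels.
#' @param seed Integer seed for the noise draws.
#' @return List with \code{z} (n x latent_dim), \code{category},
#'   \code{provenance = "fake"}.
#' @export
generate_latents <- function(G, categories, seed = 1L) {
  categories <- as.integer(categories)
  set.seed(as.integer(seed))
  noise <- matrix(rnorm(length(categories) * G$noise_dim), length(categories))
  list(z = gen_sample(G, categories, noise), category = categories,
       provenance = "fake")
}

# ---- losses (minimization convention: negative log-likelihoods) ----------

ce_true <- function(probs, labels) {
  -mean(log(clip_prob(probs[cbind(seq_along(labels), labels)])))
}

#' Original AC-GAN objectives
#'
#' The source-discrimination term L_T and the classification term L_C as
#' cross-entropies (both averaged per sample and summed over the real and
#' fake batches), with the original combinations L_D = L_T + L_C and
#' L_G = L_C - L_T.  Retained as the ablation baseline.
#'
#' @param d_real,d_fake Discriminator outputs (lists with \code{confidence}
#'   and \code{class_probs}) on the real and fake batches.
#' @param real_labels,fake_labels Integer category labels of each batch.
#' @return List with \code{L_T}, \code{L_C}, \code{L_D}, \code{L_G}.
#' @export
loss_original <- function(d_real, d_fake, real_labels, fake_labels) {
  lt <- -mean(log(clip_prob(d_real$confidence))) -
    mean(log(clip_prob(1 - d_fake$confidence)))
  lc <- ce_true(d_real$class_probs, real_labels) +
    ce_true(d_fake$class_probs, fake_labels)
  list(L_T = lt, L_C = lc, L_D = lt + lc, L_G = lc - lt)
}

#' Adjusted discriminator loss
#'
#' Adversarial cross-entropy on real and fake confidences plus the
#' classification cross-entropy on real samples only; fake samples carry no
#' classification term, so the discriminator learns category features from
#' ground truth alone.
#'
#' @param d_real,d_fake Discriminator outputs.
#' @param real_labels Integer labels of the real batch.
#' @return Scalar loss.
#' @export
loss_discriminator_adjusted <- function(d_real, d_fake, real_labels) {
  -mean(log(clip_prob(d_real$confidence))) -
    mean(log(clip_prob(1 - d_fake$confidence))) +
    ce_true(d_real$class_probs, real_labels)
}

# nearest same-category real anchor; returns squared distances and indices
anchor_match <- function(z_fake, fake_labels, z_real, real_labels) {
  n <- nrow(z_fake)
  idx <- integer(n)
  d2 <- numeric(n)
  for (i in seq_len(n)) {
    cand <- which(real_labels == fake_labels[i])
    if (!length(cand)) {
      stop("NoRealAnchor: no real latent of category ", fake_labels[i], " in batch")
    }
    dd <- colSums((t(z_real[cand, , drop = FALSE]) - z_fake[i, ])^2)
    j <- which.min(dd)
    idx[i] <- cand[j]
    d2[i] <- dd[j]
  }
  list(idx = idx, d2 = d2)
}

#' Adjusted generator loss
#'
#' Non-saturating adversarial term plus classification cross-entropy on the
#' fake batch, plus a lambda-weighted Euclidean anchor: the mean squared
#' distance from each fake latent to its nearest same-category real latent
#' in the batch, which keeps generation near the ground-truth manifold.
#'
#' @param d_fake Discriminator output on the fake batch.
#' @param fake_labels Integer labels of the fakes.
#' @param z_fake Fake latent matrix.
#' @param z_real Real latent matrix supplying anchors.
#' @param real_labels Labels of \code{z_real}.
#' @param lambda_anchor Anchor weight (default 0.1).
#' @return List with \code{loss}, \code{adv}, \code{class}, \code{anchor}
#'   (the unweighted mean squared distance) and \code{anchor_idx}.
#' @export
loss_generator_adjusted <- function(d_fake, fake_labels, z_fake, z_real,
                                    real_labels, lambda_anchor = 0.1) {
  adv <- -mean(log(clip_prob(d_fake$confidence)))
  cls <- ce_true(d_fake$class_probs, fake_labels)
  if (lambda_anchor != 0) {
    am <- anchor_match(z_fake, fake_labels, z_real, real_labels)
    anc <- mean(am$d2)
    idx <- am$idx
  } else {
    anc <- 0
    idx <- integer(0)
  }
  list(loss = adv + cls + lambda_anchor * anc,
       adv = adv, class = cls, anchor = anc, anchor_idx = idx)
}

#' Save / load a generator-discriminator checkpoint
#'
#' @param model List with elements \code{G}, \code{D} (and optionally
#'   \code{history}).
#' @param path Checkpoint file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model$G, "acgan_generator"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model$G, "acgan_generator"))
  model
}
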