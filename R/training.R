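#' Adaptive balance factor
#'
#' Maps the current generator and discriminator losses to a factor
#' alpha = L_G / (L_G + L_D + 1e-8) in [0,1].  Alpha near 1 means the
#' generator is behind and receives more update steps.
#'
#' @param L_G,L_D Non-negative running losses.
#' @return Alpha in [0,1].
#' @export
balance_factor <- function(L_G, L_D) {
  stopifnot(L_G >= 0, L_D >= 0)
  # epsilon split between numerator and denominator so two vanishing losses
  # give the symmetric 1/2 rather than 0
  a <- (L_G + 5e-9) / (L_G + L_D + 1e-8)
  min(max(a, 0), 1)
}

#' Allocate update steps from the balance factor
#'
#' Splits a per-loop budget of \code{budget_K} update slots between the two
#' networks: steps_G = max(1, round(alpha * K)), steps_D = max(1,
#' round((1 - alpha) * K)), so each network always advances at least once.
#'
#' @param alpha Balance factor in [0,1].
#' @param budget_K Update budget per outer loop (>= 2).
#' @return List with \code{alpha}, \code{steps_G}, \code{steps_D},
#'   \code{budget_K}.
#' @export
allocate_steps <- function(alpha, budget_K = 4L) {
  stopifnot(alpha >= 0, alpha <= 1, budget_K >= 2)
  list(alpha = alpha,
       steps_G = max(1L, as.integer(round(alpha * budget_K))),
       steps_D = max(1L, as.integer(round((1 - alpha) * budget_K))),
       budget_K = as.integer(budget_K))
}

#' Training configuration defaults
#'
#' @param n_categories Number of categories (filled from the data when NULL).
#' @param latent_dim,noise_dim Network dimensions.
#' @param lambda_anchor Euclidean anchor weight in the generator loss.
#' @param budget_K Update-step budget per outer loop.
#' @param stop_loss Epoch-mean discriminator-loss threshold ending training
#'   (0 disables the stop rule).
#' @param max_epochs Maximum number of passes over the data.
#' @param batch_size Minibatch size.
#' @param lr Learning rate of the RMSprop updates.
#' @param ema_decay Exponential-window decay for the running losses feeding
#'   the balance factor.
#' @param adaptive Use the balance factor; \code{FALSE} fixes
#'   steps_G = steps_D = 1 (the fixed-step baseline).
#' @param seed Root seed for initialization, shuffling, noise and dropout.
#' @return Config list.
#' @export
train_config <- function(n_categories = NULL, latent_dim = 250L, noise_dim = 50L,
                         lambda_anchor = 0.1, budget_K = 4L, stop_loss = 0.5,
                         max_epochs = 10L, batch_size = 64L, lr = 2e-4,
                         ema_decay = 0.9, adaptive = TRUE, seed = 1L) {
  stopifnot(stop_loss >= 0, max_epochs >= 1, batch_size >= 2)
  as.list(environment())
}

#' Train the conditional GAN on labelled latent vectors
#'
#' Alternates discriminator updates (adjusted discriminator loss) and
#' generator updates (adjusted generator loss with the Euclidean anchor),
#' re-allocating the per-loop update budget from the balance factor computed
#' on exponentially averaged losses.  One epoch is one pass over the data;
#' every update step consumes the next minibatch of the shuffled stream.
#' Training stops at the first epoch whose mean discriminator loss falls to
#' \code{stop_loss} or below, or at \code{max_epochs}.
#'
#' @param z Real latent matrix (n x latent_dim).
#' @param labels Integer category labels (values in 1..n_categories).
#' @param config From \code{\link{train_config}}.
#' @param verbose Print per-epoch summaries.
#' @return List with \code{G}, \code{D} and \code{history} (epoch means of
#'   both losses, the alpha trace, per-epoch latent-space category accuracy,
#'   \code{stop_epoch}, \code{stopped_early}).
#' @export
train_acgan <- function(z, labels, config = train_config(), verbose = FALSE) {
  stopifnot(is.matrix(z), nrow(z) == length(labels))
  labels <- as.integer(labels)
  k <- length(unique(labels))
  if (k < 2L) stop("DegenerateData: training needs at least two categories")
  if (is.null(config$n_categories)) config$n_categories <- max(labels)
  n <- nrow(z)
  set.seed(as.integer(config$seed))
  G <- build_generator(config$n_categories, config$noise_dim,
                       ncol(z), seed = sample.int(1e6, 1))
  D <- build_discriminator(config$n_categories, ncol(z), seed = sample.int(1e6, 1))
  opt_G <- list()
  opt_D <- list()
  by_cat <- split(seq_len(n), labels)

  ema_LD <- NA_real_
  ema_LG <- NA_real_
  ema <- function(old, new, d) if (is.na(old)) new else d * old + (1 - d) * new

  hist <- list(L_D = numeric(0), L_G = numeric(0), alpha = list(),
               accuracy = list(), stop_epoch = NA_integer_, stopped_early = FALSE)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    pos <- 0L
    ep_LD <- c(); ep_LG <- c(); ep_alpha <- c()
    next_batch <- function() {
      if (pos >= n) return(NULL)
      take <- min(config$batch_size, n - pos)
      if (take < 2L) { pos <<- n; return(NULL) }
      b <- ord[(pos + 1L):(pos + take)]
      pos <<- pos + take
      b
    }
    repeat {
      if (pos >= n) break
      alpha <- if (!config$adaptive) 0.5
               else if (is.na(ema_LG) || is.na(ema_LD)) 0.5
               else balance_factor(ema_LG, ema_LD)
      st <- if (config$adaptive) allocate_steps(alpha, config$budget_K)
            else list(steps_G = 1L, steps_D = 1L)
      ep_alpha <- c(ep_alpha, alpha)
      for (s in seq_len(st$steps_D)) {
        b <- next_batch()
        if (is.null(b)) break
        zr <- z[b, , drop = FALSE]
        yr <- labels[b]
        noise <- matrix(rnorm(length(b) * G$noise_dim), length(b))
        gf <- gen_forward(G, yr, noise, train = TRUE)
        df <- disc_forward(D, rbind(zr, gf$z), train = TRUE)
        nr <- length(b)
        ir <- seq_len(nr); ifk <- nr + seq_len(nr)
        d_real <- list(confidence = df$confidence[ir],
                       class_probs = df$class_probs[ir, , drop = FALSE])
        d_fake <- list(confidence = df$confidence[ifk],
                       class_probs = df$class_probs[ifk, , drop = FALSE])
        ld <- loss_discriminator_adjusted(d_real, d_fake, yr)
        if (!is.finite(ld)) stop("NonFinite: discriminator loss diverged")
        # gradient wrt logits of the adjusted loss
        dconf <- c((d_real$confidence - 1) / nr, d_fake$confidence / nr)
        dclass <- matrix(0, 2 * nr, D$n_categories)
        oh <- df$class_probs[ir, , drop = FALSE]
        oh[cbind(ir, yr)] <- oh[cbind(ir, yr)] - 1
        dclass[ir, ] <- oh / nr
        db <- disc_backward(D, df$cache, dconf, dclass)
        upd <- rmsprop_update(D$params, db$grads, opt_D, lr = config$lr)
        D$params <- upd$params; opt_D <- upd$state
        D <- apply_bn_updates(D, df$cache)
        ema_LD <- ema(ema_LD, ld, config$ema_decay)
        ep_LD <- c(ep_LD, ld)
      }
      for (s in seq_len(st$steps_G)) {
        b <- next_batch()
        if (is.null(b)) break
        yf <- labels[b]           # condition on the real label distribution
        noise <- matrix(rnorm(length(b) * G$noise_dim), length(b))
        gf <- gen_forward(G, yf, noise, train = TRUE)
        df <- disc_forward(D, gf$z, train = TRUE)
        nf <- length(b)
        lg <- loss_generator_adjusted(
          list(confidence = df$confidence, class_probs = df$class_probs),
          yf, gf$z, z, labels, config$lambda_anchor)
        if (!is.finite(lg$loss)) stop("NonFinite: generator loss diverged")
        dconf <- (df$confidence - 1) / nf
        dclass <- df$class_probs
        dclass[cbind(seq_len(nf), yf)] <- dclass[cbind(seq_len(nf), yf)] - 1
        dclass <- dclass / nf
        db <- disc_backward(D, df$cache, dconf, dclass)
        dz <- db$dz
        if (config$lambda_anchor != 0) {
          anchors <- z[lg$anchor_idx, , drop = FALSE]
          dz <- dz + 2 * config$lambda_anchor * (gf$z - anchors) / nf
        }
        gg <- gen_backward(G, gf$cache, dz)
        upd <- rmsprop_update(G$params, gg, opt_G, lr = config$lr)
        G$params <- upd$params; opt_G <- upd$state
        G <- apply_bn_updates(G, gf$cache)
        ema_LG <- ema(ema_LG, lg$loss, config$ema_decay)
        ep_LG <- c(ep_LG, lg$loss)
      }
    }
    hist$L_D <- c(hist$L_D, mean(ep_LD))
    hist$L_G <- c(hist$L_G, if (length(ep_LG)) mean(ep_LG) else NA_real_)
    hist$alpha[[epoch]] <- ep_alpha
    acc <- latent_category_accuracy(G, z, labels,
                                    n_per_class = min(50L, max(table(labels))))
    hist$accuracy[[epoch]] <- acc
    if (verbose) {
      message(sprintf("epoch %d: L_D %.3f  L_G %.3f  alpha %.2f  acc %.2f",
                      epoch, mean(ep_LD), mean(ep_LG), mean(ep_alpha), mean(acc)))
    }
    if (config$stop_loss > 0 && mean(ep_LD) <= config$stop_loss) {
      hist$stop_epoch <- epoch
      hist$stopped_early <- TRUE
      break
    }
  }
  if (is.na(hist$stop_epoch)) hist$stop_epoch <- length(hist$L_D)
  list(G = G, D = D, history = hist)
}

#' Latent-space category accuracy
#'
#' Generates latents for every category and scores them by nearest-neighbour
#' label agreement against a reference labelled latent set: the fraction of
#' generated latents whose nearest real latent carries the requested label.
#'
#' @param G Trained generator.
#' @param z_ref,ref_labels Reference latents and labels.
#' @param n_per_class Generated latents per category.
#' @param seed Seed for the noise draws.
#' @return Named numeric vector of per-category accuracies.
#' @export
latent_category_accuracy <- function(G, z_ref, ref_labels, n_per_class = 100L,
                                     seed = NULL) {
  cats <- sort(unique(as.integer(ref_labels)))
  req <- rep(cats, each = n_per_class)
  if (!is.null(seed)) set.seed(as.integer(seed))
  noise <- matrix(rnorm(length(req) * G$noise_dim), length(req))
  zf <- gen_sample(G, req, noise)
  rn <- rowSums(z_ref^2)
  d2 <- outer(rowSums(zf^2), rn, "+") - 2 * (zf %*% t(z_ref))
  nn <- max.col(-d2, ties.method = "first")
  hit <- as.integer(ref_labels)[nn] == req
  vapply(cats, function(cc) mean(hit[req == cc]), numeric(1))
}

#' Molecule-level category accuracy
#'
#' Generates \code{n} latents conditioned on one category, decodes them,
#' recomputes the attribute and returns the fraction landing in the
#' requested interval.
#'
#' @param G Trained generator.
#' @param codec Codec used for decoding.
#' @param spec An \code{\link{attribute_spec}}.
#' @param category Requested category.
#' @param n Number of molecules to generate.
#' @param seed Seed for the noise draws.
#' @return Fraction in [0,1].
#' @export
category_accuracy <- function(G, codec, spec, category, n = 1000L, seed = 1L) {
  stopifnot(n >= 1)
  gl <- generate_latents(G, rep(as.integer(category), n), seed = seed)
  smi <- decode_latents(codec, gl$z)
  vals <- compute_attributes(unique(smi))
  lut <- setNames(assign_category(spec, vals[[spec$name]]), vals$smiles)
  mean(lut[smi] == category)
}
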