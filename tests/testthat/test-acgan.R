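test_that("generator architecture matches its layer contract", {
  G <- build_generator(6, seed = 2)
  # widths: 50-d embedding, 128 hidden, 64x64x3 image, 500-wide middle, 250 out
  expect_equal(dim(G$params$emb), c(6L, 50L))
  expect_equal(dim(G$params$fc1$W), c(100L, 128L))
  expect_equal(dim(G$params$fc2$W), c(128L, 64L * 64L * 3L))
  expect_equal(dim(G$params$fc3$W), c(16L * 16L * 30L, 500L))
  expect_equal(dim(G$params$fc4$W), c(500L, 250L))

  set.seed(1)
  noise <- matrix(rnorm(8 * 50), 8)
  out <- gen_forward(G, rep(1:4, 2), noise, train = TRUE, return_features = TRUE)
  expect_equal(dim(out$z), c(8L, 250L))
  expect_equal(dim(out$features), c(256L, 8L, 30L))  # 16 x 16 x 30 block
  expect_error(build_generator(1), "BadConfig")
})

test_that("discriminator architecture matches its layer contract", {
  D <- build_discriminator(6, seed = 2)
  expect_equal(dim(D$params$fc1$W), c(250L, 512L))
  expect_equal(dim(D$params$fc2$W), c(512L, 64L * 64L * 3L))
  set.seed(1)
  z <- matrix(rnorm(5 * 250), 5)
  out <- disc_forward(D, z, train = FALSE, return_features = TRUE)
  expect_equal(dim(out$features), c(64L, 5L, 128L))  # 8 x 8 x 128 block
  expect_true(all(out$confidence >= 0 & out$confidence <= 1))
  expect_equal(rowSums(out$class_probs), rep(1, 5), tolerance = 1e-6)
  expect_true(all(out$class_probs >= 0))
  expect_error(build_discriminator(1), "BadConfig")
})

test_that("latent generation is seeded, labelled and category-checked", {
  G <- build_generator(4, seed = 3)
  g1 <- generate_latents(G, rep(3L, 10), seed = 5)
  expect_equal(dim(g1$z), c(10L, 250L))
  expect_true(all(g1$category == 3L))
  expect_identical(g1$provenance, "fake")
  expect_identical(g1, generate_latents(G, rep(3L, 10), seed = 5))
  g2 <- generate_latents(G, rep(3L, 10), seed = 6)
  expect_false(identical(g1$z, g2$z))
  expect_error(generate_latents(G, 9L, seed = 1), "BadCategory")
})

make_output <- function(conf, probs) list(confidence = conf, class_probs = probs)

test_that("original objectives realize the cross-entropy forms", {
  # perfect discriminator: both terms at the optimum (0 under minimization)
  perfect_r <- make_output(c(1, 1), matrix(c(1, 0, 0, 1), 2, byrow = TRUE))
  perfect_f <- make_output(c(0, 0), matrix(c(1, 0, 0, 1), 2, byrow = TRUE))
  l0 <- loss_original(perfect_r, perfect_f, c(1L, 2L), c(1L, 2L))
  expect_equal(l0$L_T, 0, tolerance = 1e-5)
  expect_equal(l0$L_C, 0, tolerance = 1e-5)

  # uniform class head over k classes: classification term = ln k per batch
  k <- 5
  unif <- matrix(1 / k, 2, k)
  lu <- loss_original(make_output(c(1, 1), unif), make_output(c(0, 0), unif),
                      c(2L, 4L), c(1L, 5L))
  expect_equal(lu$L_C, 2 * log(k), tolerance = 1e-6)

  # hand-computed two-sample oracle: real conf .9, fake conf .2,
  # true-class probs .8 (real) and .7 (fake)
  pr <- matrix(c(0.8, 0.2, 0.15, 0.8), 2, byrow = TRUE)  # row1 true=1, row2 true=2
  pf <- matrix(c(0.7, 0.3, 0.25, 0.7), 2, byrow = TRUE)
  lh <- loss_original(make_output(c(0.9, 0.9), pr), make_output(c(0.2, 0.2), pf),
                      c(1L, 2L), c(1L, 2L))
  expect_equal(lh$L_T, -log(0.9) - log(1 - 0.2), tolerance = 1e-9)
  expect_equal(lh$L_C, -mean(log(c(0.8, 0.8))) - mean(log(c(0.7, 0.7))),
               tolerance = 1e-9)
  expect_equal(lh$L_D, lh$L_T + lh$L_C)
  expect_equal(lh$L_G, lh$L_C - lh$L_T)
})

test_that("adjusted discriminator loss ignores fake classification entirely", {
  pr <- matrix(c(0.8, 0.2, 0.15, 0.8), 2, byrow = TRUE)
  d_real <- make_output(c(0.9, 0.9), pr)
  pf1 <- matrix(c(0.99, 0.01, 0.99, 0.01), 2, byrow = TRUE)
  pf2 <- matrix(c(0.01, 0.99, 0.01, 0.99), 2, byrow = TRUE)
  l1 <- loss_discriminator_adjusted(d_real, make_output(c(0.2, 0.2), pf1), c(1L, 2L))
  l2 <- loss_discriminator_adjusted(d_real, make_output(c(0.2, 0.2), pf2), c(1L, 2L))
  expect_identical(l1, l2)
  expect_equal(l1, -log(0.9) - log(0.8) - mean(log(c(0.8, 0.8))), tolerance = 1e-9)

  perfect <- loss_discriminator_adjusted(
    make_output(c(1, 1), matrix(c(1, 0, 0, 1), 2, byrow = TRUE)),
    make_output(c(0, 0), pf1), c(1L, 2L))
  expect_equal(perfect, 0, tolerance = 1e-5)
})

test_that("adjusted generator loss combines adversarial, class and anchor terms", {
  zf <- matrix(c(1, rep(0, 249)), 1)
  zr <- rbind(c(1, rep(0, 249)), c(4, rep(0, 249)))
  d_fake <- make_output(0.5, matrix(c(0.6, 0.4), 1))
  # lambda = 0 reduces to adversarial + classification
  l0 <- loss_generator_adjusted(d_fake, 1L, zf, zr, c(1L, 1L), lambda_anchor = 0)
  expect_equal(l0$loss, -log(0.5) - log(0.6), tolerance = 1e-9)
  # fake identical to its nearest anchor: anchor term 0
  li <- loss_generator_adjusted(d_fake, 1L, zf, zr, c(1L, 1L), lambda_anchor = 0.1)
  expect_equal(li$anchor, 0)
  # unique anchor at distance 3: contribution lambda * d^2
  lu <- loss_generator_adjusted(d_fake, 1L, zf, zr[2, , drop = FALSE], 1L,
                                lambda_anchor = 0.1)
  expect_equal(lu$loss - l0$loss, 0.1 * 9, tolerance = 1e-9)
  # a category with no real representative raises
  expect_error(loss_generator_adjusted(d_fake, 1L, zf, zr, c(2L, 2L)),
               "NoRealAnchor")
})

test_that("losses stay finite under probability clipping", {
  ext <- make_output(c(0, 1), matrix(c(0, 1, 1, 0), 2, byrow = TRUE))
  l <- loss_original(ext, ext, c(1L, 1L), c(2L, 2L))
  expect_true(all(is.finite(unlist(l))))
  expect_true(is.finite(loss_discriminator_adjusted(ext, ext, c(1L, 2L))))
})

test_that("a small generator step against a frozen discriminator lowers its loss", {
  set.seed(21)
  G <- build_generator(3, seed = 31)
  D <- build_discriminator(3, seed = 32)
  cats <- rep(1:3, each = 4)
  noise <- matrix(rnorm(12 * 50), 12)
  zr <- matrix(rnorm(12 * 250), 12) + 5 * (col(matrix(0, 12, 250)) <= 3)
  yr <- rep(1:3, each = 4)

  eval_loss <- function(G) {
    set.seed(77)   # fixed dropout stream
    gf <- gen_forward(G, cats, noise, train = TRUE)
    df <- disc_forward(D, gf$z, train = TRUE)
    lg <- loss_generator_adjusted(
      list(confidence = df$confidence, class_probs = df$class_probs),
      cats, gf$z, zr, yr, 0.1)
    list(loss = lg$loss, gf = gf, df = df, lg = lg)
  }
  before <- eval_loss(G)
  n <- length(cats)
  dconf <- (before$df$confidence - 1) / n
  dclass <- before$df$class_probs
  dclass[cbind(seq_len(n), cats)] <- dclass[cbind(seq_len(n), cats)] - 1
  dclass <- dclass / n
  db <- disc_backward(D, before$df$cache, dconf, dclass)
  dz <- db$dz + 2 * 0.1 * (before$gf$z - zr[before$lg$anchor_idx, , drop = FALSE]) / n
  gg <- gen_backward(G, before$gf$cache, dz)
  # plain small gradient step
  step <- function(p, g, lr = 1e-4) {
    for (nm in names(g)) {
      if (is.list(g[[nm]])) p[[nm]] <- step(p[[nm]], g[[nm]], lr)
      else p[[nm]] <- p[[nm]] - lr * g[[nm]]
    }
    p
  }
  G$params <- step(G$params, gg)
  expect_lte(eval_loss(G)$loss, before$loss + 1e-6)
})

test_that("model checkpoints round-trip", {
  G <- build_generator(3, seed = 1)
  D <- build_discriminator(3, seed = 1)
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_model(list(G = G, D = D), tmp)
  back <- load_model(tmp)
  expect_identical(back$G$params, G$params)
})

test_that("backpropagation agrees with finite differences", {
  set.seed(99)
  N <- 3L
  G <- build_generator(3, seed = 5)
  cats <- c(1L, 2L, 3L)
  noise <- matrix(rnorm(N * 50), N)
  R <- matrix(rnorm(N * 250), N)
  fwd <- function(G) { set.seed(7); sum(gen_forward(G, cats, noise, train = TRUE)$z * R) }
  set.seed(7)
  out <- gen_forward(G, cats, noise, train = TRUE)
  gr <- gen_backward(G, out$cache, R)
  eps <- 1e-3    # single-precision kernels: coarse step, loose relative band
  for (p in list(c("conv1", "W", 7), c("conv4", "W", 200), c("bn2", "gamma", 4),
                 c("fc3", "W", 1234))) {
    i <- as.integer(p[3])
    g0 <- gr[[p[1]]][[p[2]]][i]
    G2 <- G
    G2$params[[p[1]]][[p[2]]][i] <- G2$params[[p[1]]][[p[2]]][i] + eps
    f1 <- fwd(G2)
    G2$params[[p[1]]][[p[2]]][i] <- G2$params[[p[1]]][[p[2]]][i] - 2 * eps
    f0 <- fwd(G2)
    expect_equal(g0, (f1 - f0) / (2 * eps), tolerance = 2e-2)
  }

  D <- build_discriminator(3, seed = 6)
  z <- matrix(rnorm(4 * 250), 4)
  y <- c(1L, 2L)
  lossfun <- function(D, z) {
    set.seed(11)
    df <- disc_forward(D, z, train = TRUE)
    loss_discriminator_adjusted(
      list(confidence = df$confidence[1:2], class_probs = df$class_probs[1:2, , drop = FALSE]),
      list(confidence = df$confidence[3:4], class_probs = df$class_probs[3:4, , drop = FALSE]), y)
  }
  set.seed(11)
  df <- disc_forward(D, z, train = TRUE)
  dconf <- c((df$confidence[1:2] - 1) / 2, df$confidence[3:4] / 2)
  dclass <- matrix(0, 4, 3)
  oh <- df$class_probs[1:2, , drop = FALSE]
  oh[cbind(1:2, y)] <- oh[cbind(1:2, y)] - 1
  dclass[1:2, ] <- oh / 2
  db <- disc_backward(D, df$cache, dconf, dclass)
  for (p in list(c("conv3", "W", 99), c("skip", "W", 17), c("headC2", "W", 5))) {
    i <- as.integer(p[3])
    g0 <- db$grads[[p[1]]][[p[2]]][i]
    D2 <- D
    D2$params[[p[1]]][[p[2]]][i] <- D2$params[[p[1]]][[p[2]]][i] + eps
    f1 <- lossfun(D2, z)
    D2$params[[p[1]]][[p[2]]][i] <- D2$params[[p[1]]][[p[2]]][i] - 2 * eps
    f0 <- lossfun(D2, z)
    expect_equal(g0, (f1 - f0) / (2 * eps), tolerance = 2e-2)
  }
  # gradient with respect to the input latents
  for (i in c(5L, 900L)) {
    z2 <- z; z2[i] <- z2[i] + eps; f1 <- lossfun(D, z2)
    z2[i] <- z2[i] - 2 * eps; f0 <- lossfun(D, z2)
    expect_equal(db$dz[i], (f1 - f0) / (2 * eps), tolerance = 2e-2)
  }
})
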