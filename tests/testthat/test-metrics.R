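test_that("validity, novelty and uniqueness count canonical identities", {
  expect_equal(validity(c("c1ccccc1", "CCO")), 1.0)
  expect_equal(validity(c("c1ccccc1", "C1CC")), 0.5)
  expect_error(validity(character(0)), "EmptyInput")

  expect_equal(novelty(c("CCO", "c1ccccc1"), c("CCO", "c1ccccc1")), 0.0)
  expect_equal(novelty(c("CCO", "CCN"), c("c1ccccc1")), 1.0)
  # duplicates in the generated set count individually; spellings canonicalize
  gen <- c("C1=CC=CC=C1", "c1ccccc1", "CCO", "CCO", "CCN", "CCC", "CC", "C",
           "CCCC", "CCCCC")
  expect_equal(novelty(gen, c("c1ccccc1", "CCO", "C", "CC")), 0.4)

  expect_equal(uniqueness(c("C", "C", "CC")), 2 / 3)
  expect_equal(uniqueness(c("C", "CC", "CCC")), 1.0)
  dup20 <- rep(probe_set(), 4)
  expect_equal(uniqueness(dup20), 5 / 20)
})

test_that("internal diversity matches the double-loop oracle", {
  expect_equal(internal_diversity("c1ccccc1"), 0.0)
  expect_equal(internal_diversity(c("CCO", "CCO"), 2), 0.0)
  smi <- probe_set()
  bits <- morgan_bits(smi)
  for (p in c(1, 2)) {
    acc <- 0
    for (i in seq_along(bits)) for (j in seq_along(bits)) {
      acc <- acc + oracle_tanimoto(bits[[i]], bits[[j]])^p
    }
    oracle <- 1 - (acc / length(bits)^2)^(1 / p)
    expect_equal(internal_diversity(smi, p), oracle, tolerance = 1e-10)
  }
})

test_that("nearest-neighbour similarity matches the double-loop oracle", {
  smi <- probe_set()
  expect_equal(snn(smi, smi), 1.0)
  expect_equal(snn("CCO", "CCN"),
               oracle_tanimoto(morgan_bits("CCO")[[1]], morgan_bits("CCN")[[1]]),
               tolerance = 1e-10)
  G <- test_library()$molecules[1:5]
  R <- test_library()$molecules[6:12]
  bg <- morgan_bits(G); br <- morgan_bits(R)
  oracle <- mean(vapply(bg, function(b) {
    max(vapply(br, function(r) oracle_tanimoto(b, r), numeric(1)))
  }, numeric(1)))
  expect_equal(snn(G, R), oracle, tolerance = 1e-10)
})

test_that("fragment and scaffold similarities are count-vector cosines", {
  smi <- probe_set()
  expect_equal(fragment_similarity(smi, smi), 1.0)
  expect_equal(scaffold_similarity(smi, smi), 1.0)

  G <- test_library()$molecules[1:5]
  R <- test_library()$molecules[6:10]
  for (fn in list(list(fragment_profile, fragment_similarity),
                  list(scaffold_profile, scaffold_similarity))) {
    cg <- fn[[1]](G); cr <- fn[[1]](R)
    keys <- union(names(cg), names(cr))
    vg <- vr <- setNames(numeric(length(keys)), keys)
    vg[names(cg)] <- cg; vr[names(cr)] <- cr
    oracle <- sum(vg * vr) / sqrt(sum(vg^2) * sum(vr^2))
    expect_equal(fn[[2]](G, R), oracle, tolerance = 1e-10)
  }

  # different molecules sharing all scaffolds still score one
  expect_equal(scaffold_similarity(c("Cc1ccccc1", "CCc1ccccc1"),
                                   c("CCCc1ccccc1", "OCc1ccccc1")), 1.0)
  # acyclic molecules carry empty scaffold profiles
  expect_error(scaffold_similarity(c("CCO", "CCC"), c("CCN")),
               "BothProfilesEmpty")
  expect_equal(scaffold_similarity(c("CCO"), c("c1ccccc1")), 0)
  # fragment-disjoint sets
  expect_equal(fragment_similarity("CCO", "c1ccccc1CNc1ccccc1"), 0)
})

test_that("an uncleavable molecule is its own single BRICS fragment", {
  cp <- fragment_profile("CCO")
  expect_equal(sum(cp), 1)
})

test_that("activation statistics are the sample mean and covariance", {
  am <- surrogate_activation_model(dim = 16, seed = 4)
  s1 <- activation_stats("CCO", am)
  expect_equal(s1$sigma, matrix(0, 16, 16))
  expect_equal(s1$n, 1L)

  smi <- probe_set()
  st <- activation_stats(smi, am)
  act <- am(smi)
  expect_equal(st$mu, colMeans(act), tolerance = 1e-12)
  # two-pass oracle covariance
  cc <- matrix(0, 16, 16)
  for (i in seq_len(nrow(act))) {
    d <- act[i, ] - colMeans(act)
    cc <- cc + outer(d, d)
  }
  expect_equal(st$sigma, cc / (nrow(act) - 1), tolerance = 1e-10,
               ignore_attr = TRUE)

  dup <- activation_stats(rep(smi, 2), am)
  expect_equal(dup$mu, st$mu)
  expect_equal(dup$n, 10L)
})

test_that("Frechet distance matches closed forms and is a symmetric premetric", {
  mk <- function(mu, sigma) structure(list(mu = mu, sigma = sigma, n = 10L),
                                      class = "distribution_stats")
  a <- mk(c(0, 1), diag(c(1, 2)))
  expect_equal(frechet_distance(a, a), 0)
  # 1-D closed form: (mu1-mu2)^2 + (sd1-sd2)^2
  expect_equal(frechet_distance(mk(0, matrix(1)), mk(3, matrix(1))), 9,
               tolerance = 1e-8)
  expect_equal(frechet_distance(mk(0, matrix(4)), mk(1, matrix(1))),
               1 + (2 - 1)^2, tolerance = 1e-8)
  # diagonal 5-D equals the per-dimension sum of 1-D closed forms
  set.seed(9)
  m1 <- rnorm(5); m2 <- rnorm(5)
  v1 <- runif(5, 0.5, 2); v2 <- runif(5, 0.5, 2)
  expect_equal(frechet_distance(mk(m1, diag(v1)), mk(m2, diag(v2))),
               sum((m1 - m2)^2) + sum((sqrt(v1) - sqrt(v2))^2),
               tolerance = 1e-8)
  # symmetry and non-negativity on random PSD stats
  for (i in 1:20) {
    r1 <- matrix(rnorm(25), 5); r2 <- matrix(rnorm(25), 5)
    s1 <- mk(rnorm(5), crossprod(r1) / 5)
    s2 <- mk(rnorm(5), crossprod(r2) / 5)
    d12 <- frechet_distance(s1, s2)
    expect_gte(d12, 0)
    expect_equal(d12, frechet_distance(s2, s1), tolerance = 1e-6)
  }
  expect_error(frechet_distance(mk(0, matrix(1)), a), "DimensionMismatch")
})

test_that("fingerprint similarities follow the set-overlap definitions", {
  f1 <- fingerprint("c1ccccc1", "maccs")
  expect_equal(pairwise_similarity(f1, f1, "tanimoto"), 1.0)
  expect_equal(pairwise_similarity(f1, f1, "dice"), 1.0)
  mk <- function(bits) structure(list(bits = bits, nbits = 1024L,
                                      kind = "morgan_r2_1024"),
                                 class = "chem_fp")
  expect_equal(pairwise_similarity(mk(1:3), mk(2:4), "tanimoto"), 0.5)
  expect_equal(pairwise_similarity(mk(1:3), mk(2:4), "dice"), 2 * 2 / 6)
  expect_equal(pairwise_similarity(mk(1:3), mk(7:9), "tanimoto"), 0)
  expect_error(pairwise_similarity(f1, mk(1:3)), "KindMismatch")
})

test_that("bounded metrics respect their limits on random molecule subsets", {
  lib <- test_library()$molecules
  set.seed(31)
  for (i in 1:25) {
    G <- sample(lib, sample(3:8, 1))
    R <- sample(lib, sample(3:8, 1))
    vals <- c(internal_diversity(G, 1), internal_diversity(G, 2),
              snn(G, R), fragment_similarity(G, R))
    sc <- tryCatch(scaffold_similarity(G, R), error = function(e) 0.5)
    vals <- c(vals, sc)
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("set-level evaluation report carries all suite metrics", {
  G <- test_library()$molecules[1:8]
  R <- test_library()$molecules[5:15]
  rep <- evaluate_sets(G, R)
  expect_named(rep, c("validity", "novelty", "uniqueness", "int_div1",
                      "int_div2", "snn", "frag", "scaf", "fcd"))
  expect_equal(rep$validity, 1.0)
  expect_gte(rep$fcd, 0)
  self <- evaluate_sets(G, G)
  expect_equal(self$novelty, 0.0)
  expect_equal(self$snn, 1.0)
  expect_equal(self$fcd, 0, tolerance = 1e-6)
})
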