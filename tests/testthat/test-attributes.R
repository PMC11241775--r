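test_that("canonicalization is idempotent and spelling-invariant", {
  two <- parse_and_canonicalize(c("c1ccccc1", "C1=CC=CC=C1"))
  expect_identical(two[1], two[2])
  expect_identical(parse_and_canonicalize(two[1]), two[1])
  expect_error(parse_and_canonicalize("C1CC"), "InvalidSmiles")
  expect_error(parse_and_canonicalize(""), "InvalidSmiles")
  # a realistic drug-like structure parses
  expect_silent(parse_and_canonicalize("CC(=O)Nc1ccc(OCC(=O)NCC2=CC=CN=C2)cc1"))
})

test_that("attribute values are deterministic and land in their ranges", {
  smi <- probe_set()
  a1 <- compute_attributes(smi)
  a2 <- compute_attributes(smi)
  expect_identical(a1, a2)
  expect_true(all(a1$qed >= 0 & a1$qed <= 1))
  expect_true(all(a1$sas >= 1 & a1$sas <= 10))
})

test_that("interval specs define the three binning schemes", {
  expect_equal(attribute_spec("logp")$n_categories, 6L)
  expect_equal(attribute_spec("qed")$n_categories, 6L)
  expect_equal(attribute_spec("sas")$n_categories, 7L)
  lg <- attribute_spec("logp")
  expect_true(all(diff(lg$edges) > 0))
  # boundary belongs to the lower-indexed interval
  expect_identical(assign_category(lg, 0), 1L)
  expect_identical(assign_category(lg, 1.735), 3L)
  expect_identical(assign_category(lg, 4.0001), 6L)
  expect_identical(assign_category(attribute_spec("sas"), 2.246), 2L)
  expect_identical(assign_category(attribute_spec("qed"), c(0.5, 0.95)), c(1L, 6L))
  expect_error(assign_category(attribute_spec("qed"), 1.2), "OutOfRange")
  expect_error(assign_category(attribute_spec("sas"), -0.5), "OutOfRange")
  expect_error(assign_category(lg, Inf), "OutOfRange")
})

test_that("binning is a partition and monotone in the value", {
  set.seed(42)
  for (nm in c("logp", "qed", "sas")) {
    sp <- attribute_spec(nm)
    lo <- if (is.finite(sp$lower)) sp$lower else -15
    hi <- if (is.finite(sp$upper)) sp$upper else 15
    v <- sort(runif(10000, lo + 1e-9, hi))
    cc <- assign_category(sp, v)
    expect_true(all(cc >= 1L & cc <= sp$n_categories))
    expect_true(all(diff(cc) >= 0))        # monotone non-decreasing
    expect_setequal(unique(cc), seq_len(sp$n_categories))
  }
})

test_that("prepare_dataset counts rejections and categorizes survivors", {
  prep <- prepare_dataset(c("c1ccccc1", "C1CC", "CCO"), attribute_spec("logp"))
  expect_equal(nrow(prep$records), 2L)
  expect_equal(prep$n_rejected, 1L)
  expect_true(all(c("logp", "qed", "sas", "category") %in% names(prep$records)))
  expect_identical(prep$records$category,
                   assign_category(attribute_spec("logp"), prep$records$logp))

  all_ok <- prepare_dataset(probe_set(), attribute_spec("qed"))
  expect_equal(all_ok$n_rejected, 0L)
})

test_that("prepare_dataset drops molecules the codec cannot embed", {
  lib <- test_library()
  codec <- fit_surrogate_codec(lib$molecules[1:60], seed = 1)
  pool <- lib$molecules[1:100]
  encodable <- vapply(pool,
                      function(s) tryCatch({ encode_molecules(codec, s); TRUE },
                                           error = function(e) FALSE),
                      logical(1))
  expected_reject <- sum(!encodable)
  expect_gt(expected_reject, 0L)   # the held-out tail has unseen bits
  prep <- prepare_dataset(pool, attribute_spec("logp"), codec)
  expect_equal(prep$n_rejected, expected_reject)
  expect_equal(nrow(prep$records), sum(encodable))
})

test_that("oversampling balances categories, keeps originals, is seeded", {
  rec <- data.frame(smiles = sprintf("m%d", 1:8),
                    logp = 0, qed = 0.5, sas = 2,
                    category = c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 3L),
                    duplicated = FALSE)
  bal <- balance_by_oversampling(rec, seed = 7)
  expect_equal(as.vector(table(bal$category)), rep(5L, 3))
  # originals retained, duplicates only repeat existing members
  expect_true(all(rec$smiles %in% bal$smiles))
  for (cc in 1:3) {
    expect_setequal(unique(bal$smiles[bal$category == cc]),
                    rec$smiles[rec$category == cc])
  }
  expect_identical(bal, balance_by_oversampling(rec, seed = 7))
  # already balanced input comes back unchanged up to order
  even <- rec[c(1, 2, 6, 7), ]
  expect_equal(nrow(balance_by_oversampling(even, seed = 1)), 4L)
  expect_error(balance_by_oversampling(rec[0, ]), "EmptyInput")
})

test_that("smiles files round-trip through reader and writer", {
  tmp <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("# comment", "c1ccccc1 benzene", "", "CCO"), tmp)
  expect_identical(read_smiles(tmp), c("c1ccccc1", "CCO"))

  csv <- withr::local_tempfile(fileext = ".csv")
  rec <- prepare_dataset(c("c1ccccc1", "CCO"), attribute_spec("logp"))$records
  write_records(rec, csv)
  back <- read.csv(csv)
  expect_identical(back$smiles, rec$smiles)
  expect_equal(back$logp, round(rec$logp, 4))
})
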