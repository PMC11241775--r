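# End-to-end orchestration: prepare -> fit codec -> train -> generate ->
# evaluate, with one root seed split per stage.

stage_seed <- function(seed, stage) {
  # deterministic per-stage offsets below 2^31
  (as.integer(seed) * 101L + stage * 7919L) %% .Machine$integer.max
}

#' Generate scored molecules for a category
#'
#' Generates \code{n} latents conditioned on \code{category}, decodes them
#' through the codec and returns canonical SMILES with the discriminator's
#' confidence scores, sorted descending by confidence.
#'
#' @param model List with trained \code{G} and \code{D}.
#' @param codec Codec used for decoding.
#' @param category Integer category label.
#' @param n Number of molecules.
#' @param seed Integer seed.
#' @return data.frame \code{smiles}, \code{confidence}, \code{category},
#'   ordered by decreasing confidence.
#' @export
run_generate <- function(model, codec, category, n = 10L, seed = 1L) {
  if (is.null(model$G)) stop("ModelMissing: no trained generator")
  category <- as.integer(category)
  if (category < 1L || category > model$G$n_categories) stop("BadCategory")
  gl <- generate_latents(model$G, rep(category, n), seed = seed)
  smi <- decode_latents(codec, gl$z)
  conf <- discriminate(model$D, gl$z)$confidence
  out <- data.frame(smiles = smi, confidence = conf, category = category,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$confidence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write generated molecules as a .smi file
#'
#' SMILES, tab, \code{<category>_<rank>:<confidence>}.
#'
#' @param gen data.frame from \code{\link{run_generate}}.
#' @param path Output path.
#' @export
write_smi <- function(gen, path) {
  name <- sprintf("cat%d_%03d:%.4f", gen$category, seq_len(nrow(gen)),
                  gen$confidence)
  writeLines(paste(gen$smiles, name, sep = "\t"), path)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param attribute Conditioning attribute: logp, qed or sas.
#' @param seed Root seed split across the stages.
#' @param target_per_bin Fixture library size knob (used when no input
#'   SMILES are supplied).
#' @param n_generate Molecules generated per category.
#' @param lambda_anchor,budget_K,stop_loss,max_epochs,batch_size Training
#'   knobs, see \code{\link{train_config}}.
#' @param smiles Optional character vector of training SMILES (defaults to
#'   the synthetic fixture library).
#' @param out_dir Output directory for reports (NULL: nothing written).
#' @return Config list.
#' @export
pipeline_config <- function(attribute = c("logp", "qed", "sas"), seed = 1L,
                            target_per_bin = 20L, n_generate = 100L,
                            lambda_anchor = 0.1, budget_K = 4L,
                            stop_loss = 0.5, max_epochs = 2L,
                            batch_size = 64L, smiles = NULL, out_dir = NULL) {
  attribute <- match.arg(attribute)
  as.list(environment())
}

#' Run the full generation pipeline
#'
#' Prepare (clean, attribute, categorize, oversample-balance), fit the
#' surrogate codec, encode, train the conditional GAN, generate
#' \code{n_generate} molecules per category with confidence scores, and
#' evaluate the pooled generated set against the training molecules.
#'
#' @param config From \code{\link{pipeline_config}}.
#' @param verbose Print stage progress.
#' @return List with \code{records}, \code{codec}, \code{model},
#'   \code{generated} (data.frame over all categories), \code{metrics},
#'   \code{paths} (named files when \code{out_dir} is set).
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  spec <- attribute_spec(config$attribute)

  smiles <- config$smiles
  if (is.null(smiles)) {
    say("building fixture library")
    smiles <- make_library(config$target_per_bin,
                           seed = stage_seed(config$seed, 1L))$molecules
  }
  say("fitting surrogate codec on %d molecules", length(smiles))
  codec <- fit_surrogate_codec(smiles, seed = stage_seed(config$seed, 2L))

  prep <- prepare_dataset(smiles, spec, codec)
  say("prepared %d records (%d rejected)", nrow(prep$records), prep$n_rejected)
  records <- balance_by_oversampling(prep$records, seed = stage_seed(config$seed, 3L))

  z <- encode_molecules(codec, records$smiles)
  cfg <- train_config(n_categories = spec$n_categories,
                      lambda_anchor = config$lambda_anchor,
                      budget_K = config$budget_K, stop_loss = config$stop_loss,
                      max_epochs = config$max_epochs,
                      batch_size = config$batch_size,
                      seed = stage_seed(config$seed, 4L))
  say("training on %d latents", nrow(z))
  fit <- train_acgan(z, records$category, cfg, verbose = verbose)

  cats <- sort(unique(records$category))
  gen <- do.call(rbind, lapply(cats, function(cc) {
    run_generate(fit, codec, cc, config$n_generate,
                 seed = stage_seed(config$seed, 10L + cc))
  }))
  say("generated %d molecules over %d categories", nrow(gen), length(cats))
  training_ref <- unique(records$smiles[!records$duplicated])
  metrics <- evaluate_sets(gen$smiles, training_ref)

  paths <- list()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths$records <- file.path(config$out_dir, "records.csv")
    write_records(records, paths$records)
    paths$generated <- file.path(config$out_dir, "generated.smi")
    write_smi(gen, paths$generated)
    paths$metrics <- file.path(config$out_dir, "metrics.json")
    jsonlite::write_json(lapply(metrics, function(x) round(x, 4)),
                         paths$metrics, auto_unbox = TRUE)
    paths$log <- file.path(config$out_dir, "train.jsonl")
    h <- fit$history
    writeLines(vapply(seq_along(h$L_D), function(e) {
      jsonlite::toJSON(list(epoch = e, L_D = h$L_D[e], L_G = h$L_G[e],
                            alpha = mean(h$alpha[[e]]),
                            accuracy = mean(h$accuracy[[e]])),
                       auto_unbox = TRUE, digits = 6)
    }, character(1)), paths$log)
  }
  list(records = records, codec = codec, model = fit[c("G", "D")],
       history = fit$history, generated = gen, metrics = metrics,
       paths = paths)
}
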