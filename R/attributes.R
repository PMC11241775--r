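#' Parse and canonicalize SMILES strings
#'
#' Molecules are identified throughout the package by their canonical SMILES
#' under RDKit sanitization rules; canonicalization is idempotent, so two
#' spellings of the same structure map to one identity string.
#'
#' @param smiles Character vector of SMILES strings.
#' @param strict If \code{TRUE} (default) any unparseable entry is an error;
#'   otherwise invalid entries come back as \code{NA}.
#' @return Character vector of canonical SMILES (with \code{NA} for invalid
#'   input when \code{strict = FALSE}).
#' @examples
#' \dontrun{
#' parse_and_canonicalize(c("c1ccccc1", "C1=CC=CC=C1"))  # identical output
#' }
#' @export
parse_and_canonicalize <- function(smiles, strict = TRUE) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  if (any(!nzchar(smiles) | is.na(smiles))) {
    if (strict) stop("InvalidSmiles: empty SMILES string")
    smiles[is.na(smiles)] <- ""
  }
  res <- chem_query("canonicalize", smiles)
  bad <- vapply(res, is.null, logical(1))
  if (strict && any(bad)) {
    stop("InvalidSmiles: ", paste(utils::head(smiles[bad], 5), collapse = ", "))
  }
  out <- rep(NA_character_, length(smiles))
  out[!bad] <- vapply(res[!bad], identity, character(1))
  out
}

#' Check SMILES validity
#'
#' @param smiles Character vector.
#' @return Logical vector: does each entry parse and sanitize?
#' @export
is_valid_smiles <- function(smiles) {
  !is.na(parse_and_canonicalize(smiles, strict = FALSE))
}

#' Compute the three conditioning attributes of a molecule
#'
#' Returns Crippen atomic-contribution logP, the quantitative estimate of
#' drug-likeness (QED, in [0,1]) and the Ertl-Schuffenhauer synthetic
#' accessibility score (SAS, 1 = easy to 10 = hard, fragment score plus
#' complexity penalty), all computed by RDKit.
#'
#' @param smiles Character vector of valid SMILES.
#' @return A data.frame with columns \code{smiles} (canonical), \code{logp},
#'   \code{qed}, \code{sas}.
#' @export
compute_attributes <- function(smiles) {
  can <- parse_and_canonicalize(smiles)
  pr <- chem_query("props", can)
  data.frame(
    smiles = can,
    logp = vapply(pr, function(p) p$logp, numeric(1)),
    qed = vapply(pr, function(p) p$qed, numeric(1)),
    sas = vapply(pr, function(p) p$sas, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Attribute interval specifications
#'
#' The three binning schemes that turn a continuous attribute into a
#' conditioning category.  Intervals are left-open / right-closed; the first
#' logP interval is open below and the last open above, while QED and SAS are
#' bounded ([0,1] and (0,10]).  Category counts: logP 6, QED 6, SAS 7.
#'
#' @param name One of \code{"logp"}, \code{"qed"}, \code{"sas"}.
#' @return An object of class \code{attribute_spec} with fields \code{name},
#'   \code{edges} (inner interval boundaries), \code{n_categories},
#'   \code{lower}, \code{upper} (outer bounds, may be infinite).
#' @export
attribute_spec <- function(name = c("logp", "qed", "sas")) {
  name <- match.arg(name)
  spec <- switch(name,
    logp = list(edges = c(0, 1, 2, 3, 4), lower = -Inf, upper = Inf),
    qed  = list(edges = c(0.5, 0.6, 0.7, 0.8, 0.9), lower = 0, upper = 1),
    sas  = list(edges = c(2, 2.5, 3, 3.5, 4, 4.5), lower = 0, upper = 10)
  )
  structure(
    list(name = name, edges = spec$edges, n_categories = length(spec$edges) + 1L,
         lower = spec$lower, upper = spec$upper),
    class = "attribute_spec"
  )
}

#' @export
print.attribute_spec <- function(x, ...) {
  cat(sprintf("<attribute_spec %s: %d categories, inner edges %s>\n",
              x$name, x$n_categories, paste(x$edges, collapse = ", ")))
  invisible(x)
}

#' Map attribute values to interval categories
#'
#' Boundary values belong to the lower-indexed interval (closed right edge),
#' so e.g. a logP of exactly 0.0 falls in category 1.
#'
#' @param spec An \code{\link{attribute_spec}}.
#' @param value Numeric vector of finite attribute values.
#' @return Integer vector of 1-based categories.
#' @export
assign_category <- function(spec, value) {
  stopifnot(inherits(spec, "attribute_spec"), is.numeric(value))
  if (any(!is.finite(value))) stop("OutOfRange: attribute value must be finite")
  if (any(value < spec$lower | value > spec$upper)) {
    stop(sprintf("OutOfRange: %s value outside [%s, %s]",
                 spec$name, spec$lower, spec$upper))
  }
  cat <- findInterval(value, spec$edges, left.open = TRUE) + 1L
  as.integer(cat)
}

#' Read a SMILES collection from disk
#'
#' Accepts plain SMILES text (one molecule per line, \code{#} comments and
#' blank lines skipped, anything after whitespace treated as a name) or a CSV
#' file with a mandatory \code{smiles} column.
#'
#' @param path File path (.smi/.txt or .csv).
#' @return Character vector of SMILES strings.
#' @export
read_smiles <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"smiles" %in% names(df)) stop("CSV input must have a 'smiles' column")
    return(as.character(df$smiles))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  vapply(strsplit(lines, "[ \t]+"), `[[`, character(1), 1L)
}

#' Prepare cleaned, categorized training records
#'
#' Drops unparseable SMILES and, when a codec is supplied, molecules the
#' codec cannot embed; survivors are deduplicated on canonical SMILES and
#' carry attribute values plus the category for \code{spec}'s attribute.
#' Rejections are counted, not raised.
#'
#' @param smiles Character vector of candidate SMILES.
#' @param spec An \code{\link{attribute_spec}}.
#' @param codec Optional codec from \code{\link{fit_surrogate_codec}}.
#' @return List with \code{records} (data.frame \code{smiles, logp, qed, sas,
#'   category, duplicated}) and \code{n_rejected}.
#' @export
prepare_dataset <- function(smiles, spec, codec = NULL) {
  stopifnot(inherits(spec, "attribute_spec"))
  can <- parse_and_canonicalize(smiles, strict = FALSE)
  n_rejected <- sum(is.na(can))
  can <- unique(can[!is.na(can)])
  if (!is.null(codec) && length(can)) {
    ok <- vapply(can, function(s) codec_can_encode(codec, s), logical(1))
    n_rejected <- n_rejected + sum(!ok)
    can <- can[ok]
  }
  if (!length(can)) {
    return(list(records = empty_records(), n_rejected = n_rejected))
  }
  rec <- compute_attributes(can)
  rec$category <- assign_category(spec, rec[[spec$name]])
  rec$duplicated <- FALSE
  list(records = rec, n_rejected = n_rejected)
}

empty_records <- function() {
  data.frame(smiles = character(), logp = numeric(), qed = numeric(),
             sas = numeric(), category = integer(), duplicated = logical(),
             stringsAsFactors = FALSE)
}

#' Balance categories by random oversampling
#'
#' Every category present in the input is brought up to the maximum
#' per-category count by seeded duplication of its own records.  Originals
#' are all retained; duplicates are flagged in the \code{duplicated} column
#' so novelty/uniqueness computations can de-duplicate the reference set.
#'
#' @param records Records data.frame with a \code{category} column.
#' @param seed Integer seed for the duplication draws.
#' @return Balanced records data.frame.
#' @export
balance_by_oversampling <- function(records, seed = 1L) {
  if (!nrow(records)) stop("EmptyInput: no records to balance")
  counts <- table(records$category)
  target <- max(counts)
  out <- records
  out$duplicated <- if (is.null(records$duplicated)) FALSE else records$duplicated
  set.seed(as.integer(seed))
  extras <- lapply(names(counts), function(cat) {
    idx <- which(records$category == as.integer(cat))
    need <- target - length(idx)
    if (need <= 0L) return(NULL)
    dup <- records[idx[sample.int(length(idx), need, replace = TRUE)], , drop = FALSE]
    dup$duplicated <- TRUE
    dup
  })
  extras <- extras[!vapply(extras, is.null, logical(1))]
  if (length(extras)) out <- rbind(out, do.call(rbind, extras))
  rownames(out) <- NULL
  out
}

#' Write prepared records to CSV
#'
#' Canonical SMILES plus the three attributes (4 decimals) and the category.
#'
#' @param records Records data.frame.
#' @param path Output CSV path.
#' @export
write_records <- function(records, path) {
  out <- records[, c("smiles", "logp", "qed", "sas", "category")]
  for (col in c("logp", "qed", "sas")) out[[col]] <- round(out[[col]], 4)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
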