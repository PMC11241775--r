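#' @importFrom stats cov prcomp rnorm runif sd setNames
#' @importFrom utils head read.csv write.csv
NULL

# Per-operation memo caches: one environment per bridge op, keyed by the raw
# SMILES string.  Lives for the R session so test files and pipeline stages
# share results and each unique molecule crosses the Python bridge once.
.chem_cache <- new.env(parent = emptyenv())

chem_cache_env <- function(op) {
  if (is.null(.chem_cache[[op]])) .chem_cache[[op]] <- new.env(parent = emptyenv())
  .chem_cache[[op]]
}

#' Locate the Python interpreter used for cheminformatics
#'
#' The package delegates molecule parsing, descriptors and fingerprints to
#' RDKit through a batch subprocess.  The interpreter is resolved from the
#' option \code{acmolgen.python}, the environment variable
#' \code{ACMOLGEN_PYTHON}, or \code{python} on the \code{PATH}, in that order.
#'
#' @return Path to the interpreter.
#' @export
chem_python <- function() {
  p <- getOption("acmolgen.python", "")
  if (!nzchar(p)) p <- Sys.getenv("ACMOLGEN_PYTHON", "")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) stop("No python interpreter found; set options(acmolgen.python=...)")
  unname(p)
}

bridge_script <- function() {
  path <- system.file("python", "chem_bridge.py", package = "acmolgen")
  if (!nzchar(path)) {
    # during development (pkgload) system.file resolves inside the source tree
    path <- file.path("inst", "python", "chem_bridge.py")
  }
  if (!file.exists(path)) stop("chem_bridge.py not found")
  path
}

# One raw subprocess round-trip; no caching.
chem_bridge_call <- function(ops, smiles) {
  req <- tempfile(fileext = ".json")
  resp <- tempfile(fileext = ".json")
  on.exit(unlink(c(req, resp)), add = TRUE)
  jsonlite::write_json(list(ops = ops, smiles = smiles), req, auto_unbox = FALSE, null = "null")
  status <- system2(chem_python(), c(bridge_script(), req, resp),
                    stdout = FALSE, stderr = "")
  if (!identical(status, 0L) || !file.exists(resp)) {
    stop("cheminformatics backend failed (exit ", status, ")")
  }
  jsonlite::read_json(resp, simplifyVector = FALSE)
}

# Cached batch query for a single op.  Returns a list parallel to `smiles`;
# NULL entries mark molecules the toolkit could not parse.
chem_query <- function(op, smiles) {
  stopifnot(is.character(smiles))
  cache <- chem_cache_env(op)
  miss <- unique(smiles[!vapply(smiles, function(s) !is.null(cache[[s]]), logical(1))])
  miss <- miss[nzchar(miss)]
  if (length(miss)) {
    ans <- chem_bridge_call(op, miss)
    field <- switch(op, canonicalize = "canonical", op)
    for (i in seq_along(miss)) {
      if (op == "props") {
        v <- list(logp = ans$logp[[i]], qed = ans$qed[[i]], sas = ans$sas[[i]])
        if (is.null(v$logp)) v <- NULL
      } else {
        v <- ans[[field]][[i]]
      }
      cache[[miss[i]]] <- if (is.null(v)) list(.invalid = TRUE) else list(value = v)
    }
  }
  lapply(smiles, function(s) {
    if (!nzchar(s)) return(NULL)
    hit <- cache[[s]]
    if (is.null(hit) || isTRUE(hit$.invalid)) NULL else hit$value
  })
}
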