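# Session-level cache so expensive fixtures (the molecule library, trained
# models) are built once and shared across test files.
.test_cache <- new.env(parent = emptyenv())

cached <- function(name, fn) {
  if (is.null(.test_cache[[name]])) .test_cache[[name]] <- fn()
  .test_cache[[name]]
}

test_library <- function() cached("library", function() make_library(20L, seed = 1L))

test_codec <- function() {
  cached("codec", function() fit_surrogate_codec(test_library()$molecules, seed = 1L))
}

# five benzene-ring probe molecules used across metric tests
probe_set <- function() {
  c("c1ccccc1", "c1ccncc1", "Cc1ccccc1", "CCO", "CC(=O)Nc1ccccc1")
}

# plain double-loop Tanimoto on bit sets: the independent oracle
oracle_tanimoto <- function(b1, b2) {
  inter <- length(intersect(b1, b2))
  uni <- length(b1) + length(b2) - inter
  if (uni == 0) 1 else inter / uni
}
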