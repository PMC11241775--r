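#' Morgan fingerprint bit sets
#'
#' Radius-2, 1024-bit Morgan (extended connectivity) fingerprints as sorted
#' 1-based on-bit indices.
#'
#' @param smiles Character vector of valid SMILES.
#' @return List of integer vectors.
#' @export
morgan_bits <- function(smiles) {
  res <- chem_query("morgan", smiles)
  bad <- vapply(res, is.null, logical(1))
  if (any(bad)) stop("InvalidSmiles: cannot fingerprint ", paste(head(smiles[bad], 3), collapse = ", "))
  lapply(res, function(b) as.integer(unlist(b)) + 1L)
}

# Dense 0/1 fingerprint matrix (n x 1024)
morgan_matrix <- function(smiles) {
  bits <- morgan_bits(smiles)
  m <- matrix(0, length(smiles), 1024L)
  for (i in seq_along(bits)) m[i, bits[[i]]] <- 1
  m
}

#' Fit the surrogate molecule-latent codec
#'
#' Stands in for a pretrained hierarchical graph VAE: a principal-component
#' projection of Morgan radius-2/1024-bit fingerprints gives a deterministic
#' linear embedding into a \code{latent_dim}-dimensional space (zero-padded
#' when the library rank is lower), and decoding returns the nearest library
#' molecule in latent space.  Every decoded molecule is therefore a valid
#' member of the decode library by construction.
#'
#' A molecule is encodable only if all of its fingerprint bits occur in the
#' fitting library (the surrogate's "vocabulary"); molecules outside it fail
#' to encode, mirroring an encoder with a fixed motif vocabulary.
#'
#' @param library Character vector of SMILES forming the decode library.
#' @param latent_dim Latent dimensionality (default 250).
#' @param seed Integer seed stored with the codec (the fit itself is
#'   deterministic).
#' @return An object of class \code{surrogate_codec}.
#' @export
fit_surrogate_codec <- function(library, latent_dim = 250L, seed = 1L) {
  if (!length(library)) stop("EmptyLibrary: codec needs at least one molecule")
  can <- parse_and_canonicalize(library)
  can <- unique(can)
  fp <- morgan_matrix(can)
  mu <- colMeans(fp)
  xc <- sweep(fp, 2, mu)
  r <- min(nrow(fp) - 1L, ncol(fp), latent_dim)
  w <- matrix(0, ncol(fp), latent_dim)
  if (r >= 1L) {
    sv <- svd(xc, nu = 0, nv = r)
    v <- sv$v
    # deterministic sign: largest-magnitude loading positive per component
    for (j in seq_len(ncol(v))) {
      k <- which.max(abs(v[, j]))
      if (v[k, j] < 0) v[, j] <- -v[, j]
    }
    w[, seq_len(r)] <- v
  }
  lat <- xc %*% w
  codec <- structure(
    list(latent_dim = as.integer(latent_dim), library = can,
         latents = lat, mu = mu, w = w,
         known_bits = which(colSums(fp) > 0), seed = as.integer(seed)),
    class = "surrogate_codec"
  )
  codec
}

#' @export
print.surrogate_codec <- function(x, ...) {
  cat(sprintf("<surrogate_codec: %d library molecules, latent_dim %d>\n",
              length(x$library), x$latent_dim))
  invisible(x)
}

codec_can_encode <- function(codec, smiles) {
  bits <- tryCatch(morgan_bits(smiles)[[1]], error = function(e) NULL)
  !is.null(bits) && all(bits %in% codec$known_bits)
}

#' Encode molecules into latent space
#'
#' @param codec A \code{surrogate_codec}.
#' @param smiles Character vector of valid SMILES.
#' @return Numeric matrix (length(smiles) x latent_dim).
#' @export
encode_molecules <- function(codec, smiles) {
  stopifnot(inherits(codec, "surrogate_codec"))
  can <- parse_and_canonicalize(smiles)
  bits <- morgan_bits(can)
  oov <- !vapply(bits, function(b) all(b %in% codec$known_bits), logical(1))
  if (any(oov)) {
    stop("EncodeFailure: molecule outside the codec's representable set: ",
         paste(head(can[oov], 3), collapse = ", "))
  }
  fp <- matrix(0, length(can), length(codec$mu))
  for (i in seq_along(bits)) fp[i, bits[[i]]] <- 1
  sweep(fp, 2, codec$mu) %*% codec$w
}

#' Decode latent vectors into molecules
#'
#' Nearest decode-library member under Euclidean distance; exact ties are
#' broken by the lexicographically smallest canonical SMILES.
#'
#' @param codec A \code{surrogate_codec}.
#' @param z Numeric matrix (n x latent_dim) or a single latent vector.
#' @return Character vector of canonical SMILES, all members of the library.
#' @export
decode_latents <- function(codec, z) {
  stopifnot(inherits(codec, "surrogate_codec"))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (ncol(z) != codec$latent_dim) stop("latent dimension mismatch")
  if (any(!is.finite(z))) stop("latent vectors must be finite")
  # squared distances via ||z||^2 - 2 z.L' + ||L||^2
  ln <- rowSums(codec$latents^2)
  d2 <- outer(rowSums(z^2), ln, "+") - 2 * (z %*% t(codec$latents))
  vapply(seq_len(nrow(z)), function(i) {
    di <- d2[i, ]
    cand <- which(di <= min(di) + 1e-9)
    min(codec$library[cand])
  }, character(1))
}

#' Save / load a codec artifact
#'
#' @param codec A \code{surrogate_codec}.
#' @param path Artifact file path.
#' @export
save_codec <- function(codec, path) {
  saveRDS(codec, path)
  invisible(path)
}

#' @rdname save_codec
#' @export
load_codec <- function(path) {
  codec <- readRDS(path)
  stopifnot(inherits(codec, "surrogate_codec"))
  codec
}
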