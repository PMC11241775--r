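# Generation-quality metric suite: validity / novelty / uniqueness, internal
# diversity, nearest-neighbour similarity, BRICS fragment and Bemis-Murcko
# scaffold cosine similarity, and the Frechet distance on activation
# statistics with a pluggable activation model.

#' Fraction of chemically valid SMILES
#'
#' @param smiles Character vector of generated SMILES.
#' @return Fraction parsing and sanitizing successfully.
#' @export
validity <- function(smiles) {
  if (!length(smiles)) stop("EmptyInput")
  mean(is_valid_smiles(smiles))
}

#' Novelty of a generated set
#'
#' Fraction of generated molecules (counting duplicates individually) whose
#' canonical SMILES is absent from the training set.
#'
#' @param generated,training Character vectors of valid SMILES.
#' @return Fraction in [0,1].
#' @export
novelty <- function(generated, training) {
  if (!length(generated) || !length(training)) stop("EmptyInput")
  g <- parse_and_canonicalize(generated)
  r <- parse_and_canonicalize(training)
  mean(!(g %in% r))
}

#' Uniqueness of a generated set
#'
#' Distinct canonical SMILES over total count.
#'
#' @param generated Character vector of valid SMILES.
#' @return Fraction in (0,1].
#' @export
uniqueness <- function(generated) {
  if (!length(generated)) stop("EmptyInput")
  g <- parse_and_canonicalize(generated)
  length(unique(g)) / length(g)
}

# Tanimoto matrix between two bit-set lists via sparse cross-products.
tanimoto_matrix <- function(bits_a, bits_b, nbits = 1024L) {
  sm <- function(bits) {
    Matrix::sparseMatrix(
      i = unlist(bits),
      j = rep(seq_along(bits), lengths(bits)),
      x = 1, dims = c(nbits, length(bits)))
  }
  A <- sm(bits_a); B <- sm(bits_b)
  inter <- as.matrix(Matrix::crossprod(A, B))
  na <- lengths(bits_a); nb <- lengths(bits_b)
  uni <- outer(na, nb, "+") - inter
  out <- inter / uni
  out[uni == 0] <- 1   # two empty fingerprints are identical
  out
}

#' Internal diversity of a molecule set
#'
#' 1 - (mean over all ordered pairs, self-pairs included, of the p-th power
#' of pairwise Tanimoto similarity)^(1/p), on Morgan radius-2/1024
#' fingerprints.  Detects mode collapse; a single (or fully duplicated) set
#' scores 0.
#'
#' @param smiles Character vector of valid SMILES.
#' @param p Power, 1 or 2.
#' @return Value in [0,1].
#' @export
internal_diversity <- function(smiles, p = 1) {
  if (!length(smiles)) stop("EmptyInput")
  stopifnot(p %in% c(1, 2))
  bits <- morgan_bits(parse_and_canonicalize(smiles))
  tm <- tanimoto_matrix(bits, bits)
  1 - mean(tm^p)^(1 / p)
}

#' Similarity to the nearest neighbour
#'
#' Mean over the generated set of the maximum Tanimoto similarity to the
#' reference set (Morgan radius-2/1024 fingerprints).
#'
#' @param generated,reference Character vectors of valid SMILES.
#' @return Value in [0,1].
#' @export
snn <- function(generated, reference) {
  if (!length(generated) || !length(reference)) stop("EmptyInput")
  bg <- morgan_bits(parse_and_canonicalize(generated))
  br <- morgan_bits(parse_and_canonicalize(reference))
  mean(apply(tanimoto_matrix(bg, br), 1, max))
}

profile_counts <- function(keys_per_mol) {
  tab <- table(unlist(keys_per_mol))
  setNames(as.numeric(tab), names(tab))
}

cosine_profiles <- function(cg, cr) {
  if (!length(cg) && !length(cr)) {
    stop("BothProfilesEmpty: cosine similarity undefined on empty profiles")
  }
  if (!length(cg) || !length(cr)) return(0)
  keys <- union(names(cg), names(cr))
  vg <- setNames(numeric(length(keys)), keys)
  vr <- vg
  vg[names(cg)] <- cg
  vr[names(cr)] <- cr
  sum(vg * vr) / sqrt(sum(vg^2) * sum(vr^2))
}

#' BRICS fragment profile of a molecule set
#'
#' Counts of BRICS decomposition fragments; an uncleavable molecule
#' contributes itself as a single fragment key.
#'
#' @param smiles Character vector of valid SMILES.
#' @return Named numeric count vector.
#' @export
fragment_profile <- function(smiles) {
  res <- chem_query("brics", parse_and_canonicalize(smiles))
  profile_counts(lapply(res, unlist))
}

#' Bemis-Murcko scaffold profile of a molecule set
#'
#' Counts of scaffold canonical SMILES (ring systems plus linkers, with
#' ring-attached carbonyls kept).  Acyclic molecules have an empty scaffold
#' and contribute no key.
#'
#' @param smiles Character vector of valid SMILES.
#' @return Named numeric count vector.
#' @export
scaffold_profile <- function(smiles) {
  res <- chem_query("scaffold", parse_and_canonicalize(smiles))
  keys <- unlist(res)
  profile_counts(keys[nzchar(keys)])
}

#' Fragment distribution similarity
#'
#' Cosine similarity of BRICS fragment count vectors over the union key set.
#'
#' @param generated,reference Character vectors of valid SMILES.
#' @return Value in [0,1].
#' @export
fragment_similarity <- function(generated, reference) {
  if (!length(generated) || !length(reference)) stop("EmptyInput")
  cosine_profiles(fragment_profile(generated), fragment_profile(reference))
}

#' Scaffold distribution similarity
#'
#' Cosine similarity of Bemis-Murcko scaffold count vectors.  Sets of purely
#' acyclic molecules have empty profiles: both empty is an error, one empty
#' scores 0.
#'
#' @param generated,reference Character vectors of valid SMILES.
#' @return Value in [0,1].
#' @export
scaffold_similarity <- function(generated, reference) {
  if (!length(generated) || !length(reference)) stop("EmptyInput")
  cosine_profiles(scaffold_profile(generated), scaffold_profile(reference))
}

#' Default surrogate activation model
#'
#' A fixed, seeded random tanh projection of Morgan fingerprint bits plus
#' the three normalized conditioning attributes.  It is deterministic and
#' dependency-free; it captures structural variation between molecule sets
#' but is not a trained bioactivity network, so distances computed with it
#' are internally comparable only.
#'
#' @param dim Activation dimensionality (default 64).
#' @param seed Seed fixing the projection.
#' @return Function mapping a character vector of SMILES to an activation
#'   matrix (n x dim).
#' @export
surrogate_activation_model <- function(dim = 64L, seed = 42L) {
  set.seed(as.integer(seed))
  W <- matrix(rnorm(1027L * dim, sd = 1 / sqrt(1027)), 1027L, dim)
  b <- rnorm(dim, sd = 0.1)
  function(smiles) {
    can <- parse_and_canonicalize(smiles)
    fp <- morgan_matrix(can)
    at <- compute_attributes(can)
    feats <- cbind(fp, at$logp / 10, at$qed, at$sas / 10)
    tanh(sweep(feats %*% W, 2, b, "+"))
  }
}

#' Activation distribution statistics
#'
#' Sample mean and full covariance of molecule activations under a pluggable
#' activation model (any function SMILES -> activation matrix).
#'
#' @param smiles Character vector of valid SMILES.
#' @param activation_model Defaults to \code{\link{surrogate_activation_model}()}.
#' @return List of class \code{distribution_stats}: \code{mu}, \code{sigma},
#'   \code{n}.
#' @export
activation_stats <- function(smiles, activation_model = surrogate_activation_model()) {
  if (!length(smiles)) stop("EmptyInput")
  act <- activation_model(smiles)
  if (is.null(dim(act))) act <- matrix(act, nrow = length(smiles))
  sigma <- if (nrow(act) > 1L) stats::cov(act) else matrix(0, ncol(act), ncol(act))
  structure(list(mu = colMeans(act), sigma = sigma, n = nrow(act)),
            class = "distribution_stats")
}

#' Frechet distance between activation distributions
#'
#' ||mu_G - mu_R||^2 + Tr(S_G + S_R - 2 (S_G S_R)^{1/2}), the Wasserstein-2
#' distance between Gaussians.  The matrix square root is taken via
#' symmetric eigendecompositions with small negative eigenvalues (>= -1e-6)
#' clipped to zero.
#'
#' @param a,b \code{distribution_stats} objects of matching dimension.
#' @return Non-negative scalar, symmetric in its arguments.
#' @export
frechet_distance <- function(a, b) {
  stopifnot(inherits(a, "distribution_stats"), inherits(b, "distribution_stats"))
  if (length(a$mu) != length(b$mu)) stop("DimensionMismatch")
  clip_eig <- function(v) {
    if (any(v < -1e-6)) stop("covariance not positive semidefinite")
    pmax(v, 0)
  }
  ea <- eigen((a$sigma + t(a$sigma)) / 2, symmetric = TRUE)
  va <- clip_eig(ea$values)
  sqa <- ea$vectors %*% (sqrt(va) * t(ea$vectors))
  m <- sqa %*% ((b$sigma + t(b$sigma)) / 2) %*% sqa
  em <- eigen((m + t(m)) / 2, symmetric = TRUE)
  tr_sqrt <- sum(sqrt(clip_eig(em$values)))
  d <- sum((a$mu - b$mu)^2) + sum(diag(a$sigma)) + sum(diag(b$sigma)) - 2 * tr_sqrt
  max(d, 0)
}

#' Compute a fingerprint object
#'
#' @param smiles A single valid SMILES.
#' @param kind \code{"morgan_r2_1024"} or \code{"maccs"}.
#' @return List of class \code{chem_fp}: \code{bits} (1-based on-bit
#'   indices), \code{nbits}, \code{kind}.
#' @export
fingerprint <- function(smiles, kind = c("morgan_r2_1024", "maccs")) {
  kind <- match.arg(kind)
  stopifnot(length(smiles) == 1L)
  can <- parse_and_canonicalize(smiles)
  bits <- if (kind == "maccs") {
    as.integer(unlist(chem_query("maccs", can)[[1]])) + 1L
  } else {
    morgan_bits(can)[[1]]
  }
  structure(list(bits = bits, nbits = if (kind == "maccs") 167L else 1024L,
                 kind = kind),
            class = "chem_fp")
}

#' Pairwise fingerprint similarity
#'
#' Tanimoto |A n B| / |A u B| or Dice 2|A n B| / (|A| + |B|) on the on-bit
#' sets of two fingerprints of the same kind.
#'
#' @param f1,f2 \code{chem_fp} objects of identical kind.
#' @param measure \code{"tanimoto"} or \code{"dice"}.
#' @return Value in [0,1].
#' @export
pairwise_similarity <- function(f1, f2, measure = c("tanimoto", "dice")) {
  measure <- match.arg(measure)
  stopifnot(inherits(f1, "chem_fp"), inherits(f2, "chem_fp"))
  if (!identical(f1$kind, f2$kind)) stop("KindMismatch")
  inter <- length(intersect(f1$bits, f2$bits))
  na <- length(f1$bits); nb <- length(f2$bits)
  if (na + nb == 0L) return(1)
  if (measure == "tanimoto") inter / (na + nb - inter) else 2 * inter / (na + nb)
}

#' MACCS/Dice similarity of two molecules
#'
#' The drug-database comparison measure: Dice similarity on 167-bit MACCS
#' keys; 1.00 marks an exact structural-key match.
#'
#' @param smiles1,smiles2 Single valid SMILES strings.
#' @return Value in [0,1].
#' @export
maccs_dice <- function(smiles1, smiles2) {
  pairwise_similarity(fingerprint(smiles1, "maccs"),
                      fingerprint(smiles2, "maccs"), "dice")
}

#' Evaluate a generated set against a reference set
#'
#' Computes the full metric report: validity, novelty, uniqueness,
#' IntDiv1/IntDiv2, SNN, Frag, Scaf and the Frechet activation distance.
#'
#' @param generated,reference Character vectors of SMILES.
#' @param activation_model Pluggable activation model for the Frechet
#'   distance.
#' @return Named list of metric values.
#' @export
evaluate_sets <- function(generated, reference,
                          activation_model = surrogate_activation_model()) {
  gval <- is_valid_smiles(generated)
  gv <- generated[gval]
  list(
    validity = mean(gval),
    novelty = novelty(gv, reference),
    uniqueness = uniqueness(gv),
    int_div1 = internal_diversity(gv, 1),
    int_div2 = internal_diversity(gv, 2),
    snn = snn(gv, reference),
    frag = fragment_similarity(gv, reference),
    scaf = tryCatch(scaffold_similarity(gv, reference), error = function(e) NA_real_),
    fcd = frechet_distance(activation_stats(gv, activation_model),
                           activation_stats(reference, activation_model))
  )
}
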