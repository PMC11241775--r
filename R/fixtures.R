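# Seeded synthetic-data generators: a combinatorial SMILES library spanning
# every attribute bin, and Gaussian latent clusters for GAN unit tests.
# The library is a test instrument, not a claim of ZINC-like realism.

# Fragment grammar.  Left groups end in an atom with an open valence so
# plain concatenation with a core yields valid SMILES; cores carry a {R}
# substitution slot.  Halogen/alkyl-rich pieces reach high logP, polar
# pieces low logP, fused stereocenter-bearing cores high SAS, and a
# dihydroquinazolinone family covers the narrow QED > 0.9 bin.
grammar_pieces <- function(grammar = c("full", "minimal")) {
  grammar <- match.arg(grammar)
  cores <- c(
    "c1ccc({R})cc1", "c1ccc2ccccc2c1{R}", "c1ccncc1{R}", "c1ccc(CC{R})cc1",
    "C1CCN({R})CC1", "C1CCC(N{R})CC1", "c1cnc({R})cn1", "c1ccsc1{R}",
    "C1CN({R})CCO1", "c1ccc(S(=O)(=O)N{R})cc1", "c1ccc(OC{R})cc1",
    "C1CC2CCC1CC2{R}", "C1[C@H]2CC[C@@H](C1)C2{R}",
    "C1CC2(CCC1)OCCO2{R}", "[C@H]1(C2CC3CC(C2)CC1C3){R}",
    "C1CC2CCC3CCCC(C1)C23{R}", "O[C@@H]1C[C@H](O)[C@@H](O)C1{R}")
  subs <- c("C", "CC", "O", "N", "Cl", "F", "C(=O)O", "C(=O)N", "CCN", "OC",
            "S(=O)(=O)C", "C(F)(F)F", "CCCCCC", "c1ccccc1", "Cc1ccccc1",
            "OCCO", "C#N", "CO", "[C@@H](C)N", "[C@H](O)CC")
  left <- c("CC(=O)N", "CCOC(=O)", "NC(=O)", "OCC(O)CN", "NCCN", "OC(=O)",
            "CCCCCCCC", "CCCCCCCCCCCC", "FC(F)(F)", "CN(C)CCN", "O=S(=O)(N)",
            "OCC(O)C(O)C(O)CN", "CS(=O)(=O)N", "CCN(CC)CCN",
            "Clc1ccc(cc1)C(=O)N", "CC(C)(C)OC(=O)N", "N#CC(C#N)=C", "OC(CO)CN")
  left_cores <- c("c1ccc({R})cc1", "c1ccncc1{R}", "C1CCN({R})CC1",
                  "c1ccc(OC{R})cc1", "C1CC2CCC1CC2{R}",
                  "O[C@@H]1C[C@H](O)[C@@H](O)C1{R}")
  left_subs <- c("C", "O", "N", "CC", "Cl")
  if (grammar == "minimal") {
    return(list(cores = cores[1:3], subs = subs[1:5], left = character(0),
                left_cores = character(0), left_subs = character(0),
                druglike = character(0)))
  }
  dq_n <- c("C", "CC")                       # N-alkyl on the quinazolinone
  dq_benzo <- c("c2ccccc2", "c2ccc(F)cc2")   # benzo ring variant
  dq_ring <- c("CCOC", "CCCC")               # morpholine-like vs piperidine
  dq_ar <- c("c3cccnc3", "c3ccccc3", "c3ccncc3", "c3cccs3", "c3ccco3",
             "c3ccc(F)cc3", "c3ccc(C)cc3", "c3cnccn3", "c3cccc(C)c3", "c3ccsc3")
  druglike <- character(0)
  for (nn in dq_n) for (benzo in dq_benzo) for (rg in dq_ring) for (ar in dq_ar) {
    druglike <- c(druglike,
                  paste0(nn, "N1C(=O)", benzo, "NC1CN1", rg, "(", ar, ")C1"))
  }
  list(cores = cores, subs = subs, left = left, left_cores = left_cores,
       left_subs = left_subs, druglike = druglike)
}

grammar_candidates <- function(grammar = "full") {
  g <- grammar_pieces(grammar)
  out <- character(0)
  for (co in g$cores) for (s in g$subs) {
    out <- c(out, sub("{R}", s, co, fixed = TRUE))
  }
  for (l in g$left) for (co in g$left_cores) for (s in g$left_subs) {
    out <- c(out, paste0(l, sub("{R}", s, co, fixed = TRUE)))
  }
  unique(c(out, g$druglike))
}

#' Build the synthetic fixture molecule library
#'
#' Enumerates candidates from a fixed fragment grammar, computes the three
#' attributes, and greedily retains (in seeded random order) valid distinct
#' molecules until every category of every attribute spec holds at least
#' \code{target_per_bin} members.
#'
#' @param target_per_bin Minimum molecules per category (default 20).
#' @param seed Integer seed for the retention order.
#' @param grammar \code{"full"} or \code{"minimal"} (the latter cannot fill
#'   the extreme bins and exists to exercise the \code{BinUnfillable} error).
#' @return Object of class \code{fixture_library}: \code{molecules}
#'   (canonical SMILES), \code{attributes} (data.frame), \code{per_bin_counts}
#'   (data.frame attribute/category/count), \code{seed}.
#' @export
make_library <- function(target_per_bin = 20L, seed = 1L, grammar = "full") {
  stopifnot(target_per_bin >= 1)
  cand <- grammar_candidates(grammar)
  can <- parse_and_canonicalize(cand, strict = FALSE)
  can <- unique(can[!is.na(can)])
  at <- compute_attributes(can)
  specs <- lapply(c("logp", "qed", "sas"), attribute_spec)
  cats <- lapply(specs, function(sp) assign_category(sp, at[[sp$name]]))
  names(cats) <- c("logp", "qed", "sas")

  set.seed(as.integer(seed))
  ord <- sample.int(nrow(at))
  need <- lapply(specs, function(sp) rep(target_per_bin, sp$n_categories))
  names(need) <- names(cats)
  keep <- logical(nrow(at))
  for (i in ord) {
    helps <- FALSE
    for (a in names(cats)) {
      if (need[[a]][cats[[a]][i]] > 0L) helps <- TRUE
    }
    if (helps) {
      keep[i] <- TRUE
      for (a in names(cats)) {
        need[[a]][cats[[a]][i]] <- need[[a]][cats[[a]][i]] - 1L
      }
    }
    if (all(unlist(need) <= 0L)) break
  }
  unfilled <- do.call(rbind, lapply(names(need), function(a) {
    w <- which(need[[a]] > 0L)
    if (!length(w)) return(NULL)
    data.frame(attribute = a, category = w, missing = need[[a]][w])
  }))
  if (!is.null(unfilled) && nrow(unfilled)) {
    stop("BinUnfillable: grammar cannot reach ",
         paste(sprintf("%s/%d (missing %d)", unfilled$attribute,
                       unfilled$category, unfilled$missing), collapse = ", "))
  }
  at <- at[keep, , drop = FALSE]
  rownames(at) <- NULL
  counts <- do.call(rbind, lapply(specs, function(sp) {
    cc <- assign_category(sp, at[[sp$name]])
    data.frame(attribute = sp$name, category = seq_len(sp$n_categories),
               count = as.integer(tabulate(cc, sp$n_categories)))
  }))
  structure(list(molecules = at$smiles, attributes = at,
                 per_bin_counts = counts, seed = as.integer(seed)),
            class = "fixture_library")
}

#' @export
print.fixture_library <- function(x, ...) {
  cat(sprintf("<fixture_library: %d molecules, min bin count %d>\n",
              length(x$molecules), min(x$per_bin_counts$count)))
  invisible(x)
}

#' Gaussian latent clusters for GAN tests
#'
#' Class means sit at \code{separation} along orthogonal coordinate axes of
#' the latent space; samples are drawn with isotropic standard deviation
#' \code{spread}.  Balanced and fully seeded.
#'
#' @param n_per_class Samples per class.
#' @param n_classes Number of classes (>= 2, <= latent_dim).
#' @param separation Distance of each class mean from the origin.
#' @param spread Within-class standard deviation (> 0).
#' @param latent_dim Latent dimensionality (default 250).
#' @param seed Integer seed.
#' @return List of class \code{latent_clusters}: \code{z} (matrix),
#'   \code{labels}, \code{centers}, \code{spread}, \code{seed}.
#' @export
make_latent_clusters <- function(n_per_class, n_classes = 3L, separation = 10,
                                 spread = 1, latent_dim = 250L, seed = 1L) {
  if (n_classes < 2L || n_classes > latent_dim) stop("BadConfig: n_classes")
  if (spread <= 0 || separation < 0) stop("BadConfig: separation/spread")
  set.seed(as.integer(seed))
  centers <- matrix(0, n_classes, latent_dim)
  for (k in seq_len(n_classes)) centers[k, k] <- separation
  labels <- rep(seq_len(n_classes), each = n_per_class)
  z <- centers[labels, , drop = FALSE] +
    matrix(rnorm(length(labels) * latent_dim, sd = spread), length(labels))
  structure(list(z = z, labels = labels, centers = centers,
                 spread = spread, seed = as.integer(seed)),
            class = "latent_clusters")
}

#' Named latent-cluster presets
#'
#' \code{fixture_convergent}: 3 classes, separation 10, spread 1, 600 per
#' class — a regime where the discriminator separates cleanly.
#' \code{fixture_collapse_prone}: 3 classes, separation 0.5, spread 1, 120
#' per class — heavily overlapping classes that invite conditional collapse.
#'
#' @param seed Integer seed.
#' @return A \code{latent_clusters} object.
#' @export
fixture_convergent <- function(seed = 1L) {
  make_latent_clusters(600L, 3L, separation = 10, spread = 1, seed = seed)
}

#' @rdname fixture_convergent
#' @export
fixture_collapse_prone <- function(seed = 1L) {
  make_latent_clusters(120L, 3L, separation = 0.5, spread = 1, seed = seed)
}
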