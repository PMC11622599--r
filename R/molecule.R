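#' Molecule objects
#'
#' A `molecule` bundles the canonical SMILES string, the parsed molecular
#' graph, the circular fingerprint (radius 2, 2048 bits, binary) and the
#' heavy-atom count. Molecules are the unit of search for the annealing
#' optimizer; identity throughout the package is canonical-SMILES identity.
#'
#' @name molecule
NULL

molecule_from_graph <- function(g) {
  # fingerprint and heavy count are invariant under atom reordering, so the
  # graph is stored as-is; only the SMILES string is canonical
  structure(list(
    smiles = canonical_smiles_of_graph(g),
    graph = g,
    fp = morgan_bits(g),
    n_heavy = sum(!(g$element %in% c("*", "H")))
  ), class = "molecule")
}

#' Canonicalize a SMILES string into a molecule
#'
#' Parses the SMILES, keeps the largest covalent component of multi-fragment
#' (salt) inputs with a message, derives the canonical form, and computes the
#' fingerprint. Canonicalization is idempotent:
#' `canonicalize(canonicalize(x)$smiles)` equals `canonicalize(x)`.
#'
#' @param smiles a single SMILES string.
#' @return a `molecule` object.
#' @export
#' @examples
#' m <- canonicalize("OCC")
#' identical(m$smiles, canonicalize("CCO")$smiles)
canonicalize <- function(smiles) {
  if (inherits(smiles, "molecule")) return(smiles)
  g <- parse_smiles(smiles)
  g <- largest_component(g)
  molecule_from_graph(g)
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s (%d heavy atoms, %d fp bits)\n",
              x$smiles, x$n_heavy, length(x$fp)))
  invisible(x)
}

is_molecule <- function(x) inherits(x, "molecule")

as_molecule_list <- function(mols) {
  if (is_molecule(mols)) return(list(mols))
  if (is.character(mols)) return(lapply(mols, canonicalize))
  stopifnot(is.list(mols), all(vapply(mols, is_molecule, TRUE)))
  mols
}

#' Tanimoto distance between two molecules
#'
#' One minus the Tanimoto (Jaccard) similarity of the binary circular
#' fingerprints. When both fingerprints are empty the distance is defined as
#' 0 for identical canonical SMILES and 1 otherwise (with a warning).
#'
#' @param a,b `molecule` objects (or SMILES strings).
#' @return distance in `[0, 1]`.
#' @export
tanimoto_distance <- function(a, b) {
  a <- canonicalize(a); b <- canonicalize(b)
  sim <- tanimoto_from_bits(a$fp, b$fp)
  if (is.na(sim)) {
    warning("both fingerprints empty; distance defined by SMILES identity")
    return(if (identical(a$smiles, b$smiles)) 0 else 1)
  }
  1 - sim
}

# full pairwise Tanimoto distance matrix for a molecule list (vectorized)
pairwise_distance_matrix <- function(mols) {
  mols <- as_molecule_list(mols)
  n <- length(mols)
  m <- bits_to_matrix(lapply(mols, `[[`, "fp"))
  inter <- crossprod(m)
  pop <- colSums(m)
  un <- outer(pop, pop, "+") - inter
  d <- 1 - inter / un
  if (any(un == 0)) {
    smi <- vapply(mols, `[[`, "", "smiles")
    zero <- which(un == 0, arr.ind = TRUE)
    d[zero] <- ifelse(smi[zero[, 1]] == smi[zero[, 2]], 0, 1)
  }
  diag(d) <- 0
  d
}

#' Mean pairwise Tanimoto distance
#'
#' Mean over all `n(n-1)/2` unordered molecule pairs; half of this value is
#' the optimizer's initial niching radius.
#'
#' @param mols list of `molecule` objects (or character vector of SMILES).
#' @return mean pairwise distance.
#' @export
pairwise_mean_distance <- function(mols) {
  mols <- as_molecule_list(mols)
  if (length(mols) < 2L) stop("need at least 2 molecules")
  d <- pairwise_distance_matrix(mols)
  mean(d[upper.tri(d)])
}
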