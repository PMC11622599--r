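# Circular (Morgan/ECFP-type) fingerprints, radius 2, 2048 binary bits.
# Atom environments are hashed with a deterministic 31-bit polynomial hash
# (exact in double precision), so fingerprints are bit-identical across
# sessions and platforms. Bit layout is this package's own; all distances in
# the package are computed within this one fingerprint space.

FP_NBITS <- 2048L
FP_RADIUS <- 2L
HASH_MOD <- 2147483647  # 2^31 - 1

ELEMENT_CODES <- c("*", "H", "B", "C", "N", "O", "F", "P", "S", "Cl",
                   "Br", "I", "Se", "Si", "As")

hash_combine <- function(h, x) ((h * 31) %% HASH_MOD + x) %% HASH_MOD

#' Morgan-type fingerprint bits of a molecular graph
#'
#' @param g a `molgraph`.
#' @param radius neighborhood radius (number of hashing iterations).
#' @param nbits fingerprint length.
#' @return sorted integer vector of set bit indices in `[0, nbits)`.
#' @keywords internal
morgan_bits <- function(g, radius = FP_RADIUS, nbits = FP_NBITS) {
  n <- n_atoms(g)
  bc <- bond_code(g)
  deg <- atom_degree(g)
  elc <- match(g$element, ELEMENT_CODES)
  elc[is.na(elc)] <- length(ELEMENT_CODES) + 1L

  # initial atom identifiers (vectorized polynomial hash of the invariants)
  ids <- rep(17, n)
  for (x in list(elc, deg, g$charge + 10L, g$nH,
                 as.integer(g$aromatic), g$isotope)) {
    ids <- ((ids * 31) %% HASH_MOD + x) %% HASH_MOD
  }

  # padded neighbor matrices (rows = atoms)
  md <- max(deg, 1L)
  nbr_m <- matrix(0L, n, md)
  bc_m <- matrix(0L, n, md)
  ptr <- integer(n)
  for (k in seq_along(g$bond_a)) {
    a <- g$bond_a[k]; b <- g$bond_b[k]
    ptr[a] <- ptr[a] + 1L; nbr_m[a, ptr[a]] <- b; bc_m[a, ptr[a]] <- bc[k]
    ptr[b] <- ptr[b] + 1L; nbr_m[b, ptr[b]] <- a; bc_m[b, ptr[b]] <- bc[k]
  }
  pad <- nbr_m == 0L

  all_ids <- ids
  for (r in seq_len(radius)) {
    # neighbor (bond, id) codes, sorted within each row for order invariance
    code <- bc_m * (HASH_MOD + 1) + matrix(ids[pmax(nbr_m, 1L)], n, md)
    code[pad] <- Inf
    if (md > 1L) {
      o <- order(row(code), code)
      scode <- matrix(code[o], n, md, byrow = TRUE)
      sbc <- matrix(bc_m[o], n, md, byrow = TRUE)
      snbr <- matrix(ids[pmax(nbr_m, 1L)][o], n, md, byrow = TRUE)
      spad <- matrix(pad[o], n, md, byrow = TRUE)
    } else {
      sbc <- bc_m; snbr <- matrix(ids[pmax(nbr_m, 1L)], n, md); spad <- pad
    }
    h <- ((17 * 31 + r) %% HASH_MOD * 31 + ids) %% HASH_MOD
    for (col in seq_len(md)) {
      h2 <- ((h * 31) %% HASH_MOD + sbc[, col]) %% HASH_MOD
      h2 <- ((h2 * 31) %% HASH_MOD + snbr[, col]) %% HASH_MOD
      h <- ifelse(spad[, col], h, h2)
    }
    ids <- h
    all_ids <- c(all_ids, ids)
  }
  sort(unique(as.integer(all_ids %% nbits)))
}

# dense 0/1 matrix (nbits x n) from a list of bit vectors, for vectorized
# Tanimoto computations
bits_to_matrix <- function(bit_list, nbits = FP_NBITS) {
  m <- matrix(0, nrow = nbits, ncol = length(bit_list))
  for (j in seq_along(bit_list)) m[bit_list[[j]] + 1L, j] <- 1
  m
}

tanimoto_from_bits <- function(a, b) {
  ia <- length(intersect(a, b))
  un <- length(a) + length(b) - ia
  if (un == 0L) return(NA_real_)  # both empty; caller decides
  ia / un
}
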