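# BRICS retrosynthetic rules: 16 link-environment types at which acyclic
# bonds may be cleaved, plus the compatibility relation governing which
# fragment types recombine. The definitions follow the published rule set in
# its widely used modern adaptation: the secondary-amine class (type 2) is
# merged into the general amine class (type 5), types 7a/7b (alkene carbons,
# joined by a double bond) share one predicate, and 14b/16b duplicate 14/16.
# The table is 16 x 16 with row/column 2 inactive.

# Ordered list of cleavage definitions (first match wins per bond). Each row:
# left type, right type, bond order of the cleaved/re-formed bond.
BRICS_DEFS <- matrix(c(
  1, 3, 1,   1, 5, 1,   1, 10, 1,
  3, 4, 1,   3, 13, 1,  3, 14, 1,  3, 15, 1,  3, 16, 1,
  4, 5, 1,   4, 11, 1,
  5, 12, 1,  5, 14, 1,  5, 16, 1,  5, 13, 1,  5, 15, 1,
  6, 13, 1,  6, 14, 1,  6, 15, 1,  6, 16, 1,
  7, 7, 2,
  8, 9, 1,   8, 10, 1,  8, 13, 1,  8, 14, 1,  8, 15, 1,  8, 16, 1,
  9, 13, 1,  9, 14, 1,  9, 15, 1,  9, 16, 1,
  10, 13, 1, 10, 14, 1, 10, 15, 1, 10, 16, 1,
  11, 13, 1, 11, 14, 1, 11, 15, 1, 11, 16, 1,
  13, 14, 1, 13, 15, 1, 13, 16, 1,
  14, 14, 1, 14, 15, 1, 14, 16, 1,
  15, 16, 1,
  16, 16, 1
), ncol = 3, byrow = TRUE)

#' BRICS link-type compatibility table
#'
#' @return a symmetric 16 x 16 logical matrix; `TRUE` where two link types may
#'   be joined by virtual synthesis.
#' @export
brics_compatibility_table <- function() {
  tab <- matrix(FALSE, 16L, 16L,
                dimnames = list(paste0("L", 1:16), paste0("L", 1:16)))
  for (r in seq_len(nrow(BRICS_DEFS))) {
    tab[BRICS_DEFS[r, 1], BRICS_DEFS[r, 2]] <- TRUE
    tab[BRICS_DEFS[r, 2], BRICS_DEFS[r, 1]] <- TRUE
  }
  tab
}

#' Are two BRICS link types compatible?
#'
#' @param a,b integer link types in 1..16.
#' @return logical.
#' @export
brics_compatible <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (is.na(a) || is.na(b) || a < 1L || a > 16L || b < 1L || b > 16L) {
    stop("link types must be integers in 1..16")
  }
  ensure_state()
  .chemsa$compat[a, b]
}

# bond order used when joining two fragments of the given link types
brics_join_order <- function(a, b) if (a == 7L && b == 7L) 2L else 1L

# --- link-environment predicates -------------------------------------------
# ctx: precomputed per-molecule context (adjacency, ring masks, degrees)

brics_context <- function(g) {
  ringb <- ring_bond_mask(g)
  list(g = g, adj = adjacency_list(g), deg = atom_degree(g),
       ringb = ringb, ringa = ring_atom_mask(g, ringb))
}

# neighbor descriptors of atom i: element, aromatic, bond order, bond aromatic,
# bond ring membership, neighbor index
nbr_info <- function(ctx, i) {
  nb <- ctx$adj[[i]]
  g <- ctx$g
  k <- nb$bond
  list(idx = nb$nbr, el = g$element[nb$nbr], arom = g$aromatic[nb$nbr],
       order = g$bond_order[k], barom = g$bond_arom[k], bring = ctx$ringb[k])
}

has_double_to_O <- function(ctx, i) {
  nb <- nbr_info(ctx, i)
  any(nb$order == 2L & !nb$barom & nb$el == "O")
}

# do two neighbor subsets contain a pair of *distinct* neighbors?
# (SMARTS branch semantics: branches map to different atoms)
exists_distinct_pair <- function(a_set, b_set) {
  na <- sum(a_set); nb <- sum(b_set)
  if (na == 0L || nb == 0L) return(FALSE)
  !(na == 1L && nb == 1L && which(a_set) == which(b_set))
}

brics_env_match <- function(ctx, i, type) {
  g <- ctx$g
  el <- g$element[i]; arom <- g$aromatic[i]; deg <- ctx$deg[i]
  nb <- nbr_info(ctx, i)
  single_acyclic <- nb$order == 1L & !nb$barom & !nb$bring
  switch(type,
    # L1: acyl carbon C(=O) with another neighbor among {*, C, N, O}
    `1` = el == "C" && !arom && deg == 3L && has_double_to_O(ctx, i) &&
      any(nb$el %in% c("*", "C", "N", "O") & !(nb$order == 2L & nb$el == "O" & !nb$barom)),
    # L2 merged into L5 in the modern rule set: never matches
    `2` = FALSE,
    # L3: ether/ester oxygen with a single acyclic bond to carbon
    `3` = el == "O" && !arom && deg == 2L &&
      any(single_acyclic & nb$el %in% c("*", "C")),
    # L4: sp3-like carbon (no double bonds) with a single acyclic C neighbor
    `4` = el == "C" && !arom && deg >= 2L &&
      !any(nb$order == 2L & !nb$barom) &&
      any(single_acyclic & nb$el == "C"),
    # L5: amine nitrogen: all neighbors C/S/dummy, no double bond, not a lactam N
    `5` = el == "N" && !arom && deg >= 2L &&
      all(nb$el %in% c("C", "S", "*")) &&
      !any(nb$order == 2L & !nb$barom) &&
      !(ctx$ringa[i] && any(nb$bring & nb$el == "C" & !nb$arom &
                              vapply(nb$idx, function(j) has_double_to_O(ctx, j), TRUE))),
    # L6: acyclic acyl carbon with a single acyclic bond to {*, C, N, O}
    `6` = el == "C" && !arom && deg == 3L && !ctx$ringa[i] &&
      has_double_to_O(ctx, i) &&
      any(single_acyclic & nb$el %in% c("*", "C", "N", "O")),
    # L7: alkene carbon (degree 2-3) with a single bond to carbon
    `7` = el == "C" && !arom && deg %in% c(2L, 3L) &&
      any(nb$order == 1L & !nb$barom & nb$el == "C"),
    # L8: acyclic carbon, all bonds single
    `8` = el == "C" && !arom && !ctx$ringa[i] && deg >= 2L &&
      all(nb$order == 1L & !nb$barom),
    # L9: neutral aromatic nitrogen between aromatic c/n/o/s
    `9` = el == "N" && arom && g$charge[i] == 0L &&
      sum(nb$barom & nb$arom & nb$el %in% c("C", "N", "O", "S")) >= 2L,
    # L10: lactam nitrogen: ring N bonded in-ring to C(=O) and to C/N/O/S
    `10` = el == "N" && !arom && ctx$ringa[i] && {
      acyl <- nb$bring & nb$el == "C" & !nb$arom &
        vapply(nb$idx, function(j) has_double_to_O(ctx, j), TRUE)
      other <- nb$bring & !nb$arom & nb$el %in% c("C", "N", "O", "S")
      exists_distinct_pair(acyl, other)
    },
    # L11: thioether sulfur
    `11` = el == "S" && !arom && deg == 2L &&
      any(single_acyclic & nb$el %in% c("*", "C")),
    # L12: sulfonyl sulfur
    `12` = el == "S" && !arom && deg == 4L &&
      sum(nb$order == 2L & !nb$barom & nb$el == "O") >= 2L &&
      any(nb$el %in% c("*", "C")),
    # L13: ring carbon flanked in-ring by a heteroatom (N/O/S) and C/N/O/S
    `13` = el == "C" && !arom && {
      ring_single <- nb$bring & nb$order == 1L & !nb$barom & !nb$arom
      a_set <- ring_single & nb$el %in% c("C", "N", "O", "S")
      b_set <- ring_single & nb$el %in% c("N", "O", "S")
      exists_distinct_pair(a_set, b_set)
    },
    # L14: aromatic carbon adjacent to an aromatic heteroatom
    `14` = el == "C" && arom && {
      cn <- nb$barom & nb$arom & nb$el %in% c("C", "N", "O", "S")
      het <- nb$barom & nb$arom & nb$el %in% c("N", "O", "S")
      any(het) && sum(cn) >= 2L
    },
    # L15: aliphatic ring carbon with two ring single bonds to carbon
    `15` = el == "C" && !arom &&
      sum(nb$bring & nb$order == 1L & !nb$barom & nb$el == "C" & !nb$arom) >= 2L,
    # L16: benzene-like aromatic carbon
    `16` = el == "C" && arom &&
      sum(nb$barom & nb$arom & nb$el == "C") >= 2L,
    FALSE
  )
}

# all 16 environment matches for every atom: 16 x n logical matrix
brics_env_matrix <- function(ctx) {
  n <- n_atoms(ctx$g)
  m <- matrix(FALSE, 16L, n)
  for (i in seq_len(n)) {
    for (t in c(1L, 3:16)) m[t, i] <- brics_env_match(ctx, i, as.character(t))
  }
  m
}

#' Enumerate BRICS-cleavable bonds of a molecule
#'
#' Scans every acyclic bond against the ordered list of BRICS cleavage
#' definitions; the first matching definition labels the bond. Ring bonds are
#' never cleavable.
#'
#' @param mol a `molecule` (or SMILES string).
#' @return data.frame with columns `bond`, `atom_a`, `atom_b`, `link_a`,
#'   `link_b` (link types of the environments matched by each bond end);
#'   zero rows when no bond is cleavable.
#' @export
enumerate_cleavages <- function(mol) {
  g <- if (inherits(mol, "molgraph")) mol else canonicalize(mol)$graph
  ctx <- brics_context(g)
  env <- brics_env_matrix(ctx)
  res <- list()
  for (k in seq_len(n_bonds(g))) {
    if (ctx$ringb[k] || g$bond_arom[k]) next
    a <- g$bond_a[k]; b <- g$bond_b[k]
    for (r in seq_len(nrow(BRICS_DEFS))) {
      p <- BRICS_DEFS[r, 1]; q <- BRICS_DEFS[r, 2]; ord <- BRICS_DEFS[r, 3]
      if (g$bond_order[k] != ord) next
      if (env[p, a] && env[q, b]) {
        res[[length(res) + 1L]] <- c(k, a, b, p, q); break
      }
      if (env[p, b] && env[q, a]) {
        res[[length(res) + 1L]] <- c(k, a, b, q, p); break
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(bond = integer(), atom_a = integer(), atom_b = integer(),
                      link_a = integer(), link_b = integer()))
  }
  m <- do.call(rbind, res)
  data.frame(bond = m[, 1], atom_a = m[, 2], atom_b = m[, 3],
             link_a = m[, 4], link_b = m[, 5])
}
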