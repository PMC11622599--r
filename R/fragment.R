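#' Fragment objects
#'
#' A `fragment` is one side of a single BRICS cleavage: a sub-molecule with
#' exactly one attachment point, encoded as an isotope-labelled dummy atom
#' (`[5*]` carries link type 5), so a fragment round-trips through SMILES
#' text. `n_heavy` counts real atoms only, never the placeholder.
#'
#' @name fragment
NULL

new_fragment <- function(core_smiles, link_type, n_heavy, parent = NA_character_) {
  structure(list(core_smiles = core_smiles, link_type = as.integer(link_type),
                 n_heavy = as.integer(n_heavy), parent = parent),
            class = "fragment")
}

#' @export
print.fragment <- function(x, ...) {
  cat(sprintf("<fragment> %s (link L%d, %d heavy atoms)\n",
              x$core_smiles, x$link_type, x$n_heavy))
  invisible(x)
}

is_fragment <- function(x) inherits(x, "fragment")

# cached parse of a fragment core (atom order is canonical, so the dummy
# position is deterministic)
frag_graph <- function(core_smiles) {
  ensure_state()
  g <- get0(core_smiles, envir = .chemsa$graph_cache)
  if (is.null(g)) {
    g <- parse_smiles(core_smiles)
    assign(core_smiles, g, envir = .chemsa$graph_cache)
  }
  g
}

# cached fingerprint of a fragment core (dummy atom included; its isotope
# label makes link environments distinguishable, which is what the frequency
# weighting sees)
frag_fp <- function(core_smiles) {
  ensure_state()
  fp <- get0(core_smiles, envir = .chemsa$fp_cache)
  if (is.null(fp)) {
    fp <- morgan_bits(frag_graph(core_smiles))
    assign(core_smiles, fp, envir = .chemsa$fp_cache)
  }
  fp
}

# build the fragment on `side` (logical atom mask) of bond k, attaching a
# dummy of the given link type with the cut bond's order
build_fragment <- function(g, side, attach_atom, link_type, order, parent) {
  idx <- which(side)
  sub <- subgraph(g, idx)
  # append dummy atom bonded to the (remapped) attachment atom
  a_new <- match(attach_atom, idx)
  sub$element <- c(sub$element, "*")
  sub$aromatic <- c(sub$aromatic, FALSE)
  sub$charge <- c(sub$charge, 0L)
  sub$nH <- c(sub$nH, 0L)
  sub$isotope <- c(sub$isotope, as.integer(link_type))
  sub$bond_a <- c(sub$bond_a, a_new)
  sub$bond_b <- c(sub$bond_b, length(sub$element))
  sub$bond_order <- c(sub$bond_order, as.integer(order))
  sub$bond_arom <- c(sub$bond_arom, FALSE)
  core <- canonical_smiles_of_graph(sub)
  new_fragment(core, link_type, length(idx), parent)
}

#' Fragment a molecule by single BRICS cleavages
#'
#' For every cleavable bond found by [enumerate_cleavages()], both sides are
#' emitted as single-attachment-point fragments. Fragments with
#' `n_heavy <= min_heavy_exclusive` are discarded (the filter is strict:
#' the default keeps fragments of more than three real atoms). Results are
#' deduplicated by core SMILES (which encodes the link type).
#'
#' @param mol a `molecule` or SMILES string.
#' @param min_heavy_exclusive strict lower bound on fragment heavy atoms.
#' @return list of `fragment` objects (possibly empty).
#' @export
fragment_molecule <- function(mol, min_heavy_exclusive = 3L) {
  mol <- canonicalize(mol)
  ensure_state()
  key <- sprintf("%s#%d", mol$smiles, min_heavy_exclusive)
  hit <- get0(key, envir = .chemsa$frag_cache)
  if (!is.null(hit)) return(hit)

  g <- mol$graph
  cl <- enumerate_cleavages(mol)
  out <- list()
  seen <- character()
  if (nrow(cl) > 0L) {
    comp_of <- function(k, from) {
      # atoms reachable from `from` without crossing bond k
      n <- n_atoms(g)
      mask <- logical(n)
      mask[from] <- TRUE
      queue <- from
      while (length(queue) > 0L) {
        v <- queue[[1L]]; queue <- queue[-1L]
        sel <- which((g$bond_a == v | g$bond_b == v) & seq_len(n_bonds(g)) != k)
        for (kk in sel) {
          w <- if (g$bond_a[kk] == v) g$bond_b[kk] else g$bond_a[kk]
          if (!mask[w]) { mask[w] <- TRUE; queue <- c(queue, w) }
        }
      }
      mask
    }
    for (r in seq_len(nrow(cl))) {
      k <- cl$bond[r]
      ord <- g$bond_order[k]
      side_a <- comp_of(k, cl$atom_a[r])
      side_b <- !side_a
      for (spec in list(list(side = side_a, at = cl$atom_a[r], link = cl$link_a[r]),
                        list(side = side_b, at = cl$atom_b[r], link = cl$link_b[r]))) {
        if (sum(spec$side) <= min_heavy_exclusive) next
        fr <- build_fragment(g, spec$side, spec$at, spec$link, ord, mol$smiles)
        if (!(fr$core_smiles %in% seen)) {
          seen <- c(seen, fr$core_smiles)
          out[[length(out) + 1L]] <- fr
        }
      }
    }
  }
  assign(key, out, envir = .chemsa$frag_cache)
  out
}

# both sides of the r-th cleavage of a molecule, unfiltered — the exact
# complementary pair whose rejoining must reconstruct the parent
cleavage_fragments <- function(mol, r) {
  mol <- canonicalize(mol)
  g <- mol$graph
  cl <- enumerate_cleavages(mol)
  stopifnot(r >= 1L, r <= nrow(cl))
  k <- cl$bond[r]
  n <- n_atoms(g)
  mask <- logical(n)
  mask[cl$atom_a[r]] <- TRUE
  queue <- cl$atom_a[r]
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]
    sel <- which((g$bond_a == v | g$bond_b == v) & seq_len(n_bonds(g)) != k)
    for (kk in sel) {
      w <- if (g$bond_a[kk] == v) g$bond_b[kk] else g$bond_a[kk]
      if (!mask[w]) { mask[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  ord <- g$bond_order[k]
  list(build_fragment(g, mask, cl$atom_a[r], cl$link_a[r], ord, mol$smiles),
       build_fragment(g, !mask, cl$atom_b[r], cl$link_b[r], ord, mol$smiles))
}

# locate the single dummy atom of a fragment graph; errors when the
# placeholder count is not exactly one
dummy_index <- function(g) {
  d <- which(g$element == "*")
  if (length(d) != 1L) stop("fragment must have exactly one attachment point")
  d
}

#' Read fragments from SMILES lines
#'
#' Each line holds a fragment core SMILES using the isotope-labelled dummy
#' convention (for example `[5*]N1CCOCC1`). Lines whose placeholder count is
#' not exactly one, whose link label is outside 1..16, or which fail to parse
#' are dropped with a logged count.
#'
#' @param lines character vector of SMILES lines.
#' @return list of `fragment` objects.
#' @export
fragments_from_lines <- function(lines) {
  out <- list()
  dropped <- 0L
  for (ln in lines) {
    smi <- sub("[\t ].*$", "", trimws(ln))
    if (!nzchar(smi) || startsWith(smi, "#")) next
    fr <- tryCatch({
      g <- parse_smiles(smi)
      if (max(graph_components(g)) != 1L) stop("disconnected")
      d <- dummy_index(g)
      link <- g$isotope[d]
      if (link < 1L || link > 16L) stop("link label out of range")
      core <- canonical_smiles_of_graph(g)
      new_fragment(core, link, sum(g$element != "*"))
    }, error = function(e) NULL)
    if (is.null(fr)) dropped <- dropped + 1L else out[[length(out) + 1L]] <- fr
  }
  if (dropped > 0L) {
    message(sprintf("chemsa: dropped %d invalid fragment line(s)", dropped))
  }
  out
}
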