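# Canonical atom ranking (Morgan-style iterative refinement with rank
# doubling for tie breaks) and a depth-first SMILES writer. The canonical
# form is a fixed point: writing and re-parsing a canonical string yields the
# same string again.

bond_code <- function(g) ifelse(g$bond_arom, 4L, g$bond_order)

# initial atom invariants: element, aromaticity, charge, H count, isotope,
# degree, ring membership (numeric key matrix for group_rows)
initial_invariant_keys <- function(g, ringa) {
  elc <- match(g$element, ELEMENT_CODES)
  elc[is.na(elc)] <- length(ELEMENT_CODES) + 1L
  cbind(elc, as.integer(g$aromatic), g$charge, g$nH, g$isotope,
        atom_degree(g), as.integer(ringa))
}

# padded neighbor matrices for fast numeric refinement
refine_context <- function(adj, bc) {
  n <- length(adj)
  deg <- vapply(adj, function(a) length(a$nbr), 0L)
  md <- max(deg, 1L)
  nbr_m <- matrix(0L, n, md)
  bc_m <- matrix(0L, n, md)
  for (i in seq_len(n)) {
    d <- deg[i]
    if (d > 0L) {
      nbr_m[i, seq_len(d)] <- adj[[i]]$nbr
      bc_m[i, seq_len(d)] <- bc[adj[[i]]$bond]
    }
  }
  list(nbr_m = nbr_m, bc_m = bc_m, deg = deg, n = n, md = md)
}

# group rows of a numeric key matrix into dense ranks 1..k (lexicographic)
group_rows <- function(keys) {
  n <- nrow(keys)
  if (n == 1L) return(1L)
  ord <- do.call(order, lapply(seq_len(ncol(keys)), function(j) keys[, j]))
  k2 <- keys[ord, , drop = FALSE]
  new_grp <- cumsum(c(1L, as.integer(rowSums(
    k2[-1L, , drop = FALSE] != k2[-n, , drop = FALSE]) > 0)))
  out <- integer(n)
  out[ord] <- new_grp
  out
}

refine_ranks <- function(rank, rc) {
  n <- rc$n
  pad <- n + 2L  # padding sorts last
  repeat {
    code <- rc$bc_m * (n + 1L) + matrix(rank[pmax(rc$nbr_m, 1L)], n, rc$md)
    code[rc$nbr_m == 0L] <- pad * (n + 1L) + pad
    if (rc$md > 1L) {
      code <- matrix(code[order(row(code), code)], n, rc$md, byrow = TRUE)
    }
    newrank <- group_rows(cbind(rank, code))
    if (length(unique(newrank)) == length(unique(rank))) return(newrank)
    rank <- newrank
  }
}

# canonical ranks: 1..n, all distinct, graph-invariant for the molecules this
# package handles (refinement separates non-equivalent atoms; remaining ties
# are between automorphic atoms, so promoting the lowest-index member is safe)
canon_ranks <- function(g) {
  n <- n_atoms(g)
  if (n == 1L) return(1L)
  adj <- adjacency_list(g)
  rc <- refine_context(adj, bond_code(g))
  ringa <- ring_atom_mask(g)
  rank <- group_rows(initial_invariant_keys(g, ringa))
  rank <- refine_ranks(rank, rc)
  while (length(unique(rank)) < n) {
    dup <- rank[duplicated(rank)]
    tb <- min(dup)
    a <- which(rank == tb)[1L]
    rank <- rank * 2L
    rank[a] <- rank[a] - 1L
    rank <- group_rows(cbind(rank))
    rank <- refine_ranks(rank, rc)
  }
  rank
}

# would this atom's implicit-H count be reproduced by the parser without a
# bracket? (organic subset, neutral, no isotope)
implicit_h_ok <- function(g, i, sval) {
  if (g$charge[i] != 0L || g$isotope[i] != 0L) return(FALSE)
  if (!(g$element[i] %in% ORGANIC_SUBSET)) return(FALSE)
  if (g$aromatic[i] && !(tolower(g$element[i]) %in% AROMATIC_OK)) return(FALSE)
  allowed <- allowed_valences(g$element[i], 0L)
  fit <- allowed[allowed >= sval[i]]
  if (length(fit) == 0L) return(FALSE)
  (min(fit) - sval[i]) == g$nH[i]
}

atom_token <- function(g, i, sval) {
  sym <- g$element[i]
  if (g$aromatic[i]) sym <- tolower(sym)
  if (implicit_h_ok(g, i, sval)) return(sym)
  iso <- if (g$isotope[i] > 0L) as.character(g$isotope[i]) else ""
  h <- if (g$nH[i] == 0L) "" else if (g$nH[i] == 1L) "H" else paste0("H", g$nH[i])
  chg <- if (g$charge[i] == 0L) "" else {
    sgn <- if (g$charge[i] > 0L) "+" else "-"
    mag <- abs(g$charge[i])
    if (mag == 1L) sgn else paste0(sgn, mag)
  }
  paste0("[", iso, sym, h, chg, "]")
}

bond_token <- function(g, k) {
  if (g$bond_arom[k]) return("")
  if (g$bond_order[k] == 2L) return("=")
  if (g$bond_order[k] == 3L) return("#")
  # explicit single needed between two aromatic atoms (e.g. biphenyl)
  if (g$aromatic[g$bond_a[k]] && g$aromatic[g$bond_b[k]]) return("-")
  ""
}

# Write a SMILES string for a connected molgraph. `priority` orders the DFS
# (lower value visited first); when NULL, canonical ranks are used, which
# yields the canonical SMILES.
write_smiles <- function(g, priority = NULL) {
  n <- n_atoms(g)
  if (n == 0L) stop("empty graph")
  if (max(graph_components(g)) != 1L) stop("write_smiles requires a connected graph")
  if (is.null(priority)) priority <- canon_ranks(g)
  adj <- adjacency_list(g)
  sval <- atom_bond_valence(g)

  visited <- logical(n)
  used <- logical(n_bonds(g))
  ring_num <- integer(n_bonds(g))   # closure number per back edge
  closures <- vector("list", n)     # per atom: bond indices of its closures
  next_ring <- 0L
  order_children <- function(i) {
    nb <- adj[[i]]
    o <- order(priority[nb$nbr])
    list(nbr = nb$nbr[o], bond = nb$bond[o])
  }

  # phase 1: spanning DFS to mark tree edges and number ring closures
  tree_children <- vector("list", n)
  start <- which.min(priority)
  st <- list(list(v = start, ptr = 1L, ord = order_children(start)))
  visited[start] <- TRUE
  while (length(st) > 0L) {
    fr <- st[[length(st)]]
    if (fr$ptr <= length(fr$ord$nbr)) {
      st[[length(st)]]$ptr <- fr$ptr + 1L
      w <- fr$ord$nbr[fr$ptr]; bk <- fr$ord$bond[fr$ptr]
      if (used[bk]) next
      if (!visited[w]) {
        used[bk] <- TRUE
        visited[w] <- TRUE
        tree_children[[fr$v]] <- c(tree_children[[fr$v]], bk)
        st[[length(st) + 1L]] <- list(v = w, ptr = 1L, ord = order_children(w))
      } else {
        used[bk] <- TRUE
        next_ring <- next_ring + 1L
        ring_num[bk] <- next_ring
        closures[[fr$v]] <- c(closures[[fr$v]], bk)
        closures[[w]] <- c(closures[[w]], bk)
      }
    } else {
      st[[length(st)]] <- NULL
    }
  }

  ring_token <- function(k) {
    nr <- ring_num[k]
    d <- if (nr < 10L) as.character(nr) else sprintf("%%%02d", nr)
    paste0(bond_token(g, k), d)
  }

  # phase 2: recursive emission
  emit <- function(i) {
    out <- atom_token(g, i, sval)
    cls <- closures[[i]]
    if (length(cls) > 0L) {
      for (k in cls[order(ring_num[cls])]) out <- paste0(out, ring_token(k))
    }
    kids <- tree_children[[i]]
    if (length(kids) > 0L) {
      nb <- ifelse(g$bond_a[kids] == i, g$bond_b[kids], g$bond_a[kids])
      o <- order(priority[nb])
      kids <- kids[o]; nb <- nb[o]
      for (t in seq_along(kids)) {
        piece <- paste0(bond_token(g, kids[t]), emit(nb[t]))
        out <- if (t < length(kids)) paste0(out, "(", piece, ")")
               else paste0(out, piece)
      }
    }
    out
  }
  emit(start)
}

canonical_smiles_of_graph <- function(g) write_smiles(g, priority = NULL)

# a random (non-canonical but valid) SMILES rewriting, used to test that
# canonicalization is independent of atom input order
random_smiles_of_graph <- function(g) {
  write_smiles(g, priority = sample.int(n_atoms(g)))
}
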