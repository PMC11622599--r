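# Internal molecular graph representation ("molgraph"):
# parallel vectors over atoms (element, aromatic, charge, nH, isotope) and
# bonds (bond_a, bond_b, bond_order in {1,2,3}, bond_arom). Hydrogens are
# implicit everywhere; element "*" is the attachment-point dummy whose isotope
# field carries the BRICS link type.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_OK <- c("b", "c", "n", "o", "p", "s")

parse_error <- function(smiles, why) {
  stop(structure(
    class = c("chemsa_parse_error", "error", "condition"),
    list(message = sprintf("cannot parse SMILES '%s': %s", smiles, why),
         call = NULL, smiles = smiles)
  ))
}

new_molgraph <- function(element, aromatic, charge, nH, isotope,
                         bond_a, bond_b, bond_order, bond_arom) {
  structure(list(
    element = element, aromatic = aromatic, charge = as.integer(charge),
    nH = as.integer(nH), isotope = as.integer(isotope),
    bond_a = as.integer(bond_a), bond_b = as.integer(bond_b),
    bond_order = as.integer(bond_order), bond_arom = bond_arom
  ), class = "molgraph")
}

n_atoms <- function(g) length(g$element)
n_bonds <- function(g) length(g$bond_a)

# Allowed total valence (sum of bond orders + implicit H) per element/charge.
# Returns a vector of admissible valences (lowest first) or NULL when the
# element is not checked (uncommon elements pass through).
allowed_valences <- function(element, charge) {
  switch(element,
    "C" = if (charge == 0L) 4L else 3L,
    "N" = if (charge == 0L) c(3L, 5L) else if (charge > 0L) 4L else 2L,
    "O" = if (charge == 0L) 2L else if (charge > 0L) 3L else 1L,
    "S" = if (charge == 0L) c(2L, 4L, 6L) else if (charge > 0L) c(3L, 5L) else 1L,
    "P" = if (charge == 0L) c(3L, 5L) else if (charge > 0L) 4L else 2L,
    "B" = if (charge < 0L) 4L else 3L,
    "F" = , "Cl" = , "Br" = , "I" = if (charge == 0L) 1L else 0L,
    "*" = NULL,
    NULL
  )
}

# Sum of bond orders seen by each atom, with the aromatic-bond convention:
# each aromatic bond contributes 1, plus one extra unit for aromatic C/N/B/P
# (the delocalized double bond). This is the usual bookkeeping that makes
# implicit-H counts come out right without kekulization.
atom_bond_valence <- function(g) {
  n <- n_atoms(g)
  s <- numeric(n)
  ord <- ifelse(g$bond_arom, 1L, g$bond_order)
  for (k in seq_len(n_bonds(g))) {
    s[g$bond_a[k]] <- s[g$bond_a[k]] + ord[k]
    s[g$bond_b[k]] <- s[g$bond_b[k]] + ord[k]
  }
  extra <- g$aromatic & g$element %in% c("C", "N", "B", "P")
  s + as.integer(extra)
}

atom_degree <- function(g) {
  tabulate(c(g$bond_a, g$bond_b), nbins = n_atoms(g))
}

#' Parse a SMILES string into an internal molecular graph
#'
#' Supports the organic subset, bracket atoms (isotope, charge, explicit H
#' count), aromatic lowercase atoms, ring closures (including `%nn`), branches
#' and dot-separated components. Stereo markers (`@`, `/`, `\\`) are accepted
#' and ignored. Aromaticity is taken from the input flags; Kekule input is kept
#' as alternating single/double bonds (no aromaticity perception).
#'
#' @param smiles a single SMILES string.
#' @return a `molgraph` object (possibly multi-component).
#' @keywords internal
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    parse_error(if (is.character(smiles) && length(smiles) == 1L) smiles else "<non-string>",
                "input must be a single non-empty string")
  }
  s <- smiles
  nc <- nchar(s)
  el <- character(); arom <- logical(); chg <- integer(); hct <- integer()
  iso <- integer(); brkt <- logical()
  ba <- integer(); bb <- integer(); bo <- integer(); bar <- logical()

  add_bond <- function(i, j, spec) {
    # spec: NA = default (aromatic if both ends aromatic, else single)
    if (is.na(spec)) {
      if (arom[i] && arom[j]) { o <- 1L; a <- TRUE } else { o <- 1L; a <- FALSE }
    } else if (spec == ":") { o <- 1L; a <- TRUE
    } else if (spec == "=") { o <- 2L; a <- FALSE
    } else if (spec == "#") { o <- 3L; a <- FALSE
    } else { o <- 1L; a <- FALSE }  # '-', '/', '\\'
    ba <<- c(ba, i); bb <<- c(bb, j); bo <<- c(bo, o); bar <<- c(bar, a)
  }

  prev <- 0L
  pend <- NA_character_
  stack <- integer()
  rings <- list()  # key -> c(atom, bond spec as string or NA)

  add_atom <- function(element, aromatic, charge, h, isotope, bracket) {
    el <<- c(el, element); arom <<- c(arom, aromatic); chg <<- c(chg, charge)
    hct <<- c(hct, h); iso <<- c(iso, isotope); brkt <<- c(brkt, bracket)
    idx <- length(el)
    if (prev > 0L) add_bond(prev, idx, pend)
    prev <<- idx
    pend <<- NA_character_
    idx
  }

  i <- 1L
  while (i <= nc) {
    ch <- substr(s, i, i)
    ch2 <- if (i < nc) substr(s, i, i + 1L) else ""
    if (ch2 %in% c("Cl", "Br")) {
      add_atom(ch2, FALSE, 0L, NA_integer_, 0L, FALSE); i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      add_atom(ch, FALSE, 0L, NA_integer_, 0L, FALSE); i <- i + 1L
    } else if (ch %in% AROMATIC_OK) {
      add_atom(toupper(ch), TRUE, 0L, NA_integer_, 0L, FALSE); i <- i + 1L
    } else if (ch == "*") {
      add_atom("*", FALSE, 0L, 0L, 0L, TRUE); i <- i + 1L
    } else if (ch == "[") {
      j <- regexpr("]", substr(s, i, nc), fixed = TRUE)
      if (j < 0L) parse_error(s, "unclosed bracket atom")
      body <- substr(s, i + 1L, i + j - 2L)
      m <- regmatches(body, regexec(
        "^([0-9]+)?([A-Za-z][a-z]?|\\*)(@TH[12]|@{1,2})?(H[0-9]*)?((?:\\+[0-9]*)|(?:-[0-9]*))?(:[0-9]+)?$",
        body))[[1]]
      if (length(m) == 0L) parse_error(s, paste0("bad bracket atom [", body, "]"))
      isotope <- if (nzchar(m[2])) as.integer(m[2]) else 0L
      sym <- m[3]
      aromatic <- sym %in% AROMATIC_OK || sym %in% c("se", "as")
      element <- if (aromatic) {
        paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
      } else sym
      h <- if (nzchar(m[5])) {
        if (m[5] == "H") 1L else as.integer(substr(m[5], 2L, nchar(m[5])))
      } else 0L
      charge <- if (nzchar(m[6])) {
        sgn <- if (substr(m[6], 1, 1) == "+") 1L else -1L
        num <- substr(m[6], 2L, nchar(m[6]))
        if (!nzchar(num)) sgn else sgn * as.integer(num)
      } else 0L
      add_atom(element, aromatic, charge, h, isotope, TRUE)
      i <- i + j
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pend <- ch; i <- i + 1L
    } else if (ch == "(") {
      if (prev == 0L) parse_error(s, "branch with no preceding atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) parse_error(s, "unmatched ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- 0L; pend <- NA_character_; i <- i + 1L
    } else if (grepl("^[0-9]$", ch) || ch == "%") {
      if (prev == 0L) parse_error(s, "ring closure with no preceding atom")
      if (ch == "%") {
        if (i + 2L > nc) parse_error(s, "bad %nn ring closure")
        key <- substr(s, i + 1L, i + 2L)
        if (!grepl("^[0-9]{2}$", key)) parse_error(s, "bad %nn ring closure")
        i <- i + 3L
      } else {
        key <- ch; i <- i + 1L
      }
      if (!is.null(rings[[key]])) {
        op <- rings[[key]]
        spec1 <- op$spec; spec2 <- pend
        if (!is.na(spec1) && !is.na(spec2) && spec1 != spec2) {
          parse_error(s, "conflicting ring-closure bond symbols")
        }
        spec <- if (!is.na(spec1)) spec1 else spec2
        if (op$atom == prev) parse_error(s, "self ring closure")
        add_bond(op$atom, prev, spec)
        rings[[key]] <- NULL
        pend <- NA_character_
      } else {
        rings[[key]] <- list(atom = prev, spec = pend)
        pend <- NA_character_
      }
    } else if (ch == " " || ch == "\t") {
      break  # trailing title field
    } else {
      parse_error(s, paste0("unexpected character '", ch, "'"))
    }
  }
  if (length(stack) > 0L) parse_error(s, "unmatched '('")
  if (length(rings) > 0L) parse_error(s, "unclosed ring bond")
  if (length(el) == 0L) parse_error(s, "no atoms")
  if (anyDuplicated(paste(pmin(ba, bb), pmax(ba, bb)))) {
    parse_error(s, "duplicate bond")
  }

  g <- new_molgraph(el, arom, chg, ifelse(is.na(hct), 0L, hct), iso,
                    ba, bb, bo, bar)
  s_val <- atom_bond_valence(g)

  # implicit hydrogens for unbracketed organic-subset atoms
  for (a in seq_along(el)) {
    allowed <- allowed_valences(el[a], chg[a])
    if (!brkt[a]) {
      fit <- allowed[allowed >= s_val[a]]
      if (length(fit) == 0L) {
        parse_error(s, sprintf("valence %s on atom %d (%s) exceeds allowed",
                               format(s_val[a]), a, el[a]))
      }
      g$nH[a] <- as.integer(min(fit) - s_val[a])
    } else {
      total <- s_val[a] + g$nH[a]
      if (!is.null(allowed) && total > max(allowed)) {
        parse_error(s, sprintf("valence %s on atom %d (%s) exceeds allowed",
                               format(total), a, el[a]))
      }
    }
  }
  g
}

# connected components; returns integer membership vector
graph_components <- function(g) {
  n <- n_atoms(g)
  comp <- integer(n)
  adj <- adjacency_list(g)
  cid <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0L) next
    cid <- cid + 1L
    queue <- start
    comp[start] <- cid
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (w in adj[[v]]$nbr) {
        if (comp[w] == 0L) { comp[w] <- cid; queue <- c(queue, w) }
      }
    }
  }
  comp
}

# adjacency list: per atom, data.frame-free list(nbr=, bond=) integer vectors
adjacency_list <- function(g) {
  n <- n_atoms(g)
  nbrs <- vector("list", n)
  bonds <- vector("list", n)
  for (k in seq_len(n_bonds(g))) {
    a <- g$bond_a[k]; b <- g$bond_b[k]
    nbrs[[a]] <- c(nbrs[[a]], b); bonds[[a]] <- c(bonds[[a]], k)
    nbrs[[b]] <- c(nbrs[[b]], a); bonds[[b]] <- c(bonds[[b]], k)
  }
  lapply(seq_len(n), function(i) {
    list(nbr = as.integer(nbrs[[i]] %||% integer()),
         bond = as.integer(bonds[[i]] %||% integer()))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ring (non-bridge) bonds via iterative Tarjan bridge finding
ring_bond_mask <- function(g) {
  n <- n_atoms(g)
  nb <- n_bonds(g)
  if (nb == 0L) return(logical(0))
  adj <- adjacency_list(g)
  disc <- integer(n); low <- integer(n)
  is_bridge <- logical(nb)
  timer <- 0L
  for (root in seq_len(n)) {
    if (disc[root] > 0L) next
    # stack frames: atom, parent bond, next neighbor pointer
    stack <- list(list(v = root, pb = 0L, ptr = 1L))
    timer <- timer + 1L; disc[root] <- low[root] <- timer
    while (length(stack) > 0L) {
      fr <- stack[[length(stack)]]
      v <- fr$v
      if (fr$ptr <= length(adj[[v]]$nbr)) {
        w <- adj[[v]]$nbr[fr$ptr]
        bk <- adj[[v]]$bond[fr$ptr]
        stack[[length(stack)]]$ptr <- fr$ptr + 1L
        if (bk == fr$pb) next
        if (disc[w] == 0L) {
          timer <- timer + 1L; disc[w] <- low[w] <- timer
          stack[[length(stack) + 1L]] <- list(v = w, pb = bk, ptr = 1L)
        } else {
          low[v] <- min(low[v], disc[w])
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack) > 0L) {
          u <- stack[[length(stack)]]$v
          low[u] <- min(low[u], low[v])
          if (low[v] > disc[u]) is_bridge[fr$pb] <- TRUE
        }
      }
    }
  }
  !is_bridge
}

ring_atom_mask <- function(g, ringb = ring_bond_mask(g)) {
  mask <- logical(n_atoms(g))
  mask[c(g$bond_a[ringb], g$bond_b[ringb])] <- TRUE
  mask
}

# extract the induced subgraph on `keep` (logical or integer index)
subgraph <- function(g, keep) {
  idx <- if (is.logical(keep)) which(keep) else as.integer(keep)
  remap <- integer(n_atoms(g)); remap[idx] <- seq_along(idx)
  bsel <- g$bond_a %in% idx & g$bond_b %in% idx
  new_molgraph(g$element[idx], g$aromatic[idx], g$charge[idx], g$nH[idx],
               g$isotope[idx],
               remap[g$bond_a[bsel]], remap[g$bond_b[bsel]],
               g$bond_order[bsel], g$bond_arom[bsel])
}

# keep the largest covalent component (ties: the one containing the
# lowest-index atom); emits a message when components are dropped
largest_component <- function(g, quiet = FALSE) {
  comp <- graph_components(g)
  if (max(comp) == 1L) return(g)
  sizes <- tabulate(comp)
  best <- which(sizes == max(sizes))[1L]
  if (!quiet) {
    message(sprintf("chemsa: multi-component input; keeping largest of %d components",
                    max(comp)))
  }
  subgraph(g, comp == best)
}
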