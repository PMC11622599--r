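# Virtual synthesis: joining compatible single-attachment fragments into new
# molecules and generating trial batches from a seed, with optional
# frequency-based fragment weighting.

#' Fragment frequency table
#'
#' Maps fingerprint-bit indices to occurrence counts in a reference corpus.
#' Fragment sampling weights are the mean over a fragment's set bits of
#' `log(count + pseudocount)`. The default (`counts = NULL`) is the uniform
#' table: every bit counts 1, so all fragments weigh alike and sampling is
#' uniform.
#'
#' @param counts named numeric vector (names = bit indices as used by
#'   [morgan_bits()], i.e. 0-based) or NULL for uniform.
#' @param pseudocount non-negative constant added inside the log.
#' @return a `freq_table` object.
#' @export
frequency_table <- function(counts = NULL, pseudocount = 1) {
  stopifnot(pseudocount >= 0)
  vec <- rep(0, FP_NBITS)
  uniform <- is.null(counts)
  if (uniform) {
    vec[] <- 1
  } else if (length(counts) > 0) {
    idx <- as.integer(names(counts))
    if (any(is.na(idx)) || any(idx < 0L) || any(idx >= FP_NBITS)) {
      stop("bit indices must be in [0, ", FP_NBITS, ")")
    }
    if (any(counts < 0)) stop("counts must be non-negative")
    vec[idx + 1L] <- as.numeric(counts)
  }
  structure(list(counts = vec, pseudocount = pseudocount, uniform = uniform),
            class = "freq_table")
}

#' Read a frequency table from a two-column TSV (`bit_index<TAB>count`)
#'
#' Missing bits get count 0.
#' @param path file path.
#' @param pseudocount passed to [frequency_table()].
#' @export
read_freq_table <- function(path, pseudocount = 1) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("bit", "count"))
  counts <- tab$count
  names(counts) <- tab$bit
  frequency_table(counts, pseudocount)
}

#' Sampling weight of a fragment under a frequency table
#'
#' Mean over the fragment's set fingerprint bits of
#' `log(count + pseudocount)` (natural log). A fragment with an empty
#' fingerprint falls back to the pseudocount floor `log(pseudocount)`
#' (or 0 when that is not finite), with a message.
#'
#' @param f a `fragment`.
#' @param t a `freq_table`.
#' @return non-negative weight.
#' @export
fragment_weight <- function(f, t) {
  stopifnot(is_fragment(f), inherits(t, "freq_table"))
  bits <- frag_fp(f$core_smiles)
  if (length(bits) == 0L) {
    message("chemsa: fragment with empty fingerprint; using pseudocount floor")
    w <- log(t$pseudocount)
    return(if (is.finite(w)) max(w, 0) else 0)
  }
  mean(log(t$counts[bits + 1L] + t$pseudocount))
}

join_failure <- function(reason) {
  structure(list(ok = FALSE, reason = reason), class = "join_failure")
}

#' @export
print.join_failure <- function(x, ...) {
  cat(sprintf("<join failure: %s>\n", x$reason))
  invisible(x)
}

#' Did a fragment join fail?
#' @param x result of [join_fragments()].
#' @export
is_join_failure <- function(x) inherits(x, "join_failure")

#' Join two fragments into a molecule
#'
#' If the two link types are BRICS-compatible, the attachment dummies are
#' removed and a bond is formed between the two attachment atoms (a double
#' bond for the alkene 7-7 pairing, single otherwise). Incompatible pairs and
#' valence clashes return a failure value, not an error.
#'
#' @param a,b `fragment` objects.
#' @return a `molecule`, or a `join_failure` with a reason code
#'   (`"incompatible"` or `"valence"`).
#' @export
join_fragments <- function(a, b) {
  stopifnot(is_fragment(a), is_fragment(b))
  if (!brics_compatible(a$link_type, b$link_type)) {
    return(join_failure("incompatible"))
  }
  ensure_state()
  key <- paste(a$core_smiles, b$core_smiles)
  hit <- get0(key, envir = .chemsa$join_cache)
  if (!is.null(hit)) return(hit)
  res <- join_fragments_uncached(a, b)
  assign(key, res, envir = .chemsa$join_cache)
  # joining is symmetric
  assign(paste(b$core_smiles, a$core_smiles), res, envir = .chemsa$join_cache)
  res
}

join_fragments_uncached <- function(a, b) {
  ga <- frag_graph(a$core_smiles)
  gb <- frag_graph(b$core_smiles)
  da <- dummy_index(ga); db <- dummy_index(gb)
  ord <- brics_join_order(a$link_type, b$link_type)

  keep_a <- setdiff(seq_len(n_atoms(ga)), da)
  keep_b <- setdiff(seq_len(n_atoms(gb)), db)
  ka <- which(ga$bond_a == da | ga$bond_b == da)
  attach_a <- if (ga$bond_a[ka] == da) ga$bond_b[ka] else ga$bond_a[ka]
  kb <- which(gb$bond_a == db | gb$bond_b == db)
  attach_b <- if (gb$bond_a[kb] == db) gb$bond_b[kb] else gb$bond_a[kb]

  sub_a <- subgraph(ga, keep_a)
  sub_b <- subgraph(gb, keep_b)
  off <- n_atoms(sub_a)
  map_a <- match(attach_a, keep_a)
  map_b <- match(attach_b, keep_b) + off

  g <- new_molgraph(
    c(sub_a$element, sub_b$element),
    c(sub_a$aromatic, sub_b$aromatic),
    c(sub_a$charge, sub_b$charge),
    c(sub_a$nH, sub_b$nH),
    c(sub_a$isotope, sub_b$isotope),
    c(sub_a$bond_a, sub_b$bond_a + off, map_a),
    c(sub_a$bond_b, sub_b$bond_b + off, map_b),
    c(sub_a$bond_order, sub_b$bond_order, ord),
    c(sub_a$bond_arom, sub_b$bond_arom, FALSE)
  )
  # valence sanity after bond formation
  sval <- atom_bond_valence(g)
  for (i in c(map_a, map_b)) {
    allowed <- allowed_valences(g$element[i], g$charge[i])
    if (!is.null(allowed) && sval[i] + g$nH[i] > max(allowed)) {
      return(join_failure("valence"))
    }
  }
  mol <- tryCatch(molecule_from_graph(g), error = function(e) NULL)
  if (is.null(mol)) return(join_failure("valence"))
  mol
}

#' Fragment pool of a partner molecule
#'
#' Convenience wrapper equal to [fragment_molecule()]: the fragments a bank
#' partner contributes to trial generation.
#'
#' @param partner a `molecule` or SMILES string.
#' @export
partner_pool_from_molecule <- function(partner) {
  fragment_molecule(partner)
}

#' Generate trial molecules from a seed
#'
#' Draws `max_trials` (seed fragment, partner fragment) pairs, each fragment
#' sampled with probability proportional to its [fragment_weight()], joins
#' the compatible pairs, and collects the unique successful products (by
#' canonical SMILES), so at most `max_trials` chemicals are synthesized per
#' call and usually fewer (incompatible pairs, valence clashes and
#' duplicates produce nothing). Deterministic given the RNG state.
#'
#' @param seed a `molecule` (or SMILES).
#' @param partner_fragments list of `fragment` objects.
#' @param table a `freq_table` (default uniform).
#' @param max_trials number of synthesis attempts, and hence the maximum
#'   number of products (default 60).
#' @return list of `molecule` objects (possibly empty).
#' @export
generate_trials <- function(seed, partner_fragments,
                            table = frequency_table(), max_trials = 60L) {
  stopifnot(max_trials >= 1L)
  seed <- canonicalize(seed)
  seed_frags <- fragment_molecule(seed)
  if (length(seed_frags) == 0L || length(partner_fragments) == 0L) {
    return(list())
  }
  ws <- vapply(seed_frags, fragment_weight, 0, t = table)
  wp <- vapply(partner_fragments, fragment_weight, 0, t = table)
  ws <- pmax(ws, 0); wp <- pmax(wp, 0)
  if (all(ws == 0)) ws[] <- 1
  if (all(wp == 0)) wp[] <- 1

  cap <- as.integer(max_trials)
  i_seed <- sample.int(length(seed_frags), cap, replace = TRUE, prob = ws)
  i_part <- sample.int(length(partner_fragments), cap, replace = TRUE, prob = wp)

  links_s <- vapply(seed_frags, `[[`, 0L, "link_type")
  links_p <- vapply(partner_fragments, `[[`, 0L, "link_type")
  ensure_state()
  ok <- .chemsa$compat[cbind(links_s[i_seed], links_p[i_part])]

  out <- list()
  seen <- new.env(parent = emptyenv())
  for (t in which(ok)) {
    res <- join_fragments(seed_frags[[i_seed[t]]], partner_fragments[[i_part[t]]])
    if (is_join_failure(res)) next
    if (!is.null(get0(res$smiles, envir = seen))) next
    assign(res$smiles, TRUE, envir = seen)
    out[[length(out) + 1L]] <- res
    if (length(out) >= max_trials) break
  }
  out
}
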