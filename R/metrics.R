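# Diversity and novelty analytics: pairwise Tanimoto distance distributions,
# the #Circles sphere-packing diversity measure, and nearest-neighbor
# novelty against a reference set.

#' Pairwise Tanimoto distance statistics
#'
#' @param mols list of `molecule` objects (or SMILES character vector),
#'   at least 2.
#' @param breaks histogram breaks passed to [hist()].
#' @return list with `mean`, `sd`, `histogram` (a `histogram` object) and
#'   `distances` (the vector of unordered-pair distances).
#' @export
pairwise_distance_stats <- function(mols, breaks = seq(0, 1, by = 0.05)) {
  mols <- as_molecule_list(mols)
  if (length(mols) < 2L) stop("need at least 2 molecules")
  d <- pairwise_distance_matrix(mols)
  v <- d[upper.tri(d)]
  list(mean = mean(v), sd = if (length(v) < 2L) 0 else stats::sd(v),
       histogram = graphics::hist(v, breaks = breaks, plot = FALSE),
       distances = v)
}

#' #Circles diversity: maximum exclusive-sphere packing
#'
#' The size of the largest subset of molecules whose pairwise Tanimoto
#' distances all exceed `threshold` (sphere packing in chemical space).
#' `mode = "exact"` solves the maximum-independent-set problem on the
#' conflict graph by branch and bound (capped at 25 molecules);
#' `mode = "greedy"` uses deterministic farthest-point packing and is a
#' lower bound.
#'
#' @param mols list of `molecule` objects or SMILES character vector.
#' @param threshold exclusivity radius in `(0, 1]`.
#' @param mode `"greedy"` or `"exact"`.
#' @return integer packing number.
#' @export
n_circles <- function(mols, threshold = 0.7, mode = c("greedy", "exact")) {
  mode <- match.arg(mode)
  mols <- as_molecule_list(mols)
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  n <- length(mols)
  if (n == 0L) return(0L)
  if (n == 1L) return(1L)
  d <- pairwise_distance_matrix(mols)
  ok <- d > threshold            # admissible pairs
  if (mode == "exact") {
    if (n > 25L) {
      stop("exact mode is capped at 25 molecules; use mode = 'greedy'")
    }
    return(max_packing_exact(ok))
  }
  greedy_packing(d, threshold)
}

# deterministic farthest-point packing: start from molecule 1, repeatedly add
# the molecule with the largest minimum distance to the chosen set while that
# distance exceeds the threshold (ties -> lowest index)
greedy_packing <- function(d, threshold) {
  n <- nrow(d)
  chosen <- 1L
  mind <- d[, 1L]
  repeat {
    mind[chosen] <- -Inf
    best <- which.max(mind)
    if (mind[best] <= threshold) break
    chosen <- c(chosen, best)
    mind <- pmin(mind, d[, best])
  }
  length(chosen)
}

# exact maximum packing = maximum clique of the admissibility graph, by
# branch and bound with a simple remaining-vertices bound
max_packing_exact <- function(ok) {
  n <- nrow(ok)
  diag(ok) <- FALSE
  best <- 0L
  expand <- function(current, cand) {
    if (length(cand) == 0L) {
      best <<- max(best, current)
      return(invisible(NULL))
    }
    for (t in seq_along(cand)) {
      if (current + (length(cand) - t + 1L) <= best) break
      v <- cand[t]
      expand(current + 1L, cand[cand %in% which(ok[v, ]) & cand > v])
    }
    invisible(NULL)
  }
  expand(0L, seq_len(n))
  best
}

#' Nearest-neighbor novelty distances
#'
#' For each molecule, the minimum Tanimoto distance to any molecule of the
#' reference set; 0 for molecules contained in the reference.
#'
#' @param mols query molecules.
#' @param reference non-empty reference molecule list.
#' @return numeric vector, one value per query molecule.
#' @export
novelty_nn_distance <- function(mols, reference) {
  mols <- as_molecule_list(mols)
  reference <- as_molecule_list(reference)
  if (length(reference) == 0L) stop("reference must be non-empty")
  rm_fpm <- bits_to_matrix(lapply(reference, `[[`, "fp"))
  rpop <- colSums(rm_fpm)
  rsmi <- vapply(reference, `[[`, "", "smiles")
  unname(vapply(mols, function(m) {
    v <- numeric(nrow(rm_fpm)); v[m$fp + 1L] <- 1
    inter <- as.numeric(crossprod(rm_fpm, v))
    un <- rpop + length(m$fp) - inter
    d <- ifelse(un == 0, ifelse(rsmi == m$smiles, 0, 1), 1 - inter / un)
    min(d)
  }, 0))
}
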