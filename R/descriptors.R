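# Physicochemical descriptors used by the built-in objectives. These are
# deliberately lightweight graph-based implementations: molecular weight and
# H-bond counts are exact; polar surface area uses the published N/O
# contribution table; logP is a crude additive atom-contribution surrogate
# (adequate as an optimization objective, not a prediction tool).

ATOMIC_WEIGHTS <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                    F = 18.998, P = 30.974, S = 32.06, Cl = 35.45,
                    Br = 79.904, I = 126.904, Se = 78.971, Si = 28.085)

#' Molecular weight (average atomic masses, implicit H included)
#' @param mol a `molecule` or SMILES string.
#' @export
mol_weight <- function(mol) {
  g <- canonicalize(mol)$graph
  w <- ATOMIC_WEIGHTS[g$element]
  w[is.na(w)] <- 0
  sum(w) + sum(g$nH) * ATOMIC_WEIGHTS[["H"]]
}

# Lipinski-style hydrogen bond counts
count_hba <- function(g) sum(g$element %in% c("N", "O"))
count_hbd <- function(g) sum(g$nH[g$element %in% c("N", "O")])

# number of aromatic rings = cycle rank of the aromatic subgraph
count_aromatic_rings <- function(g) {
  sel <- g$bond_arom
  if (!any(sel)) return(0L)
  atoms <- sort(unique(c(g$bond_a[sel], g$bond_b[sel])))
  sub <- subgraph(g, atoms)
  sub2 <- sub
  keep_bonds <- sub$bond_arom
  sub2$bond_a <- sub$bond_a[keep_bonds]; sub2$bond_b <- sub$bond_b[keep_bonds]
  sub2$bond_order <- sub$bond_order[keep_bonds]; sub2$bond_arom <- sub$bond_arom[keep_bonds]
  ncomp <- max(graph_components(sub2))
  length(sub2$bond_a) - n_atoms(sub2) + ncomp
}

# total ring count (cycle rank of the whole graph)
count_rings <- function(g) {
  n_bonds(g) - n_atoms(g) + max(graph_components(g))
}

# rotatable bonds: acyclic single non-aromatic bonds between two heavy atoms
# of degree >= 2, where neither end is a triple-bonded (sp) atom
count_rotatable <- function(g) {
  if (n_bonds(g) == 0L) return(0L)
  ringb <- ring_bond_mask(g)
  deg <- atom_degree(g)
  sp <- logical(n_atoms(g))
  sp[c(g$bond_a[g$bond_order == 3L], g$bond_b[g$bond_order == 3L])] <- TRUE
  sel <- g$bond_order == 1L & !g$bond_arom & !ringb &
    deg[g$bond_a] >= 2L & deg[g$bond_b] >= 2L &
    !sp[g$bond_a] & !sp[g$bond_b]
  sum(sel)
}

# Topological polar surface area from N/O contribution values (published
# additive table); uncommon environments fall back to the closest listed type.
tpsa <- function(g) {
  adj <- adjacency_list(g)
  total <- 0
  for (i in seq_len(n_atoms(g))) {
    el <- g$element[i]
    if (!(el %in% c("N", "O"))) next
    nb <- adj[[i]]
    orders <- g$bond_order[nb$bond]
    aromb <- g$bond_arom[nb$bond]
    n_ar <- sum(aromb)
    n_s <- sum(orders == 1L & !aromb)
    n_d <- sum(orders == 2L & !aromb)
    n_t <- sum(orders == 3L & !aromb)
    h <- g$nH[i]
    chg <- g$charge[i]
    contrib <-
      if (el == "N" && !g$aromatic[i]) {
        if (chg > 0L) {
          if (h == 0L && n_d >= 1L) 3.01
          else if (h == 0L) 0.00
          else if (h == 1L) 4.44
          else if (h == 2L) 16.61
          else 27.64
        } else if (n_t >= 1L) 23.79
        else if (n_d >= 2L) 11.68
        else if (n_d == 1L) { if (h == 0L) 12.36 else 23.85 }
        else if (h == 0L) 3.24
        else if (h == 1L) 12.03
        else 26.02
      } else if (el == "N") {                # aromatic n
        if (h >= 1L) 15.79
        else if (n_ar >= 2L && (n_s >= 1L || n_ar >= 3L)) {
          if (n_s >= 1L) 4.93 else 4.41
        } else 12.89
      } else if (el == "O" && !g$aromatic[i]) {
        if (chg < 0L) 23.06
        else if (n_d >= 1L) 17.07
        else if (h >= 1L) 20.23
        else 9.23
      } else 13.14                           # aromatic o
    total <- total + contrib
  }
  total
}

# crude additive logP surrogate: per-atom contributions plus a hydrogen term
# on carbons; charged atoms are penalized
crippen_logp <- function(g) {
  contrib <- 0
  for (i in seq_len(n_atoms(g))) {
    el <- g$element[i]
    arom <- g$aromatic[i]
    c_i <- switch(el,
      "C" = if (arom) 0.29 else 0.14,
      "N" = if (arom) -0.50 else -0.80,
      "O" = if (arom) -0.10 else -0.45,
      "S" = 0.40, "P" = -0.50,
      "F" = 0.20, "Cl" = 0.70, "Br" = 0.90, "I" = 1.10,
      0)
    if (el == "C") c_i <- c_i + 0.10 * g$nH[i]
    if (g$charge[i] != 0L) c_i <- c_i - 1.50
    contrib <- contrib + c_i
  }
  contrib
}

#' Basic descriptor set of a molecule
#'
#' @param mol a `molecule` or SMILES string.
#' @return named list: `mw`, `logp`, `hba`, `hbd`, `psa`, `rotb`, `arom`,
#'   `rings`, `n_heavy`.
#' @export
mol_descriptors <- function(mol) {
  m <- canonicalize(mol)
  g <- m$graph
  list(mw = mol_weight(m), logp = crippen_logp(g),
       hba = count_hba(g), hbd = count_hbd(g), psa = tpsa(g),
       rotb = count_rotatable(g), arom = count_aromatic_rings(g),
       rings = count_rings(g), n_heavy = m$n_heavy)
}

# --- QED (quantitative estimate of drug-likeness) ---------------------------
# Published asymmetric double sigmoid (ADS) desirability parameters per
# descriptor, and the published default weights. The ALERTS term is fixed at
# 0 (no structural-alert library here); ALOGP uses the surrogate logP.

QED_ADS <- list(
  MW     = c(A = 2.817065973, B = 392.5754953, C = 290.7489764, D = 2.419764353,
             E = 49.22325677, F = 65.37051707, DMAX = 104.9805561),
  ALOGP  = c(A = 3.172690585, B = 137.8624751, C = 2.534937431, D = 4.581497897,
             E = 0.822739154, F = 0.576295591, DMAX = 131.3186604),
  HBA    = c(A = 2.948620388, B = 160.4605972, C = 3.615294657, D = 4.435986202,
             E = 0.290141953, F = 1.300669958, DMAX = 148.7763046),
  HBD    = c(A = 1.618662227, B = 1010.051101, C = 0.985094388, D = 0.000000001,
             E = 0.713820843, F = 0.920922555, DMAX = 258.1632616),
  PSA    = c(A = 1.876861559, B = 125.2232657, C = 62.90773554, D = 87.83366614,
             E = 12.01999824, F = 28.51324732, DMAX = 104.5686167),
  ROTB   = c(A = 0.010000000, B = 272.4121427, C = 2.558379970, D = 1.565547684,
             E = 1.271567166, F = 2.758063707, DMAX = 105.4420403),
  AROM   = c(A = 3.217788970, B = 957.7374108, C = 2.274627939, D = 0.000000001,
             E = 1.317690384, F = 0.375760881, DMAX = 312.3372610),
  ALERTS = c(A = 0.010000000, B = 1199.094025, C = -0.09002883, D = 0.000000001,
             E = 0.185904477, F = 0.875193782, DMAX = 417.7253140)
)
QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61, PSA = 0.06,
                 ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

qed_ads <- function(x, p) {
  e1 <- 1 + exp(-(x - p[["C"]] + p[["D"]] / 2) / p[["E"]])
  e2 <- 1 + exp(-(x - p[["C"]] - p[["D"]] / 2) / p[["F"]])
  dx <- p[["A"]] + p[["B"]] / e1 * (1 - 1 / e2)
  dx / p[["DMAX"]]
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' Weighted geometric mean of desirability functions over eight descriptors,
#' using the published ADS parameters and default weights. Bounded in (0, 1);
#' 1 is most drug-like.
#'
#' @param mol a `molecule` or SMILES string.
#' @export
qed_score <- function(mol) {
  d <- mol_descriptors(mol)
  x <- c(MW = d$mw, ALOGP = d$logp, HBA = d$hba, HBD = d$hbd, PSA = d$psa,
         ROTB = d$rotb, AROM = d$arom, ALERTS = 0)
  ds <- vapply(names(x), function(k) qed_ads(x[[k]], QED_ADS[[k]]), 0)
  ds <- pmin(pmax(ds, 1e-6), 1)
  exp(sum(QED_WEIGHTS * log(ds)) / sum(QED_WEIGHTS))
}

# --- synthetic accessibility -------------------------------------------------
# Ertl-style SA score in [1, 10]: a fragment-frequency term (common circular
# substructures are easy) minus complexity penalties (size, rings), rescaled.
# Fragment frequencies are calibrated on the bundled drug-like corpus at
# first use instead of PubChem; the resulting ranking behaves like the
# original (drug-like fixtures land around 2-5).

sa_fragment_scores <- function() {
  ensure_state()
  if (!is.null(.chemsa$sa_scores)) return(.chemsa$sa_scores)
  pool <- read_smiles_file(system.file("extdata", "pool_druglike.smi",
                                       package = "chemsa", mustWork = TRUE))
  counts <- numeric(FP_NBITS)
  for (m in pool) {
    b <- m$fp + 1L
    counts[b] <- counts[b] + 1
  }
  ref <- stats::quantile(counts[counts > 0], 0.75)
  sc <- ifelse(counts > 0, log10(counts) - log10(ref), -4)
  sc <- pmax(pmin(sc, 4), -4)
  .chemsa$sa_scores <- sc
  sc
}

#' Synthetic accessibility score
#'
#' Higher means harder to synthesize; clamped to `[1, 10]`. Combines a
#' corpus-calibrated circular-fragment familiarity term with size and ring
#' complexity penalties, following the published score's structure.
#'
#' @param mol a `molecule` or SMILES string.
#' @export
sa_score <- function(mol) {
  m <- canonicalize(mol)
  g <- m$graph
  sc <- sa_fragment_scores()
  bits <- m$fp
  frag_score <- if (length(bits) > 0) mean(sc[bits + 1L]) else -4
  n <- m$n_heavy
  size_penalty <- n^1.005 - n
  ring_penalty <- log(count_rings(g) + 1)
  raw <- frag_score - size_penalty - ring_penalty
  s <- 11 - (raw - (-4)) / (2.5 - (-4)) * 9
  if (s > 8) s <- 8 + log(s - 8 + 1)
  min(max(s, 1), 10)
}
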