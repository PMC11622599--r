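# Shape-overlap scoring: molecules as sets of atomic spheres (0.7 x van der
# Waals radii), compared through exact two-sphere intersection volumes. The
# score is the total cross overlap volume normalized by the larger self
# overlap, so it is 1 for identical coordinate sets and 0 for disjoint ones.
# Coordinates must already be in a common frame: alignment is the caller's
# responsibility.

# Bondi van der Waals radii (Angstrom); unknown elements fall back to carbon
VDW_RADII <- c(H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
               P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98,
               Se = 1.90, Si = 2.10)
VDW_SCALE <- 0.7

#' Atomic sphere set for shape scoring
#'
#' @param centers numeric matrix (n x 3) of coordinates in Angstrom.
#' @param elements character vector of element symbols (length n).
#' @param scale radius scale factor applied to the van der Waals radii.
#' @return a `sphere_set` with `centers`, `radii`, `elements`.
#' @export
sphere_set <- function(centers, elements, scale = VDW_SCALE) {
  centers <- as.matrix(centers)
  if (ncol(centers) != 3L || nrow(centers) < 1L) {
    stop("centers must be an n x 3 matrix with n >= 1")
  }
  if (length(elements) != nrow(centers)) {
    stop("one element symbol per center required")
  }
  r <- VDW_RADII[elements]
  r[is.na(r)] <- VDW_RADII[["C"]]
  structure(list(centers = unname(centers), radii = unname(r * scale),
                 elements = as.character(elements)),
            class = "sphere_set")
}

#' @export
print.sphere_set <- function(x, ...) {
  cat(sprintf("<sphere_set> %d atoms, radii %.2f-%.2f A\n",
              nrow(x$centers), min(x$radii), max(x$radii)))
  invisible(x)
}

#' Intersection volume of two spheres
#'
#' Exact closed form: 0 when disjoint, the smaller sphere's volume at full
#' containment, the spherical-lens formula otherwise. Symmetric in its
#' arguments.
#'
#' @param c1,c2 length-3 centers.
#' @param r1,r2 positive radii.
#' @return volume in cubic Angstrom.
#' @export
sphere_overlap_volume <- function(c1, r1, c2, r2) {
  stopifnot(r1 > 0, r2 > 0)
  d <- sqrt(sum((c1 - c2)^2))
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) {
    r <- min(r1, r2)
    return(4 / 3 * pi * r^3)
  }
  # spherical lens
  pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
}

# sum over all ordered pairs (including i = j for self sums) of pairwise
# intersection volumes between two sphere sets
overlap_volume_sum <- function(A, B) {
  total <- 0
  for (i in seq_len(nrow(A$centers))) {
    for (j in seq_len(nrow(B$centers))) {
      total <- total + sphere_overlap_volume(A$centers[i, ], A$radii[i],
                                             B$centers[j, ], B$radii[j])
    }
  }
  total
}

#' Shape-overlap (G-Align) score between two sphere sets
#'
#' The summed cross intersection volume between query and reference spheres,
#' divided by the larger of the two self-overlap sums (both self sums include
#' the i = j full-sphere terms). Ranges over `[0, 1]`; 1 means coordinate
#' identity, 0 means no overlap.
#'
#' @param Q,R `sphere_set` objects in a common coordinate frame.
#' @return score in `[0, 1]`.
#' @export
galign_score <- function(Q, R) {
  stopifnot(inherits(Q, "sphere_set"), inherits(R, "sphere_set"))
  num <- overlap_volume_sum(Q, R)
  den <- max(overlap_volume_sum(Q, Q), overlap_volume_sum(R, R))
  min(max(num / den, 0), 1)
}

#' Read molecules with 3D coordinates from an SDF (V2000) file
#'
#' A minimal reader for the fixed-width V2000 connection-table format:
#' returns one `sphere_set` per record (plus the raw coordinates and the
#' molecule title). Bonds are not needed for shape scoring and are skipped.
#'
#' @param path SDF file path.
#' @param scale radius scale factor (see [sphere_set()]).
#' @return named list of `sphere_set` objects.
#' @export
read_sdf <- function(path, scale = VDW_SCALE) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L
  while (i + 3L <= length(lines)) {
    title <- trimws(lines[i])
    counts <- lines[i + 3L]
    natoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
    if (is.na(natoms) || natoms < 1L) stop("malformed SDF counts line")
    atoms <- lines[(i + 4L):(i + 3L + natoms)]
    xyz <- t(vapply(atoms, function(l) {
      c(as.numeric(substr(l, 1L, 10L)), as.numeric(substr(l, 11L, 20L)),
        as.numeric(substr(l, 21L, 30L)))
    }, numeric(3)))
    el <- trimws(substr(atoms, 32L, 34L))
    nm <- if (nzchar(title)) title else sprintf("mol%d", length(out) + 1L)
    out[[nm]] <- sphere_set(xyz, el, scale = scale)
    # advance to the record terminator
    j <- i + 4L + natoms
    while (j <= length(lines) && trimws(lines[j]) != "$$$$") j <- j + 1L
    i <- j + 1L
  }
  if (length(out) == 0L) stop("no SDF records found in ", path)
  out
}

#' Rigid superposition of matched atom sets (Kabsch)
#'
#' Helper for tests and for scoring conformers whose atom order matches:
#' returns a copy of `Q` least-squares superposed onto `R` using the given
#' index correspondence.
#'
#' @param Q,R `sphere_set` objects.
#' @param idx_q,idx_r matched atom indices (equal length, >= 3).
#' @return `Q` with transformed centers.
#' @export
superpose <- function(Q, R, idx_q = seq_len(nrow(Q$centers)),
                      idx_r = seq_len(nrow(R$centers))) {
  stopifnot(length(idx_q) == length(idx_r), length(idx_q) >= 3L)
  X <- Q$centers[idx_q, , drop = FALSE]
  Y <- R$centers[idx_r, , drop = FALSE]
  cx <- colMeans(X); cy <- colMeans(Y)
  s <- svd(crossprod(sweep(X, 2, cx), sweep(Y, 2, cy)))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Q$centers <- sweep(sweep(Q$centers, 2, cx) %*% t(rot), 2, cy, `+`)
  Q
}
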