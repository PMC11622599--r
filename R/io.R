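# File I/O and library curation: SMILES files, bank CSV output, JSON run
# configuration, leader clustering for non-redundant pools, and bundled
# fixture generation.

chemsa_extdata <- function(file) {
  p <- system.file("extdata", file, package = "chemsa")
  if (nzchar(p)) return(p)
  # fallback for development trees
  local <- file.path("inst", "extdata", file)
  if (file.exists(local)) return(local)
  stop("bundled data file not found: ", file)
}

#' Read molecules from a SMILES file
#'
#' One molecule per line: `<smiles>[\t<name>]`. Blank lines and lines
#' starting with `#` are ignored. Malformed lines are counted, reported via
#' a message, and skipped; more than 50% malformed lines aborts with a
#' diagnostic.
#'
#' @param path file path.
#' @return list of `molecule` objects; names attribute carries any name
#'   fields.
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path)) stop("cannot read SMILES file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("empty SMILES file: ", path)
  mols <- list(); nms <- character(); bad <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\t")[[1]]
    m <- tryCatch(suppressMessages(canonicalize(parts[1])),
                  error = function(e) NULL)
    if (is.null(m)) { bad <- bad + 1L; next }
    mols[[length(mols) + 1L]] <- m
    nms <- c(nms, if (length(parts) > 1L) parts[2] else "")
  }
  if (bad > length(lines) / 2) {
    stop(sprintf("%d of %d lines malformed in %s", bad, length(lines), path))
  }
  if (bad > 0L) message(sprintf("chemsa: skipped %d malformed line(s) in %s",
                                bad, path))
  names(mols) <- nms
  mols
}

#' Write a bank to CSV
#'
#' Columns: `rank` (by objective value), `smiles`, `objective`, `sa_score`.
#'
#' @param bank a `chem_bank`.
#' @param path output path.
#' @export
write_bank_csv <- function(bank, path) {
  stopifnot(inherits(bank, "chem_bank"))
  ord <- order(bank$value, bank$smiles, method = "radix")
  df <- data.frame(
    rank = seq_along(ord),
    smiles = bank$smiles[ord],
    objective = bank$value[ord],
    sa_score = vapply(bank$mols[ord], sa_score, 0)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Read a bank CSV back as molecules
#' @param path CSV written by [write_bank_csv()].
#' @export
read_bank_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(df$smiles, canonicalize)
}

#' Leader clustering for a non-redundant pool
#'
#' Scans molecules in input order; a molecule joins an existing cluster when
#' its Tanimoto similarity to that cluster's leader is at least `threshold`,
#' otherwise it founds a new cluster. Returns the leaders. Deterministic for
#' a fixed input order.
#'
#' @param mols list of `molecule` objects or SMILES character vector.
#' @param similarity_threshold clustering similarity threshold in (0, 1).
#' @param sort_first canonical-SMILES-sort the input first (frozen order).
#' @return list of leader `molecule`s.
#' @export
curate_pool <- function(mols, similarity_threshold = 0.7, sort_first = TRUE) {
  stopifnot(similarity_threshold > 0, similarity_threshold < 1)
  mols <- as_molecule_list(mols)
  if (length(mols) == 0L) return(mols)
  if (sort_first) {
    mols <- mols[order(vapply(mols, `[[`, "", "smiles"), method = "radix")]
  }
  leaders <- list()
  fpm <- NULL
  pop <- numeric()
  for (m in mols) {
    if (length(leaders) > 0L) {
      v <- numeric(FP_NBITS); v[m$fp + 1L] <- 1
      inter <- as.numeric(crossprod(fpm, v))
      un <- pop + length(m$fp) - inter
      sim <- ifelse(un == 0, 1, inter / un)
      if (any(sim >= similarity_threshold)) next
    }
    leaders[[length(leaders) + 1L]] <- m
    fpm <- cbind(fpm, {v <- numeric(FP_NBITS); v[m$fp + 1L] <- 1; v})
    pop <- c(pop, length(m$fp))
  }
  leaders
}

#' Curate a fragment database from molecules
#'
#' Fragments every molecule by single BRICS cleavages, deduplicates by core
#' SMILES, and removes near-redundant fragments by leader clustering on the
#' core fingerprints at the given similarity threshold.
#'
#' @param mols source molecules.
#' @param similarity_threshold redundancy threshold (default 0.7).
#' @return list of `fragment` objects.
#' @export
build_fragment_db <- function(mols, similarity_threshold = 0.7) {
  mols <- as_molecule_list(mols)
  frags <- list(); seen <- character()
  for (m in mols) {
    for (f in fragment_molecule(m)) {
      if (!(f$core_smiles %in% seen)) {
        seen <- c(seen, f$core_smiles)
        frags[[length(frags) + 1L]] <- f
      }
    }
  }
  if (length(frags) <= 1L) return(frags)
  ord <- order(vapply(frags, `[[`, "", "core_smiles"), method = "radix")
  frags <- frags[ord]
  keep <- list()
  fpm <- NULL; pop <- numeric()
  for (f in frags) {
    fp <- frag_fp(f$core_smiles)
    if (length(keep) > 0L) {
      v <- numeric(FP_NBITS); v[fp + 1L] <- 1
      inter <- as.numeric(crossprod(fpm, v))
      un <- pop + length(fp) - inter
      sim <- ifelse(un == 0, 1, inter / un)
      if (any(sim >= similarity_threshold)) next
    }
    keep[[length(keep) + 1L]] <- f
    fpm <- cbind(fpm, {v <- numeric(FP_NBITS); v[fp + 1L] <- 1; v})
    pop <- c(pop, length(fp))
  }
  keep
}

#' Write fragments to a SMILES file (dummy-atom link convention)
#' @param frags list of `fragment`s.
#' @param path output path.
#' @export
write_fragments <- function(frags, path) {
  writeLines(vapply(frags, `[[`, "", "core_smiles"), path)
  invisible(path)
}

#' Read a fragment file
#' @param path SMILES-lines fragment file.
#' @export
read_fragments <- function(path) {
  fragments_from_lines(readLines(path, warn = FALSE))
}

#' Read / write a JSON run configuration
#'
#' The schema mirrors [run_config()]; unknown keys are rejected.
#' @param path JSON file path.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  extra <- setdiff(names(x), c(known, "schema_version"))
  if (length(extra) > 0L) stop("unknown config keys: ", paste(extra, collapse = ", "))
  do.call(run_config, x[intersect(names(x), known)])
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(c(schema_version = 1L, unclass(config)), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Generate bundled fixture files
#'
#' Stands in for external compound libraries so every run and test works
#' offline: `pool` draws a deterministic subset of the bundled ~300
#' drug-like molecules; `fragments` builds a curated fragment database from
#' the full bundle; `conformers` copies bundled rigid 3D conformers (SDF).
#'
#' @param kind one of `"pool"`, `"fragments"`, `"conformers"`.
#' @param n number of records (pool size, fragment count, or conformer
#'   count).
#' @param rng_seed seed controlling the deterministic selection.
#' @param dir output directory.
#' @return path of the written file.
#' @export
make_fixtures <- function(kind = c("pool", "fragments", "conformers"),
                          n = 100L, rng_seed = 1L, dir = tempdir()) {
  kind <- match.arg(kind)
  stopifnot(n >= 1L)
  if (kind == "pool") {
    lines <- readLines(chemsa_extdata("pool_druglike.smi"), warn = FALSE)
    if (n > length(lines)) stop("n exceeds bundled pool size (", length(lines), ")")
    sel <- withr_seed(rng_seed, sample.int(length(lines), n))
    out <- file.path(dir, sprintf("pool_%d_%d.smi", n, rng_seed))
    writeLines(lines[sel], out)
    return(out)
  }
  if (kind == "fragments") {
    mols <- read_smiles_file(chemsa_extdata("pool_druglike.smi"))
    db <- build_fragment_db(mols)
    if (n > length(db)) stop("n exceeds available curated fragments (", length(db), ")")
    sel <- withr_seed(rng_seed, sample.int(length(db), n))
    out <- file.path(dir, sprintf("fragments_%d_%d.smi", n, rng_seed))
    write_fragments(db[sel], out)
    return(out)
  }
  src <- readLines(chemsa_extdata("conformers.sdf"), warn = FALSE)
  ends <- which(trimws(src) == "$$$$")
  if (n > length(ends)) stop("n exceeds bundled conformer count (", length(ends), ")")
  out <- file.path(dir, sprintf("conformers_%d.sdf", n))
  writeLines(src[seq_len(ends[n])], out)
  out
}

# evaluate `expr` under a temporary RNG seed without disturbing the caller's
# RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
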