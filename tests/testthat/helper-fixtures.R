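# Shared fixtures: the bundled drug-like pool, a curated fragment database,
# and hand-constructed molecules with chosen fingerprint bits (for exercising
# the metric layer with exact distances).

.fixture_env <- new.env()

fixture_pool <- function(n = NULL) {
  if (is.null(.fixture_env$pool)) {
    .fixture_env$pool <- read_smiles_file(
      system.file("extdata", "pool_druglike.smi", package = "chemsa"))
  }
  if (is.null(n)) .fixture_env$pool else .fixture_env$pool[seq_len(n)]
}

fixture_fragment_db <- function(n = NULL) {
  if (is.null(.fixture_env$db)) {
    .fixture_env$db <- build_fragment_db(fixture_pool())
  }
  db <- .fixture_env$db
  if (is.null(n)) db else db[seq_len(min(n, length(db)))]
}

# a molecule stub with prescribed fingerprint bits; valid wherever only the
# fingerprint and SMILES identity matter
fake_mol <- function(bits, smiles = paste0("FAKE:", paste(bits, collapse = "."))) {
  structure(list(smiles = smiles, graph = NULL,
                 fp = as.integer(sort(unique(bits))), n_heavy = 1L),
            class = "molecule")
}

# objective wrapping an arbitrary function of the molecule
fun_objective <- function(f, name = "testfun") {
  objective("external", fun = f)
}

conformer_fixture <- function() {
  read_sdf(system.file("extdata", "conformers.sdf", package = "chemsa"))
}
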