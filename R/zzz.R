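# package-level state: the compatibility table and memoization caches for
# the hot paths of the optimizer (fragmentations, joins, fragment graphs).
# All cached functions are pure, so cache state never affects results.
.chemsa <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  .chemsa$compat <- brics_compatibility_table()
  reset_caches()
}

reset_caches <- function() {
  .chemsa$frag_cache <- new.env(parent = emptyenv())   # smiles -> list of fragments
  .chemsa$join_cache <- new.env(parent = emptyenv())   # "coreA coreB" -> molecule/failure
  .chemsa$graph_cache <- new.env(parent = emptyenv())  # core smiles -> molgraph
  .chemsa$fp_cache <- new.env(parent = emptyenv())     # core smiles -> fp bits
  invisible(NULL)
}

# ensure availability when the package is used via devtools::load_all or
# sourced in tests before .onLoad ran
ensure_state <- function() {
  if (is.null(.chemsa$compat)) .chemsa$compat <- brics_compatibility_table()
  if (is.null(.chemsa$frag_cache)) reset_caches()
  invisible(NULL)
}
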