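# BRICS cleavage enumeration, fragment filtering, and the link-type
# compatibility relation. The reference values in fixture-brics-bonds.tsv and
# fixture-brics-frags.tsv were computed with an independent implementation of
# the published BRICS pattern table and frozen.

read_fixture_tsv <- function(name, classes) {
  read.table(test_path(name), sep = "\t", header = TRUE, colClasses = classes)
}

test_that("molecules without BRICS environments yield no cleavages", {
  expect_equal(nrow(enumerate_cleavages(canonicalize("CC"))), 0L)
  expect_equal(nrow(enumerate_cleavages(canonicalize("c1ccccc1"))), 0L)  # ring bonds only
  expect_length(fragment_molecule(canonicalize("CCO")), 0L)
})

test_that("cleavage enumeration matches the frozen reference on 60 fixture molecules", {
  oracle <- read_fixture_tsv("fixture-brics-bonds.tsv",
                             c("character", rep("integer", 4)))
  pool <- vapply(fixture_pool(60), `[[`, "", "smiles")
  # the fixture stores 0-based atom indices in the original file's SMILES
  # order; parse those strings directly so indices align
  raw <- readLines(system.file("extdata", "pool_druglike.smi", package = "chemsa"))[1:60]
  raw <- vapply(strsplit(raw, "\t"), `[[`, "", 1L)
  for (s in raw) {
    g <- chemsa:::parse_smiles(s)
    cl <- enumerate_cleavages(g)
    mine <- if (nrow(cl) == 0L) character() else
      sort(sprintf("%d-%d:%d,%d",
                   pmin(cl$atom_a, cl$atom_b) - 1L, pmax(cl$atom_a, cl$atom_b) - 1L,
                   ifelse(cl$atom_a < cl$atom_b, cl$link_a, cl$link_b),
                   ifelse(cl$atom_a < cl$atom_b, cl$link_b, cl$link_a)))
    o <- oracle[oracle$smiles == s, ]
    theirs <- if (nrow(o) == 0L) character() else
      sort(sprintf("%d-%d:%d,%d", pmin(o$i, o$j), pmax(o$i, o$j),
                   ifelse(o$i < o$j, o$la, o$lb), ifelse(o$i < o$j, o$lb, o$la)))
    expect_identical(mine, theirs, label = paste("cleavages of", s))
  }
})

test_that("fragment multisets match the frozen reference after the >3-atom filter", {
  oracle <- read_fixture_tsv("fixture-brics-frags.tsv",
                             c("character", "integer", "integer"))
  raw <- readLines(system.file("extdata", "pool_druglike.smi", package = "chemsa"))[1:60]
  raw <- vapply(strsplit(raw, "\t"), `[[`, "", 1L)
  for (s in raw) {
    frs <- fragment_molecule(s)
    mine <- sort(vapply(frs, function(f) sprintf("%d:%d", f$n_heavy, f$link_type), ""))
    o <- oracle[oracle$smiles == s, ]
    theirs <- sort(sprintf("%d:%d", o$n_heavy, o$link))
    expect_identical(as.character(mine), as.character(theirs),
                     label = paste("fragments of", s))
  }
})

test_that("the heavy-atom filter is strictly exclusive at 3", {
  # one cleavable bond splitting 8 heavy atoms into 5 + 3: only the 5-atom
  # side survives
  m <- canonicalize("CCCc1ccco1")
  cl <- enumerate_cleavages(m)
  expect_equal(nrow(cl), 1L)
  frs <- fragment_molecule(m)
  expect_length(frs, 1L)
  expect_equal(frs[[1]]$n_heavy, 5L)
  # lowering the bound admits the 3-atom side too
  expect_length(fragment_molecule(m, min_heavy_exclusive = 2L), 2L)
})

test_that("every emitted fragment canonicalizes with exactly one placeholder", {
  for (m in fixture_pool(40)) {
    for (f in fragment_molecule(m)) {
      g <- chemsa:::frag_graph(f$core_smiles)
      expect_equal(sum(g$element == "*"), 1L)
      expect_equal(g$isotope[g$element == "*"], f$link_type)
      expect_identical(chemsa:::canonical_smiles_of_graph(g), f$core_smiles)
      expect_gt(f$n_heavy, 3L)
    }
  }
})

test_that("the compatibility table is 16x16, symmetric, and non-trivial", {
  tab <- brics_compatibility_table()
  expect_equal(dim(tab), c(16L, 16L))
  expect_true(isSymmetric(tab))
  expect_true(any(tab) && !all(tab))
  for (a in 1:16) for (b in 1:16) {
    expect_identical(brics_compatible(a, b), brics_compatible(b, a))
    expect_identical(brics_compatible(a, b), tab[a, b])
  }
})

test_that("specific pairs match the published BRICS rules", {
  yes <- list(c(1, 3), c(1, 5), c(1, 10), c(3, 4), c(4, 11), c(5, 12),
              c(7, 7), c(8, 9), c(13, 14), c(16, 16))
  no <- list(c(1, 16), c(3, 3), c(2, 5), c(2, 16), c(4, 4), c(5, 5),
             c(7, 16), c(12, 16), c(6, 12), c(11, 12))
  for (p in yes) expect_true(brics_compatible(p[1], p[2]),
                             label = sprintf("L%d-L%d allowed", p[1], p[2]))
  for (p in no) expect_false(brics_compatible(p[1], p[2]),
                             label = sprintf("L%d-L%d forbidden", p[1], p[2]))
  expect_error(brics_compatible(0, 5), "1..16")
  expect_error(brics_compatible(5, 17), "1..16")
})
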