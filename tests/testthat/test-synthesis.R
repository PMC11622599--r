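# Virtual synthesis: joining, weighting, trial generation.

test_that("rejoining the two sides of any cleavage reconstructs the parent", {
  # full-identity check over a fixture slice (the acceptance suite covers the
  # whole pool)
  for (m in fixture_pool(30)) {
    cl <- enumerate_cleavages(m)
    g <- m$graph
    for (r in seq_len(nrow(cl))) {
      parts <- chemsa:::cleavage_fragments(m, r)
      res <- join_fragments(parts[[1]], parts[[2]])
      expect_false(is_join_failure(res))
      expect_identical(res$smiles, m$smiles)
    }
  }
})

test_that("incompatible link pairs fail softly with a reason", {
  f16 <- fragment_molecule("CCCc1ccccc1")  # [16*]c1ccccc1 among others
  benz <- Filter(function(f) f$link_type == 16L, f16)[[1]]
  acyl <- Filter(function(f) f$link_type == 1L,
                 fragment_molecule("CCCCNC(=O)CCC"))[[1]]
  res <- join_fragments(benz, acyl)   # 1-16 is not an allowed pair
  expect_true(is_join_failure(res))
  expect_equal(res$reason, "incompatible")
})

test_that("random compatible joins emit valid, placeholder-free molecules", {
  db <- fixture_fragment_db()
  links <- vapply(db, `[[`, 0L, "link_type")
  set.seed(13)
  n_ok <- 0L
  tries <- 0L
  while (n_ok < 300L && tries < 5000L) {
    tries <- tries + 1L
    i <- sample.int(length(db), 1L); j <- sample.int(length(db), 1L)
    if (!brics_compatible(links[i], links[j])) next
    res <- join_fragments(db[[i]], db[[j]])
    if (is_join_failure(res)) {
      expect_true(res$reason %in% c("incompatible", "valence"))
      next
    }
    n_ok <- n_ok + 1L
    # validity oracle: re-parse the emitted SMILES from scratch
    m2 <- canonicalize(res$smiles)
    expect_identical(m2$smiles, res$smiles)
    expect_false(grepl("*", res$smiles, fixed = TRUE))
  }
  expect_gte(n_ok, 300L)
})

test_that("fragment weights follow the mean-log-frequency definition", {
  db <- fixture_fragment_db(10)
  uni <- frequency_table()
  w <- vapply(db, fragment_weight, 0, t = uni)
  expect_true(all(abs(w - w[1]) < 1e-12))  # uniform table -> equal weights

  # two set bits with counts 100 and 1000, pseudocount 0 -> (ln100 + ln1000)/2
  f <- db[[1]]
  bits <- chemsa:::frag_fp(f$core_smiles)[1:2]
  counts <- c(100, 1000)
  names(counts) <- bits
  tab <- frequency_table(counts, pseudocount = 0)
  # restrict the fragment fingerprint to those two bits via a stub fragment
  stub <- structure(list(core_smiles = f$core_smiles, link_type = f$link_type,
                         n_heavy = f$n_heavy, parent = NA), class = "fragment")
  w2 <- mean(log(c(100, 1000)))
  got <- mean(log(tab$counts[bits + 1L] + tab$pseudocount))
  expect_equal(got, w2, tolerance = 1e-12)
  expect_equal(w2, 5.756463, tolerance = 1e-6)
})

test_that("weighted sampling is proportional to the weights", {
  # weights (2,1,1) over 10,000 draws: frequencies within 3 sigma of
  # (0.5, 0.25, 0.25)
  set.seed(5)
  draws <- sample.int(3L, 10000L, replace = TRUE, prob = c(2, 1, 1))
  p <- c(0.5, 0.25, 0.25)
  for (k in 1:3) {
    phat <- mean(draws == k)
    sigma <- sqrt(p[k] * (1 - p[k]) / 10000)
    expect_lt(abs(phat - p[k]), 3 * sigma)
  }
})

test_that("trial generation respects caps, determinism, and degenerate seeds", {
  db <- fixture_fragment_db(120)
  seed <- fixture_pool(5)[[2]]

  expect_length(generate_trials(canonicalize("CCO"), db), 0L)  # unfragmentable seed
  expect_length(generate_trials(seed, list()), 0L)             # no partners

  set.seed(77)
  t1 <- generate_trials(seed, db, max_trials = 60L)
  expect_lte(length(t1), 60L)
  expect_gt(length(t1), 0L)
  smiles1 <- vapply(t1, `[[`, "", "smiles")
  expect_false(anyDuplicated(smiles1) > 0)
  for (m in t1) {
    expect_false(grepl("*", m$smiles, fixed = TRUE))
    expect_identical(canonicalize(m$smiles)$smiles, m$smiles)
  }

  set.seed(77)
  t2 <- generate_trials(seed, db, max_trials = 60L)
  expect_identical(smiles1, vapply(t2, `[[`, "", "smiles"))

  set.seed(78)
  t3 <- generate_trials(seed, db, max_trials = 5L)
  expect_lte(length(t3), 5L)
})

test_that("partner pools equal the fragmentation of the partner", {
  p <- fixture_pool(3)[[1]]
  a <- partner_pool_from_molecule(p)
  b <- fragment_molecule(p)
  expect_identical(vapply(a, `[[`, "", "core_smiles"),
                   vapply(b, `[[`, "", "core_smiles"))
  expect_length(partner_pool_from_molecule(canonicalize("CCO")), 0L)
})

test_that("self-recombination can reproduce the seed", {
  # joining complementary fragments of the same molecule reaches the seed
  m <- fixture_pool(10)[[4]]
  frs <- fragment_molecule(m, 0L)
  smis <- vapply(frs, `[[`, "", "core_smiles")
  found <- FALSE
  for (i in seq_along(frs)) for (j in seq_along(frs)) {
    if (i == j) next
    if (!brics_compatible(frs[[i]]$link_type, frs[[j]]$link_type)) next
    res <- join_fragments(frs[[i]], frs[[j]])
    if (!is_join_failure(res) && identical(res$smiles, m$smiles)) found <- TRUE
  }
  expect_true(found)
})

test_that("frequency tables read from TSV and validate their inputs", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("5\t100", "17\t3"), tf)
  tab <- read_freq_table(tf)
  expect_equal(tab$counts[6], 100)
  expect_equal(tab$counts[18], 3)
  expect_equal(tab$counts[1], 0)
  expect_error(frequency_table(c("-1" = 5)), "bit indices")
  expect_error(frequency_table(c("5" = -2)), "non-negative")
})
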