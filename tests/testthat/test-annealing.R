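# Annealing optimizer: schedule, bank initialization, seed cycling, the
# update rule, and full-run behavior.

heavy_objective <- function() objective("external", fun = function(m) m$n_heavy)

test_that("the radius schedule follows the closed form and floors at cycle 20", {
  s <- annealing_schedule(0.37)
  expect_equal(rcut_at(s, 0), 0.37)
  expect_equal(rcut_at(s, 20) / rcut_at(s, 0), 0.4, tolerance = 1e-12)
  expect_identical(rcut_at(s, 35), rcut_at(s, 20))
  expect_identical(rcut_at(s, 21), rcut_at(s, 20))
  r <- rcut_at(s, 0:40)
  expect_true(all(diff(r) <= 0))
  expect_error(rcut_at(s, -1), "non-negative")
})

test_that("bank initialization keeps the n best with deterministic ties", {
  pool <- fixture_pool(100)
  obj <- heavy_objective()
  bank <- init_bank(pool, obj, 60L)
  expect_length(bank$mols, 60L)
  # sort oracle: the 60 smallest heavy-atom counts
  heavies <- sort(vapply(pool, `[[`, 0L, "n_heavy"))
  expect_equal(sort(bank$value), as.numeric(heavies[1:60]))
  expect_false(anyDuplicated(bank$smiles) > 0)

  # pool of exactly n -> bank == pool
  small <- fixture_pool(10)
  b2 <- init_bank(small, heavy_objective(), 10L)
  expect_setequal(b2$smiles, unname(vapply(small, `[[`, "", "smiles")))

  expect_error(init_bank(fixture_pool(10), heavy_objective(), 20L), "smaller")
  dup <- c(fixture_pool(5), fixture_pool(3))
  expect_error(init_bank(dup, heavy_objective(), 4L), "duplicate")
})

test_that("the initial radius is half the mean pairwise bank distance", {
  pool <- fixture_pool(70)
  bank <- init_bank(pool, heavy_objective(), 60L)
  expect_equal(initial_rcut(bank), pairwise_mean_distance(bank$mols) / 2)
  expect_gt(initial_rcut(bank), 0)
  expect_lte(initial_rcut(bank), 0.5)

  # identical fingerprints -> 0; all pairwise distances 0.8 -> 0.4
  same <- lapply(1:5, function(i) fake_mol(1:6, smiles = paste0("s", i)))
  expect_equal(initial_rcut(chemsa:::new_bank(same, rep(0, 5))), 0)
  # three bit vectors sharing 1 of 3 bits pairwise: union 5, similarity 0.2,
  # so every pair distance is exactly 0.8
  trio <- list(fake_mol(c(1, 2, 3), "a"),
               fake_mol(c(1, 4, 5), "b"),
               fake_mol(c(1, 6, 7), "c"))
  expect_equal(initial_rcut(chemsa:::new_bank(trio, rep(0, 3))), 0.4)
})

test_that("seed selection draws distinct unused entries and flags them", {
  pool <- fixture_pool(70)
  bank <- init_bank(pool, heavy_objective(), 60L)
  set.seed(1)
  sel <- select_seeds(bank, 6L)
  expect_length(sel$seeds, 6L)
  expect_false(anyDuplicated(sel$seeds) > 0)
  expect_true(all(sel$bank$used[sel$seeds]))
  expect_equal(sum(sel$bank$used), 6L)

  # clamp to the number of remaining unused entries
  b <- sel$bank
  b$used[] <- TRUE
  b$used[c(3, 9, 17, 40)] <- FALSE
  s2 <- select_seeds(b, 6L)
  expect_setequal(s2$seeds, c(3, 9, 17, 40))
  expect_error(select_seeds(s2$bank, 6L), class = "chemsa_all_used")

  set.seed(42); a <- select_seeds(bank, 6L)$seeds
  set.seed(42); b2 <- select_seeds(bank, 6L)$seeds
  expect_identical(a, b2)
})

test_that("the update rule matches its truth table", {
  # bank of two fake molecules with controlled distances to the trial
  near <- fake_mol(c(1:8, 9, 10), "near")     # trial shares 8 of 12 bits
  far <- fake_mol(101:110, "far")             # disjoint from the trial
  trial <- fake_mol(c(1:8, 11, 12), "trial")
  d_near <- tanimoto_distance(near, trial)    # 1 - 8/12 = 1/3
  expect_equal(d_near, 1 / 3)

  mk <- function(v_near, v_far) chemsa:::new_bank(list(near, far), c(v_near, v_far))

  # inside rcut, better than nearest -> replaced_nearest
  r <- update_bank(mk(5, 9), trial, 4, rcut = 0.5)
  expect_equal(r$outcome, "replaced_nearest")
  expect_equal(r$index, 1L)
  expect_true("trial" %in% r$bank$smiles)
  expect_equal(sort(r$bank$value), c(4, 9))

  # inside rcut, worse than nearest -> discarded (even if better than worst)
  r <- update_bank(mk(5, 9), trial, 6, rcut = 0.5)
  expect_equal(r$outcome, "discarded")
  expect_identical(r$bank$smiles, c("near", "far"))

  # outside rcut, better than worst -> replaced_worst
  r <- update_bank(mk(5, 9), trial, 6, rcut = 0.2)
  expect_equal(r$outcome, "replaced_worst")
  expect_equal(r$index, 2L)
  expect_equal(sort(r$bank$value), c(5, 6))

  # outside rcut, worse than worst -> discarded (bank never degrades)
  r <- update_bank(mk(5, 9), trial, 10, rcut = 0.2)
  expect_equal(r$outcome, "discarded")

  # duplicates of a bank member are discarded regardless of value
  dup <- fake_mol(c(1:8, 9, 10), "near")
  r <- update_bank(mk(5, 9), dup, -100, rcut = 0.5)
  expect_equal(r$outcome, "discarded")
})

test_that("bank value multisets only improve: 10^4 random updates", {
  set.seed(99)
  mols <- lapply(1:30, function(i) fake_mol(sample.int(2048, 40) - 1L,
                                            smiles = paste0("b", i)))
  bank <- chemsa:::new_bank(mols, runif(30))
  violations <- 0L
  for (step in 1:10000) {
    trial <- fake_mol(sample.int(2048, 40) - 1L,
                      smiles = paste0("t", step))
    val <- runif(1, -0.2, 1.2)
    rcut <- runif(1, 0, 0.8)
    old <- sort(bank$value)
    res <- update_bank(bank, trial, val, rcut)
    new <- sort(res$bank$value)
    ok <- if (res$outcome == "discarded") {
      identical(new, old)
    } else {
      # exactly one element replaced by a strictly smaller one
      added <- setdiff(new, old)
      removed <- setdiff(old, new)
      length(added) == 1L && length(removed) == 1L && added < removed
    }
    ok <- ok && length(res$bank$mols) == 30L &&
      anyDuplicated(res$bank$smiles) == 0L
    if (!ok) violations <- violations + 1L
    bank <- res$bank
  }
  expect_identical(violations, 0L)
})

test_that("zero-cycle runs return the initial bank and full runs are deterministic", {
  pool <- fixture_pool(40)
  db <- fixture_fragment_db(80)

  obj0 <- heavy_objective()
  cfg0 <- run_config(n_bank = 15L, n_cycles = 0L, rng_seed = 3L)
  res0 <- csa_run(cfg0, pool, db, obj0)
  bank0 <- init_bank(pool, heavy_objective(), 15L)
  expect_identical(sort(res0$bank$smiles), sort(bank0$smiles))
  expect_equal(nrow(res0$history), 0L)

  cfg <- run_config(n_bank = 15L, n_cycles = 6L, rng_seed = 31L,
                    max_trials_per_source = 20L, fragment_sample = 40L)
  target <- fixture_pool(50)[[47]]
  r1 <- csa_run(cfg, pool, db, objective("simtarget", target = target$smiles))
  r2 <- csa_run(cfg, pool, db, objective("simtarget", target = target$smiles))
  expect_identical(r1$history, r2$history)
  expect_identical(r1$bank$smiles, r2$bank$smiles)
  expect_identical(r1$bank$value, r2$bank$value)

  # history structure and monotone best/mean/worst
  h <- r1$history
  expect_equal(nrow(h), 6L)
  expect_true(all(diff(h$best) <= 0))
  expect_true(all(diff(h$mean) <= 0))
  expect_true(all(diff(h$worst) <= 0))
  expect_true(all(diff(h$n_evaluations) >= 0))
  expect_equal(h$rcut, rcut_at(annealing_schedule(r1$initial_rcut), 0:5))
})

test_that("objective failures skip the trial and the run continues", {
  pool <- fixture_pool(30)
  db <- fixture_fragment_db(50)
  pool_smiles <- vapply(pool, `[[`, "", "smiles")
  flaky <- objective("external", fun = function(m) {
    # fail on a slice of the newly synthesized molecules only
    if (!(m$smiles %in% pool_smiles) && nchar(m$smiles) %% 5 == 0) stop("boom")
    m$n_heavy
  })
  cfg <- run_config(n_bank = 10L, n_cycles = 3L, rng_seed = 8L,
                    max_trials_per_source = 15L, fragment_sample = 30L)
  expect_message(res <- csa_run(cfg, pool, db, flaky), "skipped")
  expect_equal(nrow(res$history), 3L)
  expect_length(res$bank$mols, 10L)
})
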