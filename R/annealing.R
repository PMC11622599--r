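# The chemical-space-annealing optimizer: a fixed-size bank of molecules is
# evolved by virtual synthesis; a niching radius R_cut in Tanimoto-distance
# space decides whether a trial competes with its nearest neighbour or with
# the globally worst bank member, and is annealed from broad to narrow.

#' Run configuration
#'
#' Defaults are the published operating point: bank of 60, 6 seeds per batch,
#' 50 cycles, up to 60 trials per partner source, 100 fragments sampled from
#' the database per seed.
#'
#' @param n_bank bank size.
#' @param n_seeds_per_batch seeds drawn per batch.
#' @param n_cycles annealing cycles per run.
#' @param max_trials_per_source trial cap per partner source per seed.
#' @param fragment_sample size of the fragment-database sample per seed.
#' @param rng_seed integer seed for all randomness of the run.
#' @return a `run_config` list.
#' @export
run_config <- function(n_bank = 60L, n_seeds_per_batch = 6L, n_cycles = 50L,
                       max_trials_per_source = 60L, fragment_sample = 100L,
                       rng_seed = 1L) {
  cfg <- list(n_bank = as.integer(n_bank),
              n_seeds_per_batch = as.integer(n_seeds_per_batch),
              n_cycles = as.integer(n_cycles),
              max_trials_per_source = as.integer(max_trials_per_source),
              fragment_sample = as.integer(fragment_sample),
              rng_seed = as.integer(rng_seed))
  if (any(vapply(cfg, function(x) x < 0L, TRUE)) ||
      any(vapply(cfg[1:2], function(x) x < 1L, TRUE)) ||
      cfg$max_trials_per_source < 1L || cfg$fragment_sample < 1L) {
    stop("run_config values must be positive (n_cycles may be 0)")
  }
  structure(cfg, class = "run_config")
}

#' Annealing schedule for the niching radius
#'
#' `rcut(c) = r0 * decay^min(c, floor_cycle)` with the default per-cycle
#' decay `0.4^0.05`, so the radius reaches 40% of its initial value after 20
#' cycles and is constant thereafter.
#'
#' @param r0 initial radius (Tanimoto distance units, in `[0,1]`).
#' @param decay per-cycle factor.
#' @param floor_cycle cycle at which the radius stops shrinking.
#' @return an `annealing_schedule`.
#' @export
annealing_schedule <- function(r0, decay = 0.4^0.05, floor_cycle = 20L) {
  stopifnot(is.numeric(r0), r0 >= 0, decay > 0, decay <= 1, floor_cycle >= 0)
  structure(list(r0 = r0, decay = decay, floor_cycle = as.integer(floor_cycle)),
            class = "annealing_schedule")
}

#' Niching radius at a given cycle
#'
#' @param schedule an [annealing_schedule()].
#' @param cycle non-negative cycle index (0 = initial).
#' @export
rcut_at <- function(schedule, cycle) {
  stopifnot(inherits(schedule, "annealing_schedule"))
  if (any(cycle < 0)) stop("cycle must be non-negative")
  schedule$r0 * schedule$decay^pmin(cycle, schedule$floor_cycle)
}

# --- bank -------------------------------------------------------------------

new_bank <- function(mols, values) {
  smiles <- vapply(mols, `[[`, "", "smiles")
  structure(list(
    mols = mols,
    value = as.numeric(values),
    smiles = smiles,
    used = logical(length(mols)),
    fpm = bits_to_matrix(lapply(mols, `[[`, "fp"))
  ), class = "chem_bank")
}

#' @export
print.chem_bank <- function(x, ...) {
  cat(sprintf("<bank> %d molecules; best %.4f, worst %.4f\n",
              length(x$mols), min(x$value), max(x$value)))
  invisible(x)
}

bank_size <- function(bank) length(bank$mols)

#' Initialize the bank from a pool
#'
#' Evaluates every pool molecule and keeps the `n` with the best (lowest)
#' objective values; ties are broken by canonical-SMILES lexicographic order
#' so initialization is deterministic.
#'
#' @param pool list of `molecule` objects (deduplicated; at least `n`).
#' @param objective a `chem_objective`.
#' @param n bank size.
#' @return a `chem_bank`.
#' @export
init_bank <- function(pool, objective, n = 60L) {
  pool <- as_molecule_list(pool)
  smiles <- vapply(pool, `[[`, "", "smiles")
  if (anyDuplicated(smiles)) stop("pool contains duplicate molecules")
  if (length(pool) < n) stop("pool smaller than bank size")
  vals <- vapply(pool, function(m) evaluate_objective(objective, m), 0)
  ord <- order(vals, smiles, method = "radix")
  keep <- ord[seq_len(n)]
  new_bank(pool[keep], vals[keep])
}

#' Initial niching radius: half the mean pairwise bank distance
#'
#' @param bank a `chem_bank`.
#' @export
initial_rcut <- function(bank) {
  stopifnot(inherits(bank, "chem_bank"))
  pairwise_mean_distance(bank$mols) / 2
}

#' Select seed molecules from the unused bank entries
#'
#' Draws `min(k, #unused)` distinct entries uniformly at random from those
#' not yet used as seeds and marks them used. Errors (condition class
#' `chemsa_all_used`) when every entry has been used; the caller resets the
#' flags at cycle boundaries.
#'
#' @param bank a `chem_bank`.
#' @param k seeds requested.
#' @return list with elements `bank` (flags updated) and `seeds` (integer
#'   indices of the selected entries).
#' @export
select_seeds <- function(bank, k = 6L) {
  unused <- which(!bank$used)
  if (length(unused) == 0L) {
    stop(structure(class = c("chemsa_all_used", "error", "condition"),
                   list(message = "all bank entries used as seeds; reset flags",
                        call = NULL)))
  }
  take <- min(k, length(unused))
  sel <- if (length(unused) == 1L) unused else
    unused[sample.int(length(unused), take)]
  bank$used[sel] <- TRUE
  list(bank = bank, seeds = sel)
}

# Tanimoto distances from a trial fingerprint to every bank member
bank_distances <- function(bank, fp) {
  v <- numeric(nrow(bank$fpm))
  v[fp + 1L] <- 1
  inter <- as.numeric(crossprod(bank$fpm, v))
  pop <- colSums(bank$fpm)
  un <- pop + length(fp) - inter
  d <- ifelse(un == 0, 1, 1 - inter / un)
  d
}

#' Offer a trial molecule to the bank
#'
#' The annealing update rule: a duplicate of a bank member is discarded;
#' otherwise, with `d*` the distance to the nearest bank member, the trial
#' replaces that nearest member if `d* <= rcut` and its value is strictly
#' better, or replaces the worst-valued member if `d* > rcut` and its value
#' beats the worst; in every other case it is discarded. Nearest-member ties
#' go to the better-valued entry, then lexicographic SMILES.
#'
#' @param bank a `chem_bank`.
#' @param trial a `molecule`.
#' @param trial_value finite objective value of the trial.
#' @param rcut current niching radius.
#' @return list with `bank` (possibly updated), `outcome` (one of
#'   `"replaced_nearest"`, `"replaced_worst"`, `"discarded"`), and `index`
#'   (the affected entry, or `NA`).
#' @export
update_bank <- function(bank, trial, trial_value, rcut) {
  stopifnot(inherits(bank, "chem_bank"), is_molecule(trial),
            is.finite(trial_value))
  if (trial$smiles %in% bank$smiles) {
    return(list(bank = bank, outcome = "discarded", index = NA_integer_))
  }
  d <- bank_distances(bank, trial$fp)
  dmin <- min(d)
  if (dmin <= rcut) {
    cand <- which(d == dmin)
    if (length(cand) > 1L) {
      cand <- cand[order(bank$value[cand], bank$smiles[cand], method = "radix")]
    }
    e <- cand[1L]
    if (trial_value < bank$value[e]) {
      bank <- bank_replace(bank, e, trial, trial_value)
      return(list(bank = bank, outcome = "replaced_nearest", index = e))
    }
    return(list(bank = bank, outcome = "discarded", index = NA_integer_))
  }
  worst <- which(bank$value == max(bank$value))
  if (length(worst) > 1L) {
    worst <- worst[order(bank$smiles[worst], method = "radix")]
  }
  w <- worst[1L]
  if (trial_value < bank$value[w]) {
    bank <- bank_replace(bank, w, trial, trial_value)
    return(list(bank = bank, outcome = "replaced_worst", index = w))
  }
  list(bank = bank, outcome = "discarded", index = NA_integer_)
}

# replace entry e; the new entry inherits the slot's used-as-seed flag so a
# cycle is always exactly one pass over the n slots
bank_replace <- function(bank, e, trial, value) {
  bank$mols[[e]] <- trial
  bank$value[e] <- value
  bank$smiles[e] <- trial$smiles
  bank$fpm[, e] <- 0
  bank$fpm[trial$fp + 1L, e] <- 1
  bank
}

# --- full run ---------------------------------------------------------------

#' Run the chemical-space-annealing optimization
#'
#' Initializes the bank with the best `n_bank` pool molecules, then executes
#' `n_cycles` cycles. One cycle is one batch: at the fixed radius
#' `rcut_at(schedule, cycle)`, `n_seeds_per_batch` entries are drawn from
#' those not yet used as seeds (flags reset whenever the whole bank has
#' seeded), and each seed is recombined with the fragments of one random
#' initial-bank molecule (up to `max_trials_per_source` products) and with a
#' random `fragment_sample`-sized subset of the fragment database (up to the
#' same cap). Trials are evaluated and offered to the bank one at a time in
#' generation order. With the defaults (bank 60, 6 seeds, 50 cycles) a run
#' makes five passes over the bank and on the order of 10^3 unique
#' objective evaluations.
#'
#' @param config a [run_config()].
#' @param pool list of `molecule` objects (or character SMILES vector).
#' @param fragment_db list of `fragment` objects.
#' @param objective a `chem_objective`.
#' @param freq_table a `freq_table` for fragment weighting (default uniform).
#' @return list with `bank` (final `chem_bank`), `history` (one row per
#'   cycle: `cycle`, `rcut`, `best`, `mean`, `worst`, `n_evaluations`), and
#'   `initial_rcut`.
#' @export
csa_run <- function(config, pool, fragment_db, objective,
                    freq_table = frequency_table()) {
  stopifnot(inherits(config, "run_config"))
  pool <- as_molecule_list(pool)
  if (length(pool) == 0L || length(fragment_db) == 0L) {
    stop("pool and fragment_db must be non-empty")
  }
  set.seed(config$rng_seed)
  bank <- init_bank(pool, objective, config$n_bank)
  initial_bank_mols <- bank$mols  # partner source stays the *initial* bank
  schedule <- annealing_schedule(initial_rcut(bank))
  n_skipped <- 0L

  history <- vector("list", config$n_cycles)
  for (cycle in seq_len(config$n_cycles)) {
    rcut <- rcut_at(schedule, cycle - 1L)
    if (all(bank$used)) bank$used[] <- FALSE
    sel <- select_seeds(bank, config$n_seeds_per_batch)
    bank <- sel$bank
    for (s in sel$seeds) {
      seed_mol <- bank$mols[[s]]
      partner <- initial_bank_mols[[sample.int(length(initial_bank_mols), 1L)]]
      trials <- generate_trials(seed_mol, partner_pool_from_molecule(partner),
                                freq_table, config$max_trials_per_source)
      nf <- min(config$fragment_sample, length(fragment_db))
      fsel <- sample.int(length(fragment_db), nf)
      trials <- c(trials,
                  generate_trials(seed_mol, fragment_db[fsel],
                                  freq_table, config$max_trials_per_source))
      for (tr in trials) {
        val <- tryCatch(evaluate_objective(objective, tr),
                        error = function(e) NULL)
        if (is.null(val)) { n_skipped <- n_skipped + 1L; next }
        bank <- update_bank(bank, tr, val, rcut)$bank
      }
    }
    history[[cycle]] <- data.frame(
      cycle = cycle, rcut = rcut,
      best = min(bank$value), mean = mean(bank$value),
      worst = max(bank$value),
      n_evaluations = evaluation_count(objective))
  }
  history <- if (config$n_cycles > 0L) do.call(rbind, history) else
    data.frame(cycle = integer(), rcut = numeric(), best = numeric(),
               mean = numeric(), worst = numeric(), n_evaluations = integer())
  if (n_skipped > 0L) {
    message(sprintf("chemsa: skipped %d trial(s) whose objective failed", n_skipped))
  }
  list(bank = bank, history = history, initial_rcut = schedule$r0,
       n_skipped = n_skipped)
}
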