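# Boltzmann-stochastic conformational search: iterative sampling over the
# structural alphabet, energy ranking, probability updating, and archiving
# of the 99 best models.

#' Sampler configuration
#'
#' @param structures_per_step Structures generated and ranked per step.
#'   The `"desk"` preset uses 500 (sized so a full sliding-window scan
#'   runs on one desktop CPU core in minutes; convergence is
#'   indistinguishable from larger steps on 19-mer windows, see the
#'   methods vignette); the `"full"` preset restores the original budget
#'   of 10^4.
#' @param total_steps Number of steps; `NULL` means 10 x sequence length
#'   (the point where sampling probabilities stabilize).
#' @param favorable_fraction,unfavorable_fraction Fractions of the ranked
#'   step forming the favorable and unfavorable tiers that drive the
#'   probability update (top/bottom 1% by default; see the methods
#'   vignette for why narrow tiers are needed).
#' @param couples_per_update Maximum number of (position, state) couples
#'   boosted and damped per step.
#' @param boost,damp Multiplicative factors applied before renormalization.
#' @param probability_floor Minimum per-state probability retained after
#'   every update (keeps the search ergodic).
#' @param archive_size Number of best models retained (99).
#' @param clash_floor Hard minimum non-bonded heavy-atom distance (A);
#'   closer structures are resampled.
#' @param max_clash_retries Resampling rounds before a clashing structure
#'   is accepted with its (already penal) energy.
#' @param preset `"desk"` or `"full"`.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(structures_per_step = NULL, total_steps = NULL,
                           favorable_fraction = 0.01,
                           unfavorable_fraction = 0.01,
                           couples_per_update = 100L,
                           boost = 2, damp = 0.5,
                           probability_floor = 1e-4,
                           archive_size = 99L, clash_floor = 1.5,
                           max_clash_retries = 1L,
                           preset = c("desk", "full")) {
  preset <- match.arg(preset)
  if (is.null(structures_per_step))
    structures_per_step <- if (preset == "full") 10000L else 500L
  stopifnot(structures_per_step >= 1,
            favorable_fraction > 0, favorable_fraction <= 0.5,
            unfavorable_fraction > 0, unfavorable_fraction <= 0.5,
            archive_size >= 1)
  structure(list(structures_per_step = as.integer(structures_per_step),
                 total_steps = total_steps,
                 favorable_fraction = favorable_fraction,
                 unfavorable_fraction = unfavorable_fraction,
                 couples_per_update = as.integer(couples_per_update),
                 boost = boost, damp = damp,
                 probability_floor = probability_floor,
                 archive_size = as.integer(archive_size),
                 clash_floor = clash_floor,
                 max_clash_retries = as.integer(max_clash_retries),
                 preset = preset),
            class = "sampler_config")
}

# matrix of state draws (rows = structures), one categorical draw per
# position from its probability column; uses the R RNG
draw_states <- function(probs, n) {
  nres <- ncol(probs)
  out <- matrix(0L, nrow = n, ncol = nres)
  for (p in seq_len(nres))
    out[, p] <- sample.int(nrow(probs), n, replace = TRUE, prob = probs[, p])
  out
}

state_keys <- function(states) {
  apply(states, 1, paste, collapse = ",")
}

#' Draw one random conformation from the alphabet probabilities
#'
#' Each residue's state is drawn independently from its position's
#' probability vector; structures violating the hard clash floor are
#' redrawn up to the configured retry count and then accepted (their
#' energy is already prohibitive).
#'
#' @param sequence One-letter sequence.
#' @param alphabet A `structural_alphabet` whose probability matrix has
#'   one column per residue (a single column is recycled).
#' @param config A [sampler_config()].
#' @param ff Force field.
#' @return A `conformation`.
#' @export
sample_structure <- function(sequence, alphabet = load_alphabet(),
                             config = sampler_config(),
                             ff = load_forcefield()) {
  n <- nchar(sequence)
  probs <- alphabet$probabilities
  if (ncol(probs) == 1L) probs <- probs[, rep(1L, n), drop = FALSE]
  for (try in 0:config$max_clash_retries) {
    st <- drop(draw_states(probs, 1L))
    conf <- build_conformation(sequence, st, alphabet, ff = ff)
    if (min_heavy_distance(conf) >= config$clash_floor) return(conf)
  }
  conf
}

#' Update alphabet probabilities from one ranked step
#'
#' (position, state) couples found *only* in the energetically favorable
#' tier (top decile of the ranked step) are boosted; couples found *only*
#' in the unfavorable tier (bottom decile) are damped; at most
#' `couples_per_update` couples on each side, taken best-energy-first
#' (resp. worst-energy-first).  Couples present in both tiers, or in
#' neither, are untouched before renormalization.  Columns are then
#' renormalized to sum to 1 with the probability floor enforced.
#'
#' @param states Integer matrix of the step's structures (rows) by residue
#'   position (columns).
#' @param energies Energies aligned with the rows of `states`.
#' @param probs Probability matrix (states x positions).
#' @param config A [sampler_config()].
#' @return The updated probability matrix.
#' @export
update_probabilities <- function(states, energies, probs, config = sampler_config()) {
  m <- nrow(states); nres <- ncol(states); nstates <- nrow(probs)
  ord <- order(energies)
  nfav <- max(1L, floor(m * config$favorable_fraction))
  nunf <- max(1L, floor(m * config$unfavorable_fraction))
  fav <- ord[seq_len(nfav)]
  unf <- ord[seq.int(m - nunf + 1L, m)]

  couple_codes <- function(rows) {
    st <- states[rows, , drop = FALSE]
    code <- as.vector(st) + nstates * rep(0:(nres - 1L), each = length(rows))
    e <- rep(energies[rows], times = nres)
    list(code = code, e = e)
  }
  f <- couple_codes(fav); u <- couple_codes(unf)
  f_best <- tapply(f$e, f$code, min)
  u_worst <- tapply(u$e, u$code, max)
  f_codes <- as.integer(names(f_best))
  u_codes <- as.integer(names(u_worst))
  only_f <- setdiff(f_codes, u_codes)
  only_u <- setdiff(u_codes, f_codes)
  if (length(only_f)) {
    sel <- only_f[order(f_best[as.character(only_f)], only_f)]
    sel <- sel[seq_len(min(length(sel), config$couples_per_update))]
    probs[cbind((sel - 1L) %% nstates + 1L, (sel - 1L) %/% nstates + 1L)] <-
      probs[cbind((sel - 1L) %% nstates + 1L, (sel - 1L) %/% nstates + 1L)] *
      config$boost
  }
  if (length(only_u)) {
    sel <- only_u[order(-u_worst[as.character(only_u)], only_u)]
    sel <- sel[seq_len(min(length(sel), config$couples_per_update))]
    probs[cbind((sel - 1L) %% nstates + 1L, (sel - 1L) %/% nstates + 1L)] <-
      probs[cbind((sel - 1L) %% nstates + 1L, (sel - 1L) %/% nstates + 1L)] *
      config$damp
  }
  normalize_with_floor(probs, config$probability_floor)
}

# water-filling normalization: columns sum to exactly 1 with every entry
# >= floor
normalize_with_floor <- function(probs, floor) {
  for (p in seq_len(ncol(probs))) {
    v <- probs[, p] / sum(probs[, p])
    low <- v < floor
    if (any(low)) {
      v[low] <- floor
      free <- sum(v[!low])
      v[!low] <- v[!low] * (1 - floor * sum(low)) / free
    }
    probs[, p] <- v
  }
  probs
}

#' Run the stochastic conformational search
#'
#' Iterates `total_steps` steps of `structures_per_step` random structures
#' drawn from the evolving per-position state probabilities; after each
#' step the probabilities are updated from the favorable/unfavorable tiers
#' and a global archive of the best-energy distinct structures is
#' maintained.  Deterministic for a fixed seed.  Energies are evaluated in
#' the requested environment: `"hydrophobic"` (the scan default; no
#' solvation term), `"hydrophilic"` (adds implicit solvation) or
#' `"membrane"` (adds the implicit-bilayer potential at a quick best
#' insertion).
#'
#' @param sequence One-letter sequence (1 to 34 residues).
#' @param environment Energy environment.
#' @param config A [sampler_config()].
#' @param alphabet A `structural_alphabet`.
#' @param ff Force field.
#' @param seed Integer seed.
#' @param memo Optional persistent energy memo from [peplook_memo()]:
#'   state-string energies are seed-independent, so sharing a memo across
#'   runs on the same sequence (e.g. re-scans under different master
#'   seeds) avoids recomputation without changing any result.
#' @return A `model_set`: list with `models` (conformations sorted by
#'   ascending energy, at most `archive_size`), `energies`, `prime` (the
#'   first model), `states` matrix and run metadata.
#' @export
run_peplook <- function(sequence, environment = c("hydrophobic",
                                                  "hydrophilic", "membrane"),
                        config = sampler_config(),
                        alphabet = load_alphabet(),
                        ff = load_forcefield(), seed = 1L, memo = NULL) {
  environment <- match.arg(environment)
  n <- nchar(sequence)
  if (n < 1 || n > 34)
    stop("sequence length must be between 1 and 34 residues", call. = FALSE)
  total_steps <- if (is.null(config$total_steps)) 10L * n
                 else as.integer(config$total_steps)
  sys <- prepare_system(sequence, ff)
  nstates <- nrow(alphabet$states)
  probs <- matrix(1 / nstates, nrow = nstates, ncol = n)

  if (environment == "hydrophobic") {
    # compiled fast path: the whole step loop (sampling, memoized energy,
    # clash resampling, archive, probability update) runs in C++
    res <- cpp_run_peplook(alphabet$states$phi, alphabet$states$psi,
                           sys$topo$zmat, sys$pairs, sys$comb,
                           sys$short_cut, sys$w_apolar,
                           sys$ca_idx, sys$reach,
                           sys$ff$cutoff, unname(sys$ff$diel),
                           sys$topo$atoms$resid, n,
                           config$structures_per_step, total_steps,
                           config$favorable_fraction,
                           config$unfavorable_fraction,
                           config$couples_per_update, config$boost,
                           config$damp, config$probability_floor,
                           config$archive_size, config$clash_floor,
                           config$max_clash_retries, as.numeric(seed),
                           if (is.null(memo)) NULL else memo)
    models <- lapply(seq_len(nrow(res$states)), function(k)
      build_conformation(sequence, res$states[k, ], alphabet, ff = ff))
    return(structure(list(sequence = sequence, environment = environment,
                          models = models, energies = res$energy,
                          states = res$states, prime = models[[1]],
                          prime_trace = res$prime_trace, seed = seed,
                          config = config,
                          n_evaluated = total_steps * config$structures_per_step,
                          n_unique = res$n_unique_evaluated),
                     class = "model_set"))
  }

  cache <- new.env(hash = TRUE, parent = emptyenv())
  evaluate <- function(states) {
    keys <- state_keys(states)
    new <- !vapply(keys, exists, logical(1), envir = cache, inherits = FALSE)
    if (any(new)) {
      uniq <- !duplicated(keys) & new
      res <- system_energies(sys, states[uniq, , drop = FALSE], alphabet,
                             w = rep(0, nrow(sys$topo$atoms)))
      e <- res$energy
      clash <- res$min_heavy_dist < config$clash_floor
      uk <- keys[uniq]
      extra <- numeric(sum(uniq))
      if (environment != "hydrophobic") {
        su <- states[uniq, , drop = FALSE]
        for (r in seq_len(nrow(su))) {
          conf <- build_conformation(sequence, su[r, ], alphabet, ff = ff)
          extra[r] <- if (environment == "hydrophilic")
            solvation_energy(conf, ff)
          else insertion_scan(conf, membrane_model(ff), seed = seed, ff = ff,
                              n_trials = 60L, z_step = 1)$e_pot_mem
        }
      }
      for (r in seq_along(uk))
        assign(uk[r], c(e[r] + extra[r], clash[r]), envir = cache)
    }
    vals <- vapply(keys, get, numeric(2), envir = cache, inherits = FALSE)
    list(keys = keys, energy = vals[1, ], clash = vals[2, ] > 0)
  }

  archive_keys <- character(0)
  archive_energy <- numeric(0)
  archive_states <- list()
  prime_trace <- numeric(total_steps)

  withr::with_seed(seed, {
    for (step in seq_len(total_steps)) {
      states <- draw_states(probs, config$structures_per_step)
      ev <- evaluate(states)
      for (retry in seq_len(config$max_clash_retries)) {
        bad <- which(ev$clash)
        if (!length(bad)) break
        states[bad, ] <- draw_states(probs, length(bad))
        ev <- evaluate(states)
      }
      # archive update (distinct state strings, best archive_size energies)
      keep <- !duplicated(ev$keys)
      cand_keys <- c(archive_keys, ev$keys[keep])
      cand_energy <- c(archive_energy, ev$energy[keep])
      cand_states <- c(archive_states,
                       lapply(which(keep), function(r) states[r, ]))
      dup <- duplicated(cand_keys)
      cand_keys <- cand_keys[!dup]; cand_energy <- cand_energy[!dup]
      cand_states <- cand_states[!dup]
      ord <- order(cand_energy, cand_keys)
      take <- ord[seq_len(min(length(ord), config$archive_size))]
      archive_keys <- cand_keys[take]
      archive_energy <- cand_energy[take]
      archive_states <- cand_states[take]
      prime_trace[step] <- archive_energy[1]
      probs <- update_probabilities(states, ev$energy, probs, config)
    }
  })

  models <- lapply(archive_states, function(st)
    build_conformation(sequence, st, alphabet, ff = ff))
  structure(list(sequence = sequence, environment = environment,
                 models = models, energies = archive_energy,
                 states = do.call(rbind, archive_states),
                 prime = models[[1]], prime_trace = prime_trace,
                 seed = seed, config = config,
                 n_evaluated = total_steps * config$structures_per_step),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat("<model_set> ", x$sequence, " [", x$environment, "]: ",
      length(x$models), " models, prime energy ",
      sprintf("%.2f", x$energies[1]), " kJ/mol\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the model archive
#'
#' @param x A `model_set`.
#' @param ... Unused.
#' @return Tibble with `model`, `energy` (kJ/mol) and the state string.
#' @export
tidy.model_set <- function(x, ...) {
  tibble::tibble(model = seq_along(x$energies), energy = x$energies,
                 states = apply(x$states, 1, paste, collapse = ","))
}

#' One-row summary of a sampling run
#'
#' @param x A `model_set`.
#' @param ... Unused.
#' @return Tibble with the sequence, environment, model count, prime
#'   energy, energy spread and structures evaluated.
#' @export
glance.model_set <- function(x, ...) {
  tibble::tibble(sequence = x$sequence, environment = x$environment,
                 n_models = length(x$models), prime_energy = x$energies[1],
                 energy_range = diff(range(x$energies)),
                 n_evaluated = x$n_evaluated, seed = x$seed)
}

#' Create a persistent sampler energy memo
#'
#' An opaque store of already-evaluated state-string energies for one
#' sequence, shareable across [run_peplook()] calls (results are
#' identical with or without it).  Never share one memo between different
#' sequences.
#'
#' @return An external pointer usable as `memo` in [run_peplook()].
#' @export
peplook_memo <- function() cpp_new_memo()

#' Cluster archived models by all-atom RMSD
#'
#' Single-linkage clustering where two models are linked when their
#' all-atom superposed RMSD is below the threshold (1 A by default, the
#' window-length calibration criterion).
#'
#' @param model_set A `model_set` (all models share one sequence).
#' @param rmsd_threshold Linkage threshold, Angstrom.
#' @return Tibble with `model`, `energy`, `cluster` (1 = the prime's
#'   cluster first by energy), plus attributes `n_clusters` and `sizes`.
#' @export
cluster_models <- function(model_set, rmsd_threshold = 1.0) {
  models <- model_set$models
  seqs <- vapply(models, function(m) m$sequence, character(1))
  if (length(unique(seqs)) != 1L)
    stop("models with mixed sequences cannot be clustered", call. = FALSE)
  n <- length(models)
  if (n == 1L) {
    cl <- 1L
  } else {
    xyz <- lapply(models, coords_matrix)
    dm <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      dm[i, j] <- dm[j, i] <- kabsch_rmsd(xyz[[i]], xyz[[j]])
    hc <- stats::hclust(stats::as.dist(dm), method = "single")
    cl <- stats::cutree(hc, h = rmsd_threshold - 1e-9)
  }
  out <- tibble::tibble(model = seq_len(n), energy = model_set$energies,
                        cluster = as.integer(cl))
  sizes <- table(cl)
  attr(out, "n_clusters") <- length(sizes)
  attr(out, "sizes") <- as.integer(sizes)
  attr(out, "prime_cluster") <- cl[1]
  out
}
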