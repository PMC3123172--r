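test_that("state draws follow the per-position probability law", {
  probs <- matrix(1 / 64, 64, 1)
  withr::with_seed(1, draws <- tmdscan:::draw_states(probs, 1e5)[, 1])
  freq <- tabulate(draws, 64) / 1e5
  # 3 sigma binomial band around 1/64
  sd3 <- 3 * sqrt((1 / 64) * (1 - 1 / 64) / 1e5)
  expect_true(all(abs(freq - 1 / 64) < sd3 + 1e-4))
  conc <- matrix(0.005 / 63, 64, 1); conc[17, 1] <- 0.995
  withr::with_seed(2, draws2 <- tmdscan:::draw_states(conc, 1e4)[, 1])
  expect_gte(mean(draws2 == 17), 0.99)
})

test_that("sample_structure is deterministic under a fixed seed", {
  al5 <- load_alphabet(n_positions = 5)
  withr::with_seed(3, a <- sample_structure("AAAAA", al5, ff = FF))
  withr::with_seed(3, b <- sample_structure("AAAAA", al5, ff = FF))
  expect_identical(a$state_indices, b$state_indices)
  expect_identical(tmdscan:::coords_matrix(a), tmdscan:::coords_matrix(b))
})

test_that("probability updates touch only tier-exclusive couples", {
  cfg <- sampler_config(favorable_fraction = 0.25, unfavorable_fraction = 0.25)
  nstates <- 4L
  probs <- matrix(1 / nstates, nstates, 3)
  # 8 structures over 3 positions; energies rank rows 1..8
  states <- rbind(c(1, 3, 2), c(1, 3, 2), c(2, 3, 2), c(2, 1, 2),
                  c(3, 1, 2), c(3, 2, 2), c(4, 2, 2), c(4, 2, 2))
  energies <- 1:8
  # favorable tier = rows 1,2; unfavorable = rows 7,8
  up <- update_probabilities(states, energies, probs, cfg)
  expect_equal(colSums(up), rep(1, 3), tolerance = 1e-9)
  # position 1: state 1 only favorable (boosted), state 4 only
  # unfavorable (damped), states 2,3 untouched
  expect_gt(up[1, 1], probs[1, 1])
  expect_lt(up[4, 1], probs[4, 1])
  expect_equal(up[2, 1], up[3, 1])
  # position 3: state 2 is in both tiers -> the whole column is unchanged
  expect_equal(up[, 3], probs[, 3])
  # no tier-exclusive couples at all -> exact no-op
  same <- matrix(2L, nrow = 8, ncol = 3)
  expect_equal(update_probabilities(same, energies, probs, cfg), probs)
})

test_that("probability vectors stay valid distributions under repeated updates", {
  cfg <- sampler_config()
  probs <- matrix(1 / 64, 64, 4)
  withr::with_seed(9, {
    for (k in 1:25) {
      states <- matrix(sample.int(64, 200 * 4, TRUE), 200, 4)
      energies <- rnorm(200)
      probs <- update_probabilities(states, energies, probs, cfg)
      expect_equal(colSums(probs), rep(1, 4), tolerance = 1e-9)
      expect_true(all(probs >= cfg$probability_floor - 1e-12))
    }
  })
})

test_that("the archive keeps sorted, distinct, best-energy models", {
  toy <- toy_alphabet()
  cfg <- sampler_config(structures_per_step = 200, total_steps = 10)
  ms <- run_peplook("AAAAA", "hydrophobic", cfg, toy, FF, seed = 1)
  expect_true(all(diff(ms$energies) >= 0))
  expect_lte(length(ms$models), cfg$archive_size)
  keys <- apply(ms$states, 1, paste, collapse = ",")
  expect_false(anyDuplicated(keys) > 0)
  expect_identical(ms$prime, ms$models[[1]])
  # prime energy is non-increasing across steps
  expect_true(all(diff(ms$prime_trace) <= 1e-9))
})

test_that("identical seeds reproduce the whole archive bit for bit", {
  toy <- toy_alphabet()
  cfg <- sampler_config(structures_per_step = 100, total_steps = 8)
  a <- run_peplook("AAAAA", "hydrophobic", cfg, toy, FF, seed = 42)
  b <- run_peplook("AAAAA", "hydrophobic", cfg, toy, FF, seed = 42)
  expect_identical(a$states, b$states)
  expect_identical(a$energies, b$energies)
})

test_that("a shared memo changes nothing but the work done", {
  toy <- toy_alphabet()
  cfg <- sampler_config(structures_per_step = 100, total_steps = 8)
  memo <- peplook_memo()
  a <- run_peplook("AAAAA", "hydrophobic", cfg, toy, FF, seed = 7)
  b <- run_peplook("AAAAA", "hydrophobic", cfg, toy, FF, seed = 7,
                   memo = memo)
  c2 <- run_peplook("AAAAA", "hydrophobic", cfg, toy, FF, seed = 7,
                    memo = memo)
  expect_identical(a$energies, b$energies)
  expect_identical(b$states, c2$states)
  expect_gt(tmdscan:::cpp_memo_size(memo), 0)
})

test_that("the sampler finds the enumerable global minimum on a toy", {
  toy <- toy_alphabet()
  seq5 <- "LALAL"
  sys <- tmdscan:::prepare_system(seq5, FF)
  grid <- as.matrix(expand.grid(rep(list(1:4), 5)))
  all_e <- tmdscan:::system_energies(sys, grid, toy)$energy
  target <- min(all_e)
  ms <- run_peplook(seq5, "hydrophobic",
                    sampler_config(structures_per_step = 500,
                                   total_steps = 25), toy, FF, seed = 11)
  expect_equal(ms$energies[1], target, tolerance = 1e-9)
})

test_that("sequence length limits are enforced", {
  expect_error(run_peplook(strrep("A", 35), "hydrophobic",
                           sampler_config(), AL, FF), "34")
  expect_error(run_peplook("AAAA", "vacuum", sampler_config(), AL, FF))
})

test_that("single-linkage clustering matches a reference implementation", {
  two <- generate_fixture("two_bundle_modelset", length = 9, seed = 2,
                          alphabet = AL, ff = FF)
  cl <- cluster_models(two, rmsd_threshold = 1.0)
  expect_equal(attr(cl, "n_clusters"), 2L)
  expect_equal(sort(as.integer(table(cl$cluster))), c(5L, 5L))
  # 99 copies of one structure collapse to one cluster
  base <- helix_conf("AAAAA")
  copies <- structure(list(sequence = "AAAAA", models = rep(list(base), 20),
                           energies = seq(-20, -1), states = NULL,
                           prime = base, environment = "hydrophobic"),
                      class = "model_set")
  cl1 <- cluster_models(copies)
  expect_equal(attr(cl1, "n_clusters"), 1L)
  # randomized set against an O(n^2) reference single-linkage
  set.seed(5)
  models <- lapply(1:8, function(k) {
    xyz <- tmdscan:::coords_matrix(base) + matrix(rnorm(nrow(base$atoms) * 3,
                                                        0, 0.4), ncol = 3)
    tmdscan:::set_coords(base, xyz)
  })
  ms <- structure(list(sequence = "AAAAA", models = models,
                       energies = 1:8, states = NULL, prime = models[[1]],
                       environment = "hydrophobic"), class = "model_set")
  thr <- 0.8
  cl2 <- cluster_models(ms, thr)
  dm <- matrix(0, 8, 8)
  for (i in 1:7) for (j in (i + 1):8)
    dm[i, j] <- dm[j, i] <- superposed_rmsd(models[[i]], models[[j]])
  # reference: transitive closure of the adjacency below the threshold
  adj <- dm < thr
  ref <- seq_len(8)
  for (rep in 1:8) for (i in 1:8) for (j in 1:8)
    if (adj[i, j]) ref[ref == ref[j]] <- ref[i]
  expect_equal(length(unique(cl2$cluster)), length(unique(ref)))
  same_ours <- outer(cl2$cluster, cl2$cluster, "==")
  same_ref <- outer(ref, ref, "==")
  expect_identical(same_ours, same_ref)
  # mixed sequences are rejected
  ms_bad <- ms
  ms_bad$models[[2]] <- helix_conf("AAAAG")
  expect_error(cluster_models(ms_bad), "mixed")
})

test_that("solvated and membrane environments run through the general path", {
  toy <- toy_alphabet()
  cfg <- sampler_config(structures_per_step = 30, total_steps = 3)
  phil <- run_peplook("AGA", "hydrophilic", cfg, toy, FF, seed = 5)
  expect_lte(length(phil$models), 99L)
  expect_true(all(diff(phil$energies) >= 0))
  phil2 <- run_peplook("AGA", "hydrophilic", cfg, toy, FF, seed = 5)
  expect_identical(phil$energies, phil2$energies)
  memb <- run_peplook("AGA", "membrane", cfg, toy, FF, seed = 5)
  expect_true(is.finite(memb$energies[1]))
  # the two environments rank with different totals
  expect_false(identical(phil$energies[1], memb$energies[1]))
})
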