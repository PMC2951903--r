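test_that("simulated trees are valid, deterministic, binary and rooted", {
  expect_error(simulate_tree(1), "at least 2")
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(ape::Ntip(t2), 2L)
  expect_identical(ape::write.tree(simulate_tree(6, seed = 9)),
                   ape::write.tree(simulate_tree(6, seed = 9)))
  for (s in 1:30) {
    tr <- simulate_tree(8, seed = s)
    expect_equal(ape::Ntip(tr), 8L)
    expect_true(ape::is.rooted(tr))
    expect_true(ape::is.binary(tr))
    expect_equal(anyDuplicated(tr$tip.label), 0L)
  }
})

test_that("loss extremes behave as the model dictates", {
  tr <- simulate_tree(10, seed = 4)
  cfg0 <- simulation_config(seed = 4, n_leaves = 10, n_components = 20,
                            p_loss = 0, gain = "root")
  truth0 <- simulate_dollo_evolution(tr, cfg0)
  expect_true(all(truth0$tip_states == 1L))
  expect_true(all(truth0$gain_edges == "root"))
  cfg1 <- simulation_config(seed = 4, n_leaves = 10, n_components = 20,
                            p_loss = 1, gain = "root")
  truth1 <- simulate_dollo_evolution(tr, cfg1)
  expect_true(all(truth1$tip_states == 0L))
})

test_that("tip presence under root gains matches the closed form", {
  # balanced depth-3 tree: presence probability per tip is (1-p)^3
  tr <- ape::stree(8, type = "balanced")
  p_loss <- 0.2
  n_comp <- 2000
  cfg <- simulation_config(seed = 12, n_leaves = 8, n_components = n_comp,
                           p_loss = p_loss, gain = "root")
  truth <- simulate_dollo_evolution(tr, cfg)
  expected <- (1 - p_loss)^3
  se <- sqrt(expected * (1 - expected) / n_comp)
  freq <- colMeans(truth$tip_states)
  expect_true(all(abs(freq - expected) <= 3 * se + 1e-12))
})

test_that("parsimony never infers more events than the simulation realized", {
  for (s in 1:5) {
    tr <- simulate_tree(12, seed = s)
    cfg <- simulation_config(seed = s, n_leaves = 12, n_components = 40,
                             p_loss = 0.15, gain = "uniform")
    truth <- simulate_dollo_evolution(tr, cfg)
    d <- dollo_reconstruct(tr, truth$tip_states)
    realized <- 1L + lengths(truth$loss_edges)[d$component]
    keep <- !is.na(d$gain_edge)
    expect_true(all(d$cost[keep] <= realized[keep]))
  }
})

test_that("detection noise has the right rates and is coupled in q", {
  states <- matrix(rep(c(0L, 1L), each = 5000), 100)
  obs0 <- apply_detection_noise(states, 0, 0, seed = 3)
  expect_identical(obs0, states)
  obs_all <- apply_detection_noise(states, 1, 0, seed = 3)
  expect_true(all(obs_all[states == 1L] == 0L))
  q <- 0.2; r <- 0.1
  obs <- apply_detection_noise(states, q, r, seed = 3)
  fn <- mean(obs[states == 1L] == 0L)
  fp <- mean(obs[states == 0L] == 1L)
  expect_lt(abs(fn - q), 3 * sqrt(q * (1 - q) / 5000))
  expect_lt(abs(fp - r), 3 * sqrt(r * (1 - r) / 5000))
  # coupling: cells flipped at q = 0.1 are also flipped at q = 0.2
  lo <- apply_detection_noise(states, 0.1, 0, seed = 3)
  hi <- apply_detection_noise(states, 0.2, 0, seed = 3)
  expect_true(all(hi[lo == 0L & states == 1L] == 0L))
})

test_that("synthetic proteomes contain what the truth table says", {
  s <- simulate_seed_alignment("comp", length = 80, seed = 6)
  cfg0 <- simulation_config(seed = 6, substitution = 0, indel_rate = 0,
                            n_random = 5, n_fg = 4, n_wd = 3)
  sim <- simulate_proteome(list(s), cfg0)
  expect_equal(sim$proteome$sequence[sim$proteome$id == "planted_comp"],
               build_profile(s)$consensus)
  fg <- sim$proteome$sequence[sim$truth$class == "fg"]
  for (d in fg) {
    dens <- 2 * lengths(regmatches(d, gregexpr("FG", d))) / nchar(d)
    expect_gte(dens, 0.3)
  }
  expect_equal(sum(sim$truth$class == "wd"), 3L)
  # FASTA round trip
  f <- tempfile(fileext = ".fa")
  write_proteome(sim$proteome, f)
  back <- read_proteome(f, genome = "synthetic")
  expect_identical(back$sequence, sim$proteome$sequence)
  expect_identical(back$id, sim$proteome$id)
})

test_that("noise-free scenarios are perfectly precise and reproducible", {
  cfg <- simulation_config(seed = 8, n_leaves = 12, n_components = 100,
                           p_loss = 0.1, gain = "root", q = 0, r = 0)
  sc <- end_to_end_scenario(cfg)
  expect_equal(sc$scorecard$leca_precision, 1.0)
  sc2 <- end_to_end_scenario(cfg)
  expect_identical(sc$scorecard, sc2$scorecard)
  expect_identical(sc$observed, sc2$observed)
})

test_that("ancestral recall is monotone non-increasing in missed detections", {
  recalls <- vapply(c(0, 0.1, 0.2), function(q) {
    cfg <- simulation_config(seed = 15, n_leaves = 16, n_components = 200,
                             p_loss = 0.1, gain = "root", q = q)
    end_to_end_scenario(cfg)$scorecard$leca_recall
  }, numeric(1))
  expect_true(all(diff(recalls) <= 0))
})

test_that("the sequence-level scenario scores the screen against truth", {
  cfg <- simulation_config(seed = 19, n_leaves = 5, n_components = 4,
                           p_loss = 0.1, gain = "root", q = 0, r = 0,
                           substitution = 0.25, n_random = 6, n_fg = 2,
                           n_wd = 2, seq_length = 80)
  sc <- end_to_end_scenario(cfg, with_sequences = TRUE)
  expect_equal(sc$scorecard$leca_precision, 1.0)
  expect_gte(sc$scorecard$gain_edge_recovery, 0.5)
})
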