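make_bench <- function(seed = 7, n_comp = 3, sub = 0.3) {
  seeds <- lapply(seq_len(n_comp), function(i)
    simulate_seed_alignment(sprintf("comp%d", i), length = 90,
                            seed = seed + i))
  profiles <- lapply(seeds, build_profile)
  cfg <- simulation_config(seed = seed, substitution = sub,
                           n_random = 25, n_fg = 4, n_wd = 4,
                           seq_length = 140)
  sim <- simulate_proteome(seeds, cfg)
  list(seeds = seeds, profiles = profiles, sim = sim)
}

test_that("planted homologs rank first and screens are deterministic", {
  b <- make_bench()
  hits <- screen_proteome(b$profiles, b$sim$proteome, threshold = 20)
  for (i in seq_along(b$profiles)) {
    cn <- b$profiles[[i]]$component
    expect_gt(nrow(hits[[cn]]), 0)
    expect_equal(hits[[cn]]$protein_id[1], paste0("planted_", cn))
  }
  hits2 <- screen_proteome(b$profiles, b$sim$proteome, threshold = 20)
  expect_identical(lapply(hits, `[`, c("protein_id", "score")),
                   lapply(hits2, `[`, c("protein_id", "score")))
  # empty proteome
  empty <- b$sim$proteome[0, , drop = FALSE]
  expect_true(all(vapply(screen_proteome(b$profiles, empty, 20), nrow,
                         0L) == 0L))
})

test_that("raising the threshold never adds accepted calls", {
  b <- make_bench(seed = 11)
  lo <- screen_proteome(b$profiles, b$sim$proteome, threshold = 10)
  hi <- screen_proteome(b$profiles, b$sim$proteome, threshold = 30)
  for (cn in names(lo))
    expect_true(all(hi[[cn]]$protein_id %in% lo[[cn]]$protein_id))
})

test_that("threshold specifications resolve or fail loudly", {
  expect_equal(resolve_threshold(12.5), 12.5)
  expect_equal(resolve_threshold(list(quantile = 0.5, decoys = 1:9)), 5)
  expect_error(resolve_threshold(list(quantile = 0.9)), "unresolvable")
  expect_error(screen_proteome(list(), protein_records("a", "g", "MKL"), 1),
               "at least one profile")
})

test_that("repeat coverage follows its constructive definitions", {
  fg_seq <- "FGFGFGFGFGFG"
  expect_equal(detect_repeat_coverage(list(match_pos = 0:11), fg_seq, "FG"), 1)
  plain <- "AAAAKKKKEEEEDDDD"
  expect_equal(detect_repeat_coverage(list(match_pos = 0:15), plain, "FG"), 0)
  expect_equal(detect_repeat_coverage(list(match_pos = 0:15), plain, "WD"), 0)
  set.seed(3)
  wd <- lecatrace:::random_wd_decoy()
  cov <- detect_repeat_coverage(list(match_pos = 0:(nchar(wd) - 1)), wd, "WD")
  expect_gte(cov, 0.95)
  expect_error(detect_repeat_coverage(list(match_pos = 99L), "MKL", "FG"),
               "outside sequence")
})

test_that("vetting rejects repeat-only similarity and missing motifs", {
  b <- make_bench(seed = 13)
  hits <- screen_proteome(b$profiles, b$sim$proteome, threshold = -1e6)
  dec <- apply_vetting(hits, b$sim$proteome)
  fg_rows <- dec[grepl("^decoy_fg_", dec$protein_id), ]
  expect_true(all(fg_rows$status == "rejected"))
  expect_true(all(fg_rows$reason == "repeat_only_similarity"))
  expect_true(all(fg_rows$repeat_class == "FG"))
  # zero repeat coverage and no motif table: passes vetting
  clean <- dec[grepl("^planted_", dec$protein_id) &
                 dec$component == sub("planted_", "", dec$protein_id), ]
  expect_true(all(clean$status == "accepted"))
  # a configured motif outside the repeat windows rescues a repeat-
  # confined hit; a repeat-only hit without it is still repeat-rejected
  rae <- paste0(strrep("FG", 30), "SIEGR", strrep("FG", 5))
  prot <- protein_records(c("rae_like", "fg_only", "plain_nomotif"), "g",
                          c(rae, strrep("FG", 35), random_aa_seq(70)))
  p <- build_profile(seed_alignment("Rae1", strrep("FG", 35)))
  h <- screen_proteome(p, prot, threshold = -1e6)
  d <- apply_vetting(h, prot, required_motifs = list(Rae1 = "SIEGR"))
  expect_equal(d$status[d$protein_id == "rae_like"], "accepted")
  expect_equal(d$reason[d$protein_id == "fg_only"],
               "repeat_only_similarity")
  # a non-repeat hit lacking the configured motif is motif-rejected
  expect_equal(d$reason[d$protein_id == "plain_nomotif"], "motif_absent")
})

test_that("reciprocal validation passes planted truth and fails decoys", {
  b <- make_bench(seed = 17)
  refs <- protein_records(
    id = sprintf("ref_%s", vapply(b$profiles, `[[`, "", "component")),
    genome = "train",
    sequence = vapply(b$profiles, `[[`, "", "consensus"),
    component = vapply(b$profiles, `[[`, "", "component"))
  # an unrelated reference family that WD decoys resemble
  set.seed(17)
  wd_family <- lecatrace:::random_wd_decoy()
  refs <- rbind(refs, protein_records("ref_wd_family", "train", wd_family,
                                      "beta_propeller_family"))
  class(refs) <- c("protein_records", "data.frame")
  planted <- b$sim$proteome[b$sim$proteome$id == "planted_comp1", ]
  expect_true(reciprocal_validate(planted$sequence, "comp1", refs)$pass)
  # candidate identical to a reference: trivially passes
  expect_true(reciprocal_validate(refs$sequence[2], "comp2", refs)$pass)
  rv <- reciprocal_validate(wd_family, "comp1", refs)
  expect_false(rv$pass)
  expect_equal(rv$best_component, "beta_propeller_family")
  expect_error(reciprocal_validate("MKL", "c", refs[0, ]), "empty")
})

test_that("rescue recovers diverged homologs and is bounded by the screen", {
  s <- simulate_seed_alignment("comp", length = 100, seed = 23)
  p <- build_profile(s)
  cfg <- simulation_config(seed = 23, substitution = 0.45, n_random = 10,
                           n_fg = 0, n_wd = 0, seq_length = 150)
  sim <- simulate_proteome(list(s), cfg)
  planted_score <- screen_proteome(p, sim$proteome, -1e6)[[1]]
  planted_score <- planted_score$score[planted_score$protein_id ==
                                         "planted_comp"]
  primary <- planted_score + 5   # the primary screen misses the homolog
  permissive <- planted_score - 5
  expect_false("planted_comp" %in%
                 screen_proteome(p, sim$proteome, primary)[[1]]$protein_id)
  donors <- s$sequences[1]
  rescued <- rescue_search(p, donors, sim$proteome, permissive)
  expect_true("planted_comp" %in% rescued$protein_id)
  # with the permissive threshold equal to the primary one, rescue output
  # is a subset of the screen output
  res_eq <- rescue_search(p, donors, sim$proteome, primary)
  scr <- screen_proteome(p, sim$proteome, primary)[[1]]
  expect_true(all(res_eq$protein_id %in% scr$protein_id))
  # a target with no homolog yields nothing
  blank <- protein_records("none", "g", random_aa_seq(60))
  expect_equal(nrow(rescue_search(p, donors, blank, permissive,
                                  donor_min_score = 1e6)), 0L)
  expect_error(rescue_search(p, character(0), sim$proteome, 0), "donor")
})

test_that("the concordance report tallies the control set", {
  rep <- concordance_report(load_fixture("tbrucei_table1"))
  expect_equal(rep$n_recovered, 10L)
  expect_equal(rep$n_orthology_established, 10L)
  expect_equal(rep$n_extra_calls, 1L)
  expect_equal(rep$n_unassigned, 13L)
  expect_equal(rep$n_unassigned_fg, 7L)
  expect_equal(rep$n_excluded, 8L)
  expect_equal(rep$n_not_detected, 5L)
  # empty control: all tallies zero
  empty <- control_reference(character(0), logical(0), character(0),
                             logical(0), character(0))
  rep0 <- concordance_report(empty)
  expect_true(all(unlist(rep0[startsWith(names(rep0), "n_")]) == 0L))
  # out-of-universe component labels warn but do not error
  expect_warning(concordance_report(load_fixture("tbrucei_table1"),
                                    component_universe = "Sec13"),
                 "outside the matrix universe")
  # externally supplied statuses override the recorded ones
  ctrl <- load_fixture("tbrucei_table1")
  own <- data.frame(protein_id = ctrl$protein_id[1], status = "identified")
  rep2 <- concordance_report(ctrl, screen_status = own)
  expect_equal(rep2$n_recovered, 1L)
  expect_equal(rep2$n_not_detected, 23L)
})
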