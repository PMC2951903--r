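test_that("the Pom34 mitosis association is perfect and exact", {
  m <- load_fixture("fungi_table4")
  ph <- load_fixture("mitosis_phenotypes")
  a <- mitosis_association(m, ph, "Pom34")
  expect_equal(unname(as.vector(a$table)), c(12L, 0L, 0L, 7L))
  expect_true(a$perfect)
  expect_equal(a$p_value, oracle_exact_pvalue(a$table), tolerance = 1e-12)
  expect_equal(a$p_value,
               fisher.test(a$table)$p.value, tolerance = 1e-9)
  # margins always equal the number of phenotyped genomes
  expect_equal(sum(a$table), 19L)
  # a ubiquitous component shows no association
  b <- mitosis_association(m, ph, "Pom152")
  expect_false(b$perfect)
  expect_equal(sum(b$table["absent", ]), 0L)
  expect_equal(b$p_value, 1)
})

test_that("degenerate phenotype inputs error", {
  m <- load_fixture("fungi_table4")
  ph <- load_fixture("mitosis_phenotypes")
  ph$phenotype[ph$phenotype == "open"] <- "closed"
  expect_error(mitosis_association(m, ph, "Pom34"), "degenerate")
  expect_error(mitosis_association(m, load_fixture("mitosis_phenotypes"),
                                   "NotAComponent"), "unknown component")
})

test_that("exact p-values match the enumeration oracle on random tables", {
  set.seed(55)
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 5), 2)
    if (sum(tab) == 0) next
    expect_equal(exact_table_pvalue(tab), oracle_exact_pvalue(tab),
                 tolerance = 1e-12)
    expect_equal(exact_table_pvalue(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("coatomer supergroup differences match the survey", {
  m <- load_fixture("coatomer_table5")
  tax <- fixture_taxonomy(m)
  rep_grouped <- coatomer_supergroup_differences(
    m, tax, paralog_groups = list(apl = c("apl1", "apl2")))
  expect_equal(nrow(rep_grouped), 2L)
  expect_equal(rep_grouped$absent_from[rep_grouped$component == "sec16"],
               "Amoebozoa")
  expect_equal(rep_grouped$absent_from[rep_grouped$component == "sfb3"],
               "Chromalveolates,Excavates")
  # without the paralog grouping the duplicated adaptin is also flagged
  rep_plain <- coatomer_supergroup_differences(m, tax)
  expect_setequal(rep_plain$component, c("sec16", "sfb3", "apl1"))
  expect_equal(rep_plain$absent_from[rep_plain$component == "apl1"],
               "Amoebozoa,Plantae,Chromalveolates,Excavates")
  expect_error(coatomer_supergroup_differences(
    m, tax, paralog_groups = list(g = c("apl1", "nosuch"))),
    "unknown component")
})

test_that("grouping is anti-monotone: merged units never add absences", {
  set.seed(66)
  for (rep in 1:8) {
    genomes <- sprintf("g%d", 1:8)
    tax <- random_taxonomy(genomes)
    m <- random_presence_matrix(6, genomes, p = 0.5)
    plain <- coatomer_supergroup_differences(m, tax)
    grouped <- coatomer_supergroup_differences(
      m, tax, paralog_groups = list(gr = c("c01", "c02")))
    for (i in seq_len(nrow(grouped))) {
      cn <- grouped$component[i]
      members <- if (cn == "gr") c("c01", "c02") else cn
      absent <- strsplit(grouped$absent_from[i], ",")[[1]]
      for (mem in members) {
        j <- which(plain$component == mem)
        if (!length(j)) {  # all-absent members are vacuous, not reported
          expect_true(all(m$states[mem, ] == 0L))
        } else {
          expect_true(all(absent %in%
                            strsplit(plain$absent_from[j], ",")[[1]]))
        }
      }
    }
  }
})

test_that("study comparison reproduces per-study counts", {
  m <- load_fixture("nup_table2")
  tax <- fixture_taxonomy(m)
  prof <- presence_by_supergroup(m, tax)
  cmp <- study_comparison(list(this_study = prof))
  expect_equal(unname(cmp$counts[, "this_study"]),
               c(31L, 22L, 26L, 25L, 23L))
  cmp2 <- study_comparison(list(a = prof, b = prof))
  expect_equal(cmp2$counts[, "a"], cmp2$counts[, "b"])
  # mismatched component universes warn with the symmetric difference
  prof2 <- prof[-1]
  attr(prof2, "universe") <- attr(prof, "universe")
  expect_warning(study_comparison(list(a = prof, b = prof2)),
                 "component universes differ")
  # synthetic profiles: counts equal a naive recount
  set.seed(88)
  genomes <- sprintf("g%d", 1:9)
  rtax <- random_taxonomy(genomes)
  rm1 <- random_presence_matrix(5, genomes, p = 0.5)
  rprof <- presence_by_supergroup(rm1, rtax)
  rcmp <- study_comparison(list(s = rprof))
  expect_equal(unname(rcmp$counts[, "s"]),
               unname(oracle_supergroup_counts(rm1, rtax)[
                 rownames(rcmp$counts)]))
})

test_that("rendered summaries are deterministic and mark universals", {
  m <- load_fixture("nup_table2")
  tax <- fixture_taxonomy(m)
  leca <- leca_complement(m, tax, "unikont_bikont")
  r1 <- render_summary(m, tax, leca = leca)
  r2 <- render_summary(m, tax, leca = leca)
  expect_identical(r1$text, r2$text)
  expect_equal(sum(r1$table$universal), 19L)
  expect_equal(sum(r1$table$in_leca), 26L)
  expect_true(any(grepl("universal components \\(all supergroups\\): 19",
                        r1$text)))
  # empty matrix renders without error
  f <- tempfile(); writeLines("component\tg1", f)
  m0 <- read_presence_matrix(f)
  tax0 <- taxonomy_map("g1", "cls", "Plantae")
  expect_s3_class(render_summary(m0, tax0), "summary_report")
})
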