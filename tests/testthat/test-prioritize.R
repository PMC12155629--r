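# controlled fixture: an annotated module plus drugs with known targets,
# ATC classes and fingerprints
prio_fixture <- function() {
  g <- molecular_network(data.frame(
    gene_a = c("m1", "m2", "m3", "m4", "x1"),
    gene_b = c("m2", "m3", "m4", "x1", "x2")))
  module <- build_disease_module(g, c("m1", "m2", "m3"))
  gs <- list(angiogenesis = c("m1", "m2", "m3"),
             "inflammatory response" = c("m4"))
  module <- annotate_processes(module, gs,
                               c("angiogenesis", "inflammatory response"))
  catalog <- make_catalog(
    ids = c("DA", "DB", "DC", "DD", "DE"),
    atc = list("C01AA01", "N06AB03", "C01AA09", "A02BC01", "B01AC06"),
    targets = list("m1", "m2", "m1", "m2", "x2"),
    fingerprints = list(1:10, 11:20, 21:30, 31:40, 41:50))
  # DE is proximity-significant but targets no annotated process gene
  screen <- list(drugs = data.frame(
    drug_id = c("DA", "DB", "DC", "DD", "DE"),
    cluster_id = paste0("TC", 1:5),
    d = 0, z = -3, p_normal = c(0.01, 0.02, 0.03, 0.04, 0.01),
    p_empirical = 0.01, stringsAsFactors = FALSE))
  list(module = module, catalog = catalog, screen = screen)
}

test_that("shortlisting requires significance plus an annotated target", {
  fx <- prio_fixture()
  sl <- shortlist_process_drugs(fx$screen, fx$module, fx$catalog)
  expect_setequal(sl$drug_id, c("DA", "DB", "DC", "DD"))
  # DE is significant but hits no process annotation
  expect_false("DE" %in% sl$drug_id)
  expect_identical(sl$hit_processes[[match("DA", sl$drug_id)]],
                   "angiogenesis")
  # a non-significant drug is absent from screen$drugs, hence never listed
  fx2 <- fx
  fx2$screen$drugs <- fx2$screen$drugs[-1, ]
  expect_false("DA" %in% shortlist_process_drugs(fx2$screen, fx2$module,
                                                 fx2$catalog)$drug_id)
})

test_that("candidate pairs demand distinct witnesses, ATC 0 and low Tanimoto", {
  fx <- prio_fixture()
  sl <- shortlist_process_drugs(fx$screen, fx$module, fx$catalog)
  crit <- prioritization_criteria(processes = "angiogenesis")
  profiles <- similarity_profiles(fx$catalog)
  cand <- enumerate_candidate_pairs(sl, crit, profiles, fx$module,
                                    fx$catalog)
  key <- paste(cand$drug_a, cand$drug_b)
  # DA{m1} x DB{m2}: distinct witnesses in one process, ATC 0, low Tanimoto
  expect_true("DA DB" %in% key)
  w <- cand$witnesses[[match("DA DB", key)]]
  expect_identical(w$angiogenesis, c("m1", "m2"))
  # DA and DC target the same single molecule: no m1 != m2 witness
  expect_false("DA DC" %in% key)
  # DB and DD share targets via the same molecule too
  expect_false("DB DD" %in% key)
  # all emitted pairs pass every criterion (self-audit)
  for (i in seq_len(nrow(cand))) {
    expect_identical(cand$atc_sim[[i]], 0)
    expect_lte(cand$structure_sim[[i]], crit$structure_max)
    expect_gt(length(cand$witnesses[[i]]), 0)
  }
})

test_that("same 4th-level ATC class excludes a pair outright", {
  fx <- prio_fixture()
  # give DB the same 4th-level class as DA
  fx$catalog$atc_codes[[2]] <- "C01AA99"
  sl <- shortlist_process_drugs(fx$screen, fx$module, fx$catalog)
  crit <- prioritization_criteria(processes = "angiogenesis")
  profiles <- similarity_profiles(fx$catalog)
  cand <- enumerate_candidate_pairs(sl, crit, profiles, fx$module,
                                    fx$catalog)
  expect_false("DA DB" %in% paste(cand$drug_a, cand$drug_b))
})

test_that("tightening a criterion never enlarges the candidate set", {
  fx <- prio_fixture()
  sl <- shortlist_process_drugs(fx$screen, fx$module, fx$catalog)
  profiles <- similarity_profiles(fx$catalog)
  loose <- enumerate_candidate_pairs(
    sl, prioritization_criteria(structure_max = 0.5,
                                processes = "angiogenesis"),
    profiles, fx$module, fx$catalog)
  tight <- enumerate_candidate_pairs(
    sl, prioritization_criteria(structure_max = 0.0,
                                processes = "angiogenesis"),
    profiles, fx$module, fx$catalog)
  expect_true(all(paste(tight$drug_a, tight$drug_b) %in%
                  paste(loose$drug_a, loose$drug_b)))
})

test_that("cohort-usage annotation tiers pairs and flags co-prescription", {
  fx <- prio_fixture()
  sl <- shortlist_process_drugs(fx$screen, fx$module, fx$catalog)
  crit <- prioritization_criteria(processes = "angiogenesis")
  profiles <- similarity_profiles(fx$catalog)
  cand <- enumerate_candidate_pairs(sl, crit, profiles, fx$module,
                                    fx$catalog)
  # DA and DB prescribed to different patients; DC never prescribed
  rec <- make_records(c("P1", "P2"), c("2001-01-01", "2001-01-01"),
                      c("DA", "DB"))
  out <- annotate_cohort_usage(cand, rec)
  key <- paste(out$drug_a, out$drug_b)
  i_ab <- match("DA DB", key)
  expect_identical(out$cohort_status[[i_ab]], "both_prescribed")
  expect_false(out$ever_coprescribed[[i_ab]])
  # same patient receives both: flag switches on
  rec2 <- make_records(c("P1", "P1"), c("2001-01-01", "2001-01-01"),
                       c("DA", "DB"))
  out2 <- annotate_cohort_usage(cand, rec2)
  expect_true(out2$ever_coprescribed[[match("DA DB",
                                            paste(out2$drug_a,
                                                  out2$drug_b))]])
  # tiers are ordered both > one > none
  tiers <- match(out$cohort_status, c("both_prescribed", "one_prescribed",
                                      "none_prescribed"))
  expect_true(all(diff(tiers) >= 0))
})

test_that("a planted complementary pair is recovered exactly", {
  # two drugs hit distinct module molecules of one process with unrelated
  # ATC classes and dissimilar fingerprints; planted controls violate one
  # criterion each
  fx <- prio_fixture()
  catalog <- make_catalog(
    ids = c("GOOD1", "GOOD2", "SAMEMOL", "SAMEATC", "SIMFP"),
    atc = list("C01AA01", "N06AB03", "L01XX01", "C01AA77", "J01CA01"),
    targets = list("m1", "m2", "m1", "m3", "m3"),
    fingerprints = list(1:10, 11:20, 21:30, 31:40, 1:10))
  screen <- list(drugs = data.frame(
    drug_id = catalog$drug_id, cluster_id = paste0("TC", 1:5),
    d = 0, z = -3, p_normal = 0.01, p_empirical = 0.01,
    stringsAsFactors = FALSE))
  sl <- shortlist_process_drugs(screen, fx$module, catalog)
  crit <- prioritization_criteria(processes = "angiogenesis")
  profiles <- similarity_profiles(catalog)
  cand <- enumerate_candidate_pairs(sl, crit, profiles, fx$module, catalog)
  key <- paste(cand$drug_a, cand$drug_b)
  expect_true("GOOD1 GOOD2" %in% key)
  # controls: SAMEMOL shares GOOD1's only molecule; SAMEATC shares GOOD1's
  # class; SIMFP shares GOOD1's fingerprint (Tanimoto 1)
  expect_false("GOOD1 SAMEMOL" %in% key)
  expect_false("GOOD1 SAMEATC" %in% key)
  expect_false("GOOD1 SIMFP" %in% key)
})
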