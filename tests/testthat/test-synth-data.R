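test_that("background network has the configured size and is connected", {
  cfg <- synth_config(seed = 3, n_genes = 500, ppi_attachment = 3)
  g <- generate_background_network(cfg)
  expect_equal(igraph::vcount(g), 500)
  expect_true(igraph::is_connected(g))
  expect_true(all(igraph::E(g)$weight == 1))  # unweighted convention
  # same config + seed: identical edge lists
  g2 <- generate_background_network(cfg)
  expect_identical(igraph::as_edgelist(g), igraph::as_edgelist(g2))
  # weighted edges fall in [0.5, 1.5]
  gw <- generate_background_network(synth_config(seed = 3,
                                                 weighted_edges = TRUE))
  expect_true(all(igraph::E(gw)$weight >= 0.5 & igraph::E(gw)$weight <= 1.5))
})

test_that("disease signal plants a connected module and a noisy DEG list", {
  cfg <- synth_config(seed = 4)
  g <- generate_background_network(cfg)
  sig <- generate_disease_signal(g, cfg)
  expect_length(sig$planted_module, cfg$module_size)
  sub <- igraph::induced_subgraph(g, sig$planted_module)
  expect_true(igraph::is_connected(sub))
  # DEG split: ceiling(0.8 * 15) = 12 inside, 3 outside
  expect_length(sig$deg_list, cfg$n_degs)
  expect_equal(sum(sig$deg_list %in% sig$planted_module), 12)
  # determinism
  sig2 <- generate_disease_signal(g, cfg)
  expect_identical(sig$deg_list, sig2$deg_list)
})

test_that("drug catalog carries labels, ATC codes and planted duplicates", {
  cfg <- synth_config(seed = 5)
  g <- generate_background_network(cfg)
  sig <- generate_disease_signal(g, cfg)
  cat_ <- generate_drug_catalog(g, sig$planted_module, cfg)
  expect_equal(nrow(cat_), cfg$n_drugs)
  expect_equal(sum(cat_$truth_label == "proximal"),
               round(cfg$frac_proximal_drugs * cfg$n_drugs))
  # every ATC code matches the 7-character pattern
  codes <- unlist(cat_$atc_codes)
  expect_true(all(grepl("^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$", codes)))
  # mechanism genes are supersets of targets
  expect_true(all(mapply(function(t, m) all(t %in% m),
                         cat_$targets, cat_$mechanism_genes)))
  # deliberately identical target sets exist for cluster collapsing
  keys <- vapply(cat_$targets, paste, "", collapse = ";")
  expect_gt(sum(duplicated(keys)), 0)
})

test_that("planted proximal drugs sit closer to the module than background", {
  # simulation check across seeded catalogs on one network
  cfg <- synth_config(seed = 6)
  g <- generate_background_network(cfg)
  sig <- generate_disease_signal(g, cfg)
  dmin <- module_distances(g, sig$planted_module)
  gap <- vapply(1:20, function(s) {
    cfg_s <- synth_config(seed = 100 + s)
    cat_ <- generate_drug_catalog(g, sig$planted_module, cfg_s)
    sc <- vapply(cat_$targets, function(t) mean(dmin[t]), numeric(1))
    mean(sc[cat_$truth_label == "background"]) -
      mean(sc[cat_$truth_label == "proximal"])
  }, numeric(1))
  expect_true(all(gap > 0))
})

test_that("prescriptions respect cohort structure and typo contracts", {
  cfg <- synth_config(seed = 7, n_patients = 60)
  g <- generate_background_network(cfg)
  sig <- generate_disease_signal(g, cfg)
  cat_ <- generate_drug_catalog(g, sig$planted_module, cfg)
  rec <- generate_prescriptions(cat_, cfg)
  expect_equal(length(unique(rec$patient_id)), 60)
  expect_true(all(rec$phase %in% c(1L, 2L)))
  yr <- as.integer(format(rec$visit_date, "%Y"))
  expect_true(all(yr >= 1990 & yr <= 2022))
  expect_true(all(rec$endpoint %in% c("KTx", "HD", "death", "recovery",
                                      "transfer", "lost")))
  # every patient has exactly one endpoint
  per <- tapply(rec$endpoint, rec$patient_id,
                function(e) length(unique(e)))
  expect_true(all(per == 1))
  # typo_rate = 0: every raw name is canonical
  rec0 <- generate_prescriptions(cat_, synth_config(seed = 7, typo_rate = 0))
  expect_true(all(rec0$raw_name %in% cat_$name))
  # determinism
  rec2 <- generate_prescriptions(cat_, cfg)
  expect_identical(rec, rec2)
})

test_that("typos never touch the first character", {
  d <- default_dataset()
  tm <- d$truth$typo_map
  expect_gt(nrow(tm), 0)
  expect_true(all(substr(tm$raw_name, 1, 1) == substr(tm$canonical, 1, 1)))
})

test_that("prevalence spectrum spans the 30% threshold on defaults", {
  d <- default_dataset()
  rec <- d$records
  rec$drug_id <- rec$true_drug_id
  rec1 <- filter_first_phase(rec)
  npat <- length(unique(rec1$patient_id))
  prev <- vapply(unique(rec1$drug_id), function(dd)
    length(unique(rec1$patient_id[rec1$drug_id == dd])) / npat, numeric(1))
  expect_gte(sum(prev > 0.3), 3)
  expect_gte(sum(prev < 0.3), 10)
})

test_that("gene sets include the four process sets overlapping the module", {
  d <- default_dataset()
  gs <- d$genesets
  expect_true(all(pd_process_names() %in% names(gs)))
  for (p in pd_process_names()) {
    expect_gte(length(intersect(gs[[p]], d$planted_module)), 5)
  }
  cfg <- synth_config(seed = 1)
  sizes <- lengths(gs[sprintf("PATHWAY_%03d", seq_len(cfg$n_pathways))])
  expect_true(all(sizes <= cfg$pathway_size_range[2]))
})

test_that("a regenerated dataset is byte-identical on disk", {
  cfg <- synth_config(seed = 11, n_patients = 25, n_drugs = 20,
                      n_genes = 150, module_size = 15, n_degs = 8)
  d1 <- generate_synth_data(cfg)
  d2 <- generate_synth_data(cfg)
  t1 <- withr::local_tempdir()
  t2 <- withr::local_tempdir()
  write_synth_dataset(d1, t1)
  write_synth_dataset(d2, t2)
  for (f in list.files(t1)) {
    b1 <- readBin(file.path(t1, f), "raw", file.info(file.path(t1, f))$size)
    b2 <- readBin(file.path(t2, f), "raw", file.info(file.path(t2, f))$size)
    expect_identical(b1, b2)
  }
  # GMT and catalog round-trip through their readers
  gs <- read_gmt(file.path(t1, "genesets.gmt"))
  expect_identical(lapply(gs, as.character),
                   lapply(d1$genesets, as.character))
  cat_back <- read_drug_catalog(file.path(t1, "drugs.tsv"))
  expect_identical(cat_back$drug_id, d1$catalog$drug_id)
  expect_identical(cat_back$targets, unname(d1$catalog$targets))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(synth_config(n_patients = 0), "positive count")
  expect_error(synth_config(typo_rate = 1.5), "\\[0, 1\\]")
  expect_error(synth_config(module_size = 100, n_genes = 50), "exceeds")
  expect_error(synth_config(pathway_size_range = c(10, 5)), "increasing")
})
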