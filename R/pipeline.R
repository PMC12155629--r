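#' Run the full co-prescription / network-proximity pipeline
#'
#' Drives every stage on one dataset: drug-name harmonization, first-phase
#' cohort construction, patient-time Jaccard pair mining with the
#' three-group classification, endpoint statistics, the five-metric drug
#' similarity profiles, disease-module extraction and process annotation,
#' network-proximity screening of identical-target drug clusters against a
#' degree-matched null, and multi-criteria prioritization of candidate
#' drug combinations. With the default `data = NULL` a synthetic dataset is
#' generated from `cfg`.
#'
#' @param cfg A [synth_config()] used when `data` is `NULL`, and whose
#'   `seed` also seeds the proximity null model.
#' @param data Optional dataset bundle as from [generate_synth_data()]
#'   (fields `network`, `deg_list`, `catalog`, `records`, `genesets`).
#' @param criteria A [prioritization_criteria()].
#' @param null_cfg A [null_model_config()]; defaults to 1000 iterations
#'   seeded from `cfg$seed`.
#' @param threshold Prevalence threshold for the pair-group classification.
#' @param cut_height Tree cut for name harmonization.
#' @param out_dir Optional directory; when given, all stage outputs are
#'   written there as plain-text tables/JSON (deterministically, so two
#'   runs with one seed are byte-identical).
#' @return List of class `copres_pipeline` with elements `harmonization`,
#'   `records` (harmonized, phase-filtered), `pairs`, `summary`,
#'   `endpoint_tests`, `usage_correlation`, `profiles`, `module`,
#'   `clusters`, `screen`, `shortlist`, `candidates`, `funnel` (stage
#'   counts) and `data` (the input bundle).
#' @export
run_pd_pipeline <- function(cfg = synth_config(), data = NULL,
                            criteria = prioritization_criteria(),
                            null_cfg = NULL, threshold = 0.30,
                            cut_height = 0.2, out_dir = NULL) {
  if (is.null(data)) data <- generate_synth_data(cfg)
  if (is.null(null_cfg)) null_cfg <- null_model_config(seed = cfg$seed)

  harm <- harmonize_names(unique(data$records$raw_name), data$catalog,
                          cut_height = cut_height)
  rec <- apply_harmonization(data$records, harm)
  rec1 <- filter_first_phase(rec)

  pairs <- pair_usage(rec1, threshold = threshold)
  summ <- summarize_cohort(rec1)
  etests <- endpoint_comparison(summ)
  ucorr <- correlate_usage(summ)

  universe <- union(igraph::V(data$network)$name,
                    unique(unlist(data$genesets)))
  profiles <- similarity_profiles(data$catalog, data$genesets,
                                  universe = universe)

  module <- build_disease_module(data$network, data$deg_list)
  module <- annotate_processes(module, data$genesets,
                               intersect(pd_process_names(),
                                         names(data$genesets)))

  clusters <- cluster_by_identical_targets(data$catalog)
  screen <- screen_clusters(clusters, data$network, module,
                            cfg = null_cfg, alpha = criteria$alpha)
  shortlist <- shortlist_process_drugs(screen, module, data$catalog,
                                       processes = intersect(
                                         criteria$processes,
                                         names(module$process_annotations)))
  cand <- enumerate_candidate_pairs(shortlist, criteria, profiles,
                                    module, data$catalog)
  cand <- annotate_cohort_usage(cand, rec1)

  funnel <- c(n_drugs = nrow(data$catalog),
              n_clusters = nrow(screen$results),
              n_significant_clusters = sum(screen$results$significant),
              n_significant_drugs = nrow(screen$drugs),
              n_process_shortlist = nrow(shortlist),
              n_candidate_pairs = nrow(cand))

  out <- structure(list(harmonization = harm, records = rec1,
                        pairs = pairs, summary = summ,
                        endpoint_tests = etests,
                        usage_correlation = ucorr, profiles = profiles,
                        module = module, clusters = clusters,
                        screen = screen, shortlist = shortlist,
                        candidates = cand, funnel = funnel,
                        criteria = criteria, data = data),
                   class = "copres_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' @export
print.copres_pipeline <- function(x, ...) {
  cat("Co-prescription / network-proximity pipeline\n")
  cat("  patients:", nrow(x$summary$patients),
      " records:", nrow(x$records), "\n")
  grp <- table(factor(x$pairs$group, c("both", "one", "neither")))
  cat("  drug pairs:", nrow(x$pairs),
      sprintf("(both %d / one %d / neither %d)", grp[1], grp[2], grp[3]), "\n")
  cat("  module:", length(x$module$nodes), "genes;",
      sum(x$screen$results$significant), "of",
      nrow(x$screen$results), "target clusters proximity-significant\n")
  cat("  candidate combinations:", nrow(x$candidates), "\n")
  invisible(x)
}

#' Write every pipeline stage output to a directory
#'
#' Emits `harmonization_report.tsv`, `harmonized.tsv`, `pair_usage.tsv`,
#' `cohort_summary.tsv`, `endpoint_tests.json`, `similarity_profiles.tsv`,
#' `module_nodes.txt`, `module_annotations.tsv`, `module_report.json`,
#' `proximity_results.tsv`, `candidate_pairs.tsv` and
#' `prioritization_report.json`. All writers are deterministic.
#'
#' @param pipeline A `copres_pipeline` from [run_pd_pipeline()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(pipeline, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- pipeline
  num <- function(x) ifelse(is.na(x), "NA", sprintf("%.10g", x))

  write_tsv(data.frame(raw_name = p$harmonization$raw_name,
                       method = p$harmonization$method,
                       assigned = ifelse(is.na(p$harmonization$drug_id), "",
                                         p$harmonization$drug_id),
                       jw = num(p$harmonization$jw_to_canonical),
                       stringsAsFactors = FALSE),
            file.path(dir, "harmonization_report.tsv"))
  write_tsv(data.frame(patient_id = p$records$patient_id,
                       visit_date = format(p$records$visit_date),
                       drug_id = p$records$drug_id,
                       raw_name = p$records$raw_name,
                       phase = p$records$phase,
                       endpoint = p$records$endpoint,
                       stringsAsFactors = FALSE),
            file.path(dir, "harmonized.tsv"))
  pu <- p$pairs
  pu$jaccard <- num(pu$jaccard)
  pu$prevalence_a <- num(pu$prevalence_a)
  pu$prevalence_b <- num(pu$prevalence_b)
  write_tsv(pu, file.path(dir, "pair_usage.tsv"))
  cs <- p$summary$patients
  for (v in c("mean_drugs_per_point", "time_on_pd_months",
              "mean_gap_months")) cs[[v]] <- num(cs[[v]])
  write_tsv(cs, file.path(dir, "cohort_summary.tsv"))
  jsonlite::write_json(p$endpoint_tests,
                       file.path(dir, "endpoint_tests.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  pr <- p$profiles
  for (v in c("mechanism_sim", "target_sim", "pathway_sim",
              "structure_sim", "atc_sim")) pr[[v]] <- num(pr[[v]])
  write_tsv(pr, file.path(dir, "similarity_profiles.tsv"))
  writeLines(p$module$nodes, file.path(dir, "module_nodes.txt"))
  ann <- p$module$process_annotations
  write_tsv(data.frame(
    process = rep(names(ann), lengths(ann)),
    gene = unlist(ann, use.names = FALSE),
    stringsAsFactors = FALSE), file.path(dir, "module_annotations.tsv"))
  jsonlite::write_json(list(
    n_nodes = length(p$module$nodes),
    n_degs_in_module = p$module$n_degs_in_module,
    n_components_discarded = p$module$n_components_discarded,
    discarded_sizes = p$module$discarded_sizes),
    file.path(dir, "module_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  rs <- p$screen$results
  for (v in c("d", "null_mean", "null_sd", "z", "p_normal",
              "p_empirical")) rs[[v]] <- num(rs[[v]])
  write_tsv(rs, file.path(dir, "proximity_results.tsv"))
  cp <- p$candidates
  flat <- data.frame(drug_a = cp$drug_a, drug_b = cp$drug_b,
                     shared_processes = vapply(cp$shared_processes, paste,
                                               character(1), collapse = ";"),
                     witnesses = vapply(cp$witnesses, function(w)
                       paste(vapply(names(w), function(nm)
                         paste0(nm, ":", w[[nm]][1], "|", w[[nm]][2]),
                         character(1)), collapse = ";"), character(1)),
                     atc_sim = num(cp$atc_sim),
                     structure_sim = num(cp$structure_sim),
                     cohort_status = cp$cohort_status,
                     ever_coprescribed = cp$ever_coprescribed,
                     stringsAsFactors = FALSE)
  write_tsv(flat, file.path(dir, "candidate_pairs.tsv"))
  jsonlite::write_json(list(
    criteria = unclass(p$criteria),
    funnel = as.list(p$funnel)),
    file.path(dir, "prioritization_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
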