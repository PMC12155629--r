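#' Restrict records to each patient's first treatment phase
#'
#' Patients can have several dialysis phases (e.g. a second phase after a
#' failed transplant); only phase-1 records enter the analysis cohort.
#'
#' @param records Harmonized prescription records with a `phase` column.
#' @return Phase-1 records; the `"n_patients_dropped"` attribute counts
#'   patients with no phase-1 record.
#' @export
filter_first_phase <- function(records) {
  stopifnot("phase" %in% names(records))
  keep <- records$phase == 1L
  dropped <- setdiff(unique(records$patient_id),
                     unique(records$patient_id[keep]))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_patients_dropped") <- length(dropped)
  out
}

#' Assign a patient to the decade holding most prescription events
#'
#' Decades are 1: 1990-1999, 2: 2000-2009, 3: 2010-2022. Ties go to the
#' earlier decade.
#'
#' @param dates Vector of the patient's prescription-event dates.
#' @return Integer decade in `{1, 2, 3}`.
#' @export
assign_decade <- function(dates) {
  dates <- as.Date(dates)
  if (length(dates) == 0L) stop("need at least one prescription event")
  yr <- as.integer(format(dates, "%Y"))
  if (any(yr < 1990L | yr > 2022L)) {
    stop("prescription dates outside 1990-2022")
  }
  dec <- ifelse(yr < 2000L, 1L, ifelse(yr < 2010L, 2L, 3L))
  counts <- tabulate(dec, nbins = 3L)
  which.max(counts)  # which.max takes the first (earlier) maximum
}

# (patient, visit-date) occurrence sets per drug, the unit of the
# co-prescription Jaccard
.pt_sets <- function(records) {
  key <- paste(records$patient_id, records$visit_date, sep = "\r")
  split(key, records$drug_id)
}

#' Patient-time co-prescription Jaccard of two drugs
#'
#' `J = |S_A \cap S_B| / |S_A \cup S_B|` where `S_X` is the set of
#' (patient, visit-date) pairs at which drug X was prescribed; 1 means the
#' two drugs were always prescribed together.
#'
#' @param drug_a,drug_b Drug ids.
#' @param records Harmonized prescription records (`patient_id`,
#'   `visit_date`, `drug_id`).
#' @return Jaccard coefficient in `[0, 1]`; `NA` when both occurrence sets
#'   are empty.
#' @export
copres_jaccard <- function(drug_a, drug_b, records) {
  known <- unique(records$drug_id)
  if (!drug_a %in% known) stop("unknown drug id: ", drug_a)
  if (!drug_b %in% known) stop("unknown drug id: ", drug_b)
  sets <- .pt_sets(records)
  sa <- unique(sets[[drug_a]])
  sb <- unique(sets[[drug_b]])
  if (length(sa) == 0L && length(sb) == 0L) return(NA_real_)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

#' Patient prevalence of a drug
#'
#' Fraction of analysis-cohort patients with at least one record of the
#' drug.
#'
#' @param drug Drug id.
#' @param records Harmonized prescription records.
#' @return Fraction in `[0, 1]`.
#' @export
prescription_prevalence <- function(drug, records) {
  patients <- unique(records$patient_id)
  if (length(patients) == 0L) stop("no patients in records")
  length(unique(records$patient_id[records$drug_id == drug])) /
    length(patients)
}

#' Enumerate co-prescribed drug pairs with Jaccard and prevalence groups
#'
#' Builds the pair table of the co-prescription analysis: for every drug
#' pair co-prescribed at least once at the same patient visit (or the full
#' cross-product with `all_pairs = TRUE`), the patient-time Jaccard, both
#' patient prevalences, the number of patients ever holding both drugs, and
#' the three-way pattern group: `both` when both prevalences strictly
#' exceed `threshold`, `one` when exactly one does, `neither` otherwise.
#'
#' @param records Harmonized, phase-filtered prescription records.
#' @param threshold Prevalence threshold (default 0.30, strict inequality).
#' @param all_pairs Enumerate all drug pairs instead of only same-visit
#'   co-prescribed ones.
#' @return Data frame with columns `drug_a`, `drug_b` (a < b), `jaccard`,
#'   `prevalence_a`, `prevalence_b`, `n_patients_both`, `group`.
#' @export
pair_usage <- function(records, threshold = 0.30, all_pairs = FALSE) {
  sets <- lapply(.pt_sets(records), unique)
  drugs <- sort(names(sets))
  n_pat <- length(unique(records$patient_id))
  prev <- vapply(drugs, function(d) {
    length(unique(records$patient_id[records$drug_id == d])) / n_pat
  }, numeric(1))
  pat_of <- lapply(drugs, function(d) unique(records$patient_id[records$drug_id == d]))
  names(pat_of) <- drugs

  if (all_pairs) {
    if (length(drugs) < 2L) return(.empty_pair_usage())
    cmb <- utils::combn(drugs, 2L)
    pairs <- data.frame(drug_a = cmb[1, ], drug_b = cmb[2, ],
                        stringsAsFactors = FALSE)
  } else {
    # pairs sharing >= 1 same patient-visit occurrence
    key <- paste(records$patient_id, records$visit_date, sep = "\r")
    seen <- new.env(parent = emptyenv())
    for (vd in split(records$drug_id, key)) {
      vd <- sort(unique(vd))
      if (length(vd) < 2L) next
      cmb <- utils::combn(vd, 2L)
      for (j in seq_len(ncol(cmb))) {
        assign(paste(cmb[1, j], cmb[2, j], sep = "\r"), TRUE, envir = seen)
      }
    }
    ks <- ls(seen)
    if (length(ks) == 0L) return(.empty_pair_usage())
    sp <- strsplit(ks, "\r", fixed = TRUE)
    pairs <- data.frame(drug_a = vapply(sp, `[`, character(1), 1L),
                        drug_b = vapply(sp, `[`, character(1), 2L),
                        stringsAsFactors = FALSE)
  }
  pairs <- pairs[order(pairs$drug_a, pairs$drug_b), , drop = FALSE]
  jc <- numeric(nrow(pairs))
  npb <- integer(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    sa <- sets[[pairs$drug_a[[i]]]]
    sb <- sets[[pairs$drug_b[[i]]]]
    co <- length(intersect(sa, sb))
    jc[[i]] <- co / (length(sa) + length(sb) - co)
    npb[[i]] <- length(intersect(pat_of[[pairs$drug_a[[i]]]],
                                 pat_of[[pairs$drug_b[[i]]]]))
  }
  pairs$jaccard <- jc
  pairs$prevalence_a <- unname(prev[pairs$drug_a])
  pairs$prevalence_b <- unname(prev[pairs$drug_b])
  pairs$n_patients_both <- npb
  pairs$group <- classify_pair_groups(pairs$prevalence_a, pairs$prevalence_b,
                                      threshold)
  rownames(pairs) <- NULL
  pairs
}

.empty_pair_usage <- function() {
  data.frame(drug_a = character(0), drug_b = character(0),
             jaccard = numeric(0), prevalence_a = numeric(0),
             prevalence_b = numeric(0), n_patients_both = integer(0),
             group = character(0), stringsAsFactors = FALSE)
}

#' Three-way co-prescription pattern classification
#'
#' @param prevalence_a,prevalence_b Patient prevalences of the two drugs.
#' @param threshold Prevalence threshold; comparison is strict (`>`).
#' @return Character vector: `"both"`, `"one"` or `"neither"`; the three
#'   groups partition all pairs.
#' @export
classify_pair_groups <- function(prevalence_a, prevalence_b,
                                 threshold = 0.30) {
  hi_a <- prevalence_a > threshold
  hi_b <- prevalence_b > threshold
  ifelse(hi_a & hi_b, "both", ifelse(hi_a | hi_b, "one", "neither"))
}

#' Per-patient and cohort-level longitudinal summaries
#'
#' Per patient: number of prescription points (distinct visit dates),
#' number of unique drugs, mean drugs per point, time on dialysis (months
#' between first and last visit; days / 30.4375), mean inter-visit gap in
#' months (`NA` for single-visit patients), and decade assignment.
#'
#' @param records Harmonized, phase-filtered prescription records.
#' @return List of class `cohort_summary`: `patients` (one row each) and
#'   `cohort` (means and min-max ranges over patients).
#' @export
summarize_cohort <- function(records) {
  per <- split(records, records$patient_id)
  rows <- lapply(per, function(r) {
    dates <- sort(unique(r$visit_date))
    drugs_per <- vapply(split(r$drug_id, as.character(r$visit_date)),
                        function(d) length(unique(d)), numeric(1))
    span_days <- as.numeric(max(dates) - min(dates))
    gaps <- if (length(dates) > 1L) diff(as.numeric(dates)) else NA_real_
    data.frame(patient_id = r$patient_id[[1]],
               endpoint = r$endpoint[[1]],
               n_prescription_points = length(dates),
               n_unique_drugs = length(unique(r$drug_id)),
               mean_drugs_per_point = mean(drugs_per),
               time_on_pd_months = span_days / 30.4375,
               mean_gap_months = mean(gaps) / 30.4375,
               decade = assign_decade(dates),
               stringsAsFactors = FALSE)
  })
  patients <- do.call(rbind, rows)
  rownames(patients) <- NULL
  num <- c("n_prescription_points", "n_unique_drugs", "mean_drugs_per_point",
           "time_on_pd_months", "mean_gap_months")
  cohort <- lapply(num, function(v) {
    x <- patients[[v]]
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(list(mean = NA_real_, min = NA_real_,
                                     max = NA_real_))
    list(mean = mean(x), min = min(x), max = max(x))
  })
  names(cohort) <- num
  structure(list(patients = patients, cohort = cohort),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort of", nrow(x$patients), "patients\n")
  for (v in names(x$cohort)) {
    s <- x$cohort[[v]]
    cat(sprintf("  %-24s mean %.2f [%.2f-%.2f]\n", v, s$mean, s$min, s$max))
  }
  invisible(x)
}

#' Compare dialysis duration and drug usage across endpoint groups
#'
#' Kruskal-Wallis test of time on dialysis and of the number of unique
#' drugs across the endpoint groups, followed by pairwise two-sided
#' rank-sum tests with Benjamini-Hochberg adjustment and a rank-biserial
#' effect size (`2U/(n1 n2) - 1`) per pair.
#'
#' @param summaries A `cohort_summary` from [summarize_cohort()].
#' @param endpoints Endpoint labels to compare (default KTx, HD, death).
#' @return List with one element per outcome variable, each holding the
#'   Kruskal-Wallis statistic/p and a pairwise table.
#' @export
endpoint_comparison <- function(summaries,
                                endpoints = c("KTx", "HD", "death")) {
  pts <- summaries$patients
  pts <- pts[pts$endpoint %in% endpoints, , drop = FALSE]
  sizes <- table(pts$endpoint)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("excluding endpoint group(s) with < 2 patients: ",
            paste(small, collapse = ", "))
    pts <- pts[!pts$endpoint %in% small, , drop = FALSE]
  }
  if (length(unique(pts$endpoint)) < 2L) {
    stop("need at least two endpoint groups with >= 2 patients")
  }
  out <- list()
  for (v in c("time_on_pd_months", "n_unique_drugs")) {
    kw <- stats::kruskal.test(pts[[v]], factor(pts$endpoint))
    grp <- sort(unique(pts$endpoint))
    cmb <- utils::combn(grp, 2L)
    pw <- lapply(seq_len(ncol(cmb)), function(j) {
      a <- pts[[v]][pts$endpoint == cmb[1, j]]
      b <- pts[[v]][pts$endpoint == cmb[2, j]]
      wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL))
      u <- unname(wt$statistic)
      data.frame(group_a = cmb[1, j], group_b = cmb[2, j],
                 p = wt$p.value,
                 rank_biserial = 2 * u / (length(a) * length(b)) - 1,
                 stringsAsFactors = FALSE)
    })
    pw <- do.call(rbind, pw)
    pw$p_adj <- stats::p.adjust(pw$p, method = "BH")
    out[[v]] <- list(kruskal_H = unname(kw$statistic),
                     kruskal_p = kw$p.value,
                     pairwise = pw)
  }
  out
}

#' Correlation between prescription points and drug count
#'
#' Spearman rank correlation, across patients, between the number of
#' prescription points and the number of unique drugs prescribed.
#'
#' @param summaries A `cohort_summary`.
#' @return List with `rho`, `p` and `n`. Constant input yields `NA` with a
#'   warning.
#' @export
correlate_usage <- function(summaries) {
  pts <- summaries$patients
  if (nrow(pts) < 3L) stop("need at least 3 patients")
  x <- pts$n_prescription_points
  y <- pts$n_unique_drugs
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warning("constant input; correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = nrow(pts)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(pts))
}
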