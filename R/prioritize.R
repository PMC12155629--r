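#' Criteria for drug-combination prioritization
#'
#' Bundles the four filters a candidate combination must pass: a
#' significant network proximity for both drugs (`alpha`), an ATC
#' similarity of exactly `atc_required` (0: no shared 4th-level class), a
#' structural Tanimoto similarity at most `structure_max`, and target
#' membership in at least one of the configured biological-process
#' annotations of the disease module.
#'
#' @param alpha Proximity significance level (default 0.05).
#' @param atc_required Required ATC similarity, exactly (default 0).
#' @param structure_max Tanimoto ceiling for "low structural similarity"
#'   (default 0.3).
#' @param processes Process names screened (default the four GO processes
#'   of [pd_process_names()]).
#' @return A list of class `prioritization_criteria`.
#' @export
prioritization_criteria <- function(alpha = 0.05, atc_required = 0,
                                    structure_max = 0.3,
                                    processes = pd_process_names()) {
  stopifnot(alpha > 0, alpha < 1,
            structure_max >= 0, structure_max <= 1,
            length(processes) >= 1L)
  structure(list(alpha = alpha, atc_required = atc_required,
                 structure_max = structure_max,
                 processes = as.character(processes)),
            class = "prioritization_criteria")
}

#' Shortlist proximity-significant drugs hitting annotated processes
#'
#' Keeps drugs whose target cluster passed the proximity screen and that
#' have at least one direct target inside at least one of the module's
#' process annotations; each drug is tagged with its hit processes.
#'
#' @param screen Output of [screen_clusters()].
#' @param module An annotated `disease_module` (see [annotate_processes()]).
#' @param catalog Drug catalog data frame.
#' @param processes Process names to consider (default: all annotated).
#' @return Data frame with columns `drug_id`, `cluster_id`, `d`, `z`,
#'   `p_normal`, `p_empirical`, `hit_processes` (list column).
#' @export
shortlist_process_drugs <- function(screen, module, catalog,
                                    processes = names(module$process_annotations)) {
  stopifnot(inherits(module, "disease_module"))
  ann <- module$process_annotations[processes]
  if (length(ann) == 0L) stop("module has no process annotations")
  drugs <- screen$drugs
  if (nrow(drugs) == 0L) return(cbind(drugs, hit_processes = list()))
  keep <- logical(nrow(drugs))
  hits <- vector("list", nrow(drugs))
  for (i in seq_len(nrow(drugs))) {
    tg <- catalog$targets[[match(drugs$drug_id[[i]], catalog$drug_id)]]
    hp <- names(ann)[vapply(ann, function(g) any(tg %in% g), logical(1))]
    hits[[i]] <- hp
    keep[[i]] <- length(hp) > 0L
  }
  out <- drugs[keep, , drop = FALSE]
  out$hit_processes <- hits[keep]
  rownames(out) <- NULL
  out
}

#' Enumerate candidate drug combinations under the prioritization criteria
#'
#' Emits a pair (a, b) of shortlisted drugs iff: (1) both passed the
#' proximity screen and hit an annotated process; (2) some shared process P
#' has distinct witness molecules `m1 != m2` with `m1` a target of a and
#' `m2` a target of b, both inside the annotation of P; (3) their ATC
#' similarity equals `criteria$atc_required` exactly; (4) their structural
#' similarity is at most `criteria$structure_max`. Witnesses are recorded
#' per shared process.
#'
#' @param shortlist Output of [shortlist_process_drugs()].
#' @param criteria A [prioritization_criteria()].
#' @param profiles Similarity-profile table covering every shortlist pair
#'   (a missing row is a hard error).
#' @param module Annotated `disease_module`.
#' @param catalog Drug catalog data frame.
#' @return Data frame of class `candidate_pairs`: `drug_a`, `drug_b`,
#'   `shared_processes` (list), `witnesses` (list of per-process witness
#'   pairs), `atc_sim`, `structure_sim`, `p_combined` (product of the two
#'   drugs' filter p values, used only for ordering).
#' @export
enumerate_candidate_pairs <- function(shortlist, criteria, profiles,
                                      module, catalog) {
  stopifnot(inherits(criteria, "prioritization_criteria"),
            inherits(module, "disease_module"))
  ann <- module$process_annotations[criteria$processes]
  ids <- sort(unique(shortlist$drug_id))
  out <- list()
  if (length(ids) >= 2L) {
    key <- paste(profiles$drug_a, profiles$drug_b, sep = "\r")
    cmb <- utils::combn(ids, 2L)
    for (j in seq_len(ncol(cmb))) {
      a <- cmb[1, j]
      b <- cmb[2, j]
      row <- match(paste(a, b, sep = "\r"), key)
      if (is.na(row)) row <- match(paste(b, a, sep = "\r"), key)
      if (is.na(row)) stop("similarity profile missing for pair ", a, "-", b)
      atc <- profiles$atc_sim[[row]]
      str <- profiles$structure_sim[[row]]
      if (is.na(atc) || atc != criteria$atc_required) next
      if (is.na(str) || str > criteria$structure_max) next
      ta <- catalog$targets[[match(a, catalog$drug_id)]]
      tb <- catalog$targets[[match(b, catalog$drug_id)]]
      wit <- list()
      for (p in names(ann)) {
        ma <- intersect(ta, ann[[p]])
        mb <- intersect(tb, ann[[p]])
        ok <- length(ma) > 0L && length(mb) > 0L &&
          (length(union(ma, mb)) > 1L)
        if (ok) {
          # deterministic distinct witness pair (m1 in targets(a), m2 in
          # targets(b), m1 != m2, both in the process annotation)
          m1 <- min(ma)
          m2 <- min(mb)
          if (m1 == m2) {
            rest_b <- setdiff(mb, m2)
            if (length(rest_b)) m2 <- min(rest_b)
            else m1 <- min(setdiff(ma, m1))
          }
          wit[[p]] <- c(m1, m2)
        }
      }
      if (length(wit) == 0L) next
      pa <- shortlist$p_normal[match(a, shortlist$drug_id)]
      pb <- shortlist$p_normal[match(b, shortlist$drug_id)]
      out[[length(out) + 1L]] <- list(drug_a = a, drug_b = b,
                                      shared_processes = names(wit),
                                      witnesses = wit,
                                      atc_sim = atc, structure_sim = str,
                                      p_combined = pa * pb)
    }
  }
  if (length(out) == 0L) {
    res <- data.frame(drug_a = character(0), drug_b = character(0),
                      atc_sim = numeric(0), structure_sim = numeric(0),
                      p_combined = numeric(0), stringsAsFactors = FALSE)
    res$shared_processes <- list()
    res$witnesses <- list()
  } else {
    res <- data.frame(
      drug_a = vapply(out, `[[`, character(1), "drug_a"),
      drug_b = vapply(out, `[[`, character(1), "drug_b"),
      atc_sim = vapply(out, `[[`, numeric(1), "atc_sim"),
      structure_sim = vapply(out, `[[`, numeric(1), "structure_sim"),
      p_combined = vapply(out, `[[`, numeric(1), "p_combined"),
      stringsAsFactors = FALSE)
    res$shared_processes <- lapply(out, `[[`, "shared_processes")
    res$witnesses <- lapply(out, `[[`, "witnesses")
  }
  attr(res, "criteria") <- criteria
  class(res) <- c("candidate_pairs", class(res))
  res
}

#' Annotate candidate pairs with cohort usage
#'
#' Marks each pair by whether both, one or neither drug appears in the
#' harmonized cohort records, and whether the two drugs were ever
#' prescribed to the same patient. Output is sorted both-prescribed first,
#' then one, then none; within a tier by ascending combined p, then
#' ascending structural similarity.
#'
#' @param pairs Output of [enumerate_candidate_pairs()].
#' @param records Harmonized prescription records.
#' @return The pairs with `cohort_status` and `ever_coprescribed` columns,
#'   sorted by prioritization tier.
#' @export
annotate_cohort_usage <- function(pairs, records) {
  in_cohort <- unique(records$drug_id)
  pat_of <- lapply(split(records$patient_id, records$drug_id), unique)
  status <- character(nrow(pairs))
  ever <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a_in <- pairs$drug_a[[i]] %in% in_cohort
    b_in <- pairs$drug_b[[i]] %in% in_cohort
    status[[i]] <- if (a_in && b_in) "both_prescribed"
                   else if (a_in || b_in) "one_prescribed"
                   else "none_prescribed"
    ever[[i]] <- a_in && b_in &&
      length(intersect(pat_of[[pairs$drug_a[[i]]]],
                       pat_of[[pairs$drug_b[[i]]]])) > 0L
  }
  pairs$cohort_status <- status
  pairs$ever_coprescribed <- ever
  tier <- match(status, c("both_prescribed", "one_prescribed",
                          "none_prescribed"))
  ord <- order(tier, pairs$p_combined, pairs$structure_sim,
               pairs$drug_a, pairs$drug_b)
  out <- pairs[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
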