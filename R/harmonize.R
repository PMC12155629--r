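#' Normalize a raw drug-name string
#'
#' Case-folds to upper case, trims, collapses internal whitespace, and
#' strips a trailing dosage suffix (e.g. `" 40 MG"`). Applied to both raw
#' and catalog names before exact matching and string clustering.
#'
#' @param x Character vector of names.
#' @param dosage_regex Regular expression for a removable dosage suffix.
#' @return Normalized character vector.
#' @export
normalize_drug_name <- function(x,
    dosage_regex = "\\s+[0-9]+([.,][0-9]+)?\\s*(MG|MCG|G|ML|IU|%)\\.?$") {
  x <- toupper(trimws(as.character(x)))
  x <- gsub("\\s+", " ", x)
  gsub(dosage_regex, "", x)
}

#' Exact matching of raw names against the drug catalog
#'
#' A raw name matches exactly when its normalized form equals the
#' normalized name of a catalog entry that carries at least one ATC code
#' (entries without ATC codes are not considered identified drugs and never
#' match).
#'
#' @param raw_names Character vector of distinct raw names.
#' @param catalog Drug catalog data frame (`drug_id`, `name`, `atc_codes`).
#' @param dosage_regex Passed to [normalize_drug_name()].
#' @return List with `matched` (named character vector raw name ->
#'   `drug_id`) and `unmatched` (character vector of raw names).
#' @export
match_exact <- function(raw_names, catalog,
                        dosage_regex = formals(normalize_drug_name)$dosage_regex) {
  raw_names <- unique(as.character(raw_names))
  has_atc <- lengths(catalog$atc_codes) > 0L
  cnorm <- normalize_drug_name(catalog$name, dosage_regex)
  if (anyDuplicated(cnorm)) {
    stop("catalog names are not unique after normalization")
  }
  rnorm <- normalize_drug_name(raw_names, dosage_regex)
  idx <- match(rnorm, cnorm)
  ok <- !is.na(idx) & has_atc[ifelse(is.na(idx), 1L, idx)]
  matched <- stats::setNames(catalog$drug_id[idx[ok]], raw_names[ok])
  list(matched = matched, unmatched = raw_names[!ok])
}

#' Cluster unmatched names with catalog names by Jaro-Winkler distance
#'
#' Pairwise distance `1 - jaro_winkler` over the union of unmatched and
#' catalog names, agglomerated with Ward linkage and cut at `cut_height` on
#' a height axis rescaled to the dendrogram maximum (Ward merge costs grow
#' with cluster size, so raw cophenetic heights are not on the `[0, 1]`
#' distance scale; the cut is read as a fraction of the tree height). Ward
#' linkage on this non-Euclidean dissimilarity is a deliberate heuristic.
#' Within each cluster, every unmatched name is assigned to the cluster's
#' catalog name with the highest Jaro-Winkler similarity to it; clusters
#' containing no catalog name stay unresolved (the place for a
#' manual-review overrides file).
#'
#' @param unmatched Character vector of raw names that failed exact match.
#' @param catalog Drug catalog data frame.
#' @param cut_height Tree cut height on the dendrogram (default 0.2).
#' @param dosage_regex Passed to [normalize_drug_name()].
#' @return Data frame with one row per unmatched name: `raw_name`,
#'   `cluster_id`, `method` (`"clustered"` or `"unresolved"`), `drug_id`
#'   (`NA` when unresolved), `jw_to_canonical`.
#' @export
cluster_unmatched <- function(unmatched, catalog, cut_height = 0.2,
                              dosage_regex = formals(normalize_drug_name)$dosage_regex) {
  unmatched <- unique(as.character(unmatched))
  if (length(unmatched) == 0L) {
    return(data.frame(raw_name = character(0), cluster_id = integer(0),
                      method = character(0), drug_id = character(0),
                      jw_to_canonical = numeric(0), stringsAsFactors = FALSE))
  }
  cnorm <- normalize_drug_name(catalog$name, dosage_regex)
  unorm <- normalize_drug_name(unmatched, dosage_regex)
  all_names <- c(unorm, cnorm)
  is_catalog <- c(rep(FALSE, length(unorm)), rep(TRUE, length(cnorm)))
  if (length(all_names) < 2L) stop("need at least 2 names to cluster")

  m <- length(all_names)
  dm <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) {
    js <- (i + 1L):m
    dm[i, js] <- dm[js, i] <- 1 - jaro_winkler(rep(all_names[[i]],
                                                   length(js)),
                                               all_names[js])
  }
  tree <- stats::hclust(stats::as.dist(dm), method = "ward.D")
  hmax <- max(tree$height)
  cl <- if (hmax <= 0) rep(1L, m) else
    stats::cutree(tree, h = cut_height * hmax)

  out <- data.frame(raw_name = unmatched, cluster_id = cl[seq_along(unorm)],
                    method = "unresolved", drug_id = NA_character_,
                    jw_to_canonical = NA_real_, stringsAsFactors = FALSE)
  for (r in seq_along(unorm)) {
    mates <- which(is_catalog & cl == cl[[r]])
    if (length(mates) == 0L) next
    jw <- jaro_winkler(rep(unorm[[r]], length(mates)), all_names[mates])
    best <- mates[which.max(jw)]
    out$method[[r]] <- "clustered"
    out$drug_id[[r]] <- catalog$drug_id[[best - length(unorm)]]
    out$jw_to_canonical[[r]] <- max(jw)
  }
  out
}

#' Harmonize raw drug names against a catalog
#'
#' Two-stage pipeline: exact matching on normalized names (stage 1), then
#' Jaro-Winkler Ward clustering of the residue with the catalog names
#' (stage 2). Optional overrides (the reproducible form of a manual-review
#' step) take precedence over the clustering assignment.
#'
#' @param raw_names Character vector of raw names (duplicates allowed).
#' @param catalog Drug catalog data frame.
#' @param cut_height Tree cut for the clustering stage (default 0.2).
#' @param overrides Optional named character vector raw name -> `drug_id`.
#' @return Object of class `harmonization_result`: data frame with one row
#'   per distinct raw name and columns `raw_name`, `method` (`exact`,
#'   `clustered`, `override`, `unresolved`), `drug_id`, `cluster_id`,
#'   `jw_to_canonical`.
#' @export
harmonize_names <- function(raw_names, catalog, cut_height = 0.2,
                            overrides = NULL) {
  ex <- match_exact(raw_names, catalog)
  res_ex <- data.frame(raw_name = if (length(ex$matched))
                         names(ex$matched) else character(0),
                       method = rep("exact", length(ex$matched)),
                       drug_id = as.character(unname(ex$matched)),
                       cluster_id = rep(NA_integer_, length(ex$matched)),
                       jw_to_canonical = rep(1, length(ex$matched)),
                       stringsAsFactors = FALSE)
  res_cl <- cluster_unmatched(ex$unmatched, catalog, cut_height)
  res_cl <- data.frame(raw_name = res_cl$raw_name, method = res_cl$method,
                       drug_id = res_cl$drug_id,
                       cluster_id = res_cl$cluster_id,
                       jw_to_canonical = res_cl$jw_to_canonical,
                       stringsAsFactors = FALSE)
  out <- rbind(res_ex, res_cl)
  if (!is.null(overrides) && length(overrides)) {
    if (!all(overrides %in% catalog$drug_id)) {
      stop("override points at unknown drug_id")
    }
    hit <- out$raw_name %in% names(overrides)
    out$drug_id[hit] <- unname(overrides[out$raw_name[hit]])
    out$method[hit] <- "override"
    extra <- setdiff(names(overrides), out$raw_name)
    if (length(extra)) {
      out <- rbind(out, data.frame(raw_name = extra, method = "override",
                                   drug_id = unname(overrides[extra]),
                                   cluster_id = NA_integer_,
                                   jw_to_canonical = NA_real_,
                                   stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$raw_name), ]
  rownames(out) <- NULL
  class(out) <- c("harmonization_result", class(out))
  out
}

#' Apply a harmonization result to prescription records
#'
#' Attaches the harmonized `drug_id` to every record; records whose raw
#' name stayed unresolved are excluded and counted in the
#' `"n_unresolved_records"` attribute of the result.
#'
#' @param records Prescription-record data frame (needs `raw_name`).
#' @param result A `harmonization_result` from [harmonize_names()].
#' @return The records with a `drug_id` column, unresolved rows removed.
#' @export
apply_harmonization <- function(records, result) {
  idx <- match(records$raw_name, result$raw_name)
  if (anyNA(idx)) stop("records contain raw names absent from the result")
  records$drug_id <- result$drug_id[idx]
  records$harmonize_method <- result$method[idx]
  keep <- !is.na(records$drug_id)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unresolved_records") <- sum(!keep)
  out
}
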