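#' Jaccard coefficient of two sets
#'
#' `|A ∩ B| / |A ∪ B|` — also known as the Tanimoto coefficient when
#' applied to fingerprint bit sets. 1 means identical nonempty sets, 0
#' means disjoint sets.
#'
#' @param a,b Vectors treated as sets.
#' @return Jaccard coefficient in `[0, 1]`, or `NA` when both sets are
#'   empty (undefined).
#' @export
jaccard_sets <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0L && length(b) == 0L) return(NA_real_)
  length(intersect(a, b)) / length(union(a, b))
}

#' Hypergeometric pathway over-representation of a drug-target set
#'
#' One-sided hypergeometric test of each pathway's overlap with the
#' target set against the gene universe. A pathway counts as enriched when
#' the overlap holds at least `min_overlap` target genes AND the
#' Benjamini-Hochberg adjusted p (across all pathways tested for this
#' target set) is below `alpha`.
#'
#' @param targets Character vector of target genes.
#' @param genesets Named list of pathway gene sets.
#' @param universe Character vector: the gene universe; pathways and
#'   targets are intersected with it before testing.
#' @param min_overlap Minimum target-pathway overlap (default 3).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Character vector of enriched pathway names; the full test table
#'   is attached as the `"table"` attribute.
#' @export
enrich_pathways <- function(targets, genesets, universe, min_overlap = 3L,
                            alpha = 0.05) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  targets <- intersect(unique(as.character(targets)), universe)
  sets <- lapply(genesets, function(s) intersect(unique(s), universe))
  n_univ <- length(universe)
  n_tg <- length(targets)
  tab <- data.frame(pathway = names(sets),
                    size = lengths(sets),
                    overlap = vapply(sets, function(s)
                      length(intersect(s, targets)), integer(1)),
                    stringsAsFactors = FALSE)
  # P(X >= overlap), X ~ Hypergeometric(universe, pathway, draws = targets)
  tab$p <- stats::phyper(tab$overlap - 1L, tab$size, n_univ - tab$size,
                         n_tg, lower.tail = FALSE)
  tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
  tab$enriched <- tab$overlap >= min_overlap & tab$p_adj < alpha
  rownames(tab) <- NULL
  out <- tab$pathway[tab$enriched]
  attr(out, "table") <- tab
  out
}

#' Five-metric similarity profile of a drug pair
#'
#' Jaccard similarities of: mechanism gene sets; direct-target sets;
#' enriched-pathway sets (hypergeometric enrichment of each drug's targets,
#' see [enrich_pathways()]); fingerprint bit sets (= Tanimoto structural
#' similarity); and 4th-level ATC classes (the 5-character code prefixes,
#' per the WHO level convention 1/3/4/5/7 characters for levels 1-5).
#'
#' @param a,b Single-row slices of a drug catalog (or lists with the same
#'   fields).
#' @param genesets Pathway gene sets for the pathway metric.
#' @param universe Gene universe for enrichment.
#' @param enriched_a,enriched_b Optional precomputed enriched-pathway sets
#'   (to avoid recomputing enrichment per pair).
#' @return One-row data frame: `drug_a`, `drug_b`, `mechanism_sim`,
#'   `target_sim`, `pathway_sim`, `structure_sim`, `atc_sim` (each in
#'   `[0, 1]` or `NA` when undefined).
#' @export
profile_pair <- function(a, b, genesets = NULL, universe = NULL,
                         enriched_a = NULL, enriched_b = NULL) {
  field <- function(x, f) {
    v <- x[[f]]
    if (is.list(v) && length(v) == 1L) v <- v[[1]]
    v
  }
  if (is.null(enriched_a)) {
    enriched_a <- if (is.null(genesets)) character(0) else
      enrich_pathways(field(a, "targets"), genesets, universe)
  }
  if (is.null(enriched_b)) {
    enriched_b <- if (is.null(genesets)) character(0) else
      enrich_pathways(field(b, "targets"), genesets, universe)
  }
  atc4 <- function(x) unique(substr(field(x, "atc_codes"), 1L, 5L))
  data.frame(
    drug_a = field(a, "drug_id"), drug_b = field(b, "drug_id"),
    mechanism_sim = jaccard_sets(field(a, "mechanism_genes"),
                                 field(b, "mechanism_genes")),
    target_sim = jaccard_sets(field(a, "targets"), field(b, "targets")),
    pathway_sim = jaccard_sets(as.character(enriched_a),
                               as.character(enriched_b)),
    structure_sim = jaccard_sets(field(a, "fingerprint_bits"),
                                 field(b, "fingerprint_bits")),
    atc_sim = jaccard_sets(atc4(a), atc4(b)),
    stringsAsFactors = FALSE)
}

#' Similarity profiles for a set of drug pairs
#'
#' Computes [profile_pair()] over the requested pairs (default: all pairs
#' of catalog drugs), caching each drug's pathway enrichment.
#'
#' @param catalog Drug catalog data frame.
#' @param genesets Pathway gene sets.
#' @param universe Gene universe for enrichment (default: union of geneset
#'   genes).
#' @param pairs Optional data frame with columns `drug_a`, `drug_b`
#'   restricting the computation.
#' @return Data frame of similarity profiles, one row per pair, ordered by
#'   (`drug_a`, `drug_b`).
#' @export
similarity_profiles <- function(catalog, genesets = NULL, universe = NULL,
                                pairs = NULL) {
  if (is.null(universe) && !is.null(genesets)) {
    universe <- unique(unlist(genesets))
  }
  if (is.null(pairs)) {
    ids <- sort(catalog$drug_id)
    if (length(ids) < 2L) stop("need at least two drugs")
    cmb <- utils::combn(ids, 2L)
    pairs <- data.frame(drug_a = cmb[1, ], drug_b = cmb[2, ],
                        stringsAsFactors = FALSE)
  }
  idx <- match(unique(c(pairs$drug_a, pairs$drug_b)), catalog$drug_id)
  if (anyNA(idx)) stop("pairs reference drugs absent from the catalog")
  enr <- new.env(parent = emptyenv())
  get_enr <- function(i) {
    key <- catalog$drug_id[[i]]
    if (!exists(key, envir = enr)) {
      val <- if (is.null(genesets)) character(0) else
        enrich_pathways(catalog$targets[[i]], genesets, universe)
      assign(key, as.character(val), envir = enr)
    }
    get(key, envir = enr)
  }
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    ia <- match(pairs$drug_a[[r]], catalog$drug_id)
    ib <- match(pairs$drug_b[[r]], catalog$drug_id)
    profile_pair(catalog[ia, ], catalog[ib, ],
                 enriched_a = get_enr(ia), enriched_b = get_enr(ib))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$drug_a, out$drug_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two similarity metrics
#'
#' Pairwise-complete Pearson correlation over a similarity-profile table,
#' e.g. structural vs ATC similarity or pathway vs mechanism similarity.
#'
#' @param profiles Output of [similarity_profiles()].
#' @param metric_x,metric_y Column names of the two metrics.
#' @return List with `r`, `p` and `n_pairs_used`. Constant metrics give
#'   `NA` with a warning.
#' @export
correlate_metrics <- function(profiles, metric_x, metric_y) {
  x <- profiles[[metric_x]]
  y <- profiles[[metric_y]]
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3L) stop("need at least 3 pairs with both metrics defined")
  x <- x[ok]
  y <- y[ok]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warning("constant metric; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n_pairs_used = sum(ok)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_pairs_used = sum(ok))
}
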