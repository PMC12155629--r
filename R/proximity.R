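#' Collapse a drug catalog into identical-target clusters
#'
#' Drugs sharing an exactly identical direct-target set are redundant for
#' network screening and are collapsed into one cluster, scored once.
#' Grouping by target-set equality is provably the same partition as the
#' connected components of the thresholded (similarity == 1) target-Jaccard
#' adjacency, since set equality is transitive.
#'
#' @param catalog Drug catalog data frame with `drug_id` and list column
#'   `targets`.
#' @return A data frame of class `drug_target_clusters` with columns
#'   `cluster_id`, `member_drug_ids` (list), `targets` (list),
#'   `n_members`; drugs with empty target sets are excluded and listed in
#'   the `"excluded_drugs"` attribute.
#' @export
cluster_by_identical_targets <- function(catalog) {
  stopifnot(all(c("drug_id", "targets") %in% names(catalog)))
  tsets <- lapply(catalog$targets, function(t) sort(unique(as.character(t))))
  empty <- lengths(tsets) == 0L
  keys <- vapply(tsets, paste, character(1), collapse = "\r")
  keep <- which(!empty)
  grp <- split(keep, keys[keep])
  grp <- grp[order(vapply(grp, function(i) min(catalog$drug_id[i]),
                          character(1)))]
  out <- data.frame(
    cluster_id = sprintf("TC%03d", seq_along(grp)),
    n_members = lengths(grp),
    stringsAsFactors = FALSE
  )
  out$member_drug_ids <- lapply(grp, function(i) sort(catalog$drug_id[i]))
  out$targets <- lapply(grp, function(i) tsets[[i[[1]]]])
  attr(out, "excluded_drugs") <- sort(catalog$drug_id[empty])
  class(out) <- c("drug_target_clusters", class(out))
  rownames(out) <- NULL
  out
}

#' Minimum distance from every network node to a disease module
#'
#' Precomputes `min_m dist(v, m)` for all nodes `v`, the quantity the
#' proximity score and its null model are built from. Weighted shortest
#' paths are used when the network carries non-unit edge weights, hop counts
#' otherwise.
#'
#' @param network An `igraph` network.
#' @param module Character vector of module node names (must map into the
#'   network).
#' @return Named numeric vector over all network nodes; `Inf` marks nodes
#'   with no path to the module.
#' @export
module_distances <- function(network, module) {
  module <- intersect(as.character(module), igraph::V(network)$name)
  if (length(module) == 0L) stop("module does not map onto the network")
  w <- igraph::E(network)$weight
  if (is.null(w) || all(w == 1)) w <- NA  # hop counts
  d <- igraph::distances(network, v = module, weights = w)
  out <- apply(d, 2, min)
  names(out) <- colnames(d)
  out
}

#' Network proximity of a drug-target set to the disease module
#'
#' The "closest" proximity measure of network medicine: the mean, over the
#' drug's mapped and reachable targets, of the shortest-path distance to the
#' nearest module node. A score of 0 means every usable target lies inside
#' the module.
#'
#' @param network An `igraph` network.
#' @param targets Character vector of target gene symbols.
#' @param module Character vector of module node names.
#' @param dmin Optional precomputed [module_distances()] vector (pass it when
#'   scoring many sets against one module).
#' @return List with `d` (score), `n_targets_used`, `n_targets_unreachable`,
#'   `n_targets_unmapped`. `d` is `NA` (flagged via the counts) when no
#'   target is usable.
#' @export
proximity_score <- function(network, targets, module, dmin = NULL) {
  if (is.null(dmin)) dmin <- module_distances(network, module)
  targets <- unique(as.character(targets))
  if (length(targets) == 0L) stop("empty target set")
  mapped <- targets[targets %in% names(dmin)]
  dd <- dmin[mapped]
  usable <- dd[is.finite(dd)]
  list(
    d = if (length(usable)) mean(usable) else NA_real_,
    n_targets_used = length(usable),
    n_targets_unreachable = sum(!is.finite(dd)),
    n_targets_unmapped = length(targets) - length(mapped)
  )
}

#' Null-model configuration for proximity screening
#'
#' @param n_iter Number of degree-matched random target sets per cluster
#'   (default 1000).
#' @param min_bin_occupancy Minimum node count per log2-degree bin before
#'   sparse bins are merged upward (default 20).
#' @param seed Integer seed; the null is fully determined by it.
#' @return A list of class `null_model_config`.
#' @export
null_model_config <- function(n_iter = 1000L, min_bin_occupancy = 20L,
                              seed = 1L) {
  stopifnot(n_iter >= 100L, min_bin_occupancy >= 2L,
            is.numeric(seed), length(seed) == 1L)
  structure(list(n_iter = as.integer(n_iter),
                 min_bin_occupancy = as.integer(min_bin_occupancy),
                 seed = as.integer(seed)),
            class = "null_model_config")
}

#' Log2 degree bins with upward merging
#'
#' Bins network nodes by `floor(log2(degree))`; bins holding fewer than
#' `min_occupancy` nodes are merged into the next higher bin (the top bin
#' merges downward). Used for degree-preserving randomization.
#'
#' @param network An `igraph` network.
#' @param min_occupancy Minimum nodes per bin.
#' @return List with `bin_of` (integer bin index per node, named) and
#'   `members` (list of node-name vectors per bin).
#' @export
degree_bins <- function(network, min_occupancy = 20L) {
  deg <- igraph::degree(network)
  raw <- floor(log2(pmax(deg, 1)))
  lev <- sort(unique(raw))
  counts <- vapply(lev, function(l) sum(raw == l), integer(1))
  # merge sparse bins upward; a sparse top bin joins the one below it
  groups <- as.list(seq_along(lev))
  repeat {
    sums <- vapply(groups, function(ix) sum(counts[ix]), integer(1))
    if (length(groups) == 1L || all(sums >= min_occupancy)) break
    j <- which(sums < min_occupancy)[1L]
    tgt <- if (j < length(groups)) j + 1L else j - 1L
    groups[[tgt]] <- sort(c(groups[[tgt]], groups[[j]]))
    groups[[j]] <- NULL
  }
  grp_of_lev <- integer(length(lev))
  for (b in seq_along(groups)) grp_of_lev[groups[[b]]] <- b
  bin_of <- grp_of_lev[match(raw, lev)]
  names(bin_of) <- names(deg)
  members <- lapply(seq_along(groups), function(b) names(deg)[bin_of == b])
  list(bin_of = bin_of, members = members)
}

#' Sample the degree-preserving null distribution of proximity scores
#'
#' Each iteration replaces every real target by a uniform draw from its
#' log2-degree bin, enforcing distinct nodes within the set, and scores the
#' random set against the module. Only the drug side is randomized; the
#' module is held fixed.
#'
#' @param network An `igraph` network.
#' @param targets Character vector: the real target set the null is matched
#'   to (only targets that map into the network contribute).
#' @param module Character vector of module node names.
#' @param cfg A [null_model_config()].
#' @param dmin Optional precomputed [module_distances()] vector.
#' @param bins Optional precomputed [degree_bins()] result.
#' @return Numeric vector of `cfg$n_iter` null proximity scores.
#' @export
sample_null <- function(network, targets, module, cfg = null_model_config(),
                        dmin = NULL, bins = NULL) {
  if (is.null(dmin)) dmin <- module_distances(network, module)
  if (is.null(bins)) bins <- degree_bins(network, cfg$min_bin_occupancy)
  targets <- unique(as.character(targets))
  targets <- targets[targets %in% names(bins$bin_of)]
  k <- length(targets)
  if (k < 1L) stop("no target maps into the network")
  if (k > length(bins$bin_of)) stop("target set larger than the network")
  tbin <- bins$bin_of[targets]
  set.seed(cfg$seed)
  n <- cfg$n_iter
  # column j holds draws for target j across all iterations
  draws <- matrix(NA_character_, nrow = n, ncol = k)
  for (j in seq_len(k)) {
    pool <- bins$members[[tbin[[j]]]]
    draws[, j] <- pool[sample.int(length(pool), n, replace = TRUE)]
  }
  if (k > 1L) {
    bad <- which(apply(draws, 1L, anyDuplicated) > 0L)
    guard <- 0L
    while (length(bad) && guard < 50L) {
      for (j in seq_len(k)) {
        pool <- bins$members[[tbin[[j]]]]
        draws[bad, j] <- pool[sample.int(length(pool), length(bad),
                                         replace = TRUE)]
      }
      bad <- bad[apply(draws[bad, , drop = FALSE], 1L, anyDuplicated) > 0L]
      guard <- guard + 1L
    }
    if (length(bad)) {
      # tiny bins can make distinct degree-matched draws impossible;
      # fall back to distinct draws from the pooled bins for those rows
      pool <- unique(unlist(bins$members[unique(tbin)]))
      for (r in bad) draws[r, ] <- sample(pool, k)
    }
  }
  vals <- matrix(dmin[draws], nrow = n, ncol = k)
  vals[!is.finite(vals)] <- NA
  rowMeans(vals, na.rm = TRUE)
}

#' Proximity significance against a null distribution
#'
#' One-tailed test on the "closer than random" side: `z = (d - mu) / sigma`
#' with `mu`, `sigma` the mean and (population) standard deviation of the
#' null distribution; `p_normal` is the lower normal tail of `z`;
#' `p_empirical = (1 + #\{null <= d\}) / (n + 1)`.
#'
#' @param d Observed proximity score.
#' @param null_scores Numeric vector of null scores (length >= 100).
#' @return List with `z`, `p_normal`, `p_empirical`, `null_mean`, `null_sd`.
#'   Degenerate nulls (zero spread) yield `NA` for `z`/`p_normal`; the
#'   empirical p is always defined.
#' @export
significance <- function(d, null_scores) {
  null_scores <- null_scores[is.finite(null_scores)]
  if (length(null_scores) < 100L) stop("need at least 100 null scores")
  mu <- mean(null_scores)
  sigma <- sqrt(mean((null_scores - mu)^2))
  p_emp <- (1 + sum(null_scores <= d)) / (length(null_scores) + 1)
  if (sigma == 0) {
    return(list(z = NA_real_, p_normal = NA_real_, p_empirical = p_emp,
                null_mean = mu, null_sd = sigma))
  }
  z <- (d - mu) / sigma
  list(z = z, p_normal = stats::pnorm(z), p_empirical = p_emp,
       null_mean = mu, null_sd = sigma)
}

#' Screen all drug-target clusters against the disease module
#'
#' Scores every cluster's proximity, samples its degree-matched null, and
#' filters at `p < alpha` with no multiple-testing correction. Retained
#' clusters are expanded back to their member drugs.
#'
#' @param clusters Output of [cluster_by_identical_targets()].
#' @param network An `igraph` network.
#' @param module A `disease_module` or character vector of module nodes.
#' @param cfg A [null_model_config()]; per-cluster null seeds are derived
#'   from `cfg$seed`.
#' @param alpha Significance level (default 0.05).
#' @param p_type Which p value the filter uses: `"normal"` (default) or
#'   `"empirical"`.
#' @return List with `results` (one row per cluster: score, null moments, z,
#'   both p values, target counts, `significant` flag), `drugs` (per-drug
#'   expansion of significant clusters) and `dmin` (the module distance
#'   profile, reusable downstream).
#' @export
screen_clusters <- function(clusters, network, module,
                            cfg = null_model_config(), alpha = 0.05,
                            p_type = c("normal", "empirical")) {
  p_type <- match.arg(p_type)
  nodes <- if (inherits(module, "disease_module")) module$nodes else module
  dmin <- module_distances(network, nodes)
  bins <- degree_bins(network, cfg$min_bin_occupancy)
  res <- vector("list", nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    tg <- clusters$targets[[i]]
    sc <- proximity_score(network, tg, nodes, dmin = dmin)
    icfg <- cfg
    icfg$seed <- (cfg$seed + 7L * i) %% .Machine$integer.max
    row <- data.frame(cluster_id = clusters$cluster_id[[i]],
                      n_members = clusters$n_members[[i]],
                      d = sc$d, null_mean = NA_real_, null_sd = NA_real_,
                      z = NA_real_, p_normal = NA_real_,
                      p_empirical = NA_real_,
                      n_targets_used = sc$n_targets_used,
                      n_targets_unreachable = sc$n_targets_unreachable,
                      n_targets_unmapped = sc$n_targets_unmapped,
                      stringsAsFactors = FALSE)
    if (!is.na(sc$d)) {
      nul <- sample_null(network, tg, nodes, icfg, dmin = dmin, bins = bins)
      sig <- significance(sc$d, nul)
      row$null_mean <- sig$null_mean
      row$null_sd <- sig$null_sd
      row$z <- sig$z
      row$p_normal <- sig$p_normal
      row$p_empirical <- sig$p_empirical
    }
    res[[i]] <- row
  }
  results <- do.call(rbind, res)
  pcol <- if (p_type == "normal") results$p_normal else results$p_empirical
  results$significant <- !is.na(pcol) & pcol < alpha
  sig_idx <- which(results$significant)
  drugs <- data.frame(drug_id = character(0), cluster_id = character(0),
                      d = numeric(0), z = numeric(0), p_normal = numeric(0),
                      p_empirical = numeric(0), stringsAsFactors = FALSE)
  if (length(sig_idx)) {
    drugs <- do.call(rbind, lapply(sig_idx, function(i) {
      data.frame(drug_id = clusters$member_drug_ids[[i]],
                 cluster_id = results$cluster_id[[i]],
                 d = results$d[[i]], z = results$z[[i]],
                 p_normal = results$p_normal[[i]],
                 p_empirical = results$p_empirical[[i]],
                 stringsAsFactors = FALSE)
    }))
    drugs <- drugs[order(drugs$drug_id), , drop = FALSE]
    rownames(drugs) <- NULL
  }
  list(results = results, drugs = drugs, dmin = dmin,
       alpha = alpha, p_type = p_type)
}
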