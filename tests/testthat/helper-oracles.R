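# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Floyd-Warshall all-pairs shortest paths on a weighted edge list
fw_distances <- function(nodes, edges) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (r in seq_len(nrow(edges))) {
    i <- match(edges$gene_a[[r]], nodes)
    j <- match(edges$gene_b[[r]], nodes)
    w <- edges$weight[[r]]
    d[i, j] <- min(d[i, j], w)
    d[j, i] <- min(d[j, i], w)
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      dik <- d[i, k]
      if (is.finite(dik)) {
        d[i, ] <- pmin(d[i, ], dik + d[k, ])
      }
    }
  }
  d
}

# brute-force closest-distance proximity via Floyd-Warshall
fw_proximity <- function(nodes, edges, targets, module) {
  d <- fw_distances(nodes, edges)
  targets <- intersect(targets, nodes)
  dd <- apply(d[targets, module, drop = FALSE], 1, min)
  mean(dd[is.finite(dd)])
}

# exact two-sided rank-sum p by enumerating all group assignments
exact_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  ranks <- rank(pooled)
  n1 <- length(a)
  w_obs <- sum(ranks[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  w_all <- apply(combos, 2, function(ix) sum(ranks[ix]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu))
}

# exhaustive hypergeometric upper tail: P(|draw of k from universe| has
# >= x hits in the pathway), enumerated over all C(N, k) draws
exact_hyper_tail <- function(x, pathway_size, universe_size, k) {
  draws <- utils::combn(universe_size, k)
  hits <- apply(draws, 2, function(ix) sum(ix <= pathway_size))
  mean(hits >= x)
}

# a tiny random weighted-graph generator for oracle comparisons
random_small_graph <- function(n, p_edge = 0.35, weighted = TRUE) {
  nodes <- sprintf("N%02d", seq_len(n))
  cmb <- utils::combn(nodes, 2L)
  keep <- stats::runif(ncol(cmb)) < p_edge
  # make sure the graph has at least a spanning path so it is connected
  path <- cbind(nodes[-n], nodes[-1])
  ea <- c(cmb[1, keep], path[, 1])
  eb <- c(cmb[2, keep], path[, 2])
  key <- paste(pmin(ea, eb), pmax(ea, eb))
  dup <- duplicated(key)
  edges <- data.frame(gene_a = ea[!dup], gene_b = eb[!dup],
                      weight = if (weighted)
                        round(stats::runif(sum(!dup), 0.5, 2), 3)
                      else rep(1, sum(!dup)),
                      stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges,
       graph = molecular_network(edges))
}

# small drug catalog fixture with fully controlled fields
make_catalog <- function(ids, names = NULL, atc = NULL, targets = NULL,
                         mechanism = NULL, fingerprints = NULL) {
  n <- length(ids)
  if (is.null(names)) names <- paste0("DRUG", seq_len(n))
  df <- data.frame(drug_id = ids, name = names, stringsAsFactors = FALSE)
  df$atc_codes <- if (is.null(atc)) rep(list("A01AA01"), n) else atc
  df$targets <- if (is.null(targets)) rep(list(character(0)), n) else targets
  df$mechanism_genes <- if (is.null(mechanism)) df$targets else mechanism
  df$fingerprint_bits <- if (is.null(fingerprints))
    rep(list(integer(0)), n) else fingerprints
  df
}

# prescription-record fixture
make_records <- function(patient_id, visit_date, drug_id,
                         phase = 1L, endpoint = "KTx") {
  data.frame(patient_id = patient_id,
             visit_date = as.Date(visit_date),
             drug_id = drug_id,
             raw_name = drug_id,
             phase = phase,
             endpoint = endpoint,
             stringsAsFactors = FALSE)
}
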