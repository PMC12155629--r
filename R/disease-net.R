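#' Load a molecular interaction network from an edge-list file
#'
#' Reads a 2- or 3-column TSV (`gene_a`, `gene_b`, optional `weight`) into an
#' undirected [igraph::igraph] graph. Self-loops are dropped; duplicate edges
#' (in either orientation) are collapsed keeping the maximum weight; a
#' 2-column file yields unit weights.
#'
#' @param path Path to the edge-list TSV (with a header row).
#' @return An undirected simple `igraph` graph with an edge attribute
#'   `weight` (> 0) and, in attributes `n_self_loops` / `n_duplicates` of the
#'   graph, counts of dropped rows.
#' @export
load_network <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 2L) stop("edge list needs at least two columns")
  a <- trimws(as.character(df[[1]]))
  b <- trimws(as.character(df[[2]]))
  w <- if (ncol(df) >= 3L) as.numeric(df[[3]]) else rep(1, length(a))
  if (anyNA(a) || anyNA(b) || any(!nzchar(a)) || any(!nzchar(b))) {
    stop("malformed edge rows: empty or missing gene symbols")
  }
  if (anyNA(w) || any(w <= 0)) stop("edge weights must be positive")
  molecular_network(data.frame(gene_a = a, gene_b = b, weight = w,
                               stringsAsFactors = FALSE))
}

#' Build a molecular network from an edge data frame
#'
#' @param edges Data frame with columns `gene_a`, `gene_b` and optionally
#'   `weight`.
#' @return An undirected simple weighted `igraph` graph; see [load_network()].
#' @export
molecular_network <- function(edges) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(edges)))
  if (is.null(edges$weight)) edges$weight <- 1
  self <- edges$gene_a == edges$gene_b
  # canonical orientation so A-B and B-A collapse together
  lo <- pmin(edges$gene_a, edges$gene_b)
  hi <- pmax(edges$gene_a, edges$gene_b)
  key <- paste(lo, hi, sep = "\r")
  keep <- !self
  agg <- tapply(edges$weight[keep], key[keep], max)
  pairs <- strsplit(names(agg), "\r", fixed = TRUE)
  el <- cbind(vapply(pairs, `[`, character(1), 1L),
              vapply(pairs, `[`, character(1), 2L))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$weight <- as.numeric(agg)
  g$n_self_loops <- sum(self)
  g$n_duplicates <- sum(keep) - length(agg)
  g
}

#' Extract the disease module around a DEG list
#'
#' Maps differentially expressed genes (DEGs) onto the background network and
#' extracts the connected subnetwork they anchor: the candidate node set is
#' every DEG present in the network with at least one edge, together with all
#' network neighbors of those DEGs; the module is the largest connected
#' component of the subgraph induced on the candidates (ties broken toward
#' the component containing the lexicographically smallest node label).
#' Smaller components are discarded and their sizes reported.
#'
#' @param network An `igraph` background network (see [load_network()]).
#' @param degs Character vector of DEG symbols.
#' @param keep_all Keep every candidate component instead of the largest
#'   only (default `FALSE`).
#' @return An object of class `disease_module`: a list with `nodes`
#'   (character vector), `n_components_discarded`, `discarded_sizes`,
#'   `n_degs_in_module`, `degs_used`, and an (initially empty)
#'   `process_annotations` list.
#' @export
build_disease_module <- function(network, degs, keep_all = FALSE) {
  degs <- unique(trimws(as.character(degs)))
  degs <- degs[nzchar(degs)]
  if (length(degs) == 0L) stop("empty DEG list")
  vs <- igraph::V(network)$name
  present <- intersect(degs, vs)
  present <- present[igraph::degree(network, present) > 0]
  if (length(present) == 0L) {
    stop("no DEG maps onto the network with at least one edge")
  }
  nbrs <- .neighbor_names(network, present)
  candidates <- union(present, nbrs)
  sub <- igraph::induced_subgraph(network, candidates)
  comp <- igraph::components(sub)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # deterministic tie-break: component holding the smallest node label
    firsts <- vapply(best, function(k) {
      min(igraph::V(sub)$name[comp$membership == k])
    }, character(1))
    best <- best[order(firsts)][1L]
  } else {
    best <- best[[1L]]
  }
  if (keep_all) {
    nodes <- sort(igraph::V(sub)$name)
    discarded <- integer(0)
  } else {
    nodes <- sort(igraph::V(sub)$name[comp$membership == best])
    discarded <- sort(sizes[-best], decreasing = TRUE)
  }
  structure(list(
    nodes = nodes,
    n_components_discarded = length(discarded),
    discarded_sizes = as.integer(discarded),
    degs_used = sort(present),
    n_degs_in_module = sum(present %in% nodes),
    process_annotations = list()
  ), class = "disease_module")
}

#' @export
print.disease_module <- function(x, ...) {
  cat("Disease module:", length(x$nodes), "genes (",
      x$n_degs_in_module, "DEGs );",
      x$n_components_discarded, "smaller component(s) discarded\n")
  if (length(x$process_annotations)) {
    for (p in names(x$process_annotations)) {
      cat("  process '", p, "': ", length(x$process_annotations[[p]]),
          " module genes\n", sep = "")
    }
  }
  invisible(x)
}

#' Annotate a disease module with biological-process gene sets
#'
#' Intersects the module with each requested process gene set. The default
#' process list is the four GO biological processes used for prioritization:
#' angiogenesis, sprout angiogenesis, positive regulation of angiogenesis,
#' and inflammatory response.
#'
#' @param module A `disease_module` from [build_disease_module()].
#' @param genesets Named list of gene sets (see [read_gmt()]).
#' @param process_names Character vector of set names to annotate with.
#' @return The module with `process_annotations[[p]]` filled for each
#'   process; empty intersections produce a warning but are kept.
#' @export
annotate_processes <- function(module, genesets,
                               process_names = pd_process_names()) {
  stopifnot(inherits(module, "disease_module"))
  missing <- setdiff(process_names, names(genesets))
  if (length(missing)) {
    stop("unknown process name(s): ", paste(missing, collapse = ", "))
  }
  for (p in process_names) {
    hit <- sort(intersect(module$nodes, genesets[[p]]))
    if (length(hit) == 0L) {
      warning("process '", p, "' does not intersect the module")
    }
    module$process_annotations[[p]] <- hit
  }
  module
}

#' Default biological-process names used for drug prioritization
#'
#' @return Character vector of the four GO biological-process names screened
#'   for combination candidates.
#' @export
pd_process_names <- function() {
  c("angiogenesis", "sprout angiogenesis",
    "positive regulation of angiogenesis", "inflammatory response")
}
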