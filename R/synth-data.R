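#' Generate a scale-free background molecular network
#'
#' Grows an undirected preferential-attachment graph (`cfg$ppi_attachment`
#' edges per new node), the standard stand-in for the heavy-tailed degree
#' distribution of curated protein-protein interaction networks. The graph
#' is simple and connected by construction; nodes carry synthetic gene
#' symbols `G0001, G0002, ...`. With `weighted_edges`, weights are uniform
#' on `[0.5, 1.5]`; otherwise every edge has weight 1.
#'
#' @param cfg A [synth_config()].
#' @return An undirected `igraph` graph with `name` vertex and `weight` edge
#'   attributes.
#' @export
generate_background_network <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(.sub_seed(cfg, 1L))
  g <- igraph::sample_pa(cfg$n_genes, power = 1, m = cfg$ppi_attachment,
                         directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("G%04d", seq_len(cfg$n_genes))
  igraph::E(g)$weight <- if (cfg$weighted_edges) {
    stats::runif(igraph::ecount(g), 0.5, 1.5)
  } else {
    rep(1, igraph::ecount(g))
  }
  g
}

#' Plant a connected disease module and a noisy DEG list
#'
#' The module is grown by a random walk from a low-degree seed node: every
#' walk position whose closed neighborhood still fits within `module_size`
#' is accepted as a "core" node and its neighbors join the module, and any
#' remaining slots are filled with the boundary neighbors most connected
#' into the module. This neighborhood-closure growth gives the module the
#' locally dense, partly self-contained character of a real disease region
#' while keeping its induced subgraph connected. The DEG list mixes signal
#' and noise: `(1 - deg_noise)` of the `n_degs` genes are module members
#' (the core first, then interior nodes whose neighborhoods lie mostly
#' inside the module), and the remainder are off-module distractors drawn
#' from nodes at network distance >= 3 from the module where possible.
#'
#' @param network Background network from [generate_background_network()].
#' @param cfg A [synth_config()].
#' @return List with `planted_module` (character vector, connected node
#'   set) and `deg_list` (character vector of DEG symbols).
#' @export
generate_disease_signal <- function(network, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- igraph::vcount(network)
  if (cfg$module_size > n) stop("module_size exceeds network size")
  set.seed(.sub_seed(cfg, 2L))
  vs <- igraph::V(network)$name
  deg <- igraph::degree(network)
  size <- cfg$module_size

  # random-walk-driven neighborhood closure from a low-degree seed
  cur <- sample(vs[deg <= stats::quantile(deg, 0.5)], 1L)
  core <- character(0)
  module <- character(0)
  for (step in seq_len(5000L)) {
    nb <- names(igraph::neighbors(network, cur))
    cand <- union(module, c(cur, nb))
    if (!(cur %in% core) && length(cand) <= size) {
      core <- c(core, cur)
      module <- cand
    }
    if (length(module) >= size - 1L) break
    cur <- sample(nb, 1L)
  }
  while (length(module) < size) {
    fringe <- setdiff(.neighbor_names(network, module), module)
    infr <- vapply(fringe, function(v) {
      nv <- names(igraph::neighbors(network, v))
      sum(nv %in% module) / length(nv)
    }, numeric(1))
    module <- c(module, fringe[which.max(infr)])
  }
  module <- sort(module)

  n_in <- min(length(module), ceiling((1 - cfg$deg_noise) * cfg$n_degs))
  n_out <- cfg$n_degs - n_in
  # in-module DEGs: walk core first, then the most interior remaining
  # nodes (high in-module neighbor fraction, low outside spill)
  extra <- setdiff(module, core)
  infr <- vapply(extra, function(v) {
    nv <- names(igraph::neighbors(network, v))
    sum(nv %in% module) / length(nv)
  }, numeric(1))
  outn <- vapply(extra, function(v) {
    nv <- names(igraph::neighbors(network, v))
    sum(!nv %in% module)
  }, numeric(1))
  degs_in <- c(core, extra[order(-infr, outn, extra)])[seq_len(n_in)]

  degs_out <- character(0)
  if (n_out > 0L) {
    dist_to_mod <- module_distances(network, module)
    outside <- setdiff(vs, module)
    far <- outside[dist_to_mod[outside] >= 3]
    if (length(far) < n_out) far <- outside[dist_to_mod[outside] >= 2]
    if (length(far) < n_out) far <- outside
    degs_out <- sample(far, n_out)
  }
  list(planted_module = module,
       deg_list = sort(c(degs_in, degs_out)))
}

# Pronounceable uppercase synthetic drug names, pairwise dissimilar enough
# (Jaro-Winkler < 0.88) that typo clustering is well-posed.
.synth_drug_names <- function(n) {
  cons <- c("B", "C", "D", "F", "G", "K", "L", "M", "N", "P", "R", "S",
            "T", "V", "X", "Z")
  vow <- c("A", "E", "I", "O", "U")
  suf <- c("OL", "IN", "ID", "AX", "ON", "EX", "UM", "AL", "IR", "AN")
  out <- character(0)
  guard <- 0L
  while (length(out) < n && guard < 20000L) {
    guard <- guard + 1L
    nsyl <- sample(2:3, 1L)
    nm <- paste0(paste0(sample(cons, nsyl, TRUE), sample(vow, nsyl, TRUE),
                        collapse = ""),
                 sample(suf, 1L))
    if (nchar(nm) < 6L) next
    if (length(out) == 0L || max(jaro_winkler(rep(nm, length(out)), out)) < 0.88) {
      out <- c(out, nm)
    }
  }
  if (length(out) < n) stop("could not generate enough distinct drug names")
  out
}

#' Generate a synthetic drug catalog
#'
#' Creates `n_drugs` entries with canonical names, 1-3 synthetic 7-character
#' ATC codes, direct-target gene sets, mechanism gene sets (supersets of the
#' targets) and abstract fingerprint bit sets (drugs sharing a 4th-level ATC
#' class share a common core of bits). A fraction `frac_proximal_drugs` are
#' ground-truth "proximal": their targets are drawn from the planted module
#' and its neighbors (weighted toward the module itself); the rest draw
#' degree-matched targets from the whole network. Two proximal and two
#' background pairs deliberately share identical target sets to exercise
#' cluster collapsing downstream.
#'
#' @param network Background network.
#' @param planted_module Character vector of module nodes.
#' @param cfg A [synth_config()].
#' @return Catalog data frame with columns `drug_id`, `name`, `atc_codes`,
#'   `targets`, `mechanism_genes`, `fingerprint_bits` (list columns) and
#'   `truth_label` (`"proximal"` / `"background"`).
#' @export
generate_drug_catalog <- function(network, planted_module, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(.sub_seed(cfg, 3L))
  n <- cfg$n_drugs
  vs <- igraph::V(network)$name
  n_prox <- round(cfg$frac_proximal_drugs * n)
  labels <- c(rep("proximal", n_prox), rep("background", n - n_prox))

  names_ <- .synth_drug_names(n)
  mod_nbrs <- setdiff(.neighbor_names(network, planted_module),
                      planted_module)
  prox_pool <- c(planted_module, mod_nbrs)
  bins <- degree_bins(network, min_occupancy = 20L)

  draw_targets <- function(label) {
    k <- sample(2:6, 1L)
    if (label == "proximal") {
      from_mod <- stats::rbinom(k, 1L, 0.8) == 1L
      t1 <- sample(planted_module, sum(from_mod))
      t2 <- if (any(!from_mod)) sample(mod_nbrs, sum(!from_mod)) else character(0)
      unique(c(t1, t2))
    } else {
      # degree-matched to the proximal pool's degree profile
      ref <- sample(prox_pool, k, replace = TRUE)
      vapply(ref, function(r) {
        pool <- bins$members[[bins$bin_of[[r]]]]
        sample(pool, 1L)
      }, character(1), USE.NAMES = FALSE)
    }
  }
  targets <- lapply(labels, draw_targets)
  targets <- lapply(targets, function(t) sort(unique(t)))

  # planted identical target sets (first two proximal pairs, two background)
  dup_pairs <- list()
  if (n_prox >= 4L) dup_pairs <- c(dup_pairs, list(c(1L, 2L), c(3L, 4L)))
  bg_idx <- which(labels == "background")
  if (length(bg_idx) >= 4L) {
    dup_pairs <- c(dup_pairs, list(bg_idx[1:2], bg_idx[3:4]))
  }
  for (dp in dup_pairs) targets[[dp[[2]]]] <- targets[[dp[[1]]]]

  # ATC classes: a pool of 4th-level (5-character) prefixes
  n_classes <- max(8L, round(n / 4))
  letters_ <- LETTERS[1:14]
  prefixes <- character(0)
  while (length(prefixes) < n_classes) {
    pr <- paste0(sample(letters_, 1L),
                 sprintf("%02d", sample.int(99L, 1L)),
                 paste(sample(LETTERS, 2L, TRUE), collapse = ""))
    prefixes <- unique(c(prefixes, pr))
  }
  primary_class <- sample.int(n_classes, n, replace = TRUE)
  atc_codes <- lapply(seq_len(n), function(i) {
    n_codes <- sample(1:3, 1L, prob = c(0.7, 0.2, 0.1))
    cls <- unique(c(primary_class[[i]],
                    sample.int(n_classes, n_codes - 1L, replace = TRUE)))
    sort(paste0(prefixes[cls], sprintf("%02d", sample.int(99L, length(cls),
                                                          replace = TRUE))))
  })

  # fingerprints: shared class core + drug-specific bits (2048-bit space)
  class_core <- lapply(seq_len(n_classes), function(i) sample.int(2048L, 40L))
  fingerprints <- lapply(seq_len(n), function(i) {
    sort(unique(c(class_core[[primary_class[[i]]]], sample.int(2048L, 80L))))
  })

  mechanism <- lapply(seq_len(n), function(i) {
    extra_pool <- if (labels[[i]] == "proximal") prox_pool else vs
    sort(unique(c(targets[[i]], sample(extra_pool, sample(5:15, 1L)))))
  })

  out <- data.frame(drug_id = sprintf("D%03d", seq_len(n)),
                    name = names_, truth_label = labels,
                    stringsAsFactors = FALSE)
  out$atc_codes <- atc_codes
  out$targets <- targets
  out$mechanism_genes <- mechanism
  out$fingerprint_bits <- fingerprints
  out
}

# 1-2 random character edits (substitution, adjacent transposition or
# deletion), never touching the first character so the Jaro-Winkler prefix
# bonus stays informative
.corrupt_name <- function(name) {
  ch <- strsplit(name, "", fixed = TRUE)[[1]]
  for (e in seq_len(sample(1:2, 1L))) {
    if (length(ch) < 3L) break
    pos <- sample(2:length(ch), 1L)
    op <- sample(c("sub", "swap", "del"), 1L)
    if (op == "sub") {
      ch[pos] <- sample(setdiff(LETTERS, ch[pos]), 1L)
    } else if (op == "swap" && pos < length(ch)) {
      tmp <- ch[pos]
      ch[pos] <- ch[pos + 1L]
      ch[pos + 1L] <- tmp
    } else {
      ch <- ch[-pos]
    }
  }
  paste(ch, collapse = "")
}

#' Generate a longitudinal synthetic prescription table
#'
#' Per patient: visit count ~ 1 + Poisson(`mean_visits` - 1); inter-visit
#' gaps ~ Exponential(`mean_interval_days`); visit dates span 1990-2022.
#' Per-drug start probabilities come from a Beta(0.15,
#' `prevalence_dispersion`) so a minority of drugs exceed 30% patient
#' prevalence; a started drug persists across visits until a random stop
#' (continuation probability 0.85), emulating active-medication lists
#' carried forward between appointments. `planted_pairs` drug pairs are
#' forced to co-occur: the partner drug appears (only) at the lead drug's
#' visits with probability 0.95. Each record's raw name is the canonical
#' name, corrupted with probability `typo_rate` by 1-2 character edits.
#' Each patient receives one endpoint label with marginal frequencies
#' matching a realistic dialysis cohort (38/25/32/1/3/0.2% for
#' KTx/HD/death/recovery/transfer/lost), and a random 10% of patients get a
#' second treatment phase with extra records.
#'
#' @param catalog Drug catalog from [generate_drug_catalog()].
#' @param cfg A [synth_config()].
#' @return Data frame with columns `patient_id`, `visit_date`, `raw_name`,
#'   `phase`, `endpoint` plus `true_drug_id` (generator ground truth). The
#'   `"truth"` attribute lists `planted_pairs` (data frame of drug-id
#'   pairs), `typo_map` (corrupted raw name -> canonical name) and
#'   `start_prob` (per-drug).
#' @export
generate_prescriptions <- function(catalog, cfg) {
  stopifnot(inherits(cfg, "synth_config"), nrow(catalog) > 0L)
  set.seed(.sub_seed(cfg, 4L))
  n_drugs <- nrow(catalog)
  persist <- 0.85
  q <- stats::rbeta(n_drugs, 0.15, cfg$prevalence_dispersion)

  # planted pairs: lead drug gets a mid-range start probability, partner
  # drug is prescribed only alongside its lead
  n_pp <- min(cfg$planted_pairs, floor(n_drugs / 2))
  pp_idx <- sample.int(n_drugs, 2L * n_pp)
  lead <- pp_idx[seq_len(n_pp)]
  partner <- pp_idx[n_pp + seq_len(n_pp)]
  q[lead] <- stats::runif(n_pp, 0.06, 0.12)
  q[partner] <- 0
  planted <- data.frame(drug_a = pmin(catalog$drug_id[lead],
                                      catalog$drug_id[partner]),
                        drug_b = pmax(catalog$drug_id[lead],
                                      catalog$drug_id[partner]),
                        stringsAsFactors = FALSE)
  partner_of <- integer(n_drugs)
  partner_of[lead] <- partner

  ep_levels <- c("KTx", "HD", "death", "recovery", "transfer", "lost")
  ep_prob <- c(0.38, 0.25, 0.32, 0.01, 0.03, 0.002)
  ep_prob <- ep_prob / sum(ep_prob)

  epoch_lo <- as.Date("1990-03-01")
  epoch_hi <- as.Date("2021-07-01")
  date_cap <- as.Date("2022-12-31")

  rows <- vector("list", cfg$n_patients)
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%04d", p)
    endpoint <- sample(ep_levels, 1L, prob = ep_prob)
    two_phases <- stats::runif(1) < 0.10

    sim_phase <- function(start_date, n_visits, phase) {
      gaps <- round(stats::rexp(n_visits - 1L, 1 / cfg$mean_interval_days)) + 1
      dates <- start_date + c(0, cumsum(gaps))
      dates <- dates[dates <= date_cap]
      if (length(dates) == 0L) dates <- start_date
      active <- rep(FALSE, n_drugs)
      out <- vector("list", length(dates))
      for (v in seq_along(dates)) {
        starts <- !active & stats::runif(n_drugs) < q
        stays <- active & stats::runif(n_drugs) < persist
        active <- starts | stays
        # planted partners ride along with their lead drug
        for (ld in lead) {
          pt <- partner_of[ld]
          active[pt] <- active[ld] && stats::runif(1) < 0.95
        }
        ids <- which(active)
        if (length(ids) == 0L) {
          ids <- sample.int(n_drugs, 1L)  # visits always record >= 1 drug
          active[ids] <- TRUE
        }
        out[[v]] <- data.frame(patient_id = pid,
                               visit_date = dates[[v]],
                               true_drug_id = catalog$drug_id[ids],
                               raw_name = catalog$name[ids],
                               phase = phase,
                               endpoint = endpoint,
                               stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    }

    nv1 <- 1L + stats::rpois(1L, max(cfg$mean_visits - 1, 0.1))
    start1 <- epoch_lo + floor(stats::runif(1) *
                                 as.numeric(epoch_hi - epoch_lo))
    ph1 <- sim_phase(start1, nv1, 1L)
    if (two_phases) {
      nv2 <- 1L + stats::rpois(1L, 2)
      start2 <- max(ph1$visit_date) + round(stats::rexp(1, 1 / 200)) + 30
      if (start2 <= date_cap) {
        rows[[p]] <- rbind(ph1, sim_phase(start2, nv2, 2L))
      } else {
        rows[[p]] <- ph1
      }
    } else {
      rows[[p]] <- ph1
    }
  }
  rec <- do.call(rbind, rows)

  corrupt <- stats::runif(nrow(rec)) < cfg$typo_rate
  if (any(corrupt)) {
    rec$raw_name[corrupt] <- vapply(rec$raw_name[corrupt], .corrupt_name,
                                    character(1), USE.NAMES = FALSE)
  }
  # corrupted forms that happen to equal a canonical name are not typos
  corrupt <- corrupt & !(rec$raw_name %in% catalog$name)
  typo_map <- unique(data.frame(
    raw_name = rec$raw_name[corrupt],
    canonical = catalog$name[match(rec$true_drug_id[corrupt],
                                   catalog$drug_id)],
    stringsAsFactors = FALSE))
  rec <- rec[order(rec$patient_id, rec$visit_date, rec$true_drug_id), ]
  rownames(rec) <- NULL
  attr(rec, "truth") <- list(planted_pairs = planted,
                             typo_map = typo_map,
                             start_prob = stats::setNames(q, catalog$drug_id))
  rec
}

#' Generate synthetic pathway and biological-process gene sets
#'
#' Emits `n_pathways` pathway sets with sizes in `pathway_size_range` (half
#' of them biased toward the disease-module neighborhood so drug-target
#' pathway enrichment has signal to find) plus exactly four named
#' biological-process sets (see [pd_process_names()]) that each overlap the
#' planted module in at least 5 genes.
#'
#' @param network Background network.
#' @param planted_module Character vector of module nodes.
#' @param cfg A [synth_config()].
#' @return Named list of gene sets suitable for [write_gmt()].
#' @export
generate_genesets <- function(network, planted_module, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(.sub_seed(cfg, 5L))
  vs <- igraph::V(network)$name
  hood <- union(planted_module,
                .neighbor_names(network, planted_module))
  sizes <- sample(seq(cfg$pathway_size_range[1], cfg$pathway_size_range[2]),
                  cfg$n_pathways, replace = TRUE)
  sets <- lapply(seq_len(cfg$n_pathways), function(i) {
    s <- sizes[[i]]
    if (i %% 2L == 0L) {
      n_h <- min(length(hood), ceiling(0.6 * s))
      g <- c(sample(hood, n_h), sample(vs, s - n_h))
    } else {
      g <- sample(vs, s)
    }
    g <- sort(unique(g))
    attr(g, "description") <- "synthetic pathway"
    g
  })
  names(sets) <- sprintf("PATHWAY_%03d", seq_len(cfg$n_pathways))

  procs <- lapply(pd_process_names(), function(p) {
    n_mod <- min(length(planted_module), sample(6:10, 1L))
    g <- sort(unique(c(sample(planted_module, n_mod),
                       sample(vs, sample(15:25, 1L)))))
    attr(g, "description") <- "synthetic GO biological process"
    g
  })
  names(procs) <- pd_process_names()
  c(sets, procs)
}

#' Generate the full synthetic dataset
#'
#' Runs every generator stage with seeds derived from `cfg$seed` and bundles
#' the results with the ground truth needed for recovery tests.
#'
#' @param cfg A [synth_config()].
#' @return List with `network`, `planted_module`, `deg_list`, `catalog`,
#'   `records`, `genesets`, and `truth` (planted pairs, typo map, proximal
#'   drug ids, planted module, per-drug start probabilities).
#' @export
generate_synth_data <- function(cfg = synth_config()) {
  network <- generate_background_network(cfg)
  signal <- generate_disease_signal(network, cfg)
  catalog <- generate_drug_catalog(network, signal$planted_module, cfg)
  records <- generate_prescriptions(catalog, cfg)
  genesets <- generate_genesets(network, signal$planted_module, cfg)
  truth <- attr(records, "truth")
  truth$planted_module <- signal$planted_module
  truth$deg_list <- signal$deg_list
  truth$proximal_drugs <- catalog$drug_id[catalog$truth_label == "proximal"]
  list(network = network,
       planted_module = signal$planted_module,
       deg_list = signal$deg_list,
       catalog = catalog,
       records = records,
       genesets = genesets,
       truth = truth)
}

#' Write a synthetic dataset to a directory
#'
#' Emits `prescriptions.tsv`, `drugs.tsv`, `network.tsv`, `degs.txt`,
#' `genesets.gmt` and `truth.json` in plain-text layouts readable by the
#' corresponding loaders.
#'
#' @param data Output of [generate_synth_data()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synth_dataset <- function(data, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec <- data$records
  write_tsv(data.frame(patient_id = rec$patient_id,
                       visit_date = format(rec$visit_date),
                       raw_name = rec$raw_name,
                       phase = rec$phase,
                       endpoint = rec$endpoint,
                       stringsAsFactors = FALSE),
            file.path(dir, "prescriptions.tsv"))
  write_drug_catalog(data$catalog, file.path(dir, "drugs.tsv"))
  el <- igraph::as_edgelist(data$network)
  write_tsv(data.frame(gene_a = el[, 1], gene_b = el[, 2],
                       weight = igraph::E(data$network)$weight,
                       stringsAsFactors = FALSE),
            file.path(dir, "network.tsv"))
  writeLines(data$deg_list, file.path(dir, "degs.txt"))
  write_gmt(data$genesets, file.path(dir, "genesets.gmt"))
  truth <- data$truth
  truth$start_prob <- as.list(truth$start_prob)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
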