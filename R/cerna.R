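#' Directionality-constrained miRNA-transcript pairs
#'
#' Keeps a (miRNA, transcript) pair only when both partners are
#' differentially expressed in the comparison under consideration, their
#' directions are strictly opposite (miRNAs negatively regulate their
#' targets), and at least one predicted binding site supports the pair.
#'
#' @param de_mirnas data.frame with columns `feature` and `direction`
#'   (values `up` or `down`) for DE miRNAs.
#' @param de_transcripts data.frame with columns `feature`, `kind`
#'   (`lncRNA` or `mRNA`) and `direction` for DE transcripts.
#' @param site_table aggregated site table from [predict_targets()]
#'   (columns `mirna`, `transcript`, `n_sites`).
#' @return data.frame with `mirna`, `mirna_direction`, `transcript`,
#'   `kind`, `transcript_direction`, `n_sites`, ordered by
#'   (miRNA, transcript).
#' @export
filter_directional_pairs <- function(de_mirnas, de_transcripts, site_table) {
  dirs <- c(de_mirnas$direction, de_transcripts$direction)
  if (length(dirs) && !all(dirs %in% c("up", "down")))
    stop("directions must be 'up' or 'down', got: ",
         paste(setdiff(dirs, c("up", "down")), collapse = ", "))
  if (nrow(site_table) == 0L || nrow(de_mirnas) == 0L ||
      nrow(de_transcripts) == 0L)
    return(data.frame(mirna = character(0), mirna_direction = character(0),
                      transcript = character(0), kind = character(0),
                      transcript_direction = character(0),
                      n_sites = integer(0)))
  m <- merge(site_table, de_mirnas[, c("feature", "direction")],
             by.x = "mirna", by.y = "feature")
  names(m)[names(m) == "direction"] <- "mirna_direction"
  m <- merge(m, de_transcripts[, c("feature", "kind", "direction")],
             by.x = "transcript", by.y = "feature")
  names(m)[names(m) == "direction"] <- "transcript_direction"
  m <- m[m$mirna_direction != m$transcript_direction & m$n_sites >= 1L, ,
         drop = FALSE]
  out <- m[order(m$mirna, m$transcript),
           c("mirna", "mirna_direction", "transcript", "kind",
             "transcript_direction", "n_sites")]
  rownames(out) <- NULL
  out
}

#' Assemble lncRNA-miRNA-mRNA sponge triplets
#'
#' Joins lncRNA-side and mRNA-side directional pairs on their shared
#' miRNA: each miRNA with `a` lncRNA partners and `b` mRNA partners yields
#' `a * b` triplets. Both partners necessarily share the direction
#' opposite to the miRNA's.
#'
#' @param lnc_pairs,mrna_pairs data.frames from
#'   [filter_directional_pairs()] restricted to the respective kind.
#' @return data.frame with `lncrna`, `mirna`, `mrna`, `lnc_sites`,
#'   `mrna_sites`.
#' @export
assemble_triplets <- function(lnc_pairs, mrna_pairs) {
  empty <- data.frame(lncrna = character(0), mirna = character(0),
                      mrna = character(0), lnc_sites = integer(0),
                      mrna_sites = integer(0))
  if (nrow(lnc_pairs) == 0L || nrow(mrna_pairs) == 0L) return(empty)
  ln <- lnc_pairs[, c("mirna", "transcript", "n_sites")]
  names(ln) <- c("mirna", "lncrna", "lnc_sites")
  mr <- mrna_pairs[, c("mirna", "transcript", "n_sites")]
  names(mr) <- c("mirna", "mrna", "mrna_sites")
  out <- merge(ln, mr, by = "mirna")
  if (nrow(out) == 0L) return(empty)
  out <- out[order(out$lncrna, out$mirna, out$mrna),
             c("lncrna", "mirna", "mrna", "lnc_sites", "mrna_sites")]
  rownames(out) <- NULL
  out
}

#' Build the typed ceRNA network from triplets
#'
#' Nodes are typed (`lncRNA`, `miRNA`, `mRNA`) and carry a regulation
#' attribute; edges are the unique lncRNA-miRNA and miRNA-mRNA arms of the
#' triplets (lncRNA-mRNA or same-kind edges never occur by construction).
#'
#' @param triplets data.frame from [assemble_triplets()].
#' @param regulation optional data.frame with `feature`, `direction`
#'   giving each node's regulation (`up`/`down`); nodes absent from it get
#'   `none`. Conflicting directions for one feature are an error.
#' @return an object of class `cerna_network` wrapping an igraph graph,
#'   with a precomputed `degree` table.
#' @export
build_network <- function(triplets, regulation = NULL) {
  nodes <- unique(data.frame(
    name = c(triplets$lncrna, triplets$mirna, triplets$mrna),
    kind = rep(c("lncRNA", "miRNA", "mRNA"),
               times = c(nrow(triplets), nrow(triplets), nrow(triplets))),
    stringsAsFactors = FALSE))
  if (anyDuplicated(nodes$name))
    stop("node(s) appear under more than one kind: ",
         paste(unique(nodes$name[duplicated(nodes$name)]), collapse = ", "))
  reg <- setNames(rep("none", nrow(nodes)), nodes$name)
  if (!is.null(regulation) && nrow(regulation)) {
    rr <- unique(regulation[, c("feature", "direction")])
    if (anyDuplicated(rr$feature))
      stop("conflicting regulation attribute for node(s): ",
           paste(unique(rr$feature[duplicated(rr$feature)]), collapse = ", "))
    hit <- rr$feature %in% names(reg)
    reg[rr$feature[hit]] <- rr$direction[hit]
  }
  edges <- unique(rbind(
    data.frame(from = triplets$lncrna, to = triplets$mirna,
               stringsAsFactors = FALSE),
    data.frame(from = triplets$mirna, to = triplets$mrna,
               stringsAsFactors = FALSE)))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes$name, kind = nodes$kind,
                          regulation = unname(reg[nodes$name]),
                          stringsAsFactors = FALSE))
  deg <- igraph::degree(g)
  degree_table <- data.frame(
    node = names(deg), kind = igraph::V(g)$kind,
    regulation = igraph::V(g)$regulation, degree = as.integer(deg),
    stringsAsFactors = FALSE, row.names = NULL)
  degree_table <- degree_table[order(-degree_table$degree,
                                     degree_table$node), ]
  rownames(degree_table) <- NULL
  structure(list(graph = g, degree = degree_table),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  k <- table(factor(igraph::V(x$graph)$kind,
                    levels = c("lncRNA", "miRNA", "mRNA")))
  cat(sprintf(
    "ceRNA network: %d nodes (%d lncRNA, %d miRNA, %d mRNA), %d edges\n",
    igraph::vcount(x$graph), k[["lncRNA"]], k[["miRNA"]], k[["mRNA"]],
    igraph::ecount(x$graph)))
  invisible(x)
}

#' Rank network hubs by degree
#'
#' @param network a [build_network()] result.
#' @param k number of top nodes (default 25); all nodes when `k` exceeds
#'   the node count.
#' @return data.frame of the top `k` rows of the degree table, sorted by
#'   degree descending with lexicographic node id as the deterministic
#'   tie-break.
#' @export
rank_hubs <- function(network, k = 25L) {
  stopifnot(inherits(network, "cerna_network"), k >= 1L)
  head(network$degree, min(k, nrow(network$degree)))
}

#' Extract the neighborhood subnetwork around seed nodes
#'
#' @param network a [build_network()] result.
#' @param seeds character vector of node ids (must exist in the network).
#' @param radius neighborhood radius in hops (default 1; 0 gives the
#'   induced subgraph on the seeds alone).
#' @return a `cerna_network` induced on all nodes within `radius` hops of
#'   any seed.
#' @export
extract_subnet <- function(network, seeds, radius = 1L) {
  stopifnot(inherits(network, "cerna_network"))
  all_names <- igraph::V(network$graph)$name
  unknown <- setdiff(seeds, all_names)
  if (length(unknown))
    stop("unknown seed id(s): ", paste(unknown, collapse = ", "))
  nb <- igraph::ego(network$graph, order = radius,
                    nodes = seeds, mode = "all")
  keep <- unique(unlist(lapply(nb, function(v) v$name)))
  g <- igraph::induced_subgraph(network$graph, keep)
  deg <- igraph::degree(g)
  degree_table <- data.frame(
    node = names(deg), kind = igraph::V(g)$kind,
    regulation = igraph::V(g)$regulation, degree = as.integer(deg),
    stringsAsFactors = FALSE, row.names = NULL)
  degree_table <- degree_table[order(-degree_table$degree,
                                     degree_table$node), ]
  rownames(degree_table) <- NULL
  structure(list(graph = g, degree = degree_table),
            class = "cerna_network")
}

#' Export the network as an edge list or GraphML
#'
#' @param network a [build_network()] result.
#' @param path output file.
#' @param format `"tsv"` (edge list with node kinds) or `"graphml"`.
#' @return the path, invisibly.
#' @export
write_network <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network$graph, path, format = "graphml")
  } else {
    e <- igraph::as_data_frame(network$graph, what = "edges")
    v <- igraph::as_data_frame(network$graph, what = "vertices")
    kind <- setNames(v$kind, v$name)
    reg <- setNames(v$regulation, v$name)
    out <- data.frame(source = e$from, target = e$to,
                      source_kind = kind[e$from], target_kind = kind[e$to],
                      source_regulation = reg[e$from],
                      target_regulation = reg[e$to],
                      stringsAsFactors = FALSE)
    out <- out[order(out$source, out$target), ]
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Infer a ceRNA network from staged count matrices
#'
#' The full inference path: TMM normalization, exact NB tests for every
#' pairwise stage comparison, inclusive DE calling, seed-match target
#' prediction restricted to DE features, directionality filtering per
#' comparison, triplet assembly, and the union network over comparisons.
#'
#' @param mirna_counts,transcript_counts integer count matrices sharing
#'   sample columns.
#' @param stages stage labels per sample column (defaults to parsing
#'   column names).
#' @param mirna_seqs named mature miRNA sequences for DE miRNAs.
#' @param transcript_seqs named transcript sequences (lncRNA and mRNA
#'   3'UTR fragments).
#' @param transcript_kinds named character vector: `lncRNA` or `mRNA` per
#'   transcript id.
#' @param cfg matcher configuration; the default restricts inference to
#'   8mer sites, the highest-confidence canonical class.
#' @param p_thresh,lfc_thresh DE screening thresholds.
#' @return list with per-comparison DE tables (`de`), the site table
#'   (`sites`), per-comparison and pooled `triplets`, and the union
#'   `network`.
#' @export
infer_cerna_network <- function(mirna_counts, transcript_counts,
                                stages = NULL, mirna_seqs, transcript_seqs,
                                transcript_kinds,
                                cfg = matcher_config(classes = "8mer"),
                                p_thresh = 0.05, lfc_thresh = 1) {
  if (is.null(stages)) stages <- sample_stages(colnames(mirna_counts))
  stage_levels <- unique(stages)
  comps <- utils::combn(stage_levels, 2, simplify = FALSE)

  mir_fac <- tmm_factors(mirna_counts)
  tx_fac <- tmm_factors(transcript_counts)
  de <- list()
  for (cp in comps) {
    lab <- paste(cp[1], "vs", cp[2], sep = ".")
    de[[lab]] <- list(
      mirna = call_de(exact_nb_test(mirna_counts, stages, cp[1], cp[2],
                                    factors = mir_fac),
                      p_thresh, lfc_thresh),
      transcript = call_de(exact_nb_test(transcript_counts, stages,
                                         cp[1], cp[2], factors = tx_fac),
                           p_thresh, lfc_thresh))
  }

  de_mir_ids <- sort(unique(unlist(lapply(de, function(d)
    d$mirna$feature[d$mirna$significant]))))
  de_tx_ids <- sort(unique(unlist(lapply(de, function(d)
    d$transcript$feature[d$transcript$significant]))))
  sites <- predict_targets(mirna_seqs[intersect(de_mir_ids,
                                                names(mirna_seqs))],
                           transcript_seqs[intersect(de_tx_ids,
                                                     names(transcript_seqs))],
                           cfg)

  per_comp <- list()
  for (lab in names(de)) {
    dm <- de[[lab]]$mirna
    dt <- de[[lab]]$transcript
    dm <- data.frame(feature = dm$feature[dm$significant],
                     direction = dm$direction[dm$significant],
                     stringsAsFactors = FALSE)
    dt <- data.frame(feature = dt$feature[dt$significant],
                     direction = dt$direction[dt$significant],
                     stringsAsFactors = FALSE)
    dt$kind <- unname(transcript_kinds[dt$feature])
    pairs <- filter_directional_pairs(dm, dt, sites)
    trip <- assemble_triplets(pairs[pairs$kind == "lncRNA", , drop = FALSE],
                              pairs[pairs$kind == "mRNA", , drop = FALSE])
    if (nrow(trip)) trip$comparison <- lab
    per_comp[[lab]] <- trip
  }
  pooled <- do.call(rbind, per_comp[vapply(per_comp, nrow,
                                           integer(1)) > 0])
  if (is.null(pooled))
    pooled <- data.frame(lncrna = character(0), mirna = character(0),
                         mrna = character(0), lnc_sites = integer(0),
                         mrna_sites = integer(0),
                         comparison = character(0))
  uniq <- unique(pooled[, c("lncrna", "mirna", "mrna", "lnc_sites",
                            "mrna_sites")])
  rownames(uniq) <- NULL
  # union-network regulation: a node keeps its direction only when every
  # significant call agrees across comparisons; V-shaped profiles get none
  sig <- do.call(rbind, lapply(de, function(d)
    rbind(d$mirna[d$mirna$significant, c("feature", "direction")],
          d$transcript[d$transcript$significant,
                       c("feature", "direction")])))
  regulation <- NULL
  if (!is.null(sig) && nrow(sig)) {
    agg <- lapply(split(sig$direction, sig$feature), unique)
    regulation <- data.frame(
      feature = names(agg),
      direction = vapply(agg, function(d)
        if (length(d) == 1L) d else "none", character(1)),
      stringsAsFactors = FALSE, row.names = NULL)
    regulation <- regulation[regulation$direction != "none", , drop = FALSE]
  }
  network <- build_network(uniq, regulation)
  list(de = de, sites = sites, triplets_by_comparison = per_comp,
       triplets = uniq, network = network)
}
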