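## Orthology: hit filtering, bidirectional-best-hit graph, Markov clustering.
## The hit filter mirrors the thresholds used for the halobacterial dataset
## (coverage >= 75% of the pairwise alignment, E-value <= 1e-10) with an
## optional identity floor (30% for the HGT-screen mode).

#' Similarity-hit filter configuration
#'
#' @param min_coverage Minimum aligned-span coverage, as a fraction of
#'   sequence length (default 0.75).
#' @param max_evalue Maximum E-value (default 1e-10).
#' @param min_identity Minimum percent identity (default 0; set 30 for the
#'   HGT-screen mode).
#' @param coverage_mode `"both"` (default) requires the coverage threshold on
#'   both query and subject; `"query"` on the query only.
#' @return A `hit_filter_config`.
#' @export
hit_filter_config <- function(min_coverage = 0.75, max_evalue = 1e-10,
                              min_identity = 0,
                              coverage_mode = c("both", "query")) {
  coverage_mode <- match.arg(coverage_mode)
  if (min_coverage < 0 || min_coverage > 1 || max_evalue < 0 ||
      min_identity < 0 || min_identity > 100)
    halopan_error("filter thresholds out of range", "halopan_config_error")
  structure(list(min_coverage = min_coverage, max_evalue = max_evalue,
                 min_identity = min_identity, coverage_mode = coverage_mode),
            class = "hit_filter_config")
}

#' Filter similarity hits
#'
#' Retains exactly the hits meeting the coverage, E-value and identity
#' thresholds; removes self-hits; preserves input order.  Idempotent.
#'
#' @param hits Hits data.frame from [all_vs_all_hits()] or [read_blast_tsv()].
#' @param config A [hit_filter_config()].
#' @return Filtered hits (attributes preserved).
#' @export
filter_hits <- function(hits, config = hit_filter_config()) {
  stopifnot(inherits(config, "hit_filter_config"))
  if (!nrow(hits)) return(hits)
  keep <- hits$qcov >= config$min_coverage &
    hits$evalue <= config$max_evalue &
    hits$pident >= config$min_identity &
    hits$query != hits$subject
  if (config$coverage_mode == "both" && !is.null(hits$scov))
    keep <- keep & hits$scov >= config$min_coverage
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "genome_of") <- attr(hits, "genome_of")
  out
}

#' Build the bidirectional-best-hit (BDBH) graph
#'
#' For each protein and each other genome, the best hit is the highest-scoring
#' hit (ties broken by lower E-value, then lexicographic subject id).  An
#' undirected edge joins two proteins iff each is the other's best hit in its
#' genome; reciprocal best non-self hits within a genome are also joined
#' (paralog support).  Edge weight is `-log10(max(evalue, 1e-180))`, taking
#' the larger of the two directed E-values.  Every protein is a vertex, so
#' proteins without reciprocal hits become singletons downstream.
#'
#' @param hits Filtered hits.
#' @param genome_of Named character vector protein -> genome; defaults to the
#'   attribute carried by the hits.
#' @param evalue_floor Floor applied before log-weighting (default 1e-180).
#' @return An undirected weighted [igraph::graph] with a `genome` vertex
#'   attribute.
#' @export
build_bdbh_graph <- function(hits, genome_of = attr(hits, "genome_of"),
                             evalue_floor = 1e-180) {
  if (is.null(genome_of))
    halopan_error("genome_of mapping is required")
  ids <- unique(c(hits$query, hits$subject, names(genome_of)))
  unknown <- setdiff(unique(c(hits$query, hits$subject)), names(genome_of))
  if (length(unknown))
    halopan_error(paste0("proteins with unknown genome: ",
                         paste(head(unknown, 3), collapse = ", ")))
  verts <- data.frame(name = sort(names(genome_of)),
                      genome = genome_of[sort(names(genome_of))],
                      stringsAsFactors = FALSE)
  if (!nrow(hits))
    return(igraph::graph_from_data_frame(
      data.frame(from = character(0), to = character(0), weight = numeric(0)),
      directed = FALSE, vertices = verts))
  h <- as.data.table(hits[, c("query", "subject", "score", "evalue")])
  h <- h[query != subject]
  h[, sg := genome_of[subject]]
  setorder(h, query, sg, -score, evalue, subject)
  best <- h[, head(.SD, 1L), by = .(query, sg)]
  b <- best[, .(query, subject, evalue)]
  rec <- merge(b, b, by.x = c("query", "subject"),
               by.y = c("subject", "query"), suffixes = c("", ".rev"))
  rec <- rec[query < subject]
  if (!nrow(rec))
    return(igraph::graph_from_data_frame(
      data.frame(from = character(0), to = character(0), weight = numeric(0)),
      directed = FALSE, vertices = verts))
  edges <- data.frame(from = rec$query, to = rec$subject,
                      weight = -log10(pmax(pmax(rec$evalue, rec$evalue.rev),
                                           evalue_floor)),
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Markov clustering configuration
#'
#' Defaults follow OrthoMCL custom: inflation 1.5, expansion 2.
#'
#' @param inflation Inflation exponent (> 1).
#' @param expansion Matrix-power expansion (integer >= 2).
#' @param prune_threshold Entries below this are pruned each iteration.
#' @param max_iterations Iteration cap; non-convergence raises a warning.
#' @param convergence_tol Converged when the largest entry change falls below
#'   this.
#' @param add_self_loops Add a self-loop per node weighted by its maximum
#'   incident edge weight (1 for isolated nodes) before normalisation.
#' @return An `mcl_config`.
#' @export
mcl_config <- function(inflation = 1.5, expansion = 2L,
                       prune_threshold = 1e-5, max_iterations = 100L,
                       convergence_tol = 1e-6, add_self_loops = TRUE) {
  if (inflation <= 1) halopan_error("inflation must be > 1", "halopan_config_error")
  if (expansion < 2L) halopan_error("expansion must be >= 2", "halopan_config_error")
  if (max_iterations < 1L) halopan_error("max_iterations must be >= 1",
                                         "halopan_config_error")
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 prune_threshold = prune_threshold,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 add_self_loops = add_self_loops), class = "mcl_config")
}

## MCL iteration on one dense column-stochastic matrix; returns the limit
## matrix and a convergence flag.
mcl_iterate <- function(m, config) {
  norm_cols <- function(x) {
    cs <- colSums(x)
    cs[cs == 0] <- 1
    sweep(x, 2L, cs, "/")
  }
  m <- norm_cols(m)
  converged <- FALSE
  for (it in seq_len(config$max_iterations)) {
    prev <- m
    for (e in seq_len(config$expansion - 1L)) m <- m %*% m
    m <- m^config$inflation
    m[m < config$prune_threshold] <- 0
    m <- norm_cols(m)
    if (max(abs(m - prev)) < config$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  list(m = m, converged = converged)
}

## Read clusters off a converged MCL matrix: attractors are nodes with
## positive diagonal mass; each attractor's cluster is its positive row
## support; nodes claimed by several clusters go to the larger one, ties to
## the cluster with the lexicographically smallest member.
mcl_interpret <- function(m, node_ids, eps) {
  att <- which(diag(m) > eps)
  raw <- lapply(att, function(a) which(m[a, ] > eps))
  raw <- unique(raw[lengths(raw) > 0])
  assign <- rep(NA_integer_, ncol(m))
  if (length(raw)) {
    sizes <- lengths(raw)
    first <- vapply(raw, function(idx) min(node_ids[idx]), character(1))
    ord <- order(-sizes, first)
    for (ci in ord) {
      idx <- raw[[ci]]
      free <- idx[is.na(assign[idx])]
      assign[free] <- ci
    }
  }
  unassigned <- which(is.na(assign))
  res <- split(node_ids[!is.na(assign)], assign[!is.na(assign)])
  c(unname(res), as.list(node_ids[unassigned]))
}

#' Markov clustering of a similarity graph into ortholog clusters
#'
#' Runs the MCL process (column-stochastic normalisation, expansion by matrix
#' power, elementwise inflation, pruning) to convergence on each connected
#' component of the graph and reads clusters off the attractor structure.
#' Every protein lands in exactly one cluster; singletons are allowed.
#'
#' @param graph Weighted undirected graph from [build_bdbh_graph()].
#' @param config An [mcl_config()].
#' @param sequences Optional named character vector (or `AAStringSet`) used to
#'   pick the longest member as cluster representative (ties: lexicographic
#'   id); without sequences the representative is the lexicographically
#'   smallest member id.
#' @return An `ortholog_clusters` object: `membership` (named protein ->
#'   cluster id), `clusters` (named list of member ids), `representatives`,
#'   `genome_of`.
#' @export
mcl_cluster <- function(graph, config = mcl_config(), sequences = NULL) {
  if (igraph::vcount(graph) == 0) halopan_error("empty graph")
  genome_of <- igraph::vertex_attr(graph, "genome")
  names(genome_of) <- igraph::V(graph)$name
  comp <- igraph::components(graph)
  clusters <- list()
  any_nonconv <- FALSE
  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    node_ids <- igraph::V(graph)$name[vids]
    if (length(vids) == 1L) {
      clusters[[length(clusters) + 1L]] <- node_ids
      next
    }
    sub <- igraph::induced_subgraph(graph, vids)
    a <- as.matrix(igraph::as_adjacency_matrix(sub, attr = "weight",
                                               sparse = TRUE))
    if (config$add_self_loops) {
      mx <- apply(a, 2L, max)
      diag(a) <- ifelse(mx > 0, mx, 1)
    }
    it <- mcl_iterate(a, config)
    if (!it$converged) any_nonconv <- TRUE
    cl <- mcl_interpret(it$m, igraph::V(sub)$name, config$prune_threshold)
    clusters <- c(clusters, cl)
  }
  if (any_nonconv)
    warning("MCL did not converge within max_iterations on some components; ",
            "using the current matrix interpretation")
  clusters <- lapply(clusters, sort)
  sizes <- lengths(clusters)
  first <- vapply(clusters, `[`, character(1), 1L)
  ord <- order(-sizes, first)
  clusters <- clusters[ord]
  names(clusters) <- sprintf("C%05d", seq_along(clusters))
  membership <- setNames(rep(names(clusters), lengths(clusters)),
                         unlist(clusters, use.names = FALSE))
  reps <- vapply(clusters, function(mem) {
    if (is.null(sequences)) return(min(mem))
    sl <- nchar(as.character(sequences[mem]))
    mem[order(-sl, mem)][1L]
  }, character(1))
  structure(list(membership = membership, clusters = clusters,
                 representatives = reps, genome_of = genome_of),
            class = "ortholog_clusters")
}

#' @export
print.ortholog_clusters <- function(x, ...) {
  cat("ortholog_clusters:", length(x$clusters), "clusters over",
      length(x$membership), "proteins\n")
  cat("  size distribution:\n")
  print(table(lengths(x$clusters)))
  invisible(x)
}

#' Write clusters to a text file (one cluster per line: id TAB members)
#' @param clusters An `ortholog_clusters`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  lines <- vapply(names(clusters$clusters), function(cid)
    paste0(cid, "\t", paste(clusters$clusters[[cid]], collapse = " ")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
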