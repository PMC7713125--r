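## End-to-end pipeline: QC filter -> clustering -> pan matrix -> partition ->
## curves/fits -> trees -> ancestral reconstruction -> LCA report, with
## stage-named errors, per-stage seeds derived from one master seed, and a
## machine-readable summary.  Plus the evaluation harness against synthetic
## ground truth.

#' Pipeline configuration
#'
#' A declarative bundle of every stage's options; all defaults are echoed
#' into the run summary for provenance.  Exactly one of `input_dir` (a
#' directory of `<genome>.faa` files with optional `qc.tsv`) or `sim` (a
#' [sim_config()] to generate inputs) must be given.
#'
#' @param input_dir Directory of per-genome protein FASTA files.
#' @param sim A [sim_config()] for synthetic input.
#' @param output_dir Where artifacts are written.
#' @param min_completeness,max_contamination,force_include Genome QC filter
#'   (see [qc_filter_genomes()]).
#' @param hit_filter A [hit_filter_config()].
#' @param mcl An [mcl_config()].
#' @param softcore_fraction Softcore occupancy fraction.
#' @param n_permutations Genome orderings for the sampling curves.
#' @param bootstrap_replicates Bootstrap replicates for the core tree (0
#'   skips bootstrapping; the standalone [bootstrap_support()] default is
#'   500).
#' @param deletion Gap-site handling for distances.
#' @param max_core_tree_clusters Cap on strict-core clusters aligned for the
#'   core tree (smallest family ids first); `Inf` to use all.
#' @param wagner A [wagner_config()].
#' @param lca_leaves Tip labels whose MRCA is the ancestral-reconstruction
#'   target; `NULL` targets the root child with the larger clade.
#' @param outgroup Tip labels used to root the guide tree; `NULL` uses
#'   midpoint rooting.
#' @param guide_tree Optional externally computed rooted guide tree (path to
#'   a Newick file or a `phylo`) used for ancestral reconstruction instead of
#'   the in-run core tree.
#' @param seed Master seed; each stochastic stage derives its own stream.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, sim = NULL, output_dir,
                            min_completeness = 99, max_contamination = 5,
                            force_include = character(),
                            hit_filter = hit_filter_config(),
                            mcl = mcl_config(),
                            softcore_fraction = 0.95,
                            n_permutations = 10L,
                            bootstrap_replicates = 100L,
                            deletion = "complete",
                            max_core_tree_clusters = 60L,
                            wagner = wagner_config(),
                            lca_leaves = NULL, outgroup = NULL,
                            guide_tree = NULL, seed = 1L) {
  if (is.null(input_dir) == is.null(sim))
    halopan_error("give exactly one of input_dir or sim",
                  "halopan_config_error")
  if (!is.null(sim)) stopifnot(inherits(sim, "sim_config"))
  structure(list(input_dir = input_dir, sim = sim, output_dir = output_dir,
                 min_completeness = min_completeness,
                 max_contamination = max_contamination,
                 force_include = force_include, hit_filter = hit_filter,
                 mcl = mcl, softcore_fraction = softcore_fraction,
                 n_permutations = as.integer(n_permutations),
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 deletion = deletion,
                 max_core_tree_clusters = max_core_tree_clusters,
                 wagner = wagner, lca_leaves = lca_leaves,
                 outgroup = outgroup, guide_tree = guide_tree,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  message("[", stage, "] running")
  tryCatch(expr, error = function(e) {
    halopan_error(paste0("[", stage, "] ", conditionMessage(e)),
                  "halopan_stage_error")
  })
}

## default ancestral-reconstruction target: the root child with the larger
## clade (an internal, non-root node)
default_lca_node <- function(tree) {
  nt <- length(tree$tip.label)
  root <- nt + 1L
  kids <- tree$edge[tree$edge[, 1L] == root, 2L]
  sizes <- vapply(kids, function(k) {
    if (k <= nt) 1L else length(ape::extract.clade(tree, k)$tip.label)
  }, integer(1))
  kids <- kids[order(-sizes)]
  kids <- kids[kids > nt]
  if (!length(kids))
    halopan_error("guide tree has no internal non-root node to target")
  kids[1]
}

#' Run the full pan-genome pipeline
#'
#' Executes: input (read or simulate) -> genome QC filter -> all-vs-all
#' similarity, hit filter, BDBH graph, MCL clustering -> pan matrix and
#' occupancy partition (plus strict core) -> sampling curves, Tettelin fits
#' and openness -> core-gene tree (progressive alignment of strict-core
#' clusters, Poisson distances, NJ + ME, optional bootstrap) and pan-genome
#' parsimony tree -> Wagner-parsimony ancestral reconstruction on the rooted
#' guide tree -> LCA report.  All artifacts are written under
#' `config$output_dir` as each stage completes; the summary contains no
#' absolute paths or timestamps, so identical configurations (including the
#' seed) give byte-identical `summary.json`.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list: `summary` (what `summary.json`
#'   contains), plus the main in-memory objects (`clusters`, `pan_matrix`,
#'   `partition`, `curves`, `fits`, `core_tree`, `pan_tree`, `asr`, `lca`,
#'   `sim` when simulated).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sim <- NULL

  inputs <- with_stage("input", {
    if (!is.null(config$sim)) {
      sim <- simulate_pangenome(config$sim)
      write_pangenome(sim, file.path(out, "simulated"))
      read_proteomes(file.path(out, "simulated"))
    } else read_proteomes(config$input_dir)
  })

  retained <- with_stage("qc_filter", {
    if (!is.null(inputs$qc)) {
      qc_filter_genomes(inputs$qc, config$min_completeness,
                        config$max_contamination, config$force_include)
    } else names(inputs$proteomes)
  })
  proteomes <- inputs$proteomes[intersect(names(inputs$proteomes), retained)]
  if (!length(proteomes))
    halopan_error("[qc_filter] no genomes pass the QC filter",
                  "halopan_stage_error")

  clusters <- with_stage("clustering", {
    hits <- all_vs_all_hits(proteomes)
    fh <- filter_hits(hits, config$hit_filter)
    g <- build_bdbh_graph(fh)
    seqs <- unlist(unname(lapply(proteomes, function(ss)
      setNames(as.character(ss), sub("\\s.*$", "", names(ss))))))
    cl <- mcl_cluster(g, config$mcl, sequences = seqs)
    write_clusters(cl, file.path(out, "clusters.tsv"))
    cl
  })

  pm <- with_stage("pan_matrix", {
    m <- build_pan_matrix(clusters, names(proteomes))
    write_pan_matrix(m, file.path(out, "pan_matrix.tsv"))
    write_phylip_presence(m, file.path(out, "pan_matrix.phy"))
    m
  })
  part <- with_stage("partition", {
    p <- partition_occupancy(pm, config$softcore_fraction)
    write_partition_report(p, file.path(out, "partition.tsv"))
    p
  })
  strict <- extract_strict_core(pm, part)

  curves <- with_stage("curves", {
    cv <- sample_size_curves(pm, config$n_permutations, seed = config$seed)
    write_curves(cv, file.path(out, "curves.tsv"))
    cv
  })
  ## the 3-parameter exponential needs >= 4 curve points (genomes)
  fits <- openness <- NULL
  if (ncol(pm) >= 4L) {
    fits <- with_stage("tettelin_fit", {
      f <- list(pan = fit_tettelin(curves$pan), core = fit_tettelin(curves$core),
                new_genes = fit_tettelin(curves$new_genes))
      jsonlite::write_json(lapply(f, unclass), file.path(out, "fits.json"),
                           auto_unbox = TRUE, digits = NA)
      f
    })
    openness <- classify_openness(fits$new_genes)
  }

  seqs_by_id <- unlist(lapply(names(proteomes), function(g) {
    ss <- proteomes[[g]]
    setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  }))
  core_bits <- with_stage("core_tree", {
    use <- head(sort(strict), config$max_core_tree_clusters)
    if (length(use) < 1L || ncol(pm) < 3L) {
      list(tree = NULL, alignments = NULL)
    } else {
      alns <- lapply(use, function(fid) {
        mem <- clusters$clusters[[fid]]
        s <- seqs_by_id[mem]
        names(s) <- clusters$genome_of[mem]
        progressive_align(s)
      })
      names(alns) <- use
      tree <- if (config$bootstrap_replicates > 0L) {
        bootstrap_support(alns, replicates = config$bootstrap_replicates,
                          seed = config$seed, deletion = config$deletion)
      } else {
        dm <- concat_and_distance(alns, config$deletion)
        me_refine(neighbor_joining(dm), dm)
      }
      ape::write.tree(tree, file.path(out, "core_tree.nwk"))
      list(tree = tree, alignments = alns)
    }
  })

  pan_tree <- with_stage("pan_tree", {
    if (ncol(pm) < 3L) NULL else {
      pt <- pan_parsimony_tree(pm, seed = config$seed)
      ape::write.tree(pt$tree, file.path(out, "pan_tree.nwk"))
      pt
    }
  })

  asr <- lca <- NULL
  if (ncol(pm) >= 3L) {
    asr <- with_stage("ancestral_reconstruction", {
      guide <- config$guide_tree
      if (is.character(guide)) guide <- ape::read.tree(guide)
      if (is.null(guide)) {
        if (is.null(core_bits$tree))
          halopan_error("no core tree available and no guide tree supplied")
        guide <- if (!is.null(config$outgroup))
          root_on_outgroup(core_bits$tree, config$outgroup)
        else phangorn::midpoint(core_bits$tree)
      }
      guide$node.label <- NULL
      res <- wagner_parsimony(pm, guide, config$wagner)
      write_event_table(res, file.path(out, "events.tsv"))
      res
    })
    lca <- with_stage("lca_report", {
      target <- if (!is.null(config$lca_leaves)) config$lca_leaves
                else default_lca_node(asr$tree)
      rep <- classify_lca(asr, target)
      jsonlite::write_json(
        list(node_label = rep$label, n_total = rep$n_total,
             n_ancestral = length(rep$ancestral),
             n_derived = length(rep$derived),
             n_lost_on_branch = length(rep$losses_on_branch),
             pct_ancestral = rep$pct_ancestral,
             pct_derived = rep$pct_derived),
        file.path(out, "lca_report.json"), auto_unbox = TRUE, digits = NA)
      rep
    })
  }

  cfg_echo <- unclass(config)
  cfg_echo$input_dir <- NULL; cfg_echo$output_dir <- NULL
  cfg_echo$guide_tree <- if (is.null(config$guide_tree)) NULL else "supplied"
  cfg_echo <- lapply(cfg_echo, function(x) if (is.list(x)) unclass(x) else x)
  summary <- list(
    genomes_input = length(inputs$proteomes),
    genomes_retained = length(proteomes),
    n_proteins = sum(vapply(proteomes, length, integer(1))),
    n_clusters = length(clusters$clusters),
    partition = list(core = length(part$core),
                     softcore = length(part$softcore),
                     shell = length(part$shell), cloud = length(part$cloud)),
    strict_core = length(strict),
    openness = if (is.null(openness)) NULL else openness$status,
    new_genes_per_genome = if (is.null(openness)) NULL else
      openness$new_genes_per_genome,
    fits = if (is.null(fits)) NULL else lapply(fits, function(f)
      list(kappa = f$kappa, tau = f$tau, offset = f$offset)),
    core_tree_file = if (is.null(core_bits$tree)) NULL else "core_tree.nwk",
    pan_tree_file = if (is.null(pan_tree)) NULL else "pan_tree.nwk",
    pan_tree_score = if (is.null(pan_tree)) NULL else pan_tree$score,
    lca = if (is.null(lca)) NULL else
      list(node = lca$label, n_total = lca$n_total,
           n_ancestral = length(lca$ancestral),
           n_derived = length(lca$derived),
           pct_ancestral = lca$pct_ancestral,
           pct_derived = lca$pct_derived),
    config = cfg_echo,
    seed = config$seed
  )
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  structure(list(summary = summary, clusters = clusters, pan_matrix = pm,
                 partition = part, strict_core = strict, curves = curves,
                 fits = fits, openness = openness,
                 core_tree = core_bits$tree,
                 core_alignments = core_bits$alignments,
                 pan_tree = pan_tree, asr = asr, lca = lca, sim = sim,
                 output_dir = out),
            class = "pipeline_result")
}

#' Evaluate a pipeline run against simulated ground truth
#'
#' Reports: clustering adjusted Rand index against the planted families;
#' Robinson-Foulds distance between the inferred core tree and the true
#' tree; precision/recall of per-branch gain events (ancestral
#' reconstruction rerun on the true tree so branches are comparable, with
#' inferred clusters mapped to true families by member majority); and the
#' relative error of the reconstructed root family count.
#'
#' @param result A `pipeline_result` from a run on simulated data.
#' @param sim The matching `simulated_pangenome` (defaults to the one stored
#'   in the result).
#' @return data.frame with columns `metric`, `value`.
#' @export
evaluate_against_truth <- function(result, sim = result$sim) {
  stopifnot(inherits(result, "pipeline_result"))
  if (is.null(sim) || !inherits(sim, "simulated_pangenome"))
    halopan_error("ground truth (a simulated_pangenome) is required")
  truth <- sim$history
  prot <- sim$proteins
  memb <- result$clusters$membership
  if (!all(names(memb) %in% prot$protein_id))
    halopan_error("clustered proteins not present in the ground truth")
  truefam <- setNames(prot$family_id, prot$protein_id)[names(memb)]
  ari <- mclust::adjustedRandIndex(memb, truefam)

  rf <- NA_real_
  if (!is.null(result$core_tree)) {
    if (!setequal(result$core_tree$tip.label, truth$tree$tip.label))
      halopan_error("core-tree leaves do not match the true tree")
    rf <- phangorn::RF.dist(ape::unroot(result$core_tree),
                            ape::unroot(truth$tree))
  }

  ## map inferred clusters to true families by member majority
  fam_of_cluster <- vapply(result$clusters$clusters, function(mem) {
    tf <- truefam[mem]
    tt <- sort(table(tf), decreasing = TRUE)
    if (tt[1] / length(mem) > 0.5) names(tt)[1] else NA_character_
  }, character(1))

  asr_true <- wagner_parsimony(result$pan_matrix, truth$tree,
                               result$asr$config %||% wagner_config())
  nt <- length(truth$tree$tip.label)
  nn <- nt + truth$tree$Nnode
  inferred_gains <- character(0)
  for (i in seq_len(nn)) {
    ev <- asr_true$events[[i]]
    if (is.null(ev)) next
    mapped <- fam_of_cluster[ev$gained]
    mapped <- mapped[!is.na(mapped)]
    if (length(mapped)) inferred_gains <- c(inferred_gains, paste(i, mapped))
  }
  observable <- rownames(truth_pan_matrix(truth))
  true_gains <- character(0)
  for (i in seq_len(nn)) {
    ev <- truth$branch_events[[i]]
    if (is.null(ev) || !length(ev$gained)) next
    ## only families that survive to any leaf are observable
    obs <- intersect(ev$gained, observable)
    if (length(obs)) true_gains <- c(true_gains, paste(i, obs))
  }
  tp <- length(intersect(inferred_gains, true_gains))
  precision <- if (length(inferred_gains)) tp / length(inferred_gains) else NA_real_
  recall <- if (length(true_gains)) tp / length(true_gains) else NA_real_

  root_true <- length(truth$node_families[[nt + 1L]])
  root_inf <- sum(asr_true$states[, nt + 1L] > 0L)
  root_rel_err <- abs(root_inf - root_true) / root_true

  data.frame(
    metric = c("clustering_ari", "core_tree_rf", "gain_event_precision",
               "gain_event_recall", "root_size_relative_error"),
    value = c(ari, rf, precision, recall, root_rel_err)
  )
}
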