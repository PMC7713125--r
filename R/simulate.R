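## Synthetic pangenome generator: Yule tree, gene-content birth-death along
## branches, and protein sequence emission.  Everything is seeded through the
## config so a given SimConfig reproduces byte-identical output.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Configuration for the synthetic pangenome generator
#'
#' Bundles every tunable of the simulator.  Defaults describe a desk-scale
#' open-pangenome regime: a dozen genomes, a few hundred gene families, gene
#' gain outpacing loss, and within-family protein identity around 85--90%
#' against a uniform-random background.
#'
#' @param n_genomes Number of genomes (leaves of the simulated tree).
#' @param birth_rate Yule (pure-birth) speciation rate, per lineage per unit
#'   time.
#' @param root_families Number of gene families present at the root.
#' @param gain_rate Expected number of newly gained families per unit branch
#'   length (Poisson).
#' @param loss_rate Per-family loss rate per unit branch length; a family
#'   survives a branch of length `t` with probability `exp(-loss_rate * t)`.
#' @param mean_protein_len Mean ancestral protein length in residues; lengths
#'   are geometric with this mean, floored at 30.
#' @param substitution_rate Substitutions per site per unit branch length.
#'   Each substitution replaces a site with a uniformly chosen different
#'   residue.
#' @param target_genes_per_genome_range Integer pair giving the intended range
#'   of per-genome gene counts; recorded for validation and reporting (the
#'   realised counts are driven by `root_families`, `gain_rate` and
#'   `loss_rate`).
#' @param duplication_prob Probability that a family present in a genome
#'   carries a duplicated (paralogous) copy; default 0 so the strict core is
#'   clean unless paralogy is requested.
#' @param seed Integer master seed; each simulation stage derives its own
#'   stream from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_genomes = 6, root_families = 40, seed = 7)
#' sim <- simulate_pangenome(cfg)
#' length(sim$proteomes)
sim_config <- function(n_genomes = 12L, birth_rate = 1, root_families = 250L,
                       gain_rate = 12, loss_rate = 0.08,
                       mean_protein_len = 90, substitution_rate = 0.05,
                       target_genes_per_genome_range = c(180L, 320L),
                       duplication_prob = 0, seed = 1L) {
  cfg <- list(
    n_genomes = as.integer(n_genomes), birth_rate = birth_rate,
    root_families = as.integer(root_families), gain_rate = gain_rate,
    loss_rate = loss_rate, mean_protein_len = mean_protein_len,
    substitution_rate = substitution_rate,
    target_genes_per_genome_range = as.integer(target_genes_per_genome_range),
    duplication_prob = duplication_prob, seed = as.integer(seed)
  )
  if (cfg$n_genomes < 1L || cfg$root_families < 1L || cfg$mean_protein_len < 1)
    halopan_error("all counts must be positive", "halopan_config_error")
  if (cfg$birth_rate <= 0)
    halopan_error("birth_rate must be positive", "halopan_config_error")
  if (cfg$gain_rate < 0 || cfg$loss_rate < 0 || cfg$substitution_rate < 0 ||
      cfg$duplication_prob < 0 || cfg$duplication_prob > 1)
    halopan_error("rates must be nonnegative (duplication_prob in [0,1])",
                  "halopan_config_error")
  if (length(cfg$target_genes_per_genome_range) != 2L ||
      cfg$target_genes_per_genome_range[1] > cfg$target_genes_per_genome_range[2])
    halopan_error("target_genes_per_genome_range must be an ordered pair",
                  "halopan_config_error")
  structure(cfg, class = "sim_config")
}

#' Simulate a Yule (pure-birth) tree
#'
#' Simulates a rooted binary ultrametric tree under a pure-birth process with
#' rate `birth_rate`: starting from two lineages at the root, with `k` extant
#' lineages the next speciation occurs after an `Exp(k * birth_rate)` wait and
#' splits a uniformly chosen lineage; after the n-th lineage appears a final
#' `Exp(n * birth_rate)` epoch elapses before the present.  The expected
#' root-to-tip height is therefore `sum_{k=2..n} 1/(k * birth_rate)`.  With
#' `rescale = TRUE` branch lengths are divided by that expectation so the
#' height has unit mean, which makes the gain/loss and substitution rates of
#' the other generator stages directly interpretable.
#'
#' @param config A [sim_config()].
#' @param rescale Rescale branch lengths to unit expected height
#'   (default `TRUE`).
#' @return A rooted binary `phylo` with `n_genomes` leaves labelled
#'   `g01, g02, ...` and strictly positive branch lengths.
#' @export
simulate_tree <- function(config, rescale = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genomes
  if (n < 2L)
    halopan_error("n_genomes must be >= 2 to simulate a tree",
                  "halopan_config_error")
  set.seed(stage_seed(config$seed, "tree"))
  lam <- config$birth_rate

  ## node bookkeeping: internal nodes carry their split time; tips the final T
  parent <- c(NA_integer_, 1L, 1L)
  split_time <- c(0, NA, NA)           # NA until a node splits (or becomes tip)
  active <- c(2L, 3L)
  t_now <- 0
  for (k in 2:n) {
    t_now <- t_now + rexp(1L, k * lam)
    if (k == n) break
    i <- if (length(active) == 1L) 1L else sample.int(length(active), 1L)
    v <- active[i]
    split_time[v] <- t_now
    id1 <- length(parent) + 1L
    id2 <- length(parent) + 2L
    parent[c(id1, id2)] <- v
    split_time[c(id1, id2)] <- NA
    active <- c(active[-i], id1, id2)
  }
  split_time[active] <- t_now          # leaves end at the present

  is_tip <- !(seq_along(parent) %in% parent)
  ## renumber to ape convention: tips 1..n (preorder encounter), root n+1
  kids <- split(seq_along(parent)[-1L], parent[-1L])
  tip_no <- int_no <- integer(length(parent))
  tip_ct <- 0L; int_ct <- n
  num_of <- integer(length(parent))
  assign_no <- function(v) {
    if (is_tip[v]) {
      tip_ct <<- tip_ct + 1L
      num_of[v] <<- tip_ct
    } else {
      int_ct <<- int_ct + 1L
      num_of[v] <<- int_ct
      for (ch in kids[[as.character(v)]]) assign_no(ch)
    }
  }
  assign_no(1L)
  edge <- cbind(num_of[parent[-1L]], num_of[-1L])
  elen <- split_time[-1L] - split_time[parent[-1L]]
  ## order edges by parent then child for a canonical layout
  o <- order(edge[, 1L], edge[, 2L])
  tree <- structure(list(
    edge = edge[o, , drop = FALSE],
    edge.length = elen[o],
    tip.label = sprintf("g%02d", seq_len(n)),
    Nnode = n - 1L
  ), class = "phylo", order = "cladewise")
  if (rescale) {
    h_exp <- sum(1 / ((2:n) * lam))
    tree$edge.length <- tree$edge.length / h_exp
  }
  tree
}

#' Evolve gene-family content along a tree
#'
#' Plays a gene-content birth-death process down a rooted tree: the root
#' carries `root_families` families; on each branch of length `t`,
#' `Poisson(gain_rate * t)` new families are gained at uniform positions
#' along the branch and each family present is lost at rate `loss_rate`
#' (inherited families survive the branch with probability
#' `exp(-loss_rate * t)`; a family gained at position `s` survives the
#' remaining `t - s`).  Families gained and lost within the same branch are
#' unobservable anywhere and are not recorded.  Family identifiers are
#' globally unique, so a lost family is never regained.  Under this process
#' the expected family count at a node at depth `T` is
#' `R exp(-loss_rate T) + (gain_rate / loss_rate) (1 - exp(-loss_rate T))`.
#'
#' @param tree A rooted binary `phylo` with nonnegative branch lengths.
#' @param config A [sim_config()].
#' @return A `true_history` object: `tree`, `node_families` (list indexed by
#'   node number), `branch_events` (per child node: `gained`, `lost`) and
#'   `family_birth` (named vector mapping family id to the node at the bottom
#'   of its branch of origin; root families map to the root).
#' @export
evolve_gene_content <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"), inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    halopan_error("tree must have nonnegative branch lengths",
                  "halopan_tree_error")
  set.seed(stage_seed(config$seed, "content"))
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  root <- nt + 1L
  tr <- ape::reorder.phylo(tree, "cladewise")   # parents before children

  fam_id <- function(i) sprintf("F%05d", i)
  node_families <- vector("list", nn)
  branch_events <- vector("list", nn)
  root_fams <- fam_id(seq_len(config$root_families))
  node_families[[root]] <- root_fams
  family_birth <- setNames(rep(root, config$root_families), root_fams)
  next_id <- config$root_families

  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]; t <- tr$edge.length[e]
    inh <- node_families[[p]]
    p_loss <- 1 - exp(-config$loss_rate * t)
    lost <- if (length(inh) && p_loss > 0) inh[runif(length(inh)) < p_loss]
            else character(0)
    n_gain <- rpois(1L, config$gain_rate * t)
    if (n_gain > 0 && config$loss_rate > 0) {
      ## thin gains by loss over the remainder of the branch (gain position
      ## uniform on the branch)
      pos <- runif(n_gain)
      n_gain <- sum(runif(n_gain) < exp(-config$loss_rate * t * (1 - pos)))
    }
    gained <- if (n_gain > 0) fam_id(next_id + seq_len(n_gain)) else character(0)
    next_id <- next_id + n_gain
    node_families[[ch]] <- c(setdiff(inh, lost), gained)
    branch_events[[ch]] <- list(gained = gained, lost = lost)
    if (n_gain > 0) family_birth[gained] <- ch
  }
  structure(list(tree = tree, node_families = node_families,
                 branch_events = branch_events, family_birth = family_birth),
            class = "true_history")
}

## substitute ns sites of an integer-coded sequence, each replaced by a
## uniformly chosen different residue
substitute_sites <- function(s, ns) {
  if (ns == 0L) return(s)
  pos <- sample.int(length(s), ns, replace = TRUE)
  for (p in pos) s[p] <- ((s[p] - 1L + sample.int(19L, 1L)) %% 20L) + 1L
  s
}

#' Emit protein sequences for a simulated gene-content history
#'
#' Samples one ancestral sequence per family at its branch of origin and
#' evolves it down the subtree in which the family survives, accumulating
#' `Poisson(substitution_rate * length * t)` substitutions per branch.
#' Distinct families are sampled independently, so between-family identity
#' stays near the uniform background (~5%).
#'
#' @param history A `true_history` from [evolve_gene_content()].
#' @param config The same [sim_config()].
#' @return A `simulated_pangenome`: `proteomes` (named list of
#'   [Biostrings::AAStringSet], one per genome; sequence names carry the
#'   protein id and a `family=` tag used only for evaluation), `proteins`
#'   (data.frame protein_id / genome_id / family_id), `history`, `config`.
#' @export
emit_proteomes <- function(history, config) {
  stopifnot(inherits(history, "true_history"), inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "proteomes"))
  tree <- history$tree
  nt <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  elen <- setNames(tree$edge.length, tree$edge[, 2L])

  fams <- sort(names(history$family_birth))
  p_geom <- 1 / max(config$mean_protein_len - 30 + 1, 1)
  leaf_records <- lapply(seq_len(nt), function(i) list())

  descend <- function(node, fam, s) {
    if (node <= nt) {
      leaf_records[[node]][[fam]] <<- s
    }
    for (ch in kids[[as.character(node)]]) {
      if (fam %in% history$node_families[[ch]]) {
        ns <- rpois(1L, config$substitution_rate * length(s) * elen[[as.character(ch)]])
        descend(ch, fam, substitute_sites(s, ns))
      }
    }
  }
  for (fam in fams) {
    L <- 30L + rgeom(1L, p_geom)
    anc <- sample.int(20L, L, replace = TRUE)
    descend(history$family_birth[[fam]], fam, anc)
  }

  proteins <- list(); proteomes <- list()
  for (i in seq_len(nt)) {
    g <- tree$tip.label[i]
    recs <- leaf_records[[i]]
    fam_here <- sort(names(recs))
    ## optional paralogs: duplicated copy of the leaf sequence
    if (config$duplication_prob > 0 && length(fam_here)) {
      dup <- fam_here[runif(length(fam_here)) < config$duplication_prob]
      for (fm in dup) recs[[paste0(fm, "*dup")]] <- recs[[fm]]
      fam_here <- sort(names(recs))
    }
    ids <- sprintf("%s_p%04d", g, seq_along(fam_here))
    fam_clean <- sub("\\*dup$", "", fam_here)
    seqs <- vapply(fam_here, function(fm) paste(AA20[recs[[fm]]], collapse = ""),
                   character(1))
    ss <- Biostrings::AAStringSet(unname(seqs))
    names(ss) <- sprintf("%s family=%s", ids, fam_clean)
    proteomes[[g]] <- ss
    proteins[[g]] <- data.frame(protein_id = ids, genome_id = g,
                                family_id = fam_clean, stringsAsFactors = FALSE)
  }
  structure(list(proteomes = proteomes,
                 proteins = do.call(rbind, c(proteins, make.row.names = FALSE)),
                 history = history, config = config),
            class = "simulated_pangenome")
}

#' Simulate a complete pangenome with ground truth
#'
#' Convenience wrapper: [simulate_tree()], [evolve_gene_content()] and
#' [emit_proteomes()] in sequence, each on its own seed stream derived from
#' `config$seed`.
#'
#' @inheritParams simulate_tree
#' @return A `simulated_pangenome`; see [emit_proteomes()].
#' @export
simulate_pangenome <- function(config, rescale = TRUE) {
  tree <- simulate_tree(config, rescale = rescale)
  history <- evolve_gene_content(tree, config)
  emit_proteomes(history, config)
}

#' Presence/absence pan-matrix implied by a true history
#'
#' Builds the family-by-genome 0/1 matrix directly from the simulated
#' `node_families` at the leaves (no clustering involved); used as ground
#' truth when evaluating reconstruction stages.
#'
#' @param history A `true_history`.
#' @return Integer matrix, families x genomes.
#' @export
truth_pan_matrix <- function(history) {
  stopifnot(inherits(history, "true_history"))
  tree <- history$tree
  nt <- length(tree$tip.label)
  fams <- sort(unique(unlist(history$node_families[seq_len(nt)])))
  m <- matrix(0L, length(fams), nt, dimnames = list(fams, tree$tip.label))
  for (i in seq_len(nt)) m[history$node_families[[i]], i] <- 1L
  m[rowSums(m) > 0, , drop = FALSE]
}

#' Write a simulated pangenome to disk
#'
#' Writes one protein FASTA per genome (`<genome>.faa`), a QC table
#' (`qc.tsv`: genome_id, completeness, contamination) and the ground truth
#' (`truth.json`: Newick tree, per-node family sets, per-branch events).
#' Genomes listed in `qc_fail` are planted as QC failures (completeness 85,
#' contamination 8) so the quality filter can be exercised.
#'
#' @param sim A `simulated_pangenome`.
#' @param dir Output directory (created if needed).
#' @param qc_fail Character vector of genome ids to plant as QC failures.
#' @return `dir`, invisibly.
#' @export
write_pangenome <- function(sim, dir, qc_fail = character()) {
  stopifnot(inherits(sim, "simulated_pangenome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in names(sim$proteomes)) {
    Biostrings::writeXStringSet(sim$proteomes[[g]], file.path(dir, paste0(g, ".faa")))
  }
  genomes <- names(sim$proteomes)
  qc <- data.frame(genome_id = genomes,
                   completeness = ifelse(genomes %in% qc_fail, 85, 99.5),
                   contamination = ifelse(genomes %in% qc_fail, 8, 0.5))
  write.table(qc, file.path(dir, "qc.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  h <- sim$history
  nm <- node_names(h$tree)
  truth <- list(
    tree = ape::write.tree(h$tree),
    node_families = setNames(h$node_families, nm),
    branch_events = setNames(h$branch_events, nm),
    family_birth = setNames(as.list(nm[h$family_birth]), names(h$family_birth))
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a directory of per-genome protein FASTA files
#'
#' Reads every `*.faa` file (one genome per file, genome id = file stem) plus
#' an optional `qc.tsv` quality table.
#'
#' @param dir Input directory.
#' @return A `proteome_set`: list with `proteomes` (named list of
#'   `AAStringSet`) and `qc` (data.frame or `NULL`).
#' @export
read_proteomes <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.faa$", full.names = TRUE))
  if (!length(files))
    halopan_error(paste0("no .faa files found in ", dir))
  proteomes <- lapply(files, Biostrings::readAAStringSet)
  names(proteomes) <- sub("\\.faa$", "", basename(files))
  qc_path <- file.path(dir, "qc.tsv")
  qc <- if (file.exists(qc_path))
    read.table(qc_path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  else NULL
  structure(list(proteomes = proteomes, qc = qc), class = "proteome_set")
}
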