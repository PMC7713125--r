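## Pan-matrix construction, genome QC filtering, and the occupancy
## partition into core / softcore / shell / cloud plus the strict
## (single-copy) core.

#' Filter genomes on assembly completeness and contamination
#'
#' Retains genomes with completeness strictly above `min_completeness` and
#' contamination strictly below `max_contamination` (the thresholds used for
#' the halobacterial dataset are >99% and <5%), plus any `force_include`
#' genomes regardless of their QC values (incomplete outgroup genomes are
#' commonly forced back in to complete a phylogeny).
#'
#' @param records data.frame with columns `genome_id`, `completeness`,
#'   `contamination`.
#' @param min_completeness,max_contamination QC thresholds (percent).
#' @param force_include Genome ids retained regardless of QC.
#' @return Character vector of retained genome ids, in input order.
#' @export
qc_filter_genomes <- function(records, min_completeness = 99,
                              max_contamination = 5,
                              force_include = character()) {
  if (!nrow(records)) return(character(0))
  need <- c("genome_id", "completeness", "contamination")
  if (!all(need %in% names(records)))
    halopan_error("records must have genome_id, completeness, contamination")
  if (anyDuplicated(records$genome_id))
    halopan_error("duplicate genome ids in QC table")
  pass <- records$completeness > min_completeness &
    records$contamination < max_contamination
  keep <- pass | records$genome_id %in% force_include
  records$genome_id[keep]
}

#' Build the family-by-genome count matrix
#'
#' `counts[f, g]` is the number of members of family `f` contributed by
#' genome `g`; the total of the matrix equals the number of clustered
#' proteins.
#'
#' @param clusters An `ortholog_clusters` object, or a named character vector
#'   mapping protein id -> cluster id.
#' @param genome_ids Ordered genome ids (matrix columns).
#' @param genome_of Named protein -> genome mapping; defaults to the one
#'   stored in `clusters`.
#' @return Integer matrix (families x genomes) of class `pan_matrix`.
#' @export
build_pan_matrix <- function(clusters, genome_ids, genome_of = NULL) {
  if (inherits(clusters, "ortholog_clusters")) {
    membership <- clusters$membership
    genome_of <- genome_of %||% clusters$genome_of
  } else membership <- clusters
  if (is.null(genome_of))
    halopan_error("genome_of mapping is required")
  prot <- names(membership)
  g <- genome_of[prot]
  if (anyNA(g) || !all(g %in% genome_ids))
    halopan_error("cluster members from genomes outside genome_ids")
  tab <- table(factor(membership, levels = sort(unique(membership))),
               factor(g, levels = genome_ids))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m <- m[rowSums(m) > 0, , drop = FALSE]
  class(m) <- c("pan_matrix", class(m))
  m
}

#' Partition gene families by genome occupancy
#'
#' Occupancy is the number of genomes a family occurs in (with any copy
#' number).  Classes: core = occupancy `G`; softcore = occupancy at least
#' `ceil(softcore_fraction * G)` (a superset of core, as conventionally
#' reported); among non-softcore families, `M` is the modal occupancy (ties
#' to the smallest) and cloud = occupancy at most `M + cloud_offset`; shell is
#' the remainder.  The cloud rule formalises the "most populated non-core
#' cluster and its neighbouring clusters" heuristic and is configurable.
#'
#' @param matrix A `pan_matrix` (families x genomes).
#' @param softcore_fraction Softcore occupancy fraction (default 0.95).
#' @param cloud_offset Neighbouring occupancy classes joined to the mode for
#'   the cloud cutoff (default 1).
#' @return An `occupancy_partition`: family-id sets `core`, `softcore`
#'   (superset including core), `softcore_only`, `shell`, `cloud`; thresholds;
#'   and the occupancy vector.  `core`, `softcore_only`, `shell` and `cloud`
#'   partition the families.
#' @export
partition_occupancy <- function(matrix, softcore_fraction = 0.95,
                                cloud_offset = 1L) {
  if (!nrow(matrix) || ncol(matrix) < 2L)
    halopan_error("pan matrix must be nonempty with >= 2 genomes")
  G <- ncol(matrix)
  occ <- rowSums(matrix > 0)
  fams <- rownames(matrix)
  sc_thr <- ceiling(softcore_fraction * G)
  core <- fams[occ == G]
  softcore <- fams[occ >= sc_thr]
  rest <- occ[occ < sc_thr]
  if (length(rest)) {
    tab <- table(rest)
    M <- min(as.integer(names(tab)[tab == max(tab)]))
    cloud_thr <- M + cloud_offset
    cloud <- fams[occ < sc_thr & occ <= cloud_thr]
    shell <- fams[occ < sc_thr & occ > cloud_thr]
  } else {
    M <- NA_integer_; cloud_thr <- NA_integer_
    cloud <- character(0); shell <- character(0)
  }
  structure(list(core = core, softcore = softcore,
                 softcore_only = setdiff(softcore, core),
                 shell = shell, cloud = cloud,
                 softcore_threshold = as.integer(sc_thr),
                 cloud_threshold = as.integer(cloud_thr),
                 occupancy = occ), class = "occupancy_partition")
}

#' @export
print.occupancy_partition <- function(x, ...) {
  cat("occupancy partition (softcore reported as superset of core):\n")
  cat(sprintf("  core: %d  softcore: %d  shell: %d  cloud: %d\n",
              length(x$core), length(x$softcore), length(x$shell),
              length(x$cloud)))
  cat(sprintf("  softcore threshold: >= %d genomes; cloud threshold: <= %s\n",
              x$softcore_threshold, x$cloud_threshold))
  invisible(x)
}

#' Extract the strict (single-copy) core
#'
#' Core families with exactly one member in every genome: the true
#' single-copy orthologs used for concatenated core-gene trees.  Core
#' families carrying any paralogous (multi-copy) member are excluded.
#'
#' @param matrix A `pan_matrix`.
#' @param partition The [partition_occupancy()] result for `matrix`.
#' @return Character vector of strict-core family ids.
#' @export
extract_strict_core <- function(matrix, partition) {
  stopifnot(inherits(partition, "occupancy_partition"))
  core <- partition$core
  if (!length(core)) return(character(0))
  sub <- matrix[core, , drop = FALSE]
  core[apply(sub == 1L, 1L, all)]
}

#' Write / read a pan matrix as TSV
#'
#' TSV with a `family_id` column then one integer column per genome.
#' @param matrix A `pan_matrix`.
#' @param path File path.
#' @return `path` (writer) or the matrix (reader).
#' @export
write_pan_matrix <- function(matrix, path) {
  d <- data.frame(family_id = rownames(matrix), matrix, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pan_matrix
#' @export
read_pan_matrix <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                  stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- d$family_id
  class(m) <- c("pan_matrix", class(m))
  m
}

#' Write the binary presence matrix in relaxed PHYLIP format
#'
#' One row per genome: name, whitespace, then a 0/1 string over families
#' (presence of any copy), suitable for discrete-character parsimony
#' programs.
#'
#' @param matrix A `pan_matrix`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_phylip_presence <- function(matrix, path) {
  pres <- t(matrix > 0) * 1L
  lines <- c(sprintf("%d %d", nrow(pres), ncol(pres)),
             vapply(seq_len(nrow(pres)), function(i)
               paste0(rownames(pres)[i], "  ",
                      paste(pres[i, ], collapse = "")), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write the per-family partition report (family_id, occupancy, class)
#' @param partition An `occupancy_partition`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_partition_report <- function(partition, path) {
  fams <- names(partition$occupancy)
  cls <- rep("shell", length(fams))
  cls[fams %in% partition$cloud] <- "cloud"
  cls[fams %in% partition$softcore_only] <- "softcore"
  cls[fams %in% partition$core] <- "core"
  d <- data.frame(family_id = fams, occupancy = partition$occupancy,
                  class = cls)
  write.table(d[order(d$family_id), ], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
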