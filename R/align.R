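## Protein similarity search: Smith-Waterman local alignment (BLOSUM62,
## affine gaps) with a Gumbel-calibrated E-value, plus the seeded all-vs-all
## driver used by the clustering stage.  A k-mer prefilter keeps the search
## desk-scale; the decision contract downstream (coverage / E-value
## thresholds) is unaffected by it for homologous pairs.

#' Alignment scoring scheme
#'
#' @param matrix Name of a substitution matrix shipped with Biostrings
#'   (default `"BLOSUM62"`).
#' @param gap_open Gap opening penalty (positive; default 11).
#' @param gap_extend Gap extension penalty per residue (positive; default 1).
#' @return An `align_scoring` object holding the resolved matrix.
#' @export
align_scoring <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  structure(list(matrix_name = matrix, matrix = get(matrix, envir = e),
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

valid_protein <- function(x) grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x)

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman local alignment under a substitution matrix with affine gap
#' penalties (a gap of length L costs `gap_open + L * gap_extend`).  Percent
#' identity is computed over aligned columns excluding gaps.  When no
#' alignment scores above zero the score is 0 and the spans are empty.
#'
#' @param seq_a,seq_b Protein sequences (character scalars, standard 20-letter
#'   alphabet).
#' @param scoring An [align_scoring()].
#' @return List with `score`, `query_span` and `subject_span` (0-based
#'   half-open residue intervals; `c(0, 0)` when empty) and
#'   `percent_identity`.
#' @export
#' @examples
#' local_align_score("MKVLA", "MKVLA")$percent_identity
local_align_score <- function(seq_a, seq_b, scoring = align_scoring()) {
  if (!nzchar(seq_a) || !nzchar(seq_b) ||
      !valid_protein(seq_a) || !valid_protein(seq_b))
    halopan_error("sequences must be nonempty standard-alphabet proteins")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b), type = "local",
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  s <- Biostrings::score(aln)
  if (s <= 0) {
    return(list(score = 0, query_span = c(0L, 0L), subject_span = c(0L, 0L),
                percent_identity = 0))
  }
  nm <- Biostrings::nmatch(aln); nmm <- Biostrings::nmismatch(aln)
  pat <- Biostrings::pattern(aln); sub <- Biostrings::subject(aln)
  list(score = s,
       query_span = c(Biostrings::start(pat) - 1L, Biostrings::end(pat)),
       subject_span = c(Biostrings::start(sub) - 1L, Biostrings::end(sub)),
       percent_identity = 100 * nm / (nm + nmm))
}

#' Calibrate an E-value surrogate for a scoring scheme
#'
#' Aligns shuffled (uniform-random) protein pairs and fits the Gumbel
#' (extreme-value) law that local alignment scores of unrelated sequences
#' follow, by the method of moments: `lambda = pi / (sd * sqrt(6))` and
#' `K = exp(lambda * mu) / (m * n)` with `mu = mean - gamma / lambda`.
#'
#' @param scoring An [align_scoring()].
#' @param n_pairs Number of decoy pairs to align.
#' @param seq_len Length of the decoy sequences.
#' @param seed Seed for decoy generation.
#' @return An `evalue_calibration` with `lambda`, `K` and the scheme id.
#' @export
calibrate_evalue <- function(scoring = align_scoring(), n_pairs = 300L,
                             seq_len = 120L, seed = 101L) {
  set.seed(stage_seed(seed, "calibration"))
  rnd <- function() paste(sample(AA20, seq_len, replace = TRUE), collapse = "")
  n_sub <- max(10L, ceiling(n_pairs / 10))
  scores <- numeric(0)
  while (length(scores) < n_pairs) {
    subj <- rnd()
    pats <- Biostrings::AAStringSet(vapply(seq_len(10L), function(i) rnd(),
                                           character(1)))
    aln <- Biostrings::pairwiseAlignment(
      pats, subj, type = "local", substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    scores <- c(scores, Biostrings::score(aln))
  }
  scores <- scores[seq_len(n_pairs)]
  beta <- sd(scores) * sqrt(6) / pi
  mu <- mean(scores) - 0.5772156649 * beta
  lambda <- 1 / beta
  K <- exp(lambda * mu) / (as.numeric(seq_len)^2)
  structure(list(lambda = lambda, K = K, seq_len = seq_len,
                 matrix_name = scoring$matrix_name,
                 gap_open = scoring$gap_open, gap_extend = scoring$gap_extend),
            class = "evalue_calibration")
}

#' Default (cached) E-value calibration for BLOSUM62 11/1
#' @return An `evalue_calibration`, computed once per session on a fixed
#'   internal seed.
#' @export
default_calibration <- function() {
  if (is.null(.halopan_cache$calibration))
    .halopan_cache$calibration <- calibrate_evalue()
  .halopan_cache$calibration
}

#' Estimate the E-value of a local alignment score
#'
#' `E = K * m * N * exp(-lambda * score)` with `m` the query length and `N`
#' the search-space length (the subject length for a pairwise comparison, or
#' the total residue count of the database for a database search).
#'
#' @param score Alignment score(s).
#' @param query_len,subject_len Sequence lengths.
#' @param database_size Total residues searched; defaults to `subject_len`.
#' @param calibration An `evalue_calibration` from [calibrate_evalue()].
#' @return Numeric E-value(s), strictly decreasing in score.
#' @export
estimate_evalue <- function(score, query_len, subject_len,
                            database_size = NULL,
                            calibration = default_calibration()) {
  if (!inherits(calibration, "evalue_calibration"))
    halopan_error("scoring scheme is not calibrated; run calibrate_evalue()",
                  "halopan_calibration_error")
  N <- database_size %||% subject_len
  calibration$K * query_len * N * exp(-calibration$lambda * score)
}

## unique k-mers of one sequence
seq_kmers <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character(0))
  unique(substring(s, 1:(L - k + 1L), k:L))
}

## Flatten proteomes input (simulated_pangenome, proteome_set, or a named
## list of AAStringSet) into sequences + genome mapping.
flatten_proteomes <- function(proteomes) {
  if (inherits(proteomes, "simulated_pangenome")) proteomes <- proteomes$proteomes
  if (inherits(proteomes, "proteome_set")) proteomes <- proteomes$proteomes
  if (!is.list(proteomes) || is.null(names(proteomes)))
    halopan_error("proteomes must be a named list of AAStringSet (one per genome)")
  ids <- character(0); gen <- character(0); seqs <- character(0)
  for (g in names(proteomes)) {
    ss <- proteomes[[g]]
    pid <- sub("\\s.*$", "", names(ss))
    ids <- c(ids, pid)
    gen <- c(gen, rep(g, length(ss)))
    seqs <- c(seqs, as.character(ss))
  }
  if (anyDuplicated(ids))
    halopan_error("protein ids are not unique across genomes")
  list(ids = ids, genome_of = setNames(gen, ids), seqs = setNames(seqs, ids))
}

#' All-vs-all protein similarity search
#'
#' Computes local alignments between all candidate protein pairs (within and
#' between genomes) and returns one similarity hit per direction.  Candidate
#' pairs are those sharing at least `min_kmer_share` k-mers, which prunes the
#' quadratic search to near-homologous pairs; unrelated uniform-background
#' pairs share essentially no 4-mers.  Self-hits are not emitted.
#'
#' @param proteomes A `simulated_pangenome`, `proteome_set`, or named list of
#'   `AAStringSet` (one per genome).
#' @param scoring An [align_scoring()].
#' @param calibration E-value calibration (defaults to the cached one).
#' @param kmer_k,min_kmer_share Prefilter: k-mer size and minimum shared
#'   distinct k-mers for a pair to be aligned.
#' @return data.frame of hits: `query`, `subject`, `score`, `evalue`,
#'   `pident`, `qcov`, `scov` (coverages are aligned span over sequence
#'   length, in `[0,1]`), plus a `genome_of` attribute.
#' @export
all_vs_all_hits <- function(proteomes, scoring = align_scoring(),
                            calibration = default_calibration(),
                            kmer_k = 4L, min_kmer_share = 3L) {
  fp <- flatten_proteomes(proteomes)
  seqs <- fp$seqs
  np <- length(seqs)
  if (np < 2L) halopan_error("need at least two proteins")
  lens <- nchar(seqs)
  total_res <- sum(lens)

  km_list <- lapply(seqs, seq_kmers, k = kmer_k)
  dt <- data.table(kmer = unlist(km_list, use.names = FALSE),
                   pid = rep(seq_len(np), lengths(km_list)))
  jj <- dt[dt, on = "kmer", allow.cartesian = TRUE][pid < i.pid]
  if (!nrow(jj)) {
    hits <- data.frame(query = character(0), subject = character(0),
                       score = numeric(0), evalue = numeric(0),
                       pident = numeric(0), qcov = numeric(0), scov = numeric(0))
    attr(hits, "genome_of") <- fp$genome_of
    return(hits)
  }
  pairs <- jj[, .N, by = .(a = pid, b = i.pid)][N >= min_kmer_share]
  setorder(pairs, a, b)

  out <- vector("list", length(unique(pairs$a)))
  k <- 0L
  for (ia in unique(pairs$a)) {
    jb <- pairs[a == ia, b]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(seqs[jb]), seqs[[ia]], type = "local",
      substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    sc <- Biostrings::score(aln)
    keep <- sc > 0
    if (!any(keep)) next
    jbk <- jb[keep]; alnk <- aln[keep]; sck <- sc[keep]
    nm <- Biostrings::nmatch(alnk); nmm <- Biostrings::nmismatch(alnk)
    pident <- 100 * nm / (nm + nmm)
    pat <- Biostrings::pattern(alnk); sub <- Biostrings::subject(alnk)
    span_b <- Biostrings::end(pat) - Biostrings::start(pat) + 1L
    span_a <- Biostrings::end(sub) - Biostrings::start(sub) + 1L
    cov_a <- span_a / lens[ia]; cov_b <- span_b / lens[jbk]
    ev_ab <- estimate_evalue(sck, lens[ia], lens[jbk], total_res, calibration)
    ev_ba <- estimate_evalue(sck, lens[jbk], lens[ia], total_res, calibration)
    k <- k + 1L
    out[[k]] <- data.frame(
      query = c(rep(fp$ids[ia], length(jbk)), fp$ids[jbk]),
      subject = c(fp$ids[jbk], rep(fp$ids[ia], length(jbk))),
      score = c(sck, sck), evalue = c(ev_ab, ev_ba),
      pident = c(pident, pident),
      qcov = c(cov_a, cov_b), scov = c(cov_b, cov_a),
      stringsAsFactors = FALSE)
  }
  hits <- if (k) do.call(rbind, out[seq_len(k)]) else
    data.frame(query = character(0), subject = character(0),
               score = numeric(0), evalue = numeric(0),
               pident = numeric(0), qcov = numeric(0), scov = numeric(0))
  hits <- hits[order(hits$query, hits$subject), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "genome_of") <- fp$genome_of
  hits
}

#' Read precomputed tabular similarity hits (BLAST outfmt-6-like)
#'
#' Adapter for externally computed searches.  Expected columns (no header):
#' query, subject, identity, alnlen, qstart, qend, sstart, send, evalue,
#' bitscore.  Coverages are derived from the spans and the supplied sequence
#' lengths.
#'
#' @param path TSV path.
#' @param seq_lengths Named integer vector of sequence lengths for every
#'   query/subject id.
#' @return Hits data.frame as in [all_vs_all_hits()].
#' @export
read_blast_tsv <- function(path, seq_lengths) {
  d <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(d) < 10) halopan_error("expected >= 10 tab-separated columns")
  names(d)[1:10] <- c("query", "subject", "pident", "alnlen", "qstart",
                      "qend", "sstart", "send", "evalue", "score")
  miss <- setdiff(unique(c(d$query, d$subject)), names(seq_lengths))
  if (length(miss))
    halopan_error(paste0("missing sequence lengths for: ",
                         paste(head(miss, 3), collapse = ", ")))
  d$qcov <- (d$qend - d$qstart + 1) / seq_lengths[d$query]
  d$scov <- (abs(d$send - d$sstart) + 1) / seq_lengths[d$subject]
  d[, c("query", "subject", "score", "evalue", "pident", "qcov", "scov")]
}
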