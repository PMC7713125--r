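## Core-gene and pan-genome tree machinery: an in-repo progressive profile
## aligner (desk-scale substitute for an external MSA tool), Poisson-corrected
## distances from concatenated strict-core alignments, neighbor-joining with
## minimum-evolution (NNI) refinement, column-bootstrap support, and a
## presence/absence parsimony tree.

## -- progressive alignment ---------------------------------------------------

## 20 x L residue-frequency profile of a character matrix (rows = sequences);
## gap columns get reduced total weight, which softly discourages aligning
## into gappy profile regions.
col_profile <- function(chm) {
  L <- ncol(chm)
  p <- matrix(0, 20L, L, dimnames = list(AA20, NULL))
  for (j in seq_len(L)) {
    tab <- table(chm[, j])
    tab <- tab[names(tab) != "-"]
    if (length(tab)) p[names(tab), j] <- as.numeric(tab) / nrow(chm)
  }
  p
}

## Global affine-gap alignment of two profiles; returns the merged character
## matrix.  Row-vectorised DP: the horizontal gap state is folded into a
## running maximum, so the inner loop is over rows only.
profile_align_merge <- function(Am, Bm, scoring) {
  B20 <- scoring$matrix[AA20, AA20]
  go <- scoring$gap_open; ge <- scoring$gap_extend
  pa <- col_profile(Am); pb <- col_profile(Bm)
  La <- ncol(Am); Lb <- ncol(Bm)
  S <- t(pa) %*% B20 %*% pb
  M <- X <- Y <- matrix(-Inf, La + 1L, Lb + 1L)
  M[1L, 1L] <- 0
  jj <- 0:Lb
  for (i in seq_len(La + 1L)) {
    if (i > 1L) {
      prevbest <- pmax(M[i - 1L, ], X[i - 1L, ], Y[i - 1L, ])
      M[i, 2:(Lb + 1L)] <- S[i - 1L, ] + prevbest[1:Lb]
      M[i, 1L] <- -Inf
      Y[i, ] <- pmax(M[i - 1L, ] - go - ge, Y[i - 1L, ] - ge)
    }
    v <- cummax(M[i, ] + ge * jj)
    X[i, 2:(Lb + 1L)] <- v[1:Lb] - go - ge * jj[2:(Lb + 1L)]
  }
  i <- La + 1L; j <- Lb + 1L
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  ops <- matrix(0L, 0L, 2L)
  tol <- 1e-9
  while (i > 1L || j > 1L) {
    if (state == 1L) {                   # match column
      ops <- rbind(ops, c(i - 1L, j - 1L))
      pb3 <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      i <- i - 1L; j <- j - 1L
      state <- which.max(pb3)
    } else if (state == 2L) {            # gap in A, consume B column
      ops <- rbind(ops, c(0L, j - 1L))
      state <- if (X[i, j] <= M[i, j - 1L] - go - ge + tol) 1L else 2L
      j <- j - 1L
    } else {                             # gap in B, consume A column
      ops <- rbind(ops, c(i - 1L, 0L))
      state <- if (Y[i, j] <= M[i - 1L, j] - go - ge + tol) 1L else 3L
      i <- i - 1L
    }
  }
  ops <- ops[rev(seq_len(nrow(ops))), , drop = FALSE]
  na <- nrow(Am); nb <- nrow(Bm)
  out <- matrix("-", na + nb, nrow(ops))
  for (k in seq_len(nrow(ops))) {
    if (ops[k, 1L] > 0L) out[1:na, k] <- Am[, ops[k, 1L]]
    if (ops[k, 2L] > 0L) out[(na + 1L):(na + nb), k] <- Bm[, ops[k, 2L]]
  }
  rownames(out) <- c(rownames(Am), rownames(Bm))
  out
}

#' Progressive multiple alignment of one gene family
#'
#' Deterministic progressive aligner: a guide order is taken from UPGMA
#' (average-linkage) clustering of pairwise k-mer distances, and profiles are
#' merged by global profile-profile alignment with affine gap penalties.
#' Intended for desk-scale single-copy families; an externally computed
#' alignment can be substituted anywhere an alignment is accepted.
#'
#' @param sequences Named character vector or `AAStringSet` (>= 1 sequence).
#' @param scoring An [align_scoring()].
#' @return Named character vector of equal-length aligned sequences (gap
#'   `"-"`), in the input order.
#' @export
progressive_align <- function(sequences, scoring = align_scoring()) {
  x <- as.character(sequences)
  nms <- names(sequences)
  if (is.null(nms)) nms <- paste0("s", seq_along(x))
  names(x) <- nms
  if (length(x) == 1L) return(x)
  mats <- lapply(nms, function(nm) {
    m <- matrix(strsplit(x[[nm]], "")[[1]], nrow = 1L)
    rownames(m) <- nm
    m
  })
  if (length(x) == 2L) {
    merged <- profile_align_merge(mats[[1]], mats[[2]], scoring)
  } else {
    km <- lapply(x, seq_kmers, k = 3L)
    n <- length(x)
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      sh <- length(intersect(km[[i]], km[[j]]))
      D[i, j] <- D[j, i] <- 1 - sh / max(1L, min(length(km[[i]]), length(km[[j]])))
    }
    hc <- hclust(as.dist(D), method = "average")
    node <- vector("list", n - 1L)
    getm <- function(k) if (k < 0) mats[[-k]] else node[[k]]
    for (r in seq_len(nrow(hc$merge))) {
      node[[r]] <- profile_align_merge(getm(hc$merge[r, 1L]),
                                       getm(hc$merge[r, 2L]), scoring)
    }
    merged <- node[[n - 1L]]
  }
  out <- apply(merged[nms, , drop = FALSE], 1L, paste, collapse = "")
  out[nms]
}

## -- distances ---------------------------------------------------------------

## Concatenate a list of alignments (shared taxon set) into one character
## matrix, taxa x sites, clusters taken in name order.
concat_alignment <- function(alignments) {
  if (!length(alignments)) halopan_error("no alignments supplied")
  if (is.null(names(alignments)))
    names(alignments) <- sprintf("aln%04d", seq_along(alignments))
  taxa <- sort(names(alignments[[1]]))
  for (a in alignments)
    if (!setequal(names(a), taxa))
      halopan_error("alignments do not share the same taxon set")
  ord <- order(names(alignments))
  big <- vapply(taxa, function(tx)
    paste(vapply(alignments[ord], function(a) a[[tx]], character(1)),
          collapse = ""), character(1))
  chm <- do.call(rbind, strsplit(big, ""))
  rownames(chm) <- taxa
  chm
}

distance_from_chars <- function(chm, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  taxa <- rownames(chm)
  n <- length(taxa)
  if (deletion == "complete") {
    chm <- chm[, colSums(chm == "-") == 0L, drop = FALSE]
    if (!ncol(chm)) halopan_error("no gap-free columns under complete deletion")
  }
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- chm[i, ]; b <- chm[j, ]
    comp <- a != "-" & b != "-"
    nc <- sum(comp)
    if (!nc) halopan_error(paste0("no comparable sites for ", taxa[i], "-", taxa[j]))
    p <- sum(a[comp] != b[comp]) / nc
    if (p >= 1)
      halopan_error(paste0("saturated distance (p >= 1) for pair ",
                           taxa[i], "-", taxa[j]), "halopan_saturation_error")
    d[i, j] <- d[j, i] <- -log(1 - p)
  }
  d
}

#' Concatenate alignments and compute Poisson-corrected distances
#'
#' Concatenates per-cluster alignments (one sequence per taxon, as the strict
#' core guarantees) in cluster-name order and computes, per taxon pair, the
#' proportion `p` of differing sites, Poisson-corrected to
#' `d = -ln(1 - p)`.  Gapped sites are handled by complete deletion (default:
#' only columns without gaps in any taxon) or pairwise deletion.
#'
#' @param alignments Named list of alignments from [progressive_align()].
#' @param deletion `"complete"` or `"pairwise"`.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
concat_and_distance <- function(alignments,
                                deletion = c("complete", "pairwise")) {
  distance_from_chars(concat_alignment(alignments), deletion)
}

## -- trees -------------------------------------------------------------------

## Clamp negative branch lengths to zero, transferring the deficit to a
## sister edge so path lengths are approximately preserved (MEGA convention).
clamp_negative_branches <- function(tree) {
  for (pass in 1:10) {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) break
    e <- neg[1]
    p <- tree$edge[e, 1L]
    sib <- setdiff(which(tree$edge[, 1L] == p), e)
    def <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sib)) tree$edge.length[sib[1]] <- tree$edge.length[sib[1]] + def
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining; negative branch lengths are clamped to zero
#' with the deficit moved to a sister edge.  Two taxa give a single edge
#' split evenly; at least three are needed for a proper unrooted tree.
#'
#' @param dm Symmetric distance matrix with dimnames (or `dist`).
#' @return An unrooted `phylo`.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 2L) halopan_error("need at least 2 taxa")
  if (n == 2L) {
    h <- dm[1, 2] / 2
    return(ape::read.tree(text = sprintf("(%s:%.10g,%s:%.10g);",
                                         rownames(dm)[1], h, rownames(dm)[2], h)))
  }
  tr <- ape::nj(as.dist(dm))
  clamp_negative_branches(tr)
}

## OLS branch lengths for a topology; returns the fitted tree (lengths >= 0).
ols_branch_lengths <- function(tree, dm) {
  phangorn::nnls.tree(as.dist(as.matrix(dm)), tree, method = "unrooted",
                      trace = 0)
}

#' Minimum-evolution refinement by nearest-neighbor interchange
#'
#' Hill-climbs over NNI rearrangements, re-estimating branch lengths by
#' ordinary least squares at each step and keeping a move only if it reduces
#' the total tree length; stops at a local optimum, so the tree length never
#' increases.
#'
#' @param tree Starting tree (e.g. from [neighbor_joining()]).
#' @param dm The distance matrix the tree summarises.
#' @return The refined unrooted `phylo` with OLS branch lengths.
#' @export
me_refine <- function(tree, dm) {
  dm <- as.matrix(dm)
  if (!setequal(tree$tip.label, rownames(dm)))
    halopan_error("tree leaves do not match distance matrix taxa")
  cur <- ols_branch_lengths(ape::unroot(tree), dm)
  cur_len <- sum(cur$edge.length)
  if (length(tree$tip.label) < 4L) return(cur)
  repeat {
    nbs <- phangorn::nni(cur)
    fits <- lapply(nbs, ols_branch_lengths, dm = dm)
    lens <- vapply(fits, function(t) sum(t$edge.length), numeric(1))
    i <- which.min(lens)
    if (lens[i] < cur_len - 1e-9) {
      cur <- fits[[i]]; cur_len <- lens[i]
    } else break
  }
  cur
}

#' Bootstrap support for a distance tree
#'
#' Resamples columns of the concatenated alignment with replacement,
#' rebuilds a tree per replicate, and reports for each internal edge of the
#' main tree the percentage of replicates containing that bipartition (stored
#' in `node.label`).
#'
#' @param alignments Named list of alignments (see [concat_and_distance()]).
#' @param tree_builder Function distance-matrix -> `phylo`; the default is
#'   NJ followed by [me_refine()].
#' @param replicates Number of bootstrap replicates (default 500).
#' @param seed Seed for resampling.
#' @param deletion Gap-site handling, as in [concat_and_distance()].
#' @return The main tree with percentage supports in `node.label`.
#' @export
bootstrap_support <- function(alignments, tree_builder = NULL,
                              replicates = 500L, seed = 1L,
                              deletion = "complete") {
  if (replicates < 1L) halopan_error("replicates must be >= 1")
  if (is.null(tree_builder))
    tree_builder <- function(d) me_refine(neighbor_joining(d), d)
  chm <- concat_alignment(alignments)
  main <- tree_builder(distance_from_chars(chm, deletion))
  set.seed(stage_seed(seed, "boot"))
  boot <- vector("list", replicates)
  ok <- 0L
  for (r in seq_len(replicates)) {
    idx <- sample.int(ncol(chm), replace = TRUE)
    tr <- tryCatch(tree_builder(distance_from_chars(chm[, idx, drop = FALSE],
                                                    deletion)),
                   halopan_error = function(e) NULL)
    if (!is.null(tr)) { ok <- ok + 1L; boot[[ok]] <- tr }
  }
  if (!ok) halopan_error("all bootstrap replicates failed")
  cnt <- ape::prop.clades(main, boot[seq_len(ok)], rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  main$node.label <- round(100 * cnt / ok, 1)
  attr(main, "bootstrap_replicates") <- ok
  main
}

#' Pan-genome parsimony tree from gene-family presence/absence
#'
#' Treats each family's presence/absence across genomes as a binary
#' character, scores topologies by Fitch parsimony (total state changes over
#' all families), and searches by random stepwise addition with NNI
#' refinement over several restarts.  An all-constant matrix yields a star
#' tree with score 0 and a warning.
#'
#' @param matrix A `pan_matrix` (counts; any positive count is presence).
#' @param restarts Random-addition restarts (default 10).
#' @param seed Seed for the search.
#' @return List with `tree` (unrooted `phylo`) and `score` (parsimony score).
#' @export
pan_parsimony_tree <- function(matrix, restarts = 10L, seed = 1L) {
  if (ncol(matrix) < 3L) halopan_error("need at least 3 genomes")
  pres <- matrix > 0
  variable <- rowSums(pres) > 0L & rowSums(pres) < ncol(pres)
  if (!any(variable)) {
    warning("all families constant; returning a star tree with score 0")
    star <- ape::stree(ncol(matrix), type = "star")
    star$tip.label <- colnames(matrix)
    return(list(tree = star, score = 0))
  }
  chm <- t(pres) * 1L
  storage.mode(chm) <- "character"
  pd <- phangorn::phyDat(chm, type = "USER", levels = c("0", "1"))
  set.seed(stage_seed(seed, "pantree"))
  best <- NULL; best_score <- Inf
  for (r in seq_len(restarts)) {
    tr0 <- phangorn::random.addition(pd)
    tr <- phangorn::optim.parsimony(tr0, pd, rearrangements = "NNI", trace = 0)
    sc <- phangorn::parsimony(tr, pd)
    if (sc < best_score) { best <- tr; best_score <- sc }
  }
  best$edge.length <- NULL
  list(tree = best, score = as.numeric(best_score))
}

#' Root a tree on a named outgroup
#' @param tree Unrooted (or rooted) `phylo`.
#' @param outgroup Tip label(s) forming the outgroup.
#' @return Rooted `phylo`.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  miss <- setdiff(outgroup, tree$tip.label)
  if (length(miss))
    halopan_error(paste0("outgroup tips not in tree: ",
                         paste(miss, collapse = ", ")))
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}
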