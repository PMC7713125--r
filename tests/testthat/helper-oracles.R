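## Independent oracles used across the suite.  These deliberately avoid the
## package's own code paths (plain recursion / exhaustive enumeration /
## dense-loop reimplementations) so that agreement is informative.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

## Brute-force optimal local alignment score: enumerate all substring pairs
## and, for each, all gapped global alignments by plain recursion (affine
## gaps: first gap residue costs go + ge, extensions ge).
oracle_local_score <- function(a, b, B = blosum62, go = 11, ge = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  glob <- function(x, y) {
    rec <- function(i, j, last) {
      if (i > length(x) && j > length(y)) return(0)
      out <- -Inf
      if (i <= length(x) && j <= length(y))
        out <- max(out, B[x[i], y[j]] + rec(i + 1L, j + 1L, 0L))
      if (i <= length(x))
        out <- max(out, -(if (last == 1L) ge else go + ge) + rec(i + 1L, j, 1L))
      if (j <= length(y))
        out <- max(out, -(if (last == 2L) ge else go + ge) + rec(i, j + 1L, 2L))
      out
    }
    rec(1L, 1L, 0L)
  }
  best <- 0
  for (i1 in seq_along(av)) for (i2 in i1:length(av))
    for (j1 in seq_along(bv)) for (j2 in j1:length(bv))
      best <- max(best, glob(av[i1:i2], bv[j1:j2]))
  best
}

## Independent dense-matrix MCL iteration mirroring the documented
## conventions (self loops = column max, expansion 2, prune, renormalise);
## returns the partition as a sorted list of sorted member sets.
oracle_mcl <- function(adj, inflation = 2, prune = 1e-5, iters = 200) {
  m <- adj
  n <- nrow(m)
  for (j in seq_len(n)) {
    mx <- max(m[, j])
    m[j, j] <- if (mx > 0) mx else 1
  }
  normc <- function(x) {
    for (j in seq_len(ncol(x))) {
      s <- sum(x[, j])
      if (s > 0) x[, j] <- x[, j] / s
    }
    x
  }
  m <- normc(m)
  for (it in seq_len(iters)) {
    prev <- m
    m <- m %*% m
    m <- m^inflation
    m[m < prune] <- 0
    m <- normc(m)
    if (max(abs(m - prev)) < 1e-6) break
  }
  att <- which(diag(m) > prune)
  cl <- unique(lapply(att, function(a) sort(which(m[a, ] > prune))))
  assigned <- rep(NA_integer_, n)
  ord <- order(-lengths(cl), vapply(cl, min, numeric(1)))
  for (ci in ord) {
    idx <- cl[[ci]]
    assigned[idx[is.na(assigned[idx])]] <- ci
  }
  for (i in which(is.na(assigned))) assigned[i] <- max(assigned, na.rm = TRUE) + i
  unname(lapply(split(seq_len(n), assigned), sort))
}

## Fitch change count for one binary character on a rooted binary tree.
oracle_fitch <- function(tree, pres) {
  nt <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  cnt <- 0L
  rec <- function(v) {
    if (v <= nt) return(as.integer(pres[[tree$tip.label[v]]]))
    ss <- lapply(kids[[as.character(v)]], rec)
    isec <- Reduce(intersect, ss)
    if (length(isec)) return(isec)
    cnt <<- cnt + 1L
    Reduce(union, ss)
  }
  rec(nt + 1L)
  cnt
}

## Exhaustive Wagner objective for one binary family: minimum over all
## internal-state assignments of branch event costs plus the root
## origination charge.
oracle_wagner_objective <- function(tree, pres, gain, loss) {
  nt <- length(tree$tip.label)
  ni <- tree$Nnode
  best <- Inf
  tipst <- as.integer(pres[tree$tip.label])
  for (mask in 0:(2^ni - 1L)) {
    st <- c(tipst, bitwAnd(bitwShiftR(mask, 0:(ni - 1L)), 1L))
    cost <- gain * st[nt + 1L]
    for (e in seq_len(nrow(tree$edge))) {
      d <- st[tree$edge[e, 2L]] - st[tree$edge[e, 1L]]
      cost <- cost + (if (d > 0L) gain else if (d < 0L) loss else 0)
    }
    if (cost < best) best <- cost
  }
  best
}

## Total Fitch parsimony score of a presence/absence matrix on an (unrooted)
## topology, via oracle_fitch after arbitrary rooting.
oracle_matrix_fitch <- function(tree, pres_mat) {
  rt <- ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  sum(apply(pres_mat, 1L, function(row) {
    oracle_fitch(rt, setNames(as.logical(row), colnames(pres_mat)))
  }))
}

## Exhaustive sum-of-pairs optimum for three short sequences under linear
## gap cost g per gap residue (3D dynamic program, coded independently).
oracle_sp3 <- function(s1, s2, s3, B = blosum62, g = 12) {
  x <- strsplit(s1, "")[[1]]; y <- strsplit(s2, "")[[1]]; z <- strsplit(s3, "")[[1]]
  l1 <- length(x); l2 <- length(y); l3 <- length(z)
  col_sc <- function(a, b, c) {
    pair <- function(p, q) {
      if (is.na(p) && is.na(q)) 0
      else if (is.na(p) || is.na(q)) -g
      else B[p, q]
    }
    pair(a, b) + pair(a, c) + pair(b, c)
  }
  D <- array(-Inf, c(l1 + 1L, l2 + 1L, l3 + 1L))
  D[1, 1, 1] <- 0
  for (i in 0:l1) for (j in 0:l2) for (k in 0:l3) {
    if (i + j + k == 0) next
    best <- -Inf
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      if (di + dj + dk == 0) next
      if (i - di < 0 || j - dj < 0 || k - dk < 0) next
      prev <- D[i - di + 1L, j - dj + 1L, k - dk + 1L]
      if (!is.finite(prev)) next
      sc <- col_sc(if (di) x[i] else NA, if (dj) y[j] else NA,
                   if (dk) z[k] else NA)
      best <- max(best, prev + sc)
    }
    D[i + 1L, j + 1L, k + 1L] <- best
  }
  D[l1 + 1L, l2 + 1L, l3 + 1L]
}

## Sum-of-pairs score of an alignment under the same linear scheme.
sp_score <- function(aln, B = blosum62, g = 12) {
  m <- do.call(rbind, strsplit(unname(aln), ""))
  total <- 0
  for (i in seq_len(nrow(m) - 1L)) for (j in (i + 1L):nrow(m)) {
    a <- m[i, ]; b <- m[j, ]
    both <- a != "-" & b != "-"
    one <- xor(a != "-", b != "-")
    total <- total + sum(B[cbind(a[both], b[both])]) - g * sum(one)
  }
  total
}

## Shared helper: flatten a simulated pangenome's sequences to a named
## character vector keyed by protein id.
sim_sequences <- function(sim) {
  unlist(unname(lapply(names(sim$proteomes), function(g) {
    ss <- sim$proteomes[[g]]
    setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  })))
}

## Per-branch true gain pairs ("node famid"), restricted to families
## observable at the leaves.
true_gain_pairs <- function(history) {
  nt <- length(history$tree$tip.label)
  nn <- nt + history$tree$Nnode
  observable <- rownames(truth_pan_matrix(history))
  out <- character(0)
  for (i in seq_len(nn)) {
    ev <- history$branch_events[[i]]
    if (is.null(ev) || !length(ev$gained)) next
    obs <- intersect(ev$gained, observable)
    if (length(obs)) out <- c(out, paste(i, obs))
  }
  out
}
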