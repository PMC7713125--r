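test_that("progressive alignment handles trivial and pairwise cases", {
  ## identical sequences align gap-free
  al <- progressive_align(c(a = "MKVLAWPT", b = "MKVLAWPT", c = "MKVLAWPT"))
  expect_false(any(grepl("-", al)))
  expect_equal(unname(nchar(al)), rep(8L, 3))

  ## single sequence returned unchanged
  expect_equal(progressive_align(c(x = "MKV")), c(x = "MKV"))

  ## two sequences reduce to the optimal pairwise global alignment score
  set.seed(3)
  for (i in 1:5) {
    x <- paste(sample(halopan:::AA20, 12, TRUE), collapse = "")
    y <- paste(sample(halopan:::AA20, 9, TRUE), collapse = "")
    al2 <- progressive_align(c(p = x, q = y))
    aa <- strsplit(al2[["p"]], "")[[1]]; bb <- strsplit(al2[["q"]], "")[[1]]
    sc <- 0; run <- 0
    for (k in seq_along(aa)) {
      if (aa[k] == "-" || bb[k] == "-") {
        sc <- sc - (if (run > 0) 1 else 12); run <- run + 1
      } else {
        sc <- sc + blosum62[aa[k], bb[k]]; run <- 0
      }
    }
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      x, y, type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1))
    expect_equal(sc, ref, info = paste(x, y))
  }
})

test_that("three-way alignments reach 95% of the exhaustive sum-of-pairs optimum", {
  ## the exhaustive 3D oracle scores gaps linearly, so the aligner is run
  ## with the linear-equivalent scheme (open 0, extend 12); sequences are
  ## divergent copies of one ancestor, the aligner's intended regime
  lin <- align_scoring(gap_open = 0, gap_extend = 12)
  set.seed(8)
  mutate <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    pos <- sample(seq_along(v), k)
    v[pos] <- sample(halopan:::AA20, k, TRUE)
    paste(v, collapse = "")
  }
  for (i in 1:5) {
    anc <- paste(sample(halopan:::AA20, 8, TRUE), collapse = "")
    ss <- c(a = mutate(anc, 2), b = mutate(anc, 2), c = mutate(anc, 1))
    al <- progressive_align(ss, scoring = lin)
    got <- sp_score(al)
    opt <- oracle_sp3(ss[1], ss[2], ss[3])
    expect_gte(got, ifelse(opt > 0, 0.95 * opt, opt / 0.95))
  }
})

test_that("Poisson-corrected distances follow the closed form", {
  ## identical -> 0
  al <- list(c1 = c(a = "MKVL", b = "MKVL"))
  expect_equal(max(concat_and_distance(al)), 0)

  ## p = 0.1 -> -ln(0.9)
  a <- paste(rep("A", 10), collapse = "")
  b <- paste(c(rep("A", 9), "C"), collapse = "")
  d <- concat_and_distance(list(c1 = c(x = a, y = b)))
  expect_equal(d["x", "y"], 0.105360516, tolerance = 1e-8)

  ## saturation error names the pair
  e <- tryCatch(concat_and_distance(list(c1 = c(x = "AAAA", y = "CCCC"))),
                halopan_saturation_error = function(e) conditionMessage(e))
  expect_match(e, "x-y")

  ## 4-taxon toy against an independent site-by-site count
  set.seed(12)
  chm <- matrix(sample(c("A", "C", "D", "-"), 4 * 60, TRUE,
                       prob = c(.4, .3, .2, .1)), 4, 60,
                dimnames = list(paste0("t", 1:4), NULL))
  aln <- list(c1 = setNames(apply(chm, 1, paste, collapse = ""),
                            rownames(chm)))
  for (mode in c("complete", "pairwise")) {
    d2 <- concat_and_distance(aln, deletion = mode)
    for (i in 1:3) for (j in (i + 1):4) {
      a2 <- chm[i, ]; b2 <- chm[j, ]
      keep <- if (mode == "complete") colSums(chm == "-") == 0
              else a2 != "-" & b2 != "-"
      p <- sum(a2[keep] != b2[keep]) / sum(keep)
      expect_equal(d2[i, j], -log(1 - p), info = mode)
    }
  }

  ## concatenation requires a shared taxon set
  expect_error(concat_and_distance(list(c1 = c(a = "MK", b = "MK"),
                                        c2 = c(a = "MK", z = "MK"))),
               class = "halopan_input_error")
})

test_that("NJ recovers additive trees exactly and solves 3 taxa in closed form", {
  tr <- ape::read.tree(text = "((A:2,B:3):1,C:4,D:5);")
  dm <- ape::cophenetic.phylo(tr)
  nj1 <- neighbor_joining(dm)
  expect_equal(phangorn::RF.dist(ape::unroot(nj1), ape::unroot(tr)), 0)
  expect_equal(max(abs(ape::cophenetic.phylo(nj1)[rownames(dm), colnames(dm)] -
                         dm)), 0, tolerance = 1e-9)

  d3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighbor_joining(d3)
  el <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(el["a"]), (3 + 5 - 6) / 2)
  expect_equal(unname(el["b"]), (3 + 6 - 5) / 2)
  expect_equal(unname(el["c"]), (5 + 6 - 3) / 2)

  ## 2 taxa: a single split edge
  t2 <- neighbor_joining(matrix(c(0, 4, 4, 0), 2,
                                dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(sum(t2$edge.length), 4)
  expect_error(neighbor_joining(matrix(0, 1, 1, dimnames = list("a", "a"))),
               class = "halopan_input_error")

  ## negative branch lengths are clamped to zero
  set.seed(2)
  for (i in 1:10) {
    base <- ape::rtree(6)
    dmr <- ape::cophenetic.phylo(base) + matrix(runif(36, 0, 0.4), 6)
    dmr <- (dmr + t(dmr)) / 2; diag(dmr) <- 0
    expect_true(all(neighbor_joining(dmr)$edge.length >= 0))
  }
})

test_that("NJ agrees with UPGMA topology on ultrametric distances", {
  set.seed(5)
  for (i in 1:5) {
    tr <- ape::rcoal(8)
    dm <- ape::cophenetic.phylo(tr)
    nj1 <- neighbor_joining(dm)
    up <- phangorn::upgma(as.dist(dm))
    expect_equal(phangorn::RF.dist(ape::unroot(nj1), ape::unroot(up)), 0)
  }
})

test_that("ME refinement never lengthens the tree and fixes NJ on additive data", {
  tr <- ape::read.tree(text = "((A:2,B:3):1,(C:4,D:5):2,E:1);")
  dm <- ape::cophenetic.phylo(tr)
  nj1 <- neighbor_joining(dm)
  me <- me_refine(nj1, dm)
  expect_equal(phangorn::RF.dist(ape::unroot(me), ape::unroot(tr)), 0)
  expect_equal(sum(me$edge.length), sum(tr$edge.length), tolerance = 1e-6)

  set.seed(6)
  for (i in 1:100) {
    base <- ape::rtree(6)
    dmr <- ape::cophenetic.phylo(base) * matrix(runif(36, 0.7, 1.3), 6)
    dmr <- (dmr + t(dmr)) / 2; diag(dmr) <- 0
    start <- ape::rtree(6)
    start$tip.label <- base$tip.label
    fit0 <- halopan:::ols_branch_lengths(ape::unroot(start), dmr)
    me2 <- me_refine(start, dmr)
    expect_lte(sum(me2$edge.length), sum(fit0$edge.length) + 1e-9)
  }
})

test_that("ME hill-climb reaches the exhaustive optimum on most 5-taxon inputs", {
  set.seed(17)
  wins <- 0L
  topos <- phangorn::allTrees(5, rooted = FALSE, tip.label = paste0("t", 1:5))
  for (i in 1:100) {
    base <- ape::rtree(5)
    base$tip.label <- paste0("t", 1:5)
    dmr <- ape::cophenetic.phylo(base) * matrix(runif(25, 0.8, 1.2), 5)
    dmr <- (dmr + t(dmr)) / 2; diag(dmr) <- 0
    best <- min(vapply(topos, function(tp)
      sum(halopan:::ols_branch_lengths(tp, dmr)$edge.length), numeric(1)))
    got <- sum(me_refine(neighbor_joining(dmr), dmr)$edge.length)
    if (got <= best + 1e-8) wins <- wins + 1L
  }
  expect_gte(wins, 90L)
})

test_that("bootstrap saturates on clean two-clade signal and respects defaults", {
  ## clades differ at half the sites (p = 0.5, comfortably unsaturated)
  xa <- paste(rep("ARNDCQ", 40), collapse = "")
  xb <- paste(rep("AKNFCS", 40), collapse = "")
  alns <- list(c1 = c(A1 = xa, A2 = xa, B1 = xb, B2 = xb))
  expect_equal(formals(bootstrap_support)$replicates, 500L)
  tr <- bootstrap_support(alns, replicates = 50, seed = 4)
  sup <- as.numeric(tr$node.label)
  expect_true(all(sup[is.finite(sup)] %in% c(0, 100)))
  bip <- sup[-1]  # non-root internal edges
  expect_true(all(bip == 100))

  ## supports invariant to leaf input order for a fixed seed
  alns2 <- list(c1 = alns$c1[c(3, 1, 4, 2)])
  tr2 <- bootstrap_support(alns2, replicates = 50, seed = 4)
  expect_setequal(tr2$node.label, tr$node.label)
})

test_that("pan-genome parsimony: autapomorphies, constants, exhaustive oracle", {
  ## family in exactly one genome adds 1 regardless of topology; constants 0
  m <- rbind(F1 = c(1, 0, 0, 0, 0), F2 = c(1, 1, 1, 1, 1))
  colnames(m) <- paste0("g", 1:5)
  m2 <- rbind(m, F3 = c(1, 1, 0, 0, 1))
  colnames(m2) <- paste0("g", 1:5)
  r2 <- pan_parsimony_tree(m2, restarts = 3, seed = 1)
  r3 <- pan_parsimony_tree(m2[c("F2", "F3"), ], restarts = 3, seed = 1)
  expect_equal(r2$score, r3$score + 1)  # F1 contributes exactly 1

  expect_warning(r0 <- pan_parsimony_tree(m["F2", , drop = FALSE]),
                 "constant")
  expect_equal(r0$score, 0)

  ## heuristic equals exhaustive Fitch minimum over all 15 topologies
  set.seed(23)
  topos <- phangorn::allTrees(5, rooted = FALSE, tip.label = paste0("g", 1:5))
  for (i in 1:5) {
    mm <- matrix(rbinom(5 * 30, 1, 0.45), 30, 5,
                 dimnames = list(sprintf("F%03d", 1:30), paste0("g", 1:5)))
    mm <- mm[rowSums(mm) > 0, , drop = FALSE]
    res <- pan_parsimony_tree(mm, restarts = 10, seed = i)
    best <- min(vapply(topos, oracle_matrix_fitch, numeric(1), pres_mat = mm))
    expect_equal(res$score, best)
  }
})

test_that("the true simulated topology scores at the low end of random topologies", {
  cfg <- sim_config(n_genomes = 7, root_families = 60, gain_rate = 15,
                    loss_rate = 0.4, seed = 19)
  tr <- simulate_tree(cfg)
  h <- evolve_gene_content(tr, cfg)
  m <- truth_pan_matrix(h)
  true_score <- oracle_matrix_fitch(ape::unroot(tr), m)
  set.seed(101)
  rand_scores <- vapply(1:40, function(i) {
    rt <- ape::rtree(7)
    rt$tip.label <- sample(colnames(m))
    oracle_matrix_fitch(ape::unroot(rt), m)
  }, numeric(1))
  expect_gte(mean(true_score <= rand_scores), 0.95)
})

test_that("outgroup rooting validates its tips", {
  tr <- ape::rtree(5)
  rooted <- root_on_outgroup(ape::unroot(tr), tr$tip.label[1])
  expect_true(ape::is.rooted(rooted))
  expect_error(root_on_outgroup(tr, "nope"), class = "halopan_input_error")
})
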