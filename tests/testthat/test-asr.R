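balanced4 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

test_that("Wagner reconstruction matches the hand-checked small cases", {
  m <- rbind(f_ab = c(1, 1, 0, 0),   # present in one cherry only
             f_all = c(1, 1, 1, 1),  # invariant
             f_a = c(1, 0, 0, 0))    # single leaf
  colnames(m) <- c("A", "B", "C", "D")
  res <- wagner_parsimony(m, balanced4)

  ## invariant family: present everywhere, zero events, zero cost
  nt <- 4L
  expect_true(all(res$states["f_all", ] == 1L))
  expect_equal(unname(res$per_family_cost["f_all"]), 0)

  ## cherry family: a single gain on the (A,B) stem, total cost 2
  ab_stem <- ape::getMRCA(balanced4, c("A", "B"))
  expect_equal(unname(res$states["f_ab", ab_stem]), 1L)
  expect_equal(unname(res$states["f_ab", nt + 1L]), 0L)   # absent at root
  expect_true("f_ab" %in% res$events[[ab_stem]]$gained)
  expect_equal(unname(res$per_family_cost["f_ab"]), 2)

  ## single-leaf family: one terminal gain, cost 2
  expect_true("f_a" %in% res$events[[which(balanced4$tip.label == "A")]]$gained)
  expect_equal(unname(res$per_family_cost["f_a"]), 2)

  ## contract errors
  expect_error(wagner_parsimony(m, ape::unroot(balanced4)),
               class = "halopan_tree_error")
  m2 <- m; colnames(m2) <- c("A", "B", "C", "X")
  expect_error(wagner_parsimony(m2, balanced4), class = "halopan_input_error")
})

test_that("Sankoff DP equals exhaustive enumeration on random trees <= 6 leaves", {
  set.seed(55)
  costs <- list(c(2, 1), c(1, 1), c(2, 2))
  for (rep in 1:60) {
    n <- sample(3:6, 1)
    tr <- ape::rtree(n)
    m <- matrix(rbinom(3 * n, 1, 0.5), 3, n,
                dimnames = list(paste0("f", 1:3), tr$tip.label))
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (!nrow(m)) next
    for (cst in costs) {
      res <- wagner_parsimony(m, tr, wagner_config(cst[1], cst[2]))
      for (f in rownames(m)) {
        exp_obj <- oracle_wagner_objective(tr, setNames(m[f, ] > 0,
                                                        colnames(m)),
                                           cst[1], cst[2])
        expect_equal(unname(res$objective[match(f, rownames(m))]), exp_obj,
                     info = paste("costs", paste(cst, collapse = ","), "n", n))
      }
    }
  }
})

test_that("symmetric unit costs realise Fitch change counts exactly", {
  set.seed(66)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    m <- matrix(rbinom(5 * n, 1, 0.5), 5, n,
                dimnames = list(paste0("f", 1:5), tr$tip.label))
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (!nrow(m)) next
    res <- wagner_parsimony(m, tr, wagner_config(1, 1))
    for (i in seq_len(nrow(m))) {
      expect_equal(unname(res$per_family_cost[i]),
                   oracle_fitch(tr, setNames(m[i, ] > 0, colnames(m))))
    }
  }
})

test_that("count mode reduces to presence mode on 0/1 data and tracks copies", {
  set.seed(3)
  tr <- ape::rtree(5)
  m <- matrix(rbinom(20, 1, 0.5), 4, 5,
              dimnames = list(paste0("f", 1:4), tr$tip.label))
  m <- m[rowSums(m) > 0, , drop = FALSE]
  rp <- wagner_parsimony(m, tr, wagner_config(2, 1, mode = "presence"))
  rc <- wagner_parsimony(m, tr, wagner_config(2, 1, mode = "count",
                                              max_count_cap = 1))
  expect_identical(rp$states, rc$states)
  expect_equal(rp$objective, rc$objective)

  ## copy-number example: 3 copies in a cherry, absent outside
  tr3 <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  mc <- matrix(c(3L, 3L, 0L), 1, dimnames = list("f", c("A", "B", "C")))
  res <- wagner_parsimony(mc, tr3, wagner_config(2, 1, mode = "count"))
  stem <- ape::getMRCA(tr3, c("A", "B"))
  expect_equal(unname(res$states["f", stem]), 3L)
  expect_equal(unname(res$states["f", 4L]), 0L)  # root
  expect_equal(unname(res$objective), 6) # three copies gained at cost 2 each
})

test_that("event summaries satisfy the conservation identity", {
  ## deterministic toy recount on a 6-leaf tree
  set.seed(9)
  tr <- ape::rtree(6)
  m <- matrix(rbinom(8 * 6, 1, 0.5), 8, 6,
              dimnames = list(paste0("f", 1:8), tr$tip.label))
  m <- m[rowSums(m) > 0, , drop = FALSE]
  res <- wagner_parsimony(m, tr)
  tab <- summarize_events(res)
  for (i in seq_len(nrow(tab))) {
    if (is.na(tab$parent[i])) {
      expect_true(is.na(tab$gains[i]) && is.na(tab$losses[i]))
      next
    }
    expect_equal(tab$n_families[i],
                 tab$n_families[tab$parent[i]] + tab$gains[i] - tab$losses[i])
    ## independent recount from the state matrix
    d <- res$states[, tab$node[i]] - res$states[, tab$parent[i]]
    expect_equal(tab$gains[i], sum(d > 0))
    expect_equal(tab$losses[i], sum(d < 0))
  }

  ## frozen-evolution history: zero events everywhere
  cfg <- sim_config(n_genomes = 6, root_families = 25, gain_rate = 0,
                    loss_rate = 0, seed = 44)
  trf <- simulate_tree(cfg)
  h <- evolve_gene_content(trf, cfg)
  resf <- wagner_parsimony(truth_pan_matrix(h), trf)
  tabf <- summarize_events(resf)
  expect_true(all(tabf$gains[!is.na(tabf$gains)] == 0))
  expect_true(all(tabf$losses[!is.na(tabf$losses)] == 0))

  ## conservation on random synthetic histories
  for (s in 1:20) {
    cfg2 <- sim_config(n_genomes = 6, root_families = 20, gain_rate = 6,
                       loss_rate = 0.3, seed = s)
    tr2 <- simulate_tree(cfg2)
    res2 <- wagner_parsimony(truth_pan_matrix(evolve_gene_content(tr2, cfg2)),
                             tr2)
    tab2 <- summarize_events(res2)
    ok <- is.na(tab2$parent) |
      tab2$n_families == tab2$n_families[ifelse(is.na(tab2$parent), 1,
                                                tab2$parent)] +
        ifelse(is.na(tab2$gains), 0, tab2$gains) -
        ifelse(is.na(tab2$losses), 0, tab2$losses)
    expect_true(all(ok))
  }
})

test_that("LCA classification reproduces the published arithmetic and edge cases", {
  tr3 <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  m <- rbind(matrix(1L, 1117, 3),
             cbind(matrix(1L, 1374, 2), 0L))
  rownames(m) <- sprintf("F%05d", seq_len(nrow(m)))
  colnames(m) <- c("A", "B", "C")
  res <- wagner_parsimony(m, tr3)
  rep <- classify_lca(res, c("A", "B"))
  expect_equal(rep$n_total, 2491L)
  expect_length(rep$ancestral, 1117L)
  expect_length(rep$derived, 1374L)
  expect_equal(rep$pct_ancestral, 44.8)
  expect_equal(rep$pct_derived, 55.1)
  expect_length(intersect(rep$ancestral, rep$derived), 0)
  ## truncation convention: the pair may undershoot 100 by up to 0.2
  expect_gte(rep$pct_ancestral + rep$pct_derived, 99.8)
  expect_lte(rep$pct_ancestral + rep$pct_derived, 100)

  ## a node with no gains on its stem is 100% ancestral
  m2 <- matrix(1L, 10, 3, dimnames = list(paste0("f", 1:10), c("A", "B", "C")))
  res2 <- wagner_parsimony(m2, tr3)
  rep2 <- classify_lca(res2, c("A", "B"))
  expect_length(rep2$derived, 0)
  expect_equal(rep2$pct_ancestral, 100)

  ## root and leaves are refused
  expect_error(classify_lca(res, 4L), class = "halopan_input_error")
  expect_error(classify_lca(res, "A"), class = "halopan_input_error")
})

test_that("derived sets match planted gains in a loss-free simulation", {
  cfg <- sim_config(n_genomes = 10, root_families = 60, gain_rate = 10,
                    loss_rate = 0, seed = 77)
  tr <- simulate_tree(cfg)
  h <- evolve_gene_content(tr, cfg)
  res <- wagner_parsimony(truth_pan_matrix(h), tr)
  nt <- length(tr$tip.label)
  internal <- setdiff(unique(tr$edge[, 2]), seq_len(nt))
  for (node in internal) {
    rep <- classify_lca(res, node)
    expect_setequal(rep$derived, h$branch_events[[node]]$gained)
  }
})

test_that("most true gain events and the root size are recovered at G = 20", {
  cfg <- sim_config(n_genomes = 20, root_families = 150, gain_rate = 8,
                    loss_rate = 0.02, seed = 31)
  tr <- simulate_tree(cfg)
  h <- evolve_gene_content(tr, cfg)
  res <- wagner_parsimony(truth_pan_matrix(h), tr)
  truth <- true_gain_pairs(h)
  nt <- length(tr$tip.label)
  inferred <- character(0)
  for (i in seq_len(nt + tr$Nnode)) {
    ev <- res$events[[i]]
    if (!is.null(ev) && length(ev$gained))
      inferred <- c(inferred, paste(i, ev$gained))
  }
  recall <- length(intersect(inferred, truth)) / length(truth)
  expect_gte(recall, 0.9)
  root_true <- length(h$node_families[[nt + 1L]])
  root_inf <- sum(res$states[, nt + 1L] > 0L)
  expect_lte(abs(root_inf - root_true) / root_true, 0.1)
})

test_that("raising the gain cost never increases the number of inferred gains", {
  set.seed(91)
  tr <- ape::rtree(8)
  m <- matrix(rbinom(40 * 8, 1, 0.5), 40, 8,
              dimnames = list(sprintf("f%02d", 1:40), tr$tip.label))
  m <- m[rowSums(m) > 0, , drop = FALSE]
  gains_at <- vapply(c(0.5, 1, 2, 4), function(gc) {
    res <- wagner_parsimony(m, tr, wagner_config(gc, 1))
    sum(vapply(res$events, function(ev)
      if (is.null(ev)) 0L else length(ev$gained), integer(1)))
  }, numeric(1))
  expect_true(all(diff(gains_at) <= 0))
})
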