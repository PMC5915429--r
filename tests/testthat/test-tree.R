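test_that("admissible edges come from local MSTs over adjacent LDPs", {
  # two adjacent LDPs: the single edge survives
  l2 <- stub_ldps(rbind(c(0, 0, 0), c(1, 0, 0)),
                  adjacency = full_adjacency(2))
  a2 <- admissible_edges(l2, r_local = 5)
  expect_equal(nrow(a2), 1L)
  expect_equal(a2$w, 1)

  # collinear triple: local MSTs drop the long chord
  l3 <- stub_ldps(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                  adjacency = full_adjacency(3))
  a3 <- admissible_edges(l3, r_local = 10)
  expect_equal(nrow(a3), 2L)
  expect_equal(sort(a3$w), c(1, 1))

  # random instances: each admissible edge connects adjacent LDPs and
  # appears in at least one local MST (rebuilt by hand)
  set.seed(7)
  for (rep in 1:10) {
    inst <- random_ldp_instance(10)
    adm <- admissible_edges(inst$ldps, r_local = 6)
    pos <- inst$ldps$pos
    dmat <- as.matrix(dist(pos))
    for (e in seq_len(nrow(adm))) {
      expect_true(adm$to[e] %in% inst$ldps$adjacency[[adm$from[e]]])
      found <- FALSE
      for (c0 in 1:10) {
        sphere <- which(dmat[c0, ] <= 6)
        if (!all(c(adm$from[e], adm$to[e]) %in% sphere)) next
        sel <- inst$adm[inst$adm$from %in% sphere & inst$adm$to %in% sphere, ]
        chosen <- catrace:::kruskal(10, sel)
        keys <- paste(sel$from[chosen], sel$to[chosen])
        if (paste(adm$from[e], adm$to[e]) %in% keys) { found <- TRUE; break }
      }
      expect_true(found)
    }
  }

  expect_error(admissible_edges(stub_ldps(rbind(c(0, 0, 0)),
                                          adjacency = list(integer(0))),
                                r_local = 5), "no edges")
})

test_that("the constrained MST is optimal and respects the admissible set", {
  # two LDPs
  l2 <- stub_ldps(rbind(c(0, 0, 0), c(0, 2.5, 0)),
                  adjacency = full_adjacency(2))
  t2 <- build_mst(l2, admissible_edges(l2, 5))
  expect_equal(t2$w_total, 2.5)

  # unit square with full admissibility: W = 3 exactly
  sq <- stub_ldps(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                  adjacency = full_adjacency(4))
  adm <- data.frame(from = c(1, 1, 1, 2, 2, 3), to = c(2, 3, 4, 3, 4, 4))
  adm$w <- sqrt(rowSums((sq$pos[adm$from, ] - sq$pos[adm$to, ])^2))
  adm$w_cost <- adm$w
  t4 <- build_mst(sq, adm)
  expect_equal(t4$w_total, 3)

  # excluding the globally shortest pair: matches restricted brute force
  adm_r <- adm[-1, ]  # drop edge 1-2 (a unit edge)
  t4r <- build_mst(sq, adm_r)
  expect_equal(t4r$w_total, brute_mst_weight(4, adm_r))
  expect_true(all(paste(t4r$edges$from, t4r$edges$to) %in%
                  paste(adm_r$from, adm_r$to)))

  # agreement with an off-the-shelf MST on random instances
  set.seed(11)
  for (rep in 1:30) {
    n <- sample(5:9, 1)
    inst <- random_ldp_instance(n)
    tre <- build_mst(inst$ldps, inst$adm)
    gi <- igraph::graph_from_data_frame(
      cbind(inst$adm[, c("from", "to")], weight = inst$adm$w),
      directed = FALSE, vertices = data.frame(name = 1:n))
    ref <- igraph::mst(gi)
    expect_equal(tre$w_total, sum(igraph::E(ref)$weight), tolerance = 1e-9)
  }
})

test_that("edge-disjoint longest paths match brute-force enumeration", {
  # a simple path graph: P1 is the whole path, nothing remains
  pt <- structure(list(edges = data.frame(from = 1:3, to = 2:4,
                                          w = rep(1, 3),
                                          w_cost = c(2, 1, 3)),
                       vertices = 1:4, n_vertices = 4L, w_total = 3),
                  class = "skeleton_tree")
  ps <- k_longest_paths(pt, 5)
  expect_equal(length(ps), 1L)
  expect_equal(ps[[1]]$vertices, 1:4)
  expect_equal(ps[[1]]$weight, 6)

  # 3-edge star with costs 3, 2, 1: P1 = 5, P2 = 1
  st <- structure(list(edges = data.frame(from = c(1, 1, 1), to = 2:4,
                                          w = rep(1, 3),
                                          w_cost = c(3, 2, 1)),
                       vertices = 1:4, n_vertices = 4L, w_total = 3),
                  class = "skeleton_tree")
  ps <- k_longest_paths(st, 5)
  expect_equal(vapply(ps, function(p) p$weight, 1), c(5, 1))
  expect_equal(tree_score(st), 26)

  # random trees: P1 equals the all-pairs maximum; paths are edge-disjoint;
  # S(T) matches the brute-force strip-and-repeat oracle
  set.seed(3)
  for (rep in 1:25) {
    n <- sample(6:12, 1)
    tre <- random_tree(n)
    ps <- k_longest_paths(tre, 100)
    bp <- brute_longest_path(n, tre$edges)
    expect_equal(ps[[1]]$weight, bp$weight, tolerance = 1e-9)
    eids <- unlist(lapply(ps, function(p) p$edges))
    expect_false(any(duplicated(eids)))
    expect_equal(tree_score(tre), brute_tree_score(tre), tolerance = 1e-9)
  }

  # single-edge tree: S = w_cost^2
  t1 <- structure(list(edges = data.frame(from = 1, to = 2, w = 1,
                                          w_cost = 2),
                       vertices = 1:2, n_vertices = 2L, w_total = 1),
                  class = "skeleton_tree")
  expect_equal(tree_score(t1), 4)

  # S is monotone non-decreasing in the number of paths
  tre <- random_tree(10)
  s_vals <- vapply(1:6, function(k) tree_score(tre, n_paths = k), 1)
  expect_true(all(diff(s_vals) >= -1e-12))
})

test_that("tabu refinement improves the score under the length constraint", {
  # every edge short: no admissible delete, output = input
  l5 <- stub_ldps(cbind(seq(0, 1.2, by = 0.3), 0, 0),
                  adjacency = full_adjacency(5))
  adm5 <- admissible_edges(l5, 5)
  mst5 <- build_mst(l5, adm5)
  out <- tabu_refine(mst5, adm5, d_keep = 0.5, n_iter = 5, seed = 1)
  expect_equal(out$edges[, c("from", "to")], mst5$edges[, c("from", "to")])

  # determinism under a fixed seed
  skel <- helix_skeleton()
  r1 <- tabu_refine(skel$mst, skel$adm, d_keep = 0.5, n_iter = 20, seed = 99)
  r2 <- tabu_refine(skel$mst, skel$adm, d_keep = 0.5, n_iter = 20, seed = 99)
  expect_identical(r1$edges, r2$edges)

  # refined score never drops below the MST score, and the total length
  # stays within 1 percent of the MST length
  s0 <- tree_score(skel$mst)
  expect_gte(attr(r1, "score"), s0)
  expect_lte(r1$w_total, 1.01 * skel$mst$w_total + 1e-9)
  expect_equal(nrow(r1$edges), length(r1$vertices) - 1L)
  expect_true(all(diff(attr(r1, "score_trace")) >= -1e-12))

  # constructed instance: refinement finds the exhaustive optimum among
  # admissible spanning trees within the length bound
  set.seed(5)
  inst <- random_ldp_instance(6)
  mst <- build_mst(inst$ldps, inst$adm)
  ref <- tabu_refine(mst, inst$adm, d_keep = 0.1, n_iter = 200, seed = 2)
  # enumerate all spanning trees of the admissible graph under the bound
  best <- -Inf
  for (rows in utils::combn(nrow(inst$adm), 5, simplify = FALSE)) {
    sub <- inst$adm[rows, , drop = FALSE]
    adjm <- matrix(FALSE, 6, 6)
    adjm[cbind(sub$from, sub$to)] <- TRUE
    adjm <- adjm | t(adjm)
    if (length(unique(components_from_adj(adjm))) != 1L) next
    if (sum(sub$w) > 1.01 * mst$w_total + 1e-9) next
    cand <- structure(list(edges = sub, vertices = 1:6, n_vertices = 6L,
                           w_total = sum(sub$w)), class = "skeleton_tree")
    best <- max(best, tree_score(cand))
  }
  expect_equal(attr(ref, "score"), best, tolerance = 1e-9)
})
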