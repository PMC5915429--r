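# union-find with path compression
uf_new <- function(n) seq_len(n)
uf_find <- function(uf, i) {
  while (uf[i] != i) { uf[i] <- uf[uf[i]]; i <- uf[i] }
  i
}

# Kruskal on an edge table (columns from, to, w); deterministic tie-breaking
# by (w, from, to). Returns the row indices of the chosen edges.
kruskal <- function(n_vertices, edges) {
  if (nrow(edges) == 0L) return(integer(0))
  o <- order(edges$w, edges$from, edges$to)
  uf <- uf_new(n_vertices)
  chosen <- integer(0)
  for (e in o) {
    ra <- uf_find(uf, edges$from[e]); rb <- uf_find(uf, edges$to[e])
    if (ra != rb) { uf[ra] <- rb; chosen <- c(chosen, e) }
  }
  chosen
}

#' Admissible edge set for skeletonization
#'
#' Candidate edges are pairs of adjacent LDPs, weighted by Euclidean distance
#' `w` and carrying the density cost `w_cost = w * min(Theta_endpoints)`. For
#' every LDP a local minimum spanning tree is built on the LDPs within
#' `r_local` of it (restricted to adjacency edges); the union of all
#' local-MST edges is the admissible set used to constrain the global tree.
#'
#' @param ldps an `ldp_set` with adjacency filled (see [build_adjacency()]).
#' @param r_local local-sphere radius in Angstrom.
#' @return Data frame of edges `(from, to, w, w_cost)` with `from < to`.
#' @export
admissible_edges <- function(ldps, r_local) {
  stopifnot(r_local > 0, !is.null(ldps$adjacency))
  k <- nrow(ldps$pos)
  pairs <- do.call(rbind, lapply(seq_len(k), function(i) {
    js <- ldps$adjacency[[i]]
    js <- js[js > i]
    if (!length(js)) NULL else cbind(i, js)
  }))
  if (is.null(pairs) || nrow(pairs) == 0L)
    stop("LDP adjacency graph has no edges", call. = FALSE)
  w <- sqrt(rowSums((ldps$pos[pairs[, 1], , drop = FALSE] -
                     ldps$pos[pairs[, 2], , drop = FALSE])^2))
  cand <- data.frame(from = pairs[, 1], to = pairs[, 2], w = w)
  dmat <- as.matrix(dist(ldps$pos))
  in_union <- rep(FALSE, nrow(cand))
  for (c0 in seq_len(k)) {
    sphere <- which(dmat[c0, ] <= r_local)
    sel <- which(cand$from %in% sphere & cand$to %in% sphere)
    if (!length(sel)) next
    loc <- cand[sel, , drop = FALSE]
    chosen <- kruskal(k, loc)
    in_union[sel[chosen]] <- TRUE
  }
  out <- cand[in_union, , drop = FALSE]
  out$w_cost <- out$w * pmin(ldps$theta_raw[out$from],
                             ldps$theta_raw[out$to])
  rownames(out) <- NULL
  out
}

new_skeleton_tree <- function(edges, n_vertices) {
  structure(list(edges = edges,
                 vertices = sort(unique(c(edges$from, edges$to))),
                 n_vertices = n_vertices,
                 w_total = sum(edges$w)),
            class = "skeleton_tree")
}

#' @export
print.skeleton_tree <- function(x, ...) {
  cat("skeleton_tree:", length(x$vertices), "vertices,", nrow(x$edges),
      "edges, total length", format(x$w_total, digits = 6), "A\n")
  invisible(x)
}

#' Build the constrained minimum spanning tree over LDPs
#'
#' Kruskal's algorithm on the admissible edge set, minimizing total Euclidean
#' edge length. If the admissible graph is disconnected, the spanning tree of
#' the largest connected component is returned with a warning (small
#' components typically correspond to detached density fragments).
#'
#' @param ldps an `ldp_set`.
#' @param admissible edge table from [admissible_edges()].
#' @return A `skeleton_tree` (edges carry both `w` and `w_cost`).
#' @export
build_mst <- function(ldps, admissible) {
  k <- nrow(ldps$pos)
  chosen <- kruskal(k, admissible)
  edges <- admissible[chosen, , drop = FALSE]
  comp <- components_of(k, edges)
  touched <- unique(c(edges$from, edges$to))
  sizes <- table(comp[touched])
  main <- as.integer(names(sizes)[which.max(sizes)])
  if (length(sizes) > 1L)
    warning("admissible graph is disconnected; tracing the largest ",
            "component (", max(sizes), " of ", k, " LDPs; component sizes: ",
            paste(sort(as.integer(sizes), decreasing = TRUE), collapse = ", "),
            ")")
  edges <- edges[comp[edges$from] == main, , drop = FALSE]
  rownames(edges) <- NULL
  new_skeleton_tree(edges, k)
}

# connected-component labels of vertices 1..n under an edge table
components_of <- function(n, edges) {
  uf <- uf_new(n)
  from <- as.integer(edges$from); to <- as.integer(edges$to)
  for (e in seq_along(from)) {
    ra <- uf_find(uf, from[e]); rb <- uf_find(uf, to[e])
    if (ra != rb) uf[ra] <- rb
  }
  vapply(seq_len(n), function(i) as.integer(uf_find(uf, i)), 1L)
}

#' Edge-disjoint longest paths of a tree
#'
#' P1 is the path maximizing the summed density cost `w_cost`; each
#' subsequent path is the longest path of the forest left after removing the
#' edges of all previous paths. Extraction stops early when no edges remain.
#'
#' @param tree a `skeleton_tree`.
#' @param n_paths maximum number of paths (default 100).
#' @param weight which edge attribute to maximize (`"w_cost"` or `"w"`).
#' @return List of paths, each with `vertices` (LDP ids), `edges` (row index
#'   into `tree$edges`) and `weight` (path cost).
#' @export
k_longest_paths <- function(tree, n_paths = 100, weight = "w_cost") {
  stopifnot(n_paths >= 1)
  if (nrow(tree$edges) == 0L) return(list())
  em <- cbind(tree$edges$from, tree$edges$to)
  k_longest_paths_cpp(tree$n_vertices, em, tree$edges[[weight]],
                      as.integer(n_paths))
}

#' Tree score: summed squared path costs
#'
#' `S(T) = sum_n (sum_{e in P_n} w_cost(e))^2` over the edge-disjoint longest
#' paths of the tree. Squaring rewards concentrating high-density length into
#' few long paths, so a tree whose longest path runs the whole main chain
#' scores higher than one fragmented into many branches.
#'
#' @param tree a `skeleton_tree`.
#' @param n_paths number of paths included (default 100).
#' @return Numeric score.
#' @export
tree_score <- function(tree, n_paths = 100) {
  paths <- k_longest_paths(tree, n_paths)
  if (!length(paths)) return(0)
  sum(vapply(paths, function(p) p$weight, 1)^2)
}

edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "-")
}
move_key <- function(del_a, del_b, add_a, add_b) {
  k1 <- edge_key(del_a, del_b); k2 <- edge_key(add_a, add_b)
  paste(sort(c(k1, k2)), collapse = "|")
}

#' Refine a skeleton tree by tabu search
#'
#' Each iteration samples 30 candidate moves: delete an edge longer than
#' `d_keep`, then reconnect the two components with an admissible edge that
#' keeps the total tree length within `w_slack` (1.01) times the initial MST
#' length. The best-scoring candidate replaces the incumbent when it strictly
#' improves the score; the applied move and its reverse enter a FIFO tabu
#' list of capacity 100, and tabu moves may not be re-applied. The
#' best-scoring tree seen over all iterations is returned.
#'
#' @param tree initial `skeleton_tree` (normally the MST).
#' @param admissible edge table from [admissible_edges()].
#' @param d_keep minimum deletable edge length in Angstrom.
#' @param n_iter number of tabu iterations.
#' @param seed integer seed; the search is deterministic given the seed.
#' @param n_paths paths used by [tree_score()].
#' @param n_cand candidate moves sampled per iteration (default 30).
#' @param w_slack allowed total-length inflation over the initial tree.
#' @param tabu_capacity tabu list capacity.
#' @return The best `skeleton_tree` found; attributes `score`, `n_noop` and
#'   `score_trace` carry diagnostics.
#' @export
tabu_refine <- function(tree, admissible, d_keep, n_iter, seed = 1,
                        n_paths = 100, n_cand = 30, w_slack = 1.01,
                        tabu_capacity = 100) {
  stopifnot(n_iter >= 1)
  w_max <- w_slack * tree$w_total
  verts <- tree$vertices
  adm <- admissible[admissible$from %in% verts & admissible$to %in% verts, ,
                    drop = FALSE]
  inc <- tree
  inc_score <- tree_score(inc, n_paths)
  best <- inc; best_score <- inc_score
  tabu <- character(0)
  n_noop <- 0L
  trace <- numeric(n_iter)
  with_local_seed(seed, {
    for (it in seq_len(n_iter)) {
      del_ok <- which(inc$edges$w > d_keep)
      cand_best <- NULL; cand_best_score <- -Inf
      if (length(del_ok)) {
        for (s in seq_len(n_cand)) {
          dr <- del_ok[sample.int(length(del_ok), 1L)]
          da <- inc$edges$from[dr]; db <- inc$edges$to[dr]
          comp <- components_of(inc$n_vertices,
                                inc$edges[-dr, , drop = FALSE])
          side_a <- comp[da]
          cross <- which(xor(comp[adm$from] == side_a,
                             comp[adm$to] == side_a))
          if (!length(cross)) next
          w_new <- inc$w_total - inc$edges$w[dr] + adm$w[cross]
          cross <- cross[w_new <= w_max + 1e-9]
          if (!length(cross)) next
          # drop the deleted edge itself and tabu moves
          keys <- move_key(da, db, adm$from[cross], adm$to[cross])
          same <- edge_key(adm$from[cross], adm$to[cross]) == edge_key(da, db)
          ok <- !same & !(keys %in% tabu)
          cross <- cross[ok]
          if (!length(cross)) next
          ar <- cross[sample.int(length(cross), 1L)]
          new_edges <- rbind(inc$edges[-dr, , drop = FALSE],
                             adm[ar, , drop = FALSE])
          rownames(new_edges) <- NULL
          cand <- new_skeleton_tree(new_edges, inc$n_vertices)
          sc <- tree_score(cand, n_paths)
          if (sc > cand_best_score) {
            cand_best_score <- sc
            cand_best <- list(tree = cand, key = move_key(da, db,
                              adm$from[ar], adm$to[ar]))
          }
        }
      }
      if (!is.null(cand_best) && cand_best_score > inc_score) {
        inc <- cand_best$tree
        inc_score <- cand_best_score
        tabu <- c(tabu, cand_best$key, cand_best$key)
        if (length(tabu) > tabu_capacity)
          tabu <- tabu[(length(tabu) - tabu_capacity + 1L):length(tabu)]
        if (inc_score > best_score) { best <- inc; best_score <- inc_score }
      } else {
        n_noop <- n_noop + 1L
      }
      trace[it] <- best_score
    }
  })
  attr(best, "score") <- best_score
  attr(best, "n_noop") <- n_noop
  attr(best, "score_trace") <- trace
  best
}
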