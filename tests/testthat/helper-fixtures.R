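# shared fixtures, built once per test run

.fix_env <- new.env(parent = emptyenv())

helix_fixture <- function() {
  if (is.null(.fix_env$fx)) .fix_env$fx <- synthetic_helix_fixture(seed = 1)
  .fix_env$fx
}

helix_ldps <- function() {
  if (is.null(.fix_env$ldps)) {
    fx <- helix_fixture()
    .fix_env$ldps <- find_ldps(fx$map, phi_thr = 0.05 * max(fx$map$values),
                               theta_thr = 0)
  }
  .fix_env$ldps
}

helix_skeleton <- function() {
  if (is.null(.fix_env$skel)) {
    ldps <- helix_ldps()
    adm <- admissible_edges(ldps, 7.5)
    mst <- suppressWarnings(build_mst(ldps, adm))
    .fix_env$skel <- list(ldps = ldps, adm = adm, mst = mst)
  }
  .fix_env$skel
}

# a bare ldp_set with given positions/densities, single-voxel members laid
# out on a line so that consecutive ids are grid-adjacent
stub_ldps <- function(pos, theta = NULL, adjacency = NULL) {
  pos <- matrix(pos, ncol = 3)
  k <- nrow(pos)
  if (is.null(theta)) theta <- rep(1, k)
  structure(list(pos = pos, theta_raw = theta,
                 theta_norm = if (diff(range(theta)) > 0)
                   (theta - min(theta)) / diff(range(theta)) else rep(0, k),
                 members = lapply(seq_len(k), function(i)
                   matrix(c(i, 1L, 1L), ncol = 3)),
                 adjacency = adjacency,
                 grid_dim = c(k, 1L, 1L)),
            class = "ldp_set")
}

full_adjacency <- function(k) {
  lapply(seq_len(k), function(i) setdiff(seq_len(k), i))
}

# random geometric LDP instance with a connected admissible graph
random_ldp_instance <- function(n, p_edge = 0.6) {
  pos <- matrix(runif(n * 3, 0, 10), ncol = 3)
  repeat {
    adj <- matrix(runif(n * n) < p_edge, n, n)
    adj <- adj | t(adj); diag(adj) <- FALSE
    lab <- components_from_adj(adj)
    if (length(unique(lab)) == 1L) break
  }
  ldps <- stub_ldps(pos, theta = runif(n, 0.1, 1),
                    adjacency = lapply(seq_len(n), function(i) which(adj[i, ])))
  edges <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  w <- sqrt(rowSums((pos[edges[, 1], , drop = FALSE] -
                     pos[edges[, 2], , drop = FALSE])^2))
  adm <- data.frame(from = edges[, 1], to = edges[, 2], w = w)
  adm$w_cost <- adm$w * pmin(ldps$theta_raw[adm$from], ldps$theta_raw[adm$to])
  list(ldps = ldps, adm = adm)
}

components_from_adj <- function(adj) {
  n <- nrow(adj)
  lab <- rep(0L, n); cur <- 0L
  for (s in seq_len(n)) {
    if (lab[s]) next
    cur <- cur + 1L; q <- s; lab[s] <- cur
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      nb <- which(adj[v, ] & lab == 0L)
      lab[nb] <- cur; q <- c(q, nb)
    }
  }
  lab
}

# exhaustive minimum spanning tree over an admissible edge table
brute_mst_weight <- function(n, adm) {
  ne <- nrow(adm)
  best <- Inf
  for (rows in utils::combn(ne, n - 1L, simplify = FALSE)) {
    sub <- adm[rows, , drop = FALSE]
    adj <- matrix(FALSE, n, n)
    adj[cbind(sub$from, sub$to)] <- TRUE
    adj <- adj | t(adj)
    if (length(unique(components_from_adj(adj))) == 1L)
      best <- min(best, sum(sub$w))
  }
  best
}

# random spanning tree over n vertices with random costs
random_tree <- function(n) {
  edges <- data.frame(from = integer(0), to = integer(0))
  for (v in 2:n) {
    u <- sample.int(v - 1L, 1L)
    edges <- rbind(edges, data.frame(from = u, to = v))
  }
  edges$w <- runif(n - 1L, 0.5, 2)
  edges$w_cost <- runif(n - 1L, 0, 3)
  structure(list(edges = edges, vertices = seq_len(n), n_vertices = n,
                 w_total = sum(edges$w)), class = "skeleton_tree")
}

# brute-force longest path (by w_cost) over all vertex pairs of a forest
brute_longest_path <- function(n, edges) {
  adj <- lapply(seq_len(n), function(i) list())
  for (e in seq_len(nrow(edges))) {
    a <- edges$from[e]; b <- edges$to[e]
    adj[[a]][[length(adj[[a]]) + 1L]] <- c(b, e)
    adj[[b]][[length(adj[[b]]) + 1L]] <- c(a, e)
  }
  best <- list(weight = -Inf, edges = integer(0))
  walk <- function(v, parent, wsum, eset) {
    if (wsum > best$weight + 1e-12) best <<- list(weight = wsum, edges = eset)
    for (nb in adj[[v]]) {
      if (nb[1] == parent) next
      walk(nb[1], v, wsum + edges$w_cost[nb[2]], c(eset, nb[2]))
    }
  }
  for (s in seq_len(n)) walk(s, 0L, 0, integer(0))
  best
}

# brute-force tree score: iteratively strip the longest path
brute_tree_score <- function(tree, n_paths = 100) {
  edges <- tree$edges
  total <- 0
  for (i in seq_len(n_paths)) {
    if (nrow(edges) == 0L) break
    bp <- brute_longest_path(tree$n_vertices, edges)
    total <- total + bp$weight^2
    edges <- edges[-bp$edges, , drop = FALSE]
  }
  total
}

# exhaustive threading score over all monotone alignments (>= 1 match)
brute_thread_score <- function(V, A, arc, pos, gap, w_ca, d_std,
                               metric = "arc") {
  L <- length(V); N <- length(A)
  zv <- if (stats::sd(V) > 0 && L >= 2)
    (V - mean(V)) / sqrt(mean((V - mean(V))^2)) else rep(0, L)
  za <- if (stats::sd(A) > 0 && N >= 2)
    (A - mean(A)) / sqrt(mean((A - mean(A))^2)) else rep(0, N)
  SCO <- 1 - abs(outer(zv, za, "-"))
  dfun <- function(i1, i2) {
    if (metric == "arc") arc[i2] - arc[i1]
    else sqrt(sum((pos[i2, ] - pos[i1, ])^2))
  }
  best <- -Inf
  for (k in seq_len(min(L, N))) {
    for (rs in utils::combn(N, k, simplify = FALSE)) {
      for (ls in utils::combn(L, k, simplify = FALSE)) {
        sc <- sum(SCO[cbind(ls, rs)]) + gap * (N - k)
        if (k > 1)
          sc <- sc - w_ca * sum(abs(d_std - vapply(seq_len(k - 1), function(q)
            dfun(ls[q], ls[q + 1]), 1)))
        if (sc > best) best <- sc
      }
    }
  }
  best
}

# path_profile-compatible object from raw vectors
stub_path <- function(pos, V) {
  pos <- matrix(pos, ncol = 3)
  seg <- if (nrow(pos) > 1)
    sqrt(rowSums((pos[-1, , drop = FALSE] - pos[-nrow(pos), , drop = FALSE])^2))
  else numeric(0)
  structure(list(ldp_ids = seq_len(nrow(pos)), positions = pos,
                 v_raw = V, V = V, arc = c(0, cumsum(seg))),
            class = "path_profile")
}

stub_profile <- function(A) {
  structure(list(sequence = strrep("A", length(A)),
                 ss = strrep("C", length(A)), A = A),
            class = "residue_profile")
}

# single-Gaussian test map centered on a grid point
gaussian_map <- function(center = c(10, 10, 10), resolution = 3) {
  m <- atomic_model(data.frame(element = "CA", resno = 1L, resid = "ALA",
                               chain = "A", x = center[1], y = center[2],
                               z = center[3]))
  simulate_map(m, resolution = resolution, spacing = 1)
}
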