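#' Parameter grid for the model-building sweep
#'
#' Every combination of `phi_thr` x `theta_thr` x `r_local` x `d_keep` x
#' `n_iter` defines one tree-building condition; `n_trees` refined trees are
#' grown per condition (differing by tabu seed), and each tree's longest
#' path is threaded for every `sigma_path` x `d_std` x direction.
#'
#' @param phi_thr seed density threshold values (map units).
#' @param theta_thr normalized-density threshold values.
#' @param r_local local-MST sphere radii (Angstrom).
#' @param d_keep minimum deletable edge lengths (Angstrom).
#' @param n_iter tabu iteration counts.
#' @param n_trees trees per condition.
#' @param sigma_path path-smoothing bandwidths (Angstrom).
#' @param d_std standard C-alpha distances (Angstrom).
#' @param directions sequence directions to thread.
#' @param w_ca distance-penalty weight.
#' @param gap per-residue gap penalty.
#' @param sigma mean-shift bandwidth (Angstrom).
#' @param merge_dist LDP clustering threshold (Angstrom).
#' @param connectivity voxel neighborhood (6, 18, 26).
#' @param n_paths paths used in the tree score.
#' @return An object of class `parameter_grid`.
#' @export
parameter_grid <- function(phi_thr, theta_thr = 0.3, r_local = 5,
                           d_keep = 0.5, n_iter = 100, n_trees = 10,
                           sigma_path = seq(0.8, 1.4, by = 0.1),
                           d_std = seq(3.1, 3.8, by = 0.1),
                           directions = c("forward", "reverse"),
                           w_ca = 0.9, gap = -1, sigma = 1.0,
                           merge_dist = 0.5, connectivity = 26,
                           n_paths = 100) {
  stopifnot(length(phi_thr) >= 1, length(theta_thr) >= 1,
            length(r_local) >= 1, length(d_keep) >= 1, length(n_iter) >= 1,
            n_trees >= 1, length(sigma_path) >= 1, length(d_std) >= 1,
            length(directions) >= 1)
  structure(list(phi_thr = phi_thr, theta_thr = theta_thr,
                 r_local = r_local, d_keep = d_keep, n_iter = n_iter,
                 n_trees = n_trees, sigma_path = sigma_path, d_std = d_std,
                 directions = directions, w_ca = w_ca, gap = gap,
                 sigma = sigma, merge_dist = merge_dist,
                 connectivity = connectivity, n_paths = n_paths),
            class = "parameter_grid")
}

#' Number of tree-building combinations and models in a grid
#'
#' @param pg a [parameter_grid()].
#' @return `n_combos()`: combinations of the tree-building knobs;
#'   `n_models()`: total C-alpha models the sweep will produce.
#' @export
n_combos <- function(pg) {
  length(pg$phi_thr) * length(pg$theta_thr) * length(pg$r_local) *
    length(pg$d_keep) * length(pg$n_iter)
}

#' @rdname n_combos
#' @export
n_models <- function(pg) {
  n_combos(pg) * pg$n_trees * length(pg$sigma_path) * length(pg$d_std) *
    length(pg$directions)
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat("parameter_grid:", n_combos(x), "tree conditions x", x$n_trees,
      "trees x", length(x$sigma_path) * length(x$d_std) *
        length(x$directions), "threadings =", n_models(x), "models\n")
  invisible(x)
}

#' Published and desk-scale sweep presets
#'
#' `"simulated"` is the grid used for 5 Angstrom simulated benchmark maps
#' (24 conditions x 10 trees x 112 threadings = 26,880 models; the absolute
#' `phi_thr` values 9, 10, 11 suit pdb2mrc-scaled maps). `"experimental"` is
#' the grid for deposited maps (72 conditions, 80,640 models; `phi_thr` is
#' derived from the author-recommended contour level, which must be
#' supplied). `"fast"` is a desk-scale default (36 models) whose `phi_thr`
#' is 5 percent of the map maximum.
#'
#' @param name preset name.
#' @param map [density_grid()], required by `"fast"` to set `phi_thr`.
#' @param contour recommended contour level, required by `"experimental"`.
#' @return A [parameter_grid()].
#' @export
sweep_preset <- function(name = c("fast", "simulated", "experimental"),
                         map = NULL, contour = NULL) {
  name <- match.arg(name)
  switch(name,
    simulated = parameter_grid(
      phi_thr = c(9, 10, 11), theta_thr = 0.3, r_local = 5,
      d_keep = c(0.5, 1.0), n_iter = c(10, 50, 100, 500), n_trees = 10),
    experimental = {
      if (is.null(contour))
        stop("the experimental preset needs the recommended contour level")
      parameter_grid(
        phi_thr = contour * c(0.5, 0.25), theta_thr = c(0, 0.1, 0.2, 0.3),
        r_local = c(5, 7.5, 10), d_keep = c(0.5, 1.0, 1.5), n_iter = 5000,
        n_trees = 10)
    },
    fast = {
      if (is.null(map))
        stop("the fast preset needs the map to set its density threshold")
      parameter_grid(
        phi_thr = 0.05 * max(map$values), theta_thr = 0, r_local = 7.5,
        d_keep = 0.5, n_iter = 100, n_trees = 3,
        sigma_path = c(0.8, 1.2), d_std = c(3.0, 3.4, 3.8))
    })
}

#' Run the full model-building sweep
#'
#' For each tree-building condition: LDP identification, admissible edges,
#' constrained MST, `n_trees` tabu refinements (seeds derived from `seed`),
#' longest-path extraction and threading of the sequence under every
#' `(sigma_path, d_std, direction)` combination. Conditions under which no
#' seed or no LDP edge survives are skipped with a message. The run is
#' deterministic given `seed`.
#'
#' @param grid_map a [density_grid()].
#' @param sequence amino-acid string.
#' @param pg a [parameter_grid()].
#' @param seed integer base seed.
#' @param ss optional secondary-structure string.
#' @param verbose print per-stage progress.
#' @return An object of class `model_pool` with models ranked by threading
#'   score (descending, ties by model id).
#' @export
run_sweep <- function(grid_map, sequence, pg, seed = 1, ss = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(grid_map, "density_grid"),
            inherits(pg, "parameter_grid"))
  combos <- expand.grid(phi_thr = pg$phi_thr, theta_thr = pg$theta_thr,
                        r_local = pg$r_local, d_keep = pg$d_keep,
                        n_iter = pg$n_iter, KEEP.OUT.ATTRS = FALSE)
  ldp_cache <- list()
  models <- list()
  model_id <- 0L
  for (ci in seq_len(nrow(combos))) {
    cmb <- combos[ci, ]
    key <- paste(cmb$phi_thr, cmb$theta_thr, sep = "|")
    if (is.null(ldp_cache[[key]])) {
      ldp_cache[[key]] <- tryCatch(
        find_ldps(grid_map, phi_thr = cmb$phi_thr,
                  theta_thr = cmb$theta_thr, sigma = pg$sigma,
                  merge_dist = pg$merge_dist,
                  connectivity = pg$connectivity),
        error = function(e) e)
    }
    ldps <- ldp_cache[[key]]
    if (inherits(ldps, "error")) {
      message("skipping condition ", ci, ": ", conditionMessage(ldps))
      next
    }
    adm <- tryCatch(admissible_edges(ldps, r_local = cmb$r_local),
                    error = function(e) e)
    if (inherits(adm, "error")) {
      message("skipping condition ", ci, ": ", conditionMessage(adm))
      next
    }
    mst <- suppressWarnings(build_mst(ldps, adm))
    if (verbose)
      message(sprintf("condition %d/%d: %d LDPs, %d admissible edges",
                      ci, nrow(combos), nrow(ldps$pos), nrow(adm)))
    for (t in seq_len(pg$n_trees)) {
      tree_seed <- (seed + 1000L * ci + t) %% .Machine$integer.max
      tree <- tabu_refine(mst, adm, d_keep = cmb$d_keep,
                          n_iter = cmb$n_iter, seed = tree_seed,
                          n_paths = pg$n_paths)
      paths <- k_longest_paths(tree, 1)
      if (!length(paths)) next
      p1 <- paths[[1]]$vertices
      for (sp in pg$sigma_path) {
        prof_path <- path_profile(ldps, p1, grid_map, sigma_path = sp)
        for (ds in pg$d_std) {
          prof_res <- residue_profile(sequence, ss = ss)
          for (dr in pg$directions) {
            tm <- thread_sequence(prof_res, prof_path, gap = pg$gap,
                                  w_ca = pg$w_ca, d_std = ds,
                                  direction = dr)
            model_id <- model_id + 1L
            tm$model_id <- model_id
            tm$params <- c(tm$params, list(
              phi_thr = cmb$phi_thr, theta_thr = cmb$theta_thr,
              r_local = cmb$r_local, d_keep = cmb$d_keep,
              n_iter = cmb$n_iter, tree = t, sigma_path = sp,
              tree_seed = tree_seed))
            models[[model_id]] <- tm
          }
        }
      }
    }
  }
  if (!length(models))
    stop("no models could be built under any parameter combination")
  pool <- structure(list(models = models, sequence = sequence,
                         consensus = NULL), class = "model_pool")
  rank_and_select(pool, k = length(models))
}

#' @export
print.model_pool <- function(x, ...) {
  sc <- vapply(x$models, function(m) m$score, 1)
  cat("model_pool:", length(x$models), "C-alpha models, threading score",
      format(max(sc), digits = 6), "(top) to",
      format(min(sc), digits = 6), "\n")
  invisible(x)
}

#' Rank a model pool and keep the top k
#'
#' Stable deterministic sort by threading score (descending), ties broken by
#' model id (ascending).
#'
#' @param pool a `model_pool`.
#' @param k number of models to retain.
#' @return The pruned, ranked `model_pool`.
#' @export
rank_and_select <- function(pool, k) {
  stopifnot(k >= 1)
  if (k > length(pool$models)) {
    warning("k exceeds pool size; keeping all ", length(pool$models),
            " models")
    k <- length(pool$models)
  }
  sc <- vapply(pool$models, function(m) m$score, 1)
  id <- vapply(pool$models, function(m) m$model_id, 1L)
  pool$models <- pool$models[order(-sc, id)][seq_len(k)]
  pool
}

#' Assemble a model pool from threaded models
#'
#' Builds (and ranks) a `model_pool` from an explicit list of models --
#' useful when combining sweeps or constructing pools for consensus
#' analysis. Each model needs `ca_coords`, `score` and `model_id`.
#'
#' @param models list of `threaded_model` objects (or compatible lists).
#' @param sequence the amino-acid sequence the models trace.
#' @return A ranked `model_pool`.
#' @export
model_pool <- function(models, sequence) {
  stopifnot(length(models) >= 1)
  ok <- vapply(models, function(m)
    !is.null(m$ca_coords) && !is.null(m$score) && !is.null(m$model_id),
    TRUE)
  if (!all(ok)) stop("each model needs ca_coords, score and model_id")
  pool <- structure(list(models = models, sequence = sequence,
                         consensus = NULL), class = "model_pool")
  rank_and_select(pool, k = length(models))
}
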