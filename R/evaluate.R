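#' Per-residue consensus confidence of the top model
#'
#' For each C-alpha of the top-ranked model, the fraction of the other
#' `n_top - 1` pool models that place at least one C-alpha within `cutoff`.
#' High-consensus regions are reproducible across alternative models and are
#' empirically the well-modeled ones.
#'
#' @param pool a ranked `model_pool`.
#' @param n_top models considered (default 100; if the pool is smaller, all
#'   models are used with a warning).
#' @param cutoff agreement distance in Angstrom (default 3.5).
#' @return Numeric vector of per-residue fractions in \[0, 1\].
#' @export
consensus_confidence <- function(pool, n_top = 100, cutoff = 3.5) {
  stopifnot(n_top >= 2)
  if (length(pool$models) < n_top) {
    warning("pool smaller than n_top; using all ", length(pool$models),
            " models")
    n_top <- length(pool$models)
  }
  if (n_top < 2) stop("need at least two models for a consensus")
  top <- pool$models[[1]]$ca_coords
  hits <- matrix(FALSE, nrow(top), n_top - 1L)
  for (m in 2:n_top) {
    d <- cross_dist(top, pool$models[[m]]$ca_coords)
    hits[, m - 1L] <- apply(d <= cutoff, 1, any)
  }
  rowMeans(hits)
}

#' Evaluate a C-alpha model against a reference structure
#'
#' C-alpha RMSD is computed over shared residue numbers without
#' superposition (model and native live in the same map frame); set
#' `superpose = TRUE` for a Kabsch-fitted RMSD when frames differ. Coverage
#' is the fraction of native C-alphas within each cutoff of any model
#' C-alpha; precision is the converse. Both ignore sequence correspondence.
#'
#' @param model a `threaded_model` (or any list with `ca_coords`).
#' @param native an [atomic_model()] reference; its C-alphas are used.
#' @param cutoffs distance cutoffs in Angstrom for coverage/precision.
#' @param superpose Kabsch-superpose the shared C-alphas before the RMSD.
#' @return List with `ca_rmsd`, `coverage`, `precision` (named by cutoff),
#'   `per_residue_error` and `n_shared`.
#' @export
evaluate_model <- function(model, native, cutoffs = c(2, 3),
                           superpose = FALSE) {
  nat <- ca_table(native)
  mod <- model$ca_coords
  resno_mod <- seq_len(nrow(mod))
  shared <- intersect(resno_mod, nat$resno)
  if (!length(shared)) stop("model and native share no residue numbers")
  a <- mod[match(shared, resno_mod), , drop = FALSE]
  b <- as.matrix(nat[match(shared, nat$resno), c("x", "y", "z")])
  if (superpose) {
    inds <- seq_len(3L * nrow(a))
    fit <- bio3d::fit.xyz(fixed = as.vector(t(b)), mobile = as.vector(t(a)),
                          fixed.inds = inds, mobile.inds = inds)
    a <- matrix(fit, ncol = 3, byrow = TRUE)
  }
  err <- sqrt(rowSums((a - b)^2))
  natxyz <- as.matrix(nat[, c("x", "y", "z")])
  d <- cross_dist(natxyz, mod)
  coverage <- vapply(cutoffs, function(ct) mean(apply(d <= ct, 1, any)), 1)
  precision <- vapply(cutoffs, function(ct) mean(apply(d <= ct, 2, any)), 1)
  names(coverage) <- names(precision) <- as.character(cutoffs)
  list(ca_rmsd = sqrt(mean(err^2)), coverage = coverage,
       precision = precision, per_residue_error = err,
       n_shared = length(shared))
}
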