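#' Per-residue expected density profile
#'
#' The expected density of residue j is `A_j = w_ss[ss_j] * d_table[aa_j]`:
#' a per-amino-acid average density modulated by a secondary-structure
#' weight. The default density table is the residue heavy-atom count
#' normalized to mean 1 over the 20 amino acids (residue volume is the
#' dominant signal at 4-5 Angstrom); the default secondary-structure weights
#' are neutral (1 for H, E and C). Both tables are editable files under
#' `inst/extdata`.
#'
#' @param sequence amino-acid string over the 20-letter alphabet.
#' @param ss optional 3-state secondary-structure string (H/E/C) of the same
#'   length; defaults to all-coil.
#' @param d_table named per-amino-acid density vector; default from the
#'   shipped table.
#' @param w_ss named per-state weight vector (names H, E, C).
#' @return An object of class `residue_profile`: list with `sequence`, `ss`
#'   and the numeric profile `A`.
#' @export
residue_profile <- function(sequence, ss = NULL, d_table = NULL,
                            w_ss = NULL) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  n <- length(aa)
  if (is.null(ss)) ss <- strrep("C", n)
  sv <- strsplit(toupper(ss), "")[[1]]
  if (length(sv) != n) stop("ss string must match sequence length")
  if (is.null(d_table)) {
    counts <- aa_heavy_atoms()
    d_table <- counts / mean(counts)
  }
  if (is.null(w_ss)) {
    tab <- read.table(system.file("extdata", "ss_weights.tsv",
                                  package = "catrace"),
                      header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    w_ss <- stats::setNames(tab$weight, tab$ss)
  }
  if (any(!aa %in% names(d_table)))
    stop("unknown residue letter(s): ",
         paste(unique(aa[!aa %in% names(d_table)]), collapse = ", "))
  if (any(!sv %in% names(w_ss)))
    stop("unknown secondary-structure state(s): ",
         paste(unique(sv[!sv %in% names(w_ss)]), collapse = ", "))
  A <- unname(w_ss[sv] * d_table[aa])
  structure(list(sequence = sequence, ss = paste(sv, collapse = ""), A = A),
            class = "residue_profile")
}

#' Density profile along a tree path
#'
#' The raw density `v` of an LDP is the sum of map densities over the grid
#' points of its cluster. The profile is smoothed with a Gaussian filter over
#' the path's LDPs: `V_k = sum_i v_i * (1/sigma_path) * exp(-||z_i - z_k||^2
#' / (2 sigma_path))`. The exponent uses `2 * sigma_path` in the denominator
#' (set `square_sigma = TRUE` for a conventional `2 sigma^2` filter).
#'
#' @param ldps an `ldp_set`.
#' @param path_vertices ordered LDP ids along the path (e.g. `P1$vertices`
#'   from [k_longest_paths()]).
#' @param grid the [density_grid()] the LDPs came from.
#' @param sigma_path smoothing bandwidth (Angstrom).
#' @param square_sigma use `sigma_path^2` in the exponent denominator.
#' @return An object of class `path_profile`: list with `ldp_ids`,
#'   `positions` (L x 3), `v_raw`, `V` and cumulative arc length `arc`.
#' @export
path_profile <- function(ldps, path_vertices, grid, sigma_path = 1.0,
                         square_sigma = FALSE) {
  stopifnot(sigma_path > 0, length(path_vertices) >= 1)
  pos <- ldps$pos[path_vertices, , drop = FALSE]
  v <- vapply(path_vertices, function(k) {
    mem <- ldps$members[[k]]
    sum(grid$values[mem])
  }, 1)
  d2 <- as.matrix(dist(pos))^2
  denom <- if (square_sigma) 2 * sigma_path^2 else 2 * sigma_path
  V <- as.vector((1 / sigma_path) * exp(-d2 / denom) %*% v)
  seg <- sqrt(rowSums((pos[-1, , drop = FALSE] -
                       pos[-nrow(pos), , drop = FALSE])^2))
  structure(list(ldp_ids = path_vertices, positions = pos, v_raw = v, V = V,
                 arc = c(0, cumsum(seg))),
            class = "path_profile")
}

#' Z-score similarity matrix between path and residue densities
#'
#' `SCO[k, j] = 1 - |Z(V_k) - Z(A_j)|`, each string Z-scored with its
#' population standard deviation. A string with fewer than two values or
#' zero variance contributes zeros.
#'
#' @param V path density profile.
#' @param A residue density profile.
#' @return L x N similarity matrix (may contain negative scores).
#' @export
zscore_similarity <- function(V, A) {
  zv <- zscore(V); za <- zscore(A)
  1 - abs(outer(zv, za, "-"))
}

#' Distance between two path positions
#'
#' Euclidean distance between the LDPs to which two successive assigned
#' residues map (`k_prev < k_curr` under the monotone alignment).
#'
#' @param path a `path_profile`.
#' @param k_prev,k_curr path indices (1-based, `k_prev < k_curr`).
#' @param metric `"arc"` (default): distance along the path polyline;
#'   `"euclidean"`: straight-line distance. The two coincide on straight
#'   paths; on curled paths only the arc length tracks sequence progression.
#' @return Distance in Angstrom.
#' @export
measure_d <- function(path, k_prev, k_curr, metric = c("arc", "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(k_prev < k_curr)
  if (metric == "arc") path$arc[k_curr] - path$arc[k_prev]
  else vnorm(path$positions[k_curr, ] - path$positions[k_prev, ])
}

# position at arc length s along the path polyline, with linear
# extrapolation beyond either terminus
point_at_arc <- function(path, s) {
  arc <- path$arc; P <- path$positions
  L <- nrow(P)
  if (L == 1L) return(P[1, ] + c(s, 0, 0))
  if (s <= 0) {
    u <- (P[1, ] - P[2, ]) / max(arc[2] - arc[1], 1e-9)
    return(P[1, ] + u * (-s))
  }
  if (s >= arc[L]) {
    u <- (P[L, ] - P[L - 1, ]) / max(arc[L] - arc[L - 1], 1e-9)
    return(P[L, ] + u * (s - arc[L]))
  }
  i <- findInterval(s, arc)
  t <- (s - arc[i]) / max(arc[i + 1] - arc[i], 1e-9)
  P[i, ] + t * (P[i + 1, ] - P[i, ])
}

#' Thread a sequence onto a path profile
#'
#' Semi-global dynamic programming: residues map to path LDPs in strictly
#' increasing order; each match earns the Z-score similarity minus a
#' C-alpha-geometry penalty `w_ca * |d_std - d|` (d = distance between the
#' LDPs of successive assigned residues; the first match has no distance
#' term); unassigned residues pay `gap` each, while skipped LDPs are free
#' (paths carry far more LDPs than there are residues). The reverse
#' direction threads the reversed sequence. Unassigned residues are placed
#' by arc-length interpolation between flanking assignments; dangling
#' termini are extrapolated at `d_std` spacing along the terminal path
#' direction.
#'
#' @param profile a `residue_profile`.
#' @param path a `path_profile`.
#' @param gap per-residue gap penalty (a negative number, default -1).
#' @param w_ca weight of the distance penalty (default 0.9).
#' @param d_std standard C-alpha-C-alpha distance in Angstrom (default 3.8).
#' @param direction `"forward"` or `"reverse"`.
#' @param d_metric inter-residue distance metric, `"arc"` (default) or
#'   `"euclidean"`; see [measure_d()]. On a curled path the Euclidean
#'   metric lets the alignment skip whole turns at the standard C-alpha
#'   spacing, so arc length is the geometrically sound default.
#' @return An object of class `threaded_model`: list with `ca_coords`
#'   (N x 3, one row per residue of the input sequence), `assignments`
#'   (path index per residue, NA for gaps), `score`, `direction`, `params`.
#' @export
thread_sequence <- function(profile, path, gap = -1, w_ca = 0.9,
                            d_std = 3.8, direction = c("forward", "reverse"),
                            d_metric = c("arc", "euclidean")) {
  direction <- match.arg(direction)
  d_metric <- match.arg(d_metric)
  A <- profile$A
  n <- length(A)
  if (direction == "reverse") A <- rev(A)
  V <- path$V
  L <- length(V)
  SCO <- zscore_similarity(V, A)
  dmat <- if (d_metric == "arc") abs(outer(path$arc, path$arc, "-"))
          else as.matrix(dist(path$positions))
  pen <- w_ca * abs(d_std - dmat)
  M <- matrix(-Inf, L, n)        # M[i, j]: residue j matched at LDP i
  C <- matrix(-Inf, L, n)        # best M[i, j'] + (j - j') * gap over j' <= j
  ptr_i <- matrix(0L, L, n)      # predecessor LDP (0 = first match)
  Cj <- matrix(0L, L, n)         # j' achieving C[i, j]
  for (j in seq_len(n)) {
    if (j == 1L) {
      M[, 1] <- SCO[, 1]
    } else {
      M[, j] <- SCO[, j] + (j - 1) * gap  # j is the first matched residue
      for (i in seq_len(L)) {
        if (i == 1L) next
        prev <- seq_len(i - 1L)
        cand <- C[prev, j - 1] - pen[prev, i]
        b <- which.max(cand)
        if (cand[b] > M[i, j] - SCO[i, j]) {
          M[i, j] <- SCO[i, j] + cand[b]
          ptr_i[i, j] <- b
        }
      }
    }
    if (j == 1L) {
      C[, 1] <- M[, 1]
      Cj[, 1] <- 1L
    } else {
      carry <- C[, j - 1] + gap
      take_new <- M[, j] >= carry
      C[, j] <- ifelse(take_new, M[, j], carry)
      Cj[, j] <- ifelse(take_new, j, Cj[, j - 1])
    }
  }
  final <- M + matrix((n - seq_len(n)) * gap, L, n, byrow = TRUE)
  best <- arrayInd(which.max(final), dim(final))
  score <- final[best]
  # traceback
  assign_rev <- rep(NA_integer_, n)  # in the threaded (possibly reversed) order
  i <- best[1]; j <- best[2]
  repeat {
    assign_rev[j] <- i
    pi_ <- ptr_i[i, j]
    if (pi_ == 0L) break
    j2 <- Cj[pi_, j - 1]
    i <- pi_; j <- j2
  }
  # coordinates in threaded order
  arc <- path$arc
  coords <- matrix(NA_real_, n, 3)
  mj <- which(!is.na(assign_rev))
  s_res <- rep(NA_real_, n)
  s_res[mj] <- arc[assign_rev[mj]]
  j1 <- mj[1]; j2 <- mj[length(mj)]
  if (j1 > 1)
    s_res[seq_len(j1 - 1)] <- s_res[j1] - d_std * ((j1 - 1):1)
  if (j2 < n)
    s_res[(j2 + 1):n] <- s_res[j2] + d_std * seq_len(n - j2)
  if (length(mj) > 1) {
    for (q in seq_len(length(mj) - 1)) {
      a <- mj[q]; b <- mj[q + 1]
      if (b > a + 1) {
        t <- seq_len(b - a - 1) / (b - a)
        s_res[(a + 1):(b - 1)] <- s_res[a] + t * (s_res[b] - s_res[a])
      }
    }
  }
  for (j_ in seq_len(n)) coords[j_, ] <- point_at_arc(path, s_res[j_])
  if (direction == "reverse") {
    coords <- coords[n:1, , drop = FALSE]
    assignments <- rev(assign_rev)
  } else {
    assignments <- assign_rev
  }
  structure(list(ca_coords = coords, assignments = assignments,
                 score = score, direction = direction,
                 params = list(gap = gap, w_ca = w_ca, d_std = d_std,
                               d_metric = d_metric)),
            class = "threaded_model")
}

#' @export
print.threaded_model <- function(x, ...) {
  cat("threaded_model:", nrow(x$ca_coords), "residues,",
      sum(!is.na(x$assignments)), "assigned,",
      "direction", x$direction, ", score",
      format(x$score, digits = 6), "\n")
  invisible(x)
}
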