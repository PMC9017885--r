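#' Deterministic quasi-uniform perturbation directions
#'
#' The default direction set for perturbation response scanning: the 10
#' antipodally-unique vertices of a regular dodecahedron, normalised to unit
#' length. Because the response magnitude is even in the force direction,
#' averaging over this half-set equals averaging over all 20 vertices, which
#' form a spherical 5-design — so the 10-direction average is an excellent
#' quadrature for the isotropic (all-direction) response.
#'
#' @param n_directions number of directions; for `scheme = "fixed_set"` only
#'   10 is available.
#' @param scheme `"fixed_set"` (deterministic, default) or `"seeded_random"`
#'   (uniform directions on the sphere from `seed`).
#' @param seed integer seed for `"seeded_random"`.
#' @return `n_directions` x 3 matrix of unit vectors.
#' @export
prs_directions <- function(n_directions = 10L,
                           scheme = c("fixed_set", "seeded_random"),
                           seed = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "fixed_set") {
    if (n_directions != 10L) {
      stop("fixed_set provides exactly 10 directions; use seeded_random for other counts")
    }
    phi <- (1 + sqrt(5)) / 2
    v <- rbind(
      c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1),
      c(0, 1 / phi, phi), c(0, 1 / phi, -phi),
      c(1 / phi, phi, 0), c(1 / phi, -phi, 0),
      c(phi, 0, 1 / phi), c(phi, 0, -1 / phi))
    return(v / sqrt(rowSums(v^2)))
  }
  if (is.null(seed)) stop("seeded_random requires a seed")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  v <- matrix(stats::rnorm(3L * n_directions), n_directions, 3L)
  v / sqrt(rowSums(v^2))
}

#' Perturbation response scanning matrix
#'
#' Applies a unit force at each residue in turn, in several directions, and
#' records the displacement response of every residue through the linear
#' response relation dR = G F. Entry `A[i, j]` is the response magnitude of
#' residue i to a perturbation at residue j, averaged over the force
#' directions.
#'
#' @param G a `covariance_like` (ENM pseudo-inverse or MD covariance).
#' @param n_directions number of force directions (default 10).
#' @param scheme direction scheme, see [prs_directions()].
#' @param seed seed for `"seeded_random"`.
#' @param magnitude `"meansq"` (default): mean over directions of the squared
#'   Euclidean norm of the 3-vector displacement — the mean-square response,
#'   which the fixed direction set integrates exactly (its isotropic average
#'   has the closed form `trace(B' B) / 3` for the 3x3 response block `B`);
#'   `"norm"`: mean displacement norm.
#' @return object of class `perturbation_matrix`: fields `entries` (N x N,
#'   non-negative), `n`, `n_directions`, `scheme`, `seed`, `magnitude`.
#' @export
perturbation_matrix <- function(G, n_directions = 10L,
                                scheme = c("fixed_set", "seeded_random"),
                                seed = NULL,
                                magnitude = c("meansq", "norm")) {
  scheme <- match.arg(scheme)
  magnitude <- match.arg(magnitude)
  if (!inherits(G, "covariance_like")) G <- covariance_like(G)
  D <- prs_directions(n_directions, scheme, seed)
  n <- G$n
  M <- G$entries
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    Bj <- M[, (3L * j - 2L):(3L * j), drop = FALSE]     # 3N x 3
    R <- Bj %*% t(D)                                    # 3N x n_dir
    sq <- R[seq(1L, 3L * n, 3L), , drop = FALSE]^2 +
          R[seq(2L, 3L * n, 3L), , drop = FALSE]^2 +
          R[seq(3L, 3L * n, 3L), , drop = FALSE]^2      # N x n_dir
    A[, j] <- if (magnitude == "norm") rowMeans(sqrt(sq)) else rowMeans(sq)
  }
  structure(list(entries = A, n = n, n_directions = nrow(D), scheme = scheme,
                 seed = seed, magnitude = magnitude),
            class = "perturbation_matrix")
}

#' Percentile ranks
#'
#' `rank_i = |{k : value_k <= value_i}| / N`; tied values share the maximal
#' count, so the maximum rank is always exactly 1. Values are compared after
#' rounding to 12 significant digits, so ties produced by symmetric
#' geometries survive double-precision round-off.
#'
#' @param values numeric vector.
#' @return vector of ranks in `(0, 1]`.
#' @export
percentile_rank <- function(values) {
  if (length(values) == 0L) stop("empty value vector")
  rank(signif(values, 12L), ties.method = "max") / length(values)
}

new_dynamics_profile <- function(values, metric, residue_ids = NULL,
                                 functional = NULL) {
  structure(list(values = values, ranks = percentile_rank(values),
                 metric = metric, residue_ids = residue_ids,
                 functional = functional),
            class = "dynamics_profile")
}

#' @export
print.dynamics_profile <- function(x, ...) {
  cat(sprintf("%s profile over %d residues (mean %.4g, max %%rank at %s)\n",
              toupper(x$metric), length(x$values), mean(x$values),
              if (is.null(x$residue_ids)) which.max(x$values)
              else x$residue_ids[which.max(x$values)]))
  invisible(x)
}

#' Dynamic flexibility index
#'
#' `DFI_i` is the total displacement of residue i under perturbations at all
#' residues (row sum of the perturbation matrix), normalised by the total
#' displacement of all residues; the profile sums to 1 by construction. Low
#' DFI marks rigid, hinge-like positions that transmit rather than absorb
#' perturbations; high DFI marks flexible positions.
#'
#' @param A a [perturbation_matrix()].
#' @param residue_ids optional author residue ids to attach.
#' @return `dynamics_profile` with `values` (summing to 1) and percentile
#'   `ranks` (%DFI).
#' @export
dfi <- function(A, residue_ids = NULL) {
  tot <- sum(A$entries)
  if (tot <= 0) stop("null response matrix")
  new_dynamics_profile(rowSums(A$entries) / tot, "dfi", residue_ids)
}

#' Dynamic coupling index
#'
#' `DCI_i` is the mean response of residue i to perturbations at the
#' functional sites, relative to its mean response to perturbations anywhere:
#' values above 1 mark residues whose dynamics are preferentially coupled to
#' the functional set. Percentile ranks (%DCI) are taken over all residues.
#'
#' @param A a [perturbation_matrix()].
#' @param functional a [functional_sites()] or vector of residue ids; resolved
#'   against `residue_ids` when given, else taken as 1-based column indices.
#' @param residue_ids optional author residue ids for the N residues.
#' @return `dynamics_profile` with DCI `values` and `%DCI` ranks.
#' @export
dci <- function(A, functional, residue_ids = NULL) {
  ids <- as_site_ids(functional)
  if (length(ids) == 0L) stop("empty functional site set")
  if (is.null(residue_ids)) {
    fidx <- as.integer(ids)
    if (anyNA(fidx) || any(fidx < 1L | fidx > A$n)) {
      stop("functional sites must be residue indices in 1..N")
    }
  } else {
    fidx <- match(ids, as.character(residue_ids))
    if (anyNA(fidx)) stop("residue not in chain: ",
                          paste(ids[is.na(fidx)], collapse = ", "))
  }
  num <- rowMeans(A$entries[, fidx, drop = FALSE])
  den <- rowMeans(A$entries)
  if (any(den <= 0)) stop("null response matrix")
  new_dynamics_profile(num / den, "dci", residue_ids, functional = ids)
}

#' Directional asymmetry of dynamic coupling
#'
#' `raw = DCI(i | {j}) - DCI(j | {i})` and `percent` is the same difference on
#' percentile ranks, each direction ranked within the full per-residue
#' distribution of couplings to the respective single-site functional set.
#' A positive value means site j dominates the communication (i responds to
#' j more strongly than j responds to i). Antisymmetric by construction;
#' exactly zero when `i == j`.
#'
#' @param A a [perturbation_matrix()].
#' @param i,j residue ids (resolved via `residue_ids`) or 1-based indices.
#' @param residue_ids optional author residue ids.
#' @return list with components `raw` and `percent`.
#' @export
dci_asymmetry <- function(A, i, j, residue_ids = NULL) {
  if (identical(as.character(i), as.character(j))) {
    return(list(raw = 0, percent = 0))
  }
  p_ij <- dci(A, list_sites(j), residue_ids)  # coupling of everyone to {j}
  p_ji <- dci(A, list_sites(i), residue_ids)  # coupling of everyone to {i}
  ii <- resolve_one(i, A$n, residue_ids)
  jj <- resolve_one(j, A$n, residue_ids)
  list(raw = p_ij$values[ii] - p_ji$values[jj],
       percent = p_ij$ranks[ii] - p_ji$ranks[jj])
}

list_sites <- function(x) {
  if (inherits(x, "functional_sites")) x else as.character(x)
}

resolve_one <- function(id, n, residue_ids) {
  if (is.null(residue_ids)) {
    idx <- as.integer(id)
    if (is.na(idx) || idx < 1L || idx > n) stop("residue not in chain: ", id)
    idx
  } else {
    idx <- match(as.character(id), as.character(residue_ids))
    if (is.na(idx)) stop("residue not in chain: ", id)
    idx
  }
}

#' Relative change of a dynamics profile upon mutation
#'
#' Element-wise `(mutant - wildtype) / wildtype` on the profile values.
#'
#' @param mutant,wildtype `dynamics_profile` objects of equal length.
#' @return object of class `delta_profile` with `values` and `baseline`.
#' @export
delta_profile <- function(mutant, wildtype) {
  mv <- if (inherits(mutant, "dynamics_profile")) mutant$values else mutant
  wv <- if (inherits(wildtype, "dynamics_profile")) wildtype$values else wildtype
  if (length(mv) != length(wv)) stop("profile length mismatch")
  if (any(wv == 0)) {
    stop("division by zero at residue ", which(wv == 0)[1L])
  }
  structure(list(values = (mv - wv) / wv,
                 baseline = if (inherits(wildtype, "dynamics_profile"))
                   wildtype$metric else "values"),
            class = "delta_profile")
}

#' Is a site a DARC (dynamic allosteric residue coupling) site?
#'
#' A DARC site sits farther than `distance_cutoff` from every functional
#' residue (no direct contact) yet has a %DCI above `rank_threshold` (strong
#' coupling). Both inequalities are strict. Functional residues themselves
#' are never DARC sites (their distance is 0).
#'
#' @param chain a [calpha_chain()].
#' @param site author residue id.
#' @param functional a [functional_sites()].
#' @param dci_ranks per-residue %DCI vector aligned with the chain.
#' @param rank_threshold %DCI threshold (default 0.60).
#' @param distance_cutoff distance threshold in Angstrom (default 10).
#' @return logical.
#' @export
classify_darc <- function(chain, site, functional, dci_ranks,
                          rank_threshold = 0.60, distance_cutoff = 10) {
  if (rank_threshold < 0 || rank_threshold > 1) stop("rank_threshold in [0,1]")
  if (distance_cutoff < 0) stop("distance_cutoff must be non-negative")
  d <- min_site_distance(chain, site, functional)
  r <- dci_ranks[chain_index(chain, site)]
  (d > distance_cutoff) && (r > rank_threshold)
}
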