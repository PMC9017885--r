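#' Generate a synthetic C-alpha structure
#'
#' Deterministic toy geometries plus a seeded compact random coil, used to
#' exercise the whole dynamics stack without any structure download.
#'
#' \describe{
#'   \item{`tetrahedron`}{4 nodes, all pairwise distances equal to `spacing`.}
#'   \item{`collinear_chain`}{n nodes on the x axis, `spacing` apart.}
#'   \item{`zigzag_chain`}{planar zigzag with bond length `spacing` and a
#'     120-degree bond angle.}
#'   \item{`helix`}{ideal alpha-helix-like spiral (2.3 A radius, 1.5 A rise,
#'     100 degrees per residue; `spacing` scales the geometry relative to the
#'     3.8 A C-alpha default).}
#'   \item{`random_compact`}{seeded self-avoiding random walk with step
#'     `spacing`, biased toward its centre of mass so the coil stays compact.}
#' }
#'
#' @param kind one of `"tetrahedron"`, `"collinear_chain"`, `"zigzag_chain"`,
#'   `"helix"`, `"random_compact"`.
#' @param n residue count (ignored for tetrahedron, which has 4).
#' @param spacing bond length in Angstrom (default 3.8).
#' @param seed integer seed (random_compact only).
#' @return a [calpha_chain()] with residue ids `1..n`.
#' @export
make_structure <- function(kind = c("tetrahedron", "collinear_chain",
                                    "zigzag_chain", "random_compact", "helix"),
                           n = 10L, spacing = 3.8, seed = 1L) {
  kind <- match.arg(kind)
  if (spacing <= 0) stop("spacing must be positive")
  coords <- switch(kind,
    tetrahedron = {
      v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
      v * spacing / sqrt(8)      # edge length = spacing
    },
    collinear_chain = {
      if (n < 3L) stop("n must be >= 3")
      cbind(spacing * (seq_len(n) - 1L), 0, 0)
    },
    zigzag_chain = {
      if (n < 3L) stop("n must be >= 3")
      i <- seq_len(n) - 1L
      cbind(spacing * cos(pi / 6) * i, spacing * sin(pi / 6) * (i %% 2L), 0)
    },
    helix = {
      if (n < 3L) stop("n must be >= 3")
      i <- seq_len(n) - 1L
      th <- i * 100 * pi / 180
      s <- spacing / 3.8
      cbind(2.3 * s * cos(th), 2.3 * s * sin(th), 1.5 * s * i)
    },
    random_compact = {
      if (n < 3L) stop("n must be >= 3")
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
      xyz <- matrix(0, n, 3L)
      min_sep <- 0.75 * spacing
      for (i in 2:n) {
        com <- colMeans(xyz[seq_len(i - 1L), , drop = FALSE])
        for (attempt in 1:200) {
          dir <- stats::rnorm(3L)
          # pull toward the centre of mass to keep the coil compact
          dir <- dir / sqrt(sum(dir^2)) + 0.4 * (com - xyz[i - 1L, ]) / spacing
          dir <- dir / sqrt(sum(dir^2))
          cand <- xyz[i - 1L, ] + spacing * dir
          d2 <- colSums((t(xyz[seq_len(i - 1L), , drop = FALSE]) - cand)^2)
          if (min(d2) > min_sep^2) break
        }
        xyz[i, ] <- cand
      }
      xyz
    })
  calpha_chain(seq_len(nrow(coords)), coords, chain_id = "A",
               source = paste0("synthetic:", kind))
}

#' Sample a Gaussian conformational ensemble with prescribed covariance
#'
#' Draws frames from the multivariate normal with mean equal to the given
#' structure and 3N x 3N covariance `G0`. Sampling uses the eigenmodes of
#' `G0` with positive eigenvalues only, so rigid-body null-space directions
#' (when `G0` is an ENM pseudo-inverse) are never excited and superposition
#' is near-idempotent on the result.
#'
#' @param G0 a `covariance_like` (positive semidefinite).
#' @param mean_structure a [calpha_chain()] with matching residue count.
#' @param n_frames number of frames (>= 2).
#' @param seed integer seed.
#' @return a [trajectory()].
#' @export
make_gaussian_ensemble <- function(G0, mean_structure, n_frames, seed = 1L) {
  if (!inherits(G0, "covariance_like")) G0 <- covariance_like(G0)
  n <- n_residues(mean_structure)
  if (G0$n != n) stop("covariance dimension does not match structure")
  if (n_frames < 2L) stop("need at least 2 frames")
  eg <- eigen(G0$entries, symmetric = TRUE)
  keep <- eg$values > 1e-10 * max(eg$values)
  V <- eg$vectors[, keep, drop = FALSE]
  sdv <- sqrt(eg$values[keep])
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  Z <- matrix(stats::rnorm(n_frames * length(sdv)), n_frames)
  X <- Z %*% (t(V) * sdv)                 # frames x 3N displacements
  mu <- as.vector(t(mean_structure$coords))  # (x1,y1,z1,...)
  fr <- array(0, c(n_frames, n, 3L))
  xi <- seq(1L, 3L * n, 3L)
  fr[, , 1L] <- sweep(X[, xi, drop = FALSE], 2L, mu[xi], `+`)
  fr[, , 2L] <- sweep(X[, xi + 1L, drop = FALSE], 2L, mu[xi + 1L], `+`)
  fr[, , 3L] <- sweep(X[, xi + 2L, drop = FALSE], 2L, mu[xi + 2L], `+`)
  trajectory(fr)
}

#' Generate a labelled variant cohort with planted coupling signal
#'
#' Samples variant sites (without replacement, excluding the functional
#' residues themselves) and assigns disease labels whose probability rises
#' with the site's %DCI to the functional set:
#' `P(disease) = signal * plogis(steepness * (%DCI - 0.6)) +
#' (1 - signal) * 0.5`. At `signal = 0` labels are fair coin flips; at
#' `signal = 1` with steep slope, disease labels concentrate at
#' highly-coupled sites — emulating the observed enrichment of pathogenic
#' variants at sites strongly coupled to the active site.
#'
#' @param chain a [calpha_chain()].
#' @param functional a [functional_sites()].
#' @param n_variants number of variant sites to draw.
#' @param signal signal strength in `[0, 1]`.
#' @param seed integer seed.
#' @param steepness logistic slope (default 20).
#' @param A optional precomputed [perturbation_matrix()]; built from the
#'   default ENM when omitted.
#' @return data.frame with columns `protein_id`, `site`, `label`, `pct_dci`.
#' @export
make_variant_cohort <- function(chain, functional, n_variants, signal = 1,
                                seed = 1L, steepness = 20, A = NULL) {
  if (signal < 0 || signal > 1) stop("signal must be in [0, 1]")
  if (!inherits(functional, "functional_sites")) {
    functional <- functional_sites(functional)
  }
  if (is.null(A)) {
    A <- perturbation_matrix(pseudo_inverse(build_hessian(chain)))
  }
  prof <- dci(A, functional, chain$residue_ids)
  pool <- setdiff(chain$residue_ids, functional$residue_ids)
  if (n_variants > length(pool)) {
    stop("n_variants exceeds available (non-functional) sites")
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sites <- sample(pool, n_variants)
  pct <- prof$ranks[chain_index(chain, sites)]
  p <- signal * stats::plogis(steepness * (pct - 0.6)) + (1 - signal) * 0.5
  data.frame(protein_id = chain$source, site = sites,
             label = stats::rbinom(n_variants, 1L, p),
             pct_dci = unname(pct), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write a C-alpha chain as a single-model PDB file
#'
#' @param chain a [calpha_chain()].
#' @param path output path.
#' @export
write_chain_pdb <- function(chain, path) {
  n <- n_residues(chain)
  resno <- suppressWarnings(as.integer(chain$residue_ids))
  if (anyNA(resno)) resno <- seq_len(n)
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), chain$chain_id, resno,
    chain$coords[, 1L], chain$coords[, 2L], chain$coords[, 3L])
  writeLines(c(lines, "END"), path)
}
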