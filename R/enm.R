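#' Spring-constant model for the elastic network
#'
#' The network connects every residue pair with a harmonic spring. Two
#' standard spring laws are provided:
#' \describe{
#'   \item{`inverse_square`}{distance-dependent, gamma(d) = gamma0 / d^2;
#'     parameter-free beyond the overall scale and the package default.}
#'   \item{`uniform_cutoff`}{gamma(d) = gamma0 for d <= cutoff, else 0 —
#'     the classic anisotropic network model.}
#' }
#' DFI and DCI are ratio quantities, so the overall scale `gamma0` cancels;
#' it is kept for dimensional completeness.
#'
#' @param form `"inverse_square"` or `"uniform_cutoff"`.
#' @param gamma0 spring scale, > 0.
#' @param cutoff interaction cutoff in Angstrom (uniform_cutoff only).
#' @return object of class `spring_model`.
#' @export
spring_model <- function(form = c("inverse_square", "uniform_cutoff"),
                         gamma0 = 1, cutoff = 10) {
  form <- match.arg(form)
  if (gamma0 <= 0) stop("gamma0 must be positive")
  if (form == "uniform_cutoff" && cutoff <= 0) stop("cutoff must be positive")
  structure(list(form = form, gamma0 = gamma0, cutoff = cutoff),
            class = "spring_model")
}

#' Build the elastic-network Hessian
#'
#' Standard anisotropic-network Hessian over the C-alpha nodes: for a
#' connected pair (i, j) with separation vector d and spring constant
#' gamma(|d|), the 3x3 off-diagonal super-element is
#' -(gamma/|d|^2) d d^T, and each diagonal super-element is minus the sum of
#' its row's off-diagonal super-elements (translation invariance).
#'
#' @param chain a [calpha_chain()].
#' @param model a [spring_model()].
#' @return object of class `hessian_matrix`: fields `entries` (3N x 3N),
#'   `n`, `model`.
#' @export
build_hessian <- function(chain, model = spring_model()) {
  xyz <- chain$coords
  n <- nrow(xyz)
  if (n < 3L) stop("degenerate chain: fewer than 3 residues")
  H <- matrix(0, 3L * n, 3L * n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      dv <- xyz[j, ] - xyz[i, ]
      d2 <- sum(dv * dv)
      if (d2 < 1e-12) stop("zero-distance pair: residues ",
                           chain$residue_ids[i], " and ", chain$residue_ids[j])
      gam <- switch(model$form,
        inverse_square = model$gamma0 / d2,
        uniform_cutoff = if (d2 <= model$cutoff^2) model$gamma0 else 0)
      if (gam == 0) next
      blk <- -(gam / d2) * tcrossprod(dv)
      bi <- (3L * i - 2L):(3L * i)
      bj <- (3L * j - 2L):(3L * j)
      H[bi, bj] <- blk
      H[bj, bi] <- blk
      H[bi, bi] <- H[bi, bi] - blk
      H[bj, bj] <- H[bj, bj] - blk
    }
  }
  structure(list(entries = H, n = n, model = model), class = "hessian_matrix")
}

#' Pseudo-inverse of an elastic-network Hessian
#'
#' Eigendecomposes the Hessian, discards near-null modes (rigid-body
#' translations and rotations: expected count 6 for a non-collinear
#' structure), and reconstructs the covariance-like inverse from the
#' remaining modes with reciprocal eigenvalues.
#'
#' @param H a `hessian_matrix` (or plain symmetric 3N x 3N matrix).
#' @param zero_mode_tolerance modes with eigenvalue below this fraction of the
#'   largest eigenvalue are treated as null (default 1e-10).
#' @return object of class `covariance_like`: fields `entries` (3N x 3N),
#'   `n`, `origin = "enm_pseudoinverse"`, `n_zero_modes`.
#' @export
pseudo_inverse <- function(H, zero_mode_tolerance = 1e-10) {
  M <- if (inherits(H, "hessian_matrix")) H$entries else as.matrix(H)
  if (nrow(M) != ncol(M) || max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M)))) {
    stop("Hessian must be a symmetric square matrix")
  }
  n <- nrow(M) %/% 3L
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lam <- eg$values
  thresh <- zero_mode_tolerance * max(lam)
  keep <- lam > thresh
  n_zero <- sum(!keep)
  if (!any(keep)) stop("rank-deficient Hessian: all modes below tolerance")
  if (n_zero != 6L) {
    warning("discarded ", n_zero, " near-null modes (expected 6)")
  }
  V <- eg$vectors[, keep, drop = FALSE]
  G <- V %*% (t(V) / lam[keep])
  G <- (G + t(G)) / 2
  covariance_like(G, origin = "enm_pseudoinverse", n_zero_modes = n_zero)
}

#' Wrap a 3N x 3N matrix as a covariance-like object
#'
#' @param entries symmetric positive-semidefinite 3N x 3N matrix.
#' @param origin provenance: `"enm_pseudoinverse"`, `"md_covariance"` or
#'   `"external"`.
#' @param n_zero_modes number of discarded null modes, if known.
#' @param check validate symmetry (default TRUE).
#' @return object of class `covariance_like`.
#' @export
covariance_like <- function(entries, origin = "external", n_zero_modes = NA,
                            check = TRUE) {
  entries <- as.matrix(entries)
  if (nrow(entries) != ncol(entries) || nrow(entries) %% 3L != 0L) {
    stop("covariance must be a square 3N x 3N matrix")
  }
  if (check) {
    scale <- max(1, max(abs(entries)))
    if (max(abs(entries - t(entries))) > 1e-8 * scale) {
      stop("covariance must be symmetric")
    }
  }
  structure(list(entries = entries, n = nrow(entries) %/% 3L,
                 origin = origin, n_zero_modes = n_zero_modes),
            class = "covariance_like")
}

#' @export
print.covariance_like <- function(x, ...) {
  cat(sprintf("covariance_like: %d residues (3N = %d), origin = %s\n",
              x$n, 3L * x$n, x$origin))
  invisible(x)
}

#' Write a matrix dump (versioned plain-text format)
#'
#' Format: a comment header line `# prsdyn-matrix v1 n=<N>` followed by the
#' 3N x 3N matrix, one whitespace-separated row per line.
#'
#' @param x a `hessian_matrix` or `covariance_like` (or plain matrix).
#' @param path output path.
#' @export
write_matrix_dump <- function(x, path) {
  M <- if (is.list(x)) x$entries else as.matrix(x)
  n <- nrow(M) %/% 3L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# prsdyn-matrix v1 n=%d", n), con)
  utils::write.table(M, con, row.names = FALSE, col.names = FALSE)
}

#' Read a matrix dump written by [write_matrix_dump()]
#'
#' @param path input path.
#' @param origin provenance tag for the returned object.
#' @return a `covariance_like`.
#' @export
read_matrix_dump <- function(path, origin = "external") {
  header <- readLines(path, n = 1L)
  if (!grepl("^# prsdyn-matrix v1 n=\\d+$", header)) {
    stop("not a prsdyn matrix dump (bad header)")
  }
  n <- as.integer(sub("^# prsdyn-matrix v1 n=", "", header))
  M <- as.matrix(utils::read.table(path, skip = 1L))
  dimnames(M) <- NULL
  if (nrow(M) != 3L * n) stop("matrix dump size disagrees with header")
  covariance_like(M, origin = origin, check = FALSE)
}
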