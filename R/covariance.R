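#' Construct a coordinate trajectory
#'
#' @param frames numeric array of dimension (T, N, 3): T snapshots of N
#'   C-alpha positions in Angstrom.
#' @param frame_spacing time per frame (metadata only; any unit).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(frames, frame_spacing = 1) {
  if (length(dim(frames)) != 3L || dim(frames)[3L] != 3L) {
    stop("frames must be a (T, N, 3) array")
  }
  if (dim(frames)[1L] < 2L) stop("trajectory needs at least 2 frames")
  structure(list(frames = frames, frame_spacing = frame_spacing),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("trajectory: %d frames x %d residues (spacing %g)\n",
              d[1L], d[2L], x$frame_spacing))
  invisible(x)
}

n_frames <- function(traj) dim(traj$frames)[1L]

# Kabsch: rotation R minimising ||mobile %*% R - ref|| for centred N x 3 sets
kabsch_rotation <- function(mobile, ref) {
  s <- svd(crossprod(mobile, ref))
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Remove global rotation and translation from a trajectory
#'
#' Least-squares superposes every frame onto an iteratively updated mean
#' structure (Kabsch alignment; the mean is recomputed and the alignment
#' repeated `iterations` times). This removes rigid-body motion so that the
#' remaining coordinate fluctuations reflect internal dynamics only.
#'
#' @param traj a [trajectory()].
#' @param iterations mean-structure refinement passes (default 2).
#' @return superposed [trajectory()].
#' @export
superpose_frames <- function(traj, iterations = 2L) {
  fr <- traj$frames
  T <- dim(fr)[1L]
  ref <- fr[1L, , , drop = TRUE]
  if (qr(scale(ref, scale = FALSE))$rank < 2L) {
    warning("degenerate (collinear) reference geometry; superposing onto first frame only")
    iterations <- 0L
  }
  align_all <- function(fr, ref) {
    refc <- scale(ref, scale = FALSE)
    for (t in seq_len(T)) {
      X <- fr[t, , , drop = TRUE]
      mu <- colMeans(X)
      Xc <- sweep(X, 2L, mu)
      fr[t, , ] <- Xc %*% kabsch_rotation(Xc, refc)
      fr[t, , ] <- sweep(fr[t, , , drop = TRUE], 2L, -attr(refc, "scaled:center"))
    }
    fr
  }
  fr <- align_all(fr, ref)
  for (it in seq_len(iterations)) {
    ref <- apply(fr, c(2L, 3L), mean)
    fr <- align_all(fr, ref)
  }
  trajectory(fr, traj$frame_spacing)
}

# flatten one frame to the (x1,y1,z1,x2,...) layout used by 3N matrices
flatten_frames <- function(frames) {
  T <- dim(frames)[1L]; n <- dim(frames)[2L]
  out <- matrix(0, T, 3L * n)
  out[, seq(1L, 3L * n, 3L)] <- frames[, , 1L]
  out[, seq(2L, 3L * n, 3L)] <- frames[, , 2L]
  out[, seq(3L, 3L * n, 3L)] <- frames[, , 3L]
  out
}

#' Moving-window covariance matrices of a trajectory
#'
#' Splits the trajectory into overlapping windows (starts at multiples of
#' `window_length - overlap`) and returns the 3N x 3N covariance of the
#' C-alpha positions about each window's own mean. The window count is
#' `floor((T - window_length) / (window_length - overlap)) + 1`.
#'
#' @param traj a [trajectory()] (superpose first; see [superpose_frames()]).
#' @param window_length window size in frames.
#' @param overlap overlap between consecutive windows in frames
#'   (`0 <= overlap < window_length`).
#' @return list of `covariance_like` objects (origin `"md_covariance"`).
#' @export
windowed_covariance <- function(traj, window_length, overlap = 0L) {
  T <- n_frames(traj)
  if (overlap < 0L || overlap >= window_length) {
    stop("need 0 <= overlap < window_length")
  }
  if (T < window_length) stop("trajectory shorter than window")
  step <- window_length - overlap
  starts <- seq.int(1L, by = step,
                    length.out = (T - window_length) %/% step + 1L)
  X <- flatten_frames(traj$frames)
  lapply(starts, function(s) {
    covariance_like(stats::cov(X[s:(s + window_length - 1L), , drop = FALSE]),
                    origin = "md_covariance", check = FALSE)
  })
}

#' Element-wise average of covariance matrices
#'
#' @param gs non-empty list of `covariance_like` objects of equal dimension.
#' @return a `covariance_like` (origin `"md_covariance"`).
#' @export
average_covariance <- function(gs) {
  if (length(gs) == 0L) stop("empty covariance list")
  dims <- vapply(gs, function(g) nrow(g$entries), integer(1L))
  if (length(unique(dims)) != 1L) stop("covariance dimension mismatch")
  M <- Reduce(`+`, lapply(gs, `[[`, "entries")) / length(gs)
  covariance_like(M, origin = "md_covariance", check = FALSE)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame with C-alpha ATOM records, readable by
#' any standard PDB reader (and by [read_trajectory_pdb()]).
#'
#' @param traj a [trajectory()].
#' @param chain a [calpha_chain()] supplying residue numbering.
#' @param path output path.
#' @export
write_trajectory_pdb <- function(traj, chain, path) {
  fr <- traj$frames
  n <- dim(fr)[2L]
  stopifnot(n == n_residues(chain))
  resno <- suppressWarnings(as.integer(chain$residue_ids))
  if (anyNA(resno)) resno <- seq_len(n)
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(dim(fr)[1L])) {
    writeLines(sprintf("MODEL     %4d", t), con)
    writeLines(sprintf(
      "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(n), chain$chain_id, resno,
      fr[t, , 1L], fr[t, , 2L], fr[t, , 3L]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

#' Read a multi-model C-alpha PDB file as a trajectory
#'
#' @param path PDB path.
#' @param chain_id chain to extract.
#' @return a [trajectory()].
#' @export
read_trajectory_pdb <- function(path, chain_id = "A") {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sel <- which(pdb$atom$chain == chain_id & pdb$atom$elety == "CA")
  if (length(sel) == 0L) stop("chain not found: ", chain_id)
  T <- nrow(pdb$xyz)
  n <- length(sel)
  fr <- array(0, c(T, n, 3L))
  xi <- 3L * sel - 2L
  for (t in seq_len(T)) {
    row <- pdb$xyz[t, ]
    fr[t, , 1L] <- row[xi]; fr[t, , 2L] <- row[xi + 1L]; fr[t, , 3L] <- row[xi + 2L]
  }
  trajectory(fr)
}
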