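# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Carlson symmetric elliptic integrals by duplication; R_G(x, y, z) is the
# spherical average of sqrt(x a^2 + y b^2 + z c^2) over unit vectors
# (a, b, c) — the exact direction-average of a residue's displacement norm.
carlson_rf <- function(x, y, z) {
  repeat {
    lam <- sqrt(x) * sqrt(y) + sqrt(y) * sqrt(z) + sqrt(z) * sqrt(x)
    x <- (x + lam) / 4; y <- (y + lam) / 4; z <- (z + lam) / 4
    mu <- (x + y + z) / 3
    if (max(abs(c(x, y, z) - mu)) / mu < 1e-12) break
  }
  X <- 1 - x / mu; Y <- 1 - y / mu; Z <- 1 - z / mu
  E2 <- X * Y - Z^2; E3 <- X * Y * Z
  (1 - E2 / 10 + E3 / 14 + E2^2 / 24 - 3 * E2 * E3 / 44) / sqrt(mu)
}

carlson_rd <- function(x, y, z) {
  s <- 0; fac <- 1
  repeat {
    lam <- sqrt(x) * sqrt(y) + sqrt(y) * sqrt(z) + sqrt(z) * sqrt(x)
    s <- s + fac / (sqrt(z) * (z + lam)); fac <- fac / 4
    x <- (x + lam) / 4; y <- (y + lam) / 4; z <- (z + lam) / 4
    mu <- (x + y + 3 * z) / 5
    if (max(abs(c(x, y, z) - mu)) / mu < 1e-12) break
  }
  X <- (mu - x) / mu; Y <- (mu - y) / mu; Z <- -(X + Y) / 3
  EA <- X * Y - 6 * Z^2; EB <- (3 * X * Y - 8 * Z^2) * Z
  EC <- 3 * (X * Y - Z^2) * Z^2; ED <- X * Y * Z^3
  3 * s + fac * (1 - 3 * EA / 14 + EB / 6 + 9 * EA^2 / 88 - 3 * EC / 22 -
                   9 * ED / 52 + 3 * EA * EB / 26) / (mu * sqrt(mu))
}

carlson_rg <- function(x, y, z) {
  v <- sort(c(x, y, z))
  x <- v[1L]; y <- v[2L]; z <- v[3L]
  if (z < 1e-300) return(0)
  if (x < 1e-14 * z) x <- 0
  (z * carlson_rf(x, y, z) - (x - z) * (y - z) * carlson_rd(x, y, z) / 3 +
     sqrt(x) * sqrt(y) / sqrt(z)) / 2
}

# exact isotropic PRS response matrix for a covariance G (both conventions):
# per (i, j), C = 3x3 response block; meansq average = trace(C'C)/3, norm
# average = R_G of the eigenvalues of C'C.
oracle_prs_matrix <- function(G, magnitude = c("meansq", "norm")) {
  magnitude <- match.arg(magnitude)
  M <- if (inherits(G, "covariance_like")) G$entries else G
  n <- nrow(M) %/% 3L
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    B <- M[, (3L * j - 2L):(3L * j), drop = FALSE]
    for (i in seq_len(n)) {
      C <- B[(3L * i - 2L):(3L * i), , drop = FALSE]
      ev <- eigen(crossprod(C), symmetric = TRUE, only.values = TRUE)$values
      ev[ev < 0] <- 0
      A[i, j] <- if (magnitude == "meansq") sum(ev) / 3
                 else carlson_rg(ev[3L], ev[2L], ev[1L])
    }
  }
  A
}

# brute-force minimum site distance over explicit pairs
oracle_min_distance <- function(chain, site, target_ids) {
  si <- match(as.character(site), chain$residue_ids)
  min(vapply(as.character(target_ids), function(t) {
    ti <- match(t, chain$residue_ids)
    sqrt(sum((chain$coords[si, ] - chain$coords[ti, ])^2))
  }, numeric(1L)))
}

# a small hand-written PDB text fixture (three residues on the x axis, plus
# optional extras exercising altloc / missing-CA handling)
write_tiny_pdb <- function(path, missing_ca = FALSE, altloc = FALSE) {
  lines <- c(
    "ATOM      1  N   ALA A   1      -1.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    if (altloc) c(
      "ATOM      4  CA ASER A   3       7.600   0.000   0.000  0.40  0.00           C",
      "ATOM      5  CA BSER A   3       7.700   0.000   0.000  0.60  0.00           C"
    ) else
      "ATOM      4  CA  SER A   3       7.600   0.000   0.000  1.00  0.00           C",
    if (missing_ca)
      "ATOM      6  N   THR A   4      11.400   0.000   0.000  1.00  0.00           N",
    "END")
  writeLines(lines, path)
  path
}
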