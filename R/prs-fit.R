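#' Fit a perturbation-response-scanning dynamics model
#'
#' The central entry point of the package. Given a C-alpha chain, builds an
#' elastic-network model, takes the pseudo-inverse of its Hessian (or accepts
#' a supplied covariance matrix from molecular dynamics), runs perturbation
#' response scanning, and assembles the per-residue dynamics profiles: DFI
#' and %DFI always, DCI / %DCI and DARC classification when a functional site
#' set is given.
#'
#' @param chain a [calpha_chain()].
#' @param functional optional [functional_sites()] (catalytic residues).
#' @param covariance optional `covariance_like` to use instead of the ENM
#'   pseudo-inverse (e.g. from [windowed_covariance()] /
#'   [average_covariance()]).
#' @param spring a [spring_model()] (ignored when `covariance` is supplied).
#' @param n_directions,scheme,seed,magnitude passed to
#'   [perturbation_matrix()].
#' @param rank_threshold,distance_cutoff DARC thresholds (defaults 0.60 and
#'   10 Angstrom).
#' @param zero_mode_tolerance passed to [pseudo_inverse()].
#' @return object of class `prs`: list with the chain, covariance, the
#'   perturbation matrix `A`, profiles `dfi` and (optionally) `dci`, and the
#'   per-residue results table (see [as.data.frame.prs()]).
#' @examples
#' ch <- make_structure("helix", n = 30)
#' fit <- prs(ch, functional = functional_sites(c(10, 15)))
#' head(as.data.frame(fit))
#' @export
prs <- function(chain, functional = NULL, covariance = NULL,
                spring = spring_model(), n_directions = 10L,
                scheme = c("fixed_set", "seeded_random"), seed = NULL,
                magnitude = c("meansq", "norm"),
                rank_threshold = 0.60, distance_cutoff = 10,
                zero_mode_tolerance = 1e-10) {
  scheme <- match.arg(scheme)
  magnitude <- match.arg(magnitude)
  stopifnot(inherits(chain, "calpha_chain"))
  if (is.null(covariance)) {
    H <- build_hessian(chain, spring)
    G <- pseudo_inverse(H, zero_mode_tolerance)
  } else {
    G <- if (inherits(covariance, "covariance_like")) covariance
         else covariance_like(covariance)
    if (G$n != n_residues(chain)) {
      stop("covariance dimension does not match chain length")
    }
  }
  A <- perturbation_matrix(G, n_directions, scheme, seed, magnitude)
  prof_dfi <- dfi(A, chain$residue_ids)
  prof_dci <- NULL
  darc <- NULL
  if (!is.null(functional)) {
    if (!inherits(functional, "functional_sites")) {
      functional <- functional_sites(functional)
    }
    chain_index(chain, functional$residue_ids)  # validate membership
    prof_dci <- dci(A, functional, chain$residue_ids)
    darc <- vapply(chain$residue_ids, function(s)
      classify_darc(chain, s, functional, prof_dci$ranks,
                    rank_threshold, distance_cutoff), logical(1L))
  }
  structure(list(chain = chain, functional = functional, covariance = G,
                 A = A, dfi = prof_dfi, dci = prof_dci, darc = darc,
                 rank_threshold = rank_threshold,
                 distance_cutoff = distance_cutoff,
                 call = match.call()),
            class = "prs")
}

#' Per-residue results table of a PRS fit
#'
#' @param x a [prs()] fit.
#' @param ... unused.
#' @return data.frame with columns `residue_id`, `dfi`, `pct_dfi`, and when a
#'   functional set was supplied `dci`, `pct_dci`, `min_dist_A`, `is_darc`.
#' @export
as.data.frame.prs <- function(x, ...) {
  out <- data.frame(residue_id = x$chain$residue_ids,
                    dfi = x$dfi$values, pct_dfi = x$dfi$ranks,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(x$dci)) {
    out$dci <- x$dci$values
    out$pct_dci <- x$dci$ranks
    out$min_dist_A <- vapply(x$chain$residue_ids, function(s)
      min_site_distance(x$chain, s, x$functional), numeric(1L))
    out$is_darc <- unname(x$darc)
  }
  out
}

#' @export
print.prs <- function(x, ...) {
  cat("Perturbation response scanning fit\n")
  cat(sprintf("  %d residues, covariance origin: %s\n",
              n_residues(x$chain), x$covariance$origin))
  if (!is.null(x$dci)) {
    cat(sprintf("  functional set '%s': %d residues; %d DARC sites (%%DCI > %.2f, d > %.1f A)\n",
                x$functional$label, length(x$functional$residue_ids),
                sum(x$darc), x$rank_threshold, x$distance_cutoff))
  }
  invisible(x)
}

#' @export
summary.prs <- function(object, ...) {
  tab <- as.data.frame(object)
  structure(list(table = tab, n = nrow(tab),
                 dfi_range = range(tab$dfi),
                 n_darc = if (!is.null(tab$is_darc)) sum(tab$is_darc) else NA,
                 origin = object$covariance$origin),
            class = "summary.prs")
}

#' @export
print.summary.prs <- function(x, ...) {
  cat(sprintf("PRS dynamics summary: %d residues (covariance: %s)\n",
              x$n, x$origin))
  cat(sprintf("  DFI range: [%.4g, %.4g] (profile sums to 1)\n",
              x$dfi_range[1L], x$dfi_range[2L]))
  if (!is.na(x$n_darc)) {
    cat(sprintf("  DARC sites: %d of %d (%.1f%%)\n", x$n_darc, x$n,
                100 * x$n_darc / x$n))
  }
  print(utils::head(x$table))
  invisible(x)
}

#' @export
coef.prs <- function(object, ...) {
  stats::setNames(object$dfi$values, object$chain$residue_ids)
}

#' Plot %DFI (and %DCI) profiles of a PRS fit
#'
#' @param x a [prs()] fit.
#' @param which `"dfi"` or `"dci"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.prs <- function(x, which = c("dfi", "dci"), ...) {
  which <- match.arg(which)
  prof <- if (which == "dfi") x$dfi else x$dci
  if (is.null(prof)) stop("no DCI profile: fit without functional sites")
  idx <- seq_along(prof$values)
  graphics::plot(idx, 100 * prof$ranks, type = "l",
                 xlab = "residue index", ylab = paste0("%", toupper(which)),
                 ...)
  if (which == "dci" && !is.null(x$darc)) {
    graphics::points(idx[x$darc], 100 * prof$ranks[x$darc], col = 2, pch = 16)
  }
  invisible(x)
}
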