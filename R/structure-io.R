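#' Construct a C-alpha chain object
#'
#' A `calpha_chain` is the geometric substrate of the whole package: one
#' coordinate per residue (the C-alpha position), together with the author
#' residue numbering used at every user-facing interface. Internally all
#' matrices are addressed by contiguous 1-based indices; the `residue_ids`
#' vector is the bidirectional map between the two.
#'
#' @param residue_ids ordered vector of author residue identifiers. Usually
#'   integers; PDB insertion codes are carried as suffixed strings (e.g.
#'   `"100A"`). Must be unique, and strictly increasing when all-numeric.
#' @param coords numeric N x 3 matrix of coordinates in Angstrom.
#' @param chain_id single-character chain identifier.
#' @param source free-text provenance string.
#' @return object of class `calpha_chain` with fields `residue_ids` (character),
#'   `coords`, `chain_id`, `source`.
#' @export
calpha_chain <- function(residue_ids, coords, chain_id = "A", source = "") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  n <- nrow(coords)
  if (n < 3L) stop("degenerate chain: fewer than 3 residues")
  if (length(residue_ids) != n) stop("one residue id per coordinate required")
  ids <- as.character(residue_ids)
  if (anyDuplicated(ids)) stop("duplicated residue ids")
  num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num) && any(diff(num) <= 0)) {
    stop("residue ids must be strictly increasing")
  }
  if (anyNA(coords) || any(!is.finite(coords))) stop("non-finite coordinates")
  structure(
    list(residue_ids = ids, coords = coords,
         chain_id = as.character(chain_id)[1L], source = source),
    class = "calpha_chain"
  )
}

#' @export
print.calpha_chain <- function(x, ...) {
  cat(sprintf("C-alpha chain %s: %d residues (%s..%s)\n", x$chain_id,
              n_residues(x), x$residue_ids[1L],
              x$residue_ids[n_residues(x)]))
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  invisible(x)
}

#' Number of residues in a chain
#' @param chain a `calpha_chain`.
#' @return integer residue count.
#' @export
n_residues <- function(chain) nrow(chain$coords)

# author residue ids -> internal 1-based indices; errors on any miss
chain_index <- function(chain, ids) {
  idx <- match(as.character(ids), chain$residue_ids)
  if (anyNA(idx)) {
    stop("residue not in chain: ", paste(ids[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Define a functional (e.g. catalytic) site set
#'
#' @param residue_ids author residue ids of the functionally critical residues.
#' @param label free-text label, e.g. `"catalytic"`.
#' @return object of class `functional_sites`.
#' @export
functional_sites <- function(residue_ids, label = "catalytic") {
  ids <- unique(as.character(residue_ids))
  if (length(ids) == 0L) stop("empty functional site set")
  structure(list(residue_ids = ids, label = label), class = "functional_sites")
}

as_site_ids <- function(sites) {
  if (inherits(sites, "functional_sites")) sites$residue_ids
  else as.character(sites)
}

#' Read a C-alpha chain from a PDB file
#'
#' Extracts one C-alpha coordinate per residue from the requested chain and
#' model. Alternate locations are resolved to the highest-occupancy record;
#' residues that lack a C-alpha atom are skipped with a warning. Insertion
#' codes are appended to the author residue number.
#'
#' @param pdb_source path to a PDB file.
#' @param chain_id chain identifier to extract (default `"A"`).
#' @param model_index 1-based model number for multi-model files.
#' @return a [calpha_chain()].
#' @export
read_calpha_chain <- function(pdb_source, chain_id = "A", model_index = 1L) {
  pdb <- suppressWarnings(bio3d::read.pdb(pdb_source, multi = TRUE,
                                          rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  n_models <- nrow(pdb$xyz)
  if (model_index < 1L || model_index > n_models) {
    stop("model not found: ", model_index, " (file has ", n_models, ")")
  }
  in_chain <- at$chain == chain_id & at$type == "ATOM"
  if (!any(in_chain, na.rm = TRUE)) stop("chain not found: ", chain_id)
  sub <- at[which(in_chain), , drop = FALSE]
  rid <- paste0(sub$resno, ifelse(is.na(sub$insert) | sub$insert == "", "",
                                  sub$insert))
  is_ca <- sub$elety == "CA"
  missing_ca <- setdiff(unique(rid), unique(rid[is_ca]))
  if (length(missing_ca) > 0L) {
    warning("skipping ", length(missing_ca),
            " residue(s) without a C-alpha atom: ",
            paste(missing_ca, collapse = ", "))
  }
  ca <- sub[is_ca, , drop = FALSE]
  ca_rid <- rid[is_ca]
  # alternate locations: keep highest occupancy per residue (ties: first seen)
  occ <- ca$o
  occ[is.na(occ)] <- 1
  keep <- vapply(split(seq_len(nrow(ca)), factor(ca_rid, levels = unique(ca_rid))),
                 function(rows) rows[which.max(occ[rows])], integer(1L))
  ca <- ca[keep, , drop = FALSE]
  ca_rid <- unique(ca_rid)
  if (length(ca_rid) < 3L) stop("degenerate chain: fewer than 3 C-alpha atoms")
  xyz_row <- pdb$xyz[model_index, , drop = TRUE]
  ca_xyz_idx <- as.integer(rownames(ca))  # row index into pdb$atom
  take <- as.vector(vapply(ca_xyz_idx, function(i) (3L * i - 2L):(3L * i),
                           integer(3L)))
  coords <- matrix(xyz_row[take], ncol = 3L, byrow = TRUE)
  calpha_chain(ca_rid, coords, chain_id = chain_id,
               source = if (is.character(pdb_source)) pdb_source else "stream")
}

#' Minimum distance from a site to a functional-site set
#'
#' C-alpha to C-alpha Euclidean distance, minimised over the target set.
#' Returns 0 when the site is itself a member of the target set.
#'
#' @param chain a `calpha_chain`.
#' @param site author residue id.
#' @param targets a [functional_sites()] or vector of residue ids.
#' @return distance in Angstrom.
#' @export
min_site_distance <- function(chain, site, targets) {
  si <- chain_index(chain, site)
  ti <- chain_index(chain, as_site_ids(targets))
  d2 <- colSums((t(chain$coords[ti, , drop = FALSE]) - chain$coords[si, ])^2)
  sqrt(min(d2))
}

#' Fraction of sites farther than a cutoff from the functional set
#'
#' The fraction of `sites` whose minimum C-alpha distance to the target set
#' strictly exceeds `cutoff`. Used to quantify how many variant positions are
#' too distant from the active site for direct interaction.
#'
#' @inheritParams min_site_distance
#' @param sites vector of author residue ids.
#' @param cutoff distance cutoff in Angstrom (default 10).
#' @return fraction in `[0, 1]`.
#' @export
fraction_distal <- function(chain, sites, targets, cutoff = 10) {
  sites <- as_site_ids(sites)
  if (length(sites) == 0L) stop("empty site list")
  d <- vapply(sites, function(s) min_site_distance(chain, s, targets),
              numeric(1L))
  mean(d > cutoff)
}

#' Residues within a radius of a site
#'
#' All residues (the query site included) whose C-alpha lies within `radius`
#' of the query site's C-alpha.
#'
#' @inheritParams min_site_distance
#' @param radius radius in Angstrom.
#' @return character vector of author residue ids.
#' @export
neighborhood <- function(chain, site, radius) {
  si <- chain_index(chain, site)
  d2 <- colSums((t(chain$coords) - chain$coords[si, ])^2)
  chain$residue_ids[d2 <= radius^2]
}

#' Read a residue-site CSV
#'
#' Expects a column `residue_id` and optionally `label`.
#'
#' @param path CSV path.
#' @return data.frame with `residue_id` (character) and any further columns.
#' @export
read_sites_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"residue_id" %in% names(df)) {
    stop("sites CSV must have a 'residue_id' column")
  }
  df$residue_id <- as.character(df$residue_id)
  df
}

#' Write a per-site minimum-distance table
#'
#' @inheritParams fraction_distal
#' @param path output CSV path.
#' @return the table, invisibly.
#' @export
write_distance_csv <- function(chain, sites, targets, path) {
  sites <- as_site_ids(sites)
  tab <- data.frame(
    site = sites,
    min_distance_A = vapply(sites, function(s)
      min_site_distance(chain, s, targets), numeric(1L)),
    row.names = NULL
  )
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
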