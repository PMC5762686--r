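#' Pair of corresponding ligand poses (crystal reference vs docked)
#'
#' Atom correspondence is positional: row i of `reference` matches row i of
#' `docked`. Both poses live in the same (receptor) frame, so RMSD is
#' computed in place, without superposition.
#'
#' @param reference,docked numeric n x 3 matrices of heavy-atom coordinates
#'   in Angstrom.
#' @param ligand_id,structure_id optional identifiers.
#' @return A `pose_pair` list.
#' @export
pose_pair <- function(reference, docked, ligand_id = NA_character_,
                      structure_id = NA_character_) {
  reference <- as.matrix(reference); docked <- as.matrix(docked)
  if (ncol(reference) != 3 || ncol(docked) != 3) {
    stop("coordinates must be n x 3 matrices")
  }
  if (nrow(reference) != nrow(docked)) {
    stop("atom count mismatch: ", nrow(reference), " vs ", nrow(docked))
  }
  if (nrow(reference) < 1) stop("pose must contain at least one atom")
  if (any(!is.finite(reference)) || any(!is.finite(docked))) {
    stop("coordinates must be finite")
  }
  structure(list(reference = reference, docked = docked,
                 ligand_id = ligand_id, structure_id = structure_id),
            class = "pose_pair")
}

#' In-place heavy-atom RMSD between a docked pose and its crystal reference
#'
#' sqrt(mean over atoms of squared displacement). No superposition is
#' applied: docking reproduces the pose in the fixed receptor frame, so the
#' deviation itself is the quantity of interest.
#'
#' @param pair a [pose_pair()].
#' @return RMSD in Angstrom.
#' @examples
#' ref <- matrix(rnorm(15), 5, 3)
#' heavy_atom_rmsd(pose_pair(ref, ref + rep(c(1, 2, 2), each = 5))) # 3
#' @export
heavy_atom_rmsd <- function(pair) {
  if (!inherits(pair, "pose_pair")) stop("expected a pose_pair")
  d <- pair$docked - pair$reference
  sqrt(mean(rowSums(d^2)))
}

#' Judge pose-reproduction success
#'
#' A docked pose reproduces the crystal pose when its heavy-atom RMSD is
#' within the threshold (inclusive), 2 Angstrom by convention.
#'
#' @param rmsd non-negative RMSD in Angstrom.
#' @param threshold success cutoff in Angstrom (default 2.0).
#' @return Logical success flag (vectorised over `rmsd`).
#' @export
judge_success <- function(rmsd, threshold = 2.0) {
  if (any(rmsd < 0)) stop("rmsd must be non-negative")
  rmsd <= threshold
}

#' Pose-reproduction success rate of a set of redockings
#'
#' @param pairs list of [pose_pair()] objects, or a numeric vector of RMSDs.
#' @param threshold success cutoff in Angstrom (default 2.0).
#' @return Percentage of poses with RMSD <= threshold.
#' @export
success_rate <- function(pairs, threshold = 2.0) {
  if (is.numeric(pairs)) {
    rmsds <- pairs
  } else {
    if (!length(pairs)) stop("empty pose list")
    rmsds <- vapply(pairs, heavy_atom_rmsd, numeric(1))
  }
  if (!length(rmsds)) stop("empty pose list")
  100 * mean(judge_success(rmsds, threshold))
}

#' Distance time series for one intermolecular hydrogen bond
#'
#' @param times numeric vector, ns.
#' @param distances numeric vector of donor-acceptor heteroatom distances,
#'   Angstrom (positive).
#' @param pair_label label such as `"Asp-93 OD2"`.
#' @return A `distance_series` data frame.
#' @export
distance_series <- function(times, distances, pair_label = NA_character_) {
  if (length(times) != length(distances)) stop("times and distances must match")
  if (!length(times)) stop("empty distance series")
  if (any(distances <= 0)) stop("distances must be positive")
  out <- data.frame(time_ns = times, distance_A = distances)
  attr(out, "pair_label") <- pair_label
  class(out) <- c("distance_series", "data.frame")
  out
}

#' Hydrogen-bond occupancy from a distance trajectory
#'
#' Fraction of trajectory frames in which the donor-acceptor heteroatom
#' distance is within the cutoff (3.5 Angstrom default; distance-only
#' criterion, no angle term).
#'
#' @param series a [distance_series()] or numeric vector of distances (A).
#' @param cutoff heavy-atom distance cutoff in Angstrom.
#' @return Occupancy in percent (0-100).
#' @export
hbond_occupancy <- function(series, cutoff = 3.5) {
  d <- if (is.numeric(series)) series else series$distance_A
  if (!length(d)) stop("empty distance series")
  100 * mean(d <= cutoff)
}
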