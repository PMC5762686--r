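#' Fingerprint bitset
#'
#' Sparse representation of a hashed circular (Morgan-style) fingerprint:
#' the set of on-bit indices in a fixed-length bit space.
#'
#' @param molecule_id identifier.
#' @param on_bits integer vector of on-bit indices (0-based, deduplicated).
#' @param n_bits fingerprint length (default 2048).
#' @return A `fingerprint` list.
#' @export
fingerprint <- function(molecule_id, on_bits, n_bits = 2048) {
  on_bits <- sort(unique(as.integer(on_bits)))
  if (length(on_bits) && (min(on_bits) < 0 || max(on_bits) >= n_bits)) {
    stop("bit indices must lie in [0, n_bits)")
  }
  structure(list(molecule_id = as.character(molecule_id),
                 on_bits = on_bits, n_bits = as.integer(n_bits)),
            class = "fingerprint")
}

#' Tanimoto coefficient between two fingerprints
#'
#' Tc = |A intersect B| / |A union B| on the on-bit sets; 1 means an
#' identical substructure profile, 0 no shared substructures. Two empty
#' fingerprints give 0 by convention (an unparsable molecule should never
#' look maximally similar to another).
#'
#' @param a,b [fingerprint()] objects of equal length.
#' @return Tc in \[0, 1\].
#' @examples
#' tanimoto(fingerprint("x", c(1, 2, 3)), fingerprint("y", c(2, 3, 4))) # 0.5
#' @export
tanimoto <- function(a, b) {
  if (a$n_bits != b$n_bits) {
    stop("fingerprint length mismatch: ", a$n_bits, " vs ", b$n_bits)
  }
  ni <- length(intersect(a$on_bits, b$on_bits))
  nu <- length(a$on_bits) + length(b$on_bits) - ni
  if (nu == 0) return(0)
  ni / nu
}

#' Greedy diversity filter at a Tc ceiling
#'
#' First pass over the molecules in input order: a molecule is kept iff its
#' Tc to every already-kept molecule is strictly below `tc_max`, so all
#' retained pairs satisfy Tc < tc_max. Used to deduplicate an inhibitor set
#' (tc_max = 0.6) before benchmarking enrichment.
#'
#' @param fps list of [fingerprint()] objects.
#' @param tc_max pairwise Tc ceiling (default 0.6).
#' @return The retained sublist, in input order.
#' @export
diversity_filter <- function(fps, tc_max = 0.6) {
  if (!length(fps)) stop("fps must be non-empty")
  kept <- list()
  for (fp in fps) {
    ok <- all(vapply(kept, function(k) tanimoto(fp, k) < tc_max, logical(1)))
    if (ok) kept[[length(kept) + 1L]] <- fp
  }
  kept
}

#' Summed above-threshold Tanimoto similarity (chemical-novelty statistic)
#'
#' Similarity-ensemble-style statistic: the Tc of the query against every
#' reference inhibitor is computed, values at or below the threshold
#' (strictly greater than 0.3 counts, by default) are discarded as noise,
#' and the remainder summed to sigma-Tc. A query with a low sigma-Tc shares
#' little chemistry with the reference set; ranked against the references'
#' own sigma-Tc distribution this quantifies chemical novelty. The query is
#' excluded from the references by molecule_id (self-similarity of 1 would
#' otherwise put every known molecule at sigma-Tc >= 1).
#'
#' @param query a [fingerprint()].
#' @param refs list of reference [fingerprint()] objects.
#' @param threshold strict lower Tc cutoff (default 0.3).
#' @param ref_sum_tc optional numeric vector: the sigma-Tc distribution of
#'   the reference set itself, enabling rank and percentile.
#' @return A `novelty_profile` list: `query_id`, `sum_tc`, `n_contributing`,
#'   and (when `ref_sum_tc` is given) `rank` (1 = most similar, descending
#'   sigma-Tc) and `percentile` (share of references with smaller sigma-Tc).
#' @export
sum_tc <- function(query, refs, threshold = 0.3, ref_sum_tc = NULL) {
  ids <- vapply(refs, `[[`, character(1), "molecule_id")
  if (query$molecule_id %in% ids) {
    warning("query ", query$molecule_id, " found among references; excluded")
    refs <- refs[ids != query$molecule_id]
  }
  tcs <- vapply(refs, function(r) tanimoto(query, r), numeric(1))
  keep <- tcs > threshold
  out <- list(query_id = query$molecule_id,
              sum_tc = sum(tcs[keep]),
              n_contributing = sum(keep))
  if (!is.null(ref_sum_tc)) {
    out$rank <- sum(ref_sum_tc > out$sum_tc) + 1L
    out$percentile <- 100 * mean(ref_sum_tc < out$sum_tc)
  }
  structure(out, class = "novelty_profile")
}

#' Ligand efficiency
#'
#' Binding free energy per heavy atom at 298 K, in kcal/mol:
#' `LE = -1.37 log10(Kd) / HA` (-1.37 = 2.303 RT in kcal/mol).
#'
#' @param Kd dissociation constant in molar units (> 0). Vectorised.
#' @param HA heavy-atom (non-hydrogen) count (>= 1).
#' @return LE in kcal/mol per heavy atom.
#' @examples
#' ligand_efficiency(1e-6, 10) # 0.822
#' @export
ligand_efficiency <- function(Kd, HA) {
  if (any(Kd <= 0)) stop("Kd must be positive (molar)")
  if (any(HA < 1)) stop("HA must be at least 1")
  -1.37 * log10(Kd) / HA
}

#' Curate a compound table by the Lipinski rule of five
#'
#' Retains compounds with MW <= 500, logP <= 5, hydrogen-bond donors <= 5
#' and acceptors <= 10 (boundaries inclusive). Rows with missing properties
#' are skipped with a warning.
#'
#' @param props data frame with columns `molecule_id`, `MW`, `logP`, `HBD`,
#'   `HBA`.
#' @return The retained subset of `props`.
#' @export
lipinski_filter <- function(props) {
  req <- c("molecule_id", "MW", "logP", "HBD", "HBA")
  miss <- setdiff(req, names(props))
  if (length(miss)) stop("props missing column(s): ", paste(miss, collapse = ", "))
  incomplete <- !stats::complete.cases(props[, c("MW", "logP", "HBD", "HBA")])
  if (any(incomplete)) {
    warning("skipping ", sum(incomplete), " compound(s) with missing properties: ",
            paste(props$molecule_id[incomplete], collapse = ", "))
    props <- props[!incomplete, , drop = FALSE]
  }
  keep <- props$MW <= 500 & props$logP <= 5 & props$HBD <= 5 & props$HBA <= 10
  out <- props[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
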