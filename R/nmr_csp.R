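#' Combined amide chemical-shift perturbation
#'
#' Weighted combination of the 1H and 15N shift changes of a backbone amide
#' peak between apo and ligand-bound spectra:
#' \deqn{\Delta CS = \sqrt{0.5 (\Delta H^2 + (0.2 \Delta N)^2)}}
#' The 0.2 factor rescales the wider 15N dispersion onto the 1H scale.
#'
#' @param dH 1H shift difference (holo - apo), ppm. Vectorised.
#' @param dN 15N shift difference (holo - apo), ppm.
#' @return Combined perturbation in ppm (non-negative, sign-symmetric).
#' @examples
#' delta_cs(0.1, 0.5) # 0.1
#' @export
delta_cs <- function(dH, dN) {
  if (any(!is.finite(dH)) || any(!is.finite(dN))) stop("shift differences must be finite")
  sqrt(0.5 * (dH^2 + (0.2 * dN)^2))
}

#' Per-state peak table constructor
#'
#' @param residue_id integer residue numbers.
#' @param residue_name residue names (e.g. `"GLY"`); optional.
#' @param H_ppm,N_ppm 1H and 15N shifts in ppm (NA when the peak is absent).
#' @param present logical; defaults to shifts being non-NA.
#' @return A `peak_table` data frame.
#' @export
peak_table <- function(residue_id, H_ppm, N_ppm,
                       residue_name = NA_character_, present = NULL) {
  residue_id <- as.integer(residue_id)
  if (anyDuplicated(residue_id)) stop("duplicate residue_id in peak table")
  if (is.null(present)) present <- !(is.na(H_ppm) | is.na(N_ppm))
  if (any(present & (!is.finite(H_ppm) | !is.finite(N_ppm)))) {
    stop("present peaks must have finite shifts")
  }
  out <- data.frame(residue_id = residue_id,
                    residue_name = rep_len(as.character(residue_name), length(residue_id)),
                    H_ppm = as.numeric(H_ppm), N_ppm = as.numeric(N_ppm),
                    present = as.logical(present), stringsAsFactors = FALSE)
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Build a chemical-shift-perturbation table from apo and holo peak lists
#'
#' Residues are matched by `residue_id`. A residue whose peak is present in
#' the apo spectrum but absent in the holo spectrum is flagged `disappeared`
#' (typically broadened beyond detection by intermediate exchange). A holo
#' residue with no apo counterpart is an error: perturbations are defined
#' relative to the apo assignment.
#'
#' @param apo,holo [peak_table()] objects (plain data frames with the same
#'   columns are accepted).
#' @return A `csp_table` data frame: `residue_id`, `residue_name`, `dH`,
#'   `dN`, `dCS` (ppm), `disappeared`, and a `class` column initialised to
#'   NA until [classify_residues()] is applied.
#' @export
build_csp_table <- function(apo, holo) {
  for (nm in c("residue_id", "H_ppm", "N_ppm", "present")) {
    if (!nm %in% names(apo) || !nm %in% names(holo)) {
      stop("peak tables must have column ", nm)
    }
  }
  extra <- setdiff(holo$residue_id[holo$present], apo$residue_id[apo$present])
  if (length(extra)) {
    stop("holo residue(s) absent from apo table: ", paste(extra, collapse = ", "))
  }
  apo_p <- apo[apo$present, , drop = FALSE]
  m <- match(apo_p$residue_id, holo$residue_id)
  holo_present <- !is.na(m) & holo$present[m]
  dH <- ifelse(holo_present, holo$H_ppm[m] - apo_p$H_ppm, NA_real_)
  dN <- ifelse(holo_present, holo$N_ppm[m] - apo_p$N_ppm, NA_real_)
  out <- data.frame(
    residue_id = apo_p$residue_id,
    residue_name = if ("residue_name" %in% names(apo_p)) apo_p$residue_name else NA_character_,
    dH = dH, dN = dN,
    dCS = ifelse(holo_present, delta_cs(ifelse(holo_present, dH, 0),
                                        ifelse(holo_present, dN, 0)), NA_real_),
    disappeared = !holo_present,
    class = NA_character_,
    stringsAsFactors = FALSE
  )
  class(out) <- c("csp_table", "data.frame")
  out
}

#' Classify residues by perturbation magnitude
#'
#' The mean and standard deviation of dCS are computed over residues with
#' dCS > 0 only, and each residue is assigned one of four classes:
#' (i) dCS <= mean + SD, (ii) mean + SD < dCS <= mean + 2 SD,
#' (iii) dCS > mean + 2 SD, (iv) peak disappeared. Boundary values fall in
#' the lower class; disappeared residues are class iv regardless of dCS.
#'
#' @param table a `csp_table` from [build_csp_table()].
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return The table with `class` filled in, plus attributes `csp_mean`,
#'   `csp_sd` (both over positive-dCS residues).
#' @export
classify_residues <- function(table, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (!all(c("dCS", "disappeared") %in% names(table))) {
    stop("expected a csp_table from build_csp_table()")
  }
  pos <- table$dCS[!table$disappeared & !is.na(table$dCS) & table$dCS > 0]
  if (length(pos) < 2) {
    stop("classification refused: need at least 2 residues with dCS > 0 ",
         "to estimate the mean and SD (found ", length(pos), ")")
  }
  mu <- mean(pos)
  sdv <- stats::sd(pos)
  if (sd_type == "population") sdv <- sdv * sqrt((length(pos) - 1) / length(pos))
  cls <- ifelse(table$disappeared, "iv",
         ifelse(table$dCS > mu + 2 * sdv, "iii",
         ifelse(table$dCS > mu + sdv, "ii", "i")))
  table$class <- cls
  attr(table, "csp_mean") <- mu
  attr(table, "csp_sd") <- sdv
  table
}

#' Plan 1:1 compound mixtures for NMR screening
#'
#' Screening throughput doubles by recording each HSQC with k compounds
#' mixed (k = 2 in practice: 60 purchased candidates -> 30 data sets);
#' mixtures showing perturbations are deconvoluted with follow-up
#' single-compound spectra.
#'
#' @param compound_ids character vector, screened in the given order.
#' @param k compounds per mixture (default 2).
#' @return List of character vectors, ceiling(n/k) mixtures preserving order.
#' @export
plan_mixtures <- function(compound_ids, k = 2) {
  if (!length(compound_ids)) stop("compound_ids must be non-empty")
  if (k < 1) stop("k must be at least 1")
  split(compound_ids, ceiling(seq_along(compound_ids) / k))
}

#' Call a screening hit from a classified perturbation table
#'
#' A spectrum counts as a significant change - a hit - when any residue
#' shows a strong perturbation (class iii) or a disappeared peak (class iv).
#'
#' @param table a classified `csp_table` ([classify_residues()]).
#' @return Logical hit flag.
#' @export
call_hit <- function(table) {
  if (!"class" %in% names(table) || any(is.na(table$class))) {
    stop("table must be classified with classify_residues() first")
  }
  any(table$class %in% c("iii", "iv"))
}
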