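#' Read a docking-score CSV into scored libraries
#'
#' Expected header: `compound_id,score,label,structure_id,algorithm_id`
#' (label `active`/`decoy`, case-insensitive). Rows are grouped by
#' (structure_id, algorithm_id) into one [scored_library()] per group.
#'
#' @param path CSV file path.
#' @return Named list of [scored_library()] objects
#'   (`"<structure_id>/<algorithm_id>"`).
#' @export
read_score_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("compound_id", "score", "label", "structure_id", "algorithm_id")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("score CSV missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(df$score)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$score))))[1]
    stop("non-numeric score at data line ", bad, " of ", path)
  }
  groups <- split(df, paste(df$structure_id, df$algorithm_id, sep = "/"))
  lapply(groups, function(g) {
    scored_library(g$compound_id, g$score, g$label,
                   structure_id = g$structure_id[1],
                   algorithm_id = g$algorithm_id[1])
  })
}

#' Write scored libraries to CSV
#'
#' Inverse of [read_score_csv()].
#'
#' @param libs a [scored_library()] or list of them.
#' @param path output CSV path.
#' @export
write_score_csv <- function(libs, path) {
  if (inherits(libs, "scored_library")) libs <- list(libs)
  rows <- do.call(rbind, lapply(libs, function(lib) {
    data.frame(compound_id = lib$compound_id, score = lib$score,
               label = lib$label,
               structure_id = attr(lib, "structure_id"),
               algorithm_id = attr(lib, "algorithm_id"),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read ligand heavy-atom coordinates from a PDB file
#'
#' Reads ATOM/HETATM records via bio3d, drops hydrogens (element H) and
#' keeps only the first alternate location of any duplicated atom. Atom
#' (file) order defines the pose correspondence.
#'
#' @param path PDB file path.
#' @return n x 3 numeric matrix of coordinates (Angstrom), with atom names
#'   as rownames.
#' @export
read_ligand_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  elem <- trimws(at$elesy)
  elem[!nzchar(elem)] <- substr(trimws(at$elety[!nzchar(elem)]), 1, 1)
  at <- at[toupper(elem) != "H", , drop = FALSE]
  if (!nrow(at)) stop("no heavy atoms in ", path)
  key <- paste(at$chain, at$resno, at$elety)
  at <- at[!duplicated(key), , drop = FALSE]  # first altloc wins
  m <- as.matrix(at[, c("x", "y", "z")])
  rownames(m) <- trimws(at$elety)
  if (any(!is.finite(m))) stop("unreadable coordinates in ", path)
  m
}

#' Read a per-state peak CSV
#'
#' Header: `residue_id,residue_name,H_ppm,N_ppm,present`.
#'
#' @param path CSV file path.
#' @return A [peak_table()].
#' @export
read_peak_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("residue_id", "H_ppm", "N_ppm")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("peak CSV missing column(s): ", paste(miss, collapse = ", "))
  peak_table(df$residue_id, df$H_ppm, df$N_ppm,
             residue_name = if ("residue_name" %in% names(df)) df$residue_name else NA,
             present = if ("present" %in% names(df)) as.logical(df$present) else NULL)
}

#' Write a chemical-shift-perturbation table to CSV
#' @param table a `csp_table`.
#' @param path output path.
#' @export
write_csp_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a titration CSV into a titration series
#'
#' Header: `residue_id,ratio,frequency_hz,intensity`.
#'
#' @param path CSV file path.
#' @param Pt total protein concentration, uM.
#' @return A `titration_series` (without a truth block).
#' @export
read_titration_csv <- function(path, Pt) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("residue_id", "ratio", "frequency_hz", "intensity")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("titration CSV missing column(s): ", paste(miss, collapse = ", "))
  structure(list(traces = df, Pt = Pt, ratios = sort(unique(df$ratio)),
                 truth = NULL),
            class = "titration_series")
}

#' Write a titration series to CSV
#' @param series a `titration_series`.
#' @param path output path.
#' @export
write_titration_csv <- function(series, path) {
  utils::write.csv(series$traces, path, row.names = FALSE)
  invisible(path)
}

#' Read melt curves from CSV
#'
#' Header: `temperature_C,rfu,sample`; one curve per sample value.
#'
#' @param path CSV file path.
#' @return Named list of [melt_curve()] objects.
#' @export
read_melt_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("temperature_C", "rfu", "sample")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("melt CSV missing column(s): ", paste(miss, collapse = ", "))
  lapply(split(df, df$sample), function(g) {
    g <- g[order(g$temperature_C), ]
    melt_curve(g$temperature_C, g$rfu, sample = g$sample[1])
  })
}

#' Write melt curves to CSV
#' @param curves a [melt_curve()] or list of them.
#' @param path output path.
#' @export
write_melt_csv <- function(curves, path) {
  if (inherits(curves, "melt_curve")) curves <- list(curves)
  rows <- do.call(rbind, lapply(curves, function(cu) {
    data.frame(temperature_C = cu$temperature_C, rfu = cu$rfu,
               sample = attr(cu, "sample"), stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
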