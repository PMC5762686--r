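#' Labelled score list for one receptor structure / docking algorithm
#'
#' Container for the ranked output of a single virtual screen: one score per
#' compound plus an active/decoy label. Scores follow the docking convention
#' that lower is better (e.g. Glide-SP grid scores), so enrichment metrics
#' rank ascending.
#'
#' @param compound_id character vector of unique compound identifiers.
#' @param score numeric vector of docking scores (finite; lower = better).
#' @param label character vector, each element `"active"` or `"decoy"`
#'   (case-insensitive).
#' @param structure_id,algorithm_id optional context strings identifying the
#'   receptor structure and docking algorithm that produced the scores.
#' @return A `scored_library`: a data frame with columns `compound_id`,
#'   `score`, `label` and attributes `structure_id`, `algorithm_id`.
#' @examples
#' lib <- scored_library(c("a1", "d1"), c(-8.2, -5.1), c("active", "decoy"))
#' @export
scored_library <- function(compound_id, score, label,
                           structure_id = NA_character_,
                           algorithm_id = NA_character_) {
  compound_id <- as.character(compound_id)
  score <- as.numeric(score)
  label <- tolower(as.character(label))
  n <- length(compound_id)
  if (length(score) != n || length(label) != n) {
    stop("compound_id, score and label must have equal length")
  }
  if (n == 0) stop("scored_library must contain at least one compound")
  if (anyDuplicated(compound_id)) {
    dup <- compound_id[duplicated(compound_id)][1L]
    stop("duplicate compound_id in library: ", dup)
  }
  if (any(!is.finite(score))) stop("all scores must be finite")
  bad <- setdiff(unique(label), c("active", "decoy"))
  if (length(bad)) stop("unknown label value(s): ", paste(bad, collapse = ", "))
  out <- data.frame(compound_id = compound_id, score = score, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "structure_id") <- as.character(structure_id)
  attr(out, "algorithm_id") <- as.character(algorithm_id)
  class(out) <- c("scored_library", "data.frame")
  out
}

#' Build a ROC curve from a labelled score list
#'
#' Compounds are ranked by ascending score (lower = better). Walking down the
#' ranked list, each active moves the curve up by 1/n_actives and each decoy
#' moves it right by 1/n_decoys. Tied scores are traversed as one diagonal
#' block so the curve is independent of the input order of tied compounds.
#'
#' @param lib a [scored_library()] with at least one active and one decoy.
#' @return A `roc_curve`: data frame of vertices `fpr`, `tpr`, starting at
#'   (0,0) and ending at (1,1), both coordinates non-decreasing.
#' @examples
#' lib <- scored_library(paste0("c", 1:4), c(1, 2, 3, 4),
#'                       c("active", "decoy", "active", "decoy"))
#' build_roc(lib)
#' @export
build_roc <- function(lib) {
  if (!inherits(lib, "scored_library")) {
    lib <- scored_library(lib$compound_id, lib$score, lib$label)
  }
  n_act <- sum(lib$label == "active")
  n_dec <- sum(lib$label == "decoy")
  if (n_act < 1 || n_dec < 1) {
    stop("ROC construction needs at least one active and one decoy")
  }
  ord <- order(lib$score)
  sc <- lib$score[ord]
  act <- lib$label[ord] == "active"
  # one vertex after each block of tied scores
  block_end <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- cumsum(act)[block_end] / n_act
  fp <- cumsum(!act)[block_end] / n_dec
  out <- data.frame(fpr = c(0, fp), tpr = c(0, tp))
  class(out) <- c("roc_curve", "data.frame")
  out
}

as_roc <- function(roc) {
  if (!is.data.frame(roc) || !all(c("fpr", "tpr") %in% names(roc))) {
    stop("expected a roc_curve with columns fpr and tpr")
  }
  if (nrow(roc) < 2 || any(diff(roc$fpr) < 0) || any(diff(roc$tpr) < 0)) {
    stop("roc vertices must be non-decreasing in both coordinates")
  }
  roc
}

#' Area under the ROC curve, as a percentage
#'
#' Trapezoidal integration of TPR against FPR, scaled to 0-100. With the
#' diagonal tie-block convention of [build_roc()] this equals the
#' pair-counting (concordance) probability with ties counted one half.
#'
#' @param roc a `roc_curve` from [build_roc()].
#' @return AUC in percent (0-100).
#' @export
auc <- function(roc) {
  roc <- as_roc(roc)
  x <- roc$fpr; y <- roc$tpr
  100 * sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Log-scaled AUC emphasising early enrichment, as a percentage
#'
#' The FPR axis is log10-scaled over \[`lambda`, 1\] (default 0.001, spanning
#' -3..0 for a total available area of 3). TPR is integrated against
#' log10(FPR) using the previous-vertex staircase (the ROC of a ranked list
#' is a step function), FPR values below `lambda` being clamped to `lambda`.
#' The raw area is normalised by log10(1/lambda) and chance-corrected by
#' subtracting 0.145, the normalised area of the random-classifier diagonal,
#' so a perfect classifier scores 85.5 and a fully inverted one -14.5.
#'
#' @param roc a `roc_curve` from [build_roc()].
#' @param lambda lower FPR bound of the log window (0 < lambda < 1).
#' @return LogAUC in percent, in \[-14.5, 85.5\].
#' @export
logauc <- function(roc, lambda = 0.001) {
  roc <- as_roc(roc)
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0 || lambda >= 1) {
    stop("lambda must be a single number in (0, 1)")
  }
  x <- pmax(roc$fpr, lambda)
  y <- roc$tpr
  lx <- log10(x)
  raw <- sum(utils::head(y, -1) * diff(lx))
  100 * (raw / log10(1 / lambda) - 0.145)
}

#' Enrichment factor at a false-positive level
#'
#' Ratio of the true-positive rate to the false-positive rate at
#' `FPR = level`, with TPR read from the ROC staircase (previous-vertex
#' convention). An EF1 (level 0.01) of 10 means 10% of the actives score
#' better than the compound found at 1% of the decoys.
#'
#' @param roc a `roc_curve` from [build_roc()].
#' @param level false-positive fraction at which to evaluate (0 < level <= 1).
#' @return Enrichment factor (dimensionless; 1 = random).
#' @export
ef <- function(roc, level = 0.01) {
  roc <- as_roc(roc)
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level > 1) {
    stop("level must be a single number in (0, 1]")
  }
  idx <- which(roc$fpr <= level)
  tpr_at <- roc$tpr[max(idx)]
  tpr_at / level
}

#' All enrichment metrics for one screen
#'
#' @param lib a [scored_library()].
#' @param lambda lower FPR bound for [logauc()].
#' @param ef_level FPR level for [ef()].
#' @return One-row data frame: `structure_id`, `algorithm_id`, `auc`,
#'   `logauc`, `ef1` (percent, percent, ratio).
#' @export
enrichment_metrics <- function(lib, lambda = 0.001, ef_level = 0.01) {
  roc <- build_roc(lib)
  data.frame(
    structure_id = attr(lib, "structure_id") %||% NA_character_,
    algorithm_id = attr(lib, "algorithm_id") %||% NA_character_,
    auc = auc(roc),
    logauc = logauc(roc, lambda),
    ef1 = ef(roc, ef_level),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank ensemble members for screening-template selection
#'
#' Orders receptor structures (or structure x algorithm pairs) for use as
#' virtual-screening templates: primarily by descending LogAUC, but any
#' structure whose pose-reproduction success rate falls below the ensemble
#' median is demoted below all others (faithful pose reproduction is a
#' prerequisite for trusting the scores). Ties break by EF1, then AUC, then
#' structure_id.
#'
#' @param metric_table data frame with columns `structure_id`,
#'   `pose_success_pct`, `auc`, `logauc`, `ef1`.
#' @return The same data frame, reordered, with a logical column `demoted`.
#' @export
rank_ensemble <- function(metric_table) {
  req <- c("structure_id", "pose_success_pct", "auc", "logauc", "ef1")
  if (!is.data.frame(metric_table) || nrow(metric_table) < 1) {
    stop("metric_table must be a non-empty data frame")
  }
  miss <- setdiff(req, names(metric_table))
  if (length(miss)) stop("metric_table missing column(s): ", paste(miss, collapse = ", "))
  med <- stats::median(metric_table$pose_success_pct)
  metric_table$demoted <- metric_table$pose_success_pct < med
  ord <- order(metric_table$demoted, -metric_table$logauc, -metric_table$ef1,
               -metric_table$auc, metric_table$structure_id)
  out <- metric_table[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select top-scoring candidates across several screens
#'
#' Takes the union of the `n_per` best-scoring (lowest-score) compounds from
#' each library; a compound appearing in several top lists is counted once.
#'
#' @param libs list of [scored_library()] objects.
#' @param n_per number of top compounds per library (default 30).
#' @return Character vector of unique compound ids.
#' @export
select_top_candidates <- function(libs, n_per = 30) {
  if (inherits(libs, "scored_library")) libs <- list(libs)
  if (!length(libs)) stop("libs must contain at least one library")
  if (n_per < 1) stop("n_per must be at least 1")
  picks <- lapply(libs, function(lib) {
    if (n_per > nrow(lib)) {
      warning("n_per exceeds library size (", nrow(lib), "); taking all compounds")
    }
    lib$compound_id[order(lib$score)][seq_len(min(n_per, nrow(lib)))]
  })
  unique(unlist(picks))
}
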