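#' Run the full synthetic validation pipeline
#'
#' Config-driven driver tying the stages together in dependency order:
#' `simulate` (synthetic inputs) -> `enrich` / `pose_eval` -> `csp` ->
#' `kd_fit` -> `dsf` -> `chem`. Each stage writes its table under
#' `out_dir`, and a JSON run manifest (config echo, input checksums,
#' package version, per-stage output paths, timestamp) is written once at
#' the end. Re-running with the same config reproduces every output.
#'
#' @param config named list (or path to a JSON file) with elements:
#'   `out_dir` (required), `seed` (default 1), `stages` (character subset
#'   of the six stage names; default all), and optional per-stage parameter
#'   lists `enrich` (`lambda`, `ef_level`), `pose_eval` (`threshold`),
#'   `csp` (`sd_type`), `kd_fit` (`Kd`, `koff`, `Pt`), `dsf`
#'   (`delta_tms`), `chem` (`threshold`, `tc_max`). Unknown keys are
#'   rejected.
#' @return A `run_manifest` list (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  known <- c("out_dir", "seed", "stages", "enrich", "pose_eval", "csp",
             "kd_fit", "dsf", "chem")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  all_stages <- c("simulate", "enrich", "pose_eval", "csp", "kd_fit", "dsf", "chem")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  need_sim <- setdiff(stages, "simulate")
  if (length(need_sim) && !"simulate" %in% stages) {
    stop("stage(s) ", paste(need_sim, collapse = ", "),
         " need the simulate stage for their inputs")
  }
  seed <- config$seed %||% 1
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- list()
  pth <- function(f) file.path(config$out_dir, f)

  if ("simulate" %in% stages) {
    lib <- gen_screen_scores(seed = seed)
    outputs$scores <- write_score_csv(lib, pth("scores.csv"))
  }
  if ("enrich" %in% stages) {
    p <- config$enrich %||% list()
    libs <- read_score_csv(outputs$scores)
    met <- do.call(rbind, lapply(libs, enrichment_metrics,
                                 lambda = p$lambda %||% 0.001,
                                 ef_level = p$ef_level %||% 0.01))
    utils::write.csv(met, pth("enrichment_metrics.csv"), row.names = FALSE)
    outputs$enrichment_metrics <- pth("enrichment_metrics.csv")
    roc <- build_roc(libs[[1]])
    utils::write.csv(as.data.frame(roc), pth("roc.csv"), row.names = FALSE)
    outputs$roc <- pth("roc.csv")
  }
  if ("pose_eval" %in% stages) {
    p <- config$pose_eval %||% list()
    rmsds <- vapply(seq_len(20), function(i) {
      heavy_atom_rmsd(gen_pose_pair(24, target_rmsd = (i %% 5), seed = seed + i))
    }, numeric(1))
    df <- data.frame(pose = seq_along(rmsds), rmsd_A = rmsds,
                     success = judge_success(rmsds, p$threshold %||% 2))
    utils::write.csv(df, pth("pose_eval.csv"), row.names = FALSE)
    outputs$pose_eval <- pth("pose_eval.csv")
  }
  if ("csp" %in% stages) {
    p <- config$csp %||% list()
    ids <- 1:20
    apo <- peak_table(ids, H_ppm = 8 + ids / 100, N_ppm = 115 + ids / 10)
    hH <- apo$H_ppm; hN <- apo$N_ppm
    hH[5] <- hH[5] + 0.2; hN[5] <- hN[5] + 1.0   # one strong perturbation
    hH[-5] <- hH[-5] + 0.01
    holo <- peak_table(ids, H_ppm = hH, N_ppm = hN)
    tab <- classify_residues(build_csp_table(apo, holo),
                             sd_type = p$sd_type %||% "sample")
    outputs$csp <- write_csp_csv(tab, pth("csp.csv"))
  }
  if ("kd_fit" %in% stages) {
    p <- config$kd_fit %||% list()
    ser <- gen_titration(Kd = p$Kd %||% 5, koff = p$koff %||% 50,
                         Pt = p$Pt %||% 100, seed = seed)
    write_titration_csv(ser, pth("titration.csv"))
    fit <- fit_kd(ser)
    jsonlite::write_json(
      list(kd_uM = fit$kd, koff_s = fit$koff, residual = fit$residual,
           converged = fit$converged, residues = fit$residues),
      pth("kd_fit.json"), auto_unbox = TRUE, digits = NA)
    outputs$titration <- pth("titration.csv")
    outputs$kd_fit <- pth("kd_fit.json")
  }
  if ("dsf" %in% stages) {
    p <- config$dsf %||% list()
    dts <- p$delta_tms %||% c(7.3, 8.9, 3.5, 6.5, 11.3)
    curves <- c(list(gen_melt(Tm = 44.4, seed = seed, sample = "apo")),
                lapply(seq_along(dts), function(i) {
                  gen_melt(Tm = 44.4 + dts[i], seed = seed + i,
                           sample = sprintf("cmpd%d", i))
                }))
    write_melt_csv(curves, pth("melt.csv"))
    res <- lapply(curves, tm_from_derivative)
    df <- data.frame(
      sample = vapply(res, `[[`, character(1), "sample"),
      Tm_C = vapply(res, `[[`, numeric(1), "tm"))
    df$dTm_C <- df$Tm_C - df$Tm_C[df$sample == "apo"]
    utils::write.csv(df, pth("dsf.csv"), row.names = FALSE)
    outputs$melt <- pth("melt.csv")
    outputs$dsf <- pth("dsf.csv")
  }
  if ("chem" %in% stages) {
    p <- config$chem %||% list()
    fs <- gen_fingerprints(12, overlap_profile = data.frame(
      i = c(1, 3), j = c(2, 4), tc = c(0.5, 1)), seed = seed)
    fps <- fs$fingerprints
    ref_sums <- vapply(seq_along(fps), function(i) {
      sum_tc(fps[[i]], fps[-i], threshold = p$threshold %||% 0.3)$sum_tc
    }, numeric(1))
    df <- data.frame(
      molecule_id = vapply(fps, `[[`, character(1), "molecule_id"),
      sum_tc = ref_sums)
    utils::write.csv(df, pth("sum_tc.csv"), row.names = FALSE)
    outputs$sum_tc <- pth("sum_tc.csv")
  }

  manifest <- list(
    config = config,
    package_version = as.character(utils::packageVersion("screenval")),
    outputs = outputs,
    checksums = as.list(tools::md5sum(unlist(outputs))),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  class(manifest) <- "run_manifest"
  invisible(manifest)
}
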