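#' Simulate a labelled virtual-screening score list
#'
#' Emulates the score table of one receptor structure x docking algorithm:
#' decoy scores are drawn from a unit-variance normal centred at 0 and
#' active scores from one centred at -separation (lower = better, matching
#' the docking convention). With separation d the population AUC of such a
#' two-Gaussian screen is Phi(d/sqrt(2)). The default library shape, 33
#' actives among 2370 property-matched decoys, mirrors a realistic
#' benchmark set for a single target.
#'
#' @param n_actives,n_decoys class sizes (>= 1).
#' @param separation shift d between the active and decoy score
#'   distributions (dimensionless; 0 = indistinguishable).
#' @param seed integer seed; the same spec and seed give identical output.
#' @param structure_id,algorithm_id context labels.
#' @return A [scored_library()] with attribute `separation`.
#' @export
gen_screen_scores <- function(n_actives = 33, n_decoys = 2370, separation = 1,
                              seed = 1, structure_id = "SIM-A",
                              algorithm_id = "sim") {
  if (n_actives < 1 || n_decoys < 1) stop("class sizes must be at least 1")
  scores <- with_rng(seed, c(stats::rnorm(n_actives, mean = -separation, sd = 1),
                             stats::rnorm(n_decoys, mean = 0, sd = 1)))
  lib <- scored_library(
    compound_id = c(sprintf("act%05d", seq_len(n_actives)),
                    sprintf("dec%05d", seq_len(n_decoys))),
    score = scores,
    label = rep(c("active", "decoy"), c(n_actives, n_decoys)),
    structure_id = structure_id, algorithm_id = algorithm_id)
  attr(lib, "separation") <- separation
  lib
}

# Seeded RNG scope: evaluates expr under the given seed and restores the
# caller's RNG stream afterwards, so generators never leak global state.
with_rng <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

#' Generate a reference/docked pose pair with an exact planted RMSD
#'
#' Reference heavy-atom coordinates are drawn uniformly in a 10 A box; the
#' docked copy adds a Gaussian displacement field rescaled so the in-place
#' RMSD equals `target_rmsd` exactly (to floating-point precision).
#'
#' @param n_atoms number of heavy atoms (>= 1).
#' @param target_rmsd planted RMSD in Angstrom (>= 0).
#' @param seed integer seed.
#' @return A [pose_pair()] with attribute `target_rmsd`.
#' @export
gen_pose_pair <- function(n_atoms, target_rmsd, seed = 1) {
  if (n_atoms < 1) stop("n_atoms must be at least 1")
  if (target_rmsd < 0) stop("target_rmsd must be non-negative")
  coords <- with_rng(seed, {
    ref <- matrix(stats::runif(3 * n_atoms, 0, 10), n_atoms, 3)
    if (target_rmsd == 0) {
      disp <- matrix(0, n_atoms, 3)
    } else {
      disp <- matrix(stats::rnorm(3 * n_atoms), n_atoms, 3)
      disp <- disp * target_rmsd * sqrt(n_atoms / sum(disp^2))
    }
    list(ref = ref, disp = disp)
  })
  pair <- pose_pair(coords$ref, coords$ref + coords$disp,
                    ligand_id = sprintf("sim%03d", seed))
  attr(pair, "target_rmsd") <- target_rmsd
  pair
}

#' Simulate a slow-exchange NMR titration with known ground truth
#'
#' For each ligand:protein ratio the bound fraction follows the 1:1 binding
#' quadratic at the planted Kd, and each residue's 1D trace is the two-site
#' exchange line shape of [simulate_lineshape()] at that bound fraction,
#' plus additive Gaussian noise. The noiseless output is bit-identical to
#' calling [simulate_lineshape()] with the same parameters, so [fit_kd()]
#' recovery against this generator is a genuine round trip through the
#' model.
#'
#' @param Kd planted dissociation constant, uM.
#' @param koff planted dissociation rate, s^-1.
#' @param Pt total protein concentration, uM (100 uM typical of HSQC work).
#' @param ratios ligand:protein ratios; must be non-negative and include 0.
#'   Default nine points from 0 to 2 (1:0 to 1:2).
#' @param residues data frame of per-residue `nu_apo`, `nu_holo` (Hz),
#'   `R2_apo`, `R2_holo` (s^-1); defaults to two well-separated residues.
#' @param noise_sd additive noise standard deviation as an absolute
#'   intensity (the noiseless apo peak height is 1/R2_apo).
#' @param n_grid points per frequency grid.
#' @param seed integer seed.
#' @return A `titration_series` list: `traces` (data frame `residue_id`,
#'   `ratio`, `frequency_hz`, `intensity`), `Pt`, `ratios`, and a `truth`
#'   block recording the planted parameters.
#' @export
gen_titration <- function(Kd = 5, koff = 50, Pt = 100,
                          ratios = seq(0, 2, length.out = 9),
                          residues = data.frame(
                            residue_id = c(93L, 184L),
                            nu_apo = c(0, 300), nu_holo = c(120, 180),
                            R2_apo = c(25, 30), R2_holo = c(30, 25)),
                          noise_sd = 0, n_grid = 512, seed = 1) {
  if (Kd <= 0 || koff <= 0) stop("Kd and koff must be positive")
  if (any(ratios < 0) || !any(ratios == 0)) {
    stop("ratios must be non-negative and include 0")
  }
  ratios <- sort(ratios)
  pb <- bound_fraction(Pt, ratios * Pt, Kd)
  traces <- with_rng(seed, do.call(rbind, lapply(seq_len(nrow(residues)), function(i) {
    r <- residues[i, ]
    prm <- exchange_params(r$nu_apo, r$nu_holo, r$R2_apo, r$R2_holo, koff)
    grid <- default_grid(r$nu_apo, r$nu_holo, n = n_grid)
    do.call(rbind, lapply(seq_along(ratios), function(j) {
      y <- simulate_lineshape(prm, pb[j], grid)
      if (noise_sd > 0) y <- y + stats::rnorm(length(y), sd = noise_sd)
      data.frame(residue_id = r$residue_id, ratio = ratios[j],
                 frequency_hz = grid, intensity = y)
    }))
  })))
  structure(list(traces = traces, Pt = Pt, ratios = ratios,
                 truth = list(Kd = Kd, koff = koff, residues = residues,
                              pb = pb, noise_sd = noise_sd)),
            class = "titration_series")
}

#' Simulate a DSF melt curve with a planted Tm
#'
#' Logistic unfolding transition between a low (folded) and high (unfolded)
#' fluorescence plateau, centred at `Tm` with width `slope`, on a uniform
#' temperature grid (30-90 C at 0.5 C steps by default, the usual RT-PCR
#' ramp), plus additive Gaussian noise. The derivative of the noiseless
#' curve peaks exactly at `Tm`. The post-transition aggregation decay of
#' real DSF dye signals is not modelled.
#'
#' @param Tm planted melting temperature, degrees C (inside the grid).
#' @param slope transition width parameter, degrees C.
#' @param baseline_low,baseline_high folded/unfolded plateau RFU values.
#' @param temperature temperature grid, degrees C (strictly increasing).
#' @param noise_sd additive noise SD in RFU (amplitude is
#'   `baseline_high - baseline_low`).
#' @param seed integer seed.
#' @param sample sample label.
#' @return A [melt_curve()] with attribute `truth` = planted parameters.
#' @export
gen_melt <- function(Tm = 44.4, slope = 1.5, baseline_low = 0.1,
                     baseline_high = 1.1, temperature = seq(30, 90, by = 0.5),
                     noise_sd = 0, seed = 1, sample = "apo") {
  if (any(diff(temperature) <= 0)) stop("temperature grid must be strictly increasing")
  if (Tm <= min(temperature) || Tm >= max(temperature)) {
    stop("Tm must lie inside the temperature grid")
  }
  rfu <- baseline_low + (baseline_high - baseline_low) *
    stats::plogis((temperature - Tm) / slope)
  if (noise_sd > 0) {
    rfu <- rfu + with_rng(seed, stats::rnorm(length(rfu), sd = noise_sd))
  }
  curve <- melt_curve(temperature, rfu, sample = sample)
  attr(curve, "truth") <- list(Tm = Tm, slope = slope,
                               baseline_low = baseline_low,
                               baseline_high = baseline_high,
                               noise_sd = noise_sd)
  curve
}

#' Generate fingerprint bitsets with planted pairwise Tanimoto overlaps
#'
#' Molecules draw `bits_on` bits each from disjoint regions of the bit
#' space, so unrelated pairs have Tc = 0; for each requested pair (i, j,
#' tc) the two members share k bits with k chosen so the achieved
#' Tc = k/(2 bits_on - k) is as close as possible to the request (exact
#' whenever 2 bits_on tc/(1+tc) is an integer, e.g. tc = 0.5 at the default
#' bits_on = 60). Each molecule may appear in at most one planted pair so
#' the construction stays exact. The achieved Tc matrix is recorded as
#' ground truth.
#'
#' @param n number of molecules (>= 1).
#' @param overlap_profile data frame with columns `i`, `j`, `tc` (requested
#'   Tanimoto for that pair), or NULL for all-disjoint sets.
#' @param bits_on bits set per molecule.
#' @param n_bits fingerprint length.
#' @param seed integer seed.
#' @return A `fingerprint_set` list: `fingerprints` (list of
#'   [fingerprint()]), `tc_truth` (n x n matrix of planted Tc).
#' @export
gen_fingerprints <- function(n, overlap_profile = NULL, bits_on = 60,
                             n_bits = 2048, seed = 1) {
  if (n < 1) stop("n must be at least 1")
  tc_truth <- diag(1, n)
  if (!is.null(overlap_profile)) {
    op <- overlap_profile
    if (!all(c("i", "j", "tc") %in% names(op))) {
      stop("overlap_profile needs columns i, j, tc")
    }
    if (any(op$tc < 0) || any(op$tc > 1)) stop("requested tc must lie in [0, 1]")
    if (anyDuplicated(c(op$i, op$j))) {
      stop("each molecule may appear in at most one planted pair")
    }
  } else {
    op <- data.frame(i = integer(0), j = integer(0), tc = numeric(0))
  }
  need <- n * bits_on  # upper bound on distinct bits consumed
  if (need > n_bits) {
    stop("infeasible: ", n, " molecules x ", bits_on,
         " bits exceed fingerprint length ", n_bits)
  }
  pool <- with_rng(seed, sample.int(n_bits, need)) - 1L  # shuffled disjoint bit supply
  nxt <- 1L
  take <- function(k) {
    out <- pool[nxt:(nxt + k - 1L)]
    nxt <<- nxt + k
    out
  }
  bits <- vector("list", n)
  for (r in seq_len(nrow(op))) {
    i <- op$i[r]; j <- op$j[r]; tc <- op$tc[r]
    k <- round(2 * bits_on * tc / (1 + tc))
    shared <- if (k > 0) take(k) else integer(0)
    bits[[i]] <- c(shared, if (bits_on > k) take(bits_on - k) else integer(0))
    bits[[j]] <- c(shared, if (bits_on > k) take(bits_on - k) else integer(0))
    tc_truth[i, j] <- tc_truth[j, i] <- k / (2 * bits_on - k)
  }
  for (i in seq_len(n)) {
    if (is.null(bits[[i]])) bits[[i]] <- take(bits_on)
  }
  fps <- lapply(seq_len(n), function(i) {
    fingerprint(sprintf("mol%04d", i), bits[[i]], n_bits = n_bits)
  })
  structure(list(fingerprints = fps, tc_truth = tc_truth),
            class = "fingerprint_set")
}
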