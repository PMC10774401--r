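#' Simulate a complete synthetic nCounter experiment with known ground truth
#'
#' Generates a probes-by-lanes count matrix emulating a multi-region,
#' two-phase, tumor-versus-vehicle nCounter study, together with the ground
#' truth needed to validate every downstream stage by parameter recovery.
#'
#' The generative model, per lane \eqn{j} and probe \eqn{g}:
#' \itemize{
#'   \item Endogenous and Housekeeping probes: counts ~ NB(mean =
#'     \eqn{2^{b_g} \cdot s_j \cdot e_{gj}}, variance = mu + dispersion * mu^2),
#'     where \eqn{b_g} ~ Uniform(baselineLog2Range), \eqn{s_j = 2^{N(0,
#'     laneScaleSd)}} is the lane technical scale factor, and \eqn{e_{gj} =
#'     2^{\pm effectSizeLog2}} for planted DEGs in tumor lanes of their
#'     designated phase(s) (1 otherwise). `dispersion = 0` selects the Poisson
#'     limit. Housekeeping probes never receive a condition effect.
#'   \item Positive spike-in probes: Poisson around `posGain` times the
#'     conventional 6-step 4-fold titration ladder (128, 32, 8, 2, 0.5, 0.125
#'     units), scaled by the lane factor. Spike-ins carry technical noise
#'     only.
#'   \item Nonspecific background: an independent Poisson(`backgroundMean`)
#'     count added to every probe, independent of the lane factor and of lane
#'     biology. Negative spike-in probes carry background alone, so the
#'     background-subtraction stage estimates from them exactly the additive
#'     component present on every other probe.
#' }
#'
#' Planted DEG sets are disjoint across all (phase x direction) categories.
#' "Shared" genes receive the same signed effect in both phases; dark-only /
#' light-only genes receive it in one phase. Effects apply in all regions.
#'
#' @param config a [simConfig()] object.
#' @param seed integer; overrides `config@seed`. Identical config + seed give
#'   bit-identical output.
#' @return a list with elements:
#'   \describe{
#'     \item{counts}{a [NanoCountSet-class] (`stageLog = "raw"`), with
#'       `colData` columns `condition`, `phase`, `region`, `replicate`.}
#'     \item{truth}{a `GroundTruth` list: `degSets` (per phase x direction
#'       gene-id sets, with `shared` listed separately), `laneFactors`,
#'       `baselineMeans` (linear-scale), and `expectedMeans` (the background-free biological NB mean
#'       matrix actually sampled from).}
#'   }
#' @examples
#' sim <- simulateExperiment(simConfig(nDegDarkOnly = 5L, seed = 42))
#' sim$counts
#' lengths(sim$truth$degSets)
#' @export
simulateExperiment <- function(config, seed = config@seed) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(as.integer(seed))

  nE <- config@nEndogenous; nH <- config@nHousekeeping
  nP <- config@nPosControls; nN <- config@nNegControls
  endo_ids <- sprintf("GENE_%04d", seq_len(nE))
  hk_ids   <- sprintf("HK_%02d", seq_len(nH))
  pos_ids  <- sprintf("POS_%s(%g)", LETTERS[seq_len(nP)],
                      posLadder(nP))
  neg_ids  <- sprintf("NEG_%02d", seq_len(nN))
  probe_ids <- c(endo_ids, hk_ids, pos_ids, neg_ids)
  pclass <- rep(PROBE_CLASSES[c(1, 4, 2, 3)], times = c(nE, nH, nP, nN))

  sheet <- expand.grid(replicate = seq_len(config@nPerGroup),
                       condition = CONDITIONS,
                       phase = config@phases,
                       region = config@regions,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sheet <- sheet[, c("condition", "phase", "region", "replicate")]
  lane_ids <- sprintf("%s_%s_%s_%d", sheet$region, sheet$phase,
                      sheet$condition, sheet$replicate)
  rownames(sheet) <- lane_ids
  nLanes <- nrow(sheet)

  baseline_log2 <- stats::runif(nE + nH, config@baselineLog2Range[1],
                                config@baselineLog2Range[2])
  names(baseline_log2) <- c(endo_ids, hk_ids)
  lane_factors <- 2^stats::rnorm(nLanes, 0, config@laneScaleSd)
  names(lane_factors) <- lane_ids

  # disjoint planted sets: dark/light/shared x up/down
  nset <- c(dark_up = config@nDegDarkOnly, dark_down = config@nDegDarkOnly,
            light_up = config@nDegLightOnly, light_down = config@nDegLightOnly,
            shared_up = config@nDegShared, shared_down = config@nDegShared)
  picked <- sample(endo_ids, sum(nset))
  degSets <- split(picked, rep(names(nset), times = nset))[names(nset)[nset > 0]]
  degSets <- lapply(stats::setNames(names(nset), names(nset)),
                    function(k) if (is.null(degSets[[k]])) character() else degSets[[k]])

  # signed per-gene effect applicable in each phase (log2 units)
  eff <- config@effectSizeLog2
  effect_log2 <- matrix(0, nE + nH, length(config@phases),
                        dimnames = list(c(endo_ids, hk_ids), config@phases))
  apply_eff <- function(genes, phs, sign) {
    for (p in phs) effect_log2[genes, p] <<- sign * eff
  }
  if ("dark" %in% config@phases) {
    apply_eff(degSets$dark_up, "dark", +1)
    apply_eff(degSets$dark_down, "dark", -1)
  }
  if ("light" %in% config@phases) {
    apply_eff(degSets$light_up, "light", +1)
    apply_eff(degSets$light_down, "light", -1)
  }
  apply_eff(degSets$shared_up, config@phases, +1)
  apply_eff(degSets$shared_down, config@phases, -1)

  # NB mean matrix for biological probes
  mu_bio <- matrix(0, nE + nH, nLanes,
                   dimnames = list(c(endo_ids, hk_ids), lane_ids))
  base_lin <- 2^baseline_log2
  for (j in seq_len(nLanes)) {
    e <- if (sheet$condition[j] == "tumor") 2^effect_log2[, sheet$phase[j]] else 1
    mu_bio[, j] <- base_lin * lane_factors[j] * e
  }

  # nonspecific background lands on every probe; Negatives carry it alone
  counts <- matrix(0L, length(probe_ids), nLanes,
                   dimnames = list(probe_ids, lane_ids))
  counts[rownames(mu_bio), ] <- rnbinomMu(mu_bio, config@dispersion)
  mu_pos <- outer(config@posGain * posLadder(nP), lane_factors)
  counts[pos_ids, ] <- matrix(stats::rpois(length(mu_pos), mu_pos), nP, nLanes)
  if (config@backgroundMean > 0)
    counts <- counts + matrix(
      stats::rpois(length(counts), config@backgroundMean),
      nrow(counts), ncol(counts))

  ncs <- NanoCountSet(counts, probeClass = pclass, sampleData = sheet)
  truth <- structure(list(
    degSets = degSets,
    laneFactors = lane_factors,
    baselineMeans = stats::setNames(base_lin, names(baseline_log2)),
    expectedMeans = mu_bio,
    config = config, seed = as.integer(seed)
  ), class = "GroundTruth")
  list(counts = ncs, truth = truth)
}

# conventional 4-fold positive-control titration, highest first
posLadder <- function(n) 128 / 4^(seq_len(n) - 1L)

# NB draws parameterized by mean/dispersion; dispersion 0 is the Poisson limit
rnbinomMu <- function(mu, dispersion) {
  n <- length(mu)
  draw <- if (dispersion == 0) stats::rpois(n, mu)
          else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  matrix(draw, nrow(mu), ncol(mu), dimnames = dimnames(mu))
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat("GroundTruth for a simulated nCounter experiment\n")
  cat(sprintf("  planted DEG set sizes: %s\n",
              paste(sprintf("%s=%d", names(x$degSets), lengths(x$degSets)),
                    collapse = ", ")))
  cat(sprintf("  %d lanes, lane factor range [%.3f, %.3f]\n",
              length(x$laneFactors), min(x$laneFactors), max(x$laneFactors)))
  invisible(x)
}

#' Planted DEG gene ids for one phase and direction
#'
#' Convenience accessor combining phase-only and shared planted sets, i.e. the
#' full set of genes truly perturbed in that phase.
#' @param truth a `GroundTruth` from [simulateExperiment()].
#' @param phase `"dark"` or `"light"`.
#' @param direction `"up"` or `"down"`.
#' @return character vector of gene ids.
#' @export
plantedGenes <- function(truth, phase = c("dark", "light"),
                         direction = c("up", "down")) {
  phase <- match.arg(phase); direction <- match.arg(direction)
  c(truth$degSets[[paste(phase, direction, sep = "_")]],
    truth$degSets[[paste("shared", direction, sep = "_")]])
}
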