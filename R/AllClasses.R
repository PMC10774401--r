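#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- rowData colData
NULL

PROBE_CLASSES <- c("Endogenous", "Positive", "Negative", "Housekeeping")
CONDITIONS <- c("tumor", "vehicle")
PHASES <- c("dark", "light")
REGIONS <- c("HYP", "HPC", "BS")

#' NanoCountSet: an nCounter count matrix with probe and lane annotation
#'
#' `NanoCountSet` extends [SummarizedExperiment::SummarizedExperiment] to hold
#' one nCounter-style experiment: a probes-by-lanes count matrix (assay
#' `"counts"`), per-probe annotation (`rowData` columns `ProbeClass` and
#' optionally `CellType`), per-lane sample factors (`colData` columns
#' `condition`, `phase`, `region`, `replicate` when known), and an append-only
#' `stageLog` recording which transforms have been applied. The stage log is
#' the single source of truth for pipeline state: each normalization stage
#' checks it before running, so a stage can never be applied twice and the
#' fixed stage order cannot be violated silently.
#'
#' @slot stageLog character vector of applied-transform labels, starting at
#'   `"raw"`.
#' @export
setClass("NanoCountSet",
  contains = "SummarizedExperiment",
  slots = c(stageLog = "character")
)

setValidity("NanoCountSet", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    v <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(v))) msg <- c(msg, "counts must be finite")
    else if (any(v < 0)) msg <- c(msg, "counts must be nonnegative")
    else if (identical(object@stageLog, "raw") && any(v != round(v)))
      msg <- c(msg, "raw counts must be integers")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!"ProbeClass" %in% colnames(rd))
    msg <- c(msg, "rowData column 'ProbeClass' is required")
  else if (!all(rd$ProbeClass %in% PROBE_CLASSES))
    msg <- c(msg, sprintf("ProbeClass values must be one of: %s",
                          paste(PROBE_CLASSES, collapse = ", ")))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "probe ids (rownames) must be unique")
  if (length(object@stageLog) < 1L || object@stageLog[1L] != "raw")
    msg <- c(msg, "stageLog must begin with 'raw'")
  if (length(msg)) msg else TRUE
})

#' Construct a NanoCountSet
#'
#' @param counts numeric matrix, probes x lanes, nonnegative; rownames are
#'   probe ids, colnames are lane ids.
#' @param probeClass character vector (one per probe) with values
#'   `"Endogenous"`, `"Positive"`, `"Negative"` or `"Housekeeping"`.
#' @param cellType optional character vector of immune cell-type marker labels
#'   (`NA` for unannotated probes).
#' @param sampleData optional `data.frame`/`DataFrame` of lane factors
#'   (`condition`, `phase`, `region`, `replicate`), rownames matching lane ids.
#' @param stageLog character vector of applied stages; defaults to `"raw"`.
#' @return a [NanoCountSet-class] object.
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(c("A", "B", "NEG1"), c("L1", "L2")))
#' ncs <- NanoCountSet(m, probeClass = c("Endogenous", "Endogenous", "Negative"))
#' stageLog(ncs)
#' @export
NanoCountSet <- function(counts, probeClass, cellType = NULL,
                         sampleData = NULL, stageLog = "raw") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    stop("counts must have probe ids as rownames")
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("lane_%02d", seq_len(ncol(counts)))
  rd <- S4Vectors::DataFrame(ProbeClass = as.character(probeClass),
                             row.names = rownames(counts))
  if (!is.null(cellType)) rd$CellType <- as.character(cellType)
  if (is.null(sampleData)) {
    cd <- S4Vectors::DataFrame(row.names = colnames(counts))
  } else {
    cd <- S4Vectors::DataFrame(sampleData)
    rownames(cd) <- colnames(counts)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd, colData = cd)
  new("NanoCountSet", se, stageLog = stageLog)
}

#' Simulation configuration for synthetic nCounter experiments
#'
#' Holds every parameter of the synthetic experiment generator; see
#' [simulateExperiment()]. Defaults reproduce the emulated study design:
#' a 770-gene neuroinflammation panel (760 Endogenous + 10 Housekeeping),
#' 6 Positive and 8 Negative spike-in probes, 5 lanes per condition, three
#' brain regions sampled at two phases under two conditions (60 lanes).
#'
#' @slot nEndogenous,nPosControls,nNegControls,nHousekeeping probe counts per
#'   class.
#' @slot nPerGroup replicate lanes per condition cell.
#' @slot regions,phases factor level labels.
#' @slot baselineLog2Range range of per-gene baseline log2 means.
#' @slot dispersion negative-binomial dispersion (variance = mu + disp * mu^2);
#'   0 selects the Poisson limit.
#' @slot laneScaleSd SD of lane log2 scale factors (technical lane-to-lane
#'   scaling).
#' @slot backgroundMean mean Negative-probe background count.
#' @slot effectSizeLog2 magnitude of the planted tumor effect (log2 units).
#' @slot nDegDarkOnly,nDegLightOnly,nDegShared planted DEG counts per
#'   direction (up and down each get this many genes).
#' @slot posGain counts per concentration unit for the Positive-control
#'   titration ladder.
#' @slot seed default random seed.
#' @export
setClass("SimConfig", representation(
  nEndogenous = "integer", nPosControls = "integer", nNegControls = "integer",
  nHousekeeping = "integer", nPerGroup = "integer",
  regions = "character", phases = "character",
  baselineLog2Range = "numeric", dispersion = "numeric",
  laneScaleSd = "numeric", backgroundMean = "numeric",
  effectSizeLog2 = "numeric",
  nDegDarkOnly = "integer", nDegLightOnly = "integer", nDegShared = "integer",
  posGain = "numeric", seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  pos_int <- function(x, nm) if (length(x) != 1L || is.na(x) || x < 1L)
    sprintf("%s must be a positive integer", nm) else character()
  msg <- c(msg,
    pos_int(object@nEndogenous, "nEndogenous"),
    pos_int(object@nPosControls, "nPosControls"),
    pos_int(object@nNegControls, "nNegControls"),
    pos_int(object@nHousekeeping, "nHousekeeping"),
    pos_int(object@nPerGroup, "nPerGroup"))
  if (length(object@baselineLog2Range) != 2L ||
      diff(object@baselineLog2Range) < 0)
    msg <- c(msg, "baselineLog2Range must be an increasing interval")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  if (object@laneScaleSd < 0) msg <- c(msg, "laneScaleSd must be >= 0")
  if (object@backgroundMean < 0) msg <- c(msg, "backgroundMean must be >= 0")
  if (object@effectSizeLog2 <= 0) msg <- c(msg, "effectSizeLog2 must be > 0")
  deg <- c(object@nDegDarkOnly, object@nDegLightOnly, object@nDegShared)
  if (any(deg < 0L)) msg <- c(msg, "planted DEG counts must be >= 0")
  if (2L * sum(deg) > object@nEndogenous)
    msg <- c(msg, "planted DEG sets (both directions) exceed the endogenous panel size")
  if (length(object@phases) < 1L || length(object@regions) < 1L)
    msg <- c(msg, "at least one phase and one region required")
  if (length(msg)) msg else TRUE
})

#' @rdname SimConfig-class
#' @param nEndogenous,nPosControls,nNegControls,nHousekeeping,nPerGroup,regions,phases,baselineLog2Range,dispersion,laneScaleSd,backgroundMean,effectSizeLog2,nDegDarkOnly,nDegLightOnly,nDegShared,posGain,seed see slot documentation.
#' @return a validated `SimConfig` object.
#' @examples
#' cfg <- simConfig(nDegDarkOnly = 20, seed = 7)
#' cfg
#' @export
simConfig <- function(nEndogenous = 760L, nPosControls = 6L,
                      nNegControls = 8L, nHousekeeping = 10L,
                      nPerGroup = 5L,
                      regions = c("HYP", "HPC", "BS"),
                      phases = c("dark", "light"),
                      baselineLog2Range = c(4, 12),
                      dispersion = 0.1, laneScaleSd = 0.25,
                      backgroundMean = 10, effectSizeLog2 = 2,
                      nDegDarkOnly = 0L, nDegLightOnly = 0L, nDegShared = 0L,
                      posGain = 400, seed = 1L) {
  new("SimConfig",
      nEndogenous = as.integer(nEndogenous),
      nPosControls = as.integer(nPosControls),
      nNegControls = as.integer(nNegControls),
      nHousekeeping = as.integer(nHousekeeping),
      nPerGroup = as.integer(nPerGroup),
      regions = regions, phases = phases,
      baselineLog2Range = as.numeric(baselineLog2Range),
      dispersion = as.numeric(dispersion),
      laneScaleSd = as.numeric(laneScaleSd),
      backgroundMean = as.numeric(backgroundMean),
      effectSizeLog2 = as.numeric(effectSizeLog2),
      nDegDarkOnly = as.integer(nDegDarkOnly),
      nDegLightOnly = as.integer(nDegLightOnly),
      nDegShared = as.integer(nDegShared),
      posGain = as.numeric(posGain),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: synthetic nCounter experiment\n")
  cat(sprintf("  probes: %d Endogenous + %d Housekeeping + %d Positive + %d Negative\n",
              object@nEndogenous, object@nHousekeeping,
              object@nPosControls, object@nNegControls))
  cat(sprintf("  design: %d regions x %d phases x 2 conditions x %d lanes = %d lanes\n",
              length(object@regions), length(object@phases), object@nPerGroup,
              length(object@regions) * length(object@phases) * 2L * object@nPerGroup))
  cat(sprintf("  dispersion %.3g, lane scale SD %.3g log2, background mean %.3g\n",
              object@dispersion, object@laneScaleSd, object@backgroundMean))
  cat(sprintf("  planted DEGs/direction: dark-only %d, light-only %d, shared %d (effect %s%.3g log2)\n",
              object@nDegDarkOnly, object@nDegLightOnly, object@nDegShared,
              "±", object@effectSizeLog2))
})
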