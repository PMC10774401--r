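#' nCounter normalization chain
#'
#' The four-stage chain applied, in fixed order, before differential testing:
#' negative background subtraction, positive-control normalization, CodeSet
#' content normalization (both geometric-mean scalings), then quantile
#' normalization on log2 values. Each stage appends to the object's
#' [stageLog()] and refuses to run twice or out of order.
#'
#' @name normalization
NULL

#' Subtract lane background estimated from Negative probes
#'
#' Per lane, a background summary of the Negative-probe counts (their mean by
#' default, or their max, or mean + 2 SD) is subtracted from every probe;
#' results below `floor` are set to `floor`, which keeps all values strictly
#' positive for the geometric-mean stages that follow.
#'
#' @param x a raw [NanoCountSet-class].
#' @param method background summary: `"mean"` (default), `"max"`, or
#'   `"mean2sd"` (mean + 2 sample SD).
#' @param floor positive value imposed after subtraction (default 1).
#' @return the updated `NanoCountSet`; per-lane backgrounds are retrievable as
#'   `normFactors(x)$background`.
#' @export
subtractBackground <- function(x, method = c("mean", "max", "mean2sd"),
                               floor = 1) {
  method <- match.arg(method)
  stopifnot(floor > 0)
  assertStageAbsent(x, "background")
  neg <- probeClass(x) == "Negative"
  if (!any(neg))
    stop("configuration error: no Negative probes for background subtraction",
         call. = FALSE)
  m <- SummarizedExperiment::assay(x, "counts")
  negm <- m[neg, , drop = FALSE]
  bg <- switch(method,
    mean = colMeans(negm),
    max = apply(negm, 2, max),
    mean2sd = colMeans(negm) + 2 * apply(negm, 2, stats::sd))
  out <- sweep(m, 2, bg, "-")
  out[out < floor] <- floor
  SummarizedExperiment::assay(x, "counts") <- out
  S4Vectors::metadata(x)$floor <- floor
  addStage(x, sprintf("background:%s", method), bg, "background")
}

#' Positive-control normalization (geometric-mean lane scaling)
#'
#' Each lane's scaling factor is the grand geometric mean (across lanes) of
#' the lane-wise geometric means of the Positive probes, divided by this
#' lane's own Positive geometric mean; every probe in the lane is multiplied
#' by the factor. Afterwards all lanes share the same Positive geometric
#' mean, and the factors themselves have geometric mean 1.
#'
#' @param x a background-subtracted [NanoCountSet-class].
#' @return the updated object; factors in `normFactors(x)$posFactor`. Lanes
#'   whose Positive probes are all at the floor are flagged with a warning but
#'   still scaled.
#' @export
positiveControlNormalize <- function(x) {
  assertStagePresent(x, "background", "positive-control normalization")
  assertStageAbsent(x, "positive_control")
  pos <- probeClass(x) == "Positive"
  if (sum(pos) < 2L)
    stop("configuration error: >= 2 Positive probes required", call. = FALSE)
  scaleByReference(x, pos, "positive_control", "posFactor",
                   flagLabel = "Positive")
}

#' CodeSet content normalization (geometric-mean lane scaling)
#'
#' Identical factor arithmetic to [positiveControlNormalize()], over the
#' content reference probe set: Housekeeping probes (default) or all
#' Endogenous probes (`reference = "global"`).
#'
#' @param x a positive-control-normalized [NanoCountSet-class].
#' @param reference `"housekeeping"` or `"global"`.
#' @return the updated object; factors in `normFactors(x)$contentFactor`.
#' @export
contentNormalize <- function(x, reference = c("housekeeping", "global")) {
  reference <- match.arg(reference)
  assertStagePresent(x, "positive_control", "content normalization")
  assertStageAbsent(x, "content")
  ref <- if (reference == "housekeeping") probeClass(x) == "Housekeeping"
         else probeClass(x) == "Endogenous"
  if (!any(ref))
    stop(sprintf("configuration error: empty content reference set (%s)",
                 reference), call. = FALSE)
  scaleByReference(x, ref, sprintf("content:%s", reference), "contentFactor")
}

# shared geometric-mean scaling: factor_j = geomean_j(all lanes' ref geomeans)
# / lane j's ref geomean
scaleByReference <- function(x, refMask, stageLabel, factorName,
                             flagLabel = NULL) {
  m <- SummarizedExperiment::assay(x, "counts")
  laneGeo <- apply(m[refMask, , drop = FALSE], 2, geomean)
  fac <- geomean(laneGeo) / laneGeo
  if (!is.null(flagLabel)) {
    floor <- S4Vectors::metadata(x)$floor %||% 1
    fl <- apply(m[refMask, , drop = FALSE], 2, function(v) all(v <= floor))
    atFloor <- names(fac)[fl]
    if (length(atFloor))
      warning(sprintf("lane(s) with all %s probes at the floor: %s",
                      flagLabel, paste(atFloor, collapse = ", ")),
              call. = FALSE)
  }
  SummarizedExperiment::assay(x, "counts") <- sweep(m, 2, fac, "*")
  addStage(x, stageLabel, fac, factorName)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Log2-transform counts
#'
#' @param x a [NanoCountSet-class] with nonnegative values.
#' @param pseudocount nonnegative value added before taking log2 (default 0;
#'   the background floor already guarantees positivity).
#' @return the updated object (values now on the log2 scale).
#' @export
log2Transform <- function(x, pseudocount = 0) {
  stopifnot(pseudocount >= 0)
  assertStageAbsent(x, "log2")
  m <- SummarizedExperiment::assay(x, "counts")
  if (pseudocount == 0 && any(m <= 0))
    stop("zero values require a positive pseudocount", call. = FALSE)
  SummarizedExperiment::assay(x, "counts") <- log2(m + pseudocount)
  addStage(x, "log2")
}

#' Quantile normalization
#'
#' Forces all lanes (within a normalization group) to share one empirical
#' distribution: rank r in each lane is replaced by the mean, across lanes, of
#' each lane's r-th order statistic; tied values within a lane receive the
#' mean of the reference values their positions span. Applied on log2 values.
#'
#' @param x a log2-scale [NanoCountSet-class].
#' @param scope `"region"` (default): normalize each brain region's lanes as
#'   an independent group, matching the per-region comparisons downstream;
#'   `"joint"`: all lanes together. With no `region` column in `colData`,
#'   `"region"` falls back to joint.
#' @return the updated object.
#' @export
quantileNormalize <- function(x, scope = c("region", "joint")) {
  scope <- match.arg(scope)
  assertStagePresent(x, "log2", "quantile normalization")
  assertStageAbsent(x, "quantile")
  m <- SummarizedExperiment::assay(x, "counts")
  cd <- SummarizedExperiment::colData(x)
  groups <- if (scope == "region" && "region" %in% colnames(cd))
    split(seq_len(ncol(m)), cd$region) else list(all = seq_len(ncol(m)))
  for (idx in groups)
    m[, idx] <- quantileNormalizeMatrix(m[, idx, drop = FALSE])
  SummarizedExperiment::assay(x, "counts") <- m
  addStage(x, paste0("quantile:", scope))
}

# core quantile normalization with the spanned-reference tie rule
quantileNormalizeMatrix <- function(m) {
  if (ncol(m) < 2L) return(m)
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    o <- order(m[, j])
    runs <- rle(m[o, j])$lengths          # tied runs in sort order
    grp <- rep.int(seq_along(runs), runs)
    tied_mean <- as.vector(rowsum(ref, grp)) / runs
    out[o, j] <- tied_mean[grp]
  }
  out
}

#' Run the full normalization chain
#'
#' Convenience wrapper applying, in order: [subtractBackground()],
#' [positiveControlNormalize()], [contentNormalize()], [log2Transform()], and
#' (unless `quantile = FALSE`) [quantileNormalize()].
#'
#' @param x a raw [NanoCountSet-class].
#' @param background,floor passed to [subtractBackground()].
#' @param contentRef passed to [contentNormalize()].
#' @param pseudocount passed to [log2Transform()].
#' @param quantile logical; apply quantile normalization?
#' @param quantileScope passed to [quantileNormalize()].
#' @return the fully normalized `NanoCountSet` (log2 scale).
#' @examples
#' sim <- simulateExperiment(simConfig(seed = 1))
#' norm <- normalizeCounts(sim$counts)
#' stageLog(norm)
#' @export
normalizeCounts <- function(x, background = "mean", floor = 1,
                            contentRef = "housekeeping", pseudocount = 0,
                            quantile = TRUE, quantileScope = "region") {
  x <- subtractBackground(x, method = background, floor = floor)
  x <- positiveControlNormalize(x)
  x <- contentNormalize(x, reference = contentRef)
  x <- log2Transform(x, pseudocount = pseudocount)
  if (quantile) x <- quantileNormalize(x, scope = quantileScope)
  x
}
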