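#' @rdname NanoCountSet
#' @param x a `NanoCountSet`.
#' @export
setGeneric("stageLog", function(x) standardGeneric("stageLog"))

#' @rdname NanoCountSet
#' @export
setMethod("stageLog", "NanoCountSet", function(x) x@stageLog)

#' @rdname NanoCountSet
#' @export
setGeneric("probeClass", function(x) standardGeneric("probeClass"))

#' @rdname NanoCountSet
#' @export
setMethod("probeClass", "NanoCountSet", function(x) {
  stats::setNames(SummarizedExperiment::rowData(x)$ProbeClass, rownames(x))
})

#' @rdname NanoCountSet
#' @export
setGeneric("cellType", function(x) standardGeneric("cellType"))

#' @rdname NanoCountSet
#' @export
setMethod("cellType", "NanoCountSet", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  ct <- if ("CellType" %in% colnames(rd)) rd$CellType
        else rep(NA_character_, nrow(x))
  stats::setNames(ct, rownames(x))
})

#' @rdname NanoCountSet
#' @export
setGeneric("normFactors", function(x) standardGeneric("normFactors"))

#' Per-lane normalization factors recorded by the normalization stages
#'
#' A list with one element per completed stage (`background`, `posFactor`,
#' `contentFactor`), each a named numeric vector over lanes. Empty before
#' normalization.
#' @rdname NanoCountSet
#' @export
setMethod("normFactors", "NanoCountSet", function(x) {
  f <- S4Vectors::metadata(x)$normFactors
  if (is.null(f)) list() else f
})

#' @rdname NanoCountSet
#' @param object a `NanoCountSet`.
#' @export
setMethod("show", "NanoCountSet", function(object) {
  cls <- table(factor(probeClass(object), levels = PROBE_CLASSES))
  cat(sprintf("NanoCountSet: %d probes x %d lanes\n", nrow(object), ncol(object)))
  cat(sprintf("  probe classes: %s\n",
              paste(sprintf("%s %d", names(cls), cls), collapse = ", ")))
  cat(sprintf("  stages applied: %s\n", paste(object@stageLog, collapse = " -> ")))
  cd <- SummarizedExperiment::colData(object)
  if (ncol(cd))
    cat(sprintf("  lane factors: %s\n", paste(colnames(cd), collapse = ", ")))
})

# internal: append a stage label and stash per-lane factors
addStage <- function(x, label, factors = NULL, factorName = NULL) {
  x@stageLog <- c(x@stageLog, label)
  if (!is.null(factors)) {
    nf <- S4Vectors::metadata(x)$normFactors
    if (is.null(nf)) nf <- list()
    nf[[factorName]] <- factors
    S4Vectors::metadata(x)$normFactors <- nf
  }
  x
}

# stage labels may carry a ':<variant>' suffix; gating is on the stage name
hasStage <- function(x, stage) any(grepl(paste0("^", stage, "(:|$)"), x@stageLog))

assertStageAbsent <- function(x, stage) {
  if (hasStage(x, stage))
    stop(sprintf("stage '%s' has already been applied (stage log: %s)",
                 stage, paste(x@stageLog, collapse = " -> ")), call. = FALSE)
}

assertStagePresent <- function(x, stage, before) {
  if (!hasStage(x, stage))
    stop(sprintf("stage '%s' must be applied before %s (stage log: %s)",
                 stage, before, paste(x@stageLog, collapse = " -> ")),
         call. = FALSE)
}

# geometric mean on strictly positive values; flooring upstream guarantees > 0
geomean <- function(x) exp(mean(log(x)))
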