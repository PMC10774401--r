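#' Read a probe-by-lane count table into a NanoCountSet
#'
#' Expects a tab-separated table whose first column is the probe id, second
#' column the probe class (`Endogenous` / `Positive` / `Negative` /
#' `Housekeeping`), and remaining columns one lane each, with a header row of
#' lane ids — the layout [writeCountTable()] produces. Probes absent from
#' `annotation` (when supplied) are reported with a warning but kept.
#'
#' @param path path to the TSV.
#' @param annotation optional data.frame with columns `probe_id`, `class_code`
#'   and optionally `cell_type`; overrides the file's class column and attaches
#'   cell-type marker labels.
#' @return a [NanoCountSet-class] with `stageLog = "raw"`.
#' @export
readCountTable <- function(path, annotation = NULL) {
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 3L)
    stop("count table needs probe id, probe class, and >= 1 lane column",
         call. = FALSE)
  ids <- tab[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate probe rows: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  m <- as.matrix(tab[, -(1:2), drop = FALSE])
  vals <- suppressWarnings(as.numeric(m))
  if (any(is.na(vals)))
    stop("malformed numeric count field(s) in ", path, call. = FALSE)
  if (any(vals < 0)) stop("negative counts in ", path, call. = FALSE)
  counts <- matrix(vals, nrow(tab), ncol(tab) - 2L,
                   dimnames = list(ids, colnames(tab)[-(1:2)]))
  pclass <- tab[[2L]]
  ctype <- NULL
  if (!is.null(annotation)) {
    unknown <- setdiff(ids, annotation$probe_id)
    if (length(unknown))
      warning("probes absent from annotation: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    idx <- match(ids, annotation$probe_id)
    pclass <- ifelse(is.na(idx), pclass, annotation$class_code[idx])
    if ("cell_type" %in% colnames(annotation))
      ctype <- annotation$cell_type[idx]
  }
  NanoCountSet(counts, probeClass = pclass, cellType = ctype)
}

#' Write a NanoCountSet's counts as a TSV count table
#'
#' First column `probe_id`, second `probe_class`, then one column per lane.
#' Integer matrices round-trip bit-identically through [readCountTable()].
#'
#' @param x a [NanoCountSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(x, path) {
  m <- SummarizedExperiment::assay(x, "counts")
  df <- data.frame(probe_id = rownames(m),
                   probe_class = unname(probeClass(x)),
                   m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a lane sample sheet
#'
#' CSV with columns `lane_id`, `condition` (tumor/vehicle), `phase`
#' (dark/light), `region` (HYP/HPC/BS), `replicate`.
#'
#' @param path CSV path.
#' @return `readSampleSheet`: a data.frame with `lane_id` rownames.
#' @export
readSampleSheet <- function(path) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lane_id", "condition", "phase", "region", "replicate")
  miss <- setdiff(need, colnames(sheet))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(sheet$condition, CONDITIONS)
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  rownames(sheet) <- sheet$lane_id
  sheet
}

#' @rdname readSampleSheet
#' @param x a [NanoCountSet-class] whose `colData` holds the lane factors.
#' @export
writeSampleSheet <- function(x, path) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  df <- cbind(lane_id = colnames(x), cd)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member gene ids. Duplicate members within a set are collapsed.
#'
#' @param path GMT path.
#' @return named list of character vectors (set name -> unique members).
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(stats::setNames(list(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short))
    stop(sprintf("GMT format error: line(s) %s have fewer than 3 fields",
                 paste(which(short), collapse = ", ")), call. = FALSE)
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[`, "", 1L))
}

#' Write / read simulation ground truth as JSON
#'
#' @param truth a `GroundTruth` from [simulateExperiment()].
#' @param path JSON path.
#' @export
writeGroundTruth <- function(truth, path) {
  out <- list(degSets = truth$degSets,
              laneFactors = as.list(truth$laneFactors),
              baselineMeans = as.list(truth$baselineMeans),
              seed = truth$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  raw <- jsonlite::read_json(path)
  structure(list(
    degSets = lapply(raw$degSets,
                     function(s) as.character(unlist(s, use.names = FALSE))),
    laneFactors = unlist(raw$laneFactors),
    baselineMeans = unlist(raw$baselineMeans),
    seed = raw$seed), class = "GroundTruth")
}
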