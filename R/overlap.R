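#' Pool per-region DEG lists into one whole-brain unique list
#'
#' Takes the per-region `GeneStatTable`s of one phase and returns the union of
#' genes flagged by the chosen filter method in the chosen direction, with
#' provenance recording which region(s) contributed each gene. A gene up in
#' one region and down in another appears in both directional pooled lists.
#'
#' @param tables named list of `GeneStatTable`s (one per region), all from the
#'   same phase.
#' @param method filter method: `"p"`, `"fc"`, or `"both"`.
#' @param direction `"up"` or `"down"`.
#' @return a `PooledDEGList`: list with `phase`, `method`, `direction`,
#'   `genes` (character set), `provenance` (gene -> contributing regions).
#' @export
poolUniqueDegs <- function(tables, method = c("p", "fc", "both"),
                           direction = c("up", "down")) {
  method <- match.arg(method); direction <- match.arg(direction)
  phases <- unique(vapply(tables, function(t) S4Vectors::metadata(t)$phase, ""))
  if (length(phases) != 1L)
    stop("all tables must come from the same phase; got: ",
         paste(phases, collapse = ", "), call. = FALSE)
  regions <- vapply(tables, function(t) S4Vectors::metadata(t)$region, "")
  perRegion <- lapply(tables, flaggedGenes, method = method,
                      direction = direction)
  genes <- unique(unlist(perRegion, use.names = FALSE))
  if (is.null(genes)) genes <- character()
  prov <- lapply(stats::setNames(genes, genes), function(g)
    regions[vapply(perRegion, function(s) g %in% s, FALSE)])
  structure(list(phase = phases, method = method, direction = direction,
                 genes = genes, provenance = prov),
            class = "PooledDEGList")
}

#' @export
print.PooledDEGList <- function(x, ...) {
  cat(sprintf("PooledDEGList: %d unique %sregulated DEGs (%s phase, %s filter)\n",
              length(x$genes), x$direction, x$phase, x$method))
  invisible(x)
}

#' Dark/light overlap of pooled DEG lists
#'
#' Partitions two same-direction, same-method pooled lists into dark-only,
#' shared, and light-only sets and computes the shared fraction. The default
#' denominator is the union of the two lists (a three-set Venn reading);
#' `denominator = "dark"` or `"light"` divides by one phase's list size
#' instead.
#'
#' @param dark,light `PooledDEGList`s with matching `method` and `direction`.
#' @param denominator `"union"` (default), `"dark"`, or `"light"`.
#' @return an `OverlapResult`: list with `method`, `direction`, `dark_only`,
#'   `shared`, `light_only` (character sets), `fraction_shared`, `denominator`,
#'   and `empty` (TRUE when the union is empty, in which case the fraction is
#'   0).
#' @export
computeOverlap <- function(dark, light,
                           denominator = c("union", "dark", "light")) {
  denominator <- match.arg(denominator)
  if (!identical(dark$method, light$method) ||
      !identical(dark$direction, light$direction))
    stop("dark and light lists must share filter method and direction",
         call. = FALSE)
  shared <- intersect(dark$genes, light$genes)
  denomSet <- switch(denominator, union = union(dark$genes, light$genes),
                     dark = dark$genes, light = light$genes)
  empty <- length(denomSet) == 0L
  structure(list(
    method = dark$method, direction = dark$direction,
    dark_only = setdiff(dark$genes, light$genes),
    shared = shared,
    light_only = setdiff(light$genes, dark$genes),
    fraction_shared = if (empty) 0 else length(shared) / length(denomSet),
    denominator = denominator, empty = empty),
    class = "OverlapResult")
}

#' @export
print.OverlapResult <- function(x, ...) {
  cat(sprintf("OverlapResult (%s filter, %s): dark-only %d | shared %d | light-only %d; shared fraction %.3f (/%s)\n",
              x$method, x$direction, length(x$dark_only), length(x$shared),
              length(x$light_only), x$fraction_shared, x$denominator))
  invisible(x)
}

#' Range of shared percentages across filter-method x direction cells
#'
#' @param results list of `OverlapResult`s (typically the six method x
#'   direction combinations). Results whose union is empty are ignored.
#' @return numeric `c(min_pct, max_pct)`, on the 0-100 scale.
#' @export
overlapRange <- function(results) {
  fr <- vapply(results, function(r) if (r$empty) NA_real_
               else r$fraction_shared, 0)
  fr <- fr[!is.na(fr)]
  if (!length(fr))
    stop("all overlap unions are empty; no range defined", call. = FALSE)
  c(min_pct = 100 * min(fr), max_pct = 100 * max(fr))
}

#' Signed DEG counts per immune cell-type marker
#'
#' Counts, for each annotated cell type, how many of its marker genes appear
#' in each pooled DEG list: upregulated markers count positively,
#' downregulated negatively. A marker present in both an up and a down pooled
#' list contributes to both signs. Unannotated genes are ignored.
#'
#' @param pooled list of `PooledDEGList`s (any mix of phases, methods,
#'   directions).
#' @param cellTypes named character vector mapping gene id -> cell-type label
#'   (e.g. from [cellType()]); `NA` entries are unannotated.
#' @return a data.frame with columns `cell_type`, `phase`, `method`, `count`
#'   (signed: positive up, negative down).
#' @export
celltypeSummary <- function(pooled, cellTypes) {
  cellTypes <- cellTypes[!is.na(cellTypes)]
  rows <- lapply(pooled, function(pl) {
    hits <- pl$genes[pl$genes %in% names(cellTypes)]
    if (!length(hits)) return(NULL)
    tab <- table(cellTypes[hits])
    data.frame(cell_type = names(tab), phase = pl$phase, method = pl$method,
               count = as.integer(tab) *
                 (if (pl$direction == "up") 1L else -1L))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    rows <- data.frame(cell_type = character(), phase = character(),
                       method = character(), count = integer())
  rownames(rows) <- NULL
  rows
}
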