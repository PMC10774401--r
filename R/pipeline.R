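#' Run the full analysis pipeline on simulated or supplied data
#'
#' Orchestrates the whole chain: simulate (or accept) a raw count set,
#' normalize it, run the per-region x per-phase tumor-vs-vehicle comparisons,
#' apply the three DEG filters, pool per-region lists into whole-brain unique
#' DEG lists, compute dark/light overlap for every filter method x direction,
#' summarize DEGs by cell-type marker, and optionally run gene-set
#' over-representation. All randomness flows from one seed; identical inputs
#' give an identical report.
#'
#' @param config a [simConfig()] describing the synthetic experiment, or
#'   `NULL` when `counts` is supplied.
#' @param counts a raw [NanoCountSet-class] with full `colData` lane factors;
#'   overrides `config`.
#' @param seed integer seed for simulation (defaults to `config@seed`).
#' @param background,floor,contentRef,quantile,quantileScope normalization
#'   parameters, see [normalizeCounts()].
#' @param variant,alpha,sdK testing/filter parameters, see [runComparison()].
#' @param overlapDenominator see [computeOverlap()].
#' @param gmt optional named list of gene sets; when supplied, [oraTest()] is
#'   run per phase x direction on the p-filter pooled lists against the
#'   Endogenous-panel universe.
#' @param qCut q cutoff for [timeofdayDependence()] when `gmt` is given.
#' @return a `RunReport` list: `params` (every parameter, with defaults
#'   recorded), `truth` (when simulated), `tables` (per region x phase
#'   `GeneStatTable`s), `degCounts` (per comparison x method), `pooled`
#'   (per phase x method x direction `PooledDEGList`s), `overlaps` (six
#'   `OverlapResult`s), `overlapRange`, `fractionShared` (per method x
#'   direction), `celltype` summary, and `enrichment` (when `gmt` given).
#' @examples
#' rep <- runPipeline(simConfig(nDegDarkOnly = 10L, seed = 3))
#' rep$overlapRange
#' @export
runPipeline <- function(config = simConfig(), counts = NULL,
                        seed = if (!is.null(config)) config@seed else 1L,
                        background = "mean", floor = 1,
                        contentRef = "housekeeping",
                        quantile = TRUE, quantileScope = "region",
                        variant = "pooled", alpha = 0.05, sdK = 2,
                        overlapDenominator = "union",
                        gmt = NULL, qCut = 0.05) {
  truth <- NULL
  if (is.null(counts)) {
    if (is.null(config)) stop("either config or counts must be supplied")
    sim <- simulateExperiment(config, seed = seed)
    counts <- sim$counts
    truth <- sim$truth
  }
  cd <- SummarizedExperiment::colData(counts)
  regions <- unique(cd$region)
  phases <- unique(cd$phase)
  norm <- normalizeCounts(counts, background = background, floor = floor,
                          contentRef = contentRef, quantile = quantile,
                          quantileScope = quantileScope)

  tables <- list()
  degCounts <- NULL
  for (ph in phases) for (rg in regions) {
    tab <- runComparison(norm, region = rg, phase = ph, variant = variant,
                         alpha = alpha, sdK = sdK)
    tables[[paste(rg, ph, sep = "_")]] <- tab
    degCounts <- rbind(degCounts, data.frame(
      region = rg, phase = ph,
      n_p = sum(tab$flag_p), n_fc = sum(tab$flag_fc),
      n_both = sum(tab$flag_both)))
  }

  methods_ <- c("p", "fc", "both"); directions <- c("up", "down")
  pooled <- list(); overlaps <- list(); fracRows <- NULL
  for (me in methods_) for (di in directions) {
    per_phase <- lapply(stats::setNames(phases, phases), function(ph)
      poolUniqueDegs(tables[paste(regions, ph, sep = "_")],
                     method = me, direction = di))
    for (ph in phases)
      pooled[[paste(ph, me, di, sep = "_")]] <- per_phase[[ph]]
    if (all(c("dark", "light") %in% phases)) {
      ov <- computeOverlap(per_phase$dark, per_phase$light,
                           denominator = overlapDenominator)
      overlaps[[paste(me, di, sep = "_")]] <- ov
      fracRows <- rbind(fracRows, data.frame(
        method = me, direction = di,
        n_dark = length(per_phase$dark$genes),
        n_light = length(per_phase$light$genes),
        n_shared = length(ov$shared),
        fraction_shared = ov$fraction_shared, empty = ov$empty))
    }
  }

  ovRange <- tryCatch(overlapRange(overlaps), error = function(e) {
    warning("overlap range undefined: all unions empty (null-like run)",
            call. = FALSE)
    c(min_pct = NA_real_, max_pct = NA_real_)
  })

  ct <- celltypeSummary(pooled, cellType(counts))

  enr <- NULL
  if (!is.null(gmt)) {
    universe <- names(probeClass(norm))[probeClass(norm) == "Endogenous"]
    enr <- list()
    for (di in directions) {
      res <- lapply(stats::setNames(phases, phases), function(ph)
        oraTest(pooled[[paste(ph, "p", di, sep = "_")]]$genes, universe, gmt))
      enr[[di]] <- list(perPhase = res)
      if (all(c("dark", "light") %in% phases))
        enr[[di]]$dependence <- tryCatch(
          timeofdayDependence(res$dark, res$light, qCut = qCut),
          error = function(e) NULL)
    }
  }

  structure(list(
    params = list(background = background, floor = floor,
                  contentRef = contentRef, quantile = quantile,
                  quantileScope = quantileScope, variant = variant,
                  alpha = alpha, sdK = sdK,
                  overlapDenominator = overlapDenominator, qCut = qCut,
                  seed = as.integer(seed),
                  config = if (is.null(truth)) NULL else truth$config),
    truth = truth, normalized = norm, tables = tables,
    degCounts = degCounts, pooled = pooled, overlaps = overlaps,
    fractionShared = fracRows, overlapRange = ovRange,
    celltype = ct, enrichment = enr), class = "RunReport")
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport\n")
  cat(sprintf("  comparisons: %d; DEG counts (p/fc/both) per comparison:\n",
              length(x$tables)))
  print(x$degCounts, row.names = FALSE)
  if (!is.null(x$fractionShared)) {
    cat("  dark/light shared fractions:\n")
    print(x$fractionShared, row.names = FALSE)
    cat(sprintf("  overlap range: %.1f%% - %.1f%%\n",
                x$overlapRange[1], x$overlapRange[2]))
  }
  invisible(x)
}

#' Serialize a RunReport to JSON
#'
#' Writes the machine-readable portion of the report (parameters, DEG counts,
#' pooled list sizes and gene ids, overlap fractions and range, cell-type
#' summary, enrichment percentages). Identical report -> byte-identical JSON.
#'
#' @param report a `RunReport` from [runPipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRunReport <- function(report, path) {
  cfg <- report$params$config
  params <- report$params
  params$config <- if (is.null(cfg)) NULL else simConfigAsList(cfg)
  out <- list(
    params = params,
    degCounts = report$degCounts,
    pooled = lapply(report$pooled, function(p)
      list(phase = p$phase, method = p$method, direction = p$direction,
           n = length(p$genes), genes = sort(p$genes))),
    fractionShared = report$fractionShared,
    overlapRange = as.list(report$overlapRange),
    celltype = report$celltype,
    enrichmentDependence = lapply(report$enrichment, function(e)
      as.list(e$dependence)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

simConfigAsList <- function(cfg) {
  nm <- slotNames(cfg)
  stats::setNames(lapply(nm, function(s) slot(cfg, s)), nm)
}
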