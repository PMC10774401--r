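#' Hypergeometric over-representation analysis of a DEG list
#'
#' Tests each gene set for over-representation of the DEG list within the
#' measured universe. For a universe of size N containing K set members, and
#' a DEG list of n draws with k overlapping genes, the p-value is the upper
#' tail P(X >= k) of the hypergeometric distribution. Benjamini-Hochberg
#' q-values are computed across the sets of one call. The natural universe
#' for panel data is the panel's Endogenous genes.
#'
#' @param deg character vector of DEG ids; must be a subset of `universe`.
#' @param universe character vector of all measured gene ids.
#' @param sets named list of character vectors (e.g. from [readGmt()]); each
#'   set is intersected with the universe before testing.
#' @return a data.frame sorted by q then p, one row per set, with columns
#'   `set_name`, `n_universe`, `n_set`, `n_deg`, `n_overlap`, `p_hyper`,
#'   `bh_q`, `overlap_genes` (comma-separated).
#' @examples
#' ora <- oraTest(deg = c("a", "b"), universe = letters[1:10],
#'                sets = list(S1 = c("a", "b", "c"), S2 = c("x", "y", "d")))
#' ora[, c("set_name", "n_overlap", "p_hyper")]
#' @export
oraTest <- function(deg, universe, sets) {
  universe <- unique(universe)
  deg <- unique(deg)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  out <- setdiff(deg, universe)
  if (length(out))
    stop("DEG list is not a subset of the universe: ",
         paste(utils::head(out, 5), collapse = ", "), call. = FALSE)
  N <- length(universe); n <- length(deg)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    ov <- intersect(s, deg)
    k <- length(ov); K <- length(s)
    p <- if (k == 0L) 1 else stats::phyper(k - 1, K, N - K, n,
                                           lower.tail = FALSE)
    data.frame(set_name = nm, n_universe = N, n_set = K, n_deg = n,
               n_overlap = k, p_hyper = p,
               overlap_genes = paste(sort(ov), collapse = ","))
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(set_name = character(), n_universe = integer(),
                      n_set = integer(), n_deg = integer(),
                      n_overlap = integer(), p_hyper = numeric(),
                      bh_q = numeric(), overlap_genes = character()))
  res$bh_q <- stats::p.adjust(res$p_hyper, method = "BH")
  res <- res[order(res$bh_q, res$p_hyper, res$set_name),
             c("set_name", "n_universe", "n_set", "n_deg", "n_overlap",
               "p_hyper", "bh_q", "overlap_genes")]
  rownames(res) <- NULL
  res
}

#' Time-of-day dependence of enriched gene sets
#'
#' Classifies every gene set significant (q < `qCut`) in the dark-phase or
#' light-phase enrichment as dark-only, light-only, or shared, and reports
#' the three percentages over the union of significant sets. High dark-only +
#' light-only percentages indicate that the biological processes implicated
#' by the DEGs depend on the time of day of sampling.
#'
#' @param darkRes,lightRes results of [oraTest()] on the dark- and light-phase
#'   DEG lists against the same set collection.
#' @param qCut BH q-value cutoff (default 0.05).
#' @return named numeric vector `c(pct_dark_only, pct_light_only,
#'   pct_shared)`, summing to 100.
#' @export
timeofdayDependence <- function(darkRes, lightRes, qCut = 0.05) {
  sigD <- darkRes$set_name[darkRes$bh_q < qCut]
  sigL <- lightRes$set_name[lightRes$bh_q < qCut]
  un <- union(sigD, sigL)
  if (!length(un))
    stop("no gene set significant in either phase at q < ", qCut,
         call. = FALSE)
  c(pct_dark_only = 100 * length(setdiff(sigD, sigL)) / length(un),
    pct_light_only = 100 * length(setdiff(sigL, sigD)) / length(un),
    pct_shared = 100 * length(intersect(sigD, sigL)) / length(un))
}
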