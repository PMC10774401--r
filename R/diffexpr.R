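#' Two-sample t-test for one gene
#'
#' Plain two-sided two-sample t-test, pooled-variance (Student) by default or
#' Welch. With two groups the one-way ANOVA F statistic equals t squared, so
#' this is also the canonical two-group ANOVA. Degenerate inputs follow fixed
#' conventions: both groups constant with equal means gives t = 0, p = 1;
#' both constant with different means gives p = 0 (infinite t) and a
#' degeneracy flag.
#'
#' @param x,y numeric vectors (e.g. tumor and vehicle log2 expression), each
#'   of length >= 2.
#' @param variant `"pooled"` (df = nx + ny - 2) or `"welch"`.
#' @return a list with `t`, `df`, `p`, and logical `degenerate`.
#' @examples
#' geneTTest(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))$t  # -1
#' @export
geneTTest <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  r <- rowTTest(matrix(x, 1), matrix(y, 1), variant)
  list(t = r$t[1], df = r$df[1], p = r$p[1], degenerate = r$degenerate[1])
}

# vectorized row-wise two-sample t-tests on matrices (genes x replicates)
rowTTest <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  if (variant == "pooled") {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- rep.int(nx + ny - 2, length(mx))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  t <- (mx - my) / se
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se == 0
  if (any(degenerate)) {
    same <- degenerate & mx == my
    t[same] <- 0; p[same] <- 1
    diffm <- degenerate & mx != my
    t[diffm] <- sign(mx[diffm] - my[diffm]) * Inf
    p[diffm] <- 0
    degenerate <- diffm
  }
  list(t = t, df = df, p = p, degenerate = degenerate)
}

#' Tumor-vs-vehicle comparison for one region and phase
#'
#' For every Endogenous gene, computes the log2 fold change (mean tumor minus
#' mean vehicle on the log2 scale), the two-sample t statistic and two-sided
#' p-value, then applies the three DEG filters: p-value ([filterP()]),
#' fold-change SD cutoff ([filterFcSd()]), and their conjunction
#' ([filterCombined()]). Control and housekeeping probes are excluded from
#' testing.
#'
#' @param x a fully normalized (log2-scale) [NanoCountSet-class] whose
#'   `colData` has `condition`, `phase`, `region`.
#' @param region,phase which comparison cell to test.
#' @param variant t-test variant, `"pooled"` (default) or `"welch"`.
#' @param alpha p-value cutoff passed to [filterP()].
#' @param sdK SD multiplier passed to [filterFcSd()].
#' @return a `GeneStatTable`: an [S4Vectors::DataFrame] with one row per
#'   Endogenous gene and columns `gene`, `log2fc`, `t`, `p`, `bh_q`
#'   (Benjamini-Hochberg, informational only — it never drives flags),
#'   `flag_p`, `flag_fc`, `flag_both`, `direction`, `degenerate`; comparison
#'   context (region, phase, group log2FC mean and SD, cutoffs, group sizes)
#'   is in `metadata()`.
#' @export
runComparison <- function(x, region, phase, variant = "pooled",
                          alpha = 0.05, sdK = 2) {
  assertStagePresent(x, "log2", "differential testing")
  cd <- SummarizedExperiment::colData(x)
  stopifnot(all(c("condition", "phase", "region") %in% colnames(cd)))
  sel <- cd$region == region & cd$phase == phase
  tum <- sel & cd$condition == "tumor"
  veh <- sel & cd$condition == "vehicle"
  if (sum(tum) < 2L || sum(veh) < 2L)
    stop(sprintf("need >= 2 replicates per condition for %s/%s (tumor %d, vehicle %d)",
                 region, phase, sum(tum), sum(veh)), call. = FALSE)
  endo <- probeClass(x) == "Endogenous"
  m <- SummarizedExperiment::assay(x, "counts")
  tx <- m[endo, tum, drop = FALSE]
  vx <- m[endo, veh, drop = FALSE]
  tt <- rowTTest(tx, vx, variant)
  tab <- S4Vectors::DataFrame(
    gene = rownames(tx),
    log2fc = unname(rowMeans(tx) - rowMeans(vx)),
    t = unname(tt$t), p = unname(tt$p),
    bh_q = unname(stats::p.adjust(tt$p, method = "BH")),
    degenerate = unname(tt$degenerate),
    row.names = rownames(tx))
  S4Vectors::metadata(tab) <- list(region = region, phase = phase,
                                   variant = variant,
                                   nTumor = sum(tum), nVehicle = sum(veh))
  tab <- filterP(tab, alpha = alpha)
  tab <- filterFcSd(tab, k = sdK)
  filterCombined(tab)
}

#' Flag DEGs by p-value cutoff
#'
#' Sets `flag_p = p < alpha` (strict inequality, no multiple-testing
#' correction).
#'
#' @param tab a `GeneStatTable`.
#' @param alpha significance cutoff in (0, 1); default 0.05.
#' @return the table with `flag_p` and `direction` updated.
#' @export
filterP <- function(tab, alpha = 0.05) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1))
    stop("alpha must be in (0, 1)", call. = FALSE)
  tab$flag_p <- tab$p < alpha
  S4Vectors::metadata(tab)$alpha <- alpha
  updateDirection(tab)
}

#' Flag DEGs by the fold-change SD cutoff
#'
#' Computes the mean and sample SD (denominator n - 1) of this comparison
#' group's per-gene log2 fold changes and sets
#' `flag_fc = |log2fc - mean| > k * SD` (strict). A zero SD flags no genes
#' and emits a warning.
#'
#' @param tab a `GeneStatTable` with `log2fc` populated for every gene of the
#'   comparison.
#' @param k SD multiplier; default 2.
#' @return the table with `flag_fc`, `direction`, and group `fc_mean` /
#'   `fc_sd` recorded in `metadata()`.
#' @export
filterFcSd <- function(tab, k = 2) {
  mu <- mean(tab$log2fc)
  sigma <- stats::sd(tab$log2fc)
  if (is.na(sigma) || sigma == 0) {
    warning("zero SD of log2 fold changes; no genes flagged", call. = FALSE)
    tab$flag_fc <- rep(FALSE, nrow(tab))
    sigma <- 0
  } else {
    tab$flag_fc <- abs(tab$log2fc - mu) > k * sigma
  }
  md <- S4Vectors::metadata(tab)
  md$fc_mean <- mu; md$fc_sd <- sigma; md$sd_k <- k
  S4Vectors::metadata(tab) <- md
  updateDirection(tab)
}

#' Combine the p-value and fold-change flags
#'
#' `flag_both` is the conjunction of `flag_p` and `flag_fc`.
#' @param tab a `GeneStatTable` with both flags populated.
#' @return the table with `flag_both` set.
#' @export
filterCombined <- function(tab) {
  stopifnot(!is.null(tab$flag_p), !is.null(tab$flag_fc))
  tab$flag_both <- tab$flag_p & tab$flag_fc
  updateDirection(tab)
}

updateDirection <- function(tab) {
  flagged <- Reduce(`|`, Filter(Negate(is.null),
                                list(tab$flag_p, tab$flag_fc, tab$flag_both)))
  tab$direction <- ifelse(!flagged | tab$log2fc == 0, "none",
                          ifelse(tab$log2fc > 0, "up", "down"))
  tab
}

#' Genes flagged by one filter method and direction
#'
#' @param tab a `GeneStatTable`.
#' @param method `"p"`, `"fc"`, or `"both"`.
#' @param direction `"up"` or `"down"`.
#' @return character vector of gene ids.
#' @export
flaggedGenes <- function(tab, method = c("p", "fc", "both"),
                         direction = c("up", "down")) {
  method <- match.arg(method); direction <- match.arg(direction)
  flag <- tab[[paste0("flag_", method)]]
  if (is.null(flag)) stop("filter '", method, "' has not been applied")
  dirok <- if (direction == "up") tab$log2fc > 0 else tab$log2fc < 0
  tab$gene[flag & dirok]
}
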