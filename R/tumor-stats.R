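#' Tumor volume from caliper measurements
#'
#' Standard ellipsoid approximation for subcutaneous/orthotopic tumors:
#' volume = (width^2 x length) / 2, with width and length in mm and volume in
#' mm^3. Vectorized; bilateral tumors are summed per animal by the caller.
#'
#' @param width,length caliper measurements in mm, nonnegative.
#' @return tumor volume(s) in mm^3.
#' @examples
#' tumorVolume(2, 4)  # 8
#' @export
tumorVolume <- function(width, length) {
  if (any(width < 0) || any(length < 0))
    stop("caliper measurements must be nonnegative", call. = FALSE)
  width^2 * length / 2
}

#' Two-way ANOVA over condition x phase
#'
#' Fits `values ~ A * B` and reports F, degrees of freedom and p for both
#' main effects and the interaction. Sums of squares are Type II (via
#' [car::Anova]), the appropriate default for possibly unbalanced complete
#' designs; for balanced designs Type I/II/III coincide.
#'
#' @param values numeric response (e.g. summed tumor volume, spleen mass).
#' @param factorA,factorB factor labels (e.g. condition and phase), same
#'   length as `values`.
#' @return a data.frame with rows A, B, A:B and Residuals and columns
#'   `effect`, `sum_sq`, `df`, `f`, `p`. Zero residual variance leaves p
#'   undefined (NaN) and raises a warning.
#' @export
twowayAnova <- function(values, factorA, factorB) {
  a <- factor(factorA); b <- factor(factorB)
  if (nlevels(a) < 2L || nlevels(b) < 2L)
    stop("both factors need at least 2 levels", call. = FALSE)
  if (any(table(a, b) == 0L))
    stop("empty design cell; complete two-way design required", call. = FALSE)
  fit <- stats::lm(values ~ a * b)
  if (stats::df.residual(fit) < 1L)
    stop("residual degrees of freedom < 1", call. = FALSE)
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((values - mean(values))^2)
  if (sse <= 1e-12 * max(sst, 1)) {
    # perfect fit: SS still reported, F/p undefined
    warning("zero residual variance; p-values undefined", call. = FALSE)
    aov1 <- suppressWarnings(stats::anova(fit))
    return(data.frame(effect = c("A", "B", "A:B", "Residuals"),
                      sum_sq = aov1[["Sum Sq"]], df = aov1[["Df"]],
                      f = c(rep(NaN, 3), NA), p = c(rep(NaN, 3), NA)))
  }
  aov2 <- car::Anova(fit, type = 2)
  data.frame(
    effect = c("A", "B", "A:B", "Residuals"),
    sum_sq = aov2[["Sum Sq"]],
    df = aov2[["Df"]],
    f = c(aov2[["F value"]][1:3], NA),
    p = c(aov2[["Pr(>F)"]][1:3], NA))
}
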