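# small hand-built NanoCountSet: nEndo endogenous + 1 HK + 2 POS + nNeg NEG
tinyCountSet <- function(counts, nEndo = nrow(counts) - 5L, nNeg = 3L) {
  stopifnot(nrow(counts) == nEndo + 2L + nNeg)
  NanoCountSet(counts,
               probeClass = c(rep("Endogenous", nEndo), "Housekeeping", "Housekeeping",
                              rep("Negative", nNeg)))
}

# fully annotated 6-probe x nLanes set for normalization arithmetic tests:
# 1 endogenous, 1 housekeeping, 2 positive, 2 negative
normFixture <- function(endo, hk, pos1, pos2, neg1, neg2, lanes = length(endo)) {
  m <- rbind(GeneA = endo, HK_01 = hk, POS_A = pos1, POS_B = pos2,
             NEG_01 = neg1, NEG_02 = neg2)
  colnames(m) <- sprintf("L%d", seq_len(ncol(m)))
  NanoCountSet(m, probeClass = c("Endogenous", "Housekeeping",
                                 "Positive", "Positive",
                                 "Negative", "Negative"))
}

# GeneStatTable-shaped DataFrame for filter unit tests
statTable <- function(log2fc, p = rep(0.5, length(log2fc)),
                      region = "HYP", phase = "dark") {
  tab <- S4Vectors::DataFrame(
    gene = sprintf("g%03d", seq_along(log2fc)),
    log2fc = log2fc, t = rep(0, length(log2fc)), p = p,
    bh_q = p.adjust(p, "BH"), degenerate = FALSE)
  S4Vectors::metadata(tab) <- list(region = region, phase = phase)
  tab
}

# pooled-list literal for overlap tests
pooledList <- function(genes, phase = "dark", method = "p", direction = "up") {
  structure(list(phase = phase, method = method, direction = direction,
                 genes = genes,
                 provenance = lapply(setNames(genes, genes), function(g) "HYP")),
            class = "PooledDEGList")
}
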