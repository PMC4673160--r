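spp1_incidence <- function() {
  g <- spp1_gene()
  build_incidence(g$exons, g$isoforms)
}

## exons observed on the exon array lacking an exon 6 probe set
ST21_EXONS <- c(1, 2, 3, 4, 5, 7, 8)

## noise-free expression matrix from fixed per-sample isoform abundances
## (rows = samples, cols = OPNa..OPN5), one probe set per observed exon
## plus `n_common` probe sets for each common exon
noise_free_expression <- function(abund, M, observed = ST21_EXONS,
                                  n_common = 1L) {
  exon_ids <- attr(M, "exon_ids")
  freq <- attr(M, "frequency")
  cols <- list(); map <- integer(0)
  for (e in observed) {
    i <- match(e, exon_ids)
    members <- unclass(M)[, i] == 1L
    sig <- log2(rowSums(abund[, members, drop = FALSE]))
    k <- if (freq[i] == nrow(M)) n_common else 1L
    for (j in seq_len(k)) {
      ps <- sprintf("ps_e%d_%d", e, j)
      cols[[ps]] <- sig
      map[ps] <- e
    }
  }
  values <- do.call(cbind, cols)
  rownames(values) <- rownames(abund)
  expression_matrix(values, map)
}

fixed_abundances <- function() {
  abund <- rbind(s1 = c(4, 3, 2, 1, 0.5),
                 s2 = c(8, 6, 4, 2, 1),
                 s3 = c(2, 2, 2, 2, 2))
  colnames(abund) <- c("OPNa", "OPNb", "OPNc", "OPN4", "OPN5")
  abund
}

## group abundance implied by the truth matrix for a coefficient vector
truth_group <- function(truth, coefficients) {
  as.numeric(truth[, names(coefficients), drop = FALSE] %*% coefficients)
}
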