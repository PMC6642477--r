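# Bundled reference cohort: per-gene CNV genotype frequencies (percent, one
# decimal) observed by MLPA in 123 healthy individuals of Colombian origin.
# These printed percentages are the only cohort-level record available — the
# per-sample data were not deposited — so integer counts are recovered by
# largest-remainder apportionment at n = 123 (columns then sum to 123 exactly).

REFERENCE_COHORT_N <- 123L

reference_genotype_pct <- function() {
  genes <- panel_genes()
  m <- rbind(
    `Del/Del` = c(44.7, 0,    19.5, 0,    0,   0,    0,    0,    0,    0,    0,    0,    0,    0),
    `Del/Wt`  = c(5.7,  0.8,  15.4, 0.8,  0,   0.8,  4.1,  0,    0.8,  0.8,  3.3,  0,    0.8,  0),
    `Wt/Wt`   = c(33.3, 99.2, 46.3, 99.2, 100, 99.2, 95.1, 99.2, 98.4, 99.2, 83.7, 96.7, 99.2, 99.2),
    `Dup/Wt`  = c(1.6,  0,    2.4,  0,    0,   0,    0.8,  0.8,  0.8,  0,    10.6, 3.3,  0,    0.8),
    `Dup/Dup` = c(14.6, 0,    16.3, 0,    0,   0,    0,    0,    0,    0,    2.4,  0,    0,    0)
  )
  colnames(m) <- genes
  m
}

#' Reference cohort genotype frequencies
#'
#' Per-gene CNV diplotype fractions (rows Del/Del, Del/Wt, Wt/Wt, Dup/Wt,
#' Dup/Dup; columns the 14 panel genes) observed in a reference cohort of 123
#' healthy individuals of Colombian origin genotyped with the same MLPA panel.
#' Fractions are the printed one-decimal percentages divided by 100, so a
#' column may sum to 0.999 or 1.001; [reference_genotype_counts()] recovers
#' consistent integer counts.
#'
#' @return 5 x 14 numeric matrix of fractions.
#' @export
reference_genotype_freqs <- function() {
  reference_genotype_pct() / 100
}

#' Reference cohort genotype counts
#'
#' Integer genotype counts reconstructed from the printed reference-cohort
#' percentages by largest-remainder apportionment at n = 123. Every column
#' sums to 123, and every count sits within half a rounding unit of its
#' printed percentage.
#'
#' @return 5 x 14 integer matrix of counts.
#' @examples
#' reference_genotype_counts()[, "GSTM1"]
#' @export
reference_genotype_counts <- function() {
  f <- reference_genotype_freqs()
  counts <- apply(f, 2, largest_remainder_counts, n = REFERENCE_COHORT_N)
  rownames(counts) <- rownames(f)
  counts
}

#' Reference cohort allele frequencies
#'
#' Deletion and duplication allele fractions per gene, derived from the
#' reconstructed reference-cohort genotype counts by gene counting
#' (see [allele_frequencies()]). These are the generator's default study
#' conditions: simulating with them emulates a cohort like the reference one.
#'
#' @return Data frame with columns `gene`, `p_del`, `p_dup`.
#' @export
reference_allele_freqs <- function() {
  af <- allele_frequencies(genotype_freq_from_counts(reference_genotype_counts()))
  data.frame(gene = colnames(af),
             p_del = unname(af["Deletion", ]),
             p_dup = unname(af["Duplication", ]),
             stringsAsFactors = FALSE)
}
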