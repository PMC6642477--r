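# Synthetic cohort and peak-signal generator. The signal law is chosen so the
# expected dosage quotient of a target probe equals copies/2, which is the
# quantity the downstream classifier interprets.

ALLELES <- c(del = 0L, wt = 1L, dup = 2L)
GENOTYPE_LABELS <- c("Del/Del", "Del/Wt", "Wt/Wt", "Dup/Wt", "Dup/Dup")

#' Simulation configuration
#'
#' Bundles every knob of the synthetic MLPA data generator. Defaults describe
#' a well-behaved capillary run on adequate DNA: multiplicative log-normal
#' probe noise with a 5% coefficient of variation, a 10% spread in per-sample
#' global intensity, and allele frequencies taken from the bundled
#' Latin-American reference cohort (see [reference_allele_freqs()]).
#'
#' @param n_samples Number of test samples to simulate.
#' @param freqs Per-gene allele frequencies: a data frame with columns `gene`,
#'   `p_del`, `p_dup` (deletion and duplication allele fractions; the
#'   wild-type fraction is the remainder). Defaults to the bundled reference
#'   cohort frequencies over all 14 panel genes.
#' @param noise_cv Coefficient of variation of the multiplicative per-probe
#'   noise (>= 0, < 1).
#' @param sample_scale_cv Coefficient of variation of the per-sample global
#'   intensity factor (>= 0, < 1).
#' @param base_height Expected peak height, in fluorescence units, of a
#'   two-copy target in an average sample.
#' @param dna_quantity Relative input DNA quantity (1 = adequate). Q-fragment
#'   signal scales inversely with it, so low values trip the quantity QC.
#' @param p_female Probability a simulated sample is female (XX). Default
#'   0.58, the female fraction of the study population the generator emulates.
#' @param seed Integer seed; every random draw in the generator flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 123L,
                       freqs = reference_allele_freqs(),
                       noise_cv = 0.05,
                       sample_scale_cv = 0.10,
                       base_height = 1000,
                       dna_quantity = 1,
                       p_female = 0.58,
                       seed = 1L) {
  freqs <- as.data.frame(freqs)
  if (!all(c("gene", "p_del", "p_dup") %in% names(freqs)))
    stop("freqs needs columns gene, p_del, p_dup", call. = FALSE)
  if (any(freqs$p_del < 0 | freqs$p_dup < 0 | freqs$p_del + freqs$p_dup > 1))
    stop("allele frequencies must satisfy p_del, p_dup >= 0 and p_del + p_dup <= 1",
         call. = FALSE)
  if (noise_cv < 0 || noise_cv >= 1 || sample_scale_cv < 0 || sample_scale_cv >= 1)
    stop("noise_cv and sample_scale_cv must be in [0, 1)", call. = FALSE)
  if (n_samples < 1) stop("n_samples must be positive", call. = FALSE)
  if (base_height <= 0) stop("base_height must be positive", call. = FALSE)
  if (dna_quantity <= 0) stop("dna_quantity must be positive", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples), freqs = freqs,
                 noise_cv = noise_cv, sample_scale_cv = sample_scale_cv,
                 base_height = base_height, dna_quantity = dna_quantity,
                 p_female = p_female, seed = as.integer(seed)),
            class = "sim_config")
}

allele_copies <- function(allele) ALLELES[allele]

diplotype_label <- function(allele1, allele2) {
  # canonical order: del < wt < dup reported as Del/..., Dup/Wt etc.
  pair <- vapply(seq_along(allele1), function(i) {
    a <- sort(c(allele1[i], allele2[i]))  # alphabetical: del, dup, wt
    paste(a, collapse = "/")
  }, character(1))
  map <- c("del/del" = "Del/Del", "del/wt" = "Del/Wt", "wt/wt" = "Wt/Wt",
           "dup/wt" = "Dup/Wt", "dup/dup" = "Dup/Dup", "del/dup" = "Del/Dup")
  unname(map[pair])
}

new_truth <- function(df, sex = NULL) {
  df$total_copies <- allele_copies(df$allele1) + allele_copies(df$allele2)
  df$label <- diplotype_label(df$allele1, df$allele2)
  structure(df, sex = sex, class = c("mlpa_truth", "data.frame"))
}

#' Simulate a cohort of true CNV diplotypes
#'
#' Draws, independently per gene, two alleles per sample i.i.d. from the
#' (p_del, p_wt, p_dup) simplex — random mating within each gene. Genes are
#' simulated independently of each other.
#'
#' @param config A [sim_config()].
#' @return An `mlpa_truth` data frame with one row per sample x gene and
#'   columns `sample_id`, `gene`, `allele1`, `allele2`, `total_copies`,
#'   `label`. Simulated sample sexes are attached as the `sex` attribute
#'   (named character vector, `"XX"`/`"XY"`).
#' @examples
#' truth <- simulate_cohort(sim_config(n_samples = 5, seed = 42))
#' head(truth)
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  ids <- sprintf("S%04d", seq_len(n))
  rows <- lapply(seq_len(nrow(config$freqs)), function(i) {
    g <- config$freqs$gene[i]
    p <- c(config$freqs$p_del[i],
           1 - config$freqs$p_del[i] - config$freqs$p_dup[i],
           config$freqs$p_dup[i])
    a1 <- sample(c("del", "wt", "dup"), n, replace = TRUE, prob = p)
    a2 <- sample(c("del", "wt", "dup"), n, replace = TRUE, prob = p)
    data.frame(sample_id = ids, gene = g, allele1 = a1, allele2 = a2,
               stringsAsFactors = FALSE)
  })
  sex <- stats::setNames(
    ifelse(stats::runif(n) < config$p_female, "XX", "XY"), ids)
  new_truth(do.call(rbind, rows), sex = sex)
}

#' Simulate a cohort from per-gene genotype-label fractions
#'
#' Draws diplotype labels (Del/Del, Del/Wt, Wt/Wt, Dup/Wt, Dup/Dup) directly
#' from per-gene fractions, either by multinomial sampling or, with
#' `exact = TRUE`, by largest-remainder apportionment of exact integer counts
#' (no Monte-Carlo wobble — useful for reconstructing a published cohort from
#' its printed percentage table).
#'
#' @param genotype_freqs Matrix or data frame of fractions with genotype
#'   labels as row names and genes as columns (see
#'   [reference_genotype_freqs()]). Columns must each sum to 1 within `tol`
#'   (printed tables rounded to one decimal are accepted and renormalized).
#' @param n Number of samples.
#' @param seed Integer seed (ignored when `exact = TRUE`).
#' @param exact Use deterministic largest-remainder counts instead of a
#'   multinomial draw.
#' @param tol Tolerance on each column's deviation from the simplex.
#' @return An `mlpa_truth` data frame (see [simulate_cohort()]).
#' @export
simulate_from_genotype_table <- function(genotype_freqs, n, seed = 1L,
                                         exact = FALSE, tol = 0.01) {
  gf <- as.matrix(genotype_freqs)
  if (!all(rownames(gf) %in% GENOTYPE_LABELS) || is.null(rownames(gf)))
    stop("genotype_freqs row names must be among: ",
         paste(GENOTYPE_LABELS, collapse = ", "), call. = FALSE)
  if (any(gf < 0)) stop("genotype fractions must be >= 0", call. = FALSE)
  bad <- abs(colSums(gf) - 1) > tol
  if (any(bad))
    stop("genotype fractions do not sum to 1 for: ",
         paste(colnames(gf)[bad], collapse = ", "), call. = FALSE)
  n <- as.integer(n)
  ids <- sprintf("S%04d", seq_len(n))
  alleles <- list("Del/Del" = c("del", "del"), "Del/Wt" = c("del", "wt"),
                  "Wt/Wt" = c("wt", "wt"), "Dup/Wt" = c("dup", "wt"),
                  "Dup/Dup" = c("dup", "dup"))
  if (!exact) set.seed(seed)
  rows <- lapply(colnames(gf), function(g) {
    f <- gf[, g]
    if (exact) {
      counts <- largest_remainder_counts(f / sum(f), n)
      labels <- rep(rownames(gf), counts)
    } else {
      labels <- sample(rownames(gf), n, replace = TRUE, prob = f / sum(f))
    }
    data.frame(sample_id = ids, gene = g,
               allele1 = vapply(labels, function(l) alleles[[l]][1], ""),
               allele2 = vapply(labels, function(l) alleles[[l]][2], ""),
               stringsAsFactors = FALSE)
  })
  new_truth(do.call(rbind, rows))
}

#' Largest-remainder integer apportionment
#'
#' Turns fractions into integer counts summing exactly to `n`: each class gets
#' the floor of its quota `f * n`, and the remaining units go to the classes
#' with the largest fractional parts (ties broken by position, so the result
#' is deterministic).
#'
#' @param fractions Non-negative numeric vector.
#' @param n Target total.
#' @return Integer vector, same length as `fractions`, summing to `n`.
#' @export
largest_remainder_counts <- function(fractions, n) {
  stopifnot(all(fractions >= 0), n >= 0)
  quota <- fractions * n
  counts <- floor(quota)
  left <- n - sum(counts)
  if (left > 0) {
    take <- order(quota - counts, decreasing = TRUE)[seq_len(left)]
    counts[take] <- counts[take] + 1
  }
  as.integer(counts)
}

lnorm_factor <- function(k, cv) {
  if (cv == 0) return(rep(1, k))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(k, meanlog = -s^2 / 2, sdlog = s)  # unit mean
}

# nominal relative height (in units of base_height) of non-target probe kinds
Q_FRAGMENT_LEVEL <- 0.15

#' Generate an MLPA peak table from true diplotypes
#'
#' Applies the linear dosage law: a target probe's expected height is
#' `base_height * total_copies / 2`, scaled by a per-sample global intensity
#' factor and perturbed by multiplicative log-normal noise. Reference probes
#' behave as two-copy targets. Q-fragments are emitted at a low nominal level
#' that scales inversely with DNA quantity (they rise when input DNA is
#' short); D-fragments and the X-fragment at the reference level; the
#' Y-fragment at the reference level for XY samples and zero for XX. Zero-copy
#' targets emit exactly zero signal — multiplicative noise preserves the zero.
#'
#' @param truth An `mlpa_truth` from [simulate_cohort()] or
#'   [simulate_from_genotype_table()]; must cover every panel gene.
#' @param panel An `mlpa_panel`.
#' @param config The [sim_config()] controlling noise and scale. The seed used
#'   is `config$seed + 1` so peak noise is independent of the allele draw.
#' @return A data frame with columns `sample_id`, `probe_id`, `peak_height`
#'   (one row per sample x probe).
#' @export
peaks_from_truth <- function(truth, panel, config = sim_config()) {
  stopifnot(inherits(truth, "mlpa_truth"))
  validate_panel(panel)
  genes <- unique(panel$gene[panel$kind == "target"])
  missing <- setdiff(genes, unique(truth$gene))
  if (length(missing))
    stop("truth table is missing panel genes: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ids <- unique(truth$sample_id)
  sex <- attr(truth, "sex")
  if (is.null(sex)) sex <- stats::setNames(rep("XX", length(ids)), ids)
  set.seed(config$seed + 1L)
  scale <- stats::setNames(lnorm_factor(length(ids), config$sample_scale_cv), ids)

  copies <- matrix(2, nrow = length(ids), ncol = nrow(panel),
                   dimnames = list(ids, panel$probe_id))
  cn <- truth$total_copies
  idx_s <- match(truth$sample_id, ids)
  for (j in which(panel$kind == "target")) {
    sel <- truth$gene == panel$gene[j]
    copies[idx_s[sel], j] <- cn[sel]
  }
  # control fragments: expected height expressed as copy-equivalents
  copies[, panel$kind == "q_fragment"] <- 2 * Q_FRAGMENT_LEVEL / config$dna_quantity
  copies[, panel$kind == "y_fragment"] <- ifelse(sex[ids] == "XY", 2, 0)

  expected <- config$base_height * copies / 2 * scale[ids]
  noise <- matrix(lnorm_factor(length(expected), config$noise_cv),
                  nrow = nrow(expected))
  heights <- expected * noise
  data.frame(
    sample_id = rep(ids, times = nrow(panel)),
    probe_id = rep(panel$probe_id, each = length(ids)),
    peak_height = as.vector(heights),
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete MLPA run (test cohort plus reference samples)
#'
#' Convenience wrapper producing everything [mlpa_call()] needs: a test cohort
#' drawn from `config`, a set of wild-type-everywhere reference samples
#' subject to the same noise model, and their combined peak table.
#'
#' @param config A [sim_config()] for the test cohort.
#' @param panel An `mlpa_panel`.
#' @param n_reference_samples Number of all-wild-type reference samples.
#' @return A list with elements `peaks` (combined peak table), `truth` (test
#'   cohort truth), `reference_samples` (character vector of reference sample
#'   ids).
#' @export
simulate_mlpa_run <- function(config = sim_config(), panel = default_panel(),
                              n_reference_samples = 12L) {
  truth <- simulate_cohort(config)
  genes <- unique(config$freqs$gene)
  ref_cfg <- config
  ref_cfg$n_samples <- as.integer(n_reference_samples)
  ref_cfg$freqs <- data.frame(gene = genes, p_del = 0, p_dup = 0)
  ref_cfg$seed <- config$seed + 1000003L
  ref_truth <- simulate_cohort(ref_cfg)
  ref_ids <- sprintf("REFSAMPLE%03d", seq_len(n_reference_samples))
  old_ids <- unique(ref_truth$sample_id)
  ref_truth$sample_id <- ref_ids[match(ref_truth$sample_id, old_ids)]
  sex <- attr(ref_truth, "sex")
  names(sex) <- ref_ids
  attr(ref_truth, "sex") <- sex
  peaks <- rbind(peaks_from_truth(truth, panel, config),
                 peaks_from_truth(ref_truth, panel, ref_cfg))
  list(peaks = peaks, truth = truth, reference_samples = ref_ids)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("MLPA simulation config: %d samples, %d genes, ",
                     "noise CV %.3f, sample-scale CV %.3f,\n",
                     "  base height %g, DNA quantity %g, seed %d\n"),
              x$n_samples, nrow(x$freqs), x$noise_cv, x$sample_scale_cv,
              x$base_height, x$dna_quantity, x$seed))
  invisible(x)
}
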