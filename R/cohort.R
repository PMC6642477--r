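# Cohort-level population genetics summaries over gene-level CNV calls.

# accept either an mlpa_calls object or a bare gene_calls data frame
as_gene_calls <- function(x) {
  if (inherits(x, "mlpa_calls")) return(x$gene_calls)
  df <- as.data.frame(x)
  need <- c("sample_id", "gene", "genotype_label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("gene calls need columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df
}

# half-up rounding at `digits` decimals, the convention of printed frequency
# tables (base round() is half-to-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Per-gene genotype frequencies
#'
#' Tabulates the five diplotype labels per gene over the called samples.
#' Unknown (ambiguous or discordant) calls are excluded from both numerator
#' and denominator; exclusion counts are reported alongside.
#'
#' @param x An `mlpa_calls` object or a data frame with columns `sample_id`,
#'   `gene`, `genotype_label`.
#' @return A `genotype_freq_table`: list with `fractions` (5 x genes matrix of
#'   genotype fractions, rows Del/Del, Del/Wt, Wt/Wt, Dup/Wt, Dup/Dup),
#'   `n_called` and `n_unknown` (named integer vectors per gene).
#' @export
genotype_frequencies <- function(x) {
  gc <- as_gene_calls(x)
  genes <- unique(gc$gene)
  called <- gc[gc$genotype_label %in% GENOTYPE_LABELS, ]
  n_called <- table(factor(called$gene, levels = genes))
  n_unknown <- table(factor(gc$gene[!gc$genotype_label %in% GENOTYPE_LABELS],
                            levels = genes))
  empty <- names(n_called)[n_called == 0]
  if (length(empty)) {
    warning("gene(s) with zero called samples omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
    genes <- setdiff(genes, empty)
  }
  counts <- table(factor(called$genotype_label, levels = GENOTYPE_LABELS),
                  factor(called$gene, levels = genes))
  fractions <- sweep(unclass(counts), 2, as.numeric(n_called[genes]), "/")
  new_genotype_freq_table(fractions,
                          n_called = stats::setNames(as.integer(n_called[genes]), genes),
                          n_unknown = stats::setNames(as.integer(n_unknown[genes]), genes))
}

new_genotype_freq_table <- function(fractions, n_called, n_unknown = NULL) {
  fractions <- as.matrix(fractions)
  stopifnot(setequal(rownames(fractions), GENOTYPE_LABELS))
  fractions <- fractions[GENOTYPE_LABELS, , drop = FALSE]
  bad <- abs(colSums(fractions) - 1) > 1e-9
  if (any(bad))
    stop("genotype fractions must sum to 1 per gene; violated for: ",
         paste(colnames(fractions)[bad], collapse = ", "), call. = FALSE)
  if (is.null(n_unknown))
    n_unknown <- stats::setNames(rep(0L, ncol(fractions)), colnames(fractions))
  structure(list(fractions = fractions, n_called = n_called,
                 n_unknown = n_unknown),
            class = "genotype_freq_table")
}

#' Build a genotype frequency table from integer genotype counts
#'
#' @param counts 5 x genes integer matrix (rows Del/Del, Del/Wt, Wt/Wt,
#'   Dup/Wt, Dup/Dup).
#' @return A `genotype_freq_table`.
#' @export
genotype_freq_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  n <- colSums(counts)
  new_genotype_freq_table(sweep(counts, 2, n, "/"),
                          n_called = stats::setNames(as.integer(n), colnames(counts)))
}

#' @export
print.genotype_freq_table <- function(x, ...) {
  cat("Genotype frequencies (%) over",
      paste(range(x$n_called), collapse = "-"), "called samples per gene\n")
  print(round_half_up(100 * x$fractions, 1))
  if (any(x$n_unknown > 0))
    cat("Unknown calls excluded:",
        paste(sprintf("%s=%d", names(x$n_unknown)[x$n_unknown > 0],
                      x$n_unknown[x$n_unknown > 0]), collapse = " "), "\n")
  invisible(x)
}

#' Allele frequencies from genotype frequencies
#'
#' Standard gene-counting estimate for a three-allele (deletion / wild-type /
#' duplication) locus: each homozygote contributes two copies of its allele,
#' each heterozygote one, so
#' `p_del = f(Del/Del) + f(Del/Wt)/2`, `p_dup = f(Dup/Dup) + f(Dup/Wt)/2`,
#' and `p_wt` is the remainder.
#'
#' @param gt A `genotype_freq_table` (or an `mlpa_calls` object, summarized
#'   first).
#' @return Matrix with rows `Deletion`, `Duplication`, `No CNV` and one column
#'   per gene; columns sum to 1.
#' @examples
#' counts <- matrix(c(55, 7, 41, 2, 18), ncol = 1,
#'                  dimnames = list(c("Del/Del", "Del/Wt", "Wt/Wt",
#'                                    "Dup/Wt", "Dup/Dup"), "GSTM1"))
#' allele_frequencies(genotype_freq_from_counts(counts))
#' @export
allele_frequencies <- function(gt) {
  if (inherits(gt, "mlpa_calls")) gt <- genotype_frequencies(gt)
  stopifnot(inherits(gt, "genotype_freq_table"))
  f <- gt$fractions
  p_del <- as.vector(f["Del/Del", , drop = FALSE]) +
    as.vector(f["Del/Wt", , drop = FALSE]) / 2
  p_dup <- as.vector(f["Dup/Dup", , drop = FALSE]) +
    as.vector(f["Dup/Wt", , drop = FALSE]) / 2
  out <- rbind(Deletion = p_del, Duplication = p_dup,
               `No CNV` = 1 - p_del - p_dup)
  colnames(out) <- colnames(f)
  out
}

# the 13 class-set -> category rules; category 7 ("hetero and homozygous
# deletions") is textually indistinguishable from 4 and therefore unreachable
CATEGORY_RULES <- list(
  `1` = character(0),
  `2` = "HOM_DEL",
  `3` = "HET_DEL",
  `4` = c("HET_DEL", "HOM_DEL"),
  `5` = "HOM_DUP",
  `6` = "HET_DUP",
  `8` = c("HET_DUP", "HOM_DEL"),
  `9` = c("HOM_DUP", "HET_DEL"),
  `10` = c("HOM_DUP", "HOM_DEL"),
  `11` = c("HOM_DUP", "HET_DUP"),
  `12` = c("HET_DUP", "HOM_DEL", "HET_DEL"),
  `13` = c("HET_DEL", "HET_DUP", "HOM_DUP"),
  `14` = c("HET_DUP", "HOM_DUP", "HOM_DEL")
)

#' Mutational-status category of one individual
#'
#' Maps the set of non-normal gene-level copy-number classes present in a
#' sample to the 14-category mutational-status taxonomy (category 1 = wild
#' type for all genes). Class sets with no defined category — e.g. a
#' heterozygous deletion together with a heterozygous duplication and nothing
#' else — return category 0 (unclassified) with the set recorded. Category 7
#' is unreachable: its printed definition cannot be distinguished from
#' category 4's.
#'
#' @param class_set Character vector (treated as a set) drawn from HET_DEL,
#'   HOM_DEL, HET_DUP, HOM_DUP.
#' @return A list: `category` (integer, 0-14), `class_set` (sorted unique
#'   classes).
#' @examples
#' categorize_individual(character(0))              # 1: wild type
#' categorize_individual(c("HOM_DUP", "HOM_DEL"))   # 10
#' @export
categorize_individual <- function(class_set) {
  class_set <- sort(unique(class_set))
  bad <- setdiff(class_set, c("HET_DEL", "HOM_DEL", "HET_DUP", "HOM_DUP"))
  if (length(bad))
    stop("invalid class in set: ", paste(bad, collapse = ", "), call. = FALSE)
  for (cat_id in names(CATEGORY_RULES))
    if (setequal(class_set, CATEGORY_RULES[[cat_id]]))
      return(list(category = as.integer(cat_id), class_set = class_set))
  list(category = 0L, class_set = class_set)
}

#' Categorize every sample of a cohort by mutational status
#'
#' @param x An `mlpa_calls` object or gene-calls data frame (needs a
#'   `cnv_class` column).
#' @return A list: `assignments` (data frame `sample_id`, `category`,
#'   `class_set` as comma-joined string) and `category_freq` (named fraction
#'   vector over categories present).
#' @export
categorize_samples <- function(x) {
  gc <- if (inherits(x, "mlpa_calls")) x$gene_calls else as.data.frame(x)
  if (!"cnv_class" %in% names(gc))
    stop("gene calls need a cnv_class column", call. = FALSE)
  per_sample <- split(gc$cnv_class, gc$sample_id)
  rows <- lapply(names(per_sample), function(id) {
    cl <- per_sample[[id]]
    cl <- cl[cl %in% c("HET_DEL", "HOM_DEL", "HET_DUP", "HOM_DUP")]
    res <- categorize_individual(cl)
    data.frame(sample_id = id, category = res$category,
               class_set = paste(res$class_set, collapse = ","),
               stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, rows)
  freq <- table(assignments$category) / nrow(assignments)
  list(assignments = assignments,
       category_freq = stats::setNames(as.numeric(freq), names(freq)))
}

#' Four-group carrier classification
#'
#' Partitions samples by the type of CNV they carry anywhere in the panel:
#' only deletions, only duplications, both, or none. Samples whose genes are
#' all Unknown carry no information and are excluded (reported in
#' `excluded`).
#'
#' @param x An `mlpa_calls` object or gene-calls data frame.
#' @return List: `groups` (data frame `sample_id`, `group`), `group_freq`
#'   (named fractions over deletions_only / duplications_only / both / none),
#'   `excluded` (character vector of sample ids).
#' @export
carrier_groups <- function(x) {
  gc <- if (inherits(x, "mlpa_calls")) x$gene_calls else as.data.frame(x)
  if (!"cnv_class" %in% names(gc))
    stop("gene calls need a cnv_class column", call. = FALSE)
  per_sample <- split(gc$cnv_class, gc$sample_id)
  called_any <- vapply(per_sample, function(cl) any(cl %in% CN_CLASSES[1:5]),
                       logical(1))
  excluded <- names(per_sample)[!called_any]
  per_sample <- per_sample[called_any]
  group <- vapply(per_sample, function(cl) {
    has_del <- any(cl %in% c("HET_DEL", "HOM_DEL"))
    has_dup <- any(cl %in% c("HET_DUP", "HOM_DUP"))
    if (has_del && has_dup) "both"
    else if (has_del) "deletions_only"
    else if (has_dup) "duplications_only"
    else "none"
  }, character(1))
  levels <- c("deletions_only", "duplications_only", "both", "none")
  freq <- table(factor(group, levels = levels)) / length(group)
  list(groups = data.frame(sample_id = names(per_sample), group = unname(group),
                           stringsAsFactors = FALSE),
       group_freq = stats::setNames(as.numeric(freq), levels),
       excluded = excluded)
}

#' Per-gene CNV census
#'
#' For each gene, whether any deletion or duplication genotype occurs in the
#' cohort, and summary counts: genes with both CNV types, genes with exactly
#' one type, genes with any CNV. Percentages are over the genes in the table,
#' at one decimal.
#'
#' @param gt A `genotype_freq_table` (or `mlpa_calls`).
#' @return List: `per_gene` (data frame `gene`, `del_present`, `dup_present`),
#'   `n_genes`, `n_any`, `n_both`, `n_one_type`, and the corresponding
#'   percentages `pct_any`, `pct_both`, `pct_one_type`.
#' @export
gene_cnv_census <- function(gt) {
  if (inherits(gt, "mlpa_calls")) gt <- genotype_frequencies(gt)
  stopifnot(inherits(gt, "genotype_freq_table"))
  f <- gt$fractions
  del_present <- (f["Del/Del", ] + f["Del/Wt", ]) > 0
  dup_present <- (f["Dup/Dup", ] + f["Dup/Wt", ]) > 0
  n_genes <- ncol(f)
  n_both <- sum(del_present & dup_present)
  n_one <- sum(xor(del_present, dup_present))
  n_any <- sum(del_present | dup_present)
  list(per_gene = data.frame(gene = colnames(f),
                             del_present = unname(del_present),
                             dup_present = unname(dup_present),
                             stringsAsFactors = FALSE),
       n_genes = n_genes, n_any = n_any, n_both = n_both, n_one_type = n_one,
       pct_any = round_half_up(100 * n_any / n_genes, 1),
       pct_both = round_half_up(100 * n_both / n_genes, 1),
       pct_one_type = round_half_up(100 * n_one / n_genes, 1))
}

#' Sample size for estimating a proportion
#'
#' Cochran's formula `n0 = z^2 p (1 - p) / e^2`, rounded up, with the optional
#' finite population correction `n = n0 / (1 + (n0 - 1) / N)`.
#'
#' @param p Anticipated proportion, in (0, 1).
#' @param e Margin of error, > 0.
#' @param z Confidence quantile (default 1.96, the two-sided 95% level).
#' @param N Optional finite population size.
#' @return Integer sample size.
#' @examples
#' sample_size(p = 0.03, e = 0.03)  # 125
#' @export
sample_size <- function(p, e, z = 1.96, N = NULL) {
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)", call. = FALSE)
  if (e <= 0) stop("e must be > 0", call. = FALSE)
  n0 <- ceiling(z^2 * p * (1 - p) / e^2)
  if (is.null(N)) return(as.integer(n0))
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  as.integer(ceiling(n0 / (1 + (n0 - 1) / N)))
}
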