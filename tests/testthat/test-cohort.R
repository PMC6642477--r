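test_that("genotype frequencies tabulate called samples and exclude Unknown", {
  calls <- data.frame(
    sample_id = sprintf("S%02d", 1:6),
    gene = "GSTM1",
    genotype_label = c("Del/Del", "Del/Del", "Wt/Wt", "Dup/Wt", "Unknown",
                       "Wt/Wt"),
    stringsAsFactors = FALSE
  )
  gt <- genotype_frequencies(calls)
  expect_equal(unname(gt$n_called["GSTM1"]), 5L)
  expect_equal(unname(gt$n_unknown["GSTM1"]), 1L)
  expect_equal(unname(gt$fractions[, "GSTM1"]),
               c(2, 0, 2, 1, 0) / 5)
  expect_equal(sum(gt$fractions[, "GSTM1"]), 1)
})

test_that("reference-cohort reconstruction reproduces the printed genotype table", {
  counts <- reference_genotype_counts()
  expect_equal(unname(colSums(counts)), rep(123, 14))
  expect_equal(unname(counts[, "GSTM1"]), c(55L, 7L, 41L, 2L, 18L))
  expect_equal(unname(counts[, "GSTT1"]), c(24L, 19L, 57L, 3L, 20L))
  expect_equal(unname(counts[, "CYP2D6"]), c(0L, 4L, 103L, 13L, 3L))
  # fractions agree with every printed percentage at one decimal
  gt <- genotype_freq_from_counts(counts)
  pct <- round(100 * gt$fractions, 1)
  printed <- 100 * reference_genotype_freqs()
  expect_true(all(abs(pct - printed) <= 0.05 + 1e-9))
})

test_that("allele frequencies follow gene counting and sum to one", {
  counts <- matrix(c(55, 7, 41, 2, 18), ncol = 1,
                   dimnames = list(c("Del/Del", "Del/Wt", "Wt/Wt",
                                     "Dup/Wt", "Dup/Dup"), "GSTM1"))
  af <- allele_frequencies(genotype_freq_from_counts(counts))
  expect_equal(round(100 * af["Deletion", "GSTM1"], 1), 47.6)
  expect_equal(round(100 * af["Duplication", "GSTM1"], 1), 15.4)
  expect_equal(round(100 * af["No CNV", "GSTM1"], 1), 37.0)
  expect_equal(sum(af[, "GSTM1"]), 1)

  all_wt <- matrix(c(0, 0, 9, 0, 0), ncol = 1,
                   dimnames = list(rownames(counts), "G"))
  expect_equal(unname(allele_frequencies(genotype_freq_from_counts(all_wt))[, "G"]),
               c(0, 0, 1))
})

test_that("the full allele-frequency table matches the published one at 1 dp", {
  published <- rbind(
    Deletion    = c(47.6, 0.4, 27.2, 0.4, 0, 0.4, 2.0, 0, 0.4, 0.4, 1.6, 0, 0.4, 0),
    Duplication = c(15.4, 0, 17.5, 0, 0, 0, 0.4, 0.4, 0.4, 0, 7.7, 1.6, 0, 0.4),
    `No CNV`    = c(37.0, 99.6, 55.3, 99.6, 100, 99.6, 97.6, 99.6, 99.2, 99.6,
                    90.7, 98.4, 99.6, 99.6)
  )
  colnames(published) <- panel_genes()
  af <- 100 * allele_frequencies(genotype_freq_from_counts(reference_genotype_counts()))
  expect_true(all(abs(round(af, 1) - published) <= 0.05 + 1e-9))
})

test_that("mutational-status categories follow the 14-category taxonomy", {
  expect_equal(categorize_individual(character(0))$category, 1L)
  expect_equal(categorize_individual("HOM_DEL")$category, 2L)
  expect_equal(categorize_individual("HET_DEL")$category, 3L)
  expect_equal(categorize_individual(c("HET_DEL", "HOM_DEL"))$category, 4L)
  expect_equal(categorize_individual("HOM_DUP")$category, 5L)
  expect_equal(categorize_individual("HET_DUP")$category, 6L)
  expect_equal(categorize_individual(c("HET_DUP", "HOM_DEL"))$category, 8L)
  expect_equal(categorize_individual(c("HOM_DUP", "HET_DEL"))$category, 9L)
  expect_equal(categorize_individual(c("HOM_DUP", "HOM_DEL"))$category, 10L)
  expect_equal(categorize_individual(c("HOM_DUP", "HET_DUP"))$category, 11L)
  expect_equal(categorize_individual(c("HET_DUP", "HOM_DEL", "HET_DEL"))$category, 12L)
  expect_equal(categorize_individual(c("HET_DEL", "HET_DUP", "HOM_DUP"))$category, 13L)
  expect_equal(categorize_individual(c("HET_DUP", "HOM_DUP", "HOM_DEL"))$category, 14L)
  # duplicates and order never matter
  expect_equal(categorize_individual(c("HOM_DEL", "HOM_DUP", "HOM_DEL"))$category, 10L)
  # sets without a printed definition fall into category 0 with the set kept
  unclassified <- categorize_individual(c("HET_DEL", "HET_DUP"))
  expect_equal(unclassified$category, 0L)
  expect_equal(unclassified$class_set, c("HET_DEL", "HET_DUP"))
  expect_equal(categorize_individual(c("HOM_DUP", "HOM_DEL", "HET_DEL"))$category, 0L)
  expect_equal(categorize_individual(c("HET_DEL", "HOM_DEL", "HET_DUP",
                                       "HOM_DUP"))$category, 0L)
  expect_error(categorize_individual("NORMAL"), "invalid class")
})

test_that("category assignment partitions every enumerable class set", {
  classes <- c("HET_DEL", "HOM_DEL", "HET_DUP", "HOM_DUP")
  all_sets <- unlist(lapply(0:4, function(k)
    combn(classes, k, simplify = FALSE)), recursive = FALSE)
  cats <- vapply(all_sets, function(s) categorize_individual(s)$category,
                 integer(1))
  expect_length(cats, 16)
  expect_setequal(cats[cats > 0], c(1:6, 8:14))  # category 7 is unreachable
  expect_equal(sum(cats == 0), 3)
})

test_that("carrier groups partition the cohort", {
  calls <- data.frame(
    sample_id = rep(c("A", "B", "C", "D", "E"), each = 2),
    gene = rep(c("G1", "G2"), 5),
    cnv_class = c("HET_DEL", "NORMAL",      # A: deletions only
                  "NORMAL", "HOM_DUP",      # B: duplications only
                  "HOM_DUP", "HOM_DEL",     # C: both
                  "NORMAL", "NORMAL",       # D: none
                  "AMBIGUOUS", "AMBIGUOUS"),# E: uninformative
    stringsAsFactors = FALSE
  )
  calls$genotype_label <- genotype_label(calls$cnv_class)
  grp <- carrier_groups(calls)
  expect_equal(setNames(grp$groups$group, grp$groups$sample_id),
               c(A = "deletions_only", B = "duplications_only",
                 C = "both", D = "none"))
  expect_equal(grp$excluded, "E")
  expect_equal(sum(grp$group_freq), 1)
})

test_that("gene census counts deletion/duplication presence per gene", {
  gt <- genotype_freq_from_counts(reference_genotype_counts())
  cen <- gene_cnv_census(gt)
  expect_equal(cen$n_genes, 14)
  expect_equal(cen$n_any, 13)
  expect_equal(cen$pct_any, 92.9)
  expect_equal(cen$n_both, 5)
  expect_equal(cen$n_one_type, 8)
  both <- cen$per_gene$gene[cen$per_gene$del_present & cen$per_gene$dup_present]
  expect_setequal(both, c("GSTM1", "GSTT1", "CYP2A6", "CYP2C9", "CYP2D6"))
  none <- cen$per_gene$gene[!cen$per_gene$del_present & !cen$per_gene$dup_present]
  expect_equal(none, "CYP1A2")

  wt_only <- matrix(c(0, 0, 10, 0, 0), ncol = 1,
                    dimnames = list(rownames(gt$fractions), "G"))
  expect_equal(gene_cnv_census(genotype_freq_from_counts(wt_only))$n_any, 0)
})

test_that("sample-size calculation matches Cochran's formula with FPC", {
  expect_identical(sample_size(p = 0.03, e = 0.03), 125L)
  expect_identical(sample_size(p = 0.5, e = 0.05), 385L)  # ceil(384.16)
  # the finite population correction never increases n
  n0 <- sample_size(p = 0.03, e = 0.03)
  for (N in c(200, 1000, 1e6))
    expect_lte(sample_size(p = 0.03, e = 0.03, N = N), n0)
  expect_identical(sample_size(p = 0.03, e = 0.03, N = 1e9), n0)
  expect_error(sample_size(p = 0, e = 0.03), "p must be")
  expect_error(sample_size(p = 0.03, e = 0), "e must be")
})

test_that("frequencies are invariant to sample order", {
  cfg <- sim_config(n_samples = 40, seed = 13)
  res <- run_pipeline(cfg, n_reference_samples = 6)
  gt1 <- genotype_frequencies(res$calls)
  shuffled <- res$calls$gene_calls[sample(nrow(res$calls$gene_calls)), ]
  gt2 <- genotype_frequencies(shuffled)
  expect_equal(gt1$fractions[, sort(colnames(gt1$fractions))],
               gt2$fractions[, sort(colnames(gt2$fractions))])
})
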