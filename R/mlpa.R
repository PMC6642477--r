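# End-to-end calling: peaks -> QC -> relative signals -> dosage quotients ->
# probe classes -> gene-level diplotypes, wrapped in one classed object.

#' Call CNV genotypes from an MLPA peak table
#'
#' Runs the full dosage-quotient pipeline: control-fragment QC, intra-sample
#' normalization against reference probes, inter-sample normalization against
#' the designated reference samples, per-probe copy-number classification, and
#' exon-to-gene aggregation into CNV diplotype calls.
#'
#' @param peaks Peak table: data frame with columns `sample_id`, `probe_id`,
#'   `peak_height` (one row per sample x panel probe).
#' @param panel An `mlpa_panel` (default [default_panel()]).
#' @param reference_samples Character vector of sample ids assumed two-copy at
#'   every target probe. With `NULL`, the whole cohort is the reference set
#'   (population-median normalization, with a warning).
#' @param thresholds A [dq_thresholds()].
#' @param qc A [qc_thresholds()].
#' @param intra_stat,inter_stat Summary statistics for the two normalization
#'   stages (see [intra_sample_normalize()], [inter_sample_normalize()]).
#' @return An object of class `mlpa_calls`: a list with components
#'   \describe{
#'     \item{gene_calls}{data frame `sample_id`, `gene`, `cnv_class`,
#'       `genotype_label`, `discordant`, `n_probes_called` for every test
#'       (non-reference) sample}
#'     \item{dq}{long data frame of per-probe dosage quotients}
#'     \item{probe_classes}{long data frame of per-probe classes at target
#'       probes}
#'     \item{qc}{per-sample QC report}
#'     \item{dropped_samples}{samples excluded during normalization}
#'     \item{panel, thresholds, reference_samples}{the inputs used}
#'   }
#' @examples
#' run <- simulate_mlpa_run(sim_config(n_samples = 8, seed = 7))
#' calls <- mlpa_call(run$peaks, reference_samples = run$reference_samples)
#' head(calls$gene_calls)
#' @export
mlpa_call <- function(peaks, panel = default_panel(),
                      reference_samples = NULL,
                      thresholds = dq_thresholds(),
                      qc = qc_thresholds(),
                      intra_stat = c("median", "mean"),
                      inter_stat = c("mean", "median")) {
  intra_stat <- match.arg(intra_stat)
  inter_stat <- match.arg(inter_stat)
  validate_peaks(peaks, panel)
  qc_report <- qc_sample(peaks, panel, qc)
  rel <- intra_sample_normalize(peaks, panel, stat = intra_stat)
  dropped <- attr(rel, "dropped_samples")
  if (!is.null(reference_samples)) {
    usable_refs <- setdiff(reference_samples, dropped$sample_id)
    if (!length(usable_refs))
      stop("all reference samples were excluded during normalization",
           call. = FALSE)
    if (length(usable_refs) < length(reference_samples))
      warning("reference sample(s) excluded during normalization: ",
              paste(setdiff(reference_samples, usable_refs), collapse = ", "),
              call. = FALSE)
  } else usable_refs <- NULL
  # dosage quotients are meaningful for assay probes only; control fragments
  # stay at the QC stage (a reference cohort of one sex would otherwise make
  # the Y-fragment look uncallable)
  assay <- panel$probe_id[panel$kind %in% c("target", "reference")]
  dq <- inter_sample_normalize(rel[rel$probe_id %in% assay, ], usable_refs,
                               stat = inter_stat)

  tgt <- panel[panel$kind == "target", c("probe_id", "gene")]
  pc <- dq[dq$probe_id %in% tgt$probe_id, ]
  pc$gene <- tgt$gene[match(pc$probe_id, tgt$probe_id)]
  pc$class <- classify_dq(pc$dq, thresholds)

  test_ids <- setdiff(unique(pc$sample_id), usable_refs)
  genes <- unique(tgt$gene)
  rows <- vector("list", length(test_ids) * length(genes))
  k <- 0L
  split_gene <- split(pc[pc$sample_id %in% test_ids, ],
                      list(pc$gene[pc$sample_id %in% test_ids],
                           pc$sample_id[pc$sample_id %in% test_ids]),
                      sep = "\r")
  for (nm in names(split_gene)) {
    part <- split_gene[[nm]]
    if (!nrow(part)) next
    cl <- call_gene(part$class)
    k <- k + 1L
    rows[[k]] <- data.frame(sample_id = part$sample_id[1],
                            gene = part$gene[1],
                            cnv_class = cl$cnv_class,
                            genotype_label = cl$genotype_label,
                            discordant = cl$discordant,
                            n_probes_called = cl$n_probes_called,
                            stringsAsFactors = FALSE)
  }
  gene_calls <- do.call(rbind, rows[seq_len(k)])
  gene_calls <- gene_calls[order(match(gene_calls$sample_id, test_ids),
                                 match(gene_calls$gene, genes)), ]
  rownames(gene_calls) <- NULL
  structure(list(gene_calls = gene_calls, dq = dq, probe_classes = pc,
                 qc = qc_report, dropped_samples = dropped, panel = panel,
                 thresholds = thresholds,
                 reference_samples = usable_refs),
            class = "mlpa_calls")
}

#' @export
print.mlpa_calls <- function(x, ...) {
  gc <- x$gene_calls
  cat(sprintf("MLPA CNV calls: %d samples x %d genes (panel '%s')\n",
              length(unique(gc$sample_id)), length(unique(gc$gene)),
              attr(x$panel, "name")))
  if (length(x$reference_samples))
    cat(sprintf("  normalized against %d reference samples\n",
                length(x$reference_samples)))
  if (nrow(x$dropped_samples))
    cat(sprintf("  %d sample(s) excluded during normalization\n",
                nrow(x$dropped_samples)))
  tab <- table(factor(gc$genotype_label,
                      levels = c(GENOTYPE_LABELS, "Unknown")))
  cat("  gene-level genotypes: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Summarize an MLPA calling run at cohort level
#'
#' Computes the standard population reports from the gene-level calls:
#' genotype and allele frequency tables, the mutational-status category of
#' every sample, the four carrier groups, and the per-gene CNV census.
#'
#' @param object An `mlpa_calls` object.
#' @param ... Unused.
#' @return A `summary.mlpa_calls` list with components `genotype_freq`,
#'   `allele_freq`, `categories`, `category_freq`, `carrier_groups`,
#'   `group_freq`, `census`, `qc`.
#' @export
summary.mlpa_calls <- function(object, ...) {
  gt <- genotype_frequencies(object)
  cats <- categorize_samples(object)
  grp <- carrier_groups(object)
  structure(list(genotype_freq = gt,
                 allele_freq = allele_frequencies(gt),
                 categories = cats$assignments,
                 category_freq = cats$category_freq,
                 carrier_groups = grp$groups,
                 group_freq = grp$group_freq,
                 census = gene_cnv_census(gt),
                 qc = object$qc),
            class = "summary.mlpa_calls")
}

#' @export
print.summary.mlpa_calls <- function(x, ...) {
  cat("Cohort summary of MLPA CNV calls\n\n")
  cat("Allele frequencies (%):\n")
  print(round(100 * x$allele_freq, 1))
  cat("\nCarrier groups (%):\n")
  print(round(100 * x$group_freq, 1))
  cat("\nGene census: ", x$census$n_any, "/", x$census$n_genes,
      " genes with CNVs (", x$census$pct_any, "%), ",
      x$census$n_both, " with both deletions and duplications (",
      x$census$pct_both, "%), ", x$census$n_one_type,
      " with a single type (", x$census$pct_one_type, "%)\n", sep = "")
  invisible(x)
}

#' Predicted metabolizer phenotypes for all calls
#'
#' @param object An `mlpa_calls` object.
#' @param ... Unused.
#' @return Data frame `sample_id`, `gene`, `genotype_label`,
#'   `total_active_copies`, `predicted`; genes with Unknown genotype get `NA`
#'   predictions. Carries the copy-number-only caveat as a `note` attribute.
#' @export
predict.mlpa_calls <- function(object, ...) {
  gc <- object$gene_calls
  ph <- predict_phenotype(gc$genotype_label)
  out <- cbind(gc[, c("sample_id", "gene")], ph)
  rownames(out) <- NULL
  attr(out, "note") <- attr(ph, "note")
  out
}

#' Plot dosage quotients of an MLPA run
#'
#' Strip chart of per-probe dosage quotients across target probes, with the
#' called copy-number class intervals shaded. One point per sample per probe.
#'
#' @param x An `mlpa_calls` object.
#' @param samples Optional character vector restricting the plot to specific
#'   samples.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mlpa_calls <- function(x, samples = NULL, ...) {
  pc <- x$probe_classes
  if (!is.null(samples)) pc <- pc[pc$sample_id %in% samples, ]
  probes <- unique(pc$probe_id)
  xi <- match(pc$probe_id, probes)
  t <- x$thresholds
  graphics::plot(xi, pc$dq, xaxt = "n", xlab = "", ylab = "dosage quotient",
                 ylim = c(0, max(2.3, pc$dq, na.rm = TRUE)), pch = 16,
                 cex = 0.6, col = "grey20", ...)
  bands <- rbind(c(0, t$hom_del_eps), t$het_del, t$normal, t$het_dup, t$hom_dup)
  for (i in seq_len(nrow(bands)))
    graphics::rect(0.5, bands[i, 1], length(probes) + 0.5, bands[i, 2],
                   col = grDevices::adjustcolor("steelblue", 0.15),
                   border = NA)
  graphics::axis(1, at = seq_along(probes), labels = probes, las = 2,
                 cex.axis = 0.5)
  invisible(x)
}
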