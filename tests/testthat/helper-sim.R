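# shared fixtures built in code

# run the full pipeline on a simulated cohort and join calls with truth
run_pipeline <- function(config, panel = default_panel(),
                         n_reference_samples = 12L) {
  run <- simulate_mlpa_run(config, panel, n_reference_samples)
  calls <- mlpa_call(run$peaks, panel,
                     reference_samples = run$reference_samples)
  gc <- calls$gene_calls
  m <- match(paste(gc$sample_id, gc$gene),
             paste(run$truth$sample_id, run$truth$gene))
  gc$true_label <- run$truth$label[m]
  gc$true_copies <- run$truth$total_copies[m]
  list(calls = calls, gene_calls = gc, run = run)
}

# expected pipeline label: the method cannot distinguish Del/Dup from Wt/Wt
expected_label <- function(true_label) {
  ifelse(true_label == "Del/Dup", "Wt/Wt", true_label)
}

# tiny three-probe panel keeps hand-computed normalization examples readable
tiny_panel <- function() {
  probes <- data.frame(
    probe_id = c("G1_Exon1", "G1_Exon2", "G2_Exon1",
                 "REF_01", "REF_02", "REF_03"),
    gene = c("G1", "G1", "G2", "", "", ""),
    region = c("Exon1", "Exon2", "Exon1", "", "", ""),
    amplicon_length = c(130L, 150L, 170L, 200L, 220L, 240L),
    kind = c("target", "target", "target",
             "reference", "reference", "reference"),
    stringsAsFactors = FALSE
  )
  structure(probes, name = "tiny", schema = 1L,
            class = c("mlpa_panel", "data.frame"))
}

tiny_peaks <- function(heights_by_sample) {
  panel <- tiny_panel()
  do.call(rbind, lapply(names(heights_by_sample), function(id) {
    data.frame(sample_id = id, probe_id = panel$probe_id,
               peak_height = heights_by_sample[[id]],
               stringsAsFactors = FALSE)
  }))
}
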