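test_that("intra-sample normalization divides by the reference-probe median", {
  # references {100, 120, 80}: median 100, so target 50 -> 0.5, target 100 -> 1
  peaks <- tiny_peaks(list(A = c(50, 100, 200, 100, 120, 80)))
  rel <- intra_sample_normalize(peaks, tiny_panel())
  r <- setNames(rel$relative_signal, rel$probe_id)
  expect_equal(unname(r["G1_Exon1"]), 0.5)
  expect_equal(unname(r["G1_Exon2"]), 1.0)
  expect_equal(unname(r["G2_Exon1"]), 2.0)
  expect_equal(median(r[c("REF_01", "REF_02", "REF_03")]), 1.0)
})

test_that("intra-sample normalization is invariant to a sample-wide rescale", {
  h <- c(50, 100, 200, 100, 120, 80)
  rel1 <- intra_sample_normalize(tiny_peaks(list(A = h)), tiny_panel())
  rel2 <- intra_sample_normalize(tiny_peaks(list(A = 7.3 * h)), tiny_panel())
  expect_equal(rel1$relative_signal, rel2$relative_signal)
})

test_that("samples with zero reference signal are excluded with a reason", {
  peaks <- tiny_peaks(list(A = c(50, 100, 200, 100, 120, 80),
                           B = c(50, 100, 200, 0, 0, 0)))
  expect_warning(rel <- intra_sample_normalize(peaks, tiny_panel()),
                 "zero reference-probe signal")
  expect_false("B" %in% rel$sample_id)
  dropped <- attr(rel, "dropped_samples")
  expect_equal(dropped$sample_id, "B")
  expect_match(dropped$reason, "reference probes")
})

test_that("inter-sample normalization yields dq = relative / reference mean", {
  peaks <- tiny_peaks(list(TEST = c(50, 100, 200, 100, 100, 100),
                           R1 = c(100, 100, 100, 100, 100, 100)))
  rel <- intra_sample_normalize(peaks, tiny_panel())
  dq <- inter_sample_normalize(rel, "R1")
  d <- dq[dq$sample_id == "TEST", ]
  expect_equal(setNames(d$dq, d$probe_id)[c("G1_Exon1", "G1_Exon2", "G2_Exon1")],
               c(G1_Exon1 = 0.5, G1_Exon2 = 1, G2_Exon1 = 2))
  # a reference sample against the set of which it is the sole member
  r <- dq[dq$sample_id == "R1", ]
  expect_true(all(r$dq == 1))
})

test_that("duplicating a reference sample leaves every dq unchanged", {
  peaks <- tiny_peaks(list(TEST = c(50, 100, 200, 90, 110, 100),
                           R1 = c(100, 100, 100, 100, 100, 100)))
  extra <- tiny_peaks(list(R2 = c(100, 100, 100, 100, 100, 100)))
  dq1 <- inter_sample_normalize(intra_sample_normalize(peaks, tiny_panel()), "R1")
  dq2 <- inter_sample_normalize(
    intra_sample_normalize(rbind(peaks, extra), tiny_panel()), c("R1", "R2"))
  t1 <- dq1[dq1$sample_id == "TEST", ]
  t2 <- dq2[dq2$sample_id == "TEST", ]
  expect_equal(setNames(t1$dq, t1$probe_id), setNames(t2$dq, t2$probe_id))
})

test_that("permuting peak-table rows changes no dq", {
  cfg <- sim_config(n_samples = 6, seed = 8)
  run <- simulate_mlpa_run(cfg, n_reference_samples = 3)
  dq_of <- function(peaks) {
    dq <- inter_sample_normalize(
      intra_sample_normalize(peaks, default_panel()), run$reference_samples)
    dq[order(dq$sample_id, dq$probe_id), ]
  }
  set.seed(1)
  shuffled <- run$peaks[sample(nrow(run$peaks)), ]
  expect_equal(dq_of(run$peaks)$dq, dq_of(shuffled)$dq)
})

test_that("population fallback warns and normalizes against the cohort median", {
  peaks <- tiny_peaks(list(A = c(100, 100, 100, 100, 100, 100),
                           B = c(100, 100, 100, 100, 100, 100),
                           C = c(100, 100, 100, 100, 100, 100)))
  rel <- intra_sample_normalize(peaks, tiny_panel())
  expect_warning(dq <- inter_sample_normalize(rel, NULL),
                 "population-median")
  expect_true(all(dq$dq == 1))
})

test_that("control-fragment QC flags quantity and denaturation problems", {
  cfg <- sim_config(n_samples = 6, seed = 21)
  panel <- default_panel()
  peaks <- peaks_from_truth(simulate_cohort(cfg), panel, cfg)
  qc <- qc_sample(peaks, panel)
  expect_true(all(qc$q_fragment_flag == "pass"))
  expect_true(all(qc$d_fragment_flag == "pass"))
  expect_true(all(qc$inferred_sex %in% c("XX", "XY")))

  # starve one sample of DNA: Q-fragments rise 10x above the reference level
  starved <- peaks
  qcols <- panel$probe_id[panel$kind == "q_fragment"]
  one <- starved$sample_id == starved$sample_id[1] & starved$probe_id %in% qcols
  ref_level <- median(starved$peak_height[
    starved$sample_id == starved$sample_id[1] &
      starved$probe_id %in% panel$probe_id[panel$kind == "reference"]])
  starved$peak_height[one] <- 10 * ref_level
  qc2 <- qc_sample(starved, panel)
  expect_equal(qc2$q_fragment_flag[qc2$sample_id == starved$sample_id[1]], "fail")
})

test_that("sex is inferred from the X and Y fragments", {
  cfg <- sim_config(n_samples = 40, seed = 31, p_female = 0.5)
  panel <- default_panel()
  truth <- simulate_cohort(cfg)
  peaks <- peaks_from_truth(truth, panel, cfg)
  qc <- qc_sample(peaks, panel)
  expect_equal(setNames(qc$inferred_sex, qc$sample_id),
               attr(truth, "sex")[qc$sample_id])
})

test_that("peak tables round-trip through TSV", {
  cfg <- sim_config(n_samples = 3, seed = 5)
  peaks <- peaks_from_truth(simulate_cohort(cfg), default_panel(), cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_peak_table(peaks, path)
  expect_equal(read_peak_table(path), peaks, tolerance = 1e-12)
})
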