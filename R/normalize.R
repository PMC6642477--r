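# Two-stage MLPA normalization: within each sample against the reference
# probes, then across samples against the reference-sample cohort. The result
# is a dosage quotient (DQ) whose expectation is copies/2 at autosomal targets.

#' Validate a peak table against a panel
#'
#' @param peaks Data frame with columns `sample_id`, `probe_id`,
#'   `peak_height`.
#' @param panel An `mlpa_panel`.
#' @return `peaks`, invisibly.
#' @keywords internal
validate_peaks <- function(peaks, panel) {
  required <- c("sample_id", "probe_id", "peak_height")
  missing_cols <- setdiff(required, names(peaks))
  if (length(missing_cols))
    stop("peak table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(peaks$peak_height) | peaks$peak_height < 0))
    stop("peak heights must be finite and >= 0", call. = FALSE)
  unknown <- setdiff(unique(peaks$probe_id), panel$probe_id)
  if (length(unknown))
    stop("peak table contains probes absent from the panel: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  key <- paste(peaks$sample_id, peaks$probe_id)
  if (anyDuplicated(key))
    stop("duplicate (sample, probe) rows in peak table, e.g. ",
         key[anyDuplicated(key)], call. = FALSE)
  counts <- table(peaks$sample_id)
  if (length(unique(counts)) > 1 || counts[1] != nrow(panel))
    stop("every sample must have exactly one height per panel probe",
         call. = FALSE)
  invisible(peaks)
}

# peaks long -> samples x probes matrix in panel probe order
peaks_matrix <- function(peaks, panel) {
  ids <- unique(peaks$sample_id)
  m <- matrix(NA_real_, length(ids), nrow(panel),
              dimnames = list(ids, panel$probe_id))
  m[cbind(match(peaks$sample_id, ids), match(peaks$probe_id, panel$probe_id))] <-
    peaks$peak_height
  m
}

#' Intra-sample normalization against reference probes
#'
#' Divides every probe's peak height by a robust summary (by default the
#' median) of the same sample's reference-probe heights. This removes the
#' per-sample global intensity scale: multiplying one sample's entire peak
#' vector by any positive constant leaves its relative signals unchanged.
#' Samples whose reference summary is zero carry no usable scale information
#' and are excluded, with the reason recorded in the `dropped_samples`
#' attribute of the result.
#'
#' @param peaks Peak table (`sample_id`, `probe_id`, `peak_height`).
#' @param panel An `mlpa_panel`.
#' @param stat Reference-probe summary: `"median"` (default, robust to one
#'   aberrant reference probe) or `"mean"`.
#' @return Data frame (`sample_id`, `probe_id`, `relative_signal`) with
#'   attribute `dropped_samples` (data frame `sample_id`, `reason`).
#' @export
intra_sample_normalize <- function(peaks, panel, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  validate_peaks(peaks, panel)
  m <- peaks_matrix(peaks, panel)
  ref_cols <- panel$probe_id[panel$kind == "reference"]
  fn <- if (stat == "median") stats::median else mean
  ref_stat <- apply(m[, ref_cols, drop = FALSE], 1, fn)
  dead <- ref_stat <= 0
  dropped <- data.frame(sample_id = rownames(m)[dead],
                        reason = rep("all reference probes at zero height",
                                     sum(dead)),
                        stringsAsFactors = FALSE)
  if (any(dead))
    warning("excluding ", sum(dead),
            " sample(s) with zero reference-probe signal: ",
            paste(rownames(m)[dead], collapse = ", "), call. = FALSE)
  m <- m[!dead, , drop = FALSE]
  rel <- m / ref_stat[!dead]
  out <- data.frame(
    sample_id = rep(rownames(rel), times = ncol(rel)),
    probe_id = rep(colnames(rel), each = nrow(rel)),
    relative_signal = as.vector(rel),
    stringsAsFactors = FALSE
  )
  structure(out, dropped_samples = dropped)
}

#' Inter-sample normalization to dosage quotients
#'
#' Divides each sample's relative probe signal by the aggregate (by default
#' the arithmetic mean) of the relative signals of the designated reference
#' samples at the same probe. Reference samples are assumed two-copy at every
#' target probe, so the resulting dosage quotient has expectation copies/2.
#' When no reference samples are designated, the entire cohort is used as the
#' reference set with the median as aggregate (population-median
#' normalization) and a warning — only appropriate when most samples are
#' copy-number normal at most probes.
#'
#' @param rel Relative signals from [intra_sample_normalize()].
#' @param reference_samples Character vector of reference sample ids, or
#'   `NULL` for the population fallback.
#' @param stat Aggregate over reference samples: `"mean"` (default) or
#'   `"median"`.
#' @return Data frame (`sample_id`, `probe_id`, `dq`) with attribute
#'   `uncallable_probes` (probes whose reference aggregate is zero; their dq
#'   is `NA`).
#' @export
inter_sample_normalize <- function(rel, reference_samples = NULL,
                                   stat = c("mean", "median")) {
  stat <- match.arg(stat)
  ids <- unique(rel$sample_id)
  probes <- unique(rel$probe_id)
  m <- matrix(NA_real_, length(ids), length(probes),
              dimnames = list(ids, probes))
  m[cbind(match(rel$sample_id, ids), match(rel$probe_id, probes))] <-
    rel$relative_signal
  if (is.null(reference_samples) || !length(reference_samples)) {
    warning("no reference samples designated; falling back to ",
            "population-median normalization over all ", length(ids),
            " samples", call. = FALSE)
    reference_samples <- ids
    stat <- "median"
  }
  missing_refs <- setdiff(reference_samples, ids)
  if (length(missing_refs))
    stop("reference samples absent from data (or excluded by QC): ",
         paste(missing_refs, collapse = ", "), call. = FALSE)
  fn <- if (stat == "median") stats::median else mean
  ref_agg <- apply(m[reference_samples, , drop = FALSE], 2, fn)
  uncallable <- names(ref_agg)[ref_agg <= 0]
  if (length(uncallable))
    warning("probe(s) with zero reference aggregate marked uncallable: ",
            paste(uncallable, collapse = ", "), call. = FALSE)
  ref_agg[ref_agg <= 0] <- NA_real_
  dq <- sweep(m, 2, ref_agg, "/")
  out <- data.frame(
    sample_id = rep(rownames(dq), times = ncol(dq)),
    probe_id = rep(colnames(dq), each = nrow(dq)),
    dq = as.vector(dq),
    stringsAsFactors = FALSE
  )
  structure(out, uncallable_probes = uncallable)
}

#' Control-fragment QC thresholds
#'
#' @param q_max A sample fails the DNA-quantity check when the median
#'   Q-fragment relative signal exceeds this fraction of the reference-probe
#'   level (Q-fragment products dominate the reaction when input DNA is
#'   short).
#' @param d_min A sample fails the denaturation check when the median
#'   D-fragment relative signal falls below this fraction.
#' @param y_min Minimum Y-fragment relative signal to infer an XY sample.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(q_max = 0.33, d_min = 0.40, y_min = 0.30) {
  stopifnot(q_max > 0, d_min > 0, y_min > 0)
  structure(list(q_max = q_max, d_min = d_min, y_min = y_min),
            class = "qc_thresholds")
}

#' Per-sample control-fragment quality control
#'
#' Evaluates the DNA-quantity (Q) and denaturation (D) control fragments of
#' each sample relative to its reference-probe level, and infers sex from the
#' X/Y fragments. Flags are deterministic given the peak heights and
#' thresholds. If the panel lacks a control-fragment kind the corresponding
#' check is skipped with a warning (flag `"skipped"`) — never silently passed.
#'
#' @param peaks Peak table.
#' @param panel An `mlpa_panel`.
#' @param thresholds A [qc_thresholds()].
#' @return Data frame (`sample_id`, `q_fragment_flag`, `d_fragment_flag`,
#'   `inferred_sex`).
#' @export
qc_sample <- function(peaks, panel, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  validate_peaks(peaks, panel)
  m <- peaks_matrix(peaks, panel)
  ref_cols <- panel$probe_id[panel$kind == "reference"]
  ref_level <- apply(m[, ref_cols, drop = FALSE], 1, stats::median)
  rel_of <- function(kind) {
    cols <- panel$probe_id[panel$kind == kind]
    if (!length(cols)) return(NULL)
    apply(m[, cols, drop = FALSE], 1, stats::median) /
      ifelse(ref_level > 0, ref_level, NA_real_)
  }
  q_rel <- rel_of("q_fragment")
  d_rel <- rel_of("d_fragment")
  x_rel <- rel_of("x_fragment")
  y_rel <- rel_of("y_fragment")
  n <- nrow(m)
  flag <- function(rel, fail) {
    if (is.null(rel)) return(rep("skipped", n))
    ifelse(is.na(rel), "warn", ifelse(fail(rel), "fail", "pass"))
  }
  if (is.null(q_rel) || is.null(d_rel))
    warning("panel lacks Q- or D-fragments; the corresponding QC check is skipped",
            call. = FALSE)
  sex <- if (is.null(y_rel) || is.null(x_rel)) {
    rep("undetermined", n)
  } else {
    ifelse(is.na(y_rel) | is.na(x_rel), "undetermined",
           ifelse(y_rel >= thresholds$y_min, "XY",
                  ifelse(x_rel > 0, "XX", "undetermined")))
  }
  data.frame(
    sample_id = rownames(m),
    q_fragment_flag = flag(q_rel, function(r) r > thresholds$q_max),
    d_fragment_flag = flag(d_rel, function(r) r < thresholds$d_min),
    inferred_sex = sex,
    stringsAsFactors = FALSE
  )
}
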