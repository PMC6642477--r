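# Dosage-quotient classification and gene-level CNV calling.

CN_CLASSES <- c("HOM_DEL", "HET_DEL", "NORMAL", "HET_DUP", "HOM_DUP",
                "AMBIGUOUS")
CLASS_TO_LABEL <- c(HOM_DEL = "Del/Del", HET_DEL = "Del/Wt", NORMAL = "Wt/Wt",
                    HET_DUP = "Dup/Wt", HOM_DUP = "Dup/Dup",
                    AMBIGUOUS = "Unknown")

#' Dosage-quotient classification thresholds
#'
#' The canonical DQ-to-copy-number mapping for a diploid locus: DQ of 0 means
#' homozygous deletion, 0.40 < DQ < 0.65 heterozygous deletion,
#' 0.80 < DQ < 1.20 normal, 1.30 < DQ < 1.65 heterozygous duplication,
#' 1.75 < DQ < 2.15 homozygous duplication, and everything else — including
#' the interval endpoints, since all inequalities are strict — is ambiguous.
#' An exact DQ of 0 is unattainable under measurement noise, so homozygous
#' deletion is accepted for DQ below a small tolerance `hom_del_eps`; values
#' in `[hom_del_eps, 0.40]` stay ambiguous.
#'
#' @param hom_del_eps DQ strictly below this is called homozygous deletion
#'   (default 0.10).
#' @param het_del,normal,het_dup,hom_dup Open intervals `c(lo, hi)` for the
#'   remaining classes.
#' @return A list of class `dq_thresholds`.
#' @export
dq_thresholds <- function(hom_del_eps = 0.10,
                          het_del = c(0.40, 0.65),
                          normal = c(0.80, 1.20),
                          het_dup = c(1.30, 1.65),
                          hom_dup = c(1.75, 2.15)) {
  iv <- rbind(het_del, normal, het_dup, hom_dup)
  if (any(iv[, 1] >= iv[, 2]))
    stop("each interval must satisfy lo < hi", call. = FALSE)
  bounds <- c(hom_del_eps, t(iv))
  if (is.unsorted(bounds, strictly = FALSE))
    stop("intervals must be disjoint and ordered: ",
         "hom_del_eps <= het_del < normal < het_dup < hom_dup", call. = FALSE)
  structure(list(hom_del_eps = hom_del_eps, het_del = het_del,
                 normal = normal, het_dup = het_dup, hom_dup = hom_dup),
            class = "dq_thresholds")
}

#' Classify dosage quotients into copy-number classes
#'
#' Total function on finite non-negative DQ values: every value maps to
#' exactly one of HOM_DEL, HET_DEL, NORMAL, HET_DUP, HOM_DUP or AMBIGUOUS.
#' Interval endpoints are AMBIGUOUS (the defining inequalities are strict).
#' `NA` values (uncallable probes) propagate as `NA`.
#'
#' @param dq Numeric vector of dosage quotients, each finite and >= 0 (or
#'   `NA`).
#' @param thresholds A [dq_thresholds()].
#' @return Character vector of class names, same length as `dq`.
#' @examples
#' classify_dq(c(0, 0.5, 1, 1.5, 2, 0.7, 1.2))
#' @export
classify_dq <- function(dq, thresholds = dq_thresholds()) {
  stopifnot(inherits(thresholds, "dq_thresholds"))
  ok <- (is.na(dq) & !is.nan(dq)) | (is.finite(dq) & dq >= 0)
  if (!all(ok))
    stop("dq must be finite and >= 0; offending values: ",
         paste(utils::head(dq[!ok], 5), collapse = ", "), call. = FALSE)
  t <- thresholds
  cls <- rep(NA_character_, length(dq))
  i <- !is.na(dq)
  cls[i] <- "AMBIGUOUS"
  cls[i & dq < t$hom_del_eps] <- "HOM_DEL"
  cls[i & dq > t$het_del[1] & dq < t$het_del[2]] <- "HET_DEL"
  cls[i & dq > t$normal[1] & dq < t$normal[2]] <- "NORMAL"
  cls[i & dq > t$het_dup[1] & dq < t$het_dup[2]] <- "HET_DUP"
  cls[i & dq > t$hom_dup[1] & dq < t$hom_dup[2]] <- "HOM_DUP"
  cls
}

#' Aggregate per-probe classes into a gene-level CNV call
#'
#' A gene is categorized as deleted or duplicated when any of its exon probes
#' is; when probes of the same direction disagree in zygosity (HET and HOM),
#' the more extreme class wins. Probes in opposite directions (a deletion
#' class and a duplication class in one gene) make the call discordant and the
#' genotype Unknown. Ambiguous probes are ignored whenever at least one
#' sibling probe is called; a gene with only ambiguous (or `NA`) probes is
#' AMBIGUOUS.
#'
#' @param probe_classes Character vector of per-probe classes for one gene
#'   (values from [classify_dq()]).
#' @return A list: `cnv_class`, `genotype_label`, `discordant`,
#'   `n_probes_called`.
#' @examples
#' call_gene(c("NORMAL", "NORMAL", "HET_DEL"))
#' @export
call_gene <- function(probe_classes) {
  if (!length(probe_classes)) stop("zero probes for gene", call. = FALSE)
  bad <- !is.na(probe_classes) & !probe_classes %in% CN_CLASSES
  if (any(bad))
    stop("unknown probe class: ", paste(unique(probe_classes[bad]),
                                        collapse = ", "), call. = FALSE)
  called <- probe_classes[!is.na(probe_classes) &
                            probe_classes != "AMBIGUOUS"]
  n_called <- length(called)
  if (!n_called) {
    cls <- "AMBIGUOUS"
    discordant <- FALSE
  } else {
    has_del <- any(called %in% c("HET_DEL", "HOM_DEL"))
    has_dup <- any(called %in% c("HET_DUP", "HOM_DUP"))
    if (has_del && has_dup) {
      cls <- "AMBIGUOUS"
      discordant <- TRUE
    } else {
      discordant <- FALSE
      cls <- if (has_del) {
        if (any(called == "HOM_DEL")) "HOM_DEL" else "HET_DEL"
      } else if (has_dup) {
        if (any(called == "HOM_DUP")) "HOM_DUP" else "HET_DUP"
      } else "NORMAL"
    }
  }
  list(cnv_class = cls,
       genotype_label = if (discordant) "Unknown" else genotype_label(cls),
       discordant = discordant,
       n_probes_called = n_called)
}

#' Map a gene-level copy-number class to a diplotype label
#'
#' @param cnv_class Character vector of classes (HOM_DEL, HET_DEL, NORMAL,
#'   HET_DUP, HOM_DUP, AMBIGUOUS).
#' @return Character vector of labels: Del/Del, Del/Wt, Wt/Wt, Dup/Wt,
#'   Dup/Dup; AMBIGUOUS maps to Unknown.
#' @export
genotype_label <- function(cnv_class) {
  bad <- !cnv_class %in% names(CLASS_TO_LABEL)
  if (any(bad))
    stop("unknown copy-number class: ",
         paste(unique(cnv_class[bad]), collapse = ", "), call. = FALSE)
  unname(CLASS_TO_LABEL[cnv_class])
}

#' Predicted metabolizer phenotype from a CNV diplotype
#'
#' Copy-number-only phenotype prediction for a drug-metabolizing enzyme gene:
#' individuals with zero gene copies carry no active alleles and are predicted
#' poor metabolizers; more than two copies predicts increased enzyme activity
#' (ultrarapid). The prediction assesses copy number only — it cannot see
#' inactivating SNVs, nor whether a duplicated allele is active.
#'
#' @param label Character vector of diplotype labels (Del/Del, Del/Wt, Wt/Wt,
#'   Dup/Wt, Dup/Dup). `Unknown` yields `NA` (no prediction).
#' @return Data frame with `genotype_label`, `total_active_copies`,
#'   `predicted` (poor / intermediate / normal / ultrarapid), plus a `note`
#'   attribute flagging the copy-number-only caveat.
#' @examples
#' predict_phenotype(c("Del/Del", "Dup/Wt", "Wt/Wt"))
#' @export
predict_phenotype <- function(label) {
  copies <- c("Del/Del" = 0L, "Del/Wt" = 1L, "Wt/Wt" = 2L,
              "Dup/Wt" = 3L, "Dup/Dup" = 4L)
  pheno <- c("Del/Del" = "poor", "Del/Wt" = "intermediate",
             "Wt/Wt" = "normal", "Dup/Wt" = "ultrarapid",
             "Dup/Dup" = "ultrarapid")
  bad <- !label %in% c(names(copies), "Unknown")
  if (any(bad))
    stop("unknown genotype label: ", paste(unique(label[bad]), collapse = ", "),
         call. = FALSE)
  out <- data.frame(
    genotype_label = label,
    total_active_copies = unname(copies[label]),
    predicted = unname(pheno[label]),
    stringsAsFactors = FALSE
  )
  attr(out, "note") <- "copy-number-only prediction; SNV alleles not assessed"
  out
}
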