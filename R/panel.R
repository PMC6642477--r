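# Probe panel: target probes over 14 CYP-450/GST genes plus reference probes
# and Q/D/X/Y control fragments.

PROBE_KINDS <- c("target", "reference", "q_fragment", "d_fragment",
                 "x_fragment", "y_fragment")

#' Genes covered by the default pharmacogene CNV panel
#'
#' The 11 cytochrome P450 genes and 3 glutathione S-transferase genes targeted
#' by the default panel, in reporting order.
#'
#' @return Character vector of 14 gene symbols.
#' @export
panel_genes <- function() {
  c("GSTM1", "GSTP1", "GSTT1", "CYP1A1", "CYP1A2", "CYP1B1", "CYP2A6",
    "CYP2B6", "CYP2C9", "CYP2C19", "CYP2D6", "CYP2E1", "CYP3A4", "CYP3A5")
}

# gene -> exon regions grid of the default panel (40 target regions).
# Every gene has >= 2 probes except GSTT1 (single exon-1 probe).
default_panel_grid <- function() {
  list(
    GSTM1   = c("Exon2", "Exon5"),
    GSTP1   = c("Exon1", "Exon4"),
    GSTT1   = "Exon1",
    CYP1A1  = c("Exon1", "Exon2", "Exon6"),
    CYP1A2  = c("Exon2", "Exon4", "Exon7"),
    CYP1B1  = c("Exon2", "Exon3"),
    CYP2A6  = c("Exon1", "Exon4", "Exon6", "DownstreamExon9"),
    CYP2B6  = c("Exon1", "Exon4", "Exon9"),
    CYP2C9  = c("Exon1", "Exon3", "Exon5", "Exon8"),
    CYP2C19 = c("Exon3", "Exon5", "Exon9"),
    CYP2D6  = c("Exon1", "Exon2", "Exon6", "Exon9"),
    CYP2E1  = c("Exon1", "Exon4", "Exon8"),
    CYP3A4  = c("Exon1", "Exon5", "Exon10"),
    CYP3A5  = c("Exon1", "Exon3", "Exon13")
  )
}

new_mlpa_panel <- function(probes, name, schema = 1L) {
  stopifnot(is.data.frame(probes))
  structure(probes,
            name = name, schema = as.integer(schema),
            class = c("mlpa_panel", "data.frame"))
}

#' Build the default MLPA pharmacogene panel
#'
#' Constructs the probe mix used throughout the package: 40 target probes over
#' 14 CYP-450 and GST genes (each gene covered by at least two exon probes
#' except GSTT1, which carries a single exon-1 probe), `n_reference`
#' copy-number-stable reference probes, 4 DNA-quantity (Q) fragments, 3
#' denaturation-control (D) fragments, one X- and one Y-fragment. Amplicon
#' lengths are deterministic and unique: control fragments sit at the short
#' end of the size range (64-105 nt) and target/reference amplicons occupy
#' 128-504 nt. Lengths identify peaks on an electropherogram; they never enter
#' the dosage arithmetic.
#'
#' @param n_reference Number of reference probes (default 8; at least 2 are
#'   required for robust intra-sample normalization).
#' @return An `mlpa_panel` object: a data frame with columns `probe_id`,
#'   `gene`, `region`, `amplicon_length`, `kind`.
#' @examples
#' panel <- default_panel()
#' table(panel$kind)
#' @export
default_panel <- function(n_reference = 8L) {
  n_reference <- as.integer(n_reference)
  if (n_reference < 2L)
    stop("at least 2 reference probes are required", call. = FALSE)
  grid <- default_panel_grid()
  genes <- rep(names(grid), lengths(grid))
  regions <- unlist(grid, use.names = FALSE)
  targets <- data.frame(
    probe_id = paste(genes, regions, sep = "_"),
    gene = genes, region = regions,
    amplicon_length = NA_integer_, kind = "target",
    stringsAsFactors = FALSE
  )
  refs <- data.frame(
    probe_id = sprintf("REF_%02d", seq_len(n_reference)),
    gene = "", region = "",
    amplicon_length = NA_integer_, kind = "reference",
    stringsAsFactors = FALSE
  )
  controls <- data.frame(
    probe_id = c("Q_64", "Q_70", "Q_76", "Q_82",
                 "D_88", "D_92", "D_96", "X_100", "Y_105"),
    gene = "", region = "",
    amplicon_length = c(64L, 70L, 76L, 82L, 88L, 92L, 96L, 100L, 105L),
    kind = c(rep("q_fragment", 4), rep("d_fragment", 3),
             "x_fragment", "y_fragment"),
    stringsAsFactors = FALSE
  )
  probes <- rbind(targets, refs, controls)
  # unique lengths on an 8-nt ladder spanning 128..504 for targets + refs
  n_assay <- nrow(targets) + nrow(refs)
  ladder <- seq(128L, by = 8L, length.out = n_assay)
  probes$amplicon_length[probes$kind %in% c("target", "reference")] <- ladder
  rownames(probes) <- NULL
  panel <- new_mlpa_panel(probes, name = "pharmacogene-cnv-default")
  validate_panel(panel)
  panel
}

#' Validate an MLPA panel definition
#'
#' Checks the structural invariants every downstream stage relies on: unique
#' probe ids, known probe kinds, target probes carrying a gene and region,
#' non-target probes carrying neither, and a non-empty reference probe set.
#'
#' @param panel An `mlpa_panel` (or compatible data frame).
#' @param default_invariants Also enforce the default-panel composition
#'   (40 targets over the 14 panel genes, GSTT1 single-probe, 4/3/1/1 control
#'   fragments). Off by default so user panels with other compositions load.
#' @return `panel`, invisibly, if valid; otherwise an error naming the
#'   offending probe.
#' @export
validate_panel <- function(panel, default_invariants = FALSE) {
  required <- c("probe_id", "gene", "region", "amplicon_length", "kind")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols))
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dup <- unique(panel$probe_id[duplicated(panel$probe_id)])
  if (length(dup))
    stop("duplicate probe_id in panel: ", paste(dup, collapse = ", "),
         call. = FALSE)
  bad_kind <- unique(panel$kind[!panel$kind %in% PROBE_KINDS])
  if (length(bad_kind))
    stop("unknown probe kind: ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  tgt <- panel$kind == "target"
  if (any(tgt & (is.na(panel$gene) | panel$gene == "")))
    stop("target probe with empty gene: ",
         paste(panel$probe_id[tgt & (is.na(panel$gene) | panel$gene == "")],
               collapse = ", "), call. = FALSE)
  if (any(tgt & (is.na(panel$region) | panel$region == "")))
    stop("target probe with empty region: ",
         paste(panel$probe_id[tgt & (is.na(panel$region) | panel$region == "")],
               collapse = ", "), call. = FALSE)
  if (any(!tgt & panel$gene != ""))
    stop("non-target probe with a gene assignment: ",
         paste(panel$probe_id[!tgt & panel$gene != ""], collapse = ", "),
         call. = FALSE)
  if (!any(panel$kind == "reference"))
    stop("no reference probes", call. = FALSE)
  bad_len <- !is.finite(panel$amplicon_length) |
    panel$amplicon_length < 64 | panel$amplicon_length > 504
  if (any(bad_len))
    stop("amplicon_length outside [64, 504] for: ",
         paste(panel$probe_id[bad_len], collapse = ", "), call. = FALSE)
  if (default_invariants) {
    if (sum(tgt) != 40L) stop("default panel must have 40 target probes")
    if (!setequal(unique(panel$gene[tgt]), panel_genes()))
      stop("default panel must cover exactly the 14 panel genes")
    per_gene <- table(panel$gene[tgt])
    if (per_gene[["GSTT1"]] != 1L) stop("GSTT1 must have exactly 1 probe")
    if (any(per_gene[setdiff(names(per_gene), "GSTT1")] < 2L))
      stop("every gene except GSTT1 needs >= 2 probes")
    kinds <- table(factor(panel$kind, levels = PROBE_KINDS))
    if (kinds[["q_fragment"]] != 4L || kinds[["d_fragment"]] != 3L ||
        kinds[["x_fragment"]] != 1L || kinds[["y_fragment"]] != 1L)
      stop("default panel control fragments must be 4 Q, 3 D, 1 X, 1 Y")
  }
  invisible(panel)
}

#' Write a panel definition to JSON
#'
#' @param panel An `mlpa_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_panel()]
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  obj <- list(
    name = attr(panel, "name") %||% "unnamed",
    schema = attr(panel, "schema") %||% 1L,
    probes = as.data.frame(panel)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Read a panel definition from JSON
#'
#' Panels are stored as JSON with a `schema` version field and one record per
#' probe. Files violating panel invariants are rejected with a diagnostic
#' naming the offending probe.
#'
#' @param path Path to a panel JSON file.
#' @return An `mlpa_panel`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path))
    stop("panel file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$probes))
    stop("panel file has no 'probes' field: ", path, call. = FALSE)
  probes <- as.data.frame(obj$probes, stringsAsFactors = FALSE)
  probes$gene[is.na(probes$gene)] <- ""
  probes$region[is.na(probes$region)] <- ""
  probes$amplicon_length <- as.integer(probes$amplicon_length)
  panel <- new_mlpa_panel(probes, name = obj$name %||% "unnamed",
                          schema = obj$schema %||% 1L)
  validate_panel(panel)
  panel
}

#' @export
print.mlpa_panel <- function(x, ...) {
  tgt <- x$kind == "target"
  cat(sprintf("MLPA panel '%s' (schema %d): %d probes\n",
              attr(x, "name"), attr(x, "schema"), nrow(x)))
  cat(sprintf("  %d target probes over %d genes; %d reference probes; %d control fragments\n",
              sum(tgt), length(unique(x$gene[tgt])),
              sum(x$kind == "reference"),
              sum(!tgt & x$kind != "reference")))
  per_gene <- table(x$gene[tgt])
  cat("  probes per gene: ",
      paste(sprintf("%s=%d", names(per_gene), per_gene), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
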