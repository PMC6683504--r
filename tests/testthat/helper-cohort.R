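# Small in-code fixture builders shared across test files.

make_clinical <- function(ids, purity_pct = 90, recurred = FALSE,
                          dfs = 24, os = NULL, lymph_pre = NA, lymph_post = NA) {
  n <- length(ids)
  recurred <- rep_len(recurred, n)
  dfs <- rep_len(dfs, n)
  if (is.null(os)) os <- dfs + ifelse(recurred, 6, 0)
  data.frame(
    patient_id = ids,
    dfs_months = dfs, dfs_event = recurred,
    os_months = rep_len(os, n), os_event = recurred,
    recurred = recurred,
    age = 50, node_positive = FALSE, rcb_class = "I_II",
    purity_pct = rep_len(purity_pct, n),
    lymphocyte_pct_pre = rep_len(lymph_pre, n),
    lymphocyte_pct_post = rep_len(lymph_post, n),
    stringsAsFactors = FALSE)
}

make_variants <- function(patient_id = character(), timepoint = character(),
                          gene = character(), vaf = numeric(),
                          protein_change = NULL, variant_class = "MISSENSE") {
  n <- length(patient_id)
  data.frame(patient_id = patient_id, timepoint = rep_len(timepoint, n),
             gene = rep_len(gene, n),
             protein_change = if (is.null(protein_change)) rep(NA_character_, n)
                              else rep_len(protein_change, n),
             variant_class = rep_len(variant_class, n),
             vaf = rep_len(vaf, n), stringsAsFactors = FALSE)
}

make_cn <- function(patient_id, timepoint, gene, copy_number) {
  data.frame(patient_id = patient_id, timepoint = timepoint, gene = gene,
             copy_number = copy_number, stringsAsFactors = FALSE)
}

# A small called two-gene cohort with configurable TP53 copy number / VAF.
tiny_called_cohort <- function(tp53_cn = 2.0, tp53_vaf = NA, purity_pct = 100,
                               timepoint = "SURGERY") {
  cl <- make_clinical("PT001", purity_pct = purity_pct)
  cn <- make_cn("PT001", timepoint, c("TP53", "MYC"), c(tp53_cn, 2.0))
  va <- if (is.na(tp53_vaf)) make_variants() else
    make_variants("PT001", timepoint, "TP53", tp53_vaf, "p.R175H")
  co <- rd_cohort(va, cn, cl)
  ranges <- list(TP53 = build_reference_range(c(1.8, 2.0, 2.2), assay_id = "TP53"),
                 MYC = build_reference_range(c(1.8, 2.0, 2.2), assay_id = "MYC"))
  call_cohort(co, ranges)
}

# Default reference range [1.4, 2.6] used in unit examples.
unit_range <- function() build_reference_range(c(1.8, 2.0, 2.2))
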