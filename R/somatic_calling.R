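#' Build a normal-derived reference range
#'
#' Per-assay reference intervals are built from copy-number (or heterozygous
#' allele-frequency) measurements in normal genomes as mean +/- k standard
#' deviations, with the sample standard deviation (n - 1 denominator). The
#' default k = 3 is deliberately wide, to absorb the extra variance formalin
#' fixation introduces in archival tissue.
#'
#' @param normal_values numeric vector of at least two finite values.
#' @param k width multiplier (default 3).
#' @param assay_id optional label (typically the gene symbol).
#' @return object of class `reference_range` with `mean`, `sd`, `k`, `lower`,
#'   `upper`.
#' @export
build_reference_range <- function(normal_values, k = 3, assay_id = NULL) {
  check_numeric(normal_values, "normal_values")
  if (length(normal_values) < 2L) {
    rd_stop("at least 2 normal values are required to build a reference range",
            "rd_insufficient_data_error")
  }
  check_numeric(k, "k", lower = .Machine$double.eps)
  m <- mean(normal_values)
  s <- stats::sd(normal_values)
  structure(list(assay_id = assay_id, mean = m, sd = s, k = k,
                 lower = m - k * s, upper = m + k * s),
            class = "reference_range")
}

#' @export
print.reference_range <- function(x, ...) {
  cat(sprintf("reference_range%s: mean %.4g, sd %.4g, k = %g -> [%.4g, %.4g]\n",
              if (!is.null(x$assay_id)) paste0(" (", x$assay_id, ")") else "",
              x$mean, x$sd, x$k, x$lower, x$upper))
  invisible(x)
}

#' Build per-assay reference ranges from a normals table
#'
#' @param normals long data.frame with columns `gene` and `copy_number`
#'   (one row per normal genome per assay).
#' @param k width multiplier.
#' @return named list of `reference_range` objects, one per gene.
#' @export
build_reference_ranges <- function(normals, k = 3) {
  normals <- check_columns(normals, c("gene", "copy_number"), "normals")
  vals <- split(normals$copy_number, normals$gene)
  out <- lapply(names(vals), function(g) build_reference_range(vals[[g]], k, g))
  names(out) <- names(vals)
  out
}

#' Call a copy-number state
#'
#' Maps a copy number onto the five-state vocabulary against a normal-derived
#' reference range. Precedence: copy number strictly above `amp_threshold` is
#' AMPLIFIED; otherwise above the range upper bound is GAIN; otherwise below
#' `extensive_loss_threshold` is EXTENSIVE_LOSS; otherwise below the lower
#' bound is LOSS; values on the bounds (inclusive) are NORMAL.
#'
#' @param copy_number non-negative numeric (vectorized).
#' @param range a `reference_range`.
#' @param amp_threshold amplification cutoff; copy number > 4.99 is amplified.
#' @param extensive_loss_threshold deep-deletion cutoff, default 0.5.
#' @return ordered factor of states (see [cn_state_factor()]).
#' @export
call_copy_state <- function(copy_number, range, amp_threshold = 4.99,
                            extensive_loss_threshold = 0.5) {
  check_numeric(copy_number, "copy_number", lower = 0)
  stopifnot(inherits(range, "reference_range"))
  state <- rep("NORMAL", length(copy_number))
  state[copy_number < range$lower] <- "LOSS"
  state[copy_number < extensive_loss_threshold] <- "EXTENSIVE_LOSS"
  state[copy_number > range$upper] <- "GAIN"
  state[copy_number > amp_threshold] <- "AMPLIFIED"
  cn_state_factor(state)
}

#' Correct a variant allele frequency for tumor purity
#'
#' Observed VAFs are diluted by normal-cell contamination; dividing by purity
#' rescales to the tumor compartment, capped at 1.
#'
#' @param vaf observed fraction in \[0, 1\] (vectorized).
#' @param purity tumor-cell fraction in (0, 1\].
#' @return corrected VAF, `min(vaf / purity, 1)`.
#' @export
correct_vaf_for_purity <- function(vaf, purity) {
  check_numeric(vaf, "vaf", lower = 0, upper = 1)
  check_numeric(purity, "purity", upper = 1)
  if (any(purity <= 0)) rd_stop("purity must be > 0", "rd_domain_error")
  pmin(vaf / purity, 1)
}

#' Correct a copy number for tumor purity
#'
#' Assumes the admixed normal cells contribute two copies: subtracts the
#' normal contribution `2 * (1 - purity)` and rescales by purity, floored at 0.
#' Copy number 2 is a fixed point at any purity.
#'
#' @param cn_observed non-negative numeric (vectorized).
#' @param purity tumor-cell fraction in (0, 1\].
#' @return corrected copy number.
#' @export
correct_cn_for_purity <- function(cn_observed, purity) {
  check_numeric(cn_observed, "cn_observed", lower = 0)
  check_numeric(purity, "purity", upper = 1)
  if (any(purity <= 0)) rd_stop("purity must be > 0", "rd_domain_error")
  pmax((cn_observed - 2 * (1 - purity)) / purity, 0)
}

#' Detect loss of heterozygosity from allele-frequency skew
#'
#' LOH is called when a purity-corrected VAF rises above the upper bound of the
#' normal heterozygosity range (skew towards the mutant allele). Values on the
#' bound are not LOH. Downward skew is treated as subclonality, handled by the
#' risk stratification, not here.
#'
#' @param vaf_corrected corrected VAF in \[0, 1\] (vectorized).
#' @param het_range `reference_range` of heterozygous allele frequencies;
#'   see [default_het_range()].
#' @return logical vector.
#' @export
detect_loh <- function(vaf_corrected, het_range = default_het_range()) {
  check_numeric(vaf_corrected, "vaf_corrected", lower = 0, upper = 1)
  stopifnot(inherits(het_range, "reference_range"))
  vaf_corrected > het_range$upper
}

#' Default normal-heterozygosity range for TP53
#'
#' The printed normal reference range for heterozygous allele frequency,
#' 38--59\%, used when no normal SNP table is supplied. When a normals table is
#' available, rebuild it with [build_reference_range()].
#'
#' @return a `reference_range` with bounds \[0.38, 0.59\].
#' @export
default_het_range <- function() {
  structure(list(assay_id = "TP53_het", mean = 0.485, sd = 0.035, k = 3,
                 lower = 0.38, upper = 0.59), class = "reference_range")
}

#' Call copy-number states and corrected VAFs across a cohort
#'
#' For every included sample: copy numbers are purity-corrected, then called
#' against the per-assay reference ranges; VAFs are purity-corrected; TP53
#' variants get an LOH flag against the heterozygosity range. Samples flagged
#' excluded (purity below the gate) are carried through uncalled.
#'
#' @param cohort an `rd_cohort`.
#' @param cn_ranges named list of `reference_range` objects covering every
#'   panel gene present in the cohort (see [build_reference_ranges()]).
#' @param het_range heterozygosity range for LOH detection.
#' @param amp_threshold,extensive_loss_threshold passed to [call_copy_state()].
#' @return the cohort with `copynumber$cn_corrected`, `copynumber$state`,
#'   `variants$vaf_corrected` and `variants$loh` filled in; attribute
#'   `called = TRUE`.
#' @export
call_cohort <- function(cohort, cn_ranges, het_range = default_het_range(),
                        amp_threshold = 4.99, extensive_loss_threshold = 0.5) {
  stopifnot(inherits(cohort, "rd_cohort"))
  cn <- cohort$copynumber
  missing_genes <- setdiff(unique(cn$gene), names(cn_ranges))
  if (length(missing_genes)) {
    rd_stop(sprintf("no reference range for gene(s): %s",
                    paste(missing_genes, collapse = ", ")), "rd_coverage_error")
  }
  smp <- cohort$samples
  skey <- paste(smp$patient_id, smp$timepoint)
  inc <- smp$included[match(paste(cn$patient_id, cn$timepoint), skey)]
  purity <- smp$purity[match(paste(cn$patient_id, cn$timepoint), skey)]

  cn$cn_corrected <- rep(NA_real_, nrow(cn))
  cn$state <- rep(NA_character_, nrow(cn))
  idx <- which(inc)
  if (length(idx)) {
    cn$cn_corrected[idx] <- correct_cn_for_purity(cn$copy_number[idx], purity[idx])
    for (g in unique(cn$gene[idx])) {
      gi <- idx[cn$gene[idx] == g]
      cn$state[gi] <- as.character(call_copy_state(
        cn$cn_corrected[gi], cn_ranges[[g]],
        amp_threshold = amp_threshold,
        extensive_loss_threshold = extensive_loss_threshold))
    }
  }

  va <- cohort$variants
  vp <- smp$purity[match(paste(va$patient_id, va$timepoint), skey)]
  vinc <- smp$included[match(paste(va$patient_id, va$timepoint), skey)]
  va$vaf_corrected <- rep(NA_real_, nrow(va))
  va$loh <- rep(NA, nrow(va))
  vi <- which(vinc)
  if (length(vi)) {
    va$vaf_corrected[vi] <- correct_vaf_for_purity(va$vaf[vi], vp[vi])
    tp53 <- vi[va$gene[vi] == "TP53"]
    va$loh[tp53] <- detect_loh(va$vaf_corrected[tp53], het_range)
  }

  cohort$copynumber <- cn
  cohort$variants <- va
  attr(cohort, "called") <- TRUE
  attr(cohort, "het_range") <- het_range
  cohort
}

#' Compare a matched diagnosis/surgery pair
#'
#' Summarizes clonal change between the pre-treatment biopsy and the
#' residual-disease surgical sample of one patient: variants acquired and lost
#' (keyed on gene + protein change when available, else gene + class), per-gene
#' state transitions, and counts of amplification-evolution
#' (non-AMPLIFIED to AMPLIFIED) and amplification-extinction events.
#'
#' @param cohort a called `rd_cohort` containing both timepoints for the patient.
#' @param patient_id the patient to compare.
#' @return object of class `pair_evolution`: acquired/lost variant keys,
#'   `transitions` data.frame, event counts, and `identical_profile`.
#' @export
compare_matched_pair <- function(cohort, patient_id) {
  stopifnot(inherits(cohort, "rd_cohort"))
  if (!isTRUE(attr(cohort, "called"))) {
    rd_stop("cohort must be called first (see call_cohort)", "rd_state_error")
  }
  smp <- cohort$samples[cohort$samples$patient_id == patient_id, , drop = FALSE]
  if (!all(TIMEPOINTS %in% smp$timepoint)) {
    rd_stop(sprintf("patient %s lacks a matched DIAGNOSIS/SURGERY pair", patient_id),
            "rd_pairing_error")
  }
  vkey <- function(tp) {
    v <- cohort$variants[cohort$variants$patient_id == patient_id &
                           cohort$variants$timepoint == tp, , drop = FALSE]
    ifelse(!is.na(v$protein_change) & nzchar(v$protein_change),
           paste0(v$gene, ":", v$protein_change),
           paste0(v$gene, ":", v$variant_class))
  }
  pre_v <- vkey("DIAGNOSIS"); post_v <- vkey("SURGERY")
  acquired <- setdiff(post_v, pre_v)
  lost <- setdiff(pre_v, post_v)

  cnp <- cohort$copynumber[cohort$copynumber$patient_id == patient_id, , drop = FALSE]
  pre  <- cnp[cnp$timepoint == "DIAGNOSIS", c("gene", "state")]
  post <- cnp[cnp$timepoint == "SURGERY", c("gene", "state")]
  tr <- merge(pre, post, by = "gene", suffixes = c("_pre", "_post"))
  tr <- tr[order(tr$gene), , drop = FALSE]
  rownames(tr) <- NULL
  amp_evolution  <- sum(tr$state_pre != "AMPLIFIED" & tr$state_post == "AMPLIFIED",
                        na.rm = TRUE)
  amp_extinction <- sum(tr$state_pre == "AMPLIFIED" & tr$state_post != "AMPLIFIED",
                        na.rm = TRUE)
  structure(list(
    patient_id = patient_id,
    acquired = sort(acquired), lost = sort(lost),
    transitions = tr,
    n_state_changes = sum(tr$state_pre != tr$state_post, na.rm = TRUE),
    amp_evolution = amp_evolution, amp_extinction = amp_extinction,
    identical_profile = length(acquired) == 0L && length(lost) == 0L
  ), class = "pair_evolution")
}

#' @export
print.pair_evolution <- function(x, ...) {
  cat(sprintf("pair_evolution (%s): %d acquired, %d lost variants; %d state changes; %d amp evolution, %d amp extinction%s\n",
              x$patient_id, length(x$acquired), length(x$lost), x$n_state_changes,
              x$amp_evolution, x$amp_extinction,
              if (x$identical_profile) "; identical mutation profile" else ""))
  invisible(x)
}
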