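#' Collapse per-patient TP53 evidence across timepoints
#'
#' Merges a patient's diagnosis and surgery samples into one evidence record
#' for risk stratification. Mutation presence and the maximum corrected VAF
#' are unioned across timepoints (TP53 calls are stable between timepoints);
#' copy-number-derived evidence (copy loss) and LOH are taken from the
#' preferred timepoint — the surgical residual-disease sample when present,
#' else the diagnostic biopsy — because the analyses concern residual disease.
#' Patients with no included sample get an exclusion marker, not a stratum.
#'
#' @param cohort a called `rd_cohort`.
#' @return data.frame (class `tp53_evidence`) with one row per patient:
#'   `patient_id`, `excluded`, `has_mutation`, `max_vaf_corrected`, `loh`,
#'   `copy_loss`.
#' @export
collapse_patient_tp53 <- function(cohort) {
  stopifnot(inherits(cohort, "rd_cohort"))
  if (!isTRUE(attr(cohort, "called"))) {
    rd_stop("cohort must be called first (see call_cohort)", "rd_state_error")
  }
  smp <- cohort$samples
  patients <- sort(unique(smp$patient_id))
  va <- cohort$variants[cohort$variants$gene == "TP53", , drop = FALSE]
  cn <- cohort$copynumber[cohort$copynumber$gene == "TP53", , drop = FALSE]
  skey <- paste(smp$patient_id, smp$timepoint)
  va_inc <- smp$included[match(paste(va$patient_id, va$timepoint), skey)]
  va <- va[va_inc, , drop = FALSE]

  out <- lapply(patients, function(p) {
    s <- smp[smp$patient_id == p & smp$included, , drop = FALSE]
    if (nrow(s) == 0L) {
      return(data.frame(patient_id = p, excluded = TRUE, has_mutation = NA,
                        max_vaf_corrected = NA_real_, loh = NA, copy_loss = NA))
    }
    pref_tp <- if ("SURGERY" %in% s$timepoint) "SURGERY" else "DIAGNOSIS"
    v <- va[va$patient_id == p, , drop = FALSE]
    has_mut <- nrow(v) > 0L
    max_vaf <- if (has_mut) max(v$vaf_corrected, na.rm = TRUE) else NA_real_
    loh <- has_mut && any(v$loh, na.rm = TRUE)
    cnp <- cn[cn$patient_id == p & cn$timepoint == pref_tp, , drop = FALSE]
    copy_loss <- nrow(cnp) > 0L &&
      any(cnp$state %in% c("LOSS", "EXTENSIVE_LOSS"), na.rm = TRUE)
    data.frame(patient_id = p, excluded = FALSE, has_mutation = has_mut,
               max_vaf_corrected = max_vaf, loh = loh, copy_loss = copy_loss)
  })
  ev <- do.call(rbind, out)
  rownames(ev) <- NULL
  class(ev) <- c("tp53_evidence", "data.frame")
  ev
}

#' Graduated TP53 inactivation risk stratum
#'
#' Three-tier classifier of the depth of p53 inactivation:
#' \describe{
#'   \item{LOW}{no TP53 mutation, or only a subclonal mutation (maximum
#'     corrected VAF below `subclonal_cutoff`) with no compounding event.}
#'   \item{HIGH}{a TP53 mutation plus a compounding event — LOH or copy loss.
#'     A subclonal VAF with copy loss is still HIGH: copy loss itself
#'     depresses the VAF.}
#'   \item{MODERATE}{a clonal mutation with no compounding event.}
#' }
#' The 25\% subclonality cutoff avoids the ambiguity high-copy tumors introduce
#' in the VAF scale.
#'
#' @param evidence data.frame from [collapse_patient_tp53()] (or with the same
#'   columns).
#' @param subclonal_cutoff corrected-VAF fraction below which a lone mutation
#'   is considered subclonal, default 0.25.
#' @return the evidence data.frame with `stratum` (factor LOW/MODERATE/HIGH,
#'   NA for excluded patients) and `compound` columns appended.
#' @export
classify_tp53 <- function(evidence, subclonal_cutoff = 0.25) {
  need <- c("patient_id", "has_mutation", "loh", "copy_loss", "max_vaf_corrected")
  evidence <- check_columns(as.data.frame(evidence), need, "evidence")
  if (is.null(evidence$excluded)) evidence$excluded <- FALSE
  n <- nrow(evidence)
  stratum <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (isTRUE(evidence$excluded[i])) next
    if (!isTRUE(evidence$has_mutation[i])) {
      stratum[i] <- "LOW"
    } else if (isTRUE(evidence$loh[i]) || isTRUE(evidence$copy_loss[i])) {
      stratum[i] <- "HIGH"
    } else if (!is.na(evidence$max_vaf_corrected[i]) &&
               evidence$max_vaf_corrected[i] < subclonal_cutoff) {
      stratum[i] <- "LOW"
    } else {
      stratum[i] <- "MODERATE"
    }
  }
  evidence$stratum <- factor(stratum, levels = RISK_STRATA)
  evidence$compound <- compound_flag(evidence$stratum)
  class(evidence) <- c("tp53_strata", "data.frame")
  evidence
}

#' Compound TP53 mutation flag
#'
#' A compound TP53 mutation is a point mutation co-occurring with a second
#' inactivating event (LOH or copy loss) — exactly the HIGH stratum.
#'
#' @param stratum factor/character vector of strata.
#' @return logical vector (NA where the stratum is NA).
#' @export
compound_flag <- function(stratum) {
  as.character(stratum) == "HIGH"
}

#' Overlap counts between two patient sets
#'
#' Inclusion-exclusion bookkeeping for co-occurrence summaries (e.g. the
#' MYC-amplified vs compound-TP53 overlap): exclusive counts, intersection,
#' union, and the intersection as an integer percentage of the union.
#'
#' @param setA,setB vectors of patient identifiers.
#' @return list with `a_only`, `b_only`, `intersection`, `union`,
#'   `intersection_pct`.
#' @export
overlap_counts <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  i <- length(intersect(setA, setB))
  u <- length(union(setA, setB))
  list(a_only = length(setA) - i,
       b_only = length(setB) - i,
       intersection = i,
       union = u,
       intersection_pct = if (u == 0L) NA_real_ else round(100 * i / u))
}
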