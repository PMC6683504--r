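# Per-patient copy-number view of a called cohort: one row per patient per
# gene, taken from the preferred timepoint (the surgical residual-disease
# sample when present, else the diagnostic biopsy), included samples only.
patient_cn <- function(cohort, genes = NULL) {
  stopifnot(inherits(cohort, "rd_cohort"))
  if (!isTRUE(attr(cohort, "called"))) {
    rd_stop("cohort must be called first (see call_cohort)", "rd_state_error")
  }
  smp <- cohort$samples[cohort$samples$included, , drop = FALSE]
  pref <- do.call(rbind, lapply(split(smp, smp$patient_id), function(s) {
    tp <- if ("SURGERY" %in% s$timepoint) "SURGERY" else "DIAGNOSIS"
    s[s$timepoint == tp, c("patient_id", "timepoint"), drop = FALSE]
  }))
  cn <- cohort$copynumber
  if (!is.null(genes)) cn <- cn[cn$gene %in% genes, , drop = FALSE]
  out <- merge(pref, cn, by = c("patient_id", "timepoint"))
  out[order(out$patient_id, out$gene), , drop = FALSE]
}

#' Two-stage copy-number recurrence screen
#'
#' Exploratory locus-by-locus screen relating somatic copy number in
#' residual-disease tumors to recurrence, in two stages:
#' \enumerate{
#'   \item per locus, one-way ANOVA compares absolute (purity-corrected) copy
#'     number between patients who recurred and those who did not;
#'   \item stage-1 survivors are grouped by aberration status in the direction
#'     of the stage-1 mean difference (gain: state above NORMAL; loss: state
#'     below NORMAL) and tested for time-to-recurrence (DFS) by log-rank.
#' }
#' A locus is positive when it passes both stages. No multiplicity correction
#' is applied across loci, reflecting the exploratory framing; a BH-adjusted
#' stage-1 column (`q1`) is emitted alongside for users who want it.
#'
#' @param cohort a called `rd_cohort` with clinical records.
#' @param alpha1,alpha2 stage cutoffs, both 0.05 by default.
#' @return data.frame of class `screen_result`, one row per locus: `gene`,
#'   `n`, `stage1_p`, `q1`, `direction` ("gain"/"loss"), `n_aberrant`,
#'   `stage2_p`, `positive`, `diagnostic`.
#' @export
cnv_recurrence_screen <- function(cohort, alpha1 = 0.05, alpha2 = 0.05) {
  pc <- patient_cn(cohort)
  cl <- cohort$clinical
  pc <- pc[pc$patient_id %in% cl$patient_id, , drop = FALSE]
  i <- match(pc$patient_id, cl$patient_id)
  pc$recurred <- cl$recurred[i]
  pc$dfs_months <- cl$dfs_months[i]
  pc$dfs_event <- cl$dfs_event[i]

  rows <- lapply(split(pc, pc$gene), function(d) {
    out <- data.frame(gene = d$gene[1], n = nrow(d), stage1_p = NA_real_,
                      direction = NA_character_, n_aberrant = NA_integer_,
                      stage2_p = NA_real_, positive = FALSE,
                      diagnostic = NA_character_, stringsAsFactors = FALSE)
    rec <- d$cn_corrected[d$recurred]
    non <- d$cn_corrected[!d$recurred]
    if (length(rec) < 2L || length(non) < 2L) {
      out$diagnostic <- "stage1 skipped: fewer than 2 patients in a recurrence class"
      return(out)
    }
    if (length(unique(d$cn_corrected)) < 2L) {
      out$diagnostic <- "stage1 skipped: single observed copy-number value"
      return(out)
    }
    a <- one_way_anova(list(rec, non))
    out$stage1_p <- a$p
    out$direction <- if (mean(rec) - mean(non) > 0) "gain" else "loss"
    aberrant <- if (out$direction == "gain") {
      cn_state_factor(d$state) > "NORMAL"
    } else {
      cn_state_factor(d$state) < "NORMAL"
    }
    out$n_aberrant <- sum(aberrant, na.rm = TRUE)
    if (length(unique(aberrant)) < 2L) {
      out$diagnostic <- "stage2 skipped: aberration grouping is degenerate"
      return(out)
    }
    lr <- logrank_test(d$dfs_months, d$dfs_event, aberrant)
    out$stage2_p <- lr$p
    out$positive <- !is.na(out$stage1_p) && out$stage1_p < alpha1 &&
      !is.na(out$stage2_p) && out$stage2_p < alpha2
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$q1 <- bh_fdr(res$stage1_p)
  res <- res[c("gene", "n", "stage1_p", "q1", "direction", "n_aberrant",
               "stage2_p", "positive", "diagnostic")]
  class(res) <- c("screen_result", "data.frame")
  attr(res, "alpha1") <- alpha1
  attr(res, "alpha2") <- alpha2
  res
}

#' Survival by copy-number state of one gene
#'
#' Two-group Kaplan-Meier/log-rank/hazard-ratio comparison of DFS and OS,
#' splitting patients on the called state of a single panel gene:
#' `loss_vs_not` (state below NORMAL), `gain_vs_not` (above NORMAL), or
#' `amplified_vs_not`.
#'
#' @param cohort a called `rd_cohort`.
#' @param gene panel gene symbol.
#' @param split one of "loss_vs_not", "gain_vs_not", "amplified_vs_not".
#' @param covariates optional data.frame of per-patient adjustment columns
#'   (rows matched to the patients analyzed, in patient order).
#' @return list of class `survival_contrast` with `group_n` and, per endpoint
#'   (`dfs`, `os`), the `hazard_ratio_result` and `logrank_result`; or a
#'   degenerate marker (`error` field) when a split group is empty.
#' @export
survival_by_copy_state <- function(cohort, gene,
                                   split = c("loss_vs_not", "gain_vs_not",
                                             "amplified_vs_not"),
                                   covariates = NULL) {
  split <- match.arg(split)
  pc <- patient_cn(cohort, genes = gene)
  if (nrow(pc) == 0L) rd_stop(sprintf("gene '%s' not on panel", gene), "rd_coverage_error")
  cl <- cohort$clinical
  pc <- pc[pc$patient_id %in% cl$patient_id, , drop = FALSE]
  st <- cn_state_factor(pc$state)
  ind <- switch(split,
                loss_vs_not = st < "NORMAL",
                gain_vs_not = st > "NORMAL",
                amplified_vs_not = st == "AMPLIFIED")
  if (length(unique(ind[!is.na(ind)])) < 2L) {
    return(structure(list(gene = gene, split = split,
                          error = "degenerate split: a group is empty",
                          group_n = table(ind)),
                     class = "survival_contrast"))
  }
  i <- match(pc$patient_id, cl$patient_id)
  one <- function(time, event) {
    list(hr = hazard_ratio(time, event, ind, covariates = covariates),
         logrank = logrank_test(time, event, ind),
         km_aberrant = kaplan_meier(time[ind], event[ind]),
         km_other = kaplan_meier(time[!ind], event[!ind]))
  }
  structure(list(
    gene = gene, split = split,
    group_n = c(aberrant = sum(ind), other = sum(!ind)),
    dfs = one(cl$dfs_months[i], cl$dfs_event[i]),
    os = one(cl$os_months[i], cl$os_event[i])
  ), class = "survival_contrast")
}

#' @export
print.survival_contrast <- function(x, ...) {
  if (!is.null(x$error)) {
    cat(sprintf("survival_contrast (%s, %s): %s\n", x$gene, x$split, x$error))
    return(invisible(x))
  }
  cat(sprintf("survival_contrast (%s, %s): n = %d vs %d\n",
              x$gene, x$split, x$group_n[["aberrant"]], x$group_n[["other"]]))
  cat("  DFS: "); print(x$dfs$hr)
  cat("  OS:  "); print(x$os$hr)
  invisible(x)
}

#' Survival across the three TP53 risk strata
#'
#' Omnibus log-rank across LOW/MODERATE/HIGH for DFS and OS, plus the
#' HIGH-vs-rest (compound TP53) hazard-ratio contrast and per-stratum median
#' survival. An empty stratum reduces the omnibus degrees of freedom with a
#' warning.
#'
#' @param cohort an `rd_cohort` with clinical records.
#' @param strata a `tp53_strata` data.frame from [classify_tp53()].
#' @param covariates optional adjustment columns for the HIGH-vs-rest model.
#' @return list of class `stratum_survival` with per-endpoint omnibus
#'   results, compound contrasts, and median survival by stratum.
#' @export
survival_by_stratum <- function(cohort, strata, covariates = NULL) {
  stopifnot(inherits(cohort, "rd_cohort"))
  st <- as.data.frame(strata)
  st <- st[!is.na(st$stratum), , drop = FALSE]
  cl <- cohort$clinical
  st <- st[st$patient_id %in% cl$patient_id, , drop = FALSE]
  i <- match(st$patient_id, cl$patient_id)
  grp <- factor(as.character(st$stratum), levels = RISK_STRATA)
  if (any(table(grp) == 0)) {
    warning("empty stratum: omnibus degrees of freedom reduced")
  }
  high <- grp == "HIGH"
  one <- function(time, event) {
    list(omnibus = logrank_test(time, event, grp),
         compound = if (length(unique(high)) == 2L)
           list(hr = hazard_ratio(time, event, high, covariates = covariates),
                logrank = logrank_test(time, event, high)) else NULL,
         median_by_stratum = vapply(levels(droplevels(grp)), function(l) {
           km_median(kaplan_meier(time[grp == l], event[grp == l]))
         }, 0))
  }
  structure(list(
    n_by_stratum = table(grp),
    dfs = one(cl$dfs_months[i], cl$dfs_event[i]),
    os = one(cl$os_months[i], cl$os_event[i])
  ), class = "stratum_survival")
}

#' @export
print.stratum_survival <- function(x, ...) {
  cat("survival by TP53 risk stratum: n =",
      paste(sprintf("%s %d", names(x$n_by_stratum), x$n_by_stratum), collapse = ", "), "\n")
  cat(sprintf("  DFS omnibus log-rank p = %.4g; OS p = %.4g\n",
              x$dfs$omnibus$p, x$os$omnibus$p))
  if (!is.null(x$dfs$compound)) {
    cat("  HIGH vs rest DFS: "); print(x$dfs$compound$hr)
  }
  invisible(x)
}

#' Lymphocyte depletion through chemotherapy
#'
#' Total-lymphocyte percentage before vs after chemotherapy: unpaired t test
#' on all pre vs all post samples, paired t on matched pairs, and paired t
#' within non-relapsers and relapsers separately. Subgroups with fewer than
#' two pairs are skipped with a diagnostic. Lymphocyte scoring comes from
#' slide review, so samples excluded from molecular analyses still
#' contribute here.
#'
#' @param cohort an `rd_cohort`.
#' @return list of class `lymphocyte_result`: `unpaired`, `paired`,
#'   `paired_non_relapse`, `paired_relapse`, each with n's, or a skip
#'   diagnostic string.
#' @export
lymphocyte_depletion <- function(cohort) {
  stopifnot(inherits(cohort, "rd_cohort"))
  smp <- cohort$samples[!is.na(cohort$samples$lymphocyte_pct), , drop = FALSE]
  pre <- smp[smp$timepoint == "DIAGNOSIS", , drop = FALSE]
  post <- smp[smp$timepoint == "SURGERY", , drop = FALSE]
  unpaired <- if (nrow(pre) >= 2L && nrow(post) >= 2L) {
    c(t_test2(pre$lymphocyte_pct, post$lymphocyte_pct, paired = FALSE),
      list(n_pre = nrow(pre), n_post = nrow(post)))
  } else "skipped: fewer than 2 samples in a timepoint"

  both <- intersect(pre$patient_id, post$patient_id)
  pair_test <- function(ids) {
    if (length(ids) < 2L) return("skipped: fewer than 2 matched pairs")
    a <- pre$lymphocyte_pct[match(ids, pre$patient_id)]
    b <- post$lymphocyte_pct[match(ids, post$patient_id)]
    c(t_test2(a, b, paired = TRUE), list(n_pairs = length(ids)))
  }
  cl <- cohort$clinical
  rec <- cl$recurred[match(both, cl$patient_id)]
  structure(list(
    unpaired = unpaired,
    paired = pair_test(both),
    paired_non_relapse = pair_test(both[!rec %in% TRUE]),
    paired_relapse = pair_test(both[rec %in% TRUE])
  ), class = "lymphocyte_result")
}
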