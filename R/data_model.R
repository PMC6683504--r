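#' Cohort container and table readers
#'
#' An `rd_cohort` bundles the four tables the pipeline consumes:
#' \describe{
#'   \item{samples}{one row per (patient_id, timepoint) biopsy: purity as a
#'     fraction in (0,1], lymphocyte percentage (or NA), and an `included` flag
#'     marking whether the sample meets the 60\% tumor-cellularity gate used for
#'     molecular analyses. Low-purity samples are flagged, never dropped.}
#'   \item{variants}{per-sample variant calls: gene, protein_change,
#'     variant_class, vaf (observed fraction).}
#'   \item{copynumber}{per-sample per-gene copy-number estimates from the
#'     targeted panel.}
#'   \item{clinical}{per-patient follow-up: DFS/OS months and events,
#'     recurrence flag, age, nodal status, RCB class (I_II or III).}
#' }
#' Rows violating numeric invariants are rejected with row-level diagnostics
#' collected in `$rejected`; structural problems (missing columns, unknown
#' timepoint labels, duplicate keys) are errors.
#'
#' @param variants,copynumber,clinical data.frames with the columns documented
#'   in the package README; `clinical` carries `purity_pct`,
#'   `lymphocyte_pct_pre` and `lymphocyte_pct_post`, which populate the
#'   per-sample table.
#' @param min_purity inclusion threshold on tumor purity (fraction), default 0.60.
#' @return an object of class `rd_cohort`.
#' @export
rd_cohort <- function(variants, copynumber, clinical, min_purity = 0.60) {
  variants   <- check_columns(variants, c("patient_id", "timepoint", "gene",
                                          "protein_change", "variant_class", "vaf"),
                              "variants")
  copynumber <- check_columns(copynumber, c("patient_id", "timepoint", "gene",
                                            "copy_number"), "copynumber")
  clinical   <- check_columns(clinical, c("patient_id", "dfs_months", "dfs_event",
                                          "os_months", "os_event", "recurred",
                                          "age", "node_positive", "rcb_class",
                                          "purity_pct", "lymphocyte_pct_pre",
                                          "lymphocyte_pct_post"), "clinical")

  check_timepoints(variants$timepoint, "variants")
  check_timepoints(copynumber$timepoint, "copynumber")

  rejected <- list()
  keep <- function(tab, ok, reason) {
    bad <- which(!ok)
    if (length(bad)) {
      rejected[[length(rejected) + 1L]] <<- data.frame(
        table = tab, row = bad, reason = reason[bad], stringsAsFactors = FALSE)
    }
    bad
  }

  # variant invariants: VAF a fraction, class in vocabulary
  ok_vaf   <- is.finite(variants$vaf) & variants$vaf >= 0 & variants$vaf <= 1
  ok_class <- variants$variant_class %in% VARIANT_CLASSES
  reason <- ifelse(!ok_vaf, sprintf("vaf %.4g outside [0, 1]", variants$vaf),
                   sprintf("unknown variant_class '%s'", variants$variant_class))
  bad <- keep("variants", ok_vaf & ok_class, reason)
  if (length(bad)) variants <- variants[-bad, , drop = FALSE]

  # copy-number invariant: non-negative
  ok_cn <- is.finite(copynumber$copy_number) & copynumber$copy_number >= 0
  bad <- keep("copynumber", ok_cn,
              sprintf("copy_number %.4g negative or non-finite", copynumber$copy_number))
  if (length(bad)) copynumber <- copynumber[-bad, , drop = FALSE]

  # clinical invariants
  if (anyDuplicated(clinical$patient_id)) {
    rd_stop("duplicate patient_id in clinical table", "rd_uniqueness_error")
  }
  if (!all(clinical$rcb_class %in% c("I_II", "III"))) {
    rd_stop("rcb_class must be 'I_II' or 'III'", "rd_value_error")
  }
  ok_t  <- clinical$dfs_months >= 0 & clinical$os_months >= 0 &
           clinical$dfs_months <= clinical$os_months
  ok_r  <- !(clinical$recurred & !clinical$dfs_event)
  reason <- ifelse(!ok_t, "requires 0 <= dfs_months <= os_months",
                   "recurred implies dfs_event")
  bad <- keep("clinical", ok_t & ok_r, reason)
  if (length(bad)) clinical <- clinical[-bad, , drop = FALSE]

  # per-sample table from the molecular rows
  key <- unique(rbind(variants[c("patient_id", "timepoint")],
                      copynumber[c("patient_id", "timepoint")]))
  key <- key[order(key$patient_id, match(key$timepoint, TIMEPOINTS)), , drop = FALSE]
  if (anyDuplicated(paste(key$patient_id, key$timepoint))) {
    rd_stop("duplicate (patient_id, timepoint) sample", "rd_uniqueness_error")
  }
  i <- match(key$patient_id, clinical$patient_id)
  purity <- clinical$purity_pct[i]
  # tables may give purity as percent; store as a fraction in (0, 1]
  purity <- ifelse(!is.na(purity) & purity > 1, purity / 100, purity)
  lymph <- ifelse(key$timepoint == "DIAGNOSIS",
                  clinical$lymphocyte_pct_pre[i], clinical$lymphocyte_pct_post[i])
  samples <- data.frame(
    patient_id = key$patient_id, timepoint = key$timepoint,
    purity = purity, lymphocyte_pct = lymph,
    included = !is.na(purity) & purity >= min_purity,
    stringsAsFactors = FALSE)
  rownames(samples) <- NULL

  structure(list(
    samples = samples,
    variants = canonical_order(variants),
    copynumber = canonical_order(copynumber),
    clinical = clinical[order(clinical$patient_id), , drop = FALSE],
    rejected = if (length(rejected)) do.call(rbind, rejected) else
      data.frame(table = character(), row = integer(), reason = character())
  ), class = "rd_cohort")
}

check_columns <- function(df, cols, name) {
  if (!is.data.frame(df)) rd_stop(sprintf("`%s` must be a data.frame", name), "rd_schema_error")
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    rd_stop(sprintf("table '%s' is missing required column(s): %s",
                    name, paste(miss, collapse = ", ")), "rd_schema_error")
  }
  rownames(df) <- NULL
  df
}

check_timepoints <- function(tp, name) {
  bad <- setdiff(unique(tp), TIMEPOINTS)
  if (length(bad)) {
    rd_stop(sprintf("table '%s' has unknown timepoint label(s): %s (expected %s)",
                    name, paste(bad, collapse = ", "),
                    paste(TIMEPOINTS, collapse = "/")), "rd_value_error")
  }
}

canonical_order <- function(df) {
  df <- df[order(df$patient_id, match(df$timepoint, TIMEPOINTS), df$gene), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a cohort from headered TSV files
#'
#' The canonical interchange format is tab-separated text with one file each
#' for variants, copy number and clinical records (column layouts in the
#' README). Purity given as a percentage is converted to a fraction at read
#' time.
#'
#' @param variants_path,copynumber_path,clinical_path paths to TSV files.
#' @param min_purity inclusion threshold passed to [rd_cohort()].
#' @return an `rd_cohort`.
#' @export
read_cohort <- function(variants_path, copynumber_path, clinical_path,
                        min_purity = 0.60) {
  rd_cohort(read_tsv(variants_path), read_tsv(copynumber_path),
            read_tsv(clinical_path), min_purity = min_purity)
}

read_tsv <- function(path) {
  if (!file.exists(path)) rd_stop(sprintf("file not found: %s", path), "rd_io_error")
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' Write a cohort to canonical TSV files
#'
#' Writes `variants.tsv`, `copynumber.tsv` and `clinical.tsv` into `dir` in a
#' canonical row/column order, so that write-read-write round trips are
#' byte-stable.
#'
#' @param cohort an `rd_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rd_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cl <- cohort$clinical
  # purity is stored as a fraction; the interchange column is a percentage
  cl$purity_pct <- ifelse(!is.na(cl$purity_pct) & cl$purity_pct <= 1,
                          cl$purity_pct * 100, cl$purity_pct)
  paths <- c(variants   = file.path(dir, "variants.tsv"),
             copynumber = file.path(dir, "copynumber.tsv"),
             clinical   = file.path(dir, "clinical.tsv"))
  write_one <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  base_cols <- list(
    variants = c("patient_id", "timepoint", "gene", "protein_change",
                 "variant_class", "vaf"),
    copynumber = c("patient_id", "timepoint", "gene", "copy_number"))
  write_one(cohort$variants[base_cols$variants], paths["variants"])
  write_one(cohort$copynumber[base_cols$copynumber], paths["copynumber"])
  write_one(cl, paths["clinical"])
  invisible(paths)
}

#' @export
print.rd_cohort <- function(x, ...) {
  cat(sprintf("rd_cohort: %d patients, %d samples (%d included at purity >= 0.60)\n",
              nrow(x$clinical), nrow(x$samples), sum(x$samples$included)))
  cat(sprintf("  %d variant calls, %d copy-number rows",
              nrow(x$variants), nrow(x$copynumber)))
  if (!is.null(attr(x, "called")) && isTRUE(attr(x, "called"))) cat(" [states called]")
  cat("\n")
  if (nrow(x$rejected)) {
    cat(sprintf("  %d rejected row(s); see $rejected\n", nrow(x$rejected)))
  }
  invisible(x)
}

#' Read variant calls from a VCF subset
#'
#' Optional convenience reader for a VCF v4.2 subset: one `VariantCall` per
#' PASS record, allele frequency taken from the `AF` FORMAT field (or INFO when
#' FORMAT lacks it) and the gene symbol from the `GENE` INFO key. Non-PASS
#' records are skipped and counted in the `skipped` attribute. Requires the
#' VariantAnnotation package.
#'
#' @param path VCF file path.
#' @param sample_id sample column to read AF from when FORMAT carries it.
#' @return data.frame of variant calls with attribute `skipped`.
#' @export
read_variants_vcf <- function(path, sample_id = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    rd_stop("read_variants_vcf requires the VariantAnnotation package",
            "rd_dependency_error")
  }
  vcf <- VariantAnnotation::readVcf(path)
  n <- length(vcf)
  if (n == 0L) {
    out <- data.frame(gene = character(), protein_change = character(),
                      variant_class = character(), vaf = numeric())
    attr(out, "skipped") <- 0L
    return(out)
  }
  filt <- VariantAnnotation::filt(vcf)
  pass <- is.na(filt) | filt %in% c("PASS", ".")
  skipped <- sum(!pass)
  vcf <- vcf[pass]
  info <- VariantAnnotation::info(vcf)
  gene <- if ("GENE" %in% names(info)) as.character(info$GENE) else
    rep(NA_character_, sum(pass))
  af <- NULL
  gn <- VariantAnnotation::geno(vcf)
  if ("AF" %in% names(gn)) {
    m <- gn$AF
    col <- if (!is.null(sample_id) && sample_id %in% colnames(m)) sample_id else 1L
    af <- vapply(seq_len(nrow(m)), function(i) as.numeric(m[[i, col]][1]), 0)
  } else if ("AF" %in% names(info)) {
    af <- vapply(info$AF, function(v) as.numeric(v[1]), 0)
  }
  if (is.null(af)) rd_stop("VCF has no AF field in FORMAT or INFO", "rd_format_error")
  out <- data.frame(gene = gene,
                    protein_change = NA_character_,
                    variant_class = "OTHER",
                    vaf = af, stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}
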