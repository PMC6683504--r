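#' Write / read an expression table
#'
#' Headered TSV with gene metadata columns (`gene`, `cytoband`, `coding`,
#' `length_bp`) followed by one column per sample. A header comment line
#' (`# values: rpkm` or `# values: counts`) flags the value scale.
#'
#' @param expr an `expr_matrix`.
#' @param path output file.
#' @param values "rpkm" or "counts".
#' @return invisibly, `path`.
#' @export
write_expression <- function(expr, path, values = c("rpkm", "counts")) {
  values <- match.arg(values)
  stopifnot(inherits(expr, "expr_matrix"))
  df <- cbind(expr$genes, as.data.frame(expr$values, check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# values: %s", values), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @return `read_expression`: an `expr_matrix` with attribute `values_type`.
#' @export
read_expression <- function(path) {
  first <- readLines(path, n = 1L)
  vt <- if (grepl("^# values:", first)) trimws(sub("^# values:", "", first)) else "rpkm"
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  meta_cols <- c("gene", "cytoband", "coding", "length_bp")
  df <- check_columns(df, meta_cols, "expression")
  vals <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  rownames(vals) <- df$gene
  out <- expression_matrix(vals, df[meta_cols])
  attr(out, "values_type") <- vt
  out
}

#' Write a simulated cohort to disk
#'
#' Emits the canonical analysis tables plus `normals.tsv`,
#' `het_normals.tsv` and (when present) `expression.tsv` into `dir`, and the
#' ground-truth tables into a separate `truth/` subdirectory so they can never
#' be mistaken for analysis inputs.
#'
#' @param sim an `rd_sim` from [generate_cohort()].
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "rd_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(sim$cohort, dir)
  w <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  w(sim$normals, "normals.tsv")
  w(data.frame(vaf = sim$het_normals), "het_normals.tsv")
  if (!is.null(sim$expression)) {
    write_expression(sim$expression, file.path(dir, "expression.tsv"))
  }
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  utils::write.table(sim$truth$patients, file.path(tdir, "patients.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$cn_events, file.path(tdir, "cn_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a pipeline configuration file
#'
#' YAML file with two optional top-level blocks: `cohort` (any
#' [cohort_config()] argument) and `analysis` (thresholds: `k`,
#' `amp_threshold`, `extensive_loss_threshold`, `subclonal_cutoff`, `alpha1`,
#' `alpha2`, `fdr`). Missing fields take the package defaults.
#'
#' @param path YAML file.
#' @return list with `cohort` (a `cohort_config`) and `analysis` (named list).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) rd_stop(sprintf("config not found: %s", path), "rd_config_error")
  raw <- yaml::read_yaml(path)
  co <- raw$cohort
  if (!is.null(co)) {
    for (f in c("mutation_freq", "cn_event_freq", "stratum_hr", "lymphocyte")) {
      if (!is.null(co[[f]])) co[[f]] <- unlist(co[[f]])
    }
    if (!is.null(co$purity_range)) co$purity_range <- as.numeric(unlist(co$purity_range))
  }
  cohort <- do.call(cohort_config, if (is.null(co)) list() else co)
  analysis <- utils::modifyList(read_pipeline_config_defaults(),
                                if (is.null(raw$analysis)) list() else raw$analysis)
  list(cohort = cohort, analysis = analysis)
}

#' Default analysis thresholds
#'
#' The thresholds the pipeline uses when a config file does not override them:
#' reference-range width k = 3, amplification above 4.99 copies, extensive
#' loss below 0.5, subclonality below a corrected VAF of 0.25, screen stage
#' cutoffs of 0.05, and a 10\% FDR for differential expression.
#'
#' @return named list of thresholds.
#' @export
read_pipeline_config_defaults <- function() {
  list(k = 3, amp_threshold = 4.99, extensive_loss_threshold = 0.5,
       subclonal_cutoff = 0.25, alpha1 = 0.05, alpha2 = 0.05, fdr = 0.10)
}

#' Run the pipeline end to end
#'
#' Executes the configured stages in order — `simulate` (or load existing
#' tables), `call`, `stratify`, `survive`, `screen`, `express` — writing one
#' result table per stage into `output_dir` plus a `manifest.json` recording
#' the config hash, seed, package version, input-table hashes and stage
#' timings. Re-running with the same config and seed reproduces the result
#' tables exactly.
#'
#' @param config path to a YAML config (see [read_pipeline_config()]) or the
#'   list that function returns.
#' @param output_dir directory for inputs and results.
#' @param stages character vector of stages, or "all".
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, output_dir, stages = "all") {
  all_stages <- c("simulate", "call", "stratify", "survive", "screen", "express")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  if (is.character(config)) {
    config_hash <- unname(tools::md5sum(config))
    config <- read_pipeline_config(config)
  } else {
    config_hash <- NA_character_
  }
  an <- config$analysis
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list()
  timings <- list()
  w <- function(df, f) utils::write.table(df, file.path(output_dir, f),
                                          sep = "\t", quote = FALSE, row.names = FALSE)
  need <- function(files, stage) {
    miss <- files[!file.exists(file.path(output_dir, files))]
    if (length(miss)) {
      rd_stop(sprintf("stage '%s' requires missing upstream table(s): %s",
                      stage, paste(miss, collapse = ", ")), "rd_stage_error")
    }
  }
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  if ("simulate" %in% stages) {
    state$sim <- tick("simulate", {
      sim <- generate_cohort(config$cohort)
      write_sim(sim, output_dir)
      sim
    })
    state$cohort <- state$sim$cohort
    state$expression <- state$sim$expression
  }

  load_cohort <- function() {
    need(c("variants.tsv", "copynumber.tsv", "clinical.tsv"), "call")
    read_cohort(file.path(output_dir, "variants.tsv"),
                file.path(output_dir, "copynumber.tsv"),
                file.path(output_dir, "clinical.tsv"))
  }

  if ("call" %in% stages) {
    state$called <- tick("call", {
      if (is.null(state$cohort)) state$cohort <- load_cohort()
      need("normals.tsv", "call")
      normals <- read_tsv(file.path(output_dir, "normals.tsv"))
      ranges <- build_reference_ranges(normals, k = an$k)
      het <- if (file.exists(file.path(output_dir, "het_normals.tsv"))) {
        build_reference_range(read_tsv(file.path(output_dir, "het_normals.tsv"))$vaf,
                              k = an$k, assay_id = "TP53_het")
      } else default_het_range()
      called <- call_cohort(state$cohort, ranges, het_range = het,
                            amp_threshold = an$amp_threshold,
                            extensive_loss_threshold = an$extensive_loss_threshold)
      w(called$copynumber, "called_states.tsv")
      called
    })
  }

  if ("stratify" %in% stages) {
    state$strata <- tick("stratify", {
      if (is.null(state$called)) rd_stop(
        "stage 'stratify' requires the 'call' stage (called_states.tsv)",
        "rd_stage_error")
      ev <- collapse_patient_tp53(state$called)
      st <- classify_tp53(ev, subclonal_cutoff = an$subclonal_cutoff)
      out <- as.data.frame(st)
      names(out)[names(out) == "compound"] <- "compound_flag"
      w(out, "strata.tsv")
      st
    })
  }

  if ("survive" %in% stages) {
    state$survival <- tick("survive", {
      if (is.null(state$called) || is.null(state$strata)) rd_stop(
        "stage 'survive' requires 'call' and 'stratify'", "rd_stage_error")
      tp53 <- survival_by_copy_state(state$called, "TP53", "loss_vs_not")
      myc <- survival_by_copy_state(state$called, "MYC", "amplified_vs_not")
      strat <- survival_by_stratum(state$called, state$strata)
      lymph <- lymphocyte_depletion(state$called)
      row_of <- function(label, x) {
        if (!is.null(x$error)) {
          return(data.frame(comparison = label, n_aberrant = NA, n_other = NA,
                            dfs_hr = NA, dfs_ci_lower = NA, dfs_ci_upper = NA,
                            dfs_logrank_p = NA, os_hr = NA, os_logrank_p = NA,
                            note = x$error))
        }
        data.frame(comparison = label,
                   n_aberrant = x$group_n[["aberrant"]],
                   n_other = x$group_n[["other"]],
                   dfs_hr = x$dfs$hr$hr, dfs_ci_lower = x$dfs$hr$ci_lower,
                   dfs_ci_upper = x$dfs$hr$ci_upper,
                   dfs_logrank_p = x$dfs$logrank$p,
                   os_hr = x$os$hr$hr, os_logrank_p = x$os$logrank$p,
                   note = "")
      }
      tab <- rbind(row_of("TP53_loss_vs_not", tp53),
                   row_of("MYC_amplified_vs_not", myc))
      if (!is.null(strat$dfs$compound)) {
        tab <- rbind(tab, data.frame(
          comparison = "TP53_compound_vs_rest",
          n_aberrant = unname(strat$n_by_stratum[["HIGH"]]),
          n_other = sum(strat$n_by_stratum) - unname(strat$n_by_stratum[["HIGH"]]),
          dfs_hr = strat$dfs$compound$hr$hr,
          dfs_ci_lower = strat$dfs$compound$hr$ci_lower,
          dfs_ci_upper = strat$dfs$compound$hr$ci_upper,
          dfs_logrank_p = strat$dfs$compound$logrank$p,
          os_hr = strat$os$compound$hr$hr,
          os_logrank_p = strat$os$compound$logrank$p,
          note = sprintf("omnibus dfs p=%.4g, os p=%.4g",
                         strat$dfs$omnibus$p, strat$os$omnibus$p)))
      }
      w(tab, "survival_contrasts.tsv")
      list(tp53 = tp53, myc = myc, strata = strat, lymphocytes = lymph, table = tab)
    })
  }

  if ("screen" %in% stages) {
    state$screen <- tick("screen", {
      if (is.null(state$called)) rd_stop(
        "stage 'screen' requires 'call'", "rd_stage_error")
      sc <- cnv_recurrence_screen(state$called, alpha1 = an$alpha1,
                                  alpha2 = an$alpha2)
      w(as.data.frame(sc), "screen_results.tsv")
      sc
    })
  }

  if ("express" %in% stages) {
    state$express <- tick("express", {
      if (is.null(state$expression)) {
        ep <- file.path(output_dir, "expression.tsv")
        if (!file.exists(ep)) rd_stop(
          "stage 'express' requires expression.tsv", "rd_stage_error")
        state$expression <- read_expression(ep)
        if (identical(attr(state$expression, "values_type"), "counts")) {
          vals <- rpkm(state$expression$values,
                       state$expression$genes$length_bp,
                       colSums(state$expression$values))
          state$expression <- expression_matrix(vals, state$expression$genes)
        }
      }
      if (is.null(state$strata)) rd_stop(
        "stage 'express' requires 'stratify'", "rd_stage_error")
      st <- state$strata
      sm <- colnames(state$expression$values)
      grp <- factor(ifelse(st$compound[match(sm, st$patient_id)],
                           "compound", "other"), levels = c("other", "compound"))
      de <- differential_expression(state$expression, grp, fdr = an$fdr)
      ta <- transcriptional_amplification(de)
      reg_groups <- factor(ifelse(
        smad4_gain_patients(state$called, sm), "gain", "other"),
        levels = c("other", "gain"))
      reg <- regional_screen(state$expression, c("18q21.1", "18q21.2"),
                             reg_groups, coding_only = TRUE, fdr = an$fdr)
      w(as.data.frame(de), "de_results.tsv")
      if (!is.null(reg$de)) w(as.data.frame(reg$de), "regional_screen.tsv")
      list(de = de, transcriptional_amplification = ta, regional = reg)
    })
  }

  manifest <- list(
    package = "rdscreen",
    version = as.character(utils::packageVersion("rdscreen")),
    config_hash = config_hash,
    seed = config$cohort$seed,
    stages = stages,
    analysis = an,
    timings_sec = timings,
    input_hashes = as.list(tools::md5sum(Filter(file.exists, file.path(
      output_dir, c("variants.tsv", "copynumber.tsv", "clinical.tsv",
                    "normals.tsv", "het_normals.tsv", "expression.tsv")))))
  )
  names(manifest$input_hashes) <- basename(names(manifest$input_hashes))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(state, list(manifest = manifest)))
}

# Patients whose preferred-timepoint SMAD4 state is a gain (used to group the
# regional expression screen).
smad4_gain_patients <- function(called, sample_ids) {
  pc <- patient_cn(called, genes = "SMAD4")
  st <- cn_state_factor(pc$state[match(sample_ids, pc$patient_id)])
  !is.na(st) & st > "NORMAL"
}
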