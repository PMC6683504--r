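#' Synthetic-cohort configuration
#'
#' Parameters of the simulated residual-disease cohort. Defaults encode the
#' cohort structure the analyses assume: TP53/PIK3CA mutation frequencies of
#' 0.88/0.11, TP53 copy loss in 29\% of cases, recurrent gains on 1q/8q/10p
#' with MYC amplified in 24\% and MCL1 in 21\%, BRCA2 loss in 68\% (co-lost
#' with FLT3/RB1), SMAD4-region gains in 37\%, tumor purity uniform on
#' 0.6-1.0, proportional-hazards survival keyed to the TP53 risk stratum, a
#' global multiplicative expression up-shift in compound-TP53 samples, and
#' post-chemotherapy lymphocyte depletion.
#'
#' @param n_patients cohort size (default 75; every patient has a surgical
#'   residual-disease sample, a `pair_fraction` subset also has a diagnostic
#'   biopsy).
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @param n_normals number of normal genomes behind the reference ranges.
#' @param mutation_freq named per-gene mutation probabilities.
#' @param loh_freq,subclonal_freq probability that a TP53 mutation shows LOH
#'   skew / is subclonal (mutually exclusive; their sum must be <= 1).
#' @param cn_event_freq named frequencies of the planted copy-number events:
#'   `TP53_loss`, `MYC_amp`, `MCL1_amp`, `BRCA2_loss`, `SMAD4_gain`,
#'   `broad_gain` (per-gene gain probability on 1q/8q/10p).
#' @param purity_range uniform range of tumor purity.
#' @param stratum_hr hazard multipliers per risk stratum (LOW is baseline 1).
#' @param planted_locus optional `list(gene, hr, direction, freq)` planting a
#'   copy-number event (`direction` "gain" or "loss", default "gain";
#'   carrier frequency `freq`, default 0.37) at one panel gene, with a
#'   recurrence hazard multiplier `hr` for carriers. The planted event
#'   overrides any other simulated event at that gene.
#' @param baseline_hazard monthly recurrence hazard of the LOW stratum.
#' @param followup_months administrative censoring horizon (uniform entry).
#' @param post_recurrence_rate monthly death hazard after recurrence (OS is
#'   DFS plus this exponential tail, so dfs <= os by construction).
#' @param pair_fraction fraction of patients with a matched diagnostic biopsy.
#' @param lymphocyte named vector: `mean_pre`, `sd_pre`, `depletion_mean`,
#'   `depletion_sd` (percentage points).
#' @param expression generate the expression matrix (disable for speed in
#'   copy-number-only simulations).
#' @param n_background_genes background genes beyond the panel and the 18q21
#'   region block.
#' @param expression_upshift global multiplicative shift applied to every gene
#'   in compound-TP53 samples (the transcriptional-amplification footprint).
#' @param myc_expression_shift multiplier on MYC expression in MYC-amplified
#'   samples.
#' @param regional_gene,regional_shift the 18q21 gene upregulated in
#'   SMAD4-gain samples and its multiplier.
#' @param noise master noise toggle; off removes all measurement noise —
#'   purity mixing becomes exactly invertible, and expression reduces to the
#'   planted per-gene means and multiplicative signals (no sampling noise or
#'   dropout), so every planted label is recoverable exactly.
#' @param cn_noise_sd,vaf_noise_sd measurement noise SDs on observed copy
#'   number and VAF.
#' @param normal_cn_sd SD of normal-genome copy number around 2.
#' @param het_vaf_mean,het_vaf_sd normal heterozygous allele-frequency
#'   distribution (defaults give a +/- 3 SD range approximating 0.38-0.59).
#' @param censoring_rate optional extra exponential dropout rate (0 = only
#'   administrative censoring).
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 75,
                          seed = 1,
                          n_normals = 24,
                          mutation_freq = c(TP53 = 0.88, PIK3CA = 0.11),
                          loh_freq = 0.45,
                          subclonal_freq = 0.20,
                          cn_event_freq = c(TP53_loss = 0.29, MYC_amp = 0.24,
                                            MCL1_amp = 0.21, BRCA2_loss = 0.68,
                                            SMAD4_gain = 0.37, broad_gain = 0.60),
                          purity_range = c(0.60, 1.00),
                          stratum_hr = c(LOW = 1.0, MODERATE = 1.5, HIGH = 2.5),
                          planted_locus = NULL,
                          baseline_hazard = 0.015,
                          followup_months = 72,
                          post_recurrence_rate = 0.06,
                          pair_fraction = 0.24,
                          lymphocyte = c(mean_pre = 20, sd_pre = 12,
                                         depletion_mean = -8, depletion_sd = 10),
                          expression = TRUE,
                          n_background_genes = 300,
                          expression_upshift = 1.5,
                          myc_expression_shift = 2.5,
                          regional_gene = "SMAD2",
                          regional_shift = 2.5,
                          noise = TRUE,
                          cn_noise_sd = 0.08,
                          vaf_noise_sd = 0.02,
                          normal_cn_sd = 0.15,
                          het_vaf_mean = 0.485,
                          het_vaf_sd = 0.035,
                          censoring_rate = 0) {
  cfg <- as.list(environment())
  freqs <- c(mutation_freq, cn_event_freq, loh_freq, subclonal_freq, pair_fraction)
  if (any(freqs < 0 | freqs > 1)) {
    rd_stop("all frequencies must lie in [0, 1]", "rd_config_error")
  }
  if (loh_freq + subclonal_freq > 1) {
    rd_stop("loh_freq + subclonal_freq exceeds 1: a mutation cannot be both",
            "rd_config_error")
  }
  if (!"TP53" %in% names(mutation_freq)) {
    rd_stop("mutation_freq must include TP53", "rd_config_error")
  }
  need_ev <- c("TP53_loss", "MYC_amp", "MCL1_amp", "BRCA2_loss", "SMAD4_gain")
  if (!all(need_ev %in% names(cn_event_freq))) {
    rd_stop(sprintf("cn_event_freq must name: %s", paste(need_ev, collapse = ", ")),
            "rd_config_error")
  }
  if (any(stratum_hr <= 0) || baseline_hazard <= 0) {
    rd_stop("hazards must be > 0", "rd_config_error")
  }
  if (purity_range[1] <= 0 || purity_range[2] > 1 ||
      purity_range[1] > purity_range[2]) {
    rd_stop("purity_range must be increasing within (0, 1]", "rd_config_error")
  }
  if (!is.null(planted_locus)) {
    if (!all(c("gene", "hr") %in% names(planted_locus))) {
      rd_stop("planted_locus needs fields `gene` and `hr`", "rd_config_error")
    }
    if (!planted_locus$gene %in% panel_genes()$gene) {
      rd_stop(sprintf("planted_locus gene '%s' is not on the panel",
                      planted_locus$gene), "rd_config_error")
    }
    if (is.null(planted_locus$direction)) cfg$planted_locus$direction <- "gain"
    if (!cfg$planted_locus$direction %in% c("gain", "loss")) {
      rd_stop("planted_locus direction must be 'gain' or 'loss'", "rd_config_error")
    }
    if (is.null(planted_locus$freq)) cfg$planted_locus$freq <- 0.37
  }
  structure(cfg, class = "cohort_config")
}

# Broad-gain genes: loci on 1q, 8q and 10p where gains are near-universal in
# this disease.
BROAD_GAIN_GENES <- c("MCL1", "BCL9", "MDM4", "MYC", "NBN", "GATA3")

# Draw one patient's true per-gene copy number and event labels.
draw_cn_truth <- function(cfg, panel) {
  cn <- stats::setNames(rep(2, nrow(panel)), panel$gene)
  event <- stats::setNames(rep("none", nrow(panel)), panel$gene)
  gain_cn <- function(n) stats::runif(n, 2.9, 4.4)
  amp_cn <- function(n) stats::runif(n, 5.2, 8.0)
  ev <- cfg$cn_event_freq
  bg <- if ("broad_gain" %in% names(ev)) ev[["broad_gain"]] else 0
  for (g in BROAD_GAIN_GENES) {
    if (stats::runif(1) < bg) { cn[g] <- gain_cn(1); event[g] <- "gain" }
  }
  if (stats::runif(1) < ev[["MYC_amp"]])  { cn["MYC"] <- amp_cn(1);  event["MYC"] <- "amp" }
  if (stats::runif(1) < ev[["MCL1_amp"]]) { cn["MCL1"] <- amp_cn(1); event["MCL1"] <- "amp" }
  if (stats::runif(1) < ev[["TP53_loss"]]) { cn["TP53"] <- 1.0; event["TP53"] <- "loss" }
  if (stats::runif(1) < ev[["BRCA2_loss"]]) {
    cn["BRCA2"] <- 1.0; event["BRCA2"] <- "loss"
    # 13q losses travel together
    for (g in c("FLT3", "RB1")) {
      if (stats::runif(1) < 0.6) { cn[g] <- 1.0; event[g] <- "loss" }
    }
  }
  if (stats::runif(1) < ev[["SMAD4_gain"]]) {
    cn["SMAD4"] <- gain_cn(1); event["SMAD4"] <- "gain"
    # 18q21 genes are gained in high concordance
    if (stats::runif(1) < 0.95) { cn["SMAD2"] <- gain_cn(1); event["SMAD2"] <- "gain" }
  }
  # a planted locus overrides any other event at its gene
  pl <- cfg$planted_locus
  if (!is.null(pl)) {
    if (stats::runif(1) < pl$freq) {
      if (pl$direction == "gain") {
        cn[pl$gene] <- gain_cn(1); event[pl$gene] <- "gain"
      } else {
        cn[pl$gene] <- 1.0; event[pl$gene] <- "loss"
      }
    } else {
      cn[pl$gene] <- 2.0; event[pl$gene] <- "none"
    }
  }
  list(cn = cn, event = event)
}

# Truth-side stratum rule (mirrors the classifier's definition on planted flags).
truth_stratum <- function(has_mut, subclonal, loh, copy_loss) {
  if (!has_mut) return("LOW")
  if (loh || copy_loss) return("HIGH")
  if (subclonal) return("LOW")
  "MODERATE"
}

#' Generate a synthetic residual-disease cohort
#'
#' Draws a full cohort with known ground truth: normal genomes behind the
#' reference ranges, per-patient true copy-number events and TP53 mutation
#' state, observed values mixed with normal contamination at (1 - purity) plus
#' optional measurement noise, exponential proportional-hazards survival keyed
#' to the true risk stratum (and any planted locus), lymphocyte percentages
#' with post-chemotherapy depletion, and an expression matrix carrying the
#' transcriptional-amplification and 18q21 regional signals. Ground-truth
#' labels are returned alongside, never inside, the analysis tables.
#'
#' @param config a [cohort_config()].
#' @return object of class `rd_sim`: list with `cohort` (an [rd_cohort()]),
#'   `normals` (long data.frame gene/normal_id/copy_number), `het_normals`
#'   (normal heterozygous VAF draws), `expression` (an
#'   [expression_matrix()] over surgical samples, or NULL), and `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  panel <- panel_genes()
  n <- config$n_patients
  ids <- sprintf("PT%03d", seq_len(n))

  normals <- expand.grid(normal_id = sprintf("N%02d", seq_len(config$n_normals)),
                         gene = panel$gene, stringsAsFactors = FALSE)
  normals$copy_number <- stats::rnorm(nrow(normals), 2, config$normal_cn_sd)
  het_normals <- stats::rnorm(3 * config$n_normals,
                              config$het_vaf_mean, config$het_vaf_sd)

  purity <- stats::runif(n, config$purity_range[1], config$purity_range[2])
  has_pair <- stats::runif(n) < config$pair_fraction

  # TP53 mutation state
  p_mut <- config$mutation_freq[["TP53"]]
  has_mut <- stats::runif(n) < p_mut
  u <- stats::runif(n)
  subclonal <- has_mut & u < config$subclonal_freq
  loh <- has_mut & u >= config$subclonal_freq &
    u < config$subclonal_freq + config$loh_freq

  truth_cn <- lapply(seq_len(n), function(i) draw_cn_truth(config, panel))
  copy_loss <- vapply(truth_cn, function(tc) tc$event[["TP53"]] == "loss", TRUE)
  stratum <- vapply(seq_len(n), function(i) {
    truth_stratum(has_mut[i], subclonal[i], loh[i], copy_loss[i])
  }, "")

  vaf_true <- rep(NA_real_, n)
  vaf_true[has_mut & subclonal] <- stats::runif(sum(has_mut & subclonal), 0.06, 0.20)
  vaf_true[has_mut & loh] <- stats::runif(sum(has_mut & loh), 0.63, 0.95)
  clonal <- has_mut & !subclonal & !loh
  vaf_true[clonal] <- stats::runif(sum(clonal), 0.30, 0.55)

  # survival under proportional hazards
  hr_pl <- rep(1, n)
  if (!is.null(config$planted_locus)) {
    want <- if (config$planted_locus$direction == "gain") c("gain", "amp") else "loss"
    carrier <- vapply(truth_cn, function(tc) {
      tc$event[[config$planted_locus$gene]] %in% want
    }, TRUE)
    hr_pl[carrier] <- config$planted_locus$hr
  }
  rate <- config$baseline_hazard * config$stratum_hr[stratum] * hr_pl
  t_rec <- stats::rexp(n, rate)
  cens <- stats::runif(n, 0, config$followup_months)
  if (config$censoring_rate > 0) {
    cens <- pmin(cens, stats::rexp(n, config$censoring_rate))
  }
  dfs_months <- round(pmin(t_rec, cens), 2)
  recurred <- t_rec <= cens
  os_months <- dfs_months
  os_event <- rep(FALSE, n)
  post_t <- round(stats::rexp(n, config$post_recurrence_rate), 2)
  os_months[recurred] <- dfs_months[recurred] + post_t[recurred]
  os_event[recurred] <- TRUE

  ly <- config$lymphocyte
  lymph_pre <- pmin(pmax(stats::rnorm(n, ly[["mean_pre"]], ly[["sd_pre"]]), 0), 100)
  lymph_post <- pmin(pmax(lymph_pre + stats::rnorm(n, ly[["depletion_mean"]],
                                                   ly[["depletion_sd"]]), 0), 100)
  lymph_pre[!has_pair] <- NA  # no diagnostic slide without a diagnostic biopsy

  clinical <- data.frame(
    patient_id = ids,
    dfs_months = dfs_months, dfs_event = recurred,
    os_months = round(os_months, 2), os_event = os_event,
    recurred = recurred,
    age = round(stats::runif(n, 32, 72)),
    node_positive = stats::runif(n) < 0.5,
    rcb_class = ifelse(stats::runif(n) < 0.5, "I_II", "III"),
    purity_pct = round(purity * 100, 1),
    lymphocyte_pct_pre = round(lymph_pre, 1),
    lymphocyte_pct_post = round(lymph_post, 1),
    stringsAsFactors = FALSE)
  purity_stored <- clinical$purity_pct / 100

  observe_cn <- function(cn_true, p) {
    obs <- p * cn_true + (1 - p) * 2
    if (config$noise) obs <- obs + stats::rnorm(length(obs), 0, config$cn_noise_sd)
    pmax(obs, 0)
  }
  observe_vaf <- function(v, p) {
    obs <- v * p
    if (config$noise) obs <- obs + stats::rnorm(length(obs), 0, config$vaf_noise_sd)
    pmin(pmax(obs, 0), 1)
  }

  protein_changes <- sprintf("p.%s%d%s",
                             sample(LETTERS, n, replace = TRUE),
                             sample(50:350, n, replace = TRUE),
                             sample(c(LETTERS, "*"), n, replace = TRUE))
  vclass <- sample(c("MISSENSE", "NONSENSE", "FRAMESHIFT", "SPLICE"), n,
                   replace = TRUE, prob = c(0.70, 0.15, 0.10, 0.05))

  cn_true_mat <- vapply(truth_cn, `[[`, numeric(nrow(panel)), "cn")
  tp_of <- function(i) c("SURGERY", if (has_pair[i]) "DIAGNOSIS")
  cn_rows <- lapply(seq_len(n), function(i) {
    tps <- tp_of(i)
    data.frame(patient_id = ids[i],
               timepoint = rep(tps, each = nrow(panel)),
               gene = rep(panel$gene, length(tps)),
               copy_number = as.vector(vapply(tps, function(tp) {
                 observe_cn(cn_true_mat[, i], purity_stored[i])
               }, numeric(nrow(panel)))),
               stringsAsFactors = FALSE)
  })
  var_rows <- lapply(which(has_mut), function(i) {
    tps <- tp_of(i)
    data.frame(patient_id = ids[i], timepoint = tps, gene = "TP53",
               protein_change = protein_changes[i], variant_class = vclass[i],
               vaf = observe_vaf(rep(vaf_true[i], length(tps)), purity_stored[i]),
               stringsAsFactors = FALSE)
  })
  # secondary mutations (stable across timepoints)
  for (g in setdiff(names(config$mutation_freq), "TP53")) {
    hit <- stats::runif(n) < config$mutation_freq[[g]]
    vafs <- stats::runif(n, 0.15, 0.45)
    pcs <- sprintf("p.%s%d%s", sample(LETTERS, n, TRUE),
                   sample(50:900, n, TRUE), sample(LETTERS, n, TRUE))
    for (i in which(hit)) {
      for (tp in c("SURGERY", if (has_pair[i]) "DIAGNOSIS")) {
        var_rows[[length(var_rows) + 1L]] <- data.frame(
          patient_id = ids[i], timepoint = tp, gene = g,
          protein_change = pcs[i], variant_class = "MISSENSE",
          vaf = observe_vaf(vafs[i], purity_stored[i]),
          stringsAsFactors = FALSE)
      }
    }
  }

  variants <- if (length(var_rows)) do.call(rbind, var_rows) else
    data.frame(patient_id = character(), timepoint = character(),
               gene = character(), protein_change = character(),
               variant_class = character(), vaf = numeric())
  copynumber <- do.call(rbind, cn_rows)
  cohort <- rd_cohort(variants, copynumber, clinical)

  compound <- stratum == "HIGH"
  expr <- NULL
  if (config$expression) {
    expr <- simulate_expression(config, ids, truth_cn, compound)
  }

  truth <- list(
    patients = data.frame(
      patient_id = ids, purity = purity_stored, has_pair = has_pair,
      has_mutation = has_mut, subclonal = subclonal, loh = loh,
      copy_loss = copy_loss, stratum = stratum, compound = compound,
      vaf_true = vaf_true, hazard = unname(rate), stringsAsFactors = FALSE),
    cn_events = do.call(rbind, lapply(seq_len(n), function(i) {
      ev <- truth_cn[[i]]$event
      data.frame(patient_id = ids[i], gene = names(ev), event = unname(ev),
                 cn_true = unname(truth_cn[[i]]$cn), stringsAsFactors = FALSE)
    }))
  )
  structure(list(cohort = cohort, normals = normals, het_normals = het_normals,
                 expression = expr, truth = truth, config = config),
            class = "rd_sim")
}

# Expression matrix over surgical samples with planted signals.
simulate_expression <- function(cfg, ids, truth_cn, compound) {
  panel <- panel_genes()
  region_extra <- data.frame(
    gene = c(sprintf("RG%02d", 1:15), "RGNC1", "RGNC2"),
    cytoband = rep(c("18q21.1", "18q21.2"), length.out = 17),
    coding = c(rep(TRUE, 15), FALSE, FALSE),
    stringsAsFactors = FALSE)
  bg <- data.frame(
    gene = sprintf("BG%03d", seq_len(cfg$n_background_genes)),
    cytoband = paste0(sample(c(1:5, 7:20, 22), cfg$n_background_genes, TRUE),
                      sample(c("p", "q"), cfg$n_background_genes, TRUE),
                      sample(11:36, cfg$n_background_genes, TRUE)),
    coding = stats::runif(cfg$n_background_genes) < 0.9,
    stringsAsFactors = FALSE)
  genes <- rbind(
    data.frame(gene = panel$gene, cytoband = panel$cytoband, coding = TRUE,
               stringsAsFactors = FALSE),
    region_extra, bg)
  genes$length_bp <- round(stats::runif(nrow(genes), 600, 6000))

  mu <- stats::rlnorm(nrow(genes), meanlog = 3, sdlog = 1)
  vals <- matrix(mu, nrow = nrow(genes), ncol = length(ids))
  if (cfg$noise) {
    vals <- vals * matrix(stats::rlnorm(nrow(genes) * length(ids), 0, 0.4),
                          nrow = nrow(genes))
  }
  rownames(vals) <- genes$gene
  colnames(vals) <- ids

  myc_amp <- vapply(truth_cn, function(tc) tc$event[["MYC"]] == "amp", TRUE)
  smad4_gain <- vapply(truth_cn, function(tc) tc$event[["SMAD4"]] == "gain", TRUE)
  vals["MYC", myc_amp] <- vals["MYC", myc_amp] * cfg$myc_expression_shift
  if (cfg$regional_gene %in% rownames(vals)) {
    vals[cfg$regional_gene, smad4_gain] <-
      vals[cfg$regional_gene, smad4_gain] * cfg$regional_shift
  }
  vals[, compound] <- vals[, compound] * cfg$expression_upshift
  if (cfg$noise) {
    # sparse dropout so detection filters have something to do
    drop <- matrix(stats::runif(length(vals)) < 0.03, nrow = nrow(vals))
    vals[drop] <- 0
  }
  expression_matrix(vals, genes)
}

#' @export
print.rd_sim <- function(x, ...) {
  cat(sprintf("rd_sim (seed %d): %d patients, %d matched pairs%s\n",
              x$config$seed, x$config$n_patients, sum(x$truth$patients$has_pair),
              if (is.null(x$expression)) "" else
                sprintf(", expression %d genes", nrow(x$expression$values))))
  cat("  true strata:",
      paste(sprintf("%s %d", RISK_STRATA,
                    tabulate(factor(x$truth$patients$stratum, RISK_STRATA), 3)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Generate matched diagnosis/surgery pairs with planted evolution events
#'
#' Builds a cohort of `n_pairs` patients, each with both timepoints, and
#' plants the requested clonal-evolution events: variant acquisition or loss,
#' and amplification evolution (diploid at diagnosis, amplified at surgery) or
#' extinction (the reverse).
#'
#' @param config a [cohort_config()] (its `n_patients` is overridden).
#' @param n_pairs number of matched pairs (>= 1).
#' @param evolution_spec data.frame with columns `pair` (1-based index),
#'   `gene` (panel gene), `type` (one of "acquire_variant", "lose_variant",
#'   "amp_evolve", "amp_extinct"); or NULL for no planted events.
#' @return an `rd_sim` whose truth includes the planted `evolution_spec`.
#' @export
generate_matched_pairs <- function(config, n_pairs, evolution_spec = NULL) {
  stopifnot(inherits(config, "cohort_config"), n_pairs >= 1L)
  panel <- panel_genes()
  if (!is.null(evolution_spec)) {
    evolution_spec <- check_columns(evolution_spec, c("pair", "gene", "type"),
                                    "evolution_spec")
    bad <- setdiff(evolution_spec$gene, panel$gene)
    if (length(bad)) {
      rd_stop(sprintf("evolution_spec references off-panel gene(s): %s",
                      paste(bad, collapse = ", ")), "rd_config_error")
    }
    if (!all(evolution_spec$type %in% c("acquire_variant", "lose_variant",
                                        "amp_evolve", "amp_extinct"))) {
      rd_stop("unknown evolution_spec type", "rd_config_error")
    }
    if (any(evolution_spec$pair < 1 | evolution_spec$pair > n_pairs)) {
      rd_stop("evolution_spec pair index out of range", "rd_config_error")
    }
  }
  cfg <- config
  cfg$n_patients <- n_pairs
  cfg$pair_fraction <- 1
  cfg$expression <- FALSE
  sim <- generate_cohort(cfg)

  if (!is.null(evolution_spec) && nrow(evolution_spec)) {
    ids <- sprintf("PT%03d", seq_len(n_pairs))
    co <- sim$cohort
    purity <- sim$truth$patients$purity
    for (r in seq_len(nrow(evolution_spec))) {
      pid <- ids[evolution_spec$pair[r]]
      g <- evolution_spec$gene[r]
      p <- purity[evolution_spec$pair[r]]
      type <- evolution_spec$type[r]
      if (type %in% c("amp_evolve", "amp_extinct")) {
        amp_tp <- if (type == "amp_evolve") "SURGERY" else "DIAGNOSIS"
        dip_tp <- setdiff(TIMEPOINTS, amp_tp)
        sel_amp <- co$copynumber$patient_id == pid & co$copynumber$gene == g &
          co$copynumber$timepoint == amp_tp
        sel_dip <- co$copynumber$patient_id == pid & co$copynumber$gene == g &
          co$copynumber$timepoint == dip_tp
        noise <- function() if (cfg$noise) stats::rnorm(1, 0, cfg$cn_noise_sd) else 0
        co$copynumber$copy_number[sel_amp] <-
          max(p * stats::runif(1, 5.5, 7.5) + (1 - p) * 2 + noise(), 0)
        co$copynumber$copy_number[sel_dip] <-
          max(p * 2 + (1 - p) * 2 + noise(), 0)
      } else {
        tp <- if (type == "acquire_variant") "SURGERY" else "DIAGNOSIS"
        vaf <- stats::runif(1, 0.30, 0.55) * p
        if (cfg$noise) vaf <- min(max(vaf + stats::rnorm(1, 0, cfg$vaf_noise_sd), 0), 1)
        newv <- data.frame(
          patient_id = pid, timepoint = tp, gene = g,
          protein_change = sprintf("p.%s%d%s", sample(LETTERS, 1),
                                   sample(50:900, 1), sample(LETTERS, 1)),
          variant_class = "MISSENSE", vaf = vaf, stringsAsFactors = FALSE)
        co$variants <- canonical_order(rbind(co$variants, newv))
      }
    }
    sim$cohort <- co
  }
  sim$truth$evolution_spec <- evolution_spec
  sim
}
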