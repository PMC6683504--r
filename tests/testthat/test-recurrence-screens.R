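called_sim <- function(cfg) {
  sim <- generate_cohort(cfg)
  list(sim = sim,
       called = call_cohort(sim$cohort, build_reference_ranges(sim$normals),
                            build_reference_range(sim$het_normals)))
}

test_that("a cohort with no recurrences skips stage 1 everywhere", {
  cfg <- cohort_config(n_patients = 30, seed = 61, expression = FALSE,
                       baseline_hazard = 1e-9)
  cs <- called_sim(cfg)
  expect_true(all(!cs$sim$cohort$clinical$recurred))
  sc <- cnv_recurrence_screen(cs$called)
  expect_equal(sum(sc$positive), 0L)
  expect_true(all(is.na(sc$stage1_p)))
  expect_true(all(grepl("stage1 skipped", sc$diagnostic)))
})

test_that("raising either alpha never removes a screen positive", {
  cfg <- cohort_config(n_patients = 120, seed = 62, expression = FALSE,
                       planted_locus = list(gene = "SMAD4", hr = 2.5))
  cs <- called_sim(cfg)
  strict <- cnv_recurrence_screen(cs$called, alpha1 = 0.05, alpha2 = 0.05)
  loose <- cnv_recurrence_screen(cs$called, alpha1 = 0.20, alpha2 = 0.20)
  expect_true(all(loose$positive[strict$positive]))
})

test_that("stage bookkeeping reconciles: every survivor has a p or a diagnostic", {
  cfg <- cohort_config(n_patients = 100, seed = 63, expression = FALSE)
  cs <- called_sim(cfg)
  sc <- cnv_recurrence_screen(cs$called)
  expect_equal(nrow(sc), length(unique(cs$called$copynumber$gene)))
  survivors <- !is.na(sc$stage1_p) & sc$stage1_p < attr(sc, "alpha1")
  expect_true(all(!is.na(sc$stage2_p[survivors]) |
                    !is.na(sc$diagnostic[survivors])))
  # positives passed both stages by definition
  expect_true(all(sc$stage1_p[sc$positive] < 0.05 &
                    sc$stage2_p[sc$positive] < 0.05))
})

test_that("a planted gain-linked locus is usually detected", {
  det <- vapply(1:15, function(s) {
    cfg <- cohort_config(n_patients = 200, seed = s, expression = FALSE,
                         stratum_hr = c(LOW = 1, MODERATE = 1, HIGH = 1),
                         planted_locus = list(gene = "SMAD4", hr = 2.3,
                                              direction = "gain", freq = 0.37))
    cs <- called_sim(cfg)
    sc <- cnv_recurrence_screen(cs$called)
    sc$positive[sc$gene == "SMAD4"]
  }, TRUE)
  expect_gte(mean(det), 0.7)
})

test_that("permuting recurrence labels restores the null positive rate", {
  cfg <- cohort_config(n_patients = 120, seed = 64, expression = FALSE,
                       stratum_hr = c(LOW = 1, MODERATE = 1, HIGH = 1),
                       planted_locus = list(gene = "SMAD4", hr = 2.5,
                                            direction = "gain", freq = 0.37))
  cs <- called_sim(cfg)
  set.seed(64)
  rates <- vapply(1:30, function(i) {
    perm <- cs$called
    idx <- sample(nrow(perm$clinical))
    perm$clinical[c("dfs_months", "dfs_event", "recurred")] <-
      perm$clinical[idx, c("dfs_months", "dfs_event", "recurred")]
    mean(cnv_recurrence_screen(perm)$positive)
  }, 0)
  expect_lt(mean(rates), 0.05 + 2 * sqrt(0.05 * 0.95 / (30 * 70)))
})

test_that("survival splits group patients exactly by state threshold", {
  cfg <- cohort_config(n_patients = 80, seed = 65, expression = FALSE)
  cs <- called_sim(cfg)
  res <- survival_by_copy_state(cs$called, "TP53", "loss_vs_not")
  pc <- rdscreen:::patient_cn(cs$called, genes = "TP53")
  expect_equal(unname(res$group_n[["aberrant"]]),
               sum(pc$state %in% c("LOSS", "EXTENSIVE_LOSS")))
  expect_equal(sum(res$group_n), nrow(pc))

  # degenerate split: an all-normal gene yields a marker, not a test
  allnorm <- cs$called
  sel <- allnorm$copynumber$gene == "PNP"
  allnorm$copynumber$state[sel] <- "NORMAL"
  res <- survival_by_copy_state(allnorm, "PNP", "amplified_vs_not")
  expect_false(is.null(res$error))
  expect_null(res$dfs)
})

test_that("stratum survival reports a 2-df omnibus and handles identical groups", {
  # identical survival data in all three strata -> chisq 0, p = 1
  ids <- sprintf("P%02d", 1:30)
  cl <- make_clinical(ids, recurred = rep(c(TRUE, FALSE), 15),
                      dfs = rep(c(6, 12, 18, 24, 30), 6))
  co <- rd_cohort(make_variants(), make_cn(ids, "SURGERY", "TP53", 2), cl)
  called <- call_cohort(co, list(TP53 = unit_range()))
  strata <- data.frame(patient_id = ids,
                       stratum = factor(rep(RISK <- c("LOW", "MODERATE", "HIGH"), 10),
                                        levels = RISK))
  strata$compound <- strata$stratum == "HIGH"
  res <- survival_by_stratum(called, strata)
  expect_equal(res$dfs$omnibus$df, 2L)
  expect_equal(res$dfs$omnibus$p, 1, tolerance = 1e-9)

  # empty stratum: df reduced with a warning
  strata2 <- strata
  strata2$stratum[strata2$stratum == "MODERATE"] <- "LOW"
  expect_warning(res2 <- survival_by_stratum(called, strata2), "empty stratum")
  expect_equal(res2$dfs$omnibus$df, 1L)
})

test_that("planted ordered hazards produce ordered median survival", {
  ok <- vapply(1:20, function(s) {
    cfg <- cohort_config(n_patients = 300, seed = 300 + s, expression = FALSE,
                         stratum_hr = c(LOW = 1, MODERATE = 1.5, HIGH = 2.5))
    cs <- called_sim(cfg)
    st <- classify_tp53(collapse_patient_tp53(cs$called))
    med <- survival_by_stratum(cs$called, st)$dfs$median_by_stratum
    !anyNA(med) && med[["LOW"]] > med[["MODERATE"]] &&
      med[["MODERATE"]] > med[["HIGH"]]
  }, TRUE)
  expect_gte(mean(ok), 0.75)
})

test_that("lymphocyte tests partition matched pairs by recurrence", {
  cfg <- cohort_config(n_patients = 120, seed = 66, expression = FALSE,
                       pair_fraction = 0.6)
  cs <- called_sim(cfg)
  res <- lymphocyte_depletion(cs$called)
  expect_equal(res$paired$n_pairs,
               res$paired_non_relapse$n_pairs + res$paired_relapse$n_pairs)
  expect_equal(res$unpaired$n_post, 120L)

  # identical pre/post values: paired p = 1
  ids <- sprintf("Q%02d", 1:10)
  cl <- make_clinical(ids, lymph_pre = seq(10, 28, by = 2),
                      lymph_post = seq(10, 28, by = 2))
  cn <- rbind(make_cn(ids, "DIAGNOSIS", "TP53", 2),
              make_cn(ids, "SURGERY", "TP53", 2))
  co <- call_cohort(rd_cohort(make_variants(), cn, cl),
                    list(TP53 = unit_range()))
  flat <- lymphocyte_depletion(co)
  expect_equal(flat$paired$p, 1)
  expect_equal(flat$unpaired$p, 1)
})

test_that("planted lymphocyte depletion is detected in most seeds", {
  hits <- vapply(1:15, function(s) {
    cfg <- cohort_config(n_patients = 100, seed = 600 + s, expression = FALSE,
                         pair_fraction = 0.5,
                         lymphocyte = c(mean_pre = 20, sd_pre = 12,
                                        depletion_mean = -8, depletion_sd = 10))
    cs <- called_sim(cfg)
    lymphocyte_depletion(cs$called)$paired$p < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.6)
})

test_that("subgroups with fewer than two pairs are skipped with a diagnostic", {
  ids <- c("R1", "R2", "R3")
  cl <- make_clinical(ids, recurred = c(TRUE, FALSE, FALSE),
                      lymph_pre = c(20, 22, 24), lymph_post = c(12, 15, 18))
  cn <- rbind(make_cn(ids, "DIAGNOSIS", "TP53", 2),
              make_cn(ids, "SURGERY", "TP53", 2))
  co <- call_cohort(rd_cohort(make_variants(), cn, cl),
                    list(TP53 = unit_range()))
  res <- lymphocyte_depletion(co)
  expect_type(res$paired_relapse, "character")  # one relapser -> skip
  expect_match(res$paired_relapse, "skipped")
  expect_equal(res$paired_non_relapse$n_pairs, 2L)
})
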