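make_expr <- function(values, cytoband = "1p13", coding = TRUE) {
  genes <- data.frame(gene = rownames(values),
                      cytoband = rep_len(cytoband, nrow(values)),
                      coding = rep_len(coding, nrow(values)),
                      length_bp = 1000)
  expression_matrix(values, genes)
}

test_that("RPKM follows its formula and invariances", {
  counts <- matrix(c(0L, 10L), nrow = 2, ncol = 1,
                   dimnames = list(c("g1", "g2"), "s1"))
  out <- rpkm(counts, c(2000, 2000), 5e6)
  expect_equal(out["g1", 1], 0)
  expect_equal(out["g2", 1], 1.0)   # 10 / (2kb * 5M reads)

  # scaling counts and library size together leaves RPKM fixed
  expect_equal(rpkm(counts * 3, c(2000, 2000), 3 * 5e6), out)

  # zero preservation and within-sample order
  set.seed(8)
  cmat <- matrix(rpois(60, 20), 6, 10,
                 dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  cmat[2, ] <- 0
  r <- rpkm(cmat, rep(1500, 6), colSums(cmat))
  expect_true(all(r[2, ] == 0))
  expect_equal(order(r[, 1][cmat[, 1] > 0]), order(cmat[, 1][cmat[, 1] > 0]))

  expect_error(rpkm(cmat, rep(1500, 6), rep(0, 10)), "library sizes")
  expect_error(rpkm(cmat, rep(0, 6), colSums(cmat)), "lengths")
})

test_that("expression matrices validate metadata and non-negativity", {
  v <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  g <- data.frame(gene = c("a", "b"), cytoband = "1q21", coding = TRUE,
                  length_bp = 100)
  expect_s3_class(expression_matrix(v, g), "expr_matrix")
  expect_error(expression_matrix(-v, g), "non-negative")
  expect_error(expression_matrix(v, g[1, ]), "cover every")
  g$length_bp <- 0
  expect_error(expression_matrix(v, g), "positive")
})

test_that("differential expression recovers a planted shifted gene", {
  set.seed(17)
  v <- matrix(rlnorm(50 * 40, 3, 0.4), 50, 40,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:40)))
  grp <- factor(rep(c("ref", "focal"), each = 20), levels = c("ref", "focal"))
  v["g05", grp == "focal"] <- v["g05", grp == "focal"] * 4
  de <- differential_expression(make_expr(v), grp)
  expect_true(de$significant[de$gene == "g05"])
  expect_equal(de$direction[de$gene == "g05"], 1)

  # swapping labels flips direction, p unchanged
  de_sw <- differential_expression(make_expr(v),
                                   factor(grp, levels = c("focal", "ref")))
  expect_equal(de_sw$p, de$p, tolerance = 1e-12)
  expect_equal(de_sw$effect, -de$effect, tolerance = 1e-12)
})

test_that("null matrices yield almost no significant genes at FDR 10%", {
  set.seed(18)
  hits <- vapply(1:10, function(i) {
    v <- matrix(rlnorm(100 * 30, 3, 0.5), 100, 30,
                dimnames = list(sprintf("n%03d", 1:100), sprintf("s%02d", 1:30)))
    grp <- sample(rep(c("a", "b"), 15))
    sum(differential_expression(make_expr(v), grp)$significant)
  }, 0)
  expect_lt(mean(hits), 1)
})

test_that("constant genes are flagged with p = 1", {
  v <- matrix(rlnorm(20, 3, 0.4), 2, 10,
              dimnames = list(c("flat", "ok"), paste0("s", 1:10)))
  v["flat", ] <- 5
  de <- differential_expression(make_expr(v), rep(c("a", "b"), each = 5))
  expect_true(de$constant[de$gene == "flat"])
  expect_equal(de$p[de$gene == "flat"], 1)
  expect_false(de$significant[de$gene == "flat"])
})

test_that("paired differential expression uses complete pairs", {
  set.seed(19)
  v <- matrix(rlnorm(20 * 12, 3, 0.3), 20, 12,
              dimnames = list(sprintf("g%02d", 1:20),
                              c(paste0("pre", 1:6), paste0("post", 1:6))))
  v["g01", 7:12] <- v["g01", 1:6] * 3   # consistent within-pair shift
  grp <- rep(c("pre", "post"), each = 6)
  ids <- rep(sprintf("p%d", 1:6), 2)
  de <- differential_expression(make_expr(v), factor(grp, c("pre", "post")),
                                paired_ids = ids)
  expect_true(de$significant[de$gene == "g01"])
  expect_equal(de$direction[de$gene == "g01"], 1)
})

test_that("the up-fraction statistic counts significant directions", {
  de <- structure(data.frame(gene = letters[1:6],
                             direction = c(1, 1, 1, -1, 1, -1),
                             effect = c(1, 1, 1, -1, 1, -1),
                             p = 0.001, q = c(0.01, 0.01, 0.01, 0.01, 0.5, 0.5),
                             significant = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                             constant = FALSE),
                  class = c("de_result", "data.frame"))
  ta <- transcriptional_amplification(de)
  expect_equal(ta$n_significant, 4L)
  expect_equal(ta$up_fraction, 0.75)

  de$direction[4] <- 1
  expect_equal(transcriptional_amplification(de)$up_fraction, 1.0)

  de$significant[] <- FALSE
  expect_true(transcriptional_amplification(de)$undefined)
})

test_that("a global up-shift in focal samples gives an up fraction near 1", {
  set.seed(20)
  v <- matrix(rlnorm(200 * 52, 3, 0.4), 200, 52,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:52)))
  grp <- factor(rep(c("other", "compound"), c(37, 15)),
                levels = c("other", "compound"))
  v[, grp == "compound"] <- v[, grp == "compound"] * 1.5
  de <- differential_expression(make_expr(v), grp)
  ta <- transcriptional_amplification(de)
  expect_gt(ta$n_significant, 0)
  expect_gte(ta$up_fraction, 0.95)

  # group swap maps the fraction to its complement
  de_sw <- differential_expression(make_expr(v),
                                   factor(grp, levels = c("compound", "other")))
  ta_sw <- transcriptional_amplification(de_sw)
  expect_equal(ta_sw$up_fraction, 1 - ta$up_fraction)
})

test_that("the regional screen filters by cytoband, coding and detection", {
  set.seed(22)
  n_s <- 40
  v <- matrix(rlnorm(6 * n_s, 3, 0.3), 6, n_s,
              dimnames = list(c("SMAD2", "SMAD4", "R3", "NC1", "OFF1", "SILENT"),
                              sprintf("s%02d", 1:n_s)))
  genes <- data.frame(
    gene = rownames(v),
    cytoband = c("18q21.1", "18q21.2", "18q21.1", "18q21.2", "5q32", "18q21.1"),
    coding = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    length_bp = 1000)
  v["SILENT", ] <- 0
  grp <- factor(rep(c("other", "gain"), each = n_s / 2),
                levels = c("other", "gain"))
  v["SMAD2", grp == "gain"] <- v["SMAD2", grp == "gain"] * 3
  v["NC1", grp == "gain"] <- v["NC1", grp == "gain"] * 3
  expr <- expression_matrix(v, genes)

  res <- regional_screen(expr, c("18q21.1", "18q21.2"), grp)
  expect_setequal(res$region_genes, c("SMAD2", "SMAD4", "R3", "NC1", "SILENT"))
  expect_setequal(res$expressed_genes, c("SMAD2", "SMAD4", "R3", "NC1"))
  expect_equal(res$overexpressed, "SMAD2")  # coding filter drops NC1

  # non-coding overexpression is reported only when coding_only is off
  res_nc <- regional_screen(expr, c("18q21.1", "18q21.2"), grp,
                            coding_only = FALSE)
  expect_setequal(res_nc$overexpressed, c("SMAD2", "NC1"))

  expect_warning(res0 <- regional_screen(expr, "21q11", grp), "no genes")
  expect_equal(res0$region_genes, character(0))
})

test_that("conditional single-gene contrasts reproduce the exclusion logic", {
  set.seed(23)
  n <- 60
  amp <- rep(c(TRUE, FALSE), c(15, 45))
  compound <- amp | (runif(n) < 0.1)   # association only through amplification
  v <- matrix(rlnorm(2 * n, 3, 0.3), 2, n,
              dimnames = list(c("MYC", "OTHER"), sprintf("s%02d", 1:n)))
  v["MYC", amp] <- v["MYC", amp] * 3
  expr <- make_expr(v)
  grp <- factor(ifelse(compound, "compound", "other"),
                levels = c("other", "compound"))

  before <- expression_by_group(expr, "MYC", grp)
  expect_lt(before$p, 0.05)
  after <- expression_by_group(expr, "MYC", grp,
                               exclude = colnames(v)[amp])
  expect_gt(after$p, 0.05)

  # excluding nothing is a no-op
  noop <- expression_by_group(expr, "MYC", grp, exclude = character(0))
  expect_equal(noop$p, before$p)

  # identical groups: p = 1
  flat <- make_expr(matrix(rep(c(1, 2, 3, 4), 2), 1, 8,
                           dimnames = list("G", paste0("s", 1:8))))
  expect_equal(expression_by_group(flat, "G",
                                   rep(c("a", "b"), each = 4))$p, 1)

  # exclusion emptying a group yields a skip diagnostic
  res <- expression_by_group(expr, "MYC", grp,
                             exclude = colnames(v)[compound])
  expect_match(res$skipped, "fewer than 2")
})

test_that("panel detection fraction counts detected panel genes", {
  set.seed(24)
  v <- matrix(rlnorm(10 * 20, 3, 0.3), 10, 20,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:20)))
  v[3:10, ] <- 0
  expr <- make_expr(v)
  panel <- sprintf("g%02d", 1:10)
  expect_equal(panel_detection_fraction(expr, panel), 0.2)
  expect_equal(panel_detection_fraction(expr, c("g01", "g02")), 1.0)
  expect_equal(panel_detection_fraction(expr, rev(panel)),
               panel_detection_fraction(expr, panel))
  expect_error(panel_detection_fraction(expr, character(0)), "non-empty")
})
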