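#' Expression matrix container
#'
#' Genes x samples matrix of non-negative RPKM values with per-gene metadata
#' (cytoband, coding flag, transcript length). Gene ids must be unique and the
#' metadata must cover every row.
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns.
#' @param genes data.frame with columns `gene`, `cytoband`, `coding`,
#'   `length_bp`.
#' @return object of class `expr_matrix` (list with `values`, `genes`).
#' @export
expression_matrix <- function(values, genes) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (any(values < 0)) rd_stop("expression values must be non-negative", "rd_value_error")
  genes <- check_columns(genes, c("gene", "cytoband", "coding", "length_bp"), "genes")
  if (anyDuplicated(rownames(values)) || anyDuplicated(genes$gene)) {
    rd_stop("gene ids must be unique", "rd_uniqueness_error")
  }
  if (!setequal(rownames(values), genes$gene)) {
    rd_stop("gene metadata must cover every matrix row", "rd_schema_error")
  }
  if (any(genes$length_bp <= 0)) rd_stop("length_bp must be positive", "rd_value_error")
  genes <- genes[match(rownames(values), genes$gene), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(values = values, genes = genes), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%d coding)\n",
              nrow(x$values), ncol(x$values), sum(x$genes$coding)))
  invisible(x)
}

#' RPKM normalization
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `count / (length_kb * library_size_millions)` per cell. Scaling a library's
#' counts and size by the same factor leaves RPKM fixed.
#'
#' @param counts genes x samples matrix of read counts.
#' @param gene_length_bp positive transcript lengths, one per row.
#' @param library_sizes positive total mapped reads, one per column.
#' @return matrix of RPKM values with the same dimnames.
#' @export
rpkm <- function(counts, gene_length_bp, library_sizes) {
  stopifnot(is.matrix(counts), length(gene_length_bp) == nrow(counts),
            length(library_sizes) == ncol(counts))
  if (any(gene_length_bp <= 0)) rd_stop("gene lengths must be > 0", "rd_value_error")
  if (any(library_sizes <= 0)) rd_stop("library sizes must be > 0", "rd_value_error")
  counts / (gene_length_bp / 1e3) / rep(library_sizes / 1e6, each = nrow(counts))
}

#' Per-gene differential expression
#'
#' Gene-by-gene group comparison on log2(RPKM + 1): one-way ANOVA across the
#' group labels, or a paired t test when pair identifiers are supplied (two
#' groups, complete pairs). P-values get Benjamini-Hochberg adjustment and a
#' significance call at the stated FDR. For two groups the effect direction is
#' the sign of (focal mean - reference mean), where the reference is the first
#' factor level and the focal group the second; swapping labels flips every
#' direction and leaves p unchanged. Genes constant across all samples get
#' p = 1 and a diagnostic flag.
#'
#' @param expr an `expr_matrix`.
#' @param group_labels factor/character of length ncol; first level is the
#'   reference group.
#' @param paired_ids optional pair identifiers (e.g. patient ids) of length
#'   ncol; switches to a paired t test on complete pairs.
#' @param fdr significance threshold on q, default 0.10.
#' @return data.frame of class `de_result`: `gene`, `direction` (+1/-1/0),
#'   `effect` (focal - reference mean difference on the log2 scale), `p`, `q`,
#'   `significant`, `constant`.
#' @export
differential_expression <- function(expr, group_labels, paired_ids = NULL,
                                    fdr = 0.10) {
  stopifnot(inherits(expr, "expr_matrix"))
  g <- droplevels(factor(group_labels))
  stopifnot(length(g) == ncol(expr$values))
  if (any(table(g) < 2L)) {
    rd_stop("differential expression needs at least 2 samples per group",
            "rd_value_error")
  }
  lv <- levels(g)
  x <- log2(expr$values + 1)
  n_genes <- nrow(x)

  if (!is.null(paired_ids)) {
    if (length(lv) != 2L) {
      rd_stop("paired differential expression requires exactly 2 groups",
              "rd_value_error")
    }
    ids1 <- paired_ids[g == lv[1]]; ids2 <- paired_ids[g == lv[2]]
    common <- intersect(ids1, ids2)
    if (length(common) < 2L) rd_stop("fewer than 2 complete pairs", "rd_value_error")
    a <- x[, g == lv[1], drop = FALSE][, match(common, ids1), drop = FALSE]
    b <- x[, g == lv[2], drop = FALSE][, match(common, ids2), drop = FALSE]
    stat <- lapply(seq_len(n_genes), function(i) t_test2(b[i, ], a[i, ], paired = TRUE))
    p <- vapply(stat, `[[`, 0, "p")
    eff <- vapply(stat, `[[`, 0, "mean_diff")
    constant <- apply(cbind(a, b), 1, function(v) length(unique(v)) == 1L)
  } else {
    groups_idx <- split(seq_along(g), g)
    stat <- lapply(seq_len(n_genes), function(i) {
      one_way_anova(lapply(groups_idx, function(j) x[i, j]))
    })
    p <- vapply(stat, `[[`, 0, "p")
    if (length(lv) == 2L) {
      eff <- rowMeans(x[, g == lv[2], drop = FALSE]) -
        rowMeans(x[, g == lv[1], drop = FALSE])
    } else {
      eff <- rep(NA_real_, n_genes)
    }
    constant <- apply(x, 1, function(v) length(unique(v)) == 1L)
  }
  p[constant] <- 1
  eff[constant] <- 0
  q <- bh_fdr(p)
  out <- data.frame(gene = rownames(x), direction = sign(eff), effect = eff,
                    p = p, q = q, significant = q <= fdr & !constant,
                    constant = constant, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  attr(out, "reference") <- lv[1]
  attr(out, "focal") <- if (length(lv) == 2L) lv[2] else NA_character_
  attr(out, "fdr") <- fdr
  out
}

#' Transcriptional-amplification statistic
#'
#' Among significantly differential genes, the fraction overexpressed in the
#' focal group. A global, almost entirely upward shift (up fraction near 1) is
#' the expression footprint of MYC-driven transcriptional amplification.
#'
#' @param de a `de_result` with a defined focal group.
#' @return list with `n_significant`, `n_up`, `up_fraction` (NA with an
#'   `undefined` marker when nothing is significant).
#' @export
transcriptional_amplification <- function(de) {
  stopifnot(inherits(de, "de_result"))
  sig <- de[de$significant, , drop = FALSE]
  n <- nrow(sig)
  if (n == 0L) {
    return(list(n_significant = 0L, n_up = 0L, up_fraction = NA_real_,
                undefined = TRUE))
  }
  n_up <- sum(sig$direction > 0)
  list(n_significant = n, n_up = n_up, up_fraction = n_up / n, undefined = FALSE)
}

#' Cytoband-region expression screen
#'
#' Filters the expression matrix to genes whose cytoband starts with any of
#' the given prefixes (e.g. `c("18q21.1", "18q21.2")`), restricts to expressed
#' genes (nonzero in at least `expressed_frac` of samples), runs differential
#' expression between the groups, and reports the genes significantly
#' overexpressed in the focal (gain) group, optionally limited to
#' protein-coding genes.
#'
#' @param expr an `expr_matrix`.
#' @param cytoband_prefixes character vector of cytoband prefixes.
#' @param group_labels two-level factor; the second level is the gain/focal
#'   group.
#' @param coding_only report only protein-coding overexpressed genes,
#'   default TRUE.
#' @param expressed_frac detection threshold, default 0.20.
#' @param fdr passed to [differential_expression()].
#' @return list with `region_genes`, `expressed_genes`, `overexpressed`
#'   (character vectors) and the region `de` table.
#' @export
regional_screen <- function(expr, cytoband_prefixes, group_labels,
                            coding_only = TRUE, expressed_frac = 0.20,
                            fdr = 0.10) {
  stopifnot(inherits(expr, "expr_matrix"))
  in_region <- Reduce(`|`, lapply(cytoband_prefixes,
                                  function(p) startsWith(expr$genes$cytoband, p)))
  region <- expr$genes$gene[in_region]
  if (length(region) == 0L) {
    warning("no genes annotated to the requested region")
    return(list(region_genes = character(), expressed_genes = character(),
                overexpressed = character(), de = NULL))
  }
  vals <- expr$values[region, , drop = FALSE]
  expressed <- region[rowMeans(vals > 0) >= expressed_frac]
  if (length(expressed) == 0L) {
    return(list(region_genes = region, expressed_genes = character(),
                overexpressed = character(), de = NULL))
  }
  sub <- expression_matrix(expr$values[expressed, , drop = FALSE],
                           expr$genes[expr$genes$gene %in% expressed, , drop = FALSE])
  de <- differential_expression(sub, group_labels, fdr = fdr)
  over <- de$gene[de$significant & de$direction > 0]
  if (coding_only) {
    over <- over[expr$genes$coding[match(over, expr$genes$gene)]]
  }
  list(region_genes = region, expressed_genes = expressed,
       overexpressed = over, de = de)
}

#' Single-gene expression contrast
#'
#' Two-group Student's t test on one gene's expression values, with an
#' optional exclusion set applied first — the conditional analysis (e.g.
#' association of MYC expression with TP53 status after removing
#' MYC-amplified samples).
#'
#' @param expr an `expr_matrix`.
#' @param gene gene symbol.
#' @param group_labels two-level factor over samples.
#' @param exclude optional character vector of sample (column) names removed
#'   before testing.
#' @return `t_test2` result plus group n's, or a list with a `skipped`
#'   diagnostic when exclusion empties a group.
#' @export
expression_by_group <- function(expr, gene, group_labels, exclude = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (!gene %in% rownames(expr$values)) {
    rd_stop(sprintf("gene '%s' not in expression matrix", gene), "rd_coverage_error")
  }
  keep <- rep(TRUE, ncol(expr$values))
  if (!is.null(exclude)) keep <- !(colnames(expr$values) %in% exclude)
  v <- expr$values[gene, keep]
  g <- droplevels(factor(group_labels[keep]))
  if (nlevels(g) < 2L || any(table(g) < 2L)) {
    return(list(skipped = "a group has fewer than 2 samples after exclusion",
                group_n = table(g)))
  }
  lv <- levels(g)
  c(t_test2(v[g == lv[2]], v[g == lv[1]], paired = FALSE),
    list(group_n = table(g), reference = lv[1], focal = lv[2]))
}

#' Fraction of a gene panel detected
#'
#' QC statistic: the fraction of a panel's genes detected in the matrix,
#' where detection means nonzero expression in at least `detected_frac` of
#' samples. Invariant to panel order.
#'
#' @param expr an `expr_matrix`.
#' @param gene_panel non-empty character vector of gene symbols.
#' @param detected_frac detection threshold, default 0.20.
#' @return fraction in \[0, 1\].
#' @export
panel_detection_fraction <- function(expr, gene_panel, detected_frac = 0.20) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (length(gene_panel) == 0L) rd_stop("gene_panel must be non-empty", "rd_value_error")
  detected <- rownames(expr$values)[rowMeans(expr$values > 0) >= detected_frac]
  length(intersect(unique(gene_panel), detected)) / length(unique(gene_panel))
}
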