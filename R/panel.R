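#' Targeted copy-number panel
#'
#' The 70-gene copy-number panel used throughout the package: cancer genes with
#' loci on 21 chromosomes (none on chr6 or chr21), averaging about three targets
#' per chromosome. The synthetic-cohort generator simulates copy number over
#' exactly this panel, and the recurrence screen iterates over it.
#'
#' @return data.frame with columns `gene`, `chrom`, `cytoband`.
#' @export
panel_genes <- function() {
  g <- c(
    "MCL1",  "1",  "1q21.3",   "BCL9",   "1",  "1q21.2",
    "NRAS",  "1",  "1p13.2",   "MDM4",   "1",  "1q32.1",
    "ALK",   "2",  "2p23.2",   "MSH2",   "2",  "2p21",
    "ERBB4", "2",  "2q34",     "PIK3CA", "3",  "3q26.32",
    "CTNNB1","3",  "3p22.1",   "MLH1",   "3",  "3p22.2",
    "VHL",   "3",  "3p25.3",   "FGFR3",  "4",  "4p16.3",
    "KIT",   "4",  "4q12",     "PDGFRA", "4",  "4q12",
    "FBXW7", "4",  "4q31.3",   "APC",    "5",  "5q22.2",
    "CSF1R", "5",  "5q32",     "FLT4",   "5",  "5q35.3",
    "EGFR",  "7",  "7p11.2",   "MET",    "7",  "7q31.2",
    "BRAF",  "7",  "7q34",     "SMO",    "7",  "7q32.1",
    "MYC",   "8",  "8q24.21",  "FGFR1",  "8",  "8p11.23",
    "NBN",   "8",  "8q21.3",   "CDKN2A", "9",  "9p21.3",
    "ABL1",  "9",  "9q34.12",  "NOTCH1", "9",  "9q34.3",
    "JAK2",  "9",  "9p24.1",   "GATA3",  "10", "10p14",
    "PTEN",  "10", "10q23.31", "FGFR2",  "10", "10q26.13",
    "RET",   "10", "10q11.21", "BIRC2",  "11", "11q22.2",
    "BIRC3", "11", "11q22.2",  "ATM",    "11", "11q22.3",
    "CCND1", "11", "11q13.3",  "HRAS",   "11", "11p15.5",
    "KRAS",  "12", "12p12.1",  "CDK4",   "12", "12q14.1",
    "MDM2",  "12", "12q15",    "ERBB3",  "12", "12q13.2",
    "BRCA2", "13", "13q13.1",  "FLT3",   "13", "13q12.2",
    "RB1",   "13", "13q14.2",  "PNP",    "14", "14q11.2",
    "AKT1",  "14", "14q32.33", "IDH2",   "15", "15q26.1",
    "MAP2K1","15", "15q22.31", "CDH1",   "16", "16q22.1",
    "TSC2",  "16", "16p13.3",  "PALB2",  "16", "16p12.2",
    "TP53",  "17", "17p13.1",  "ERBB2",  "17", "17q12",
    "NF1",   "17", "17q11.2",  "BRCA1",  "17", "17q21.31",
    "SMAD4", "18", "18q21.2",  "SMAD2",  "18", "18q21.1",
    "BCL2",  "18", "18q21.33", "STK11",  "19", "19p13.3",
    "AKT2",  "19", "19q13.2",  "CCNE1",  "19", "19q12",
    "SRC",   "20", "20q11.23", "AURKA",  "20", "20q13.2",
    "GNAS",  "20", "20q13.32", "NF2",    "22", "22q12.2",
    "CHEK2", "22", "22q12.1",  "EP300",  "22", "22q13.2",
    "AR",    "X",  "Xq12",     "KDM6A",  "X",  "Xp11.3"
  )
  m <- matrix(g, ncol = 3, byrow = TRUE)
  data.frame(gene = m[, 1], chrom = m[, 2], cytoband = m[, 3],
             stringsAsFactors = FALSE)
}
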