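#' Define a set of biallelic loci
#'
#' A locus set is the typing panel of a study: short labels, the two alleles
#' ("I"/"D" labels for indels are accepted), and which allele is scored as
#' the risk allele. Risk-allele dosage g in {0, 1, 2} is the genotype coding
#' every downstream analysis consumes.
#'
#' @param locus_id character vector of short unique labels (e.g. "PTPN22").
#' @param allele_a,allele_b allele labels per locus; must differ within a locus.
#' @param risk_allele per-locus risk allele; each must equal `allele_a` or
#'   `allele_b` at that locus.
#' @param rsid optional dbSNP identifiers (used to match PLINK MAP files).
#' @return a data.frame of class `"locus_set"` with one row per locus.
#' @seealso [ra_loci()] for the built-in 11-locus rheumatoid-arthritis panel.
#' @export
locus_set <- function(locus_id, allele_a, allele_b, risk_allele,
                      rsid = NA_character_) {
  ls <- data.frame(locus_id = as.character(locus_id),
                   rsid = as.character(rsid),
                   allele_a = as.character(allele_a),
                   allele_b = as.character(allele_b),
                   risk_allele = as.character(risk_allele),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(ls$locus_id))
    stop_data("duplicate locus_id: %s",
              paste(unique(ls$locus_id[duplicated(ls$locus_id)]), collapse = ", "))
  bad <- ls$allele_a == ls$allele_b
  if (any(bad))
    stop_data("allele_a equals allele_b at locus %s", ls$locus_id[bad][1])
  bad <- !(ls$risk_allele == ls$allele_a | ls$risk_allele == ls$allele_b)
  if (any(bad))
    stop_data("risk_allele not one of the locus alleles at %s", ls$locus_id[bad][1])
  class(ls) <- c("locus_set", "data.frame")
  ls
}

#' The 11-locus rheumatoid-arthritis candidate panel
#'
#' The panel of 11 SNP/indel markers in nine genes used throughout the
#' package examples: ACE I/D, three VDR restriction-site polymorphisms
#' (BsmI, FokI, TaqI), TNFR2, IL4-590, STAT4, TRAF1-C5, PTPN22, HLA-DRB1
#' and TNF-alpha -308. Risk alleles are the six identified as susceptibility
#' alleles in this panel (TNFR2 G, TRAF1 A, PTPN22 T, HLA-DRB1 G,
#' TNF-alpha A, IL4-590 T) plus, for the remaining loci, the allele in the
#' direction of the reported effect (ACE D, BsmI T, FokI C, TaqI G, STAT4 T).
#' All defaults are overridable by building your own [locus_set()].
#'
#' @return a `"locus_set"` with 11 rows.
#' @export
ra_loci <- function() {
  locus_set(
    locus_id = c("ACE", "VDR_Bsm1", "VDR_Fok1", "VDR_Taq1", "TNFR2",
                 "IL4_590", "STAT4", "TRAF1", "PTPN22", "HLA_DRB1", "TNFa_308"),
    rsid = c("rs4646994", "rs1544410", "rs10735810", "rs731236", "rs1061622",
             "rs2243250", "rs7574865", "rs10818488", "rs2476601", "rs660895",
             "rs1800629"),
    allele_a = c("I", "A", "T", "A", "T", "C", "G", "G", "C", "A", "G"),
    allele_b = c("D", "T", "C", "G", "G", "T", "T", "A", "T", "G", "A"),
    risk_allele = c("D", "T", "C", "G", "G", "T", "T", "A", "T", "G", "A")
  )
}

#' Published per-group frequency summaries for the RA panel
#'
#' Per-locus, per-group allele and genotype frequencies as published for the
#' East Midlands RA case-control sample (137 patients, 150 controls).
#' Genotype frequencies are given in risk-allele dosage order (g = 0, 1, 2).
#' These rounded values are inputs for count reconstruction, the PRS
#' mean-difference identity, and the table-driven simulator.
#'
#' @return data.frame with columns `locus_id`, `group` (`"case"`/`"control"`),
#'   `risk_freq` (printed risk-allele frequency), `g0`, `g1`, `g2`
#'   (printed genotype frequencies by risk-allele dosage).
#' @export
ra_published_freqs <- function() {
  tab <- rbind(
    # locus            case: risk  g0    g1    g2    control: risk g0    g1    g2
    c("ACE",       0.56, 0.28, 0.32, 0.40,   0.55, 0.19, 0.51, 0.30),
    c("VDR_Bsm1",  0.50, 0.28, 0.43, 0.28,   0.46, 0.33, 0.41, 0.26),
    c("VDR_Fok1",  0.42, 0.33, 0.48, 0.18,   0.39, 0.37, 0.43, 0.17),
    c("VDR_Taq1",  0.36, 0.40, 0.48, 0.12,   0.34, 0.47, 0.38, 0.14),
    c("TNFR2",     0.41, 0.33, 0.53, 0.14,   0.28, 0.49, 0.46, 0.05),
    c("IL4_590",   0.22, 0.63, 0.31, 0.07,   0.14, 0.74, 0.25, 0.01),
    c("STAT4",     0.24, 0.52, 0.47, 0.01,   0.27, 0.49, 0.48, 0.03),
    c("TRAF1",     0.54, 0.21, 0.50, 0.29,   0.38, 0.35, 0.54, 0.11),
    c("PTPN22",    0.23, 0.59, 0.35, 0.06,   0.12, 0.77, 0.22, 0.01),
    c("HLA_DRB1",  0.36, 0.40, 0.47, 0.13,   0.25, 0.55, 0.40, 0.05),
    c("TNFa_308",  0.30, 0.52, 0.37, 0.11,   0.22, 0.60, 0.37, 0.03)
  )
  out <- data.frame(
    locus_id = rep(tab[, 1], each = 2),
    group = rep(c("case", "control"), nrow(tab)),
    risk_freq = as.numeric(t(tab[, c(2, 6)])),
    g0 = as.numeric(t(tab[, c(3, 7)])),
    g1 = as.numeric(t(tab[, c(4, 8)])),
    g2 = as.numeric(t(tab[, c(5, 9)])),
    stringsAsFactors = FALSE
  )
  out
}

#' Published per-allele (log-additive) odds ratios for the RA panel
#'
#' Crude and covariate-adjusted per-allele odds ratios published for the
#' 11-locus panel. These serve as weight sources for the weighted polygenic
#' risk score ("crude" or "adjusted" schemes).
#'
#' @return data.frame with columns `locus_id`, `crude_or`, `adjusted_or`.
#' @export
ra_published_or <- function() {
  data.frame(
    locus_id = c("ACE", "VDR_Bsm1", "VDR_Fok1", "VDR_Taq1", "TNFR2",
                 "IL4_590", "STAT4", "TRAF1", "PTPN22", "HLA_DRB1", "TNFa_308"),
    crude_or    = c(1.02, 1.14, 1.15, 1.11, 1.87, 1.77, 1.47, 1.99, 2.15, 1.73, 1.49),
    adjusted_or = c(1.10, 1.03, 1.02, 1.04, 2.28, 1.83, 1.68, 1.78, 2.63, 1.92, 1.00),
    stringsAsFactors = FALSE
  )
}

#' Published covariate distributions for the RA sample
#'
#' Group-specific lifestyle and demographic distributions of the study
#' sample, used by the synthetic-cohort generator: mean age, proportion
#' male, diet proportions (vegetarian / mixed / mostly meat) and weekly
#' alcohol bands (0, 1-6, 7-13, 14+ units). Printed percentages that do not
#' sum to one (the control diet column) are renormalised. Age standard
#' deviations were not published; 12 years is used as a realistic value for
#' an adult case-control sample.
#'
#' @return a list with `case` and `control` components, each holding
#'   `age_mean`, `age_sd`, `p_male`, `diet` (named probabilities) and
#'   `alcohol` (named probabilities).
#' @export
ra_published_covariates <- function() {
  norm <- function(x) x / sum(x)
  list(
    case = list(
      age_mean = 49.0, age_sd = 12,
      p_male = 37 / 137,
      diet = norm(c(vegetarian = 5, mixed = 90, mostly_meat = 22)),
      alcohol = norm(c(`0` = 79, `1-6` = 33, `7-13` = 11, `14+` = 14))
    ),
    control = list(
      age_mean = 58.9, age_sd = 12,
      p_male = 64 / 148,
      diet = norm(c(vegetarian = 15, mixed = 96, mostly_meat = 15)),
      alcohol = norm(c(`0` = 61, `1-6` = 47, `7-13` = 14, `14+` = 27))
    )
  )
}
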