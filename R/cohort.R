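DIET_LEVELS <- c("vegetarian", "mixed", "mostly_meat")
ALCOHOL_LEVELS <- c("0", "1-6", "7-13", "14+")
SMOKING_LEVELS <- c("never", "ever", "unknown")

#' Build a case-control cohort
#'
#' A cohort bundles the typing panel ([locus_set()]), per-individual
#' phenotype/covariate records, and a genotype matrix coded as risk-allele
#' dosage: g = 0 (no copy of the risk allele), 1 (heterozygote), 2
#' (risk-allele homozygote), `NA` missing. Every analysis in the package
#' consumes this dosage coding.
#'
#' @param loci a [locus_set()].
#' @param sample_id unique sample identifiers.
#' @param status `"case"`/`"control"` (factor or character); `NA` allowed.
#' @param geno integer matrix, individuals x loci, entries in `{0,1,2,NA}`;
#'   column order must follow `loci$locus_id`.
#' @param age numeric years (optional).
#' @param sex `"male"`/`"female"` (optional).
#' @param diet one of `"vegetarian"`, `"mixed"`, `"mostly_meat"` (optional).
#' @param alcohol weekly-units band: `"0"`, `"1-6"`, `"7-13"`, `"14+"`
#'   (ordered; entered in regressions as integer scores 0-3).
#' @param smoking `"never"`, `"ever"` or `"unknown"` (optional).
#' @return an object of class `"raprs_cohort"`.
#' @export
cohort <- function(loci, sample_id, status, geno,
                   age = NULL, sex = NULL, diet = NULL,
                   alcohol = NULL, smoking = NULL) {
  stopifnot(inherits(loci, "locus_set"))
  n <- length(sample_id)
  geno <- as.matrix(geno)
  if (is.null(dim(geno)) || nrow(geno) != n || ncol(geno) != nrow(loci))
    stop_data("genotype matrix must be %d individuals x %d loci", n, nrow(loci))
  storage.mode(geno) <- "integer"
  ok <- is.na(geno) | geno %in% 0:2
  if (!all(ok))
    stop_data("genotype dosages must be 0, 1, 2 or NA")
  dimnames(geno) <- list(as.character(sample_id), loci$locus_id)

  as_level <- function(x, levels, what, ordered = FALSE) {
    if (is.null(x)) return(factor(rep(NA_character_, n), levels = levels, ordered = ordered))
    x <- as.character(x)
    bad <- !is.na(x) & !(x %in% levels)
    if (any(bad))
      stop_data("invalid %s value '%s'", what, x[bad][1])
    factor(x, levels = levels, ordered = ordered)
  }
  info <- data.frame(
    sample_id = as.character(sample_id),
    status = as_level(status, c("control", "case"), "status"),
    age = if (is.null(age)) rep(NA_real_, n) else as.numeric(age),
    sex = as_level(sex, c("female", "male"), "sex"),
    diet = as_level(diet, DIET_LEVELS, "diet"),
    alcohol = as_level(alcohol, ALCOHOL_LEVELS, "alcohol", ordered = TRUE),
    smoking = as_level(smoking, SMOKING_LEVELS, "smoking"),
    stringsAsFactors = FALSE
  )
  structure(list(loci = loci, info = info, geno = geno),
            class = "raprs_cohort")
}

#' @export
print.raprs_cohort <- function(x, ...) {
  st <- table(x$info$status)
  cat(sprintf("Case-control cohort: %d individuals (%d cases, %d controls), %d loci\n",
              nrow(x$info), st[["case"]], st[["control"]], nrow(x$loci)))
  cat("Loci:", paste(x$loci$locus_id, collapse = ", "), "\n")
  miss <- mean(is.na(x$geno))
  if (miss > 0) cat(sprintf("Missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
summary.raprs_cohort <- function(object, ...) validate_cohort(object)

#' Number of individuals / loci in a cohort
#' @param cohort a [cohort()].
#' @return integer count.
#' @export
n_individuals <- function(cohort) nrow(cohort$info)

#' @rdname n_individuals
#' @export
n_loci <- function(cohort) nrow(cohort$loci)

#' Swap the risk allele at a locus
#'
#' Recodes dosages at one locus so the other allele is counted: every
#' non-missing g becomes 2 - g and the locus definition is updated.
#'
#' @param cohort a [cohort()].
#' @param locus_id locus to recode.
#' @return the recoded cohort.
#' @export
swap_risk_allele <- function(cohort, locus_id) {
  j <- match(locus_id, cohort$loci$locus_id)
  if (is.na(j)) stop_data("unknown locus '%s'", locus_id)
  cohort$geno[, j] <- 2L - cohort$geno[, j]
  other <- ifelse(cohort$loci$risk_allele[j] == cohort$loci$allele_a[j],
                  cohort$loci$allele_b[j], cohort$loci$allele_a[j])
  cohort$loci$risk_allele[j] <- other
  cohort
}

# dosage from an allele-pair string like "C/T" given a locus definition
.pair_to_dosage <- function(pair, locus) {
  alleles <- strsplit(pair, "/", fixed = TRUE)[[1]]
  if (length(alleles) != 2) return(structure(NA_integer_, bad = TRUE))
  known <- c(locus$allele_a, locus$allele_b)
  if (!all(alleles %in% known)) return(structure(NA_integer_, bad = TRUE))
  sum(alleles == locus$risk_allele)
}

#' Read a cohort from a tidy delimited table
#'
#' One row per individual. Mandatory columns `sample_id` and `status`;
#' optional covariate columns `age`, `sex`, `diet`, `alcohol`, `smoking`;
#' one column per locus named by its `locus_id`, holding either a dosage
#' (0/1/2) or an allele pair such as `"C/T"`. Allele pairs are converted to
#' risk-allele dosage against `locus_spec`; alleles not defined at the locus
#' are a data error naming the sample and locus. The delimiter is detected
#' among tab and comma.
#'
#' @param path file path.
#' @param locus_spec a [locus_set()] defining alleles and risk alleles.
#' @param status_codes named character vector mapping raw status values to
#'   `"case"`/`"control"`. The default accepts `case`/`control` literals,
#'   0/1 coding (1 = case) and PLINK-style 1/2 coding (2 = case, only used
#'   when a `2` is present).
#' @return a [cohort()].
#' @export
read_cohort_table <- function(path, locus_spec, status_codes = NULL) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""), stringsAsFactors = FALSE)
  for (col in c("sample_id", "status"))
    if (!col %in% names(tab))
      stop_data("format error: mandatory column '%s' missing", col)
  missing_loci <- setdiff(locus_spec$locus_id, names(tab))
  if (length(missing_loci))
    stop_data("format error: locus column '%s' missing", missing_loci[1])

  raw <- tab$status
  if (is.null(status_codes)) {
    vals <- unique(raw[!is.na(raw)])
    if (all(vals %in% c("case", "control"))) {
      status <- raw
    } else if (all(vals %in% c("0", "1"))) {
      status <- ifelse(raw == "1", "case", "control")
    } else if (all(vals %in% c("1", "2"))) {
      status <- ifelse(raw == "2", "case", "control")
    } else stop_data("data error: unrecognised status coding: %s",
                     paste(utils::head(vals), collapse = ", "))
  } else {
    status <- unname(status_codes[raw])
    if (any(is.na(status) & !is.na(raw)))
      stop_data("data error: status value not covered by status_codes")
  }

  n <- nrow(tab)
  geno <- matrix(NA_integer_, n, nrow(locus_spec))
  for (j in seq_len(nrow(locus_spec))) {
    locus <- locus_spec[j, ]
    col <- tab[[locus$locus_id]]
    for (i in seq_len(n)) {
      v <- col[i]
      if (is.na(v)) next
      if (v %in% c("0", "1", "2")) { geno[i, j] <- as.integer(v); next }
      d <- .pair_to_dosage(v, locus)
      if (isTRUE(attr(d, "bad")))
        stop_data("data error: sample '%s', locus '%s': allele pair '%s' not in {%s,%s}",
                  tab$sample_id[i], locus$locus_id, v, locus$allele_a, locus$allele_b)
      geno[i, j] <- d
    }
  }
  cohort(locus_spec, tab$sample_id, status, geno,
         age = if ("age" %in% names(tab)) suppressWarnings(as.numeric(tab$age)),
         sex = tab[["sex"]], diet = tab[["diet"]],
         alcohol = tab[["alcohol"]], smoking = tab[["smoking"]])
}

#' Read a cohort from PLINK text PED/MAP files
#'
#' Standard 6-column PED prefix (family, individual, paternal, maternal,
#' sex, phenotype) followed by two allele columns per locus; the MAP file
#' supplies locus identifiers in column 2, matched against `locus_spec` by
#' `rsid` first, then by `locus_id`. Phenotype 1 = control, 2 = case,
#' 0/-9 = missing; allele code "0" marks a missing genotype.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @param locus_spec a [locus_set()].
#' @return a [cohort()] with loci ordered as in `locus_spec`.
#' @export
read_plink_text <- function(ped_path, map_path, locus_spec) {
  map <- utils::read.table(map_path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(map) < 2) stop_data("format error: MAP file needs >= 2 columns")
  map_ids <- map[[2]]
  ped <- utils::read.table(ped_path, header = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(ped) != 6 + 2 * length(map_ids))
    stop_data("format error: PED has %d allele columns for %d MAP loci",
              ncol(ped) - 6, length(map_ids))
  idx <- match(map_ids, locus_spec$rsid)
  idx[is.na(idx)] <- match(map_ids[is.na(idx)], locus_spec$locus_id)
  if (anyNA(idx))
    stop_data("data error: MAP locus '%s' not in locus_spec", map_ids[is.na(idx)][1])

  pheno <- ped[[6]]
  if (!all(pheno %in% c("0", "1", "2", "-9")))
    stop_data("data error: phenotype value '%s' outside {0,1,2,-9}",
              setdiff(pheno, c("0", "1", "2", "-9"))[1])
  status <- ifelse(pheno == "2", "case", ifelse(pheno == "1", "control", NA))
  sex <- ifelse(ped[[5]] == "1", "male", ifelse(ped[[5]] == "2", "female", NA))

  n <- nrow(ped)
  geno <- matrix(NA_integer_, n, nrow(locus_spec))
  for (k in seq_along(map_ids)) {
    j <- idx[k]
    locus <- locus_spec[j, ]
    a1 <- ped[[6 + 2 * k - 1]]
    a2 <- ped[[6 + 2 * k]]
    for (i in seq_len(n)) {
      if (a1[i] == "0" || a2[i] == "0") next  # missing
      pair <- c(a1[i], a2[i])
      if (!all(pair %in% c(locus$allele_a, locus$allele_b)))
        stop_data("data error: sample '%s', locus '%s': allele '%s' undefined",
                  ped[[2]][i], locus$locus_id,
                  setdiff(pair, c(locus$allele_a, locus$allele_b))[1])
      geno[i, j] <- sum(pair == locus$risk_allele)
    }
  }
  ids <- ped[[2]]
  if (anyDuplicated(ids)) ids <- paste(ped[[1]], ped[[2]], sep = "_")
  cohort(locus_spec, ids, status, geno, sex = sex)
}

#' Write a cohort to a tab-delimited table
#'
#' Writes the tidy-table representation [read_cohort_table()] accepts:
#' genotypes as dosages, missing values as `NA`. The round trip
#' `read_cohort_table(write_cohort_table(x), x$loci)` reproduces genotypes,
#' status and covariates exactly.
#'
#' @param cohort a [cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  tab <- cbind(cohort$info, as.data.frame(cohort$geno, check.names = FALSE))
  # factors to character for a stable text round trip
  tab[] <- lapply(tab, function(x) if (is.factor(x)) as.character(x) else x)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Validate a cohort
#'
#' Reports group sizes, per-locus missingness and structural problems
#' (duplicate sample ids, missing status). Problems are reported, never
#' thrown; the cohort is not modified.
#'
#' @param cohort a [cohort()].
#' @return an object of class `"raprs_validation"`: a list with `n_cases`,
#'   `n_controls`, `missingness` (named per-locus fraction) and `errors`
#'   (character vector of messages, empty when clean).
#' @export
validate_cohort <- function(cohort) {
  errors <- character()
  dup <- unique(cohort$info$sample_id[duplicated(cohort$info$sample_id)])
  if (length(dup))
    errors <- c(errors, sprintf("duplicate sample_id: %s", paste(dup, collapse = ", ")))
  n_na_status <- sum(is.na(cohort$info$status))
  if (n_na_status)
    errors <- c(errors, sprintf("%d individuals with missing status", n_na_status))
  miss <- colMeans(is.na(cohort$geno))
  structure(list(
    n_cases = sum(cohort$info$status == "case", na.rm = TRUE),
    n_controls = sum(cohort$info$status == "control", na.rm = TRUE),
    missingness = miss,
    errors = errors
  ), class = "raprs_validation")
}

#' @export
print.raprs_validation <- function(x, ...) {
  cat(sprintf("Cohort validation: %d cases, %d controls\n", x$n_cases, x$n_controls))
  if (any(x$missingness > 0)) {
    worst <- sort(x$missingness[x$missingness > 0], decreasing = TRUE)
    cat("Per-locus missingness:\n")
    for (l in names(worst)) cat(sprintf("  %s: %.1f%%\n", l, 100 * worst[[l]]))
  } else cat("No missing genotypes\n")
  if (length(x$errors)) {
    cat("Problems:\n")
    for (e in x$errors) cat("  -", e, "\n")
  } else cat("No structural problems\n")
  invisible(x)
}
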