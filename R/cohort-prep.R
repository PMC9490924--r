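#' Encode raw clinical records into model-ready covariates
#'
#' Applies the cohort's fixed encoding: age is dichotomized at 65 years
#' (`age_group` 1 for 65 and older), sex is 1 for male and 0 for female,
#' pack-years plus free-text smoking history collapse to a three-level
#' smoking status, and pathologic stage collapses to three groups
#' (early = I/Ia/Ib, locally advanced = II/IIa/IIb/IIIa,
#' advanced = IIIb/IV). Heavy smoker means 30 or more pack years or a
#' 'current smoker' history; zero pack years or 'lifelong non-smoker' (or,
#' with pack years missing, 'current reformed smoker for > 15 years') means
#' non-smoker; everything below 30 pack years (or, missing, 'current
#' reformed smoker for < or = 15 years') means light smoker.
#'
#' Rows that cannot be mapped are dropped and reported (with a reason) in
#' the `rejected` attribute of the result.
#'
#' @param raw Data frame with columns `patient_id`, `age`, `sex`,
#'   `pack_years`, `smoking_history`, `stage` (missing values allowed).
#' @param row_filter Optional predicate `function(row)` returning `FALSE`
#'   for rows to exclude up front (generic dataset-specific cleaning, e.g.
#'   demographic exclusions); excluded rows are logged with reason
#'   `"row_filter"`.
#' @return Data frame with `patient_id`, `age_group`, `sex`, `smoking`
#'   (factor non_smoker/light/heavy), `stage` (factor
#'   early/locally_advanced/advanced); attribute `rejected` lists dropped
#'   rows and reasons.
#' @export
encode_clinical <- function(raw, row_filter = NULL) {
  need <- c("patient_id", "age", "sex", "pack_years", "smoking_history",
            "stage")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) stop("raw clinical table lacks columns: ",
                                 paste(missing_cols, collapse = ", "))
  rejected <- data.frame(patient_id = character(0), reason = character(0))
  reject <- function(id, reason) {
    rejected <<- rbind(rejected,
                       data.frame(patient_id = id, reason = reason))
    NULL
  }
  norm <- function(x) tolower(trimws(as.character(x)))
  rows <- lapply(seq_len(nrow(raw)), function(i) {
    r <- raw[i, ]
    id <- as.character(r$patient_id)
    if (!is.null(row_filter) && !isTRUE(row_filter(r)))
      return(reject(id, "row_filter"))
    if (is.na(r$age)) return(reject(id, "missing age"))
    sex <- switch(norm(r$sex), male = 1L, female = 0L, -1L)
    if (sex < 0L) return(reject(id, "unmappable sex"))
    hist <- norm(r$smoking_history)
    py <- suppressWarnings(as.numeric(r$pack_years))
    smoking <-
      if ((!is.na(py) && py >= 30) || identical(hist, "current smoker"))
        "heavy"
      else if ((!is.na(py) && py == 0) ||
               identical(hist, "lifelong non-smoker") ||
               (is.na(py) &&
                identical(hist, "current reformed smoker for > 15 years")))
        "non_smoker"
      else if ((!is.na(py) && py < 30) ||
               (is.na(py) &&
                identical(hist,
                          "current reformed smoker for < or = 15 years")))
        "light"
      else return(reject(id, "unmappable smoking"))
    st <- sub("^stage\\s+", "", norm(r$stage))
    stage <-
      if (st %in% c("i", "ia", "ib")) "early"
      else if (st %in% c("ii", "iia", "iib", "iiia")) "locally_advanced"
      else if (st %in% c("iiib", "iv")) "advanced"
      else return(reject(id, "unmappable stage"))
    data.frame(patient_id = id, age_group = as.integer(r$age >= 65),
               sex = sex, smoking = smoking, stage = stage)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(patient_id = character(0), age_group = integer(0),
                      sex = integer(0), smoking = character(0),
                      stage = character(0))
  out$smoking <- factor(out$smoking,
                        levels = c("non_smoker", "light", "heavy"))
  out$stage <- factor(out$stage,
                      levels = c("early", "locally_advanced", "advanced"))
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Filter mutation genes by carrier count
#'
#' Keeps only genes carried (mutated) by at least `min_carriers` patients;
#' with the default 16, genes mutated in up to 15 patients are removed.
#'
#' @param mutations Data frame or matrix of binary mutation indicators,
#'   patients in rows, genes in columns (a `patient_id` column is passed
#'   through untouched).
#' @param min_carriers Minimum carrier count to keep a gene (default 16).
#' @return The input restricted to surviving gene columns; attribute
#'   `dropped` names the removed genes with their carrier counts.
#' @export
filter_genes <- function(mutations, min_carriers = 16L) {
  df <- as.data.frame(mutations)
  gene_cols <- setdiff(names(df), "patient_id")
  if (length(gene_cols) == 0L || nrow(df) == 0L)
    stop("mutation matrix is empty")
  m <- as.matrix(df[gene_cols])
  if (!all(m %in% c(0, 1))) stop("mutation indicators must be binary 0/1")
  carriers <- colSums(m)
  keep <- carriers >= min_carriers
  out <- df[c(intersect("patient_id", names(df)), gene_cols[keep])]
  attr(out, "dropped") <- carriers[!keep]
  out
}

check_unique_ids <- function(tab, name) {
  if (anyDuplicated(tab$patient_id))
    stop("duplicate patient_id in ", name, " table")
}

#' Merge features, clinical, survival and mutation tables into one dataset
#'
#' Inner join of the four tables on `patient_id`, in deterministic
#' ascending id order. Row counts before/after each join step are recorded
#' in the `join_log` attribute; duplicate ids within any table are an
#' error, and an empty intersection raises a warning.
#'
#' @param features,clinical,survival,mutations Data frames each carrying a
#'   `patient_id` column; `survival` must have positive `time` and binary
#'   `event`.
#' @return One-row-per-patient data frame with all columns.
#' @export
merge_cohort <- function(features, clinical, survival, mutations) {
  tabs <- list(features = features, clinical = clinical,
               survival = survival, mutations = mutations)
  for (nm in names(tabs)) {
    if (!"patient_id" %in% names(tabs[[nm]]))
      stop(nm, " table lacks patient_id")
    check_unique_ids(tabs[[nm]], nm)
  }
  if (any(survival$time <= 0, na.rm = TRUE))
    stop("survival times must be positive")
  if (!all(survival$event %in% c(0, 1)))
    stop("event indicator must be binary 0/1")
  log <- data.frame(step = "features", rows = nrow(features))
  out <- features
  for (nm in c("clinical", "survival", "mutations")) {
    out <- merge(out, tabs[[nm]], by = "patient_id", sort = TRUE)
    log <- rbind(log, data.frame(step = paste0("+", nm), rows = nrow(out)))
  }
  if (nrow(out) == 0L) warning("empty patient-id intersection across tables")
  out <- out[order(out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "join_log") <- log
  out
}
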