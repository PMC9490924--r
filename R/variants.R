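#' Feature-set variants for the outcome models
#'
#' The survival and mutation models are compared across fixed combinations
#' of predictors: the clinical covariates alone, clinical plus one scalar
#' spatial metric (ITLR, Shannon, Simpson), clinical plus the TMEC or TIP
#' vectors, both, or (for mutation classification only) TMEC alone.
#'
#' Because TIP entries sum to 1 (and TMEC entries likewise when defined),
#' one entry per vector is linearly redundant in a proportional-hazards
#' design; for Cox models the normal-lung column (`t_lung` / `m_lung`) is
#' treated as the reference tissue and omitted. Classification models keep
#' all entries (the learners are penalized or tree-based).
#'
#' @param variant Variant name; see `survival_variants()` /
#'   `mutation_variants()` for the valid sets.
#' @param for_cox Drop the reference tissue column of each composition
#'   vector (used when building Cox designs).
#' @return `variant_features` returns the feature column names of the
#'   variant (character, possibly empty for `"clinical"`); the two
#'   `_variants()` helpers return the valid variant names.
#' @export
variant_features <- function(variant, for_cox = FALSE) {
  tip <- paste0("t_", tolower(tissue_class_names()))
  tmec <- paste0("m_", tolower(setdiff(tissue_class_names(), "TUMOR")))
  if (for_cox) {
    tip <- setdiff(tip, "t_lung")
    tmec <- setdiff(tmec, "m_lung")
  }
  switch(variant,
         "clinical" = character(0),
         "clinical+ITLR" = "itlr",
         "clinical+Shannon" = "shannon",
         "clinical+Simpson" = "simpson",
         "clinical+TMEC" = tmec,
         "clinical+TIP" = tip,
         "clinical+TMEC+TIP" = c(tmec, tip),
         "TMEC" = tmec,
         stop("unknown variant: ", variant))
}

#' @rdname variant_features
#' @export
survival_variants <- function() {
  c("clinical", "clinical+ITLR", "clinical+Shannon", "clinical+Simpson",
    "clinical+TMEC", "clinical+TIP", "clinical+TMEC+TIP")
}

#' @rdname variant_features
#' @export
mutation_variants <- function() c(survival_variants(), "TMEC")

clinical_columns <- function() c("age_group", "sex", "smoking", "stage")

# Model frame for a variant: clinical covariates (unless variant is pure
# TMEC), the variant's feature columns, and optional mutation indicators.
variant_design <- function(dataset, variant, mutations = NULL,
                           for_cox = FALSE) {
  feats <- variant_features(variant, for_cox = for_cox)
  cols <- c(if (variant != "TMEC") clinical_columns(), feats, mutations)
  missing <- setdiff(cols, names(dataset))
  if (length(missing)) stop("dataset lacks columns: ",
                            paste(missing, collapse = ", "))
  design <- dataset[cols]
  if (anyNA(design)) stop("variant design contains missing values")
  design
}
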