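#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic-data module: label-grid geometry and
#' class mixture, cohort size, and the ground-truth survival (Cox) and
#' mutation (logistic) models. All randomness downstream derives from
#' `seed` through fixed sub-seed offsets, so an identical config gives
#' byte-identical output.
#'
#' @param grid_rows,grid_cols Grid dimensions in patches (>= 3).
#' @param target_prevalence Named fractions over the eight tissue classes
#'   (lower-case names, see [tissue_class_names()]); must be nonnegative
#'   and sum to 1. Default: uniform.
#' @param background_border Width of the all-BACKGROUND outer ring, in
#'   patches.
#' @param contiguity Positive region-growth strength; the generator jumps
#'   to a new blob seed with probability `exp(-contiguity)`, so large
#'   values give large contiguous regions and values near 0 give speckle.
#' @param n_patients Number of patients in [gen_cohort()].
#' @param slides_per_patient Slides simulated (and averaged) per patient.
#' @param prevalence_dispersion Dirichlet concentration governing
#'   patient-to-patient variation of the class mixture around
#'   `target_prevalence` (smaller = more heterogeneous cohorts; the
#'   default 4 emulates the strong slide-to-slide variability of real
#'   cohorts).
#' @param min_tumor_frac,max_tumor_frac Bounds on each patient's tumor
#'   share after the Dirichlet draw (defaults 0.05 and 0.95). Diagnostic
#'   slides of a tumor cohort always contain some tumor and are never
#'   tumor-only, and the bounds keep the tumor-neighborhood features
#'   defined on every slide.
#' @param cox_betas Named log-hazard coefficients on feature/covariate
#'   columns (e.g. `c(t_necrosis = 1)`); `NULL` for a null survival model.
#' @param baseline_rate Exponential baseline hazard per day (default
#'   `log(2)/730`: two-year median survival at covariate effect 1).
#' @param censor_frac Target fraction of censored patients in `[0, 1]`.
#' @param logit_betas Named logistic coefficients for the first gene in
#'   `mutation_genes`; `NULL` for a null mutation model.
#' @param logit_intercept Logistic intercept (default -1, about 27%
#'   mutation prevalence under the null).
#' @param mutation_genes Gene column names to simulate; genes after the
#'   first are intercept-only.
#' @param clinical_probs List with `sex`, `age` (Bernoulli probabilities)
#'   and `smoking`, `stage` (length-3 category probabilities).
#' @param seed Integer master seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(grid_rows = 24L, grid_cols = 24L,
                       target_prevalence = NULL,
                       background_border = 2L, contiguity = 5,
                       n_patients = 200L, slides_per_patient = 1L,
                       prevalence_dispersion = 4,
                       min_tumor_frac = 0.05, max_tumor_frac = 0.95,
                       cox_betas = NULL, baseline_rate = log(2) / 730,
                       censor_frac = 0.25,
                       logit_betas = NULL, logit_intercept = -1,
                       mutation_genes = c("EGFR", "STK11", "TP53"),
                       clinical_probs = list(sex = 0.5, age = 0.5,
                                             smoking = c(0.2, 0.4, 0.4),
                                             stage = c(0.5, 0.35, 0.15)),
                       seed = 1L) {
  classes <- tolower(tissue_class_names())
  if (is.null(target_prevalence))
    target_prevalence <- stats::setNames(rep(1 / 8, 8), classes)
  if (is.null(names(target_prevalence)) ||
      !all(names(target_prevalence) %in% classes))
    stop("target_prevalence must be named by tissue classes: ",
         paste(classes, collapse = ", "))
  full <- stats::setNames(rep(0, 8), classes)
  full[names(target_prevalence)] <- as.numeric(target_prevalence)
  if (any(full < 0)) stop("target_prevalence entries must be nonnegative")
  if (abs(sum(full) - 1) > 1e-9) stop("target_prevalence must sum to 1")
  if (grid_rows < 3 || grid_cols < 3) stop("grid dimensions must be >= 3")
  if (grid_rows - 2 * background_border < 1 ||
      grid_cols - 2 * background_border < 1)
    stop("grid too small to honor background_border")
  if (contiguity <= 0) stop("contiguity must be positive")
  if (censor_frac < 0 || censor_frac > 1) stop("censor_frac must be in [0, 1]")
  if (n_patients < 1 || slides_per_patient < 1)
    stop("n_patients and slides_per_patient must be positive")
  if (min_tumor_frac < 0 || max_tumor_frac > 1 ||
      min_tumor_frac >= max_tumor_frac)
    stop("tumor fraction bounds must satisfy 0 <= min < max <= 1")
  cfg <- list(grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              target_prevalence = full,
              background_border = as.integer(background_border),
              contiguity = contiguity,
              n_patients = as.integer(n_patients),
              slides_per_patient = as.integer(slides_per_patient),
              prevalence_dispersion = prevalence_dispersion,
              min_tumor_frac = min_tumor_frac,
              max_tumor_frac = max_tumor_frac,
              cox_betas = cox_betas, baseline_rate = baseline_rate,
              censor_frac = censor_frac,
              logit_betas = logit_betas, logit_intercept = logit_intercept,
              mutation_genes = mutation_genes,
              clinical_probs = clinical_probs, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Seeded multi-source region growth over the grid interior. Class quotas
# are fixed by largest-remainder apportionment, so realized fractions match
# targets up to one patch per class. Growth pops cells from the class's
# frontier (4-neighbors of its region); with probability exp(-contiguity),
# or when the frontier is exhausted, the class instead starts a new blob at
# the next free cell of a pre-shuffled visit order.
grow_interior <- function(n_r, n_c, prevalence, contiguity) {
  n <- n_r * n_c
  quota <- apportion(prevalence, n)
  assign <- integer(n)        # 0 = free; else class index 1..8
  visit <- sample.int(n)      # jump targets, consumed left to right
  vptr <- 1L
  p_jump <- exp(-contiguity)
  frontier <- vector("list", 8L)
  ftop <- integer(8L)
  for (k in 1:8) frontier[[k]] <- integer(64L)
  push <- function(k, cells) {
    need <- ftop[k] + length(cells)
    if (need > length(frontier[[k]]))
      frontier[[k]] <<- c(frontier[[k]],
                          integer(max(length(frontier[[k]]), need)))
    frontier[[k]][(ftop[k] + 1L):need] <<- cells
    ftop[k] <<- need
  }
  remaining <- quota
  active <- which(remaining > 0L)
  while (length(active) > 0L) {
    k <- if (length(active) == 1L) active else
      active[sample.int(length(active), 1L, prob = remaining[active])]
    cell <- 0L
    if (ftop[k] > 0L && stats::runif(1) >= p_jump) {
      while (ftop[k] > 0L) {
        cand <- frontier[[k]][ftop[k]]
        ftop[k] <- ftop[k] - 1L
        if (assign[cand] == 0L) { cell <- cand; break }
      }
    }
    if (cell == 0L) {
      while (assign[visit[vptr]] != 0L) vptr <- vptr + 1L
      cell <- visit[vptr]
    }
    assign[cell] <- k
    remaining[k] <- remaining[k] - 1L
    if (remaining[k] == 0L) active <- active[active != k]
    r <- ((cell - 1L) %% n_r) + 1L
    cc <- ((cell - 1L) %/% n_r) + 1L
    nb <- integer(0)
    if (r > 1L) nb <- c(nb, cell - 1L)
    if (r < n_r) nb <- c(nb, cell + 1L)
    if (cc > 1L) nb <- c(nb, cell - n_r)
    if (cc < n_c) nb <- c(nb, cell + n_r)
    nb <- nb[assign[nb] == 0L]
    if (length(nb)) push(k, nb)
  }
  matrix(assign - 1L, n_r, n_c)  # back to class codes 0..7
}

#' Generate a synthetic tissue label grid
#'
#' Produces a slide-shaped label grid whose outer `background_border` ring
#' is BACKGROUND and whose interior is filled by seeded multi-source region
#' growing: each tissue class forms contiguous blobs whose realized
#' fraction matches `target_prevalence` up to integer rounding (well within
#' +/- 0.05).
#'
#' @param cfg A [sim_config()].
#' @return Integer label grid matrix (codes 0-8) with attribute `slide_id`.
#' @export
gen_label_grid <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    b <- cfg$background_border
    interior <- grow_interior(cfg$grid_rows - 2L * b, cfg$grid_cols - 2L * b,
                              cfg$target_prevalence, cfg$contiguity)
    grid <- matrix(background_code(), cfg$grid_rows, cfg$grid_cols)
    if (b > 0) {
      grid[(b + 1L):(cfg$grid_rows - b), (b + 1L):(cfg$grid_cols - b)] <-
        interior
    } else grid[, ] <- interior
    grid
  })
}

#' Generate a per-patch class-probability table from a label grid
#'
#' Each patch's true class receives probability `confidence`; the remainder
#' is spread over the other eight classes with Dirichlet jitter. Rows sum
#' to 1 exactly (up to floating-point error).
#'
#' @param grid Label grid matrix.
#' @param confidence Probability on the true class, in `(1/9, 1]`. Near the
#'   lower bound the rows approach the uniform distribution.
#' @param seed Integer seed.
#' @param concentration Per-component Dirichlet concentration of the jitter
#'   (default 10: mild, near-even spread).
#' @param slide_id Slide identifier written to the table.
#' @return Data frame with `slide_id`, 0-based `row`, `col`, the true
#'   `label`, and the 9 [probability_columns()].
#' @export
gen_probability_table <- function(grid, confidence, seed,
                                  concentration = 10, slide_id = "slide_1") {
  validate_grid(grid)
  if (confidence <= 1 / 9 || confidence > 1)
    stop("confidence must lie in (1/9, 1]")
  with_seed(seed, {
    nr <- nrow(grid); nc <- ncol(grid)
    labels <- as.integer(t(grid))  # row-major patch order
    n <- length(labels)
    p <- matrix(0, n, 9L)
    if (confidence < 1) {
      g <- matrix(stats::rgamma(n * 8L, shape = concentration), n, 8L)
      g <- g / rowSums(g) * (1 - confidence)
      for (i in seq_len(n)) {
        others <- setdiff(0:8, labels[i])
        p[i, others + 1L] <- g[i, ]
      }
    }
    p[cbind(seq_len(n), labels + 1L)] <- confidence
    out <- data.frame(slide_id = slide_id,
                      row = rep(0:(nr - 1L), each = nc),
                      col = rep(0:(nc - 1L), times = nr),
                      label = labels)
    out[probability_columns()] <- p
    out
  })
}

#' Generate a synthetic H&E-like RGB patch
#'
#' Fixture generator for the tissue-relevance filter: pixels are either
#' "dark" (hematoxylin-like purple, luma far below 200) or "light"
#' (near-white glass, luma far above 200). `blank` patches are all light,
#' `tissue` patches carry 30% dark pixels, and `mixed` patches carry an
#' exact `round(dark_frac * n)` dark pixels so the black/white pixel ratio
#' is controlled to a single pixel.
#'
#' @param kind One of `"tissue"`, `"blank"`, `"mixed"`.
#' @param side_px Patch side in pixels (>= 8).
#' @param seed Integer seed.
#' @param dark_frac Dark-pixel fraction for `kind = "mixed"`.
#' @return RGB array `side_px x side_px x 3` in `[0, 255]`.
#' @export
gen_patch_image <- function(kind = c("tissue", "blank", "mixed"),
                            side_px = 172L, seed = 1L, dark_frac = 0.5) {
  kind <- match.arg(kind)
  if (side_px < 8) stop("side_px must be >= 8")
  if (dark_frac < 0 || dark_frac > 1) stop("dark_frac must be in [0, 1]")
  with_seed(seed, {
    n <- side_px * side_px
    k <- switch(kind, blank = 0L, tissue = as.integer(round(0.3 * n)),
                mixed = as.integer(round(dark_frac * n)))
    dark <- rep(FALSE, n)
    if (k > 0) dark[sample.int(n, k)] <- TRUE
    img <- array(0, c(side_px, side_px, 3L))
    jitter <- function(center, spread)
      pmin(pmax(center + stats::runif(n, -spread, spread), 0), 255)
    light <- cbind(jitter(240, 12), jitter(238, 12), jitter(242, 12))
    darkc <- cbind(jitter(120, 25), jitter(60, 25), jitter(140, 25))
    for (ch in 1:3)
      img[, , ch] <- matrix(ifelse(dark, darkc[, ch], light[, ch]),
                            side_px, side_px)
    img
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Solve the uniform-censoring upper bound c so that the expected censored
# fraction over the cohort's exponential rates hits the target.
solve_censor_bound <- function(rates, target) {
  cens_frac <- function(cc) mean((1 - exp(-rates * cc)) / (rates * cc))
  upper <- 1 / min(rates)
  while (cens_frac(upper) > target && upper < 1e12) upper <- upper * 10
  stats::uniroot(function(cc) cens_frac(cc) - target,
                 lower = 1e-9, upper = upper, tol = 1e-10)$root
}

# Numeric design columns a ground-truth beta map may reference.
cohort_design_columns <- function(dataset) {
  cbind(as.matrix(dataset[intersect(spatial_feature_names(),
                                    names(dataset))]),
        age_group = dataset$age_group, sex = dataset$sex,
        smoking_light = as.numeric(dataset$smoking == "light"),
        smoking_heavy = as.numeric(dataset$smoking == "heavy"),
        stage_locally_advanced =
          as.numeric(dataset$stage == "locally_advanced"),
        stage_advanced = as.numeric(dataset$stage == "advanced"))
}

linear_predictor <- function(design, betas) {
  if (is.null(betas) || length(betas) == 0L) return(rep(0, nrow(design)))
  betas <- unlist(betas)
  missing <- setdiff(names(betas), colnames(design))
  if (length(missing)) stop("unknown beta columns: ",
                            paste(missing, collapse = ", "))
  x <- design[, names(betas), drop = FALSE]
  if (anyNA(x)) stop("beta references a feature undefined on some patients")
  drop(x %*% betas)
}

#' Generate a full synthetic patient cohort with known ground truth
#'
#' For each patient the class mixture is drawn from a Dirichlet around the
#' config's target prevalence, `slides_per_patient` label grids are grown,
#' and the package's own spatial features are computed and averaged per
#' patient. Clinical covariates are sampled from the configured categorical
#' distributions. Survival times come from an exponential baseline scaled
#' by `exp(sum(cox_betas * x))` using the realized features, with
#' independent uniform censoring calibrated numerically to `censor_frac`.
#' The first configured gene's mutation status is Bernoulli with logit
#' `logit_intercept + sum(logit_betas * x)`; further genes are
#' intercept-only.
#'
#' @param cfg A [sim_config()].
#' @return Data frame (one row per patient): `patient_id`, the 18
#'   [spatial_feature_names()] columns, `age_group`, `sex`, `smoking`,
#'   `stage`, `time` (days), `event` (1 = death observed), and one binary
#'   column per configured gene.
#' @export
gen_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_patients
    classes <- tolower(tissue_class_names())
    alpha <- cfg$prevalence_dispersion * cfg$target_prevalence
    prev <- matrix(0, n, 8L, dimnames = list(NULL, classes))
    pos <- alpha > 0
    for (i in seq_len(n)) {
      g <- stats::rgamma(sum(pos), shape = alpha[pos])
      if (all(g == 0)) g[sample.int(length(g), 1L)] <- 1
      prev[i, pos] <- g / sum(g)
      # every slide carries some tumor but is never tumor-only
      pt <- min(max(prev[i, "tumor"], cfg$min_tumor_frac),
                cfg$max_tumor_frac)
      rest <- prev[i, colnames(prev) != "tumor"]
      prev[i, colnames(prev) != "tumor"] <-
        if (sum(rest) > 0) rest / sum(rest) * (1 - pt)
        else rep((1 - pt) / 7, 7)
      prev[i, "tumor"] <- pt
    }
    grid_seeds <- matrix(
      sub_seed(cfg$seed, seq_len(n * cfg$slides_per_patient)),
      n, cfg$slides_per_patient)
    grids <- list(); pids <- character(0)
    for (i in seq_len(n)) {
      for (s in seq_len(cfg$slides_per_patient)) {
        cfg_i <- cfg
        cfg_i$target_prevalence <- prev[i, ]
        cfg_i$seed <- grid_seeds[i, s]
        grids[[length(grids) + 1L]] <- gen_label_grid(cfg_i)
        pids <- c(pids, sprintf("P%04d", i))
      }
    }
    feats <- feature_table(grids, pids)

    cp <- cfg$clinical_probs
    clinical <- data.frame(
      patient_id = feats$patient_id,
      age_group = stats::rbinom(n, 1L, cp$age),
      sex = stats::rbinom(n, 1L, cp$sex),
      smoking = factor(sample(c("non_smoker", "light", "heavy"), n,
                              replace = TRUE, prob = cp$smoking),
                       levels = c("non_smoker", "light", "heavy")),
      stage = factor(sample(c("early", "locally_advanced", "advanced"), n,
                            replace = TRUE, prob = cp$stage),
                     levels = c("early", "locally_advanced", "advanced")))
    dataset <- merge(feats, clinical, by = "patient_id", sort = TRUE)

    design <- cohort_design_columns(dataset)
    lp <- linear_predictor(design, cfg$cox_betas)
    rates <- cfg$baseline_rate * exp(lp)
    t_event <- stats::rexp(n, rate = rates)
    if (cfg$censor_frac <= 0) {
      time <- t_event; event <- rep(1L, n)
    } else if (cfg$censor_frac >= 1) {
      time <- stats::runif(n, 0, 1 / cfg$baseline_rate)
      event <- rep(0L, n)
    } else {
      cmax <- solve_censor_bound(rates, cfg$censor_frac)
      cens <- stats::runif(n, 0, cmax)
      event <- as.integer(t_event <= cens)
      time <- pmin(t_event, cens)
    }
    dataset$time <- time
    dataset$event <- event

    lp_mut <- cfg$logit_intercept + linear_predictor(design, cfg$logit_betas)
    for (g in seq_along(cfg$mutation_genes)) {
      p <- if (g == 1L) sigmoid(lp_mut)
           else rep(sigmoid(cfg$logit_intercept), n)
      dataset[[cfg$mutation_genes[g]]] <- stats::rbinom(n, 1L, p)
    }
    attr(dataset, "config") <- cfg
    dataset
  })
}

#' Write / read a synthetic cohort as CSV tables plus a YAML config
#'
#' `write_cohort` splits an [gen_cohort()] result into `features.csv`,
#' `clinical.csv`, `survival.csv` and `mutations.csv` under `dir` (the
#' four-table layout consumed by [merge_cohort()]), and records the
#' generating configuration as `config.yaml` when available.
#'
#' @param dataset Cohort data frame from [gen_cohort()].
#' @param dir Output directory (created if needed).
#' @return `write_cohort` invisibly returns `dir`; `read_cohort` returns a
#'   named list of the four tables.
#' @export
write_cohort <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  feat_cols <- intersect(spatial_feature_names(), names(dataset))
  clin_cols <- c("age_group", "sex", "smoking", "stage")
  gene_cols <- setdiff(names(dataset),
                       c("patient_id", feat_cols, clin_cols, "time", "event"))
  utils::write.csv(dataset[c("patient_id", feat_cols)],
                   file.path(dir, "features.csv"), row.names = FALSE)
  utils::write.csv(dataset[c("patient_id", clin_cols)],
                   file.path(dir, "clinical.csv"), row.names = FALSE)
  utils::write.csv(dataset[c("patient_id", "time", "event")],
                   file.path(dir, "survival.csv"), row.names = FALSE)
  utils::write.csv(dataset[c("patient_id", gene_cols)],
                   file.path(dir, "mutations.csv"), row.names = FALSE)
  cfg <- attr(dataset, "config")
  if (!is.null(cfg)) write_sim_config(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  list(features = utils::read.csv(file.path(dir, "features.csv")),
       clinical = utils::read.csv(file.path(dir, "clinical.csv")),
       survival = utils::read.csv(file.path(dir, "survival.csv")),
       mutations = utils::read.csv(file.path(dir, "mutations.csv")))
}

#' @rdname write_cohort
#' @param cfg A [sim_config()].
#' @param path YAML file path.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- unclass(cfg)
  out$target_prevalence <- as.list(out$target_prevalence)
  if (!is.null(out$cox_betas)) out$cox_betas <- as.list(out$cox_betas)
  if (!is.null(out$logit_betas)) out$logit_betas <- as.list(out$logit_betas)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(sim_config, raw[intersect(names(raw), names(formals(sim_config)))])
}
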