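#' Specification for a synthetic patient cohort
#'
#' Describes the six (risk level x sex) cells a generated cohort should
#' reproduce: cell sizes, mean risk-factor profiles at start, mean 12-month
#' changes and mean ages, together with the dispersion (coefficient of
#' variation per field), a copula correlation among the obesity/glycemia
#' fields, and sex-level rates for smoking and previous myocardial
#' infarction. The default spec is built from the reference tables shipped
#' with the package, so `generate_cohort(cohort_spec())` emulates the study
#' cohort: 142 included patients in cells of 4/19/39 (men) and 37/28/15
#' (women), plus 37 additional participants who fail an inclusion criterion
#' (179 in total).
#'
#' @param fixtures output of [load_fixture_tables()]; loaded on demand
#' @param dispersion named vector of per-field coefficients of variation;
#'   defaults are derived from the cohort-wide SD/mean ratios of the
#'   characteristics table (averaged over sexes; total cholesterol, which has
#'   no published SD, gets a typical lipid CV)
#' @param rho correlation among waist/BMI/fasting-glucose/triglyceride fields
#'   in the Gaussian copula (metabolic factors co-occur; the exact covariance
#'   is an assumption, not an estimate)
#' @param age_sd within-cell age standard deviation, years
#' @param smoking_rate,mi_rate named rates by sex (`M`, `F`)
#' @param n_excluded_m,n_excluded_f extra participants per sex failing one
#'   inclusion criterion each
#' @param seed default master seed carried by the spec
#' @return list with class `"cohort_spec"`
#' @export
cohort_spec <- function(fixtures = load_fixture_tables(),
                        dispersion = c(waist = 0.10, bmi = 0.14, fg = 0.28,
                                       tg = 0.60, hdl = 0.28, chol = 0.12,
                                       sbp = 0.125, dbp = 0.12),
                        rho = 0.3,
                        age_sd = 8,
                        smoking_rate = c(M = 0.14, F = 0.32),
                        mi_rate = c(M = 0.13, F = 0.02),
                        n_excluded_m = 18, n_excluded_f = 19,
                        seed = 20131L) {
  stopifnot(all(dispersion > 0), rho > -1, rho < 1)
  cells <- table2_cells(fixtures$table2)
  if (any(vapply(cells, function(cl) cl$n < 1, logical(1)))) {
    stop("cohort_spec: every cell needs n >= 1", call. = FALSE)
  }
  corr <- diag(length(RF_FIELDS))
  dimnames(corr) <- list(RF_FIELDS, RF_FIELDS)
  met <- c("waist", "bmi", "fg", "tg")
  corr[met, met] <- rho
  diag(corr) <- 1
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) stop("cohort_spec: correlation not positive semi-definite",
                            call. = FALSE)
  structure(list(cells = cells, dispersion = dispersion[RF_FIELDS],
                 corr = corr, age_sd = age_sd,
                 smoking_rate = smoking_rate, mi_rate = mi_rate,
                 n_excluded_m = n_excluded_m, n_excluded_f = n_excluded_f,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# deterministic child seed derivation, kept below 2^31
child_seed <- function(master, k) {
  as.integer((as.double(master) * 7919 + 104729 * k) %% 2147483647)
}

# admissible criteria counts per risk level
level_counts <- function(level) {
  switch(level, low = 0:1, medium = 2L, high = 3:5)
}

# draw `m` joint profiles around `mu` (Gaussian copula on normal marginals)
draw_profiles <- function(m, mu, sd, chol_corr) {
  z <- matrix(stats::rnorm(m * length(mu)), nrow = m) %*% chol_corr
  x <- sweep(sweep(z, 2, sd, "*"), 2, mu, "+")
  colnames(x) <- names(mu)
  x
}

# validity: positive fields, sbp > dbp, criteria count admissible for level
valid_rows <- function(x, sex, level, thresholds) {
  df <- as.data.frame(x)
  df$diabetes <- df$fg >= 7.0
  k <- rowSums(criteria_matrix(df, sex, thresholds))
  ok <- rowSums(x <= 0) == 0 & x[, "sbp"] > x[, "dbp"] & k %in% level_counts(level)
  list(ok = ok, k = k)
}

# Sample n classification-consistent profiles for one cell. Rejection against
# the admissible criteria-count range biases the accepted mean away from the
# target, so the proposal mean is recentred iteratively using a large accepted
# pool (low-noise bias estimate), and the reported n profiles are then chosen
# as the best-matching of many random subsets of the final pool. For cells
# whose printed target mean itself crosses a criteria threshold the
# conditional mean is structurally bounded; recentring brings the residual
# bias down to the order of the cell mean's standard error.
sample_cell <- function(cell, n, dispersion, corr, thresholds,
                        n_iter = 12, max_tries = 120, n_subsets = 400) {
  mu_target <- cell$mean_start
  sdv <- pmax(dispersion * mu_target, 1e-9)
  ch <- chol(corr)
  mu_prop <- mu_target
  pool_target <- max(40 * n, 400)
  shift_cap <- 3 * sdv
  pool <- NULL; kpool <- NULL
  for (iter in seq_len(n_iter)) {
    acc <- matrix(numeric(0), ncol = length(mu_target),
                  dimnames = list(NULL, names(mu_target)))
    kacc <- integer(0)
    tries <- 0
    while (nrow(acc) < pool_target && tries < max_tries) {
      x <- draw_profiles(2048, mu_prop, sdv, ch)
      v <- valid_rows(x, cell$sex, cell$level, thresholds)
      acc <- rbind(acc, x[v$ok, , drop = FALSE])
      kacc <- c(kacc, v$k[v$ok])
      tries <- tries + 1
    }
    if (nrow(acc) < n) {
      if (iter > 1) { # proposal wandered into a low-acceptance region: back off
        mu_prop <- (mu_prop + mu_target) / 2
        next
      }
      stop("generate_cohort: cell ", cell$sex, "/", cell$level,
           " infeasible: cannot draw ", n,
           " classification-consistent profiles around its target mean",
           call. = FALSE)
    }
    pool <- acc; kpool <- as.integer(kacc)
    dev <- (colMeans(acc) - mu_target) / sdv
    if (max(abs(dev)) < 0.03) break
    shift <- pmin(pmax(-0.6 * dev * sdv, -shift_cap), shift_cap)
    mu_prop <- pmax(mu_prop + shift, 0.1 * mu_target)
    # keep the proposal mean within a sane band around the target
    mu_prop <- pmin(pmax(mu_prop, mu_target - 4 * sdv), mu_target + 4 * sdv)
  }
  # pick the n-subset of the pool whose mean best matches the target
  best <- NULL; best_score <- Inf
  for (s in seq_len(n_subsets)) {
    idx <- if (nrow(pool) == n) seq_len(n) else sample.int(nrow(pool), n)
    score <- max(abs(colMeans(pool[idx, , drop = FALSE]) - mu_target) /
                   (sdv / sqrt(n)))
    if (score < best_score) {
      best <- idx; best_score <- score
    }
    if (nrow(pool) == n) break
  }
  list(x = pool[best, , drop = FALSE], k = kpool[best])
}

#' Generate a synthetic patient cohort
#'
#' Draws patient-level records whose per-cell means and 12-month changes
#' emulate the targets in the spec, with every generated patient's criteria
#' count consistent with its intended risk cell (resampling with iterative
#' recentring of the proposal distribution; infeasible targets raise an error
#' naming the cell). Diagnosed type 2 diabetes is set deterministically at
#' fasting glucose >= 7.0 mmol/L so the flag never alters a patient's
#' criteria count. Excluded participants (those failing one of the four
#' inclusion criteria) are appended with flags distributed round-robin over
#' the criteria; patients failing the data-completeness criterion have no
#' 12-month profile.
#'
#' @param spec a [cohort_spec()]
#' @param seed master seed; defaults to the spec's own
#' @param noise_frac SD of individual 12-month changes, as a fraction of the
#'   field's cross-sectional SD (noise is recentred to zero mean per cell)
#' @param thresholds see [mets_thresholds()]
#' @return a cohort tibble in the canonical patient format (see
#'   [read_cohort()])
#' @export
#' @examples
#' spec <- cohort_spec()
#' cohort <- generate_cohort(spec, seed = 1)
#' nrow(cohort)                         # 179 participants
#' sum(apply_inclusion_filter(cohort)$included$flag_complete)  # 142 included
generate_cohort <- function(spec, seed = spec$seed, noise_frac = 0.25,
                            thresholds = mets_thresholds()) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- list()
  for (i in seq_along(spec$cells)) {
    cell <- spec$cells[[i]]
    set.seed(child_seed(seed, i))
    smp <- sample_cell(cell, cell$n, spec$dispersion, spec$corr, thresholds)
    zage <- stats::rnorm(cell$n)
    age <- round(cell$age + spec$age_sd * (zage - mean(zage)))
    age <- pmin(84, pmax(18, age))
    x <- smp$x
    df <- tibble::tibble(
      sex = cell$sex, level_intended = cell$level, age = as.numeric(age),
      smoker = as.numeric(stats::runif(cell$n) < spec$smoking_rate[[cell$sex]]),
      previous_mi = as.numeric(stats::runif(cell$n) < spec$mi_rate[[cell$sex]]),
      diabetes = as.numeric(x[, "fg"] >= 7.0)
    )
    for (f in RF_FIELDS) df[[paste0(f, "_start")]] <- as.numeric(x[, f])
    df$flag_mets <- 1; df$flag_registered <- 1
    df$flag_no_drug_increase <- 1; df$flag_complete <- 1
    out[[i]] <- df
  }
  cohort <- dplyr::bind_rows(out)
  cohort <- apply_intervention_effects(cohort, spec, noise_frac = noise_frac,
                                       seed = child_seed(seed, 300))

  # appended participants failing one inclusion criterion each
  n_exc <- c(M = spec$n_excluded_m, F = spec$n_excluded_f)
  exc <- list()
  flags <- c("flag_mets", "flag_registered", "flag_no_drug_increase",
             "flag_complete")
  for (sx in c("M", "F")) {
    if (n_exc[[sx]] == 0) next
    set.seed(child_seed(seed, if (sx == "M") 201 else 202))
    # profiles drawn around the sex-level averages, unconstrained
    cellpool <- Filter(function(cl) cl$sex == sx, spec$cells)
    pick <- sample(length(cellpool), n_exc[[sx]], replace = TRUE)
    rows <- lapply(seq_len(n_exc[[sx]]), function(j) {
      cl <- cellpool[[pick[j]]]
      x <- draw_profiles(1, cl$mean_start, spec$dispersion * cl$mean_start,
                         chol(spec$corr))
      x <- pmax(x, 0.05 * cl$mean_start)
      if (x[, "dbp"] >= x[, "sbp"]) x[, "dbp"] <- x[, "sbp"] - 1
      d <- tibble::tibble(sex = sx, level_intended = NA_character_,
                          age = round(cl$age), smoker = 0, previous_mi = 0,
                          diabetes = as.numeric(x[, "fg"] >= 7.0))
      for (f in RF_FIELDS) d[[paste0(f, "_start")]] <- as.numeric(x[, f])
      for (f in RF_FIELDS) d[[paste0(f, "_12m")]] <- as.numeric(x[, f])
      d$flag_mets <- 1; d$flag_registered <- 1
      d$flag_no_drug_increase <- 1; d$flag_complete <- 1
      fail <- flags[(j - 1) %% 4 + 1]
      d[[fail]] <- 0
      if (fail == "flag_complete") {
        for (f in RF_FIELDS) d[[paste0(f, "_12m")]] <- NA_real_
      }
      d
    })
    exc[[sx]] <- dplyr::bind_rows(rows)
  }
  cohort <- dplyr::bind_rows(cohort, dplyr::bind_rows(exc))
  cohort$id <- sprintf("P%03d", seq_len(nrow(cohort)))
  dplyr::relocate(cohort, "id")
}

#' Fill 12-month profiles from per-cell target changes
#'
#' Sets each patient's 12-month profile to start + (cell mean change + noise),
#' where the noise is zero-mean within the cell (recentred), so the per-cell
#' mean change equals its target before any truncation. Changes that would
#' push a field at or below zero are clipped at 5% of the start value with a
#' message; diastolic pressure is kept below systolic.
#'
#' @param cohort a cohort tibble with `_start` columns; cells are identified
#'   by `level_intended` when present, otherwise by stratifying on the start
#'   profiles
#' @param spec the [cohort_spec()] carrying per-cell target changes
#' @param noise_frac SD of individual changes as a fraction of the field's
#'   cross-sectional SD; 0 makes every change equal the cell target
#' @param seed RNG seed for the change noise
#' @return the cohort with `_12m` columns filled
#' @export
apply_intervention_effects <- function(cohort, spec, noise_frac = 0.25,
                                       seed = spec$seed) {
  key <- if ("level_intended" %in% names(cohort)) {
    cohort$level_intended
  } else {
    as.character(stratify_cohort(cohort)$risk_group)
  }
  for (f in RF_FIELDS) cohort[[paste0(f, "_12m")]] <- NA_real_
  ci <- 0
  for (cell in spec$cells) {
    ci <- ci + 1
    idx <- which(cohort$sex == cell$sex & key == cell$level)
    if (length(idx) == 0) next
    set.seed(child_seed(seed, 100 + ci))
    target_diff <- cell$mean_12m - cell$mean_start
    for (f in RF_FIELDS) {
      start <- cohort[[paste0(f, "_start")]][idx]
      eps <- stats::rnorm(length(idx), 0,
                          noise_frac * spec$dispersion[[f]] * cell$mean_start[[f]])
      if (length(idx) > 1) eps <- eps - mean(eps)
      x12 <- start + target_diff[[f]] + eps
      clip <- x12 <= 0.05 * start
      if (any(clip)) {
        message("apply_intervention_effects: clipped ", sum(clip), " ", f,
                " change(s) in cell ", cell$sex, "/", cell$level,
                " to keep the profile positive")
        x12[clip] <- 0.05 * start[clip]
      }
      cohort[[paste0(f, "_12m")]][idx] <- as.numeric(x12)
    }
    swap <- which(cohort$dbp_12m[idx] >= cohort$sbp_12m[idx])
    cohort$dbp_12m[idx][swap] <- cohort$sbp_12m[idx][swap] - 1
  }
  cohort
}

#' Compare generated per-cell means with their targets
#'
#' For every cell and continuous field, reports the z-score of the generated
#' start mean against the target, using the spec's target dispersion:
#' z = (generated - target) / (sd_target / sqrt(n)). Twelve-month mean changes
#' are scored the same way against the target change, with the change-noise
#' SD. Cells absent from the cohort are reported as such, not failed.
#'
#' @param cohort a generated (or real) cohort, restricted to included patients
#' @param spec the [cohort_spec()] holding the targets
#' @param noise_frac the change-noise fraction used at generation
#' @return list with `report` (tibble of z-scores) and `pass` (all |z| < 3
#'   over non-absent cells)
#' @export
validate_against_moments <- function(cohort, spec, noise_frac = 0.25) {
  if (!"risk_group" %in% names(cohort)) cohort <- stratify_cohort(cohort)
  rep <- list()
  for (cell in spec$cells) {
    sub <- cohort[cohort$sex == cell$sex & cohort$risk_group == cell$level, ]
    if (nrow(sub) == 0) {
      rep[[length(rep) + 1]] <- tibble::tibble(
        sex = cell$sex, level = cell$level, variable = NA_character_,
        measure = NA_character_, z = NA_real_, absent = TRUE)
      next
    }
    n <- nrow(sub)
    for (f in RF_FIELDS) {
      sd_t <- spec$dispersion[[f]] * cell$mean_start[[f]]
      z_start <- (mean(sub[[paste0(f, "_start")]]) - cell$mean_start[[f]]) /
        (sd_t / sqrt(n))
      rows <- tibble::tibble(sex = cell$sex, level = cell$level, variable = f,
                             measure = "start", z = z_start, absent = FALSE)
      if (all(!is.na(sub[[paste0(f, "_12m")]]))) {
        d <- sub[[paste0(f, "_12m")]] - sub[[paste0(f, "_start")]]
        target_d <- cell$mean_12m[[f]] - cell$mean_start[[f]]
        sd_d <- max(noise_frac * sd_t, 1e-9)
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          sex = cell$sex, level = cell$level, variable = f,
          measure = "diff", z = (mean(d) - target_d) / (sd_d / sqrt(n)),
          absent = FALSE))
      }
      rep[[length(rep) + 1]] <- rows
    }
  }
  report <- dplyr::bind_rows(rep)
  list(report = report,
       pass = all(abs(report$z[!report$absent]) < 3, na.rm = TRUE))
}
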