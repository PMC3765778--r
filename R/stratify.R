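#' Consensus metabolic-syndrome criteria thresholds
#'
#' Cut-offs for the five countable criteria: central obesity (waist
#' circumference), raised triglycerides, reduced HDL cholesterol, raised blood
#' pressure and raised fasting glucose (or previously diagnosed type 2
#' diabetes). Values follow the harmonised consensus definition; they live in
#' configuration, not code, so alternative definitions can be swapped in.
#'
#' @param waist_male,waist_female waist circumference cut-offs, cm
#' @param tg triglyceride cut-off, mmol/L (criterion met at or above)
#' @param hdl_male,hdl_female HDL cut-offs, mmol/L (criterion met below)
#' @param sbp,dbp blood-pressure cut-offs, mmHg (met at or above either)
#' @param fg fasting-glucose cut-off, mmol/L (met at or above, or diagnosed
#'   type 2 diabetes)
#' @return a named list of thresholds
#' @export
#' @examples
#' mets_thresholds()$fg
mets_thresholds <- function(waist_male = 94, waist_female = 80,
                            tg = 1.7,
                            hdl_male = 1.03, hdl_female = 1.29,
                            sbp = 130, dbp = 85,
                            fg = 5.6) {
  thr <- list(
    waist_male = waist_male, waist_female = waist_female,
    tg = tg, hdl_male = hdl_male, hdl_female = hdl_female,
    sbp = sbp, dbp = dbp, fg = fg
  )
  stopifnot(all(vapply(thr, function(x) is.numeric(x) && x > 0, logical(1))))
  thr
}

#' Construct and validate a risk-factor profile
#'
#' A profile is one person's metabolic risk-factor vector at a single time
#' point. All continuous fields must be positive and systolic pressure must
#' exceed diastolic.
#'
#' @param waist waist circumference, cm
#' @param bmi body mass index, kg/m^2
#' @param fg fasting glucose, mmol/L
#' @param tg triglycerides, mmol/L
#' @param hdl HDL cholesterol, mmol/L
#' @param chol total cholesterol, mmol/L
#' @param sbp,dbp systolic / diastolic blood pressure, mmHg
#' @param smoker smoking indicator (0/1) or, for a group-average profile, the
#'   smoking rate in `[0, 1]`
#' @param diabetes previously diagnosed type 2 diabetes (logical, or a rate)
#' @param previous_mi previous myocardial infarction (logical, or a rate)
#' @return a named list with class `"rf_profile"`
#' @export
#' @examples
#' risk_profile(waist = 111.5, bmi = 32.5, fg = 6.4, tg = 2.4, hdl = 1.1,
#'              chol = 4.4, sbp = 149, dbp = 87)
risk_profile <- function(waist, bmi, fg, tg, hdl, chol, sbp, dbp,
                         smoker = 0, diabetes = FALSE, previous_mi = FALSE) {
  cont <- c(waist = waist, bmi = bmi, fg = fg, tg = tg, hdl = hdl,
            chol = chol, sbp = sbp, dbp = dbp)
  bad <- names(cont)[!is.finite(cont) | cont <= 0]
  if (length(bad) > 0) {
    stop("risk_profile: non-positive or missing field(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (sbp <= dbp) {
    stop("risk_profile: sbp must exceed dbp (got ", sbp, "/", dbp, ")",
         call. = FALSE)
  }
  structure(
    c(as.list(cont),
      list(smoker = as.numeric(smoker),
           diabetes = as.numeric(diabetes),
           previous_mi = as.numeric(previous_mi))),
    class = "rf_profile"
  )
}

# which of the five criteria a set of patients meets; returns a logical matrix
# with one column per criterion. `df` needs waist/tg/hdl/sbp/dbp/fg columns
# (any suffix already stripped) plus diabetes; `sex` is "M"/"F".
criteria_matrix <- function(df, sex, thresholds = mets_thresholds()) {
  need <- c("waist", "tg", "hdl", "sbp", "dbp", "fg", "diabetes")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("criteria_matrix: missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  male <- sex == "M"
  cbind(
    waist = df$waist >= ifelse(male, thresholds$waist_male, thresholds$waist_female),
    tg    = df$tg >= thresholds$tg,
    hdl   = df$hdl < ifelse(male, thresholds$hdl_male, thresholds$hdl_female),
    bp    = df$sbp >= thresholds$sbp | df$dbp >= thresholds$dbp,
    fg    = df$fg >= thresholds$fg | as.logical(df$diabetes)
  )
}

#' Count metabolic-syndrome criteria met by a profile
#'
#' The five countable criteria are central obesity, raised triglycerides,
#' reduced HDL, raised blood pressure, and raised fasting glucose or
#' previously diagnosed type 2 diabetes (the diagnosis alone satisfies the
#' glucose criterion). All five are counted additively; central obesity is one
#' criterion among five, not a prerequisite.
#'
#' @param profile an [risk_profile()] (or a named list with the same fields)
#' @param sex `"M"` or `"F"` (sex-specific waist and HDL cut-offs)
#' @param thresholds see [mets_thresholds()]
#' @return integer in 0..5
#' @export
#' @examples
#' p <- risk_profile(waist = 111.5, bmi = 32.5, fg = 6.4, tg = 2.4,
#'                   hdl = 1.1, chol = 4.4, sbp = 149, dbp = 87)
#' count_mets_criteria(p, "M")  # 4: waist, TG, BP, FG (HDL 1.1 >= 1.03)
count_mets_criteria <- function(profile, sex, thresholds = mets_thresholds()) {
  stopifnot(sex %in% c("M", "F"))
  need <- c("waist", "tg", "hdl", "sbp", "dbp", "fg")
  miss <- need[!need %in% names(profile)]
  if (length(miss) > 0) {
    stop("count_mets_criteria: profile is missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(profile[c(need)], optional = TRUE)
  df$diabetes <- if ("diabetes" %in% names(profile)) profile$diabetes else 0
  as.integer(rowSums(criteria_matrix(df, sex, thresholds)))
}

#' Assign a risk group from a criteria count
#'
#' Fewer than two criteria is low risk, exactly two is medium, three or more
#' is high.
#'
#' @param criteria_count integer vector with values in 0..5
#' @return factor with levels `low < medium < high`
#' @export
#' @examples
#' assign_risk_group(c(0, 2, 4))
assign_risk_group <- function(criteria_count) {
  k <- criteria_count
  if (any(is.na(k)) || any(k != floor(k)) || any(k < 0 | k > 5)) {
    stop("assign_risk_group: criteria count must be an integer in [0, 5]",
         call. = FALSE)
  }
  factor(ifelse(k < 2, "low", ifelse(k == 2, "medium", "high")),
         levels = c("low", "medium", "high"), ordered = TRUE)
}

#' Read / write a patient cohort table
#'
#' The canonical patient format is a delimited table with one row per patient:
#' `id`, `sex` ("M"/"F"), `age`, the four inclusion flags (`flag_mets`,
#' `flag_registered`, `flag_no_drug_increase`, `flag_complete`), the binary
#' fields `smoker`, `diabetes`, `previous_mi`, and the continuous risk factors
#' `waist, bmi, fg, tg, hdl, chol, sbp, dbp` with suffixes `_start` and
#' `_12m`.
#'
#' @param path file path
#' @return a tibble (for `read_cohort`)
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sex", "age", paste0(RF_FIELDS, "_start"))
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("read_cohort: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$sex %in% c("M", "F"))) {
    stop("read_cohort: sex must be coded \"M\"/\"F\"", call. = FALSE)
  }
  if ("smoker" %in% names(df) && anyNA(df$smoker)) {
    warning("read_cohort: missing smoking status set to non-smoker for ",
            sum(is.na(df$smoker)), " patient(s)")
    df$smoker[is.na(df$smoker)] <- 0
  }
  tibble::as_tibble(df)
}

#' @rdname read_cohort
#' @param cohort a cohort tibble
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Apply the four inclusion criteria
#'
#' Patients enter the analysis only if all four flags hold: diagnosed with the
#' metabolic syndrome, registered at a primary-care centre at program start,
#' no increased drug treatment during the study period, and complete
#' risk-factor data at start and follow-up.
#'
#' @param cohort a cohort tibble carrying the four `flag_*` columns
#' @return list with `included` (the retained subset) and `report`, a tibble
#'   of per-criterion failure counts plus totals
#' @export
apply_inclusion_filter <- function(cohort) {
  flags <- c("flag_mets", "flag_registered", "flag_no_drug_increase",
             "flag_complete")
  miss <- setdiff(flags, names(cohort))
  if (length(miss) > 0) {
    stop("apply_inclusion_filter: missing flag column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  fm <- vapply(flags, function(f) as.logical(cohort[[f]]), logical(nrow(cohort)))
  fm <- matrix(fm, nrow = nrow(cohort),
               dimnames = list(NULL, flags)) # guard n = 1
  keep <- rowSums(!fm) == 0
  report <- tibble::tibble(
    criterion = c(flags, "all_met"),
    n_failing = c(colSums(!fm), sum(!keep))
  )
  list(included = cohort[keep, , drop = FALSE], report = report,
       n_total = nrow(cohort), n_included = sum(keep))
}

#' Stratify a cohort into risk groups
#'
#' Adds `criteria_count` and `risk_group` columns based on the start profiles.
#'
#' @inheritParams apply_inclusion_filter
#' @param thresholds see [mets_thresholds()]
#' @return the cohort with two extra columns
#' @export
stratify_cohort <- function(cohort, thresholds = mets_thresholds()) {
  prof <- stats::setNames(
    cohort[paste0(c("waist", "tg", "hdl", "sbp", "dbp", "fg"), "_start")],
    c("waist", "tg", "hdl", "sbp", "dbp", "fg"))
  prof$diabetes <- if ("diabetes" %in% names(cohort)) cohort$diabetes else 0
  k <- as.integer(rowSums(criteria_matrix(prof, cohort$sex, thresholds)))
  cohort$criteria_count <- k
  cohort$risk_group <- assign_risk_group(k)
  cohort
}

#' Summarize a stratified cohort into (risk level x sex) cells
#'
#' Computes, for each of the up-to-six cells, the number of patients, mean
#' age, the rates of smoking, diagnosed diabetes and previous MI, and the
#' arithmetic mean of every continuous risk factor at start and at 12 months,
#' plus their difference. Means are computed in full precision; rounding is
#' applied only when formatting.
#'
#' @param cohort a stratified cohort (see [stratify_cohort()]); non-stratified
#'   cohorts are stratified on the fly
#' @param thresholds see [mets_thresholds()]
#' @return tibble with one row per non-empty (sex, risk level) cell
#' @export
summarize_groups <- function(cohort, thresholds = mets_thresholds()) {
  if (!"risk_group" %in% names(cohort)) {
    cohort <- stratify_cohort(cohort, thresholds)
  }
  has_12m <- all(paste0(RF_FIELDS, "_12m") %in% names(cohort))
  out <- cohort |>
    dplyr::group_by(.data$sex, .data$risk_group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_age = mean(.data$age),
      p_smoker = mean(.data$smoker),
      p_diabetes = mean(.data$diabetes),
      p_mi = mean(.data$previous_mi),
      dplyr::across(dplyr::ends_with("_start") | dplyr::ends_with("_12m"),
                    mean),
      .groups = "drop"
    )
  if (has_12m) {
    for (f in RF_FIELDS) {
      out[[paste0(f, "_diff")]] <- out[[paste0(f, "_12m")]] -
        out[[paste0(f, "_start")]]
    }
  }
  dplyr::arrange(out, .data$sex, .data$risk_group)
}

# turn one summary row into the group object the simulator consumes
group_from_summary <- function(row) {
  start <- stats::setNames(as.numeric(row[paste0(RF_FIELDS, "_start")]),
                           RF_FIELDS)
  m12 <- if (all(paste0(RF_FIELDS, "_12m") %in% names(row))) {
    stats::setNames(as.numeric(row[paste0(RF_FIELDS, "_12m")]), RF_FIELDS)
  } else start
  list(
    sex = as.character(row$sex),
    level = as.character(row$risk_group),
    n = as.integer(row$n),
    age = as.numeric(row$mean_age),
    profile_start = c(start, smoker = as.numeric(row$p_smoker)),
    profile_12m = c(m12, smoker = as.numeric(row$p_smoker)),
    p_t2d = as.numeric(row$p_diabetes),
    p_mi = as.numeric(row$p_mi)
  )
}
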