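#' Load the study reference tables
#'
#' Reads the five reference tables shipped with the package (or from a user
#' directory): cohort characteristics (`table1.csv`), group-level risk-factor
#' means at start and 12 months (`table2.csv`), unit values for program
#' resources (`table3.csv`), model-estimated future health and costs per group
#' (`table4.csv`), and the published cost-per-QALY results (`table5.csv`).
#' Values are stored exactly as printed in the source report.
#'
#' A self-consistency check recomputes every "difference" cell of tables 2 and
#' 4 as (12 months - start) and compares it with the printed value; mismatches
#' beyond printing precision are reported in `$consistency` rather than
#' silently accepted, because a handful of printed difference cells in the
#' source carry sign typos.
#'
#' @param dir directory containing `table1.csv` ... `table5.csv`; defaults to
#'   the copies installed with the package
#' @param tol_ratio multiple of half a unit in the last printed digit
#'   tolerated before a difference cell is flagged; the default 2 allows one
#'   full last-digit unit, since start and 12-month values were rounded
#'   independently before printing
#' @return list with elements `table1` ... `table5` (tibbles) and
#'   `consistency`, a tibble of recomputed vs printed difference cells with a
#'   `consistent` flag
#' @export
#' @examples
#' fx <- load_fixture_tables()
#' subset(fx$consistency, !consistent)  # the known printed typos
load_fixture_tables <- function(dir = system.file("extdata", package = "metscea"),
                                tol_ratio = 2) {
  files <- file.path(dir, paste0("table", 1:5, ".csv"))
  missing <- files[!file.exists(files)]
  if (length(missing) > 0) {
    stop("load_fixture_tables: missing fixture file(s): ",
         paste(basename(missing), collapse = ", "), call. = FALSE)
  }
  read1 <- function(path, cols) {
    df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) stop("load_fixture_tables: cannot parse ",
                                            basename(path), ": ",
                                            conditionMessage(e), call. = FALSE))
    miss <- setdiff(cols, names(df))
    if (nrow(df) == 0 || length(miss) > 0) {
      stop("load_fixture_tables: ", basename(path),
           if (nrow(df) == 0) " is empty"
           else paste0(" lacks column(s): ", paste(miss, collapse = ", ")),
           call. = FALSE)
    }
    tibble::as_tibble(df)
  }
  t1 <- read1(files[1], c("variable", "unit", "men_mean", "women_mean"))
  t2 <- read1(files[2], c("sex", "level", "variable", "start", "m12", "diff"))
  t3 <- read1(files[3], c("category", "resource", "unit", "value_eur",
                          "is_wage", "societal_only"))
  t4 <- read1(files[4], c("sex", "level", "measure", "start", "m12", "diff"))
  t5 <- read1(files[5], c("perspective", "sex", "level", "delta_qaly",
                          "net_cost", "cost_per_qaly"))

  check <- function(tab, table_name, var_col) {
    rows <- tab[!is.na(tab$diff) & !is.na(tab$m12), ]
    recomputed <- rows$m12 - rows$start
    # printed precision: half a unit in the last decimal shown
    step <- vapply(rows$diff, function(x) {
      s <- format(x, trim = TRUE, scientific = FALSE)
      dp <- if (grepl("\\.", s)) nchar(sub("^[^.]*\\.", "", s)) else 0
      10^(-dp)
    }, numeric(1))
    tibble::tibble(
      table = table_name,
      sex = rows$sex, level = rows$level, variable = rows[[var_col]],
      printed_diff = rows$diff, recomputed_diff = recomputed,
      consistent = abs(recomputed - rows$diff) <= tol_ratio * step / 2 + 1e-9
    )
  }
  consistency <- dplyr::bind_rows(check(t2, "table2", "variable"),
                                  check(t4, "table4", "measure"))
  list(table1 = t1, table2 = t2, table3 = t3, table4 = t4, table5 = t5,
       consistency = consistency)
}

# extract the per-cell n / age / mean profiles of table 2 as a list of cells
table2_cells <- function(table2) {
  cells <- expand.grid(sex = c("M", "F"), level = c("low", "medium", "high"),
                       stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sx <- cells$sex[i]; lv <- cells$level[i]
    sub <- table2[table2$sex == sx & table2$level == lv, ]
    get <- function(v, col) {
      x <- sub[[col]][sub$variable == v]
      if (length(x) == 0) NA_real_ else x
    }
    list(
      sex = sx, level = lv,
      n = as.integer(get("n", "start")),
      age = get("age", "start"),
      mean_start = stats::setNames(
        vapply(RF_FIELDS, get, numeric(1), col = "start"), RF_FIELDS),
      mean_12m = stats::setNames(
        vapply(RF_FIELDS, get, numeric(1), col = "m12"), RF_FIELDS)
    )
  })
  # cells absent from the table (no n row) are dropped
  Filter(function(cl) !is.na(cl$n), out)
}
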