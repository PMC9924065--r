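# NONMEM-style event-record dataset dialect: comma-delimited, one row per
# dose event or observation, missing values as ".", header mandatory.
# Times are decimal hours from the first CPG2 dose; phase-2 HD-MTX infusion
# events carry negative times.

.DIALECT_COLS <- c("ID", "TIME", "NOMINAL", "EVID", "ANALYTE", "AMT", "DUR",
                   "DV", "TDV", "BLQ", "MDV", "WT", "HT", "BSA", "AGE",
                   "SCR")

.fmt <- function(x) {
  ifelse(is.na(x), ".", vapply(x, function(v) sprintf("%.17g", v),
                               character(1)))
}

.num <- function(x, col, lines) {
  x[x == "."] <- NA
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop(sprintf("malformed numeric value in column %s, line %d",
                 col, lines[bad[1]]))
  out
}

.RUN_CONFIG_KEYS <- c(
  seed = "integer", phase = "integer", n_subjects = "integer",
  dose_u_per_kg = "numeric", missing_prob = "numeric",
  units_per_mg = "numeric", ode_rtol = "numeric", ode_atol = "numeric",
  method = "character", out_dir = "character")

#' Read a run configuration file
#'
#' Plain-text `key = value` configuration for reproducible pipeline runs
#' (seed, cohort size, potency constant, solver tolerances, estimation
#' method, output directory).  Lines starting with `#` are comments.
#' Unknown keys are rejected; values are validated against their declared
#' types.
#'
#' @param path configuration file path
#' @return named list of validated settings
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (i in seq_along(lines)) {
    kv <- strsplit(lines[i], "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop(sprintf("malformed config line %d: %s", i, lines[i]))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(.RUN_CONFIG_KEYS))
      stop(sprintf("unknown configuration key: %s", key))
    out[[key]] <- switch(.RUN_CONFIG_KEYS[[key]],
      integer = {
        v <- suppressWarnings(as.integer(val))
        if (is.na(v)) stop(sprintf("key %s needs an integer", key))
        v
      },
      numeric = {
        v <- suppressWarnings(as.numeric(val))
        if (is.na(v)) stop(sprintf("key %s needs a number", key))
        v
      },
      character = val)
  }
  out
}

#' Write a cohort in the event-record CSV dialect
#'
#' One row per dose event (`EVID = 1`, `AMT`/`DUR` set, `DV` missing) or
#' observation (`EVID = 0`, `MDV = 0`), comma-delimited with missing values
#' as `"."`.  Covariates (WT kg, HT cm, BSA m2, AGE y, SCR mg/dl) are
#' repeated on every row.  `TDV` carries the error-free simulated value for
#' synthetic cohorts and `BLQ` the below-quantification flag.
#'
#' @param cohort a `pk_cohort`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_dataset <- function(cohort, path) {
  rows <- list()
  for (s in cohort) {
    cv <- s$covariates
    base <- function(n) if (is.null(cv[[n]])) NA_real_ else cv[[n]]
    covs <- c(WT = base("weight"), HT = base("height"), BSA = base("bsa"),
              AGE = base("age"), SCR = base("scr"))
    for (i in seq_len(nrow(s$doses)))
      rows[[length(rows) + 1]] <- data.frame(
        ID = s$id, TIME = s$doses$time[i], NOMINAL = ".",
        EVID = 1, ANALYTE = s$doses$analyte[i],
        AMT = s$doses$amount[i], DUR = s$doses$duration[i],
        DV = NA_real_, TDV = NA_real_, BLQ = NA_real_, MDV = 1,
        t(covs), stringsAsFactors = FALSE)
    for (i in seq_len(nrow(s$obs)))
      rows[[length(rows) + 1]] <- data.frame(
        ID = s$id, TIME = s$obs$time[i], NOMINAL = s$obs$nominal[i],
        EVID = 0, ANALYTE = s$obs$analyte[i],
        AMT = NA_real_, DUR = NA_real_,
        DV = s$obs$dv[i], TDV = s$obs$tdv[i],
        BLQ = as.numeric(s$obs$blq[i]), MDV = 0,
        t(covs), stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$ID, df$TIME, df$EVID), , drop = FALSE]
  num_cols <- setdiff(.DIALECT_COLS, c("ID", "NOMINAL", "ANALYTE"))
  for (cc in num_cols) df[[cc]] <- .fmt(df[[cc]])
  write.csv(df[, .DIALECT_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event-record CSV dataset
#'
#' Parses and validates the dialect written by [write_dataset()]: all
#' dialect columns must be present, times must be non-decreasing within a
#' subject, and dose rows must carry no observation.  Violations are
#' reported with the offending line number.
#'
#' @param path input file path
#' @return a `pk_cohort`
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(.DIALECT_COLS, names(df))
  if (length(missing_cols))
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  lines <- seq_len(nrow(df)) + 1L   # header is line 1
  for (cc in setdiff(.DIALECT_COLS, c("ID", "NOMINAL", "ANALYTE")))
    df[[cc]] <- .num(df[[cc]], cc, lines)
  if (any(!df$ANALYTE %in% c("CPG2", "MTX")))
    stop(sprintf("unknown analyte at line %d",
                 lines[which(!df$ANALYTE %in% c("CPG2", "MTX"))[1]]))
  bad_dose <- which(df$EVID == 1 & !is.na(df$DV))
  if (length(bad_dose))
    stop(sprintf("dose row carries an observation at line %d",
                 lines[bad_dose[1]]))

  subjects <- list()
  for (id in unique(df$ID)) {
    rows <- df[df$ID == id, , drop = FALSE]
    rl <- lines[df$ID == id]
    if (is.unsorted(rows$TIME))
      stop(sprintf(
        "times decrease within subject %s near line %d", id,
        rl[which(diff(rows$TIME) < 0)[1] + 1L]))
    r1 <- rows[1, ]
    cov <- covariates(weight = r1$WT,
                      height = if (is.na(r1$HT)) NULL else r1$HT,
                      bsa = if (is.na(r1$BSA)) NULL else r1$BSA,
                      age = if (is.na(r1$AGE)) NULL else r1$AGE,
                      scr = if (is.na(r1$SCR)) NULL else r1$SCR)
    d <- rows[rows$EVID == 1, , drop = FALSE]
    doses <- data.frame(time = d$TIME, amount = d$AMT, duration = d$DUR,
                        analyte = d$ANALYTE, stringsAsFactors = FALSE)
    o <- rows[rows$EVID == 0, , drop = FALSE]
    obs <- data.frame(time = o$TIME, nominal = o$NOMINAL,
                      analyte = o$ANALYTE, dv = o$DV,
                      blq = o$BLQ == 1, tdv = o$TDV,
                      stringsAsFactors = FALSE)
    subjects[[length(subjects) + 1]] <-
      .new_subject(id, cov, doses, obs, truth = NULL)
  }
  structure(subjects, class = "pk_cohort",
            design = NULL, seed = NA, units_per_mg = NA)
}
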