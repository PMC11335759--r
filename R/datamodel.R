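#' Core data model for stimulation cohorts
#'
#' A cohort bundles four linked tables:
#' \describe{
#'   \item{baselines}{one row per patient: `patient_id`, `physician_id`,
#'     `arm` (`"treatment"`/`"control"`), `age` (years), `amh` (ng/mL, may
#'     be `NA`), `afc` (antral follicle count, may be `NA`), `bmi`
#'     (kg/m^2, may be `NA`).}
#'   \item{visits}{one row per monitoring day: `patient_id`, `cycle_day`,
#'     `follicles` (semicolon-joined diameters in mm), `e2` (pg/mL),
#'     `fsh_pure`, `fsh_combo`, `lh` (IU given that day), `is_trigger_day`,
#'     `trigger_type` (`"hcg"`, `"lupron"`, `"dual"`, or `"none"`).}
#'   \item{outcomes}{one row per completed cycle: `patient_id`,
#'     `oocytes_retrieved`, `mii_count`, `total_fsh_iu`, `trigger_day`.}
#'   \item{surveys}{optional; one row per tool view: `patient_id`, `tool`
#'     (`"starting_dose"`/`"trigger"`), `cycle_day` (`NA` for the
#'     starting-dose tool), `verdict` (`"confirmed"`, `"changed"`,
#'     `"ignored"`, `"unavailable"`).}
#' }
#'
#' `cohort()` validates the tables and links; [read_cohort()] and
#' [write_cohort()] move the same structure through CSV files (UTF-8,
#' comma-separated, header row, missing values as empty fields).
#'
#' @param baselines,visits,outcomes data frames as described above.
#' @param surveys optional survey data frame.
#' @return An object of class `stim_cohort`: a list with elements
#'   `baselines`, `visits`, `outcomes`, `surveys`.
#' @export
cohort <- function(baselines, visits, outcomes, surveys = NULL) {
  x <- structure(
    list(baselines = baselines, visits = visits,
         outcomes = outcomes, surveys = surveys),
    class = "stim_cohort"
  )
  validate_cohort(x)
}

#' @export
print.stim_cohort <- function(x, ...) {
  cat(sprintf(
    "<stim_cohort> %d patients, %d visits, %d outcomes%s\n",
    nrow(x$baselines), nrow(x$visits), nrow(x$outcomes),
    if (is.null(x$surveys)) "" else sprintf(", %d survey responses", nrow(x$surveys))
  ))
  invisible(x)
}

COHORT_SCHEMAS <- list(
  baselines = c("patient_id", "physician_id", "arm", "age", "amh", "afc", "bmi"),
  visits    = c("patient_id", "cycle_day", "follicles", "e2", "fsh_pure",
                "fsh_combo", "lh", "is_trigger_day", "trigger_type"),
  outcomes  = c("patient_id", "oocytes_retrieved", "mii_count",
                "total_fsh_iu", "trigger_day"),
  surveys   = c("patient_id", "tool", "cycle_day", "verdict")
)

check_columns <- function(df, table) {
  need <- COHORT_SCHEMAS[[table]]
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort_schema(sprintf(
      "table '%s' is missing required column(s): %s",
      table, paste(missing, collapse = ", ")
    ))
  }
  df[need]
}

#' Validate a cohort's invariants
#'
#' Checks field-level invariants (age, BMI and dose ranges, verdict and
#' trigger-type categories), referential integrity (every visit, outcome and
#' survey row names a known patient), per-cycle structure (at most one visit
#' per patient-day, exactly one trigger day per completed cycle,
#' `trigger_type == "none"` exactly on non-trigger days), and outcome
#' consistency (`mii_count <= oocytes_retrieved`; `total_fsh_iu` equals the
#' sum of `fsh_pure + fsh_combo` over the patient's visits).
#'
#' @param x a `stim_cohort`.
#' @return `x`, invisibly usable, after passing all checks.
#' @export
validate_cohort <- function(x) {
  b <- check_columns(x$baselines, "baselines")
  v <- check_columns(x$visits, "visits")
  o <- check_columns(x$outcomes, "outcomes")
  s <- if (!is.null(x$surveys)) check_columns(x$surveys, "surveys") else NULL

  bad <- function(tbl, rows, what) {
    abort_validation(sprintf(
      "%s: %s (rows %s)", tbl, what,
      paste(utils::head(rows, 10), collapse = ", ")
    ))
  }

  if (anyDuplicated(b$patient_id)) {
    bad("baselines", which(duplicated(b$patient_id)), "duplicate patient_id")
  }
  if (any(i <- !(b$arm %in% c("treatment", "control")))) {
    bad("baselines", which(i), "arm must be 'treatment' or 'control'")
  }
  if (any(i <- !(b$age > 18 & b$age < 55))) {
    bad("baselines", which(i), "age outside (18, 55)")
  }
  if (any(i <- !is.na(b$amh) & b$amh < 0)) bad("baselines", which(i), "negative amh")
  if (any(i <- !is.na(b$afc) & (b$afc < 0 | b$afc != floor(b$afc)))) {
    bad("baselines", which(i), "afc must be a non-negative integer")
  }
  if (any(i <- !is.na(b$bmi) & !(b$bmi > 12 & b$bmi < 70))) {
    bad("baselines", which(i), "bmi outside (12, 70)")
  }

  ids <- b$patient_id
  for (tbl in list(list(v, "visits"), list(o, "outcomes"),
                   if (!is.null(s)) list(s, "surveys"))) {
    if (is.null(tbl)) next
    orphan <- setdiff(tbl[[1]]$patient_id, ids)
    if (length(orphan) > 0) {
      abort_referential(sprintf(
        "%s references unknown patient_id(s): %s",
        tbl[[2]], paste(utils::head(orphan, 10), collapse = ", ")
      ))
    }
  }

  if (nrow(v) > 0) {
    if (any(i <- v$cycle_day < 1 | v$cycle_day != floor(v$cycle_day))) {
      bad("visits", which(i), "cycle_day must be an integer >= 1")
    }
    key <- paste(v$patient_id, v$cycle_day)
    if (anyDuplicated(key)) {
      bad("visits", which(duplicated(key)), "more than one visit per patient-day")
    }
    if (any(i <- v$e2 < 0 | v$fsh_pure < 0 | v$fsh_combo < 0 | v$lh < 0)) {
      bad("visits", which(i), "negative e2 or dose")
    }
    if (any(i <- !(v$trigger_type %in% c("hcg", "lupron", "dual", "none")))) {
      bad("visits", which(i), "unknown trigger_type")
    }
    if (any(i <- xor(v$is_trigger_day, v$trigger_type != "none"))) {
      bad("visits", which(i), "trigger_type must be 'none' exactly when is_trigger_day is FALSE")
    }
    fol <- parse_follicles(v$follicles)
    i <- vapply(fol, function(d) length(d) > 0 && any(d <= 0), logical(1))
    if (any(i)) bad("visits", which(i), "non-positive follicle diameter")
  }

  if (nrow(o) > 0) {
    if (any(i <- o$mii_count > o$oocytes_retrieved)) {
      bad("outcomes", which(i), "mii_count exceeds oocytes_retrieved")
    }
    if (any(i <- o$mii_count < 0 | o$oocytes_retrieved < 0)) {
      bad("outcomes", which(i), "negative outcome count")
    }
    # completed cycles carry exactly one trigger day, matching the outcome row
    trig <- v[v$is_trigger_day, , drop = FALSE]
    ntrig <- table(factor(trig$patient_id, levels = o$patient_id))
    if (any(i <- as.integer(ntrig) != 1L)) {
      bad("outcomes", which(i), "completed cycle without exactly one trigger-day visit")
    }
    trig_day <- trig$cycle_day[match(o$patient_id, trig$patient_id)]
    if (any(i <- trig_day != o$trigger_day)) {
      bad("outcomes", which(i), "trigger_day disagrees with the flagged visit")
    }
    fsh_by_pat <- tapply(v$fsh_pure + v$fsh_combo, v$patient_id, sum)
    got <- as.numeric(fsh_by_pat[o$patient_id])
    got[is.na(got)] <- 0
    if (any(i <- abs(got - o$total_fsh_iu) > 1e-6)) {
      bad("outcomes", which(i), "total_fsh_iu does not equal the sum of per-visit FSH")
    }
  }

  if (!is.null(s) && nrow(s) > 0) {
    if (any(i <- !(s$tool %in% c("starting_dose", "trigger")))) {
      bad("surveys", which(i), "unknown tool")
    }
    if (any(i <- !(s$verdict %in% c("confirmed", "changed", "ignored", "unavailable")))) {
      bad("surveys", which(i), "unknown verdict")
    }
  }

  x$baselines <- b; x$visits <- v; x$outcomes <- o; x$surveys <- s
  x
}

#' Parse and format semicolon-joined follicle diameters
#'
#' Visit tables store the day's follicle diameters as a single
#' semicolon-joined string (e.g. `"12.5;14;16.5"`) so the CSV stays flat.
#'
#' @param x character vector of joined diameters; empty strings give
#'   zero-length numeric vectors.
#' @return `parse_follicles()`: a list of numeric vectors (mm);
#'   `format_follicles()`: a character vector.
#' @export
parse_follicles <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) return(numeric(0))
    as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

#' @rdname parse_follicles
#' @param diameters a list of numeric vectors, or one numeric vector.
#' @export
format_follicles <- function(diameters) {
  if (is.numeric(diameters)) diameters <- list(diameters)
  vapply(diameters, function(d) paste(format(d, trim = TRUE, digits = 15),
                                      collapse = ";"), character(1))
}

#' Read a cohort from CSV files
#'
#' @param baselines_path,visits_path,outcomes_path paths to the three
#'   required CSV files.
#' @param surveys_path optional path to the survey CSV.
#' @return a validated `stim_cohort`.
#' @seealso [write_cohort()] for the inverse; the round trip is lossless.
#' @export
read_cohort <- function(baselines_path, visits_path, outcomes_path,
                        surveys_path = NULL) {
  rd <- function(path, chr_cols) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                          colClasses = NA, fileEncoding = "UTF-8")
    for (cc in intersect(chr_cols, names(df))) {
      df[[cc]] <- ifelse(is.na(df[[cc]]), "", as.character(df[[cc]]))
    }
    df
  }
  b <- rd(baselines_path, "patient_id")
  v <- rd(visits_path, c("patient_id", "follicles"))
  o <- rd(outcomes_path, "patient_id")
  s <- if (!is.null(surveys_path)) rd(surveys_path, "patient_id") else NULL
  if (!is.null(v$is_trigger_day)) v$is_trigger_day <- as.logical(v$is_trigger_day)
  cohort(b, v, o, s)
}

#' Write a cohort to CSV files
#'
#' Writes `baselines.csv`, `visits.csv`, `outcomes.csv` and, when surveys
#' are present, `surveys.csv` into `dir`. Missing values are written as
#' empty fields.
#'
#' @param x a `stim_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "stim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE, na = "",
                     quote = FALSE, fileEncoding = "UTF-8")
  }
  wr(x$baselines, "baselines.csv")
  wr(x$visits, "visits.csv")
  wr(x$outcomes, "outcomes.csv")
  if (!is.null(x$surveys)) wr(x$surveys, "surveys.csv")
  invisible(dir)
}

#' Total FSH administered over a set of visits
#'
#' Total FSH is the sum of pure-FSH preparations plus the FSH component of
#' combined FSH+LH preparations; the LH component is excluded.
#'
#' @param visits a visit data frame (one patient's visits).
#' @return total FSH in IU.
#' @examples
#' v <- data.frame(fsh_pure = c(225, 225), fsh_combo = c(75, 75), lh = c(75, 75))
#' total_fsh(v)  # 600
#' @export
total_fsh <- function(visits) {
  if (nrow(visits) == 0) return(0)
  if (any(visits$fsh_pure < 0 | visits$fsh_combo < 0)) {
    abort_validation("negative FSH dose")
  }
  sum(visits$fsh_pure + visits$fsh_combo)
}

FOLLICLE_BIN_LABELS <- c("<11", "11-13", "14-15", "16-17", "18-19", ">19")
FOLLICLE_BIN_LOWER  <- c(-Inf, 11, 14, 16, 18, 20)

#' Bin follicle diameters into the six standard monitoring groups
#'
#' Diameters (mm) are assigned to six ordered bins: `<11`, `11-13`,
#' `14-15`, `16-17`, `18-19`, `>19`.  Integer-labelled bins are half-open
#' on the millimetre scale: `11-13` means `11 <= d < 14`, `14-15` means
#' `14 <= d < 16`, and so on; `>19` means `d >= 20`.  Every positive
#' diameter lands in exactly one bin.
#'
#' @param diameters numeric vector of follicle diameters in mm, all > 0.
#' @return named integer vector of length 6 (counts per bin).
#' @examples
#' bin_follicles(c(10, 12, 14.5, 16, 18, 20))
#' @export
bin_follicles <- function(diameters) {
  if (length(diameters) > 0 && (any(is.na(diameters)) || any(diameters <= 0))) {
    abort_validation("follicle diameters must be positive")
  }
  idx <- findInterval(diameters, FOLLICLE_BIN_LOWER)
  counts <- tabulate(idx, nbins = 6L)
  names(counts) <- FOLLICLE_BIN_LABELS
  counts
}
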