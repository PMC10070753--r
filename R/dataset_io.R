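#' Assemble a PK dataset from event and covariate tables
#'
#' The central data container: one dosing/observation event stream per
#' subject plus one row of time-constant (baseline / intra-operative
#' summary) covariates per subject.
#'
#' @param events data.frame with columns `ID` (character or coercible),
#'   `TIME` (h since first dose), `AMT` (mg, 0 for observations), `DUR`
#'   (infusion duration h, 0 = bolus), `DV` (ng/mL), `EVID` (1 dose /
#'   0 observation), `MDV` (1 = DV ignored).
#' @param covariates data.frame with column `ID` and one column per
#'   covariate; one row per subject. May be NULL when no covariates are
#'   carried.
#' @param lloq Assay lower limit of quantitation (ng/mL); default 0.1.
#'
#' @return An object of class `pk_dataset` with elements `events`,
#'   `covariates`, `lloq`.
#'
#' @details Validation enforces the event semantics: dose rows have
#'   `AMT > 0` and `MDV = 1`; usable observations (`EVID = 0, MDV = 0`)
#'   have non-missing `DV >= 0`; per-subject records are time-sorted;
#'   every subject has at least one dose; no usable observation precedes
#'   the first dose (pre-dose rows must be flagged `MDV = 1`).
#' @export
pk_dataset <- function(events, covariates = NULL, lloq = 0.1) {
  req <- c("ID", "TIME", "AMT", "DUR", "DV", "EVID", "MDV")
  miss <- setdiff(req, names(events))
  if (length(miss))
    stop("events table lacks required columns: ", paste(miss, collapse = ", "))
  events$ID <- as.character(events$ID)
  events <- events[, req]
  if (!is.null(covariates)) {
    if (!"ID" %in% names(covariates)) stop("covariates table lacks ID column")
    covariates$ID <- as.character(covariates$ID)
    if (anyDuplicated(covariates$ID))
      stop("covariates table has duplicated subject IDs")
  }
  x <- structure(list(events = events, covariates = covariates, lloq = lloq),
                 class = "pk_dataset")
  validate_pk_dataset(x)
  x
}

validate_pk_dataset <- function(x) {
  ev <- x$events
  for (id in unique(ev$ID)) {
    e <- ev[ev$ID == id, ]
    if (is.unsorted(e$TIME))
      stop("subject ", id, ": event times are not sorted (row ",
           which(ev$ID == id)[which(diff(e$TIME) < 0)[1] + 1], ")")
    dose <- e$EVID == 1
    if (!any(dose))
      stop("subject ", id, ": no dose event")
    if (any(e$AMT[dose] <= 0))
      stop("subject ", id, ": dose event with non-positive AMT")
    if (any(e$MDV[dose] != 1))
      stop("subject ", id, ": dose events must carry MDV=1")
    obs <- e$EVID == 0 & e$MDV == 0
    if (any(obs)) {
      if (any(is.na(e$DV[obs])) || any(e$DV[obs] < 0))
        stop("subject ", id, ": usable observation with missing or negative DV")
      t_first_dose <- min(e$TIME[dose])
      if (any(e$TIME[obs] < t_first_dose))
        stop("subject ", id, ": observation before the first dose event ",
             "(flag pre-dose rows with MDV=1)")
    }
  }
  if (!is.null(x$covariates)) {
    extra <- setdiff(unique(ev$ID), x$covariates$ID)
    if (length(extra))
      stop("subjects without covariate rows: ", paste(extra, collapse = ", "))
  }
  invisible(x)
}

#' @export
print.pk_dataset <- function(x, ...) {
  nobs <- sum(x$events$EVID == 0 & x$events$MDV == 0)
  cat(sprintf("pk_dataset: %d subjects, %d usable observations, LLOQ %g ng/mL\n",
              length(unique(x$events$ID)), nobs, x$lloq))
  invisible(x)
}

#' Number of subjects / subject IDs
#' @param x A `pk_dataset`.
#' @return Character vector of subject IDs in order of appearance.
#' @export
subject_ids <- function(x) unique(x$events$ID)

#' Extract one subject's dose schedule and usable observations
#'
#' @param x A `pk_dataset`.
#' @param id Subject ID.
#' @return List with `id`, `doses` (data.frame `time`, `amt`, `dur`),
#'   `times`, `dv` (usable observations only) and `covs` (named list,
#'   or NULL).
#' @export
subject_data <- function(x, id) {
  e <- x$events[x$events$ID == id, ]
  doses <- e[e$EVID == 1, c("TIME", "AMT", "DUR")]
  names(doses) <- c("time", "amt", "dur")
  obs <- e[e$EVID == 0 & e$MDV == 0, c("TIME", "DV")]
  covs <- NULL
  if (!is.null(x$covariates))
    covs <- as.list(x$covariates[x$covariates$ID == id, , drop = FALSE])
  list(id = id, doses = doses, times = obs$TIME, dv = obs$DV, covs = covs)
}

#' Read a NONMEM-style PK dataset from delimited text
#'
#' Comma-separated file with a header row; conventional column names
#' ID, TIME, AMT, RATE (mg/h; 0 = bolus), DV, MDV, EVID, plus any number
#' of covariate columns (time-constant per subject; first row per subject
#' is used). Missing values are encoded as ".". RATE is converted to an
#' infusion duration internally (`DUR = AMT/RATE`); a `DUR` column is
#' also accepted directly.
#'
#' @param path File path.
#' @param column_map Optional named character vector mapping required
#'   names to the file's column names, e.g. `c(ID = "SUBJ")`.
#' @param lloq LLOQ (ng/mL) recorded on the dataset.
#'
#' @return A [pk_dataset()].
#' @export
read_pk_dataset <- function(path, column_map = NULL, lloq = 0.1) {
  raw <- utils::read.csv(path, na.strings = ".", check.names = FALSE,
                         colClasses = NA, stringsAsFactors = FALSE)
  if (!is.null(column_map))
    for (std in names(column_map)) {
      if (!column_map[[std]] %in% names(raw))
        stop("mapped column '", column_map[[std]], "' not found in file")
      names(raw)[names(raw) == column_map[[std]]] <- std
    }
  req <- c("ID", "TIME", "AMT", "DV", "EVID", "MDV")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("file lacks required columns: ", paste(miss, collapse = ", "))
  if (nrow(raw) == 0) {
    ev0 <- data.frame(ID = character(), TIME = numeric(), AMT = numeric(),
                      DUR = numeric(), DV = numeric(), EVID = integer(),
                      MDV = integer())
    return(structure(list(events = ev0, covariates = NULL, lloq = lloq),
                     class = "pk_dataset"))
  }
  if ("DUR" %in% names(raw)) {
    dur <- ifelse(is.na(raw$DUR), 0, raw$DUR)
  } else if ("RATE" %in% names(raw)) {
    rate <- ifelse(is.na(raw$RATE), 0, raw$RATE)
    dur <- ifelse(rate > 0, raw$AMT / rate, 0)
  } else dur <- rep(0, nrow(raw))
  ev <- data.frame(ID = as.character(raw$ID), TIME = raw$TIME,
                   AMT = ifelse(is.na(raw$AMT), 0, raw$AMT), DUR = dur,
                   DV = raw$DV, EVID = raw$EVID, MDV = raw$MDV)
  covcols <- setdiff(names(raw), c(req, "RATE", "DUR"))
  covs <- NULL
  if (length(covcols)) {
    first <- !duplicated(ev$ID)
    covs <- cbind(data.frame(ID = ev$ID[first]),
                  raw[first, covcols, drop = FALSE])
    rownames(covs) <- NULL
  }
  pk_dataset(ev, covs, lloq = lloq)
}

#' Write a PK dataset as delimited text
#'
#' Inverse of [read_pk_dataset()]: one rectangular CSV with the
#' NONMEM-conventional columns (infusions written as RATE = AMT/DUR) and
#' covariate columns repeated on every row of a subject. Missing values
#' are written as ".". `read_pk_dataset(write_pk_dataset(d))` reproduces
#' `d` field-for-field.
#'
#' @param data A [pk_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(data, path) {
  ev <- data$events
  out <- data.frame(ID = ev$ID, TIME = ev$TIME, AMT = ev$AMT,
                    RATE = ifelse(ev$DUR > 0, ev$AMT / ev$DUR, 0),
                    DV = ev$DV, EVID = ev$EVID, MDV = ev$MDV)
  if (!is.null(data$covariates)) {
    cv <- data$covariates
    out <- cbind(out, cv[match(ev$ID, cv$ID),
                         setdiff(names(cv), "ID"), drop = FALSE])
  }
  m <- as.matrix(format(out, trim = TRUE, digits = 15, scientific = FALSE))
  m[is.na(out) | m == "NA"] <- "."
  utils::write.table(m, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
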