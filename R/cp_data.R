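#' Counting-process survival data with time-varying covariates
#'
#' A `cp_data` object holds long-format survival records in the standard
#' counting-process encoding: one row per subject per covariate interval,
#' with columns `id`, `tstart`, `tstop`, `status` and one column per
#' covariate.  Intervals are half-open, `(tstart, tstop]`, and the covariate
#' values on a row are the values in force on that interval.  A subject's
#' rows partition `(0, t_i]` where `t_i` is the observed event or censoring
#' time; `status = 1` may appear only on a subject's final row.
#'
#' Two covariate sets are tracked: `x_cols` enter the logistic incidence
#' (cure probability) component and `z_cols` the Cox latency component.
#' The sets may overlap or coincide.
#'
#' @param records data.frame with columns `id`, `tstart`, `tstop`, `status`
#'   plus the covariate columns.
#' @param x_cols character vector of incidence covariate column names.
#' @param z_cols character vector of latency covariate column names.
#' @param validate logical; check the counting-process invariants.
#'
#' @return An object of class `cp_data`: a list with elements `records`
#'   (the data.frame, ordered by id then tstart), `x_cols` and `z_cols`.
#' @export
cp_data <- function(records, x_cols, z_cols, validate = TRUE) {
  stopifnot(is.data.frame(records))
  needed <- c("id", "tstart", "tstop", "status")
  missing_cols <- setdiff(c(needed, x_cols, z_cols), names(records))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  records <- records[order(records$id, records$tstart), , drop = FALSE]
  rownames(records) <- NULL
  obj <- structure(list(records = records,
                        x_cols = as.character(x_cols),
                        z_cols = as.character(z_cols)),
                   class = "cp_data")
  if (validate) validate_cp_data(obj)
  obj
}

#' Validate counting-process invariants
#'
#' Checks that each subject's rows form a contiguous partition of
#' `(0, t_i]` (first row starts at 0, each row starts where the previous
#' stopped, `tstop > tstart`), that `status` is 0/1 and equals 1 at most
#' once per subject and only on the final row, and that no covariate value
#' is missing.  Errors name the offending subject.
#'
#' @param data a `cp_data` object.
#' @return `data`, invisibly, if valid.
#' @export
validate_cp_data <- function(data) {
  stopifnot(inherits(data, "cp_data"))
  r <- data$records
  if (nrow(r) == 0) return(invisible(data))
  if (anyNA(r[c("id", "tstart", "tstop", "status", data$x_cols, data$z_cols)]))
    stop("missing values in counting-process data")
  if (!all(r$status %in% c(0, 1)))
    stop("status must be 0 or 1")
  if (!all(is.finite(r$tstop)) || !all(is.finite(r$tstart)))
    stop("non-finite interval boundaries")
  if (any(r$tstart < 0)) stop("negative start times")
  if (any(r$tstop <= r$tstart)) {
    bad <- r$id[which(r$tstop <= r$tstart)[1]]
    stop("empty or reversed interval for subject ", bad)
  }
  idx <- split(seq_len(nrow(r)), r$id)
  for (id in names(idx)) {
    k <- idx[[id]]
    st <- r$tstart[k]; sp <- r$tstop[k]
    if (st[1] != 0)
      stop("first interval does not start at 0 for subject ", id)
    if (length(k) > 1 && any(abs(st[-1] - sp[-length(k)]) > 0)) {
      stop("gap or overlap for subject ", id)
    }
    ev <- r$status[k]
    if (sum(ev) > 1) stop("multiple events for subject ", id)
    if (sum(ev) == 1 && ev[length(k)] != 1)
      stop("status = 1 on a non-final row for subject ", id)
  }
  invisible(data)
}

#' @export
print.cp_data <- function(x, ...) {
  r <- x$records
  cat("<cp_data> ", length(unique(r$id)), " subjects, ", nrow(r), " rows, ",
      sum(r$status), " events\n", sep = "")
  cat("  incidence covariates:", paste(x$x_cols, collapse = ", "), "\n")
  cat("  latency covariates:  ", paste(x$z_cols, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.cp_data <- function(x, ...) x$records

#' Number of subjects in a counting-process dataset
#' @param data a `cp_data` object.
#' @return integer count.
#' @export
n_subjects <- function(data) length(unique(data$records$id))

## Per-subject summary used throughout: one row per subject with observed
## time, event indicator and last-row index; ordered as the records are.
subject_index <- function(data) {
  r <- data$records
  last <- !duplicated(r$id, fromLast = TRUE)
  data.frame(id = r$id[last],
             time = r$tstop[last],
             status = r$status[last],
             row = which(last),
             stringsAsFactors = FALSE)
}

#' Read counting-process data from CSV
#'
#' @param path file path to a CSV with header.
#' @param x_cols,z_cols covariate column names for the incidence and latency
#'   components (after renaming via `schema`).
#' @param schema optional named character vector mapping the canonical names
#'   `id`, `tstart`, `tstop`, `status` to the column names used in the file,
#'   e.g. `c(tstart = "start")`.
#' @return a validated `cp_data` object, subjects ordered by id then tstart.
#' @export
read_counting_process <- function(path, x_cols, z_cols, schema = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      j <- match(schema[[canon]], names(df))
      if (is.na(j)) stop("schema column not found: ", schema[[canon]])
      names(df)[j] <- canon
    }
  }
  cp_data(df, x_cols = x_cols, z_cols = z_cols)
}

#' Write counting-process data to CSV
#'
#' One row per subject-interval; exact round trip with
#' [read_counting_process()] (values written at full precision).
#'
#' @param data a `cp_data` object.
#' @param path output file path.
#' @export
write_counting_process <- function(data, path) {
  stopifnot(inherits(data, "cp_data"))
  utils::write.csv(format(data$records, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
}

#' Per-subject covariate design values
#'
#' The incidence component uses a single covariate vector per subject even
#' though the stored covariates are time-varying; this function resolves the
#' choice.  With `at = "entry"` (the default) the covariates in force on the
#' first interval, `(0, s1]`, are used -- matching the simulator, where the
#' cure indicator is drawn once from the entry covariates.  With
#' `at = "last"` the final interval's values are used.
#'
#' @param data a `cp_data` object.
#' @param which `"incidence"` (the `x_cols`) or `"latency"` (the `z_cols`).
#' @param at `"entry"` or `"last"`.
#' @return numeric matrix, one row per subject (ordered by id), one column
#'   per covariate.
#' @export
covariate_at_entry <- function(data, which = c("incidence", "latency"),
                               at = c("entry", "last")) {
  which <- match.arg(which)
  at <- match.arg(at)
  cols <- if (which == "incidence") data$x_cols else data$z_cols
  r <- data$records
  pick <- if (at == "entry") !duplicated(r$id) else !duplicated(r$id, fromLast = TRUE)
  m <- as.matrix(r[pick, cols, drop = FALSE])
  rownames(m) <- r$id[pick]
  m
}
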