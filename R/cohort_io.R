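# Longitudinal lesion / burden data model and CSV readers-writers.
#
# Two CSV dialects are supported (header row mandatory, decimal point,
# UTF-8):
#   lesion-level: patient_id, scan_time_days, lesion_id, long_axis_mm,
#                 short_axis_mm
#   burden-level: patient_id, time_days, burden_norm
# Cohort-level metadata (histology, cohort name) live in a YAML sidecar.

#' Spherical lesion volume from long and short axes
#'
#' Lesion volumes are estimated as 3D spheres whose diameter is the
#' geometric mean of the measured long and short axes.
#'
#' @param long_axis,short_axis Axis lengths in mm, >= 0. Vectorized.
#' @return Volume in mm^3.
#' @examples
#' lesion_volume(10, 4)   # sphere of diameter sqrt(40)
#' @export
lesion_volume <- function(long_axis, short_axis) {
  if (any(!is.finite(long_axis)) || any(!is.finite(short_axis)) ||
      any(long_axis < 0) || any(short_axis < 0))
    stop("lesion axes must be finite and >= 0")
  diameter_to_volume(sqrt(long_axis * short_axis))
}

#' One patient's normalized burden series
#'
#' Container for a patient's normalized tumor-burden time series. Times
#' are days since the first checkpoint-inhibitor dose; the baseline scan
#' at t = 0 has burden exactly 1. An optional pretreatment point (time
#' < 0) carries the burden normalized by the same baseline volume.
#'
#' @param patient_id Identifier (scalar).
#' @param times Numeric, strictly increasing, first element 0.
#' @param burdens Numeric, same length, >= 0, first element 1.
#' @param pretreatment Optional length-2 numeric \code{c(time, burden)}
#'   with time < 0, or NULL.
#' @param histology,cohort Optional labels.
#' @return An object of class \code{"patient_series"}.
#' @export
patient_series <- function(patient_id, times, burdens, pretreatment = NULL,
                           histology = NA_character_, cohort = NA_character_) {
  stopifnot(length(patient_id) == 1L, length(times) == length(burdens))
  if (length(times) < 1L || times[1] != 0)
    stop("series must start with a baseline scan at t = 0")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (abs(burdens[1] - 1) > 1e-12)
    stop("baseline burden at t = 0 must equal 1")
  if (any(!is.finite(burdens)) || any(burdens < 0))
    stop("burdens must be finite and >= 0")
  if (!is.null(pretreatment)) {
    stopifnot(length(pretreatment) == 2L)
    if (!is.finite(pretreatment[1]) || pretreatment[1] >= 0)
      stop("pretreatment time must be < 0")
    if (!is.finite(pretreatment[2]) || pretreatment[2] < 0)
      stop("pretreatment burden must be finite and >= 0")
    pretreatment <- as.numeric(pretreatment)
  }
  structure(list(patient_id = as.character(patient_id),
                 times = as.numeric(times), burdens = as.numeric(burdens),
                 pretreatment = pretreatment,
                 histology = histology, cohort = cohort),
            class = "patient_series")
}

#' @export
print.patient_series <- function(x, ...) {
  cat(sprintf("patient %s (%s): %d on-treatment scans over %g d%s\n",
              x$patient_id,
              if (is.na(x$histology)) "histology NA" else x$histology,
              length(x$times), max(x$times),
              if (is.null(x$pretreatment)) ""
              else sprintf(", pretreatment at %g d", x$pretreatment[1])))
  invisible(x)
}

#' A named collection of patient series
#'
#' @param patients List of \code{\link{patient_series}} objects with
#'   unique patient ids.
#' @param name Cohort label.
#' @return An object of class \code{"cohort"}: a list with elements
#'   \code{patients} (named by patient id) and \code{name}.
#' @export
cohort <- function(patients, name = "cohort") {
  stopifnot(is.list(patients),
            all(vapply(patients, inherits, logical(1), "patient_series")))
  ids <- vapply(patients, function(p) p$patient_id, character(1))
  if (anyDuplicated(ids))
    stop("patient ids must be unique within a cohort")
  names(patients) <- ids
  structure(list(patients = patients, name = name), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort '%s': %d patients\n", x$name, length(x$patients)))
  invisible(x)
}

#' @export
length.cohort <- function(x) length(x$patients)

#' Sum lesion volumes into a per-scan total
#'
#' Converts lesion-level axis measurements for one patient into a total
#' indexed-lesion volume per scan time. Every indexed lesion must be
#' measured at every scan it appears in; a changing lesion set (for
#' example new lesions appearing mid-treatment) is rejected because the
#' indexed sum is then not comparable across scans.
#'
#' @param measurements data.frame with columns \code{scan_time_days},
#'   \code{lesion_id}, \code{long_axis_mm}, \code{short_axis_mm} (one
#'   patient's rows).
#' @return data.frame with columns \code{scan_time_days},
#'   \code{total_volume_mm3}, \code{n_lesions}, ordered by time.
#' @export
aggregate_burden <- function(measurements) {
  req <- c("scan_time_days", "lesion_id", "long_axis_mm", "short_axis_mm")
  if (!all(req %in% names(measurements)))
    stop("measurements must have columns: ", paste(req, collapse = ", "))
  if (nrow(measurements) == 0L)
    stop("no measurements")
  m <- measurements
  if (any(is.na(m$short_axis_mm))) {
    warning("missing short axis: using short = long (uniaxial report)")
    m$short_axis_mm[is.na(m$short_axis_mm)] <-
      m$long_axis_mm[is.na(m$short_axis_mm)]
  }
  if (any(m$long_axis_mm < m$short_axis_mm))
    stop("long axis must be >= short axis")
  lesions <- sort(unique(as.character(m$lesion_id)))
  times <- sort(unique(m$scan_time_days))
  tab <- table(m$scan_time_days, as.character(m$lesion_id))
  if (any(tab != 1L))
    stop("every indexed lesion must be measured exactly once at every scan; ",
         "fixed lesion set per patient is required")
  m$volume <- lesion_volume(m$long_axis_mm, m$short_axis_mm)
  vols <- tapply(m$volume, m$scan_time_days, sum)
  data.frame(scan_time_days = as.numeric(names(vols)),
             total_volume_mm3 = as.numeric(vols),
             n_lesions = length(lesions))[order(as.numeric(names(vols))), ,
                                          drop = FALSE]
}

#' Normalize a raw volume series to baseline
#'
#' Divides raw total volumes by the volume at t = 0 so the baseline
#' burden is exactly 1; a pretreatment scan (time < 0), if present, is
#' normalized by the same factor. Patients without a positive baseline
#' volume are rejected (mirroring clinical exclusion for missing
#' baseline measurements). Scans strictly between the pretreatment scan
#' and t = 0 are not part of the data model and are dropped with a
#' warning; only the scan immediately preceding the first dose is used
#' as the pretreatment point.
#'
#' @param times Numeric scan times in days (may include negatives).
#' @param volumes Raw total volumes, same length.
#' @param patient_id,histology,cohort Passed to
#'   \code{\link{patient_series}}.
#' @return A \code{\link{patient_series}}.
#' @export
normalize_series <- function(times, volumes, patient_id = "p",
                             histology = NA_character_,
                             cohort = NA_character_) {
  stopifnot(length(times) == length(volumes))
  o <- order(times)
  times <- times[o]; volumes <- volumes[o]
  i0 <- which(times == 0)
  if (length(i0) != 1L || !is.finite(volumes[i0]) || volumes[i0] <= 0)
    stop("patient ", patient_id,
         ": a scan at t = 0 with positive volume is required")
  pre_idx <- which(times < 0)
  pretreatment <- NULL
  if (length(pre_idx) > 0L) {
    if (length(pre_idx) > 1L)
      warning("patient ", patient_id, ": multiple pretreatment scans; ",
              "using the one immediately preceding t = 0")
    ip <- pre_idx[which.max(times[pre_idx])]
    pretreatment <- c(times[ip], volumes[ip] / volumes[i0])
  }
  on_idx <- which(times >= 0)
  patient_series(patient_id,
                 times = times[on_idx],
                 burdens = volumes[on_idx] / volumes[i0],
                 pretreatment = pretreatment,
                 histology = histology, cohort = cohort)
}

#' Build a cohort from lesion-level measurements
#'
#' Aggregates lesion volumes per scan, normalizes each patient to the
#' t = 0 baseline and assembles a \code{\link{cohort}}. Patients failing
#' baseline requirements are dropped and reported.
#'
#' @param lesions data.frame in the lesion-level dialect (columns
#'   \code{patient_id}, \code{scan_time_days}, \code{lesion_id},
#'   \code{long_axis_mm}, \code{short_axis_mm}).
#' @param metadata Optional list with \code{name} and a named
#'   \code{histology} map (patient_id -> label), as read by
#'   \code{\link{read_cohort_metadata}}.
#' @return A list with \code{cohort} and a character vector
#'   \code{excluded} of dropped patient ids.
#' @export
cohort_from_lesions <- function(lesions, metadata = NULL) {
  name <- if (!is.null(metadata$name)) metadata$name else "cohort"
  hist_map <- metadata$histology
  ids <- unique(as.character(lesions$patient_id))
  patients <- list()
  excluded <- character(0)
  for (id in ids) {
    rows <- lesions[as.character(lesions$patient_id) == id, , drop = FALSE]
    ps <- tryCatch({
      agg <- aggregate_burden(rows)
      normalize_series(agg$scan_time_days, agg$total_volume_mm3,
                       patient_id = id,
                       histology = if (!is.null(hist_map[[id]]))
                         hist_map[[id]] else NA_character_,
                       cohort = name)
    }, error = function(e) {
      warning("excluding patient ", id, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(ps)) excluded <- c(excluded, id) else
      patients[[length(patients) + 1L]] <- ps
  }
  list(cohort = cohort(patients, name = name), excluded = excluded)
}

#' Read / write the lesion-level CSV dialect
#'
#' @param path File path.
#' @return \code{read_lesion_csv}: data.frame with the five schema
#'   columns.
#' @export
read_lesion_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  req <- c("patient_id", "scan_time_days", "lesion_id",
           "long_axis_mm", "short_axis_mm")
  if (!all(req %in% names(df)))
    stop("lesion CSV must have columns: ", paste(req, collapse = ", "))
  df[req]
}

#' @rdname read_lesion_csv
#' @param lesions data.frame in the lesion-level schema.
#' @export
write_lesion_csv <- function(lesions, path) {
  req <- c("patient_id", "scan_time_days", "lesion_id",
           "long_axis_mm", "short_axis_mm")
  utils::write.csv(lesions[req], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write the burden-level CSV dialect
#'
#' Burden-level rows carry one normalized burden per patient and time;
#' pretreatment points are rows with negative \code{time_days}.
#'
#' @param path File path.
#' @param metadata Optional metadata list (see
#'   \code{\link{read_cohort_metadata}}).
#' @return \code{read_burden_csv}: a list with \code{cohort} and
#'   \code{excluded} (as \code{\link{cohort_from_lesions}}).
#' @export
read_burden_csv <- function(path, metadata = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  req <- c("patient_id", "time_days", "burden_norm")
  if (!all(req %in% names(df)))
    stop("burden CSV must have columns: ", paste(req, collapse = ", "))
  name <- if (!is.null(metadata$name)) metadata$name else "cohort"
  hist_map <- metadata$histology
  patients <- list(); excluded <- character(0)
  for (id in unique(as.character(df$patient_id))) {
    rows <- df[as.character(df$patient_id) == id, , drop = FALSE]
    rows <- rows[order(rows$time_days), , drop = FALSE]
    ps <- tryCatch({
      pre <- rows[rows$time_days < 0, , drop = FALSE]
      on <- rows[rows$time_days >= 0, , drop = FALSE]
      pretreatment <- if (nrow(pre) > 0L)
        c(pre$time_days[nrow(pre)], pre$burden_norm[nrow(pre)]) else NULL
      patient_series(id, on$time_days, on$burden_norm,
                     pretreatment = pretreatment,
                     histology = if (!is.null(hist_map[[id]]))
                       hist_map[[id]] else NA_character_,
                     cohort = name)
    }, error = function(e) {
      warning("excluding patient ", id, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(ps)) excluded <- c(excluded, id) else
      patients[[length(patients) + 1L]] <- ps
  }
  list(cohort = cohort(patients, name = name), excluded = excluded)
}

#' @rdname read_burden_csv
#' @param x A \code{\link{cohort}}.
#' @export
write_burden_csv <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  rows <- lapply(x$patients, function(p) {
    t <- p$times; b <- p$burdens
    if (!is.null(p$pretreatment)) {
      t <- c(p$pretreatment[1], t); b <- c(p$pretreatment[2], b)
    }
    data.frame(patient_id = p$patient_id, time_days = t, burden_norm = b)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  # full-precision round trip
  df$time_days <- format(df$time_days, digits = 17, trim = TRUE,
                         scientific = FALSE)
  df$burden_norm <- format(df$burden_norm, digits = 17, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write the cohort YAML metadata sidecar
#'
#' The sidecar carries the cohort name and a per-patient histology map.
#'
#' @param path File path.
#' @return A list with elements \code{name} and \code{histology}.
#' @export
read_cohort_metadata <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_cohort_metadata
#' @param metadata List with \code{name} and \code{histology}.
#' @export
write_cohort_metadata <- function(metadata, path) {
  yaml::write_yaml(metadata, path)
  invisible(path)
}
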