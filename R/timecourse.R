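#' Time-course dataset of internal concentrations
#'
#' The fitting target for all compartment models: a long-format table of
#' measured internal concentrations by replicate, phase, tissue and
#' pigmentation line. Times are hours since exposure start on one absolute
#' axis for both phases; the `phase` label, not a second time origin,
#' distinguishes uptake from depuration samples.
#'
#' @param data A data.frame with columns `replicate_id`, `phase`
#'   (`"uptake"`/`"depuration"`), `time_h`, `tissue` (`"whole"`, `"brain"`,
#'   `"eyes"` or `"trunk"`), `pigmentation` (`"WT"`, `"albino"` or `"PTU"`),
#'   `conc_mg_per_kg`.
#' @param t_uptake Optional uptake duration (h); when given, depuration rows
#'   must have `time_h > t_uptake`.
#' @return The validated data.frame with class `timecourse`.
#' @export
timecourse <- function(data, t_uptake = NULL) {
  required <- c("replicate_id", "phase", "time_h", "tissue",
                "pigmentation", "conc_mg_per_kg")
  missing <- setdiff(required, names(data))
  if (length(missing)) {
    stop_invalid("missing time-course columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(data) == 0L) stop_invalid("empty time-course dataset")
  bad_phase <- !data$phase %in% c("uptake", "depuration")
  if (any(bad_phase)) {
    stop_invalid("invalid phase at row(s) ", paste(which(bad_phase), collapse = ", "))
  }
  bad_tissue <- !data$tissue %in% c("whole", "brain", "eyes", "trunk")
  if (any(bad_tissue)) {
    stop_invalid("invalid tissue at row(s) ", paste(which(bad_tissue), collapse = ", "))
  }
  bad_pig <- !data$pigmentation %in% c("WT", "albino", "PTU")
  if (any(bad_pig)) {
    stop_invalid("invalid pigmentation at row(s) ", paste(which(bad_pig), collapse = ", "))
  }
  if (anyNA(data$time_h) || any(data$time_h < 0)) {
    stop_invalid("times must be non-negative at row(s) ",
                 paste(which(is.na(data$time_h) | data$time_h < 0), collapse = ", "))
  }
  bad_conc <- is.na(data$conc_mg_per_kg) | data$conc_mg_per_kg < 0
  if (any(bad_conc)) {
    stop_invalid("negative or missing concentration at row(s) ",
                 paste(which(bad_conc), collapse = ", "))
  }
  if (!is.null(t_uptake)) {
    bad_dep <- data$phase == "depuration" & data$time_h <= t_uptake
    if (any(bad_dep)) {
      stop_invalid("depuration rows must have time_h > t_uptake at row(s) ",
                   paste(which(bad_dep), collapse = ", "))
    }
  }
  key <- paste(data$replicate_id, data$time_h, data$tissue, data$pigmentation)
  if (anyDuplicated(key)) {
    stop_invalid("duplicate (replicate, time, tissue, pigmentation) at row(s) ",
                 paste(which(duplicated(key)), collapse = ", "))
  }
  ord <- order(data$replicate_id, data$tissue, data$time_h)
  data <- data[ord, required, drop = FALSE]
  rownames(data) <- NULL
  class(data) <- c("timecourse", "data.frame")
  data
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("<timecourse> %d records, %d replicate(s), tissues: %s\n",
              nrow(x), length(unique(x$replicate_id)),
              paste(sort(unique(x$tissue)), collapse = ", ")))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Read / write a time-course CSV
#'
#' The interchange format: comma-separated UTF-8 with header
#' `replicate_id, phase, time_h, tissue, pigmentation, conc_mg_per_kg`.
#' Malformed rows are reported with their row numbers.
#'
#' @param path Path to the CSV file.
#' @return [read_timecourse()]: a validated [timecourse()];
#'   [write_timecourse()]: `path`, invisibly.
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(data) == 0L) stop_invalid("empty time-course file: ", path)
  timecourse(data)
}

#' @rdname read_timecourse
#' @param x A [timecourse()] (or compatible data.frame).
#' @export
write_timecourse <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Pooled per-time means of one tissue series; internal workhorse for fitting.
pool_series <- function(data, tissue = "whole", phase = NULL) {
  rows <- data$tissue == tissue
  if (!is.null(phase)) rows <- rows & data$phase %in% phase
  d <- data[rows, , drop = FALSE]
  if (nrow(d) == 0L) return(data.frame(time_h = numeric(), conc = numeric()))
  agg <- stats::aggregate(conc_mg_per_kg ~ time_h, data = d, FUN = mean)
  names(agg) <- c("time_h", "conc")
  agg[order(agg$time_h), , drop = FALSE]
}
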