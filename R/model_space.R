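#' Timespan scheme for time-of-day group allocation
#'
#' Defines the six contiguous clock-time bins (covering 09:00--21:00) to which
#' subjects are allocated by their mid-scan time. Intervals are half-open
#' `[start, end)` except the last, which also contains 21:00, so boundary
#' times such as 11:00 fall into the later bin.
#'
#' @param boundaries Numeric vector of 7 increasing clock times in fractional
#'   hours; consecutive pairs delimit the six bins. Default `9, 11, ..., 21`.
#' @param labels Character vector of 6 bin labels.
#' @return An object of class `timespan_scheme` with elements `boundaries`
#'   and `labels`.
#' @examples
#' sch <- timespan_scheme()
#' allocate_timespan(c(9.5, 13, 21), sch)
#' @export
timespan_scheme <- function(boundaries = seq(9, 21, by = 2),
                            labels = sprintf("%02d:00-%02d:59",
                                             head(boundaries, -1),
                                             boundaries[-1] - 1L)) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) != 7L || any(diff(boundaries) <= 0))
    stop("`boundaries` must be 7 strictly increasing clock times", call. = FALSE)
  if (boundaries[1] != 9 || boundaries[7] != 21)
    stop("the scheme must cover 09:00-21:00", call. = FALSE)
  if (length(labels) != 6L)
    stop("`labels` must have 6 entries", call. = FALSE)
  structure(list(boundaries = boundaries, labels = as.character(labels)),
            class = "timespan_scheme")
}

#' Allocate subjects to timespans by mid-scan clock time
#'
#' @param mid_scan_time Numeric vector of clock times in fractional hours
#'   (e.g. 9.5 for 09:30). Must lie within 9--21.
#' @param scheme A [timespan_scheme()].
#' @return Integer vector of timespan indices in 1..6.
#' @export
allocate_timespan <- function(mid_scan_time, scheme = timespan_scheme()) {
  stopifnot(inherits(scheme, "timespan_scheme"))
  t <- as.numeric(mid_scan_time)
  bad <- !is.finite(t) | t < scheme$boundaries[1] | t > scheme$boundaries[7]
  if (any(bad))
    stop(sprintf("mid-scan time(s) %s outside the admissible window %g:00-%g:00",
                 paste(format(t[bad]), collapse = ", "),
                 scheme$boundaries[1], scheme$boundaries[7]), call. = FALSE)
  idx <- findInterval(t, scheme$boundaries, rightmost.closed = TRUE)
  as.integer(pmin(idx, 6L))
}

#' Time-effect column of a time-of-day model
#'
#' Returns the mean-centred 6-vector (one value per timespan) encoding the
#' hypothesised time-of-day profile:
#' models 1--6 a deviation for one single timespan; models 7--11 a deviation
#' over two adjacent timespans; models 12--17 phase-shifted sinusoids with one
#' full period over the six timespans (model 12 peaks at timespan 2, each
#' successive model peaks one timespan later, so model 15 is the inverted
#' waveform of model 12); model 18 the null model (all zeros).
#'
#' @param model_id Integer in 1..18.
#' @return Numeric 6-vector summing to zero.
#' @examples
#' time_effect_column(7)   # deviation over timespans 1-2
#' time_effect_column(18)  # null model
#' @export
time_effect_column <- function(model_id) {
  if (length(model_id) != 1L || !is.finite(model_id) ||
      model_id != round(model_id) || model_id < 1 || model_id > 18)
    stop("`model_id` must be a single integer in 1..18", call. = FALSE)
  model_id <- as.integer(model_id)
  if (model_id <= 6L) {
    v <- as.numeric(seq_len(6L) == model_id)
  } else if (model_id <= 11L) {
    v <- as.numeric(seq_len(6L) %in% c(model_id - 6L, model_id - 5L))
  } else if (model_id <= 17L) {
    # one full period over 6 bins; model 12 peaks at timespan 2
    phase <- model_id - 12L
    v <- cos(2 * pi * (seq_len(6L) - 2L - phase) / 6)
  } else {
    v <- rep(0, 6L)
  }
  v - mean(v)
}

#' Build one second-level design matrix
#'
#' Constructs the 12-row design (rows ordered timespan-major:
#' (t1,LR),(t1,RL),...,(t6,RL)) with one column for the overall mean, one
#' mean-centred time-effect column, and five sum-to-zero effects-coded columns
#' for the timespan factor. The LR and RL rows of a timespan are identical, so
#' the two sessions are averaged through the common design.
#'
#' @param model_id Integer in 1..18.
#' @param scheme A [timespan_scheme()] (labels used for row names).
#' @return An object of class `tod_design`: list with `model_id`, `matrix`
#'   (12 x 7), `column_names`, `time_column` (the 6-vector), `scheme`.
#' @export
build_design_matrix <- function(model_id, scheme = timespan_scheme()) {
  tc <- time_effect_column(model_id)
  # sum-to-zero effects coding of the 6-level timespan factor (5 columns)
  eff <- stats::contr.sum(6)
  X6 <- cbind(mean = 1, time = tc, eff)
  rows <- rep(seq_len(6L), each = 2L)
  X <- X6[rows, , drop = FALSE]
  cn <- c("mean", "time", paste0("timespan", 1:5))
  colnames(X) <- cn
  rownames(X) <- paste0("t", rows, c("_LR", "_RL"))
  structure(list(model_id = as.integer(model_id), matrix = X,
                 column_names = cn, time_column = tc, scheme = scheme),
            class = "tod_design")
}

#' Enumerate the 18-model time-of-day hypothesis space
#'
#' @param scheme A [timespan_scheme()].
#' @return An object of class `tod_model_space`: list of 18 [build_design_matrix()]
#'   results plus the scheme.
#' @export
enumerate_model_space <- function(scheme = timespan_scheme()) {
  designs <- lapply(1:18, build_design_matrix, scheme = scheme)
  cols <- vapply(designs, function(d) ncol(d$matrix), integer(1))
  stopifnot(length(designs) == 18L, all(cols == cols[1]))
  structure(list(designs = designs, scheme = scheme), class = "tod_model_space")
}

#' @export
print.tod_model_space <- function(x, ...) {
  cat("Time-of-day model space: 18 designs over", length(x$scheme$labels),
      "timespans x 2 sessions\n")
  invisible(x)
}

#' Tidy a design matrix into a long tibble
#'
#' @param x A `tod_design`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `timespan`, `session`, one column per
#'   design column.
#' @export
tidy.tod_design <- function(x, ...) {
  tb <- tibble::as_tibble(x$matrix)
  tb$row <- rownames(x$matrix)
  tb$timespan <- rep(seq_len(6L), each = 2L)
  tb$session <- rep(c("LR", "RL"), 6L)
  dplyr::select(tb, "row", "timespan", "session", dplyr::everything())
}

#' Export a design matrix to delimited text or JSON
#'
#' @param x A `tod_design`.
#' @param path Output file path; format chosen by extension (`.json` or
#'   anything else for tab-delimited text).
#' @return `path`, invisibly.
#' @export
write_design <- function(x, path) {
  stopifnot(inherits(x, "tod_design"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(model_id = x$model_id, column_names = x$column_names,
           matrix = unname(apply(x$matrix, 1, as.numeric, simplify = FALSE))),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(x$matrix, path, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  invisible(path)
}
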