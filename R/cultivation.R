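CULTIVATION_REQUIRED <- c("time_h", "dcw_g_l", "xylose_g_l")
CULTIVATION_OPTIONAL <- c("xylitol_g_l", "arabitol_g_l", "glucose_g_l",
                          "carotenoid_mg_l", "lipid_g_l", "co2_mmol_l_h",
                          "nh4_g_l")

#' Construct a cultivation time series
#'
#' A `cultivation_series` holds the time-resolved off-line measurements of one
#' batch cultivation: dry cell weight, extracellular sugar and polyol
#' concentrations, intracellular product titres and (optionally) CO2
#' evolution and residual ammonium.
#'
#' @param samples data frame with column `time_h` (strictly increasing),
#'   `dcw_g_l`, `xylose_g_l`, and optionally the columns named in the TSV
#'   schema (`xylitol_g_l`, `arabitol_g_l`, `glucose_g_l`, `carotenoid_mg_l`,
#'   `lipid_g_l`, `co2_mmol_l_h`, `nh4_g_l`).
#' @param condition_label condition name, e.g. `"REF"`.
#' @param replicate replicate index.
#' @return object of class `cultivation_series`.
#' @export
cultivation_series <- function(samples, condition_label = "REF", replicate = 1L) {
  stopifnot(is.data.frame(samples))
  miss <- setdiff(CULTIVATION_REQUIRED, names(samples))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(samples) < 4L) stop("a cultivation series needs at least 4 samples")
  dt <- diff(samples$time_h)
  if (any(dt <= 0)) {
    stop("time not strictly increasing at row ", which(dt <= 0)[1] + 1L)
  }
  conc_cols <- intersect(c(CULTIVATION_REQUIRED[-1], CULTIVATION_OPTIONAL),
                         names(samples))
  for (cc in conc_cols) {
    bad <- which(!is.na(samples[[cc]]) & samples[[cc]] < 0)
    if (length(bad)) {
      stop("negative value in column '", cc, "' at row ", bad[1])
    }
  }
  keep <- intersect(c(CULTIVATION_REQUIRED, CULTIVATION_OPTIONAL), names(samples))
  out <- list(
    condition_label = condition_label,
    replicate = as.integer(replicate),
    samples = samples[, keep, drop = FALSE]
  )
  class(out) <- "cultivation_series"
  out
}

#' Read a cultivation time series from TSV
#'
#' Expects a tab-separated, dot-decimal UTF-8 table with a mandatory header.
#' Missing optional columns yield absent fields, not zeros.
#'
#' @param path path to the TSV file.
#' @param condition_label,replicate metadata attached to the series.
#' @return a [cultivation_series()].
#' @export
read_cultivation <- function(path, condition_label = "REF", replicate = 1L) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = TRUE, fileEncoding = "UTF-8")
  cultivation_series(tab, condition_label = condition_label,
                     replicate = replicate)
}

#' Write a cultivation series to TSV
#'
#' @param series a [cultivation_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cultivation <- function(series, path) {
  stopifnot(inherits(series, "cultivation_series"))
  utils::write.table(series$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.cultivation_series <- function(x, ...) {
  s <- x$samples
  cat("Cultivation series: condition", x$condition_label,
      "replicate", x$replicate, "\n")
  cat(sprintf("  %d samples spanning %.1f-%.1f h\n", nrow(s),
              min(s$time_h), max(s$time_h)))
  cat(sprintf("  DCW %.2f -> %.2f g/L; xylose %.1f -> %.1f g/L\n",
              s$dcw_g_l[1], s$dcw_g_l[nrow(s)],
              s$xylose_g_l[1], s$xylose_g_l[nrow(s)]))
  invisible(x)
}

# linear interpolation of the time at which column `col` crosses `value`
series_crossing_time <- function(samples, col, value, rising = FALSE) {
  y <- samples[[col]]
  t <- samples$time_h
  ok <- !is.na(y)
  y <- y[ok]; t <- t[ok]
  if (rising) {
    idx <- which(y[-1] >= value & y[-length(y)] < value)
  } else {
    idx <- which(y[-1] < value & y[-length(y)] >= value)
  }
  if (length(idx) == 0L) return(NA_real_)
  i <- idx[1]
  t[i] + (value - y[i]) * (t[i + 1] - t[i]) / (y[i + 1] - y[i])
}
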