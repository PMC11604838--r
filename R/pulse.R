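#' Complex RF pulse on a uniform time raster
#'
#' An RF pulse is a piecewise-constant complex waveform: `re` and `im` hold
#' the two field components in microtesla, one value per dwell.
#'
#' @param re real channel (uT), or a complex vector (then `im` must be NULL).
#' @param im imaginary channel (uT); defaults to zeros.
#' @param dwell seconds per sample (> 0).
#' @return an object of class `rf_pulse` with fields `re`, `im`, `dwell`, `n`.
#' @export
rf_pulse <- function(re, im = NULL, dwell) {
  if (is.complex(re)) {
    stopifnot(is.null(im))
    im <- Im(re)
    re <- Re(re)
  }
  if (is.null(im)) im <- numeric(length(re))
  re <- as.numeric(re)
  im <- as.numeric(im)
  n <- length(re)
  if (n < 1L) stop("an RF pulse needs at least one sample")
  if (length(im) != n) stop("re and im must have equal length")
  if (!is.numeric(dwell) || length(dwell) != 1L || !is.finite(dwell) || dwell <= 0)
    stop("dwell must be a single positive number (seconds)")
  if (!all(is.finite(re)) || !all(is.finite(im)))
    stop("non-finite RF sample rejected")
  structure(list(re = re, im = im, dwell = dwell, n = n),
            class = "rf_pulse")
}

#' @export
print.rf_pulse <- function(x, ...) {
  cat(sprintf("<rf_pulse> %d samples, dwell %.4g us, duration %.4g ms, peak %.4g uT\n",
              x$n, x$dwell * 1e6, x$n * x$dwell * 1e3, pulse_peak(x)))
  invisible(x)
}

#' Pulse duration in seconds
#' @param rf an `rf_pulse`.
#' @export
pulse_duration <- function(rf) rf$n * rf$dwell

#' Peak complex magnitude of a pulse (uT)
#' @param rf an `rf_pulse`.
#' @export
pulse_peak <- function(rf) max(sqrt(rf$re^2 + rf$im^2))

#' Scale a pulse to a requested peak amplitude
#' @param rf an `rf_pulse`.
#' @param b1max desired peak magnitude (uT).
#' @export
pulse_scale_to_peak <- function(rf, b1max) {
  p <- pulse_peak(rf)
  if (p == 0) stop("cannot rescale an all-zero pulse")
  rf_pulse(rf$re * b1max / p, rf$im * b1max / p, rf$dwell)
}

#' Concatenate two pulses sharing a raster
#' @param a,b `rf_pulse` objects with equal dwell.
#' @export
pulse_concat <- function(a, b) {
  if (a$dwell != b$dwell) stop("dwell mismatch in pulse concatenation")
  rf_pulse(c(a$re, b$re), c(a$im, b$im), a$dwell)
}

#' Per-axis gradient waveform paired with an RF raster
#'
#' @param g numeric matrix (samples x axes, 1-3 axes) or vector, in mT/m.
#' @param dwell seconds per sample.
#' @param gmax,smax optional hardware bounds (mT/m, T/m/s); when given, the
#'   waveform is validated against them.
#' @return object of class `grad_waveform`.
#' @export
gradient_waveform <- function(g, dwell, gmax = NA_real_, smax = NA_real_) {
  if (is.vector(g)) g <- matrix(g, ncol = 1L)
  g <- as.matrix(g)
  if (ncol(g) < 1L || ncol(g) > 3L) stop("gradients must have 1-3 axes")
  if (!all(is.finite(g))) stop("non-finite gradient sample rejected")
  if (dwell <= 0) stop("dwell must be positive")
  gw <- structure(list(g = g, dwell = dwell, n = nrow(g),
                       gmax = gmax, smax = smax),
                  class = "grad_waveform")
  check_gradient_limits(gw)
  gw
}

check_gradient_limits <- function(gw, tol = 1e-9) {
  if (is.finite(gw$gmax)) {
    mx <- max(abs(gw$g))
    if (mx > gw$gmax * (1 + tol))
      stop(sprintf("gradient amplitude %.4g mT/m exceeds gmax = %.4g mT/m",
                   mx, gw$gmax))
  }
  if (is.finite(gw$smax) && gw$n > 1L) {
    # inter-sample slew in T/m/s (the rise from zero at the waveform edges is
    # the business of prepend_balanced_ramp, not of the raster itself)
    sl <- max(abs(diff(gw$g))) / gw$dwell / 1000
    if (sl > gw$smax * (1 + 1e-6))
      stop(sprintf("gradient slew %.4g T/m/s exceeds smax = %.4g T/m/s",
                   sl, gw$smax))
  }
  invisible(TRUE)
}

#' @export
print.grad_waveform <- function(x, ...) {
  cat(sprintf("<grad_waveform> %d samples x %d axes, dwell %.4g us, max |G| %.4g mT/m\n",
              x$n, ncol(x$g), x$dwell * 1e6, max(abs(x$g))))
  invisible(x)
}

# ---- plain-text waveform files -------------------------------------------
# Header lines '# dwell_s=<float>' and '# units=uT' (or mT/m), then one
# whitespace-separated row per sample. Samples are written with 17
# significant digits, which round-trips doubles exactly (and in particular
# preserves 12 significant digits).

#' Write / read an RF pulse as plain text
#' @param rf an `rf_pulse`.
#' @param path file path.
#' @export
write_pulse <- function(rf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dwell_s=%.17g", rf$dwell), con)
  writeLines("# units=uT", con)
  writeLines(sprintf("%.17g %.17g", rf$re, rf$im), con)
  invisible(path)
}

#' @rdname write_pulse
#' @export
read_pulse <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  dw <- sub("^# *dwell_s=", "", grep("dwell_s=", hdr, value = TRUE)[1])
  if (is.na(dw)) stop("pulse file lacks a '# dwell_s=' header: ", path)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  vals <- lapply(seq_along(body), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "[[:space:]]+")[[1]]))
    if (length(v) != 2L || anyNA(v))
      stop(sprintf("malformed pulse file %s at line %d", path,
                   which(lines == body[i])[1]))
    v
  })
  m <- do.call(rbind, vals)
  rf_pulse(m[, 1], m[, 2], as.numeric(dw))
}

#' Write / read a gradient waveform as plain text
#' @param gw a `grad_waveform`.
#' @param path file path.
#' @export
write_gradient <- function(gw, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dwell_s=%.17g", gw$dwell), con)
  writeLines("# units=mT/m", con)
  if (is.finite(gw$gmax)) writeLines(sprintf("# gmax=%.12g", gw$gmax), con)
  if (is.finite(gw$smax)) writeLines(sprintf("# smax=%.12g", gw$smax), con)
  writeLines(apply(gw$g, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_gradient
#' @export
read_gradient <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    h <- grep(paste0(key, "="), hdr, value = TRUE)
    if (!length(h)) return(NA_real_)
    as.numeric(sub(paste0("^# *", key, "="), "", h[1]))
  }
  dw <- getv("dwell_s")
  if (is.na(dw)) stop("gradient file lacks a '# dwell_s=' header: ", path)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(body, function(s)
    as.numeric(strsplit(trimws(s), "[[:space:]]+")[[1]])))
  gradient_waveform(m, dw, gmax = getv("gmax"), smax = getv("smax"))
}
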