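#' Read a radiocarbon calibration curve
#'
#' Reads the standard IntCal-style comma-separated layout: comment lines
#' starting with `#`, then rows of `CAL BP, 14C age, Error` (further
#' columns ignored). Knots are stored sorted by ascending calendar age;
#' calendar ages must be strictly monotone and curve errors positive.
#' Linear interpolation between knots is exposed via the fitted curve
#' object.
#'
#' @param path Curve file (`.14c`-style CSV).
#' @return An object of class `calibration_curve`: list with `cal_bp`,
#'   `c14_age`, `sigma_curve` (equal-length numeric vectors).
#' @export
read_calcurve <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  if (!length(ln)) stop("format error: no data rows in curve file")
  # tolerate a single non-numeric header row
  first <- strsplit(ln[1], ",")[[1]]
  if (suppressWarnings(anyNA(as.numeric(first[1:3])))) ln <- ln[-1]
  df <- utils::read.csv(text = paste(ln, collapse = "\n"), header = FALSE)
  if (ncol(df) < 3L)
    stop("format error: curve needs columns CAL BP, 14C age, Error")
  calibration_curve(df[[1]], df[[2]], df[[3]])
}

#' Construct a calibration curve from vectors
#'
#' @param cal_bp Calendar ages (years BP), strictly monotone.
#' @param c14_age Conventional radiocarbon age at each knot.
#' @param sigma_curve Curve 1-sigma at each knot (> 0).
#' @return A `calibration_curve`.
#' @export
calibration_curve <- function(cal_bp, c14_age, sigma_curve) {
  cal_bp <- as.numeric(cal_bp); c14_age <- as.numeric(c14_age)
  sigma_curve <- as.numeric(sigma_curve)
  if (length(cal_bp) != length(c14_age) ||
      length(cal_bp) != length(sigma_curve))
    stop("format error: curve columns have unequal lengths")
  d <- diff(cal_bp)
  if (!(all(d > 0) || all(d < 0)))
    stop("format error: cal BP grid is not strictly monotone")
  if (any(sigma_curve <= 0))
    stop("format error: curve sigma must be > 0")
  o <- order(cal_bp)
  structure(list(cal_bp = cal_bp[o], c14_age = c14_age[o],
                 sigma_curve = sigma_curve[o]),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %d knots, %0.f-%0.f cal BP\n",
              length(x$cal_bp), min(x$cal_bp), max(x$cal_bp)))
  invisible(x)
}

# linear interpolation of curve mean and sigma at calendar ages theta
curve_at <- function(curve, theta) {
  list(mu = stats::approx(curve$cal_bp, curve$c14_age, theta)$y,
       sigma = stats::approx(curve$cal_bp, curve$sigma_curve, theta)$y)
}

#' Calibrate a radiocarbon determination
#'
#' Computes the posterior density over calendar age on a 1-year grid:
#' `density(theta) proportional to
#' exp(-(c14_age - mu(theta))^2 / (2 (c14_err^2 + sigma_curve(theta)^2)))`
#' with the curve mean and error linearly interpolated between knots,
#' then normalised to sum to one over the grid. Measurement-side
#' corrections (background subtraction, added external error) are
#' assumed already folded into the reported age and error; no reservoir
#' adjustment is applied. Deterministic.
#'
#' @param c14_age Conventional radiocarbon age (14C BP).
#' @param c14_err Its 1-sigma error (> 0).
#' @param curve A `calibration_curve`.
#' @param window Optional calendar window `c(a, b)` (years BP, any
#'   order) to evaluate on; default the full curve span.
#' @return An object of class `calibrated_date`: list with `theta_grid`
#'   (ascending cal BP), `density` (sums to 1), `c14_age`, `c14_err`.
#' @export
calibrate_date <- function(c14_age, c14_err, curve, window = NULL) {
  if (c14_err <= 0) stop("c14_err must be > 0")
  span <- range(curve$cal_bp)
  if (is.null(window)) window <- span
  window <- sort(as.numeric(window))
  if (window[1] < span[1] || window[2] > span[2])
    stop("range error: window outside the calibration curve span")
  theta <- seq(ceiling(window[1]), floor(window[2]), by = 1)
  cv <- curve_at(curve, theta)
  v <- c14_err^2 + cv$sigma^2
  logd <- -(c14_age - cv$mu)^2 / (2 * v)
  d <- exp(logd - max(logd))
  d <- d / sum(d)
  structure(list(theta_grid = theta, density = d, c14_age = c14_age,
                 c14_err = c14_err),
            class = "calibrated_date")
}

#' @export
print.calibrated_date <- function(x, ...) {
  h <- hpd_interval(x, 0.682)
  cat(sprintf("<calibrated_date> %0.f +/- %0.f 14C BP\n", x$c14_age,
              x$c14_err))
  cat("  68.2% HPD ranges (cal BP):\n")
  for (i in seq_len(nrow(h)))
    cat(sprintf("    %0.f to %0.f (%.1f%%)\n", h$old[i], h$young[i],
                100 * h$mass[i]))
  invisible(x)
}

#' @method plot calibrated_date
#' @export
plot.calibrated_date <- function(x, mass = 0.682, ...) {
  graphics::plot(x$theta_grid, x$density, type = "l",
                 xlim = rev(range(x$theta_grid)),
                 xlab = "calendar age (cal BP)",
                 ylab = "posterior density", ...)
  h <- hpd_interval(x, mass)
  for (i in seq_len(nrow(h))) {
    sel <- x$theta_grid <= h$old[i] & x$theta_grid >= h$young[i]
    graphics::polygon(c(x$theta_grid[sel], rev(x$theta_grid[sel])),
                      c(x$density[sel], numeric(sum(sel))),
                      col = "grey80", border = NA)
  }
  graphics::lines(x$theta_grid, x$density)
  invisible(x)
}

#' Highest posterior density ranges of a calibrated date
#'
#' Accumulates grid points by descending density until the requested
#' mass is reached, then merges adjacent grid points into contiguous
#' calendar ranges. The result is the smallest set of grid points whose
#' mass is at least `mass`, reported oldest-first as
#' `(old bound, young bound, mass)` per range — possibly several
#' disjoint ranges when the calibration curve makes the posterior
#' multimodal.
#'
#' @param cal A `calibrated_date`.
#' @param mass Total posterior mass to cover (default 0.682).
#' @return A data frame of class `hpd_ranges` with columns `old`,
#'   `young`, `mass`, ordered oldest range first.
#' @export
hpd_interval <- function(cal, mass = 0.682) {
  stopifnot(mass > 0, mass < 1)
  ord <- order(cal$density, decreasing = TRUE)
  cum <- cumsum(cal$density[ord])
  k <- which(cum >= mass)[1]
  sel <- sort(ord[seq_len(k)])
  brk <- c(0L, which(diff(sel) > 1L), length(sel))
  out <- do.call(rbind, lapply(seq_len(length(brk) - 1L), function(i) {
    idx <- sel[(brk[i] + 1L):brk[i + 1L]]
    data.frame(old = max(cal$theta_grid[idx]),
               young = min(cal$theta_grid[idx]),
               mass = sum(cal$density[idx]))
  }))
  out <- out[order(-out$old), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hpd_ranges", "data.frame")
  out
}

#' Collagen quality screening for radiocarbon dating
#'
#' The standard pass rule for bone collagen: more than 1% collagen by
#' weight and an atomic C:N ratio between 2.9 and 3.6 inclusive. Samples
#' failing either criterion are flagged with the reason.
#'
#' @param yield_pct Collagen yield, percent of starting weight.
#' @param c_n Atomic C:N ratio.
#' @return An object of class `collagen_qc`: list with `yield_pct`,
#'   `c_n`, `passed`, `reasons` (character vector, empty when passed).
#' @export
collagen_qc <- function(yield_pct, c_n) {
  stopifnot(yield_pct >= 0, c_n >= 0)
  reasons <- character(0)
  if (!(yield_pct > 1))
    reasons <- c(reasons, sprintf(
      "collagen yield %.2f%% not above the 1%% threshold", yield_pct))
  if (!(c_n >= 2.9 && c_n <= 3.6))
    reasons <- c(reasons, sprintf(
      "C:N ratio %.2f outside the accepted range 2.9-3.6", c_n))
  structure(list(yield_pct = yield_pct, c_n = c_n,
                 passed = length(reasons) == 0L, reasons = reasons),
            class = "collagen_qc")
}

#' @export
print.collagen_qc <- function(x, ...) {
  cat(sprintf("<collagen_qc> yield %.2f%%, C:N %.2f: %s\n", x$yield_pct,
              x$c_n, if (x$passed) "PASS" else "FAIL"))
  for (r in x$reasons) cat("  -", r, "\n")
  invisible(x)
}
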