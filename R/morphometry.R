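# Cortical width measurement: upper-border extraction, polynomial border
# model selected by cross-validated least squares, and width profiling along
# the inward normal of the border tangent.

#' Upper border of a cortical mask
#'
#' For every column containing foreground, the topmost (minimum-row)
#' foreground pixel. Columns without foreground are omitted. Coordinates are
#' 0-based.
#'
#' @param mask a [cortical_mask] (or 0/1 matrix).
#' @return data.frame with columns `col`, `row` (0-based), ordered by `col`.
#' @export
upper_border <- function(mask) {
  m <- if (inherits(mask, "cortical_mask")) mask$pixels else mask
  if (sum(m) == 0) stop("empty mask: no upper border")
  cols <- which(colSums(m) > 0)
  rows <- vapply(cols, function(cc) which(m[, cc] > 0)[1L], numeric(1))
  data.frame(col = cols - 1L, row = rows - 1L)
}

fit_poly_lsq <- function(col, row, degree) {
  # centred/scaled design keeps degree-5 fits on pixel columns well
  # conditioned; coefficients are mapped back to raw column powers
  mu <- mean(col); sc <- max(stats::sd(col), 1e-9)
  z <- (col - mu) / sc
  X <- outer(z, 0:degree, `^`)
  beta <- qr.coef(qr(X), row)
  beta[is.na(beta)] <- 0
  # expand in (col - mu)/sc: polynomial in raw col via binomial expansion
  raw <- rep(0, degree + 1L)               # ascending powers of col
  for (j in 0:degree) {
    bj <- beta[j + 1L] / sc^j
    for (i in 0:j) {
      raw[i + 1L] <- raw[i + 1L] + bj * choose(j, i) * (-mu)^(j - i)
    }
  }
  rev(raw)                                 # highest degree first
}

#' Fit the border polynomial with cross-validated degree selection
#'
#' For each candidate degree a least-squares polynomial `row ~ col` is
#' fitted; the selected degree minimizes 5-fold cross-validated squared
#' error (folds assigned cyclically in column order, a fixed assignment).
#' Near-ties go to the lower degree, so exact low-order data never selects
#' a redundant higher degree.
#'
#' @param points data.frame with `col`, `row` (as from [upper_border]).
#' @param candidate_degrees integer degrees to consider (default `1:5`).
#' @return A `border_curve`: `coefficients` (highest degree first),
#'   `degree`, `domain` `(col_min, col_max)`, and `sse` of the selected
#'   full-data fit.
#' @export
fit_border_polynomial <- function(points, candidate_degrees = 1:5) {
  points <- points[order(points$col), , drop = FALSE]
  n <- nrow(points)
  if (n < max(candidate_degrees) + 1L)
    stop(sprintf("need at least %d border points for degree %d, got %d",
                 max(candidate_degrees) + 1L, max(candidate_degrees), n))
  if (length(unique(points$col)) < 2L) stop("need >= 2 distinct columns")
  k <- 5L
  fold <- ((seq_len(n) - 1L) %% k) + 1L
  cv_err <- vapply(candidate_degrees, function(d) {
    errs <- 0
    for (f in seq_len(k)) {
      tr <- fold != f
      if (sum(tr) < d + 1L) return(Inf)
      cf <- fit_poly_lsq(points$col[tr], points$row[tr], d)
      pred <- polyval_desc(cf, points$col[!tr])
      errs <- errs + sum((points$row[!tr] - pred)^2)
    }
    errs / n
  }, numeric(1))
  # near-tie tolerance: prefer the simplest degree among indistinguishable fits
  tol <- 1e-8 * max(1, min(cv_err[is.finite(cv_err)]))
  ok <- which(cv_err <= min(cv_err) + tol)
  sel <- ok[which.min(candidate_degrees[ok])]
  d <- candidate_degrees[sel]
  cf <- fit_poly_lsq(points$col, points$row, d)
  sse <- sum((points$row - polyval_desc(cf, points$col))^2)
  structure(list(coefficients = cf, degree = d,
                 domain = c(min(points$col), max(points$col)),
                 sse = sse, cv_error = stats::setNames(cv_err,
                   paste0("degree", candidate_degrees))),
            class = "border_curve")
}

#' @export
print.border_curve <- function(x, ...) {
  cat(sprintf("<border_curve degree=%d domain=[%g, %g] sse=%.3g>\n",
              x$degree, x$domain[1], x$domain[2], x$sse))
  invisible(x)
}

#' Width profile perpendicular to the border tangent
#'
#' Samples the border curve across the central `1 - 2*margin_frac` of its
#' column domain. At each sample the tangent slope is the analytic
#' derivative of the polynomial; the profiler marches from the border point
#' along the inward (downward) unit normal in 0.25 px steps with
#' nearest-neighbour mask lookup until it leaves the foreground. The width
#' is the distance travelled (midpoint-corrected for the half-pixel at the
#' entry border). Samples starting on background or whose normal exits the
#' image are skipped.
#'
#' @param mask a [cortical_mask].
#' @param curve a `border_curve`.
#' @param margin_frac fraction of the domain excluded at each side
#'   (default 0.1).
#' @param step column sampling interval in px (default 1).
#' @return A `width_profile`: data.frame `samples` (`col`, `width`), and
#'   `min_width`, `max_width`, `avg_width`.
#' @export
width_profile <- function(mask, curve, margin_frac = 0.1, step = 1) {
  if (margin_frac < 0 || margin_frac >= 0.5) stop("margin_frac must be in [0, 0.5)")
  m <- if (inherits(mask, "cortical_mask")) mask$pixels else mask
  nr <- nrow(m); nc <- ncol(m)
  dom <- curve$domain
  span <- dom[2] - dom[1]
  lo <- dom[1] + margin_frac * span
  hi <- dom[2] - margin_frac * span
  cols <- seq(lo, hi, by = step)
  dcf <- polyderiv_desc(curve$coefficients)
  samples <- lapply(cols, function(cc) {
    r0 <- polyval_desc(curve$coefficients, cc)
    slope <- polyval_desc(dcf, cc)
    nrm <- c(-slope, 1) / sqrt(1 + slope^2)   # (dcol, drow), inward = down
    # nearest-neighbour lookup at the start point
    ri <- round_half_up(r0) + 1; ci <- round_half_up(cc) + 1
    if (ri < 1 || ri > nr || ci < 1 || ci > nc || m[ri, ci] == 0)
      return(NULL)
    t <- 0
    repeat {
      t <- t + 0.25
      r <- r0 + t * nrm[2]; c2 <- cc + t * nrm[1]
      ri <- round_half_up(r) + 1; ci <- round_half_up(c2) + 1
      if (ri < 1 || ri > nr || ci < 1 || ci > nc)
        return(NULL)                          # ran off the image: skip sample
      if (m[ri, ci] == 0)
        return(data.frame(col = cc, width = t + 0.25))
    }
  })
  samples <- do.call(rbind, samples)
  if (is.null(samples) || nrow(samples) < 3L)
    stop("profile too sparse: fewer than 3 retained width samples")
  structure(list(samples = samples,
                 min_width = min(samples$width),
                 max_width = max(samples$width),
                 avg_width = mean(samples$width)),
            class = "width_profile")
}

#' @export
print.width_profile <- function(x, ...) {
  cat(sprintf("<width_profile n=%d min=%.2f max=%.2f avg=%.2f px>\n",
              nrow(x$samples), x$min_width, x$max_width, x$avg_width))
  invisible(x)
}

#' Measure one side's cortical width summary
#'
#' Composition of [upper_border], [fit_border_polynomial] (candidate degrees
#' 1-5) and [width_profile] (10% margins, 1 px sampling).
#'
#' @param roi the side's [roi_image] (carried for provenance; widths depend
#'   only on the mask).
#' @param mask the side's [cortical_mask].
#' @return Named list `min`, `max`, `avg` (px) plus the underlying `curve`
#'   and `profile`.
#' @export
measure_side <- function(roi, mask) {
  border <- upper_border(mask)
  curve <- fit_border_polynomial(border, candidate_degrees = 1:5)
  prof <- width_profile(mask, curve, margin_frac = 0.1, step = 1)
  list(min = prof$min_width, max = prof$max_width, avg = prof$avg_width,
       curve = curve, profile = prof)
}
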