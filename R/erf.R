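#' Exposure-response function parameters
#'
#' Holds the (Prodmean, Prodsd) pair per work intensity for the normal-CDF
#' exposure-response model: the fraction of work time lost at a given WBGT
#' is the normal CDF with mean `Prodmean` and standard deviation `Prodsd`.
#' The three metabolic-rate classes are 200 W (light work, service), 300 W
#' (moderate, manufacturing) and 400 W (heavy, agriculture and
#' construction). Physically sensible parameter sets have
#' `Prodmean(400) <= Prodmean(300) <= Prodmean(200)`: heavier work starts
#' losing productivity at lower WBGT.
#'
#' @param prodmean,prodsd numeric length-3 vectors for intensities
#'   (200, 300, 400) W, in degC; `prodsd` must be positive.
#' @param provenance label recording where the parameters came from:
#'   `"standard-fit"`, `"global-anchor"` or `"calibrated"`.
#' @return data frame of class `erf_params` with columns `intensity_w`,
#'   `prodmean`, `prodsd` and attribute `provenance`.
#' @export
erf_params <- function(prodmean, prodsd,
                       provenance = c("standard-fit", "global-anchor",
                                      "calibrated")) {
  provenance <- match.arg(provenance)
  out <- data.frame(intensity_w = c(200, 300, 400),
                    prodmean = as.numeric(prodmean),
                    prodsd = as.numeric(prodsd))
  attr(out, "provenance") <- provenance
  class(out) <- c("erf_params", "data.frame")
  validate_erf_params(out)
}

#' @rdname erf_params
#' @param params object to validate.
#' @export
validate_erf_params <- function(params) {
  if (!inherits(params, "erf_params")) stop("not an erf_params object")
  if (!all(c(200, 300, 400) %in% params$intensity_w))
    stop("all three intensities (200, 300, 400 W) must be present")
  if (any(!is.finite(params$prodmean))) stop("prodmean must be finite")
  if (any(params$prodsd <= 0)) stop("prodsd must be > 0")
  m <- params$prodmean[match(c(400, 300, 200), params$intensity_w)]
  if (is.unsorted(m))
    warning("prodmean not ordered 400 <= 300 <= 200 W; ",
            "heavier work should lose productivity at lower WBGT")
  params
}

.erf_lookup <- function(params, intensity) {
  i <- match(intensity, params$intensity_w)
  if (is.na(i)) stop("unknown work intensity: ", intensity,
                     " (must be 200, 300 or 400 W)")
  params[i, ]
}

#' Fraction of work time lost at a given WBGT
#'
#' The exposure-response function
#' \deqn{Loss = \tfrac12\left[1 + \mathrm{erf}\!\left(\frac{WBGT - Prodmean}{Prodsd\sqrt 2}\right)\right]}
#' i.e. the normal CDF with mean `Prodmean` and sd `Prodsd` evaluated at
#' the WBGT, per work intensity. Strictly increasing in WBGT, 0.5 at the
#' midpoint, with limits 0 and 1.
#'
#' @param wbgt WBGT values, degC (vector or array).
#' @param intensity one of 200, 300, 400 (W).
#' @param params an [erf_params()] object.
#' @return loss fraction in (0, 1), same shape as `wbgt`.
#' @export
loss_fraction <- function(wbgt, intensity, params) {
  p <- .erf_lookup(params, intensity)
  stats::pnorm(wbgt, mean = p$prodmean, sd = p$prodsd)
}

#' Fit normal-CDF exposure-response curves to a work/rest table
#'
#' Per work intensity, finds (Prodmean, Prodsd) minimizing the sum of
#' squared residuals between the observed loss fraction
#' `1 - work_fraction` and the normal CDF, by bounded Levenberg-Marquardt
#' least squares. Initialization: Prodmean starts at the WBGT of the point
#' whose loss is closest to 0.5; Prodsd at half the WBGT span between the
#' points with losses nearest 0.16 and 0.84 (the +/- 1 sd quantiles), and
#' is constrained to (0.1, 20) degC.
#'
#' @param table a work/rest table: data frame with columns `intensity_w`,
#'   `wbgt_c`, `work_fraction` covering all three intensities with at
#'   least 4 distinct WBGT points each.
#' @return an [erf_params()] with provenance `"standard-fit"`; attribute
#'   `"fit_report"` holds per-intensity residual norms and convergence.
#' @export
fit_workrest_cdf <- function(table) {
  table <- validate_workrest_table(table)
  report <- list()
  fit1 <- function(sub) {
    loss <- 1 - sub$work_fraction
    if (length(unique(sub$work_fraction)) < 2 ||
        all(loss <= 0) || all(loss >= 1))
      stop("degenerate work/rest table at intensity ", sub$intensity_w[1],
           " W: loss fraction carries no curve information")
    m0 <- sub$wbgt_c[which.min(abs(loss - 0.5))]
    s0 <- abs(sub$wbgt_c[which.min(abs(loss - 0.84))] -
                sub$wbgt_c[which.min(abs(loss - 0.16))]) / 2
    s0 <- min(20, max(0.5, s0))
    fit <- minpack.lm::nlsLM(
      loss ~ pnorm(wbgt_c, m, s),
      data = data.frame(wbgt_c = sub$wbgt_c, loss = loss),
      start = list(m = m0, s = s0),
      lower = c(m = -50, s = 0.1), upper = c(m = 80, s = 20),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    if (!fit$convInfo$isConv)
      stop("CDF fit did not converge at intensity ", sub$intensity_w[1],
           " W: ", fit$convInfo$stopMessage)
    list(coef = stats::coef(fit),
         rss = sum(stats::resid(fit)^2), converged = TRUE)
  }
  res <- lapply(c(200, 300, 400), function(w) {
    fit1(table[table$intensity_w == w, , drop = FALSE])
  })
  out <- erf_params(prodmean = vapply(res, function(r) r$coef[["m"]], 0),
                    prodsd = vapply(res, function(r) r$coef[["s"]], 0),
                    provenance = "standard-fit")
  attr(out, "fit_report") <- data.frame(
    intensity_w = c(200, 300, 400),
    rss = vapply(res, function(r) r$rss, 0),
    converged = vapply(res, function(r) r$converged, TRUE))
  out
}

#' Transfer occupational-standard intensity offsets onto an anchor curve
#'
#' Two-step calibration: curves are first fitted to the occupational
#' work/rest standard for all three intensities; the epidemiologically
#' derived 300 W anchor then replaces the 300 W standard curve exactly,
#' and the 200 and 400 W curves are obtained by adding the standard-fit
#' parameter differences (200 minus 300, 400 minus 300) onto the anchor,
#' componentwise in Prodmean and Prodsd. `sd_mode = "anchor"` instead
#' reuses the anchor's Prodsd for all intensities.
#'
#' @param standard an [erf_params()] with provenance `"standard-fit"`.
#' @param anchor300 numeric `c(prodmean, prodsd)` of the 300 W
#'   epidemiological anchor curve.
#' @param sd_mode `"difference"` (default) to transfer sd offsets, or
#'   `"anchor"` to reuse the anchor sd everywhere.
#' @return an [erf_params()] with provenance `"calibrated"`.
#' @export
calibrate_chinese_erf <- function(standard, anchor300,
                                  sd_mode = c("difference", "anchor")) {
  standard <- validate_erf_params(standard)
  sd_mode <- match.arg(sd_mode)
  if (length(anchor300) != 2 || anchor300[2] <= 0)
    stop("anchor300 must be c(prodmean, prodsd) with prodsd > 0")
  s3 <- .erf_lookup(standard, 300)
  mean_new <- anchor300[1] +
    standard$prodmean[match(c(200, 300, 400), standard$intensity_w)] - s3$prodmean
  sd_new <- if (sd_mode == "difference") {
    anchor300[2] +
      standard$prodsd[match(c(200, 300, 400), standard$intensity_w)] - s3$prodsd
  } else rep(anchor300[2], 3)
  if (any(sd_new <= 0))
    stop("calibration produced non-positive Prodsd; ",
         "offsets incompatible with the anchor")
  erf_params(mean_new, sd_new, provenance = "calibrated")
}

#' Validate a work/rest table
#'
#' @param table data frame with columns `intensity_w`, `wbgt_c`,
#'   `work_fraction`.
#' @return the table, with class `workrest_table`, or an error naming the
#'   offending column.
#' @export
validate_workrest_table <- function(table) {
  req <- c("intensity_w", "wbgt_c", "work_fraction")
  miss <- setdiff(req, names(table))
  if (length(miss)) stop("work/rest table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(table$work_fraction < 0 | table$work_fraction > 1))
    stop("column work_fraction has values outside [0, 1]")
  if (!all(table$intensity_w %in% c(200, 300, 400)))
    stop("column intensity_w has values outside {200, 300, 400}")
  for (w in unique(table$intensity_w)) {
    if (length(unique(table$wbgt_c[table$intensity_w == w])) < 4)
      stop("fewer than 4 distinct WBGT points at intensity ", w,
           " W: fit would be under-determined")
  }
  class(table) <- unique(c("workrest_table", class(table)))
  table
}

# sector <-> intensity/setting mapping used throughout the pipeline:
# agriculture & construction are heavy outdoor work, manufacturing moderate
# indoor, service light indoor.
sector_table <- function() {
  data.frame(sector = c("agriculture", "construction", "manufacturing", "service"),
             intensity_w = c(400, 400, 300, 200),
             indoor = c(FALSE, FALSE, TRUE, TRUE),
             stringsAsFactors = FALSE)
}

#' Default synthetic exposure-response parameter sets
#'
#' Stand-in parameter sets with the right qualitative structure (heavier
#' work loses productivity at lower WBGT), for use where the real
#' occupational-standard fit or epidemiological anchor values are not
#' supplied. These are synthetic placeholders, not published values;
#' replace them with fitted or published parameters for real analyses.
#'
#' @return list with `standard` (an [erf_params()], provenance
#'   `"standard-fit"`) and `anchor300` (numeric `c(prodmean, prodsd)`).
#' @export
default_erf_inputs <- function() {
  list(standard = erf_params(prodmean = c(36, 33, 31), prodsd = c(4, 4, 4),
                             provenance = "standard-fit"),
       anchor300 = c(32.5, 4.2))
}
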