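# DPPH radical-scavenging statistics: percent inhibition, IC50 estimation
# and descriptor-activity correlation. Concentrations are in ppm throughout
# (no molar conversion: molecular weights are out of scope).

#' Percent inhibition of the DPPH radical
#'
#' The standard colorimetric definition,
#' `100 * (A_control - A_sample) / A_control`. Negative values (a
#' pro-oxidant or artifactual reading) are reported with a message, not an
#' error.
#'
#' @param absorbance_control Control absorbance(s), AU, strictly positive.
#' @param absorbance_sample Sample absorbance(s), AU.
#' @return Percent inhibition.
#' @export
#' @examples
#' percent_inhibition(0.8, 0.4)  # 50
percent_inhibition <- function(absorbance_control, absorbance_sample) {
  stopifnot(is.numeric(absorbance_control), is.numeric(absorbance_sample),
            all(is.finite(absorbance_control)), all(is.finite(absorbance_sample)))
  if (any(absorbance_control <= 0)) {
    stop("percent_inhibition: control absorbance must be > 0", call. = FALSE)
  }
  inh <- 100 * (absorbance_control - absorbance_sample) / absorbance_control
  if (any(inh < 0)) message("note: negative inhibition (pro-oxidant reading)")
  inh
}

#' Dose-response curve container
#'
#' Holds one compound's DPPH dose-response data, either as absorbance pairs
#' (converted to percent inhibition on construction) or as inhibition
#' percentages directly. Replicate readings at the same concentration are
#' kept and averaged at fit time.
#'
#' @param compound_id Identifier.
#' @param concentration Concentrations in ppm, strictly positive.
#' @param inhibition Percent inhibition (mutually exclusive with the
#'   absorbance pair).
#' @param absorbance_sample,absorbance_control Absorbances in AU.
#' @return Object of class `dose_response_curve`: a data.frame with columns
#'   `concentration_ppm`, `inhibition_pct` plus a `compound_id` attribute.
#' @export
dose_response_curve <- function(compound_id, concentration, inhibition = NULL,
                                absorbance_sample = NULL,
                                absorbance_control = NULL) {
  stopifnot(is.numeric(concentration), all(is.finite(concentration)),
            all(concentration > 0))
  if (is.null(inhibition)) {
    if (is.null(absorbance_sample) || is.null(absorbance_control)) {
      stop("dose_response_curve: supply inhibition or both absorbances",
           call. = FALSE)
    }
    inhibition <- percent_inhibition(absorbance_control, absorbance_sample)
  }
  stopifnot(length(inhibition) == length(concentration))
  out <- data.frame(concentration_ppm = as.numeric(concentration),
                    inhibition_pct = as.numeric(inhibition))
  out <- out[order(out$concentration_ppm), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, compound_id = compound_id,
            class = c("dose_response_curve", "data.frame"))
}

#' Read an assay table
#'
#' CSV/TSV with either (`compound_id`, `concentration_ppm`,
#' `absorbance_sample`, `absorbance_control`) or (`compound_id`,
#' `concentration_ppm`, `inhibition_pct`).
#'
#' @param path File path.
#' @return Named list of [dose_response_curve()]s.
#' @export
read_assay_table <- function(path) {
  df <- read_delimited(path)
  require_columns(df, c("compound_id", "concentration_ppm"), path, "assay")
  conc <- parse_signed(df$concentration_ppm)$value
  curves <- list()
  for (id in unique(df$compound_id)) {
    idx <- which(df$compound_id == id)
    if ("inhibition_pct" %in% names(df)) {
      curves[[id]] <- dose_response_curve(
        id, conc[idx], inhibition = parse_signed(df$inhibition_pct)$value[idx])
    } else {
      require_columns(df, c("absorbance_sample", "absorbance_control"), path, "assay")
      curves[[id]] <- dose_response_curve(
        id, conc[idx],
        absorbance_sample = parse_signed(df$absorbance_sample)$value[idx],
        absorbance_control = parse_signed(df$absorbance_control)$value[idx])
    }
  }
  curves
}

# Mean inhibition per unique concentration, ordered by concentration.
collapse_replicates <- function(curve) {
  agg <- stats::aggregate(inhibition_pct ~ concentration_ppm,
                          data = as.data.frame(curve), FUN = mean)
  agg[order(agg$concentration_ppm), , drop = FALSE]
}

#' Estimate the IC50 from a dose-response curve
#'
#' Two models:
#' \describe{
#'   \item{`loglinear_interpolation` (default)}{Linear interpolation of
#'     percent inhibition versus log10(concentration) between the two
#'     observations bracketing 50%. Fewest assumptions; requires the data
#'     to span the 50% level unless `allow_extrapolation = TRUE`, in which
#'     case the nearest segment is extended and the fit is flagged.}
#'   \item{`four_parameter_logistic`}{Least-squares fit of
#'     `y = bottom + (top - bottom) / (1 + (ic50 / c)^hill)`; the reported
#'     IC50 is the fitted inflection-scale parameter. Needs >= 4 points.
#'     Because the response is percent inhibition — anchored at 0 by
#'     definition and saturating at 100 — the asymptotes are fixed at
#'     `bottom = 0`, `top = 100` by default (the normalized-response
#'     logistic), which roughly halves the IC50 error on short dilution
#'     series; set `fix_asymptotes = FALSE` to free all four parameters.
#'     Fitting uses `stats::nls` (port algorithm) with an `optim()`
#'     sum-of-squares fallback.}
#' }
#'
#' @param curve A [dose_response_curve()].
#' @param model `"loglinear_interpolation"` or `"four_parameter_logistic"`.
#' @param allow_extrapolation Permit an IC50 outside the observed range in
#'   interpolation mode (flagged in the result).
#' @param fix_asymptotes Logistic mode only: anchor `bottom`/`top` at 0/100
#'   (default) instead of fitting them.
#' @return Object of class `ic50_fit`: list with `ic50` (ppm), `model`,
#'   `extrapolated`, `diagnostics` (n points, residual summary) and, for the
#'   logistic model, `parameters`.
#' @export
fit_ic50 <- function(curve,
                     model = c("loglinear_interpolation",
                               "four_parameter_logistic"),
                     allow_extrapolation = FALSE,
                     fix_asymptotes = TRUE) {
  model <- match.arg(model)
  stopifnot(inherits(curve, "dose_response_curve"))
  pts <- collapse_replicates(curve)
  if (nrow(pts) < 3L) {
    stop("fit_ic50: need >= 3 distinct concentrations", call. = FALSE)
  }
  if (diff(range(pts$inhibition_pct)) == 0) {
    stop("fit_ic50: degenerate (constant) response", call. = FALSE)
  }
  id <- attr(curve, "compound_id")
  if (model == "loglinear_interpolation") {
    y <- pts$inhibition_pct
    lc <- log10(pts$concentration_ppm)
    exact <- which(y == 50)
    if (length(exact)) {
      ic50 <- pts$concentration_ppm[exact[1L]]
      extrapolated <- FALSE
    } else {
      cross <- which(diff(sign(y - 50)) != 0)
      if (length(cross)) {
        i <- cross[1L]
        ic50 <- 10^(lc[i] + (50 - y[i]) * (lc[i + 1L] - lc[i]) / (y[i + 1L] - y[i]))
        extrapolated <- FALSE
      } else if (allow_extrapolation) {
        # extend the segment nearest the 50% level
        i <- if (max(y) < 50) nrow(pts) - 1L else 1L
        ic50 <- 10^(lc[i] + (50 - y[i]) * (lc[i + 1L] - lc[i]) / (y[i + 1L] - y[i]))
        extrapolated <- TRUE
      } else {
        stop("fit_ic50(", id, "): observations do not bracket 50% inhibition; ",
             "set allow_extrapolation = TRUE to extrapolate", call. = FALSE)
      }
    }
    fitted50 <- stats::approx(lc, y, xout = log10(ic50), rule = 2)$y
    res <- list(ic50 = ic50, model = model, extrapolated = extrapolated,
                parameters = NULL,
                diagnostics = list(n = nrow(pts), residual_at_ic50 = fitted50 - 50,
                                   residual_sd = NA_real_))
  } else {
    if (nrow(pts) < 4L) {
      stop("fit_ic50: four_parameter_logistic needs >= 4 distinct concentrations",
           call. = FALSE)
    }
    conc <- pts$concentration_ppm
    y <- pts$inhibition_pct
    guess <- tryCatch(
      fit_ic50(curve, "loglinear_interpolation", allow_extrapolation = TRUE)$ic50,
      error = function(e) exp(mean(log(conc))))
    fpl <- function(bottom, top, log_ic50, hill, c.) {
      bottom + (top - bottom) / (1 + (exp(log_ic50) / c.)^hill)
    }
    if (fix_asymptotes) {
      fit <- tryCatch(
        stats::nls(y ~ fpl(0, 100, log_ic50, hill, conc),
                   start = list(log_ic50 = log(guess), hill = 1),
                   algorithm = "port",
                   lower = c(log_ic50 = log(min(conc)) - 7, hill = 0.05),
                   upper = c(log_ic50 = log(max(conc)) + 7, hill = 20),
                   control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        p <- c(list(bottom = 0, top = 100), as.list(coef(fit)))
        residuals <- resid(fit)
      } else {
        sse <- function(par) sum((y - fpl(0, 100, par[1L], exp(par[2L]), conc))^2)
        op <- stats::optim(c(log(guess), 0), sse, method = "Nelder-Mead",
                           control = list(maxit = 2000, reltol = 1e-12))
        p <- list(bottom = 0, top = 100, log_ic50 = op$par[1L],
                  hill = exp(op$par[2L]))
        residuals <- y - fpl(0, 100, p$log_ic50, p$hill, conc)
      }
    } else {
      start <- list(bottom = min(y), top = max(y), log_ic50 = log(guess), hill = 1)
      fit <- tryCatch(
        stats::nls(y ~ fpl(bottom, top, log_ic50, hill, conc), start = start,
                   algorithm = "port",
                   lower = c(bottom = -20, top = 10, log_ic50 = log(min(conc)) - 7,
                             hill = 0.05),
                   upper = c(bottom = 45, top = 150, log_ic50 = log(max(conc)) + 7,
                             hill = 20),
                   control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        p <- as.list(coef(fit))
        residuals <- resid(fit)
      } else {
        sse <- function(par) {
          sum((y - fpl(par[1L], par[2L], par[3L], exp(par[4L]), conc))^2)
        }
        op <- stats::optim(c(min(y), max(y), log(guess), 0), sse,
                           method = "Nelder-Mead",
                           control = list(maxit = 2000, reltol = 1e-12))
        p <- list(bottom = op$par[1L], top = op$par[2L], log_ic50 = op$par[3L],
                  hill = exp(op$par[4L]))
        residuals <- y - fpl(p$bottom, p$top, p$log_ic50, p$hill, conc)
      }
    }
    ic50 <- exp(p$log_ic50)
    extrapolated <- max(y) < 50 || min(y) > 50
    res <- list(ic50 = ic50, model = model, extrapolated = extrapolated,
                parameters = list(bottom = p$bottom, top = p$top,
                                  ic50 = ic50, hill = p$hill),
                diagnostics = list(n = nrow(pts),
                                   residual_sd = stats::sd(residuals)))
  }
  if (!res$extrapolated && res$ic50 <= 0) {
    stop("fit_ic50(", id, "): non-positive IC50 from a non-extrapolated fit",
         call. = FALSE)
  }
  structure(res, compound_id = id, class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  cat(sprintf("<ic50_fit %s: IC50 = %.4g ppm (%s%s, n = %d)>\n",
              attr(x, "compound_id"), x$ic50, x$model,
              if (x$extrapolated) ", extrapolated" else "",
              x$diagnostics$n))
  invisible(x)
}

#' Pearson correlation between a descriptor and IC50
#'
#' Product-moment correlation of `y` (IC50, ppm) on `x` (a reactivity
#' descriptor), with the least-squares line of y on x and per-compound
#' residuals. Used to compare in silico descriptors with in vitro activity.
#'
#' @param x Descriptor values (length >= 3, nonzero variance).
#' @param y IC50 values in ppm (same length, nonzero variance).
#' @param descriptor_used Name of the descriptor, recorded in the result.
#' @param compound_id Optional identifiers for the residual table.
#' @return Object of class `correlation_result`: list with `r`, `slope`,
#'   `intercept`, `residuals` (named ppm), `descriptor_used`, `n`.
#' @export
#' @examples
#' pearson_correlation(1:5, c(2, 1, 4, 3, 5))$r  # 0.8
pearson_correlation <- function(x, y, descriptor_used = "descriptor",
                                compound_id = NULL) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("pearson_correlation: length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("pearson_correlation: need >= 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_correlation: zero variance; correlation undefined", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  res <- stats::resid(fit)
  names(res) <- if (is.null(compound_id)) as.character(seq_along(x)) else compound_id
  structure(
    list(r = stats::cor(x, y), slope = unname(coef(fit)[2L]),
         intercept = unname(coef(fit)[1L]), residuals = res,
         descriptor_used = descriptor_used, n = length(x)),
    class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result %s vs IC50: r = %.4f (n = %d)>\n",
              x$descriptor_used, x$r, x$n))
  invisible(x)
}

#' Correlate every available descriptor with IC50
#'
#' The in-silico quantity best tracking the assay is rarely known a priori,
#' so the whole battery is reported: each numeric descriptor column is
#' correlated against IC50 across the compounds present in both tables.
#'
#' @param descriptors data.frame with `compound_id` and numeric descriptor
#'   columns (e.g. a merged [descriptor_table()] / [dam_points()] table).
#' @param ic50 data.frame with `compound_id`, `ic50_ppm`.
#' @param columns Descriptor columns to use; defaults to every numeric
#'   column except identifiers.
#' @return List with `summary` (data.frame descriptor/r/slope/intercept/n)
#'   and `results` (named list of [pearson_correlation()] objects).
#' @export
correlate_descriptors <- function(descriptors, ic50, columns = NULL) {
  stopifnot(is.data.frame(descriptors), is.data.frame(ic50),
            "compound_id" %in% names(descriptors),
            all(c("compound_id", "ic50_ppm") %in% names(ic50)))
  m <- merge(descriptors, ic50[, c("compound_id", "ic50_ppm")], by = "compound_id")
  if (is.null(columns)) {
    columns <- setdiff(names(m)[vapply(m, is.numeric, TRUE)],
                       c("ic50_ppm", "donor_rank"))
  }
  results <- list()
  rows <- list()
  for (col in columns) {
    ok <- is.finite(m[[col]]) & is.finite(m$ic50_ppm)
    if (sum(ok) < 3L || stats::sd(m[[col]][ok]) == 0) next
    cr <- pearson_correlation(m[[col]][ok], m$ic50_ppm[ok],
                              descriptor_used = col,
                              compound_id = m$compound_id[ok])
    results[[col]] <- cr
    rows[[col]] <- data.frame(descriptor = col, r = cr$r, slope = cr$slope,
                              intercept = cr$intercept, n = cr$n,
                              stringsAsFactors = FALSE)
  }
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(descriptor = character(), r = numeric(), slope = numeric(),
               intercept = numeric(), n = integer())
  rownames(summary) <- NULL
  list(summary = summary, results = results)
}
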