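# The soil multi-nutrient cycling index: min-max normalise each of seven
# nutrient variables over all samples jointly, then average per sample.

#' Min-max normalise a variable over all samples
#'
#' (X - X_min) / (X_max - X_min) where X_min and X_max are the minimum
#' and maximum observed over all samples, so the observed minimum maps to
#' 0 and the maximum to 1.  Constant variables are an error: the
#' normalisation is undefined and silently dropping the variable would
#' change the index definition.
#'
#' @param values numeric vector (>= 2 samples).
#' @param name variable name used in error messages.
#' @return List with `normalized`, `x_min`, `x_max`.
#' @export
min_max_normalize <- function(values, name = "variable") {
  if (length(values) < 2)
    stop("min-max normalisation needs at least 2 samples", call. = FALSE)
  x_min <- min(values); x_max <- max(values)
  if (x_max <= x_min)
    stop("constant variable '", name,
         "': min-max normalisation is undefined", call. = FALSE)
  list(normalized = (values - x_min) / (x_max - x_min),
       x_min = x_min, x_max = x_max)
}

#' Soil multi-nutrient cycling index (MNC)
#'
#' Each variable is min-max normalised over all provided samples jointly
#' (not per crop); the per-sample MNC is the mean of the normalised
#' values.  Defaults to the seven nutrient properties SOC, TN, TP, TK,
#' Olsen-P, Avail-K and NO3-N.
#'
#' @param nt a [nutrient_table()].
#' @param variables variables to average (default [mnc_vars()]).
#' @return An object of class `rc_mnc`: list with `mnc` (named
#'   per-sample vector in [0, 1]), `normalized` (samples x variables
#'   matrix), `ranges` (variable x (x_min, x_max)), `variables`, `crop`.
#' @export
compute_mnc <- function(nt, variables = mnc_vars()) {
  nt <- nutrient_table(nt)
  miss <- setdiff(variables, names(nt))
  if (length(miss))
    stop("missing MNC variable ", paste(miss, collapse = ", "),
         call. = FALSE)
  nor <- matrix(NA_real_, nrow(nt), length(variables),
                dimnames = list(nt$sample_id, variables))
  ranges <- matrix(NA_real_, length(variables), 2,
                   dimnames = list(variables, c("x_min", "x_max")))
  for (v in variables) {
    mm <- min_max_normalize(nt[[v]], name = v)
    nor[, v] <- mm$normalized
    ranges[v, ] <- c(mm$x_min, mm$x_max)
  }
  structure(list(mnc = rowMeans(nor), normalized = nor, ranges = ranges,
                 variables = variables,
                 crop = stats::setNames(nt$crop, nt$sample_id)),
            class = "rc_mnc")
}

#' @export
print.rc_mnc <- function(x, ...) {
  cat(sprintf("MNC over %d variables, %d samples; mean = %.3f\n",
              length(x$variables), length(x$mnc), mean(x$mnc)))
  invisible(x)
}

#' Nutrient availability ratios
#'
#' Per-sample AN:TN, Olsen-P:TP and Avail-K:TK in percent.  AN and TN
#' share units (g kg-1); Olsen-P and Avail-K are in mg kg-1 against
#' totals in g kg-1, so those numerators are divided by 1000 before the
#' percentage is taken.  Zero denominators give per-sample missing
#' values with a warning.
#'
#' @param nt a [nutrient_table()].
#' @return Data frame `sample_id`, `crop`, `AN_TN`, `Olsen_P_TP`,
#'   `Avail_K_TK` (percent); attribute `units` documents the conversion.
#' @export
availability_ratios <- function(nt) {
  nt <- nutrient_table(nt)
  ratio <- function(num, den, scale) {
    bad <- den == 0
    if (any(bad))
      warning(sum(bad), " zero denominator(s): ratio set missing",
              call. = FALSE)
    out <- ifelse(bad, NA_real_, num / den * scale)
    out
  }
  out <- data.frame(
    sample_id = nt$sample_id, crop = nt$crop,
    AN_TN = ratio(nt$AN, nt$TN, 100),            # g/kg over g/kg
    Olsen_P_TP = ratio(nt$Olsen_P, nt$TP, 0.1),  # mg/kg over g/kg: /1000*100
    Avail_K_TK = ratio(nt$Avail_K, nt$TK, 0.1),
    stringsAsFactors = FALSE)
  attr(out, "units") <-
    "percent; mg kg-1 numerators divided by 1000 against g kg-1 totals"
  out
}
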