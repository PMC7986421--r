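#' Floral-competence threshold from a reference accession
#'
#' The threshold is the pre-vernalization (day-0) fitted total-FLC level of
#' a no-requirement spring reference accession: its total FLC is, by
#' definition of "no requirement", already low enough to permit flowering,
#' so it provides a lower bound on the competence level. With the default
#' synthetic reference this evaluates to 75 TPM.
#'
#' @param fits A `"decay_fit_panel"` (from [fit_panel()]).
#' @param reference Reference accession id (default `"Westar_like"`).
#' @param override If non-`NULL`, returned as-is (explicit threshold in TPM).
#' @return Threshold in TPM.
#' @export
#' @examples
#' competence_threshold(override = 75)
competence_threshold <- function(fits = NULL, reference = "Westar_like",
                                 override = NULL) {
  if (!is.null(override)) {
    .assert_scalar_num(override, "override", lower = 1e-9)
    return(override)
  }
  stopifnot(inherits(fits, "decay_fit_panel"))
  key <- paste(reference, "total", sep = ":")
  f <- fits$fits[[key]]
  if (is.null(f)) .stopf("reference accession '%s' has no total-FLC fit", reference)
  f$a + f$c
}

#' Day a single exponential trajectory crosses a threshold
#'
#' Closed form for `a * exp(b * t) + c = threshold`: returns 0 when the
#' day-0 level is already at or below the threshold, `Inf` (unbounded, no
#' crossing) when the floor `c` is at or above the threshold or the
#' trajectory does not decay (`b >= 0`), and
#' `log((threshold - c) / a) / b` otherwise.
#'
#' @param fit A `"decay_fit"`, or a numeric vector `c(a = , b = , c = )`.
#' @param threshold Competence threshold in TPM (> 0).
#' @return Crossing day (>= 0), or `Inf` if the trajectory never crosses.
#' @export
#' @examples
#' crossing_time(c(a = 300, b = -0.05, c = 0), threshold = 75)  # log(4)/0.05
crossing_time <- function(fit, threshold) {
  .assert_scalar_num(threshold, "threshold", lower = 1e-12)
  p <- if (inherits(fit, "decay_fit")) coef(fit) else fit
  if (!all(c("a", "b", "c") %in% names(p)) || !all(is.finite(p))) {
    .stopf("'fit' must supply finite parameters a, b, c")
  }
  a <- p[["a"]]; b <- p[["b"]]; cc <- p[["c"]]
  if (a + cc <= threshold) return(0)
  if (cc >= threshold || b >= 0) return(Inf)
  log((threshold - cc) / a) / b
}

#' Day a sum of exponential trajectories crosses a threshold
#'
#' Total FLC under per-paralogue rates is a sum of exponentials
#' `sum_p (prevern_p - c_p) * exp(b_p * t) + c_p` with no closed-form
#' crossing; the earliest `t` with total <= threshold is found numerically.
#' When every term is non-increasing the total is monotone and the crossing
#' is bracketed directly; otherwise (some `b_p > 0`) a coarse forward scan
#' locates the first down-crossing. Bisection then refines it to 1e-6 days.
#'
#' @param prevern Named numeric vector: day-0 TPM per paralogue (>= 0).
#' @param rates Named numeric vector of rates `b` (per day), same names.
#' @param floors Named numeric floors `c` (>= 0, below `prevern`); default 0.
#' @param threshold Competence threshold (TPM, > 0).
#' @param horizon Days after which the prediction is censored (default 365).
#' @return Crossing day in `[0, horizon]`, or `Inf` if the total is still
#'   above the threshold at the horizon (censored / unbounded).
#' @export
#' @examples
#' crossing_time_total(c(x = 200, y = 100), c(x = -0.1, y = -0.01),
#'                     threshold = 75)
crossing_time_total <- function(prevern, rates, floors = NULL, threshold,
                                horizon = 365) {
  .assert_scalar_num(threshold, "threshold", lower = 1e-12)
  .assert_scalar_num(horizon, "horizon", lower = 1e-9)
  if (is.null(names(prevern)) || is.null(names(rates))) {
    .stopf("'prevern' and 'rates' must be named by paralogue")
  }
  if (any(prevern < 0)) .stopf("'prevern' must be non-negative")
  if (is.null(floors)) floors <- setNames(numeric(length(prevern)), names(prevern))
  missing_rate <- setdiff(names(prevern), names(rates))
  if (length(missing_rate)) {
    .stopf("no rate for paralogue(s): %s", paste(missing_rate, collapse = ", "))
  }
  b <- rates[names(prevern)]
  cc <- floors[names(prevern)]; cc[is.na(cc)] <- 0
  amp <- pmax(prevern - cc, 0)
  total_at <- function(t) sum(amp * exp(b * t) + cc)

  if (total_at(0) <= threshold) return(0)
  monotone <- all(b[amp > 0] <= 0)
  if (monotone) {
    if (total_at(horizon) > threshold) return(Inf)
    lo <- 0; hi <- horizon
  } else {
    # coarse scan for the first down-crossing
    step <- 0.25
    tgrid <- seq(0, horizon, by = step)
    vals <- vapply(tgrid, total_at, numeric(1))
    below <- which(vals <= threshold)
    if (!length(below)) return(Inf)
    hi <- tgrid[below[1L]]; lo <- hi - step
  }
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (total_at(mid) <= threshold) hi <- mid else lo <- mid
    if (hi - lo < 1e-6) break
  }
  hi
}

#' Build per-(accession, paralogue) decay rates under a scenario
#'
#' The three scenarios translate the rates fitted in a small measured panel
#' into rates for accessions that were only measured pre-vernalization:
#' \describe{
#'   \item{common}{one rate everywhere: the mean of all usable fitted rates
#'     (no differences between paralogues or accessions);}
#'   \item{paralogue}{per-paralogue rate: the mean of that paralogue's
#'     fitted rates across accessions (paralogues differ, accessions do
#'     not);}
#'   \item{extreme}{per-paralogue and per-crop-type: accessions with a low
#'     vernalization requirement (spring, semi-winter) receive the most
#'     negative fitted rate for each paralogue and high-requirement
#'     accessions (winter, swede) the least negative, the assignment that
#'     maximises the separation between the two groups.}
#' }
#' Degenerate (all-zero) fits are excluded from pooling; a paralogue with
#' no usable fit inherits the common mean rate and is flagged in the
#' `"fallback"` attribute.
#'
#' @param fits A `"decay_fit_panel"` from the measured panel.
#' @param scenario `"common"`, `"paralogue"` or `"extreme"`.
#' @param crop_type_map Named character vector: crop type per target
#'   accession (required for `"extreme"`).
#' @param accessions Target accession ids; default the names of
#'   `crop_type_map`.
#' @return Numeric matrix (accessions x paralogues) of rates, class
#'   `"scenario_rates"` with attributes `"scenario"` and `"fallback"`.
#' @export
build_scenario_rates <- function(fits, scenario = c("common", "paralogue", "extreme"),
                                 crop_type_map = NULL, accessions = names(crop_type_map)) {
  stopifnot(inherits(fits, "decay_fit_panel"))
  scenario <- match.arg(scenario)
  if (is.null(accessions)) .stopf("supply 'accessions' or a named 'crop_type_map'")
  tab <- fits$table
  usable <- tab$target != "total" & !grepl("degenerate", tab$flags)
  tab <- tab[usable, ]
  if (!nrow(tab)) .stopf("no usable paralogue fits")
  paralogues <- unique(fits$table$target[fits$table$target != "total"])
  common_mean <- mean(tab$b)

  per_par <- function(fun) {
    vapply(paralogues, function(p) {
      bs <- tab$b[tab$target == p]
      if (!length(bs)) NA_real_ else fun(bs)
    }, numeric(1))
  }
  fallback <- character(0)
  m <- matrix(NA_real_, length(accessions), length(paralogues),
              dimnames = list(accessions, paralogues))
  if (scenario == "common") {
    m[] <- common_mean
  } else if (scenario == "paralogue") {
    mu <- per_par(mean)
    fallback <- paralogues[is.na(mu)]
    mu[is.na(mu)] <- common_mean
    m[] <- rep(mu, each = length(accessions))
  } else {
    if (is.null(crop_type_map)) .stopf("'extreme' requires a crop_type_map")
    unknown <- setdiff(unique(crop_type_map), crop_types())
    if (length(unknown)) .stopf("unknown crop type(s): %s",
                                paste(unknown, collapse = ", "))
    missing_ct <- setdiff(accessions, names(crop_type_map))
    if (length(missing_ct)) .stopf("no crop type for accession(s): %s",
                                   paste(missing_ct, collapse = ", "))
    bmin <- per_par(min); bmax <- per_par(max)
    fallback <- paralogues[is.na(bmin)]
    bmin[is.na(bmin)] <- common_mean; bmax[is.na(bmax)] <- common_mean
    low <- crop_type_map[accessions] %in% .low_requirement_types
    m[low, ] <- rep(bmin, each = sum(low))
    m[!low, ] <- rep(bmax, each = sum(!low))
  }
  structure(m, scenario = scenario, fallback = fallback,
            class = c("scenario_rates", class(m)))
}

#' Predict vernalization requirement for a pre-vernalization panel
#'
#' For each accession, the measured pre-vernalization per-paralogue levels
#' are taken as the starting amplitudes of a floor-free exponential decay
#' (model M1, c = 0) with rates from a scenario, and the requirement is the
#' day the summed trajectory crosses the competence threshold
#' ([crossing_time_total()]).
#'
#' @param prevern Matrix (accessions x paralogues) of day-0 TPM, e.g. from
#'   [generate_prevernalization()].
#' @param rates A `"scenario_rates"` matrix covering all accessions; extra
#'   paralogue columns are ignored, missing ones are an error.
#' @param threshold Competence threshold (TPM).
#' @param horizon Censoring horizon in days (default 365).
#' @return Data frame of class `"vernalization_prediction"`: `accession`,
#'   `crossing_day` (`Inf` = censored/unbounded), `censored`, `threshold`,
#'   `scenario`.
#' @export
predict_requirements <- function(prevern, rates, threshold, horizon = 365) {
  if (!is.matrix(prevern)) .stopf("'prevern' must be an accessions x paralogues matrix")
  missing_acc <- setdiff(rownames(prevern), rownames(rates))
  if (length(missing_acc)) {
    .stopf("no rates for accession(s): %s", paste(missing_acc, collapse = ", "))
  }
  missing_par <- setdiff(colnames(prevern), colnames(rates))
  if (length(missing_par)) {
    .stopf("no rates for paralogue(s): %s", paste(missing_par, collapse = ", "))
  }
  pars <- colnames(prevern)
  days <- vapply(rownames(prevern), function(acc) {
    pv <- setNames(as.numeric(prevern[acc, pars]), pars)
    bb <- setNames(as.numeric(rates[acc, pars]), pars)
    crossing_time_total(pv, bb, threshold = threshold, horizon = horizon)
  }, numeric(1))
  out <- data.frame(accession = rownames(prevern), crossing_day = days,
                    censored = !is.finite(days), threshold = threshold,
                    scenario = attr(rates, "scenario") %||% NA_character_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("vernalization_prediction", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Crop-type separation summary of vernalization predictions
#'
#' Summarises how well predicted requirements separate the low-requirement
#' group (spring, semi-winter) from the high-requirement group (winter,
#' swede): per-type requirement ranges, the number of high-requirement
#' accessions predicted to cross the threshold before the most
#' cold-dependent low-requirement accession (the "overlap"), and censoring
#' counts. Unbounded predictions are treated as +Inf.
#'
#' @param predictions A `"vernalization_prediction"` data frame.
#' @param crop_type_map Named character vector of crop types per accession.
#' @return List of class `"separation_report"`: `per_type` (data frame of
#'   min/max/median crossing day and censored count per crop type),
#'   `overlap` (count), `max_low` (the low-group maximum), `n_censored`.
#' @export
separation_report <- function(predictions, crop_type_map) {
  stopifnot(inherits(predictions, "vernalization_prediction"))
  if (!nrow(predictions)) .stopf("no predictions")
  ct <- crop_type_map[predictions$accession]
  if (anyNA(ct)) {
    .stopf("no crop type for accession(s): %s",
           paste(predictions$accession[is.na(ct)], collapse = ", "))
  }
  unknown <- setdiff(unique(ct), crop_types())
  if (length(unknown)) .stopf("unknown crop type(s): %s",
                              paste(unknown, collapse = ", "))
  d <- predictions$crossing_day
  per_type <- do.call(rbind, lapply(intersect(crop_types(), unique(ct)), function(tp) {
    dd <- d[ct == tp]
    data.frame(crop_type = tp, n = length(dd), min = min(dd),
               median = median(dd), max = max(dd),
               censored = sum(!is.finite(dd)), stringsAsFactors = FALSE)
  }))
  low <- ct %in% .low_requirement_types
  max_low <- if (any(low)) max(d[low]) else -Inf
  overlap <- sum(d[!low] < max_low)
  structure(list(per_type = per_type, overlap = overlap, max_low = max_low,
                 n_censored = sum(!is.finite(d))),
            class = "separation_report")
}

#' @importFrom stats median aggregate
#' @export
print.separation_report <- function(x, ...) {
  cat("Crop-type separation of predicted vernalization requirement\n")
  print(x$per_type, row.names = FALSE)
  cat(sprintf(
    "  high-requirement accessions predicted below the low-group maximum (%.3g d): %d\n",
    x$max_low, x$overlap))
  cat(sprintf("  censored (no crossing by horizon): %d\n", x$n_censored))
  invisible(x)
}
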