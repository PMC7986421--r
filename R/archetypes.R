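#' Construct an accession archetype
#'
#' An archetype is the generating truth for one synthetic accession: for each
#' paralogue an initial expression level `a` (TPM), an exponential rate `b`
#' (per day; negative means decay under cold) and a floor `c` (TPM), so the
#' noiseless trajectory of paralogue p is `a_p * exp(b_p * day) + c_p`.
#'
#' @param accession Accession identifier (string).
#' @param crop_type One of [crop_types()].
#' @param a,b,c Numeric vectors named by paralogue (see [flc_paralogues()]).
#'   `a` and `c` must be non-negative; `b` is unconstrained in sign (some
#'   paralogues maintain or slightly increase expression under cold).
#'   `c` defaults to all-zero.
#' @param strategy Optional composition-strategy label (`"A"`, `"B"` or
#'   `"C"`), used for winter accessions only.
#' @return An object of class `"flc_archetype"`.
#' @export
#' @examples
#' p <- flc_paralogues()
#' arch <- archetype("toy", "spring",
#'   a = setNames(rep(10, 9), p),
#'   b = setNames(rep(-0.05, 9), p))
#' arch
archetype <- function(accession, crop_type, a, b, c = NULL, strategy = NA_character_) {
  stopifnot(is.character(accession), length(accession) == 1L, nzchar(accession))
  crop_type <- match.arg(crop_type, crop_types())
  roster <- names(a)
  if (is.null(roster) || anyDuplicated(roster)) {
    .stopf("'a' must be named by paralogue, names unique")
  }
  if (is.null(c)) c <- setNames(numeric(length(a)), roster)
  for (nm in c("a", "b", "c")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != length(a) || !all(is.finite(v))) {
      .stopf("archetype '%s': '%s' must be finite numeric, one per paralogue",
             accession, nm)
    }
    if (!setequal(names(v), roster)) {
      .stopf("archetype '%s': names of '%s' must match names of 'a'", accession, nm)
    }
  }
  b <- b[roster]; c <- c[roster]
  if (any(a < 0) || any(c < 0)) {
    .stopf("archetype '%s': 'a' and 'c' must be non-negative TPM", accession)
  }
  structure(
    list(accession = accession, crop_type = crop_type, strategy = strategy,
         a = a, b = b, c = c),
    class = "flc_archetype")
}

#' @export
print.flc_archetype <- function(x, ...) {
  cat(sprintf("FLC accession archetype '%s' (%s%s)\n", x$accession, x$crop_type,
              if (!is.na(x$strategy)) paste0(", strategy ", x$strategy) else ""))
  cat(sprintf("  day-0 total: %.1f TPM over %d paralogues\n",
              sum(x$a + x$c), length(x$a)))
  tab <- data.frame(a = x$a, b = x$b, c = x$c)
  print(tab, ...)
  invisible(x)
}

# Baseline per-paralogue cold-response rates (per day). Ordering of
# responsiveness follows the observed gene-level behaviour: A03a and the
# tandem/segmental duplicates decay fast, A02/A10 moderately, C02 is nearly
# stable and C09b maintains or slightly increases expression.
.baseline_rates <- function() {
  setNames(
    c(-0.05, -0.15, -0.12, -0.04, -0.008, -0.10, -0.10, -0.09, 0.001),
    flc_paralogues())
}

#' Default accession archetypes
#'
#' Seven archetypes spanning the four crop types, including the three winter
#' composition strategies: A (high total, heavy in the fast-decaying
#' `BnaFLC.A03a` plus `BnaFLC.A10`), B (low total, proportionally more stable
#' paralogues) and C (high total carried by stable paralogues). The
#' spring archetype `Westar_like` has day-0 total exactly equal to
#' `threshold` (default 75 TPM), mirroring the use of a no-requirement spring
#' accession to set the floral-competence threshold. The semi-winter
#' archetype allocates more than 40% of its day-0 total to `BnaFLC.A03a`,
#' its fastest-decaying paralogue. `BnaFLC.C03b` is a presumed pseudogene and
#' is unexpressed (a = 0) in every archetype.
#'
#' Per-archetype rates are the baseline per-paralogue rates scaled by a
#' responsiveness multiplier (springs/semi-winters respond fast, swede
#' slowly), so the same paralogue decays at different rates in different
#' accessions.
#'
#' @param threshold Day-0 total (TPM) for the reference spring archetype.
#' @return List of [archetype()] objects.
#' @export
#' @examples
#' sapply(default_archetypes(), function(a) sum(a$a + a$c))
default_archetypes <- function(threshold = 75) {
  .assert_scalar_num(threshold, "threshold", lower = 1e-6)
  p <- flc_paralogues()
  base_b <- .baseline_rates()
  comp <- list(
    #              A02 A03a A03b A10 C02 C03a C03b C09a C09b
    Westar_like  = c(10,  25,   2,  15,   8,  10,   0,   3,   2),
    Stellar_like = c( 8,  18,   1,  10,   7,   7,   0,   2,   2),
    ZS11_like    = c(25, 120,   5,  30,  25,  35,   0,  10,  10),
    Winter_A     = c(30,  90,   5,  80,  30,  30,   0,  10,   5),
    Winter_B     = c(20,  10,   2,  20,  30,   5,   0,   3,  50),
    Winter_C     = c(40,  10,   0,  50,  90,  15,   0,   5,  30),
    Swede_like   = c(50,  20,   0, 100,  70,  15,   0,   5,  40))
  types <- c(Westar_like = "spring", Stellar_like = "spring",
             ZS11_like = "semi_winter", Winter_A = "winter",
             Winter_B = "winter", Winter_C = "winter", Swede_like = "swede")
  mult <- c(Westar_like = 1.2, Stellar_like = 1.1, ZS11_like = 1.3,
            Winter_A = 1.0, Winter_B = 0.7, Winter_C = 0.9, Swede_like = 0.5)
  strat <- c(Westar_like = NA, Stellar_like = NA, ZS11_like = NA,
             Winter_A = "A", Winter_B = "B", Winter_C = "C", Swede_like = NA)
  # rescale the reference spring composition so its total is exactly the
  # requested threshold
  comp$Westar_like <- comp$Westar_like * (threshold / sum(comp$Westar_like))
  lapply(names(comp), function(nm) {
    archetype(nm, types[[nm]],
              a = setNames(comp[[nm]], p),
              b = base_b * mult[[nm]],
              strategy = strat[[nm]])
  })
}

#' Replicate-noise and sampling design specification
#'
#' Observation noise is multiplicative lognormal: an observed TPM is the
#' noiseless mean times `exp(e)`, `e ~ N(0, sigma_log^2)`. Values below the
#' detection floor are recorded as 0 (quantified-but-absent), as TPM
#' pipelines emit zeros rather than missing values.
#'
#' @param sigma_log Standard deviation of the log-scale noise (>= 0).
#' @param detection_floor TPM below which an observation is recorded as 0.
#' @param replicates Replicates per timepoint (>= 1).
#' @param timepoints Days-of-cold grid; strictly increasing, starting at 0.
#' @return An object of class `"flc_noise_spec"`.
#' @export
noise_spec <- function(sigma_log = 0.2, detection_floor = 0.1,
                       replicates = 3L, timepoints = c(0, 7, 14, 21, 28, 42, 56, 84)) {
  .assert_scalar_num(sigma_log, "sigma_log", lower = 0)
  .assert_scalar_num(detection_floor, "detection_floor", lower = 0)
  .assert_scalar_num(replicates, "replicates", lower = 1)
  if (!is.numeric(timepoints) || length(timepoints) < 1L ||
      any(!is.finite(timepoints)) || any(timepoints < 0)) {
    .stopf("'timepoints' must be non-negative and finite")
  }
  if (is.unsorted(timepoints, strictly = TRUE)) {
    .stopf("'timepoints' must be strictly increasing")
  }
  if (timepoints[1L] != 0) {
    .stopf("'timepoints' must include day 0")
  }
  structure(
    list(sigma_log = sigma_log, detection_floor = detection_floor,
         replicates = as.integer(replicates), timepoints = as.numeric(timepoints)),
    class = "flc_noise_spec")
}
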