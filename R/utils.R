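#' The nine B. napus FLC paralogues
#'
#' Default paralogue roster: the nine *BnaFLC* copies with Darmor-*bzh* gene
#' models. Ordered A genome then C genome.
#'
#' @return Character vector of nine paralogue identifiers.
#' @export
#' @examples
#' flc_paralogues()
flc_paralogues <- function() {
  c("BnaFLC.A02", "BnaFLC.A03a", "BnaFLC.A03b", "BnaFLC.A10",
    "BnaFLC.C02", "BnaFLC.C03a", "BnaFLC.C03b", "BnaFLC.C09a",
    "BnaFLC.C09b")
}

#' Recognised crop types
#'
#' Vernalization-requirement classes of *B. napus* accessions, from no
#' requirement (spring) to an extreme requirement (swede).
#'
#' @return Character vector of the four crop-type labels.
#' @export
crop_types <- function() {
  c("spring", "semi_winter", "winter", "swede")
}

# Crop types with a low vs high vernalization requirement (used by the
# EXTREME scenario and by separation_report).
.low_requirement_types <- c("spring", "semi_winter")
.high_requirement_types <- c("winter", "swede")

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. seed = NULL means "use current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    .stopf("'%s' must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    .stopf("'%s' must be in [%s, %s]", name, format(lower), format(upper))
  }
  invisible(x)
}
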