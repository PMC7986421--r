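#' Generate a synthetic replicate-level expression panel
#'
#' Simulates a vernalization time course for each archetype: for every
#' paralogue, timepoint and replicate the observation is
#' `(a_p * exp(b_p * day) + c_p) * exp(e)`, `e ~ N(0, sigma_log^2)`, with
#' values below the detection floor recorded as 0. With the same seed the
#' panel is reproduced exactly.
#'
#' @param archetypes List of [archetype()] objects (e.g.
#'   [default_archetypes()]); accession ids must be unique.
#' @param noise A [noise_spec()].
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @return An `"expression_panel"` object (see [expression_panel()]); the
#'   generating parameters are attached as attribute `"truth"`.
#' @export
#' @examples
#' panel <- generate_panel(default_archetypes(), noise_spec(), seed = 1)
#' panel
generate_panel <- function(archetypes = default_archetypes(),
                           noise = noise_spec(), seed = NULL) {
  if (!length(archetypes)) .stopf("'archetypes' must be a non-empty list")
  if (!all(vapply(archetypes, inherits, logical(1), "flc_archetype"))) {
    .stopf("every element of 'archetypes' must be an 'flc_archetype'")
  }
  if (!inherits(noise, "flc_noise_spec")) .stopf("'noise' must be a noise_spec()")
  ids <- vapply(archetypes, `[[`, character(1), "accession")
  if (anyDuplicated(ids)) .stopf("accession ids must be unique")

  days <- noise$timepoints
  reps <- noise$replicates
  with_seed(seed, {
    rows <- lapply(archetypes, function(arch) {
      roster <- names(arch$a)
      grid <- expand.grid(paralogue = roster, day = days,
                          replicate = seq_len(reps),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      mu <- arch$a[grid$paralogue] * exp(arch$b[grid$paralogue] * grid$day) +
        arch$c[grid$paralogue]
      eps <- if (noise$sigma_log > 0) rnorm(nrow(grid), 0, noise$sigma_log) else 0
      tpm <- mu * exp(eps)
      tpm[tpm < noise$detection_floor] <- 0
      data.frame(accession = arch$accession, paralogue = grid$paralogue,
                 day = grid$day, replicate = paste0("rep", grid$replicate),
                 tpm = tpm, stringsAsFactors = FALSE)
    })
    records <- do.call(rbind, rows)
    rownames(records) <- NULL
    meta <- data.frame(
      accession = ids,
      crop_type = vapply(archetypes, `[[`, character(1), "crop_type"),
      stringsAsFactors = FALSE)
    panel <- expression_panel(records, meta,
                              roster = names(archetypes[[1L]]$a))
    attr(panel, "truth") <- archetypes
    panel
  })
}

#' Generate the winter composition-strategy panel
#'
#' Builds a panel of winter accessions drawn from the three composition
#' strategies (A: high total, fast-paralogue heavy; B: low total, stable
#' heavy; C: high total, stable heavy), `n_per_strategy` accessions each.
#' Accessions within a strategy share the strategy archetype's generating
#' parameters and differ only by replicate noise. Clustering the day-0
#' composition ([composition_profiles()] + [cluster_profiles()]) and cutting
#' at the documented separation height ([strategy_cut_height()]) recovers
#' the planted strategies.
#'
#' @param n_per_strategy Accessions per strategy (>= 2 for clustering).
#' @param noise A [noise_spec()].
#' @param seed Integer seed or `NULL`.
#' @return An `"expression_panel"`; planted strategy labels are attached as
#'   attribute `"strategy"` (named by accession).
#' @export
winter_strategy_panel <- function(n_per_strategy = 4L, noise = noise_spec(),
                                  seed = NULL) {
  .assert_scalar_num(n_per_strategy, "n_per_strategy", lower = 1)
  defaults <- default_archetypes()
  winters <- Filter(function(a) a$crop_type == "winter", defaults)
  archs <- list()
  for (w in winters) {
    for (i in seq_len(n_per_strategy)) {
      a <- w
      a$accession <- sprintf("%s_%02d", w$accession, i)
      archs <- c(archs, list(a))
    }
  }
  panel <- generate_panel(archs, noise, seed = seed)
  labels <- vapply(archs, `[[`, character(1), "strategy")
  names(labels) <- vapply(archs, `[[`, character(1), "accession")
  attr(panel, "strategy") <- labels
  panel
}

#' Documented strategy-separation cut height
#'
#' The dendrogram height (Euclidean distance, TPM units) at which cutting
#' the average-linkage clustering of day-0 compositions from
#' [winter_strategy_panel()] separates the three planted strategies under
#' the default noise level. Between-strategy centroid distances in the
#' default archetypes exceed 70 TPM while within-strategy distances under
#' default noise stay well below this height.
#'
#' @return A single numeric height (TPM).
#' @export
strategy_cut_height <- function() 55

#' Generate a pre-vernalization expression panel
#'
#' Emulates a diversity panel measured once before vernalization (the
#' paper-scale design: 37 spring, 6 semi-winter, 43 winter and 9 swede
#' accessions). Each accession samples an archetype of its crop type
#' (winter accessions sample one of the three strategies uniformly) and its
#' day-0 per-paralogue levels are the archetype's `a + c` jittered by
#' lognormal factors `exp(N(0, jitter_log^2))`.
#'
#' @param n_per_type Named integer vector of accession counts per crop type.
#' @param jitter_log Log-scale standard deviation of between-accession
#'   composition jitter.
#' @param seed Integer seed or `NULL`.
#' @return List with `prevern` (accessions x paralogues matrix of day-0 TPM),
#'   `crop_type` (named character vector) and `archetype` (named character
#'   vector of the sampled source archetype).
#' @export
generate_prevernalization <- function(n_per_type = c(spring = 37, semi_winter = 6,
                                                     winter = 43, swede = 9),
                                      jitter_log = 0.3, seed = NULL) {
  if (is.null(names(n_per_type)) ||
      !all(names(n_per_type) %in% crop_types())) {
    .stopf("'n_per_type' must be named by crop type")
  }
  .assert_scalar_num(jitter_log, "jitter_log", lower = 0)
  defaults <- default_archetypes()
  by_type <- split(defaults, vapply(defaults, `[[`, character(1), "crop_type"))
  roster <- flc_paralogues()
  with_seed(seed, {
    rows <- list(); types <- character(0); sources <- character(0)
    for (ct in names(n_per_type)) {
      pool <- by_type[[ct]]
      if (is.null(pool)) .stopf("no default archetype for crop type '%s'", ct)
      for (i in seq_len(n_per_type[[ct]])) {
        arch <- pool[[sample.int(length(pool), 1L)]]
        acc <- sprintf("%s_%03d", ct, i)
        level <- (arch$a + arch$c)[roster] *
          exp(rnorm(length(roster), 0, jitter_log))
        level[(arch$a + arch$c)[roster] == 0] <- 0  # unexpressed stays zero
        rows[[acc]] <- level
        types <- c(types, setNames(ct, acc))
        sources <- c(sources, setNames(arch$accession, acc))
      }
    }
    prevern <- do.call(rbind, rows)
    colnames(prevern) <- roster
    list(prevern = prevern, crop_type = types, archetype = sources)
  })
}
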