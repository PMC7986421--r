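#' Gene-dynamics profile matrix
#'
#' Feature matrix for clustering genes by their expression dynamics: each
#' paralogue's replicate-mean TPM at every (accession, day) of the panel,
#' concatenated. A fitted-curve variant evaluates each gene's selected
#' decay model on the panel's day grid instead of using measured means.
#'
#' @param panel An `"expression_panel"`.
#' @param features `"measured"` (replicate means; default) or `"fitted"`
#'   (model predictions from [fit_panel()]).
#' @param fits Optional precomputed `"decay_fit_panel"` for
#'   `features = "fitted"`.
#' @return Numeric matrix, genes in rows.
#' @export
expression_profiles <- function(panel, features = c("measured", "fitted"),
                                fits = NULL) {
  features <- match.arg(features)
  if (features == "measured") return(mean_profile(panel, "gene"))
  if (is.null(fits)) fits <- fit_panel(panel)
  days <- sort(unique(panel$records$day))
  accs <- panel$meta$accession
  genes <- panel$roster
  m <- matrix(NA_real_, length(genes), length(accs) * length(days),
              dimnames = list(genes, as.vector(t(outer(accs, days, paste, sep = "@")))))
  for (g in genes) {
    for (acc in accs) {
      f <- fits$fits[[paste(acc, g, sep = ":")]]
      if (!is.null(f)) {
        m[g, paste(acc, days, sep = "@")] <- predict(f, days)
      }
    }
  }
  m
}

#' Accession composition profile matrix
#'
#' Feature matrix for clustering accessions by pre-vernalization FLC
#' composition: replicate-mean TPM per paralogue at a given day (default
#' day 0).
#'
#' @param panel An `"expression_panel"`.
#' @param day Day of cold at which to take the composition (default 0).
#' @return Numeric matrix, accessions in rows, paralogues in columns.
#' @export
composition_profiles <- function(panel, day = 0) {
  stopifnot(inherits(panel, "expression_panel"))
  rec <- panel$records[panel$records$day == day, ]
  if (!nrow(rec)) .stopf("no observations at day %g", day)
  agg <- aggregate(tpm ~ accession + paralogue, data = rec, FUN = mean)
  accs <- panel$meta$accession
  pars <- panel$roster
  m <- matrix(0, length(accs), length(pars), dimnames = list(accs, pars))
  keep <- agg$accession %in% accs & agg$paralogue %in% pars
  m[cbind(match(agg$accession[keep], accs), match(agg$paralogue[keep], pars))] <-
    agg$tpm[keep]
  m
}

#' Euclidean distances between profiles
#'
#' @param profiles Numeric matrix (entities in rows). Rows with missing
#'   entries are dropped with a warning; remaining entries must be finite.
#' @return A [stats::dist] object.
#' @export
profile_dist <- function(profiles) {
  if (!is.matrix(profiles)) .stopf("'profiles' must be a matrix")
  incomplete <- rowSums(!is.finite(profiles)) > 0
  if (any(incomplete)) {
    warning(sprintf("dropping %d profile(s) with missing entries: %s",
                    sum(incomplete),
                    paste(rownames(profiles)[incomplete], collapse = ", ")),
            call. = FALSE)
    profiles <- profiles[!incomplete, , drop = FALSE]
  }
  if (nrow(profiles) < 2L) .stopf("need >= 2 complete profiles")
  dist(profiles, method = "euclidean")
}

#' Agglomerative clustering of expression profiles
#'
#' Hierarchical clustering of a distance matrix. Distances are in TPM (no
#' feature scaling by default, so fixed-height cuts are on the TPM scale);
#' set `scale = TRUE` to z-scale columns first when calling
#' [profile_dist()] yourself.
#'
#' @param d A [stats::dist] object (e.g. from [profile_dist()]) or a
#'   symmetric matrix.
#' @param linkage `"average"` (UPGMA; default), `"single"`, `"complete"`
#'   or `"ward"` (Ward.D2).
#' @return An [stats::hclust] tree.
#' @export
#' @examples
#' panel <- winter_strategy_panel(seed = 1)
#' hc <- cluster_profiles(profile_dist(composition_profiles(panel)))
#' cut_clusters(hc, strategy_cut_height())
cluster_profiles <- function(d, linkage = c("average", "single", "complete", "ward")) {
  linkage <- match.arg(linkage)
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d))) .stopf("distance matrix must be symmetric")
    d <- stats::as.dist(d)
  }
  if (!inherits(d, "dist")) .stopf("'d' must be a dist object or symmetric matrix")
  if (any(!is.finite(d))) .stopf("non-finite distances")
  method <- if (linkage == "ward") "ward.D2" else linkage
  hclust(d, method = method)
}

#' Cut a dendrogram at a fixed height
#'
#' Clusters are the connected components of merges below `height`.
#' Labels are integers ordered by first appearance in the tree's leaf
#' order, so the labelling is invariant to the input entity order.
#'
#' @param hc An [stats::hclust] tree.
#' @param height Cut height (>= 0), in the units of the clustering distance.
#' @return Named integer vector of cluster labels.
#' @export
cut_clusters <- function(hc, height) {
  stopifnot(inherits(hc, "hclust"))
  .assert_scalar_num(height, "height", lower = 0)
  raw <- cutree(hc, h = height)
  # relabel in leaf order
  leaf_labels <- raw[hc$order]
  mapping <- setNames(seq_along(unique(leaf_labels)), unique(leaf_labels))
  out <- mapping[as.character(raw)]
  names(out) <- names(raw)
  out
}

#' Export a dendrogram as Newick
#'
#' Converts an [stats::hclust] tree to Newick text (merge heights as branch
#' lengths) via [ape::as.phylo()].
#'
#' @param hc An [stats::hclust] tree.
#' @param path Optional file to write to.
#' @return Newick string, invisibly if `path` is given.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  stopifnot(inherits(hc, "hclust"))
  tree <- ape::as.phylo(hc)
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
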