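#' Construct and validate an expression panel
#'
#' The panel is the central data container: a long (tidy) table of
#' replicate-level TPM observations indexed by accession, paralogue,
#' day-of-cold and replicate, plus accession metadata (crop type).
#'
#' @param records Data frame with columns `accession`, `paralogue`, `day`,
#'   `replicate`, `tpm`. TPM must be finite and >= 0; days >= 0; the key
#'   (accession, paralogue, day, replicate) must be unique.
#' @param meta Data frame with columns `accession`, `crop_type`; every
#'   accession present in `records` must appear exactly once.
#' @param roster Paralogue roster over which totals are taken; defaults to
#'   the nine *BnaFLC* ids.
#' @return An object of class `"expression_panel"`: a list with elements
#'   `records`, `meta`, `roster`.
#' @export
expression_panel <- function(records, meta, roster = flc_paralogues()) {
  need <- c("accession", "paralogue", "day", "replicate", "tpm")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    .stopf("'records' must be a data frame with columns %s",
           paste(need, collapse = ", "))
  }
  records <- records[need]
  for (col in c("accession", "paralogue", "replicate")) {
    records[[col]] <- as.character(records[[col]])
  }
  bad <- which(!is.finite(records$tpm) | records$tpm < 0)
  if (length(bad)) {
    .stopf("invalid TPM (negative or non-finite) in records row(s) %s",
           paste(head(bad, 5L), collapse = ", "))
  }
  bad <- which(!is.finite(records$day) | records$day < 0)
  if (length(bad)) {
    .stopf("invalid day (negative or non-finite) in records row(s) %s",
           paste(head(bad, 5L), collapse = ", "))
  }
  key <- paste(records$accession, records$paralogue, records$day,
               records$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    .stopf("duplicate (accession, paralogue, day, replicate) key in records row(s) %s",
           paste(head(which(duplicated(key)), 5L), collapse = ", "))
  }
  if (!is.data.frame(meta) || !all(c("accession", "crop_type") %in% names(meta))) {
    .stopf("'meta' must be a data frame with columns accession, crop_type")
  }
  meta <- data.frame(accession = as.character(meta$accession),
                     crop_type = as.character(meta$crop_type),
                     stringsAsFactors = FALSE)
  if (anyDuplicated(meta$accession)) .stopf("duplicate accession in metadata")
  unknown <- setdiff(meta$crop_type, crop_types())
  if (length(unknown)) {
    .stopf("unknown crop type(s): %s", paste(unknown, collapse = ", "))
  }
  missing_meta <- setdiff(unique(records$accession), meta$accession)
  if (length(missing_meta)) {
    .stopf("accession(s) without metadata: %s",
           paste(missing_meta, collapse = ", "))
  }
  structure(list(records = records, meta = meta, roster = roster),
            class = "expression_panel")
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf(
    "FLC expression panel: %d accessions, %d paralogues in roster, %d records\n",
    nrow(x$meta), length(x$roster), nrow(x$records)))
  days <- sort(unique(x$records$day))
  cat(sprintf("  days of cold: %s\n", paste(days, collapse = ", ")))
  tab <- table(x$meta$crop_type)
  cat(sprintf("  crop types: %s\n",
              paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Read an expression panel from TSV files
#'
#' @param path Tab-delimited panel file with header columns `accession`,
#'   `paralogue`, `day`, `replicate`, `tpm` (UTF-8, dot decimal).
#' @param meta_path Tab-delimited metadata file with header columns
#'   `accession`, `crop_type`.
#' @param roster Paralogue roster (default the nine *BnaFLC* ids).
#' @return An `"expression_panel"`. Malformed rows abort with the offending
#'   file line number (header = line 1).
#' @seealso [write_panel()]
#' @export
read_panel <- function(path, meta_path, roster = flc_paralogues()) {
  records <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "paralogue", "day", "replicate", "tpm")
  if (!all(need %in% names(records))) {
    .stopf("'%s': missing column(s) %s", path,
           paste(setdiff(need, names(records)), collapse = ", "))
  }
  # report malformed rows with their file line numbers (+1 for the header)
  bad <- which(!is.finite(records$tpm) | records$tpm < 0)
  if (length(bad)) {
    .stopf("'%s': negative or non-numeric tpm at line(s) %s", path,
           paste(bad + 1L, collapse = ", "))
  }
  bad <- which(!is.finite(records$day) | records$day < 0)
  if (length(bad)) {
    .stopf("'%s': negative or non-numeric day at line(s) %s", path,
           paste(bad + 1L, collapse = ", "))
  }
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  expression_panel(records, meta, roster = roster)
}

#' Write an expression panel to TSV files
#'
#' @param panel An `"expression_panel"`.
#' @param path,meta_path Output paths for the records and metadata tables.
#' @return Invisibly, `panel`.
#' @export
write_panel <- function(panel, path, meta_path) {
  stopifnot(inherits(panel, "expression_panel"))
  write.table(panel$records, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(panel$meta, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(panel)
}

#' Total FLC expression per sample
#'
#' Sums TPM over the paralogue roster for every (accession, day, replicate)
#' sample. Paralogues missing from a sequenced sample contribute 0
#' (quantified-but-absent).
#'
#' @param panel An `"expression_panel"`.
#' @return Data frame with columns `accession`, `day`, `replicate`, `tpm`
#'   (the total), of class `c("total_series", "data.frame")`.
#' @export
#' @examples
#' panel <- generate_panel(seed = 1)
#' head(total_flc(panel))
total_flc <- function(panel) {
  stopifnot(inherits(panel, "expression_panel"))
  rec <- panel$records[panel$records$paralogue %in% panel$roster, ]
  if (!nrow(rec)) .stopf("panel has no records for roster paralogues")
  agg <- aggregate(tpm ~ accession + day + replicate, data = rec, FUN = sum)
  agg <- agg[order(agg$accession, agg$day, agg$replicate), ]
  rownames(agg) <- NULL
  class(agg) <- c("total_series", "data.frame")
  agg
}

#' Replicate-mean expression profiles
#'
#' Builds the feature matrices used for strategy clustering.
#'
#' With `level = "gene"` rows are paralogues and columns are
#' (accession, day) pairs: the per-gene expression profile across the whole
#' panel, as used to cluster genes by their dynamics. With
#' `level = "accession_paralogue"` rows are accession:paralogue combinations
#' and columns are days. Cells are arithmetic means over replicates;
#' combinations never observed are `NA` and flagged via the `"missing"`
#' attribute.
#'
#' @param panel An `"expression_panel"`.
#' @param level `"gene"` or `"accession_paralogue"`.
#' @return Numeric matrix with informative dimnames.
#' @export
mean_profile <- function(panel, level = c("gene", "accession_paralogue")) {
  stopifnot(inherits(panel, "expression_panel"))
  level <- match.arg(level)
  rec <- panel$records
  agg <- aggregate(tpm ~ accession + paralogue + day, data = rec, FUN = mean)
  if (level == "gene") {
    col_id <- paste(agg$accession, agg$day, sep = "@")
    row_id <- agg$paralogue
    rows <- intersect(panel$roster, unique(row_id))
    accs <- sort(unique(agg$accession)); days <- sort(unique(agg$day))
    cols <- as.vector(t(outer(accs, days, paste, sep = "@")))
  } else {
    col_id <- as.character(agg$day)
    row_id <- paste(agg$accession, agg$paralogue, sep = ":")
    rows <- sort(unique(row_id))
    cols <- as.character(sort(unique(agg$day)))
  }
  m <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  keep <- row_id %in% rows
  m[cbind(match(row_id[keep], rows), match(col_id[keep], cols))] <- agg$tpm[keep]
  attr(m, "missing") <- which(is.na(m), arr.ind = TRUE)
  m
}
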