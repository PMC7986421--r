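#' Alignment scoring scheme
#'
#' Scores for the local-alignment read assignment: a positive match score
#' and non-positive mismatch/gap penalties. A gap of length L costs
#' `gap_open + (L - 1) * gap_extend` (linear when the two are equal, the
#' default).
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch penalty (<= 0).
#' @param gap_open,gap_extend Gap penalties (<= 0).
#' @return An object of class `"align_scoring"`.
#' @export
align_scoring <- function(match = 1, mismatch = -1, gap_open = -2,
                          gap_extend = -2) {
  .assert_scalar_num(match, "match", lower = 1e-12)
  .assert_scalar_num(mismatch, "mismatch", upper = 0)
  .assert_scalar_num(gap_open, "gap_open", upper = 0)
  .assert_scalar_num(gap_extend, "gap_extend", upper = 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "align_scoring")
}

#' Local alignment score of reads against a reference
#'
#' Smith-Waterman local alignment score (affine gaps, score only), the
#' stand-in for a read aligner when assigning reads among a small set of
#' near-identical paralogue references. `N` matches nothing (it scores as a
#' mismatch against every base).
#'
#' @param read Character vector of reads (A/C/G/T/N).
#' @param reference Single reference sequence.
#' @param scoring An [align_scoring()].
#' @return Numeric vector of scores (>= 0), one per read.
#' @export
#' @examples
#' local_align_score("ACGTACGT", "TTTACGTACGTTTT")
local_align_score <- function(read, reference, scoring = align_scoring()) {
  stopifnot(inherits(scoring, "align_scoring"))
  read <- as.character(read); reference <- as.character(reference)
  if (length(reference) != 1L || !nzchar(reference)) {
    .stopf("'reference' must be a single non-empty sequence")
  }
  if (!length(read) || any(!nzchar(read))) .stopf("'read' must be non-empty")
  .sw_score_batch(read, reference, scoring$match, scoring$mismatch,
                  scoring$gap_open, scoring$gap_extend)
}

#' Assign simulated reads to their best-scoring reference
#'
#' Scores every read (or read pair, mate scores summed) against every
#' reference on both strands and assigns it to the reference with the
#' strictly highest score. Reads whose best and second-best scores differ by
#' at most `tie_margin` are `ambiguous`; reads whose best score falls below
#' `min_score_frac * match * read length` are `unassigned`. When the true
#' origins are supplied, a confusion matrix (rows: true origin; columns:
#' references plus `ambiguous`/`unassigned`) and mis-assignment rates are
#' tabulated. Ambiguous reads are excluded from the mis-assignment
#' numerator but reported.
#'
#' @param reads Named character vector (or DNAStringSet) of reads.
#' @param references Named character vector (or DNAStringSet) of references.
#' @param truth Optional data frame with columns `read_id`, `origin`.
#' @param mates Optional named character vector of second mates (same names
#'   as `reads`).
#' @param scoring An [align_scoring()].
#' @param tie_margin Score margin within which the top two references tie.
#' @param min_score_frac Fraction of the maximum attainable score below
#'   which a read is unassigned.
#' @return Object of class `"mismap_result"`: `assignments` (data frame:
#'   `read_id`, `assigned`, `best_score`, `margin`), and when `truth` is
#'   given `confusion` (matrix), `per_origin_correct` (named rates) and
#'   `rates` (list: `misassigned`, `ambiguous`, `unassigned`, `correct`).
#' @export
#' @examples
#' fam <- generate_paralogue_family(2, 300, identity = 95, seed = 1)
#' rr <- generate_reads(fam, read_length = 80, error_rate = 0, depth = 20,
#'                      seed = 2)
#' res <- assign_reads(rr$reads, fam, truth = rr$truth)
#' res
assign_reads <- function(reads, references, truth = NULL, mates = NULL,
                         scoring = align_scoring(), tie_margin = 0,
                         min_score_frac = 0.6) {
  refs <- .as_named_character(references, "references")
  if (!length(refs)) .stopf("empty reference set")
  reads <- .as_named_character(reads, "reads")
  .assert_scalar_num(tie_margin, "tie_margin", lower = 0)
  .assert_scalar_num(min_score_frac, "min_score_frac", lower = 0, upper = 1)

  score_block <- function(seqs) {
    rc <- .revcomp(seqs)
    vapply(refs, function(ref) {
      pmax(.sw_score_batch(seqs, ref, scoring$match, scoring$mismatch,
                           scoring$gap_open, scoring$gap_extend),
           .sw_score_batch(rc, ref, scoring$match, scoring$mismatch,
                           scoring$gap_open, scoring$gap_extend))
    }, numeric(length(seqs)))
  }
  scores <- score_block(reads)           # reads x refs
  if (!is.matrix(scores)) scores <- matrix(scores, nrow = length(reads),
                                           dimnames = list(NULL, names(refs)))
  total_len <- nchar(reads)
  if (!is.null(mates)) {
    mates <- .as_named_character(mates, "mates")
    if (!identical(names(mates), names(reads))) {
      .stopf("'mates' must be named identically to 'reads'")
    }
    ms <- score_block(mates)
    if (!is.matrix(ms)) ms <- matrix(ms, nrow = length(mates))
    scores <- scores + ms
    total_len <- total_len + nchar(mates)
  }
  ord <- t(apply(scores, 1L, function(s) -sort(-s)[1:2]))
  best <- ord[, 1L]
  second <- if (ncol(scores) > 1L) ord[, 2L] else -Inf
  assigned <- colnames(scores)[max.col(scores, ties.method = "first")]
  min_score <- min_score_frac * scoring$match * total_len
  assigned[best - second <= tie_margin] <- "ambiguous"
  assigned[best < min_score] <- "unassigned"
  assignments <- data.frame(read_id = names(reads), assigned = assigned,
                            best_score = best, margin = best - second,
                            stringsAsFactors = FALSE)
  out <- list(assignments = assignments, references = names(refs))
  if (!is.null(truth)) {
    if (!all(c("read_id", "origin") %in% names(truth))) {
      .stopf("'truth' must have columns read_id, origin")
    }
    origin <- setNames(truth$origin, truth$read_id)[names(reads)]
    if (anyNA(origin)) .stopf("truth table missing read id(s)")
    cols <- c(names(refs), "ambiguous", "unassigned")
    confusion <- table(factor(origin, levels = names(refs)),
                       factor(assigned, levels = cols))
    confusion <- unclass(confusion)
    names(dimnames(confusion)) <- c("true_origin", "assigned")
    correct <- assigned == origin
    wrong <- assigned %in% names(refs) & !correct
    per_origin <- vapply(names(refs), function(r) {
      sel <- origin == r
      if (!any(sel)) NA_real_ else mean(correct[sel])
    }, numeric(1))
    out$confusion <- confusion
    out$per_origin_correct <- per_origin
    out$rates <- list(
      misassigned = mean(wrong),
      ambiguous = mean(assigned == "ambiguous"),
      unassigned = mean(assigned == "unassigned"),
      correct = mean(correct))
  }
  class(out) <- "mismap_result"
  out
}

#' @export
print.mismap_result <- function(x, ...) {
  cat(sprintf("Read assignment against %d references: %d reads\n",
              length(x$references), nrow(x$assignments)))
  if (!is.null(x$rates)) {
    cat(sprintf("  correct %.2f%%, mis-assigned %.2f%%, ambiguous %.2f%%, unassigned %.2f%%\n",
                100 * x$rates$correct, 100 * x$rates$misassigned,
                100 * x$rates$ambiguous, 100 * x$rates$unassigned))
    cat("Confusion matrix (true origin x assigned):\n")
    print(x$confusion)
  }
  invisible(x)
}

#' Write a confusion matrix to TSV
#'
#' @param result A `"mismap_result"` with a confusion matrix.
#' @param path Output path.
#' @return Invisibly, the confusion matrix.
#' @export
write_confusion <- function(result, path) {
  stopifnot(inherits(result, "mismap_result"))
  if (is.null(result$confusion)) .stopf("result has no confusion matrix (no truth)")
  df <- data.frame(true_origin = rownames(result$confusion),
                   result$confusion, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(result$confusion)
}
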