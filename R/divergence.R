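#' Global protein alignment
#'
#' Needleman-Wunsch global alignment of two amino-acid sequences
#' (BLOSUM62 by default, affine gaps), the first step of codon-aware CDS
#' alignment. Stop codons translate to `*`, which BLOSUM62 scores, so
#' pseudogene translations align without special casing.
#'
#' @param seq_a,seq_b Amino-acid sequences (single strings).
#' @param substitution_matrix Matrix name (e.g. `"BLOSUM62"`) or a numeric
#'   substitution matrix.
#' @param gap_open,gap_extend Gap opening/extension penalties (positive).
#' @return List with `a`, `b` (aligned strings with `-` gaps) and `score`.
#' @export
#' @examples
#' global_protein_align("ACD", "AD")
global_protein_align <- function(seq_a, seq_b,
                                 substitution_matrix = "BLOSUM62",
                                 gap_open = 10, gap_extend = 1) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) .stopf("sequences must be non-empty")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  list(a = as.character(Biostrings::alignedPattern(al)),
       b = as.character(Biostrings::alignedSubject(al)),
       score = Biostrings::score(al))
}

#' Translate a coding sequence
#'
#' Standard genetic code; the trailing stop codon, if present, is removed
#' before translation. Internal stops appear as `*` (pseudogenes).
#'
#' @param cds Nucleotide coding sequence (length a multiple of 3).
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3 != 0) .stopf("CDS length must be a multiple of 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           no.init.codon = TRUE))
  sub("\\*$", "", aa)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Replaces each aligned residue by its source codon and each protein gap by
#' a `---` codon gap (the pal2nal-style construction), producing an in-frame
#' nucleotide alignment whose gaps occur only in whole-codon units.
#'
#' @param protein_alignment List with aligned strings `a` and `b` (from
#'   [global_protein_align()]).
#' @param cds_a,cds_b The source coding sequences; each must translate to
#'   its aligned protein (gaps removed). A trailing stop codon is ignored.
#' @param pseudogene If `TRUE`, internal stop codons are permitted.
#' @return Object of class `"codon_alignment"`: list with `seqs` (character
#'   vector of the two aligned nucleotide sequences) and `pseudogene`.
#' @export
codon_backtranslate <- function(protein_alignment, cds_a, cds_b,
                                pseudogene = FALSE) {
  aln <- c(protein_alignment$a, protein_alignment$b)
  cds <- c(.strip_stop(cds_a), .strip_stop(cds_b))
  out <- character(2L)
  for (i in 1:2) {
    prot <- gsub("-", "", aln[i], fixed = TRUE)
    trans <- translate_cds(cds[i])
    if (!identical(trans, prot)) {
      .stopf("CDS %d does not translate to its aligned protein", i)
    }
    if (!pseudogene && grepl("*", prot, fixed = TRUE)) {
      .stopf("internal stop codon in CDS %d; set pseudogene = TRUE to allow", i)
    }
    res <- strsplit(aln[i], "", fixed = TRUE)[[1L]]
    codons <- substring(cds[i], seq(1L, nchar(cds[i]), 3L),
                        seq(3L, nchar(cds[i]), 3L))
    filled <- rep("---", length(res))
    filled[res != "-"] <- codons
    out[i] <- paste(filled, collapse = "")
  }
  structure(list(seqs = out, pseudogene = pseudogene),
            class = "codon_alignment")
}

.strip_stop <- function(cds) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3 != 0) .stopf("CDS length must be a multiple of 3")
  last <- substring(cds, nchar(cds) - 2L, nchar(cds))
  if (.genetic_code()[[last]] == "*") cds <- substring(cds, 1L, nchar(cds) - 3L)
  cds
}

#' Codon-aware alignment of two coding sequences
#'
#' Convenience wrapper: translate, globally align the proteins, and
#' back-translate to a codon alignment.
#'
#' @param cds_a,cds_b Coding sequences.
#' @param pseudogene Allow internal stop codons?
#' @param ... Passed to [global_protein_align()].
#' @return A `"codon_alignment"`.
#' @export
codon_align <- function(cds_a, cds_b, pseudogene = FALSE, ...) {
  pa <- global_protein_align(translate_cds(.strip_stop(cds_a)),
                             translate_cds(.strip_stop(cds_b)), ...)
  codon_backtranslate(pa, cds_a, cds_b, pseudogene = pseudogene)
}

#' Pairwise sequence identity
#'
#' Percent identical positions between two aligned sequences. By default
#' columns containing a gap are excluded from the denominator (identical
#' sites / aligned non-gap sites); set `include_gaps = TRUE` to count them
#' as differences.
#'
#' @param aligned_pair Character vector of two aligned sequences of equal
#'   length, or a `"codon_alignment"`.
#' @param include_gaps Count gap columns in the denominator?
#' @return Identity in percent.
#' @export
#' @examples
#' pairwise_identity(c("ACGT", "ACGA"))  # 75
pairwise_identity <- function(aligned_pair, include_gaps = FALSE) {
  if (inherits(aligned_pair, "codon_alignment")) aligned_pair <- aligned_pair$seqs
  if (length(aligned_pair) != 2L) .stopf("need exactly two aligned sequences")
  if (nchar(aligned_pair[1L]) != nchar(aligned_pair[2L])) {
    .stopf("aligned sequences must have equal length")
  }
  a <- strsplit(toupper(aligned_pair[1L]), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(aligned_pair[2L]), "", fixed = TRUE)[[1L]]
  gap <- a == "-" | b == "-"
  if (include_gaps) {
    denom <- length(a)
    matches <- sum(a == b & !gap)
  } else {
    denom <- sum(!gap)
    matches <- sum(a[!gap] == b[!gap])
  }
  if (denom == 0) .stopf("no comparable columns")
  100 * matches / denom
}

#' Nei-Gojobori dN/dS for a codon alignment pair
#'
#' The Nei and Gojobori (1986) method with Jukes-Cantor correction. Each
#' codon contributes fractional synonymous site counts (per position, the
#' fraction of the three possible changes that are synonymous; changes to
#' stop codons count as nonsynonymous, so S + N = 3 x compared codons).
#' Differences in codons that differ at multiple positions are averaged with
#' equal weight over all substitution pathways, excluding pathways through
#' stop codons (all pathways are used if every one is blocked). Codons
#' containing gaps, ambiguity characters or stop codons are skipped.
#'
#' Proportions are corrected as `d = -(3/4) log(1 - 4p/3)`; `omega = dN/dS`
#' is `NA` with flag `"undefined_omega"` when `dS = 0`, and a proportion
#' at or beyond the correction's domain (`p >= 3/4`) flags `"saturated"`.
#'
#' @param alignment A `"codon_alignment"` or character vector of two equal
#'   length, in-frame aligned coding sequences.
#' @return Object of class `"dnds"`: list with `S`, `N`, `Sd`, `Nd`, `pS`,
#'   `pN`, `dS`, `dN`, `omega`, `n_codons` (compared), `flags`.
#' @export
#' @examples
#' r <- nei_gojobori(c("TTTGGGCCCAAA", "TTCGGGCCCAAA"))
#' r$S   # 8/3
#' r$dS  # 0.5199
nei_gojobori <- function(alignment) {
  if (inherits(alignment, "codon_alignment")) alignment <- alignment$seqs
  if (length(alignment) != 2L) .stopf("need exactly two aligned sequences")
  s1 <- toupper(alignment[1L]); s2 <- toupper(alignment[2L])
  if (nchar(s1) != nchar(s2)) .stopf("aligned sequences must have equal length")
  if (nchar(s1) %% 3 != 0) .stopf("alignment length must be a multiple of 3")
  code <- .genetic_code()
  idx <- seq(1L, nchar(s1), 3L)
  c1 <- substring(s1, idx, idx + 2L)
  c2 <- substring(s2, idx, idx + 2L)
  valid_codon <- function(x) {
    !is.na(code[x]) & code[x] != "*" & !grepl("[^ACGT]", x)
  }
  keep <- valid_codon(c1) & valid_codon(c2)
  c1 <- c1[keep]; c2 <- c2[keep]
  if (!length(c1)) .stopf("no comparable codons")

  S <- (sum(vapply(c1, .syn_sites, numeric(1), code = code)) +
          sum(vapply(c2, .syn_sites, numeric(1), code = code))) / 2
  N <- 3 * length(c1) - S
  Sd <- 0; Nd <- 0
  for (k in seq_along(c1)) {
    d <- .pathway_diffs(c1[k], c2[k], code)
    Sd <- Sd + d[1L]; Nd <- Nd + d[2L]
  }
  pS <- Sd / S; pN <- Nd / N
  flags <- character(0)
  jc <- function(p) {
    if (p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS); dN <- jc(pN)
  if (anyNA(c(dS, dN))) flags <- c(flags, "saturated")
  omega <- if (is.na(dS) || is.na(dN)) NA_real_
    else if (dS == 0) { flags <- c(flags, "undefined_omega"); NA_real_ }
    else dN / dS
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN, omega = omega, n_codons = length(c1),
                 flags = flags),
            class = "dnds")
}

#' @export
print.dnds <- function(x, ...) {
  cat(sprintf("Nei-Gojobori dN/dS over %d codons\n", x$n_codons))
  cat(sprintf("  S = %.4g, N = %.4g, Sd = %.4g, Nd = %.4g\n",
              x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  dS = %.4g, dN = %.4g, omega = %s\n", x$dS, x$dN,
              if (is.na(x$omega)) "undefined" else sprintf("%.4g", x$omega)))
  if (length(x$flags)) cat(sprintf("  flags: %s\n", paste(x$flags, collapse = ", ")))
  invisible(x)
}

# fraction of synonymous sites in one codon (denominator 3 per position;
# changes to stop codons count as nonsynonymous)
.syn_sites <- function(codon, code) {
  nts <- c("A", "C", "G", "T")
  aa <- code[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(nts, substr(codon, pos, pos))) {
      v <- codon
      substr(v, pos, pos) <- nt
      if (code[[v]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# synonymous/nonsynonymous difference counts between two codons, averaged
# with equal weight over substitution pathways; pathways through stop codons
# are dropped (all retained if every pathway is blocked)
.pathway_diffs <- function(codon1, codon2, code) {
  pos <- which(strsplit(codon1, "")[[1L]] != strsplit(codon2, "")[[1L]])
  if (!length(pos)) return(c(0, 0))
  if (length(pos) == 1L) {
    syn <- code[[codon1]] == code[[codon2]]
    return(if (syn) c(1, 0) else c(0, 1))
  }
  perms <- if (length(pos) == 2L) list(pos, rev(pos)) else {
    do.call(c, lapply(seq_along(pos), function(i) {
      rest <- pos[-i]
      lapply(list(rest, rev(rest)), function(r) c(pos[i], r))
    }))
  }
  paths <- lapply(perms, function(order) {
    cur <- codon1; sd <- 0; nd <- 0; blocked <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(codon2, p, p)
      if (code[[nxt]] == "*") { blocked <- TRUE; break }
      if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (blocked) NULL else c(sd, nd)
  })
  ok <- Filter(Negate(is.null), paths)
  if (!length(ok)) {
    # all pathways pass through a stop; retain them, scoring steps by
    # amino-acid change with stops treated as nonsynonymous steps
    ok <- lapply(perms, function(order) {
      cur <- codon1; sd <- 0; nd <- 0
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(codon2, p, p)
        if (code[[nxt]] != "*" && code[[nxt]] == code[[cur]]) sd <- sd + 1
        else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    })
  }
  colMeans(do.call(rbind, ok))
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration via [ape::nj()]. Negative branch lengths are
#' clamped to zero and flagged in the `"clamped"` attribute.
#'
#' @param d Symmetric non-negative distance matrix (or [stats::dist]),
#'   n >= 2 taxa.
#' @return An [ape::read.tree()]-style `"phylo"` tree (unrooted).
#' @export
#' @examples
#' d <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
#' nj_tree(d)
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || !isSymmetric(unname(d))) {
    .stopf("'d' must be a symmetric distance matrix")
  }
  if (any(d < 0) || any(!is.finite(d))) .stopf("distances must be finite and >= 0")
  n <- nrow(d)
  if (n < 2L) .stopf("need >= 2 taxa")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  }
  if (n == 2L) {
    tree <- ape::read.tree(text = sprintf("(%s:%g,%s:%g);", rownames(d)[1L],
                                          d[1L, 2L] / 2, rownames(d)[2L],
                                          d[1L, 2L] / 2))
    attr(tree, "clamped") <- FALSE
    return(tree)
  }
  tree <- ape::nj(d)
  clamped <- any(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped") <- clamped
  tree
}

#' Jukes-Cantor distances on a codon (or nucleotide) alignment
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @return Symmetric distance matrix (pairwise gap deletion).
#' @export
jc_distance <- function(seqs) {
  m <- .seq_matrix(seqs)
  dna <- ape::as.DNAbin(m)
  as.matrix(ape::dist.dna(dna, model = "JC69", pairwise.deletion = TRUE))
}

.seq_matrix <- function(seqs) {
  seqs <- .as_named_character(seqs, "seqs")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) .stopf("sequences must have equal length")
  m <- do.call(rbind, strsplit(tolower(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

#' Neighbour-joining tree with bootstrap support
#'
#' Builds the full-data NJ tree from Jukes-Cantor distances on the
#' alignment, then resamples alignment columns with replacement (whole
#' codons for in-frame alignments), rebuilds the tree per replicate, and
#' reports each internal bipartition's frequency as a percentage on the
#' full-data tree.
#'
#' @param seqs Named character vector of >= 4 equal-length aligned coding
#'   sequences (gap-free columns are resampled; columns with gaps are
#'   dropped first).
#' @param n_replicates Bootstrap replicates (default 1000).
#' @param seed Integer seed or `NULL`.
#' @param codon Resample codon columns (default) or single nucleotides.
#' @return List of class `"nj_bootstrap"`: `tree` (the full-data `"phylo"`
#'   with `node.label` set to support percentages), `support` (numeric),
#'   `n_replicates`, `flags` (contains `"arbitrary_topology"` when the
#'   alignment has no variable sites).
#' @export
bootstrap_support <- function(seqs, n_replicates = 1000L, seed = NULL,
                              codon = TRUE) {
  if (n_replicates < 1) .stopf("'n_replicates' must be >= 1")
  m <- .seq_matrix(seqs)
  if (nrow(m) < 4L) .stopf("need >= 4 taxa for bootstrap support")
  has_gap <- colSums(m == "-") > 0
  if (codon) {
    ncod <- ncol(m) %/% 3L
    if (ncod * 3L != ncol(m)) .stopf("alignment length must be a multiple of 3")
    gap_codon <- colSums(matrix(has_gap, nrow = 3L)) > 0
    keep_cols <- rep(!gap_codon, each = 3L)
  } else keep_cols <- !has_gap
  m <- m[, keep_cols, drop = FALSE]
  flags <- character(0)
  informative <- sum(apply(m, 2L, function(col) length(unique(col)) > 1L))
  if (informative == 0L) flags <- c(flags, "arbitrary_topology")

  dist_of <- function(mm) {
    as.matrix(ape::dist.dna(ape::as.DNAbin(mm), model = "JC69",
                            pairwise.deletion = TRUE))
  }
  full <- nj_tree(dist_of(m))
  n_units <- if (codon) ncol(m) %/% 3L else ncol(m)
  trees <- with_seed(seed, lapply(seq_len(n_replicates), function(i) {
    u <- sample.int(n_units, n_units, replace = TRUE)
    cols <- if (codon) as.vector(rbind(3L * u - 2L, 3L * u - 1L, 3L * u)) else u
    nj_tree(dist_of(m[, cols, drop = FALSE]))
  }))
  counts <- ape::prop.clades(full, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / n_replicates
  full$node.label <- formatC(support, format = "f", digits = 1)
  structure(list(tree = full, support = support,
                 n_replicates = n_replicates, flags = flags),
            class = "nj_bootstrap")
}

#' @export
print.nj_bootstrap <- function(x, ...) {
  cat(sprintf("NJ tree with bootstrap support (%d replicates)\n",
              x$n_replicates))
  cat(sprintf("  supports: %s\n",
              paste(formatC(x$support, format = "f", digits = 1),
                    collapse = ", ")))
  if (length(x$flags)) cat(sprintf("  flags: %s\n", paste(x$flags, collapse = ", ")))
  cat(sprintf("  newick: %s\n", ape::write.tree(x$tree)))
  invisible(x)
}
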