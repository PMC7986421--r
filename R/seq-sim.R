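#' Simulate a family of near-identical paralogue coding sequences
#'
#' Evolves `n_paralogues` in-frame coding sequences from a random common
#' ancestor on a star topology. Each paralogue mutates its own set of codons
#' (disjoint between paralogues), so the realised pairwise difference count
#' between two paralogues is the sum of their per-branch mutation counts and
#' the pairwise identity hits the target essentially exactly. Mutated sites
#' can be spread evenly along the sequence (`positions = "even"`), which
#' guarantees diagnostic sites in every read-length window of moderate size,
#' or placed at random codons.
#'
#' Each mutation is synonymous with probability
#' `syn_weight / (syn_weight + nonsyn_weight)` when the codon admits a
#' synonymous single-nucleotide change; changes creating stop codons are
#' avoided unless `pseudogene = TRUE`.
#'
#' @param n_paralogues Number of sequences (>= 2).
#' @param length Ancestor length in nucleotides (multiple of 3, >= 30).
#' @param identity Target pairwise identity in percent, in (0, 100].
#' @param syn_weight,nonsyn_weight Relative weights of synonymous vs
#'   nonsynonymous substitutions.
#' @param positions `"even"` or `"random"` placement of mutated codons.
#' @param pseudogene If `TRUE`, internal stop codons may be created.
#' @param seed Integer seed or `NULL`.
#' @return A [Biostrings::DNAStringSet] named `paralog_01`, ... with the
#'   ancestor attached as attribute `"ancestor"`.
#' @export
#' @examples
#' fam <- generate_paralogue_family(2, length = 600, identity = 98.5, seed = 1)
#' fam
generate_paralogue_family <- function(n_paralogues = 2L, length = 600L,
                                      identity = 98.5, syn_weight = 1,
                                      nonsyn_weight = 1,
                                      positions = c("even", "random"),
                                      pseudogene = FALSE, seed = NULL) {
  .assert_scalar_num(n_paralogues, "n_paralogues", lower = 2)
  .assert_scalar_num(length, "length", lower = 30)
  if (length %% 3 != 0) .stopf("'length' must be a multiple of 3")
  if (!is.numeric(identity) || identity <= 0 || identity > 100) {
    .stopf("'identity' must be in (0, 100] percent")
  }
  .assert_scalar_num(syn_weight, "syn_weight", lower = 0)
  .assert_scalar_num(nonsyn_weight, "nonsyn_weight", lower = 0)
  if (syn_weight + nonsyn_weight <= 0) .stopf("weights must not both be zero")
  positions <- match.arg(positions)

  code <- .genetic_code()
  sense <- names(code)[code != "*"]
  n_codons <- length %/% 3L
  # per-pair mismatch target; split across the two branches
  m_pair <- round(length * (1 - identity / 100))
  d_branch <- rep(c(ceiling(m_pair / 2), floor(m_pair / 2)),
                  length.out = n_paralogues)
  total_sites <- sum(d_branch)
  if (total_sites > n_codons) {
    .stopf("identity target unreachable: %d mutated codons needed, %d available",
           total_sites, n_codons)
  }

  with_seed(seed, {
    anc_codons <- sample(sense, n_codons, replace = TRUE)
    site_pool <- if (total_sites == 0) integer(0)
      else if (positions == "even") {
        unique(pmin(n_codons, ceiling(seq_len(total_sites) *
                                        n_codons / total_sites)))
      } else sort(sample.int(n_codons, total_sites))
    if (length(site_pool) < total_sites) {  # collision fallback
      extra <- setdiff(seq_len(n_codons), site_pool)
      site_pool <- sort(c(site_pool, extra[seq_len(total_sites - length(site_pool))]))
    }
    # round-robin assignment interleaves the paralogues' sites along the
    # gene while honouring each branch's mutation count exactly
    owner <- integer(total_sites)
    remaining <- d_branch
    k <- 1L
    for (i in seq_len(total_sites)) {
      while (remaining[k] == 0L) k <- k %% n_paralogues + 1L
      owner[i] <- k
      remaining[k] <- remaining[k] - 1L
      k <- k %% n_paralogues + 1L
    }
    seqs <- character(n_paralogues)
    p_syn <- syn_weight / (syn_weight + nonsyn_weight)
    # codons not scheduled for mutation, available as nearby replacement
    # sites when a codon cannot realise the requested substitution class
    free <- setdiff(seq_len(n_codons), site_pool)
    for (k in seq_len(n_paralogues)) {
      codons <- anc_codons
      for (site in site_pool[owner == k]) {
        want_syn <- runif(1) < p_syn
        v <- .codon_variants(anc_codons[site], code, pseudogene)
        pool <- v$vars[v$syn == want_syn]
        if (!length(pool) && length(free)) {
          # e.g. Met/Trp admit no synonymous change: move the mutation to
          # the nearest untouched codon that does
          for (cand in free[order(abs(free - site))]) {
            vv <- .codon_variants(anc_codons[cand], code, pseudogene)
            cand_pool <- vv$vars[vv$syn == want_syn]
            if (length(cand_pool)) {
              free <- setdiff(free, cand)
              site <- cand
              pool <- cand_pool
              break
            }
          }
        }
        if (!length(pool)) pool <- v$vars
        if (!length(pool)) next
        codons[site] <- pool[sample.int(length(pool), 1L)]
      }
      seqs[k] <- paste(codons, collapse = "")
    }
    out <- Biostrings::DNAStringSet(setNames(seqs, sprintf("paralog_%02d",
                                                           seq_len(n_paralogues))))
    attr(out, "ancestor") <- paste(anc_codons, collapse = "")
    out
  })
}

.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

# All single-nucleotide variants of a codon, classified as synonymous or not.
.codon_variants <- function(codon, code, allow_stop) {
  nts <- c("A", "C", "G", "T")
  aa <- code[[codon]]
  vars <- character(0); syn <- logical(0)
  for (pos in 1:3) {
    for (nt in setdiff(nts, substr(codon, pos, pos))) {
      v <- codon
      substr(v, pos, pos) <- nt
      if (code[[v]] == "*" && !allow_stop) next
      vars <- c(vars, v)
      syn <- c(syn, code[[v]] == aa)
    }
  }
  list(vars = vars, syn = syn)
}

#' Simulate sequencing reads with known origin
#'
#' Draws reads uniformly along each reference, with i.i.d. substitution
#' errors at `error_rate` per base (no indels). In paired mode each fragment
#' of `insert` nucleotides yields a forward mate at the fragment start and a
#' reverse-complemented mate at its end, so mate start offsets equal
#' `insert - read_length`. In single-end mode read orientation is random.
#'
#' @param references Named character vector or [Biostrings::DNAStringSet].
#' @param read_length Read length in nt (<= shortest reference).
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param depth Reads (or read pairs) per reference (> 0).
#' @param paired Simulate read pairs?
#' @param insert Fragment length for paired mode (`read_length <= insert <=`
#'   reference length).
#' @param seed Integer seed or `NULL`.
#' @return List with `reads` (character, named by read id), `mates`
#'   (character or `NULL`) and `truth` (data frame: `read_id`, `origin`,
#'   `start`, `strand`).
#' @export
#' @examples
#' fam <- generate_paralogue_family(2, 600, 98.5, seed = 1)
#' rr <- generate_reads(fam, read_length = 150, error_rate = 0, depth = 10,
#'                      seed = 2)
#' head(rr$truth)
generate_reads <- function(references, read_length = 150L, error_rate = 0.001,
                           depth = 100L, paired = FALSE, insert = 300L,
                           seed = NULL) {
  refs <- .as_named_character(references, "references")
  .assert_scalar_num(read_length, "read_length", lower = 1)
  .assert_scalar_num(error_rate, "error_rate", lower = 0, upper = 0.999)
  if (depth <= 0) .stopf("'depth' must be > 0")
  lens <- nchar(refs)
  if (read_length > min(lens)) .stopf("read_length exceeds a reference length")
  if (paired) {
    .assert_scalar_num(insert, "insert", lower = read_length)
    if (insert > min(lens)) .stopf("'insert' exceeds a reference length")
  }
  with_seed(seed, {
    reads <- character(0); mates <- character(0)
    ids <- character(0); origins <- character(0)
    starts <- integer(0); strands <- character(0)
    for (ref_id in names(refs)) {
      ref <- refs[[ref_id]]
      span <- if (paired) insert else read_length
      start <- sample.int(nchar(ref) - span + 1L, depth, replace = TRUE)
      r1 <- substring(ref, start, start + read_length - 1L)
      if (paired) {
        m_start <- start + insert - read_length
        r2 <- .revcomp(substring(ref, m_start, m_start + read_length - 1L))
        strand <- rep("+", depth)
      } else {
        flip <- runif(depth) < 0.5
        r1[flip] <- .revcomp(r1[flip])
        strand <- ifelse(flip, "-", "+")
      }
      id <- sprintf("%s_read_%05d", ref_id, seq_len(depth))
      reads <- c(reads, setNames(.add_errors(r1, error_rate), id))
      if (paired) mates <- c(mates, setNames(.add_errors(r2, error_rate), id))
      ids <- c(ids, id); origins <- c(origins, rep(ref_id, depth))
      starts <- c(starts, start); strands <- c(strands, strand)
    }
    list(reads = reads, mates = if (paired) mates else NULL,
         truth = data.frame(read_id = ids, origin = origins, start = starts,
                            strand = strands, stringsAsFactors = FALSE))
  })
}

.as_named_character <- function(x, what) {
  if (inherits(x, "DNAStringSet")) x <- as.character(x)
  if (!is.character(x) || is.null(names(x)) || anyDuplicated(names(x))) {
    .stopf("'%s' must be a named character vector or DNAStringSet with unique names",
           what)
  }
  toupper(x)
}

.revcomp <- function(x) {
  if (!length(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# i.i.d. substitution errors; each error picks one of the 3 other bases
.add_errors <- function(reads, error_rate) {
  if (error_rate == 0 || !length(reads)) return(reads)
  nts <- c("A", "C", "G", "T")
  vapply(reads, function(r) {
    n <- nchar(r)
    hit <- which(runif(n) < error_rate)
    if (!length(hit)) return(r)
    chars <- strsplit(r, "", fixed = TRUE)[[1L]]
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(nts, b), 1L)
    }, character(1))
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write reads to FASTQ and the origin truth table to TSV
#'
#' @param sim Output of [generate_reads()].
#' @param fastq_path Path for the (first-mate) FASTQ file.
#' @param mate_path Optional path for the second-mate FASTQ file.
#' @param truth_path Optional path for the truth TSV
#'   (`read_id`, `origin`, `start`, `strand`).
#' @param quality Constant Phred+33 quality character (default `"I"`, Q40).
#' @return Invisibly, `sim`.
#' @export
write_reads <- function(sim, fastq_path, mate_path = NULL, truth_path = NULL,
                        quality = "I") {
  .write_fastq(sim$reads, fastq_path, quality)
  if (!is.null(mate_path)) {
    if (is.null(sim$mates)) .stopf("no mates to write")
    .write_fastq(sim$mates, mate_path, quality)
  }
  if (!is.null(truth_path)) {
    write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(sim)
}

.write_fastq <- function(reads, path, quality) {
  qs <- Biostrings::BStringSet(vapply(nchar(reads), function(n) {
    strrep(quality, n)
  }, character(1)))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads),
    Biostrings::PhredQuality(qs))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}
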