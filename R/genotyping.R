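# CRISPR single-allele genotyping: classify amplicon sequences against a
# reference by global alignment, census wild-type vs edited alleles with an
# exact two-sided binomial heterozygosity test, and locate frameshift-
# induced premature stop codons.

#' Classify one allele sequence against the reference
#'
#' Global (Needleman-Wunsch) alignment with match +1, mismatch -1, gap -2;
#' the net gap length falling within `window_bp` of the expected Cas9 cut
#' site determines the class: `insertion(+n)`, `deletion(-n)`, `wt` (zero
#' differences), or `complex` (differences that are not a single clean
#' indel at the cut site).
#'
#' @param seq Allele sequence (character or DNAString).
#' @param ref Reference amplicon (character or DNAString).
#' @param cut_site 1-based position of the predicted double-strand break in
#'   the reference.
#' @param window_bp Inspection window around the cut site (>= 10).
#' @return Object of class `allele_call`: `class` (`"wt"`, `"insertion"`,
#'   `"deletion"`, `"complex"`), `n` (indel length, 0 for wt/complex),
#'   `offset` (indel position minus cut site, NA unless an indel), `score`.
#' @export
classify_allele <- function(seq, ref, cut_site, window_bp = 20L) {
  seq <- as.character(seq); ref <- as.character(ref)
  check(nchar(seq) > 0L && nchar(ref) > 0L, "empty sequence or reference")
  check_count(cut_site, "cut_site", min = 1L)
  check(cut_site <= nchar(ref), "`cut_site` beyond the reference")
  check_count(window_bp, "window_bp", min = 10L)
  if (identical(seq, ref)) {
    return(structure(list(class = "wt", n = 0L, offset = NA_integer_,
                          score = nchar(ref)),
                     class = "allele_call"))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = seq, subject = ref, type = "global",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 2)
  ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  asub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  # walk the alignment, recording gap runs with their reference coordinate
  ref_pos <- 0L
  runs <- list()
  cur <- NULL
  mismatches <- 0L
  for (i in seq_along(ap)) {
    kind <- if (asub[i] == "-") "ins" else if (ap[i] == "-") "del" else "match"
    if (kind == "match") {
      ref_pos <- ref_pos + 1L
      if (ap[i] != asub[i]) mismatches <- mismatches + 1L
      if (!is.null(cur)) { runs[[length(runs) + 1L]] <- cur; cur <- NULL }
    } else {
      if (kind == "del") ref_pos <- ref_pos + 1L
      if (is.null(cur) || cur$kind != kind) {
        if (!is.null(cur)) runs[[length(runs) + 1L]] <- cur
        cur <- list(kind = kind, len = 1L, at = ref_pos)
      } else {
        cur$len <- cur$len + 1L
      }
    }
  }
  if (!is.null(cur)) runs[[length(runs) + 1L]] <- cur
  near <- Filter(function(r) abs(r$at - cut_site) <= window_bp, runs)
  net <- sum(vapply(near, function(r)
    if (r$kind == "ins") r$len else -r$len, integer(1)))
  clean <- length(runs) == length(near) && length(near) == 1L &&
    mismatches == 0L
  cls <- if (net > 0 && clean) "insertion"
         else if (net < 0 && clean) "deletion"
         else "complex"
  structure(list(class = cls,
                 n = if (cls == "complex") 0L else abs(net),
                 offset = if (length(near) == 1L)
                   as.integer(near[[1L]]$at - cut_site) else NA_integer_,
                 score = Biostrings::score(aln)),
            class = "allele_call")
}

#' @export
print.allele_call <- function(x, ...) {
  lab <- switch(x$class,
                wt = "wt",
                insertion = sprintf("insertion(+%d)", x$n),
                deletion = sprintf("deletion(-%d)", x$n),
                complex = "complex")
  cat(sprintf("<allele_call> %s%s\n", lab,
              if (!is.na(x$offset)) sprintf(" at cut%+d bp", x$offset) else ""))
  invisible(x)
}

#' Census allele calls and test for heterozygosity
#'
#' Counts wild-type, mutant (single-indel) and other calls, and computes the
#' exact two-sided binomial p-value of the mutant count among wt+mutant
#' alleles against proportion 0.5 (summing the probabilities of all
#' outcomes no more likely than the observed one). A verdict of
#' "consistent with heterozygous" requires p >= 0.05.
#'
#' @param calls List of [classify_allele()] results.
#' @return Object of class `census_result`: `n_total, n_wt, n_mut, n_other,
#'   p_value, consistent_heterozygous`.
#' @export
allele_census <- function(calls) {
  check(is.list(calls) && length(calls) >= 1L, "need at least one call")
  cls <- vapply(calls, function(x) x$class, character(1))
  n_wt <- sum(cls == "wt")
  n_mut <- sum(cls %in% c("insertion", "deletion"))
  n_other <- sum(cls == "complex")
  n <- n_wt + n_mut
  p <- if (n == 0L) 1 else exact_binomial_two_sided(n_mut, n, 0.5)
  structure(list(n_total = length(calls), n_wt = n_wt, n_mut = n_mut,
                 n_other = n_other, p_value = p,
                 consistent_heterozygous = p >= 0.05),
            class = "census_result")
}

# Exact two-sided binomial: sum P(k) over all k with P(k) <= P(observed)
# (with a small relative tolerance for floating-point equality).
exact_binomial_two_sided <- function(x, n, p0 = 0.5) {
  d <- stats::dbinom(0:n, n, p0)
  dx <- d[x + 1L]
  sum(d[d <= dx * (1 + 1e-7)])
}

#' @export
print.census_result <- function(x, ...) {
  cat(sprintf(
    "%d alleles: %d wt, %d mutant, %d other; exact binomial p = %.3g -> %s with heterozygous\n",
    x$n_total, x$n_wt, x$n_mut, x$n_other, x$p_value,
    if (x$consistent_heterozygous) "consistent" else "NOT consistent"))
  invisible(x)
}

#' Locate a frameshift-induced premature stop codon
#'
#' Scans the edited sequence codon by codon in the stated reading frame,
#' starting from the codon containing the edit, for the first stop codon
#' (TAA/TAG/TGA); the reference is scanned identically to confirm the stop
#' is novel (absent or farther in the unedited sequence).
#'
#' @param edited_seq,ref_seq Character sequences.
#' @param cds_frame_offset Reading-frame offset in {0, 1, 2}: codons start
#'   at position `cds_frame_offset + 1`.
#' @param edit_pos 1-based position of the edit in the edited sequence.
#' @return Object of class `stop_report`: `found`, `distance_bp` (bp from
#'   `edit_pos` to the first base of the novel stop), `codon_index` (codon
#'   number from the start of the frame, 1-based).
#' @export
find_premature_stop <- function(edited_seq, ref_seq, cds_frame_offset,
                                edit_pos) {
  check(cds_frame_offset %in% 0:2, "`cds_frame_offset` must be 0, 1 or 2")
  check_count(edit_pos, "edit_pos", min = 1L)
  check(edit_pos <= nchar(edited_seq), "`edit_pos` beyond the sequence")
  first_stop <- function(s) {
    start <- cds_frame_offset + 1L +
      3L * ((edit_pos - cds_frame_offset - 1L) %/% 3L)
    start <- max(start, cds_frame_offset + 1L)
    pos <- seq(start, nchar(s) - 2L, by = 3L)
    for (p in pos) {
      codon <- toupper(substr(s, p, p + 2L))
      if (codon %in% c("TAA", "TAG", "TGA")) return(p)
    }
    NA_integer_
  }
  se <- first_stop(edited_seq)
  sr <- first_stop(ref_seq)
  found <- !is.na(se) && (is.na(sr) || (sr - edit_pos) != (se - edit_pos))
  structure(list(
    found = found,
    distance_bp = if (found) as.integer(se - edit_pos) else NA_integer_,
    codon_index = if (found)
      as.integer((se - cds_frame_offset - 1L) %/% 3L + 1L) else NA_integer_),
    class = "stop_report")
}

#' @export
print.stop_report <- function(x, ...) {
  if (x$found) {
    cat(sprintf("premature stop %d bp from the edit (codon %d)\n",
                x$distance_bp, x$codon_index))
  } else cat("no novel premature stop found\n")
  invisible(x)
}

#' Synthetic example amplicon with an engineered frameshift cassette
#'
#' A 150-bp synthetic amplicon (the real locus sequence is not publicly
#' available, so fixtures are engineered to have the documented properties):
#' random flanks around a coding cassette positioned so that inserting a C
#' after `cut_site` creates a frameshift whose first novel in-frame stop
#' codon begins 8 bp downstream of the inserted base.
#'
#' @return List with `ref` (character sequence), `cut_site` (1-based
#'   position of the predicted double-strand break), `frame_offset`
#'   (reading-frame offset for [find_premature_stop()]) and `edit_pos`
#'   (position of the inserted base in the edited sequence).
#' @export
example_amplicon <- function() {
  cassette <- "ATGGCTGCAGCACCGCATGACGGTCATGCC"   # insertion after base 10
  flank <- function(n, seed) withr::with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
  ref <- paste0(flank(65, 20220927), cassette, flank(55, 20220928))
  list(ref = ref, cut_site = 75L, frame_offset = 2L, edit_pos = 76L)
}
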