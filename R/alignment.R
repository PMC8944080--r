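#' Global pairwise alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment by dynamic programming with a linear gap
#' penalty. The scoring scheme is configurable; the default (+1 match, -1
#' mismatch, -1 gap) yields scores that an exhaustive enumeration of all
#' global alignments reproduces, which is how the implementation is tested.
#' Ties in the traceback are broken deterministically: diagonal, then up
#' (gap in `b`), then left (gap in `a`).
#'
#' @param a,b amino-acid strings over the 20-letter alphabet (plus `X`).
#' @param match,mismatch,gap scoring parameters (gap is the per-column
#'   penalty, linear gap model).
#' @return An object of class `alignment`: a list with `a_aln`, `b_aln`
#'   (aligned strings of equal length, `-` for gaps) and `score`.
#' @seealso [percent_identity()], [identity_matrix()]
#' @examples
#' aln <- global_align("ACDE", "ACE")
#' aln$score
#' percent_identity(aln)
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  stop_if(!is.character(a) || length(a) != 1L || nchar(a) == 0L,
          "'a' must be a single non-empty sequence string")
  stop_if(!is.character(b) || length(b) != 1L || nchar(b) == 0L,
          "'b' must be a single non-empty sequence string")
  ok <- c(AA_ALPHABET, "X")
  bad_a <- setdiff(strsplit(a, "")[[1]], ok)
  bad_b <- setdiff(strsplit(b, "")[[1]], ok)
  stop_if(length(bad_a) > 0L,
          "illegal characters in 'a': ", paste(bad_a, collapse = ", "))
  stop_if(length(bad_b) > 0L,
          "illegal characters in 'b': ", paste(bad_b, collapse = ", "))
  res <- nw_align_cpp(a, b, match, mismatch, gap)
  structure(res, class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("Global alignment (score ", x$score, ", identity ",
      sprintf("%.1f%%", 100 * percent_identity(x)), ")\n", sep = "")
  cat(" ", x$a_aln, "\n ", x$b_aln, "\n", sep = "")
  invisible(x)
}

#' Percent identity of an alignment
#'
#' Fraction of identical columns over the full alignment length; gap columns
#' count in the denominator (stated convention of this pipeline).
#'
#' @param alignment an `alignment` object from [global_align()], or a list
#'   with aligned strings `a_aln` and `b_aln` of equal length.
#' @return identity fraction in `[0, 1]`.
#' @export
percent_identity <- function(alignment) {
  a <- strsplit(alignment$a_aln, "")[[1]]
  b <- strsplit(alignment$b_aln, "")[[1]]
  stop_if(length(a) != length(b), "aligned strings differ in length")
  stop_if(length(a) == 0L, "empty alignment")
  sum(a == b & a != "-") / length(a)
}

#' All-vs-all percent-identity matrix
#'
#' Aligns every pair of records once with [global_align()] and returns the
#' symmetric identity matrix (unit diagonal), the input to hierarchical
#' clustering of candidate enzyme families.
#'
#' @param records a sequence record table (see [read_fasta()]) with columns
#'   `id` and `sequence`, or a named character vector of sequences.
#' @param match,mismatch,gap scoring parameters passed to [global_align()].
#' @return a symmetric numeric matrix with `dimnames` set to the record ids,
#'   class `identity_matrix`.
#' @examples
#' m <- identity_matrix(c(s1 = "ACDE", s2 = "ACDE", s3 = "WYWY"))
#' as_distance(m)
#' @export
identity_matrix <- function(records, match = 1, mismatch = -1, gap = -1) {
  if (is.character(records)) {
    seqs <- records
    ids <- names(records) %||% paste0("seq", seq_along(records))
  } else {
    seqs <- records$sequence
    ids <- records$id
  }
  n <- length(seqs)
  stop_if(n < 2L, "need at least 2 records")
  stop_if(anyDuplicated(ids) > 0L, "record ids must be unique")
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      pid <- tryCatch(
        percent_identity(global_align(seqs[i], seqs[j],
                                      match = match, mismatch = mismatch,
                                      gap = gap)),
        error = function(e) stop("alignment of pair (", ids[i], ", ", ids[j],
                                 ") failed: ", conditionMessage(e),
                                 call. = FALSE))
      m[i, j] <- m[j, i] <- pid
    }
  }
  structure(m, class = c("identity_matrix", "matrix"))
}

#' Distance view of an identity matrix
#'
#' `1 - identity`, the metric used for hierarchical clustering of the
#' candidate sequences.
#'
#' @param m an identity matrix from [identity_matrix()].
#' @return a `dist` object.
#' @export
as_distance <- function(m) {
  stats::as.dist(1 - unclass(m))
}
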