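#' Motif-complexity score for VNTR repeat units
#'
#' Scores how well a repeat-unit sequence can be explained by a shorter
#' internal repeat. The unit is compared against shifted copies of itself
#' after masking a small number of positions with wildcards; a score close
#' to 1 indicates internal repeat structure (for example, `TTTTTCTT` is
#' really an interrupted homopolymer). VNTR loci whose unit scores above a
#' threshold (default 0.8) are discarded by [filter_vntrs()], because a
#' genotyper run with such a unit tends to capture a simpler repeat and
#' produce unreliable calls.
#'
#' For a unit `M` of length `n`, every subset of `k = select_k(n)` positions
#' is masked in turn; the masked string is concatenated to itself and the
#' original masked string is compared with each length-`n` window at shifts
#' `1..n-1`. A position matches when either side is a wildcard or both
#' characters are equal. The score is the maximum match count over all masks
#' and shifts, divided by `n`.
#'
#' The direction of the comparison admits two readings; the default
#' (`mode = "similarity"`) maximizes the wildcard-aware match count so that
#' perfectly periodic motifs score 1. `mode = "literal"` instead maximizes
#' the wildcard-aware mismatch count (a raw Hamming distance reading) and is
#' provided for comparison only.
#'
#' @param motif DNA string over \{A,C,G,T\} (case-insensitive), length 1-40+.
#' @param mode `"similarity"` (default) or `"literal"`; see Details.
#' @return A number in `[0, 1]`.
#' @examples
#' motif_score("AAAAAAAA")  # 1: homopolymer
#' motif_score("TTTTTCTT")  # 1: interrupted homopolymer, filtered at 0.8
#' motif_score("ACGT")      # 0.5
#' @export
motif_score <- function(motif, mode = c("similarity", "literal")) {
  mode <- match.arg(mode)
  motif <- check_dna(motif, "motif")
  n <- nchar(motif)
  if (n == 1L) {
    # No valid shift exists for a single-base unit; it is trivially periodic.
    return(if (mode == "similarity") 1 else 0)
  }
  k <- select_k(n)
  ch <- strsplit(motif, "", fixed = TRUE)[[1]]
  subsets <- utils::combn(n, k, simplify = FALSE)
  best <- 0L
  for (sub in subsets) {
    masked <- ch
    masked[sub] <- "*"
    doubled <- c(masked, masked)
    for (j in seq_len(n - 1L)) {
      win <- doubled[(j + 1L):(j + n)]
      if (mode == "similarity") {
        v <- sum(masked == "*" | win == "*" | masked == win)
      } else {
        v <- sum(masked != "*" & win != "*" & masked != win)
      }
      if (v > best) best <- v
    }
  }
  best / n
}

#' Mask size for the motif-complexity score
#'
#' @param n Motif length (>= 1).
#' @return Number of positions masked at a time: `ceiling(n / 10)` for
#'   `n <= 40`, else 1.
#' @export
select_k <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("motif length must be >= 1")
  if (n <= 40) as.integer(ceiling(n / 10)) else 1L
}

#' Enumerate masked variants of a motif
#'
#' All `choose(n, k)` strings obtained by replacing each size-`k` subset of
#' positions with the wildcard `*`, enumerated in lexicographic order of the
#' position indices.
#'
#' @param motif DNA string.
#' @param k Number of positions to mask (defaults to [select_k()]).
#' @return Character vector of masked motifs.
#' @export
masked_variants <- function(motif, k = select_k(nchar(motif))) {
  motif <- check_dna(motif, "motif")
  n <- nchar(motif)
  if (k > n) stop("k must not exceed motif length")
  ch <- strsplit(motif, "", fixed = TRUE)[[1]]
  vapply(utils::combn(n, k, simplify = FALSE), function(sub) {
    m <- ch
    m[sub] <- "*"
    paste(m, collapse = "")
  }, character(1))
}

#' Filter VNTR records by motif complexity
#'
#' Partitions records into kept and discarded sets; a record is discarded
#' when the motif score of its repeat unit strictly exceeds `threshold`.
#'
#' @param units Character vector of repeat units, or a list of records with a
#'   `$unit` field (e.g. `tr_record` objects).
#' @param threshold Score above which a unit is discarded (default 0.8).
#' @param mode Passed to [motif_score()].
#' @return List with elements `kept`, `discarded` (same type as input) and
#'   `scores` (numeric vector, one per input record).
#' @export
filter_vntrs <- function(units, threshold = 0.8, mode = "similarity") {
  if (length(units) == 0L) {
    return(list(kept = units, discarded = units, scores = numeric(0)))
  }
  seqs <- if (is.character(units)) units else
    vapply(units, function(r) r$unit, character(1))
  scores <- vapply(seqs, motif_score, numeric(1), mode = mode, USE.NAMES = FALSE)
  drop <- scores > threshold
  list(kept = units[!drop], discarded = units[drop], scores = scores)
}

#' Repeat copy number of an allele
#'
#' Copy number is the allele length divided by the repeat-unit length and may
#' be fractional for interrupted or partial repeats. For example the CA10
#' fragment-analysis reference allele (66 bp, CAG unit) carries 22 copies.
#'
#' @param allele Allele sequence (DNA string) or length in bp (numeric).
#' @param unit Repeat-unit sequence or unit length in bp.
#' @return Copy number (possibly fractional).
#' @export
repeat_copy_number <- function(allele, unit) {
  len <- if (is.character(allele)) nchar(check_dna(allele, "allele")) else as.numeric(allele)
  ulen <- if (is.character(unit)) nchar(check_dna(unit, "unit")) else as.numeric(unit)
  if (ulen <= 0) stop("unit length must be positive")
  len / ulen
}
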