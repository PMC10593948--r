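# Population-level TR statistics: spectra, heterozygosity, divergence,
# expansion-outlier detection, variant burden and sequence-context features.

#' Build an allele-frequency spectrum
#'
#' Alleles are keyed by copy-number offset from the reference by default
#' (matching length-based spectra), or by any user-supplied key.
#'
#' @param keys Vector of allele keys (one per observed allele, 2 per called
#'   sample), e.g. copy offsets.
#' @return Named numeric vector of frequencies (sums to 1) with attribute
#'   `n` = number of observed alleles; class `afs`.
#' @export
allele_spectrum <- function(keys) {
  keys <- keys[!is.na(keys)]
  if (length(keys) == 0L) stop("empty allele spectrum")
  tab <- table(keys)
  p <- as.numeric(tab) / sum(tab)
  names(p) <- names(tab)
  structure(p, n = sum(tab), class = "afs")
}

#' Heterozygosity of a spectrum
#'
#' `H = 1 - sum(p_i^2)` over allele frequencies; 0 for a monomorphic locus.
#'
#' @param afs Spectrum from [allele_spectrum()] or a bare frequency vector.
#' @return Value in `[0, 1)`.
#' @export
heterozygosity <- function(afs) {
  if (length(afs) == 0L) stop("empty allele spectrum")
  1 - sum(as.numeric(afs)^2)
}

#' Count common alleles
#'
#' @param afs Frequency vector.
#' @param min_freq Inclusive frequency threshold (default 0.01).
#' @return Number of alleles with frequency `>= min_freq`.
#' @export
count_common_alleles <- function(afs, min_freq = 0.01) {
  sum(as.numeric(afs) >= min_freq)
}

#' Jensen-Shannon distance between two spectra
#'
#' Spectra are aligned on the union of their allele keys (absent keys
#' zero-filled); the divergence uses base-2 logarithms and the square root
#' is taken, so identical spectra score 0 and disjoint spectra score 1.
#'
#' @param afs_a,afs_b Named frequency vectors.
#' @return Jensen-Shannon distance in `[0, 1]`.
#' @export
spectrum_divergence <- function(afs_a, afs_b) {
  keys <- union(names(afs_a), names(afs_b))
  p <- as.numeric(afs_a[keys]); p[is.na(p)] <- 0
  q <- as.numeric(afs_b[keys]); q[is.na(q)] <- 0
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(x, y) {
    sel <- x > 0
    sum(x[sel] * log2(x[sel] / y[sel]))
  }
  jsd <- 0.5 * kl(p, m) + 0.5 * kl(q, m)
  sqrt(max(jsd, 0))
}

#' Expansion outlier threshold
#'
#' `Q3 + 3 * IQR` over pooled allele copy numbers; alleles strictly above
#' the threshold are expansion outliers. Quartiles use linear interpolation
#' between order statistics (`stats::quantile` type 7 by default).
#'
#' @param copy_numbers Numeric vector of allele copy numbers (>= 4 values).
#' @param type Quantile type passed to [stats::quantile()].
#' @return Threshold in copies; `NA` when fewer than 4 observations (not
#'   assessable).
#' @export
expansion_threshold <- function(copy_numbers, type = 7) {
  copy_numbers <- copy_numbers[!is.na(copy_numbers)]
  if (length(copy_numbers) < 4L) return(NA_real_)
  qs <- stats::quantile(copy_numbers, c(0.25, 0.75), type = type, names = FALSE)
  qs[2] + 3 * (qs[2] - qs[1])
}

#' Detect population-specific repeat expansions
#'
#' For each non-homopolymer locus, the expansion threshold is computed on
#' copy numbers pooled across both groups; a locus is reported when
#' 1) the threshold exceeds `min_threshold` copies, 2) the expansion
#' frequency (fraction of alleles above the threshold) exceeds `min_freq`
#' in at least one group, and 3) the expansion frequency in one group is at
#' least `min_ratio` times the other group's.
#'
#' @param df `data.frame` with one row per observed allele: columns `locus`,
#'   `group` (two levels), `copy_number`, `unit_length` (bp).
#' @param groupA,groupB The two group labels in `df$group`.
#' @param min_threshold Minimum expansion threshold in copies (default 10).
#' @param min_freq Minimum expansion frequency in some group (default 0.01).
#' @param min_ratio Minimum between-group frequency ratio (default 10).
#' @param type Quantile type for [expansion_threshold()].
#' @return `data.frame` with one row per reported locus: `locus`,
#'   `threshold`, `freq_A`, `freq_B`, `enriched_group`.
#' @export
detect_population_specific_expansions <- function(df, groupA, groupB,
                                                  min_threshold = 10,
                                                  min_freq = 0.01,
                                                  min_ratio = 10,
                                                  type = 7) {
  df <- df[df$unit_length > 1L, , drop = FALSE]  # homopolymers excluded
  out <- lapply(split(df, df$locus), function(d) {
    thr <- expansion_threshold(d$copy_number, type = type)
    if (is.na(thr) || thr <= min_threshold) return(NULL)
    fa <- mean(d$copy_number[d$group == groupA] > thr)
    fb <- mean(d$copy_number[d$group == groupB] > thr)
    if (is.nan(fa) || is.nan(fb)) return(NULL)
    if (max(fa, fb) <= min_freq) return(NULL)
    hi <- max(fa, fb); lo <- min(fa, fb)
    if (lo > 0 && hi / lo < min_ratio) return(NULL)
    data.frame(locus = d$locus[1], threshold = thr, freq_A = fa, freq_B = fb,
               enriched_group = if (fa >= fb) groupA else groupB,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(locus = character(0), threshold = numeric(0),
                      freq_A = numeric(0), freq_B = numeric(0),
                      enriched_group = character(0))
  }
  rownames(res) <- NULL
  res
}

#' Build expansion-detection input from a consensus callset
#'
#' Flattens called genotypes to one row per observed allele with copy
#' numbers and the sample's group label under a user-defined bipartition of
#' populations.
#'
#' @param callset Consensus [tr_callset()].
#' @param pop_of_sample Named character vector: sample -> population.
#' @param groupA_pops,groupB_pops Population labels forming the two groups.
#' @return `data.frame(locus, group, copy_number, unit_length)` suitable for
#'   [detect_population_specific_expansions()] with groups `"A"` and `"B"`.
#' @export
expansion_input <- function(callset, pop_of_sample, groupA_pops, groupB_pops) {
  ct <- calls_table(callset)
  pops <- pop_of_sample[ct$sample]
  grp <- ifelse(pops %in% groupA_pops, "A",
                ifelse(pops %in% groupB_pops, "B", NA_character_))
  keep <- !is.na(grp)
  ct <- ct[keep, , drop = FALSE]
  grp <- grp[keep]
  ref_cn <- ct$ref_len / ct$unit_len
  data.frame(locus = rep(ct$locus, 2), group = rep(grp, 2),
             copy_number = c(ref_cn + ct$off1, ref_cn + ct$off2),
             unit_length = rep(ct$unit_len, 2))
}

#' Per-sample variant allele burden
#'
#' Fraction of a sample's called alleles that differ from the reference
#' allele, over all loci where the sample is called. Homopolymer loci are
#' excluded by default.
#'
#' @param callset Consensus [tr_callset()].
#' @param exclude_homopolymers Drop loci with 1 bp repeat units (default
#'   `TRUE`).
#' @return Named numeric vector (one entry per sample; `NA` for samples
#'   with no called loci).
#' @export
variant_allele_burden <- function(callset, exclude_homopolymers = TRUE) {
  nonref <- stats::setNames(numeric(length(callset$samples)), callset$samples)
  total <- nonref
  for (r in callset$records) {
    if (exclude_homopolymers && nchar(r$unit) == 1L) next
    called <- !is.na(r$gt[, 1])
    ids <- rownames(r$gt)[called]
    nonref[ids] <- nonref[ids] + rowSums(r$gt[called, , drop = FALSE] != 1L)
    total[ids] <- total[ids] + 2
  }
  ifelse(total > 0, nonref / total, NA_real_)
}

#' Count repeat-like 4-mers in a sequence context
#'
#' Counts sliding 4-mers of the form XYXY (dinucleotide-like, including
#' X = Y, i.e. homopolymer runs), overlapping occurrences included. Used as
#' a sequence-context feature around TR loci.
#'
#' @param context DNA string (e.g. 64 bp of flanking sequence).
#' @return Integer count (0 for sequences shorter than 4 bp).
#' @export
count_repetitive_4mers <- function(context) {
  context <- toupper(context)
  n <- nchar(context)
  if (n < 4L) return(0L)
  ch <- strsplit(context, "", fixed = TRUE)[[1]]
  i <- seq_len(n - 3L)
  sum(ch[i] == ch[i + 2L] & ch[i + 1L] == ch[i + 3L])
}

#' Sequence context around a locus
#'
#' Extracts `window` bases on each side of a span (truncated with a warning
#' at contig edges).
#'
#' @param reference `DNAStringSet`.
#' @param chrom Contig name.
#' @param start,end 0-based half-open locus span.
#' @param window Flank width in bp (default 64).
#' @return List with `left` and `right` flank strings.
#' @export
locus_context <- function(reference, chrom, start, end, window = 64L) {
  clen <- length(reference[[chrom]])
  ls <- max(0L, start - window)
  re <- min(clen, end + window)
  if (ls > start - window || re < end + window) {
    warning("context window truncated at contig boundary")
  }
  list(left = fetch_reference_flank(reference, chrom, ls, start),
       right = fetch_reference_flank(reference, chrom, end, re))
}
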