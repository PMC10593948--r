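# Imputation concordance, a naive most-common-genotype imputer, and SNP-TR
# linkage disequilibrium / tag-SNP search.

#' Concordance between an observed and an imputed diploid genotype
#'
#' 1 when the sorted allele pairs are identical, 0 when neither imputed
#' allele matches an observed allele, else 0.5 (one but not both matched).
#' Alleles are compared under a common key (length or sequence), unordered.
#'
#' @param x Observed genotype, length-2 vector.
#' @param y Imputed genotype, length-2 vector.
#' @return 0, 0.5 or 1; `NA` when either side contains a no-call.
#' @export
genotype_concordance <- function(x, y) {
  if (anyNA(x) || anyNA(y)) return(NA_real_)
  sx <- sort(x); sy <- sort(y)
  if (identical(as.vector(sx), as.vector(sy))) return(1)
  # multiset intersection size
  matched <- 0L
  pool <- sx
  for (a in sy) {
    hit <- match(a, pool)
    if (!is.na(hit)) {
      matched <- matched + 1L
      pool <- pool[-hit]
    }
  }
  if (matched == 0L) 0 else 0.5
}

#' Mean concordance at a locus
#'
#' @param observed,imputed Matrices `samples x 2` of allele keys (rows with
#'   any `NA` excluded from the average).
#' @return Mean per-sample concordance; `NA` when no pair is evaluable.
#' @export
locus_concordance <- function(observed, imputed) {
  stopifnot(nrow(observed) == nrow(imputed))
  c_ij <- vapply(seq_len(nrow(observed)), function(i) {
    genotype_concordance(observed[i, ], imputed[i, ])
  }, numeric(1))
  if (all(is.na(c_ij))) return(NA_real_)
  mean(c_ij, na.rm = TRUE)
}

#' Naive imputation: most common diploid genotype
#'
#' The modal unordered genotype among the training samples; ties are broken
#' by smaller total allele value, then lexicographically.
#'
#' @param training Matrix `samples x 2` of allele keys (numeric); `NA` rows
#'   ignored.
#' @return Length-2 vector (sorted), or `NULL` when no training genotype is
#'   called.
#' @export
naive_impute <- function(training) {
  called <- !is.na(training[, 1]) & !is.na(training[, 2])
  g <- training[called, , drop = FALSE]
  if (nrow(g) == 0L) return(NULL)
  g <- t(apply(g, 1, sort))
  key <- paste(g[, 1], g[, 2], sep = "|")
  counts <- table(key)
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1L) {
    pairs <- do.call(rbind, lapply(strsplit(top, "|", fixed = TRUE), as.numeric))
    ord <- order(pairs[, 1] + pairs[, 2], pairs[, 1], pairs[, 2])
    top <- top[ord]
  }
  as.numeric(strsplit(top[1], "|", fixed = TRUE)[[1]])
}

#' Leave-one-out concordance of the naive imputer
#'
#' For each called sample, the most common genotype among the remaining
#' samples is used as its imputed genotype and scored against the observed
#' one.
#'
#' @param genotypes Matrix `samples x 2` of allele keys.
#' @return List with `concordance` (locus mean) and `per_sample` (named
#'   vector).
#' @export
loo_naive_concordance <- function(genotypes) {
  n <- nrow(genotypes)
  c_i <- vapply(seq_len(n), function(i) {
    if (anyNA(genotypes[i, ])) return(NA_real_)
    imp <- naive_impute(genotypes[-i, , drop = FALSE])
    if (is.null(imp)) return(NA_real_)
    genotype_concordance(genotypes[i, ], imp)
  }, numeric(1))
  names(c_i) <- rownames(genotypes)
  list(concordance = if (all(is.na(c_i))) NA_real_ else mean(c_i, na.rm = TRUE),
       per_sample = c_i)
}

#' LD between a SNP and a TR
#'
#' Squared Pearson correlation between the phased SNP allele vector and the
#' TR allele-length vector; both vectors have `2n` entries (two phased
#' alleles per sample, in consistent order).
#'
#' @param snp_alleles Numeric vector of `2n` SNP allele values (0/1).
#' @param tr_alleles Numeric vector of `2n` TR allele lengths (copies
#'   relative to reference).
#' @return r-squared in `[0, 1]`; `NA` when either vector is constant (not
#'   assessable).
#' @export
ld_r2 <- function(snp_alleles, tr_alleles) {
  if (length(snp_alleles) != length(tr_alleles)) {
    stop("SNP and TR allele vectors must have equal length")
  }
  if (stats::sd(snp_alleles) == 0 || stats::sd(tr_alleles) == 0) {
    return(NA_real_)
  }
  stats::cor(snp_alleles, tr_alleles)^2
}

#' Best tag SNP for a TR locus
#'
#' Scans SNPs within a window of the TR span and returns the one with the
#' strongest LD; ties are resolved by distance to the TR, then by smaller
#' position.
#'
#' @param tr_span List or vector with `start`, `end` (0-based half-open TR
#'   span).
#' @param tr_alleles Numeric vector of `2n` phased TR allele values.
#' @param snp_positions Integer vector of SNP positions (0-based).
#' @param snp_haplotypes Matrix `2n x n_snps` of phased SNP alleles, columns
#'   aligned with `snp_positions`.
#' @param window Window half-width in bp (default 50000).
#' @param snp_ids Optional SNP identifiers.
#' @return List with `snp` (index or id), `r2`, `distance` (bp from the TR
#'   span; 0 inside), `position`; `NULL` when no SNP with computable LD lies
#'   in the window.
#' @export
best_tag_snp <- function(tr_span, tr_alleles, snp_positions, snp_haplotypes,
                         window = 50000L, snp_ids = NULL) {
  start <- tr_span[["start"]]; end <- tr_span[["end"]]
  # bp between the SNP base and the nearest base of the span (0 inside)
  dist <- pmax(0L, start - snp_positions, snp_positions - (end - 1L))
  inside <- which(dist <= window)
  if (length(inside) == 0L) return(NULL)
  r2 <- vapply(inside, function(j) {
    ld_r2(snp_haplotypes[, j], tr_alleles)
  }, numeric(1))
  ok <- !is.na(r2)
  if (!any(ok)) return(NULL)
  inside <- inside[ok]; r2 <- r2[ok]
  ord <- order(-r2, dist[inside], snp_positions[inside])
  j <- inside[ord[1]]
  list(snp = if (!is.null(snp_ids)) snp_ids[j] else j,
       r2 = r2[ord[1]], distance = dist[j], position = snp_positions[j])
}
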