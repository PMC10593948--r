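# Trio-based and locus-level quality control of consensus callsets.

#' Mendelian consistency of one trio genotype
#'
#' True when one child allele can be assigned to the mother's pair and the
#' other to the father's pair. Alleles are compared as consensus allele
#' identities.
#'
#' @param child,mother,father Length-2 vectors of allele identities.
#' @return `TRUE`/`FALSE`; `NA` when any genotype contains a no-call (such
#'   trios are excluded, not counted as inconsistent).
#' @export
is_mendelian_consistent <- function(child, mother, father) {
  if (anyNA(child) || anyNA(mother) || anyNA(father)) return(NA)
  (child[1] %in% mother && child[2] %in% father) ||
    (child[2] %in% mother && child[1] %in% father)
}

# Per-trio evaluation at one locus: eligibility, consistency, trio score.
trio_checks <- function(record, pedigree) {
  gt <- record$gt
  q <- record$q
  names(q) <- rownames(gt)
  out <- lapply(seq_len(nrow(pedigree)), function(i) {
    ids <- as.character(pedigree[i, c("child", "mother", "father")])
    if (!all(ids %in% rownames(gt))) return(NULL)
    g <- gt[ids, , drop = FALSE]
    if (anyNA(g)) {
      return(data.frame(trio = i, eligible = FALSE, consistent = NA,
                        trio_score = NA_real_))
    }
    # eligibility: at least one member not homozygous reference
    nonref <- any(g != 1L)
    data.frame(trio = i, eligible = nonref,
               consistent = if (nonref)
                 is_mendelian_consistent(g[1, ], g[2, ], g[3, ]) else NA,
               trio_score = min(q[ids]))
  })
  do.call(rbind, out)
}

#' Mendelian inheritance rate at one locus
#'
#' A trio is eligible when all three members are called and at least one is
#' not homozygous for the reference allele. The MI rate is the fraction of
#' eligible trios whose child genotype is explainable by one allele from
#' each parent.
#'
#' @param record A consensus [tr_record()].
#' @param pedigree `data.frame` with columns `child`, `mother`, `father`.
#' @return List with `n_eligible`, `n_consistent`, `mi_rate`,
#'   `mi_error_rate` (rates `NA` when no trio is eligible — the locus is not
#'   assessable).
#' @export
locus_mi_rate <- function(record, pedigree) {
  tc <- trio_checks(record, pedigree)
  elig <- !is.null(tc) && any(tc$eligible)
  if (!elig) {
    return(list(n_eligible = 0L, n_consistent = 0L,
                mi_rate = NA_real_, mi_error_rate = NA_real_))
  }
  ok <- tc$consistent[tc$eligible]
  list(n_eligible = length(ok), n_consistent = sum(ok),
       mi_rate = mean(ok), mi_error_rate = 1 - mean(ok))
}

#' Mendelian inheritance rate as a function of score threshold
#'
#' At each threshold, only trio/locus pairs whose trio score (the minimum
#' consensus score among the three members) reaches the threshold are
#' included; the aggregate MI rate over all loci is reported.
#'
#' @param callset Consensus [tr_callset()].
#' @param pedigree Trio table.
#' @param thresholds Numeric vector of score thresholds.
#' @return `data.frame` with columns `threshold`, `n_pairs`, `mi_rate`
#'   (`NA` when no pair passes a threshold).
#' @export
mi_by_score_threshold <- function(callset, pedigree, thresholds) {
  if (length(thresholds) == 0L) stop("thresholds must be non-empty")
  checks <- do.call(rbind, lapply(callset$records, trio_checks,
                                  pedigree = pedigree))
  checks <- checks[checks$eligible & !is.na(checks$consistent), , drop = FALSE]
  out <- lapply(thresholds, function(th) {
    sel <- checks$trio_score >= th
    data.frame(threshold = th, n_pairs = sum(sel),
               mi_rate = if (any(sel)) mean(checks$consistent[sel]) else NA_real_)
  })
  do.call(rbind, out)
}

#' Monte-Carlo Hardy-Weinberg test for multiallelic loci
#'
#' Permutation test with the observed heterozygote count as statistic:
#' called alleles are shuffled and re-paired into genotypes; the two-sided
#' p-value is the fraction of permutations whose heterozygote count deviates
#' from the permutation mean by at least as much as the observed count.
#' Distribution-free, so it applies to loci with any number of alleles.
#'
#' @param gt Integer matrix `samples x 2` of allele indices (`NA` rows
#'   ignored).
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @return p-value in `(0, 1]`; `NA` when fewer than 2 called samples.
#' @export
hwe_permutation_test <- function(gt, n_perm = 10000L, seed = 1L) {
  called <- !is.na(gt[, 1]) & !is.na(gt[, 2])
  g <- gt[called, , drop = FALSE]
  n <- nrow(g)
  if (n < 2L) return(NA_real_)
  alleles <- as.vector(t(g))
  obs <- sum(g[, 1] != g[, 2])
  perm <- with_substream(seed, "hwe", {
    vapply(seq_len(n_perm), function(i) {
      a <- sample(alleles)
      sum(a[seq(1, 2 * n, 2)] != a[seq(2, 2 * n, 2)])
    }, numeric(1))
  })
  center <- mean(perm)
  (1 + sum(abs(perm - center) >= abs(obs - center))) / (n_perm + 1)
}

#' Per-locus QC summary
#'
#' @param record A [tr_record()].
#' @param pedigree Optional trio table for the MI error rate.
#' @param hwe_perm,seed Passed to [hwe_permutation_test()].
#' @return List with `call_rate`, `hwe_p`, `mi_error_rate` (`NA` when not
#'   assessable).
#' @export
locus_qc_summary <- function(record, pedigree = NULL, hwe_perm = 10000L,
                             seed = 1L) {
  called <- !is.na(record$gt[, 1])
  mi <- if (!is.null(pedigree)) locus_mi_rate(record, pedigree)$mi_error_rate
        else NA_real_
  list(call_rate = mean(called),
       hwe_p = hwe_permutation_test(record$gt, n_perm = hwe_perm, seed = seed),
       mi_error_rate = mi)
}

#' Locus-level filters
#'
#' Keeps loci passing all enabled filters: minimum call rate, minimum
#' Hardy-Weinberg p-value and maximum Mendelian error rate. A filter whose
#' threshold is `NULL` is disabled; a locus with an `NA` summary value
#' passes that filter (not assessable is not failure).
#'
#' @param summaries `data.frame` with columns `call_rate`, `hwe_p`,
#'   `mi_error_rate` (one row per locus).
#' @param call_rate_min Minimum locus call rate (default 0.75).
#' @param hwe_p_min Minimum HWE p-value (default 1e-6).
#' @param mi_error_max Maximum Mendelian error rate (default 0.05).
#' @return Logical vector: locus kept.
#' @export
filter_loci <- function(summaries, call_rate_min = 0.75, hwe_p_min = 1e-6,
                        mi_error_max = 0.05) {
  keep <- rep(TRUE, nrow(summaries))
  pass <- function(v, ok) ifelse(is.na(v), TRUE, ok)
  if (!is.null(call_rate_min)) {
    keep <- keep & pass(summaries$call_rate, summaries$call_rate >= call_rate_min)
  }
  if (!is.null(hwe_p_min)) {
    keep <- keep & pass(summaries$hwe_p, summaries$hwe_p >= hwe_p_min)
  }
  if (!is.null(mi_error_max)) {
    keep <- keep & pass(summaries$mi_error_rate,
                        summaries$mi_error_rate <= mi_error_max)
  }
  keep
}
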