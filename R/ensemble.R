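# Consensus calling across TR genotypers.
#
# Pipeline per locus: group overlapping same-unit records from different
# callers into a mergeable set, extend every allele to the union span using
# reference flanks, unify allele representations (sequence-resolved alleles
# take precedence), then score every candidate diploid genotype by a
# quality-weighted vote and keep the argmax.

#' ExpansionHunter per-allele quality
#'
#' `1 / exp(4 * CI / CN)` where `CN` is the allele copy number and `CI` the
#' width of its confidence interval in copies. A zero copy number yields a
#' score of 0 (such genotypes only win when unopposed).
#'
#' @param cn Copy number (>= 0).
#' @param ci_width Confidence-interval width in copies (>= 0).
#' @return Score in `[0, 1]`.
#' @examples
#' eh_allele_quality(20, 0)   # 1
#' eh_allele_quality(10, 10)  # exp(-4)
#' @export
eh_allele_quality <- function(cn, ci_width) {
  stopifnot(cn >= 0, ci_width >= 0)
  if (cn == 0) return(0)
  exp(-4 * ci_width / cn)
}

#' ExpansionHunter genotype quality
#'
#' Weighted mean of the two per-allele scores, weighting the lower score 0.8
#' and the higher 0.2 so that a single poor allele dominates.
#'
#' @param s1,s2 Per-allele scores from [eh_allele_quality()].
#' @return Quality in `[0, 1]`.
#' @export
eh_genotype_quality <- function(s1, s2) {
  0.8 * min(s1, s2) + 0.2 * max(s1, s2)
}

#' Group per-caller records into mergeable sets
#'
#' Restricts all callsets to their mutual samples, then sweeps the pooled,
#' position-sorted records: records are mergeable when their spans overlap
#' (>= 1 bp, pairwise) and their repeat units are identical (exact string
#' equality); at most one record per caller joins a set — a second
#' overlapping record from the same caller starts a new set. Loci covered by
#' a single caller pass through as singleton sets.
#'
#' @param callsets Named or unnamed list of [tr_callset()] objects, one per
#'   caller.
#' @return List with `sets` (each a list of records restricted to the mutual
#'   samples) and `samples` (the mutual sample ids).
#' @export
find_mergeable_sets <- function(callsets) {
  samples <- Reduce(intersect, lapply(callsets, function(cs) cs$samples))
  if (length(samples) == 0L) stop("no mutual samples across callers")
  pool <- list()
  for (cs in callsets) {
    chroms <- vapply(cs$records, function(r) r$chrom, character(1))
    starts <- vapply(cs$records, function(r) r$start, integer(1))
    if (is.unsorted(order(chroms, starts))) {
      stop("records are not sorted by position")
    }
    for (r in cs$records) {
      r$gt <- r$gt[samples, , drop = FALSE]
      r$q <- r$q[match(samples, cs$samples)]
      if (!is.null(r$ci)) r$ci <- r$ci[samples, , drop = FALSE]
      if (!is.null(r$src)) r$src <- r$src[match(samples, cs$samples)]
      pool[[length(pool) + 1L]] <- r
    }
  }
  if (length(pool) == 0L) return(list(sets = list(), samples = samples))
  ord <- order(vapply(pool, function(r) r$chrom, character(1)),
               vapply(pool, function(r) r$start, integer(1)),
               vapply(pool, function(r) r$end, integer(1)),
               CALLER_PRIORITY[vapply(pool, function(r) r$caller, character(1))])
  pool <- pool[ord]
  sets <- list()
  open <- list()  # each: list(members, chrom, min_end)
  close_before <- function(chrom, start) {
    still <- list()
    for (o in open) {
      if (o$chrom != chrom || o$max_end <= start) {
        sets[[length(sets) + 1L]] <<- o$members
      } else still[[length(still) + 1L]] <- o
    }
    open <<- still
  }
  for (r in pool) {
    close_before(r$chrom, r$start)
    placed <- FALSE
    for (oi in seq_along(open)) {
      o <- open[[oi]]
      callers <- vapply(o$members, function(m) m$caller, character(1))
      overlaps_all <- all(vapply(o$members, function(m) {
        r$start < m$end && m$start < r$end
      }, logical(1)))
      if (overlaps_all && !(r$caller %in% callers) &&
          identical(o$members[[1]]$unit, r$unit)) {
        o$members[[length(o$members) + 1L]] <- r
        o$max_end <- max(o$max_end, r$end)
        open[[oi]] <- o
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      open[[length(open) + 1L]] <- list(members = list(r), chrom = r$chrom,
                                        max_end = r$end)
    }
  }
  for (o in open) sets[[length(sets) + 1L]] <- o$members
  list(sets = sets, samples = samples)
}

#' Extend all alleles of a mergeable set to the union span
#'
#' Every record is rewritten on the span covering all member records;
#' alleles gain the reference flank sequence on each side (sequence-resolved
#' alleles are extended literally, length-only alleles gain the flank
#' lengths).
#'
#' @param set List of records (one mergeable set).
#' @param reference `DNAStringSet` reference genome.
#' @return List of records, all spanning the union interval.
#' @export
extend_alleles_to_union_span <- function(set, reference) {
  us <- min(vapply(set, function(r) r$start, integer(1)))
  ue <- max(vapply(set, function(r) r$end, integer(1)))
  lapply(set, function(r) {
    if (r$start == us && r$end == ue) return(r)
    lf <- fetch_reference_flank(reference, r$chrom, us, r$start)
    rf <- fetch_reference_flank(reference, r$chrom, r$end, ue)
    alle <- r$alleles
    alle$seq <- ifelse(is.na(alle$seq), NA_character_,
                       paste0(lf, alle$seq, rf))
    alle$len <- alle$len + nchar(lf) + nchar(rf)
    tr_record(r$caller, r$chrom, us, ue, r$unit, alle, r$gt, r$q,
              ci = r$ci, src = r$src)
  })
}

#' Build the consensus allele set for a mergeable set
#'
#' Alleles from all callers, already extended to a common span, are unified
#' into one ordered allele table plus per-caller index mappings. When a
#' sequence-resolved (HipSTR) record is present its sequences represent each
#' length class and same-length alleles from other callers are mapped onto
#' them; two same-length, different-sequence resolved alleles are both
#' retained, and length-only alleles of that length map to the most common
#' of the two (by called-genotype count). Without a sequence-resolved
#' record, consensus alleles are length-only and representative metadata
#' comes from the available callers in fixed priority order
#' (GangSTR > ExpansionHunter > adVNTR).
#'
#' @param extended List of records on a common span (see
#'   [extend_alleles_to_union_span()]).
#' @return List with `alleles` (`data.frame(seq, len)`, row 1 = reference)
#'   and `mapping` (per caller, integer vector: caller allele index ->
#'   consensus allele index).
#' @export
build_consensus_alleles <- function(extended) {
  if (length(extended) == 0L) stop("empty mergeable set")
  callers <- vapply(extended, function(r) r$caller, character(1))
  ref_seqs <- vapply(extended, function(r) r$alleles$seq[1], character(1))
  ref_seq <- ref_seqs[!is.na(ref_seqs)][1]
  ref_len <- extended[[1]]$alleles$len[1]
  cons <- data.frame(seq = ref_seq, len = ref_len, stringsAsFactors = FALSE)

  hip <- extended[callers == "HIPSTR"]
  # register sequence-resolved alleles first
  if (length(hip) > 0L) {
    h <- hip[[1]]
    for (a in seq_len(nrow(h$alleles))[-1]) {
      s <- h$alleles$seq[a]
      if (!any(!is.na(cons$seq) & cons$seq == s)) {
        cons <- rbind(cons, data.frame(seq = s, len = h$alleles$len[a],
                                       stringsAsFactors = FALSE))
      }
    }
  }
  # usage counts of sequence-resolved alleles, for length-ambiguous mapping
  seq_counts <- rep(0L, nrow(cons))
  if (length(hip) > 0L) {
    h <- hip[[1]]
    hmap <- match_alleles(h$alleles, cons)
    used <- table(factor(hmap[h$gt[!is.na(h$gt)]], levels = seq_len(nrow(cons))))
    seq_counts <- as.integer(used)
  }
  # length-only callers in priority order
  others <- extended[callers != "HIPSTR"]
  others <- others[order(CALLER_PRIORITY[vapply(others, function(r) r$caller,
                                                character(1))])]
  for (r in others) {
    for (a in seq_len(nrow(r$alleles))[-1]) {
      L <- r$alleles$len[a]
      if (!any(cons$len == L)) {
        cons <- rbind(cons, data.frame(seq = NA_character_, len = L,
                                       stringsAsFactors = FALSE))
        seq_counts <- c(seq_counts, 0L)
      }
    }
  }
  # stable order: reference first, then by length, then sequence
  rest <- order(cons$len[-1], ifelse(is.na(cons$seq[-1]), "", cons$seq[-1]))
  perm <- c(1L, rest + 1L)
  cons <- cons[perm, , drop = FALSE]
  rownames(cons) <- NULL
  seq_counts <- seq_counts[perm]

  mapping <- lapply(extended, function(r) {
    map_caller_alleles(r, cons, seq_counts)
  })
  names(mapping) <- callers
  list(alleles = cons, mapping = mapping)
}

# exact match of sequence-resolved alleles against the consensus table
match_alleles <- function(alle, cons) {
  vapply(seq_len(nrow(alle)), function(a) {
    s <- alle$seq[a]
    hit <- which(!is.na(cons$seq) & cons$seq == s)
    if (length(hit) == 0L) hit <- which(cons$len == alle$len[a])[1]
    hit[1]
  }, integer(1))
}

map_caller_alleles <- function(r, cons, seq_counts) {
  vapply(seq_len(nrow(r$alleles)), function(a) {
    if (a == 1L) return(1L)
    s <- r$alleles$seq[a]
    if (!is.na(s)) {
      hit <- which(!is.na(cons$seq) & cons$seq == s)
      if (length(hit) > 0L) return(hit[1])
    }
    hits <- which(cons$len == r$alleles$len[a])
    if (length(hits) == 0L) return(NA_integer_)
    if (length(hits) > 1L) {
      # ambiguous length class: take the most common resolved allele
      hits <- hits[order(-seq_counts[hits], hits)]
    }
    hits[1]
  }, integer(1))
}

#' Score candidate diploid genotypes for one sample
#'
#' Implements the quality-weighted vote: with `Q[g, m]` equal to method
#' `m`'s quality when its genotype equals `g` and 0 otherwise,
#' `S_g = (sum_m Q[g, m] / sum_{g'} sum_m Q[g', m]) * max_m Q[g, m]`.
#' Genotypes are unordered pairs of consensus allele indices. Methods that
#' made no call contribute nothing.
#'
#' @param method_calls List of entries `list(method =, g = c(i, j), q =)`;
#'   `g` is an unordered allele-index pair, `q` the method's quality.
#' @return `data.frame` with columns `g1`, `g2`, `S`, `maxQ` and a list
#'   column `methods` of supporting-method character vectors; empty when no
#'   method called or total quality is 0.
#' @export
score_diploid_genotypes <- function(method_calls) {
  method_calls <- Filter(function(mc) !is.null(mc) && !anyNA(mc$g) &&
                           !is.na(mc$q), method_calls)
  empty <- data.frame(g1 = integer(0), g2 = integer(0), S = numeric(0),
                      maxQ = numeric(0))
  empty$methods <- list()
  if (length(method_calls) == 0L) return(empty)
  gkeys <- vapply(method_calls, function(mc) paste(sort(mc$g), collapse = "/"),
                  character(1))
  qs <- vapply(method_calls, function(mc) mc$q, numeric(1))
  denom <- sum(qs)
  if (denom <= 0) return(empty)
  uk <- unique(gkeys)
  out <- lapply(uk, function(key) {
    sel <- gkeys == key
    pair <- as.integer(strsplit(key, "/", fixed = TRUE)[[1]])
    d <- data.frame(g1 = pair[1], g2 = pair[2],
                    S = sum(qs[sel]) / denom * max(qs[sel]),
                    maxQ = max(qs[sel]))
    d$methods <- list(vapply(method_calls[sel], function(mc) mc$method,
                             character(1)))
    d
  })
  do.call(rbind, out)
}

#' Pick the best-scoring genotype
#'
#' Argmax of the score; exact ties (after rounding to 9 decimals) are
#' resolved in favor of the genotype supported by the highest-priority
#' caller (HipSTR > GangSTR > ExpansionHunter > adVNTR).
#'
#' @param scored Output of [score_diploid_genotypes()].
#' @return `NULL` for an empty input; otherwise a list with `g` (sorted
#'   index pair), `S`, `methods` and `tie_broken`.
#' @export
pick_best_genotype <- function(scored) {
  if (nrow(scored) == 0L) return(NULL)
  s9 <- round(scored$S, 9)
  top <- which(s9 == max(s9))
  tie <- length(top) > 1L
  if (tie) {
    prio <- vapply(top, function(i) {
      min(CALLER_PRIORITY[scored$methods[[i]]])
    }, numeric(1))
    top <- top[order(prio)]
  }
  i <- top[1]
  list(g = c(scored$g1[i], scored$g2[i]), S = scored$S[i],
       methods = scored$methods[[i]], tie_broken = tie)
}

#' Consensus-call a cohort across callers
#'
#' Composes the full per-locus pipeline — mergeable-set identification,
#' allele extension and unification, genotype scoring and argmax selection —
#' over every locus and mutual sample. Loci covered by a single caller pass
#' through with their original genotypes and qualities.
#'
#' @param callsets List of [tr_callset()] objects (one per caller).
#' @param reference `DNAStringSet` reference genome.
#' @return A [tr_callset()] of consensus records (caller `"CONSENSUS"`);
#'   per-sample `q` holds the genotype score and `src` the supporting
#'   methods (`"-"`-joined).
#' @export
ensemble_call <- function(callsets, reference) {
  ms <- find_mergeable_sets(callsets)
  samples <- ms$samples
  records <- lapply(ms$sets, function(set) {
    ext <- tryCatch(extend_alleles_to_union_span(set, reference),
                    error = function(e) {
                      warning("flank extension failed (", conditionMessage(e),
                              "); set left unmerged, using first record")
                      set[1]
                    })
    cs <- build_consensus_alleles(ext)
    n <- length(samples)
    gt <- matrix(NA_integer_, n, 2, dimnames = list(samples, NULL))
    q <- rep(NA_real_, n)
    src <- rep(NA_character_, n)
    tie <- rep(FALSE, n)
    for (s in seq_len(n)) {
      mcs <- lapply(seq_along(ext), function(i) {
        r <- ext[[i]]
        a <- r$gt[s, ]
        if (anyNA(a) || is.na(r$q[s])) return(NULL)
        g <- sort(cs$mapping[[i]][a])
        if (anyNA(g)) return(NULL)
        list(method = r$caller, g = g, q = r$q[s])
      })
      best <- pick_best_genotype(score_diploid_genotypes(mcs))
      if (!is.null(best)) {
        gt[s, ] <- best$g
        q[s] <- best$S
        src[s] <- paste(sort(best$methods), collapse = "-")
        tie[s] <- best$tie_broken
      }
    }
    r1 <- ext[[1]]
    rec <- tr_record("CONSENSUS", r1$chrom, r1$start, r1$end, r1$unit,
                     cs$alleles, gt, q, src = src)
    rec$tie_broken <- tie
    rec
  })
  ord <- order(vapply(records, function(r) r$chrom, character(1)),
               vapply(records, function(r) r$start, integer(1)))
  tr_callset(records[ord], samples)
}
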