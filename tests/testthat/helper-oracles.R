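# Independent oracles and tiny fixture builders shared across tests.
# The oracles deliberately use different code paths (explicit loops,
# enumeration) from the package implementation they check.

# --- Brute-force genotype-score evaluator -----------------------------------
# Direct transcription of the quality-weighted vote: for every candidate
# genotype g, Q[g, m] = q_m when method m called g, else 0;
# S_g = sum_m Q[g,m] / sum_{g'} sum_m Q[g',m] * max_m Q[g,m].
oracle_scores <- function(method_calls) {
  gs <- unique(lapply(method_calls, function(mc) sort(mc$g)))
  denom <- 0
  for (g in gs) {
    for (mc in method_calls) {
      if (identical(sort(mc$g), g)) denom <- denom + mc$q
    }
  }
  out <- data.frame(g1 = integer(0), g2 = integer(0), S = numeric(0))
  for (g in gs) {
    qs <- numeric(0)
    for (mc in method_calls) {
      qs <- c(qs, if (identical(sort(mc$g), g)) mc$q else 0)
    }
    out <- rbind(out, data.frame(g1 = g[1], g2 = g[2],
                                 S = sum(qs) / denom * max(qs)))
  }
  out
}

# random scoring instance: n_methods methods voting over a small allele space
random_scoring_instance <- function(n_alleles = 3L, n_methods = NULL) {
  if (is.null(n_methods)) n_methods <- sample.int(4L, 1L)
  methods <- sample(c("HIPSTR", "GANGSTR", "EH", "ADVNTR"), n_methods)
  lapply(methods, function(m) {
    list(method = m, g = sort(sample.int(n_alleles, 2L, replace = TRUE)),
         q = round(stats::runif(1, 0.05, 1), 4))
  })
}

# --- Triple-loop motif-score oracle -----------------------------------------
# Explicit loops over mask subsets, shifts and positions; similarity mode.
oracle_motif_score <- function(motif) {
  n <- nchar(motif)
  if (n == 1L) return(1)
  k <- if (n <= 40) ceiling(n / 10) else 1L
  ch <- strsplit(motif, "")[[1]]
  best <- 0L
  for (sub in utils::combn(n, k, simplify = FALSE)) {
    m1 <- ch
    for (p in sub) m1[p] <- "*"
    m2 <- c(m1, m1)
    for (j in 1:(n - 1)) {
      matches <- 0L
      for (p in 1:n) {
        a <- m1[p]; b <- m2[j + p]
        if (a == "*" || b == "*" || a == b) matches <- matches + 1L
      }
      if (matches > best) best <- matches
    }
  }
  best / n
}

# --- Exhaustive Mendelian-consistency oracle --------------------------------
oracle_mendelian <- function(child, mother, father) {
  for (cm in 1:2) {
    for (cf in 1:2) {
      if (cm == cf) next
      if (child[cm] %in% mother && child[cf] %in% father) return(TRUE)
    }
  }
  FALSE
}

# --- Fixture builders -------------------------------------------------------

# minimal record: sequence-resolved unless seqs = NULL
make_record <- function(caller, start, end, unit, lens, seqs = NULL,
                        gt, q, samples = rownames(gt), chrom = "chrT",
                        ci = NULL) {
  alle <- data.frame(
    seq = if (is.null(seqs)) c(seqs_first_ref(start, end, unit, lens),
                               rep(NA_character_, length(lens) - 1L))
          else seqs,
    len = as.integer(lens), stringsAsFactors = FALSE)
  rownames(gt) <- samples
  tr_record(caller, chrom, start, end, unit, alle, gt, q, ci = ci)
}

seqs_first_ref <- function(start, end, unit, lens) {
  consensusTR:::unit_fill(unit, lens[1])
}

# a reference whose bases are known at specific positions:
# layout: 100 bp of 'T', then from pos 100 a given core string, then 'G' tail
make_reference <- function(core, at = 100L, total = 400L) {
  pre <- strrep("T", at)
  post <- strrep("G", max(0L, total - at - nchar(core)))
  g <- Biostrings::DNAStringSet(paste0(pre, core, post))
  names(g) <- "chrT"
  g
}

gt_matrix <- function(..., samples) {
  m <- rbind(...)
  rownames(m) <- samples
  m
}
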