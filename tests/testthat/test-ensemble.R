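# Consensus calling: quality formulas, genotype scoring, allele unification.

test_that("per-allele quality follows the exponential CI penalty", {
  expect_identical(eh_allele_quality(20, 0), 1)
  expect_equal(eh_allele_quality(10, 10), exp(-4), tolerance = 1e-15)
  expect_equal(eh_allele_quality(40, 10), exp(-1), tolerance = 1e-15)
  expect_identical(eh_allele_quality(0, 5), 0)  # zero copy number
  expect_error(eh_allele_quality(10, -1))
})

test_that("genotype quality weights the lower allele score 0.8", {
  expect_equal(eh_genotype_quality(1, 1), 1)
  expect_equal(eh_genotype_quality(0.5, 1), 0.6)
  expect_equal(eh_genotype_quality(1, 0.5), 0.6)  # order-free
  expect_equal(eh_genotype_quality(0, 1), 0.2)
})

test_that("genotype scores reproduce hand-worked cases", {
  one <- score_diploid_genotypes(list(list(method = "HIPSTR", g = c(1, 2), q = 1)))
  expect_equal(one$S, 1)
  agree <- score_diploid_genotypes(list(
    list(method = "HIPSTR", g = c(1, 2), q = 0.9),
    list(method = "GANGSTR", g = c(2, 1), q = 0.6)))  # unordered comparison
  expect_equal(nrow(agree), 1L)
  expect_equal(agree$S, 0.9)  # (1.5/1.5) * 0.9
  disagree <- score_diploid_genotypes(list(
    list(method = "HIPSTR", g = c(1, 2), q = 0.9),
    list(method = "GANGSTR", g = c(1, 1), q = 0.6)))
  expect_equal(sort(disagree$S), c(0.24, 0.54), tolerance = 1e-12)
  # all methods absent or zero quality: no candidate genotypes
  expect_equal(nrow(score_diploid_genotypes(list())), 0L)
  expect_equal(nrow(score_diploid_genotypes(list(
    list(method = "EH", g = c(1, 1), q = 0)))), 0L)
})

test_that("scores match the brute-force evaluator and votes sum to one", {
  set.seed(101)
  for (i in 1:300) {
    mcs <- random_scoring_instance(n_alleles = sample(2:3, 1))
    got <- score_diploid_genotypes(mcs)
    want <- oracle_scores(mcs)
    key <- function(d) paste(d$g1, d$g2)
    expect_equal(got$S[order(key(got))], want$S[order(key(want))],
                 tolerance = 1e-12)
    # fractional votes over candidate genotypes sum to 1
    votes <- got$S / got$maxQ
    expect_equal(sum(votes), 1, tolerance = 1e-12)
    expect_true(all(got$S > 0 & got$S <= 1))
  }
})

test_that("raising the best supporter's quality never lowers the best score", {
  set.seed(202)
  for (i in 1:100) {
    mcs <- random_scoring_instance()
    best <- pick_best_genotype(score_diploid_genotypes(mcs))
    j <- which(vapply(mcs, function(mc) mc$method, character(1)) %in%
                 best$methods)[1]
    mcs2 <- mcs
    mcs2[[j]]$q <- min(1, mcs2[[j]]$q + stats::runif(1, 0, 1 - mcs2[[j]]$q))
    best2 <- pick_best_genotype(score_diploid_genotypes(mcs2))
    expect_gte(best2$S + 1e-12, best$S)
  }
})

test_that("ties fall to the higher-priority caller", {
  strict <- pick_best_genotype(score_diploid_genotypes(list(
    list(method = "HIPSTR", g = c(1, 2), q = 0.9),
    list(method = "GANGSTR", g = c(1, 1), q = 0.6))))
  expect_equal(strict$g, c(1, 2))
  expect_false(strict$tie_broken)
  tie_hip <- pick_best_genotype(score_diploid_genotypes(list(
    list(method = "GANGSTR", g = c(1, 1), q = 0.5),
    list(method = "HIPSTR", g = c(1, 2), q = 0.5))))
  expect_equal(tie_hip$g, c(1, 2))
  expect_true(tie_hip$tie_broken)
  tie_gang <- pick_best_genotype(score_diploid_genotypes(list(
    list(method = "ADVNTR", g = c(1, 1), q = 0.5),
    list(method = "GANGSTR", g = c(1, 2), q = 0.5))))
  expect_equal(tie_gang$g, c(1, 2))
})

make_pair <- function(unitA = "AC", unitB = "AC",
                      spanA = c(100L, 110L), spanB = c(98L, 112L)) {
  samples <- "s1"
  ra <- make_record("HIPSTR", spanA[1], spanA[2], unitA,
                    spanA[2] - spanA[1],
                    seqs = strrep("AC", (spanA[2] - spanA[1]) / 2),
                    gt = gt_matrix(c(1L, 1L), samples = samples), q = 0.9)
  rb <- make_record("GANGSTR", spanB[1], spanB[2], unitB,
                    spanB[2] - spanB[1], seqs = NULL,
                    gt = gt_matrix(c(1L, 1L), samples = samples), q = 0.8)
  list(tr_callset(list(ra), samples), tr_callset(list(rb), samples))
}

test_that("mergeable sets require overlap and identical units", {
  both <- find_mergeable_sets(make_pair())
  expect_length(both$sets, 1L)
  expect_length(both$sets[[1]], 2L)
  units <- find_mergeable_sets(make_pair(unitB = "AG"))
  expect_length(units$sets, 2L)  # unit mismatch: two singletons
  disjoint <- find_mergeable_sets(make_pair(spanB = c(300L, 310L)))
  expect_length(disjoint$sets, 2L)
  # unsorted input within one callset is rejected
  samples <- "s1"
  r1 <- make_record("HIPSTR", 200L, 210L, "AC", 10L, seqs = strrep("AC", 5),
                    gt = gt_matrix(c(1L, 1L), samples = samples), q = 1)
  r2 <- make_record("HIPSTR", 100L, 110L, "AC", 10L, seqs = strrep("AC", 5),
                    gt = gt_matrix(c(1L, 1L), samples = samples), q = 1)
  expect_error(find_mergeable_sets(list(tr_callset(list(r1, r2), samples))),
               "sorted")
})

test_that("a second record from the same caller starts a new set", {
  samples <- "s1"
  mk <- function(caller, s, e) {
    make_record(caller, s, e, "AC", e - s, seqs = strrep("AC", (e - s) / 2),
                gt = gt_matrix(c(1L, 1L), samples = samples), q = 1)
  }
  cs <- list(tr_callset(list(mk("HIPSTR", 100L, 110L),
                             mk("HIPSTR", 104L, 114L)), samples),
             tr_callset(list(mk("GANGSTR", 100L, 112L)), samples))
  out <- find_mergeable_sets(cs)
  expect_length(out$sets, 2L)
  sizes <- sort(vapply(out$sets, length, integer(1)))
  expect_equal(sizes, c(1L, 2L))
})

test_that("alleles extend to the union span with reference flanks", {
  # reference holds TT at [98,100) and GG at [106,108)
  ref <- make_reference(paste0("TT", "ACACAC", "GG"), at = 98L)
  samples <- "s1"
  ra <- make_record("HIPSTR", 100L, 106L, "AC", 6L, seqs = "ACACAC",
                    gt = gt_matrix(c(1L, 1L), samples = samples), q = 1)
  rb <- make_record("GANGSTR", 98L, 108L, "AC", 10L, seqs = NULL,
                    gt = gt_matrix(c(1L, 1L), samples = samples), q = 1)
  ext <- extend_alleles_to_union_span(list(ra, rb), ref)
  expect_equal(ext[[1]]$alleles$seq[1], "TTACACACGG")
  expect_equal(ext[[1]]$alleles$len[1], 10L)
  expect_equal(ext[[2]], rb)  # already spans the union
  # length-only allele gains exactly the flank length
  rc <- make_record("GANGSTR", 100L, 106L, "AC", c(6L, 8L), seqs = NULL,
                    gt = gt_matrix(c(1L, 2L), samples = samples), q = 1)
  ext2 <- extend_alleles_to_union_span(list(rc, rb), ref)
  expect_equal(ext2[[1]]$alleles$len, c(10L, 12L))
  expect_true(is.na(ext2[[1]]$alleles$seq[2]))
})

test_that("consensus alleles prefer sequence-resolved representations", {
  samples <- c("s1", "s2", "s3")
  seqX <- paste0(strrep("AC", 9), "AG")  # 20 bp, two sequence variants
  seqY <- strrep("AC", 10)
  hip <- make_record("HIPSTR", 100L, 110L, "AC", c(10L, 20L, 20L),
                     seqs = c(strrep("AC", 5), seqX, seqY),
                     gt = gt_matrix(c(2L, 2L), c(2L, 3L), c(1L, 1L),
                                    samples = samples),
                     q = c(0.9, 0.9, 0.9))
  gang <- make_record("GANGSTR", 100L, 110L, "AC", c(10L, 20L), seqs = NULL,
                      gt = gt_matrix(c(1L, 2L), c(1L, 2L), c(2L, 2L),
                                     samples = samples),
                      q = c(0.8, 0.8, 0.8))
  cs <- build_consensus_alleles(list(hip, gang))
  # both 20 bp sequence variants retained as distinct consensus alleles
  expect_equal(sum(cs$alleles$len == 20L), 2L)
  # the length-only 20 bp allele maps onto the more frequent variant (seqX,
  # used 3 times vs once for seqY)
  gmap <- cs$mapping[["GANGSTR"]]
  expect_equal(cs$alleles$seq[gmap[2]], seqX)
  # a single length-only caller passes through with lengths preserved
  solo <- build_consensus_alleles(list(gang))
  expect_equal(solo$alleles$len, c(10L, 20L))
  expect_true(is.na(solo$alleles$seq[2]))
  expect_error(build_consensus_alleles(list()), "empty")
})

test_that("single-caller loci pass through genotypes and qualities", {
  cfg <- sim_config(seed = 5, n_loci = 6L, n_samples = c(A = 15L),
                    callers = default_caller_models(miscall_rate = 0.1)["HIPSTR"])
  sim <- simulate_cohort(cfg)
  cons <- ensemble_call(sim$callsets, sim$ref$genome)
  orig <- sim$callsets$HIPSTR
  expect_length(cons$records, length(orig$records))
  for (l in seq_along(cons$records)) {
    ro <- orig$records[[l]]; rc <- cons$records[[l]]
    expect_equal(rc$alleles$len[rc$gt], ro$alleles$len[ro$gt])
    expect_equal(rc$q, ro$q)
    expect_true(all(rc$src[!is.na(rc$src)] == "HIPSTR"))
  }
})

test_that("an engineered two-caller disagreement resolves by the vote", {
  ref <- make_reference(strrep("AC", 5), at = 100L)
  samples <- c("s1", "s2")
  hip <- make_record("HIPSTR", 100L, 110L, "AC", c(10L, 12L),
                     seqs = c(strrep("AC", 5), strrep("AC", 6)),
                     gt = gt_matrix(c(1L, 2L), c(1L, 2L), samples = samples),
                     q = c(0.9, 0.3))
  gang <- make_record("GANGSTR", 100L, 110L, "AC", c(10L, 12L), seqs = NULL,
                      gt = gt_matrix(c(1L, 2L), c(1L, 1L), samples = samples),
                      q = c(0.6, 0.8))
  cons <- ensemble_call(list(tr_callset(list(hip), samples),
                             tr_callset(list(gang), samples)),
                        ref)
  r <- cons$records[[1]]
  # s1: agreement; S = (0.9+0.6)/1.5 * 0.9 = 0.9
  expect_equal(unname(r$gt["s1", ]), c(1L, 2L))
  expect_equal(r$q[1], 0.9)
  expect_equal(r$src[1], "GANGSTR-HIPSTR")
  # s2: disagreement; gangstr's hom-ref wins: (0.8/1.1)*0.8 > (0.3/1.1)*0.3
  expect_equal(unname(r$gt["s2", ]), c(1L, 1L))
  expect_equal(r$q[2], 0.8 / 1.1 * 0.8, tolerance = 1e-12)
  expect_equal(r$src[2], "GANGSTR")
})

test_that("consensus beats noisy callers when one caller is clean", {
  cfg <- sim_config(
    seed = 17, n_loci = 20L, n_samples = c(A = 40L),
    callers = list(
      HIPSTR = utils::modifyList(default_caller_models()$HIPSTR,
                                 list(miscall_rate = 0, nocall_rate = 0,
                                      q_correct = c(1, 1), span_jitter = 0L)),
      GANGSTR = utils::modifyList(default_caller_models()$GANGSTR,
                                  list(miscall_rate = 0.2,
                                       q_correct = c(0.4, 0.6),
                                       q_error = c(0.4, 0.6))),
      ADVNTR = utils::modifyList(default_caller_models()$ADVNTR,
                                 list(miscall_rate = 0.2,
                                      q_correct = c(0.4, 0.6),
                                      q_error = c(0.4, 0.6)))))
  sim <- simulate_cohort(cfg)
  cons <- ensemble_call(sim$callsets, sim$ref$genome)
  acc <- function(callset) {
    hits <- 0L; tot <- 0L
    for (l in seq_along(callset$records)) {
      r <- callset$records[[l]]
      truth <- sim$truth$geno[[l]][rownames(r$gt), , drop = FALSE]
      called <- !is.na(r$gt[, 1])
      ulen <- nchar(r$unit)
      obs_off <- matrix((r$alleles$len[r$gt[called, ]] - r$alleles$len[1]) / ulen,
                        ncol = 2)
      tru <- t(apply(truth[called, , drop = FALSE], 1, sort))
      obs <- t(apply(obs_off, 1, sort))
      hits <- hits + sum(rowSums(obs == tru) == 2)
      tot <- tot + nrow(obs)
    }
    hits / tot
  }
  accs <- vapply(sim$callsets, acc, numeric(1))
  expect_gte(acc(cons), max(accs))
})
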