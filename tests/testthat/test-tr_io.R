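# VCF dialect parsing, writing, flank extraction and span harmonization.

test_that("VCF positions convert to 0-based half-open spans", {
  samples <- c("s1", "s2")
  rec <- make_record("HIPSTR", 100L, 110L, "AC", c(10L, 12L),
                     seqs = c(strrep("AC", 5), strrep("AC", 6)),
                     gt = gt_matrix(c(1L, 2L), c(1L, 1L), samples = samples),
                     q = c(0.95, 0.9))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_caller_vcf(tr_callset(list(rec), samples), path, "hipstr")
  line <- grep("^chrT", readLines(path), value = TRUE)
  expect_equal(as.integer(strsplit(line, "\t")[[1]][2]), 101L)  # POS = start+1
  back <- parse_caller_vcf(path, "hipstr")
  expect_equal(back$records[[1]]$start, 100L)
  expect_equal(back$records[[1]]$end, 110L)
})

test_that("parse-write-parse is the identity on records", {
  samples <- c("s1", "s2", "s3")
  for (dialect in c("hipstr", "gangstr", "eh", "advntr", "consensus")) {
    seqs <- if (dialect %in% c("hipstr", "consensus"))
      c(strrep("AC", 5), strrep("AC", 6), strrep("AC", 4)) else NULL
    ci <- if (dialect == "eh")
      gt_matrix(c(0, 20), c(0, 0), c(NA, NA), samples = samples) else NULL
    rec <- make_record(toupper(sub("^eh$", "EH", dialect)), 100L, 110L, "AC",
                       c(10L, 12L, 8L), seqs = seqs,
                       gt = gt_matrix(c(1L, 2L), c(1L, 3L), c(NA, NA),
                                      samples = samples),
                       q = c(0.9, 0.85, NA), ci = ci)
    if (dialect == "eh") {
      rec$q <- c(eh_genotype_quality(eh_allele_quality(5, 0),
                                     eh_allele_quality(6, 20)),
                 eh_genotype_quality(1, 1), NA)
    }
    p1 <- withr::local_tempfile(fileext = ".vcf")
    p2 <- withr::local_tempfile(fileext = ".vcf")
    cs1 <- tr_callset(list(rec), samples)
    write_caller_vcf(cs1, p1, dialect)
    cs2 <- parse_caller_vcf(p1, dialect)
    write_caller_vcf(cs2, p2, dialect)
    cs3 <- parse_caller_vcf(p2, dialect)
    r2 <- cs2$records[[1]]; r3 <- cs3$records[[1]]
    expect_equal(r2$start, 100L); expect_equal(r2$end, 110L)
    expect_equal(r2$alleles$len, c(10L, 12L, 8L))
    expect_equal(unname(r2$gt), unname(rbind(c(1L, 2L), c(1L, 3L), c(NA, NA))),
                 label = dialect)
    expect_equal(r3[c("start", "end", "unit", "alleles")],
                 r2[c("start", "end", "unit", "alleles")], label = dialect)
    expect_equal(r3$gt, r2$gt)
    expect_equal(r3$q, r2$q, tolerance = 1e-12)
  }
})

test_that("ExpansionHunter confidence intervals parse to widths", {
  samples <- "s1"
  vcf <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=RU,Number=1,Type=String,Description="x">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="x">',
           '##FORMAT=<ID=REPCN,Number=1,Type=String,Description="x">',
           '##FORMAT=<ID=REPCI,Number=1,Type=String,Description="x">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"),
           paste(c("chrT", "101", ".", strrep("AC", 12), strrep("AC", 40),
                   ".", ".", "RU=AC", "GT:REPCN:REPCI",
                   "0/1:12/40:12-12/30-50"), collapse = "\t"))
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  cs <- parse_caller_vcf(path, "eh")
  r <- cs$records[[1]]
  expect_equal(unname(r$ci[1, ]), c(0, 20))
  expect_equal(r$q[1],
               eh_genotype_quality(eh_allele_quality(12, 0),
                                   eh_allele_quality(40, 20)))
  # a call without a CI is treated as absent
  vcf[7] <- sub("0/1:12/40:12-12/30-50", "0/1:12/40:.", vcf[7])
  writeLines(vcf, path)
  r <- parse_caller_vcf(path, "eh")$records[[1]]
  expect_true(all(is.na(r$gt)))
})

test_that("empty and malformed inputs are handled", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "s1"), collapse = "\t")), path)
  cs <- suppressWarnings(parse_caller_vcf(path, "hipstr"))
  expect_length(cs$records, 0L)
  expect_error(parse_caller_vcf(path, "bogus"), "dialect")
})

test_that("reference flank extraction is exact, uppercase and bounded", {
  ref <- make_reference("acgtACGT", at = 98L)
  expect_equal(fetch_reference_flank(ref, "chrT", 98L, 100L), "AC")
  expect_equal(fetch_reference_flank(ref, "chrT", 100L, 100L), "")
  expect_equal(fetch_reference_flank(ref, "chrT", 98L, 106L), "ACGTACGT")
  expect_error(fetch_reference_flank(ref, "chrX", 0L, 1L), "contig")
  expect_error(fetch_reference_flank(ref, "chrT", 0L, 10000L), "bounds")
})

test_that("span harmonization trims to the largest common interval", {
  samples <- c("s1", "s2")
  core <- strrep("AC", 5)
  # record A spans [100,110); record B spans [98,110) with 2 extra flank bases
  ra <- make_record("HIPSTR", 100L, 110L, "AC", c(10L, 12L),
                    seqs = c(core, strrep("AC", 6)),
                    gt = gt_matrix(c(1L, 2L), c(1L, 1L), samples = samples),
                    q = c(0.9, 0.9))
  rb <- make_record("HIPSTR", 98L, 110L, "AC", c(12L, 14L),
                    seqs = c(paste0("TT", core), paste0("TT", strrep("AC", 6))),
                    gt = gt_matrix(c(1L, 2L), c(1L, 1L), samples = samples),
                    q = c(0.8, 0.8))
  out <- harmonize_reference_spans(list(ra, rb))
  expect_equal(out[[1]], ra)  # already on the common interval
  expect_equal(out[[2]]$start, 100L)
  expect_equal(out[[2]]$alleles$seq[1], core)  # leading TT removed
  expect_equal(out[[2]]$alleles$len, c(10L, 12L))
  # trimmed reference alleles identical across records
  expect_identical(out[[1]]$alleles$seq[1], out[[2]]$alleles$seq[1])
  # no allele lengthened, no no-call became called
  for (i in 1:2) {
    expect_true(all(out[[i]]$alleles$len <=
                      max(list(ra, rb)[[i]]$alleles$len)))
  }
})

test_that("alleles emptied by trimming convert carriers to no-calls", {
  samples <- c("s1", "s2")
  core <- strrep("AC", 5)
  # allele 2 of rb is a pure 2 bp left-flank insertion: trimming [98,110)
  # down to [100,110) leaves it 0 bp wide relative to its record, i.e. the
  # allele is only the flank
  ra <- make_record("HIPSTR", 100L, 110L, "AC", c(10L),
                    seqs = core,
                    gt = gt_matrix(c(1L, 1L), c(1L, 1L), samples = samples),
                    q = c(0.9, 0.9))
  rb <- make_record("HIPSTR", 98L, 110L, "AC", c(12L, 2L),
                    seqs = c(paste0("TT", core), "TT"),
                    gt = gt_matrix(c(1L, 2L), c(1L, 1L), samples = samples),
                    q = c(0.8, 0.8))
  out <- harmonize_reference_spans(list(ra, rb))
  expect_true(all(is.na(out[[2]]$gt["s1", ])))   # carried the emptied allele
  expect_equal(unname(out[[2]]$gt["s2", ]), c(1L, 1L))
  expect_equal(nrow(out[[2]]$alleles), 1L)
  # zero-width common interval drops everything
  rc <- make_record("HIPSTR", 200L, 210L, "AC", 10L, seqs = core,
                    gt = gt_matrix(c(1L, 1L), c(1L, 1L), samples = samples),
                    q = c(0.9, 0.9))
  expect_warning(out2 <- harmonize_reference_spans(list(ra, rc)), "zero-width")
  expect_length(out2, 0L)
})

test_that("consensus VCF lists non-reference alleles in stable order", {
  samples <- c("s1", "s2")
  rec <- make_record("CONSENSUS", 100L, 110L, "AC", c(10L, 8L, 12L),
                     seqs = c(strrep("AC", 5), strrep("AC", 4), strrep("AC", 6)),
                     gt = gt_matrix(c(2L, 3L), c(NA, NA), samples = samples),
                     q = c(0.7, NA))
  rec$src <- c("GANGSTR-HIPSTR", NA)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_consensus_vcf(tr_callset(list(rec), samples), path)
  fields <- strsplit(grep("^chrT", readLines(path), value = TRUE), "\t")[[1]]
  expect_equal(fields[5], paste(strrep("AC", 4), strrep("AC", 6), sep = ","))
  expect_match(fields[10], "GANGSTR-HIPSTR")
  expect_equal(fields[11], "./.:.:.")  # all-no-call sample still emitted
  back <- parse_caller_vcf(path, "consensus")
  expect_equal(unname(back$records[[1]]$gt["s1", ]), c(2L, 3L))
  expect_equal(back$records[[1]]$src[1], "GANGSTR-HIPSTR")
})

test_that("pedigree and population tables round-trip", {
  ped <- data.frame(child = "c1", mother = "m1", father = "f1")
  path <- withr::local_tempfile(fileext = ".ped")
  write_sample_table(ped, path)
  expect_equal(read_pedigree(path), ped)
  writeLines("c1\tc1\tf1", path)
  expect_error(read_pedigree(path), "distinct")
  pop <- data.frame(sample = c("s1", "s2"), population = c("A", "B"))
  write_sample_table(pop, path)
  expect_equal(read_population_table(path), pop)
})
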