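# Seeded synthetic-cohort generator.
#
# Produces every input the pipeline consumes: a reference contig with
# embedded perfect repeats, population-structured truth genotypes with
# frequency decay away from the reference length, trios with a controllable
# Mendelian-error rate, per-caller discordant VCFs in the four dialects, and
# phased SNP haplotypes for LD evaluation. All draws come from labeled
# substreams of a master seed, so outputs are byte-identical across runs and
# adding one generator never perturbs another.

#' Default caller error models
#'
#' @param miscall_rate,nocall_rate Per-call probabilities shared by all four
#'   callers.
#' @return Named list of per-caller model lists (fields: `dialect`,
#'   `miscall_rate`, `nocall_rate`, `q_correct`, `q_error` — uniform ranges
#'   for call quality, `span_jitter` bp (HipSTR only), `ci_error_frac` — CI
#'   width as a fraction of CN on erroneous ExpansionHunter calls, `loci` —
#'   optional locus-index subset).
#' @export
default_caller_models <- function(miscall_rate = 0.02, nocall_rate = 0.02) {
  base <- list(miscall_rate = miscall_rate, nocall_rate = nocall_rate,
               q_correct = c(0.9, 1), q_error = c(0.1, 0.5),
               span_jitter = 0L, ci_error_frac = 0.5, loci = NULL)
  list(
    HIPSTR  = utils::modifyList(base, list(dialect = "hipstr", span_jitter = 2L)),
    GANGSTR = utils::modifyList(base, list(dialect = "gangstr")),
    EH      = utils::modifyList(base, list(dialect = "eh")),
    ADVNTR  = utils::modifyList(base, list(dialect = "advntr"))
  )
}

#' Simulation configuration
#'
#' Defaults describe a small two-population cohort with modest caller noise:
#' allele-frequency spectra decay geometrically with copy-number distance
#' from the reference and carry a slight bias toward contractions;
#' populations differ by multiplicative log-normal drift on the spectrum
#' weights.
#'
#' @param seed Master seed; every generator derives a labeled substream.
#' @param n_loci Number of TR loci on the synthetic contig.
#' @param n_samples Named integer vector: samples per population.
#' @param units Repeat-unit pool sampled per locus.
#' @param copies_range Reference copy-number range (inclusive).
#' @param max_offset Largest copy offset in the base spectrum.
#' @param decay Geometric decay of allele frequency per copy of offset.
#' @param short_bias Multiplier (> 1) favoring contractions.
#' @param drift SD of the log-normal population perturbation of spectrum
#'   weights (0 = identical spectra).
#' @param callers Per-caller error models, see [default_caller_models()].
#' @param trios List: `n` trios and `mendelian_error_rate`; trio members are
#'   added as extra samples of `trio_population`.
#' @param trio_population Population whose spectrum trios are drawn from.
#' @param expansions Optional `data.frame(locus, population, freq, offset)`
#'   of injected expansion alleles (offset in copies).
#' @param snp List: `n_per_locus`, `maf` range, `tag_strength` (coupling
#'   probability of the designated tag SNP).
#' @param gap_bp Minimum flank gap between consecutive loci (bp).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 42L, n_loci = 30L,
                       n_samples = c(POP1 = 60L, POP2 = 60L),
                       units = c("A", "AC", "AG", "AT", "CAG", "AAG", "AGAT", "AATG"),
                       copies_range = c(8L, 15L),
                       max_offset = 3L, decay = 0.4, short_bias = 1.15,
                       drift = 0.3,
                       callers = default_caller_models(),
                       trios = list(n = 0L, mendelian_error_rate = 0),
                       trio_population = names(n_samples)[1],
                       expansions = NULL,
                       snp = list(n_per_locus = 5L, maf = c(0.1, 0.5),
                                  tag_strength = 1),
                       gap_bp = 200L) {
  structure(as.list(environment()), class = "sim_config")
}

#' Generate the synthetic reference
#'
#' Each locus is a perfect repeat `unit^copies` embedded in random flanking
#' sequence; consecutive loci are separated by at least `gap_bp` bases.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (`DNAStringSet`, one contig `chrS`) and `loci`
#'   (`data.frame`: `locus`, `chrom`, `start`, `end`, `unit`, `ref_copies`).
#' @export
generate_reference <- function(config) {
  with_substream(config$seed, "reference", {
    pieces <- character(0)
    pos <- 0L
    rows <- vector("list", config$n_loci)
    for (i in seq_len(config$n_loci)) {
      gap <- config$gap_bp + sample.int(100L, 1L)
      flank <- paste(sample(c("A", "C", "G", "T"), gap, replace = TRUE),
                     collapse = "")
      unit <- sample(config$units, 1L)
      copies <- sample(seq(config$copies_range[1], config$copies_range[2]), 1L)
      rep_seq <- strrep(unit, copies)
      start <- pos + gap
      end <- start + nchar(rep_seq)
      pieces <- c(pieces, flank, rep_seq)
      rows[[i]] <- data.frame(locus = i, chrom = "chrS", start = start,
                              end = end, unit = unit, ref_copies = copies,
                              stringsAsFactors = FALSE)
      pos <- end
    }
    tail_flank <- paste(sample(c("A", "C", "G", "T"), 300L, replace = TRUE),
                        collapse = "")
    genome <- Biostrings::DNAStringSet(paste(c(pieces, tail_flank), collapse = ""))
    names(genome) <- "chrS"
    list(genome = genome, loci = do.call(rbind, rows))
  })
}

# base spectrum over copy offsets for one locus (before drift/injection)
base_spectrum <- function(config) {
  off <- seq(-config$max_offset, config$max_offset)
  w <- config$decay^abs(off) * ifelse(off < 0, config$short_bias, 1)
  stats::setNames(w / sum(w), off)
}

#' Simulate population-structured truth genotypes
#'
#' Per-locus spectra over copy offsets decay with distance from the
#' reference; per-population spectra are drifted versions of the base
#' spectrum; configured expansion alleles are injected at their target
#' frequency. Diploid genotypes are independent draws from the population
#' spectrum.
#'
#' @param config A [sim_config()].
#' @param ref Output of [generate_reference()].
#' @return List with `samples`, `pops` (named vector sample -> population),
#'   `spectra` (`spectra[[locus]][[pop]]`, named frequency vectors over
#'   offsets) and `geno` (`geno[[locus]]`, integer matrix `samples x 2` of
#'   copy offsets).
#' @export
simulate_truth_genotypes <- function(config, ref) {
  pops <- rep(names(config$n_samples), config$n_samples)
  samples <- paste0(pops, "_", unlist(lapply(config$n_samples, seq_len)))
  names(pops) <- samples
  base <- base_spectrum(config)
  spectra <- vector("list", config$n_loci)
  geno <- vector("list", config$n_loci)
  for (l in seq_len(config$n_loci)) {
    spectra[[l]] <- list()
    gmat <- matrix(NA_integer_, length(samples), 2,
                   dimnames = list(samples, NULL))
    for (p in names(config$n_samples)) {
      sp <- with_substream(config$seed, paste0("spectrum_", l, "_", p), {
        w <- as.numeric(base) * exp(stats::rnorm(length(base), 0, config$drift))
        stats::setNames(w / sum(w), names(base))
      })
      inj <- config$expansions
      if (!is.null(inj)) {
        hit <- inj$locus == l & inj$population == p
        if (any(hit)) {
          f <- inj$freq[hit][1]
          sp <- c(sp * (1 - f), stats::setNames(f, inj$offset[hit][1]))
        }
      }
      spectra[[l]][[p]] <- sp
      idx <- which(pops == p)
      draws <- with_substream(config$seed, paste0("geno_", l, "_", p), {
        matrix(sample(as.integer(names(sp)), 2 * length(idx), replace = TRUE,
                      prob = as.numeric(sp)), ncol = 2)
      })
      gmat[idx, ] <- draws
    }
    geno[[l]] <- gmat
  }
  list(samples = samples, pops = pops, spectra = spectra, geno = geno)
}

#' Simulate trios
#'
#' Parents are drawn from the configured population's spectra; each child
#' inherits one allele per parent. With probability equal to the
#' Mendelian-error rate, one child allele is replaced by a spectrum draw
#' restricted to alleles that make the trio Mendelian-inconsistent, so the
#' configured rate is the rate of observable inheritance violations (when no
#' violating allele exists — the parents jointly cover the allele space —
#' the trio is left error-free). Because an MI analysis excludes trios that
#' are homozygous reference throughout, the raw injection probability is
#' thinned by the expected ineligible fraction so that the configured rate
#' equals the expected measured MI-error rate among eligible trios. Trio
#' members are appended to the truth table as new samples.
#'
#' @param config A [sim_config()] with `trios$n > 0`.
#' @param truth Output of [simulate_truth_genotypes()].
#' @return List with `truth` (extended) and `pedigree`
#'   (`data.frame(child, mother, father)`).
#' @export
simulate_trios <- function(config, truth) {
  nt <- config$trios$n
  if (nt == 0L) return(list(truth = truth, pedigree = NULL))
  err <- config$trios$mendelian_error_rate
  pop <- config$trio_population
  kids <- sprintf("trio%d_child", seq_len(nt))
  moms <- sprintf("trio%d_mother", seq_len(nt))
  dads <- sprintf("trio%d_father", seq_len(nt))
  new_samples <- c(rbind(kids, moms, dads))
  truth$samples <- c(truth$samples, new_samples)
  truth$pops <- c(truth$pops,
                  stats::setNames(rep(pop, length(new_samples)), new_samples))
  for (l in seq_along(truth$geno)) {
    sp <- truth$spectra[[l]][[pop]]
    offs <- as.integer(names(sp))
    probs <- as.numeric(sp)
    # probability that an error-free trio is MI-ineligible (all hom-ref);
    # thinning the injection rate by it makes the configured error rate the
    # expected violation rate among eligible trios
    p0 <- if ("0" %in% names(sp)) sp[["0"]] else 0
    q_inelig <- p0^6
    e_adj <- err * (1 - q_inelig) / (1 - err * q_inelig)
    add <- with_substream(config$seed, paste0("trio_", l), {
      m <- matrix(NA_integer_, length(new_samples), 2,
                  dimnames = list(new_samples, NULL))
      for (t in seq_len(nt)) {
        mo <- sample(offs, 2, replace = TRUE, prob = probs)
        fa <- sample(offs, 2, replace = TRUE, prob = probs)
        ch <- c(mo[sample.int(2, 1)], fa[sample.int(2, 1)])
        if (stats::runif(1) < e_adj) {
          j <- sample.int(2, 1)
          breaks_mi <- vapply(offs, function(a) {
            g <- ch; g[j] <- a
            !is_mendelian_consistent(g, mo, fa)
          }, logical(1))
          if (any(breaks_mi)) {
            ch[j] <- if (sum(breaks_mi) == 1L) offs[breaks_mi] else
              sample(offs[breaks_mi], 1, prob = probs[breaks_mi])
          }
        }
        m[kids[t], ] <- ch
        m[moms[t], ] <- mo
        m[dads[t], ] <- fa
      }
      m
    })
    truth$geno[[l]] <- rbind(truth$geno[[l]], add)
  }
  list(truth = truth,
       pedigree = data.frame(child = kids, mother = moms, father = dads,
                             stringsAsFactors = FALSE))
}

#' Emit per-caller callsets from the truth
#'
#' Applies each caller's error model to the truth genotypes: calls are
#' dropped (no-call) or miscalled (offset perturbed by 1-2 copies) at the
#' configured rates; correct calls receive high qualities and miscalls low
#' ones. The HipSTR dialect is sequence-resolved and optionally shifts its
#' span into the left flank (absorbing the flank bases into every allele);
#' the ExpansionHunter dialect carries copy numbers with confidence
#' intervals that widen on erroneous calls.
#'
#' @param config A [sim_config()].
#' @param ref Output of [generate_reference()].
#' @param truth Output of [simulate_truth_genotypes()] (possibly extended by
#'   [simulate_trios()]).
#' @return Named list of [tr_callset()] objects, one per configured caller.
#' @export
emit_caller_vcfs <- function(config, ref, truth) {
  samples <- truth$samples
  out <- list()
  for (cname in names(config$callers)) {
    cm <- config$callers[[cname]]
    loci <- cm$loci %||% seq_len(config$n_loci)
    records <- vector("list", length(loci))
    for (li in seq_along(loci)) {
      l <- loci[li]
      row <- ref$loci[l, ]
      ulen <- nchar(row$unit)
      true_off <- truth$geno[[l]][samples, , drop = FALSE]
      obs <- with_substream(config$seed, paste0("call_", cname, "_", l), {
        o <- true_off
        n2 <- length(o)
        mis <- matrix(stats::runif(n2) < cm$miscall_rate, nrow(o))
        o[mis] <- o[mis] + sample(c(-2L, -1L, 1L, 2L), sum(mis), replace = TRUE)
        o[] <- pmax(o, 1L - row$ref_copies)  # keep allele lengths positive
        nocall <- stats::runif(nrow(o)) < cm$nocall_rate
        o[nocall, ] <- NA_integer_
        qok <- stats::runif(nrow(o), cm$q_correct[1], cm$q_correct[2])
        qbad <- stats::runif(nrow(o), cm$q_error[1], cm$q_error[2])
        bad <- mis[, 1] | mis[, 2]
        list(off = o, bad = bad, q = ifelse(bad, qbad, qok))
      })
      offs <- sort(unique(c(0L, as.vector(obs$off[!is.na(obs$off)]))))
      offs <- c(0L, setdiff(offs, 0L))  # reference first
      lens <- (row$ref_copies + offs) * ulen
      ref_seq <- fetch_reference_flank(ref$genome, row$chrom, row$start, row$end)
      seqs <- vapply(lens, unit_fill, character(1), unit = row$unit)
      seqs[1] <- ref_seq
      start <- row$start; end <- row$end
      if (cm$dialect == "hipstr" && cm$span_jitter > 0L) {
        j <- min(cm$span_jitter, start)
        lf <- fetch_reference_flank(ref$genome, row$chrom, start - j, start)
        seqs <- paste0(lf, seqs)
        lens <- lens + j
        start <- start - j
      }
      alleles <- data.frame(
        seq = if (cm$dialect == "hipstr") seqs else
          c(seqs[1], rep(NA_character_, length(seqs) - 1L)),
        len = as.integer(lens), stringsAsFactors = FALSE)
      gt <- matrix(NA_integer_, length(samples), 2,
                   dimnames = list(samples, NULL))
      called <- !is.na(obs$off[, 1])
      if (any(called)) {
        gt[called, 1] <- match(obs$off[called, 1], offs)
        gt[called, 2] <- match(obs$off[called, 2], offs)
        gt[called, ] <- t(apply(gt[called, , drop = FALSE], 1, sort))
      }
      q <- ifelse(called, obs$q, NA_real_)
      ci <- NULL
      if (cm$dialect == "eh") {
        ci <- matrix(NA_real_, length(samples), 2,
                     dimnames = list(samples, NULL))
        cns <- (row$ref_copies + obs$off)
        w <- ifelse(obs$bad, cm$ci_error_frac, 0) * cns
        ci[called, ] <- w[called, ]
        q[called] <- vapply(which(called), function(s) {
          eh_genotype_quality(eh_allele_quality(cns[s, 1], ci[s, 1]),
                              eh_allele_quality(cns[s, 2], ci[s, 2]))
        }, numeric(1))
      }
      records[[li]] <- tr_record(cname, row$chrom, start, end, row$unit,
                                 alleles, gt, q, ci = ci)
    }
    out[[cname]] <- tr_callset(records, samples)
  }
  out
}

#' Simulate a phased SNP panel tagging each TR
#'
#' For each locus, `n_per_locus` SNPs are placed in the flank upstream of
#' the repeat. One designated tag SNP is coupled to the TR: on each
#' haplotype, with probability `tag_strength` its allele equals the
#' indicator of a non-reference TR allele, otherwise it is an independent
#' Bernoulli draw; the remaining SNPs are independent with a minor-allele
#' frequency drawn from the configured range. TR haplotype order is
#' `(sample1 allele1, sample1 allele2, sample2 allele1, ...)`.
#'
#' @param config A [sim_config()].
#' @param ref Output of [generate_reference()].
#' @param truth Truth genotypes.
#' @return Per-locus list: `positions`, `ids`, `tag` (index of the
#'   designated tag SNP), `haps` (`2n x n_per_locus` 0/1 matrix), `tr_hap`
#'   (length-`2n` vector of TR copy offsets).
#' @export
simulate_snp_panel <- function(config, ref, truth) {
  nsnp <- config$snp$n_per_locus
  lapply(seq_len(config$n_loci), function(l) {
    row <- ref$loci[l, ]
    tr_hap <- as.vector(t(truth$geno[[l]][truth$samples, , drop = FALSE]))
    with_substream(config$seed, paste0("snp_", l), {
      lo <- max(0L, row$start - config$gap_bp + 10L)
      positions <- sort(sample(seq(lo, row$start - 1L), nsnp))
      tag <- sample.int(nsnp, 1L)
      haps <- matrix(0L, length(tr_hap), nsnp)
      for (j in seq_len(nsnp)) {
        maf <- stats::runif(1, config$snp$maf[1], config$snp$maf[2])
        haps[, j] <- as.integer(stats::runif(length(tr_hap)) < maf)
      }
      couple <- stats::runif(length(tr_hap)) < config$snp$tag_strength
      haps[couple, tag] <- as.integer(tr_hap[couple] != 0L)
      list(positions = positions,
           ids = sprintf("snp_%d_%d", l, seq_len(nsnp)),
           tag = tag, haps = haps, tr_hap = tr_hap)
    })
  })
}

#' Write a phased SNP panel as VCF
#'
#' @param panel Output of [simulate_snp_panel()].
#' @param samples Sample ids (haplotype rows are consecutive pairs).
#' @param path Output path.
#' @param chrom Contig name.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(panel, samples, path, chrom = "chrS") {
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Phased genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  lines <- character(0)
  for (p in panel) {
    for (j in seq_along(p$positions)) {
      gts <- vapply(seq_along(samples), function(s) {
        sprintf("%d|%d", p$haps[2 * s - 1, j], p$haps[2 * s, j])
      }, character(1))
      lines <- c(lines, paste(c(chrom, p$positions[j] + 1L, p$ids[j],
                                "A", "G", ".", ".", ".", "GT", gts),
                              collapse = "\t"))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, lines), con, sep = "\n")
  invisible(path)
}

#' Run the full generator and optionally write all fixtures
#'
#' @param config A [sim_config()].
#' @param outdir Optional directory; when given, writes `reference.fa`,
#'   `loci.tsv`, one `<caller>.vcf` per caller, `pedigree.ped`,
#'   `populations.tsv`, `snps.vcf` and `truth.tsv`.
#' @return List with `ref`, `truth`, `pedigree`, `callsets`, `snp_panel`.
#' @export
simulate_cohort <- function(config, outdir = NULL) {
  ref <- generate_reference(config)
  truth <- simulate_truth_genotypes(config, ref)
  tr <- simulate_trios(config, truth)
  truth <- tr$truth
  callsets <- emit_caller_vcfs(config, ref, truth)
  panel <- simulate_snp_panel(config, ref, truth)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(ref$genome, file.path(outdir, "reference.fa"))
    utils::write.table(ref$loci, file.path(outdir, "loci.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (cname in names(callsets)) {
      write_caller_vcf(callsets[[cname]],
                       file.path(outdir, paste0(tolower(cname), ".vcf")),
                       config$callers[[cname]]$dialect)
    }
    if (!is.null(tr$pedigree)) {
      write_sample_table(tr$pedigree, file.path(outdir, "pedigree.ped"))
    }
    write_sample_table(data.frame(sample = truth$samples,
                                  population = truth$pops[truth$samples]),
                       file.path(outdir, "populations.tsv"))
    write_snp_vcf(panel, truth$samples, file.path(outdir, "snps.vcf"))
    tt <- do.call(rbind, lapply(seq_along(truth$geno), function(l) {
      data.frame(locus = l, sample = rownames(truth$geno[[l]]),
                 off1 = truth$geno[[l]][, 1], off2 = truth$geno[[l]][, 2])
    }))
    utils::write.table(tt, file.path(outdir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(ref = ref, truth = truth, pedigree = tr$pedigree,
       callsets = callsets, snp_panel = panel)
}
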