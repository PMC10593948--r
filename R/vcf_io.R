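# VCF I/O for the four caller dialects plus the consensus dialect.
#
# Dialect FORMAT conventions (VCF 4.2, INFO carries RU=<repeat unit>):
#   hipstr / gangstr / advntr : GT:Q        Q in [0,1], per call
#   eh                        : GT:REPCN:REPCI  copy numbers + per-allele CIs
#   consensus                 : GT:SCORE:SRC    genotype score + method tags
# HipSTR and consensus records are sequence-resolved; for the copy-number
# dialects only allele lengths are retained (the ALT column still holds a
# serialized perfect-repeat sequence so files remain valid VCF).

VCF_DIALECTS <- c("hipstr", "gangstr", "eh", "advntr", "consensus")

dialect_caller <- function(dialect) {
  switch(dialect, hipstr = "HIPSTR", gangstr = "GANGSTR", eh = "EH",
         advntr = "ADVNTR", consensus = "CONSENSUS")
}

#' Parse a caller VCF into a callset
#'
#' Reads a multi-sample VCF in one of the supported dialects and returns
#' normalized records: 1-based VCF positions become 0-based half-open spans,
#' ExpansionHunter confidence intervals become per-allele widths
#' (`upper - lower`, in copies), and per-call qualities are mapped to
#' `Q in [0, 1]` (for the ExpansionHunter dialect, `Q` is derived from the
#' copy numbers and CI widths via [eh_genotype_quality()]). Calls missing a
#' required per-call field (`Q`, or `REPCI` for ExpansionHunter) are treated
#' as absent.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param dialect One of `"hipstr"`, `"gangstr"`, `"eh"`, `"advntr"`,
#'   `"consensus"`. Dialects are declared, not sniffed.
#' @return A [tr_callset()] with records sorted by `(chrom, start)`.
#' @export
parse_caller_vcf <- function(path, dialect) {
  if (!dialect %in% VCF_DIALECTS) {
    stop("unknown dialect '", dialect, "'; valid dialects: ",
         paste(VCF_DIALECTS, collapse = ", "))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  samples <- colnames(vcf@gt)[-1] %||% character(0)
  if (nrow(fix) == 0L) return(tr_callset(list(), samples))
  info <- vcf@fix[, "INFO"]
  records <- vector("list", nrow(fix))
  kept <- logical(nrow(fix))
  for (i in seq_len(nrow(fix))) {
    rec <- parse_vcf_row(fix[i, ], info[i], vcf@gt[i, , drop = TRUE],
                         samples, dialect, i)
    if (!is.null(rec)) {
      records[[i]] <- rec
      kept[i] <- TRUE
    }
  }
  records <- records[kept]
  ord <- order(vapply(records, function(r) r$chrom, character(1)),
               vapply(records, function(r) r$start, integer(1)))
  tr_callset(records[ord], samples)
}

parse_vcf_row <- function(fixrow, info, gtrow, samples, dialect, rowno) {
  ru <- sub(".*RU=([ACGTacgt]+).*", "\\1", info)
  if (identical(ru, info)) {
    warning("record ", rowno, ": no RU tag in INFO; record skipped")
    return(NULL)
  }
  ref <- toupper(fixrow[["REF"]])
  alt <- fixrow[["ALT"]]
  alts <- if (is.na(alt) || alt == ".") character(0) else
    toupper(strsplit(alt, ",", fixed = TRUE)[[1]])
  seqs <- c(ref, alts)
  lens <- nchar(seqs)
  keep_seq <- dialect %in% c("hipstr", "consensus")
  alleles <- data.frame(
    seq = if (keep_seq) seqs else c(ref, rep(NA_character_, length(alts))),
    len = as.integer(lens), stringsAsFactors = FALSE)
  start <- as.integer(fixrow[["POS"]]) - 1L
  end <- start + nchar(ref)

  fmt <- strsplit(gtrow[[1]], ":", fixed = TRUE)[[1]]
  need <- switch(dialect, eh = c("GT", "REPCN", "REPCI"),
                 consensus = c("GT", "SCORE", "SRC"), c("GT", "Q"))
  if (!all(need %in% fmt)) {
    warning("record ", rowno, ": FORMAT lacks ", paste(setdiff(need, fmt), collapse = ","),
            "; record skipped")
    return(NULL)
  }
  n <- length(samples)
  gt <- matrix(NA_integer_, n, 2, dimnames = list(samples, NULL))
  q <- rep(NA_real_, n)
  ci <- if (dialect == "eh") matrix(NA_real_, n, 2, dimnames = list(samples, NULL)) else NULL
  src <- if (dialect == "consensus") rep(NA_character_, n) else NULL
  for (s in seq_len(n)) {
    fields <- strsplit(gtrow[[s + 1L]], ":", fixed = TRUE)[[1]]
    names(fields) <- fmt[seq_along(fields)]
    g <- fields[["GT"]]
    if (is.na(g) || grepl("\\.", g)) next
    idx <- as.integer(strsplit(g, "[/|]")[[1]]) + 1L
    if (length(idx) != 2L || anyNA(idx) || any(idx > nrow(alleles))) next
    if (dialect == "eh") {
      repci <- fields["REPCI"]
      repcn <- fields["REPCN"]
      if (is.na(repci) || is.na(repcn) || repci == "." || repcn == ".") next
      cns <- as.numeric(strsplit(repcn, "/", fixed = TRUE)[[1]])
      bounds <- strsplit(strsplit(repci, "/", fixed = TRUE)[[1]], "-", fixed = TRUE)
      if (length(cns) != 2L || length(bounds) != 2L) next
      widths <- vapply(bounds, function(b) as.numeric(b[2]) - as.numeric(b[1]),
                       numeric(1))
      gt[s, ] <- sort(idx)
      ci[s, ] <- widths
      q[s] <- eh_genotype_quality(eh_allele_quality(cns[1], widths[1]),
                                  eh_allele_quality(cns[2], widths[2]))
    } else if (dialect == "consensus") {
      sc <- suppressWarnings(as.numeric(fields["SCORE"]))
      if (is.na(sc)) next
      gt[s, ] <- sort(idx)
      q[s] <- sc
      src[s] <- fields[["SRC"]]
    } else {
      qs <- suppressWarnings(as.numeric(fields["Q"]))
      if (is.na(qs)) next  # missing Q: call treated as absent
      gt[s, ] <- sort(idx)
      q[s] <- qs
    }
  }
  tr_record(dialect_caller(dialect), fixrow[["CHROM"]], start, end,
            check_dna(ru, "repeat unit"), alleles, gt, q, ci = ci, src = src)
}

#' Write a callset as a VCF file
#'
#' Serializes records in the stated dialect; output is deterministic
#' (byte-identical for identical inputs) and re-parseable by
#' [parse_caller_vcf()]. Length-only alleles are serialized as perfect
#' repeats of the unit truncated to the allele length. For consensus
#' callsets the per-call fields are the genotype, its score and the
#' method-of-origin annotation.
#'
#' @param callset A [tr_callset()].
#' @param path Output path (plain text; use a `.vcf` extension).
#' @param dialect Target dialect (see [parse_caller_vcf()]).
#' @return `path`, invisibly.
#' @export
write_caller_vcf <- function(callset, path, dialect) {
  if (!dialect %in% VCF_DIALECTS) stop("unknown dialect '", dialect, "'")
  fmtdef <- switch(dialect,
    eh = c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=REPCN,Number=1,Type=String,Description="Allele copy numbers">',
           '##FORMAT=<ID=REPCI,Number=1,Type=String,Description="Allele copy-number confidence intervals">'),
    consensus = c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                  '##FORMAT=<ID=SCORE,Number=1,Type=Float,Description="Consensus genotype score">',
                  '##FORMAT=<ID=SRC,Number=1,Type=String,Description="Supporting methods">'),
    c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      '##FORMAT=<ID=Q,Number=1,Type=Float,Description="Call quality">'))
  header <- c("##fileformat=VCFv4.2",
              '##INFO=<ID=RU,Number=1,Type=String,Description="Repeat unit">',
              fmtdef,
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", callset$samples), collapse = "\t"))
  fmt <- switch(dialect, eh = "GT:REPCN:REPCI", consensus = "GT:SCORE:SRC", "GT:Q")
  lines <- vapply(callset$records, function(r) {
    seqs <- ifelse(is.na(r$alleles$seq),
                   vapply(r$alleles$len, unit_fill, character(1), unit = r$unit),
                   r$alleles$seq)
    alt <- if (nrow(r$alleles) > 1L) paste(seqs[-1], collapse = ",") else "."
    ulen <- nchar(r$unit)
    cells <- vapply(seq_along(r$q), function(s) {
      a <- r$gt[s, ]
      if (anyNA(a)) {
        return(switch(dialect, eh = "./.:.:.", consensus = "./.:.:.", "./.:."))
      }
      g <- paste(sort(a) - 1L, collapse = "/")
      if (dialect == "eh") {
        cns <- r$alleles$len[a] / ulen
        w <- if (!is.null(r$ci) && !anyNA(r$ci[s, ])) r$ci[s, ] else c(0, 0)
        sprintf("%s:%s:%s", g,
                paste(sprintf("%g", cns), collapse = "/"),
                paste(sprintf("%g-%g", cns, cns + w), collapse = "/"))
      } else if (dialect == "consensus") {
        srcs <- if (!is.null(r$src) && !is.na(r$src[s])) r$src[s] else "."
        sprintf("%s:%s:%s", g, sprintf("%.9g", r$q[s]), srcs)
      } else {
        sprintf("%s:%s", g, sprintf("%.9g", r$q[s]))
      }
    }, character(1))
    paste(c(r$chrom, r$start + 1L, sprintf("%s_%d", r$chrom, r$start),
            seqs[1], alt, ".", ".", paste0("RU=", r$unit), fmt, cells),
          collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, lines), con, sep = "\n")
  invisible(path)
}

#' Write a consensus callset as VCF
#'
#' Convenience wrapper for [write_caller_vcf()] in the consensus dialect.
#'
#' @inheritParams write_caller_vcf
#' @return `path`, invisibly.
#' @export
write_consensus_vcf <- function(callset, path) {
  write_caller_vcf(callset, path, "consensus")
}

#' Load a reference genome FASTA
#'
#' @param path FASTA path.
#' @return A named `DNAStringSet` (names truncated to the first token).
#' @export
read_reference <- function(path) {
  ref <- Biostrings::readDNAStringSet(path)
  names(ref) <- sub("\\s.*", "", names(ref))
  ref
}

#' Extract a reference flank sequence
#'
#' @param reference A `DNAStringSet` (e.g. from [read_reference()]).
#' @param chrom Contig name.
#' @param start,end 0-based half-open interval.
#' @return Uppercase DNA string of length `end - start` (empty string for a
#'   zero-length interval).
#' @export
fetch_reference_flank <- function(reference, chrom, start, end) {
  if (!chrom %in% names(reference)) stop("contig '", chrom, "' not in reference")
  if (start > end) stop("start must be <= end")
  if (start == end) return("")
  clen <- length(reference[[chrom]])
  if (start < 0 || end > clen) {
    stop(sprintf("interval [%d,%d) out of bounds for contig %s (length %d)",
                 start, end, chrom, clen))
  }
  toupper(as.character(Biostrings::subseq(reference[[chrom]], start + 1L, end)))
}

#' Harmonize reference spans across files of one caller
#'
#' When the same locus is reported with slightly different coordinates in
#' different cohort files of the same caller, all records are trimmed to the
#' largest common reference interval: `[max(start), min(end))`. Alleles lose
#' the corresponding flank bases; any allele whose trimmed sequence is empty
#' is removed and every genotype carrying it becomes a no-call. Alleles that
#' collide after trimming (same length and sequence) are merged.
#'
#' @param records List of [tr_record()] objects from the same caller for the
#'   same locus.
#' @return List of trimmed records (empty, with a warning, if the common
#'   interval has zero width). All trimmed records share the reference
#'   allele.
#' @export
harmonize_reference_spans <- function(records) {
  if (length(records) <= 1L) return(records)
  cs <- max(vapply(records, function(r) r$start, integer(1)))
  ce <- min(vapply(records, function(r) r$end, integer(1)))
  if (cs >= ce) {
    warning("zero-width common reference interval; records dropped")
    return(list())
  }
  lapply(records, function(r) trim_record(r, cs, ce))
}

trim_record <- function(r, cs, ce) {
  left <- cs - r$start
  right <- r$end - ce
  if (left == 0L && right == 0L) return(r)
  newlen <- r$alleles$len - left - right
  newseq <- ifelse(is.na(r$alleles$seq), NA_character_,
                   substr(r$alleles$seq, left + 1L,
                          nchar(r$alleles$seq) - right))
  empty <- newlen <= 0L
  # genotypes carrying an emptied allele become no-calls
  gt <- r$gt
  q <- r$q
  hit <- !is.na(gt[, 1]) & (empty[gt[, 1]] | empty[gt[, 2]])
  gt[hit, ] <- NA_integer_
  q[hit] <- NA_real_
  keep <- which(!empty)
  alle <- data.frame(seq = newseq[keep], len = as.integer(newlen[keep]),
                     stringsAsFactors = FALSE)
  # merge alleles that became identical after trimming
  key <- paste(alle$len, ifelse(is.na(alle$seq), "", alle$seq))
  first <- match(key, key)
  uniq <- which(first == seq_along(first))
  remap <- integer(nrow(r$alleles))
  remap[keep] <- match(first, uniq)
  gt[] <- ifelse(is.na(gt), NA_integer_, remap[gt])
  tr_record(r$caller, r$chrom, cs, ce, r$unit, alle[uniq, , drop = FALSE],
            gt, q, ci = r$ci, src = r$src)
}
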