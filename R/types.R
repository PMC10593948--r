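# Core containers: per-caller locus records and multi-sample callsets.
#
# Coordinates are 0-based half-open internally; VCF I/O converts at the
# boundary. Allele index 1 is always the reference allele over the record
# span. Genotypes are unordered pairs of allele indices (NA = no-call).

CALLERS <- c("HIPSTR", "GANGSTR", "EH", "ADVNTR")
CALLER_PRIORITY <- c(HIPSTR = 1L, GANGSTR = 2L, EH = 3L, ADVNTR = 4L, CONSENSUS = 5L)

#' Construct a single-locus TR record
#'
#' One caller's view of one tandem-repeat locus: span, repeat unit, allele
#' table and per-sample diploid genotypes with qualities.
#'
#' @param caller Caller id: `"HIPSTR"`, `"GANGSTR"`, `"EH"`, `"ADVNTR"` or
#'   `"CONSENSUS"`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open span of the reference allele.
#' @param unit Repeat unit (uppercase DNA, 1-20 bp typical).
#' @param alleles `data.frame(seq, len)`; row 1 is the reference allele.
#'   `seq` may be `NA` for length-only callers (all but HipSTR); `len` is in
#'   base pairs.
#' @param gt Integer matrix `samples x 2` of allele indices (1 = reference);
#'   `NA` marks a no-call. Rownames are sample ids.
#' @param q Numeric vector of per-sample qualities in `[0, 1]` (for a
#'   consensus record, the genotype score); `NA` where no call.
#' @param ci Optional numeric matrix `samples x 2` of per-allele confidence
#'   interval widths in repeat copies (ExpansionHunter dialect only).
#' @param src Optional character vector of per-sample supporting-method
#'   annotations (consensus records).
#' @return An object of class `tr_record`.
#' @export
tr_record <- function(caller, chrom, start, end, unit, alleles, gt, q,
                      ci = NULL, src = NULL) {
  stopifnot(start < end, is.data.frame(alleles),
            all(c("seq", "len") %in% names(alleles)),
            is.matrix(gt), ncol(gt) == 2L, !is.null(rownames(gt)))
  unit <- check_dna(unit, "repeat unit")
  if (length(q) != nrow(gt)) stop("q must have one entry per sample")
  structure(list(caller = caller, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 unit = unit, alleles = alleles, gt = gt,
                 q = as.numeric(q), ci = ci, src = src),
            class = "tr_record")
}

#' @export
print.tr_record <- function(x, ...) {
  ncall <- sum(!is.na(x$gt[, 1]))
  cat(sprintf("<tr_record %s %s:%d-%d unit=%s alleles=%d called=%d/%d>\n",
              x$caller, x$chrom, x$start, x$end, x$unit,
              nrow(x$alleles), ncall, nrow(x$gt)))
  invisible(x)
}

#' Construct a multi-locus callset
#'
#' @param records List of [tr_record()] objects sharing a sample universe.
#' @param samples Character vector of sample ids (column universe of all
#'   records).
#' @return An object of class `tr_callset`.
#' @export
tr_callset <- function(records, samples) {
  structure(list(records = records, samples = samples), class = "tr_callset")
}

#' @export
print.tr_callset <- function(x, ...) {
  cat(sprintf("<tr_callset: %d loci x %d samples>\n",
              length(x$records), length(x$samples)))
  invisible(x)
}

#' Flatten a callset to a long calls table
#'
#' One row per called (sample, locus) pair with allele lengths in bp, copy
#' offsets from the reference, and the call score. Convenient input for the
#' population-genetics functions.
#'
#' @param callset A [tr_callset()].
#' @return `data.frame` with columns `locus` (index), `chrom`, `start`,
#'   `unit_len`, `ref_len`, `sample`, `a1`, `a2` (allele indices), `len1`,
#'   `len2` (bp), `off1`, `off2` (copies relative to reference), `score`.
#' @export
calls_table <- function(callset) {
  out <- lapply(seq_along(callset$records), function(i) {
    r <- callset$records[[i]]
    called <- which(!is.na(r$gt[, 1]) & !is.na(r$gt[, 2]))
    if (length(called) == 0L) return(NULL)
    ulen <- nchar(r$unit)
    rlen <- r$alleles$len[1]
    l1 <- r$alleles$len[r$gt[called, 1]]
    l2 <- r$alleles$len[r$gt[called, 2]]
    data.frame(locus = i, chrom = r$chrom, start = r$start,
               unit_len = ulen, ref_len = rlen,
               sample = rownames(r$gt)[called],
               a1 = r$gt[called, 1], a2 = r$gt[called, 2],
               len1 = l1, len2 = l2,
               off1 = (l1 - rlen) / ulen, off2 = (l2 - rlen) / ulen,
               score = r$q[called], stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Read a trio pedigree file
#'
#' Tab-separated file with columns child, mother, father (no header).
#'
#' @param path File path.
#' @return `data.frame` with columns `child`, `mother`, `father`.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("child", "mother", "father"),
                           stringsAsFactors = FALSE)
  bad <- apply(ped, 1, function(r) length(unique(r)) != 3L)
  if (any(bad)) stop("pedigree rows must name three distinct samples (rows ",
                     paste(which(bad), collapse = ","), ")")
  ped
}

#' Read a sample-to-population table
#'
#' Tab-separated file with columns sample, population and optionally
#' superpopulation (no header).
#'
#' @param path File path.
#' @return `data.frame` with columns `sample`, `population` and, when
#'   present, `superpopulation`.
#' @export
read_population_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  names(tab) <- c("sample", "population", "superpopulation")[seq_len(ncol(tab))]
  tab
}

#' Write a pedigree / population table
#'
#' @param x `data.frame` as returned by [read_pedigree()] or
#'   [read_population_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
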