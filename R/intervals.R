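#' Read a BED file of genomic intervals
#'
#' Thin wrapper over [rtracklayer::import()] returning a `GRanges`. Used for
#' low-complexity-region (LCR) exclusion tracks and per-sample callable
#' masks (regions with adequate aligned depth and mapping quality).
#'
#' @param path BED file path.
#' @return a `GRanges`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::reduce(gr)
}

#' Write genomic intervals as BED
#' @param gr a `GRanges`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Jointly callable autosomal base pairs for a trio
#'
#' The denominator of the germline mutation rate: the number of autosomal
#' positions callable (depth >= 12, mapping quality >= 20, as encoded in the
#' masks) in the child *and* both parents, excluding low-complexity regions
#' and the X chromosome.
#'
#' @param child,mother,father per-sample callable masks (`GRanges`).
#' @param lcr low-complexity exclusion intervals (`GRanges`), may be empty.
#' @param x_chrom name of the X-like chromosome to exclude.
#' @return base-pair count (numeric scalar).
#' @export
callable_autosomal_bp <- function(child, mother, father,
                                  lcr = GenomicRanges::GRanges(),
                                  x_chrom = "chrX") {
  grs <- list(child, mother, father, lcr)
  lv <- unique(unlist(lapply(grs, GenomeInfoDb::seqlevels)))
  grs <- lapply(grs, function(g) {
    GenomeInfoDb::seqlevels(g) <- lv
    g
  })
  r <- GenomicRanges::intersect(grs[[1]], grs[[2]], ignore.strand = TRUE)
  r <- GenomicRanges::intersect(r, grs[[3]], ignore.strand = TRUE)
  if (length(grs[[4]])) r <- GenomicRanges::setdiff(r, grs[[4]], ignore.strand = TRUE)
  r <- r[as.character(GenomicRanges::seqnames(r)) != x_chrom]
  sum(as.numeric(GenomicRanges::width(r)))
}

#' Callable autosomal fraction for a trio
#'
#' [callable_autosomal_bp()] divided by the total autosomal genome size,
#' used to scale expected DNM counts in coverage-aware regression models.
#'
#' @inheritParams callable_autosomal_bp
#' @param genome data frame with columns `chrom` and `length`.
#' @return fraction in \[0, 1\].
#' @export
callable_fraction <- function(child, mother, father, lcr, genome,
                              x_chrom = "chrX") {
  tot <- sum(as.numeric(genome$length[genome$chrom != x_chrom]))
  callable_autosomal_bp(child, mother, father, lcr, x_chrom) / tot
}

## intervals as a plain data.frame (chrom, start, end; 1-based closed) -> GRanges
df_to_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
}
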