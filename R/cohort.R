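#' Construct a cohort of jointly genotyped variant sites
#'
#' A cohort bundles a site table with a long-format table of per-sample
#' genotype calls. Samples without an explicit call row at a site are taken
#' to carry the `default_call` (a confidently genotyped homozygous-reference
#' call); this sparse representation keeps large cohorts tractable, since at
#' any candidate site only the focal family and incidental carriers deviate
#' from the reference.
#'
#' @param sites data frame: `site_id`, `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `context` (trinucleotide, `NA` for indels), `filter_pass`,
#'   `in_lcr`.
#' @param calls data frame: `site_id`, `sample_id`, `gt` (one of `hom_ref`,
#'   `het`, `hom_alt`, `missing`, `hemizygous_alt`), `dp`, `ad_ref`,
#'   `ad_alt`, `gq`.
#' @param samples character vector of all sample ids in the cohort.
#' @param default_call list with `gt`, `dp`, `ad_ref`, `ad_alt`, `gq` used
#'   for samples with no explicit row.
#' @return an object of class `dnm_cohort`.
#' @export
new_cohort <- function(sites, calls, samples,
                       default_call = list(gt = "hom_ref", dp = 30L,
                                           ad_ref = 30L, ad_alt = 0L,
                                           gq = 99L)) {
  stopifnot(all(c("site_id", "chrom", "pos", "ref", "alt") %in% names(sites)),
            all(c("site_id", "sample_id", "gt", "dp", "ad_ref", "ad_alt",
                  "gq") %in% names(calls)))
  if (is.null(sites$context)) sites$context <- NA_character_
  if (is.null(sites$filter_pass)) sites$filter_pass <- TRUE
  if (is.null(sites$in_lcr)) sites$in_lcr <- FALSE
  if (anyDuplicated(sites$site_id)) stop("duplicate site_id")
  bad_gt <- !calls$gt %in% c("hom_ref", "het", "hom_alt", "missing",
                             "hemizygous_alt")
  if (any(bad_gt)) stop("invalid genotype codes in calls")
  rownames(sites) <- NULL
  rownames(calls) <- NULL
  structure(list(sites = sites, calls = calls,
                 samples = as.character(samples),
                 default_call = default_call,
                 .index = new.env(parent = emptyenv())),
            class = "dnm_cohort")
}

#' @export
print.dnm_cohort <- function(x, ...) {
  cat(sprintf("<dnm_cohort> %d sites x %d samples (%d explicit calls)\n",
              nrow(x$sites), length(x$samples), nrow(x$calls)))
  invisible(x)
}

call_key <- function(site_id, sample_id) paste(site_id, sample_id, sep = "\r")

#' Look up genotype calls (with implicit reference defaults)
#'
#' @param cohort a [new_cohort()] object.
#' @param site_id,sample_id equal-length vectors (recycled).
#' @return data frame with one row per query: `site_id`, `sample_id`, `gt`,
#'   `dp`, `ad_ref`, `ad_alt`, `gq`, `present` (TRUE if the sample is in the
#'   cohort at all).
#' @export
get_calls <- function(cohort, site_id, sample_id) {
  n <- max(length(site_id), length(sample_id))
  site_id <- rep_len(site_id, n)
  sample_id <- rep_len(sample_id, n)
  ## the (site, sample) key of the call table is memoized; the call table
  ## is treated as immutable after construction
  env <- cohort$.index
  if (is.null(env) ) {
    key <- call_key(cohort$calls$site_id, cohort$calls$sample_id)
  } else {
    if (is.null(env$key) || length(env$key) != nrow(cohort$calls)) {
      env$key <- call_key(cohort$calls$site_id, cohort$calls$sample_id)
    }
    key <- env$key
  }
  idx <- match(call_key(site_id, sample_id), key)
  d <- cohort$default_call
  out <- data.frame(
    site_id = site_id, sample_id = sample_id,
    gt = ifelse(is.na(idx), d$gt, cohort$calls$gt[idx]),
    dp = ifelse(is.na(idx), d$dp, cohort$calls$dp[idx]),
    ad_ref = ifelse(is.na(idx), d$ad_ref, cohort$calls$ad_ref[idx]),
    ad_alt = ifelse(is.na(idx), d$ad_alt, cohort$calls$ad_alt[idx]),
    gq = ifelse(is.na(idx), d$gq, cohort$calls$gq[idx]),
    stringsAsFactors = FALSE
  )
  out$present <- sample_id %in% cohort$samples
  out
}

#' Expand a cohort to one explicit call per site/sample pair
#'
#' Densifies the sparse call table; mainly used to compare cohorts after a
#' round trip through VCF.
#'
#' @param cohort a cohort.
#' @return data frame ordered by site then sample.
#' @export
expand_calls <- function(cohort) {
  grid <- expand.grid(sample_id = cohort$samples,
                      site_id = cohort$sites$site_id,
                      stringsAsFactors = FALSE)
  out <- get_calls(cohort, grid$site_id, grid$sample_id)
  out$present <- NULL
  out[order(out$site_id, out$sample_id), ]
}

gt_has_alt <- function(gt) gt %in% c("het", "hom_alt", "hemizygous_alt")

## allele balance = alt / (ref + alt); NA when no informative reads
allele_balance <- function(ad_ref, ad_alt) {
  tot <- ad_ref + ad_alt
  ifelse(tot > 0, ad_alt / tot, NA_real_)
}

## exact threshold comparison on allele-depth fractions: thresholds are
## 2-decimal rationals, so compare 100*alt >= 100*thr*(ref+alt) in integers
ab_ge <- function(ad_ref, ad_alt, thr) {
  tot <- ad_ref + ad_alt
  !is.na(tot) & tot > 0 & (100 * ad_alt >= round(100 * thr) * tot)
}

# ---------------------------------------------------------------------------
# VCF I/O

gt_to_vcf <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               missing = "./.", hemizygous_alt = "1")

#' Write a cohort as a multi-sample VCF 4.2 file
#'
#' Emits GT:AD:DP:GQ per sample; the trinucleotide context and LCR flag are
#' carried in INFO (`CTX=`, `LCR`), the site id in the ID column, and the
#' GATK-style PASS status in FILTER.
#'
#' @param cohort a cohort.
#' @param path output path.
#' @param genome optional data frame (`chrom`, `length`) for contig headers.
#' @return invisibly, `path`.
#' @export
write_vcf <- function(cohort, path, genome = NULL) {
  s <- cohort$sites
  s <- s[order(s$chrom, s$pos), , drop = FALSE]
  hdr <- c("##fileformat=VCFv4.2", "##source=dnmkit")
  if (!is.null(genome)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          genome$chrom, as.integer(genome$length)))
  }
  hdr <- c(hdr,
    '##INFO=<ID=CTX,Number=1,Type=String,Description="Trinucleotide reference context">',
    '##INFO=<ID=LCR,Number=0,Type=Flag,Description="Site in a low-complexity region">',
    '##FILTER=<ID=fail,Description="Failed joint-calling filters">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples), collapse = "\t"))
  ## genotype matrix: default string everywhere, then overwrite explicit calls
  d <- cohort$default_call
  def <- sprintf("%s:%d,%d:%d:%d", gt_to_vcf[[d$gt]], d$ad_ref, d$ad_alt,
                 d$dp, d$gq)
  m <- matrix(def, nrow = nrow(s), ncol = length(cohort$samples))
  cc <- cohort$calls
  ri <- match(cc$site_id, s$site_id)
  ci <- match(cc$sample_id, cohort$samples)
  keep <- !is.na(ri) & !is.na(ci)
  cc <- cc[keep, , drop = FALSE]
  str <- sprintf("%s:%s:%s:%s", gt_to_vcf[cc$gt],
                 ifelse(cc$gt == "missing", ".",
                        paste0(cc$ad_ref, ",", cc$ad_alt)),
                 ifelse(is.na(cc$dp), ".", cc$dp),
                 ifelse(is.na(cc$gq), ".", cc$gq))
  m[cbind(ri[keep], ci[keep])] <- str
  info <- ifelse(is.na(s$context), ".", paste0("CTX=", s$context))
  info <- ifelse(s$in_lcr, ifelse(info == ".", "LCR", paste0(info, ";LCR")),
                 info)
  body <- paste(s$chrom, s$pos, s$site_id, s$ref, s$alt, ".",
                ifelse(s$filter_pass, "PASS", "fail"), info, "GT:AD:DP:GQ",
                apply(m, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a multi-sample VCF into a cohort
#'
#' Parses with \pkg{vcfR}; all calls become explicit rows. Multi-allelic
#' records are dropped with a message (sites are normalized to biallelic
#' before analysis; records failing that normalization are not analyzed).
#'
#' @param path VCF path.
#' @return a [new_cohort()] object.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    message(sum(multi), " multi-allelic record(s) dropped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  info <- vcfR::getINFO(v)
  ctx <- ifelse(grepl("CTX=", info), sub(".*CTX=([ACGT]{3}).*", "\\1", info),
                NA_character_)
  ids <- fix$ID
  if (anyNA(ids) || anyDuplicated(ids)) ids <- sprintf("S%06d", seq_len(nrow(fix)))
  sites <- data.frame(
    site_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, context = ctx,
    filter_pass = fix$FILTER %in% c("PASS", "."),
    in_lcr = grepl("(^|;)LCR(;|$)", info),
    stringsAsFactors = FALSE
  )
  gt <- vcfR::extract.gt(v, "GT")
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(v, "GQ", as.numeric = TRUE)
  ad <- vcfR::extract.gt(v, "AD")
  samples <- colnames(gt)
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep("missing", length(g))
    out[g %in% c("0/0", "0")] <- "hom_ref"
    out[g %in% c("0/1", "1/0")] <- "het"
    out[g == "1/1"] <- "hom_alt"
    out[g == "1"] <- "hemizygous_alt"
    out
  }
  adr <- suppressWarnings(as.integer(sub(",.*", "", ad)))
  ada <- suppressWarnings(as.integer(sub(".*,", "", ad)))
  calls <- data.frame(
    site_id = rep(sites$site_id, times = ncol(gt)),
    sample_id = rep(samples, each = nrow(gt)),
    gt = code(as.vector(gt)),
    dp = as.integer(as.vector(dp)),
    ad_ref = adr, ad_alt = ada,
    gq = as.integer(as.vector(gq)),
    stringsAsFactors = FALSE
  )
  new_cohort(sites, calls, samples)
}

# ---------------------------------------------------------------------------
# Tabular evidence I/O

#' Read or write fragment-level read co-observation evidence
#'
#' The read-evidence table records, per sequencing fragment, the alleles
#' observed at two sites (a DNM site and a nearby heterozygous site), used
#' for read tracing and the three-haplotype test. Columns: `fragment_id`,
#' `sample_id`, `chrom`, `posA`, `alleleA`, `posB`, `alleleB`, `baseq_ok`,
#' `mapq_ok`.
#'
#' @param x data frame (for writing).
#' @param path TSV path.
#' @return `read_read_evidence` returns the data frame.
#' @export
read_read_evidence <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(fragment_id = "character",
                                   sample_id = "character",
                                   chrom = "character",
                                   alleleA = "character",
                                   alleleB = "character"),
                    stringsAsFactors = FALSE)
}

#' @rdname read_read_evidence
#' @export
write_read_evidence <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write deep-resequencing parental read support
#'
#' One row per (deep-sequenced first-generation parent, site): the number
#' of reads supporting the candidate allele at mapping quality >= 20 and
#' base quality >= 20 in the ~60X alignments. Columns: `sample_id`,
#' `chrom`, `pos`, `allele`, `n_reads`.
#'
#' @param x data frame (for writing).
#' @param path TSV path.
#' @return `read_deep_reads` returns the data frame.
#' @export
read_deep_reads <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(sample_id = "character",
                                   chrom = "character",
                                   allele = "character"),
                    stringsAsFactors = FALSE)
}

#' @rdname read_deep_reads
#' @export
write_deep_reads <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
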