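#' Filtering thresholds for DNM discovery
#'
#' @param min_depth minimum aligned depth in the child and both parents.
#' @param min_gq minimum Phred-scaled genotype quality in the child and
#'   both parents.
#' @param max_parent_alt_reads maximum reads supporting the de novo allele
#'   in either parent (0: any parental support rejects).
#' @param min_ab_g3 minimum allele balance for third-generation DNMs.
#' @param carrier_ab allele-balance threshold promoting a possible carrier
#'   to a likely carrier.
#' @param min_transmission_ab minimum median allele balance across
#'   second-generation transmissions.
#' @param min_g3_for_transmission if set, second-generation candidates from
#'   families with fewer sequenced grandchildren than this are excluded
#'   (there is too little power to validate transmission); `NULL` disables
#'   the exclusion.
#' @param x_chrom name of the X chromosome in the site table.
#' @return a `dnm_params` list.
#' @export
dnm_params <- function(min_depth = 12L, min_gq = 20L,
                       max_parent_alt_reads = 0L,
                       min_ab_g3 = 0.3, carrier_ab = 0.2,
                       min_transmission_ab = 0.3,
                       min_g3_for_transmission = NULL,
                       x_chrom = "chrX") {
  structure(as.list(environment()), class = "dnm_params")
}

discovery_filters <- c("parents_genotyped", "child_genotype",
                       "parental_genotype", "depth", "gq",
                       "parental_alt_reads", "site_filter", "lcr",
                       "likely_carrier")

#' Cohort-wide carrier status for a candidate allele
#'
#' Possible carriers are samples genotyped with the candidate allele outside
#' the candidate's immediate family ([immediate_family()]); likely carriers
#' are the subset with depth >= `min_depth`, allele balance >=
#' `carrier_ab` and GQ >= `min_gq`.
#'
#' @param cohort a cohort.
#' @param site_id site identifier.
#' @param child_id the candidate's sample id (defines the exempt family).
#' @param pedigree the pedigree.
#' @param params a [dnm_params()].
#' @return list with character vectors `possible` and `likely`
#'   (`likely` is always a subset of `possible`).
#' @export
carrier_status <- function(cohort, site_id, child_id, pedigree,
                           params = dnm_params()) {
  idx <- alt_call_index(cohort)
  carrier_status_idx(idx, site_id, immediate_family(pedigree, child_id),
                     params)
}

## alt-genotype calls split by site, for repeated carrier lookups
alt_call_index <- function(cohort) {
  cc <- cohort$calls[gt_has_alt(cohort$calls$gt), , drop = FALSE]
  split(cc, cc$site_id)
}

carrier_status_idx <- function(idx, site_id, exempt, params) {
  at <- idx[[site_id]]
  if (is.null(at)) return(list(possible = character(), likely = character()))
  at <- at[!at$sample_id %in% exempt, , drop = FALSE]
  likely <- at$sample_id[!is.na(at$dp) & at$dp >= params$min_depth &
                           ab_ge(at$ad_ref, at$ad_alt, params$carrier_ab) &
                           !is.na(at$gq) & at$gq >= params$min_gq]
  list(possible = unique(at$sample_id), likely = unique(likely))
}

## per-child immediate-family cache
family_cache <- function(pedigree) {
  env <- new.env(parent = emptyenv())
  function(id) {
    if (is.null(env[[id]])) env[[id]] <- immediate_family(pedigree, id)
    env[[id]]
  }
}

#' Identify candidate de novo mutations
#'
#' Scans every genotyped child (second and third generation) for sites
#' where the child carries an allele absent from both parents, applying in
#' order: both parents genotyped; child genotype heterozygous (or, on the
#' X, hemizygous-alt for males); both parents without the allele; depth >=
#' `min_depth` and GQ >= `min_gq` in the trio; no reads supporting the de
#' novo allele in either parent; site PASS; site outside low-complexity
#' regions; and no likely carriers elsewhere in the cohort. Each rejected
#' candidate records its first failing filter; the full ordered trail is
#' kept per candidate.
#'
#' @param cohort a cohort.
#' @param pedigree the pedigree.
#' @param params a [dnm_params()].
#' @return data frame of candidates (status `candidate` or `rejected`,
#'   columns `first_fail` and `trail` record the filter trail). The number
#'   of children skipped for lack of genotyped parents is in
#'   `attr(, "n_skipped_no_parents")`.
#' @export
find_candidates <- function(cohort, pedigree, params = dnm_params()) {
  cc <- cohort$calls
  cand <- cc[gt_has_alt(cc$gt), , drop = FALSE]
  gen <- pedigree$generation[match(cand$sample_id, pedigree$id)]
  cand <- cand[!is.na(gen) & gen %in% c("G2", "G3"), , drop = FALSE]
  if (!nrow(cand)) {
    out <- data.frame(site_id = character(), child_id = character())
    attr(out, "n_skipped_no_parents") <- 0L
    return(out)
  }
  pidx <- match(cand$sample_id, pedigree$id)
  father <- pedigree$father_id[pidx]
  mother <- pedigree$mother_id[pidx]
  sex <- pedigree$sex[pidx]
  generation <- pedigree$generation[pidx]
  sidx <- match(cand$site_id, cohort$sites$site_id)
  site <- cohort$sites[sidx, , drop = FALSE]
  is_x <- site$chrom == params$x_chrom
  ## children lacking a usable parent reference are skipped, not rejected
  no_par <- is.na(father) | is.na(mother) |
    !(father %in% cohort$samples) | !(mother %in% cohort$samples)
  n_skipped <- sum(no_par)
  fcall <- get_calls(cohort, cand$site_id, ifelse(no_par, cand$sample_id, father))
  mcall <- get_calls(cohort, cand$site_id, ifelse(no_par, cand$sample_id, mother))
  pass <- matrix(NA, nrow(cand), length(discovery_filters),
                 dimnames = list(NULL, discovery_filters))
  pass[, "parents_genotyped"] <- !no_par
  pass[, "child_genotype"] <- ifelse(
    is_x & sex == "male", cand$gt == "hemizygous_alt", cand$gt == "het")
  pass[, "parental_genotype"] <- fcall$gt == "hom_ref" & mcall$gt == "hom_ref"
  pass[, "depth"] <- !is.na(cand$dp) & cand$dp >= params$min_depth &
    !is.na(fcall$dp) & fcall$dp >= params$min_depth &
    !is.na(mcall$dp) & mcall$dp >= params$min_depth
  pass[, "gq"] <- !is.na(cand$gq) & cand$gq >= params$min_gq &
    !is.na(fcall$gq) & fcall$gq >= params$min_gq &
    !is.na(mcall$gq) & mcall$gq >= params$min_gq
  pass[, "parental_alt_reads"] <-
    !is.na(fcall$ad_alt) & fcall$ad_alt <= params$max_parent_alt_reads &
    !is.na(mcall$ad_alt) & mcall$ad_alt <= params$max_parent_alt_reads
  pass[, "site_filter"] <- site$filter_pass
  pass[, "lcr"] <- !site$in_lcr
  ## carrier screen only for rows surviving everything cheaper
  alive <- rowSums(!pass[, seq_len(8), drop = FALSE]) == 0
  lk <- rep(TRUE, nrow(cand))
  idx <- alt_call_index(cohort)
  fam <- family_cache(pedigree)
  for (i in which(alive)) {
    cs <- carrier_status_idx(idx, cand$site_id[i], fam(cand$sample_id[i]),
                             params)
    lk[i] <- length(cs$likely) == 0
  }
  pass[, "likely_carrier"] <- lk
  firsts <- apply(pass, 1, function(p) {
    bad <- which(!p)
    if (length(bad)) discovery_filters[bad[1]] else NA_character_
  })
  trail <- apply(pass, 1, function(p) {
    upto <- if (any(!p)) which(!p)[1] else length(p)
    paste(paste0(discovery_filters[seq_len(upto)],
                 ifelse(p[seq_len(upto)], ":P", ":F")), collapse = ";")
  })
  out <- data.frame(
    site_id = cand$site_id, child_id = cand$sample_id,
    generation = generation,
    chrom = site$chrom, pos = site$pos, ref = site$ref, alt = site$alt,
    context = site$context,
    ab = allele_balance(cand$ad_ref, cand$ad_alt),
    ad_ref = cand$ad_ref, ad_alt = cand$ad_alt,
    dp = cand$dp, gq = cand$gq,
    status = ifelse(is.na(firsts), "candidate", "rejected"),
    first_fail = firsts, trail = trail,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_skipped_no_parents") <- n_skipped
  out
}

#' Validate second-generation candidates by transmission
#'
#' A second-generation candidate is validated when at least one
#' third-generation child inherited the allele with depth >= `min_depth`
#' and GQ >= `min_gq`, and the median allele balance across those
#' transmissions is >= `min_transmission_ab`. With
#' `min_g3_for_transmission` set, candidates from sibships smaller than the
#' cutoff are excluded rather than assessed.
#'
#' @param candidates rows of [find_candidates()] output with status
#'   `candidate` and generation `G2`.
#' @param cohort,pedigree,params as elsewhere.
#' @return the candidate frame with `status`
#'   (`validated` / `rejected` / `excluded_small_family`),
#'   `rejection_reason`, `n_transmissions`, `median_transmission_ab` and
#'   `transmitted_to` columns.
#' @export
validate_transmission <- function(candidates, cohort, pedigree,
                                  params = dnm_params()) {
  stopifnot(all(candidates$generation == "G2"))
  n <- nrow(candidates)
  status <- character(n); reason <- rep(NA_character_, n)
  ntr <- integer(n); medab <- rep(NA_real_, n); trto <- character(n)
  for (i in seq_len(n)) {
    kids <- children_of(pedigree, candidates$child_id[i])
    kids <- kids[kids %in% cohort$samples]
    if (!is.null(params$min_g3_for_transmission) &&
        length(kids) < params$min_g3_for_transmission) {
      status[i] <- "excluded_small_family"
      reason[i] <- "small_sibship"
      next
    }
    kc <- get_calls(cohort, candidates$site_id[i], kids)
    ok <- gt_has_alt(kc$gt) & !is.na(kc$dp) & kc$dp >= params$min_depth &
      !is.na(kc$gq) & kc$gq >= params$min_gq
    kc <- kc[ok, , drop = FALSE]
    ntr[i] <- nrow(kc)
    if (!nrow(kc)) {
      status[i] <- "rejected"; reason[i] <- "no_transmission"
      next
    }
    abs_ <- allele_balance(kc$ad_ref, kc$ad_alt)
    medab[i] <- stats::median(abs_, na.rm = TRUE)
    trto[i] <- paste(kc$sample_id, collapse = ",")
    if (!is.na(medab[i]) &&
        medab[i] >= params$min_transmission_ab - 1e-12) {
      status[i] <- "validated"
    } else {
      status[i] <- "rejected"; reason[i] <- "low_transmission_ab"
    }
  }
  candidates$status <- status
  candidates$rejection_reason <- reason
  candidates$n_transmissions <- ntr
  candidates$median_transmission_ab <- medab
  candidates$transmitted_to <- trto
  candidates
}

#' Apply the stringent third-generation filters
#'
#' Third-generation candidates cannot be validated by transmission, so they
#' must additionally have allele balance >= `min_ab_g3`, *zero possible
#' carriers* in the rest of the cohort, and no high-quality grandparental
#' genotype carrying the allele. Candidates failing only the grandparental
#' check are apparent DNMs that were likely inherited through a
#' mis-genotyped parent: they are rejected with reason
#' `grandparental_support` and feed the missed-heterozygote rate.
#'
#' @param candidates rows of [find_candidates()] output with status
#'   `candidate` and generation `G3`.
#' @param cohort,pedigree,params as elsewhere.
#' @return the candidate frame with updated `status`, `rejection_reason`
#'   and logical `mhr_flag`.
#' @export
gen3_filters <- function(candidates, cohort, pedigree,
                         params = dnm_params()) {
  stopifnot(all(candidates$generation == "G3"))
  n <- nrow(candidates)
  status <- rep("validated", n); reason <- rep(NA_character_, n)
  mhr_flag <- rep(FALSE, n)
  idx <- alt_call_index(cohort)
  fam <- family_cache(pedigree)
  for (i in seq_len(n)) {
    if (!ab_ge(candidates$ad_ref[i], candidates$ad_alt[i],
               params$min_ab_g3)) {
      status[i] <- "rejected"; reason[i] <- "low_allele_balance"
      next
    }
    cs <- carrier_status_idx(idx, candidates$site_id[i],
                             fam(candidates$child_id[i]), params)
    if (length(cs$possible)) {
      status[i] <- "rejected"; reason[i] <- "possible_carrier"
      next
    }
    ## grandparental check (missing grandparents are skipped)
    par <- parents_of(pedigree, candidates$child_id[i])
    gps <- unlist(lapply(stats::na.omit(unname(par)), function(p)
      stats::na.omit(unname(parents_of(pedigree, p)))))
    gps <- gps[gps %in% cohort$samples]
    if (length(gps)) {
      gc <- get_calls(cohort, candidates$site_id[i], gps)
      hit <- gt_has_alt(gc$gt) & !is.na(gc$dp) & gc$dp >= params$min_depth &
        !is.na(gc$gq) & gc$gq >= params$min_gq
      if (any(hit)) {
        status[i] <- "rejected"; reason[i] <- "grandparental_support"
        mhr_flag[i] <- TRUE
      }
    }
  }
  candidates$status <- status
  candidates$rejection_reason <- reason
  candidates$mhr_flag <- mhr_flag
  candidates
}

#' Estimate the missed-heterozygote rate (MHR)
#'
#' The fraction of third-generation DNMs (validated plus
#' grandparental-supported) that show high-quality grandparental evidence
#' for the allele -- i.e. were likely inherited from a mis-genotyped
#' parent rather than de novo.
#'
#' @param g3 output of [gen3_filters()].
#' @return list with `mhr` and `counts` (`c(supported, total)`).
#' @export
estimate_mhr <- function(g3) {
  supported <- sum(g3$mhr_flag)
  total <- sum(g3$status == "validated") + supported
  if (total == 0) stop("no third-generation DNMs; MHR undefined")
  list(mhr = supported / total, counts = c(supported = supported,
                                           total = total))
}

#' Estimate the false-positive rate (FPR) from deep parental resequencing
#'
#' For second-generation DNMs whose first-generation parents were
#' resequenced at high depth, a candidate contradicted by >= `min_support`
#' reads carrying the de novo allele in a parent's deep alignments
#' (mapping quality >= 20, base quality >= 20, as encoded in the table) is
#' a false positive.
#'
#' @param g2 validated second-generation candidates.
#' @param deep_reads deep read-support table ([read_deep_reads()] format).
#' @param deep_g2 ids of second-generation individuals whose parents are in
#'   the deep-sequenced subset.
#' @param pedigree the pedigree.
#' @param min_support flagging threshold (reads).
#' @return list with `fpr` and `counts` (`c(flagged, total)`).
#' @export
estimate_fpr <- function(g2, deep_reads, deep_g2, pedigree,
                         min_support = 2L) {
  sub <- g2[g2$child_id %in% deep_g2, , drop = FALSE]
  if (!nrow(sub)) stop("no DNMs in children of deep-sequenced parents")
  flagged <- vapply(seq_len(nrow(sub)), function(i) {
    par <- stats::na.omit(unname(parents_of(pedigree, sub$child_id[i])))
    any(deep_reads$sample_id %in% par &
          deep_reads$chrom == sub$chrom[i] &
          deep_reads$pos == sub$pos[i] &
          deep_reads$allele == sub$alt[i] &
          deep_reads$n_reads >= min_support)
  }, logical(1))
  list(fpr = mean(flagged), counts = c(flagged = sum(flagged),
                                       total = nrow(sub)))
}

#' Run candidate discovery, validation and error-rate estimation
#'
#' Convenience wrapper: [find_candidates()], then
#' [validate_transmission()] on second-generation candidates,
#' [gen3_filters()] on third-generation candidates, [estimate_mhr()], and
#' [estimate_fpr()] when deep read evidence is supplied.
#'
#' @param cohort,pedigree,params as elsewhere.
#' @param deep_reads,deep_g2 optional deep-resequencing evidence.
#' @return a `dnm_callset` list: `candidates`, `g2`, `g3`, `mhr`, `fpr`.
#' @export
discover_dnms <- function(cohort, pedigree, params = dnm_params(),
                          deep_reads = NULL, deep_g2 = NULL) {
  cand <- find_candidates(cohort, pedigree, params)
  g2 <- cand[cand$status == "candidate" & cand$generation == "G2", ,
             drop = FALSE]
  g3 <- cand[cand$status == "candidate" & cand$generation == "G3", ,
             drop = FALSE]
  g2 <- validate_transmission(g2, cohort, pedigree, params)
  g3 <- gen3_filters(g3, cohort, pedigree, params)
  mhr <- if (nrow(g3)) tryCatch(estimate_mhr(g3), error = function(e) NULL)
  fpr <- NULL
  if (!is.null(deep_reads) && !is.null(deep_g2)) {
    fpr <- tryCatch(
      estimate_fpr(g2[g2$status == "validated", , drop = FALSE],
                   deep_reads, deep_g2, pedigree),
      error = function(e) NULL)
  }
  structure(list(candidates = cand, g2 = g2, g3 = g3, mhr = mhr, fpr = fpr,
                 params = params),
            class = "dnm_callset")
}

#' @export
print.dnm_callset <- function(x, ...) {
  cat(sprintf(paste0("<dnm_callset> %d raw candidates; G2 validated: %d; ",
                     "G3 validated: %d\n"),
              nrow(x$candidates),
              sum(x$g2$status == "validated"),
              sum(x$g3$status == "validated")))
  if (!is.null(x$mhr)) {
    cat(sprintf("  MHR %.4f (%d/%d)\n", x$mhr$mhr, x$mhr$counts[1],
                x$mhr$counts[2]))
  }
  if (!is.null(x$fpr)) {
    cat(sprintf("  FPR %.4f (%d/%d)\n", x$fpr$fpr, x$fpr$counts[1],
                x$fpr$counts[2]))
  }
  invisible(x)
}
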