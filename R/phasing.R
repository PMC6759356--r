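#' Find informative sites around a DNM
#'
#' An informative site is a nearby variant heterozygous in the focal
#' individual and carried by exactly one of their two parents, so that the
#' allele tags one parental haplotype. For transmission phasing the marker
#' must additionally be observed in every third-generation individual that
#' inherited the DNM (pass `carriers`).
#'
#' @param dnm a one-row data frame (or list) with `chrom`, `pos`,
#'   `child_id` -- typically a row of the validated candidate table.
#' @param cohort,pedigree as elsewhere.
#' @param window_bp search window on each side of the DNM (inclusive).
#' @param carriers optional character vector of DNM-carrier ids the marker
#'   allele must be observed in.
#' @param params quality thresholds ([dnm_params()]).
#' @return data frame: `site_id`, `pos`, `distance_to_dnm`,
#'   `carrier_parent` (`"father"`/`"mother"`), `carrier_parent_id`,
#'   `marker_ref`, `marker_alt`.
#' @export
find_informative_sites <- function(dnm, cohort, pedigree, window_bp = 2e5,
                                   carriers = NULL,
                                   params = dnm_params()) {
  focal <- dnm$child_id
  par <- parents_of(pedigree, focal)
  if (anyNA(par)) return(informative_empty())
  s <- cohort$sites
  near <- which(s$chrom == dnm$chrom & s$pos != dnm$pos &
                  abs(s$pos - dnm$pos) <= window_bp)
  if (!length(near)) return(informative_empty())
  sid <- s$site_id[near]
  foc <- get_calls(cohort, sid, focal)
  keep <- foc$gt == "het"
  sid <- sid[keep]; near <- near[keep]
  if (!length(sid)) return(informative_empty())
  fa <- get_calls(cohort, sid, par[["father"]])
  mo <- get_calls(cohort, sid, par[["mother"]])
  one <- xor(gt_has_alt(fa$gt), gt_has_alt(mo$gt))
  sid <- sid[one]; near <- near[one]
  cp <- ifelse(gt_has_alt(fa$gt[one]), "father", "mother")
  if (!is.null(carriers) && length(carriers) && length(sid)) {
    seen_in_all <- vapply(sid, function(id) {
      kc <- get_calls(cohort, id, carriers)
      all(gt_has_alt(kc$gt))
    }, logical(1))
    sid <- sid[seen_in_all]; near <- near[seen_in_all]
    cp <- cp[seen_in_all]
  }
  if (!length(sid)) return(informative_empty())
  data.frame(
    site_id = sid,
    pos = cohort$sites$pos[near],
    distance_to_dnm = cohort$sites$pos[near] - dnm$pos,
    carrier_parent = cp,
    carrier_parent_id = unname(unlist(par)[cp]),
    marker_ref = cohort$sites$ref[near],
    marker_alt = cohort$sites$alt[near],
    stringsAsFactors = FALSE
  )
}

informative_empty <- function() {
  data.frame(site_id = character(), pos = integer(),
             distance_to_dnm = integer(), carrier_parent = character(),
             carrier_parent_id = character(), marker_ref = character(),
             marker_alt = character(), stringsAsFactors = FALSE)
}

phase_call <- function(origin, method, n_agree, n_total) {
  data.frame(origin = origin, method = method,
             n_agree = as.integer(n_agree), n_total = as.integer(n_total),
             stringsAsFactors = FALSE)
}

## DNM-carrier children of a G2 focal individual, with quality filters
dnm_carrier_children <- function(dnm, cohort, pedigree, params) {
  kids <- children_of(pedigree, dnm$child_id)
  kids <- kids[kids %in% cohort$samples]
  if (!length(kids)) return(character())
  kc <- get_calls(cohort, dnm$site_id, kids)
  kc$sample_id[gt_has_alt(kc$gt) & !is.na(kc$dp) &
                 kc$dp >= params$min_depth & !is.na(kc$gq) &
                 kc$gq >= params$min_gq]
}

#' Phase a second-generation DNM by three-generation transmission
#'
#' For each informative site, the transmission pattern is the combination
#' of (first-generation carrier parent, second-generation child, exact set
#' of third-generation grandchildren that co-inherited marker and DNM).
#' The DNM is assigned the carrier parent of the modal pattern when that
#' pattern accounts for at least `min_share` of informative sites;
#' otherwise it is unphased.
#'
#' @param dnm one-row candidate (must include `site_id`, `child_id`).
#' @param informative_sites result of [find_informative_sites()] (with
#'   `carriers` restriction applied).
#' @param cohort,pedigree,params as elsewhere.
#' @param min_share modal-pattern share required for a confident call.
#' @return a one-row phase call: `origin` (`paternal`/`maternal`/
#'   `unphased`), `method`, `n_agree`, `n_total`.
#' @export
phase_by_transmission <- function(dnm, informative_sites, cohort, pedigree,
                                  min_share = 0.75,
                                  params = dnm_params()) {
  if (!nrow(informative_sites)) {
    return(phase_call("unphased", "transmission", 0, 0))
  }
  D <- dnm_carrier_children(dnm, cohort, pedigree, params)
  patterns <- vapply(seq_len(nrow(informative_sites)), function(i) {
    kc <- get_calls(cohort, informative_sites$site_id[i], D)
    co <- sort(kc$sample_id[gt_has_alt(kc$gt)])
    paste(informative_sites$carrier_parent[i],
          paste(co, collapse = "+"), sep = "|")
  }, character(1))
  tab <- sort(table(patterns), decreasing = TRUE)
  share <- tab[1] / length(patterns)
  if (share >= min_share) {
    side <- sub("\\|.*", "", names(tab)[1])
    phase_call(if (side == "father") "paternal" else "maternal",
               "transmission", tab[1], length(patterns))
  } else {
    phase_call("unphased", "transmission", tab[1], length(patterns))
  }
}

#' Phase a DNM by read tracing
#'
#' Fragments co-observing the de novo allele and an allele of a nearby
#' informative site vote for a parent: seeing the inherited single-parent
#' allele on the same fragment places the DNM on that parent's chromosome,
#' while seeing the *other* allele places it on the other parent's
#' chromosome (phasing by exclusion). Votes are aggregated across
#' fragments with the same modal-share rule as transmission phasing.
#'
#' @param dnm one-row candidate (`chrom`, `pos`, `alt`, `child_id`).
#' @param read_evidence fragment co-observation table.
#' @param cohort,pedigree,params as elsewhere.
#' @param window_bp read-tracing window (about one fragment length).
#' @param min_share modal-vote share required.
#' @return a one-row phase call.
#' @export
phase_by_read_tracing <- function(dnm, read_evidence, cohort, pedigree,
                                  window_bp = 500, min_share = 0.75,
                                  params = dnm_params()) {
  re <- read_evidence
  re <- re[re$sample_id == dnm$child_id & re$chrom == dnm$chrom &
             re$baseq_ok & re$mapq_ok, , drop = FALSE]
  if (nrow(re)) {
    ## orient fragments so A is the DNM site
    swap <- re$posB == dnm$pos
    if (any(swap)) {
      tmp <- re[swap, ]
      re[swap, c("posA", "alleleA", "posB", "alleleB")] <-
        tmp[, c("posB", "alleleB", "posA", "alleleA")]
    }
    re <- re[re$posA == dnm$pos & abs(re$posB - dnm$pos) <= window_bp, ,
             drop = FALSE]
    re <- re[re$alleleA == dnm$alt, , drop = FALSE]
  }
  if (!nrow(re)) return(phase_call("unphased", "read_tracing", 0, 0))
  inf <- find_informative_sites(dnm, cohort, pedigree,
                                window_bp = window_bp, params = params)
  if (!nrow(inf)) return(phase_call("unphased", "read_tracing", 0, 0))
  m <- match(re$posB, inf$pos)
  re <- re[!is.na(m), , drop = FALSE]
  inf_m <- inf[stats::na.omit(m), , drop = FALSE]
  if (!nrow(re)) return(phase_call("unphased", "read_tracing", 0, 0))
  vote <- ifelse(re$alleleB == inf_m$marker_alt, inf_m$carrier_parent,
                 ifelse(re$alleleB == inf_m$marker_ref,
                        ifelse(inf_m$carrier_parent == "father", "mother",
                               "father"),
                        NA_character_))
  vote <- vote[!is.na(vote)]
  if (!length(vote)) return(phase_call("unphased", "read_tracing", 0, 0))
  tab <- sort(table(vote), decreasing = TRUE)
  if (tab[1] / length(vote) >= min_share) {
    phase_call(if (names(tab)[1] == "father") "paternal" else "maternal",
               "read_tracing", tab[1], length(vote))
  } else {
    phase_call("unphased", "read_tracing", tab[1], length(vote))
  }
}

#' Phase a shared post-PGCS mosaic DNM by grandparental haplotype sharing
#'
#' If every third-generation carrier of a shared mosaic DNM inherited the
#' same grandparental haplotype from one second-generation parent (all
#' carriers carry that parent's informative markers near the DNM, with no
#' marker splitting the carrier set), the mutation is assigned to that
#' parent's germline. If neither parent's markers show consistent sharing
#' (or both do), the DNM stays unphased.
#'
#' @param shared_dnm list/row with `chrom`, `pos`, `carriers` (character
#'   vector of >= 2 G3 ids), `father_id`, `mother_id`.
#' @param cohort,pedigree,params as elsewhere.
#' @param window_bp marker search window.
#' @return a one-row phase call (method `grandparental_sharing`).
#' @export
phase_shared_mosaic <- function(shared_dnm, cohort, pedigree,
                                window_bp = 2e5, params = dnm_params()) {
  carriers <- shared_dnm$carriers
  if (is.list(carriers)) carriers <- carriers[[1]]
  stopifnot(length(carriers) >= 2)
  assess <- function(parent_id) {
    fake <- list(chrom = shared_dnm$chrom, pos = shared_dnm$pos,
                 child_id = parent_id)
    inf <- find_informative_sites(fake, cohort, pedigree,
                                  window_bp = window_bp, params = params)
    if (!nrow(inf)) return(list(full = 0L, partial = 0L, total = 0L))
    hit <- vapply(inf$site_id, function(id) {
      kc <- get_calls(cohort, id, carriers)
      sum(gt_has_alt(kc$gt))
    }, integer(1))
    list(full = sum(hit == length(carriers)),
         partial = sum(hit > 0 & hit < length(carriers)),
         total = nrow(inf))
  }
  fa <- assess(shared_dnm$father_id)
  mo <- assess(shared_dnm$mother_id)
  fa_ok <- fa$full > 0 && fa$partial == 0
  mo_ok <- mo$full > 0 && mo$partial == 0
  if (fa_ok && !mo_ok) {
    phase_call("paternal", "grandparental_sharing", fa$full, fa$total)
  } else if (mo_ok && !fa_ok) {
    phase_call("maternal", "grandparental_sharing", mo$full, mo$total)
  } else {
    phase_call("unphased", "grandparental_sharing", 0,
               fa$total + mo$total)
  }
}

#' Reconcile transmission and read-tracing phase calls
#'
#' Both methods phased and agree: consensus with that origin. Both phased
#' and disagree: unphased, flagged as a conflict. One method phased: its
#' call stands.
#'
#' @param transmission,read_tracing one-row phase calls.
#' @return one-row data frame with `origin`, `method`, `conflict`.
#' @export
consensus_phase <- function(transmission, read_tracing) {
  t_o <- transmission$origin; r_o <- read_tracing$origin
  if (t_o != "unphased" && r_o != "unphased") {
    if (t_o == r_o) {
      data.frame(origin = t_o, method = "consensus", conflict = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(origin = "unphased", method = "consensus", conflict = TRUE,
                 stringsAsFactors = FALSE)
    }
  } else if (t_o != "unphased") {
    data.frame(origin = t_o, method = "transmission", conflict = FALSE,
               stringsAsFactors = FALSE)
  } else if (r_o != "unphased") {
    data.frame(origin = r_o, method = "read_tracing", conflict = FALSE,
               stringsAsFactors = FALSE)
  } else {
    data.frame(origin = "unphased", method = "none", conflict = FALSE,
               stringsAsFactors = FALSE)
  }
}

#' Phase a set of validated DNMs by both strategies
#'
#' Applies transmission phasing (second generation only; it requires
#' observing transmissions) and read tracing to each DNM, then reconciles
#' them. The concordance summary counts agreement among DNMs phased by
#' both strategies.
#'
#' @param dnms validated candidate rows (`site_id`, `child_id`, `chrom`,
#'   `pos`, `alt`, `generation`).
#' @param cohort,pedigree,params as elsewhere.
#' @param read_evidence fragment table.
#' @param window_far,window_near search windows (bp).
#' @return a `dnm_phasing` list: `calls` (one row per DNM with per-method
#'   origins and the consensus) and `concordance`
#'   (`agree`, `both_phased`, `fraction`).
#' @export
phase_dnms <- function(dnms, cohort, pedigree, read_evidence,
                       window_far = 2e5, window_near = 500,
                       params = dnm_params()) {
  n <- nrow(dnms)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    dnm <- dnms[i, ]
    if (dnm$generation == "G2") {
      D <- dnm_carrier_children(dnm, cohort, pedigree, params)
      inf <- find_informative_sites(dnm, cohort, pedigree,
                                    window_bp = window_far, carriers = D,
                                    params = params)
      tr <- phase_by_transmission(dnm, inf, cohort, pedigree,
                                  params = params)
    } else {
      tr <- phase_call("unphased", "transmission", 0, 0)
    }
    rd <- phase_by_read_tracing(dnm, read_evidence, cohort, pedigree,
                                window_bp = window_near, params = params)
    cons <- consensus_phase(tr, rd)
    rows[[i]] <- data.frame(
      site_id = dnm$site_id, child_id = dnm$child_id,
      origin_transmission = tr$origin,
      support_transmission = sprintf("%d/%d", tr$n_agree, tr$n_total),
      origin_read_tracing = rd$origin,
      support_read_tracing = sprintf("%d/%d", rd$n_agree, rd$n_total),
      origin = cons$origin, method = cons$method, conflict = cons$conflict,
      stringsAsFactors = FALSE)
  }
  calls <- if (n) do.call(rbind, rows) else
    data.frame(site_id = character(), child_id = character(),
               origin = character())
  both <- calls$origin_transmission != "unphased" &
    calls$origin_read_tracing != "unphased"
  agree <- both & calls$origin_transmission == calls$origin_read_tracing
  structure(list(
    calls = calls,
    concordance = list(agree = sum(agree), both_phased = sum(both),
                       fraction = if (sum(both)) sum(agree) / sum(both)
                                  else NA_real_)),
    class = "dnm_phasing")
}

#' @export
print.dnm_phasing <- function(x, ...) {
  tab <- table(factor(x$calls$origin,
                      levels = c("paternal", "maternal", "unphased")))
  cat(sprintf("<dnm_phasing> %d DNMs: %d paternal, %d maternal, %d unphased\n",
              nrow(x$calls), tab["paternal"], tab["maternal"],
              tab["unphased"]))
  if (x$concordance$both_phased > 0) {
    cat(sprintf("  strategy concordance %.3f (%d/%d doubly phased)\n",
                x$concordance$fraction, x$concordance$agree,
                x$concordance$both_phased))
  }
  invisible(x)
}
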