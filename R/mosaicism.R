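#' Detect shared post-PGCS germline mosaic DNMs
#'
#' Within each family unit's sibship, identical single-nucleotide DNMs
#' observed in two or more siblings -- while absent from the blood
#' genotypes (and allele depths) of the second-generation parents and any
#' sequenced first-generation grandparents -- are called shared post-PGCS
#' germline mosaics: a single mutational event in a parent's germ-cell
#' lineage after primordial germ cell specification, transmitted through
#' multiple gametes. Groups at which a parent nonetheless shows >=
#' `min_reads` raw aligned reads supporting the allele are removed (the
#' genotype caller can locally drop such reads, masking a true parental
#' carrier).
#'
#' @param g3_dnms validated third-generation DNM rows (from
#'   [gen3_filters()], status `validated`).
#' @param family_units [split_family_units()] output.
#' @param cohort,pedigree as elsewhere.
#' @param raw_parent_reads optional raw read-support table (format of
#'   [read_deep_reads()]) from parental 30X alignments.
#' @param min_reads parental read support that removes a group.
#' @return data frame, one row per shared mosaic site: `family_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `context`, `n_carriers`, `carriers`
#'   (comma-separated), `father_id`, `mother_id`, `parent_read_support`,
#'   `removed`.
#' @export
detect_shared_postpgcs <- function(g3_dnms, family_units, cohort, pedigree,
                                   raw_parent_reads = NULL,
                                   min_reads = 2L) {
  dn <- g3_dnms[g3_dnms$status == "validated" &
                  nchar(g3_dnms$ref) == 1 &
                  nchar(g3_dnms$alt) == 1, , drop = FALSE]
  if (!nrow(dn)) return(shared_empty())
  fu_of <- function(child) {
    hit <- vapply(family_units$children, function(ch) child %in% ch,
                  logical(1))
    family_units$family_id[hit][1]
  }
  dn$family_id <- vapply(dn$child_id, fu_of, character(1))
  key <- paste(dn$family_id, dn$chrom, dn$pos, dn$ref, dn$alt, sep = "\r")
  rows <- lapply(split(seq_len(nrow(dn)), key), function(idx) {
    if (length(idx) < 2) return(NULL)
    g <- dn[idx, ]
    fu <- family_units[family_units$family_id == g$family_id[1], ]
    parents <- c(fu$father_id, fu$mother_id)
    gps <- unlist(lapply(parents, function(p)
      stats::na.omit(unname(parents_of(pedigree, p)))))
    gps <- gps[gps %in% cohort$samples]
    prog <- get_calls(cohort, g$site_id[1], c(parents, gps))
    absent <- all(!gt_has_alt(prog$gt)) &&
      all(prog$ad_alt[prog$sample_id %in% parents] == 0, na.rm = TRUE)
    if (!absent) return(NULL)
    support <- 0L
    if (!is.null(raw_parent_reads) && nrow(raw_parent_reads)) {
      hit <- raw_parent_reads$sample_id %in% parents &
        raw_parent_reads$chrom == g$chrom[1] &
        raw_parent_reads$pos == g$pos[1] &
        raw_parent_reads$allele == g$alt[1]
      if (any(hit)) support <- max(raw_parent_reads$n_reads[hit])
    }
    data.frame(
      family_id = g$family_id[1], chrom = g$chrom[1], pos = g$pos[1],
      ref = g$ref[1], alt = g$alt[1], context = g$context[1],
      n_carriers = nrow(g),
      carriers = paste(sort(g$child_id), collapse = ","),
      father_id = fu$father_id, mother_id = fu$mother_id,
      parent_read_support = support,
      removed = support >= min_reads,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(shared_empty())
  rownames(out) <- NULL
  out
}

shared_empty <- function() {
  data.frame(family_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), context = character(),
             n_carriers = integer(), carriers = character(),
             father_id = character(), mother_id = character(),
             parent_read_support = integer(), removed = logical(),
             stringsAsFactors = FALSE)
}

#' Classify a second-generation DNM as germline or gonosomal
#'
#' A heterozygous second-generation DNM that arose in a first-generation
#' gamete lies on one inherited background haplotype and is therefore in
#' *complete* linkage with nearby informative markers: every
#' third-generation child that inherited the marker haplotype also
#' inherited the DNM. A post-zygotic (gonosomal) mutation is present in
#' only a fraction of the germ cells carrying that haplotype, so one or
#' more children inherit the informative alleles *without* the DNM
#' (incomplete linkage). No allele-balance filter is applied to the
#' second-generation genotype itself; linkage alone separates the classes.
#'
#' Classification requires at least `min_informative_children` children
#' carrying a linked marker: with fewer, incomplete linkage is
#' undetectable and the DNM conservatively stays germline (flagged).
#' The discordant child must lack the DNM at every linked marker.
#'
#' @param dnm one-row validated G2 candidate.
#' @param cohort,pedigree,params as elsewhere.
#' @param window_bp marker search window.
#' @param min_informative_children sensitivity floor (default 2).
#' @return one-row data frame: `site_id`, `child_id`, `category`
#'   (`single_gamete_germline` / `gonosomal_incomplete_linkage` /
#'   `unclassifiable`), `n_linked_markers`, `n_informative_children`,
#'   `discordant_children`, `low_power`.
#' @export
detect_gonosomal <- function(dnm, cohort, pedigree, window_bp = 2e5,
                             params = dnm_params(),
                             min_informative_children = 2L) {
  D <- dnm_carrier_children(dnm, cohort, pedigree, params)
  inf <- find_informative_sites(dnm, cohort, pedigree,
                                window_bp = window_bp, params = params)
  res <- function(category, n_linked = 0L, n_inf = 0L, disc = character(),
                  low_power = FALSE) {
    data.frame(site_id = dnm$site_id, child_id = dnm$child_id,
               category = category, n_linked_markers = n_linked,
               n_informative_children = n_inf,
               discordant_children = paste(disc, collapse = ","),
               low_power = low_power, stringsAsFactors = FALSE)
  }
  if (!nrow(inf) || !length(D)) return(res("unclassifiable"))
  kids <- children_of(pedigree, dnm$child_id)
  kids <- kids[kids %in% cohort$samples]
  sets <- lapply(inf$site_id, function(id) {
    kc <- get_calls(cohort, id, kids)
    kc$sample_id[gt_has_alt(kc$gt) & !is.na(kc$dp) &
                   kc$dp >= params$min_depth & !is.na(kc$gq) &
                   kc$gq >= params$min_gq]
  })
  linked <- vapply(sets, function(S) length(intersect(S, D)) > 0,
                   logical(1))
  if (!any(linked)) return(res("unclassifiable"))
  sets <- sets[linked]
  n_inf <- max(lengths(sets))
  if (n_inf < min_informative_children) {
    return(res("single_gamete_germline", sum(linked), n_inf,
               low_power = TRUE))
  }
  disc <- Reduce(intersect, lapply(sets, function(S) setdiff(S, D)))
  if (length(disc)) {
    res("gonosomal_incomplete_linkage", sum(linked), n_inf, disc)
  } else {
    res("single_gamete_germline", sum(linked), n_inf)
  }
}

#' Three-haplotype (post-zygotic) test from fragment evidence
#'
#' At a truly germline heterozygous DNM, fragments spanning the DNM and a
#' nearby heterozygous site show exactly two allele combinations (the two
#' haplotypes). A post-zygotic mutation in the child creates a third
#' combination -- the DNM haplotype background without the mutant allele.
#' If at least three distinct combinations are observed at a linked site
#' and the third-ranked combination is supported by >= `min_reads`
#' fragments, the DNM is flagged post-zygotic.
#'
#' @param dnm one-row candidate (`chrom`, `pos`, `child_id`).
#' @param read_evidence fragment table.
#' @param window_bp linked-site window.
#' @param min_reads support required for the third combination.
#' @return one-row data frame: `site_id`, `child_id`, `category`
#'   (`postzygotic_three_haplotype` / `germline_consistent` /
#'   `unclassifiable`), `third_hap_fragments`.
#' @export
detect_postzygotic_three_haplotypes <- function(dnm, read_evidence,
                                                window_bp = 500,
                                                min_reads = 2L) {
  re <- read_evidence
  re <- re[re$sample_id == dnm$child_id & re$chrom == dnm$chrom &
             re$baseq_ok & re$mapq_ok, , drop = FALSE]
  if (nrow(re)) {
    swap <- re$posB == dnm$pos
    if (any(swap)) {
      tmp <- re[swap, ]
      re[swap, c("posA", "alleleA", "posB", "alleleB")] <-
        tmp[, c("posB", "alleleB", "posA", "alleleA")]
    }
    re <- re[re$posA == dnm$pos & abs(re$posB - dnm$pos) <= window_bp, ,
             drop = FALSE]
  }
  res <- function(category, third = 0L) {
    data.frame(site_id = dnm$site_id, child_id = dnm$child_id,
               category = category, third_hap_fragments = as.integer(third),
               stringsAsFactors = FALSE)
  }
  if (!nrow(re)) return(res("unclassifiable"))
  best_third <- 0L
  flagged <- FALSE
  for (pb in unique(re$posB)) {
    sub <- re[re$posB == pb, ]
    tab <- sort(table(paste(sub$alleleA, sub$alleleB)), decreasing = TRUE)
    if (length(tab) >= 3 && tab[3] >= min_reads) {
      flagged <- TRUE
      best_third <- max(best_third, as.integer(tab[3]))
    }
  }
  if (flagged) res("postzygotic_three_haplotype", best_third)
  else res("germline_consistent")
}

#' Classify validated DNMs into mosaicism categories
#'
#' Runs the three classifiers over a discovery callset: the
#' three-haplotype test removes post-zygotic third-generation DNMs from
#' the germline callset; shared post-PGCS mosaics are detected within
#' sibships; and each validated second-generation DNM is classified
#' germline vs gonosomal by marker linkage. Every validated DNM ends in
#' exactly one category (or an explicit `unclassifiable`).
#'
#' @param callset a [discover_dnms()] result.
#' @param cohort,pedigree as elsewhere.
#' @param read_evidence fragment table.
#' @param raw_parent_reads optional raw parental read support
#'   (see [detect_shared_postpgcs()]).
#' @param family_units defaults to [split_family_units()] of the pedigree.
#' @param params thresholds.
#' @return a `dnm_classification` list: `g3` (validated G3 rows plus
#'   `postzygotic` and `shared` flags), `shared_sites`
#'   (per-site mosaic groups), `g2` (validated G2 rows plus `category`),
#'   `n_postzygotic_removed`.
#' @export
classify_dnms <- function(callset, cohort, pedigree, read_evidence,
                          raw_parent_reads = NULL,
                          family_units = split_family_units(pedigree),
                          params = dnm_params()) {
  g3 <- callset$g3[callset$g3$status == "validated", , drop = FALSE]
  if (nrow(g3)) {
    pz <- vapply(seq_len(nrow(g3)), function(i) {
      detect_postzygotic_three_haplotypes(
        g3[i, ], read_evidence, min_reads = 2L)$category ==
        "postzygotic_three_haplotype"
    }, logical(1))
    g3$postzygotic <- pz
  } else {
    g3$postzygotic <- logical(0)
  }
  germ3 <- g3[!g3$postzygotic, , drop = FALSE]
  shared <- detect_shared_postpgcs(germ3, family_units, cohort, pedigree,
                                   raw_parent_reads = raw_parent_reads)
  kept <- shared[!shared$removed, , drop = FALSE]
  g3$shared <- FALSE
  if (nrow(kept) && nrow(g3)) {
    skey <- paste(kept$chrom, kept$pos, kept$alt)
    g3$shared <- !g3$postzygotic &
      paste(g3$chrom, g3$pos, g3$alt) %in% skey
  }
  g2 <- callset$g2[callset$g2$status == "validated", , drop = FALSE]
  if (nrow(g2)) {
    gon <- do.call(rbind, lapply(seq_len(nrow(g2)), function(i) {
      detect_gonosomal(g2[i, ], cohort, pedigree, params = params)
    }))
    g2$category <- gon$category
    g2$discordant_children <- gon$discordant_children
    g2$low_power <- gon$low_power
  }
  structure(list(g3 = g3, shared_sites = shared, g2 = g2,
                 n_postzygotic_removed = sum(g3$postzygotic)),
            class = "dnm_classification")
}

#' @export
print.dnm_classification <- function(x, ...) {
  cat(sprintf(paste0("<dnm_classification> G3: %d validated, %d ",
                     "post-zygotic removed, %d shared mosaic calls at %d ",
                     "sites\n"),
              nrow(x$g3), x$n_postzygotic_removed, sum(x$g3$shared),
              sum(!x$shared_sites$removed)))
  if (nrow(x$g2)) {
    tab <- table(x$g2$category)
    cat("  G2:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Per-child shared-mosaic statistics
#'
#' For each third-generation child: the number of their DNMs shared with
#' at least one sibling (`mosaic_number`), their total germline DNM count
#' including shared ones (`total_dnms`), the shared fraction, paternal age
#' and sibship size. Children with zero DNMs get an `NA` fraction and are
#' flagged.
#'
#' @param classification a [classify_dnms()] result.
#' @param pedigree the pedigree.
#' @param family_units family units.
#' @return data frame, one row per third-generation child.
#' @export
per_child_mosaic_stats <- function(classification, pedigree,
                                   family_units =
                                     split_family_units(pedigree)) {
  g3 <- classification$g3[!classification$g3$postzygotic, , drop = FALSE]
  kids <- pedigree$id[pedigree$generation == "G3"]
  fu_id <- vapply(kids, function(kid) {
    hit <- vapply(family_units$children, function(ch) kid %in% ch,
                  logical(1))
    if (any(hit)) family_units$family_id[hit][1] else NA_character_
  }, character(1))
  n_sibs <- family_units$n_children[match(fu_id, family_units$family_id)] - 1L
  total <- vapply(kids, function(kid) sum(g3$child_id == kid), integer(1))
  shared <- vapply(kids, function(kid)
    sum(g3$child_id == kid & g3$shared), integer(1))
  out <- data.frame(
    child_id = kids,
    family_id = fu_id,
    mosaic_number = shared,
    total_dnms = total,
    mosaic_fraction = ifelse(total > 0, shared / total, NA_real_),
    no_dnms = total == 0,
    dad_age = pedigree$dad_age[match(kids, pedigree$id)],
    mom_age = pedigree$mom_age[match(kids, pedigree$id)],
    n_siblings = n_sibs,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
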