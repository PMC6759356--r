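#' Configuration for the synthetic three-generation cohort generator
#'
#' Defaults emulate a large multi-sibship three-generation cohort: ~33
#' families of 4--16 third-generation children (median ~8); an identity-link
#' paternal age effect of 1.44 DNMs/year and maternal effect of 0.38
#' DNMs/year (intercepts chosen so that a father of 29 contributes ~56 DNMs
#' and a mother of 26 contributes ~14, i.e. ~80% of germline DNMs are
#' paternal); ~7 gonosomal (post-zygotic, soma+germline) mutations per
#' second-generation individual (~9% of their candidate DNMs); a pool of ~6
#' post-PGCS germline mosaic mutations per second-generation parent, each
#' transmitted to each child independently with probability 0.25 and with no
#' age dependence; a 0.4% missed-heterozygote genotyping-error rate and a
#' 4.5% false-positive candidate rate; and flanking informative markers
#' supporting both transmission phasing (within 200 kb) and read tracing
#' (within 500 bp).
#'
#' @param n_families number of three-generation families.
#' @param children_per_family integer range (lo, hi) of sibship sizes;
#'   sizes are drawn as `lo + Binomial(hi - lo, 1/3)`, giving a median near
#'   8 for the default (4, 16).
#' @param dad_age_range,mom_age_range parental age (years) at the birth of
#'   the *first* third-generation child; later siblings add cumulative gaps
#'   drawn from `sibling_gap`.
#' @param sibling_gap range of year gaps between consecutive siblings.
#' @param g2_dad_age_range age of a first-generation father at the birth of
#'   his second-generation child; the mother is 0--4 years younger.
#' @param Bp,B0p,Bm,B0m identity-link slope and intercept (DNMs, DNMs/year)
#'   of the paternal and maternal germline mutation models.
#' @param gonosomal_rate expected gonosomal mutations per second-generation
#'   individual.
#' @param mosaic_pool_size expected post-PGCS mosaic mutations per
#'   second-generation parent germline.
#' @param mosaic_transmission_prob,gonosomal_transmission_prob per-child
#'   probability of inheriting a given mosaic / gonosomal mutation
#'   (marginally; co-segregation with the background haplotype is enforced,
#'   so the within-haplotype rate is twice this).
#' @param mhr_rate probability that an apparent third-generation DNM is an
#'   inherited variant whose carrier parent was mis-genotyped hom-ref.
#' @param fpr_rate fraction of second-generation candidates that are
#'   spurious (contradicted by deep parental resequencing).
#' @param spectrum_germline,spectrum_mosaic named per-class probabilities
#'   over [mutation_classes()] for single-gamete and mosaic mutations.
#' @param depth_mean,gq_levels,gq_probs genotype-evidence noise model.
#' @param genotype_noise logical; `FALSE` makes depths, qualities and
#'   allele balances deterministic (the "zero-noise" regime used to verify
#'   exact recovery of the simulated truth).
#' @param gonosomal_ab_mean,gonosomal_ab_conc Beta allele-balance model for
#'   gonosomal carriers (mean and concentration); gonosomal mutations are
#'   present in only a fraction of somatic cells, so their allele balance is
#'   lower and more dispersed than germline heterozygotes.
#' @param informative_far_rate expected informative markers per DNM within
#'   +/-200 kb (per focal parent); `informative_near_rate` likewise within
#'   +/-500 bp.
#' @param frags_per_marker fragments co-observing each (DNM, near-marker)
#'   allele pair.
#' @param third_hap_reads fragments supporting the third haplotype at
#'   gonosomal sites.
#' @param mosaic_parent_support_rate fraction of mosaic sites at which a
#'   parent shows >= 2 raw supporting reads (removed by the classifier).
#' @param n_deep_g2 number of second-generation individuals whose
#'   first-generation parents are deep-resequenced (the FPR subset).
#' @param genome data frame (`chrom`, `length`); one X-like chromosome.
#' @param x_chrom name of the X-like chromosome.
#' @param lcr_fraction fraction of each chromosome masked as low-complexity.
#' @param mask_gap_n,mask_gap_mean expected number and mean length (bp) of
#'   per-sample uncallable gaps per chromosome.
#' @param phase_window_far,phase_window_near phasing search windows (bp).
#' @param seed master seed; per-family substreams are derived from it.
#' @return a `dnm_sim_config` list.
#' @export
sim_config <- function(n_families = 33L,
                       children_per_family = c(4L, 16L),
                       dad_age_range = c(18, 28),
                       mom_age_range = c(16, 24),
                       sibling_gap = c(1, 3),
                       g2_dad_age_range = c(22, 36),
                       Bp = 1.44, B0p = 14.24,
                       Bm = 0.38, B0m = 4.12,
                       gonosomal_rate = 7,
                       mosaic_pool_size = 6,
                       mosaic_transmission_prob = 0.25,
                       gonosomal_transmission_prob = 0.25,
                       mhr_rate = 0.004,
                       fpr_rate = 0.045,
                       spectrum_germline = c("C>A" = 0.08, "C>G" = 0.09,
                                             "C>T" = 0.25, "CpG>TpG" = 0.15,
                                             "T>A" = 0.06, "T>C" = 0.27,
                                             "T>G" = 0.04, "indel" = 0.06),
                       spectrum_mosaic = c("C>A" = 0.10, "C>G" = 0.07,
                                           "C>T" = 0.22, "CpG>TpG" = 0.30,
                                           "T>A" = 0.07, "T>C" = 0.18,
                                           "T>G" = 0.06, "indel" = 0),
                       depth_mean = 30,
                       gq_levels = c(99L, 60L, 30L),
                       gq_probs = c(0.90, 0.08, 0.02),
                       genotype_noise = TRUE,
                       gonosomal_ab_mean = 0.35,
                       gonosomal_ab_conc = 30,
                       informative_far_rate = 3,
                       informative_near_rate = 1.5,
                       frags_per_marker = 5,
                       third_hap_reads = 3,
                       mosaic_parent_support_rate = 0,
                       n_deep_g2 = 4L,
                       genome = data.frame(
                         chrom = c("chr1", "chr2", "chr3", "chr4", "chrX"),
                         length = rep(1e7, 5)),
                       x_chrom = "chrX",
                       lcr_fraction = 0.05,
                       mask_gap_n = 15,
                       mask_gap_mean = 2e4,
                       phase_window_far = 2e5,
                       phase_window_near = 500,
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(mosaic_transmission_prob, gonosomal_transmission_prob,
             mhr_rate, fpr_rate, lcr_fraction, mosaic_parent_support_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (mosaic_transmission_prob > 0.5 || gonosomal_transmission_prob > 0.5) {
    stop("haplotype co-segregation caps per-child transmission at 0.5")
  }
  for (nm in c("spectrum_germline", "spectrum_mosaic")) {
    sp <- cfg[[nm]]
    if (!setequal(names(sp), mutation_classes()) ||
        abs(sum(sp) - 1) > 1e-8 || any(sp < 0)) {
      stop(nm, " must be a probability vector over mutation_classes()")
    }
    cfg[[nm]] <- sp[mutation_classes()]
  }
  for (r in list(dad_age_range, mom_age_range, g2_dad_age_range)) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < 0) stop("degenerate age range")
  }
  if (diff(children_per_family) < 0 || children_per_family[1] < 1) {
    stop("degenerate children_per_family range")
  }
  max_dad <- dad_age_range[2] + sibling_gap[2] * (children_per_family[2] - 1)
  if (Bp * dad_age_range[1] + B0p <= 0 || Bp * max_dad + B0p <= 0 ||
      Bm * mom_age_range[1] + B0m <= 0) {
    stop("identity-link predictor must be positive over the age range")
  }
  if (!x_chrom %in% genome$chrom) stop("genome must contain the X-like chromosome")
  structure(cfg, class = "dnm_sim_config")
}

fam_label <- function(i) sprintf("F%02d", i)

## per-family substreams derived from the master seed keep families
## reproducible independently of one another
family_seeds <- function(config, offset) {
  set.seed(config$seed + offset)
  sample.int(.Machine$integer.max - 1L, config$n_families)
}

#' Simulate a three-generation pedigree
#'
#' Each family comprises two first-generation couples, one second-generation
#' couple, and a sibship of third-generation children with increasing
#' parental ages by birth order.
#'
#' @param config a [sim_config()].
#' @return a [new_pedigree()] object.
#' @export
simulate_pedigree <- function(config) {
  seeds <- family_seeds(config, 0L)
  fams <- lapply(seq_len(config$n_families), function(f) {
    set.seed(seeds[f])
    fl <- fam_label(f)
    n_kids <- config$children_per_family[1] +
      stats::rbinom(1, diff(config$children_per_family), 1 / 3)
    id <- function(x) paste0(fl, "_", x)
    g1 <- data.frame(
      id = id(c("G1PF", "G1PM", "G1MF", "G1MM")),
      sex = c("male", "female", "male", "female"),
      father_id = NA_character_, mother_id = NA_character_,
      dad_age = NA_real_, mom_age = NA_real_
    )
    g2_dad_age <- round(stats::runif(2, config$g2_dad_age_range[1],
                                     config$g2_dad_age_range[2]))
    g2_mom_age <- round(pmax(16, g2_dad_age - stats::runif(2, 0, 4)))
    g2 <- data.frame(
      id = id(c("G2F", "G2M")),
      sex = c("male", "female"),
      father_id = id(c("G1PF", "G1MF")),
      mother_id = id(c("G1PM", "G1MM")),
      dad_age = g2_dad_age, mom_age = g2_mom_age
    )
    gaps <- cumsum(c(0, stats::runif(n_kids - 1, config$sibling_gap[1],
                                     config$sibling_gap[2])))
    dad0 <- stats::runif(1, config$dad_age_range[1], config$dad_age_range[2])
    mom0 <- stats::runif(1, config$mom_age_range[1], config$mom_age_range[2])
    ## ages recorded in whole years, as pedigree metadata usually is;
    ## rounding also breaks the exact within-family collinearity of the
    ## two parents' ages
    g3 <- data.frame(
      id = id(sprintf("C%02d", seq_len(n_kids))),
      sex = sample(c("male", "female"), n_kids, replace = TRUE),
      father_id = id("G2F"), mother_id = id("G2M"),
      dad_age = round(dad0 + gaps), mom_age = round(mom0 + gaps)
    )
    out <- rbind(g1, g2, g3)
    out$family <- fl
    out
  })
  new_pedigree(do.call(rbind, fams), pedigree_id = "simulated")
}

#' Simulate per-sample callable masks and an LCR track
#'
#' Every sample's mask covers each chromosome minus a random set of
#' uncallable gaps; the LCR track is a fixed set of low-complexity
#' exclusion intervals shared by the cohort.
#'
#' @param pedigree a pedigree.
#' @param config a [sim_config()].
#' @return list with `masks` (named list of `GRanges`) and `lcr` (`GRanges`).
#' @export
simulate_masks <- function(pedigree, config) {
  set.seed(config$seed + 1L)
  gnm <- config$genome
  chrom_gr <- GenomicRanges::GRanges(
    gnm$chrom, IRanges::IRanges(1, as.integer(gnm$length)),
    seqinfo = GenomeInfoDb::Seqinfo(gnm$chrom, as.integer(gnm$length)))
  ## fixed LCR: evenly spaced segments totaling lcr_fraction per chromosome
  lcr_df <- do.call(rbind, lapply(seq_len(nrow(gnm)), function(i) {
    L <- gnm$length[i]
    n <- 10L
    len <- floor(L * config$lcr_fraction / n)
    starts <- floor(seq(1, L - len, length.out = n) +
                    stats::runif(n, 0, L / (4 * n)))
    starts <- pmin(starts, L - len + 1)
    data.frame(chrom = gnm$chrom[i], start = starts, end = starts + len - 1)
  }))
  lcr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    lcr_df$chrom, IRanges::IRanges(lcr_df$start, lcr_df$end),
    seqinfo = GenomeInfoDb::seqinfo(chrom_gr)))
  masks <- lapply(pedigree$id, function(s) {
    gap_l <- lapply(seq_len(nrow(gnm)), function(i) {
      L <- gnm$length[i]
      n <- stats::rpois(1, config$mask_gap_n)
      if (n == 0) return(NULL)
      w <- pmax(1L, round(stats::rexp(n, 1 / config$mask_gap_mean)))
      st <- floor(stats::runif(n, 1, L - w))
      data.frame(chrom = gnm$chrom[i], start = st, end = st + w - 1)
    })
    gap_df <- do.call(rbind, gap_l)
    if (is.null(gap_df)) return(chrom_gr)
    gaps <- GenomicRanges::GRanges(
      gap_df$chrom, IRanges::IRanges(gap_df$start, gap_df$end),
      seqinfo = GenomeInfoDb::seqinfo(chrom_gr))
    GenomicRanges::setdiff(chrom_gr, GenomicRanges::reduce(gaps))
  })
  names(masks) <- pedigree$id
  list(masks = masks, lcr = lcr)
}

## haplotype-of-origin draws: for each family, which of the G2 parent's two
## haplotypes ("pat" = from that parent's father) each child inherited, per
## chromosome; no recombination within a chromosome
simulate_haplotypes <- function(pedigree, config) {
  seeds <- family_seeds(config, 2L)
  fams <- unique(pedigree$family)
  out <- lapply(seq_along(fams), function(f) {
    set.seed(seeds[f] %% (.Machine$integer.max - 10L) + 7L)
    kids <- pedigree$id[pedigree$family == fams[f] & pedigree$generation == "G3"]
    chroms <- config$genome$chrom
    a <- array(sample(c("pat", "mat"), length(kids) * 2 * length(chroms),
                      replace = TRUE),
               dim = c(length(kids), 2, length(chroms)),
               dimnames = list(kids, c("father", "mother"), chroms))
    a
  })
  names(out) <- fams
  out
}

draw_class <- function(n, spectrum) {
  if (n == 0) return(character())
  sample(names(spectrum), n, replace = TRUE, prob = spectrum)
}

## generate (ref, alt, context) consistent with a class label, with random
## strand so that purine-reference records exercise the normalization
draw_alleles <- function(classes) {
  n <- length(classes)
  bases <- c("A", "C", "G", "T")
  ref <- alt <- ctx <- character(n)
  for (i in seq_len(n)) {
    cl <- classes[i]
    if (cl == "indel") {
      b <- sample(bases, 1)
      extra <- paste(sample(bases, sample(1:4, 1), replace = TRUE),
                     collapse = "")
      if (stats::runif(1) < 0.5) {
        ref[i] <- paste0(b, extra); alt[i] <- b
      } else {
        ref[i] <- b; alt[i] <- paste0(b, extra)
      }
      ctx[i] <- NA_character_
    } else if (cl == "CpG>TpG") {
      ref[i] <- "C"; alt[i] <- "T"
      ctx[i] <- paste0(sample(bases, 1), "CG")
    } else {
      ref[i] <- substr(cl, 1, 1)
      alt[i] <- substr(cl, 3, 3)
      right <- if (cl == "C>T") sample(c("A", "C", "T"), 1) else sample(bases, 1)
      ctx[i] <- paste0(sample(bases, 1), ref[i], right)
    }
  }
  ## flip a random half of the SNVs onto the purine-reference strand
  flip <- which(!is.na(ctx) & stats::runif(n) < 0.5)
  if (length(flip)) {
    ref[flip] <- revcomp(ref[flip])
    alt[flip] <- revcomp(alt[flip])
    ctx[flip] <- revcomp(ctx[flip])
  }
  data.frame(ref = ref, alt = alt, context = ctx, stringsAsFactors = FALSE)
}

## uniform positions within an allowed GRanges, unique against `used`
draw_positions <- function(n, allowed, used) {
  if (n == 0) {
    return(data.frame(chrom = character(), pos = integer()))
  }
  w <- as.numeric(GenomicRanges::width(allowed))
  cw <- cumsum(w)
  chroms <- as.character(GenomicRanges::seqnames(allowed))
  starts <- GenomicRanges::start(allowed)
  res_chrom <- character(n); res_pos <- integer(n)
  filled <- 0L
  guard <- 0L
  while (filled < n) {
    guard <- guard + 1L
    if (guard > 200L) stop("could not place unique positions; genome too small")
    m <- (n - filled) * 2L
    u <- stats::runif(m, 0, cw[length(cw)])
    iv <- findInterval(u, c(0, cw), rightmost.closed = TRUE)
    pos <- as.integer(starts[iv] + floor(u - c(0, cw)[iv]))
    key <- paste0(chroms[iv], ":", pos)
    ok <- !duplicated(key) & !vapply(key, exists, logical(1), envir = used)
    take <- which(ok)[seq_len(min(sum(ok), n - filled))]
    for (k in key[take]) assign(k, TRUE, envir = used)
    idx <- filled + seq_along(take)
    res_chrom[idx] <- chroms[iv[take]]
    res_pos[idx] <- pos[take]
    filled <- filled + length(take)
  }
  data.frame(chrom = res_chrom, pos = res_pos, stringsAsFactors = FALSE)
}


## n-way interval intersection via coverage slicing: much cheaper than
## chained pairwise intersects when many masks are combined
intersect_all <- function(grs) {
  lv <- unique(unlist(lapply(grs, GenomeInfoDb::seqlevels)))
  grs <- lapply(grs, function(g) {
    GenomeInfoDb::seqlevels(g) <- lv
    g
  })
  cov <- GenomicRanges::coverage(do.call(c, unname(grs)))
  sl <- IRanges::slice(cov, lower = length(grs), rangesOnly = TRUE)
  GenomicRanges::GRanges(sl)
}

#' Simulate the ground-truth mutation and error events of a cohort
#'
#' Draws, per third-generation child, paternal and maternal single-gamete
#' germline DNM counts from identity-link Poisson models scaled by the
#' trio's callable fraction; per second-generation individual, their own
#' germline DNMs (from first-generation parental ages), gonosomal mutations,
#' and a post-PGCS mosaic pool with age-independent, haplotype-consistent
#' transmission; plus missed-heterozygote genotyping errors and spurious
#' (false-positive) candidates at the configured rates. Every event gets a
#' unique position in territory that is callable in the whole family and
#' outside the LCR track, and alleles/contexts drawn from the configured
#' mutation spectrum.
#'
#' @param pedigree a [simulate_pedigree()] result.
#' @param config a [sim_config()].
#' @param masks result of [simulate_masks()] (list with `masks`, `lcr`).
#' @param hap per-family haplotype-inheritance draws; defaults to a fresh
#'   draw derived from the config seed.
#' @return data frame of truth records (classes `germline_single_gamete`,
#'   `gonosomal`, `postpgcs_mosaic`, `missed_het_error`, `false_positive`),
#'   one row per event, with carrier, parent-of-origin, background
#'   haplotype, transmission and allele columns.
#' @export
simulate_mutations <- function(pedigree, config, masks,
                               hap = simulate_haplotypes(pedigree, config)) {
  seeds <- family_seeds(config, 3L)
  used <- new.env(hash = TRUE, parent = emptyenv())
  fams <- unique(pedigree$family)
  autosomes <- config$genome$chrom[config$genome$chrom != config$x_chrom]
  auto_bp <- sum(config$genome$length[config$genome$chrom != config$x_chrom])
  rows <- vector("list", length(fams))
  for (f in seq_along(fams)) {
    set.seed(seeds[f])
    fl <- fams[f]
    ped_f <- pedigree[pedigree$family == fl, , drop = FALSE]
    kids <- ped_f$id[ped_f$generation == "G3"]
    k <- length(kids)
    g2f <- paste0(fl, "_G2F"); g2m <- paste0(fl, "_G2M")
    hap_f <- hap[[fl]]
    genome_gr <- GenomicRanges::GRanges(
      config$genome$chrom,
      IRanges::IRanges(1, as.integer(config$genome$length)))
    lcr_free <- GenomicRanges::setdiff(genome_gr, masks$lcr)
    fam_allowed <- intersect_all(c(masks$masks[ped_f$id], list(lcr_free)))
    fam_allowed <- fam_allowed[
      as.character(GenomicRanges::seqnames(fam_allowed)) %in% autosomes]
    ## per-sample callable territory (minus LCR, autosomes) computed once
    clean <- lapply(masks$masks[ped_f$id], function(gr) {
      gr <- GenomicRanges::setdiff(gr, masks$lcr)
      gr[as.character(GenomicRanges::seqnames(gr)) %in% autosomes]
    })
    cf_cache <- new.env(parent = emptyenv())
    cfrac <- function(ids) {
      key <- paste(ids, collapse = "|")
      if (!is.null(cf_cache[[key]])) return(cf_cache[[key]])
      out <- sum(as.numeric(GenomicRanges::width(intersect_all(clean[ids])))) /
        auto_bp
      cf_cache[[key]] <- out
      out
    }
    ev <- list(); ei <- 0L
    add <- function(class, carrier, origin, hp, chrom, transmitted,
                    aux1 = NA_character_, spectrum = "germline") {
      ei <<- ei + 1L
      ev[[ei]] <<- data.frame(
        family = fl, class = class, carrier_id = carrier,
        origin_parent_id = origin, hap = hp, chrom = chrom,
        transmitted_to = paste(transmitted, collapse = ","),
        aux1 = as.character(aux1), spectrum = spectrum,
        stringsAsFactors = FALSE)
    }
    ## --- G3 single-gamete germline DNMs -------------------------------
    for (kid in kids) {
      cf <- cfrac(c(kid, g2f, g2m))
      da <- ped_f$dad_age[ped_f$id == kid]
      ma <- ped_f$mom_age[ped_f$id == kid]
      n_p <- stats::rpois(1, (config$Bp * da + config$B0p) * cf)
      n_m <- stats::rpois(1, (config$Bm * ma + config$B0m) * cf)
      for (i in seq_len(n_p)) {
        ch <- sample(autosomes, 1)
        add("germline_single_gamete", kid, g2f,
            hap_f[kid, "father", ch], ch, character())
      }
      for (i in seq_len(n_m)) {
        ch <- sample(autosomes, 1)
        add("germline_single_gamete", kid, g2m,
            hap_f[kid, "mother", ch], ch, character())
      }
    }
    ## --- events arising in (or masked by) the second generation -------
    for (x in c(g2f, g2m)) {
      role <- if (x == g2f) "father" else "mother"
      side <- if (x == g2f) c("G1PF", "G1PM") else c("G1MF", "G1MM")
      g1p <- paste0(fl, "_", side[1]); g1m <- paste0(fl, "_", side[2])
      cf_x <- cfrac(c(x, g1p, g1m))
      da <- ped_f$dad_age[ped_f$id == x]
      ma <- ped_f$mom_age[ped_f$id == x]
      n_p <- stats::rpois(1, (config$Bp * da + config$B0p) * cf_x)
      n_m <- stats::rpois(1, (config$Bm * ma + config$B0m) * cf_x)
      ## single-gamete germline DNMs of the G2 individual: arose on the
      ## gamete contributed by one G1 parent, so they sit on that
      ## haplotype and co-segregate into the third generation with it
      for (spec in list(list(n = n_p, hp = "pat", origin = g1p),
                        list(n = n_m, hp = "mat", origin = g1m))) {
        for (i in seq_len(spec$n)) {
          ch <- sample(autosomes, 1)
          trans <- kids[hap_f[kids, role, ch] == spec$hp]
          add("germline_single_gamete", x, spec$origin, spec$hp, ch, trans)
        }
      }
      ## gonosomal: post-zygotic in x, on a background haplotype, present
      ## in blood but transmitted to only a fraction of the children who
      ## inherited that haplotype
      n_g <- stats::rpois(1, config$gonosomal_rate * cf_x)
      for (i in seq_len(n_g)) {
        hp <- sample(c("pat", "mat"), 1)
        ch <- sample(autosomes, 1)
        on_hap <- kids[hap_f[kids, role, ch] == hp]
        frac <- config$gonosomal_transmission_prob / 0.5
        trans <- on_hap[stats::runif(length(on_hap)) < frac]
        add("gonosomal", x, if (hp == "pat") g1p else g1m, hp, ch, trans)
      }
      ## post-PGCS mosaic pool: absent from x's soma, present in a
      ## fraction of gametes carrying one haplotype; age-independent
      n_mo <- stats::rpois(1, config$mosaic_pool_size * cf_x)
      for (i in seq_len(n_mo)) {
        hp <- sample(c("pat", "mat"), 1)
        ch <- sample(autosomes, 1)
        on_hap <- kids[hap_f[kids, role, ch] == hp]
        frac <- config$mosaic_transmission_prob / 0.5
        trans <- on_hap[stats::runif(length(on_hap)) < frac]
        add("postpgcs_mosaic", x, x, hp, ch, trans, spectrum = "mosaic")
      }
      ## false positives: variants truly inherited from a G1 parent whose
      ## standard-depth genotype missed them; deep resequencing of that
      ## parent reveals supporting reads
      exp_valid <- (config$Bp * da + config$B0p + config$Bm * ma +
                    config$B0m) * cf_x
      n_fp <- stats::rpois(1, config$fpr_rate / (1 - config$fpr_rate) *
                             exp_valid)
      for (i in seq_len(n_fp)) {
        hp <- sample(c("pat", "mat"), 1)
        err_g1 <- if (hp == "pat") g1p else g1m
        ch <- sample(autosomes, 1)
        trans <- kids[hap_f[kids, role, ch] == hp]
        add("false_positive", x, err_g1, hp, ch, trans, aux1 = err_g1)
      }
    }
    ## --- missed heterozygotes: inherited variants surfacing as G3 DNMs
    lam_fam <- sum(vapply(kids, function(kid) {
      da <- ped_f$dad_age[ped_f$id == kid]
      ma <- ped_f$mom_age[ped_f$id == kid]
      config$Bp * da + config$B0p + config$Bm * ma + config$B0m
    }, numeric(1)))
    exp_carriers <- k * 0.5 / (1 - 0.5^k)
    n_mh <- stats::rpois(1, config$mhr_rate / (1 - config$mhr_rate) *
                           lam_fam / exp_carriers)
    for (i in seq_len(n_mh)) {
      err_parent <- sample(c(g2f, g2m), 1)
      side <- if (err_parent == g2f) c("G1PF", "G1PM") else c("G1MF", "G1MM")
      support_g1 <- paste0(fl, "_", sample(side, 1))
      carriers <- kids[stats::runif(k) < 0.5]
      if (!length(carriers)) carriers <- sample(kids, 1)
      add("missed_het_error", err_parent, support_g1, NA_character_,
          sample(autosomes, 1), carriers, aux1 = support_g1)
    }
    out <- do.call(rbind, ev)
    if (is.null(out)) next
    ## positions: drawn uniformly within allowed territory, constrained to
    ## each event's chromosome (grouped for efficiency)
    out$pos <- NA_integer_
    for (ch in unique(out$chrom)) {
      idx <- which(out$chrom == ch)
      sub <- fam_allowed[
        as.character(GenomicRanges::seqnames(fam_allowed)) == ch]
      p <- draw_positions(length(idx), sub, used)
      out$pos[idx] <- p$pos
    }
    classes <- character(nrow(out))
    gi <- out$spectrum == "germline"
    classes[gi] <- draw_class(sum(gi), config$spectrum_germline)
    classes[!gi] <- draw_class(sum(!gi), config$spectrum_mosaic)
    al <- draw_alleles(classes)
    out$ref <- al$ref; out$alt <- al$alt; out$context <- al$context
    out$mut_class <- classes
    out$spectrum <- NULL
    rows[[f]] <- out
  }
  truth <- do.call(rbind, rows)
  truth$event_id <- sprintf("E%06d", seq_len(nrow(truth)))
  rownames(truth) <- NULL
  truth
}

## vectorized genotype-evidence draws; ab_mean is the expected allele
## balance for het calls (0.5 germline; lower, Beta-drawn, for gonosomal)
gen_calls <- function(gt, ab_mean, config) {
  n <- length(gt)
  if (config$genotype_noise) {
    dp <- pmax(stats::rpois(n, config$depth_mean), 2L)
    gq <- sample(config$gq_levels, n, replace = TRUE, prob = config$gq_probs)
  } else {
    dp <- rep.int(as.integer(round(config$depth_mean)), n)
    gq <- rep.int(99L, n)
  }
  ad_alt <- integer(n)
  het <- which(gt == "het")
  if (length(het)) {
    raw <- if (config$genotype_noise) {
      stats::rbinom(length(het), dp[het], ab_mean[het])
    } else {
      round(dp[het] * ab_mean[het])
    }
    ad_alt[het] <- pmin(pmax(raw, 1L), dp[het] - 1L)
  }
  ha <- gt %in% c("hom_alt", "hemizygous_alt")
  ad_alt[ha] <- dp[ha]
  ad_ref <- dp - ad_alt
  miss <- gt == "missing"
  dp[miss] <- NA; ad_ref[miss] <- NA; ad_alt[miss] <- NA; gq[miss] <- NA
  data.frame(dp = dp, ad_ref = ad_ref, ad_alt = ad_alt, gq = gq)
}

rand_snv <- function() {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, 1)
  alt <- sample(setdiff(bases, ref), 1)
  ctx <- paste0(sample(bases, 1), ref, sample(bases, 1))
  list(ref = ref, alt = alt, ctx = ctx)
}

#' Emit genotypes, informative markers and read evidence for a truth set
#'
#' Materializes every truth event as a jointly genotyped site (explicit
#' calls for the whole family; implicit confident hom-ref elsewhere), plants
#' inherited informative marker sites around each DNM -- heterozygous in
#' the focal individual, carried by exactly one of their parents, and
#' co-segregating with the true haplotype -- for both transmission phasing
#' (+/-200 kb) and read tracing (+/-500 bp), and emits fragment-level
#' co-observations consistent with the true phase (including third-haplotype
#' fragments at gonosomal sites). Missed-heterozygote events emit the
#' carrier parent as a confident hom-ref call while a grandparent retains
#' the het call; false-positive events add deep-resequencing read support
#' in the mis-genotyped first-generation parent.
#'
#' @param truth a [simulate_mutations()] result.
#' @param pedigree,config,hap as in [simulate_mutations()].
#' @return list with `cohort` (a [new_cohort()]), `read_evidence`,
#'   `deep_reads`, `raw_parent_reads` (data frames) and `deep_g2`
#'   (ids of second-generation individuals with deep-sequenced parents).
#' @export
simulate_genotypes_and_reads <- function(truth, pedigree, config,
                                         hap = simulate_haplotypes(pedigree,
                                                                   config)) {
  seeds <- family_seeds(config, 4L)
  fams <- unique(pedigree$family)
  used <- new.env(hash = TRUE, parent = emptyenv())
  for (kk in paste0(truth$chrom, ":", truth$pos)) assign(kk, TRUE, used)
  glen <- stats::setNames(config$genome$length, config$genome$chrom)
  ## deep-resequenced subset: the G1 parents of the first n_deep_g2
  ## second-generation individuals
  all_g2 <- pedigree$id[pedigree$generation == "G2"]
  deep_g2 <- utils::head(all_g2, config$n_deep_g2)
  out_sites <- list(); out_calls <- list(); out_re <- list()
  out_deep <- list(); out_raw <- list()
  for (f in seq_along(fams)) {
    set.seed(seeds[f])
    fl <- fams[f]
    ped_f <- pedigree[pedigree$family == fl, , drop = FALSE]
    members <- ped_f$id
    kids <- ped_f$id[ped_f$generation == "G3"]
    g2f <- paste0(fl, "_G2F"); g2m <- paste0(fl, "_G2M")
    hap_f <- hap[[fl]]
    tr_f <- truth[truth$family == fl, , drop = FALSE]
    S <- list(); CLgt <- list(); CLab <- list(); si <- 0L
    RE <- list(); ri <- 0L; frag_n <- 0L
    add_site <- function(chrom, pos, ref, alt, ctx, gt_map,
                         abm_map = NULL) {
      si <<- si + 1L
      gt <- stats::setNames(rep("hom_ref", length(members)), members)
      gt[names(gt_map)] <- gt_map
      abm <- stats::setNames(rep(0.5, length(members)), members)
      if (!is.null(abm_map)) abm[names(abm_map)] <- abm_map
      S[[si]] <<- list(chrom = chrom, pos = pos, ref = ref, alt = alt,
                       ctx = ctx)
      CLgt[[si]] <<- gt
      CLab[[si]] <<- abm
      si
    }
    add_frags <- function(sample_id, chrom, posA, posB, alleleA, alleleB,
                          n_each) {
      keep <- n_each > 0
      if (!any(keep)) return(invisible())
      alleleA <- rep(alleleA[keep], n_each[keep])
      alleleB <- rep(alleleB[keep], n_each[keep])
      m <- length(alleleA)
      ri <<- ri + 1L
      RE[[ri]] <<- data.frame(
        fragment_id = sprintf("%s_frag%06d", fl, frag_n + seq_len(m)),
        sample_id = sample_id, chrom = chrom, posA = posA,
        alleleA = alleleA, posB = posB, alleleB = alleleB,
        baseq_ok = TRUE, mapq_ok = TRUE, stringsAsFactors = FALSE)
      frag_n <<- frag_n + m
    }
    marker_pos <- function(chrom, pos, near) {
      L <- glen[[chrom]]
      for (att in 1:50) {
        off <- if (near) sample(10:500, 1) else sample(501:config$phase_window_far, 1)
        p <- pos + sample(c(-1L, 1L), 1) * off
        if (p < 1 || p > L) next
        kk <- paste0(chrom, ":", p)
        if (!exists(kk, envir = used)) {
          assign(kk, TRUE, used)
          return(p)
        }
      }
      stop("could not place a marker position")
    }
    ## plant one inherited marker: het in G2 individual s on haplotype u,
    ## carried by the corresponding G1 parent, co-segregating into G3
    plant_marker <- function(s, u, chrom, pos_m) {
      role <- if (s == g2f) "father" else "mother"
      sided <- parents_of(ped_f, s)
      g1_carrier <- unname(if (u == "pat") sided["father"] else sided["mother"])
      al <- rand_snv()
      gt_map <- stats::setNames(rep("het", 2), c(s, g1_carrier))
      carr <- kids[hap_f[kids, role, chrom] == u]
      if (length(carr)) gt_map[carr] <- "het"
      add_site(chrom, pos_m, al$ref, al$alt, al$ctx, gt_map)
      list(ref = al$ref, alt = al$alt, carrier_g1 = g1_carrier)
    }
    for (i in seq_len(nrow(tr_f))) {
      e <- tr_f[i, ]
      trans <- if (nzchar(e$transmitted_to))
        strsplit(e$transmitted_to, ",", fixed = TRUE)[[1]] else character()
      carrier_gen <- ped_f$generation[ped_f$id == e$carrier_id]
      if (e$class == "germline_single_gamete" && carrier_gen == "G3") {
        gt_map <- stats::setNames("het", e$carrier_id)
        add_site(e$chrom, e$pos, e$ref, e$alt, e$context, gt_map)
        ## read-tracing markers around the child's DNM
        n_near <- stats::rpois(1, config$informative_near_rate)
        role_o <- if (e$origin_parent_id == g2f) "father" else "mother"
        dnm_hap_par <- e$origin_parent_id
        for (j in seq_len(n_near)) {
          s <- sample(c(g2f, g2m), 1)
          role_s <- if (s == g2f) "father" else "mother"
          u <- hap_f[e$carrier_id, role_s, e$chrom]
          pm <- marker_pos(e$chrom, e$pos, near = TRUE)
          mk <- plant_marker(s, u, e$chrom, pm)
          cis <- s == dnm_hap_par  # marker sits on the DNM's haplotype
          nn <- config$frags_per_marker
          if (e$mut_class == "indel") next  # fragment table is SNV-only
          if (cis) {
            add_frags(e$carrier_id, e$chrom, e$pos, pm,
                      c(e$alt, e$ref), c(mk$alt, mk$ref), c(nn, nn))
          } else {
            add_frags(e$carrier_id, e$chrom, e$pos, pm,
                      c(e$alt, e$ref), c(mk$ref, mk$alt), c(nn, nn))
          }
        }
      } else if (e$class %in% c("germline_single_gamete", "gonosomal",
                                "false_positive") && carrier_gen == "G2") {
        x <- e$carrier_id
        gt_map <- stats::setNames(rep("het", 1 + length(trans)),
                                  c(x, trans))
        abm_map <- NULL
        if (e$class == "gonosomal") {
          m <- config$gonosomal_ab_mean; cc <- config$gonosomal_ab_conc
          ab <- if (config$genotype_noise)
            stats::rbeta(1, m * cc, (1 - m) * cc) else m
          abm_map <- stats::setNames(ab, x)
        }
        if (e$class == "false_positive") {
          ## truly inherited: the mis-genotyped G1 parent is emitted as a
          ## confident hom-ref call; its deep resequencing shows support
          gt_map[e$aux1] <- "hom_ref"
        }
        add_site(e$chrom, e$pos, e$ref, e$alt, e$context, gt_map, abm_map)
        if (e$class == "false_positive" && x %in% deep_g2) {
          out_deep[[length(out_deep) + 1L]] <- data.frame(
            sample_id = e$aux1, chrom = e$chrom, pos = e$pos,
            allele = e$alt, n_reads = 2L + stats::rbinom(1, 58, 0.4),
            stringsAsFactors = FALSE)
        }
        ## transmission-phasing markers (within 200 kb) in x
        n_far <- stats::rpois(1, config$informative_far_rate)
        for (j in seq_len(n_far)) {
          u <- sample(c("pat", "mat"), 1)
          pm <- marker_pos(e$chrom, e$pos, near = FALSE)
          plant_marker(x, u, e$chrom, pm)
        }
        ## read-tracing markers (within 500 bp) in x
        n_near <- stats::rpois(1, config$informative_near_rate)
        for (j in seq_len(n_near)) {
          if (e$mut_class == "indel") break
          u <- sample(c("pat", "mat"), 1)
          pm <- marker_pos(e$chrom, e$pos, near = TRUE)
          mk <- plant_marker(x, u, e$chrom, pm)
          cis <- u == e$hap
          nn <- config$frags_per_marker
          if (cis) {
            a_main <- c(e$alt, e$ref); b_main <- c(mk$alt, mk$ref)
            third <- c(e$ref, mk$alt)
          } else {
            a_main <- c(e$alt, e$ref); b_main <- c(mk$ref, mk$alt)
            third <- c(e$ref, mk$ref)
          }
          add_frags(x, e$chrom, e$pos, pm, a_main, b_main, c(nn, nn))
          if (e$class == "gonosomal" && config$third_hap_reads > 0) {
            ## somatic cells lacking the mutation expose a third haplotype
            add_frags(x, e$chrom, e$pos, pm, third[1], third[2],
                      config$third_hap_reads)
          }
        }
      } else if (e$class == "postpgcs_mosaic") {
        p <- e$carrier_id
        gt_map <- stats::setNames(rep("het", length(trans)), trans)
        add_site(e$chrom, e$pos, e$ref, e$alt, e$context, gt_map)
        ## raw-alignment support in the carrier parent for a small
        ## configurable fraction of mosaic sites
        if (stats::runif(1) < config$mosaic_parent_support_rate) {
          out_raw[[length(out_raw) + 1L]] <- data.frame(
            sample_id = p, chrom = e$chrom, pos = e$pos, allele = e$alt,
            n_reads = 2L + stats::rpois(1, 2), stringsAsFactors = FALSE)
        }
        ## grandparental-haplotype markers for both G2 parents
        for (s in c(g2f, g2m)) {
          n_far <- stats::rpois(1, config$informative_far_rate)
          for (j in seq_len(n_far)) {
            u <- sample(c("pat", "mat"), 1)
            pm <- marker_pos(e$chrom, e$pos, near = FALSE)
            plant_marker(s, u, e$chrom, pm)
          }
        }
      } else if (e$class == "missed_het_error") {
        ## carrier parent truly het but called hom-ref with zero alt
        ## reads; one grandparent retains the high-quality het call
        gt_map <- stats::setNames(rep("het", length(trans) + 1),
                                  c(trans, e$aux1))
        gt_map[e$carrier_id] <- "hom_ref"
        add_site(e$chrom, e$pos, e$ref, e$alt, e$context, gt_map)
      }
    }
    ## materialize this family's sites and calls
    if (si == 0L) next
    sites_f <- data.frame(
      site_id = sprintf("%sS%05d", fl, seq_len(si)),
      chrom = vapply(S, `[[`, "", "chrom"),
      pos = vapply(S, function(z) as.integer(z$pos), 0L),
      ref = vapply(S, `[[`, "", "ref"),
      alt = vapply(S, `[[`, "", "alt"),
      context = vapply(S, function(z)
        if (is.na(z$ctx)) NA_character_ else z$ctx, ""),
      filter_pass = TRUE, in_lcr = FALSE, stringsAsFactors = FALSE)
    gt_all <- unlist(CLgt, use.names = TRUE)
    calls_f <- data.frame(
      site_id = rep(sites_f$site_id, each = length(members)),
      sample_id = names(gt_all),
      gt = unname(gt_all),
      stringsAsFactors = FALSE)
    ev <- gen_calls(calls_f$gt, unname(unlist(CLab)), config)
    calls_f <- cbind(calls_f, ev)
    out_sites[[f]] <- sites_f
    out_calls[[f]] <- calls_f
    if (ri > 0) out_re[[f]] <- do.call(rbind, RE)
  }
  sites <- do.call(rbind, out_sites)
  calls <- do.call(rbind, out_calls)
  ## keep only non-default calls explicit (plus all focal-family het/alt
  ## rows); retaining the full family keeps parental depth/GQ realistic
  cohort <- new_cohort(sites, calls, pedigree$id)
  empty_re <- data.frame(fragment_id = character(), sample_id = character(),
                         chrom = character(), posA = integer(),
                         alleleA = character(), posB = integer(),
                         alleleB = character(), baseq_ok = logical(),
                         mapq_ok = logical(), stringsAsFactors = FALSE)
  empty_dr <- data.frame(sample_id = character(), chrom = character(),
                         pos = integer(), allele = character(),
                         n_reads = integer(), stringsAsFactors = FALSE)
  list(cohort = cohort,
       read_evidence = if (length(out_re)) do.call(rbind, out_re) else empty_re,
       deep_reads = if (length(out_deep)) do.call(rbind, out_deep) else empty_dr,
       raw_parent_reads = if (length(out_raw)) do.call(rbind, out_raw) else empty_dr,
       deep_g2 = deep_g2)
}

#' Simulate a complete synthetic cohort
#'
#' Chains [simulate_pedigree()], [simulate_masks()], haplotype draws,
#' [simulate_mutations()] and [simulate_genotypes_and_reads()] under the
#' config's master seed (per-family substreams make families independently
#' reproducible).
#'
#' @param config a [sim_config()].
#' @return a `dnm_sim` list: `config`, `pedigree`, `masks`, `lcr`, `truth`,
#'   `cohort`, `read_evidence`, `deep_reads`, `raw_parent_reads`, `deep_g2`,
#'   `hap`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  ped <- simulate_pedigree(config)
  mk <- simulate_masks(ped, config)
  hp <- simulate_haplotypes(ped, config)
  truth <- simulate_mutations(ped, config, mk, hp)
  gr <- simulate_genotypes_and_reads(truth, ped, config, hp)
  structure(list(config = config, pedigree = ped, masks = mk$masks,
                 lcr = mk$lcr, truth = truth, cohort = gr$cohort,
                 read_evidence = gr$read_evidence,
                 deep_reads = gr$deep_reads,
                 raw_parent_reads = gr$raw_parent_reads,
                 deep_g2 = gr$deep_g2, hap = hp),
            class = "dnm_sim")
}

#' @export
print.dnm_sim <- function(x, ...) {
  cat(sprintf(paste0("<dnm_sim> %d families, %d samples, %d truth events, ",
                     "%d sites\n"),
              length(unique(x$pedigree$family)), nrow(x$pedigree),
              nrow(x$truth), nrow(x$cohort$sites)))
  invisible(x)
}

#' Write a simulated cohort to disk (VCF, PED, BED, TSV)
#'
#' Emits `cohort.vcf`, `cohort.ped`, `ages.csv`, `lcr.bed`,
#' `masks/<sample>.bed`, `reads.tsv`, `deep_reads.tsv`,
#' `raw_parent_reads.tsv`, `truth.tsv`, `deep_g2.txt` and `genome.tsv`
#' under `dir`; [read_cohort()] round-trips them.
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  pth <- function(x) file.path(dir, x)
  write_vcf(sim$cohort, pth("cohort.vcf"), genome = sim$config$genome)
  write_ped(sim$pedigree, pth("cohort.ped"), ages_path = pth("ages.csv"))
  write_bed(sim$lcr, pth("lcr.bed"))
  for (s in names(sim$masks)) {
    write_bed(sim$masks[[s]], file.path(dir, "masks", paste0(s, ".bed")))
  }
  write_read_evidence(sim$read_evidence, pth("reads.tsv"))
  write_deep_reads(sim$deep_reads, pth("deep_reads.tsv"))
  write_deep_reads(sim$raw_parent_reads, pth("raw_parent_reads.tsv"))
  utils::write.table(sim$truth, pth("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(sim$deep_g2, pth("deep_g2.txt"))
  utils::write.table(sim$config$genome, pth("genome.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir directory path.
#' @return list with `pedigree`, `cohort`, `lcr`, `masks`, `read_evidence`,
#'   `deep_reads`, `raw_parent_reads`, `truth`, `deep_g2`, `genome`.
#' @export
read_cohort <- function(dir) {
  pth <- function(x) file.path(dir, x)
  ped <- read_ped(pth("cohort.ped"), ages = pth("ages.csv"))
  mask_files <- list.files(file.path(dir, "masks"), full.names = TRUE)
  masks <- lapply(mask_files, read_bed)
  names(masks) <- sub("\\.bed$", "", basename(mask_files))
  list(
    pedigree = ped,
    cohort = read_vcf(pth("cohort.vcf")),
    lcr = read_bed(pth("lcr.bed")),
    masks = masks,
    read_evidence = read_read_evidence(pth("reads.tsv")),
    deep_reads = read_deep_reads(pth("deep_reads.tsv")),
    raw_parent_reads = read_deep_reads(pth("raw_parent_reads.tsv")),
    truth = utils::read.table(pth("truth.tsv"), header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE,
                              colClasses = "character"),
    deep_g2 = readLines(pth("deep_g2.txt")),
    genome = utils::read.table(pth("genome.tsv"), header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  )
}

#' Simulate per-child DNM counts under an identity-link Poisson age model
#'
#' The elementary generative model behind the cohort simulator, exposed
#' directly: ages uniform on a range, counts Poisson with mean
#' `slope * age + intercept`. Used for regression-recovery checks.
#'
#' @param n number of children.
#' @param slope additional DNMs per year of parental age.
#' @param intercept expected DNMs at age zero.
#' @param age_range uniform range of parental ages (years).
#' @return data frame with `age` and `count`.
#' @export
simulate_dnm_counts <- function(n, slope, intercept, age_range) {
  age <- stats::runif(n, age_range[1], age_range[2])
  mu <- slope * age + intercept
  if (any(mu <= 0)) stop("identity-link mean must be positive")
  data.frame(age = age, count = stats::rpois(n, mu))
}
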