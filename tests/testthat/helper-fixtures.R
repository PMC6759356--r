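# Shared fixtures: hand-built toy cohorts and lazily cached simulations.

## one three-generation family (3 children) plus an unrelated founder pair
toy_pedigree <- function() {
  new_pedigree(data.frame(
    id = c("gpf", "gpm", "gmf", "gmm", "dad", "mom",
           "c1", "c2", "c3", "u1", "u2"),
    sex = c("male", "female", "male", "female", "male", "female",
            "male", "female", "female", "male", "female"),
    father_id = c(NA, NA, NA, NA, "gpf", "gmf", "dad", "dad", "dad",
                  NA, NA),
    mother_id = c(NA, NA, NA, NA, "gpm", "gmm", "mom", "mom", "mom",
                  NA, NA),
    dad_age = c(NA, NA, NA, NA, 30, 28, 25, 28, 31, NA, NA),
    mom_age = c(NA, NA, NA, NA, 27, 26, 23, 26, 29, NA, NA),
    stringsAsFactors = FALSE
  ))
}

## build a cohort from a compact spec: sites is a data.frame; calls is a
## list of lists(site, sample, gt, dp, ad_alt, gq) with defaults filled in
toy_cohort <- function(sites, calls, samples = toy_pedigree()$id) {
  rows <- lapply(calls, function(cl) {
    dp <- if (is.null(cl$dp)) 30L else cl$dp
    ad_alt <- if (!is.null(cl$ad_alt)) cl$ad_alt
      else if (cl$gt == "het") dp %/% 2L
      else if (cl$gt %in% c("hom_alt", "hemizygous_alt")) dp
      else 0L
    data.frame(site_id = cl$site, sample_id = cl$sample, gt = cl$gt,
               dp = dp, ad_ref = dp - ad_alt, ad_alt = ad_alt,
               gq = if (is.null(cl$gq)) 99L else cl$gq,
               stringsAsFactors = FALSE)
  })
  new_cohort(sites, do.call(rbind, rows), samples)
}

toy_site <- function(site_id, chrom = "chr1", pos = 1000L, ref = "C",
                     alt = "T", context = "ACA", filter_pass = TRUE,
                     in_lcr = FALSE) {
  data.frame(site_id = site_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, context = context, filter_pass = filter_pass,
             in_lcr = in_lcr, stringsAsFactors = FALSE)
}

## cached simulations shared across test files (built once per run)
.sim_cache <- new.env(parent = emptyenv())

zero_noise_sim <- function() {
  if (is.null(.sim_cache$zero)) {
    cfg <- sim_config(n_families = 3L, children_per_family = c(4L, 6L),
                      mhr_rate = 0, fpr_rate = 0, genotype_noise = FALSE,
                      seed = 101L)
    .sim_cache$zero <- simulate_cohort(cfg)
  }
  .sim_cache$zero
}

zero_noise_callset <- function() {
  if (is.null(.sim_cache$zero_cs)) {
    sim <- zero_noise_sim()
    .sim_cache$zero_cs <- discover_dnms(sim$cohort, sim$pedigree,
                                        deep_reads = sim$deep_reads,
                                        deep_g2 = sim$deep_g2)
  }
  .sim_cache$zero_cs
}

zero_noise_classification <- function() {
  if (is.null(.sim_cache$zero_cl)) {
    sim <- zero_noise_sim()
    .sim_cache$zero_cl <- classify_dnms(zero_noise_callset(), sim$cohort,
                                        sim$pedigree, sim$read_evidence,
                                        raw_parent_reads = sim$raw_parent_reads)
  }
  .sim_cache$zero_cl
}

noisy_sim <- function() {
  if (is.null(.sim_cache$noisy)) {
    cfg <- sim_config(n_families = 6L, children_per_family = c(6L, 10L),
                      seed = 202L)
    .sim_cache$noisy <- simulate_cohort(cfg)
  }
  .sim_cache$noisy
}

noisy_callset <- function() {
  if (is.null(.sim_cache$noisy_cs)) {
    sim <- noisy_sim()
    .sim_cache$noisy_cs <- discover_dnms(sim$cohort, sim$pedigree,
                                         deep_reads = sim$deep_reads,
                                         deep_g2 = sim$deep_g2)
  }
  .sim_cache$noisy_cs
}

## truth lookup by position
truth_at <- function(truth, chrom, pos) {
  truth[match(paste(chrom, pos), paste(truth$chrom, truth$pos)), ]
}

truth_carriers <- function(truth_row) {
  if (!nzchar(truth_row$transmitted_to)) character()
  else strsplit(truth_row$transmitted_to, ",", fixed = TRUE)[[1]]
}

## brute-force eligibility for gonosomal detection at zero noise, computed
## by direct genotype-table queries: a truth event is detectable iff some
## informative marker tags the DNM background haplotype (its child carrier
## set contains every DNM carrier) and at least one marker-carrier child
## lacks the DNM
gonosomal_eligible <- function(sim, ev) {
  cohort <- sim$cohort; ped <- sim$pedigree
  x <- ev$carrier_id
  kids <- children_of(ped, x)
  D <- truth_carriers(ev)
  if (!length(D)) return(FALSE)
  s <- cohort$sites
  near <- s[s$chrom == ev$chrom & s$pos != as.integer(ev$pos) &
              abs(s$pos - as.integer(ev$pos)) <= 2e5, , drop = FALSE]
  par <- ped[ped$id == x, ]
  for (i in seq_len(nrow(near))) {
    cc <- cohort$calls[cohort$calls$site_id == near$site_id[i], ]
    alt <- cc$sample_id[cc$gt %in% c("het", "hom_alt", "hemizygous_alt")]
    if (!x %in% cc$sample_id[cc$gt == "het"]) next
    if (sum(c(par$father_id, par$mother_id) %in% alt) != 1) next
    S <- intersect(alt, kids)
    if (all(D %in% S) && length(setdiff(S, D)) > 0) return(TRUE)
  }
  FALSE
}
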