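## toy cohort exercising each discovery filter
discovery_fixture <- function() {
  ped <- toy_pedigree()
  sites <- rbind(
    toy_site("S_clean", pos = 1000L),
    toy_site("S_paltread", pos = 2000L),
    toy_site("S_likelycarr", pos = 3000L),
    toy_site("S_posscarr", pos = 4000L),
    toy_site("S_sibcarr", pos = 5000L),
    toy_site("S_xmale_hemi", chrom = "chrX", pos = 6000L),
    toy_site("S_xmale_het", chrom = "chrX", pos = 7000L),
    toy_site("S_gpsupport", pos = 8000L),
    toy_site("S_lowab", pos = 9000L),
    toy_site("S_lowdepth", pos = 10000L),
    toy_site("S_filtered", pos = 11000L, filter_pass = FALSE),
    toy_site("S_lcr", pos = 12000L, in_lcr = TRUE),
    toy_site("S_homalt", pos = 13000L)
  )
  calls <- list(
    list(site = "S_clean", sample = "c1", gt = "het", dp = 15L),
    list(site = "S_clean", sample = "dad", gt = "hom_ref", dp = 20L),
    list(site = "S_clean", sample = "mom", gt = "hom_ref", dp = 20L),
    ## father shows one read supporting the de novo allele
    list(site = "S_paltread", sample = "c1", gt = "het"),
    list(site = "S_paltread", sample = "dad", gt = "hom_ref", dp = 20L,
         ad_alt = 1L),
    ## unrelated sample is a high-quality (likely) carrier
    list(site = "S_likelycarr", sample = "c1", gt = "het"),
    list(site = "S_likelycarr", sample = "u1", gt = "het", dp = 30L),
    ## unrelated carrier at allele balance 0.1: possible but not likely
    list(site = "S_posscarr", sample = "c1", gt = "het"),
    list(site = "S_posscarr", sample = "u1", gt = "het", dp = 30L,
         ad_alt = 3L),
    ## only a sibling carries the allele: family exemption
    list(site = "S_sibcarr", sample = "c1", gt = "het"),
    list(site = "S_sibcarr", sample = "c2", gt = "het"),
    ## X rules: males must be hemizygous-alt
    list(site = "S_xmale_hemi", sample = "c1", gt = "hemizygous_alt"),
    list(site = "S_xmale_het", sample = "c1", gt = "het"),
    ## high-quality grandparental carrier -> missed-het routing
    list(site = "S_gpsupport", sample = "c1", gt = "het"),
    list(site = "S_gpsupport", sample = "gpf", gt = "het", dp = 20L,
         gq = 40L),
    ## third-generation allele balance below 0.3
    list(site = "S_lowab", sample = "c1", gt = "het", dp = 15L,
         ad_alt = 4L),
    ## parental depth below 12
    list(site = "S_lowdepth", sample = "c1", gt = "het"),
    list(site = "S_lowdepth", sample = "dad", gt = "hom_ref", dp = 10L),
    list(site = "S_filtered", sample = "c1", gt = "het"),
    list(site = "S_lcr", sample = "c1", gt = "het"),
    list(site = "S_homalt", sample = "c1", gt = "hom_alt")
  )
  list(ped = ped, cohort = toy_cohort(sites, calls))
}

test_that("candidate filters fire in order with recorded reasons", {
  fx <- discovery_fixture()
  cand <- find_candidates(fx$cohort, fx$ped)
  row <- function(site, child = "c1")
    cand[cand$site_id == site & cand$child_id == child, ]
  expect_equal(row("S_clean")$status, "candidate")
  expect_equal(row("S_paltread")$first_fail, "parental_alt_reads")
  expect_equal(row("S_likelycarr")$first_fail, "likely_carrier")
  ## possible-but-not-likely carrier survives the cohort screen
  expect_equal(row("S_posscarr")$status, "candidate")
  ## sibling carriers are exempt
  expect_equal(row("S_sibcarr")$status, "candidate")
  ## X chromosome: hemizygous-alt male passes, het male fails
  expect_equal(row("S_xmale_hemi")$status, "candidate")
  expect_equal(row("S_xmale_het")$first_fail, "child_genotype")
  expect_equal(row("S_lowdepth")$first_fail, "depth")
  expect_equal(row("S_filtered")$first_fail, "site_filter")
  expect_equal(row("S_lcr")$first_fail, "lcr")
  expect_equal(row("S_homalt")$first_fail, "child_genotype")
  ## every rejected candidate has exactly one failing filter in its trail,
  ## and it is the last one recorded
  rej <- cand[cand$status == "rejected", ]
  nfails <- lengths(regmatches(rej$trail, gregexpr(":F", rej$trail)))
  expect_true(all(nfails == 1L))
  expect_true(all(grepl(":F$", rej$trail)))
})

test_that("carrier_status separates possible from likely carriers", {
  fx <- discovery_fixture()
  cs <- carrier_status(fx$cohort, "S_posscarr", "c1", fx$ped)
  expect_equal(cs$possible, "u1")
  expect_equal(cs$likely, character())
  cs2 <- carrier_status(fx$cohort, "S_likelycarr", "c1", fx$ped)
  expect_equal(cs2$likely, "u1")
  cs3 <- carrier_status(fx$cohort, "S_sibcarr", "c1", fx$ped)
  expect_equal(cs3$possible, character())
  expect_true(all(cs3$likely %in% cs3$possible))
})

test_that("third-generation filters enforce AB, carriers and grandparents", {
  fx <- discovery_fixture()
  cand <- find_candidates(fx$cohort, fx$ped)
  g3 <- cand[cand$status == "candidate" & cand$generation == "G3", ]
  out <- gen3_filters(g3, fx$cohort, fx$ped)
  row <- function(site) out[out$site_id == site, ]
  expect_equal(row("S_clean")$status, "validated")
  ## possible carrier in the rest of the cohort rejects a G3 DNM
  expect_equal(row("S_posscarr")$rejection_reason, "possible_carrier")
  ## grandparental support routes to the missed-het tally
  expect_equal(row("S_gpsupport")$rejection_reason, "grandparental_support")
  expect_true(row("S_gpsupport")$mhr_flag)
  expect_equal(row("S_lowab")$rejection_reason, "low_allele_balance")
  mhr <- estimate_mhr(out)
  expect_equal(unname(mhr$counts["supported"]), 1L)
})

test_that("transmission validation uses the median allele balance", {
  ped <- toy_pedigree()
  sites <- rbind(toy_site("T_good", pos = 1000L),
                 toy_site("T_lowmed", pos = 2000L),
                 toy_site("T_none", pos = 3000L))
  calls <- list(
    list(site = "T_good", sample = "dad", gt = "het"),
    list(site = "T_good", sample = "c1", gt = "het", dp = 20L, ad_alt = 9L),
    list(site = "T_good", sample = "c2", gt = "het", dp = 20L, ad_alt = 10L),
    list(site = "T_good", sample = "c3", gt = "het", dp = 25L, ad_alt = 7L),
    ## transmissions at AB 0.25 and 0.31: median 0.28 < 0.3
    list(site = "T_lowmed", sample = "dad", gt = "het"),
    list(site = "T_lowmed", sample = "c1", gt = "het", dp = 20L,
         ad_alt = 5L),
    list(site = "T_lowmed", sample = "c2", gt = "het", dp = 100L,
         ad_alt = 31L),
    ## no child passes depth
    list(site = "T_none", sample = "dad", gt = "het"),
    list(site = "T_none", sample = "c1", gt = "het", dp = 8L)
  )
  cohort <- toy_cohort(sites, calls)
  cand <- find_candidates(cohort, ped)
  g2 <- cand[cand$generation == "G2" & cand$status == "candidate", ]
  out <- validate_transmission(g2, cohort, ped)
  row <- function(site) out[out$site_id == site, ]
  expect_equal(row("T_good")$status, "validated")
  expect_equal(row("T_good")$median_transmission_ab, 0.45)
  expect_equal(row("T_lowmed")$status, "rejected")
  expect_equal(row("T_lowmed")$rejection_reason, "low_transmission_ab")
  expect_equal(row("T_lowmed")$median_transmission_ab, 0.28)
  expect_equal(row("T_none")$rejection_reason, "no_transmission")
  ## small-sibship exclusion knob
  out2 <- validate_transmission(g2, cohort, ped,
                                dnm_params(min_g3_for_transmission = 5L))
  expect_true(all(out2$status == "excluded_small_family"))
})

test_that("deep-read FPR flags >= 2 supporting reads only", {
  ped <- toy_pedigree()
  g2 <- data.frame(site_id = c("A", "B"), child_id = "dad",
                   chrom = "chr1", pos = c(100L, 200L), ref = "C",
                   alt = "T", stringsAsFactors = FALSE)
  deep <- data.frame(sample_id = c("gpf", "gpf"), chrom = "chr1",
                     pos = c(100L, 200L), allele = "T",
                     n_reads = c(1L, 2L), stringsAsFactors = FALSE)
  est <- estimate_fpr(g2, deep, deep_g2 = "dad", ped)
  expect_equal(unname(est$counts), c(1L, 2L))
  expect_equal(est$fpr, 0.5)
  expect_error(estimate_fpr(g2, deep, deep_g2 = "mom", ped), "no DNMs")
})

test_that("zero-noise discovery recovers the simulated truth exactly", {
  sim <- zero_noise_sim()
  cs <- zero_noise_callset()
  tr <- sim$truth
  ## third generation: truth = G3 single-gamete DNMs plus every mosaic
  ## transmission (child, site) pair
  g3_truth <- c(
    paste(tr$chrom, tr$pos, tr$carrier_id)[
      tr$class == "germline_single_gamete" & grepl("_C\\d+$", tr$carrier_id)],
    unlist(lapply(which(tr$class == "postpgcs_mosaic"), function(i) {
      carr <- truth_carriers(tr[i, ])
      if (length(carr)) paste(tr$chrom[i], tr$pos[i], carr) else character()
    })))
  g3_called <- with(cs$g3[cs$g3$status == "validated", ],
                    paste(chrom, pos, child_id))
  expect_setequal(g3_called, g3_truth)  # precision = recall = 1
  ## second generation: truth = G2-carrier events with >= 1 transmission
  g2_rows <- tr[tr$class %in% c("germline_single_gamete", "gonosomal") &
                  grepl("_G2[FM]$", tr$carrier_id), ]
  g2_truth <- paste(g2_rows$chrom, g2_rows$pos, g2_rows$carrier_id)[
    nzchar(g2_rows$transmitted_to)]
  g2_called <- with(cs$g2[cs$g2$status == "validated", ],
                    paste(chrom, pos, child_id))
  expect_setequal(g2_called, g2_truth)
  ## zero-noise error rates are exactly zero
  expect_equal(cs$mhr$mhr, 0)
  expect_equal(cs$fpr$fpr, 0)
})

test_that("tightening thresholds never enlarges the candidate set", {
  sim <- zero_noise_sim()
  base <- find_candidates(sim$cohort, sim$pedigree)
  base_set <- with(base[base$status == "candidate", ],
                   paste(site_id, child_id))
  for (p in list(dnm_params(min_depth = 20L),
                 dnm_params(min_gq = 60L),
                 dnm_params(max_parent_alt_reads = -1L))) {
    tight <- find_candidates(sim$cohort, sim$pedigree, p)
    tight_set <- with(tight[tight$status == "candidate", ],
                      paste(site_id, child_id))
    expect_true(all(tight_set %in% base_set))
  }
  ## and on the G3 allele-balance threshold
  cs <- zero_noise_callset()
  g3c <- cs$candidates[cs$candidates$status == "candidate" &
                         cs$candidates$generation == "G3", ]
  loose <- gen3_filters(g3c, sim$cohort, sim$pedigree, dnm_params())
  strict <- gen3_filters(g3c, sim$cohort, sim$pedigree,
                         dnm_params(min_ab_g3 = 0.4))
  expect_true(all(strict$site_id[strict$status == "validated"] %in%
                    loose$site_id[loose$status == "validated"]))
})

test_that("MHR and FPR estimates recover the configured error rates", {
  sim <- noisy_sim()
  cs <- noisy_callset()
  cfg <- sim$config
  ## missed-heterozygote rate within 3 binomial SEs of the configured 0.4%
  n <- unname(cs$mhr$counts["total"])
  se <- sqrt(cfg$mhr_rate * (1 - cfg$mhr_rate) / n)
  expect_lt(abs(cs$mhr$mhr - cfg$mhr_rate), 3 * se)
  ## false-positive rate within 3 binomial SEs of the configured 4.5%
  nf <- unname(cs$fpr$counts["total"])
  sef <- sqrt(cfg$fpr_rate * (1 - cfg$fpr_rate) / nf)
  expect_lt(abs(cs$fpr$fpr - cfg$fpr_rate), 3 * sef)
  ## and the truth bookkeeping agrees: flagged DNMs are truth false
  ## positives
  tr <- sim$truth
  g2v <- cs$g2[cs$g2$status == "validated" &
                 cs$g2$child_id %in% sim$deep_g2, ]
  tcls <- tr$class[match(paste(g2v$chrom, g2v$pos),
                         paste(tr$chrom, tr$pos))]
  flagged <- vapply(seq_len(nrow(g2v)), function(i) {
    par <- stats::na.omit(unname(dnmkit:::parents_of(sim$pedigree,
                                                     g2v$child_id[i])))
    any(sim$deep_reads$sample_id %in% par &
          sim$deep_reads$pos == g2v$pos[i] &
          sim$deep_reads$n_reads >= 2)
  }, logical(1))
  expect_true(all(tcls[flagged] == "false_positive"))
})
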