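test_that("frequency tables are valid, deterministic, and symmetric in the limit", {
  pan <- tiny_panel()
  f1 <- sample_frequency_table(pan, concentration = 1.5, seed = 4)
  f2 <- sample_frequency_table(pan, concentration = 1.5, seed = 4)
  expect_identical(f1, f2)
  sums <- tapply(f1$frequency, f1$marker, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  ## uniform limit
  fu <- sample_frequency_table(pan, concentration = Inf, seed = 4)
  expect_true(all(abs(fu$frequency[fu$marker == "L1"] - 1 / 8) < 1e-12))
  ## Dirichlet symmetry: per-allele mean over draws ~ 1/k within 3 s.e.
  draws <- vapply(1:300, function(s)
    sample_frequency_table(pan, concentration = 1.5,
                           seed = s)$frequency[1], numeric(1))
  k <- 8
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 1 / k), 3 * se)
  expect_error(sample_frequency_table(pan, concentration = -1))
})

test_that("genotype simulation honours Hardy-Weinberg with inbreeding", {
  freqs <- validate_freqs(data.frame(marker = "L1",
                                     allele = c("8", "9"),
                                     frequency = c(0.5, 0.5)))
  prof <- simulate_genotypes(freqs, 2e4, f = 0, seed = 8)
  het <- mean(prof$allele1 != prof$allele2)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / 2e4))
  ## fully inbred limit: no heterozygotes
  prof1 <- simulate_genotypes(freqs, 500, f = 1, seed = 8)
  expect_true(all(prof1$allele1 == prof1$allele2))
  ## intermediate F: heterozygosity (1 - F) * 2pq
  prof5 <- simulate_genotypes(freqs, 2e4, f = 0.5, seed = 9)
  het5 <- mean(prof5$allele1 != prof5$allele2)
  expect_lt(abs(het5 - 0.25), 3 * sqrt(0.25 * 0.75 / 2e4))
})

test_that("forced LD pairs honour D = 0 independence and reject infeasible D", {
  pan <- tiny_panel()
  freqs <- sample_frequency_table(pan, concentration = 3, seed = 14)
  prof <- simulate_genotypes(freqs, 800, seed = 15,
                             ld_pair = list(locus_a = "L1", locus_b = "L2",
                                            D = 0))
  ## two-locus genotype independence: chi-square on the contingency of
  ## genotype ids
  ga <- prof[prof$marker == "L1", ]; gb <- prof[prof$marker == "L2", ]
  gid_a <- paste(ga$allele1, ga$allele2)[order(ga$sample_id)]
  gid_b <- paste(gb$allele1, gb$allele2)[order(gb$sample_id)]
  keep_a <- names(which(table(gid_a) >= 20))
  keep_b <- names(which(table(gid_b) >= 20))
  sub <- gid_a %in% keep_a & gid_b %in% keep_b
  cs <- suppressWarnings(chisq.test(table(gid_a[sub], gid_b[sub]),
                                    simulate.p.value = TRUE, B = 500))
  expect_gt(cs$p.value, 0.001)
  expect_error(
    simulate_genotypes(freqs, 10, seed = 1,
                       ld_pair = list(locus_a = "L1", locus_b = "L2",
                                      D = 0.9)),
    class = "kinstr_sim_error")
})

test_that("noise-free model limit yields exact sizes and equal heights", {
  pan <- tiny_panel()
  prof <- make_profiles(list(S1 = list(L1 = c("8", "12"),
                                       L2 = c("11", "11"))))
  m <- epg_model(height_dispersion = Inf, sizing_sd = 0,
                 stutter_sd = 0,
                 phr_decay = c(L1 = 0, L2 = 0, L3 = 0),
                 stutter_ratio = c(L1 = 0, L2 = 0, L3 = 0))
  pk <- simulate_epg(prof, pan, template_pg = 500, model = m, seed = 2)
  expect_equal(nrow(pk), 3)   # two het peaks + one hom peak, no stutter
  l1 <- pk[pk$marker == "L1", ]
  expect_equal(sort(l1$size_nt),
               sort(unname(pan$loci$L1$actual_size_nt[c("8", "12")])))
  expect_equal(l1$height_rfu[1], l1$height_rfu[2])
  hom <- pk[pk$marker == "L2", ]
  expect_equal(hom$height_rfu, 2 * l1$height_rfu[1])
})

test_that("simulated peak tables are seed-reproducible with truth flags", {
  pan <- tiny_panel()
  freqs <- sample_frequency_table(pan, concentration = 2, seed = 3)
  prof <- simulate_genotypes(freqs, 25, seed = 5)
  p1 <- simulate_epg(prof, pan, template_pg = 500, seed = 6)
  p2 <- simulate_epg(prof, pan, template_pg = 500, seed = 6)
  expect_identical(p1, p2)
  expect_true(all(c("is_stutter", "true_allele") %in% names(p1)))
  ## stutter sits one repeat unit below its parent
  st <- p1[p1$is_stutter, ]
  expect_true(all(allele_value(st$allele) ==
                    allele_value(st$true_allele) - 1))
})

test_that("expected heterozygote imbalance follows the exponential decay", {
  ## lambda chosen so E[PHR] = 50% at delta = 16 nt
  pan <- tiny_panel()
  lam <- -log(0.5) / 16
  prof <- make_profiles(setNames(lapply(1:400, function(i)
    list(L1 = c("8", "12"))), paste0("S", 1:400)))   # delta = 16 nt
  m <- epg_model(phr_decay = c(L1 = lam, L2 = lam, L3 = lam),
                 stutter_ratio = c(L1 = 0, L2 = 0, L3 = 0), stutter_sd = 0)
  pk <- simulate_epg(prof, pan, template_pg = 500, model = m, seed = 13)
  phr <- vapply(split(pk, pk$sample_id), function(g)
    100 * min(g$height_rfu) / max(g$height_rfu), numeric(1))
  ## gamma height noise makes the realised mean PHR sit slightly above
  ## the mean-ratio target; 3 points covers it comfortably at n = 400
  expect_lt(abs(mean(phr) - 50), 3)
})

test_that("dilution series drops out monotonically and is reproducible", {
  pan <- tiny_panel()
  prof <- make_profiles(list(CTRL = list(L1 = c("8", "12"),
                                         L2 = c("10", "13"),
                                         L3 = c("15", "20"))))
  one <- simulate_dilution_series(prof, pan, levels_pg = 500,
                                  replicates = 1, seed = 3)
  expect_length(one, 1)
  s1 <- simulate_dilution_series(prof, pan, replicates = 2, seed = 3)
  s2 <- simulate_dilution_series(prof, pan, replicates = 2, seed = 3)
  expect_identical(s1, s2)
  expect_length(s1, 10)
  expect_error(simulate_dilution_series(prof, pan, levels_pg = c(100, 200),
                                        replicates = 1, seed = 1),
               class = "kinstr_sim_error")
})

test_that("severe degradation suppresses long amplicons first", {
  pan <- sureid_panel()
  loci <- names(autosomal_panel(pan)$loci)
  ## one fully heterozygous profile across all loci
  prof <- make_profiles(list(D = setNames(lapply(loci, function(l) {
    pan$loci[[l]]$ladder_alleles[c(1, 3)]
  }), loci)))
  m <- epg_model(degradation_index = 50)
  det <- numeric(0); msize <- numeric(0)
  for (s in 1:30) {
    pk <- simulate_epg(prof, pan, template_pg = 120, model = m,
                       seed = 1000 + s)
    pk <- pk[!pk$is_stutter & pk$height_rfu >= 50, ]
    for (l in loci) {
      det <- c(det, sum(pk$marker == l))
      msize <- c(msize, mean(allele_size(pan, l,
                                         pan$loci[[l]]$ladder_alleles[c(1, 3)])))
    }
  }
  ## completeness falls with amplicon size: strong negative rank correlation
  rho <- cor(tapply(det, msize, mean), sort(unique(msize)),
             method = "spearman")
  expect_lt(rho, -0.5)
})
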