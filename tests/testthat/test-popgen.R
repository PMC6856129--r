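test_that("allele frequencies are chromosome-count proportions", {
  prof <- make_profiles(list(S1 = list(L = c("A", "A")),
                             S2 = list(L = c("A", "B"))))
  f <- allele_frequencies(prof)
  expect_equal(f$frequency[f$allele == "A"], 0.75)
  expect_equal(f$frequency[f$allele == "B"], 0.25)
  ## a singleton among 500 samples is 1/1000
  big <- make_profiles(setNames(lapply(1:500, function(i) {
    list(L = if (i == 1) c("7", "12") else c("12", "12"))
  }), sprintf("S%03d", 1:500)))
  fb <- allele_frequencies(big)
  expect_equal(fb$frequency[fb$allele == "7"], 0.001)
  expect_error(allele_frequencies(prof[0, ]), class = "kinstr_freq_error")
})

test_that("locus summary reproduces the hand-computed four-sample table", {
  ## genotypes AA, AB, AB, BB
  prof <- make_profiles(list(S1 = list(L = c("10", "10")),
                             S2 = list(L = c("10", "11")),
                             S3 = list(L = c("10", "11")),
                             S4 = list(L = c("11", "11"))))
  s <- locus_forensic_summary(prof, "L")
  expect_equal(s$h, 0.5)
  expect_equal(s$MP, 0.375)     # 0.25^2 + 0.5^2 + 0.25^2
  expect_equal(s$PD, 0.625)
  expect_equal(s$TPI, 1.0)
  expect_equal(s$PE, 0.1875)    # 0.25 * (1 - 2 * 0.5 * 0.25)
  expect_equal(s$PIC, 0.375)    # 1 - 0.5 - 2 * 0.0625
  expect_equal(s$k, 2)
  ## PIC bounded by expected heterozygosity
  expect_lte(s$PIC, 1 - sum(s$freqs^2))
})

test_that("degenerate loci are handled: monomorphic and fully heterozygous", {
  mono <- make_profiles(list(S1 = list(L = c("9", "9")),
                             S2 = list(L = c("9", "9"))))
  s <- locus_forensic_summary(mono, "L")
  expect_equal(s$h, 0)
  expect_equal(s$MP, 1)
  expect_equal(s$PD, 0)
  expect_equal(s$PIC, 0)
  allhet <- make_profiles(list(S1 = list(L = c("8", "9")),
                               S2 = list(L = c("8", "9"))))
  expect_warning(s2 <- locus_forensic_summary(allhet, "L"),
                 "TPI undefined")
  expect_true(is.infinite(s2$TPI))
  expect_error(locus_forensic_summary(mono[1, ], "L"),
               class = "kinstr_popgen_error")
})

test_that("summary statistics converge to allele-frequency closed forms under HWE", {
  pan <- tiny_panel()
  freqs <- data.frame(marker = "L1", allele = c("8", "9"),
                      frequency = c(0.5, 0.5))
  prof <- simulate_genotypes(freqs, 2e4, seed = 31)
  s <- locus_forensic_summary(prof, "L1")
  se_h <- sqrt(0.5 * 0.5 / 2e4)
  expect_lt(abs(s$h - 0.5), 3 * se_h)
  ## HWE-expected MP for p = (.5, .5): 2 * .25^2 + .5^2 = 0.375
  expect_lt(abs(s$MP - 0.375), 0.02)
  s_hwe <- locus_forensic_summary(prof, "L1", hwe_expected = TRUE)
  expect_lt(abs(s_hwe$MP - 0.375), 0.01)
})

test_that("combined indices multiply in log space and satisfy identities", {
  prof <- make_profiles(list(S1 = list(L = c("10", "10")),
                             S2 = list(L = c("10", "11")),
                             S3 = list(L = c("10", "11")),
                             S4 = list(L = c("11", "11"))))
  s <- locus_forensic_summary(prof, "L")
  ## single locus: identities
  ci1 <- combined_indices(list(s))
  expect_equal(ci1$CMP, s$MP)
  expect_equal(ci1$CPE, s$PE)
  expect_equal(ci1$CPI, s$TPI)
  ## two loci multiply
  ci2 <- combined_indices(list(s, s))
  expect_equal(ci2$CMP, s$MP^2, tolerance = 1e-12)
  expect_equal(ci2$CPE, 1 - (1 - s$PE)^2, tolerance = 1e-12)
  ## synthetic many-locus scale check: 22 loci at MP ~0.06 lands near 1e-27
  fake <- lapply(1:22, function(i) list(MP = 0.06, PE = 0.5, TPI = 2))
  ci22 <- combined_indices(fake)
  expect_equal(ci22$log10_CMP, 22 * log10(0.06), tolerance = 1e-12)
  expect_lt(ci22$CMP, 1e-26)
  expect_gt(ci22$CMP, 1e-28)
})

test_that("paternity posterior follows the Bayesian update formula", {
  expect_equal(paternity_posterior(1, 0.5)$percent, 50)
  expect_equal(paternity_posterior(10, 0)$percent, 0)
  expect_equal(paternity_posterior(10, 1)$percent, 100)
  expect_error(paternity_posterior(10, 1.2), class = "kinstr_popgen_error")
  expect_error(paternity_posterior(0, 0.5), class = "kinstr_popgen_error")
  ## W(0.5) = CPI / (CPI + 1), and W strictly increasing in the prior
  cpi <- 1234.5
  expect_equal(paternity_posterior(cpi, 0.5)$posterior, cpi / (cpi + 1),
               tolerance = 1e-12)
  w <- vapply(seq(0.05, 0.95, by = 0.05),
              function(p) paternity_posterior(cpi, p)$posterior, numeric(1))
  expect_true(all(diff(w) > 0))
})

test_that("most common profile frequency equals the brute-force heterozygote maximum", {
  one <- data.frame(marker = "L", allele = c("a", "b"),
                    frequency = c(0.5, 0.5))
  expect_equal(most_common_profile_frequency(validate_freqs(one))$frequency,
               0.5)
  two <- rbind(one, data.frame(marker = "M", allele = c("a", "b"),
                               frequency = c(0.5, 0.5)))
  expect_equal(most_common_profile_frequency(validate_freqs(two))$frequency,
               0.25)
  ## randomized tables vs exhaustive per-locus pair search
  set.seed(77)
  for (rep in 1:5) {
    freqs <- do.call(rbind, lapply(1:6, function(l) {
      k <- sample(3:6, 1)
      p <- rgamma(k, 1); p <- p / sum(p)
      data.frame(marker = paste0("L", l), allele = as.character(seq_len(k)),
                 frequency = p)
    }))
    got <- most_common_profile_frequency(validate_freqs(freqs))$frequency
    brute <- prod(vapply(split(freqs, freqs$marker), function(f) {
      max(combn(f$frequency, 2, function(x) 2 * x[1] * x[2]))
    }, numeric(1)))
    expect_equal(got, brute, tolerance = 1e-12)
  }
})

test_that("pairwise matching counts full and partial locus matches", {
  prof <- make_profiles(list(
    S1 = list(L1 = c("8", "9"), L2 = c("10", "11")),
    S2 = list(L1 = c("8", "9"), L2 = c("10", "11")),
    S3 = list(L1 = c("8", "10"), L2 = c("12", "13"))))
  m <- pairwise_matching(prof)
  expect_equal(m$max_full, 2)          # duplicated profile matches everywhere
  expect_equal(m$max_partial, 2)
  ## {8,9} vs {8,10}: partial but not full
  two <- make_profiles(list(S1 = list(L1 = c("8", "9")),
                            S2 = list(L1 = c("8", "10"))))
  m2 <- pairwise_matching(two)
  expect_equal(m2$max_full, 0)
  expect_equal(m2$max_partial, 1)
  expect_error(pairwise_matching(two[two$sample_id == "S1", ]),
               class = "kinstr_popgen_error")
})

test_that("observed match distribution agrees with the closed-form match probability", {
  ## mean full matches per pair ~ sum of per-locus MP under HWE simulation
  pan <- tiny_panel()
  freqs <- sample_frequency_table(pan, concentration = 2, seed = 41)
  prof <- simulate_genotypes(freqs, 80, seed = 42)
  m <- pairwise_matching(prof)
  expected <- sum(vapply(unique(prof$marker), function(l)
    locus_forensic_summary(prof, l)$MP, numeric(1)))
  counts <- rep(as.integer(names(m$full_histogram)),
                as.integer(m$full_histogram))
  expect_lt(abs(mean(counts) - expected), 0.1)
})
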