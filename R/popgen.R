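#' Allele frequencies from genotype profiles
#'
#' Counts allele observations over the `2N` chromosomes of the samples
#' called at each locus (no-call rows do not contribute to that locus's
#' `N`).
#'
#' @param profiles a `str_profiles` data.frame ([read_genotypes()]).
#' @param loci optional subset of loci; default all loci present.
#' @return a `str_freqs` data.frame (`marker`, `allele`, `frequency`), with
#'   an `n_samples` attribute giving per-locus sample counts.
#' @export
allele_frequencies <- function(profiles, loci = NULL) {
  p <- profiles[!is.na(profiles$allele1) & !is.na(profiles$allele2), ]
  if (!is.null(loci)) p <- p[p$marker %in% loci, ]
  if (!nrow(p)) {
    stop_kinstr("no called genotypes to count", class = "kinstr_freq_error")
  }
  out <- do.call(rbind, lapply(split(p, p$marker), function(g) {
    obs <- c(g$allele1, g$allele2)
    tab <- table(obs)
    data.frame(marker = g$marker[1], allele = names(tab),
               frequency = as.numeric(tab) / length(obs),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$marker, allele_value(out$allele)), ]
  rownames(out) <- NULL
  n_samples <- vapply(split(p, p$marker), nrow, integer(1))
  structure(validate_freqs(out), n_samples = n_samples)
}

#' Per-locus forensic summary statistics
#'
#' The standard identity/kinship panel statistics for one locus, computed
#' from observed genotype proportions `f_g` and allele frequencies `p_i`:
#' observed heterozygosity `h`; homozygosity `H = 1 - h`; match probability
#' `MP = sum f_g^2`; power of discrimination `PD = 1 - MP`; power of
#' exclusion `PE = h^2 (1 - 2 h H^2)`; typical paternity index
#' `TPI = 1 / (2H)`; and polymorphic information content
#' `PIC = 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2`. MP follows the
#' observed-proportion convention of forensic summary software; set
#' `hwe_expected = TRUE` to use Hardy-Weinberg expected genotype
#' proportions instead.
#'
#' @param profiles a `str_profiles` data.frame.
#' @param locus locus name.
#' @param hwe_expected use HWE-expected rather than observed genotype
#'   proportions for MP/PD.
#' @return list of class `locus_summary`: `locus`, `n`, `k` (allele count),
#'   `h`, `H`, `MP`, `PD`, `PE`, `TPI`, `PIC`, `freqs`.
#' @export
locus_forensic_summary <- function(profiles, locus, hwe_expected = FALSE) {
  g <- profiles[profiles$marker == locus & !is.na(profiles$allele1), ]
  n <- nrow(g)
  if (n < 2) {
    stop_kinstr("need >= 2 called samples at ", locus,
                class = "kinstr_popgen_error")
  }
  het <- g$allele1 != g$allele2
  h <- mean(het)
  H <- 1 - h
  obs <- c(g$allele1, g$allele2)
  p <- as.numeric(table(obs)) / (2 * n)
  names(p) <- names(table(obs))
  if (hwe_expected) {
    ## MP from HWE genotype probabilities: p_i^2 homs and 2 p_i p_j hets
    het_p <- 2 * outer(p, p)[upper.tri(diag(length(p)))]
    mp <- sum(p^4) + sum(het_p^2)
  } else {
    gid <- paste(g$allele1, g$allele2)
    f_g <- as.numeric(table(gid)) / n
    mp <- sum(f_g^2)
  }
  pe <- h^2 * (1 - 2 * h * H^2)
  tpi <- if (H == 0) {
    warning("all samples heterozygous at ", locus,
            ": TPI undefined (reported Inf)")
    Inf
  } else 1 / (2 * H)
  pp <- outer(p^2, p^2)
  pic <- 1 - sum(p^2) - sum(pp[upper.tri(pp)]) * 2
  structure(list(locus = locus, n = n, k = length(p), h = h, H = H,
                 MP = mp, PD = 1 - mp, PE = pe, TPI = tpi,
                 PIC = pic, freqs = p),
            class = "locus_summary")
}

#' @export
print.locus_summary <- function(x, ...) {
  cat(sprintf(
    "%s: n=%d k=%d h=%.3f MP=%.4f PD=%.4f PE=%.4f TPI=%.3f PIC=%.4f\n",
    x$locus, x$n, x$k, x$h, x$MP, x$PD, x$PE, x$TPI, x$PIC))
  invisible(x)
}

#' @rdname locus_forensic_summary
#' @param loci loci to summarise (default: all loci in `profiles`).
#' @return `forensic_summaries()`: a list of `locus_summary` objects.
#' @export
forensic_summaries <- function(profiles, loci = NULL,
                               hwe_expected = FALSE) {
  loci <- loci %||% sort(unique(profiles$marker))
  out <- lapply(loci, function(l)
    locus_forensic_summary(profiles, l, hwe_expected = hwe_expected))
  names(out) <- loci
  out
}

#' Combined multi-locus indices
#'
#' Multiplies per-locus statistics across independent loci, in log10 space
#' to survive the tiny magnitudes involved (combined match probabilities
#' reach the 1e-27 scale for 22-locus panels): combined match probability
#' `CMP = prod MP_l`; combined power of exclusion
#' `CPE = 1 - prod (1 - PE_l)`; combined typical paternity index
#' `CPI = prod TPI_l`.
#'
#' @param summaries list of `locus_summary` objects
#'   ([forensic_summaries()]).
#' @return list of class `combined_indices`: `CMP`, `CPE`, `CPI`,
#'   `log10_CMP`, `log10_CPI`, `one_in` (1/CMP, the "1 in X" report
#'   figure), `n_loci`.
#' @export
combined_indices <- function(summaries) {
  mp <- vapply(summaries, `[[`, numeric(1), "MP")
  pe <- vapply(summaries, `[[`, numeric(1), "PE")
  tpi <- vapply(summaries, `[[`, numeric(1), "TPI")
  log10_cmp <- sum(log10(mp))
  log10_cpi <- sum(log10(tpi))
  structure(list(CMP = 10^log10_cmp,
                 CPE = 1 - exp(sum(log1p(-pe))),
                 CPI = 10^log10_cpi,
                 log10_CMP = log10_cmp, log10_CPI = log10_cpi,
                 one_in = 10^(-log10_cmp), n_loci = length(summaries)),
            class = "combined_indices")
}

#' @export
print.combined_indices <- function(x, ...) {
  cat(sprintf("combined indices over %d loci:\n", x$n_loci))
  cat(sprintf("  CMP = %.3g (1 in %.3g)\n", x$CMP, x$one_in))
  cat(sprintf("  CPE = %.9f\n", x$CPE))
  cat(sprintf("  CPI = %.2f\n", x$CPI))
  invisible(x)
}

#' Posterior probability of paternity
#'
#' Bayesian update of a prior probability of paternity by the combined
#' paternity index: `W = CPI * Pr / (CPI * Pr + 1 - Pr)`, reported as a
#' percentage. The formatted value uses 8 decimal places with half-up
#' rounding, the convention of paternity reports.
#'
#' @param cpi combined paternity index (> 0).
#' @param prior prior probability of paternity in `[0, 1]`.
#' @return list with `posterior` (probability in `[0,1]`), `percent`
#'   (numeric percentage) and `percent_8dp` (half-up rounded to 8
#'   decimals).
#' @examples
#' paternity_posterior(93835307.21, 0.5)$percent_8dp  # 99.99999893
#' @export
paternity_posterior <- function(cpi, prior) {
  if (!is.finite(cpi) || cpi <= 0) {
    stop_kinstr("cpi must be positive and finite",
                class = "kinstr_popgen_error")
  }
  if (prior < 0 || prior > 1) {
    stop_kinstr("prior must lie in [0, 1]", class = "kinstr_popgen_error")
  }
  w <- cpi * prior / (cpi * prior + 1 - prior)
  list(posterior = w, percent = 100 * w,
       percent_8dp = round_half_up(100 * w, 8))
}

#' Frequency of the theoretical most common profile
#'
#' The product over loci of `2 p_(1) p_(2)`, where `p_(1) >= p_(2)` are the
#' two highest allele frequencies at each locus (ties broken by allele
#' label order): the frequency of the most common fully heterozygous
#' profile. Computed in log10 space.
#'
#' @param freqs a `str_freqs` data.frame.
#' @return list with `frequency`, `log10_frequency`, `one_in`, and
#'   `profile` (data.frame of the locus-wise allele pairs).
#' @export
most_common_profile_frequency <- function(freqs) {
  per_locus <- lapply(split(freqs, freqs$marker), function(f) {
    f <- f[order(-f$frequency, order_alleles(f$allele)), ]
    if (nrow(f) < 2) {
      stop_kinstr("locus ", f$marker[1], " has fewer than two alleles",
                  class = "kinstr_freq_error")
    }
    data.frame(marker = f$marker[1], allele1 = f$allele[1],
               allele2 = f$allele[2],
               genotype_freq = 2 * f$frequency[1] * f$frequency[2],
               stringsAsFactors = FALSE)
  })
  prof <- do.call(rbind, per_locus)
  rownames(prof) <- NULL
  lg <- sum(log10(prof$genotype_freq))
  list(frequency = 10^lg, log10_frequency = lg, one_in = 10^(-lg),
       profile = prof)
}

#' Pairwise profile matching
#'
#' For every pair of samples, counts loci with an identical unordered
#' genotype (full match) and loci sharing at least one allele (partial
#' match). Loci uncalled in either member of a pair are skipped for that
#' pair.
#'
#' @param profiles a `str_profiles` data.frame with >= 2 samples.
#' @return list of class `match_report`: `max_full` and `max_partial`
#'   (maxima over pairs), `full_histogram` (named vector: distribution of
#'   full-match counts over pairs), `n_pairs`, `top_pairs` (data.frame of
#'   the pairs attaining `max_full`).
#' @export
pairwise_matching <- function(profiles) {
  samples <- unique(profiles$sample_id)
  ns <- length(samples)
  if (ns < 2) {
    stop_kinstr("need >= 2 samples", class = "kinstr_popgen_error")
  }
  loci <- unique(profiles$marker)
  full <- matrix(0L, ns, ns)
  part <- matrix(0L, ns, ns)
  for (l in loci) {
    g <- profiles[profiles$marker == l, ]
    i <- match(g$sample_id, samples)
    a1 <- rep(NA_character_, ns); a2 <- rep(NA_character_, ns)
    a1[i] <- g$allele1; a2[i] <- g$allele2
    called <- !is.na(a1)
    gid <- paste(a1, a2)
    eq <- outer(gid, gid, "==") & outer(called, called, "&")
    share <- (outer(a1, a1, "==") | outer(a1, a2, "==") |
                outer(a2, a1, "==") | outer(a2, a2, "=="))
    share[is.na(share)] <- FALSE
    full <- full + ifelse(eq, 1L, 0L)
    part <- part + ifelse(share, 1L, 0L)
  }
  ut <- upper.tri(full)
  fh <- table(factor(full[ut], levels = 0:length(loci)))
  best <- which(full == max(full[ut]) & ut, arr.ind = TRUE)
  structure(list(max_full = max(full[ut]), max_partial = max(part[ut]),
                 full_histogram = fh, n_pairs = sum(ut),
                 top_pairs = data.frame(sample_a = samples[best[, 1]],
                                        sample_b = samples[best[, 2]],
                                        stringsAsFactors = FALSE)),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "pairwise matching over %d pairs: max full-locus matches %d, max partial %d\n",
    x$n_pairs, x$max_full, x$max_partial))
  invisible(x)
}
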