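#' Electropherogram simulation model
#'
#' Parameter set for the peak-level simulator. The signal model is
#' copy-number driven: each allele contributes an effective template of
#' `template_pg / (2 * pg_per_copy)` genome copies, attenuated
#' multiplicatively by degradation (exponential decay in amplicon size at a
#' rate set by the degradation index) and by the amplification-efficiency
#' knob; the peak height is Gamma-distributed with shape equal to that
#' effective copy number and a fixed RFU-per-copy scale, so low-template
#' reactions are both weaker and noisier — the mechanism behind stochastic
#' dropout in dilution series. Heterozygote imbalance follows an
#' exponential decay in the allele size difference: the expected ratio of
#' the longer to the shorter allele's peak is `exp(-lambda * delta_nt)`.
#'
#' @param rfu_per_copy expected RFU contributed per effective template
#'   copy. The default (12) puts a 500 pg heterozygote peak near 900 RFU
#'   and calibrates the dilution series so that 125 pg yields complete
#'   profiles at the 50/150 RFU thresholds while 31 pg shows substantial
#'   dropout.
#' @param pg_per_copy template mass per haploid genome copy (pg); 3.3 pg is
#'   the standard human figure.
#' @param height_dispersion `NA` (default) makes the Gamma shape equal the
#'   effective copy number; a finite value fixes the shape regardless of
#'   template; `Inf` switches peak heights to their deterministic means
#'   (the noise-free limit).
#' @param phr_decay named numeric: per-locus imbalance rate lambda (per
#'   nt). `NULL` defers to [default_phr_decay()].
#' @param stutter_ratio named numeric: per-locus expected (n-1)-repeat
#'   stutter fraction. `NULL` defers to [default_stutter_ratios()].
#' @param stutter_sd s.d. of the per-peak stutter ratio.
#' @param sizing_sd s.d. (nt) of fragment-size measurement noise.
#' @param degradation_index ratio of small-amplicon (80 nt) to
#'   large-amplicon (220 nt) signal; 1 = undegraded. Values up to ~58 are
#'   seen in severely degraded skeletal samples.
#' @param efficiency global amplification-efficiency multiplier (inhibitor
#'   knob); 1 = uninhibited.
#' @param min_peak_rfu peaks below this height are not recorded.
#' @return list of class `epg_model`.
#' @export
epg_model <- function(rfu_per_copy = 12, pg_per_copy = 3.3,
                      height_dispersion = NA_real_, phr_decay = NULL,
                      stutter_ratio = NULL, stutter_sd = 0.02,
                      sizing_sd = 0.05, degradation_index = 1,
                      efficiency = 1, min_peak_rfu = 1) {
  stopifnot(rfu_per_copy > 0, pg_per_copy > 0, stutter_sd >= 0,
            sizing_sd >= 0, degradation_index >= 1, efficiency > 0)
  structure(list(rfu_per_copy = rfu_per_copy, pg_per_copy = pg_per_copy,
                 height_dispersion = height_dispersion,
                 phr_decay = phr_decay, stutter_ratio = stutter_ratio,
                 stutter_sd = stutter_sd, sizing_sd = sizing_sd,
                 degradation_index = degradation_index,
                 efficiency = efficiency, min_peak_rfu = min_peak_rfu),
            class = "epg_model")
}

#' Default per-locus imbalance and stutter parameters
#'
#' `default_phr_decay()` sets the imbalance rate so the expected
#' heterozygote peak-height ratio falls to ~45% at a 50 nt allele size
#' difference for the longest, most imbalance-prone locus (D21S2055, whose
#' wide allele range makes large size differences common) and to ~90% at a
#' typical 8 nt (two-repeat) difference elsewhere.
#' `default_stutter_ratios()` spans the range observed for tetranucleotide
#' multiplexes — lowest at D2S441 (3.8%), highest at D12S391 (16.15%) —
#' with the remaining loci spread so the grand mean is ~9.2%.
#'
#' @param panel a [kit_panel()].
#' @return named numeric vector over the panel's autosomal loci.
#' @export
default_phr_decay <- function(panel) {
  loci <- names(autosomal_panel(panel)$loci)
  lam <- setNames(rep(-log(0.90) / 8, length(loci)), loci)
  if ("D21S2055" %in% loci) lam["D21S2055"] <- -log(0.45) / 50
  lam
}

#' @rdname default_phr_decay
#' @export
default_stutter_ratios <- function(panel) {
  loci <- names(autosomal_panel(panel)$loci)
  sr <- setNames(rep(NA_real_, length(loci)), loci)
  if ("D2S441" %in% loci) sr["D2S441"] <- 0.038
  if ("D12S391" %in% loci) sr["D12S391"] <- 0.1615
  rest <- names(sr)[is.na(sr)]
  sr[rest] <- seq(0.060, 0.122, length.out = length(rest))
  sr
}

#' Draw a synthetic allele-frequency table
#'
#' Draws per-locus allele relative frequencies from a symmetric Dirichlet
#' over each locus's ladder alleles — a stand-in spectrum for populations
#' whose real frequency tables are not deposited. Smaller concentration
#' values give spikier spectra (one or two dominant alleles, a tail of rare
#' ones), as real STR loci show; `concentration = Inf` gives the uniform
#' table.
#'
#' @param panel a [kit_panel()] (amelogenin is skipped).
#' @param concentration symmetric Dirichlet concentration (> 0), or `Inf`
#'   for exactly uniform frequencies.
#' @param seed integer seed.
#' @return a `str_freqs` data.frame.
#' @export
sample_frequency_table <- function(panel, concentration = 1.5, seed = 1L) {
  stopifnot(concentration > 0)
  pan <- autosomal_panel(panel)
  set.seed(seed)
  out <- do.call(rbind, lapply(pan$loci, function(l) {
    k <- length(l$ladder_alleles)
    if (k < 2) {
      stop_kinstr("locus ", l$name, " has fewer than 2 ladder alleles",
                  class = "kinstr_sim_error")
    }
    p <- if (is.infinite(concentration)) rep(1 / k, k) else {
      x <- rgamma(k, concentration)
      x / sum(x)
    }
    data.frame(marker = l$name, allele = l$ladder_alleles, frequency = p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  validate_freqs(out)
}

## genotype draw at one locus: HWE with optional inbreeding F
## P(aa) = p_a^2 + F p_a (1 - p_a); P(ab) = 2 p_a p_b (1 - F)
draw_genotypes <- function(alleles, p, n, f) {
  a1 <- sample(alleles, n, replace = TRUE, prob = p)
  a2 <- sample(alleles, n, replace = TRUE, prob = p)
  if (f > 0) {
    ibd <- runif(n) < f
    a2[ibd] <- a1[ibd]
  }
  sort_genotype(a1, a2)
}

#' Simulate diploid genotype profiles
#'
#' Draws `n` individuals' genotypes locus by locus from an allele-frequency
#' table under Hardy-Weinberg proportions with optional inbreeding `F`
#' (genotype `(a,b)` has probability `p_a^2 + F p_a (1-p_a)` if `a = b`,
#' else `2 p_a p_b (1-F)`). Loci are independent unless a forced linkage-
#' disequilibrium pair is configured, in which case that pair's two-locus
#' genotypes are drawn by uniting two haplotypes whose frequencies deviate
#' from independence by `D` on the first-allele pair (the remaining
#' haplotype mass is spread proportionally, keeping both margins intact).
#'
#' @param freqs a `str_freqs` data.frame.
#' @param n number of individuals.
#' @param f inbreeding coefficient in `[0, 1]` (1 = fully inbred limit,
#'   no heterozygotes).
#' @param ld_pair optional `list(locus_a =, locus_b =, D =)` forcing
#'   disequilibrium `D` between the first (most frequent) alleles of the
#'   two loci.
#' @param seed integer seed.
#' @param sample_prefix prefix for generated sample ids.
#' @return a `str_profiles` data.frame.
#' @export
simulate_genotypes <- function(freqs, n, f = 0, ld_pair = NULL, seed = 1L,
                               sample_prefix = "S") {
  stopifnot(f >= 0, f <= 1, n >= 1)
  freqs <- validate_freqs(freqs)
  set.seed(seed)
  ids <- sprintf("%s%04d", sample_prefix, seq_len(n))
  ld_loci <- character()
  blocks <- list()
  if (!is.null(ld_pair)) {
    ld_loci <- c(ld_pair$locus_a, ld_pair$locus_b)
    if (!all(ld_loci %in% freqs$marker)) {
      stop_kinstr("ld_pair loci missing from frequency table",
                  class = "kinstr_sim_error")
    }
    blocks[[1]] <- draw_ld_pair(freqs, ld_pair, n)
  }
  per_locus <- lapply(split(freqs, freqs$marker), function(fl) {
    if (fl$marker[1] %in% ld_loci) return(NULL)
    g <- draw_genotypes(fl$allele, fl$frequency, n, f)
    data.frame(sample_id = ids, marker = fl$marker[1],
               allele1 = g$a1, allele2 = g$a2, stringsAsFactors = FALSE)
  })
  if (length(blocks)) {
    b <- blocks[[1]]
    per_locus <- c(per_locus, lapply(split(b, b$marker), function(x) {
      x$sample_id <- ids[x$row]
      x[, c("sample_id", "marker", "allele1", "allele2")]
    }))
  }
  out <- do.call(rbind, per_locus[!vapply(per_locus, is.null, logical(1))])
  out <- out[order(out$sample_id, out$marker), ]
  rownames(out) <- NULL
  class(out) <- c("str_profiles", "data.frame")
  out
}

## haplotype-frequency construction for a forced LD pair: D is added to the
## (first allele A1, first allele B1) haplotype; the deficit is spread over
## the other haplotypes of A1's row and B1's column proportionally so both
## allele-frequency margins are preserved.
draw_ld_pair <- function(freqs, ld_pair, n) {
  fa <- freqs[freqs$marker == ld_pair$locus_a, ]
  fb <- freqs[freqs$marker == ld_pair$locus_b, ]
  fa <- fa[order(-fa$frequency), ]; fb <- fb[order(-fb$frequency), ]
  pa <- fa$frequency; pb <- fb$frequency
  d <- ld_pair$D
  dmax <- min(pa[1] * (1 - pb[1]), (1 - pa[1]) * pb[1])
  dmin <- -min(pa[1] * pb[1], (1 - pa[1]) * (1 - pb[1]))
  if (d > dmax + 1e-12 || d < dmin - 1e-12) {
    stop_kinstr("infeasible D: must lie in [", signif(dmin, 4), ", ",
                signif(dmax, 4), "] for these allele frequencies",
                class = "kinstr_sim_error")
  }
  h <- outer(pa, pb)
  ## collapse to (A1 vs rest) x (B1 vs rest), shift mass by D, then spread
  ## inside the "rest" groups proportionally
  h[1, 1] <- h[1, 1] + d
  if (length(pb) > 1) h[1, -1] <- h[1, -1] * (pa[1] * (1 - pb[1]) - d) /
    (pa[1] * (1 - pb[1]))
  if (length(pa) > 1) h[-1, 1] <- h[-1, 1] * ((1 - pa[1]) * pb[1] - d) /
    ((1 - pa[1]) * pb[1])
  if (length(pa) > 1 && length(pb) > 1) {
    h[-1, -1] <- h[-1, -1] * ((1 - pa[1]) * (1 - pb[1]) + d) /
      ((1 - pa[1]) * (1 - pb[1]))
  }
  stopifnot(abs(sum(h) - 1) < 1e-9)
  hap <- which(h > -1, arr.ind = TRUE)
  idx1 <- sample(nrow(hap), n, replace = TRUE, prob = as.vector(h))
  idx2 <- sample(nrow(hap), n, replace = TRUE, prob = as.vector(h))
  ga <- sort_genotype(fa$allele[hap[idx1, 1]], fa$allele[hap[idx2, 1]])
  gb <- sort_genotype(fb$allele[hap[idx1, 2]], fb$allele[hap[idx2, 2]])
  rbind(data.frame(row = seq_len(n), marker = ld_pair$locus_a,
                   allele1 = ga$a1, allele2 = ga$a2,
                   stringsAsFactors = FALSE),
        data.frame(row = seq_len(n), marker = ld_pair$locus_b,
                   allele1 = gb$a1, allele2 = gb$a2,
                   stringsAsFactors = FALSE))
}

#' Simulate an electropherogram peak table
#'
#' Generates called peaks (with simulation truth flags) for each profile at
#' a given template mass under an [epg_model()]: Gamma peak heights driven
#' by effective copy number, heterozygote imbalance decaying exponentially
#' with allele size difference (the shorter amplicon takes the larger
#' expected share, consistent with degradation), one back-stutter peak per
#' true allele at one repeat unit below its parent, Gaussian sizing noise,
#' and height-threshold dropout of sub-`min_peak_rfu` peaks. A stutter
#' product landing on a true allele of the same locus adds to that allele's
#' peak instead of appearing separately.
#'
#' @param profiles a `str_profiles` data.frame.
#' @param panel a [kit_panel()].
#' @param template_pg template DNA mass per reaction, in picograms.
#' @param model an [epg_model()].
#' @param seed integer seed.
#' @return a `str_peaks` data.frame with truth columns `is_stutter` and
#'   `true_allele`.
#' @export
simulate_epg <- function(profiles, panel, template_pg = 500,
                         model = epg_model(), seed = 1L) {
  stopifnot(template_pg > 0)
  pan <- autosomal_panel(panel)
  lam <- model$phr_decay %||% default_phr_decay(panel)
  sr <- model$stutter_ratio %||% default_stutter_ratios(panel)
  k_deg <- log(model$degradation_index) / 140  # DI = exp(k * (220 - 80))
  set.seed(seed)
  p <- profiles[!is.na(profiles$allele1) & profiles$marker %in% names(pan$loci), ]
  ## precompute per-locus ladder size lookups once
  size_cache <- lapply(pan$loci, function(l) {
    known <- unique(c(p$allele1[p$marker == l$name],
                      p$allele2[p$marker == l$name]))
    if (!length(known)) return(numeric())
    setNames(allele_size(pan, l$name, known), known)
  })
  acc <- list(sample_id = list(), marker = list(), dye = list(),
              allele = list(), size_nt = list(), height_rfu = list(),
              is_stutter = list(), true_allele = list())
  for (r in seq_len(nrow(p))) {
    l <- pan$loci[[p$marker[r]]]
    a <- unique(c(p$allele1[r], p$allele2[r]))
    sizes <- unname(size_cache[[l$name]][a])
    copies <- template_pg / (2 * model$pg_per_copy) * model$efficiency *
      exp(-k_deg * pmax(sizes - 80, 0))
    if (length(a) == 2) {
      ratio <- exp(-lam[[l$name]] * abs(sizes[1] - sizes[2]))
      share <- if (sizes[1] <= sizes[2]) c(2 / (1 + ratio),
                                           2 * ratio / (1 + ratio))
      else c(2 * ratio / (1 + ratio), 2 / (1 + ratio))
    } else {
      share <- 2
    }
    mean_h <- copies * share * model$rfu_per_copy
    shape <- if (is.na(model$height_dispersion)) copies * share
    else rep(model$height_dispersion, length(a))
    h <- if (any(is.infinite(shape))) mean_h
    else rgamma(length(a), shape = shape, scale = mean_h / shape)
    ## back-stutter: one repeat unit below each parent
    st_ratio <- pmax(rnorm(length(a), sr[[l$name]], model$stutter_sd), 0)
    st_h <- h * st_ratio
    st_val <- allele_value(a) - 1
    st_lab <- allele_label(st_val)
    st_size <- sizes - l$repeat_unit_nt
    ## stutter masked by a true allele adds to its peak
    hit <- match(st_lab, a)
    for (s in which(!is.na(hit))) h[hit[s]] <- h[hit[s]] + st_h[s]
    keep_st <- is.na(hit) & st_h >= model$min_peak_rfu & st_val > 0
    keep_al <- h >= model$min_peak_rfu
    n_al <- sum(keep_al); n_st <- sum(keep_st)
    if (n_al + n_st == 0) next
    i <- length(acc$marker) + 1L
    acc$sample_id[[i]] <- rep(p$sample_id[r], n_al + n_st)
    acc$marker[[i]] <- rep(l$name, n_al + n_st)
    acc$dye[[i]] <- rep(l$dye, n_al + n_st)
    acc$allele[[i]] <- c(a[keep_al], st_lab[keep_st])
    acc$size_nt[[i]] <- c(sizes[keep_al], st_size[keep_st]) +
      rnorm(n_al + n_st, 0, model$sizing_sd)
    acc$height_rfu[[i]] <- c(h[keep_al], st_h[keep_st])
    acc$is_stutter[[i]] <- c(rep(FALSE, n_al), rep(TRUE, n_st))
    acc$true_allele[[i]] <- c(a[keep_al], a[keep_st])
  }
  out <- data.frame(sample_id = unlist(acc$sample_id) %||% character(),
                    marker = unlist(acc$marker) %||% character(),
                    dye = unlist(acc$dye) %||% character(),
                    allele = unlist(acc$allele) %||% character(),
                    size_nt = unlist(acc$size_nt) %||% numeric(),
                    height_rfu = unlist(acc$height_rfu) %||% numeric(),
                    is_stutter = unlist(acc$is_stutter) %||% logical(),
                    true_allele = unlist(acc$true_allele) %||% character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("str_peaks", "data.frame")
  out
}

#' Simulate a dilution series
#'
#' Replicated peak tables over a descending series of template masses, the
#' standard sensitivity/stochastic-threshold experiment. Per-replicate
#' seeds are derived deterministically from the master seed.
#'
#' @param profile a `str_profiles` data.frame (typically one control
#'   sample).
#' @param panel a [kit_panel()].
#' @param levels_pg template masses in pg, descending.
#' @param replicates replicates per level.
#' @param model an [epg_model()].
#' @param seed master integer seed.
#' @return data.frame-indexed list: elements named `"<pg>pg_r<i>"`, each a
#'   `str_peaks` table with attributes `template_pg` and `replicate`.
#' @export
simulate_dilution_series <- function(profile, panel,
                                     levels_pg = c(500, 250, 125, 62, 31),
                                     replicates = 5, model = epg_model(),
                                     seed = 1L) {
  if (any(levels_pg <= 0) || is.unsorted(rev(levels_pg), strictly = TRUE)) {
    stop_kinstr("levels_pg must be positive and strictly descending",
                class = "kinstr_sim_error")
  }
  out <- list()
  idx <- 0L
  for (lv in levels_pg) {
    for (rep_i in seq_len(replicates)) {
      idx <- idx + 1L
      tab <- simulate_epg(profile, panel, template_pg = lv, model = model,
                          seed = derive_seed(seed, idx))
      attr(tab, "template_pg") <- lv
      attr(tab, "replicate") <- rep_i
      out[[sprintf("%gpg_r%d", lv, rep_i)]] <- tab
    }
  }
  out
}
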