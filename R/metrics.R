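#' Allele-calling thresholds
#'
#' Detection and binning thresholds for genotype calling: minimum peak
#' heights of 50 RFU for heterozygous and 150 RFU for homozygous calls (the
#' stochastic-threshold convention for sensitivity studies), an optional
#' reduced threshold of 30 RFU for re-examining dropout, a ±0.5 nt ladder
#' bin window, and a stutter filter expressed as a height fraction of the
#' neighbouring one-repeat-larger peak.
#'
#' @param t_het minimum height (RFU) to call a heterozygous allele.
#' @param t_hom minimum height (RFU) to accept a single peak as a
#'   homozygote.
#' @param reduced reduced threshold (RFU) for dropout re-examination.
#' @param ladder_window_nt half-width (nt) of the allele bin around each
#'   ladder allele's nominal size.
#' @param stutter_filter peaks one repeat below a >= `1/stutter_filter`
#'   times taller peak are treated as stutter and excluded from calling.
#' @return list of class `call_thresholds`.
#' @export
call_thresholds <- function(t_het = 50, t_hom = 150, reduced = 30,
                            ladder_window_nt = 0.5, stutter_filter = 0.20) {
  if (!(reduced < t_het && t_het <= t_hom)) {
    stop_kinstr("need reduced < t_het <= t_hom",
                class = "kinstr_metrics_error")
  }
  stopifnot(ladder_window_nt > 0, stutter_filter >= 0, stutter_filter < 1)
  structure(list(t_het = t_het, t_hom = t_hom, reduced = reduced,
                 ladder_window_nt = ladder_window_nt,
                 stutter_filter = stutter_filter),
            class = "call_thresholds")
}

## label peaks of one locus by the ladder bins: nearest ladder allele
## within +/- window; otherwise "OL"
bin_alleles <- function(sizes, locus, thresholds) {
  vapply(sizes, function(s) {
    d <- abs(locus$actual_size_nt - s)
    j <- which.min(d)
    if (d[j] <= thresholds$ladder_window_nt) locus$ladder_alleles[j] else "OL"
  }, character(1))
}

#' Call genotypes from a peak table
#'
#' Re-implements the allele-calling contract of profiling software on a
#' peak table: peaks are labelled by ladder bins (nearest ladder allele
#' within the bin window, else off-ladder `"OL"`), stutter-filtered, then
#' thresholded. Two surviving peaks at or above `t_het` give a
#' heterozygote; a single peak at or above `t_hom` a homozygote; a single
#' peak between `t_het` and `t_hom` is conservatively left uncalled with a
#' `possible_dropout` flag; more than two surviving peaks leave the locus
#' uncalled with a `too_many_peaks` flag (mixtures are out of scope).
#' Peaks sized outside their locus window are flagged `out_of_window`, and
#' additionally `window_collision` when they land inside another
#' same-dye locus's window.
#'
#' @param peaks a `str_peaks` data.frame (one or more samples).
#' @param panel a [kit_panel()].
#' @param thresholds a [call_thresholds()].
#' @return list of class `called_profiles`: `profiles` (a `str_profiles`
#'   data.frame covering every panel locus and sample, `NA` alleles where
#'   uncalled) and `flags` (data.frame `sample_id`, `marker`, `flag`).
#' @export
call_profile <- function(peaks, panel, thresholds = call_thresholds()) {
  pan <- autosomal_panel(panel)
  peaks <- flag_windows(peaks, panel)
  samples <- unique(peaks$sample_id)
  prof <- list(); flags <- list()
  fi <- 0L
  add_flag <- function(s, m, fl) {
    fi <<- fi + 1L
    flags[[fi]] <<- data.frame(sample_id = s, marker = m, flag = fl,
                               stringsAsFactors = FALSE)
  }
  for (s in samples) {
    for (lname in names(pan$loci)) {
      l <- pan$loci[[lname]]
      pk <- peaks[peaks$sample_id == s & peaks$marker == lname, ]
      a1 <- NA_character_; a2 <- NA_character_
      if (nrow(pk)) {
        pk$call <- bin_alleles(pk$size_nt, l, thresholds)
        if (any(pk$out_of_window)) add_flag(s, lname, "out_of_window")
        if (any(pk$window_collision)) add_flag(s, lname, "window_collision")
        ## stutter filter: drop peaks one repeat below a much taller peak
        v <- allele_value(pk$call)
        is_st <- vapply(seq_len(nrow(pk)), function(i) {
          if (is.na(v[i])) return(FALSE)
          parent <- which(!is.na(v) & abs(v - (v[i] + 1)) < 1e-9)
          length(parent) > 0 &&
            pk$height_rfu[i] <= thresholds$stutter_filter *
              max(pk$height_rfu[parent])
        }, logical(1))
        pk <- pk[!is_st, ]
        surv <- pk[pk$height_rfu >= thresholds$t_het, ]
        if (nrow(surv) > 2) {
          add_flag(s, lname, "too_many_peaks")
        } else if (nrow(surv) == 2) {
          g <- sort_genotype(surv$call[1], surv$call[2])
          a1 <- g$a1; a2 <- g$a2
        } else if (nrow(surv) == 1) {
          if (surv$height_rfu[1] >= thresholds$t_hom) {
            a1 <- a2 <- surv$call[1]
          } else {
            add_flag(s, lname, "possible_dropout")
          }
        }
      }
      prof[[paste(s, lname)]] <- data.frame(
        sample_id = s, marker = lname, allele1 = a1, allele2 = a2,
        stringsAsFactors = FALSE)
    }
  }
  profiles <- do.call(rbind, prof)
  rownames(profiles) <- NULL
  class(profiles) <- c("str_profiles", "data.frame")
  flags <- if (fi) do.call(rbind, flags) else
    data.frame(sample_id = character(), marker = character(),
               flag = character(), stringsAsFactors = FALSE)
  structure(list(profiles = profiles, flags = flags),
            class = "called_profiles")
}

#' Profile completeness against known truth
#'
#' Percentage of true alleles recovered in called genotypes. Homozygous
#' loci are tallied both ways the field uses: as one distinct allele
#' (`pct_unique`, the convention of dilution-series figures where a
#' homozygote is one merged cell) and as two allele copies (`pct_copies`).
#'
#' @param called a `str_profiles` data.frame of called genotypes.
#' @param truth a `str_profiles` data.frame of true genotypes.
#' @return list: `pct_unique`, `pct_copies`, `n_detected`, `n_true`.
#' @export
profile_completeness <- function(called, truth) {
  truth <- truth[!is.na(truth$allele1), ]
  key <- paste(truth$sample_id, truth$marker)
  ckey <- paste(called$sample_id, called$marker)
  det_u <- 0L; tot_u <- 0L; det_c <- 0L; tot_c <- 0L
  for (i in seq_len(nrow(truth))) {
    ta <- c(truth$allele1[i], truth$allele2[i])
    ua <- unique(ta)
    j <- match(key[i], ckey)
    ca <- if (!is.na(j)) c(called$allele1[j], called$allele2[j]) else
      c(NA, NA)
    tot_u <- tot_u + length(ua)
    tot_c <- tot_c + 2L
    hit_u <- sum(ua %in% ca)
    det_u <- det_u + hit_u
    ## copies: homozygote counts twice if its allele is called
    det_c <- det_c + if (length(ua) == 1) 2L * (ua %in% ca) else hit_u
  }
  list(pct_unique = if (tot_u) 100 * det_u / tot_u else 0,
       pct_copies = if (tot_c) 100 * det_c / tot_c else 0,
       n_detected = det_u, n_true = tot_u)
}

#' Allele-level completeness of a simulated peak table
#'
#' Detection tally straight from a truth-flagged peak table, the way
#' dilution-series figures count: a true allele is detected when a
#' non-stutter peak with its label reaches the heterozygote threshold
#' (heterozygous locus) or the homozygote threshold (homozygous locus).
#'
#' @param peaks a truth-flagged `str_peaks` table ([simulate_epg()]).
#' @param truth the `str_profiles` table the peaks were generated from.
#' @param thresholds a [call_thresholds()]; set `t_het`/`t_hom` to
#'   `reduced` to re-examine dropout at the reduced threshold.
#' @return list as in [profile_completeness()].
#' @export
epg_completeness <- function(peaks, truth, thresholds = call_thresholds()) {
  truth <- truth[!is.na(truth$allele1), ]
  pk <- peaks[!peaks$is_stutter, ]
  pkey <- paste(pk$sample_id, pk$marker, pk$allele)
  det_u <- 0L; tot_u <- 0L; det_c <- 0L; tot_c <- 0L
  for (i in seq_len(nrow(truth))) {
    ua <- unique(c(truth$allele1[i], truth$allele2[i]))
    thr <- if (length(ua) == 2) thresholds$t_het else thresholds$t_hom
    h <- pk$height_rfu[match(paste(truth$sample_id[i], truth$marker[i], ua),
                             pkey)]
    hit <- !is.na(h) & h >= thr
    tot_u <- tot_u + length(ua); tot_c <- tot_c + 2L
    det_u <- det_u + sum(hit)
    det_c <- det_c + if (length(ua) == 1) 2L * sum(hit) else sum(hit)
  }
  list(pct_unique = if (tot_u) 100 * det_u / tot_u else 0,
       pct_copies = if (tot_c) 100 * det_c / tot_c else 0,
       n_detected = det_u, n_true = tot_u)
}

#' Heterozygote peak balance report
#'
#' Peak-height ratio (PHR) analysis of confidently heterozygous loci:
#' `PHR = 100 min(h1, h2) / max(h1, h2)` per heterozygote, per-locus mean
#' and minimum, the PHR-vs-size-difference curve (mean PHR over genotypes
#' sharing the same allele size difference, with a centred moving average
#' as the smoothed curve), and the dye-balance summaries (ratio of lowest
#' to highest mean locus total height within and across dye channels).
#'
#' @param peaks a `str_peaks` data.frame (non-stutter peaks are used; if a
#'   truth `is_stutter` column is absent all peaks are considered).
#' @param called a `str_profiles` data.frame of called genotypes (only
#'   heterozygous calls contribute).
#' @param panel a [kit_panel()].
#' @param smooth_window moving-average window for the smoothed curve, in
#'   size-difference grid points (default 5).
#' @return list of class `balance_report`: `per_het` (data.frame of each
#'   heterozygote's PHR and size difference), `per_locus` (mean/min PHR),
#'   `curve` (delta_nt, mean_phr, smoothed_phr, n), `intra_dye`
#'   (per-dye lowest/highest locus ratio), `inter_dye`.
#' @export
heterozygote_balance <- function(peaks, called, panel, smooth_window = 5) {
  pan <- autosomal_panel(panel)
  pk <- if (!is.null(peaks$is_stutter)) peaks[!peaks$is_stutter, ] else peaks
  het <- called[!is.na(called$allele1) & called$allele1 != called$allele2 &
                  called$marker %in% names(pan$loci), ]
  if (!nrow(het)) {
    warning("no heterozygous calls: empty balance report")
    return(structure(list(per_het = NULL, per_locus = NULL, curve = NULL,
                          intra_dye = NULL, inter_dye = NA_real_),
                     class = "balance_report"))
  }
  pkey <- paste(pk$sample_id, pk$marker, pk$allele)
  h1 <- pk$height_rfu[match(paste(het$sample_id, het$marker, het$allele1),
                            pkey)]
  h2 <- pk$height_rfu[match(paste(het$sample_id, het$marker, het$allele2),
                            pkey)]
  ok <- !is.na(h1) & !is.na(h2)
  het <- het[ok, ]; h1 <- h1[ok]; h2 <- h2[ok]
  s1 <- mapply(function(m, a) allele_size(pan, m, a), het$marker,
               het$allele1)
  s2 <- mapply(function(m, a) allele_size(pan, m, a), het$marker,
               het$allele2)
  per_het <- data.frame(sample_id = het$sample_id, marker = het$marker,
                        phr = 100 * pmin(h1, h2) / pmax(h1, h2),
                        delta_nt = abs(s1 - s2), stringsAsFactors = FALSE)
  per_locus <- do.call(rbind, lapply(split(per_het, per_het$marker),
    function(g) data.frame(marker = g$marker[1], n = nrow(g),
                           mean_phr = mean(g$phr), min_phr = min(g$phr),
                           stringsAsFactors = FALSE)))
  rownames(per_locus) <- NULL
  ## PHR vs size-difference curve with centred moving-average smoothing
  d <- sort(unique(per_het$delta_nt))
  curve <- data.frame(delta_nt = d,
                      mean_phr = vapply(d, function(x)
                        mean(per_het$phr[per_het$delta_nt == x]),
                        numeric(1)),
                      n = vapply(d, function(x)
                        sum(per_het$delta_nt == x), integer(1)))
  half <- floor(smooth_window / 2)
  curve$smoothed_phr <- vapply(seq_along(d), function(i) {
    j <- max(1, i - half):min(nrow(curve), i + half)
    mean(curve$mean_phr[j])
  }, numeric(1))
  ## dye balance on mean total locus heights
  tot <- tapply(pk$height_rfu, list(pk$sample_id, pk$marker), sum)
  locus_mean <- colMeans(tot, na.rm = TRUE)
  dye_of <- vapply(names(locus_mean), function(m)
    pan$loci[[m]]$dye %||% NA_character_, character(1))
  intra <- vapply(split(locus_mean, dye_of), function(x)
    100 * min(x) / max(x), numeric(1))
  dye_means <- vapply(split(locus_mean, dye_of), mean, numeric(1))
  structure(list(per_het = per_het, per_locus = per_locus, curve = curve,
                 intra_dye = intra,
                 inter_dye = 100 * min(dye_means) / max(dye_means)),
            class = "balance_report")
}

#' Stutter ratio summary
#'
#' Per-locus back-stutter ratios, `100 * stutter height / parent height`,
#' from a truth-flagged peak table. A stutter position that coincides with
#' a true called allele is excluded (its height is confounded with real
#' signal).
#'
#' @param peaks a truth-flagged `str_peaks` table ([simulate_epg()]).
#' @param panel a [kit_panel()].
#' @return list of class `stutter_report`: `per_locus` (marker, n,
#'   mean_ratio, min_ratio, max_ratio in percent), `grand_mean`, `range`.
#' @export
stutter_summary <- function(peaks, panel) {
  if (is.null(peaks$is_stutter)) {
    stop_kinstr("stutter_summary needs a truth-flagged peak table",
                class = "kinstr_metrics_error")
  }
  st <- peaks[peaks$is_stutter, ]
  par <- peaks[!peaks$is_stutter, ]
  pkey <- paste(par$sample_id, par$marker, par$allele)
  ph <- par$height_rfu[match(paste(st$sample_id, st$marker, st$true_allele),
                             pkey)]
  ## exclude stutter whose position is itself a true allele of the locus
  ## (the generator already merges those, but guard for external tables)
  clash <- !is.na(match(paste(st$sample_id, st$marker, st$allele), pkey))
  ok <- !is.na(ph) & !clash
  ratio <- 100 * st$height_rfu[ok] / ph[ok]
  marker <- st$marker[ok]
  per_locus <- do.call(rbind, lapply(split(ratio, marker), function(x)
    data.frame(n = length(x), mean_ratio = mean(x), min_ratio = min(x),
               max_ratio = max(x))))
  per_locus <- data.frame(marker = rownames(per_locus), per_locus,
                          row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_locus = per_locus,
                 grand_mean = mean(per_locus$mean_ratio),
                 range = range(per_locus$mean_ratio)),
            class = "stutter_report")
}

#' Sizing precision and accuracy
#'
#' `sizing_precision()` groups observed fragment sizes by locus and allele
#' and reports the per-allele sample standard deviation (denominator
#' `n - 1`); single-observation alleles are listed but excluded from the
#' s.d. summary. `sizing_accuracy()` compares per-allele mean observed
#' sizes with the nominal ("actual") ladder sizes; alleles deviating by
#' 0.5 nt or more — outside the allele bin — are flagged.
#'
#' @param peaks a `str_peaks` data.frame (stutter rows excluded if
#'   flagged).
#' @return `sizing_precision()`: list of class `sizing_report` with
#'   `per_allele` (marker, allele, n, mean_size, sd_nt), `max_sd`,
#'   `min_sd`, `n_single` (alleles with one observation, excluded).
#' @export
sizing_precision <- function(peaks) {
  pk <- if (!is.null(peaks$is_stutter)) peaks[!peaks$is_stutter, ] else peaks
  g <- split(pk$size_nt, paste(pk$marker, pk$allele, sep = ":"))
  per <- do.call(rbind, lapply(names(g), function(k) {
    x <- g[[k]]
    parts <- strsplit(k, ":", fixed = TRUE)[[1]]
    data.frame(marker = parts[1], allele = parts[2], n = length(x),
               mean_size = mean(x),
               sd_nt = if (length(x) > 1) sd(x) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  multi <- per[per$n > 1, ]
  structure(list(per_allele = per,
                 max_sd = if (nrow(multi)) max(multi$sd_nt) else NA_real_,
                 min_sd = if (nrow(multi)) min(multi$sd_nt) else NA_real_,
                 n_single = sum(per$n == 1)),
            class = "sizing_report")
}

#' @rdname sizing_precision
#' @param panel a [kit_panel()] providing the nominal sizes.
#' @return `sizing_accuracy()`: list of class `sizing_report` with
#'   `per_allele` (marker, allele, n, mean_size, actual_size, deviation_nt,
#'   flagged), `max_abs_deviation`.
#' @export
sizing_accuracy <- function(peaks, panel) {
  pk <- if (!is.null(peaks$is_stutter)) peaks[!peaks$is_stutter, ] else peaks
  pan <- autosomal_panel(panel)
  pk <- pk[pk$marker %in% names(pan$loci), ]
  g <- split(seq_len(nrow(pk)), paste(pk$marker, pk$allele, sep = ":"))
  per <- do.call(rbind, lapply(names(g), function(k) {
    i <- g[[k]]
    parts <- strsplit(k, ":", fixed = TRUE)[[1]]
    l <- pan$loci[[parts[1]]]
    act <- unname(l$actual_size_nt[parts[2]])
    if (is.na(act)) return(NULL)  # off-ladder: no nominal size
    data.frame(marker = parts[1], allele = parts[2], n = length(i),
               mean_size = mean(pk$size_nt[i]), actual_size = act,
               deviation_nt = mean(pk$size_nt[i]) - act,
               stringsAsFactors = FALSE)
  }))
  per$flagged <- abs(per$deviation_nt) >= 0.5
  structure(list(per_allele = per,
                 max_abs_deviation = max(abs(per$deviation_nt))),
            class = "sizing_report")
}

#' Allelic ladder coverage report
#'
#' From a set of genotype profiles, lists alleles observed in the
#' population but absent from the allelic ladder, with observation counts
#' and relative frequencies (over the `2N` allele observations at the
#' locus), and classifies each by its expected fragment size: inside its
#' locus window, outside it (`out_of_window`), or inside another same-dye
#' locus's window (`window_collision` — the misassignment risk case).
#'
#' @param profiles a `str_profiles` data.frame.
#' @param panel a [kit_panel()].
#' @return list of class `ladder_report`: `off_ladder` (data.frame marker,
#'   allele, count, frequency, expected_size_nt, out_of_window,
#'   window_collision), `n_off_ladder`, `n_out_of_window`.
#' @export
ladder_coverage <- function(profiles, panel) {
  pan <- autosomal_panel(panel)
  p <- profiles[!is.na(profiles$allele1) &
                  profiles$marker %in% names(pan$loci), ]
  rows <- list()
  for (lname in unique(p$marker)) {
    l <- pan$loci[[lname]]
    g <- p[p$marker == lname, ]
    obs <- c(g$allele1, g$allele2)
    tab <- table(obs)
    extra <- setdiff(names(tab), l$ladder_alleles)
    for (a in extra) {
      sz <- allele_size(pan, lname, a)
      oow <- sz < l$size_window_nt[1] | sz > l$size_window_nt[2]
      coll <- oow && any(vapply(pan$loci, function(o) {
        o$name != lname && o$dye == l$dye &&
          sz >= o$size_window_nt[1] && sz <= o$size_window_nt[2]
      }, logical(1)))
      rows[[paste(lname, a)]] <- data.frame(
        marker = lname, allele = a, count = as.integer(tab[a]),
        frequency = as.numeric(tab[a]) / length(obs),
        expected_size_nt = sz, out_of_window = oow,
        window_collision = coll, stringsAsFactors = FALSE)
    }
  }
  off <- if (length(rows)) do.call(rbind, rows) else
    data.frame(marker = character(), allele = character(),
               count = integer(), frequency = numeric(),
               expected_size_nt = numeric(), out_of_window = logical(),
               window_collision = logical(), stringsAsFactors = FALSE)
  rownames(off) <- NULL
  off <- off[order(off$marker, allele_value(off$allele)), ]
  structure(list(off_ladder = off, n_off_ladder = nrow(off),
                 n_out_of_window = sum(off$out_of_window)),
            class = "ladder_report")
}

#' Inter-kit concordance
#'
#' Compares unordered genotypes of the same samples typed with two kits at
#' their shared loci.
#'
#' @param profiles_a,profiles_b `str_profiles` data.frames from the two
#'   kits.
#' @param shared_loci loci to compare; defaults to the intersection. Loci
#'   absent from either set are dropped with a warning.
#' @return list of class `concordance_report`: `per_locus` (marker,
#'   n_compared, n_concordant, pct_concordant), `discordances` (data.frame
#'   of mismatching sample/locus genotype pairs), `overall_pct`.
#' @export
concordance <- function(profiles_a, profiles_b, shared_loci = NULL) {
  shared <- shared_loci %||% intersect(unique(profiles_a$marker),
                                       unique(profiles_b$marker))
  missing <- setdiff(shared, intersect(unique(profiles_a$marker),
                                       unique(profiles_b$marker)))
  if (length(missing)) {
    warning("loci absent from one profile set, skipped: ",
            paste(missing, collapse = ", "))
    shared <- setdiff(shared, missing)
  }
  per <- list(); disc <- list()
  for (l in shared) {
    a <- profiles_a[profiles_a$marker == l & !is.na(profiles_a$allele1), ]
    b <- profiles_b[profiles_b$marker == l & !is.na(profiles_b$allele1), ]
    common <- intersect(a$sample_id, b$sample_id)
    ga <- paste(a$allele1, a$allele2)[match(common, a$sample_id)]
    gb <- paste(b$allele1, b$allele2)[match(common, b$sample_id)]
    same <- ga == gb
    per[[l]] <- data.frame(marker = l, n_compared = length(common),
                           n_concordant = sum(same),
                           pct_concordant = 100 * mean(same),
                           stringsAsFactors = FALSE)
    if (any(!same)) {
      disc[[l]] <- data.frame(marker = l, sample_id = common[!same],
                              genotype_a = ga[!same], genotype_b = gb[!same],
                              stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  structure(list(per_locus = per,
                 discordances = if (length(disc)) do.call(rbind, disc)
                 else NULL,
                 overall_pct = 100 * sum(per$n_concordant) /
                   sum(per$n_compared)),
            class = "concordance_report")
}
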