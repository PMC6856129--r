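#' Read a genotype table
#'
#' Reads diploid STR genotypes from a comma-separated file with header
#' `SampleID,Marker,Allele1,Allele2` (one called locus per row — the long
#' layout exported by genotyping software once wide GeneMapper rows are
#' melted). A blank `Allele2` is the homozygote shorthand and is expanded to
#' a duplicated allele label. Genotypes are stored unordered: alleles are
#' sorted by repeat value on read.
#'
#' @param path input CSV path.
#' @param panel optional [kit_panel()]; if supplied, marker names are alias-
#'   resolved and unknown markers rejected (unless `permissive = TRUE`).
#' @param permissive keep rows whose marker is not in `panel` instead of
#'   erroring.
#' @return data.frame of class `str_profiles` with columns
#'   `sample_id`, `marker`, `allele1`, `allele2`.
#' @export
read_genotypes <- function(path, panel = NULL, permissive = FALSE) {
  d <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("SampleID", "Marker", "Allele1", "Allele2")
  if (!all(need %in% names(d))) {
    stop_kinstr("genotype table needs header ", paste(need, collapse = ","),
                class = "kinstr_io_error")
  }
  a1 <- trimws(d$Allele1); a2 <- trimws(d$Allele2)
  no_call <- a1 == "" & a2 == ""
  a2[a2 == "" & !no_call] <- a1[a2 == "" & !no_call]  # blank Allele2 = homozygote
  bad <- !no_call & (!is_valid_allele(a1) | !is_valid_allele(a2))
  if (any(bad)) {
    stop_kinstr("unparsable allele label in row(s) ",
                paste(head(which(bad) + 1L, 5), collapse = ", "),
                " of ", path, class = "kinstr_io_error")
  }
  marker <- d$Marker
  if (!is.null(panel)) {
    marker <- resolve_locus(panel, marker, permissive = TRUE)
    unknown <- !marker %in% names(panel$loci)
    if (any(unknown) && !permissive) {
      stop_kinstr("unknown marker(s): ",
                  paste(unique(marker[unknown]), collapse = ", "),
                  class = "kinstr_io_error")
    }
  }
  g <- sort_genotype(a1[!no_call], a2[!no_call])
  out <- data.frame(sample_id = d$SampleID, marker = marker,
                    allele1 = NA_character_, allele2 = NA_character_,
                    stringsAsFactors = FALSE)
  out$allele1[!no_call] <- g$a1
  out$allele2[!no_call] <- g$a2
  class(out) <- c("str_profiles", "data.frame")
  out
}

#' @rdname read_genotypes
#' @param profiles a `str_profiles` data.frame.
#' @return `write_genotypes()`: `path`, invisibly. Homozygotes are written
#'   with the allele duplicated, never blank.
#' @export
write_genotypes <- function(profiles, path) {
  write.csv(data.frame(SampleID = profiles$sample_id,
                       Marker = profiles$marker,
                       Allele1 = profiles$allele1,
                       Allele2 = profiles$allele2),
            path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a peak table
#'
#' Reads called electropherogram peaks from a CSV with header
#' `SampleID,Marker,Dye,Allele,Size_nt,Height_RFU`. Optional extra columns
#' (e.g. the simulation truth flag `IsStutter`) are preserved. Writing then
#' reading a table is identity after sizes are rounded to 4 and heights to
#' 1 decimal place.
#'
#' @param path input CSV path.
#' @param panel optional [kit_panel()]; when given, each peak is checked
#'   against its locus size window and an `out_of_window` flag column added.
#' @return data.frame of class `str_peaks` with columns `sample_id`,
#'   `marker`, `dye`, `allele`, `size_nt`, `height_rfu` (+ flags).
#' @export
read_peaks <- function(path, panel = NULL) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("SampleID", "Marker", "Dye", "Allele", "Size_nt", "Height_RFU")
  if (!all(need %in% names(d))) {
    stop_kinstr("peak table needs header ", paste(need, collapse = ","),
                class = "kinstr_io_error")
  }
  out <- data.frame(sample_id = as.character(d$SampleID),
                    marker = as.character(d$Marker),
                    dye = as.character(d$Dye),
                    allele = as.character(d$Allele),
                    size_nt = as.numeric(d$Size_nt),
                    height_rfu = as.numeric(d$Height_RFU),
                    stringsAsFactors = FALSE)
  if ("IsStutter" %in% names(d)) out$is_stutter <- as.logical(d$IsStutter)
  if (any(out$height_rfu <= 0 | !is.finite(out$height_rfu))) {
    stop_kinstr("peak heights must be positive, see row(s) ",
                paste(head(which(out$height_rfu <= 0) + 1L, 5), collapse = ", "),
                class = "kinstr_io_error")
  }
  if (any(out$size_nt <= 0)) {
    stop_kinstr("peak sizes must be positive", class = "kinstr_io_error")
  }
  if (!is.null(panel)) out <- flag_windows(out, panel)
  class(out) <- c("str_peaks", "data.frame")
  out
}

#' @rdname read_peaks
#' @param peaks a `str_peaks` data.frame.
#' @return `write_peaks()`: `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  d <- data.frame(SampleID = peaks$sample_id, Marker = peaks$marker,
                  Dye = peaks$dye, Allele = peaks$allele,
                  Size_nt = sprintf("%.4f", peaks$size_nt),
                  Height_RFU = sprintf("%.1f", peaks$height_rfu))
  if (!is.null(peaks$is_stutter)) d$IsStutter <- peaks$is_stutter
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## per-peak window flags: outside own locus window; inside another locus's
## window on the same dye (the misassignment risk for off-ladder alleles)
flag_windows <- function(peaks, panel) {
  marker <- resolve_locus(panel, peaks$marker, permissive = TRUE)
  win <- t(vapply(marker, function(m) {
    if (m %in% names(panel$loci)) panel$loci[[m]]$size_window_nt
    else c(NA_real_, NA_real_)
  }, numeric(2)))
  peaks$out_of_window <- !is.na(win[, 1]) &
    (peaks$size_nt < win[, 1] | peaks$size_nt > win[, 2])
  peaks$window_collision <- vapply(seq_len(nrow(peaks)), function(i) {
    if (!isTRUE(peaks$out_of_window[i])) return(FALSE)
    any(vapply(panel$loci, function(l) {
      l$name != marker[i] && l$dye == peaks$dye[i] &&
        peaks$size_nt[i] >= l$size_window_nt[1] &&
        peaks$size_nt[i] <= l$size_window_nt[2]
    }, logical(1)))
  }, logical(1))
  peaks
}

#' Read or write an allele-frequency table
#'
#' Frequency tables use the header `Marker,Allele,Frequency`, one allele per
#' row; per-locus frequencies must sum to 1 (tolerance 1e-9) and lie in
#' (0, 1].
#'
#' @param path CSV path.
#' @return data.frame of class `str_freqs` with columns `marker`, `allele`,
#'   `frequency`.
#' @export
read_freqs <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("Marker", "Allele", "Frequency")
  if (!all(need %in% names(d))) {
    stop_kinstr("frequency table needs header ", paste(need, collapse = ","),
                class = "kinstr_io_error")
  }
  out <- data.frame(marker = as.character(d$Marker),
                    allele = as.character(d$Allele),
                    frequency = as.numeric(d$Frequency),
                    stringsAsFactors = FALSE)
  validate_freqs(out)
}

#' @rdname read_freqs
#' @param freqs a `str_freqs` data.frame.
#' @export
write_freqs <- function(freqs, path) {
  write.csv(data.frame(Marker = freqs$marker, Allele = freqs$allele,
                       Frequency = freqs$frequency),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_freqs <- function(freqs) {
  if (any(freqs$frequency <= 0 | freqs$frequency > 1)) {
    stop_kinstr("allele frequencies must lie in (0, 1]",
                class = "kinstr_freq_error")
  }
  sums <- tapply(freqs$frequency, freqs$marker, sum)
  off <- abs(sums - 1) > 1e-9
  if (any(off)) {
    stop_kinstr("frequencies do not sum to 1 at: ",
                paste(names(sums)[off], collapse = ", "),
                class = "kinstr_freq_error")
  }
  class(freqs) <- c("str_freqs", "data.frame")
  freqs
}

#' Read a locus map table
#'
#' Reads a minimal locus annotation table (`Locus,Chromosome,Map_cM`) of the
#' kind used for syntenic-pair enumeration and map-distance work, where no
#' ladder or dye information is needed.
#'
#' @param path CSV path.
#' @return data.frame with columns `locus`, `chromosome`, `map_position_cm`.
#' @export
read_locus_map <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("Locus", "Chromosome", "Map_cM")
  if (!all(need %in% names(d))) {
    stop_kinstr("locus map needs header ", paste(need, collapse = ","),
                class = "kinstr_io_error")
  }
  data.frame(locus = as.character(d$Locus),
             chromosome = as.character(d$Chromosome),
             map_position_cm = as.numeric(d$Map_cM),
             stringsAsFactors = FALSE)
}

#' Bundled panel and locus fixtures
#'
#' `sureid_panel()` loads the bundled 23-marker supplementary-kit panel
#' definition (22 autosomal STRs plus amelogenin, with dye layout, size
#' windows, ladder alleles and map positions). The ladder "actual sizes" in
#' the fixture are synthetic placeholders on a consistent 4 nt repeat grid,
#' not manufacturer values (which are not published). `globalfiler_loci()`
#' and `penta_loci()` return locus map tables for the 21 autosomal STRs of
#' the reference CODIS/ESS kit and for the Penta D/E loci.
#'
#' @return `sureid_panel()`: a [kit_panel()]; the others: locus map
#'   data.frames (`locus`, `chromosome`, `map_position_cm`).
#' @export
sureid_panel <- function() {
  load_panel(system.file("extdata", "sureid23comp_panel.json",
                         package = "kinstr", mustWork = TRUE))
}

#' @rdname sureid_panel
#' @export
globalfiler_loci <- function() {
  read_locus_map(system.file("extdata", "globalfiler_loci.csv",
                             package = "kinstr", mustWork = TRUE))
}

#' @rdname sureid_panel
#' @export
penta_loci <- function() {
  read_locus_map(system.file("extdata", "penta_loci.csv",
                             package = "kinstr", mustWork = TRUE))
}

#' Combined supplementary + reference locus table
#'
#' The locus set formed by merging the reference kit's 21 autosomal STRs
#' with the supplementary panel's non-CODIS STRs (shared CODIS/ESS loci are
#' typed by both kits and enter once, via the reference kit). With the
#' defaults this is the 38-locus set used for syntenic-pair work.
#'
#' @param panel supplementary [kit_panel()] (default the bundled fixture).
#' @param reference reference-kit locus table (default [globalfiler_loci()]).
#' @param include_penta also append the Penta D/E loci.
#' @return locus table data.frame.
#' @export
combined_loci <- function(panel = sureid_panel(),
                          reference = globalfiler_loci(),
                          include_penta = FALSE) {
  sup <- as_locus_table(autosomal_panel(panel))
  sup <- sup[!sup$locus %in% reference$locus, ]
  out <- rbind(as_locus_table(reference), sup)
  if (include_penta) out <- rbind(out, as_locus_table(penta_loci()))
  rownames(out) <- NULL
  out
}
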