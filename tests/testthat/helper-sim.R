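## shared simulation helpers: small panels and genotype tables built in code

## a compact two-dye test panel (fast to simulate, easy to reason about)
tiny_panel <- function() {
  kit_panel("tiny", list(
    locus_def("L1", 1, "BLUE", c(100, 140), as.character(8:15),
              setNames(seq(106, by = 4, length.out = 8), 8:15)),
    locus_def("L2", 1, "BLUE", c(150, 190),
              c("10", "11", "11.3", "12", "13"),
              setNames(c(156, 160, 163, 164, 168),
                       c("10", "11", "11.3", "12", "13")),
              map_position_cm = 10),
    locus_def("L3", 2, "GREEN", c(100, 160), as.character(14:24),
              setNames(seq(106, by = 4, length.out = 11), 14:24),
              map_position_cm = 55)
  ))
}

## profiles data.frame from a compact list spec:
## list(S1 = list(L1 = c("8", "9"), ...), ...)
make_profiles <- function(spec) {
  rows <- do.call(rbind, lapply(names(spec), function(s) {
    do.call(rbind, lapply(names(spec[[s]]), function(m) {
      a <- spec[[s]][[m]]
      data.frame(sample_id = s, marker = m, allele1 = a[1], allele2 = a[2],
                 stringsAsFactors = FALSE)
    }))
  }))
  class(rows) <- c("str_profiles", "data.frame")
  rows
}

## one-sample peak table from vectors
make_peaks <- function(marker, allele, height, size, dye = "BLUE",
                       sample_id = "S1", is_stutter = NULL) {
  d <- data.frame(sample_id = sample_id, marker = marker, dye = dye,
                  allele = as.character(allele), size_nt = size,
                  height_rfu = height, stringsAsFactors = FALSE)
  if (!is.null(is_stutter)) d$is_stutter <- is_stutter
  class(d) <- c("str_peaks", "data.frame")
  d
}

## genotype table for two loci in the layout em_haplotype_freqs expects
two_locus_genotypes <- function(a1, a2, b1, b2) {
  data.frame(a1 = as.character(a1), a2 = as.character(a2),
             b1 = as.character(b1), b2 = as.character(b2),
             stringsAsFactors = FALSE)
}

## random genotype-array margins with a feasible table (for HWE oracles)
random_genotype_array <- function(k, n, seed) {
  set.seed(seed)
  p <- as.vector(rmultinom(1, 10, rep(1, k)) + 1)
  p <- p / sum(p)
  a1 <- sample(k, n, TRUE, p); a2 <- sample(k, n, TRUE, p)
  counts <- matrix(0L, k, k)
  for (i in seq_len(n)) {
    lo <- max(a1[i], a2[i]); hi <- min(a1[i], a2[i])
    counts[lo, hi] <- counts[lo, hi] + 1L
  }
  genotype_array(counts = counts)
}
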