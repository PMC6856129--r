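#' Parse STR allele labels
#'
#' STR alleles are named by repeat count, with microvariants carrying a
#' fractional part counting leftover nucleotides (`"11.3"` = 11 full repeats
#' plus 3 nt). Labels are kept as strings throughout the package and compared
#' through this parser, never as floating-point numbers. The sex-typing
#' pseudo-alleles `"X"`/`"Y"` and the off-ladder marker `"OL"` are recognised
#' but carry no repeat value.
#'
#' @param labels character vector of allele labels.
#' @param strict error on labels that are neither STR repeat labels nor
#'   X/Y/OL (`TRUE`, the I/O validation mode); `FALSE` parses what it can
#'   and leaves the rest `NA`.
#' @return data.frame with columns `label`, `repeats` (integer), `partial`
#'   (integer nt, 0--3), and `value` (repeats + partial/10, a sortable key;
#'   `NA` for X/Y/OL).
#' @examples
#' parse_allele(c("11.3", "12", "X"))
#' @export
parse_allele <- function(labels, strict = TRUE) {
  labels <- as.character(labels)
  ok_num <- grepl("^[0-9]+(\\.[123])?$", labels)
  ok_special <- labels %in% c("X", "Y", "OL")
  if (strict && any(!ok_num & !ok_special)) {
    bad <- unique(labels[!ok_num & !ok_special])
    stop_kinstr("invalid allele label(s): ", paste(bad, collapse = ", "),
                class = "kinstr_allele_error")
  }
  reps <- rep(NA_integer_, length(labels))
  reps[ok_num] <- as.integer(sub("\\..*$", "", labels[ok_num]))
  part <- integer(length(labels))
  has_frac <- ok_num & grepl("\\.", labels)
  part[has_frac] <- as.integer(sub("^[0-9]+\\.", "", labels[has_frac]))
  part[!ok_num] <- NA_integer_
  data.frame(label = labels, repeats = reps, partial = part,
             value = reps + part / 10, stringsAsFactors = FALSE)
}

#' @rdname parse_allele
#' @return `allele_value()`: the numeric sort key only (`NA` where not an
#'   STR repeat label).
#' @export
allele_value <- function(labels) parse_allele(labels, strict = FALSE)$value

is_valid_allele <- function(labels) {
  grepl("^[0-9]+(\\.[123])?$", labels) | labels %in% c("X", "Y")
}

## canonical label for a repeat value (11.0 -> "11", 11.3 -> "11.3")
allele_label <- function(value) {
  reps <- floor(value + 1e-9)
  part <- as.integer(round((value - reps) * 10))
  ifelse(part == 0L, sprintf("%d", as.integer(reps)),
         sprintf("%d.%d", as.integer(reps), part))
}

## order allele labels by repeat value, X/Y last
order_alleles <- function(labels) {
  v <- suppressWarnings(allele_value(labels))
  order(is.na(v), v, labels)
}

## canonical unordered genotype: two labels sorted by repeat value
sort_genotype <- function(a1, a2) {
  v1 <- allele_value(a1); v2 <- allele_value(a2)
  swap <- !is.na(v1) & !is.na(v2) & v2 < v1
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  list(a1 = a1, a2 = a2)
}
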