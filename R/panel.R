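#' Locus definition
#'
#' Builds the definition of one multiplex locus: its chromosome, dye channel,
#' fragment-size window, ladder alleles and their nominal ("actual") fragment
#' sizes, and optionally a cumulative genetic-map position.
#'
#' @param name locus identifier (e.g. `"D2S441"`).
#' @param chromosome chromosome label, `"1"`--`"22"` for autosomal STRs or
#'   `"XY"` for the amelogenin sex-typing marker.
#' @param dye dye channel label.
#' @param size_window_nt numeric length-2, min and max fragment size (nt).
#' @param ladder_alleles character vector of allele labels present in the
#'   allelic ladder.
#' @param actual_size_nt named numeric vector mapping each ladder allele to
#'   its nominal fragment size in nt.
#' @param aliases alternative names resolving to this locus.
#' @param map_position_cm cumulative genetic map distance in centimorgans,
#'   or `NA` if unmapped.
#' @param repeat_unit_nt repeat unit length in nt (4 for the tetranucleotide
#'   STRs handled here; 0 for amelogenin).
#' @return object of class `locus_def`.
#' @export
locus_def <- function(name, chromosome, dye, size_window_nt, ladder_alleles,
                      actual_size_nt, aliases = character(),
                      map_position_cm = NA_real_, repeat_unit_nt = 4L) {
  stopifnot(length(size_window_nt) == 2)
  if (!length(ladder_alleles)) {
    stop_kinstr("locus ", name, ": empty ladder allele list",
                class = "kinstr_panel_error")
  }
  if (size_window_nt[1] >= size_window_nt[2]) {
    stop_kinstr("locus ", name, ": size window min must be below max",
                class = "kinstr_panel_error")
  }
  bad <- ladder_alleles[!is_valid_allele(ladder_alleles)]
  if (length(bad)) {
    stop_kinstr("locus ", name, ": unparsable ladder allele(s) ",
                paste(bad, collapse = ", "), class = "kinstr_panel_error")
  }
  actual_size_nt <- actual_size_nt[ladder_alleles]
  if (anyNA(actual_size_nt)) {
    stop_kinstr("locus ", name, ": every ladder allele needs an actual size",
                class = "kinstr_panel_error")
  }
  out_of_window <- actual_size_nt < size_window_nt[1] |
    actual_size_nt > size_window_nt[2]
  if (any(out_of_window)) {
    stop_kinstr("locus ", name, ": ladder allele size outside size window: ",
                paste(ladder_alleles[out_of_window], collapse = ", "),
                class = "kinstr_panel_error")
  }
  structure(list(name = name, chromosome = as.character(chromosome),
                 dye = dye, size_window_nt = as.numeric(size_window_nt),
                 ladder_alleles = as.character(ladder_alleles),
                 actual_size_nt = actual_size_nt,
                 aliases = as.character(aliases),
                 map_position_cm = as.numeric(map_position_cm),
                 repeat_unit_nt = as.integer(repeat_unit_nt)),
            class = "locus_def")
}

#' Kit panel
#'
#' Assembles locus definitions into a multiplex kit panel. Locus aliases are
#' resolved at construction time: a locus supplied under an alias (for
#' instance the superseded name D5S2500 for D5S2800) is exposed under its
#' corrected primary name.
#'
#' @param name kit identifier.
#' @param loci list of [locus_def()] objects.
#' @return object of class `kit_panel` with elements `name`, `loci`
#'   (named list) and `dyes` (channel order of first appearance).
#' @export
kit_panel <- function(name, loci) {
  if (!length(loci)) {
    stop_kinstr("panel ", name, ": empty locus list",
                class = "kinstr_panel_error")
  }
  stopifnot(all(vapply(loci, inherits, logical(1), "locus_def")))
  ## alias resolution: a locus whose name matches another locus's alias list
  ## is renamed to the primary name
  primary <- vapply(loci, `[[`, character(1), "name")
  for (i in seq_along(loci)) {
    for (j in seq_along(loci)) {
      if (i != j && primary[i] %in% loci[[j]]$aliases) {
        stop_kinstr("panel ", name, ": locus ", primary[i],
                    " duplicates an alias of ", primary[j],
                    class = "kinstr_panel_error")
      }
    }
  }
  if (anyDuplicated(primary)) {
    stop_kinstr("panel ", name, ": duplicate locus name(s): ",
                paste(unique(primary[duplicated(primary)]), collapse = ", "),
                class = "kinstr_panel_error")
  }
  names(loci) <- primary
  dyes <- unique(vapply(loci, `[[`, character(1), "dye"))
  structure(list(name = name, loci = loci, dyes = dyes), class = "kit_panel")
}

#' @export
print.kit_panel <- function(x, ...) {
  cat(sprintf("<kit_panel> %s: %d loci, %d dye channels\n",
              x$name, length(x$loci), length(x$dyes)))
  for (l in x$loci) {
    cat(sprintf("  %-15s chr %-3s %-6s [%5.0f,%5.0f] nt, %d ladder alleles\n",
                l$name, l$chromosome, l$dye, l$size_window_nt[1],
                l$size_window_nt[2], length(l$ladder_alleles)))
  }
  invisible(x)
}

#' Load a panel definition from JSON
#'
#' Reads a kit panel from a JSON file. The file carries a kit `name` and a
#' `loci` array whose entries hold the fields of [locus_def()]; see the
#' bundled fixture (`system.file("extdata", "sureid23comp_panel.json",
#' package = "kinstr")`) for the schema. Aliases are resolved on load: a
#' locus named by one of its aliases (e.g. D5S2500) is returned under its
#' primary name (D5S2800).
#'
#' @param path path to the panel JSON file.
#' @return a [kit_panel()].
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) {
    stop_kinstr("panel file not found: ", path, class = "kinstr_io_error")
  }
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(spec$loci) || !length(spec$loci)) {
    stop_kinstr("panel ", path, ": empty locus list",
                class = "kinstr_panel_error")
  }
  ## superseded locus names corrected on load (nomenclature fixes)
  corrections <- c(D5S2500 = "D5S2800")
  loci <- lapply(spec$loci, function(l) {
    nm <- l$name
    aliases <- as.character(unlist(l$aliases %||% list()))
    if (nm %in% names(corrections)) {
      aliases <- unique(c(aliases, nm))
      nm <- unname(corrections[nm])
      aliases <- setdiff(aliases, nm)
    }
    sizes <- unlist(l$actual_size_nt)
    locus_def(name = nm,
              chromosome = l$chromosome,
              dye = l$dye,
              size_window_nt = as.numeric(unlist(l$size_window_nt)),
              ladder_alleles = as.character(unlist(l$ladder_alleles)),
              actual_size_nt = sizes,
              aliases = aliases,
              map_position_cm = as.numeric(l$map_position_cm %||% NA_real_),
              repeat_unit_nt = as.integer(l$repeat_unit_nt %||% 4L))
  })
  ## resolve aliases across loci: if any locus's name appears in another's
  ## alias set the panel constructor rejects it; a lone aliased name is
  ## corrected here
  alias_map <- list()
  for (l in loci) for (a in l$aliases) alias_map[[a]] <- l$name
  panel <- kit_panel(spec$name %||% basename(path), loci)
  attr(panel, "alias_map") <- alias_map
  panel
}

#' Write a panel definition to JSON
#'
#' Inverse of [load_panel()]: `load_panel(write_panel(p, f))` returns a panel
#' identical to `p` (alias resolution is idempotent, so an already-corrected
#' panel round-trips unchanged).
#'
#' @param panel a [kit_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  loci <- lapply(unname(panel$loci), function(l) {
    list(name = l$name, chromosome = l$chromosome, dye = l$dye,
         size_window_nt = l$size_window_nt,
         ladder_alleles = l$ladder_alleles,
         actual_size_nt = as.list(l$actual_size_nt),
         aliases = l$aliases,
         map_position_cm = l$map_position_cm,
         repeat_unit_nt = l$repeat_unit_nt)
  })
  jsonlite::write_json(list(name = panel$name, loci = loci), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Resolve a locus name against a panel
#'
#' Maps aliases (e.g. `"D5S2500"`) to the primary locus name and validates
#' that the locus exists in the panel.
#'
#' @param panel a [kit_panel()].
#' @param locus character vector of locus names or aliases.
#' @param permissive if `TRUE`, unknown names are returned unchanged instead
#'   of raising an error.
#' @return character vector of primary locus names.
#' @export
resolve_locus <- function(panel, locus, permissive = FALSE) {
  amap <- attr(panel, "alias_map") %||% list()
  for (l in panel$loci) for (a in l$aliases) amap[[a]] <- l$name
  out <- vapply(as.character(locus), function(nm) {
    if (nm %in% names(panel$loci)) return(nm)
    if (nm %in% names(amap)) return(amap[[nm]])
    if (permissive) return(nm)
    stop_kinstr("unknown locus: ", nm, class = "kinstr_panel_error")
  }, character(1))
  unname(out)
}

#' Autosomal STR subset of a panel
#'
#' Drops amelogenin (and any other non-autosomal marker) from a panel.
#' Population statistics in this package are computed on autosomal STRs
#' only.
#'
#' @param panel a [kit_panel()].
#' @return a [kit_panel()] containing only loci with chromosome 1--22.
#' @export
autosomal_panel <- function(panel) {
  keep <- vapply(panel$loci, function(l) l$chromosome %in% as.character(1:22),
                 logical(1))
  kit_panel(panel$name, panel$loci[keep])
}

#' Nominal fragment size of an allele
#'
#' Returns the manufacturer ("actual") size of a ladder allele, or a size
#' extrapolated from the ladder for an off-ladder allele: the nearest ladder
#' allele's size shifted by the repeat-value difference times the repeat
#' unit (fractional repeats count 1 nt each).
#'
#' @param panel a [kit_panel()].
#' @param locus locus name.
#' @param alleles character vector of allele labels.
#' @return numeric vector of sizes in nt.
#' @export
allele_size <- function(panel, locus, alleles) {
  l <- panel$loci[[resolve_locus(panel, locus)]]
  av <- allele_value(alleles)
  lv <- allele_value(l$ladder_alleles)
  vapply(seq_along(alleles), function(i) {
    hit <- match(alleles[i], l$ladder_alleles)
    if (!is.na(hit)) return(unname(l$actual_size_nt[hit]))
    j <- which.min(abs(lv - av[i]))
    whole <- floor(av[i]) - floor(lv[j])
    frac <- round((av[i] %% 1) * 10) - round((lv[j] %% 1) * 10)
    unname(l$actual_size_nt[j]) + whole * l$repeat_unit_nt + frac
  }, numeric(1))
}

## normalise a panel or a data.frame into a locus table
## (locus, chromosome, map_position_cm) for linkage work
as_locus_table <- function(x) {
  if (inherits(x, "kit_panel")) {
    data.frame(
      locus = vapply(x$loci, `[[`, character(1), "name"),
      chromosome = vapply(x$loci, `[[`, character(1), "chromosome"),
      map_position_cm = vapply(x$loci, `[[`, numeric(1), "map_position_cm"),
      row.names = NULL, stringsAsFactors = FALSE)
  } else if (is.data.frame(x)) {
    need <- c("locus", "chromosome")
    if (!all(need %in% names(x))) {
      stop_kinstr("locus table needs columns: ", paste(need, collapse = ", "),
                  class = "kinstr_panel_error")
    }
    x$chromosome <- as.character(x$chromosome)
    if (is.null(x$map_position_cm)) x$map_position_cm <- NA_real_
    x[, c("locus", "chromosome", "map_position_cm")]
  } else {
    stop_kinstr("expected a kit_panel or a locus data.frame",
                class = "kinstr_panel_error")
  }
}
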