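#' The ten chemical classes of the targeted identification library
#'
#' Section order of the packaged library: alcohols, aldehydes, aromatics,
#' acids, esters, heterocyclic, hydrocarbons, ketones, others, terpenes.
#' @export
target_classes <- c("alcohols", "aldehydes", "aromatics", "acids", "esters",
                    "heterocyclic", "hydrocarbons", "ketones", "others",
                    "terpenes")

#' Load the targeted identification library
#'
#' Reads a delimited-text target library (one header row; columns `name`,
#' `cas`, `class`, `rt1_min`, `rt1_rsd`, `rt2_s`, `rt2_rsd`, `it_exp`,
#' `it_tab`, `f_all`) into a validated `target_library` data frame. The
#' packaged library transcribes the 268 printed analyte rows of the silage
#' study's identification table verbatim, including its internal
#' inconsistencies (the printed grand total of 269 and aldehyde count of 37
#' do not match the rows actually printed); see `gcxgcfp_example()`.
#'
#' Sentinel strings are preserved as typed flags rather than numbers:
#' `"ND"` in the Fisher-ratio column sets `f_nd = TRUE` (`f_all = NA`),
#' `"NC"` and `">2500"` in the experimental retention-index column set
#' `it_unbounded = TRUE` (`it_exp = NA`). Downstream filters can therefore
#' distinguish "not determined" from zero.
#'
#' @param path Path to a CSV file.
#' @return A data frame of class `target_library` with columns `name`, `cas`,
#'   `chem_class` (factor over [target_classes]), `rt1_min`, `rt1_rsd_pct`,
#'   `rt2_s`, `rt2_rsd_pct`, `it_exp`, `it_unbounded`, `it_tab`, `f_all`,
#'   `f_nd`.
#' @examples
#' lib <- load_target_library(gcxgcfp_example("target_library.csv"))
#' class_counts(lib)[["esters"]]
#' @export
load_target_library <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.csv(path, colClasses = "character")
  needed <- c("name", "cas", "class", "rt1_min", "rt1_rsd", "rt2_s",
              "rt2_rsd", "it_exp", "it_tab", "f_all")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L) return(empty_target_library())

  bad_cas <- which(!grepl("^[0-9]+-[0-9]+-[0-9]$", raw$cas))
  if (length(bad_cas))
    stop("malformed CAS registry number in row(s) ",
         paste(bad_cas, collapse = ", "), ": ",
         paste(raw$cas[bad_cas], collapse = ", "))

  unknown <- setdiff(unique(raw$class), target_classes)
  if (length(unknown))
    stop("unknown chemical class header(s): ", paste(unknown, collapse = ", "))

  dup <- raw$cas[duplicated(raw$cas)]
  if (length(dup)) {
    for (d in unique(dup)) {
      nm <- unique(raw$name[raw$cas == d])
      if (length(nm) == 1L)
        stop("duplicate CAS ", d, " for identical record '", nm, "'")
      warning("CAS ", d, " shared by distinct analytes (",
              paste(nm, collapse = "; "),
              "); both records kept, retention index separates them",
              call. = FALSE)
    }
  }

  num <- function(x) suppressWarnings(as.numeric(x))
  it_unbounded <- raw$it_exp %in% c("NC", ">2500")
  it_exp <- num(raw$it_exp)
  bad_it <- which(!it_unbounded & is.na(it_exp))
  if (length(bad_it))
    stop("unparseable it_exp in row(s) ", paste(bad_it, collapse = ", "))
  f_nd <- raw$f_all == "ND"
  f_all <- num(raw$f_all)

  lib <- data.frame(
    name = raw$name,
    cas = raw$cas,
    chem_class = factor(raw$class, levels = target_classes),
    rt1_min = num(raw$rt1_min),
    rt1_rsd_pct = num(raw$rt1_rsd),
    rt2_s = num(raw$rt2_s),
    rt2_rsd_pct = num(raw$rt2_rsd),
    it_exp = it_exp,
    it_unbounded = it_unbounded,
    it_tab = num(raw$it_tab),
    f_all = f_all,
    f_nd = f_nd,
    stringsAsFactors = FALSE
  )
  validate_target_library(lib)
  class(lib) <- c("target_library", "data.frame")
  lib
}

empty_target_library <- function() {
  lib <- data.frame(name = character(), cas = character(),
                    chem_class = factor(character(), levels = target_classes),
                    rt1_min = numeric(), rt1_rsd_pct = numeric(),
                    rt2_s = numeric(), rt2_rsd_pct = numeric(),
                    it_exp = numeric(), it_unbounded = logical(),
                    it_tab = numeric(), f_all = numeric(), f_nd = logical(),
                    stringsAsFactors = FALSE)
  class(lib) <- c("target_library", "data.frame")
  lib
}

validate_target_library <- function(lib) {
  if (any(lib$rt1_min <= 0, na.rm = TRUE))
    stop("first-dimension retention times must be positive")
  if (any(lib$rt2_s < 0 | lib$rt2_s >= 3.5, na.rm = TRUE))
    stop("second-dimension retention times must lie in [0, 3.5) s")
  if (any(c(lib$rt1_rsd_pct, lib$rt2_rsd_pct) < 0, na.rm = TRUE))
    stop("%RSD fields must be non-negative")
  invisible(lib)
}

#' Write a target library back to delimited text
#'
#' Inverse of [load_target_library()]: typed sentinels are re-encoded as the
#' strings `"ND"`, `"NC"` (unbounded with no recorded index; only the
#' out-of-ladder hydrocarbon row) and `">2500"`. A written library loads back
#' with all fields identical.
#'
#' @param lib A `target_library`.
#' @param path Output CSV path.
#' @export
write_target_library <- function(lib, path) {
  stopifnot(inherits(lib, "target_library"))
  fmt <- function(x) ifelse(is.na(x), "", format(x, trim = TRUE,
                                                 scientific = FALSE))
  it_exp <- fmt(lib$it_exp)
  # Unbounded rows: "NC" (index not computable; such rows carry a tabulated
  # index) vs ">2500" (beyond the alkane ladder; no tabulated index printed).
  it_exp[lib$it_unbounded] <- ifelse(is.na(lib$it_tab[lib$it_unbounded]),
                                     ">2500", "NC")
  f_all <- fmt(lib$f_all)
  f_all[lib$f_nd] <- "ND"
  out <- data.frame(name = lib$name, cas = lib$cas,
                    class = as.character(lib$chem_class),
                    rt1_min = fmt(lib$rt1_min), rt1_rsd = fmt(lib$rt1_rsd_pct),
                    rt2_s = fmt(lib$rt2_s), rt2_rsd = fmt(lib$rt2_rsd_pct),
                    it_exp = it_exp, it_tab = fmt(lib$it_tab), f_all = f_all,
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Per-class analyte counts
#'
#' Counts library records per chemical class; classes with no record report
#' 0 and the counts always sum to the library size.
#'
#' @param lib A `target_library`.
#' @return Named integer vector over all ten classes.
#' @export
class_counts <- function(lib) {
  stopifnot(inherits(lib, "target_library"))
  tab <- table(lib$chem_class)
  setNames(as.integer(tab), names(tab))
}

#' @export
print.target_library <- function(x, ...) {
  cat("target_library:", nrow(x), "analytes\n")
  print(class_counts(x))
  invisible(x)
}

#' Path to a packaged example data file
#'
#' @param file File name under the package's `extdata` (default lists them).
#' @export
gcxgcfp_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "gcxgcfp")))
  path <- system.file("extdata", file, package = "gcxgcfp")
  if (path == "") stop("no packaged file called ", file)
  path
}

#' Deterministic reference spectra for a library
#'
#' Generates one synthetic reference spectrum per record via
#' [simulate_spectrum()], keyed by CAS number, standing in for a spectral
#' database so identification is reproducible offline. Records sharing a CAS
#' (the printed isomer pair) share a spectrum.
#'
#' @param lib A `target_library`.
#' @param seed_base Integer mixed into every per-compound hash (default 1).
#' @return Named list of `mass_spectrum`, one per row of `lib`.
#' @export
library_spectra <- function(lib, seed_base = 1L) {
  stopifnot(inherits(lib, "target_library"))
  out <- lapply(lib$cas, simulate_spectrum, seed_base = seed_base)
  names(out) <- lib$cas
  out
}
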