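# Curated differential-metabolite panel and molecular-formula mass arithmetic.

# IUPAC monoisotopic atomic masses (Da), most abundant isotope.
.monoiso <- c(
  C  = 12.0,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  P  = 30.97376151,
  S  = 31.97207069,
  F  = 18.9984031627,
  Cl = 34.968852682,
  Na = 22.989769282,
  K  = 38.9637064864,
  Se = 79.9165218,
  I  = 126.9044719
)

#' Parse a molecular formula
#'
#' Parses a plain molecular formula string such as `"C11H12N2O2"` into a
#' named count vector.  The grammar is an element symbol (one upper-case
#' letter optionally followed by one lower-case letter) followed by an
#' optional positive integer count; parentheses, charges and isotope labels
#' are not supported (none occur in the packaged panel).
#'
#' @param formula Character scalar, e.g. `"C6H12O6"`.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("H2O")
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    stop("`formula` must be a single non-empty character string")
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (paste(tokens, collapse = "") != formula) {
    stop("malformed molecular formula: '", formula, "'")
  }
  elems <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  if (any(counts < 1L)) stop("malformed molecular formula: '", formula, "'")
  out <- tapply(counts, factor(elems, levels = unique(elems)), sum)
  storage.mode(out) <- "integer"
  c(out)
}

#' Monoisotopic mass of a molecular formula
#'
#' Sums IUPAC monoisotopic atomic masses over the elements of a formula.
#' This is the neutral monoisotopic mass, the convention used for the
#' tabulated masses of the packaged metabolite panel.
#'
#' @param formula Either a formula string (see [parse_formula()]) or a named
#'   count vector/list (element symbol -> count).
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C11H12N2O2") # tryptophan, 204.0899
#' @export
monoisotopic_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else unlist(formula)
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("formula counts must be named by element symbol")
  }
  unknown <- setdiff(names(counts), names(.monoiso))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (any(counts <= 0)) stop("element counts must be positive")
  sum(.monoiso[names(counts)] * as.numeric(counts))
}

#' Mass error in parts per million
#'
#' @param observed Observed mass (Da).
#' @param theoretical Theoretical mass (Da); must be positive.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @examples
#' ppm_error(204.089941, 204.089878)
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("`theoretical` mass must be positive")
  1e6 * (observed - theoretical) / theoretical
}

#' Load the differential-metabolite panel
#'
#' Reads a metabolite panel from CSV.  The default is the packaged panel of
#' 43 endogenous metabolites found differential in contused skeletal muscle,
#' with molecular formula, measured neutral monoisotopic mass, printed mass
#' error, retention time and database identifiers.  The tabulated "m/z"
#' column holds neutral monoisotopic masses (it matches the formula masses,
#' e.g. valine at 117.0789 Da), not protonated-adduct m/z values.
#'
#' @param path CSV path; columns `index,name,formula,mz,mass_error_ppm,
#'   rt_min,mzcloud_id,hmdb_id`.  Empty identifier cells are read as `NA`.
#' @return A `metabolite_panel` data frame, one row per metabolite, in file
#'   order.
#' @examples
#' panel <- load_panel()
#' nrow(panel)
#' @export
load_panel <- function(path = system.file("extdata", "metabolite_panel.csv",
                                          package = "woundage")) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(mzcloud_id = "character",
                                hmdb_id = "character"))
  needed <- c("index", "name", "formula", "mz", "mass_error_ppm",
              "rt_min", "mzcloud_id", "hmdb_id")
  if (!identical(names(df), needed)) {
    stop("panel header must be: ", paste(needed, collapse = ","))
  }
  if (nrow(df) == 0L) {
    class(df) <- c("metabolite_panel", "data.frame")
    return(df)
  }
  df$mzcloud_id[!nzchar(trimws(df$mzcloud_id))] <- NA_character_
  df$hmdb_id[!nzchar(trimws(df$hmdb_id))] <- NA_character_
  if (anyDuplicated(df$index)) {
    stop("duplicate metabolite index in panel: ",
         paste(unique(df$index[duplicated(df$index)]), collapse = ", "))
  }
  for (i in seq_len(nrow(df))) {
    counts <- tryCatch(parse_formula(df$formula[i]), error = function(e) {
      stop("row ", i, " (", df$name[i], "): ", conditionMessage(e),
           call. = FALSE)
    })
    unknown <- setdiff(names(counts), names(.monoiso))
    if (length(unknown)) {
      stop("row ", i, " (", df$name[i], "): unknown element ",
           paste(unknown, collapse = ", "))
    }
  }
  stopifnot(all(df$index >= 1L), all(df$mz > 0), all(df$rt_min >= 0))
  if (any(abs(df$mass_error_ppm) >= 10)) {
    stop("panel mass errors must satisfy |ppm| < 10")
  }
  class(df) <- c("metabolite_panel", "data.frame")
  df
}

#' @export
print.metabolite_panel <- function(x, ...) {
  cat("Metabolite panel:", nrow(x), "records (",
      sum(!is.na(x$hmdb_id)), "with HMDB IDs )\n")
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("...", nrow(x) - 5L, "more rows\n")
  invisible(x)
}
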