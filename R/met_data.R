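#' Multi-environment trial data container
#'
#' Validates and indexes a long-format MET phenotype table: one row per plot
#' (RCBD/IBD) or per adjusted entry mean, with categorical columns for
#' genotype and location and, optionally, breeding region (mega-environment),
#' year, replicate and incomplete block, plus one numeric trait.
#'
#' Factor levels are ordered by first appearance in the table (not
#' alphabetically), so that array indices downstream are stable under edits
#' that preserve row order.
#'
#' @param data a data.frame in long format.
#' @param gen,loc,trait names of the genotype, location and trait columns.
#' @param reg,year,repl,block optional column names for region, year,
#'   replicate and block-within-replicate. `NULL` means absent.
#'
#' @return An object of class `met_data`: a list with
#' \describe{
#'   \item{records}{data.frame with standardized columns `gen`, `loc`,
#'     optional `reg`, `year`, `repl`, `block` (factors) and numeric `value`.}
#'   \item{genotypes, locations, regions, years}{ordered label vectors
#'     (`regions`/`years` are `character(0)` when absent).}
#'   \item{incidence}{J x K logical matrix: does genotype j have at least one
#'     record at location k.}
#'   \item{location_region}{named character vector mapping each location to
#'     its region (only when regions are present).}
#' }
#'
#' @examples
#' df <- data.frame(Gen = c("A", "A", "B"), Loc = c("E1", "E2", "E1"),
#'                  Y = c(10, 11, 9))
#' met <- met_data(df, gen = "Gen", loc = "Loc", trait = "Y")
#' met$incidence
#' @export
met_data <- function(data, gen, loc, trait, reg = NULL, year = NULL,
                     repl = NULL, block = NULL) {
  stopifnot(is.data.frame(data))
  need <- c(gen = gen, loc = loc, trait = trait, reg = reg, year = year,
            repl = repl, block = block)
  missing_cols <- setdiff(unname(need), names(data))
  if (length(missing_cols) > 0) {
    stop("column(s) not found in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }

  raw <- data[[trait]]
  if (!is.numeric(raw)) {
    parsed <- suppressWarnings(as.numeric(as.character(raw)))
    bad <- which(is.na(parsed) & !is.na(raw) & trimws(as.character(raw)) != "")
    if (length(bad) > 0) {
      stop(sprintf("non-numeric trait value in column '%s' at row %d: '%s'",
                   trait, bad[1], as.character(raw[bad[1]])), call. = FALSE)
    }
    raw <- parsed
  }
  if (anyNA(raw) || any(!is.finite(raw))) {
    bad <- which(is.na(raw) | !is.finite(raw))
    stop(sprintf("missing or non-finite trait value at row %d", bad[1]),
         call. = FALSE)
  }

  first_appearance <- function(x) unique(as.character(x))
  fac <- function(x, levels) factor(as.character(x), levels = levels)

  recs <- data.frame(
    gen = fac(data[[gen]], first_appearance(data[[gen]])),
    loc = fac(data[[loc]], first_appearance(data[[loc]]))
  )
  for (nm in c("reg", "year", "repl", "block")) {
    col <- need[nm]
    if (!is.na(col)) {
      v <- data[[col]]
      if (anyNA(v) || any(trimws(as.character(v)) == "")) {
        stop(sprintf("column '%s' is declared but has missing entries (row %d)",
                     col, which(is.na(v) | trimws(as.character(v)) == "")[1]),
             call. = FALSE)
      }
      recs[[nm]] <- fac(v, first_appearance(v))
    }
  }
  recs$value <- raw

  genotypes <- levels(recs$gen)
  locations <- levels(recs$loc)
  if (length(genotypes) < 2 || length(locations) < 2) {
    stop("need at least 2 genotypes and 2 locations", call. = FALSE)
  }

  location_region <- NULL
  if (!is.null(recs$reg)) {
    tab <- unique(recs[, c("loc", "reg")])
    dup <- tab$loc[duplicated(tab$loc)]
    if (length(dup) > 0) {
      stop(sprintf("location '%s' is mapped to more than one region",
                   as.character(dup[1])), call. = FALSE)
    }
    location_region <- stats::setNames(as.character(tab$reg),
                                       as.character(tab$loc))[locations]
  }

  incidence <- table(recs$gen, recs$loc) > 0
  incidence <- matrix(incidence, nrow = length(genotypes),
                      dimnames = list(genotypes, locations))

  structure(list(
    records = recs,
    genotypes = genotypes,
    locations = locations,
    regions = if (is.null(recs$reg)) character(0) else levels(recs$reg),
    years = if (is.null(recs$year)) character(0) else levels(recs$year),
    incidence = incidence,
    location_region = location_region
  ), class = "met_data")
}

#' Read a MET table from a delimited text file
#'
#' @param path path to a CSV (or other delimited) file with a header row.
#' @param gen,loc,trait,reg,year,repl,block column names, as in [met_data()].
#' @param sep field delimiter, `","` by default.
#' @return A [met_data] object.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(Gen = c("A", "A", "B"), Loc = c("E1", "E2", "E1"),
#'                      Y = c(10, 11, 9)), tf, row.names = FALSE)
#' met <- read_met_table(tf, gen = "Gen", loc = "Loc", trait = "Y")
#' @export
read_met_table <- function(path, gen = "Gen", loc = "Loc", trait = "Y",
                           reg = NULL, year = NULL, repl = NULL, block = NULL,
                           sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  met_data(df, gen = gen, loc = loc, trait = trait, reg = reg, year = year,
           repl = repl, block = block)
}

#' Write a validated MET table back to CSV
#'
#' Writes the standardized records (columns `gen`, `loc`, and any of `reg`,
#' `year`, `repl`, `block`, plus `value`) so that re-reading reproduces the
#' same label sets, incidence and values.
#'
#' @param met a [met_data] object.
#' @param path output file path.
#' @export
write_met_table <- function(met, path) {
  stopifnot(inherits(met, "met_data"))
  utils::write.csv(met$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize a MET dataset
#'
#' @param object a [met_data] object.
#' @param ... unused.
#' @return list with `J`, `K`, `M`, `Q`, `n_records` and `imbalance`, the
#'   fraction of genotype-by-location cells with no record,
#'   `1 - filled / (J * K)`.
#' @export
summary.met_data <- function(object, ...) {
  J <- length(object$genotypes)
  K <- length(object$locations)
  out <- list(
    J = J, K = K,
    M = length(object$regions),
    Q = length(object$years),
    n_records = nrow(object$records),
    imbalance = 1 - sum(object$incidence) / (J * K)
  )
  class(out) <- "summary.met_data"
  out
}

#' @export
print.summary.met_data <- function(x, ...) {
  cat(sprintf(
    "MET data: %d genotypes x %d locations (%d regions, %d years)\n",
    x$J, x$K, x$M, x$Q))
  cat(sprintf("  %d records, %.1f%% of genotype x location cells empty\n",
              x$n_records, 100 * x$imbalance))
  invisible(x)
}

#' @export
print.met_data <- function(x, ...) {
  print(summary(x))
  invisible(x)
}
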