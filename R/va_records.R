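#' Age stratum boundaries for verbal autopsy records
#'
#' VA studies of this design stratify deaths into three age groups that use
#' different cause-of-death category schemes: neonates (under 29 days),
#' children (29 days to 14 years) and adults (15 to 69 years). Deaths above
#' the adult cap are outside the study design and are excluded at load time.
#'
#' @return A list with elements `neonate_max_days` (29; exclusive upper
#'   bound in days), `child_max_years` (15; exclusive upper bound in years)
#'   and `adult_max_years` (69; inclusive upper bound in years).
#' @export
age_bounds <- function() {
  list(neonate_max_days = 29, child_max_years = 15, adult_max_years = 69)
}

#' Assign an age group from an age value
#'
#' Deterministically maps ages to the three VA strata: `< 29` days is
#' neonate, 29 days to 14 years is child, 15 to 69 years is adult. Ages
#' above `max_years` are out of the study range and return `NA` with a
#' warning.
#'
#' @param age_value Numeric vector of non-negative ages.
#' @param age_unit `"years"` or `"days"` (recycled to the length of
#'   `age_value` if scalar).
#' @param max_years Maximum age retained, in years (default 69).
#' @return Character vector in `c("neonate", "child", "adult")`, with `NA`
#'   for out-of-range ages.
#' @examples
#' assign_age_group(c(28, 29), "days")   # neonate, child
#' assign_age_group(15, "years")         # adult
#' @export
assign_age_group <- function(age_value, age_unit = "years", max_years = 69) {
  stopifnot(is.numeric(age_value), all(age_value >= 0, na.rm = TRUE))
  age_unit <- match.arg(rep(age_unit, length.out = length(age_value)),
                        c("years", "days"), several.ok = TRUE)
  days <- ifelse(age_unit == "days", age_value, age_value * 365.25)
  years <- ifelse(age_unit == "years", age_value, age_value / 365.25)
  b <- age_bounds()
  out <- ifelse(days < b$neonate_max_days, "neonate",
         ifelse(years < b$child_max_years, "child", "adult"))
  over <- !is.na(years) & years > max_years
  if (any(over)) {
    warning(sum(over), " record(s) older than ", max_years,
            " years are out of range and set to NA", call. = FALSE)
    out[over] <- NA_character_
  }
  out
}

va_age_groups <- function() c("adult", "child", "neonate")

#' Construct a cause-of-death category scheme
#'
#' A scheme names the ordered CoD category list for each age stratum, plus
#' an optional ICD-10 prefix lookup table mapping codes into those
#' categories. Adults and children typically share one list; neonates use a
#' separate, shorter list.
#'
#' @param name Scheme name.
#' @param categories_by_age_group Named list with character vectors for
#'   `adult`, `child` and `neonate`.
#' @param icd_map Optional data frame with columns `code_prefix` and
#'   `category` (see [read_icd_map()]).
#' @return An object of class `cod_scheme`.
#' @seealso [default_scheme()], [map_icd_to_category()]
#' @export
cod_scheme <- function(name, categories_by_age_group, icd_map = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  missing_groups <- setdiff(va_age_groups(), names(categories_by_age_group))
  if (length(missing_groups))
    stop("scheme is missing category lists for: ",
         paste(missing_groups, collapse = ", "))
  for (g in va_age_groups()) {
    cats <- categories_by_age_group[[g]]
    if (!is.character(cats) || !length(cats) || anyDuplicated(cats))
      stop("category list for '", g, "' must be a non-empty character ",
           "vector without duplicates")
  }
  scheme <- structure(
    list(name = name,
         categories_by_age_group = categories_by_age_group[va_age_groups()],
         icd_map = NULL),
    class = "cod_scheme")
  if (!is.null(icd_map)) scheme <- set_icd_map(scheme, icd_map)
  scheme
}

#' @export
print.cod_scheme <- function(x, ...) {
  cat("CoD scheme '", x$name, "'\n", sep = "")
  for (g in va_age_groups())
    cat("  ", g, ": ", length(x$categories_by_age_group[[g]]),
        " categories\n", sep = "")
  if (!is.null(x$icd_map))
    cat("  ICD-10 map: ", nrow(x$icd_map), " prefixes\n", sep = "")
  invisible(x)
}

#' Categories of a scheme for one age group
#' @param scheme A [cod_scheme()].
#' @param age_group One of `"adult"`, `"child"`, `"neonate"`.
#' @return Ordered character vector of categories.
#' @export
scheme_categories <- function(scheme, age_group) {
  stopifnot(inherits(scheme, "cod_scheme"))
  age_group <- match.arg(age_group, va_age_groups())
  scheme$categories_by_age_group[[age_group]]
}

#' The default 15 + 15 + 5 category scheme
#'
#' The built-in scheme groups ICD-10 codes into 15 broad categories for
#' adult and child deaths (acute respiratory infections, diarrhea,
#' pulmonary tuberculosis, other infections, neoplasms, nutrition,
#' cardiovascular disease, chronic respiratory disease, liver cirrhosis,
#' other non-communicable diseases, road/transport injuries, other
#' injuries, ill-defined, suicide, maternal) and 5 categories for neonatal
#' deaths. The ICD-10 prefix map itself is user-supplied (see
#' [read_icd_map()]); the scheme ships only the category lists.
#'
#' @return A `cod_scheme` named `"mds15"` with no ICD map attached.
#' @export
default_scheme <- function() {
  adult <- c(
    "Acute respiratory infections",
    "Diarrhea",
    "Pulmonary tuberculosis",
    "Other and unspecified infections",
    "Neoplasms",
    "Nutrition",
    "Cardiovascular disease",
    "Chronic respiratory disease",
    "Liver cirrhosis",
    "Other non-communicable diseases",
    "Road and transport injuries",
    "Other injuries",
    "Ill-defined",
    "Suicide",
    "Maternal")
  neonate <- c(
    "Prematurity/low birth weight",
    "Neonatal infections",
    "Birth asphyxia/trauma",
    "Ill-defined or cause unknown",
    "Other")
  cod_scheme("mds15",
             list(adult = adult, child = adult, neonate = neonate))
}

#' Read or write a scheme as JSON
#'
#' Schemes serialize as `{"name": ..., "categories_by_age_group":
#' {"adult": [...], "child": [...], "neonate": [...]}}`.
#'
#' @param path File path.
#' @return `read_scheme()` returns a `cod_scheme`; `write_scheme()` its
#'   `path`, invisibly.
#' @export
read_scheme <- function(path) {
  stopifnot(file.exists(path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cod_scheme(x$name, as.list(x$categories_by_age_group))
}

#' @rdname read_scheme
#' @param scheme A `cod_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "cod_scheme"))
  jsonlite::write_json(
    list(name = scheme$name,
         categories_by_age_group = scheme$categories_by_age_group),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read an ICD-10 prefix-to-category mapping table
#'
#' The mapping file is a two-column delimited file `code_prefix,category`.
#' Prefixes are normalized to uppercase with dots removed, so `"I50.9"`
#' and `"i509"` are equivalent.
#'
#' @param path CSV file path.
#' @return Data frame with columns `code_prefix` and `category`.
#' @export
read_icd_map <- function(path) {
  stopifnot(file.exists(path))
  map <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("code_prefix", "category")
  if (!all(required %in% names(map)))
    stop("ICD map file must have columns: ", paste(required, collapse = ", "))
  map$code_prefix <- normalize_icd(map$code_prefix)
  if (anyDuplicated(map$code_prefix))
    stop("duplicate code_prefix entries in ICD map: ",
         paste(unique(map$code_prefix[duplicated(map$code_prefix)]),
               collapse = ", "))
  map[required]
}

#' Attach an ICD map to a scheme
#'
#' Every mapped category must already appear in at least one of the
#' scheme's category lists.
#'
#' @param scheme A `cod_scheme`.
#' @param icd_map Data frame with `code_prefix` and `category` columns.
#' @return The scheme with `icd_map` attached.
#' @export
set_icd_map <- function(scheme, icd_map) {
  stopifnot(inherits(scheme, "cod_scheme"), is.data.frame(icd_map))
  icd_map$code_prefix <- normalize_icd(icd_map$code_prefix)
  if (anyDuplicated(icd_map$code_prefix))
    stop("icd_map keys must be unique")
  all_cats <- unique(unlist(scheme$categories_by_age_group))
  unknown <- setdiff(unique(icd_map$category), all_cats)
  if (length(unknown))
    stop("icd_map uses categories not in scheme '", scheme$name, "': ",
         paste(unknown, collapse = ", "))
  scheme$icd_map <- icd_map[c("code_prefix", "category")]
  scheme
}

#' Normalize an ICD-10 code for prefix matching
#'
#' Uppercases and strips whitespace and dots, so `"j18.9"` and `"J18 9"`
#' both normalize to `"J189"`.
#'
#' @param code Character vector of ICD-10 codes.
#' @return Character vector of normalized codes.
#' @export
normalize_icd <- function(code) gsub("[. ]", "", toupper(trimws(code)))

#' Map ICD-10 codes to scheme categories
#'
#' Codes are normalized (uppercased, dots stripped) and matched against the
#' scheme's prefix table by longest matching prefix, the standard way ICD
#' codes are grouped (e.g. prefix `"I5"` captures `"I50.9"`). With
#' `exact = TRUE` only whole-code matches count.
#'
#' @param icd10 Character vector of ICD-10 codes.
#' @param scheme A `cod_scheme` with an ICD map attached.
#' @param age_group Age stratum whose category list the result must belong
#'   to.
#' @param exact If `TRUE`, require exact code matches instead of longest
#'   prefix.
#' @return Character vector of categories, same length as `icd10`.
#'   Unmapped codes are an error (never silently dropped), as are codes
#'   mapping to a category outside the age group's list.
#' @export
map_icd_to_category <- function(icd10, scheme, age_group, exact = FALSE) {
  stopifnot(inherits(scheme, "cod_scheme"))
  if (is.null(scheme$icd_map))
    stop("scheme '", scheme$name, "' has no ICD map attached; see set_icd_map()")
  cats <- scheme_categories(scheme, age_group)
  codes <- normalize_icd(icd10)
  map <- scheme$icd_map
  out <- character(length(codes))
  for (i in seq_along(codes)) {
    if (exact) {
      hit <- match(codes[i], map$code_prefix)
    } else {
      is_prefix <- startsWith(codes[i], map$code_prefix)
      hit <- if (any(is_prefix)) {
        cand <- which(is_prefix)
        cand[which.max(nchar(map$code_prefix[cand]))]
      } else NA_integer_
    }
    if (is.na(hit))
      stop("unmapped ICD-10 code: '", icd10[i], "'", call. = FALSE)
    out[i] <- map$category[hit]
  }
  bad <- setdiff(unique(out), cats)
  if (length(bad))
    stop("mapped categories not in the '", age_group, "' list of scheme '",
         scheme$name, "': ", paste(bad, collapse = ", "))
  out
}

va_corpus_columns <- function()
  c("record_id", "age_group", "narrative", "icd10", "category", "source_tag")

#' Build a VA corpus data frame
#'
#' A corpus is a plain data frame with one row per death and columns
#' `record_id`, `age_group`, `narrative`, `icd10`, `category`,
#' `source_tag`. Optional fields default to `NA`.
#'
#' @param record_id Unique identifiers.
#' @param age_group `"adult"`, `"child"` or `"neonate"` per record.
#' @param narrative Free-text narratives.
#' @param icd10,category,source_tag Optional per-record fields.
#' @param scheme Optional `cod_scheme` used to validate `category`.
#' @return A data frame of class `c("va_corpus", "data.frame")`.
#' @export
va_corpus <- function(record_id, age_group, narrative,
                      icd10 = NA_character_, category = NA_character_,
                      source_tag = NA_character_, scheme = NULL) {
  corpus <- data.frame(record_id = as.character(record_id),
                       age_group = as.character(age_group),
                       narrative = as.character(narrative),
                       icd10 = as.character(icd10),
                       category = as.character(category),
                       source_tag = as.character(source_tag),
                       stringsAsFactors = FALSE)
  class(corpus) <- c("va_corpus", "data.frame")
  validate_corpus(corpus, scheme)
  corpus
}

#' Validate a VA corpus
#'
#' Checks record-id uniqueness, age-group values, non-empty narratives and
#' (when a scheme is supplied) that every assigned category belongs to the
#' scheme list for the record's age group.
#'
#' @param corpus A corpus data frame.
#' @param scheme Optional `cod_scheme`.
#' @return The corpus, invisibly; errors on violation.
#' @export
validate_corpus <- function(corpus, scheme = NULL) {
  stopifnot(is.data.frame(corpus))
  missing_cols <- setdiff(va_corpus_columns(), names(corpus))
  if (length(missing_cols))
    stop("corpus is missing columns: ", paste(missing_cols, collapse = ", "))
  dup <- unique(corpus$record_id[duplicated(corpus$record_id)])
  if (length(dup))
    stop("duplicate record_id values: ",
         paste(head(dup, 10), collapse = ", "))
  bad_age <- !corpus$age_group %in% va_age_groups()
  if (any(bad_age))
    stop("invalid age_group values: ",
         paste(unique(corpus$age_group[bad_age]), collapse = ", "))
  empty <- is.na(corpus$narrative) | !nzchar(trimws(corpus$narrative))
  if (any(empty))
    stop(sum(empty), " record(s) have an empty narrative; drop or flag ",
         "them before building a corpus")
  if (!is.null(scheme)) {
    for (g in va_age_groups()) {
      labs <- corpus$category[corpus$age_group == g]
      labs <- labs[!is.na(labs)]
      bad <- setdiff(unique(labs), scheme_categories(scheme, g))
      if (length(bad))
        stop("categories not in scheme '", scheme$name, "' for ", g, ": ",
             paste(bad, collapse = ", "))
    }
  }
  invisible(corpus)
}

#' Load VA records from a delimited or JSON-lines file
#'
#' Required fields are `record_id`, `narrative` and either `age_group` or
#' an `age_value` (+ optional `age_unit`, default years) pair from which
#' the stratum is derived via [assign_age_group()]. Rows with an empty
#' narrative, or ages above `max_age_years`, are skipped with a warning
#' naming their line numbers; duplicate record ids are fatal. Counts of
#' loaded vs skipped rows are reported via `message()`.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"jsonl"`.
#' @param scheme Optional `cod_scheme` used to validate categories.
#' @param max_age_years Exclusion cap passed to [assign_age_group()].
#' @return A `va_corpus` data frame.
#' @export
read_va_records <- function(path, format = c("auto", "csv", "jsonl"),
                            scheme = NULL, max_age_years = 69) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  if (format == "auto")
    format <- if (grepl("\\.jsonl$|\\.ndjson$", path)) "jsonl" else "csv"
  raw <- if (format == "csv") {
    read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
             fileEncoding = "UTF-8")
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, function(l) jsonlite::fromJSON(l))
    all_names <- unique(unlist(lapply(rows, names)))
    as.data.frame(
      stats::setNames(lapply(all_names, function(nm) {
        vapply(rows, function(r)
          if (is.null(r[[nm]])) NA_character_ else as.character(r[[nm]]),
          character(1))
      }), all_names),
      stringsAsFactors = FALSE)
  }
  if (!"record_id" %in% names(raw)) stop("missing required column: record_id")
  if (!"narrative" %in% names(raw)) stop("missing required column: narrative")
  if (!"age_group" %in% names(raw) && !"age_value" %in% names(raw))
    stop("missing required column: age_group or age_value")
  n_in <- nrow(raw)
  skip <- rep(FALSE, n_in)
  reason <- character(n_in)

  if (!"age_group" %in% names(raw) ||
      all(is.na(raw$age_group) | !nzchar(raw$age_group))) {
    unit <- if ("age_unit" %in% names(raw)) raw$age_unit else "years"
    unit[is.na(unit) | !nzchar(unit)] <- "years"
    raw$age_group <- suppressWarnings(
      assign_age_group(as.numeric(raw$age_value), unit,
                       max_years = max_age_years))
  }
  out_of_range <- is.na(raw$age_group) | !raw$age_group %in% va_age_groups()
  skip[out_of_range] <- TRUE
  reason[out_of_range] <- "age out of range"
  no_narr <- is.na(raw$narrative) | !nzchar(trimws(raw$narrative))
  skip[no_narr & !skip] <- TRUE
  reason[no_narr & reason == ""] <- "empty narrative"

  if (any(skip))
    warning("skipped ", sum(skip), " row(s): ",
            paste(sprintf("line %d (%s)", which(skip) + 1L,
                          reason[skip]), collapse = "; "),
            call. = FALSE)
  kept <- raw[!skip, , drop = FALSE]
  dup <- unique(kept$record_id[duplicated(kept$record_id)])
  if (length(dup))
    stop("duplicate record_id values in ", path, ": ",
         paste(head(dup, 10), collapse = ", "))
  opt <- function(nm) if (nm %in% names(kept)) kept[[nm]] else NA_character_
  corpus <- va_corpus(kept$record_id, kept$age_group, kept$narrative,
                      icd10 = opt("icd10"), category = opt("category"),
                      source_tag = opt("source_tag"), scheme = scheme)
  message("loaded ", nrow(corpus), " of ", n_in, " record(s) from ", path,
          " (", sum(skip), " skipped)")
  corpus
}

#' Write VA records to CSV or JSON-lines
#'
#' Inverse of [read_va_records()]: a write–read round trip preserves all
#' corpus fields.
#'
#' @param corpus A `va_corpus` data frame.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_va_records <- function(corpus, path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  validate_corpus(corpus)
  if (format == "auto")
    format <- if (grepl("\\.jsonl$|\\.ndjson$", path)) "jsonl" else "csv"
  cols <- va_corpus_columns()
  if (format == "csv") {
    write.csv(corpus[cols], path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    lines <- vapply(seq_len(nrow(corpus)), function(i) {
      row <- as.list(corpus[i, cols])
      row <- row[!vapply(row, function(v) is.na(v), logical(1))]
      jsonlite::toJSON(row, auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Stratify a corpus by age group
#'
#' @param corpus A `va_corpus`.
#' @return Named list of corpora, one per age group present; every record
#'   lands in exactly one stratum.
#' @export
split_by_age_group <- function(corpus) {
  validate_corpus(corpus)
  split(corpus, factor(corpus$age_group, levels = va_age_groups()),
        drop = TRUE)
}
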