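#' Path to a shipped study fixture
#'
#' The package ships UTF-8 CSV transcriptions of the study's printed tables:
#' the compound-to-class listing (`table1_classes.csv`), the per-compound
#' concentration tables for the Guariba and Valparaiso areas
#' (`table2_guariba.csv`, `table3_valparaiso.csv`), the antioxidant IC50
#' table (`table4_antioxidant.csv`), the fitted coded-factor coefficients
#' (`table5_coefficients.csv`), and the per-sample harvest conditions
#' (`sample_conditions_synthetic_infection.csv`; its numeric
#' `infection_level` column is a synthetic stand-in, see
#' [read_sample_conditions()]).
#'
#' @param name File name of the fixture.
#' @return Absolute path to the installed file.
#' @export
#' @examples
#' straw_fixture("table1_classes.csv")
straw_fixture <- function(name) {
  path <- system.file("extdata", name, package = "strawpoly")
  if (!nzchar(path)) stop("no fixture named '", name, "'", call. = FALSE)
  path
}

#' The nine sugarcane varieties of the sampling plan
#'
#' Closed list, in the study's listing order; the response-surface coding
#' maps this ordinal position onto the coded interval \[-1, 1\].
#' @export
straw_varieties <- function() {
  c("SP813250", "SP803280", "CU0618", "RB985476", "CTC4",
    "CU7870", "CTC15", "RB966928", "CTC9001")
}

#' The three polyphenol classes and two antioxidant responses
#' @return Character vector of the five modelled response names.
#' @export
straw_responses <- function() {
  c("hydroxybenzoic", "hydroxycinnamic", "flavones", "abts_ic50", "dpph_ic50")
}

# Parse one concentration cell: "value ± sd", "value", "-", "" or "ND".
# Returns list(value, sd, detected). "-"/"" mean not detected (0 by
# convention); "ND" means not determined (NA). Malformed cells error.
parse_measure_cell <- function(cell, row = "?", col = "?") {
  raw <- normalize_name(cell)
  if (raw == "-" || raw == "") {
    return(list(value = 0, sd = NA_real_, detected = FALSE))
  }
  if (toupper(raw) == "ND") {
    return(list(value = NA_real_, sd = NA_real_, detected = NA))
  }
  has_sep <- grepl("±|\\+/-", raw)
  parts <- trimws(strsplit(raw, "±|\\+/-")[[1]])
  vals <- suppressWarnings(as.numeric(parts))
  bad <- if (has_sep) {
    length(parts) != 2L || any(!nzchar(parts)) || any(is.na(vals))
  } else {
    length(parts) != 1L || !nzchar(parts) || is.na(vals)
  }
  if (bad) {
    stop("unparseable cell '", cell, "' at ", cell_ref(row, col),
         call. = FALSE)
  }
  list(value = vals[1L],
       sd = if (length(vals) == 2L) vals[2L] else NA_real_,
       detected = TRUE)
}

#' Read a compound-to-class map
#'
#' @param path CSV with columns `compound` and `class`; defaults to the
#'   shipped listing of the 40 identified compounds.
#' @return Data frame with normalized `compound` names and `class` values in
#'   `hydroxybenzoic_acids`, `hydroxycinnamic_acids`, `flavones`.
#' @export
read_class_map <- function(path = straw_fixture("table1_classes.csv")) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  stopifnot(all(c("compound", "class") %in% names(map)))
  map$compound <- normalize_name(map$compound)
  valid <- c("hydroxybenzoic_acids", "hydroxycinnamic_acids", "flavones")
  if (!all(map$class %in% valid)) {
    stop("unknown class label(s): ",
         paste(setdiff(map$class, valid), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(map$compound)) {
    stop("duplicated compound in class map", call. = FALSE)
  }
  map
}

#' Look up the polyphenol class of a compound
#'
#' @param name Compound name (normalized before matching).
#' @param map Class map from [read_class_map()].
#' @return The class label.
#' @export
#' @examples
#' map_class("Chlorogenic acid", read_class_map())
map_class <- function(name, map = read_class_map()) {
  key <- normalize_name(name)
  hit <- match(key, map$compound)
  if (any(is.na(hit))) {
    stop("compound(s) not in class map: ",
         paste(key[is.na(hit)], collapse = ", "), call. = FALSE)
  }
  map$class[hit]
}

#' Read a per-compound concentration table
#'
#' Reads a wide CSV whose header names the samples and whose cells follow
#' the `"value ± sd"` grammar of the printed tables; `"-"` marks a
#' compound that was not detected in that extract and is recorded as
#' concentration 0.
#'
#' @param path CSV fixture path.
#' @param map Optional class map; when given, every compound must be
#'   mappable (validation error otherwise).
#' @return Long data frame: `sample_id`, `compound`, `concentration`
#'   (ug/g dry extract), `sd`, `detected`.
#' @export
read_compound_table <- function(path, map = NULL) {
  wide <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                          encoding = "UTF-8")
  stopifnot(names(wide)[1L] == "compound")
  compounds <- normalize_name(wide$compound)
  samples <- names(wide)[-1L]
  if (!is.null(map)) {
    unknown <- setdiff(compounds, map$compound)
    if (length(unknown)) {
      stop("unknown compound(s) not in class map: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  out <- vector("list", length(samples))
  for (j in seq_along(samples)) {
    cells <- wide[[j + 1L]]
    parsed <- lapply(seq_along(cells), function(i) {
      parse_measure_cell(cells[i], row = compounds[i], col = samples[j])
    })
    out[[j]] <- data.frame(
      sample_id = samples[j],
      compound = compounds,
      concentration = vapply(parsed, `[[`, numeric(1), "value"),
      sd = vapply(parsed, `[[`, numeric(1), "sd"),
      detected = vapply(parsed, `[[`, logical(1), "detected"),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (any(res$concentration < 0, na.rm = TRUE)) {
    stop("negative concentration in ", path, call. = FALSE)
  }
  res
}

#' Read the antioxidant IC50 table
#'
#' @param path CSV fixture with `abts`/`dpph` cells in the
#'   `"value ± sd"` grammar; `ND` (not determined) becomes `NA` and is
#'   excluded from any model fitted to that response.
#' @return Data frame with `sample_id`, printed condition metadata, and
#'   numeric `abts_ic50`, `abts_sd`, `dpph_ic50`, `dpph_sd` (mg/mL).
#' @export
read_antioxidant_table <- function(path = straw_fixture("table4_antioxidant.csv")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  for (assay in c("abts", "dpph")) {
    parsed <- lapply(seq_len(nrow(tab)), function(i) {
      parse_measure_cell(tab[[assay]][i], row = tab$sample_id[i], col = assay)
    })
    tab[[paste0(assay, "_ic50")]] <- vapply(parsed, `[[`, numeric(1), "value")
    tab[[paste0(assay, "_sd")]] <- vapply(parsed, `[[`, numeric(1), "sd")
  }
  tab$abts <- NULL
  tab$dpph <- NULL
  tab
}

#' Read per-sample harvest conditions
#'
#' The printed tables state only a high/low borer-infection class (high:
#' 4--11\%, low: 0--4\%); the numeric `infection_level` column in the
#' shipped fixture is a synthetic stand-in at the class midpoints (7.5 and
#' 2.0\%), which is why the file name carries `synthetic_infection`.
#'
#' @param path CSV with columns `sample_id`, `area`, `collection_date`,
#'   `variety`, `infection_class`, `infection_level`, `harvest_number`.
#' @return Validated data frame; `collection_date` is a `Date`.
#' @export
read_sample_conditions <- function(
    path = straw_fixture("sample_conditions_synthetic_infection.csv")) {
  cond <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  cond$collection_date <- as.Date(cond$collection_date)
  validate_conditions(cond)
  cond
}

#' Validate a table of harvest conditions
#'
#' Checks the sampling-plan invariants: known area and variety levels,
#' harvest number in 1--7, non-negative infection level.
#'
#' @param cond Data frame of conditions.
#' @return The input, invisibly, if valid.
#' @export
validate_conditions <- function(cond) {
  need <- c("sample_id", "area", "collection_date", "variety",
            "infection_level", "harvest_number")
  missing_cols <- setdiff(need, names(cond))
  if (length(missing_cols)) {
    stop("conditions lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(cond$area %in% c("Guariba", "Valparaiso"))) {
    stop("unknown area level(s): ",
         paste(setdiff(cond$area, c("Guariba", "Valparaiso")), collapse = ", "),
         call. = FALSE)
  }
  if (!all(cond$variety %in% straw_varieties())) {
    stop("unknown variety level(s): ",
         paste(setdiff(cond$variety, straw_varieties()), collapse = ", "),
         call. = FALSE)
  }
  if (!all(cond$harvest_number %in% 1:7)) {
    stop("harvest_number outside 1..7", call. = FALSE)
  }
  if (any(cond$infection_level < 0)) {
    stop("negative infection_level", call. = FALSE)
  }
  invisible(cond)
}

#' Aggregate per-compound concentrations into class responses
#'
#' Per sample, each polyphenol class response is the sum of the
#' concentrations of that class's compounds; compounds recorded as not
#' detected contribute 0. Antioxidant IC50s are merged in when supplied.
#'
#' @param measurements Long measurement table from [read_compound_table()].
#' @param map Class map from [read_class_map()].
#' @param antioxidant Optional table from [read_antioxidant_table()].
#' @return Response table: one row per sample with `hydroxybenzoic`,
#'   `hydroxycinnamic`, `flavones` (ug/g) and, if supplied, `abts_ic50`,
#'   `dpph_ic50` (mg/mL, `NA` where not determined).
#' @export
aggregate_classes <- function(measurements, map = read_class_map(),
                              antioxidant = NULL) {
  cls <- map_class(measurements$compound, map)
  samples <- unique(measurements$sample_id)
  short <- c(hydroxybenzoic_acids = "hydroxybenzoic",
             hydroxycinnamic_acids = "hydroxycinnamic",
             flavones = "flavones")
  out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  for (k in names(short)) {
    sel <- cls == k
    sums <- tapply(measurements$concentration[sel],
                   factor(measurements$sample_id[sel], levels = samples),
                   sum)
    sums[is.na(sums)] <- 0
    out[[short[[k]]]] <- as.numeric(sums)
  }
  empty <- tapply(measurements$detected,
                  factor(measurements$sample_id, levels = samples),
                  function(d) !any(d, na.rm = TRUE))
  if (any(empty)) {
    warning("sample(s) with no detected compounds: ",
            paste(samples[empty], collapse = ", "), call. = FALSE)
  }
  if (!is.null(antioxidant)) {
    i <- match(out$sample_id, antioxidant$sample_id)
    out$abts_ic50 <- antioxidant$abts_ic50[i]
    out$dpph_ic50 <- antioxidant$dpph_ic50[i]
  }
  out
}

#' Per-compound extrema within a geographic area
#'
#' @param measurements Long measurement table.
#' @param conditions Conditions table mapping `sample_id` to `area`.
#' @param area Area to summarise (`"Guariba"` or `"Valparaiso"`).
#' @return Data frame per compound: min and max detected concentration with
#'   the attributed sample ids.
#' @export
summarize_extrema <- function(measurements, conditions, area) {
  if (!area %in% conditions$area) {
    stop("unknown group '", area, "'", call. = FALSE)
  }
  ids <- conditions$sample_id[conditions$area == area]
  m <- measurements[measurements$sample_id %in% ids, , drop = FALSE]
  if (!nrow(m)) stop("no measurements for area '", area, "'", call. = FALSE)
  res <- do.call(rbind, lapply(split(m, m$compound), function(d) {
    data.frame(compound = d$compound[1L],
               area = area,
               min = min(d$concentration),
               min_sample = d$sample_id[which.min(d$concentration)],
               max = max(d$concentration),
               max_sample = d$sample_id[which.max(d$concentration)],
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

#' Write / read a response table as tidy long CSV
#'
#' Values are written in full precision so that a write/read round trip
#' reproduces the table exactly (to 1e-9 and beyond).
#'
#' @param responses Response table from [aggregate_classes()].
#' @param path Output CSV path.
#' @return `write_responses_csv` returns `path` invisibly;
#'   `read_responses_csv` returns the wide response table.
#' @export
write_responses_csv <- function(responses, path) {
  value_cols <- setdiff(names(responses), "sample_id")
  long <- do.call(rbind, lapply(value_cols, function(v) {
    vals <- responses[[v]]
    data.frame(sample_id = responses$sample_id, response = v,
               value = ifelse(is.na(vals), NA_character_,
                              sprintf("%.17g", vals)),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_responses_csv
#' @export
read_responses_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  samples <- unique(long$sample_id)
  out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  for (v in unique(long$response)) {
    sel <- long[long$response == v, ]
    out[[v]] <- as.numeric(sel$value)[match(samples, sel$sample_id)]
  }
  out
}

#' Load the full transcribed study dataset
#'
#' Convenience reader combining the shipped fixtures: conditions, long
#' measurements for both areas, the class map, the antioxidant table, and
#' the aggregated response table.
#'
#' @return A list with elements `conditions`, `measurements`, `class_map`,
#'   `antioxidant`, `responses`.
#' @export
load_study_data <- function() {
  map <- read_class_map()
  meas <- rbind(
    read_compound_table(straw_fixture("table2_guariba.csv"), map = map),
    read_compound_table(straw_fixture("table3_valparaiso.csv"), map = map)
  )
  cond <- read_sample_conditions()
  anti <- read_antioxidant_table()
  resp <- aggregate_classes(meas, map, antioxidant = anti)
  resp <- resp[match(cond$sample_id, resp$sample_id), , drop = FALSE]
  rownames(resp) <- NULL
  list(conditions = cond, measurements = meas, class_map = map,
       antioxidant = anti, responses = resp)
}
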