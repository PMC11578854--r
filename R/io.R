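# File formats: strict CSV schemas for the three data streams, the
# key-value truth file written alongside synthetic scenarios, and the
# quadrat-to-colony survey extrapolation helper.

check_columns <- function(d, cols, what, path) {
  miss <- setdiff(cols, names(d))
  if (length(miss) > 0)
    stopf("%s file '%s' is missing column(s): %s", what, path,
          paste(miss, collapse = ", "))
}

bad_rows <- function(cond) which(cond) + 1L  # +1 for the header line

#' Read breeding-pair survey counts
#'
#' Schema: columns `year`, `pairs`; nonnegative integer pairs; no
#' duplicate years.  Validation failures report file line numbers.
#'
#' @param path CSV path
#' @return validated data.frame
#' @export
read_counts <- function(path) {
  d <- read.csv(path)
  check_columns(d, c("year", "pairs"), "count", path)
  if (any(bad <- !is.finite(d$pairs) | d$pairs < 0 | d$pairs != round(d$pairs)))
    stopf("count file '%s': invalid pair count at line(s) %s", path,
          paste(bad_rows(bad), collapse = ", "))
  if (anyDuplicated(d$year))
    stopf("count file '%s': duplicate year(s) %s", path,
          paste(unique(d$year[duplicated(d$year)]), collapse = ", "))
  d[order(d$year), c("year", "pairs")]
}

#' Write breeding-pair survey counts
#' @param counts data.frame (`year`, `pairs`)
#' @param path CSV path
#' @export
write_counts <- function(counts, path) {
  write.csv(counts[, c("year", "pairs")], path, row.names = FALSE)
}

#' Read long-format encounter-count CMR data
#'
#' Schema: `individual_id`, `year`, `age_at_mark`, `mark_year`,
#' `encounter_count` — one row per individual-season from the marking
#' season onward.  Checks: no duplicate (id, year); nonnegative counts;
#' a count of at least 1 at each individual's marking season; age at
#' mark 1 (chick) or >= 4 (adult).
#'
#' @param path CSV path
#' @return validated data.frame
#' @export
read_cmr <- function(path) {
  d <- read.csv(path)
  check_columns(d, c("individual_id", "year", "age_at_mark", "mark_year",
                     "encounter_count"), "CMR", path)
  if (any(bad <- !is.finite(d$encounter_count) | d$encounter_count < 0))
    stopf("CMR file '%s': negative or missing encounter count at line(s) %s",
          path, paste(bad_rows(bad), collapse = ", "))
  if (any(bad <- !(d$age_at_mark == 1 | d$age_at_mark >= 4)))
    stopf("CMR file '%s': age_at_mark must be 1 or >= 4 at line(s) %s",
          path, paste(bad_rows(bad), collapse = ", "))
  key <- paste(d$individual_id, d$year)
  if (any(dup <- duplicated(key)))
    stopf("CMR file '%s': duplicate (individual, year) row(s) at line(s) %s",
          path, paste(bad_rows(dup), collapse = ", "))
  if (any(bad <- d$year == d$mark_year & d$encounter_count < 1))
    stopf("CMR file '%s': marking-season count must be >= 1 at line(s) %s",
          path, paste(bad_rows(bad), collapse = ", "))
  d
}

#' Write long-format CMR data
#' @param cmr data.frame as read by [read_cmr()]
#' @param path CSV path
#' @export
write_cmr <- function(cmr, path) {
  write.csv(cmr[, c("individual_id", "year", "age_at_mark", "mark_year",
                    "encounter_count")], path, row.names = FALSE)
}

#' Read productivity records
#'
#' Schema: `year`, `burrows_monitored`, `chicks_fledged` with
#' `0 <= chicks_fledged <= burrows_monitored`.
#'
#' @param path CSV path
#' @return validated data.frame
#' @export
read_productivity <- function(path) {
  d <- read.csv(path)
  check_columns(d, c("year", "burrows_monitored", "chicks_fledged"),
                "productivity", path)
  if (any(bad <- !is.finite(d$chicks_fledged) | d$chicks_fledged < 0 |
            d$chicks_fledged > d$burrows_monitored))
    stopf("productivity file '%s': chicks_fledged outside [0, burrows] at line(s) %s",
          path, paste(bad_rows(bad), collapse = ", "))
  if (anyDuplicated(d$year))
    stopf("productivity file '%s': duplicate year(s)", path)
  d[order(d$year), c("year", "burrows_monitored", "chicks_fledged")]
}

#' Write productivity records
#' @param productivity data.frame as read by [read_productivity()]
#' @param path CSV path
#' @export
write_productivity <- function(productivity, path) {
  write.csv(productivity[, c("year", "burrows_monitored", "chicks_fledged")],
            path, row.names = FALSE)
}

#' Read a scenario directory into a typed bundle
#'
#' @param dir directory written by [generate_scenario()], or any
#'   directory holding the three stream CSVs (missing streams yield
#'   `NULL` entries so single-dataset fits still work)
#' @return list with `counts`, `cmr`, `productivity`, and `truth` when
#'   present
#' @export
read_scenario <- function(dir) {
  rd <- function(f, reader) {
    p <- file.path(dir, f)
    if (file.exists(p)) reader(p) else NULL
  }
  list(counts = rd("counts.csv", read_counts),
       cmr = rd("cmr.csv", read_cmr),
       productivity = rd("productivity.csv", read_productivity),
       truth = rd("truth.txt", read_truth))
}

# --- truth file (structured key-value text) ----------------------------

kv_line <- function(key, value) {
  paste0(key, ": ", paste(format(value, digits = 15, scientific = FALSE,
                                 trim = TRUE), collapse = " "))
}

#' Write the truth record of a synthetic scenario
#' @param bundle result of [generate_scenario()]
#' @param path output text path
#' @export
write_truth <- function(bundle, path) {
  cfg <- bundle$config
  r <- cfg$rates; d <- cfg$detect
  lines <- c(
    kv_line("seed", bundle$seed),
    kv_line("species_label", cfg$design$species_label),
    kv_line("years", cfg$design$years),
    kv_line("survey_years", cfg$design$survey_years),
    kv_line("alpha1", r$alpha1),
    kv_line("alpha2", r$alpha2),
    kv_line("f", r$f),
    kv_line("omega", r$omega),
    kv_line("gamma1", d$gamma1),
    kv_line("gamma2", d$gamma2),
    kv_line("epsilon_prebreeder", d$epsilon[1, ]),
    kv_line("epsilon_breeder", d$epsilon[2, ]),
    kv_line("theta", d$theta),
    kv_line("initial_total_pairs", cfg$initial_total_pairs),
    kv_line("initial_immigrant_lambda", cfg$initial_immigrant_lambda),
    kv_line("Ntot", bundle$states$Ntot))
  for (s in seq_len(5)) {
    lines <- c(lines, kv_line(STAGE_NAMES[s], bundle$states$N[s, ]))
  }
  writeLines(lines, path)
}

#' Read a truth record
#' @param path truth text path
#' @return named list; multi-valued keys become numeric vectors
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  out <- list()
  for (ln in lines[nzchar(lines)]) {
    key <- sub(":.*$", "", ln)
    val <- trimws(sub("^[^:]*:", "", ln))
    parts <- strsplit(val, " +")[[1]]
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (anyNA(num)) val else num
  }
  out
}

#' Extrapolate quadrat burrow occupancy to colony breeding pairs
#'
#' Density surveys count occupied burrows in quadrats along transects;
#' assuming even burrow distribution, the density per square metre is
#' scaled to the colony's breeding area.  Defaults: 2 x 2 m quadrats
#' and a 20,000 square metre breeding area.
#'
#' @param occupied number of occupied burrows counted
#' @param n_quadrats number of quadrats surveyed
#' @param quadrat_area area of one quadrat in square metres (default 4)
#' @param breeding_area colony breeding area in square metres
#'   (default 20000)
#' @return estimated number of breeding pairs (rounded to integer)
#' @export
extrapolate_pairs <- function(occupied, n_quadrats, quadrat_area = 4,
                              breeding_area = 20000) {
  if (any(c(n_quadrats, quadrat_area, breeding_area) <= 0) || occupied < 0)
    stopf("areas and quadrat counts must be positive; occupied nonnegative")
  round(occupied / (n_quadrats * quadrat_area) * breeding_area)
}
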