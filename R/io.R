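#' CSV schemas used by the pipeline
#'
#' Each schema lists required columns with their types and an optional
#' whole-table validator. Unknown extra columns are kept with a warning,
#' never silently dropped.
#'
#' @return named list of schema definitions.
#' @export
table_schemas <- function() {
  list(
    mortality = list(
      columns = c(treatment_id = "character", replicate = "character",
                  day = "numeric", n_initial = "numeric",
                  n_dead_cum = "numeric"),
      validate = check_mortality_records),
    germination = list(
      columns = c(temperature = "numeric", plate_id = "character",
                  coverslip_index = "numeric",
                  n_germinated = "numeric", n_scored = "numeric"),
      validate = function(d) {
        bad <- which(d$n_germinated < 0 | d$n_germinated > d$n_scored)
        if (length(bad))
          stop("germination: n_germinated outside [0, n_scored] at row(s) ",
               paste(bad, collapse = ", "))
        invisible(TRUE)
      }),
    radial_growth = list(
      columns = c(plate_id = "character", strain = "character",
                  temperature = "numeric", day = "numeric",
                  q1 = "numeric", q2 = "numeric", q3 = "numeric",
                  q4 = "numeric"),
      validate = function(d) {
        bad <- which(d$q1 < 0 | d$q2 < 0 | d$q3 < 0 | d$q4 < 0)
        if (length(bad))
          stop("radial_growth: negative radius at row(s) ",
               paste(bad, collapse = ", "))
        invisible(TRUE)
      }),
    growth_rates = list(
      columns = c(strain = "character", temperature = "numeric",
                  plate_id = "character", beta = "numeric"),
      validate = NULL),
    survival = list(
      columns = c(subject_id = "character", group = "character",
                  time = "numeric", event = "numeric"),
      validate = function(d) {
        bad <- which(d$time <= 0 | !(d$event %in% c(0, 1)))
        if (length(bad))
          stop("survival: invalid time/event at row(s) ",
               paste(bad, collapse = ", "))
        invisible(TRUE)
      }),
    conidia_loads = list(
      columns = c(fly_id = "character", sex = "character",
                  role = "character", irradiated = "logical",
                  day_post_exposure = "numeric",
                  conidia_per_ml = "numeric"),
      validate = function(d) {
        bad <- which(d$conidia_per_ml < 0)
        if (length(bad))
          stop("conidia_loads: negative load at row(s) ",
               paste(bad, collapse = ", "))
        invisible(TRUE)
      }))
}

#' Read and validate a pipeline CSV
#'
#' Header-validated, type-coerced read of one of the pipeline's tables.
#' Missing columns, non-numeric cells and violated invariants fail with the
#' offending column or row named.
#'
#' @param path CSV path.
#' @param schema schema name, one of `names(table_schemas())`.
#' @return validated data.frame.
#' @export
read_table <- function(path, schema) {
  schemas <- table_schemas()
  schema <- match.arg(schema, names(schemas))
  if (!file.exists(path)) stop("file not found: ", path)
  sch <- schemas[[schema]]
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(names(sch$columns), names(d))
  if (length(missing))
    stop(schema, ": missing column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(d), names(sch$columns))
  if (length(extra))
    warning(schema, ": unknown column(s) kept: ",
            paste(extra, collapse = ", "))
  for (col in names(sch$columns)) {
    type <- sch$columns[[col]]
    if (type == "numeric") {
      v <- suppressWarnings(as.numeric(d[[col]]))
      bad <- which(is.na(v) & !is.na(d[[col]]))
      if (length(bad))
        stop(schema, ": non-numeric value in column '", col,
             "' at row(s) ", paste(bad, collapse = ", "))
      d[[col]] <- v
    } else if (type == "logical") {
      d[[col]] <- as.logical(d[[col]])
    } else d[[col]] <- as.character(d[[col]])
  }
  if (!is.null(sch$validate)) sch$validate(d)
  d
}

#' Write a pipeline CSV
#'
#' Plain UTF-8 CSV with a header row and '.' decimal separator; the inverse
#' of [read_table()] on the value level.
#'
#' @param d data.frame.
#' @param path output path (parent directory is created).
#' @return `path`, invisibly.
#' @export
write_table <- function(d, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

# small deterministic string hash (djb2) used to stamp outputs with the
# configuration they came from
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}
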