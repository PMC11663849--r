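#' Published cardinal-temperature estimates for the ICIPE strain panel
#'
#' Literature-reported cardinal temperature and maximal-rate estimates for
#' the SIT-compatible *Metarhizium anisopliae* / *Beauveria bassiana* strain
#' panel (ICIPE 20, 41, 62, 78, 603), shipped as a plain-text reference
#' table. Three sources are available: the tabulated CTMI parameter columns
#' (`"table_ctmi"`: `mu_opt`, `Tmin`, `Topt`, `Tmax`), the tabulated
#' Lactin-1 columns (`"table_lactin1"`: `a`, `Tmin`, `Tmax`) and the
#' narrative CTMI cardinal values (`"reported_ctmi"`: `Tmin`, `Topt`,
#' `Tmax`). The tabulated and narrative CTMI values disagree for some
#' strains; both are reported verbatim and the caller chooses.
#'
#' @param source one of `"table_ctmi"`, `"table_lactin1"`,
#'   `"reported_ctmi"`.
#' @return data.frame, one row per strain, one column per parameter.
#' @export
published_cardinal_estimates <- function(source = c("table_ctmi",
                                                    "table_lactin1",
                                                    "reported_ctmi")) {
  source <- match.arg(source)
  path <- system.file("extdata", "published_cardinal_estimates.csv",
                      package = "epfsit", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d <- d[d$source == source, c("strain", "param", "value")]
  wide <- stats::reshape(d, idvar = "strain", timevar = "param",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}

#' Published median lethal times of the EPF strain panel
#'
#' Literature-reported LT50 estimates (days +/- SE) of eleven
#' entomopathogenic fungal strains against irradiated *Glossina pallidipes*
#' males, used as inputs to the SIT-compatibility classification.
#'
#' @return data.frame: `strain`, `species`, `lt50` (days), `se` (days).
#' @export
published_lt50 <- function() {
  path <- system.file("extdata", "published_lt50.csv",
                      package = "epfsit", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
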