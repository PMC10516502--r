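# Techno-complex to species-class attribution. Mousterian, Micoquian and
# Chatelperronian are Neanderthal-affiliated (NAI); Aurignacian, Initial
# Upper Paleolithic, Neronian and Uluzzian are H. sapiens-affiliated (SAI).
# Szeletian, Bohunician and LRJ lack diagnostic human fossils and are always
# excluded.
TECHNO_CLASS <- c(
  "mousterian" = "NAI", "micoquian" = "NAI", "chatelperronian" = "NAI",
  "aurignacian" = "SAI", "initial upper paleolithic" = "SAI", "iup" = "SAI",
  "neronian" = "SAI", "uluzzian" = "SAI",
  "szeletian" = "excluded", "bohunician" = "excluded", "lrj" = "excluded",
  "lincombian-ranisian-jerzmanowician" = "excluded",
  "paleontological" = "excluded"
)

#' Map techno-complex labels to species classes
#'
#' @param techno character vector of techno-complex labels (case- and
#'   accent-insensitive on the supported set).
#' @param toggles list of sensitivity toggles: `chatelperronian_excluded`,
#'   `uluzzian_excluded`, `uluzzian_to_nai` (all default `FALSE`).
#' @return character vector of "NAI", "SAI" or "excluded"; unknown labels map
#'   to "excluded" with a warning.
#' @export
technocomplex_class <- function(techno, toggles = list()) {
  key <- tolower(trimws(techno))
  key <- gsub("â", "a", key)  # tolerate accented Chatelperronian
  cls <- unname(TECHNO_CLASS[key])
  unknown <- is.na(cls)
  if (any(unknown)) {
    warning(sprintf("unknown techno-complex label(s) excluded: %s",
                    paste(unique(techno[unknown]), collapse = ", ")),
            call. = FALSE)
    cls[unknown] <- "excluded"
  }
  if (isTRUE(toggles$chatelperronian_excluded)) cls[key == "chatelperronian"] <- "excluded"
  if (isTRUE(toggles$uluzzian_excluded)) cls[key == "uluzzian"] <- "excluded"
  if (isTRUE(toggles$uluzzian_to_nai)) cls[key == "uluzzian"] <- "NAI"
  cls
}

#' Filter chronometric dates (filtering criteria 1 / 2)
#'
#' Both criteria always remove conventional radiocarbon measurements,
#' QC-flagged records (contamination, low collagen yield, burnt bone) and
#' dates with a coefficient of variation (error/age) of 0.05 or larger.
#' Criteria 2 additionally keeps only dates on material brought or modified
#' by humans (`anthropic` flag). Techno-complexes are mapped to NAI/SAI per
#' [technocomplex_class()]; "excluded" classes are dropped.
#'
#' @param dates chronometric date table with columns `techno`, `method`,
#'   `age`, `error`, `anthropic`, and logical QC columns `contamination`,
#'   `low_collagen`, `burnt_bone`. `age_units` declares "yr" or "ka"
#'   (error in the same units).
#' @param criteria "fc1" or "fc2".
#' @param toggles attribution toggles, see [technocomplex_class()].
#' @return the filtered table with added columns `class` and `age_ka`,
#'   `error_ka`.
#' @export
filter_dates <- function(dates, criteria = c("fc1", "fc2"), toggles = list()) {
  criteria <- match.arg(criteria)
  if (nrow(dates) == 0) {
    dates$class <- character(0)
    dates$age_ka <- numeric(0)
    dates$error_ka <- numeric(0)
    return(dates)
  }
  stop_if_not(all(dates$error > 0), "errors must be > 0")
  stop_if_not(all(dates$age > 0), "ages must be > 0")
  k <- if ("age_units" %in% names(dates)) ifelse(dates$age_units == "ka", 1, 1e-3) else 1e-3
  dates$age_ka <- dates$age * k
  dates$error_ka <- dates$error * k
  keep <- dates$method != "radiocarbon-conventional" &
    !(dates$contamination %||% FALSE) &
    !(dates$low_collagen %||% FALSE) &
    !(dates$burnt_bone %||% FALSE) &
    (dates$error / dates$age) < 0.05
  if (criteria == "fc2") keep <- keep & dates$anthropic
  out <- dates[keep, , drop = FALSE]
  out$class <- technocomplex_class(out$techno, toggles)
  out <- out[out$class != "excluded", , drop = FALSE]
  rownames(out) <- NULL
  out
}
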