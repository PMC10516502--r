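# Packaged reference tables: published regional summaries of MIS3 European
# ecosystem productivity (NPP mean/SD/CV and herbivore carrying capacity by
# size class, Table fixture `productivity_summary.tsv`) and of the
# Middle-to-Upper-Paleolithic-transition chronology per region under the two
# chronometric filtering criteria (`chronology_fc1.tsv`, `chronology_fc2.tsv`).
# HPD columns are stored exactly as printed (`*_1`, `*_2`); readers normalise
# them to young/old bounds.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "paleocc")
  stop_if_not(nzchar(p), sprintf("fixture %s not found", file))
  p
}

#' Read the packaged regional productivity summary table
#'
#' @return data.frame with one row per biogeographic region: NPP mean, SD
#'   and CV, and mean/95% CI carrying capacity of the small, medium and
#'   large herbivore size classes (kg/km^2/yr), plus the printed percentile
#'   classes.
#' @export
read_productivity_fixture <- function() {
  utils::read.table(fixture_path("productivity_summary.tsv"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read a packaged regional chronology table
#'
#' @param criteria "fc1" or "fc2".
#' @return list of [region_chronology()] objects (NAI disappearance and SAI
#'   appearance posterior modes with 68/95% HPD bounds, ka BP); regions with
#'   no SAI representation under the criteria carry `sai_start = NULL`.
#' @export
read_chronology_fixture <- function(criteria = c("fc1", "fc2")) {
  criteria <- match.arg(criteria)
  tab <- utils::read.table(fixture_path(sprintf("chronology_%s.tsv", criteria)),
                           header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  mk <- function(row, prefix, kind) {
    mode <- row[[paste0(prefix, "_mode")]]
    if (is.na(mode)) return(NULL)
    h68 <- sort(c(row[[paste0(prefix, "_hpd68_1")]], row[[paste0(prefix, "_hpd68_2")]]))
    h95 <- sort(c(row[[paste0(prefix, "_hpd95_1")]], row[[paste0(prefix, "_hpd95_2")]]))
    list(kind = kind, mode = mode,
         hpd68 = c(lower = h68[1], upper = h68[2]),
         hpd95 = c(lower = h95[1], upper = h95[2]))
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    region_chronology(row$region,
                      nai_end = mk(row, "nai", "end"),
                      sai_start = mk(row, "sai", "start"),
                      criteria = criteria)
  })
  names(out) <- tab$region
  out
}

#' Published no-coexistence partition
#'
#' The four regions where the NAI end predates the SAI appearance in the
#' published chronology (25% of the European regions). This partition cannot
#' be rederived mechanically from the printed chronology tables alone, so it
#' is shipped as data and accepted as an explicit input by the group
#' comparisons.
#'
#' @return character vector of region ids.
#' @export
non_coexistence_regions <- function() c("R_2", "R_3", "R_13", "R_16")

#' Region groups used in the printed CV contrasts
#'
#' @return named list: `italian_peninsula` (the Adriatic, Prealpine, Italian
#'   Mediterranean and Ligurian regions) and `iberian_mediterranean` (the two
#'   Mediterranean regions of the Iberian Peninsula).
#' @export
region_groups <- function() {
  list(italian_peninsula = c("R_6", "R_7", "R_8", "R_9"),
       iberian_mediterranean = c("R_14", "R_15"))
}
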