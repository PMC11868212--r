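#' Write and read site tables as CSV
#'
#' The on-disk format is a plain CSV with the documented header: `id`, `x`,
#' `y` (metres), `zone`, `moss_species`, `tree_cover`, one column per
#' quantitative covariate, and the response `cd` (micrograms per gram) when
#' present. `read_site_table()` validates the invariants at load time —
#' response strictly inside `(0, cd_max)`, percentage columns inside
#' `[0, 100]`, no missing values — and reports offending data line numbers.
#'
#' @param sites A site table.
#' @param path File path.
#' @return `write_site_table()` returns `path` invisibly;
#'   `read_site_table()` returns a validated tibble.
#' @export
write_site_table <- function(sites, path) {
  readr::write_csv(sites, path)
  invisible(path)
}

#' @rdname write_site_table
#' @param cd_max Upper bound the response must respect.
#' @param required_covariates Covariate columns that must be present (e.g.
#'   those referenced by a model configuration).
#' @param percent_columns Columns validated against `[0, 100]`; by default
#'   any column whose family base matches a known land-use name.
#' @export
read_site_table <- function(path, cd_max = 1.5,
                            required_covariates = character(),
                            percent_columns = NULL) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    abort(sprintf("malformed CSV: first problem at line %d (%s).",
                  probs$row[1] + 1L, probs$expected[1]))
  }
  needed <- c("id", "x", "y", "zone", "moss_species", "tree_cover")
  missing_cols <- setdiff(c(needed, required_covariates), names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  na_rows <- which(!complete.cases(tab))
  if (length(na_rows) > 0) {
    abort(sprintf("missing values at data line(s): %s",
                  paste(head(na_rows + 1L, 5), collapse = ", ")))
  }
  if ("cd" %in% names(tab)) {
    bad <- which(tab$cd <= 0 | tab$cd >= cd_max)
    if (length(bad) > 0) {
      abort(sprintf(
        "response outside (0, %g) at data line(s): %s",
        cd_max, paste(head(bad + 1L, 5), collapse = ", ")))
    }
  }
  if (is.null(percent_columns)) {
    fams <- parse_covariate_name(covariate_columns(tab))
    percent_columns <- fams$variable[fams$family %in%
      c("Forest", "Urban", "Industrial", "Pasture", "Agricultural",
        "Fruits", "Vegetation", "Water", "Sea")]
  }
  for (cl in intersect(percent_columns, names(tab))) {
    bad <- which(tab[[cl]] < 0 | tab[[cl]] > 100)
    if (length(bad) > 0) {
      abort(sprintf("'%s' outside [0, 100] at data line(s): %s",
                    cl, paste(head(bad + 1L, 5), collapse = ", ")))
    }
  }
  tab
}

#' Write all study outputs to a directory
#'
#' Serialises the artefacts of a [run_study()] result as plain CSV files —
#' site table, screening reports, coefficient tables, selection traces,
#' Moran table, prediction maps (regression, per-zone mosaic and kriging)
#' and the LOOCV comparison — plus a `manifest.csv` listing every file with
#' its MD5 hash, the seed and the package version, so a rerun with the same
#' configuration and seed can be verified byte by byte.
#'
#' @param study A `moss_study` from [run_study()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the manifest tibble.
#' @export
write_study_outputs <- function(study, dir) {
  stopifnot(inherits(study, "moss_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    p <- file.path(dir, name)
    readr::write_csv(x, p)
    p
  }
  paths <- c(
    wr(study$sites, "sites.csv"),
    wr(tidy(study$france$screening), "screening_france.csv"),
    wr(tidy(study$france$fit), "coefficients_france.csv"),
    wr(study$france$selection$trace, "selection_trace_france.csv"),
    wr(study$moran_table, "moran.csv"),
    wr(as.data.frame(study$france$prediction), "prediction_france.csv"),
    wr(as.data.frame(study$kriging$prediction), "prediction_kriging.csv"),
    wr(study$comparison, "loocv_comparison.csv")
  )
  if (!is.null(study$zone_mosaic)) {
    paths <- c(paths, wr(as.data.frame(study$zone_mosaic),
                         "prediction_zone_mosaic.csv"))
  }
  manifest <- tibble::tibble(
    file = basename(paths),
    md5 = unname(tools::md5sum(paths)),
    seed = study$config$seed,
    package_version = as.character(utils::packageVersion("mossmap")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}
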