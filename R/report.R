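#' Assemble publication-style output tables
#'
#' Builds the tabular backbone of the standard displays: a volcano table
#' (hazard ratio vs p per specification), a hazard-ratio distribution
#' table split by coding direction of each permuted group, its empirical
#' CDF table, an optional decile-median table, and a run manifest. Tables
#' are the contract; plotting ([plot_volcano()] and friends) is a thin
#' separable layer over them.
#'
#' @param results A [run_specs()] result tibble (nonempty).
#' @param family Optional [agnostic_family()]; enables the
#'   distribution/ECDF tables.
#' @param summaries Optional [summarize_directions()] tibble.
#' @param decile_medians Optional tibble of per-index decile-bin medians.
#' @param manifest Named list of provenance to record (seeds, parameter
#'   hashes, exclusion counts); the package version is added.
#' @param measure Hazard-ratio column feeding the distribution/ECDF
#'   tables.
#' @return A list of class `pdi_report` with elements `volcano`,
#'   `distribution`, `ecdf`, `decile_medians`, `summaries`, `manifest`.
#' @export
build_report <- function(results, family = NULL, summaries = NULL,
                         decile_medians = NULL, manifest = list(),
                         measure = "hr10") {
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop("results are empty", call. = FALSE)
  }
  volcano <- dplyr::bind_rows(
    results |>
      dplyr::filter(!is.na(.data$hr10)) |>
      dplyr::transmute(.data$label, .data$family, .data$index, .data$stratum,
                       form = "per10", hr = .data$hr10, p = .data$hr10_p),
    if ("hrx" %in% names(results)) {
      results |>
        dplyr::filter(!is.na(.data$hrx)) |>
        dplyr::transmute(.data$label, .data$family, .data$index, .data$stratum,
                         form = "extreme_decile", hr = .data$hrx,
                         p = .data$hrx_p)
    }
  )
  distribution <- NULL
  ecdf_tbl <- NULL
  if (!is.null(family) && !is.null(attr(family, "permuted_groups"))) {
    permuted <- attr(family, "permuted_groups")
    distribution <- purrr::map(permuted, function(g) {
      dir <- coding_direction(family, g)
      results |>
        dplyr::filter(.data$label %in% names(dir), !is.na(.data[[measure]])) |>
        dplyr::transmute(
          group = g,
          direction = unname(dir[.data$label]),
          .data$label, .data$stratum, hr = .data[[measure]]
        )
    }) |> dplyr::bind_rows()
    ecdf_tbl <- distribution |>
      dplyr::group_by(.data$group, .data$direction, .data$stratum) |>
      dplyr::arrange(.data$hr, .by_group = TRUE) |>
      dplyr::mutate(cum_frac = dplyr::row_number() / dplyr::n()) |>
      dplyr::ungroup() |>
      dplyr::select("group", "direction", "stratum", "hr", "cum_frac")
  }
  manifest <- c(
    manifest,
    list(
      package = "pdiverse",
      package_version = as.character(utils::packageVersion("pdiverse")),
      n_results = nrow(results),
      families = sort(unique(results$family)),
      strata = sort(unique(results$stratum))
    )
  )
  structure(
    list(volcano = volcano, distribution = distribution, ecdf = ecdf_tbl,
         decile_medians = decile_medians, summaries = summaries,
         manifest = manifest),
    class = "pdi_report"
  )
}

#' @export
print.pdi_report <- function(x, ...) {
  cat("<pdi_report>\n")
  for (nm in c("volcano", "distribution", "ecdf", "decile_medians",
               "summaries")) {
    n <- if (is.null(x[[nm]])) 0 else nrow(x[[nm]])
    cat("  ", nm, ": ", n, " rows\n", sep = "")
  }
  invisible(x)
}

canonical_table <- function(tbl) {
  tbl <- dplyr::arrange(tbl, dplyr::across(dplyr::everything()))
  num <- vapply(tbl, is.numeric, logical(1))
  for (cl in names(tbl)[num]) {
    v <- tbl[[cl]]
    tbl[[cl]] <- ifelse(is.na(v), NA_character_,
                        formatC(v, digits = 10, format = "g"))
  }
  tbl
}

#' Export a report bundle to disk
#'
#' Writes one CSV per table (canonically ordered rows, numbers formatted
#' to 10 significant digits so repeated exports of the same bundle are
#' byte-identical) and the manifest as JSON, under deterministic file
#' names. Round-trips through [read_report()].
#'
#' @param bundle A `pdi_report` from [build_report()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
export_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "pdi_report"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  written <- character()
  for (nm in c("volcano", "distribution", "ecdf", "decile_medians",
               "summaries")) {
    tbl <- bundle[[nm]]
    if (is.null(tbl) || nrow(tbl) == 0) next
    path <- file.path(dir, paste0(nm, ".csv"))
    tryCatch(
      readr::write_csv(canonical_table(tbl), path, na = ""),
      error = function(e) {
        stop("failed writing ", path, ": ", conditionMessage(e), call. = FALSE)
      }
    )
    written <- c(written, path)
  }
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(bundle$manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(written, manifest_path))
}

#' Read an exported report bundle
#'
#' @param dir Directory written by [export_report()].
#' @return A list with the tables found (parsed back to numeric columns)
#'   and the manifest.
#' @export
read_report <- function(dir) {
  out <- list()
  for (nm in c("volcano", "distribution", "ecdf", "decile_medians",
               "summaries")) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(path)) {
      out[[nm]] <- readr::read_csv(path, na = "", show_col_types = FALSE,
                                   progress = FALSE)
    }
  }
  mp <- file.path(dir, "manifest.json")
  if (file.exists(mp)) out$manifest <- jsonlite::read_json(mp)
  out
}
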