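#' Read and validate a long-format isotopologue intensity table
#'
#' The pipeline's input dialect: one row per (sample, species, isotopologue)
#' with columns `sample_id`, `tissue`, `timepoint_h`, `age_group`, `species`,
#' `isotopologue` (integer 0..C) and `intensity`; an optional `corrected`
#' column (0/1) marks natural-abundance-corrected data. CSV or TSV chosen by
#' file extension; UTF-8 with header. Every validation failure reports the
#' offending rows.
#'
#' @param path File path, or a data frame already in the dialect (validated
#'   in place).
#' @param route_table Species vocabulary; rows with unknown species are
#'   rejected.
#' @param tissues Tissue vocabulary (including `"serum"`); unknown tissues
#'   are rejected.
#' @return A validated tibble of sample panels.
#' @export
read_isotopologue_table <- function(path,
                                    route_table = default_route_table(),
                                    tissues = default_tissues()) {
  if (is.data.frame(path)) {
    tbl <- tibble::as_tibble(path)
  } else {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                             progress = FALSE)
  }
  if (nrow(tbl) == 0L) stop("input table is empty", call. = FALSE)
  required <- c("sample_id", "tissue", "timepoint_h", "age_group", "species",
                "isotopologue", "intensity")
  missing_cols <- setdiff(required, colnames(tbl))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"corrected" %in% colnames(tbl)) tbl$corrected <- 0L

  bad_tissue <- !tbl$tissue %in% tissues
  if (any(bad_tissue)) {
    stop("unknown tissue(s) ", paste(unique(tbl$tissue[bad_tissue]), collapse = ", "),
         " at rows ", paste(utils::head(which(bad_tissue), 5L), collapse = ", "),
         call. = FALSE)
  }
  bad_species <- !tbl$species %in% route_table$species
  if (any(bad_species)) {
    stop("unknown species ", paste(unique(tbl$species[bad_species]), collapse = ", "),
         " at rows ", paste(utils::head(which(bad_species), 5L), collapse = ", "),
         call. = FALSE)
  }
  carbons <- stats::setNames(route_table$carbons, route_table$species)
  bad_iso <- tbl$isotopologue < 0 | tbl$isotopologue > carbons[tbl$species]
  if (any(bad_iso)) {
    stop("isotopologue index out of 0..C at rows ",
         paste(utils::head(which(bad_iso), 5L), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(tbl$intensity) | tbl$intensity < 0)) {
    bad <- which(is.na(tbl$intensity) | tbl$intensity < 0)
    stop("negative or missing intensity at rows ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  key <- paste(tbl$sample_id, tbl$species, tbl$isotopologue)
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate (sample, species, isotopologue) keys at rows ",
         paste(utils::head(which(dup), 5L), collapse = ", "), call. = FALSE)
  }
  tbl
}

#' Write a long-format isotopologue table
#'
#' @param tbl Table in the dialect of [read_isotopologue_table()].
#' @param path Destination path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_isotopologue_table <- function(tbl, path) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(tbl, path, delim = delim)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects every tunable of the analysis pipeline with the package's
#' documented defaults: natural 13C abundance, the detection filter
#' thresholds, the donor-screen thresholds, permutation-test settings, and
#' the tissue/species vocabularies. A configuration can be echoed to and
#' restored from YAML, so a run is reproducible from its config plus seed.
#'
#' @param input Input table path or data frame.
#' @param outdir Optional output directory; when set, [run_pipeline()]
#'   writes every result table there as CSV plus a config echo and log.
#' @param p13 Natural 13C abundance.
#' @param detection_threshold,detection_min_fraction Labeling detection
#'   filter (strict inequalities).
#' @param detection_floor Labeling-extent floor below which synthesis fits
#'   are pinned to g = 0.
#' @param le_tolerance,similarity_threshold Donor-screen thresholds.
#' @param n_perm,seed Permutation-test settings.
#' @param fit_timepoint Timepoint (h) at which fits, screens and
#'   deconvolutions are performed.
#' @param route_table,tissues Vocabularies.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, outdir = NULL, p13 = 0.0107,
                            detection_threshold = 0.005,
                            detection_min_fraction = 0.5,
                            detection_floor = 0.005,
                            le_tolerance = 0.05, similarity_threshold = 0.8,
                            n_perm = 999, seed = 1L, fit_timepoint = 24,
                            route_table = default_route_table(),
                            tissues = default_tissues()) {
  structure(
    list(input = input, outdir = outdir, p13 = p13,
         detection_threshold = detection_threshold,
         detection_min_fraction = detection_min_fraction,
         detection_floor = detection_floor, le_tolerance = le_tolerance,
         similarity_threshold = similarity_threshold,
         n_perm = as.integer(n_perm), seed = as.integer(seed),
         fit_timepoint = fit_timepoint, route_table = route_table,
         tissues = tissues),
    class = "pipeline_config")
}

#' Echo a pipeline configuration to YAML (and read it back)
#'
#' @param config A [pipeline_config()].
#' @param path Destination YAML path.
#' @return `path` invisibly for the writer; a `pipeline_config` for the
#'   reader.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lst <- unclass(config)
  lst$route_table <- as.data.frame(config$route_table)
  lst$input <- if (is.character(config$input)) config$input else NULL
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  rt <- tibble::as_tibble(as.data.frame(lst$route_table))
  rt$n_units <- as.integer(rt$n_units)
  rt$n_steps <- as.integer(rt$n_steps)
  pipeline_config(
    input = lst$input, outdir = lst$outdir, p13 = lst$p13,
    detection_threshold = lst$detection_threshold,
    detection_min_fraction = lst$detection_min_fraction,
    detection_floor = lst$detection_floor, le_tolerance = lst$le_tolerance,
    similarity_threshold = lst$similarity_threshold, n_perm = lst$n_perm,
    seed = lst$seed, fit_timepoint = lst$fit_timepoint, route_table = rt,
    tissues = lst$tissues)
}
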