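# Stage helpers operate on the validated long table dialect and return tidy
# tables; run_pipeline() chains them and optionally writes CSV outputs.

iso_vector_from_rows <- function(rows, species, corrected = FALSE) {
  v <- numeric(species$carbons + 1L)
  v[rows$isotopologue + 1L] <- rows$intensity
  iso_vector(species, v, corrected = corrected)
}

#' Natural-abundance correction of a long intensity table
#'
#' Applies [correct_natural_abundance()] per (sample, species). Samples whose
#' correction fails (or whose total intensity is zero) are dropped with a
#' diagnostic attribute rather than aborting the run.
#'
#' @param tbl Validated long table ([read_isotopologue_table()]).
#' @param p13 Natural 13C abundance.
#' @param route_table Species vocabulary.
#' @return Long table of corrected intensities (`corrected = 1`), with a
#'   `failures` attribute listing dropped (sample, species) pairs.
#' @export
correct_table <- function(tbl, p13 = 0.0107, route_table = default_route_table()) {
  species_cache <- stats::setNames(
    lapply(route_table$species, lookup_species, route_table = route_table),
    route_table$species)
  failures <- list()
  out <- tbl |>
    dplyr::group_by(.data$sample_id, .data$species) |>
    dplyr::group_map(function(rows, grp) {
      sp <- species_cache[[grp$species]]
      res <- tryCatch({
        v <- iso_vector_from_rows(rows, sp, corrected = all(rows$corrected == 1L))
        corr <- if (v$corrected) v else correct_natural_abundance(v, p13)
        rows$intensity <- corr$intensities[rows$isotopologue + 1L]
        rows$corrected <- 1L
        rows$sample_id <- grp$sample_id
        rows$species <- grp$species
        rows
      }, error = function(e) {
        failures[[length(failures) + 1L]] <<- tibble::tibble(
          sample_id = grp$sample_id, species = grp$species,
          reason = conditionMessage(e))
        NULL
      })
      res
    }) |>
    dplyr::bind_rows()
  attr(out, "failures") <- dplyr::bind_rows(failures)
  out
}

#' Per-sample MIDs and elementary labeling quantities
#'
#' Normalizes each corrected (sample, species) vector to a MID and computes
#' the labeling extent, 13C enrichment and 13C-labeled intensity.
#'
#' @param corrected Corrected long table from [correct_table()].
#' @param route_table Species vocabulary.
#' @return A list: `mids` (long table of labeled fractions) and `summary`
#'   (one row per sample and species: `labeling_extent`, `c13_enrichment`,
#'   `labeled_intensity`, `total_intensity`).
#' @export
mid_table <- function(corrected, route_table = default_route_table()) {
  species_cache <- stats::setNames(
    lapply(route_table$species, lookup_species, route_table = route_table),
    route_table$species)
  mids <- list()
  summaries <- list()
  corrected |>
    dplyr::group_by(.data$sample_id, .data$species) |>
    dplyr::group_walk(function(rows, grp) {
      sp <- species_cache[[grp$species]]
      v <- iso_vector_from_rows(rows, sp, corrected = TRUE)
      if (sum(v$intensities) <= 0) return(invisible(NULL))
      m <- normalize_mid(v)
      meta <- rows[1L, c("tissue", "timepoint_h", "age_group", "replicate")]
      mids[[length(mids) + 1L]] <<- tibble::tibble(
        sample_id = grp$sample_id, tissue = meta$tissue,
        timepoint_h = meta$timepoint_h, age_group = meta$age_group,
        replicate = meta$replicate, species = grp$species,
        isotopologue = 0:sp$carbons, fraction = m$fractions)
      summaries[[length(summaries) + 1L]] <<- tibble::tibble(
        sample_id = grp$sample_id, tissue = meta$tissue,
        timepoint_h = meta$timepoint_h, age_group = meta$age_group,
        replicate = meta$replicate, species = grp$species,
        labeling_extent = labeling_extent(m),
        c13_enrichment = c13_enrichment(m),
        labeled_intensity = labeled_intensity(v),
        total_intensity = sum(v$intensities))
    })
  list(mids = dplyr::bind_rows(mids), summary = dplyr::bind_rows(summaries))
}

# reassemble ffa_mid objects per (tissue, species, ...) group from mids table
mids_as_objects <- function(mids, route_table = default_route_table()) {
  species_cache <- stats::setNames(
    lapply(route_table$species, lookup_species, route_table = route_table),
    route_table$species)
  mids |>
    dplyr::arrange(.data$sample_id, .data$species, .data$isotopologue) |>
    dplyr::group_by(.data$sample_id, .data$tissue, .data$timepoint_h,
                    .data$age_group, .data$replicate, .data$species) |>
    dplyr::group_map(function(rows, grp) {
      list(meta = grp, mid = ffa_mid(species_cache[[grp$species]], rows$fraction))
    })
}

#' Isotopic-labeling detection flags per tissue and species
#'
#' Applies the strict detection rule of [is_labeled_ffa()] across the
#' samples of each (tissue, species) group at labeled timepoints.
#'
#' @param mids MID table from [mid_table()].
#' @param threshold,min_fraction Detection rule parameters.
#' @param route_table Species vocabulary.
#' @return Tibble: `tissue`, `species`, `n_samples`, `labeled`.
#' @export
detection_table <- function(mids, threshold = 0.005, min_fraction = 0.5,
                            route_table = default_route_table()) {
  labeled_tp <- mids[mids$timepoint_h > 0, ]
  objs <- mids_as_objects(labeled_tp, route_table)
  meta <- dplyr::bind_rows(lapply(objs, `[[`, "meta"))
  groups <- split(seq_along(objs), paste(meta$tissue, meta$species, sep = "\r"))
  out <- lapply(groups, function(idx) {
    ms <- lapply(objs[idx], `[[`, "mid")
    tibble::tibble(tissue = meta$tissue[idx[1L]],
                   species = meta$species[idx[1L]],
                   n_samples = length(idx),
                   labeled = is_labeled_ffa(ms, threshold, min_fraction))
  })
  dplyr::bind_rows(out)
}

#' Run the full tracing analysis pipeline
#'
#' Chains every stage on one input table: natural-abundance correction,
#' labeling detection, MIDs and labeling summaries, per-replicate synthesis
#' fits with pool-size-corrected pseudo rates, tissue-serum MID similarity,
#' donor screening, palmitate/stearate synthesis-uptake deconvolution, and
#' Monte Carlo permutation tests of each tissue's MID against serum. Fits,
#' screens and tests run at `config$fit_timepoint`. Per-group failures are
#' recorded as missing rows with a reason, never as aborts. When
#' `config$outdir` is set, all result tables, a YAML config echo and a
#' JSON-lines log are written there.
#'
#' @param config A [pipeline_config()] whose `input` is set.
#' @return A list of tidy tables: `corrected`, `detection`, `mids`,
#'   `labeling_summary`, `synthesis_fits`, `pool_size_factors`,
#'   `pseudo_rates`, `similarity`, `donor_screen`, `deconvolution`,
#'   `permutation`, plus `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$input)) stop("config$input is not set", call. = FALSE)
  log_lines <- character()
  log_stage <- function(stage, detail = "") {
    log_lines <<- c(log_lines, sprintf(
      '{"stage":"%s","detail":"%s","elapsed_s":%.3f}',
      stage, detail, as.numeric(proc.time()[["elapsed"]]) - t0))
  }
  t0 <- as.numeric(proc.time()[["elapsed"]])

  tbl <- read_isotopologue_table(config$input, config$route_table, config$tissues)
  log_stage("read", sprintf("%d rows", nrow(tbl)))

  corrected <- correct_table(tbl, config$p13, config$route_table)
  log_stage("correct", sprintf("%d rows", nrow(corrected)))

  mt <- mid_table(corrected, config$route_table)
  detection <- detection_table(mt$mids, config$detection_threshold,
                               config$detection_min_fraction,
                               config$route_table)
  log_stage("detect")

  at_tp <- mt$mids[mt$mids$timepoint_h == config$fit_timepoint, ]
  objs <- mids_as_objects(at_tp, config$route_table)
  meta <- dplyr::bind_rows(lapply(objs, `[[`, "meta"))
  is_serum <- meta$tissue == "serum"

  # ---- synthesis fits (per replicate, tissue samples only) -------------
  fit_rows <- lapply(which(!is_serum), function(k) {
    m <- objs[[k]]$mid
    g <- objs[[k]]$meta
    fit <- tryCatch(
      fit_synthesis_fraction(m, route_table = config$route_table,
                             detection_floor = config$detection_floor,
                             tissue = g$tissue),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(
        tissue = g$tissue, species = g$species, age_group = g$age_group,
        replicate = g$replicate, g = NA_real_, x0 = NA_real_, x1 = NA_real_,
        x2 = NA_real_, sse = NA_real_, converged = FALSE, pinned = FALSE,
        reason = "fit error"))
    }
    tibble::tibble(
      tissue = g$tissue, species = g$species, age_group = g$age_group,
      replicate = g$replicate, g = fit$g, x0 = fit$acetyl$x0,
      x1 = fit$acetyl$x1, x2 = fit$acetyl$x2, sse = fit$sse,
      converged = fit$converged, pinned = fit$pinned,
      reason = if (fit$pinned) "below detection floor" else NA_character_)
  })
  synthesis_fits <- dplyr::bind_rows(fit_rows)
  log_stage("synthesis_fits", sprintf("%d fits", nrow(synthesis_fits)))

  # ---- pool-size factors and pseudo rates ------------------------------
  totals <- mt$summary |>
    dplyr::filter(.data$timepoint_h == config$fit_timepoint,
                  .data$tissue != "serum") |>
    dplyr::group_by(.data$species, .data$tissue) |>
    dplyr::summarise(total = mean(.data$total_intensity), .groups = "drop")
  psf <- totals |>
    dplyr::group_by(.data$species) |>
    dplyr::group_map(function(rows, grp) {
      suppressWarnings(pool_size_factors(
        stats::setNames(rows$total, rows$tissue), species = grp$species))
    }) |>
    dplyr::bind_rows()
  g_mean <- synthesis_fits |>
    dplyr::group_by(.data$tissue, .data$species) |>
    dplyr::summarise(g_mean = mean(.data$g), g_sd = stats::sd(.data$g),
                     pinned = all(.data$pinned), .groups = "drop")
  pseudo_rates <- dplyr::left_join(g_mean, psf, by = c("tissue", "species")) |>
    dplyr::mutate(pseudo_rate = .data$g_mean * .data$factor)
  log_stage("pseudo_rates")

  # ---- serum reference MIDs (mean across replicates per species) -------
  serum_mean <- serum_mean_mids(at_tp, config$route_table)

  # ---- similarity and donor screen -------------------------------------
  similarity <- list()
  donor <- list()
  tissue_groups <- split(which(!is_serum),
                         paste(meta$tissue[!is_serum], meta$species[!is_serum],
                               sep = "\r"))
  serum_groups <- split(which(is_serum), meta$species[is_serum])
  for (grp_key in names(tissue_groups)) {
    idx <- tissue_groups[[grp_key]]
    tis <- meta$tissue[idx[1L]]
    spn <- meta$species[idx[1L]]
    t_mids <- lapply(objs[idx], `[[`, "mid")
    s_idx <- serum_groups[[spn]]
    if (is.null(s_idx) || length(s_idx) < 2L || length(t_mids) < 2L) next
    s_mids <- lapply(objs[s_idx], `[[`, "mid")
    ds <- donor_screen(t_mids, s_mids, config$le_tolerance,
                       config$similarity_threshold, tissue = tis)
    donor[[length(donor) + 1L]] <- ds
    similarity[[length(similarity) + 1L]] <- tibble::tibble(
      tissue = tis, species = spn, median_similarity = ds$median_similarity)
    }
  similarity <- dplyr::bind_rows(similarity)
  donor <- dplyr::bind_rows(donor)
  log_stage("donor_screen")

  # ---- deconvolution for FFA(16:0) then FFA(18:0) ----------------------
  deconv <- deconvolution_stage(objs, meta, serum_mean, config)
  log_stage("deconvolution")

  # ---- permutation tests: tissue vs serum per species ------------------
  perm <- list()
  for (grp_key in names(tissue_groups)) {
    idx <- tissue_groups[[grp_key]]
    tis <- meta$tissue[idx[1L]]
    spn <- meta$species[idx[1L]]
    s_idx <- serum_groups[[spn]]
    if (is.null(s_idx) || length(s_idx) < 2L || length(idx) < 2L) next
    res <- permutation_test_mid(lapply(objs[idx], `[[`, "mid"),
                                lapply(objs[s_idx], `[[`, "mid"),
                                n_perm = config$n_perm, seed = config$seed)
    perm[[length(perm) + 1L]] <- tibble::tibble(
      tissue = tis, species = spn, statistic = res$statistic,
      p_value = res$p_value, n_perm = res$n_perm)
  }
  perm <- dplyr::bind_rows(perm)
  log_stage("permutation")

  results <- list(corrected = corrected, detection = detection,
                  mids = mt$mids, labeling_summary = mt$summary,
                  synthesis_fits = synthesis_fits, pool_size_factors = psf,
                  pseudo_rates = pseudo_rates, similarity = similarity,
                  donor_screen = donor, deconvolution = deconv,
                  permutation = perm, config = config)
  if (!is.null(config$outdir)) {
    write_pipeline_results(results, config$outdir, log_lines)
  }
  results
}

# mean serum MID per species across replicates at the fit timepoint
serum_mean_mids <- function(mids_at_tp, route_table) {
  serum <- mids_at_tp[mids_at_tp$tissue == "serum", ]
  if (nrow(serum) == 0L) return(list())
  means <- serum |>
    dplyr::group_by(.data$species, .data$isotopologue) |>
    dplyr::summarise(fraction = mean(.data$fraction), .groups = "drop")
  out <- list()
  for (spn in unique(means$species)) {
    rows <- means[means$species == spn, ]
    rows <- rows[order(rows$isotopologue), ]
    fr <- rows$fraction / sum(rows$fraction)
    out[[spn]] <- ffa_mid(lookup_species(spn, route_table), fr)
  }
  out
}

deconvolution_stage <- function(objs, meta, serum_mean, config) {
  out <- list()
  has16 <- "FFA(16:0)" %in% names(serum_mean)
  has18 <- "FFA(18:0)" %in% names(serum_mean)
  tissues <- unique(meta$tissue[meta$tissue != "serum"])
  for (tis in tissues) {
    idx16 <- which(meta$tissue == tis & meta$species == "FFA(16:0)")
    fits16 <- list()
    for (k in idx16) {
      if (!has16) break
      f <- tryCatch(
        deconvolve_16_0(objs[[k]]$mid, serum_mean[["FFA(16:0)"]], tissue = tis),
        error = function(e) NULL)
      if (!is.null(f)) {
        fits16[[as.character(meta$replicate[k])]] <- f
        out[[length(out) + 1L]] <- deconv_row(f, meta$replicate[k])
      }
    }
    idx18 <- which(meta$tissue == tis & meta$species == "FFA(18:0)")
    for (k in idx18) {
      if (!has18) break
      rep_key <- as.character(meta$replicate[k])
      f16 <- fits16[[rep_key]]
      if (is.null(f16) || is.na(f16$alpha)) next
      f <- tryCatch(
        deconvolve_18_0(objs[[k]]$mid, serum_mean[["FFA(18:0)"]],
                        f16$acetyl, denovo_mid(f16$acetyl, 8L), tissue = tis),
        error = function(e) NULL)
      if (!is.null(f)) {
        # an unidentifiable palmitate fit gives an unreliable acetyl simplex
        if (isTRUE(f16$non_identifiable)) f$non_identifiable <- TRUE
        out[[length(out) + 1L]] <- deconv_row(f, meta$replicate[k])
      }
    }
  }
  dplyr::bind_rows(out)
}

deconv_row <- function(f, replicate) {
  tibble::tibble(
    tissue = f$tissue, species = f$species$name, replicate = replicate,
    alpha = f$alpha, beta = f$beta,
    comp_synthesis = unname(f$composition["synthesis"]),
    comp_uptake = unname(f$composition["uptake"]),
    sse = f$sse, converged = f$converged,
    non_identifiable = f$non_identifiable, reason = f$reason)
}

#' Write pipeline result tables to a directory
#'
#' One CSV per result table, a YAML echo of the configuration, and a
#' JSON-lines log.
#'
#' @param results List from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @param log_lines Optional character vector of JSON log lines.
#' @return `outdir`, invisibly.
#' @export
write_pipeline_results <- function(results, outdir, log_lines = character()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tables <- results[vapply(results, is.data.frame, logical(1))]
  for (nm in names(tables)) {
    readr::write_csv(tables[[nm]], file.path(outdir, paste0(nm, ".csv")))
  }
  if (!is.null(results$config)) {
    write_pipeline_config(results$config, file.path(outdir, "config.yaml"))
  }
  writeLines(log_lines, file.path(outdir, "run_log.jsonl"))
  invisible(outdir)
}
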