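#' Configuration for the synthetic multi-tissue tracing study
#'
#' Builds the full parameterization of a simulated [U-13C]-glucose tracing
#' experiment: 15 tissues plus serum, the 13-species labeled FFA panel,
#' timepoints 0/6/24 h with n = 4 mice at baseline and n = 6 after refeeding,
#' tissue-specific acetyl-CoA labeling, tissue- and species-specific newly
#' synthesized fractions g and serum-uptake fractions beta, a liver-coupled
#' serum pool, natural 13C abundance convolution, and multiplicative
#' log-normal measurement noise.
#'
#' Default parameter choices emulate the biology the study describes:
#' lipogenic tissues (BAT, WAT, liver, kidney, lung) synthesize the short
#' SFA/MUFA species most actively with g around 0.2-0.4 at 24 h; brain
#' regions favor palmitate and the C20 PUFAs; PUFA and very-long-chain MUFA
#' synthesis stays below 0.1 everywhere; the lung takes up the largest share
#' of circulating palmitate while BAT and intestine take up little; and g at
#' 6 h is 60 percent of its 24 h value except in adipose tissues, which
#' plateau early.
#'
#' @param seed Integer seed (mandatory; drives all randomness downstream).
#' @param tissues Tissue vocabulary (serum excluded; it is always simulated).
#' @param route_table Species panel with synthesis routes.
#' @param timepoints Labeling durations in hours.
#' @param replicates Named integer vector, one entry per timepoint.
#' @param acetyl Tibble `tissue, x0, x1, x2` of acetyl-CoA labeling.
#' @param g Tibble `tissue, species, g` of newly synthesized fractions at the
#'   24 h reference timepoint.
#' @param beta Tibble `tissue, species, beta` of serum-uptake fractions.
#' @param intensity Tibble `tissue, species, scale` of total-intensity scales
#'   (arbitrary LC-MS units).
#' @param timepoint_scale Named numeric: multiplier on g per timepoint.
#' @param adipose_plateau Tissues whose 6 h g already equals the 24 h value.
#' @param donor_tissue Tissue whose noiseless MID defines the serum pool.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   intensity noise (>= 0).
#' @param p13 Natural 13C abundance used for forward convolution.
#' @param age_group Label attached to every sample.
#' @param age_g_multiplier Named numeric per tissue; multiplies g (used by
#'   [aging_scenario()]).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              tissues = default_tissues(include_serum = FALSE),
                              route_table = default_route_table(),
                              timepoints = c(0, 6, 24),
                              replicates = c(`0` = 4L, `6` = 6L, `24` = 6L),
                              acetyl = default_acetyl_table(tissues),
                              g = default_g_table(tissues, route_table$species),
                              beta = default_beta_table(tissues, route_table$species),
                              intensity = default_intensity_table(tissues, route_table$species),
                              timepoint_scale = c(`0` = 0, `6` = 0.6, `24` = 1),
                              adipose_plateau = c("BAT", "WAT"),
                              donor_tissue = "liver",
                              noise_cv = 0.02,
                              p13 = 0.0107,
                              age_group = "young",
                              age_g_multiplier = stats::setNames(rep(1, length(tissues)), tissues)) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(noise_cv >= 0, p13 >= 0, p13 < 0.05)
  if (!donor_tissue %in% tissues) {
    stop("donor_tissue '", donor_tissue, "' is not in the tissue vocabulary",
         call. = FALSE)
  }
  if (!all(as.character(timepoints) %in% names(replicates))) {
    stop("replicates must name every timepoint", call. = FALSE)
  }
  cfg <- structure(
    list(seed = as.integer(seed), tissues = tissues, route_table = route_table,
         timepoints = timepoints, replicates = replicates, acetyl = acetyl,
         g = g, beta = beta, intensity = intensity,
         timepoint_scale = timepoint_scale, adipose_plateau = adipose_plateau,
         donor_tissue = donor_tissue, noise_cv = noise_cv, p13 = p13,
         age_group = age_group, age_g_multiplier = age_g_multiplier),
    class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  pars <- dplyr::inner_join(cfg$g, cfg$beta, by = c("tissue", "species"))
  bad <- pars$g * max(cfg$timepoint_scale) *
    cfg$age_g_multiplier[pars$tissue] + pars$beta > 1
  if (any(bad)) {
    stop("invalid config: g + beta exceeds 1 for ",
         paste(pars$tissue[bad], pars$species[bad], collapse = ", "),
         call. = FALSE)
  }
  if (any(pars$g < 0 | pars$g > 1 | pars$beta < 0 | pars$beta > 1)) {
    stop("g and beta must lie in [0, 1]", call. = FALSE)
  }
  simplex <- abs(cfg$acetyl$x0 + cfg$acetyl$x1 + cfg$acetyl$x2 - 1)
  if (any(simplex > 1e-9)) {
    stop("acetyl fractions must sum to 1 per tissue", call. = FALSE)
  }
  invisible(cfg)
}

#' @rdname simulation_config
#' @export
default_acetyl_table <- function(tissues = default_tissues(FALSE)) {
  base <- tibble::tribble(
    ~tissue,        ~x1,   ~x2,
    "liver",        0.05,  0.25,
    "kidney",       0.05,  0.23,
    "lung",         0.05,  0.20,
    "heart",        0.04,  0.16,
    "spleen",       0.04,  0.14,
    "muscle",       0.04,  0.12,
    "BAT",          0.05,  0.30,
    "WAT",          0.05,  0.25,
    "intestine",    0.04,  0.18,
    "cortex",       0.06,  0.13,
    "midbrain",     0.06,  0.15,
    "cerebellum",   0.06,  0.15,
    "olfactory",    0.06,  0.14,
    "hippocampus",  0.06,  0.13,
    "pons",         0.06,  0.12
  )
  out <- base[base$tissue %in% tissues, ]
  missing <- setdiff(tissues, out$tissue)
  if (length(missing)) {
    out <- dplyr::bind_rows(out, tibble::tibble(tissue = missing, x1 = 0.05, x2 = 0.18))
  }
  dplyr::mutate(out, x0 = 1 - .data$x1 - .data$x2, .before = "x1")
}

# per-tissue overall synthesis activity multipliers
tissue_activity <- function() {
  c(liver = 0.9, kidney = 0.8, lung = 0.75, heart = 0.5, spleen = 0.4,
    muscle = 0.35, BAT = 1.0, WAT = 0.85, intestine = 0.5,
    cortex = 0.35, midbrain = 0.5, cerebellum = 0.5, olfactory = 0.5,
    hippocampus = 0.35, pons = 0.35)
}

#' @rdname simulation_config
#' @export
default_g_table <- function(tissues = default_tissues(FALSE),
                            species = default_route_table()$species) {
  act <- tissue_activity()
  act[setdiff(tissues, names(act))] <- 0.5
  base_periph <- c(`FFA(14:0)` = 0.30, `FFA(16:0)` = 0.35, `FFA(16:1)` = 0.30,
                   `FFA(18:0)` = 0.15, `FFA(18:1)` = 0.25, `FFA(20:0)` = 0.06,
                   `FFA(20:1)` = 0.08, `FFA(20:2)` = 0.05, `FFA(20:3)` = 0.06,
                   `FFA(20:4)` = 0.06, `FFA(20:5)` = 0.05, `FFA(22:1)` = 0.05,
                   `FFA(24:1)` = 0.04)
  base_brain <- c(`FFA(14:0)` = 0.10, `FFA(16:0)` = 0.35, `FFA(16:1)` = 0.06,
                  `FFA(18:0)` = 0.08, `FFA(18:1)` = 0.08, `FFA(20:0)` = 0.03,
                  `FFA(20:1)` = 0.03, `FFA(20:2)` = 0.03, `FFA(20:3)` = 0.10,
                  `FFA(20:4)` = 0.10, `FFA(20:5)` = 0.03, `FFA(22:1)` = 0.03,
                  `FFA(24:1)` = 0.03)
  grid <- tidyr::expand_grid(tissue = tissues, species = species)
  base <- ifelse(grid$tissue %in% brain_tissues(),
                 base_brain[grid$species], base_periph[grid$species])
  base[is.na(base)] <- 0.05
  dplyr::mutate(grid, g = unname(act[.data$tissue] * base))
}

#' @rdname simulation_config
#' @export
default_beta_table <- function(tissues = default_tissues(FALSE),
                               species = default_route_table()$species) {
  uptake <- c(liver = 0, kidney = 0.10, lung = 0.25, heart = 0.20,
              spleen = 0.15, muscle = 0.15, BAT = 0.05, WAT = 0.08,
              intestine = 0.05, cortex = 0.02, midbrain = 0.02,
              cerebellum = 0.02, olfactory = 0.02, hippocampus = 0.02,
              pons = 0.02)
  uptake[setdiff(tissues, names(uptake))] <- 0.1
  exchanged <- c("FFA(16:0)", "FFA(16:1)", "FFA(18:0)", "FFA(18:1)")
  grid <- tidyr::expand_grid(tissue = tissues, species = species)
  dplyr::mutate(grid, beta = ifelse(.data$species %in% exchanged,
                                    unname(uptake[.data$tissue]), 0))
}

#' @rdname simulation_config
#' @export
default_intensity_table <- function(tissues = default_tissues(FALSE),
                                    species = default_route_table()$species) {
  tis_scale <- c(liver = 1.0, kidney = 0.8, lung = 0.7, heart = 0.5,
                 spleen = 0.4, muscle = 0.4, BAT = 1.2, WAT = 1.0,
                 intestine = 0.6, cortex = 0.3, midbrain = 0.3,
                 cerebellum = 0.3, olfactory = 0.3, hippocampus = 0.3,
                 pons = 0.3)
  tis_scale[setdiff(tissues, names(tis_scale))] <- 0.5
  sp_scale <- c(`FFA(14:0)` = 0.3, `FFA(16:0)` = 1.0, `FFA(16:1)` = 0.5,
                `FFA(18:0)` = 0.8, `FFA(18:1)` = 0.9, `FFA(20:0)` = 0.15,
                `FFA(20:1)` = 0.15, `FFA(20:2)` = 0.1, `FFA(20:3)` = 0.15,
                `FFA(20:4)` = 0.25, `FFA(20:5)` = 0.1, `FFA(22:1)` = 0.1,
                `FFA(24:1)` = 0.1)
  grid <- tidyr::expand_grid(tissue = tissues, species = species)
  sp <- sp_scale[grid$species]
  sp[is.na(sp)] <- 0.2
  dplyr::mutate(grid, scale = 1e6 * unname(tis_scale[.data$tissue]) * unname(sp))
}

#' Derive an aged-cohort configuration
#'
#' Scales the newly synthesized fractions g per tissue to emulate the
#' age-associated decline in fatty acid biosynthesis: by default peripheral
#' tissues fall to 60 percent of the young value while brain regions are
#' spared.
#'
#' @param base A [simulation_config()] for the young cohort.
#' @param decline Named numeric multipliers in [0, 1] per tissue; tissues not
#'   named keep multiplier 1.
#' @param age_group Label for the derived cohort.
#' @return A new `simulation_config`.
#' @export
aging_scenario <- function(base,
                           decline = stats::setNames(
                             rep(0.6, length(peripheral_tissues())),
                             peripheral_tissues()),
                           age_group = "old") {
  stopifnot(inherits(base, "simulation_config"))
  if (any(decline > 1 | decline < 0)) {
    stop("decline multipliers must lie in [0, 1]", call. = FALSE)
  }
  unknown <- setdiff(names(decline), base$tissues)
  if (length(unknown)) {
    stop("decline names unknown tissues: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  mult <- base$age_g_multiplier
  mult[names(decline)] <- mult[names(decline)] * decline
  cfg <- base
  cfg$age_g_multiplier <- mult
  cfg$age_group <- age_group
  validate_simulation_config(cfg)
  cfg
}

# noiseless per-(tissue, species) MID fractions at one timepoint, plus the
# serum pool derived from the donor tissue
noiseless_mids <- function(cfg, timepoint) {
  tp_scale <- cfg$timepoint_scale[[as.character(timepoint)]]
  pars <- dplyr::inner_join(cfg$g, cfg$beta, by = c("tissue", "species"))
  pars <- dplyr::inner_join(pars, cfg$acetyl, by = "tissue")
  out <- vector("list", nrow(pars))
  own <- vector("list", nrow(pars))
  for (r in seq_len(nrow(pars))) {
    row <- pars[r, ]
    scale_r <- if (row$tissue %in% cfg$adipose_plateau && timepoint > 0) 1 else tp_scale
    g_eff <- row$g * scale_r * cfg$age_g_multiplier[[row$tissue]]
    sp <- lookup_species(row$species, cfg$route_table)
    e0 <- c(1, numeric(sp$carbons))
    route <- route_mid(sp, acetyl_labeling(row$x0, row$x1, row$x2),
                       cfg$route_table)$fractions
    own[[r]] <- (1 - g_eff) * e0 + g_eff * route
    out[[r]] <- list(species = row$species, tissue = row$tissue,
                     g_eff = g_eff, beta = row$beta,
                     x0 = row$x0, x1 = row$x1, x2 = row$x2)
  }
  pars$own <- own
  pars$meta <- out
  # serum pool: the donor tissue's own (synthesis-only) noiseless MID
  serum <- pars[pars$tissue == cfg$donor_tissue, c("species", "own")]
  serum_mid <- stats::setNames(serum$own, serum$species)
  # mix serum uptake into each tissue
  mids <- vector("list", nrow(pars))
  for (r in seq_len(nrow(pars))) {
    row <- pars[r, ]
    sp <- row$species
    e0 <- c(1, numeric(length(row$own[[1L]]) - 1L))
    mids[[r]] <- row$own[[1L]] + row$beta * (serum_mid[[sp]] - e0)
  }
  pars$mid <- mids
  list(pars = pars, serum = serum_mid)
}

#' Simulate a study-shaped isotopologue dataset with known ground truth
#'
#' Forward-composes the whole measurement model: per (tissue, species,
#' timepoint) the noiseless MID is the three-way mixture of a pre-existing
#' unlabeled pool, the synthesis-route MID at the tissue's acetyl-CoA
#' labeling (weight g), and the serum pool (weight beta); the serum pool is
#' the donor tissue's synthesis-only MID; fractions are scaled to intensities,
#' forward-convolved with natural 13C abundance, and perturbed by independent
#' multiplicative log-normal noise per isotopologue. Output is the long-format
#' uncorrected intensity table the pipeline readers consume, byte-identical
#' for identical config and seed.
#'
#' @param cfg A [simulation_config()].
#' @return A list: `data` (long tibble: `sample_id`, `tissue`, `timepoint_h`,
#'   `age_group`, `replicate`, `species`, `isotopologue`, `intensity`,
#'   `corrected`), `truth` (per tissue/species/timepoint ground truth:
#'   realized g, beta, acetyl simplex, noiseless labeling extent and
#'   synthesis/uptake composition of the labeled pool), and `config`.
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  validate_simulation_config(cfg)
  sigma <- sqrt(log(1 + cfg$noise_cv^2))
  scale_tbl <- cfg$intensity
  key <- function(t, s) paste(t, s, sep = "\r")
  scale_map <- stats::setNames(scale_tbl$scale, key(scale_tbl$tissue, scale_tbl$species))

  rows <- list()
  truth_rows <- list()
  with_preserved_seed(cfg$seed, {
    for (tp in cfg$timepoints) {
      nm <- noiseless_mids(cfg, tp)
      n_rep <- cfg$replicates[[as.character(tp)]]
      # tissue samples
      for (r in seq_len(nrow(nm$pars))) {
        row <- nm$pars[r, ]
        sp <- lookup_species(row$species, cfg$route_table)
        mid_true <- row$mid[[1L]]
        own <- row$own[[1L]]
        g_eff <- row$meta[[1L]]$g_eff
        lab_syn <- g_eff * (1 - route_d0(sp, row, cfg))
        lab_upt <- row$beta * sum(nm$serum[[row$species]][-1L])
        truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
          age_group = cfg$age_group, tissue = row$tissue,
          timepoint_h = tp, species = row$species,
          g_true = g_eff, beta_true = row$beta,
          x0 = row$x0, x1 = row$x1, x2 = row$x2,
          labeling_extent_true = 1 - mid_true[1L],
          comp_synthesis_true = if (lab_syn + lab_upt > 0)
            lab_syn / (lab_syn + lab_upt) else NA_real_,
          comp_uptake_true = if (lab_syn + lab_upt > 0)
            lab_upt / (lab_syn + lab_upt) else NA_real_)
        scale <- scale_map[[key(row$tissue, row$species)]]
        raw_true <- natural_abundance_matrix(sp$carbons, cfg$p13) %*%
          (scale * mid_true)
        for (rep_i in seq_len(n_rep)) {
          noisy <- as.numeric(raw_true) *
            stats::rlnorm(sp$carbons + 1L, meanlog = -sigma^2 / 2, sdlog = sigma)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            sample_id = sprintf("%s_%s_t%g_r%d", cfg$age_group, row$tissue, tp, rep_i),
            tissue = row$tissue, timepoint_h = tp, age_group = cfg$age_group,
            replicate = rep_i, species = row$species,
            isotopologue = 0:sp$carbons, intensity = noisy, corrected = 0L)
        }
      }
      # serum samples
      for (sp_name in names(nm$serum)) {
        sp <- lookup_species(sp_name, cfg$route_table)
        mid_true <- nm$serum[[sp_name]]
        scale <- scale_map[[key(cfg$donor_tissue, sp_name)]] * 0.5
        raw_true <- natural_abundance_matrix(sp$carbons, cfg$p13) %*%
          (scale * mid_true)
        truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
          age_group = cfg$age_group, tissue = "serum", timepoint_h = tp,
          species = sp_name, g_true = NA_real_, beta_true = NA_real_,
          x0 = NA_real_, x1 = NA_real_, x2 = NA_real_,
          labeling_extent_true = 1 - mid_true[1L],
          comp_synthesis_true = NA_real_, comp_uptake_true = NA_real_)
        for (rep_i in seq_len(n_rep)) {
          noisy <- as.numeric(raw_true) *
            stats::rlnorm(sp$carbons + 1L, meanlog = -sigma^2 / 2, sdlog = sigma)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            sample_id = sprintf("%s_serum_t%g_r%d", cfg$age_group, tp, rep_i),
            tissue = "serum", timepoint_h = tp, age_group = cfg$age_group,
            replicate = rep_i, species = sp_name,
            isotopologue = 0:sp$carbons, intensity = noisy, corrected = 0L)
        }
      }
    }
  })
  list(data = dplyr::bind_rows(rows), truth = dplyr::bind_rows(truth_rows),
       config = cfg)
}

# M0 fraction of the synthesis-route MID for ground-truth bookkeeping
route_d0 <- function(sp, row, cfg) {
  route_mid(sp, acetyl_labeling(row$x0, row$x1, row$x2),
            cfg$route_table)$fractions[1L]
}

#' Small fixed worked dataset for documentation and smoke tests
#'
#' A deterministic miniature of the full design: liver, lung and cortex plus
#' serum; FFA(16:0), FFA(16:1) and FFA(18:0); the 24 h timepoint with n = 4
#' replicates; 2 percent noise; fixed seed. Regenerated in code on every
#' call, so it is always in sync with the generator; the copy under
#' `inst/extdata/` is the materialization used by the file readers'
#' examples.
#'
#' @return As [simulate_panel()].
#' @export
worked_fixture <- function() {
  tissues <- c("liver", "lung", "cortex")
  rt <- default_route_table()
  rt <- rt[rt$species %in% c("FFA(16:0)", "FFA(16:1)", "FFA(18:0)"), ]
  cfg <- simulation_config(
    seed = 20240601L, tissues = tissues, route_table = rt,
    timepoints = 24, replicates = c(`24` = 4L),
    acetyl = default_acetyl_table(tissues),
    g = default_g_table(tissues, rt$species),
    beta = default_beta_table(tissues, rt$species),
    intensity = default_intensity_table(tissues, rt$species))
  simulate_panel(cfg)
}
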