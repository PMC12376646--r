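#' Acetyl-CoA isotopologue labeling simplex
#'
#' Fractions (x0, x1, x2) of acetyl-CoA 2-carbon units carrying 0, 1 or 2
#' 13C atoms (also written D0/D1/D2 in the fitting context). With
#' [U-13C]-glucose tracing, x2 reflects flux through fully labeled pyruvate;
#' the M+1 channel arises mainly from citrate cleavage and natural dilution.
#'
#' @param x0,x1,x2 Fractions in [0, 1] summing to 1 within 1e-9.
#' @return An object of class `acetyl_labeling`.
#' @export
acetyl_labeling <- function(x0, x1, x2) {
  x <- c(x0 = x0, x1 = x1, x2 = x2)
  if (anyNA(x) || any(x < -1e-12) || any(x > 1 + 1e-12)) {
    stop("acetyl fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(x) - 1) > 1e-9) {
    stop("acetyl fractions must sum to 1 within 1e-9", call. = FALSE)
  }
  structure(as.list(pmin(pmax(x, 0), 1)), class = "acetyl_labeling")
}

#' @export
print.acetyl_labeling <- function(x, ...) {
  cat(sprintf("<acetyl_labeling> x0=%.3f x1=%.3f x2=%.3f\n", x$x0, x$x1, x$x2))
  invisible(x)
}

acetyl_vec <- function(acetyl) {
  stopifnot(inherits(acetyl, "acetyl_labeling"))
  c(acetyl$x0, acetyl$x1, acetyl$x2)
}

#' Theoretical MID of a fully de novo synthesized fatty acid
#'
#' A chain built from `n_units` independent acetyl units, each carrying 0, 1
#' or 2 labeled carbons with probabilities (x0, x1, x2), has mass-shift
#' distribution
#' `D_i = sum over (m, n) with 2m + n = i of multinomial(n_units; m, n)
#'  * x2^m * x1^n * x0^(n_units - m - n)`
#' -- the n_units-fold convolution of the acetyl simplex, computed here by
#' repeated convolution so that `sum(D) = 1` holds exactly.
#'
#' @param acetyl An [acetyl_labeling].
#' @param n_units Number of acetyl units (1-12; 8 for palmitate).
#' @return Numeric vector `D_0..D_{2 n_units}` summing to 1.
#' @examples
#' denovo_mid(acetyl_labeling(0.5, 0, 0.5), 8)[3] # D_2 = 8 * 0.5^8
#' @export
denovo_mid <- function(acetyl, n_units) {
  x <- acetyl_vec(acetyl)
  n_units <- as.integer(n_units)
  if (n_units < 1L || n_units > 12L) {
    stop("n_units must be between 1 and 12", call. = FALSE)
  }
  d <- 1
  for (k in seq_len(n_units)) d <- convolve_unit(d, x)
  d
}

# discrete convolution of a mass-shift distribution with one acetyl unit
convolve_unit <- function(d, x) {
  n <- length(d)
  out <- numeric(n + 2L)
  out[seq_len(n)] <- d * x[1L]
  out[seq_len(n) + 1L] <- out[seq_len(n) + 1L] + d * x[2L]
  out[seq_len(n) + 2L] <- out[seq_len(n) + 2L] + d * x[3L]
  out
}

#' MID after one 2-carbon elongation step
#'
#' Appending one acetyl unit to a precursor chain shifts its mass-shift
#' distribution by convolution with the unit's labeling:
#' `E_i = D_i * x0 + D_{i-1} * x1 + D_{i-2} * x2`
#' (out-of-range terms zero). The output has two more mass channels than the
#' precursor and sums to 1.
#'
#' @param precursor Numeric mass-shift distribution (or an [ffa_mid]).
#' @param acetyl An [acetyl_labeling] for the elongating unit.
#' @return Numeric vector of length `length(precursor) + 2`.
#' @export
elongate_mid <- function(precursor, acetyl) {
  if (inherits(precursor, "ffa_mid")) precursor <- precursor$fractions
  stopifnot(is.numeric(precursor), all(precursor >= 0))
  convolve_unit(precursor, acetyl_vec(acetyl))
}

#' Theoretical MID of a newly synthesized fatty acid along its route
#'
#' Composes [denovo_mid()] and [elongate_mid()] according to the species'
#' declared synthesis route:
#' de novo species use `C/2` acetyl units; elongation species extend the de
#' novo C16 distribution by `n_steps` units; desaturation species inherit
#' their precursor's distribution unchanged (a double bond shifts no mass);
#' essential-elongation species (PUFAs) extend an unlabeled dietary precursor,
#' so only the appended units carry label.
#'
#' @param species An [ffa_species] or species name.
#' @param acetyl An [acetyl_labeling].
#' @param route_table Route table used to resolve precursor species.
#' @return An [ffa_mid] for `species`.
#' @export
route_mid <- function(species, acetyl, route_table = default_route_table()) {
  species <- if (inherits(species, "ffa_species")) species else
    lookup_species(species, route_table)
  fr <- switch(
    species$route,
    de_novo = denovo_mid(acetyl, species$carbons %/% 2L),
    elongation = {
      d <- denovo_mid(acetyl, 8L)
      for (k in seq_len(species$n_steps)) d <- elongate_mid(d, acetyl)
      d
    },
    desaturation = {
      if (is.na(species$precursor)) {
        stop("desaturation route for ", species$name, " lacks a precursor",
             call. = FALSE)
      }
      route_mid(species$precursor, acetyl, route_table)$fractions
    },
    essential_elongation = {
      pre_len <- species$carbons - 2L * species$n_steps + 1L
      d <- c(1, numeric(pre_len - 1L))
      for (k in seq_len(species$n_steps)) d <- elongate_mid(d, acetyl)
      d
    },
    stop("species ", species$name, " has no declared route", call. = FALSE)
  )
  ffa_mid(species, fr)
}

# shared bounded multi-start optimizer; starts is a matrix (one row per start)
multistart_lbfgsb <- function(objective, starts, lower, upper) {
  fits <- apply(starts, 1L, function(par0) {
    stats::optim(par0, objective, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(factr = 1e5, pgtol = 1e-12, maxit = 500L))
  })
  values <- vapply(fits, `[[`, numeric(1), "value")
  # tie-break: lowest SSE, then lowest first parameter
  ord <- order(values, vapply(fits, function(f) f$par[1L], numeric(1)))
  best <- fits[[ord[1L]]]
  # converged if any start reached the shared minimum cleanly (the line
  # search can abort with a nonzero code at an exactly-zero gradient)
  codes <- vapply(fits, `[[`, numeric(1), "convergence")
  at_min <- values <= best$value + 1e-12
  # a fit at the SSE tolerance floor is converged even when the line search
  # aborts on an exactly-flat objective
  list(par = best$par, sse = best$value,
       converged = any(codes[at_min] == 0) || best$value < 1e-10,
       n_starts = nrow(starts))
}

# stick-breaking map from (u1, u2) in [0,1]^2 onto the acetyl simplex
unit_square_to_simplex <- function(u1, u2) {
  x1 <- u1
  x2 <- (1 - u1) * u2
  acetyl_labeling(1 - x1 - x2, x1, x2)
}

#' Fit the newly synthesized fraction g(t) of a fatty acid
#'
#' Quasi-multinomial two-pool model: the observed MID is a mixture of a
#' pre-existing, fully unlabeled pool and a newly synthesized pool whose MID
#' follows the species' synthesis route at the tissue's acetyl-CoA labeling:
#' `M_i = (1 - g) * 1[i = 0] + g * route_mid(x)_i`.
#' The synthesis fraction g and the acetyl simplex x = (x0, x1, x2) are
#' estimated by bounded least squares (L-BFGS-B on a smooth stick-breaking
#' parameterization of x) from 8 deterministic multi-starts; ties break to
#' the lowest SSE, then the lowest g, so the fit is reproducible.
#'
#' @param observed An [ffa_mid] (natural-abundance corrected, normalized).
#' @param species Species to model; defaults to the MID's own species.
#' @param route_table Route table resolving the species' synthesis route.
#' @param detection_floor If the observed labeling extent is below this
#'   floor, g is pinned to 0 and the fit flagged (`pinned = TRUE`).
#' @param tissue Optional tissue label carried into the result.
#' @return An object of class `synthesis_fit`: fields `species`, `tissue`,
#'   `g`, `acetyl`, `sse`, `converged`, `pinned`, `n_starts`.
#' @export
fit_synthesis_fraction <- function(observed, species = observed$species,
                                   route_table = default_route_table(),
                                   detection_floor = 0.005,
                                   tissue = NA_character_) {
  stopifnot(inherits(observed, "ffa_mid"))
  species <- if (inherits(species, "ffa_species")) species else
    lookup_species(species, route_table)
  obs <- observed$fractions

  if (labeling_extent(observed) < detection_floor) {
    return(structure(
      list(species = species, tissue = tissue, g = 0,
           acetyl = acetyl_labeling(1, 0, 0), sse = NA_real_,
           converged = TRUE, pinned = TRUE, n_starts = 0L),
      class = "synthesis_fit"))
  }

  e0 <- c(1, numeric(species$carbons))
  model0 <- function(x) route_mid(species, x, route_table)$fractions
  objective <- function(par) {
    mix <- (1 - par[1L]) * e0 +
      par[1L] * model0(unit_square_to_simplex(par[2L], par[3L]))
    sum((obs - mix)^2)
  }

  starts <- as.matrix(expand.grid(g = c(0.1, 0.6),
                                  u1 = c(0.1, 0.4),
                                  u2 = c(0.2, 0.7)))
  fit <- multistart_lbfgsb(objective, starts, lower = rep(0, 3), upper = rep(1, 3))
  structure(
    list(species = species, tissue = tissue, g = unname(fit$par[1L]),
         acetyl = unit_square_to_simplex(fit$par[2L], fit$par[3L]),
         sse = fit$sse, converged = fit$converged, pinned = FALSE,
         n_starts = fit$n_starts),
    class = "synthesis_fit")
}

#' @export
print.synthesis_fit <- function(x, ...) {
  cat(sprintf(
    "<synthesis_fit> %s%s  g=%.4f  sse=%.3g  converged=%s%s\n",
    x$species$name,
    if (is.na(x$tissue)) "" else paste0(" [", x$tissue, "]"),
    x$g, x$sse, x$converged, if (x$pinned) " (pinned: below detection)" else ""))
  invisible(x)
}

#' Pool-size factors from per-tissue total FFA intensities
#'
#' Mean total intensities of one species across tissues, min-max rescaled to
#' [0, 1]. When all tissues have equal totals (including the single-tissue
#' case) the factor is 1 for every tissue, with a warning.
#'
#' @param totals Named numeric vector, tissue -> mean total intensity.
#' @param species Species label attached to the output.
#' @return A tibble with columns `species`, `tissue`, `factor`.
#' @export
pool_size_factors <- function(totals, species = NA_character_) {
  if (length(totals) == 0L) stop("need at least one tissue", call. = FALSE)
  if (anyNA(totals) || any(totals < 0)) {
    stop("intensity totals must be non-negative", call. = FALSE)
  }
  rng <- range(totals)
  if (rng[1L] == rng[2L]) {
    warning("all tissue totals equal; pool-size factors set to 1")
    f <- rep(1, length(totals))
  } else {
    f <- (totals - rng[1L]) / (rng[2L] - rng[1L])
  }
  tibble::tibble(species = species, tissue = names(totals), factor = unname(f))
}

#' Pseudo relative biosynthesis rate
#'
#' The fitted synthesis fraction g(t) scaled by the tissue's pool-size
#' factor. Because g is a fraction of the (tissue-specific) FFA pool, scaling
#' by relative pool size makes rates comparable across tissues -- still a
#' relative quantity, not an absolute flux.
#'
#' @param fit A `synthesis_fit`.
#' @param factor A one-row slice of [pool_size_factors()] output (or a bare
#'   numeric factor in [0, 1]).
#' @return Non-negative scalar.
#' @export
pseudo_rate <- function(fit, factor) {
  stopifnot(inherits(fit, "synthesis_fit"))
  if (is.data.frame(factor)) {
    stopifnot(nrow(factor) == 1L)
    if (!is.na(factor$species) && factor$species != fit$species$name) {
      stop("pool-size factor is for ", factor$species,
           ", fit is for ", fit$species$name, call. = FALSE)
    }
    factor <- factor$factor
  }
  stopifnot(is.numeric(factor), length(factor) == 1L, factor >= 0, factor <= 1)
  fit$g * factor
}
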