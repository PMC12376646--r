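#' Isotopologue intensity vector for one FFA in one sample
#'
#' Wraps the raw (or natural-abundance-corrected) peak intensities
#' I_M0..I_MC of all isotopologues of one fatty acid, measured in arbitrary
#' LC-MS intensity units.
#'
#' @param species An [ffa_species] (or species name resolvable via
#'   [lookup_species()]).
#' @param intensities Numeric vector of length C+1, all entries >= 0.
#' @param corrected Has natural-abundance correction been applied?
#' @return An object of class `iso_vector`.
#' @examples
#' v <- iso_vector("FFA(16:0)", c(700, 0, 300, rep(0, 14)))
#' @export
iso_vector <- function(species, intensities, corrected = FALSE) {
  species <- as_ffa_species(species)
  intensities <- as.numeric(intensities)
  if (length(intensities) != species$carbons + 1L) {
    stop("intensities must have length C+1 = ", species$carbons + 1L,
         " for ", species$name, ", got ", length(intensities), call. = FALSE)
  }
  if (anyNA(intensities) || any(intensities < 0)) {
    stop("intensities must be non-negative and non-missing", call. = FALSE)
  }
  structure(list(species = species, intensities = intensities,
                 corrected = isTRUE(corrected)),
            class = "iso_vector")
}

#' @export
print.iso_vector <- function(x, ...) {
  cat(sprintf("<iso_vector> %s  total=%.4g  corrected=%s\n",
              x$species$name, sum(x$intensities), x$corrected))
  invisible(x)
}

as_ffa_species <- function(x) {
  if (inherits(x, "ffa_species")) return(x)
  if (is.character(x) && length(x) == 1L) return(lookup_species(x))
  stop("expected an ffa_species or a species name", call. = FALSE)
}

#' Mass isotopologue distribution (MID)
#'
#' Fractional abundances L_M0..L_MC of the isotopologues of one fatty acid.
#' Entries must lie in [0, 1] and sum to 1 within 1e-9; the MID is the
#' central currency of every downstream stage (labeling extents, similarity
#' scores, synthesis fitting, deconvolution).
#'
#' @param species An [ffa_species] or species name.
#' @param fractions Numeric vector of length C+1 summing to 1.
#' @return An object of class `ffa_mid`.
#' @export
ffa_mid <- function(species, fractions) {
  species <- as_ffa_species(species)
  fractions <- as.numeric(fractions)
  if (length(fractions) != species$carbons + 1L) {
    stop("fractions must have length C+1 = ", species$carbons + 1L,
         call. = FALSE)
  }
  if (anyNA(fractions) || any(fractions < -1e-12) || any(fractions > 1 + 1e-12)) {
    stop("MID fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("MID fractions must sum to 1 within 1e-9 (got ",
         format(sum(fractions), digits = 12), ")", call. = FALSE)
  }
  structure(list(species = species, fractions = pmin(pmax(fractions, 0), 1)),
            class = "ffa_mid")
}

#' @export
print.ffa_mid <- function(x, ...) {
  cat(sprintf("<ffa_mid> %s  LE=%.4f\n", x$species$name, labeling_extent(x)))
  invisible(x)
}

#' Normalize isotopologue intensities to a mass isotopologue distribution
#'
#' The labeled fraction of each isotopologue is its intensity divided by the
#' summed intensity of all isotopologues of that fatty acid.
#'
#' @param v An [iso_vector].
#' @return An [ffa_mid].
#' @examples
#' m <- normalize_mid(iso_vector("FFA(16:0)", c(700, 0, 300, rep(0, 14))))
#' m$fractions[1] # 0.7
#' @export
normalize_mid <- function(v) {
  stopifnot(inherits(v, "iso_vector"))
  total <- sum(v$intensities)
  if (total <= 0) {
    stop("missing measurement: zero total intensity for ", v$species$name,
         call. = FALSE)
  }
  ffa_mid(v$species, v$intensities / total)
}

#' Natural-abundance convolution matrix for a C-carbon molecule
#'
#' Entry `[j+1, i+1]` is the probability that a molecule carrying i
#' deliberately incorporated 13C atoms is observed at mass shift j, i.e. that
#' j - i of its remaining C - i carbons are naturally occurring 13C:
#' `choose(C - i, j - i) * p13^(j - i) * (1 - p13)^(C - j)`.
#' The matrix is lower-triangular with positive diagonal.
#'
#' @param carbons Total carbon number C.
#' @param p13 Natural 13C abundance (default 0.0107).
#' @return A (C+1) x (C+1) matrix.
#' @export
natural_abundance_matrix <- function(carbons, p13 = 0.0107) {
  stopifnot(carbons >= 1, p13 >= 0, p13 < 0.05)
  n <- carbons + 1L
  M <- matrix(0, n, n)
  for (i in 0:carbons) {
    j <- i:carbons
    M[j + 1L, i + 1L] <- stats::dbinom(j - i, size = carbons - i, prob = p13)
  }
  M
}

#' Forward-convolve labeled intensities with natural 13C abundance
#'
#' The adjoint of [correct_natural_abundance()]: predicts the raw observed
#' isotopologue pattern from the true (label-only) one. Used by the
#' synthetic-data generator and by round-trip checks.
#'
#' @param v An [iso_vector] holding corrected (label-only) intensities.
#' @param p13 Natural 13C abundance.
#' @return An uncorrected [iso_vector].
#' @export
convolve_natural_abundance <- function(v, p13 = 0.0107) {
  stopifnot(inherits(v, "iso_vector"))
  M <- natural_abundance_matrix(v$species$carbons, p13)
  iso_vector(v$species, as.numeric(M %*% v$intensities), corrected = FALSE)
}

#' Correct isotopologue intensities for natural 13C abundance
#'
#' Solves M c = raw for the label-only intensities c under non-negativity,
#' where M is the binomial convolution matrix of
#' [natural_abundance_matrix()]. Carbon-only correction: at the high
#' resolving power typical of Orbitrap FFA acquisitions, 13C isotopologues
#' are resolved from 2H/17O/18O fine structure, so only carbon needs
#' deconvolution.
#'
#' @param v An uncorrected [iso_vector].
#' @param p13 Natural 13C abundance; `p13 = 0` returns the input flagged
#'   corrected.
#' @param residual_tol Maximum tolerated relative residual mass
#'   `||M c - raw|| / ||raw||` before the solve is declared failed; the
#'   default accommodates the negative-intensity clipping that measurement
#'   noise induces.
#' @return A corrected [iso_vector].
#' @export
correct_natural_abundance <- function(v, p13 = 0.0107, residual_tol = 0.05) {
  stopifnot(inherits(v, "iso_vector"))
  if (v$corrected) {
    stop("input is already flagged as corrected", call. = FALSE)
  }
  if (p13 == 0) {
    return(iso_vector(v$species, v$intensities, corrected = TRUE))
  }
  M <- natural_abundance_matrix(v$species$carbons, p13)
  # Lower-triangular system; exact forward substitution first, non-negative
  # least squares only when noise drives the direct solution negative.
  c_exact <- try(forwardsolve(M, v$intensities), silent = TRUE)
  if (!inherits(c_exact, "try-error") && all(c_exact >= -1e-9 * sum(v$intensities))) {
    c_hat <- pmax(c_exact, 0)
  } else {
    c_hat <- pracma::lsqnonneg(M, v$intensities)$x
  }
  resid <- sqrt(sum((M %*% c_hat - v$intensities)^2))
  denom <- sqrt(sum(v$intensities^2))
  if (denom > 0 && resid / denom > residual_tol) {
    stop("natural-abundance correction failed for ", v$species$name,
         ": relative residual ", format(resid / denom, digits = 3),
         call. = FALSE)
  }
  iso_vector(v$species, c_hat, corrected = TRUE)
}

#' Intensity of 13C-labeled fatty acid
#'
#' The 13C-weighted summed intensity `sum(i * I_Mi, i = 1..C)`: each
#' isotopologue contributes in proportion to the number of labeled carbons it
#' carries, so M0 contributes nothing. Quantifies incorporation of dietary
#' tracer carbon into the newly synthesized FFA pool. Only meaningful after
#' natural-abundance correction -- uncorrected input is refused, since
#' naturally occurring 13C would be double-counted as label.
#'
#' @param v A corrected [iso_vector].
#' @return Non-negative scalar in intensity units.
#' @export
labeled_intensity <- function(v) {
  stopifnot(inherits(v, "iso_vector"))
  if (!v$corrected) {
    stop("labeled_intensity requires natural-abundance-corrected intensities",
         call. = FALSE)
  }
  idx <- seq_along(v$intensities) - 1L
  sum(idx * v$intensities)
}

#' Labeling extent of a fatty acid (molecule-level labeled fraction)
#'
#' `LE = 1 - L_M0`: the fraction of molecules carrying at least one 13C atom.
#'
#' @param m An [ffa_mid].
#' @return Scalar in [0, 1].
#' @export
labeling_extent <- function(m) {
  stopifnot(inherits(m, "ffa_mid"))
  1 - m$fractions[1L]
}

#' 13C enrichment of a fatty acid (atom-level labeled fraction)
#'
#' `sum(i * L_Mi) / C`: the fraction of all carbon atoms in the pool that are
#' 13C label. Always <= the labeling extent, since each labeled molecule
#' counts fully toward LE but only i/C toward enrichment.
#'
#' @param m An [ffa_mid].
#' @return Scalar in [0, 1].
#' @export
c13_enrichment <- function(m) {
  stopifnot(inherits(m, "ffa_mid"))
  idx <- seq_along(m$fractions) - 1L
  sum(idx * m$fractions) / m$species$carbons
}

#' Isotopic-labeling detection filter
#'
#' A fatty acid counts as isotopically labeled when some isotopologue other
#' than M0 has a labeled fraction strictly greater than `threshold` in
#' strictly more than `min_fraction` of the samples. Both inequalities are
#' strict.
#'
#' @param mids A list of [ffa_mid] objects for one species across samples.
#' @param threshold Labeled-fraction detection floor (default 0.005).
#' @param min_fraction Required fraction of qualifying samples (default 0.5).
#' @return Logical scalar.
#' @export
is_labeled_ffa <- function(mids, threshold = 0.005, min_fraction = 0.5) {
  if (length(mids) == 0L) {
    stop("is_labeled_ffa needs at least one sample", call. = FALSE)
  }
  stopifnot(all(vapply(mids, inherits, logical(1), "ffa_mid")))
  frac <- do.call(rbind, lapply(mids, function(m) m$fractions))
  labeled <- frac[, -1L, drop = FALSE] > threshold
  pass_rate <- colMeans(labeled)
  any(pass_rate > min_fraction)
}
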