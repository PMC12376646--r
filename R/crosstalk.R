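#' MID similarity score between a tissue and serum
#'
#' Normalized Manhattan distance over the labeled isotopologues:
#' `score = 1 / (1 + sum_{i=1..C} |L_tissue,i - L_serum,i|)`.
#' M0 is excluded by the summation bounds. The score lies in (0, 1] and is 1
#' exactly when the labeled fractions coincide; it is symmetric in its two
#' arguments.
#'
#' @param tissue_mid,serum_mid [ffa_mid] objects for the same species.
#' @return Scalar in (0, 1].
#' @export
mid_similarity <- function(tissue_mid, serum_mid) {
  stopifnot(inherits(tissue_mid, "ffa_mid"), inherits(serum_mid, "ffa_mid"))
  if (tissue_mid$species$name != serum_mid$species$name) {
    stop("MID similarity requires matching species (",
         tissue_mid$species$name, " vs ", serum_mid$species$name, ")",
         call. = FALSE)
  }
  1 / (1 + sum(abs(labeled_fractions(tissue_mid) - labeled_fractions(serum_mid))))
}

#' Screen a tissue as a candidate donor of a serum fatty acid
#'
#' Two principles identify tissues whose synthesized FFA supplies the
#' circulating pool: (1) the donor's labeling extent must be at least as high
#' as serum's (labeled molecules are diluted on export, and at exchange
#' equilibrium the extents converge), and (2) the donor's MID must closely
#' resemble serum's. Both are assessed on replicate panels: criterion 1
#' compares mean labeling extents with a relative tolerance; criterion 2
#' thresholds the median similarity score across replicate pairs.
#'
#' @param tissue_mids,serum_mids Lists of [ffa_mid] replicates (same species,
#'   >= 2 each).
#' @param le_tolerance Relative tolerance on the labeling-extent comparison
#'   (default 0.05, i.e. tissue mean LE >= 95 percent of serum mean LE).
#' @param similarity_threshold Minimum median similarity score (default 0.8).
#' @param tissue Optional tissue label carried into the result.
#' @return A one-row tibble: `species`, `tissue`, `le_tissue`, `le_serum`,
#'   `le_pass`, `median_similarity`, `similarity_pass`, `verdict`.
#' @export
donor_screen <- function(tissue_mids, serum_mids,
                         le_tolerance = 0.05, similarity_threshold = 0.8,
                         tissue = NA_character_) {
  if (length(tissue_mids) < 2L || length(serum_mids) < 2L) {
    stop("donor_screen needs >= 2 replicates per group", call. = FALSE)
  }
  species <- tissue_mids[[1L]]$species$name
  le_t <- mean(vapply(tissue_mids, labeling_extent, numeric(1)))
  le_s <- mean(vapply(serum_mids, labeling_extent, numeric(1)))
  le_pass <- le_t >= le_s * (1 - le_tolerance)
  # replicate-paired similarity scores, summarized by the median
  sims <- vapply(seq_len(min(length(tissue_mids), length(serum_mids))),
                 function(k) mid_similarity(tissue_mids[[k]], serum_mids[[k]]),
                 numeric(1))
  med_sim <- stats::median(sims)
  sim_pass <- med_sim >= similarity_threshold
  tibble::tibble(
    species = species, tissue = tissue,
    le_tissue = le_t, le_serum = le_s, le_pass = le_pass,
    median_similarity = med_sim, similarity_pass = sim_pass,
    verdict = if (le_pass && sim_pass) "donor-consistent" else "not-donor-consistent")
}

# best SSE of a single-route model obs ~ w * pattern with w in [0, 1]
single_route_sse <- function(obs, pattern) {
  denom <- sum(pattern^2)
  w <- if (denom > 0) min(max(sum(obs * pattern) / denom, 0), 1) else 0
  sum((obs - w * pattern)^2)
}

# normalized labeled fractions (sum 1 over i = 1..C), or NULL when unlabeled
normalized_labeled <- function(m, floor = 1e-4) {
  lf <- labeled_fractions(m)
  s <- sum(lf)
  if (s < floor) return(NULL)
  lf / s
}

deconvolution_result <- function(species, tissue, alpha, beta, acetyl, sse,
                                 converged, non_identifiable = FALSE,
                                 reason = NA_character_) {
  total <- alpha + beta
  composition <- if (!is.na(alpha) && total > 0) {
    c(synthesis = alpha / total, uptake = beta / total)
  } else {
    c(synthesis = NA_real_, uptake = NA_real_)
  }
  structure(
    list(species = species, tissue = tissue, alpha = alpha, beta = beta,
         acetyl = acetyl, sse = sse, converged = converged,
         non_identifiable = non_identifiable, composition = composition,
         reason = reason),
    class = "deconvolution_fit")
}

#' @export
print.deconvolution_fit <- function(x, ...) {
  if (is.na(x$alpha)) {
    cat(sprintf("<deconvolution_fit> %s: no fit (%s)\n",
                x$species$name, x$reason))
  } else {
    cat(sprintf(
      "<deconvolution_fit> %s%s  alpha=%.3f beta=%.3f  composition=%.3f/%.3f%s\n",
      x$species$name,
      if (is.na(x$tissue)) "" else paste0(" [", x$tissue, "]"),
      x$alpha, x$beta, x$composition[1L], x$composition[2L],
      if (x$non_identifiable) "  (non-identifiable)" else ""))
  }
  invisible(x)
}

#' Deconvolve de novo synthesis versus serum uptake for palmitate
#'
#' The labeled isotopologue pattern of tissue FFA(16:0) is modeled as a
#' mixture of two routes: de novo synthesis from acetyl-CoA, whose labeled
#' pattern is the multinomial `D_i` of [denovo_mid()] normalized over
#' i = 1..C, and uptake from serum, whose pattern `U_i` is the serum MID's
#' labeled fractions normalized over i = 1..C:
#' `M_i,pre = alpha * D_i / sum(D_1..C) + beta * U_i`.
#' alpha, beta in [0, 1] and the acetyl simplex x are estimated by bounded
#' multi-start least squares against the tissue's normalized labeled
#' fractions; alpha + beta is not constrained to 1, and the reported
#' composition is the renormalized pair (alpha, beta) / (alpha + beta).
#'
#' When each single-route model (pure synthesis with its own acetyl simplex,
#' or pure serum uptake) explains the observed pattern essentially as well
#' as the joint fit, the alpha/beta split is arbitrary along a ridge and the
#' fit is flagged non-identifiable; `identifiability_tol` sets the profile
#' SSE tolerance of that check (as a Manhattan-distance scale, squared and
#' divided by the number of labeled channels).
#'
#' @param observed Tissue [ffa_mid] for FFA(16:0), corrected.
#' @param serum Serum [ffa_mid] for FFA(16:0) (mean across serum replicates).
#' @param tissue Optional tissue label.
#' @param labeling_floor Minimum labeled-fraction sum below which the tissue
#'   (or serum) is treated as unlabeled and no fit is attempted.
#' @param identifiability_tol Manhattan-distance flag threshold (default 0.02).
#' @return A `deconvolution_fit`.
#' @export
deconvolve_16_0 <- function(observed, serum, tissue = NA_character_,
                            labeling_floor = 1e-4, identifiability_tol = 0.02) {
  stopifnot(inherits(observed, "ffa_mid"), inherits(serum, "ffa_mid"))
  species <- observed$species
  if (species$carbons != 16L || serum$species$carbons != 16L) {
    stop("deconvolve_16_0 expects C16 MIDs", call. = FALSE)
  }
  U <- normalized_labeled(serum, labeling_floor)
  if (is.null(U)) {
    return(deconvolution_result(species, tissue, NA_real_, NA_real_, NULL,
                                NA_real_, FALSE, reason = "serum unlabeled"))
  }
  obs <- normalized_labeled(observed, labeling_floor)
  if (is.null(obs)) {
    return(deconvolution_result(species, tissue, NA_real_, NA_real_, NULL,
                                NA_real_, FALSE, reason = "tissue unlabeled"))
  }

  norm_denovo <- function(x) {
    d <- denovo_mid(x, 8L)[-1L]
    s <- sum(d)
    # x = (1, 0, 0) leaves no labeled mass; return zeros so the objective
    # stays finite and that corner is simply a bad fit
    if (s <= 0) numeric(length(d)) else d / s
  }
  objective <- function(par) {
    dn <- norm_denovo(unit_square_to_simplex(par[3L], par[4L]))
    sum((obs - (par[1L] * dn + par[2L] * U))^2)
  }
  starts <- as.matrix(expand.grid(alpha = c(0.2, 0.8), u1 = c(0.1, 0.4),
                                  u2 = c(0.2, 0.7)))
  starts <- cbind(starts[, 1L, drop = FALSE], beta = 1 - starts[, 1L],
                  starts[, 2:3, drop = FALSE])
  fit <- multistart_lbfgsb(objective, starts, lower = rep(0, 4), upper = rep(1, 4))
  x_hat <- unit_square_to_simplex(fit$par[3L], fit$par[4L])
  # the split is unidentifiable when each single-route model explains the
  # data as well as the joint fit (profile SSE within tolerance)
  sse_uptake_only <- single_route_sse(obs, U)
  syn_obj <- function(par) {
    dn <- norm_denovo(unit_square_to_simplex(par[2L], par[3L]))
    sum((obs - par[1L] * dn)^2)
  }
  syn_starts <- as.matrix(expand.grid(alpha = c(0.3, 0.9), u1 = c(0.1, 0.4),
                                      u2 = c(0.2, 0.7)))
  sse_syn_only <- multistart_lbfgsb(syn_obj, syn_starts,
                                    lower = rep(0, 3), upper = rep(1, 3))$sse
  tol_sse <- identifiability_tol^2 / length(obs)
  non_ident <- sse_uptake_only < fit$sse + tol_sse &&
    sse_syn_only < fit$sse + tol_sse
  deconvolution_result(species, tissue, unname(fit$par[1L]),
                       unname(fit$par[2L]), x_hat, fit$sse, fit$converged,
                       non_identifiable = non_ident)
}

#' Deconvolve elongation synthesis versus serum uptake for stearate
#'
#' Tissue FFA(18:0) is made by elongating FFA(16:0) with one further acetyl
#' unit, so its synthesis-route pattern is the convolution
#' `E_i = D_i * x0 + D_{i-1} * x1 + D_{i-2} * x2`
#' of the tissue's palmitate distribution with the acetyl labeling, both
#' taken from the same tissue's FFA(16:0) fit. Only alpha and beta are free:
#' `M_i,pre = alpha * E_i / sum(E_1..C) + beta * U_i`, fit as in
#' [deconvolve_16_0()].
#'
#' @param observed Tissue [ffa_mid] for FFA(18:0).
#' @param serum18 Serum [ffa_mid] for FFA(18:0).
#' @param acetyl_from_16_0 [acetyl_labeling] fitted on the tissue's FFA(16:0).
#' @param d16 Palmitate mass-shift distribution from the same fit (numeric
#'   vector over M0..M16, e.g. `denovo_mid(acetyl, 8)`).
#' @param tissue,labeling_floor,identifiability_tol As in [deconvolve_16_0()].
#' @return A `deconvolution_fit`.
#' @export
deconvolve_18_0 <- function(observed, serum18, acetyl_from_16_0, d16,
                            tissue = NA_character_, labeling_floor = 1e-4,
                            identifiability_tol = 0.02) {
  stopifnot(inherits(observed, "ffa_mid"), inherits(serum18, "ffa_mid"))
  species <- observed$species
  if (species$carbons != 18L || serum18$species$carbons != 18L) {
    stop("deconvolve_18_0 expects C18 MIDs", call. = FALSE)
  }
  if (inherits(d16, "ffa_mid")) d16 <- d16$fractions
  E <- elongate_mid(d16, acetyl_from_16_0)
  E_lab <- E[-1L]
  U <- normalized_labeled(serum18, labeling_floor)
  if (is.null(U) || sum(E_lab) < 1e-12) {
    return(deconvolution_result(species, tissue, NA_real_, NA_real_,
                                acetyl_from_16_0, NA_real_, FALSE,
                                reason = "synthesis and serum patterns unlabeled"))
  }
  obs <- normalized_labeled(observed, labeling_floor)
  if (is.null(obs)) {
    return(deconvolution_result(species, tissue, NA_real_, NA_real_,
                                acetyl_from_16_0, NA_real_, FALSE,
                                reason = "tissue unlabeled"))
  }
  En <- E_lab / sum(E_lab)
  objective <- function(par) sum((obs - (par[1L] * En + par[2L] * U))^2)
  starts <- as.matrix(expand.grid(alpha = c(0.2, 0.8), beta = c(0.2, 0.8)))
  fit <- multistart_lbfgsb(objective, starts, lower = c(0, 0), upper = c(1, 1))
  tol_sse <- identifiability_tol^2 / length(obs)
  non_ident <- single_route_sse(obs, U) < fit$sse + tol_sse &&
    single_route_sse(obs, En) < fit$sse + tol_sse
  deconvolution_result(species, tissue, unname(fit$par[1L]),
                       unname(fit$par[2L]), acetyl_from_16_0, fit$sse,
                       fit$converged, non_identifiable = non_ident)
}

#' Monte Carlo permutation test comparing two groups of MIDs
#'
#' Test statistic: the Manhattan distance between group mean labeled
#' fractions, `sum_{i=1..C} |mean_a L_i - mean_b L_i|` (M0 excluded,
#' matching the similarity-score geometry). Group labels are permuted
#' `n_perm` times and the p-value uses the add-one estimator
#' `p = (1 + #permuted >= observed) / (1 + n_perm)`, so p is never 0 and is
#' bounded below by `1 / (n_perm + 1)`.
#'
#' @param group_a,group_b Lists of [ffa_mid] replicates (>= 2 each) for the
#'   same species.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Optional integer seed; the global RNG state is preserved.
#' @return A list: `p_value`, `statistic`, `n_perm`.
#' @export
permutation_test_mid <- function(group_a, group_b, n_perm = 999, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("permutation test needs >= 2 samples per group", call. = FALSE)
  }
  A <- do.call(rbind, lapply(group_a, labeled_fractions))
  B <- do.call(rbind, lapply(group_b, labeled_fractions))
  if (ncol(A) != ncol(B)) stop("groups must share a species", call. = FALSE)
  X <- rbind(A, B)
  na <- nrow(A)
  n <- nrow(X)
  col_total <- colSums(X)
  stat_from_idx <- function(idx) {
    sa <- colSums(X[idx, , drop = FALSE])
    sum(abs(sa / na - (col_total - sa) / (n - na)))
  }
  observed <- stat_from_idx(seq_len(na))
  perm <- with_preserved_seed(seed, {
    vapply(seq_len(n_perm), function(k) stat_from_idx(sample.int(n, na)),
           numeric(1))
  })
  p <- (1 + sum(perm >= observed - 1e-12)) / (1 + n_perm)
  list(p_value = p, statistic = observed, n_perm = as.integer(n_perm))
}

#' Labeled-fraction matrix across tissues and species
#'
#' For each tissue, the mean 13C-labeled intensity of each FFA species is
#' expressed as a fraction of the summed mean labeled intensities of all
#' species in that tissue, so each row is the tissue's composition of newly
#' synthesized FFAs and sums to 1. Tissues with zero total labeled intensity
#' yield all-NA rows.
#'
#' @param labeled A tidy data frame with columns `tissue`, `species`, and
#'   `labeled_intensity` (one row per sample; replicates are averaged).
#' @return A matrix, rows tissues, columns species.
#' @export
labeled_fraction_matrix <- function(labeled) {
  stopifnot(all(c("tissue", "species", "labeled_intensity") %in% colnames(labeled)))
  means <- labeled |>
    dplyr::group_by(.data$tissue, .data$species) |>
    dplyr::summarise(mean_li = mean(.data$labeled_intensity), .groups = "drop")
  wide <- tidyr::pivot_wider(means, names_from = "species",
                             values_from = "mean_li", values_fill = 0)
  m <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(m) <- wide$tissue
  totals <- rowSums(m)
  out <- sweep(m, 1L, totals, "/")
  out[totals == 0, ] <- NA_real_
  out
}
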