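#' Free fatty acid species with a declared synthesis route
#'
#' An `ffa_species` records the identity of a free fatty acid -- carbon count
#' and number of double bonds -- together with the biosynthetic route through
#' which newly made molecules acquire label from acetyl-CoA:
#'
#' * `"de_novo"`: the chain is assembled entirely from 2-carbon acetyl units
#'   (`n_units = carbons / 2`), e.g. myristate and palmitate.
#' * `"elongation"`: a de novo C16 backbone is extended by `n_steps`
#'   elongation cycles of 2 carbons each (stearate and the long-chain MUFAs).
#' * `"desaturation"`: a double bond is introduced into an existing chain;
#'   the carbon-label mass pattern is that of the precursor, unchanged.
#' * `"essential_elongation"`: elongation of an unlabeled (dietary/essential)
#'   polyunsaturated precursor, so only the appended units can carry label.
#'
#' @param name Species label, conventionally `"FFA(C:d)"`.
#' @param carbons Total carbon number C (even, >= 14 for the panel used here).
#' @param double_bonds Number of double bonds (>= 0).
#' @param route One of `"de_novo"`, `"elongation"`, `"desaturation"`,
#'   `"essential_elongation"`.
#' @param precursor Name of the precursor species for desaturation /
#'   elongation routes (`NA` for de novo).
#' @param n_units Number of acetyl units for de novo assembly.
#' @param n_steps Number of 2-carbon elongation steps applied to the
#'   precursor backbone.
#'
#' @return An object of class `ffa_species`.
#' @examples
#' ffa_species("FFA(16:0)", 16, 0, "de_novo", n_units = 8)
#' @export
ffa_species <- function(name, carbons, double_bonds = 0,
                        route = c("de_novo", "elongation", "desaturation",
                                  "essential_elongation"),
                        precursor = NA_character_,
                        n_units = NA_integer_, n_steps = NA_integer_) {
  route <- match.arg(route)
  carbons <- as.integer(carbons)
  stopifnot(length(carbons) == 1L, carbons > 0L)
  if (carbons %% 2L != 0L) {
    stop("carbons must be even for acetyl-unit-built fatty acids, got ",
         carbons, call. = FALSE)
  }
  if (double_bonds < 0) stop("double_bonds must be >= 0", call. = FALSE)
  if (route == "de_novo") {
    if (is.na(n_units)) n_units <- carbons %/% 2L
    if (n_units > carbons %/% 2L) {
      stop("n_units cannot exceed carbons/2", call. = FALSE)
    }
  }
  if (route %in% c("elongation", "essential_elongation") && is.na(n_steps)) {
    stop("route '", route, "' requires n_steps", call. = FALSE)
  }
  structure(
    list(name = name, carbons = carbons,
         double_bonds = as.integer(double_bonds), route = route,
         precursor = precursor, n_units = as.integer(n_units),
         n_steps = as.integer(n_steps)),
    class = "ffa_species"
  )
}

#' @export
print.ffa_species <- function(x, ...) {
  cat(sprintf("<ffa_species> %s  C=%d  d=%d  route=%s\n",
              x$name, x$carbons, x$double_bonds, x$route))
  invisible(x)
}

#' Default route table for the 13-species labeled FFA panel
#'
#' The panel of 13 labeled free fatty acids (C14-C24, 0-5 double bonds)
#' resolved in multi-tissue tracing studies, with default synthesis routes:
#' myristate and palmitate are fully de novo; palmitoleate and oleate are
#' desaturation products (no mass-pattern change relative to their saturated
#' precursors); stearate and the very-long-chain MUFAs are successive
#' elongations of the de novo C16 backbone; the C20 PUFAs are single
#' elongations of unlabeled essential C18 precursors.
#'
#' @return A tibble with columns `species`, `carbons`, `double_bonds`,
#'   `route`, `precursor`, `n_units`, `n_steps`.
#' @export
default_route_table <- function() {
  tibble::tribble(
    ~species,     ~carbons, ~double_bonds, ~route,                 ~precursor,   ~n_units, ~n_steps,
    "FFA(14:0)",  14L,      0L,            "de_novo",              NA,           7L,       NA,
    "FFA(16:0)",  16L,      0L,            "de_novo",              NA,           8L,       NA,
    "FFA(16:1)",  16L,      1L,            "desaturation",         "FFA(16:0)",  NA,       NA,
    "FFA(18:0)",  18L,      0L,            "elongation",           "FFA(16:0)",  NA,       1L,
    "FFA(18:1)",  18L,      1L,            "desaturation",         "FFA(18:0)",  NA,       NA,
    "FFA(20:0)",  20L,      0L,            "elongation",           "FFA(16:0)",  NA,       2L,
    "FFA(20:1)",  20L,      1L,            "elongation",           "FFA(16:0)",  NA,       2L,
    "FFA(20:2)",  20L,      2L,            "essential_elongation", "FFA(18:2)",  NA,       1L,
    "FFA(20:3)",  20L,      3L,            "essential_elongation", "FFA(18:3)",  NA,       1L,
    "FFA(20:4)",  20L,      4L,            "essential_elongation", "FFA(18:3)",  NA,       1L,
    "FFA(20:5)",  20L,      5L,            "essential_elongation", "FFA(18:4)",  NA,       1L,
    "FFA(22:1)",  22L,      1L,            "elongation",           "FFA(16:0)",  NA,       3L,
    "FFA(24:1)",  24L,      1L,            "elongation",           "FFA(16:0)",  NA,       4L
  )
}

#' Look up one species from a route table
#'
#' @param name Species label as in the route table.
#' @param route_table A route table as returned by [default_route_table()].
#' @return An [ffa_species] object.
#' @export
lookup_species <- function(name, route_table = default_route_table()) {
  row <- route_table[route_table$species == name, ]
  if (nrow(row) == 0L) {
    stop("species '", name, "' is not in the route table", call. = FALSE)
  }
  row <- row[1L, ]
  ffa_species(row$species, row$carbons, row$double_bonds, row$route,
              precursor = row$precursor,
              n_units = if (is.na(row$n_units)) NA_integer_ else row$n_units,
              n_steps = if (is.na(row$n_steps)) NA_integer_ else row$n_steps)
}

#' Default tissue vocabulary: 15 tissues plus serum
#'
#' Nine peripheral tissues (liver, kidney, lung, heart, spleen, muscle, brown
#' and white adipose, small intestine), six brain regions (cortex, midbrain,
#' cerebellum, olfactory bulb, hippocampus, pons), and circulating serum.
#'
#' @param include_serum Append `"serum"` to the vector.
#' @return Character vector of tissue labels.
#' @export
default_tissues <- function(include_serum = TRUE) {
  tissues <- c("liver", "kidney", "lung", "heart", "spleen", "muscle",
               "BAT", "WAT", "intestine",
               "cortex", "midbrain", "cerebellum", "olfactory", "hippocampus",
               "pons")
  if (include_serum) c(tissues, "serum") else tissues
}

#' Peripheral (non-brain) tissue labels
#' @return Character vector.
#' @export
peripheral_tissues <- function() {
  c("liver", "kidney", "lung", "heart", "spleen", "muscle",
    "BAT", "WAT", "intestine")
}

#' Brain-region tissue labels
#' @return Character vector.
#' @export
brain_tissues <- function() {
  c("cortex", "midbrain", "cerebellum", "olfactory", "hippocampus", "pons")
}
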