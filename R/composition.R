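#' Lignin monomer composition
#'
#' Represents the measured proportions of the three thioacidolysis monomers:
#' p-hydroxyphenyl (H), guaiacyl (G) and syringyl (S).  Fractions are
#' normalized to sum to one on construction (published tables often carry
#' rounded percentages such as 7/85.5/7.4 that sum to 99.9).
#'
#' @param h,g,s Non-negative monomer fractions (or percentages; any common
#'   positive scale works since the triple is renormalized).
#' @return An object of class `monomer_composition`: named numeric vector
#'   `c(h=, g=, s=)` summing to 1.
#' @examples
#' monomer_composition(7, 85.5, 7.4)   # internodes 1-2 of wild-type alfalfa
#' @export
monomer_composition <- function(h, g, s) {
  x <- c(h = h, g = g, s = s)
  if (any(!is.finite(x)) || any(x < 0))
    stop("monomer fractions must be finite and non-negative")
  tot <- sum(x)
  if (tot <= 0) stop("monomer fractions must not all be zero")
  structure(x / tot, class = "monomer_composition")
}

#' @export
print.monomer_composition <- function(x, ...) {
  cat(sprintf("H/G/S composition: %.4f / %.4f / %.4f (S/G = %s)\n",
              x["h"], x["g"], x["s"],
              if (x["g"] > 0) sprintf("%.4f", x["s"] / x["g"]) else "undefined"))
  invisible(x)
}

#' S/G ratio of a composition
#' @param comp A `monomer_composition`.
#' @return `s/g`, or `NA` if `g` is zero.
#' @export
sg_ratio <- function(comp) {
  stopifnot(inherits(comp, "monomer_composition"))
  if (comp[["g"]] <= 0) return(NA_real_)
  comp[["s"]] / comp[["g"]]
}

#' Proportionality constraints on the transport fluxes
#'
#' Reformulates a measured monomer composition as linear equality constraints
#' on the three cell-wall transport fluxes: `v6 = h*(v6+v15+v19)` and
#' `v15 = g*(v6+v15+v19)`.  The analogous S constraint is implied by the other
#' two and is omitted, so the system stays full-rank.
#'
#' @param comp A `monomer_composition` (or a length-3 non-negative vector,
#'   which is normalized first).
#' @return A list with `A` (2 x 3 coefficient matrix over `v6`, `v15`, `v19`)
#'   and `b` (zero right-hand sides): rows satisfy `A %*% c(v6,v15,v19) = b`.
#' @export
composition_constraints <- function(comp) {
  if (!inherits(comp, "monomer_composition")) {
    if (length(comp) != 3L) stop("composition must have three entries (h, g, s)")
    comp <- monomer_composition(comp[[1]], comp[[2]], comp[[3]])
  }
  A <- rbind(
    h = c(v6 = 1 - comp[["h"]], v15 = -comp[["h"]], v19 = -comp[["h"]]),
    g = c(v6 = -comp[["g"]], v15 = 1 - comp[["g"]], v19 = -comp[["g"]])
  )
  list(A = A, b = c(h = 0, g = 0))
}
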