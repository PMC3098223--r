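# Enzyme vocabulary. TRANSPORT and OVERFLOW are pseudo-enzymes: they label the
# cell-wall export steps and the efflux reactions draining intermediates into
# peripheral pathways (salicylic acid, flavonoids, 5H incorporation).
.ENZYMES <- c("PAL", "C4H", "4CL", "HCT", "C3H", "CCR1", "CCR2",
              "CCoAOMT", "COMT", "F5H", "CAD", "TRANSPORT", "OVERFLOW")

.OVERFLOW_LB <- 0.01

# Full reaction map of the revised alfalfa monolignol pathway: 21 core
# conversions/transport steps (v1-v21) plus three overflow effluxes (v22-v24).
# Shikimate and CoA are treated as perfectly recycled cofactors, so both
# HCT-catalyzed transesterifications appear as simple conversions.  v24 doubles
# as the 5H-monomer sink (incorporation of 5-hydroxyconiferyl alcohol into the
# polymer); it is not part of the H+G+S monomer total.
.reference_reactions <- function() {
  data.frame(
    id = paste0("v", 1:24),
    enzyme = c("PAL", "C4H", "4CL", "CCR1", "CAD", "TRANSPORT", "HCT", "C3H",
               "HCT", "CCR2", "CCoAOMT", "COMT", "CCR1", "CAD", "TRANSPORT",
               "F5H", "COMT", "CAD", "TRANSPORT", "F5H", "COMT",
               "OVERFLOW", "OVERFLOW", "OVERFLOW"),
    substrate = c("phenylalanine", "cinnamic_acid", "p_coumaric_acid",
                  "p_coumaroyl_CoA", "p_coumaraldehyde", "p_coumaryl_alcohol",
                  "p_coumaroyl_CoA", "p_coumaroyl_shikimate",
                  "caffeoyl_shikimate", "caffeoyl_CoA", "caffeoyl_CoA",
                  "caffeyl_aldehyde", "feruloyl_CoA", "coniferyl_aldehyde",
                  "coniferyl_alcohol", "coniferyl_aldehyde",
                  "5OH_coniferyl_aldehyde", "sinapyl_aldehyde",
                  "sinapyl_alcohol", "coniferyl_alcohol",
                  "5OH_coniferyl_alcohol", "cinnamic_acid", "p_coumaroyl_CoA",
                  "5OH_coniferyl_alcohol"),
    product = c("cinnamic_acid", "p_coumaric_acid", "p_coumaroyl_CoA",
                "p_coumaraldehyde", "p_coumaryl_alcohol", "H_lignin",
                "p_coumaroyl_shikimate", "caffeoyl_shikimate", "caffeoyl_CoA",
                "caffeyl_aldehyde", "feruloyl_CoA", "coniferyl_aldehyde",
                "coniferyl_aldehyde", "coniferyl_alcohol", "G_lignin",
                "5OH_coniferyl_aldehyde", "sinapyl_aldehyde", "sinapyl_alcohol",
                "S_lignin", "5OH_coniferyl_alcohol", "sinapyl_alcohol",
                "salicylate_sink", "flavonoid_sink", "5H_sink"),
    lower_bound = c(rep(0, 21), rep(.OVERFLOW_LB, 3)),
    upper_bound = 1,
    stringsAsFactors = FALSE
  )
}

.BOUNDARY_METABOLITES <- c("phenylalanine", "H_lignin", "G_lignin", "S_lignin",
                           "salicylate_sink", "flavonoid_sink", "5H_sink")

#' Build the reference monolignol pathway network
#'
#' Constructs the fixed stoichiometric model of monolignol biosynthesis in
#' alfalfa stems.  The `"extended"` variant carries 24 reactions: the core
#' pathway from phenylalanine to the three cell-wall transport steps
#' (p-hydroxyphenyl `v6`, guaiacyl `v15`, syringyl `v19`) plus three overflow
#' effluxes (`v22` from cinnamic acid towards salicylate, `v23` from
#' p-coumaroyl-CoA towards flavonoids, `v24` draining 5-hydroxyconiferyl
#' alcohol into the polymer as 5H units).  The `"unextended"` variant is the
#' same network without the overflows (21 reactions).  All reactions are
#' irreversible; overflow reactions carry a lower bound of 0.01 in normalized
#' flux units so they cannot vanish during optimization.
#'
#' @param variant `"extended"` (24 reactions) or `"unextended"` (21 reactions).
#' @return An object of class `lignin_network`: a list with elements
#'   `reactions` (data frame: `id`, `enzyme`, `substrate`, `product`,
#'   `lower_bound`, `upper_bound`), `metabolites` (data frame: `id`,
#'   `is_boundary`) and `variant`.
#' @examples
#' net <- build_reference_network("extended")
#' reactions_for_enzyme(net, "COMT")
#' @export
build_reference_network <- function(variant = c("extended", "unextended")) {
  variant <- match.arg(variant)
  rx <- .reference_reactions()
  if (variant == "unextended") {
    rx <- rx[rx$enzyme != "OVERFLOW", , drop = FALSE]
  }
  .lignin_network(rx, variant)
}

.lignin_network <- function(reactions, variant) {
  mets <- unique(c(reactions$substrate, reactions$product))
  metabolites <- data.frame(
    id = mets,
    is_boundary = mets %in% .BOUNDARY_METABOLITES,
    stringsAsFactors = FALSE
  )
  net <- structure(
    list(reactions = reactions, metabolites = metabolites, variant = variant),
    class = "lignin_network"
  )
  validate_network(net)
  net
}

#' Validate a pathway network
#'
#' Checks the structural invariants of a `lignin_network`: unique reaction and
#' metabolite ids, non-negative lower bounds (irreversibility), overflow lower
#' bounds at 0.01 in the extended variant, and that every internal (non-
#' boundary) metabolite has at least one producing and one consuming reaction.
#'
#' @param net A `lignin_network`.
#' @return `net`, invisibly; errors describe the violated invariant.
#' @export
validate_network <- function(net) {
  rx <- net$reactions
  if (anyDuplicated(rx$id)) stop("duplicate reaction ids")
  if (anyDuplicated(net$metabolites$id)) stop("duplicate metabolite ids")
  if (!all(rx$enzyme %in% .ENZYMES)) {
    stop("unknown enzyme label(s): ",
         paste(setdiff(rx$enzyme, .ENZYMES), collapse = ", "))
  }
  if (any(rx$lower_bound < 0)) stop("negative lower bound: reactions are irreversible")
  if (any(rx$upper_bound < rx$lower_bound)) stop("upper bound below lower bound")
  ov <- rx$enzyme == "OVERFLOW"
  if (net$variant == "extended") {
    if (sum(ov) != 3L || nrow(rx) != 24L)
      stop("extended variant must have 24 reactions incl. 3 overflows")
  } else {
    if (any(ov) || nrow(rx) != 21L)
      stop("unextended variant must have 21 reactions and no overflows")
  }
  internal <- net$metabolites$id[!net$metabolites$is_boundary]
  produced <- internal %in% rx$product
  consumed <- internal %in% rx$substrate
  if (!all(produced & consumed)) {
    stop("internal metabolite without producer+consumer: ",
         paste(internal[!(produced & consumed)], collapse = ", "))
  }
  invisible(net)
}

#' Stoichiometric matrix over internal metabolites
#'
#' Returns the matrix `N` with one row per internal (non-boundary) metabolite
#' and one column per reaction, entries in \{-1, 0, +1\} (all stoichiometric
#' coefficients in this linear/branched pathway are 1; cofactors are excluded).
#' A flux vector `v` is at steady state iff `N %*% v == 0`.
#'
#' @param net A `lignin_network`.
#' @return A numeric matrix with dimnames (metabolite ids x reaction ids).
#' @export
stoichiometric_matrix <- function(net) {
  stopifnot(inherits(net, "lignin_network"))
  rx <- net$reactions
  internal <- net$metabolites$id[!net$metabolites$is_boundary]
  N <- matrix(0, length(internal), nrow(rx),
              dimnames = list(internal, rx$id))
  for (j in seq_len(nrow(rx))) {
    if (rx$substrate[j] %in% internal) N[rx$substrate[j], j] <- N[rx$substrate[j], j] - 1
    if (rx$product[j] %in% internal) N[rx$product[j], j] <- N[rx$product[j], j] + 1
  }
  N
}

#' Reactions catalyzed by an enzyme
#'
#' Several enzymes of the pathway catalyze multiple steps (CAD reduces all
#' three hydroxycinnamyl aldehydes; COMT methylates caffeyl aldehyde,
#' 5-hydroxyconiferyl aldehyde and 5-hydroxyconiferyl alcohol), so a gene
#' knockdown maps to a set of reactions.
#'
#' @param net A `lignin_network`.
#' @param enzyme Enzyme symbol, e.g. `"COMT"`.  `TRANSPORT` and `OVERFLOW`
#'   are rejected when `knockdown = TRUE` since they are not gene products.
#' @param knockdown If `TRUE` (default) the query is for a gene knockdown and
#'   pseudo-enzymes are rejected.
#' @return Character vector of reaction ids.
#' @export
reactions_for_enzyme <- function(net, enzyme, knockdown = TRUE) {
  stopifnot(inherits(net, "lignin_network"))
  if (!is.character(enzyme) || length(enzyme) != 1L || !(enzyme %in% .ENZYMES))
    stop("unknown enzyme: ", enzyme)
  if (knockdown && enzyme %in% c("TRANSPORT", "OVERFLOW"))
    stop(enzyme, " is not a gene product; cannot be knocked down")
  net$reactions$id[net$reactions$enzyme == enzyme]
}

#' @export
print.lignin_network <- function(x, ...) {
  cat(sprintf("Monolignol pathway network (%s): %d reactions, %d metabolites (%d internal)\n",
              x$variant, nrow(x$reactions), nrow(x$metabolites),
              sum(!x$metabolites$is_boundary)))
  invisible(x)
}

#' Write / read a network as TSV
#'
#' Serializes the reaction table (columns `reaction_id`, `enzyme`, `substrate`,
#' `product`, `lower_bound`, `upper_bound`); the round-trip is lossless.
#'
#' @param net A `lignin_network`.
#' @param path File path.
#' @return `write_network_tsv` returns `path` invisibly; `read_network_tsv`
#'   returns a `lignin_network`.
#' @export
write_network_tsv <- function(net, path) {
  stopifnot(inherits(net, "lignin_network"))
  out <- net$reactions
  names(out)[names(out) == "id"] <- "reaction_id"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path) {
  rx <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("reaction_id", "enzyme", "substrate", "product",
            "lower_bound", "upper_bound")
  if (!all(need %in% names(rx)))
    stop("missing column(s): ", paste(setdiff(need, names(rx)), collapse = ", "))
  names(rx)[names(rx) == "reaction_id"] <- "id"
  variant <- if (any(rx$enzyme == "OVERFLOW")) "extended" else "unextended"
  .lignin_network(rx[, c("id", "enzyme", "substrate", "product",
                         "lower_bound", "upper_bound")], variant)
}
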