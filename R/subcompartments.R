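#' The five primary subcompartment labels
#'
#' Inter-chromosomal Hi-C contact patterns segregate 100 kb genomic bins into
#' five primary spatial subcompartments: A1 and A2 (active, early-replicating
#' chromatin) and B1, B2 and B3 (repressed, late-replicating chromatin).
#' The rare B4 class (confined to a small part of chromosome 19) is not
#' modelled. The order of the returned vector is the canonical index order
#' used throughout the package (A1 = class 1, ..., B3 = class 5); argmax ties
#' in classification are broken in this order.
#'
#' @return Character vector `c("A1", "A2", "B1", "B2", "B3")`.
#' @export
subcompartments <- function() c("A1", "A2", "B1", "B2", "B3")

# Coerce a vector of labels to a factor on the canonical five levels,
# rejecting anything outside them (NA allowed).
as_subcompartment <- function(x) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% subcompartments())
  if (any(bad))
    stop("unknown subcompartment label(s): ",
         paste(unique(x[bad]), collapse = ", "))
  factor(x, levels = subcompartments())
}
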