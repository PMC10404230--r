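#' The eight founder strains of a Diversity Outbred population
#'
#' Founder haplotypes are labelled `A`--`H` throughout the package, in the
#' conventional order of the eight DO founder strains.
#'
#' @return Named character vector mapping letter codes to strain names.
#' @export
#' @examples
#' do_founders()
do_founders <- function() {
  c(A = "A/J", B = "C57BL/6J", C = "129S1/SvImJ", D = "NOD/ShiLtJ",
    E = "NZO/HlLtJ", F = "CAST/EiJ", G = "PWK/PhJ", H = "WSB/EiJ")
}

founder_codes <- function() names(do_founders())

# cM per bp under the package's fixed genetic-map scaling (0.5 cM/Mb)
CM_PER_BP <- 5e-7
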