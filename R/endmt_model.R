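# The bundled EndMT model: 29 molecules, synchronous Boolean update rules.

# Canonical (alphabetical) node order. The first node is the least
# significant bit of the integer state encoding.
ENDMT_NODES <- c(
  "AP1", "CTNNB", "DLL4", "ETS1", "FGF2", "FLI1", "GATA2", "HIF1a", "LEF1",
  "NFkB", "NOTCH", "NRARP", "NRP1", "PDGF_AB", "SMAD1", "SMAD2", "SMAD6",
  "SNAI1", "SNAI2", "STAT3", "TGFB", "TGFBR", "TWIST1", "VEGFA", "VEGFR2",
  "WNT5b", "WNT7a", "ZEB1", "ZEB2")

# One canonical ASCII spelling per molecule; common typographic variants are
# accepted on input and normalized. "VEGF2" is an alias of VEGFR2: the
# published rule for ETS1 names a "VEGF2" node that does not exist in the
# model, and VEGFR2 is the only consistent reading (ETS1 and VEGFR2 are
# co-activated in every tip-cell pattern). The substitution is recorded in
# the model provenance rather than silently applied.
ENDMT_ALIASES <- c(
  "HIF1alpha" = "HIF1a", "HIF1A" = "HIF1a",
  "NFkappaB" = "NFkB", "NFKB" = "NFkB",
  "TGFbeta" = "TGFB", "TGFb" = "TGFB",
  "TGFbetaR" = "TGFBR", "TGFbR" = "TGFBR",
  "CTNNB1" = "CTNNB", "beta_catenin" = "CTNNB",
  "NPR1" = "NRP1",
  "VEGF2" = "VEGFR2")

#' Normalize EndMT node names
#'
#' Maps accepted aliases (e.g. \code{HIF1alpha}, \code{NFkappaB},
#' \code{TGFbeta}, \code{VEGF2}) onto the canonical ASCII spellings used by
#' the bundled model.
#'
#' @param x character vector of node names.
#' @return character vector of canonical names; unknown names pass through.
#' @export
normalize_endmt_names <- function(x) {
  hit <- x %in% names(ENDMT_ALIASES)
  x[hit] <- ENDMT_ALIASES[x[hit]]
  x
}

# Update rules as published. The ETS1 rule is written here with the alias
# already resolved; see build_endmt_network() for the provenance note.
ENDMT_RULES <- c(
  AP1     = "WNT5b | SMAD2",
  CTNNB   = "WNT5b | WNT7a",
  DLL4    = "DLL4",
  ETS1    = "VEGFR2 | FGF2 | ZEB2 | AP1",
  FGF2    = "FGF2",
  FLI1    = "FLI1 | GATA2 | HIF1a",
  GATA2   = "FLI1 | GATA2 | VEGFR2",
  HIF1a   = "HIF1a",
  LEF1    = "LEF1 | NRARP | SMAD2 | NFkB | CTNNB",
  NFkB    = "PDGF_AB",
  NOTCH   = "DLL4 & !NRARP",
  NRARP   = "NOTCH",
  NRP1    = "VEGFA & (ETS1 | GATA2) & !NOTCH",
  PDGF_AB = "PDGF_AB",
  SMAD1   = "TGFBR & !SMAD6",
  SMAD2   = "TGFBR & !SMAD6 & NRP1",
  SMAD6   = "FLI1 & GATA2 & (NOTCH | SMAD1)",
  SNAI1   = paste("(HIF1a | STAT3 | CTNNB | AP1 | NFkB | SMAD2)",
                  "& (NOTCH | CTNNB) & !TWIST1 & !SNAI1 & !SNAI2"),
  SNAI2   = "!(SNAI1 & GATA2) & (SMAD2 | SNAI2 | TWIST1 | LEF1 | NOTCH)",
  STAT3   = "VEGFR2",
  TGFB    = "TGFB",
  TGFBR   = "TGFB & !FGF2",
  TWIST1  = "CTNNB | HIF1a",
  VEGFA   = "(!WNT5b & !TGFBR & (STAT3 | HIF1a)) | VEGFA",
  VEGFR2  = "VEGFA & !SNAI1 & !NOTCH & (FLI1 | GATA2 | ETS1)",
  WNT5b   = "WNT5b",
  WNT7a   = "WNT7a",
  ZEB1    = "SNAI2 | CTNNB | LEF1",
  ZEB2    = "HIF1a | ETS1 | SMAD2 | AP1 | SNAI1")

#' Build the bundled EndMT Boolean network
#'
#' Returns the 29-node synchronous Boolean network of endothelial cell
#' activation and the endothelial-to-mesenchymal transition. Seven nodes
#' (DLL4, FGF2, HIF1a, PDGF_AB, TGFB, WNT5b, WNT7a) carry identity rules and
#' act as microenvironmental inputs, giving 128 possible microenvironments.
#'
#' The published ETS1 rule names a "VEGF2" regulator; no node of that name
#' exists and it is read as VEGFR2. This substitution is recorded in the
#' returned network's \code{provenance} field.
#'
#' @return a \code{boolean_network} with 29 nodes.
#' @examples
#' net <- build_endmt_network()
#' sum(source_nodes(net))  # 7 microenvironmental inputs
#' @export
build_endmt_network <- function() {
  boolean_network(
    ENDMT_RULES, name = "EndMT", nodes = ENDMT_NODES,
    provenance = c(
      "rules: published Boolean update rules of the EndMT regulatory network",
      "alias: the published ETS1 rule's 'VEGF2' regulator is read as VEGFR2"))
}

#' Source-node names of the EndMT model
#' @return character vector of the 7 microenvironmental input nodes.
#' @export
endmt_source_names <- function() {
  c("DLL4", "FGF2", "HIF1a", "PDGF_AB", "TGFB", "WNT5b", "WNT7a")
}
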