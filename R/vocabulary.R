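#' Canonical apoptosis protein vocabulary
#'
#' The fixed panel of 19 apoptosis regulators the pipeline operates on:
#' 17 proteins quantified in nM by calibrated immunoblotting and the two
#' TRAIL death receptors (DR4, DR5) quantified as relative surface
#' expression.
#'
#' @return Character vector of the 19 canonical protein names.
#' @export
canonical_proteins <- function() {
  c("Apaf-1", "Bak", "Bax", "Bcl-2", "Bcl-xL", "Bid", "Bim",
    "caspase-3", "caspase-8", "caspase-9", "cFLIP", "FADD",
    "Mcl-1", "Noxa", "Puma", "SMAC", "XIAP", "DR4", "DR5")
}

#' Default measurement units per protein
#'
#' @return Named character vector: `"nM"` for immunoblot proteins,
#'   `"relative"` for the surface receptors DR4/DR5.
#' @export
default_units <- function() {
  u <- stats::setNames(rep("nM", 19L), canonical_proteins())
  u[c("DR4", "DR5")] <- "relative"
  u
}

# lowercase alphanumeric key used for alias matching
.norm_key <- function(x) gsub("[^a-z0-9]", "", tolower(x))

# alias table: normalized key -> canonical name. Covers case/punctuation
# variants plus common synonyms (casp3, DIABLO, FLIP, ...).
.protein_alias_table <- local({
  canon <- c("Apaf-1", "Bak", "Bax", "Bcl-2", "Bcl-xL", "Bid", "Bim",
             "caspase-3", "caspase-8", "caspase-9", "cFLIP", "FADD",
             "Mcl-1", "Noxa", "Puma", "SMAC", "XIAP", "DR4", "DR5")
  tab <- stats::setNames(canon, gsub("[^a-z0-9]", "", tolower(canon)))
  extra <- c(
    apaf1   = "Apaf-1",
    bcl2l1  = "Bcl-xL", bclx = "Bcl-xL",
    casp3   = "caspase-3", casp8 = "caspase-8", casp9 = "caspase-9",
    flip    = "cFLIP", cflar = "cFLIP",
    mcl1l   = "Mcl-1",
    pmaip1  = "Noxa",
    bbc3    = "Puma",
    diablo  = "SMAC", smacdiablo = "SMAC",
    birc4   = "XIAP",
    tnfrsf10a = "DR4", trailr1 = "DR4",
    tnfrsf10b = "DR5", trailr2 = "DR5"
  )
  c(tab, extra)
})

#' Normalize protein names to the canonical vocabulary
#'
#' Matching is case- and punctuation-insensitive and resolves common
#' aliases (e.g. `"BCL-XL"`, `"BclxL"`, `"casp3"`, `"DIABLO"`).
#'
#' @param x Character vector of protein names.
#' @return Character vector of canonical names.
#' @export
normalize_protein_names <- function(x) {
  key <- .norm_key(x)
  hit <- .protein_alias_table[key]
  bad <- is.na(hit)
  if (any(bad)) {
    stop("unknown protein name(s): ", paste(unique(x[bad]), collapse = ", "),
         " (canonical vocabulary has 19 names; see canonical_proteins())",
         call. = FALSE)
  }
  unname(hit)
}

#' Canonical treatment arm labels
#'
#' @return Character vector of recognized treatment labels.
#' @export
canonical_treatments <- function() {
  c("TMZ", "TRAIL", "TMZ+TRAIL", "TMZ+ABT737", "TRAIL+ABT737", "ABT737")
}

.treatment_alias_table <- local({
  canon <- c("TMZ", "TRAIL", "TMZ+TRAIL", "TMZ+ABT737", "TRAIL+ABT737",
             "ABT737")
  tab <- stats::setNames(canon, gsub("[^a-z0-9+]", "", tolower(canon)))
  extra <- c("tmz+abt-737" = "TMZ+ABT737", "trail+abt-737" = "TRAIL+ABT737",
             "abt-737" = "ABT737", "combo" = "TMZ+TRAIL",
             "tmz+trail" = "TMZ+TRAIL")
  names(extra) <- gsub("[^a-z0-9+]", "", names(extra))
  c(tab, extra)
})

normalize_treatment_labels <- function(x) {
  key <- gsub("[^a-z0-9+]", "", tolower(x))
  hit <- .treatment_alias_table[key]
  bad <- is.na(hit)
  if (any(bad)) {
    stop("unknown treatment label(s): ",
         paste(unique(x[bad]), collapse = ", "),
         "; recognized: ", paste(canonical_treatments(), collapse = ", "),
         call. = FALSE)
  }
  unname(hit)
}
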