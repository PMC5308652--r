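#' Define a functional group
#'
#' A functional group (FG) combines a small set of pathway-related proteins
#' into a single feature by an arithmetic rule that encodes their
#' biological interplay.
#'
#' @param name FG identifier.
#' @param combinator One of `"SUM"`, `"PRODUCT"`, `"RATIO"`, `"SINGLE"`.
#'   For `PRODUCT`, `members` may be a list of character vectors: each
#'   element (factor) is summed, then the factors are multiplied, so the FG
#'   vanishes exactly when an obligatory factor is absent.
#' @param members Protein names (character vector, or list of character
#'   vectors for a product of factor-sums). Ignored for `RATIO`.
#' @param numerator,denominator Protein names for `RATIO` groups; the FG
#'   value is `sum(numerator) / sum(denominator)`.
#' @return An object of class `fg_definition`.
#' @export
fg_definition <- function(name,
                          combinator = c("SUM", "PRODUCT", "RATIO",
                                         "SINGLE"),
                          members = NULL, numerator = NULL,
                          denominator = NULL) {
  combinator <- match.arg(combinator)
  norm <- function(x) if (is.null(x)) NULL else normalize_protein_names(x)
  if (combinator == "RATIO") {
    if (!length(numerator) || !length(denominator)) {
      stop("RATIO needs nonempty numerator and denominator", call. = FALSE)
    }
    numerator <- norm(numerator)
    denominator <- norm(denominator)
    members <- NULL
  } else {
    if (is.list(members)) {
      if (combinator != "PRODUCT") {
        stop("factor-list members are only valid for PRODUCT",
             call. = FALSE)
      }
      members <- lapply(members, norm)
      if (!length(members) || any(!lengths(members))) {
        stop("PRODUCT factors must be nonempty", call. = FALSE)
      }
    } else {
      members <- norm(members)
      if (combinator == "SINGLE" && length(members) != 1L) {
        stop("SINGLE must have exactly one member", call. = FALSE)
      }
      if (!length(members)) stop("members must be nonempty", call. = FALSE)
    }
  }
  structure(list(name = name, combinator = combinator, members = members,
                 numerator = numerator, denominator = denominator),
            class = "fg_definition")
}

#' Proteins used by a functional-group definition
#' @param def An `fg_definition`.
#' @return Character vector of member protein names.
#' @export
fg_members <- function(def) {
  if (def$combinator == "RATIO") c(def$numerator, def$denominator)
  else unlist(def$members, use.names = FALSE)
}

#' Default functional-group definitions
#'
#' The 11 pathway-derived groups covering all 19 canonical proteins, each
#' used exactly once:
#' \itemize{
#'   \item `Bcl-2+Bcl-xL+Mcl-1` — SUM of the anti-apoptotic guardians
#'     (functionally redundant antagonists of Bax/Bak).
#'   \item `Bax+Bak` — SUM of the MOMP pore formers.
#'   \item `Bid`, `Bim`, `Puma`, `Noxa` — the BH3-only proteins kept as
#'     SINGLE variables (they differ in activator/sensitizer capacity).
#'   \item `Apaf-1*Casp9` — PRODUCT; the apoptosome vanishes when either
#'     component is absent.
#'   \item `DISC` — death-inducing signaling complex from DR4, DR5, FADD.
#'     Default rule `(DR4 + DR5) * FADD`: the receptors are redundant
#'     (either seeds the complex) while FADD is obligatory. A strict
#'     triple product is available via `disc_rule = "triple_product"`.
#'   \item `Casp8/cFLIP`, `Casp3/XIAP` — RATIOs of apoptotic caspases to
#'     their direct antagonists, oriented so larger values mean greater
#'     death competence (configurable via `ratio_orientation`).
#'   \item `SMAC` — SINGLE.
#' }
#'
#' @param disc_rule `"receptor_sum"` (default, `(DR4+DR5)*FADD`) or
#'   `"triple_product"` (`DR4*DR5*FADD`).
#' @param ratio_orientation `"effector_over_inhibitor"` (default) or
#'   `"inhibitor_over_effector"`.
#' @param merge_bh3 If `TRUE`, Bid/Bim/Puma/Noxa are merged into one SUM
#'   group (8 groups total). Not the default; kept for comparison runs.
#' @return List of `fg_definition` objects (11 under the defaults).
#' @export
default_fg_definitions <- function(disc_rule = c("receptor_sum",
                                                 "triple_product"),
                                   ratio_orientation =
                                     c("effector_over_inhibitor",
                                       "inhibitor_over_effector"),
                                   merge_bh3 = FALSE) {
  disc_rule <- match.arg(disc_rule)
  ratio_orientation <- match.arg(ratio_orientation)
  disc_members <- switch(disc_rule,
    receptor_sum = list(c("DR4", "DR5"), "FADD"),
    triple_product = list("DR4", "DR5", "FADD"))
  ratio <- function(name, effector, inhibitor) {
    if (ratio_orientation == "effector_over_inhibitor") {
      fg_definition(name, "RATIO", numerator = effector,
                    denominator = inhibitor)
    } else {
      fg_definition(name, "RATIO", numerator = inhibitor,
                    denominator = effector)
    }
  }
  bh3 <- if (merge_bh3) {
    list(fg_definition("Bid+Bim+Puma+Noxa", "SUM",
                       c("Bid", "Bim", "Puma", "Noxa")))
  } else {
    list(fg_definition("Bid", "SINGLE", "Bid"),
         fg_definition("Bim", "SINGLE", "Bim"),
         fg_definition("Puma", "SINGLE", "Puma"),
         fg_definition("Noxa", "SINGLE", "Noxa"))
  }
  c(list(fg_definition("Bcl-2+Bcl-xL+Mcl-1", "SUM",
                       c("Bcl-2", "Bcl-xL", "Mcl-1")),
         fg_definition("Bax+Bak", "SUM", c("Bax", "Bak"))),
    bh3,
    list(fg_definition("Apaf-1*Casp9", "PRODUCT",
                       list("Apaf-1", "caspase-9")),
         fg_definition("DISC", "PRODUCT", disc_members),
         ratio("Casp8/cFLIP", "caspase-8", "cFLIP"),
         ratio("Casp3/XIAP", "caspase-3", "XIAP"),
         fg_definition("SMAC", "SINGLE", "SMAC")))
}

# evaluate one FG on a named numeric vector of protein values
.fg_value <- function(def, x, ratio_policy = "strict", ratio_eps = NULL,
                      context = "") {
  switch(def$combinator,
    SUM = sum(x[def$members]),
    SINGLE = unname(x[def$members]),
    PRODUCT = {
      factors <- if (is.list(def$members)) def$members
                 else as.list(def$members)
      prod(vapply(factors, function(f) sum(x[f]), numeric(1L)))
    },
    RATIO = {
      num <- sum(x[def$numerator])
      den <- sum(x[def$denominator])
      if (den == 0) {
        if (ratio_policy == "strict") {
          stop(sprintf("zero denominator for FG '%s'%s", def$name,
                       if (nzchar(context)) paste0(" (", context, ")")
                       else ""),
               call. = FALSE)
        }
        den <- ratio_eps
      }
      num / den
    })
}

#' Compute the functional-group matrix
#'
#' Encodes a protein panel into FG values by the arithmetic rules of the
#' supplied definitions. Replicates are averaged first if present.
#'
#' @param panel A `protein_panel` (or a cell line x protein numeric
#'   matrix).
#' @param defs List of `fg_definition`s; default [default_fg_definitions()].
#' @param ratio_policy `"strict"` (zero denominator is an error, default)
#'   or `"floor"` (substitute `ratio_eps_frac` times the denominator's
#'   panel median).
#' @param ratio_eps_frac Floor fraction under `"floor"` policy.
#' @return Numeric matrix, rows = cell lines, columns = FG names.
#' @export
compute_fg_matrix <- function(panel, defs = default_fg_definitions(),
                              ratio_policy = c("strict", "floor"),
                              ratio_eps_frac = 1e-6) {
  ratio_policy <- match.arg(ratio_policy)
  X <- if (inherits(panel, "protein_panel")) panel_matrix(panel)
       else as.matrix(panel)
  need <- unique(unlist(lapply(defs, fg_members)))
  miss <- setdiff(need, colnames(X))
  if (length(miss)) {
    stop("panel lacks protein(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  eps_for <- function(def) {
    if (def$combinator != "RATIO") return(NULL)
    den_med <- stats::median(rowSums(X[, def$denominator, drop = FALSE]))
    ratio_eps_frac * den_med
  }
  out <- matrix(NA_real_, nrow(X), length(defs),
                dimnames = list(rownames(X),
                                vapply(defs, `[[`, character(1L), "name")))
  for (j in seq_along(defs)) {
    eps <- eps_for(defs[[j]])
    for (i in seq_len(nrow(X))) {
      out[i, j] <- .fg_value(defs[[j]], X[i, ], ratio_policy, eps,
                             context = rownames(X)[i])
    }
  }
  out
}

#' Compute FG values for a single cell line
#'
#' @param values Named numeric vector of protein values.
#' @inheritParams compute_fg_matrix
#' @return Named numeric vector of FG values.
#' @export
compute_fg_row <- function(values, defs = default_fg_definitions(),
                           ratio_policy = c("strict", "floor"),
                           ratio_eps_frac = 1e-6) {
  ratio_policy <- match.arg(ratio_policy)
  names(values) <- normalize_protein_names(names(values))
  vapply(defs, function(def) {
    eps <- if (def$combinator == "RATIO") {
      # single-row floor: scale to the row's overall signal so a zero
      # denominator yields a large but finite ratio
      base <- max(sum(values[def$denominator]),
                  stats::median(values[values > 0]), 1)
      ratio_eps_frac * base
    } else NULL
    .fg_value(def, values, ratio_policy, eps)
  }, numeric(1L), USE.NAMES = FALSE) |>
    stats::setNames(vapply(defs, `[[`, character(1L), "name"))
}

#' Serialize FG definitions to YAML
#'
#' @param defs List of `fg_definition`s.
#' @param path Optional output file; if `NULL` the YAML string is returned.
#' @return YAML string (invisibly if written to file).
#' @export
fg_definitions_to_yaml <- function(defs, path = NULL) {
  plain <- lapply(defs, function(d) {
    out <- list(name = d$name, combinator = d$combinator)
    if (d$combinator == "RATIO") {
      out$numerator <- as.list(d$numerator)
      out$denominator <- as.list(d$denominator)
    } else if (is.list(d$members)) {
      out$factors <- lapply(d$members, as.list)
    } else {
      out$members <- as.list(d$members)
    }
    out
  })
  txt <- yaml::as.yaml(plain)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read FG definitions from YAML
#'
#' @param path YAML file produced by [fg_definitions_to_yaml()] (or
#'   hand-written in the same layout).
#' @return List of `fg_definition`s.
#' @export
fg_definitions_from_yaml <- function(path) {
  plain <- yaml::read_yaml(path)
  lapply(plain, function(d) {
    members <- if (!is.null(d$factors)) {
      lapply(d$factors, unlist)
    } else {
      unlist(d$members)
    }
    fg_definition(d$name, d$combinator, members = members,
                  numerator = unlist(d$numerator),
                  denominator = unlist(d$denominator))
  })
}
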