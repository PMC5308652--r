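#' Construct a protein panel
#'
#' A protein panel holds replicate-resolved quantifications of the 19
#' canonical apoptosis proteins across a set of cell lines. Values are
#' nonnegative; 17 immunoblot proteins carry nM units, the surface
#' receptors DR4/DR5 relative units.
#'
#' @param measurements data.frame with columns `cell_line`, `protein`,
#'   `replicate`, `value`. Protein names are normalized to the canonical
#'   vocabulary.
#' @param units Named character vector of per-protein units; defaults to
#'   [default_units()].
#' @return An object of class `protein_panel` with components
#'   `measurements`, `units`, `cell_lines`, `proteins`.
#' @export
protein_panel <- function(measurements, units = default_units()) {
  req <- c("cell_line", "protein", "replicate", "value")
  miss <- setdiff(req, names(measurements))
  if (length(miss)) {
    stop("measurements lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  m <- measurements[req]
  m$cell_line <- as.character(m$cell_line)
  m$protein <- normalize_protein_names(as.character(m$protein))
  m$replicate <- as.integer(m$replicate)
  m$value <- as.numeric(m$value)
  if (anyNA(m$value)) stop("missing protein values", call. = FALSE)
  if (any(m$value < 0)) {
    i <- which(m$value < 0)[1L]
    stop(sprintf("negative value for %s / %s (replicate %d)",
                 m$cell_line[i], m$protein[i], m$replicate[i]),
         call. = FALSE)
  }
  if (anyDuplicated(m[c("cell_line", "protein", "replicate")])) {
    stop("duplicate (cell_line, protein, replicate) measurement",
         call. = FALSE)
  }
  lines <- unique(m$cell_line)
  prots <- canonical_proteins()[canonical_proteins() %in% unique(m$protein)]
  # every line must carry every measured protein at least once
  tab <- table(m$cell_line, m$protein)
  if (any(tab == 0L)) {
    bad <- which(tab == 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf("no measurement for %s / %s",
                 rownames(tab)[bad[1L]], colnames(tab)[bad[2L]]),
         call. = FALSE)
  }
  units <- units[prots]
  structure(list(measurements = m, units = units,
                 cell_lines = lines, proteins = prots),
            class = "protein_panel")
}

#' @export
print.protein_panel <- function(x, ...) {
  cat(sprintf("protein_panel: %d cell lines x %d proteins, %d measurements\n",
              length(x$cell_lines), length(x$proteins),
              nrow(x$measurements)))
  invisible(x)
}

#' Number of measurements in a panel
#' @param panel A `protein_panel`.
#' @return Integer measurement count (lines x proteins x replicates for a
#'   complete panel).
#' @export
n_measurements <- function(panel) nrow(panel$measurements)

#' Read a protein panel from delimited text
#'
#' Expects a header row naming proteins, a first column of cell-line
#' identifiers, and an optional `replicate` column; remaining columns are
#' protein quantifications. Protein headers are alias-normalized.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @param units Per-protein units (see [protein_panel()]).
#' @return A `protein_panel`.
#' @export
read_protein_panel <- function(path, sep = ",", units = default_units()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         check.names = FALSE, stringsAsFactors = FALSE,
                         comment.char = "")
  if (ncol(d) < 2L) stop("panel table needs >= 2 columns", call. = FALSE)
  line_col <- names(d)[1L]
  rep_col <- names(d)[.norm_key(names(d)) == "replicate"]
  prot_cols <- setdiff(names(d), c(line_col, rep_col))
  # normalization errors here name the offending column
  normalize_protein_names(prot_cols)
  long <- data.frame(
    cell_line = rep(d[[line_col]], times = length(prot_cols)),
    protein = rep(prot_cols, each = nrow(d)),
    replicate = if (length(rep_col)) rep(d[[rep_col]], length(prot_cols))
                else 1L,
    value = unlist(d[prot_cols], use.names = FALSE)
  )
  protein_panel(long, units = units)
}

#' Write a protein panel to delimited text
#'
#' Wide layout (one row per cell line and replicate); values written at
#' full precision so write/read round-trips are exact.
#'
#' @param panel A `protein_panel`.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_protein_panel <- function(panel, path, sep = ",") {
  m <- panel$measurements
  wide <- stats::reshape(m, idvar = c("cell_line", "replicate"),
                         timevar = "protein", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide <- wide[c("cell_line", "replicate", panel$proteins)]
  wide <- wide[order(match(wide$cell_line, panel$cell_lines),
                     wide$replicate), ]
  num <- vapply(wide, is.numeric, logical(1L)) & names(wide) != "replicate"
  wide[num] <- lapply(wide[num], function(v) format(v, digits = 17L))
  utils::write.table(wide, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Average replicate measurements
#'
#' Collapses a panel to one value per (cell line, protein) by arithmetic
#' mean of the replicates; units are unchanged. Idempotent.
#'
#' @param panel A `protein_panel`.
#' @return A `protein_panel` with a single replicate per measurement.
#' @export
aggregate_replicates <- function(panel) {
  m <- panel$measurements
  agg <- stats::aggregate(value ~ cell_line + protein, data = m, FUN = mean)
  agg$replicate <- 1L
  protein_panel(agg, units = panel$units)
}

is_aggregated <- function(panel) {
  !anyDuplicated(panel$measurements[c("cell_line", "protein")])
}

#' Panel values as a cell line x protein matrix
#'
#' Requires an aggregated panel (one replicate); use
#' [aggregate_replicates()] first.
#'
#' @param panel A `protein_panel`.
#' @return Numeric matrix, rows = cell lines, columns = proteins.
#' @export
panel_matrix <- function(panel) {
  if (!is_aggregated(panel)) panel <- aggregate_replicates(panel)
  m <- panel$measurements
  out <- matrix(NA_real_, length(panel$cell_lines), length(panel$proteins),
                dimnames = list(panel$cell_lines, panel$proteins))
  out[cbind(m$cell_line, m$protein)] <- m$value
  out
}

#' Read a viability (response) table from delimited text
#'
#' Rows carry a cell line, a treatment label and a survival value relative
#' to untreated control. Survival is stored internally as a fraction;
#' percent input is divided by 100.
#'
#' @param path File path.
#' @param dialect `"percent"` or `"fraction"`: unit of the survival column.
#' @param sep Field separator.
#' @return data.frame with columns `cell_line`, `treatment`, `survival`
#'   (fraction of control), class `response_table`.
#' @export
read_viability <- function(path, dialect = c("percent", "fraction"),
                           sep = ",") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         check.names = FALSE, stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  req <- c("cell_line", "treatment", "survival")
  miss <- setdiff(req, names(d))
  if (length(miss)) {
    stop("viability table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  s <- as.numeric(d$survival)
  # strings like "25%" are accepted in percent dialect
  if (anyNA(s)) s <- as.numeric(sub("%$", "", trimws(d$survival)))
  if (anyNA(s)) stop("non-numeric survival values", call. = FALSE)
  if (dialect == "percent") s <- s / 100
  response_table(data.frame(cell_line = as.character(d$cell_line),
                            treatment = as.character(d$treatment),
                            survival = s))
}

#' Construct/validate a response table
#'
#' @param d data.frame with columns `cell_line`, `treatment`, `survival`
#'   (fraction of control; values slightly above 1 are permitted as assay
#'   noise).
#' @return The validated data.frame with class `response_table`.
#' @export
response_table <- function(d) {
  d$treatment <- normalize_treatment_labels(d$treatment)
  if (any(d$survival < 0)) {
    i <- which(d$survival < 0)[1L]
    stop(sprintf("negative survival for %s / %s",
                 d$cell_line[i], d$treatment[i]), call. = FALSE)
  }
  if (anyDuplicated(d[c("cell_line", "treatment")])) {
    stop("duplicate (cell_line, treatment) rows after aggregation",
         call. = FALSE)
  }
  class(d) <- c("response_table", "data.frame")
  d
}

#' Write a response table to delimited text
#'
#' Always writes the fraction dialect at full precision.
#'
#' @param responses A `response_table`.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_viability <- function(responses, path, sep = ",") {
  out <- as.data.frame(responses)
  out$survival <- format(out$survival, digits = 17L)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Survival values for one treatment arm
#'
#' @param responses A `response_table`.
#' @param treatment Treatment label.
#' @param cell_lines Optional ordering/subset of cell lines.
#' @return Named numeric vector of survival fractions.
#' @export
arm_survival <- function(responses, treatment, cell_lines = NULL) {
  treatment <- normalize_treatment_labels(treatment)
  d <- responses[responses$treatment == treatment, ]
  s <- stats::setNames(d$survival, d$cell_line)
  if (!is.null(cell_lines)) {
    miss <- setdiff(cell_lines, names(s))
    if (length(miss)) {
      stop("no ", treatment, " survival for: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    s <- s[cell_lines]
  }
  s
}

#' Write a pipeline result with run metadata
#'
#' Data frames are written as delimited text (full numeric precision);
#' any other serializable result is written as JSON. A JSON metadata
#' sidecar (`<path>.meta.json`) records the seed, configuration and its
#' MD5 hash, and package/R versions.
#'
#' @param results data.frame or list.
#' @param path Output path.
#' @param metadata Named list merged into the sidecar (e.g. `seed`,
#'   `config`).
#' @param sep Field separator for tabular output.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, metadata = list(), sep = ",") {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("unwritable path (no such directory): ", dir,
                             call. = FALSE)
  if (is.data.frame(results)) {
    out <- as.data.frame(results)
    num <- vapply(out, is.numeric, logical(1L))
    out[num] <- lapply(out[num], function(v) format(v, digits = 17L))
    utils::write.table(out, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
  } else {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
  }
  meta <- c(metadata, list(
    package_version = as.character(utils::packageVersion("apoptopredict")),
    r_version = R.version.string,
    written = format(Sys.time(), tz = "UTC", usetz = TRUE)
  ))
  if (!is.null(metadata$config)) {
    tmp <- tempfile()
    on.exit(unlink(tmp), add = TRUE)
    jsonlite::write_json(metadata$config, tmp, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    meta$config_hash <- unname(tools::md5sum(tmp))
  }
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
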