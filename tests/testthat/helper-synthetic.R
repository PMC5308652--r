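# shared fixtures, built in code

# random positive cell line x protein matrix over the canonical vocabulary
rand_panel_matrix <- function(n_lines, seed) {
  set.seed(seed)
  prots <- canonical_proteins()
  X <- matrix(stats::rlnorm(n_lines * length(prots), meanlog = 2,
                            sdlog = 0.8),
              n_lines, length(prots),
              dimnames = list(paste0("L", seq_len(n_lines)), prots))
  X
}

# independent hand-arithmetic oracle for the 11 default FGs: explicit
# formulas, no use of the fg_definition machinery
fg_oracle <- function(X, disc = c("receptor_sum", "triple_product")) {
  disc <- match.arg(disc)
  disc_val <- if (disc == "receptor_sum") {
    (X[, "DR4"] + X[, "DR5"]) * X[, "FADD"]
  } else {
    X[, "DR4"] * X[, "DR5"] * X[, "FADD"]
  }
  cbind(
    "Bcl-2+Bcl-xL+Mcl-1" = X[, "Bcl-2"] + X[, "Bcl-xL"] + X[, "Mcl-1"],
    "Bax+Bak" = X[, "Bax"] + X[, "Bak"],
    "Bid" = X[, "Bid"],
    "Bim" = X[, "Bim"],
    "Puma" = X[, "Puma"],
    "Noxa" = X[, "Noxa"],
    "Apaf-1*Casp9" = X[, "Apaf-1"] * X[, "caspase-9"],
    "DISC" = disc_val,
    "Casp8/cFLIP" = X[, "caspase-8"] / X[, "cFLIP"],
    "Casp3/XIAP" = X[, "caspase-3"] / X[, "XIAP"],
    "SMAC" = X[, "SMAC"]
  )
}

# random FG-like matrix (generic features, for PCA/LDA tests)
rand_fg_matrix <- function(n, p = 11, seed = 1) {
  set.seed(seed)
  matrix(stats::rnorm(n * p), n, p,
         dimnames = list(paste0("L", seq_len(n)), paste0("FG", seq_len(p))))
}

# small panel written to a temp CSV in the wide layout read_protein_panel
# expects; returns the path
write_panel_csv <- function(X, replicate = NULL, path = tempfile(fileext = ".csv")) {
  d <- data.frame(cell_line = rownames(X), X, check.names = FALSE)
  if (!is.null(replicate)) d <- cbind(d[1], replicate = replicate, d[-1])
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  path
}
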