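## Published competition-coefficient blocks. a[i, j] is the per-individual
## depressive effect of species j on species i. The blocks are
## subset-specific: the same pair carries different coefficients in the
## 2-, 3- and 4-species systems, so lookup is keyed by the exact subset.
.coefficient_blocks <- local({
  blk <- function(species, values) {
    a <- matrix(values, nrow = length(species), byrow = TRUE,
                dimnames = list(species, species))
    a
  }
  list(
    "Sf+Bf" = blk(c("Sf", "Bf"), c(1, 4.10e-4,
                                   3.02e-4, 1)),
    "Sf+Sc" = blk(c("Sf", "Sc"), c(1, 1.99e-4,
                                   1.07e-4, 1)),
    "Sf+Cp" = blk(c("Sf", "Cp"), c(1, 2.20e-4,
                                   2.10e-4, 1)),
    "Bf+Sc" = blk(c("Bf", "Sc"), c(1, 2.51e-4,
                                   3.31e-4, 1)),
    "Bf+Cp" = blk(c("Bf", "Cp"), c(1, 9.12e-5,
                                   4.15e-4, 1)),
    "Sc+Cp" = blk(c("Sc", "Cp"), c(1, 1.42e-4,
                                   3.13e-4, 1)),
    "Sf+Bf+Sc" = blk(c("Sf", "Bf", "Sc"),
                     c(1, 3.02e-4, 3.10e-4,
                       9.70e-5, 1, 1.13e-4,
                       1.02e-4, 1.18e-5, 1)),
    "Sf+Bf+Cp" = blk(c("Sf", "Bf", "Cp"),
                     c(1, 1.70e-4, 9.20e-5,
                       7.60e-5, 1, 5.70e-5,
                       1.91e-5, 3.09e-4, 1)),
    "Sf+Sc+Cp" = blk(c("Sf", "Sc", "Cp"),
                     c(1, 5.00e-5, 8.70e-5,
                       2.51e-4, 1, 1.02e-4,
                       1.78e-4, 2.15e-4, 1)),
    "Bf+Sc+Cp" = blk(c("Bf", "Sc", "Cp"),
                     c(1, 9.00e-5, 5.10e-5,
                       8.20e-5, 1, 1.02e-4,
                       3.50e-4, 2.01e-4, 1)),
    "Sf+Bf+Sc+Cp" = blk(c("Sf", "Bf", "Sc", "Cp"),
                        c(1, 2.19e-4, 2.50e-4, 5.10e-5,
                          2.40e-4, 1, 2.07e-4, 2.30e-5,
                          2.20e-4, 3.04e-4, 1, 2.10e-5,
                          2.01e-4, 2.02e-4, 8.00e-5, 1))
  )
})

subset_key <- function(species) paste(canonical_species(species), collapse = "+")

#' Competition-coefficient matrix for a species subset
#'
#' Returns the published interspecific competition coefficients
#' \eqn{a_{ij}} (per-individual effect of species \eqn{j} on species
#' \eqn{i}) for an exact species subset. Coefficients were estimated from
#' density-dependent larval-survival experiments separately for every
#' 2-, 3- and 4-species combination, so the same pair of species carries
#' different values depending on which system it is embedded in; lookup is
#' therefore keyed by the full subset, never by pair. A singleton subset
#' returns the 1x1 identity (no interspecific competition).
#'
#' @param species Character vector of 1-4 species codes (see
#'   [pest_species_ids()]); order is irrelevant.
#' @return A square numeric matrix of class `competition_matrix` with unit
#'   diagonal, rows/columns named by species code in canonical order.
#'   `a[i, j]` is the effect of `j` on `i`.
#' @export
#' @examples
#' competition_matrix(c("Bf", "Cp"))
#' competition_matrix("Sf")
#' competition_matrix(pest_species_ids())["Cp", "Sc"]
competition_matrix <- function(species) {
  species <- canonical_species(species)
  if (length(species) == 1L) {
    a <- matrix(1, 1, 1, dimnames = list(species, species))
    return(as_competition_matrix(a))
  }
  key <- subset_key(species)
  a <- .coefficient_blocks[[key]]
  if (is.null(a)) {
    stop("no published coefficient block for subset {", key, "}")
  }
  as_competition_matrix(a)
}

#' Coerce a labelled square matrix to a competition matrix
#'
#' Validates the structural invariants of a competition matrix: square,
#' species-labelled with matching row/column names, unit diagonal and
#' non-negative off-diagonal entries.
#'
#' @param a A square numeric matrix with row and column names equal to
#'   species codes.
#' @return The matrix with class `competition_matrix`.
#' @export
as_competition_matrix <- function(a) {
  if (!is.matrix(a) || !is.numeric(a) || nrow(a) != ncol(a))
    stop("competition matrix must be a square numeric matrix")
  if (is.null(rownames(a)) || !identical(rownames(a), colnames(a)))
    stop("competition matrix must have identical row and column species labels")
  if (any(abs(diag(a) - 1) > 0))
    stop("competition matrix diagonal must be exactly 1")
  if (any(a < 0))
    stop("competition coefficients must be non-negative")
  class(a) <- c("competition_matrix", class(unclass(a)))
  a
}

#' @export
print.competition_matrix <- function(x, ...) {
  cat("Competition matrix (a[i, j] = effect of j on i), ",
      nrow(x), " species: ", paste(rownames(x), collapse = ", "), "\n",
      sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Write or read a competition matrix as labelled CSV
#'
#' The CSV carries species codes as header row and first column; values are
#' written in full precision so a write/read round trip is exact.
#'
#' @param a A `competition_matrix` (or coercible labelled square matrix).
#' @param path File path.
#' @param validate Validate the invariants before writing. Set to `FALSE`
#'   for estimated matrices, which may legitimately carry (flagged)
#'   negative coefficients.
#' @return `read_competition_matrix()` returns a `competition_matrix`;
#'   `write_competition_matrix()` returns `path` invisibly.
#' @export
write_competition_matrix <- function(a, path, validate = TRUE) {
  if (validate) a <- as_competition_matrix(a)
  else stopifnot(is.matrix(a), nrow(a) == ncol(a),
                 identical(rownames(a), colnames(a)))
  df <- data.frame(species = rownames(a),
                   apply(unclass(a), 2, function(col) sprintf("%.17g", col)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_competition_matrix
#' @export
read_competition_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"species" %in% names(df)) stop("matrix CSV must have a 'species' column")
  a <- as.matrix(df[, setdiff(names(df), "species"), drop = FALSE])
  rownames(a) <- df$species
  storage.mode(a) <- "double"
  as_competition_matrix(a)
}
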