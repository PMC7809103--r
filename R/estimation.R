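#' Residual of the linear equilibrium system
#'
#' At equilibrium the total number of larvae a habitat can carry for
#' species \eqn{i} decomposes linearly into its own survivors and the
#' competition-weighted survivors of the other species:
#' \eqn{K_i = N_i + \sum_{j \ne i} a_{ij} N_j}. This function returns the
#' residual \eqn{K_i - N_i - \sum_{j \ne i} a_{ij} N_j} per species; a
#' zero vector means `(N, K)` satisfy the equilibrium exactly. Because the
#' matrix has unit diagonal, the residual is simply `K - a %*% N`.
#'
#' @param N Numeric vector of species abundances.
#' @param matrix Square competition matrix (unit diagonal).
#' @param K Numeric vector of carrying capacities, same length as `N`.
#' @return Numeric residual vector.
#' @export
#' @examples
#' a <- competition_matrix(c("Bf", "Cp"))
#' equilibrium_residual(c(10, 10), a, c(10 + 10 * a[1, 2], 10 + 10 * a[2, 1]))
equilibrium_residual <- function(N, matrix, K) {
  if (length(N) != nrow(matrix) || length(K) != nrow(matrix))
    stop("dimension mismatch between N, K and the matrix")
  as.vector(K - unclass(matrix) %*% N)
}

#' Solve the equilibrium system for coexistence abundances
#'
#' Solves the linear system \eqn{K = A N} (with \eqn{A} the unit-diagonal
#' competition matrix) for the equilibrium abundances. A warning is issued
#' when any component is negative, i.e. the coefficients admit no feasible
#' coexistence at those capacities.
#'
#' @inheritParams equilibrium_residual
#' @return Numeric vector `N` with `equilibrium_residual(N, matrix, K)`
#'   equal to zero up to solver precision.
#' @export
#' @examples
#' solve_equilibrium(competition_matrix(c("Bf", "Cp")), c(625, 625))
solve_equilibrium <- function(matrix, K) {
  if (length(K) != nrow(matrix))
    stop("dimension mismatch between K and the matrix")
  a <- unclass(matrix)
  rc <- rcond(a)
  if (!is.finite(rc) || rc < .Machine$double.eps * 100)
    stop("singular (or numerically singular) competition system")
  N <- as.vector(solve(a, K))
  names(N) <- rownames(a)
  if (any(N < 0))
    warning("equilibrium has negative components: coexistence infeasible at these capacities")
  N
}

#' Estimate competition coefficients from density experiments
#'
#' Recovers the interspecific competition coefficients from
#' density-dependent larval-survival experiments by multiple regression.
#' For each focal species \eqn{i} the equilibrium relation is rearranged
#' to the intercept-free linear model
#' \deqn{K_i^{obs} - N_i = \sum_{j \ne i} a_{ij} N_j + \varepsilon,}
#' where \eqn{K_i^{obs}} is the observed total larval survival of the
#' replicate and the \eqn{N_j} are the competitor densities, and fitted by
#' ordinary least squares. The estimated matrix is assembled with unit
#' diagonal. Negative estimates are retained but flagged.
#'
#' @param data A data frame with columns `focal` (species code),
#'   `N_<sp>` for every species in the experiment (densities, e.g. larvae
#'   per arena), `survived` (the observed total survival response) and
#'   optionally `replicate`.
#' @param species Optional character vector restricting/ordering the
#'   species; defaults to the species for which `N_` columns exist.
#' @return An object of class `competition_fit` with components
#'   `matrix` (the estimated `competition_matrix`), `se` (standard errors,
#'   `NA` on the diagonal), `sigma` (per-focal residual standard error),
#'   `condition` (per-focal design condition number), `negative_flags`
#'   (names of negative estimates) and `n` (rows per focal species).
#' @seealso [generate_density_experiment()] for synthetic experiments.
#' @export
#' @examples
#' truth <- competition_matrix(c("Bf", "Cp"))
#' exp_data <- generate_density_experiment(truth, density_design(c("Bf", "Cp")))
#' coef(fit_competition(exp_data))
fit_competition <- function(data, species = NULL) {
  if (!all(c("focal", "survived") %in% names(data)))
    stop("data must have 'focal' and 'survived' columns")
  dens_cols <- grep("^N_", names(data), value = TRUE)
  if (is.null(species)) species <- canonical_species(sub("^N_", "", dens_cols))
  else species <- canonical_species(species)
  missing_cols <- setdiff(paste0("N_", species), names(data))
  if (length(missing_cols) > 0)
    stop("missing density column(s): ", paste(missing_cols, collapse = ", "))
  bad_focal <- setdiff(unique(data$focal), species)
  if (length(bad_focal) > 0)
    stop("focal species not in the species set: ",
         paste(bad_focal, collapse = ", "))

  m <- length(species)
  a <- diag(1, m); se <- matrix(NA_real_, m, m)
  dimnames(a) <- dimnames(se) <- list(species, species)
  sigma <- condition <- stats::setNames(rep(NA_real_, m), species)
  nrows <- stats::setNames(integer(m), species)
  neg <- character(0)
  for (i in species) {
    rows <- data[data$focal == i, , drop = FALSE]
    competitors <- setdiff(species, i)
    if (nrow(rows) < length(competitors) + 1)
      stop("focal species ", i, ": need at least ", length(competitors) + 1,
           " rows, got ", nrow(rows))
    X <- as.matrix(rows[, paste0("N_", competitors), drop = FALSE])
    colnames(X) <- competitors
    constant <- apply(X, 2, function(col) length(unique(col)) == 1)
    if (qr(X)$rank < ncol(X) || (nrow(X) > 1 && any(constant)))
      stop("focal species ", i, ": rank-deficient design (collinear or constant competitor densities)")
    y <- rows$survived - rows[[paste0("N_", i)]]
    fit <- stats::lm.fit(X, y)
    coefs <- fit$coefficients
    dof <- nrow(X) - ncol(X)
    rss <- sum(fit$residuals^2)
    s2 <- if (dof > 0) rss / dof else NA_real_
    XtX_inv <- chol2inv(chol(crossprod(X)))
    a[i, competitors] <- coefs
    se[i, competitors] <- sqrt(s2 * diag(XtX_inv))
    sigma[i] <- sqrt(s2)
    condition[i] <- kappa(X)
    nrows[i] <- nrow(rows)
    if (any(coefs < 0))
      neg <- c(neg, paste0(i, "<-", competitors[coefs < 0]))
  }
  structure(list(matrix = structure(a, class = c("competition_matrix",
                                                 "matrix", "array")),
                 se = se, sigma = sigma, condition = condition,
                 negative_flags = neg, n = nrows, species = species,
                 data = data),
            class = "competition_fit")
}

#' @export
coef.competition_fit <- function(object, ...) object$matrix

#' @export
print.competition_fit <- function(x, ...) {
  cat("Competition-coefficient fit,", length(x$species), "species (",
      paste(x$species, collapse = ", "), ")\n")
  print(signif(unclass(x$matrix), 4))
  if (length(x$negative_flags) > 0)
    cat("Flagged negative estimates:", paste(x$negative_flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.competition_fit <- function(object, ...) {
  cat("Intercept-free least-squares fit of competition coefficients\n")
  for (i in object$species) {
    competitors <- setdiff(object$species, i)
    cat(sprintf("focal %s (n = %d, residual sd = %.4g, design condition = %.3g):\n",
                i, object$n[i], object$sigma[i], object$condition[i]))
    tab <- data.frame(competitor = competitors,
                      estimate = object$matrix[i, competitors],
                      std_error = object$se[i, competitors])
    print(tab, row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' @export
residuals.competition_fit <- function(object, ...) {
  data <- object$data
  predicted <- predict(object, data)
  data$survived - predicted
}

#' @export
predict.competition_fit <- function(object, newdata = object$data, ...) {
  species <- object$species
  a <- unclass(object$matrix)
  vapply(seq_len(nrow(newdata)), function(k) {
    i <- newdata$focal[k]
    sum(a[i, ] * as.numeric(newdata[k, paste0("N_", species)]))
  }, numeric(1))
}
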