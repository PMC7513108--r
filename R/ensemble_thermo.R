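# Cost functions over per-conformation energy terms, Boltzmann weights,
# minimal contributing subsets and ranking reports.

#' Construct or read a per-conformation energy table
#'
#' Rows are conformations; columns are the free-energy decomposition
#' terms G ~ Eintra + Gsolv - T Sconf + const: average intramolecular
#' enthalpy `Eintra`, solvation free-energy `Gsolv` and the entropic term
#' `minusTSconf` (= -T Sconf), all in kcal/mol. `minusTSconf` may be
#' absent when only entropy-free cost functions are evaluated.
#'
#' @param x a data.frame with columns `name`, `Eintra`, `Gsolv` and
#'   optionally `minusTSconf`, or a path to a CSV/TSV file with that
#'   header.
#' @return An object of class `energy_table` (a data.frame).
#' @export
energy_table <- function(x) {
  if (is.character(x) && length(x) == 1) {
    line1 <- readLines(x, n = 1)
    sep <- if (grepl("\t", line1)) "\t" else ","
    x <- utils::read.table(x, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  }
  x <- as.data.frame(x)
  need <- c("name", "Eintra", "Gsolv")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("energy table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(x) == 0) stop("empty energy table")
  num_cols <- intersect(c("Eintra", "Gsolv", "minusTSconf"), names(x))
  for (cc in num_cols) {
    x[[cc]] <- as.numeric(x[[cc]])
    if (!all(is.finite(x[[cc]]))) stop("non-finite values in column ", cc)
  }
  if (anyDuplicated(x$name)) stop("duplicate conformation names")
  rownames(x) <- NULL
  class(x) <- c("energy_table", "data.frame")
  x
}

#' The bundled six-conformation reference energy table
#'
#' Ships with the package: native state NAT and five decoys DEC1..DEC5
#' with per-column-shifted Eintra, Gsolv and -TSconf in kcal/mol.
#'
#' @return An `energy_table` with six rows.
#' @export
reference_energy_table <- function() {
  energy_table(system.file("extdata", "table1.csv", package = "confent",
                           mustWork = TRUE))
}

#' Evaluate a cost function over an energy table
#'
#' Cost functions: `Eintra` (enthalpy only), `G0 = Eintra + Gsolv`
#' (everything but configurational entropy) and
#' `Ghat = Eintra + Gsolv - T Sconf` (the full free-energy estimate).
#' Values are shifted so the lowest equals zero; the shift has no effect
#' on Boltzmann weights.
#'
#' @param table an `energy_table`.
#' @param X cost function name: `"Ghat"`, `"G0"` or `"Eintra"`.
#' @return Named numeric vector of shifted costs (kcal/mol), min = 0.
#' @export
evaluate_cost <- function(table, X = c("Ghat", "G0", "Eintra")) {
  X <- match.arg(X)
  if (X == "Ghat" && is.null(table$minusTSconf)) {
    stop("cost function Ghat needs column minusTSconf")
  }
  v <- switch(X,
    Eintra = table$Eintra,
    G0 = table$Eintra + table$Gsolv,
    Ghat = table$Eintra + table$Gsolv + table$minusTSconf
  )
  stats::setNames(v - min(v), table$name)
}

#' Boltzmann weights of a set of conformations
#'
#' w(k) = exp(-beta G_k) / sum_i exp(-beta G_i) with
#' beta = 1 / (kB T); the minimum cost is subtracted before
#' exponentiation for numerical stability (weights are invariant under
#' any constant shift of the costs).
#'
#' @param costs named numeric vector of costs (kcal/mol), e.g. from
#'   [evaluate_cost()].
#' @param T temperature in Kelvin (default 300).
#' @param cost_name optional label recorded on the result.
#' @return An object of class `weight_vector`: normalized `weights`,
#'   `beta` (mol/kcal), `cost_name`, `T`.
#' @export
boltzmann_weights <- function(costs, T = 300, cost_name = NULL) {
  if (length(costs) == 0) stop("empty cost set")
  if (!all(is.finite(costs))) stop("non-finite costs")
  beta <- 1 / (.kB * T)
  e <- exp(-beta * (costs - min(costs)))
  w <- e / sum(e)
  structure(
    list(weights = w, beta = beta, T = T,
         cost_name = if (is.null(cost_name)) NA_character_ else cost_name),
    class = "weight_vector"
  )
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("weight_vector (", if (is.na(x$cost_name)) "costs" else x$cost_name,
      ", T = ", x$T, " K):\n", sep = "")
  w <- sort(x$weights, decreasing = TRUE)
  for (nm in names(w)) {
    cat(sprintf("  %-10s %.6g\n", nm, w[[nm]]))
  }
  invisible(x)
}

#' Minimal subset of conformations carrying the equilibrium weight
#'
#' For each cost function the conformations are sorted by descending
#' Boltzmann weight and the shortest prefix whose weights sum beyond
#' 1 - epsilon is retained (optimal for a single cost function; ties
#' broken by name). The joint subset is the union over cost functions:
#' every conformation outside it is negligible under all of them.
#'
#' @param table an `energy_table`.
#' @param costs character vector of cost function names.
#' @param eps negligibility threshold (default 1e-7).
#' @param T temperature in Kelvin.
#' @return An object of class `minimal_subset`: `per_cost` (named list
#'   of member vectors), `joint` (union), `eps`, `T`.
#' @export
minimal_subset <- function(table, costs = c("Eintra", "G0", "Ghat"),
                           eps = 1e-7, T = 300) {
  if (eps <= 0 || eps >= 1) stop("eps must lie in (0, 1)")
  per <- lapply(costs, function(X) {
    w <- boltzmann_weights(evaluate_cost(table, X), T = T)$weights
    ord <- order(-w, names(w))
    cum <- cumsum(w[ord])
    k <- which(cum > 1 - eps)[1]
    if (is.na(k)) k <- length(w)  # numerical shortfall: keep all
    names(w)[ord][seq_len(k)]
  })
  names(per) <- costs
  joint <- table$name[table$name %in% unique(unlist(per))]
  structure(
    list(per_cost = per, joint = joint, eps = eps, T = T),
    class = "minimal_subset"
  )
}

#' @export
print.minimal_subset <- function(x, ...) {
  cat("minimal_subset (eps = ", format(x$eps), ", T = ", x$T, " K):\n",
      sep = "")
  for (nm in names(x$per_cost)) {
    cat("  ", nm, ": {", paste(x$per_cost[[nm]], collapse = ", "), "}\n",
        sep = "")
  }
  cat("  joint: {", paste(x$joint, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Ranking report over all energy columns and cost functions
#'
#' Reproduces the standard presentation of a conformational free-energy
#' comparison: each column (Eintra, Gsolv, -TSconf, G0, Ghat) shifted so
#' its lowest value is zero, with per-column ranks (ties share the lower
#' rank).
#'
#' @param table an `energy_table` with all three term columns.
#' @param T temperature (recorded; the table terms are already energies).
#' @return An object of class `rank_report`: data.frame with shifted
#'   values and `<col>_rank` columns.
#' @export
rank_report <- function(table, T = 300) {
  if (is.null(table$minusTSconf)) {
    stop("rank report needs column minusTSconf")
  }
  shift <- function(v) v - min(v)
  out <- data.frame(name = table$name, stringsAsFactors = FALSE)
  cols <- list(
    Eintra = shift(table$Eintra),
    Gsolv = shift(table$Gsolv),
    minusTSconf = shift(table$minusTSconf),
    G0 = evaluate_cost(table, "G0"),
    Ghat = evaluate_cost(table, "Ghat")
  )
  for (nm in names(cols)) {
    out[[nm]] <- as.numeric(cols[[nm]])
    out[[paste0(nm, "_rank")]] <- rank(cols[[nm]], ties.method = "min")
  }
  attr(out, "T") <- T
  class(out) <- c("rank_report", "data.frame")
  out
}

#' @export
print.rank_report <- function(x, ...) {
  cat("rank_report (kcal/mol, columns shifted to min 0; [rank]):\n")
  cols <- c("Eintra", "Gsolv", "minusTSconf", "G0", "Ghat")
  hdr <- sprintf("  %-10s %s", "name",
                 paste(sprintf("%-12s", cols), collapse = ""))
  cat(hdr, "\n")
  for (i in seq_len(nrow(x))) {
    cells <- vapply(cols, function(cc) {
      sprintf("%5.1f [%d]  ", x[[cc]][i], x[[paste0(cc, "_rank")]][i])
    }, character(1))
    cat(sprintf("  %-10s %s\n", x$name[i], paste(cells, collapse = "")))
  }
  invisible(x)
}

#' Express an energy gap in multiples of kB T
#'
#' @param gap energy difference in kcal/mol.
#' @param T temperature in Kelvin (default 300).
#' @return Dimensionless gap / (kB T); 1 kcal/mol is about 1.67 kB T at
#'   300 K.
#' @export
energy_gap_in_kBT <- function(gap, T = 300) {
  gap / (.kB * T)
}
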