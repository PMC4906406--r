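# Freeman-Halton extension of Fisher's exact test for r x c tables:
# full enumeration of tables with the observed margins under the
# multivariate hypergeometric null, with probability ordering.

# log multivariate hypergeometric probability of a table given margins
.log_table_prob <- function(tab) {
  rs <- rowSums(tab)
  cs <- colSums(tab)
  sum(lfactorial(rs)) + sum(lfactorial(cs)) -
    lfactorial(sum(tab)) - sum(lfactorial(tab))
}

# all compositions of total into `k` parts with part i <= cap[i]
.compositions <- function(total, cap) {
  if (length(cap) == 1) {
    if (total <= cap[1]) {
      return(list(total))
    }
    return(list())
  }
  out <- list()
  for (x in 0:min(total, cap[1])) {
    rest <- .compositions(total - x, cap[-1])
    for (r in rest) out[[length(out) + 1]] <- c(x, r)
  }
  out
}

# recursive enumeration of all tables with given margins; calls fn(tab)
.enumerate_tables <- function(row_margins, col_margins, fn, guard) {
  nr <- length(row_margins)
  count <- 0L
  recurse <- function(rows_done, cols_left) {
    if (length(rows_done) == nr - 1) {
      last <- cols_left
      if (any(last < 0)) {
        return()
      }
      count <<- count + 1L
      if (count > guard) {
        abort(paste(
          "enumeration guard exceeded; use monte_carlo = TRUE",
          "for a seeded approximation"
        ), class = "ctdnaprof_guard_error")
      }
      fn(do.call(rbind, c(rows_done, list(last))))
      return()
    }
    i <- length(rows_done) + 1
    for (comp in .compositions(row_margins[i], cols_left)) {
      recurse(c(rows_done, list(comp)), cols_left - comp)
    }
  }
  recurse(list(), col_margins)
  count
}

#' Freeman-Halton exact test for an r x c contingency table
#'
#' Computes the exact two-sided p-value for independence in an r x c
#' table of counts by enumerating every table with the observed margins
#' and summing the multivariate hypergeometric probabilities of tables
#' no more probable than the observed one (probability ordering, with a
#' small relative tie tolerance guarding floating-point comparisons).
#' For 2 x 2 input this reduces to the classical Fisher exact test.
#'
#' Enumeration is guarded; above `guard` tables, set
#' `monte_carlo = TRUE` for a seeded random-table approximation.
#'
#' @param table Matrix (or coercible) of non-negative integer counts.
#' @param tie_tol Relative tolerance for probability ties (default 1e-7).
#' @param guard Maximum number of tables to enumerate (default 1e7).
#' @param monte_carlo Use Monte-Carlo sampling of fixed-margin tables
#'   instead of enumeration.
#' @param n_sim Number of Monte-Carlo tables.
#' @param seed Seed for the Monte-Carlo mode.
#' @return The exact (or Monte-Carlo) p-value.
#' @export
#' @examples
#' freeman_halton_p(matrix(c(3, 1, 1, 3), nrow = 2)) # 0.4857...
freeman_halton_p <- function(table, tie_tol = 1e-7, guard = 1e7,
                             monte_carlo = FALSE, n_sim = 1e5, seed = 1L) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab))) {
    abort_validation("table must contain non-negative integer counts")
  }
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    return(1) # a degenerate margin admits a single table
  }
  rs <- rowSums(tab)
  cs <- colSums(tab)
  log_obs <- .log_table_prob(tab)
  cutoff <- log_obs + log1p(tie_tol)
  if (monte_carlo) {
    sims <- withr::with_seed(seed, r2dtable(n_sim, rs, cs))
    hits <- sum(vapply(sims, .log_table_prob, numeric(1)) <= cutoff)
    return((hits + 1) / (n_sim + 1))
  }
  p <- 0
  .enumerate_tables(rs, cs, function(t2) {
    lp <- .log_table_prob(t2)
    if (lp <= cutoff) p <<- p + exp(lp)
  }, guard = guard)
  min(1, p)
}
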