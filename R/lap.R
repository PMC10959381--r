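#' Solve a rectangular linear assignment problem with a non-link option
#'
#' Minimum-cost one-to-one matching between two sets where every element may
#' instead remain unmatched at an alternative (non-link) cost. Following the
#' standard particle-tracking formulation, the alternative cost is
#' `1.05 * cmax`, where `cmax` is the largest finite linking cost of the
#' problem instance; forbidden pairings are encoded as `Inf` (or `NA`) in
#' `cost`. If every cost is forbidden, `cmax` is undefined and no links are
#' made.
#'
#' Internally the n x m problem is embedded in an (n+m) x (n+m) square
#' matrix: the real costs in the top-left block, the per-element alternative
#' costs on the diagonals of the top-right and bottom-left blocks, and zeros
#' in the bottom-right block, so the optimum minimises
#' `sum(linked costs) + alt * (number of unlinked elements)`.
#'
#' @param cost numeric matrix of linking costs; `Inf`/`NA` entries are
#'   forbidden.
#' @param alternative_factor multiplier on `cmax` for the non-link cost
#'   (default 1.05).
#' @param alternative_cost optional explicit non-link cost overriding the
#'   `cmax`-based one.
#' @return integer vector of length `nrow(cost)`; entry i is the matched
#'   column of row i, or `NA` if row i takes the non-link option.
#' @export
solve_assignment <- function(cost, alternative_factor = 1.05,
                             alternative_cost = NULL) {
  if (!is.matrix(cost)) cost <- as.matrix(cost)
  n <- nrow(cost)
  m <- ncol(cost)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  cost[is.na(cost)] <- Inf
  finite <- is.finite(cost)
  if (!any(finite)) return(rep(NA_integer_, n))
  alt <- if (is.null(alternative_cost)) {
    alternative_factor * max(cost[finite])
  } else {
    alternative_cost
  }
  # Large-but-finite stand-in for forbidden links, safely above any total the
  # optimum can reach, so the solver's potentials stay finite.
  big <- (max(cost[finite]) + abs(alt) + 1) * (n + m) * 4
  sq <- matrix(big, n + m, n + m)
  tl <- cost
  tl[!finite] <- big
  sq[seq_len(n), seq_len(m)] <- tl
  sq[cbind(seq_len(n), m + seq_len(n))] <- alt
  sq[cbind(n + seq_len(m), seq_len(m))] <- alt
  sq[n + seq_len(m), m + seq_len(n)] <- 0
  a <- lap_hungarian(sq)
  match <- a[seq_len(n)]
  match[match > m] <- NA_integer_
  # Guard: a forbidden pairing can only appear if the instance was degenerate.
  bad <- !is.na(match) & !finite[cbind(seq_len(n), ifelse(is.na(match), 1L, match))]
  match[bad] <- NA_integer_
  match
}
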