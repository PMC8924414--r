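#' Health states of the progression model
#'
#' The cohort model distributes patients over three mutually exclusive
#' states: progression-free survival (`PFS`, on study drug), progressive
#' disease (`PD`, on subsequent-line therapy) and `DEATH`, an absorbing
#' state. Everyone starts in `PFS`.
#'
#' @return Character vector of the state names in model order.
#' @export
health_states <- function() c("PFS", "PD", "DEATH")

#' Monthly transition-probability matrix
#'
#' Builds a validated row-stochastic transition matrix over
#' \{PFS, PD, DEATH\} for a one-month cycle. Backward transitions are
#' impossible (no recovery from progression) and death is absorbing, so the
#' matrix is upper triangular and fully described by five probabilities.
#'
#' @param pfs_pfs,pfs_pd,pfs_death Monthly probabilities of staying
#'   progression-free, progressing, and dying from PFS. Must sum to 1.
#' @param pd_pd,pd_death Monthly probabilities of staying in PD and of dying
#'   from PD. Must sum to 1.
#' @param tol Row-sum tolerance.
#' @return An object of class `transition_matrix`: a named list of the five
#'   probabilities with an `as.matrix()` method.
#' @examples
#' m <- transition_matrix(0.781, 0.130, 0.089, 0.900, 0.100)
#' as.matrix(m)
#' @export
transition_matrix <- function(pfs_pfs, pfs_pd, pfs_death, pd_pd, pd_death,
                              tol = 1e-9) {
  p <- c(pfs_pfs = pfs_pfs, pfs_pd = pfs_pd, pfs_death = pfs_death,
         pd_pd = pd_pd, pd_death = pd_death)
  for (nm in names(p)) assert_scalar_number(p[[nm]], nm, 0, 1)
  bad <- character()
  if (abs(pfs_pfs + pfs_pd + pfs_death - 1) > tol)
    bad <- c(bad, sprintf("PFS row sums to %.12f", pfs_pfs + pfs_pd + pfs_death))
  if (abs(pd_pd + pd_death - 1) > tol)
    bad <- c(bad, sprintf("PD row sums to %.12f", pd_pd + pd_death))
  if (length(bad))
    stop_validation("invalid transition matrix: %s", paste(bad, collapse = "; "))
  structure(as.list(p), class = "transition_matrix")
}

#' @export
as.matrix.transition_matrix <- function(x, ...) {
  s <- health_states()
  matrix(c(x$pfs_pfs, x$pfs_pd, x$pfs_death,
           0,         x$pd_pd,  x$pd_death,
           0,         0,        1),
         nrow = 3, byrow = TRUE, dimnames = list(from = s, to = s))
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Monthly transition matrix (PFS, PD, DEATH):\n")
  print(round(as.matrix(x), 6))
  invisible(x)
}

#' @export
format.transition_matrix <- function(x, ...) {
  sprintf("transition_matrix(%.4g, %.4g, %.4g, %.4g, %.4g)",
          x$pfs_pfs, x$pfs_pd, x$pfs_death, x$pd_pd, x$pd_death)
}

is_transition_matrix <- function(x) inherits(x, "transition_matrix")
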