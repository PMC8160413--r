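#' Multinomial-logit log-likelihood of one respondent's choices
#'
#' Random-utility choice model: the utility of alternative j in a task is
#' `U_j = x_j' beta`, and the probability of choosing it is
#' `exp(U_j) / sum_k exp(U_k)`. The log-likelihood is the sum over tasks of
#' the log probability of the chosen alternative, computed with max-shifted
#' (overflow-safe) normalization.
#'
#' @param beta Numeric coefficient vector (effects-coded part-worths).
#' @param task_matrices List of numeric matrices, one per task, each with
#'   one row per alternative and `length(beta)` columns.
#' @param chosen Integer vector, one entry per task: the row index of the
#'   chosen alternative.
#' @return The log-likelihood (scalar).
#' @export
#' @examples
#' X <- rbind(c(1), c(-1))
#' mnl_loglik(0, list(X), 1) # log(1/2)
mnl_loglik <- function(beta, task_matrices, chosen) {
  if (!is.list(task_matrices)) abort("`task_matrices` must be a list of matrices.")
  if (length(task_matrices) != length(chosen)) {
    abort("`chosen` must have one entry per task.")
  }
  beta <- as.numeric(beta)
  ll <- 0
  for (t in seq_along(task_matrices)) {
    X <- task_matrices[[t]]
    if (ncol(X) != length(beta)) {
      abort(sprintf("Task %d has %d columns; beta has length %d.",
                    t, ncol(X), length(beta)))
    }
    j <- chosen[t]
    if (is.na(j) || j < 1L || j > nrow(X)) {
      abort(sprintf("Invalid chosen alternative %s in task %d.", j, t))
    }
    u <- drop(X %*% beta)
    m <- max(u)
    ll <- ll + (u[j] - m) - log(sum(exp(u - m)))
  }
  ll
}
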