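#' Generate a paired choice-set design
#'
#' Builds the set of choice tasks shown to a respondent: `n_tasks` tasks of
#' `n_alts` hypothetical products each, with level assignments that are
#' level-balanced (each level of each attribute appears equally often, up to
#' the unavoidable remainder), near-orthogonal (level pairs across attribute
#' pairs co-occur about equally often), and with minimal attribute-level
#' overlap between the alternatives of a task. Construction is a balanced
#' random start followed by greedy pairwise-swap refinement of a weighted
#' score; swaps exchange two slots of the same attribute, so exact level
#' balance is preserved by construction. Identical alternatives within a
#' task are forbidden (every task contrasts two distinct hypothetical
#' products).
#'
#' @param attribute_space An [attribute_space()]; default the five GBCM
#'   attributes of [build_default_attribute_space()].
#' @param n_tasks Number of choice tasks (default 15).
#' @param n_alts Alternatives per task (default 2, a paired design).
#' @param n_shown Number of attributes displayed per task. Defaults to all
#'   attributes (full profile); smaller values give a partial-profile design
#'   in which attributes rotate across tasks.
#' @param seed Integer seed; the same seed and configuration reproduce the
#'   design exactly.
#' @param n_sweeps Swap-refinement budget (proposed swaps).
#'
#' @return A `choice_design` tibble in long format: `task_id`, `alt_id`, and
#'   one numeric column per attribute holding the level value shown (`NA`
#'   when the attribute is not displayed in that task). The attribute space
#'   and seed are attached as attributes.
#' @export
#' @examples
#' design <- generate_design(seed = 1)
#' diagnose_design(design)
generate_design <- function(attribute_space = build_default_attribute_space(),
                            n_tasks = 15, n_alts = 2, n_shown = NULL,
                            seed = 1L, n_sweeps = 4000L) {
  check_attribute_space(attribute_space)
  n_attr <- nrow(attribute_space)
  n_shown <- n_shown %||% n_attr
  if (n_tasks < 1L) abort("`n_tasks` must be >= 1.")
  if (n_alts < 2L) abort("`n_alts` must be >= 2.")
  if (n_shown < 1L || n_shown > n_attr) {
    abort(sprintf("`n_shown` must be in [1, %d].", n_attr))
  }
  lvls <- space_levels(attribute_space)

  # which attributes appear in which task: deterministic rotation keeps the
  # per-attribute display counts balanced for partial profiles
  shown <- matrix(FALSE, n_tasks, n_attr)
  for (t in seq_len(n_tasks)) {
    idx <- ((t - 1L) * n_shown + seq_len(n_shown) - 1L) %% n_attr + 1L
    shown[t, idx] <- TRUE
  }

  # infeasible if some task cannot host n_alts distinct profiles
  for (t in seq_len(n_tasks)) {
    n_profiles <- prod(lengths(lvls)[shown[t, ]])
    if (n_profiles < n_alts) {
      abort(sprintf(
        "Infeasible design: task %d admits only %d distinct profiles for %d alternatives.",
        t, n_profiles, n_alts
      ))
    }
  }

  withr::with_seed(seed, {
    # balanced start: per attribute, a shuffled multiset of level indices whose
    # counts differ by at most one
    assign <- array(NA_integer_, c(n_tasks, n_alts, n_attr))
    for (a in seq_len(n_attr)) {
      rows <- which(shown[, a])
      n_slots <- length(rows) * n_alts
      if (n_slots == 0L) next
      L <- length(lvls[[a]])
      counts <- rep(n_slots %/% L, L)
      rem <- n_slots %% L
      if (rem > 0L) {
        bump <- sample.int(L, rem)
        counts[bump] <- counts[bump] + 1L
      }
      pool <- sample(rep.int(seq_len(L), counts))
      assign[rows, , a] <- matrix(pool, nrow = length(rows), ncol = n_alts)
    }
    assign <- .refine_design(assign, shown, n_sweeps)
  })

  if (.design_duplicates(assign, shown) > 0L) {
    abort("Design refinement could not remove duplicate alternatives; increase `n_sweeps`.")
  }

  out <- tidyr::expand_grid(task_id = seq_len(n_tasks), alt_id = seq_len(n_alts))
  for (a in seq_len(n_attr)) {
    vals <- lvls[[a]][assign[cbind(out$task_id, out$alt_id, a)]]
    out[[attribute_space$attribute[a]]] <- vals
  }
  structure(
    out,
    attribute_space = attribute_space,
    seed = seed,
    n_alts = n_alts,
    n_tasks = n_tasks,
    class = c("choice_design", class(out))
  )
}

# number of task-internal duplicate alternative pairs
.design_duplicates <- function(assign, shown) {
  n_tasks <- dim(assign)[1]; n_alts <- dim(assign)[2]
  dup <- 0L
  for (t in seq_len(n_tasks)) {
    sub <- matrix(assign[t, , shown[t, ]], nrow = n_alts)
    prof <- apply(sub, 1, paste, collapse = ",")
    dup <- dup + (n_alts - length(unique(prof)))
  }
  dup
}

# greedy refinement: swap two same-attribute slots, keep the swap if the
# weighted score does not get worse; the inner loop lives in C++
# (.refine_design_cpp), driven by R's RNG for seeded reproducibility
.refine_design <- function(assign, shown, n_sweeps) {
  n_tasks <- dim(assign)[1]; n_alts <- dim(assign)[2]; n_attr <- dim(assign)[3]
  L <- as.integer(apply(assign, 3, max, na.rm = TRUE))
  # slot matrix with alternatives fastest within task; 0 codes "not shown"
  M <- matrix(0L, n_tasks * n_alts, n_attr)
  for (a in seq_len(n_attr)) {
    v <- t(assign[, , a])
    v[is.na(v)] <- 0L
    M[, a] <- as.vector(v)
  }
  M <- .refine_design_cpp(M, n_tasks, n_alts, L, as.integer(n_sweeps))
  for (a in seq_len(n_attr)) {
    v <- matrix(M[, a], nrow = n_alts)
    v[v == 0L] <- NA_integer_
    assign[, , a] <- t(v)
  }
  assign
}

#' Diagnose balance, orthogonality and overlap of a choice design
#'
#' Exact counts quantifying the design goals: per-attribute level counts
#' with their deviation from the uniform ideal (`balance_score` is the
#' largest absolute deviation), pairwise level co-occurrence counts across
#' attribute pairs, and the attribute-level overlap rate (the fraction of
#' displayed task-attribute slots in which all alternatives carry the same
#' level).
#'
#' @param design A `choice_design` from [generate_design()] (any tibble in
#'   the same long layout with an attached attribute space works).
#' @return A list of class `design_diagnostics`: `level_counts` (tibble),
#'   `balance_score`, `pairwise_cooccurrence` (tibble), `overlap_rate`.
#' @export
diagnose_design <- function(design) {
  space <- attr(design, "attribute_space")
  if (is.null(space)) abort("`design` carries no attribute space.")
  attrs <- space$attribute
  lvls <- space_levels(space)

  level_counts <- purrr::map_dfr(attrs, function(a) {
    vals <- design[[a]]
    vals <- vals[!is.na(vals)]
    counts <- vapply(lvls[[a]], function(l) sum(vals == l), integer(1))
    tibble::tibble(
      attribute = a, level = lvls[[a]], count = counts,
      ideal = length(vals) / length(lvls[[a]])
    )
  })
  balance_score <- max(abs(level_counts$count - level_counts$ideal))

  co <- list()
  if (length(attrs) > 1L) {
    for (i in seq_along(attrs)[-length(attrs)]) {
      for (j in (i + 1L):length(attrs)) {
        keep <- !is.na(design[[attrs[i]]]) & !is.na(design[[attrs[j]]])
        if (!any(keep)) next
        tab <- as.data.frame(table(design[[attrs[i]]][keep], design[[attrs[j]]][keep]))
        co[[length(co) + 1L]] <- tibble::tibble(
          attribute_a = attrs[i], attribute_b = attrs[j],
          level_a = as.numeric(as.character(tab$Var1)),
          level_b = as.numeric(as.character(tab$Var2)),
          count = tab$Freq
        )
      }
    }
  }
  co <- if (length(co)) dplyr::bind_rows(co) else tibble::tibble()

  slots <- 0L; same <- 0L
  for (t in unique(design$task_id)) {
    sub <- design[design$task_id == t, , drop = FALSE]
    for (a in attrs) {
      v <- sub[[a]]
      if (anyNA(v)) next
      slots <- slots + 1L
      if (length(unique(v)) == 1L) same <- same + 1L
    }
  }
  structure(
    list(
      level_counts = level_counts,
      balance_score = balance_score,
      pairwise_cooccurrence = co,
      overlap_rate = if (slots > 0L) same / slots else NA_real_,
      n_overlap_slots = same,
      n_shown_slots = slots
    ),
    class = "design_diagnostics"
  )
}

#' @export
print.design_diagnostics <- function(x, ...) {
  cat("<design_diagnostics>\n")
  cat(sprintf("  balance_score (max |count - ideal|): %.2f\n", x$balance_score))
  cat(sprintf(
    "  overlap_rate: %.3f (%d of %d shown slots)\n",
    x$overlap_rate, x$n_overlap_slots, x$n_shown_slots
  ))
  invisible(x)
}
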