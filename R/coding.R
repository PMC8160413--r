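#' Effects-code a choice design
#'
#' Turns the long design/response layout (one numeric level column per
#' attribute) into the effects-coded model matrix used by the multinomial
#' logit likelihood. Each attribute with L levels contributes L - 1 free
#' columns: level l < L maps to the l-th unit vector, the reference (last)
#' level to -1 in every column, so implied level utilities sum to zero
#' within each attribute. Attributes not shown in a task (`NA` level, a
#' partial profile) code to an all-zero block. The mapping back from coded
#' columns to (attribute, level) is retained so coding is reversible.
#'
#' @param design A `choice_design` (or responses tibble in the same layout)
#'   with an attached attribute space, or any such tibble plus an explicit
#'   `attribute_space`.
#' @param attribute_space Optional [attribute_space()] overriding the one
#'   attached to `design`.
#' @return A list of class `coded_design`: `X` (rows in design order, one
#'   column per free effects-coded cell, named `attribute@level`), `map`
#'   (tibble attribute/level/column), and the attribute space.
#' @export
encode_design <- function(design, attribute_space = NULL) {
  space <- attribute_space %||% attr(design, "attribute_space")
  if (is.null(space)) abort("No attribute space supplied or attached to `design`.")
  check_attribute_space(space)
  lvls <- space_levels(space)
  if (any(lengths(lvls) < 2L)) abort("Effects coding needs >= 2 levels per attribute.")

  blocks <- list()
  map <- list()
  col0 <- 0L
  for (a in space$attribute) {
    lv <- lvls[[a]]
    L <- length(lv)
    vals <- design[[a]]
    if (is.null(vals)) abort(sprintf("Design is missing attribute column '%s'.", a))
    idx <- match(vals, lv)
    if (any(is.na(idx) & !is.na(vals))) {
      bad <- unique(vals[is.na(idx) & !is.na(vals)])
      abort(sprintf("Unknown level(s) %s for attribute '%s'.",
                    paste(bad, collapse = ", "), a))
    }
    B <- matrix(0, nrow = nrow(design), ncol = L - 1L,
                dimnames = list(NULL, paste0(a, "@", lv[-L])))
    show <- !is.na(idx)
    for (l in seq_len(L - 1L)) B[show & idx == l, l] <- 1
    B[show & idx == L, ] <- -1
    blocks[[a]] <- B
    map[[a]] <- tibble::tibble(
      attribute = a, level = lv,
      column = c(col0 + seq_len(L - 1L), NA_integer_)
    )
    col0 <- col0 + L - 1L
  }
  structure(
    list(X = do.call(cbind, blocks), map = dplyr::bind_rows(map),
         attribute_space = space),
    class = "coded_design"
  )
}

#' Decode an effects-coded matrix back to level values
#'
#' Inverse of [encode_design()]: recovers, for every row, the numeric level
#' shown for each attribute (`NA` for an all-zero block, i.e. an attribute
#' not displayed in that task).
#'
#' @param coded A `coded_design`.
#' @return A tibble with one numeric column per attribute.
#' @export
decode_design <- function(coded) {
  stopifnot(inherits(coded, "coded_design"))
  space <- coded$attribute_space
  lvls <- space_levels(space)
  out <- tibble::tibble(.rows = nrow(coded$X))
  for (a in space$attribute) {
    m <- coded$map[coded$map$attribute == a, ]
    cols <- m$column[!is.na(m$column)]
    B <- coded$X[, cols, drop = FALSE]
    L <- length(lvls[[a]])
    idx <- rep(NA_integer_, nrow(B))
    is_ref <- rowSums(B == -1) == (L - 1L)
    idx[is_ref] <- L
    for (l in seq_len(L - 1L)) idx[!is_ref & B[, l] == 1] <- l
    out[[a]] <- lvls[[a]][idx]
  }
  out
}

#' Expand an effects-coded coefficient vector to full level utilities
#'
#' @param beta Numeric vector in the column order of [encode_design()].
#' @param coded A `coded_design` providing the column map.
#' @return Tidy tibble `attribute`, `level`, `utility`; within each
#'   attribute the utilities sum to zero (the reference level carries minus
#'   the sum of the free coefficients).
#' @export
expand_partworths <- function(beta, coded) {
  stopifnot(inherits(coded, "coded_design"))
  map <- coded$map
  util <- numeric(nrow(map))
  for (a in unique(map$attribute)) {
    rows <- which(map$attribute == a)
    cols <- map$column[rows]
    free <- beta[cols[!is.na(cols)]]
    util[rows] <- c(free, -sum(free))
  }
  tibble::tibble(attribute = map$attribute, level = map$level, utility = util)
}

# internal inverse of expand_partworths: tidy partworths for one respondent
# -> effects-coded coefficient vector (drops each attribute's last level)
collapse_partworths <- function(pw, coded) {
  map <- coded$map
  beta <- numeric(max(map$column, na.rm = TRUE))
  for (a in unique(map$attribute)) {
    m <- map[map$attribute == a, ]
    sub <- pw[pw$attribute == a, ]
    u <- sub$utility[match(m$level, sub$level)]
    if (anyNA(u)) abort(sprintf("Part-worths missing level(s) for attribute '%s'.", a))
    keep <- !is.na(m$column)
    beta[m$column[keep]] <- u[keep]
  }
  beta
}
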