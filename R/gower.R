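#' Gower distance between two mixed-type records
#'
#' Mean over variables of the per-variable dissimilarity: for numeric
#' variables `|x - y| / range`, for categorical variables 0 if equal and 1
#' otherwise. Symmetric, in `[0, 1]`, and 0 iff all compared variables are
#' equal.
#'
#' @param x,y lists or one-row data frames exposing the variables named in
#'   `spec`.
#' @param spec a list with `numeric` (named numeric vector of strictly
#'   positive ranges) and `categorical` (character vector of variable
#'   names); see [gower_spec()].
#' @return dissimilarity in `[0, 1]`.
#' @export
gower_distance <- function(x, y, spec) {
  vars <- c(names(spec$numeric), spec$categorical)
  for (v in vars) {
    if (is.null(x[[v]]) || is.null(y[[v]])) stop("missing variable: ", v)
  }
  d <- 0
  for (v in names(spec$numeric)) {
    rg <- spec$numeric[[v]]
    if (!is.finite(rg) || rg <= 0) stop("zero or invalid range for variable: ", v)
    d <- d + abs(as.numeric(x[[v]]) - as.numeric(y[[v]])) / rg
  }
  for (v in spec$categorical) {
    d <- d + as.numeric(x[[v]] != y[[v]])
  }
  d / length(vars)
}

#' Build a Gower variable specification from data
#'
#' Ranges for numeric variables are taken over the union of the two pools
#' so donor and recipient values are normalized on a common scale.
#'
#' @param data data frame (typically `rbind` of shared covariates from both
#'   pools).
#' @param numeric_vars,categorical_vars variable names by type.
#' @return a list with components `numeric` (named ranges) and
#'   `categorical`.
#' @export
gower_spec <- function(data, numeric_vars, categorical_vars) {
  rg <- vapply(numeric_vars, function(v) {
    r <- range(as.numeric(data[[v]]))
    r[2] - r[1]
  }, numeric(1))
  if (any(rg <= 0)) stop("zero range for variable(s): ",
                         paste(numeric_vars[rg <= 0], collapse = ", "))
  list(numeric = rg, categorical = categorical_vars)
}

# Full recipient x donor Gower cross-distance matrix (vectorized).
gower_cross <- function(recipients, donors, spec) {
  nr <- nrow(recipients); nd <- nrow(donors)
  vars_n <- names(spec$numeric)
  p <- length(vars_n) + length(spec$categorical)
  D <- matrix(0, nr, nd)
  for (v in vars_n) {
    rg <- spec$numeric[[v]]
    if (rg <= 0) stop("zero range for variable: ", v)
    D <- D + abs(outer(as.numeric(recipients[[v]]), as.numeric(donors[[v]]), "-")) / rg
  }
  for (v in spec$categorical) {
    D <- D + outer(recipients[[v]], donors[[v]], "!=")
  }
  D / p
}

#' One-to-one nearest-neighbor matching with replacement
#'
#' Maps every recipient to the donor at minimum Gower distance; donors may
#' be reused, ties break toward the lowest donor id, and output order
#' follows the recipient pool.
#'
#' @param recipients,donors data frames exposing the variables in `spec`;
#'   rows are records. An `id` column, if present, names the returned
#'   mapping.
#' @param spec a Gower specification, see [gower_spec()].
#' @param chunk number of recipient rows per distance block (memory bound).
#' @return integer vector of donor row indices, one per recipient, with the
#'   matched minimum distances in attribute `"distance"`.
#' @export
match_donors <- function(recipients, donors, spec, chunk = 512L) {
  if (nrow(donors) == 0L) stop("empty donor pool")
  if (nrow(recipients) == 0L) stop("empty recipient pool")
  nr <- nrow(recipients)
  idx <- integer(nr)
  dmin <- numeric(nr)
  starts <- seq(1L, nr, by = chunk)
  for (s in starts) {
    rows <- s:min(s + chunk - 1L, nr)
    D <- gower_cross(recipients[rows, , drop = FALSE], donors, spec)
    # ties.method = "first" gives the lowest donor index on ties
    j <- max.col(-D, ties.method = "first")
    idx[rows] <- j
    dmin[rows] <- D[cbind(seq_along(rows), j)]
  }
  if (!is.null(recipients$id)) names(idx) <- recipients$id
  attr(idx, "distance") <- dmin
  idx
}
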