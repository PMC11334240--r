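#' Build a Hounsfield look-up table (HLUT)
#'
#' Nodes pair a CT number with a density and composition; conversion
#' interpolates linearly between consecutive nodes. In the calibrated
#' flavor node CT numbers come from [predict_hu()] at the high-energy
#' beam; in the published-table flavor they are supplied verbatim via
#' `node_hu`. Nodes sharing a CT number (within 1e-9 HU) are collapsed
#' by averaging density and composition; the table is sorted by HU.
#'
#' @param basis A [tissue_basis()] providing densities and compositions.
#' @param params A [stoich_params()] for the calibrated flavor, or
#'   `NULL` when `node_hu` is given.
#' @param node_hu Optional vector of node CT numbers (one per basis
#'   tissue, published-table flavor).
#' @param elements Element table.
#' @return A data frame of class `hlut` with columns `hu`,
#'   `density_g_cm3` and one column per element.
#' @export
build_hlut <- function(basis, params = NULL, node_hu = NULL,
                       elements = element_table()) {
  stopifnot(inherits(basis, "tissue_basis"))
  if (is.null(node_hu)) {
    stopifnot(inherits(params, "stoich_params"))
    node_hu <- vapply(basis$tissues, predict_hu, 0, params = params,
                      elements = elements)
  }
  stopifnot(length(node_hu) == length(basis$tissues))
  df <- as.data.frame(basis)
  df$name <- NULL
  df$category <- NULL
  df <- cbind(hu = node_hu, df)
  # collapse duplicate-HU nodes by averaging
  key <- round(df$hu, 9)
  df <- stats::aggregate(df[setdiff(names(df), "hu")],
                         by = list(hu = key), FUN = mean)
  df <- df[order(df$hu), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) < 2L)
    stop("an HLUT needs at least 2 distinct nodes", call. = FALSE)
  if (any(df$density_g_cm3 <= 0))
    stop("node densities must be positive", call. = FALSE)
  class(df) <- c("hlut", "data.frame")
  df
}

#' Single-energy CT conversion by HLUT interpolation
#'
#' Density and each elemental weight fraction interpolate linearly in HU
#' within each node interval; interpolated weight fractions are then
#' renormalized to unit sum. CT numbers below the first (above the last)
#' node clamp to that end node.
#'
#' @param hu Array (or vector) of CT numbers.
#' @param table An [build_hlut()] table.
#' @return List with `density` (same shape as `hu`) and `weights`
#'   (named list of weight-fraction arrays summing to 1 voxelwise).
#' @export
sect_convert <- function(hu, table) {
  stopifnot(inherits(table, "hlut"))
  nodes <- table$hu
  syms <- setdiff(names(table), c("hu", "density_g_cm3"))
  x <- pmin(pmax(as.vector(hu), nodes[1]), nodes[length(nodes)])
  interp <- function(y) stats::approx(nodes, y, xout = x,
                                      ties = "ordered")$y
  density <- interp(table$density_g_cm3)
  w <- lapply(syms, function(s) interp(table[[s]]))
  tot <- Reduce(`+`, w)
  w <- lapply(w, function(v) v / tot)
  shape <- function(v) if (is.array(hu)) array(v, dim = dim(hu)) else v
  list(density = shape(density),
       weights = stats::setNames(lapply(w, shape), syms))
}

#' @rdname build_hlut
#' @param path CSV file with columns `hu`, `density_g_cm3` and element
#'   columns (published-node flavor).
#' @export
read_hlut <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  stopifnot(all(c("hu", "density_g_cm3") %in% names(df)))
  df <- df[order(df$hu), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("hlut", "data.frame")
  df
}
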