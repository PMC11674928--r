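#' Structural connectome
#'
#' Validating constructor for the anatomical substrate of the model: a square,
#' symmetric, nonnegative weight matrix with zero diagonal, optional region
#' labels and optional 3-D coordinates in mm (needed only for the turbulence
#' measures).
#'
#' @param weights N x N numeric matrix of connection weights.
#' @param labels optional character vector of N region labels; defaults to
#'   `R000`, `R001`, ...
#' @param coordinates optional N x 3 numeric matrix of region centroids, mm.
#' @param tol symmetry tolerance on `max(abs(weights - t(weights)))`.
#'
#' @return An object of class `dmf_connectome` with elements `weights`,
#'   `labels` and `coordinates`.
#' @examples
#' con <- connectome(matrix(c(0, 1, 1, 0), 2, 2))
#' node_strength(con)
#' @export
connectome <- function(weights, labels = NULL, coordinates = NULL,
                       tol = 1e-8) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights))
    stop("connectome weights must be a square matrix")
  n <- nrow(weights)
  if (n < 1L) stop("connectome must have at least one region")
  if (any(!is.finite(weights))) stop("connectome weights must be finite")
  if (any(weights < 0)) stop("connectome weights must be nonnegative")
  if (max(abs(weights - t(weights))) > tol)
    stop("connectome weights must be symmetric (tolerance ", tol, ")")
  if (any(diag(weights) != 0)) stop("connectome diagonal must be zero")
  if (is.null(labels)) labels <- sprintf("R%03d", seq_len(n) - 1L)
  if (length(labels) != n) stop("need one label per region")
  if (!is.null(coordinates)) {
    coordinates <- as.matrix(coordinates)
    if (nrow(coordinates) != n || ncol(coordinates) != 3L)
      stop("coordinates must be an N x 3 matrix (mm)")
    if (any(!is.finite(coordinates))) stop("coordinates must be finite")
  }
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, labels = labels,
                 coordinates = coordinates),
            class = "dmf_connectome")
}

#' Node strength
#'
#' Row sums of the connectivity matrix, beta_n = sum_p C_np. For a symmetric
#' matrix each link contributes to two row sums; `halve = TRUE` divides by 2
#' to compensate this double counting, a convention sometimes used when
#' regressing inhibitory weights on strength. The default is the literal row
#' sum.
#'
#' @param con a [connectome()] object or a plain square matrix.
#' @param halve divide the row sums by 2.
#' @return Numeric vector of length N.
#' @export
node_strength <- function(con, halve = FALSE) {
  w <- if (inherits(con, "dmf_connectome")) con$weights else as.matrix(con)
  if (nrow(w) != ncol(w)) stop("connectome weights must be a square matrix")
  b <- rowSums(w)
  if (halve) b / 2 else b
}

#' @export
print.dmf_connectome <- function(x, ...) {
  cat("Structural connectome:", nrow(x$weights), "regions,",
      sum(x$weights[upper.tri(x$weights)] > 0), "edges",
      if (!is.null(x$coordinates)) "(with coordinates)" else "", "\n")
  invisible(x)
}
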