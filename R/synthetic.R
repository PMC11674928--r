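#' Synthetic structural connectome
#'
#' Generates a random symmetric, nonnegative, zero-diagonal, connected weight
#' matrix for testing and simulation without external data. Three models:
#' `"distance-exponential"` places regions on a sphere and sets
#' weight = exp(-distance / 40 mm) on a random edge mask (mimicking the
#' distance dependence of empirical connectomes), `"uniform-random"` draws
#' uniform weights on the mask, `"modular"` adds strong within-block /
#' weak between-block structure. Disconnected draws are redrawn (up to 100
#' times). If `target_mean_strength` is set the matrix is rescaled so the
#' mean node strength matches it to 1e-9.
#'
#' @param n_regions number of regions, >= 2.
#' @param model connectivity model (see above).
#' @param density fraction of possible edges present, in (0, 1].
#' @param weight_scale multiplicative weight scale.
#' @param target_mean_strength optional target for `mean(node_strength)`.
#' @param seed integer seed.
#' @param n_modules number of blocks for the modular model.
#' @param radius radius of the sphere on which regions are placed, mm.
#'   Coarse whole-brain fixtures use the default 70 mm; turbulence analyses
#'   need inter-node spacing comparable to the 1/lambda kernel range
#'   (a few mm), i.e. a denser fixture with a smaller radius.
#' @return A [connectome()] with coordinates attached (sphere of radius
#'   `radius` mm).
#' @export
make_connectome <- function(n_regions, model = c("distance-exponential",
                                                 "uniform-random", "modular"),
                            density = 0.35, weight_scale = 1,
                            target_mean_strength = NULL, seed = 1,
                            n_modules = 2, radius = 70) {
  model <- match.arg(model)
  stopifnot(n_regions >= 2, density > 0, density <= 1)
  set.seed(seed)
  for (try in 1:100) {
    coords <- .sphere_points(n_regions, radius = radius)
    d <- as.matrix(dist(coords))
    w <- matrix(0, n_regions, n_regions)
    mask <- matrix(FALSE, n_regions, n_regions)
    mask[upper.tri(mask)] <- runif(n_regions * (n_regions - 1) / 2) < density
    mask <- mask | t(mask)
    if (model == "distance-exponential") {
      w[mask] <- exp(-d[mask] / 40)
    } else if (model == "uniform-random") {
      u <- matrix(0, n_regions, n_regions)
      u[upper.tri(u)] <- runif(n_regions * (n_regions - 1) / 2)
      u <- u + t(u)
      w[mask] <- u[mask]
    } else {
      blk <- rep(seq_len(n_modules), length.out = n_regions)
      same <- outer(blk, blk, "==")
      u <- matrix(0, n_regions, n_regions)
      u[upper.tri(u)] <- runif(n_regions * (n_regions - 1) / 2)
      u <- u + t(u)
      w[mask] <- u[mask] * ifelse(same[mask], 1, 0.2)
    }
    diag(w) <- 0
    w <- (w + t(w)) / 2
    w <- w * weight_scale
    if (.is_connected(w)) {
      if (!is.null(target_mean_strength)) {
        m <- mean(rowSums(w))
        if (m == 0) next
        w <- w * (target_mean_strength / m)
      }
      return(connectome(w, coordinates = coords))
    }
  }
  stop("could not draw a connected connectome at this density in 100 tries")
}

.sphere_points <- function(n, radius = 70) {
  x <- matrix(rnorm(3 * n), n, 3)
  x / sqrt(rowSums(x^2)) * radius
}

.is_connected <- function(w) {
  n <- nrow(w)
  adj <- w > 0
  reach <- logical(n)
  reach[1] <- TRUE
  repeat {
    new <- reach | (adj %*% reach > 0)
    if (all(new == reach)) break
    reach <- as.logical(new)
  }
  all(reach)
}

#' Synthetic region coordinates
#'
#' Random 3-D region centroids, either on a sphere surface of radius `scale`
#' mm or uniformly inside a cube of side `scale` mm.
#'
#' @param n number of regions, >= 2.
#' @param geometry `"sphere"` or `"box"`.
#' @param scale radius (sphere) or side length (box), mm.
#' @param seed integer seed.
#' @return N x 3 numeric matrix, mm.
#' @export
make_coordinates <- function(n, geometry = c("sphere", "box"), scale = 70,
                             seed = 1) {
  geometry <- match.arg(geometry)
  if (n < 2) stop("need at least two regions")
  set.seed(seed)
  if (geometry == "sphere") .sphere_points(n, scale)
  else matrix(runif(3 * n, 0, scale), n, 3)
}

#' Surrogate "empirical" BOLD cohort
#'
#' Generates a cohort of independent model simulations at known parameters
#' (G*, alpha*), inhibitory weights from the linear FIC rule. Used as a
#' stand-in for an empirical fMRI cohort so fitting experiments have a
#' well-defined ground truth.
#'
#' @param con a [connectome()].
#' @param G_star,alpha_star generating parameters.
#' @param n_subjects number of independent simulations (distinct seeds).
#' @param duration,TR simulation length and sampling interval, s.
#' @param seed base seed; subject i uses seed + i.
#' @param transient_discard transient removed from each run, s.
#' @param params,hemo model parameters.
#' @return List of N x T BOLD matrices.
#' @export
make_surrogate_cohort <- function(con, G_star, alpha_star, n_subjects = 13,
                                  duration = 500, TR = 2, seed = 1,
                                  transient_discard = 10,
                                  params = dmf_parameters(),
                                  hemo = hemodynamic_parameters()) {
  stopifnot(inherits(con, "dmf_connectome"), n_subjects >= 1)
  beta <- node_strength(con)
  J <- linear_fic(G_star, beta, alpha_star)
  lapply(seq_len(n_subjects), function(i) {
    cfg <- integration_config(duration = duration, TR = TR,
                              transient_discard = transient_discard,
                              seed = seed + i)
    sim <- tryCatch(
      run_simulation(con, coupling_config(G_star, J, alpha = alpha_star),
                     cfg, params, hemo),
      dmf_divergence_error = function(e)
        stop("surrogate cohort diverged at (G*, alpha*) = (", G_star, ", ",
             alpha_star, "): choose a lower G* or rescale the connectome",
             call. = FALSE))
    sim$bold
  })
}
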