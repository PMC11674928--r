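#' Read a structural connectome from delimited text
#'
#' Reads a square numeric weight matrix (comma, tab or whitespace separated;
#' delimiter auto-detected). Small asymmetries (max |C - C'| <= 1e-6, e.g.
#' from averaging directional tract probabilities) are silently symmetrized
#' by (C + C')/2 with a message; larger asymmetry is an error. Negative or
#' non-finite entries are rejected; any nonzero diagonal is zeroed with a
#' message.
#'
#' @param path file path.
#' @param delimiter field delimiter, or `NULL` to auto-detect.
#' @param coordinates_path optional path to an N x 3 coordinate table (mm,
#'   same row order).
#' @return A [connectome()] with labels `R000`, `R001`, ...
#' @export
read_connectome <- function(path, delimiter = NULL, coordinates_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- .read_matrix(path, delimiter)
  if (nrow(m) != ncol(m)) stop("connectome file is not a square matrix")
  if (any(!is.finite(m))) stop("connectome contains NaN/Inf entries")
  if (any(m < 0)) stop("connectome contains negative weights")
  asym <- max(abs(m - t(m)))
  if (asym > 1e-6)
    stop("connectome asymmetry ", signif(asym, 3), " exceeds 1e-6")
  if (asym > 0) {
    message("symmetrizing connectome (asymmetry ", signif(asym, 3), ")")
    m <- (m + t(m)) / 2
  }
  if (any(diag(m) != 0)) {
    message("zeroing nonzero diagonal")
    diag(m) <- 0
  }
  coords <- NULL
  if (!is.null(coordinates_path)) {
    coords <- .read_matrix(coordinates_path, delimiter)
    if (ncol(coords) != 3L || nrow(coords) != nrow(m))
      stop("coordinates must be an N x 3 table matching the connectome")
  }
  connectome(m, coordinates = coords)
}

.detect_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl(",", line)) "," else if (grepl("\t", line)) "\t" else ""
}

.read_matrix <- function(path, delimiter = NULL) {
  sep <- if (is.null(delimiter)) .detect_sep(path) else delimiter
  as.matrix(read.table(path, sep = sep, header = FALSE,
                       colClasses = "numeric"))
}

#' Write / read BOLD matrices as delimited text
#'
#' Regions x time matrices with a header row of column names and region
#' labels in the first column. Values are written with 17 significant
#' digits, so a write/read round-trip is bit-stable.
#'
#' @param bold N x T numeric matrix (regions x time).
#' @param path file path.
#' @param sep field delimiter.
#' @return `write_bold` returns `path` invisibly; `read_bold` the matrix with
#'   region labels as row names.
#' @export
write_bold <- function(bold, path, sep = ",") {
  bold <- as.matrix(bold)
  labels <- rownames(bold)
  if (is.null(labels)) labels <- sprintf("R%03d", seq_len(nrow(bold)) - 1L)
  df <- data.frame(label = labels,
                   matrix(sprintf("%.17g", bold), nrow(bold)),
                   stringsAsFactors = FALSE)
  names(df) <- c("label", sprintf("t%05d", seq_len(ncol(bold))))
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bold
#' @export
read_bold <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- .detect_sep(path)
  df <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  if (nrow(m) > 50 * ncol(m))
    warning("matrix has many more rows than columns; ",
            "expected orientation is regions x time")
  m
}

#' Write a simulation result as a hierarchical JSON container
#'
#' Serializes a [run_simulation()] result (BOLD, rate summaries and the
#' configuration echo) into a single JSON document with top-level fields
#' `bold`, `rate_mean`, `rate_std`, `config` and `seed`.
#'
#' @param sim a `dmf_sim` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(sim, path) {
  stopifnot(inherits(sim, "dmf_sim"))
  jsonlite::write_json(
    list(bold = sim$bold, rate_mean = sim$rate_mean,
         rate_std = sim$rate_std,
         config = unclass(sim$config), seed = sim$seed),
    path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Write calibrated inhibitory-weight vectors as delimited text
#'
#' One column per coupling value, header `G_<value>`.
#'
#' @param J_by_G list of entries `list(G = <scalar>, J = <vector>)`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fic_table <- function(J_by_G, path) {
  m <- do.call(cbind, lapply(J_by_G, function(e) e$J))
  colnames(m) <- vapply(J_by_G, function(e) sprintf("G_%g", e$G), "")
  write.table(format(m, digits = 17, trim = TRUE), path, sep = ",",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a run configuration document
#'
#' A single JSON (or YAML, if the `yaml` package is available) document with
#' optional sections `dmf`, `hemodynamic`, `integration`, `observables`,
#' `turbulence` and `fit`, whose keys must match the arguments of the
#' corresponding constructors ([dmf_parameters()],
#' [hemodynamic_parameters()], [integration_config()],
#' [observables_config()], [turbulence_config()], [fit_config()]). Unknown
#' sections or keys are rejected. Every field is optional; omitted fields
#' take the documented defaults.
#'
#' @param path path to the configuration file.
#' @return An object of class `dmf_run_config`: the validated nested list.
#' @seealso [build_run_config()] to instantiate the configured objects.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configuration needs the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  ctors <- list(dmf = dmf_parameters, hemodynamic = hemodynamic_parameters,
                integration = integration_config,
                observables = observables_config,
                turbulence = turbulence_config, fit = fit_config)
  bad <- setdiff(names(cfg), names(ctors))
  if (length(bad) > 0)
    stop("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in names(cfg)) {
    unknown <- setdiff(names(cfg[[sec]]), names(formals(ctors[[sec]])))
    if (length(unknown) > 0)
      stop("unknown key(s) in section '", sec, "': ",
           paste(unknown, collapse = ", "))
  }
  structure(cfg, class = "dmf_run_config")
}

#' Instantiate the objects described by a run configuration
#'
#' @param cfg a [read_run_config()] result (or an equivalent nested list).
#' @param overrides named list of per-section overrides (e.g.
#'   `list(integration = list(seed = 7))`), taking precedence over the file.
#' @return List with `params`, `hemo`, `integration` (or `NULL` when no
#'   duration is configured), `observables`, `turbulence` and `fit`.
#' @export
build_run_config <- function(cfg = list(), overrides = list()) {
  merged <- function(sec) {
    out <- cfg[[sec]] %||% list()
    for (k in names(overrides[[sec]])) out[[k]] <- overrides[[sec]][[k]]
    out
  }
  int <- merged("integration")
  list(params = do.call(dmf_parameters, merged("dmf")),
       hemo = do.call(hemodynamic_parameters, merged("hemodynamic")),
       integration = if (is.null(int$duration)) NULL
                     else do.call(integration_config, int),
       observables = do.call(observables_config, merged("observables")),
       turbulence = do.call(turbulence_config, merged("turbulence")),
       fit = do.call(fit_config, merged("fit")))
}
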