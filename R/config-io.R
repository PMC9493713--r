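#' Read and write strike configurations and endocast definitions as JSON
#'
#' The JSON schema mirrors the constructor arguments one-to-one (see the
#' README for an annotated example); round-trips are lossless.
#'
#' @param config a [strike_profile_config].
#' @param path file path.
#' @export
write_strike_config_json <- function(config, path) {
  stopifnot(inherits(config, "strike_profile_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_strike_config_json
#' @export
read_strike_config_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  prey <- x$prey
  if (!is.null(prey)) prey <- as.list(prey)
  strike_profile_config(
    channels = lapply(x$channels, as.list),
    fps = x$fps, duration_ms = x$duration_ms, noise_sigma = x$noise_sigma,
    seed = x$seed, prey = prey, tongue_stretch = x$tongue_stretch)
}

#' @rdname write_strike_config_json
#' @param def an [endocast_definition].
#' @export
write_endocast_json <- function(def, path) {
  stopifnot(inherits(def, "endocast_definition"))
  jsonlite::write_json(list(locators = def$locators, alpha = def$alpha,
                            bilateral_factor = def$bilateral_factor),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_strike_config_json
#' @export
read_endocast_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  endocast_definition(as.data.frame(x$locators), alpha = x$alpha,
                      bilateral_factor = x$bilateral_factor)
}

#' Read and write rigid-body definitions as JSON
#'
#' Schema: an object mapping body name to `{markers: [...], reference:
#' [[x,y,z], ...]}` (reference rows correspond to markers, cm).
#'
#' @param defs named list of [rigid_body_def] objects.
#' @param path file path.
#' @export
write_bodies_json <- function(defs, path) {
  out <- lapply(defs, function(d)
    list(markers = d$markers,
         reference = unname(apply(d$reference, 1, function(r) r,
                                  simplify = FALSE))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bodies_json
#' @export
read_bodies_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list()
  for (nm in names(x))
    out[[nm]] <- rigid_body_def(nm, x[[nm]]$markers,
                                rbind3(x[[nm]]$reference))
  out
}

#' Write ground-truth poses as sidecar transform CSVs
#'
#' One file per body (named `<body>_truth.csv`), 16 columns per frame in the
#' row-vector, row-major dialect of [write_transforms_csv].
#'
#' @param truth a `strike_ground_truth` (from [simulate_strike]).
#' @param dir output directory (created if missing).
#' @return invisibly, the written paths.
#' @export
write_ground_truth_csv <- function(truth, dir) {
  stopifnot(inherits(truth, "strike_ground_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(truth$poses)) {
    p <- file.path(dir, paste0(nm, "_truth.csv"))
    write_transforms_csv(truth$poses[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
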