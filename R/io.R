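# Container I/O and configuration.
#
# Typed artifact objects (movies, banks, surfaces, batteries) are stored in
# a versioned container built on R native serialization; arrays round-trip
# bit-exactly and metadata exactly.

CONTAINER_SCHEMA <- "streakvision-1"

#' Write a typed object to a container file
#'
#' @param object any package object (movie, bank, surface, battery, ...).
#' @param path output file path.
#' @export
write_container <- function(object, path) {
  payload <- list(schema_version = CONTAINER_SCHEMA,
                  class = class(object),
                  package_version = as.character(utils::packageVersion("streakvision")),
                  object = object)
  saveRDS(payload, path)
  invisible(path)
}

#' Read a typed object from a container file
#'
#' @param path container file path.
#' @return the stored object, with its class restored.
#' @export
read_container <- function(path) {
  payload <- readRDS(path)
  if (!is.list(payload) || !identical(payload$schema_version, CONTAINER_SCHEMA))
    stop_param("container schema mismatch: expected '", CONTAINER_SCHEMA,
               "', found '", payload$schema_version %||% "<missing>", "'")
  payload$object
}

#' Assemble a run configuration
#'
#' @param stimulus,saccade,canvas,bank,trf,normalization,switch named lists
#'   of overrides for the corresponding module defaults.
#' @param seed integer seed.
#' @param scale_mode `"full"` or `"test"`.
#' @export
run_config <- function(stimulus = list(), saccade = list(), canvas = list(),
                       bank = list(), trf = list(), normalization = list(),
                       switch = list(), seed = 1L,
                       scale_mode = c("test", "full")) {
  scale_mode <- match.arg(scale_mode)
  structure(list(stimulus = stimulus, saccade = saccade, canvas = canvas,
                 bank = bank, trf = trf, normalization = normalization,
                 switch = switch, seed = as.integer(seed),
                 scale_mode = scale_mode),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Sections mirror [run_config()] arguments.
#'
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_param("the 'yaml' package is required to read configuration files")
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg[intersect(names(cfg), names(formals(run_config)))])
}

#' Export a battery's engagement tables as CSV
#'
#' Long-format table (theta, omega, trial, direction, streak, power).
#'
#' @param battery a `switch_battery`.
#' @param path output CSV path.
#' @export
write_engagement_csv <- function(battery, path) {
  d <- dim(battery$engagement)
  grid <- expand.grid(theta = battery$bank_spec$sf_set,
                      omega = battery$bank_spec$ori_set,
                      trial = seq_len(d[3]))
  grid$power <- as.vector(battery$engagement)
  grid$direction <- battery$table$direction[grid$trial]
  grid$streak <- battery$table$streak[grid$trial]
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

#' Export a battery's switch-time table as CSV
#'
#' @param battery a `switch_battery`.
#' @param path output CSV path.
#' @export
write_switch_csv <- function(battery, path) {
  tab <- battery$table
  tab$wi <- battery$contingency$wi
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
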