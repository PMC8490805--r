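# Observation series, CSV readers/writers and the YAML run configuration.

#' Time-stamped observation series
#'
#' @param times Strictly increasing observation instants (minutes); spacing
#'   need not be equal.
#' @param values Numeric matrix (length(times) x p) of observed node counts,
#'   or a vector for p = 1.
#' @param channels Optional channel names (column order preserved).
#' @return An `observation_series`.
#' @export
observation_series <- function(times, values, channels = NULL) {
  times <- as.numeric(times)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (is.null(dim(values))) values <- matrix(as.numeric(values), ncol = 1)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(times)) stop("values and times lengths differ")
  if (any(!is.finite(values))) stop("observations must be finite")
  if (!is.null(channels)) {
    if (length(channels) != ncol(values)) stop("channel count mismatch")
    colnames(values) <- channels
  } else if (is.null(colnames(values))) {
    colnames(values) <- paste0("z", seq_len(ncol(values)))
  }
  structure(list(times = times, values = values,
                 channels = colnames(values)),
            class = "observation_series")
}

#' Read an observation series from CSV
#'
#' Expects a header `time_min` followed by one column per observed channel;
#' times must be strictly increasing.
#'
#' @param path CSV file path.
#' @return An [observation_series()].
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!("time_min" %in% names(df))) stop("missing 'time_min' column")
  if (ncol(df) < 2L) stop("no observation channels in file")
  for (nm in names(df))
    if (!is.numeric(df[[nm]]))
      stop(sprintf("non-numeric cells in column '%s'", nm))
  tm <- df$time_min
  bad <- which(diff(tm) <= 0)
  if (length(bad))
    stop(sprintf("times not strictly increasing at row %d", bad[1] + 1L))
  observation_series(tm, as.matrix(df[setdiff(names(df), "time_min")]))
}

#' Write an observation series to CSV
#'
#' Writes full double precision (`%.17g`), so a read/write round trip is
#' numerically exact, and embeds no timestamps, so output bytes are
#' deterministic for fixed input.
#'
#' @param series An [observation_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(series, path) {
  stopifnot(inherits(series, "observation_series"))
  header <- paste(c("time_min", series$channels), collapse = ",")
  rows <- if (length(series$times) == 0L) character(0) else
    apply(cbind(series$times, series$values), 1L, function(rr)
      paste(sprintf("%.17g", rr), collapse = ","))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write an order log to CSV
#'
#' @param log An `order_log` from [simulate_porter_day()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_order_log <- function(log, path) {
  num <- vapply(log, is.numeric, logical(1))
  out <- log
  for (nm in names(out)[num & names(out) != "order_id" & names(out) != "porter_id"])
    out[[nm]] <- sprintf("%.17g", out[[nm]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

config_defaults <- function() {
  list(
    observation = list(nodes = NULL, noise_sd = 1),
    filter = list(sigma0 = 10),
    estimator = list(a = 0.1, p0 = 1e4, refresh = TRUE, burn_in_epochs = 60,
                     cadence = 30),
    synthetic = list(kind = "sde", q_process = 0.01, duration_min = 480,
                     dt_min = 1, u = NULL, eta0 = NULL,
                     porter = list(n_porters = 80, daily_orders = 1000,
                                   peak_multiplier = 2, night = 0.25,
                                   sla_minutes = 20, n_days = 1,
                                   stage_composition = "sequential",
                                   preset = "default")),
    output_dir = ".", log_level = "info")
}

# Fail-closed merge: every key in `given` must exist in `defaults`.
merge_config <- function(defaults, given, path = "") {
  if (is.null(given)) return(defaults)
  if (!is.list(defaults)) return(given)
  extra <- setdiff(names(given), names(defaults))
  if (length(extra))
    stop(sprintf("unknown config key '%s%s'", path, extra[1]), call. = FALSE)
  for (nm in names(given)) {
    sub <- if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])))
      merge_config(defaults[[nm]], given[[nm]], paste0(path, nm, "."))
    else given[[nm]]
    defaults[[nm]] <- sub
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML document with sections `network` (path to a rule-DSL file,
#' relative to the config file) or `rules` (inline rule text), `rates`
#' (named nominal per-minute rate constants), `seed`, and optional
#' `observation`, `filter`, `estimator`, `synthetic`, `output_dir`,
#' `log_level` sections.  Unknown keys are rejected; observed node names and
#' rate names are resolved against the parsed network; defaults
#' (`a = 0.1`, `p0 = 1e4`, `sigma0 = 10`) fill unspecified fields.
#'
#' @param path Path to the YAML config file.
#' @return A `run_config`: the merged config list plus `net` (the parsed
#'   `flow_network`), `k` (a [rate_parameters()]), and `om` (an
#'   [observation_model()], when observed nodes are configured).
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  top_known <- c("network", "rules", "rates", "seed", "observation", "filter",
                 "estimator", "synthetic", "output_dir", "log_level")
  extra <- setdiff(names(raw), top_known)
  if (length(extra)) stop(sprintf("unknown config key '%s'", extra[1]))
  if (is.null(raw$network) && is.null(raw$rules))
    stop("config must give 'network' (file path) or 'rules' (inline)")
  if (is.null(raw$seed)) stop("config must give 'seed'")
  seed <- raw$seed
  if (!is.numeric(seed) || seed != round(seed) || seed < 0)
    stop("seed must be a nonnegative integer")

  rules_text <- if (!is.null(raw$rules)) raw$rules else {
    npath <- raw$network
    if (!file.exists(npath))
      npath <- file.path(dirname(path), raw$network)
    if (!file.exists(npath)) stop(sprintf("network file '%s' not found", raw$network))
    paste(readLines(npath), collapse = "\n")
  }
  net <- parse_rule_file(rules_text)

  cfg <- merge_config(config_defaults(),
                      raw[intersect(names(raw), c("observation", "filter",
                                                  "estimator", "synthetic",
                                                  "output_dir", "log_level"))])
  cfg$seed <- as.integer(seed)
  cfg$network <- raw$network
  cfg$rules <- rules_text
  cfg$rates_raw <- raw$rates

  k <- NULL
  if (!is.null(raw$rates)) {
    kv <- unlist(raw$rates)
    bad <- setdiff(names(kv), net$rate_names)
    if (length(bad)) stop(sprintf("rate '%s' not declared in the network", bad[1]))
    if (!setequal(names(kv), net$rate_names))
      stop("rates must cover every declared rate constant")
    k <- rate_parameters(kv, net)
  }

  om <- NULL
  if (!is.null(cfg$observation$nodes)) {
    nodes <- cfg$observation$nodes
    bad <- setdiff(nodes, net$species)
    if (length(bad))
      stop(sprintf("observed node '%s' not declared in the network", bad[1]))
    H <- matrix(0, length(nodes), length(net$species),
                dimnames = list(nodes, net$species))
    H[cbind(seq_along(nodes), match(nodes, net$species))] <- 1
    om <- observation_model(H, rep_len(cfg$observation$noise_sd^2,
                                       length(nodes)))
  }
  structure(c(cfg, list(net = net, k = k, om = om)), class = "run_config")
}

#' Dump a run configuration back to YAML
#'
#' Writes the resolved configuration (with defaults filled in) such that
#' [load_config()] on the result reproduces an equal `run_config`.
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- list(rules = cfg$rules, seed = cfg$seed, rates = cfg$rates_raw,
              observation = cfg$observation, filter = cfg$filter,
              estimator = cfg$estimator, synthetic = cfg$synthetic,
              output_dir = cfg$output_dir, log_level = cfg$log_level)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Derive a component-specific seed from the run seed
#'
#' One run seed governs all randomness; per-component sub-streams are derived
#' deterministically so component-level reruns match full-run results.
#'
#' @param seed Nonnegative integer run seed.
#' @param component Character tag of the component.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, component) {
  h <- 2166136261
  for (b in utf8ToInt(component)) h <- ((h * 16777619) + b) %% 2147483647
  as.integer((seed + h) %% 2147483647)
}
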