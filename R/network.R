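#' Flow networks from transfer rules
#'
#' A flow network describes how items (patients, orders, materials) move
#' between labelled nodes of a hospital process.  Each transfer rule consumes
#' integer multiples of some species and produces integer multiples of others
#' at a first-order rate \eqn{v_j = k_j \eta_{d(j)}}, where \eqn{d(j)} is the
#' rule's single unit-coefficient driver species.  Rules with an empty input
#' side model exogenous arrivals and must name an input channel; their flow is
#' \eqn{v_j = k_j u_m(t)}.
#'
#' @name flow_network
#' @keywords internal
NULL

SPECIES_RE <- "^[A-Za-z_][A-Za-z0-9_.]*$"

new_flow_network <- function(species, rules, rate_names, input_channels) {
  structure(
    list(species = species, rules = rules, rate_names = rate_names,
         input_channels = input_channels),
    class = "flow_network")
}

#' Parse a rule-DSL document into a flow network
#'
#' One rule per line:
#' `[coef] SPECIES {+ [coef] SPECIES} -> [coef] SPECIES {+ ...} @ RATE [channel]`.
#' `0` denotes an empty side, `#` starts a comment, an omitted coefficient is 1.
#' Species and rate registries are built in order of first appearance.
#'
#' @param text Character scalar (possibly multi-line) or character vector of
#'   lines holding the rule document.
#' @param linear If `TRUE` (default) enforce the linear-model restriction:
#'   every non-source rule has exactly one input species with coefficient 1.
#' @return A `flow_network` with fields `species`, `rules`, `rate_names` and
#'   `input_channels`.
#' @examples
#' net <- parse_rule_file("WAIT -> TRANSIT @ k1")
#' net$species
#' @export
parse_rule_file <- function(text, linear = TRUE) {
  stopifnot(is.character(text))
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines_clean <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines_clean)))
  if (length(keep) == 0L) stop("no rules in input")

  species <- character(0)
  rate_names <- character(0)
  channels <- character(0)
  rules <- list()

  reg_species <- function(nm) {
    if (!(nm %in% species)) species <<- c(species, nm)
    nm
  }

  for (ln in keep) {
    raw <- trimws(lines_clean[ln])
    err <- function(msg) stop(sprintf("line %d: %s", ln, msg), call. = FALSE)

    halves <- strsplit(raw, "->", fixed = TRUE)[[1]]
    if (length(halves) != 2L) err("expected exactly one '->'")
    rhs_rate <- strsplit(halves[2], "@", fixed = TRUE)[[1]]
    if (length(rhs_rate) != 2L) err("expected exactly one '@ RATE'")

    rate_part <- trimws(rhs_rate[2])
    channel <- NA_character_
    chan_m <- regmatches(rate_part, regexec("^(\\S+)\\s*\\[([^]]+)\\]$", rate_part))[[1]]
    if (length(chan_m) == 3L) {
      rate_part <- chan_m[2]
      channel <- trimws(chan_m[3])
    }
    if (!grepl(SPECIES_RE, rate_part)) err(sprintf("invalid rate name '%s'", rate_part))
    if (rate_part %in% rate_names) err(sprintf("duplicate rate name '%s'", rate_part))

    parse_side <- function(side) {
      side <- trimws(side)
      if (side == "0") return(stats::setNames(integer(0), character(0)))
      terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
      out <- integer(0)
      for (tm in terms) {
        if (!nzchar(tm)) err("empty term")
        m <- regmatches(tm, regexec("^([0-9]+)?\\s*(\\S+)$", tm))[[1]]
        if (length(m) != 3L) err(sprintf("cannot parse term '%s'", tm))
        coef <- if (nzchar(m[2])) as.integer(m[2]) else 1L
        nm <- m[3]
        if (!grepl(SPECIES_RE, nm)) err(sprintf("invalid species name '%s'", nm))
        reg_species(nm)
        out[nm] <- (if (nm %in% names(out)) out[[nm]] else 0L) + coef
      }
      out
    }

    inputs <- parse_side(halves[1])
    outputs <- parse_side(rhs_rate[1])
    if (length(inputs) == 0L && length(outputs) == 0L) err("rule with both sides empty")

    if (length(inputs) == 0L) {
      if (is.na(channel))
        err("source rule (empty input side) must name an input channel in [...]")
      driver <- channel
      driver_kind <- "channel"
      if (!(channel %in% channels)) channels <- c(channels, channel)
    } else {
      if (!is.na(channel))
        err("input channel allowed only on source rules")
      if (linear) {
        if (length(inputs) != 1L || inputs[[1]] != 1L)
          err("linear mode requires exactly one input species with coefficient 1")
      }
      driver <- names(inputs)[which.max(inputs > 0)]
      driver_kind <- "species"
    }

    rate_names <- c(rate_names, rate_part)
    rules[[length(rules) + 1L]] <- list(
      inputs = inputs, outputs = outputs, rate_name = rate_part,
      driver = driver, driver_kind = driver_kind)
  }

  new_flow_network(species, rules, rate_names, channels)
}

#' Serialize a flow network back to rule-DSL text
#'
#' Inverse of [parse_rule_file()]: `parse_rule_file(serialize_rules(net))`
#' reproduces `net` exactly.
#'
#' @param net A `flow_network`.
#' @return Character scalar holding one rule per line.
#' @export
serialize_rules <- function(net) {
  stopifnot(inherits(net, "flow_network"))
  fmt_side <- function(side) {
    if (length(side) == 0L) return("0")
    paste(vapply(names(side), function(nm) {
      if (side[[nm]] == 1L) nm else paste(side[[nm]], nm)
    }, character(1)), collapse = " + ")
  }
  paste(vapply(net$rules, function(r) {
    line <- sprintf("%s -> %s @ %s", fmt_side(r$inputs), fmt_side(r$outputs),
                    r$rate_name)
    if (r$driver_kind == "channel") line <- sprintf("%s [%s]", line, r$driver)
    line
  }, character(1)), collapse = "\n")
}

#' Rate parameters aligned with a network
#'
#' @param values Numeric vector of nonnegative per-minute rates, one per rule.
#' @param net A `flow_network` the values align with (order of
#'   `net$rate_names`); a named `values` vector is reordered to match.
#' @return A `rate_parameters` object with fields `values`, `nominal`, `names`.
#' @export
rate_parameters <- function(values, net) {
  stopifnot(inherits(net, "flow_network"))
  r <- length(net$rate_names)
  if (!is.null(names(values))) {
    if (!setequal(names(values), net$rate_names))
      stop("rate names do not match the network")
    values <- values[net$rate_names]
  }
  if (length(values) != r) stop(sprintf("expected %d rates, got %d", r, length(values)))
  if (any(!is.finite(values)) || any(values < 0)) stop("rates must be finite and >= 0")
  structure(list(values = as.numeric(values), nominal = as.numeric(values),
                 names = net$rate_names),
            class = "rate_parameters")
}

as_rate_values <- function(k, net) {
  if (inherits(k, "rate_parameters")) k$values
  else rate_parameters(k, net)$values
}

#' Compile a flow network into linear dynamics
#'
#' Builds the system matrix `A(k)` and input matrix `B(k)` of the linear
#' compartmental model \eqn{d\eta/dt = A(k)\eta + B(k)u(t)}.  Each non-source
#' rule `j` with driver species `d(j)` contributes `k_j (b_ij - a_ij)` to
#' `A[i, d(j)]` for every species `i`; each source rule contributes
#' `k_j b_ij` to `B[i, m(j)]` for its input channel `m(j)`.
#'
#' @param net A `flow_network`.
#' @param k Rate parameters ([rate_parameters()] or a numeric vector).
#' @param G Noise-injection matrix (default: identity on the state rows).
#' @param Q Symmetric positive semi-definite noise-intensity matrix
#'   (default: `diag(q_default, N)`).
#' @param q_default Diagonal value used when `Q` is not supplied.
#' @return A `linear_dynamics` object with fields `A`, `B`, `G`, `Q`,
#'   `state_labels` and `input_labels`.
#' @export
build_system_matrices <- function(net, k, G = NULL, Q = NULL, q_default = 1e-2) {
  stopifnot(inherits(net, "flow_network"))
  kv <- as_rate_values(k, net)
  N <- length(net$species)
  m <- length(net$input_channels)
  A <- matrix(0, N, N, dimnames = list(net$species, net$species))
  B <- matrix(0, N, max(m, 0L), dimnames = list(net$species, net$input_channels))
  for (j in seq_along(net$rules)) {
    r <- net$rules[[j]]
    contrib <- rule_contribution(net, j)
    A <- A + kv[j] * contrib$dA
    if (m > 0L) B <- B + kv[j] * contrib$dB
  }
  if (is.null(G)) G <- diag(1, N)
  if (is.null(Q)) Q <- diag(q_default, ncol(G))
  linear_dynamics(A, B, G, Q, state_labels = net$species,
                  input_labels = net$input_channels)
}

# Per-rule contribution with the rate set to 1 (A and B are linear in k).
rule_contribution <- function(net, j) {
  N <- length(net$species)
  m <- length(net$input_channels)
  r <- net$rules[[j]]
  dA <- matrix(0, N, N, dimnames = list(net$species, net$species))
  dB <- matrix(0, N, max(m, 0L), dimnames = list(net$species, net$input_channels))
  a <- stats::setNames(numeric(N), net$species)
  b <- stats::setNames(numeric(N), net$species)
  a[names(r$inputs)] <- r$inputs
  b[names(r$outputs)] <- r$outputs
  if (r$driver_kind == "species") {
    dA[, r$driver] <- dA[, r$driver] + (b - a)
  } else {
    dB[, r$driver] <- dB[, r$driver] + b
  }
  list(dA = dA, dB = dB)
}

#' Per-parameter derivatives of the system matrices
#'
#' `A(k)` and `B(k)` are linear and homogeneous in `k`, so each derivative
#' pair is constant in `k` and equals rule `j`'s contribution with `k_j = 1`;
#' consequently `sum_j k_j dA_j = A(k)`.
#'
#' @inheritParams build_system_matrices
#' @return List of length `r`; element `j` has fields `dA` (N x N) and
#'   `dB` (N x m).
#' @export
rate_jacobians <- function(net, k = NULL) {
  stopifnot(inherits(net, "flow_network"))
  if (!is.null(k)) as_rate_values(k, net)  # validates alignment only
  lapply(seq_along(net$rules), function(j) rule_contribution(net, j))
}

#' Structural diagnostics for a flow network
#'
#' Reports, without mutating the network: species unreachable from the
#' network's roots (source-rule outputs plus driver species never produced by
#' any rule), absorbing species (no outgoing rule), whether every rule
#' conserves unit counts, and linear-mode violations.
#'
#' @param net A `flow_network`.
#' @return A `network_diagnostics` list with fields `unreachable`,
#'   `absorbing`, `conserving`, `linear_violations`.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "flow_network"))
  produced <- unique(unlist(lapply(net$rules, function(r) names(r$outputs))))
  roots <- character(0)
  for (r in net$rules) {
    if (r$driver_kind == "channel") roots <- union(roots, names(r$outputs))
    else if (!(r$driver %in% produced)) roots <- union(roots, r$driver)
  }
  reach <- roots
  repeat {
    nxt <- reach
    for (r in net$rules) {
      if (r$driver_kind == "species" && r$driver %in% reach)
        nxt <- union(nxt, names(r$outputs))
    }
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  drivers <- vapply(net$rules, function(r)
    if (r$driver_kind == "species") r$driver else NA_character_, character(1))
  absorbing <- setdiff(net$species, drivers[!is.na(drivers)])
  conserving <- all(vapply(net$rules, function(r)
    sum(r$inputs) == sum(r$outputs), logical(1)))
  lin_viol <- vapply(net$rules, function(r)
    r$driver_kind == "species" &&
      (length(r$inputs) != 1L || r$inputs[[1]] != 1L), logical(1))
  structure(list(
    unreachable = setdiff(net$species, reach),
    absorbing = absorbing,
    conserving = conserving,
    linear_violations = which(lin_viol)
  ), class = "network_diagnostics")
}

#' @export
print.flow_network <- function(x, ...) {
  cat(sprintf("flow_network: %d species, %d rules, %d input channel(s)\n",
              length(x$species), length(x$rules), length(x$input_channels)))
  cat(serialize_rules(x), "\n")
  invisible(x)
}

#' @export
print.network_diagnostics <- function(x, ...) {
  cat("network diagnostics\n")
  cat("  unreachable:", if (length(x$unreachable)) paste(x$unreachable, collapse = ", ") else "none", "\n")
  cat("  absorbing:  ", if (length(x$absorbing)) paste(x$absorbing, collapse = ", ") else "none", "\n")
  cat("  conserving: ", x$conserving, "\n")
  cat("  linear-mode violations:",
      if (length(x$linear_violations)) paste(x$linear_violations, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Construct a linear dynamics object
#'
#' Container for the matrices of a linear stochastic system
#' \eqn{dx = A x\,dt + B u\,dt + G\,dw}, with `w` a Wiener process of
#' intensity `Q`.
#'
#' @param A System matrix (n x n).
#' @param B Input matrix (n x m); may have zero columns.
#' @param G Noise-injection matrix (n x q); default identity.
#' @param Q Symmetric PSD noise-intensity matrix (q x q); default zero.
#' @param state_labels,input_labels Optional character labels.
#' @return A `linear_dynamics` object.
#' @export
linear_dynamics <- function(A, B = NULL, G = NULL, Q = NULL,
                            state_labels = NULL, input_labels = NULL) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (ncol(A) != n) stop("A must be square")
  if (is.null(B)) B <- matrix(0, n, 0)
  B <- as.matrix(B)
  if (nrow(B) != n) stop("B must have as many rows as A")
  if (is.null(G)) G <- diag(1, n)
  G <- as.matrix(G)
  if (nrow(G) != n) stop("G must have as many rows as A")
  if (is.null(Q)) Q <- matrix(0, ncol(G), ncol(G))
  Q <- as.matrix(Q)
  if (nrow(Q) != ncol(G) || ncol(Q) != ncol(G)) stop("Q must be q x q with q = ncol(G)")
  if (max(abs(Q - t(Q))) > 1e-10) stop("Q must be symmetric")
  if (min(eigen((Q + t(Q)) / 2, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("Q must be positive semi-definite")
  structure(list(A = A, B = B, G = G, Q = (Q + t(Q)) / 2,
                 state_labels = state_labels %||% rownames(A),
                 input_labels = input_labels %||% colnames(B)),
            class = "linear_dynamics")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
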