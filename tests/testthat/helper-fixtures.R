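# Shared fixtures: small flow networks and an independent Runge-Kutta oracle.

tandem_rules <- function() {
  paste("# arrivals enter the waiting node, move to transit, then leave",
        "0 -> WAIT @ k0 [u_arrivals]",
        "WAIT -> TRANSIT @ k1",
        "TRANSIT -> 0 @ k2",
        sep = "\n")
}

make_tandem <- function() parse_rule_file(tandem_rules())

make_decay <- function() parse_rule_file("WAIT -> TRANSIT @ k1")

# closed chain: every rule moves one unit, so totals are conserved
make_ring <- function() {
  parse_rule_file("A -> B @ k1\nB -> C @ k2\nC -> A @ k3")
}

tandem_k <- function() c(k0 = 1, k1 = 0.2, k2 = 0.1)

# step-profile arrival intensity: persistently exciting input signal
step_input <- function(t) 2 + 2 * (t %% 240 >= 60 & t %% 240 < 180)

# fixed-step classical RK4 integrator, independent of the package's
# matrix-exponential stepping
rk4_oracle <- function(A, B, u, x0, times, substeps = 200) {
  uf <- if (is.null(u)) function(t) numeric(ncol(B)) else
    if (is.function(u)) u else function(t) u
  f <- function(t, x) as.numeric(A %*% x) +
    (if (ncol(B) > 0) as.numeric(B %*% uf(t)) else 0)
  out <- matrix(NA_real_, length(times), length(x0))
  x <- as.numeric(x0)
  out[1, ] <- x
  for (i in seq_len(length(times) - 1L)) {
    h <- (times[i + 1] - times[i]) / substeps
    t <- times[i]
    for (s in seq_len(substeps)) {
      k1 <- f(t, x); k2 <- f(t + h / 2, x + h / 2 * k1)
      k3 <- f(t + h / 2, x + h / 2 * k2); k4 <- f(t + h, x + h * k3)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[i + 1, ] <- x
  }
  out
}

random_stable_network <- function(n_species, seed) {
  set.seed(seed)
  sp <- LETTERS[seq_len(n_species)]
  lines <- character(0)
  ki <- 0
  for (i in seq_len(n_species)) {
    j <- sample(setdiff(seq_len(n_species), i), 1)
    ki <- ki + 1
    lines <- c(lines, sprintf("%s -> %s @ k%d", sp[i], sp[j], ki))
  }
  ki <- ki + 1
  lines <- c(lines, sprintf("%s -> 0 @ k%d", sp[1], ki))  # leak keeps A stable
  list(net = parse_rule_file(paste(lines, collapse = "\n")),
       k = stats::setNames(runif(ki, 0.05, 0.5), paste0("k", seq_len(ki))))
}
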