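# Shared fixtures built in code: the worked 3-element example and seeded
# random instances for property-style tests.

tiny_instance <- function() {
  ids <- c("a", "b", "c")
  S <- matrix(c(1, 0.5, 0.2,
                0.5, 1, 0.1,
                0.2, 0.1, 1), 3, 3, dimnames = list(ids, ids))
  split_instance(tibble::tibble(id = ids), S)
}

# random unit-weight instance with uniform similarities (and optional
# two-class labels) for oracle-equivalence and invariance sweeps
random_instance <- function(n, seed, with_classes = FALSE) {
  withr::with_seed(seed, {
    ids <- paste0("x", sprintf("%02d", seq_len(n)))
    S <- matrix(0, n, n, dimnames = list(ids, ids))
    S[upper.tri(S)] <- round(runif(n * (n - 1) / 2), 3)
    S <- S + t(S)
    diag(S) <- 1
    items <- tibble::tibble(id = ids)
    if (with_classes) items$classes <- sample(c("A", "B"), n, replace = TRUE)
    split_instance(items, S)
  })
}

random_specs_grid <- function(n_cases, seed) {
  withr::with_seed(seed, {
    g <- tibble::tibble(
      case = seq_len(n_cases),
      n = sample(4:10, n_cases, replace = TRUE),
      k = sample(2:3, n_cases, replace = TRUE, prob = c(0.7, 0.3)),
      epsilon = sample(c(0, 0.1, 0.34), n_cases, replace = TRUE),
      with_classes = sample(c(TRUE, FALSE), n_cases, replace = TRUE)
    )
    # exact fractions (epsilon 0) need n divisible by k to be satisfiable
    g$n <- ifelse(g$epsilon == 0, pmax(g$k * (g$n %/% g$k), 2 * g$k), g$n)
    g
  })
}

spec_for_case <- function(k, epsilon) {
  # exact k=3 fractions must divide integer masses, so epsilon 0 uses thirds
  fr <- if (k == 2) c(0.5, 0.5)
        else if (epsilon == 0) rep(1 / 3, 3)
        else c(0.4, 0.3, 0.3)
  split_spec(fractions = fr, epsilon = epsilon, delta = max(epsilon, 0.34))
}

# path graph a-b-c-d as a splitting instance
path4_instance <- function() {
  make_graph_instance(cbind(c("a", "b", "c"), c("b", "c", "d")))
}
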