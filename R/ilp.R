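#' Build the integer linear program for a splitting problem
#'
#' Encodes the leakage-minimizing split as a 0/1 ILP. Binary assignment
#' variables `xi[x, i]` place element x in fold i; binary cut variables
#' `zeta[x, x']` (one per unordered same-type pair with positive similarity
#' weight) indicate that a pair is separated. The objective sums
#' `sim(x, x') * kappa(x) * kappa(x') * zeta[x, x']`; constraints are
#' one-fold-per-element rows, per-(fold, type) fraction lower bounds, per
#' (fold, type, class) stratification lower bounds (only when class
#' information exists), and the linearization
#' `zeta[x, x'] >= xi[x, i] - xi[x', i]` for every fold, which forces the cut
#' variable to 1 exactly when the pair is separated (minimization pushes it
#' back to 0 otherwise). Zero-weight pairs need no cut variable: they cannot
#' contribute to the objective.
#'
#' @param instance A [split_instance()].
#' @param spec A [split_spec()].
#' @return An `ilp_model`: objective vector, sparse constraint triplets with
#'   row bounds, and the variable bookkeeping needed to decode a solution.
#' @export
build_ilp <- function(instance, spec) {
  items <- instance$items
  ids <- items$id
  n <- length(ids)
  k <- spec$k
  w <- inst_weights(instance)

  # assignment variable index: x-major, fold-minor
  xi_idx <- function(x, i) (x - 1L) * k + i

  # positive-weight same-type pairs
  pairs <- list()
  for (ty in inst_types(instance)) {
    tids <- inst_ids(instance, ty)
    if (length(tids) < 2) next
    S <- similarity_matrix(instance, ty)
    cmb <- combn(tids, 2)
    wts <- S[cbind(cmb[1, ], cmb[2, ])] * w[cmb[1, ]] * w[cmb[2, ]]
    keep <- wts > 0
    if (any(keep)) {
      pairs[[as.character(ty)]] <- tibble(
        x = cmb[1, keep], xp = cmb[2, keep], weight = unname(wts[keep]))
    }
  }
  pairs <- if (length(pairs) > 0) bind_rows(pairs) else
    tibble(x = character(), xp = character(), weight = numeric())
  n_cut <- nrow(pairs)
  n_assign <- n * k
  nvar <- n_assign + n_cut
  obj <- c(rep(0, n_assign), pairs$weight)

  rows <- new_row_builder()
  # one fold per element
  for (x in seq_len(n)) {
    rows$add(cols = xi_idx(x, seq_len(k)), vals = rep(1, k), lb = 1, ub = 1,
             label = paste0("assign:", ids[x]))
  }
  # fraction bounds per (fold, type)
  tm <- type_mass(instance)
  for (r in seq_len(nrow(tm))) {
    ty <- tm$entity_type[r]
    xs <- which(items$entity_type == ty)
    for (i in seq_len(k)) {
      bound <- (1 - spec$epsilon) * spec$fractions[i] * tm$n_r[r]
      rows$add(cols = xi_idx(xs, i), vals = w[ids[xs]], lb = bound, ub = Inf,
               label = paste0("fraction:fold", i, ":type", ty))
    }
  }
  # stratification bounds per (fold, type, class), only with real classes
  totals <- class_mass_totals(instance)
  if (nrow(totals) > 0) {
    cm <- instance$class_mass
    for (r in seq_len(nrow(totals))) {
      ty <- totals$entity_type[r]; cl <- totals$class[r]
      sub <- cm[cm$class == cl & cm$id %in% inst_ids(instance, ty), ]
      xs <- match(sub$id, ids)
      for (i in seq_len(k)) {
        bound <- (1 - spec$delta) * spec$fractions[i] * totals$n_rc[r]
        rows$add(cols = xi_idx(xs, i), vals = sub$mass, lb = bound, ub = Inf,
                 label = paste0("class:fold", i, ":type", ty, ":", cl))
      }
    }
  }
  # cut linearization
  if (n_cut > 0) {
    xi_x <- match(pairs$x, ids); xi_xp <- match(pairs$xp, ids)
    for (p in seq_len(n_cut)) {
      zcol <- n_assign + p
      for (i in seq_len(k)) {
        rows$add(cols = c(xi_idx(xi_x[p], i), xi_idx(xi_xp[p], i), zcol),
                 vals = c(1, -1, -1), lb = -Inf, ub = 0,
                 label = paste0("cut:", pairs$x[p], ":", pairs$xp[p], ":fold", i))
      }
    }
  }
  built <- rows$build()
  structure(
    list(obj = obj, nvar = nvar, n_assign = n_assign, n_cut = n_cut,
         a_row = built$row, a_col = built$col, a_val = built$val,
         row_lb = built$lb, row_ub = built$ub, row_label = built$label,
         nrow = built$nrow, ids = ids, k = k, pairs = pairs,
         time_limit = spec$solver_time_limit_s),
    class = "ilp_model"
  )
}

new_row_builder <- function() {
  rows <- list(); lbs <- numeric(); ubs <- numeric(); labels <- character()
  add <- function(cols, vals, lb, ub, label = "") {
    rows[[length(rows) + 1L]] <<- list(cols = as.integer(cols), vals = as.numeric(vals))
    lbs <<- c(lbs, lb); ubs <<- c(ubs, ub); labels <<- c(labels, label)
  }
  build <- function() {
    lens <- map_int(rows, ~ length(.x$cols))
    list(row = rep(seq_along(rows), lens),
         col = unlist(map(rows, "cols"), use.names = FALSE),
         val = unlist(map(rows, "vals"), use.names = FALSE),
         lb = lbs, ub = ubs, label = labels, nrow = length(rows))
  }
  list(add = add, build = build)
}

#' Available mixed-integer solver backends
#'
#' `"highs"` solves through the HiGHS solver in SciPy's `milp`, invoked via
#' the system `python` (the default); `"enumeration"` is the exact
#' brute-force path of [brute_force_optimum()], usable only on small
#' instances.
#'
#' @return Character vector of backend names usable with [solve_split()].
#' @export
milp_backends <- function() {
  av <- character()
  ok <- tryCatch({
    find_python(); TRUE
  }, error = function(e) FALSE)
  if (ok) av <- c(av, "highs")
  c(av, "enumeration")
}

#' Solve a splitting problem to optimality
#'
#' Builds the ILP with [build_ilp()] and solves it with the requested
#' backend. On success the decoded partition is verified: its recomputed
#' leakage must match the solver objective to `1e-6` and its constraint
#' report must be feasible.
#'
#' @param instance A [split_instance()].
#' @param spec A [split_spec()]; `solver_time_limit_s` caps the solver.
#' @param backend One of [milp_backends()].
#' @return A `split_solution`: list with `partition` ([fold_partition()] or
#'   `NULL`), `status` (`"optimal"`, `"feasible-time-limit"` or
#'   `"infeasible"`), `objective`, `solver_name`, `wall_limit_s` and
#'   `message`.
#' @export
#' @examples
#' \dontrun{
#' inst <- make_block_instance(block_sizes = c(3, 3))
#' sol <- solve_split(inst, split_spec(fractions = c(0.5, 0.5), epsilon = 0.2))
#' sol$objective
#' }
solve_split <- function(instance, spec, backend = "highs") {
  res <- solve_split_batch(list(instance), list(spec), backend = backend)
  res[[1]]
}

#' Solve many splitting problems in one backend call
#'
#' Identical to [solve_split()] applied elementwise, but all models are
#' serialized and solved in a single solver-process invocation, which
#' matters when benchmarking hundreds of small instances.
#'
#' @param instances List of [split_instance()] objects.
#' @param specs List of [split_spec()] objects (recycled if length 1).
#' @param backend One of [milp_backends()].
#' @return List of `split_solution` objects.
#' @export
solve_split_batch <- function(instances, specs, backend = "highs") {
  if (!backend %in% milp_backends()) {
    abort(paste0("backend '", backend, "' unavailable; available: ",
                 paste(milp_backends(), collapse = ", ")))
  }
  if (length(specs) == 1 && length(instances) > 1) {
    specs <- rep(specs, length(instances))
  }
  stopifnot(length(instances) == length(specs))
  if (backend == "enumeration") {
    return(map2(instances, specs, function(inst, sp) {
      brute_force_optimum(inst, sp, max_elements = 16L)
    }))
  }
  models <- map2(instances, specs, build_ilp)
  payload <- list(models = map(models, function(m) {
    list(obj = m$obj, nvar = m$nvar, nrow = m$nrow,
         a_row = m$a_row, a_col = m$a_col, a_val = m$a_val,
         row_lb = clamp_inf(m$row_lb), row_ub = clamp_inf(m$row_ub),
         time_limit = m$time_limit)
  }))
  raw <- run_python_helper("milp_solve.py", payload)
  purrr::pmap(list(raw, models, instances, specs), decode_solution)
}

clamp_inf <- function(x) {
  x[x == Inf] <- 1e30
  x[x == -Inf] <- -1e30
  x
}

decode_solution <- function(r, model, instance, spec) {
  status <- switch(as.character(r$status),
                   "0" = "optimal", "1" = "feasible-time-limit",
                   "2" = "infeasible", "error")
  if (status %in% c("infeasible", "error")) {
    msg <- check_spec_feasibility(instance, spec)
    if (length(msg) == 0) {
      msg <- "no integer assignment satisfies the fraction/stratification lower bounds"
    }
    return(new_solution(NULL, "infeasible", NA_real_, "highs",
                        spec$solver_time_limit_s, paste(msg, collapse = "; ")))
  }
  x <- unlist(r$x)
  k <- model$k
  assign <- map_int(seq_along(model$ids), function(j) {
    which.max(x[((j - 1) * k + 1):(j * k)])
  })
  part <- fold_partition(setNames(assign, model$ids), provenance = "exact")
  obj <- leakage(part, instance)
  if (status == "optimal" && abs(obj - r$objective) > 1e-6) {
    warn(paste0("solver objective ", r$objective,
                " differs from recomputed leakage ", obj))
  }
  part$objective <- obj
  sol <- new_solution(part, status, obj, "highs", spec$solver_time_limit_s, NULL)
  if (model$n_cut > 0) {
    sol$cut_values <- model$pairs
    sol$cut_values$zeta <- x[model$n_assign + seq_len(model$n_cut)]
  }
  sol
}

new_solution <- function(partition, status, objective, solver, limit, message) {
  structure(
    list(partition = partition, status = status, objective = objective,
         solver_name = solver, wall_limit_s = limit, message = message),
    class = "split_solution"
  )
}

#' Exhaustive optimum for small instances
#'
#' Enumerates all `k^n` fold assignments, keeps those satisfying the
#' fraction and stratification bounds, and returns the minimum-leakage one.
#' Ties are broken by the lexicographically smallest assignment vector.
#' Serves as the independent oracle against which the ILP path is tested.
#'
#' @param instance A [split_instance()] with at most `max_elements` elements.
#' @param spec A [split_spec()].
#' @param max_elements Enumeration guard (default 12).
#' @return A `split_solution` with provenance `"exact"`, solver
#'   `"enumeration"`; status `"infeasible"` when no assignment passes.
#' @export
brute_force_optimum <- function(instance, spec, max_elements = 12L) {
  ids <- instance$items$id
  n <- length(ids)
  k <- spec$k
  if (n > max_elements) {
    abort(paste0("instance has ", n, " elements; enumeration capped at ", max_elements))
  }
  A <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  colnames(A) <- ids
  w <- inst_weights(instance)

  feas <- rep(TRUE, nrow(A))
  tm <- type_mass(instance)
  for (r in seq_len(nrow(tm))) {
    ty <- tm$entity_type[r]
    tids <- inst_ids(instance, ty)
    for (i in seq_len(k)) {
      mass <- (A[, tids, drop = FALSE] == i) %*% w[tids]
      feas <- feas & (mass >= (1 - spec$epsilon) * spec$fractions[i] * tm$n_r[r] - 1e-9)
    }
  }
  totals <- class_mass_totals(instance)
  if (nrow(totals) > 0) {
    cm <- instance$class_mass
    for (r in seq_len(nrow(totals))) {
      ty <- totals$entity_type[r]; cl <- totals$class[r]
      sub <- cm[cm$class == cl & cm$id %in% inst_ids(instance, ty), ]
      for (i in seq_len(k)) {
        mass <- (A[, sub$id, drop = FALSE] == i) %*% sub$mass
        feas <- feas & (mass >= (1 - spec$delta) * spec$fractions[i] * totals$n_rc[r] - 1e-9)
      }
    }
  }
  if (!any(feas)) {
    return(new_solution(NULL, "infeasible", NA_real_, "enumeration", Inf,
                        "no assignment satisfies the bounds"))
  }
  A <- A[feas, , drop = FALSE]

  leak <- rep(0, nrow(A))
  for (ty in inst_types(instance)) {
    tids <- inst_ids(instance, ty)
    if (length(tids) < 2) next
    S <- similarity_matrix(instance, ty)
    cmb <- combn(tids, 2)
    for (p in seq_len(ncol(cmb))) {
      a <- cmb[1, p]; b <- cmb[2, p]
      wt <- S[a, b] * w[a] * w[b]
      if (wt > 0) leak <- leak + wt * (A[, a] != A[, b])
    }
  }
  best <- min(leak)
  cand <- which(leak <= best + 1e-12)
  if (length(cand) > 1) {  # lexicographically smallest assignment vector
    ord <- do.call(order, as.data.frame(A[cand, , drop = FALSE]))
    cand <- cand[ord[1]]
  }
  assign <- A[cand[1], ]
  part <- fold_partition(setNames(as.integer(assign), ids),
                         provenance = "exact", objective = best)
  new_solution(part, "optimal", best, "enumeration", Inf, NULL)
}

#' Export an ILP model in LP file format
#'
#' Writes a human-readable CPLEX-LP rendering of the model, for debugging
#' with external solvers.
#'
#' @param model An `ilp_model` from [build_ilp()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lp <- function(model, path) {
  vn <- c(paste0("x", seq_len(model$n_assign)),
          if (model$n_cut > 0) paste0("z", seq_len(model$n_cut)))
  lines <- c("Minimize", paste(" obj:", paste(
    sprintf("%+g %s", model$obj[model$obj != 0], vn[model$obj != 0]),
    collapse = " ")))
  lines <- c(lines, "Subject To")
  for (rr in seq_len(model$nrow)) {
    sel <- model$a_row == rr
    expr <- paste(sprintf("%+g %s", model$a_val[sel], vn[model$a_col[sel]]),
                  collapse = " ")
    lb <- model$row_lb[rr]; ub <- model$row_ub[rr]
    nm <- gsub("[^A-Za-z0-9_]", "_", model$row_label[rr])
    if (is.finite(lb) && is.finite(ub) && lb == ub) {
      lines <- c(lines, sprintf(" %s: %s = %g", nm, expr, lb))
    } else {
      if (is.finite(lb)) lines <- c(lines, sprintf(" %s_lb: %s >= %g", nm, expr, lb))
      if (is.finite(ub)) lines <- c(lines, sprintf(" %s_ub: %s <= %g", nm, expr, ub))
    }
  }
  lines <- c(lines, "Binary", paste(" ", paste(vn, collapse = " ")), "End")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.ilp_model <- function(x, ...) {
  cat("<ilp_model> ", x$nvar, " binary variables (", x$n_assign, " assignment, ",
      x$n_cut, " cut), ", x$nrow, " constraint rows\n", sep = "")
  invisible(x)
}

#' @export
print.split_solution <- function(x, ...) {
  cat("<split_solution> status: ", x$status, ", solver: ", x$solver_name, sep = "")
  if (!is.na(x$objective)) cat(", objective: ", signif(x$objective, 6), sep = "")
  cat("\n")
  if (!is.null(x$message)) cat("  ", x$message, "\n", sep = "")
  invisible(x)
}
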