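#' Check split-fraction and stratification constraints
#'
#' Evaluates every lower bound the splitting problem imposes on a partition:
#' for each (fold i, entity type r) the achieved cardinality mass must reach
#' `(1 - epsilon) * s_i * n_r`, and, when class information is present, for
#' each (fold, type, class) the per-class mass must reach
#' `(1 - delta) * s_i * n_r^c`. When no element carries a class label all
#' elements implicitly share a single dummy class, in which case the
#' stratification bounds coincide with the fraction bounds and are not
#' reported separately.
#'
#' @param partition A [fold_partition()] total over the instance.
#' @param instance A [split_instance()].
#' @param spec A [split_spec()].
#' @return A `constraint_report`: a tibble with one row per bound, columns
#'   `fold`, `entity_type`, `class` (`NA` for fraction bounds), `mass`
#'   (achieved), `bound`, and `met`; the attribute `feasible` (and
#'   [is_feasible()]) is `TRUE` iff every bound is met.
#' @export
#' @examples
#' inst <- make_block_instance(block_sizes = c(5, 5))
#' spec <- split_spec(fractions = c(0.5, 0.5), epsilon = 0.2)
#' part <- fold_partition(setNames(rep(1:2, each = 5), inst$items$id), "baseline")
#' check_constraints(part, inst, spec)
check_constraints <- function(partition, instance, spec) {
  assert_total_partition(partition, instance)
  items <- instance$items %>%
    mutate(fold = partition$assignment[.data$id])

  grid_fr <- tidyr::expand_grid(
    fold = seq_len(spec$k),
    entity_type = inst_types(instance)
  )
  achieved_fr <- items %>%
    group_by(.data$fold, .data$entity_type) %>%
    summarise(mass = sum(.data$weight), .groups = "drop")
  frac_tbl <- tibble(fold = seq_len(spec$k), s_i = unname(spec$fractions))
  rep_fr <- grid_fr %>%
    left_join(achieved_fr, by = c("fold", "entity_type")) %>%
    left_join(type_mass(instance), by = "entity_type") %>%
    left_join(frac_tbl, by = "fold") %>%
    mutate(mass = dplyr::coalesce(.data$mass, 0),
           bound = (1 - spec$epsilon) * .data$s_i * .data$n_r,
           class = NA_character_) %>%
    select("fold", "entity_type", "class", "mass", "bound")

  rep_cl <- NULL
  totals <- class_mass_totals(instance)
  if (nrow(totals) > 0) {
    cm <- instance$class_mass %>%
      left_join(select(items, "id", "entity_type", "fold"), by = "id")
    grid_cl <- tidyr::expand_grid(fold = seq_len(spec$k), totals)
    achieved_cl <- cm %>%
      group_by(.data$fold, .data$entity_type, .data$class) %>%
      summarise(mass = sum(.data$mass), .groups = "drop")
    rep_cl <- grid_cl %>%
      left_join(achieved_cl, by = c("fold", "entity_type", "class")) %>%
      left_join(frac_tbl, by = "fold") %>%
      mutate(mass = dplyr::coalesce(.data$mass, 0),
             bound = (1 - spec$delta) * .data$s_i * .data$n_rc) %>%
      select("fold", "entity_type", "class", "mass", "bound")
  }

  report <- bind_rows(rep_fr, rep_cl) %>%
    mutate(met = .data$mass >= .data$bound - 1e-9)
  structure(report, class = c("constraint_report", class(report)),
            feasible = all(report$met))
}

#' Is a constraint report (or partition) feasible?
#'
#' @param x A `constraint_report` from [check_constraints()].
#' @return Logical scalar.
#' @export
is_feasible <- function(x) {
  isTRUE(attr(x, "feasible"))
}

#' Flag fraction bounds that no integer assignment can meet
#'
#' Because cardinalities are integers, the effective lower bound of each
#' (fold, type) fraction constraint is its ceiling; if those ceilings sum to
#' more than the available mass `n_r`, the problem is infeasible regardless
#' of the similarity structure. This is reported at validation time so that
#' an over-tight `epsilon` fails fast rather than after a solver run.
#'
#' @param instance A [split_instance()].
#' @param spec A [split_spec()].
#' @return Character vector of messages naming the unmeetable bound sets;
#'   empty if the necessary condition holds.
#' @export
check_spec_feasibility <- function(instance, spec) {
  msgs <- character()
  tm <- type_mass(instance)
  for (i in seq_len(nrow(tm))) {
    bounds <- ceiling((1 - spec$epsilon) * spec$fractions * tm$n_r[i] - 1e-9)
    if (sum(bounds) > tm$n_r[i]) {
      msgs <- c(msgs, paste0(
        "entity type ", tm$entity_type[i], ": integer fraction bounds (",
        paste(bounds, collapse = " + "), ") exceed available mass ", tm$n_r[i],
        "; raise epsilon or change fractions"))
    }
  }
  msgs
}

#' @export
print.constraint_report <- function(x, ...) {
  cat("<constraint_report> feasible: ", attr(x, "feasible"), "\n", sep = "")
  NextMethod()
}
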