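#' Tidy a fold partition
#'
#' @param x A [fold_partition()].
#' @param instance Optional [split_instance()]; when supplied, entity types,
#'   weights and classes are joined in.
#' @param ... Unused.
#' @return Tibble with one row per element: `id`, `fold`, and (with an
#'   instance) `entity_type`, `weight`, `classes`.
#' @export
tidy.fold_partition <- function(x, instance = NULL, ...) {
  tbl <- tibble(id = names(x$assignment), fold = unname(x$assignment))
  if (!is.null(instance)) {
    tbl <- left_join(tbl, instance$items, by = "id")
  }
  tbl
}

#' One-row summary of a fold partition
#'
#' @param x A [fold_partition()].
#' @param ... Unused.
#' @return Tibble with `n_elements`, `k`, `provenance`, `objective`.
#' @export
glance.fold_partition <- function(x, ...) {
  tibble(n_elements = length(x$assignment),
         k = length(unique(x$assignment)),
         provenance = x$provenance,
         objective = x$objective %||% NA_real_)
}

#' Tidy a solver result
#'
#' @param x A `split_solution` from [solve_split()].
#' @param ... Passed to [tidy.fold_partition()].
#' @return The tidied partition (empty tibble when infeasible).
#' @export
tidy.split_solution <- function(x, ...) {
  if (is.null(x$partition)) return(tibble(id = character(), fold = integer()))
  tidy(x$partition, ...)
}

#' One-row summary of a solver result
#'
#' @param x A `split_solution`.
#' @param ... Unused.
#' @return Tibble with `status`, `objective`, `solver_name`, `wall_limit_s`.
#' @export
glance.split_solution <- function(x, ...) {
  tibble(status = x$status, objective = x$objective,
         solver_name = x$solver_name, wall_limit_s = x$wall_limit_s)
}

#' Tidy a leakage result
#'
#' @param x A `leakage_result` from [scaled_leakage()].
#' @param ... Unused.
#' @return One-row tibble with `raw`, `scaled`, `denominator`.
#' @export
tidy.leakage_result <- function(x, ...) {
  tibble(raw = x$raw, scaled = x$scaled, denominator = x$denominator)
}

#' Plot fold composition
#'
#' Stacked bar chart of cardinality mass per fold, faceted by entity type
#' and filled by class when class labels exist — a quick visual check that
#' fractions and stratification came out as requested.
#'
#' @param object A [fold_partition()].
#' @param instance The matching [split_instance()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fold_partition <- function(object, instance, ...) {
  tbl <- tidy(object, instance = instance) %>%
    mutate(class = map_chr(.data$classes %||% list(),
                           ~ if (length(.x) == 0) "(none)" else paste(.x, collapse = "+")),
           fold = factor(.data$fold))
  ggplot(tbl, aes(x = .data$fold, y = .data$weight, fill = .data$class)) +
    geom_col() +
    facet_wrap(~ .data$entity_type, labeller = label_both) +
    labs(x = "fold", y = "cardinality mass", fill = "class",
         title = paste0("Fold composition (", object$provenance, " split)")) +
    theme_minimal()
}

#' Plot a constraint report
#'
#' Achieved mass vs. lower bound for every fraction and stratification
#' constraint; unmet bounds are flagged in red.
#'
#' @param object A `constraint_report` from [check_constraints()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.constraint_report <- function(object, ...) {
  tbl <- as_tibble(object) %>%
    mutate(constraint = ifelse(is.na(.data$class),
                               paste0("fold", .data$fold, "/type", .data$entity_type),
                               paste0("fold", .data$fold, "/type", .data$entity_type,
                                      "/", .data$class)))
  ggplot(tbl, aes(x = .data$constraint)) +
    geom_col(aes(y = .data$mass, fill = .data$met)) +
    geom_point(aes(y = .data$bound), shape = 95, size = 8) +
    scale_fill_manual(values = c(`TRUE` = "grey40", `FALSE` = "firebrick")) +
    coord_flip() +
    labs(y = "cardinality mass (bar) and lower bound (dash)", x = NULL,
         fill = "bound met") +
    theme_minimal()
}
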