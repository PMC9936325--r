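#' Classify expressed features as up / down / unchanged
#'
#' For each feature that passed the expression floor, computes
#' `percent_of_wt = 100 * rpm_KO / rpm_WT` and assigns a class:
#' UP when expression in the knockout is at least `up`% of wild type,
#' DOWN when at most `down`%, UNCHANGED otherwise. The decision is made by
#' cross-multiplication (`100 * rpm_ko` vs `threshold * rpm_wt`), never on a
#' rounded ratio, so a feature sitting exactly on a threshold is classified
#' bit-exactly (150.0000 is UP and 50.0000 is DOWN). A feature absent from
#' wild type but expressed in the knockout has infinite percent and is UP.
#'
#' @param records Floored expression tibble from [apply_floor()].
#' @param up,down Class thresholds in percent of wild type (defaults 150, 50;
#'   must satisfy 0 < down < 100 < up).
#' @return The tibble with `percent_of_wt` and `call` (UP/DOWN/UNCHANGED)
#'   columns appended.
#' @examples
#' rec <- tibble::tibble(
#'   feature_id = c("a", "b", "c"), feature_type = "miRNA",
#'   raw_wt = c(100, 100, 100), raw_ko = c(150, 50, 100),
#'   rpm_wt = c(100, 100, 100), rpm_ko = c(150, 50, 100)
#' )
#' classify_expression(rec)$call # "UP" "DOWN" "UNCHANGED"
#' @export
classify_expression <- function(records, up = 150, down = 50) {
  stopifnot(0 < down, down < 100, 100 < up)
  if (any(records$rpm_wt == 0 & records$rpm_ko == 0)) {
    stop("feature with zero expression in both libraries; ",
         "classify only floored records", call. = FALSE)
  }
  percent <- ifelse(records$rpm_wt == 0, Inf,
                    100 * records$rpm_ko / records$rpm_wt)
  call <- dplyr::case_when(
    100 * records$rpm_ko >= up * records$rpm_wt ~ "UP",
    100 * records$rpm_ko <= down * records$rpm_wt ~ "DOWN",
    TRUE ~ "UNCHANGED"
  )
  dplyr::mutate(records, percent_of_wt = percent, call = call)
}

#' Summarise the class structure of a two-library comparison
#'
#' Per feature type, counts expressed / up / down / unchanged features and
#' computes the mean percent-of-WT over the DOWN set and over the UP set.
#' Class means are arithmetic means of per-feature percentages; infinite
#' percentages (wild-type zero) are excluded from the UP mean and their count
#' reported. A pooled alternative (100 * sum(rpm_KO) / sum(rpm_WT) over the
#' same class set) is emitted alongside for comparison. Top-10 lists are
#' ranked by |log2(percent/100)| descending, ties broken by feature id.
#'
#' @param calls Classified tibble from [classify_expression()].
#' @param n_top Size of the top up/down lists (default 10).
#' @return An `sdrna_switch_summary`: list with `by_type` (tibble: one row per
#'   feature type with counts, class means, pooled percents, and the number of
#'   infinite percents excluded from the UP mean), `top_down` and `top_up`
#'   (ranked tibbles).
#' @export
summarize_switch <- function(calls, n_top = 10) {
  empty_type <- tibble(
    feature_type = character(), n_expressed = integer(), n_up = integer(),
    n_down = integer(), n_unchanged = integer(),
    mean_percent_of_wt_down = numeric(), mean_percent_of_wt_up = numeric(),
    pooled_percent_down = numeric(), pooled_percent_up = numeric(),
    n_up_infinite = integer()
  )
  if (nrow(calls) == 0) {
    return(structure(list(by_type = empty_type,
                          top_down = calls, top_up = calls),
                     class = "sdrna_switch_summary"))
  }
  by_type <- calls |>
    dplyr::group_by(.data$feature_type) |>
    dplyr::summarise(
      n_expressed = dplyr::n(),
      n_up = sum(.data$call == "UP"),
      n_down = sum(.data$call == "DOWN"),
      n_unchanged = sum(.data$call == "UNCHANGED"),
      mean_percent_of_wt_down =
        mean(.data$percent_of_wt[.data$call == "DOWN"]),
      mean_percent_of_wt_up =
        mean(.data$percent_of_wt[.data$call == "UP" &
                                   is.finite(.data$percent_of_wt)]),
      pooled_percent_down =
        100 * sum(.data$rpm_ko[.data$call == "DOWN"]) /
          sum(.data$rpm_wt[.data$call == "DOWN"]),
      pooled_percent_up =
        100 * sum(.data$rpm_ko[.data$call == "UP"]) /
          sum(.data$rpm_wt[.data$call == "UP"]),
      n_up_infinite = sum(.data$call == "UP" &
                            !is.finite(.data$percent_of_wt)),
      .groups = "drop"
    )
  ranked <- calls |>
    dplyr::mutate(effect = abs(log2(.data$percent_of_wt / 100))) |>
    dplyr::arrange(dplyr::desc(.data$effect), .data$feature_id)
  structure(
    list(
      by_type = by_type,
      top_down = utils::head(dplyr::filter(ranked, .data$call == "DOWN"),
                             n_top),
      top_up = utils::head(dplyr::filter(ranked, .data$call == "UP"), n_top)
    ),
    class = "sdrna_switch_summary"
  )
}

#' @export
print.sdrna_switch_summary <- function(x, ...) {
  cat("<sdrna_switch_summary>\n")
  print(x$by_type)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @rdname summarize_switch
#' @param x An `sdrna_switch_summary`.
#' @param ... Unused.
#' @export
tidy.sdrna_switch_summary <- function(x, ...) {
  x$by_type
}

#' Class-composition bar chart for a switch summary
#'
#' One stacked bar per feature type showing the share of features called
#' down (blue), unchanged (grey) and up (red) in the knockout, labelled with
#' the class counts.
#'
#' @param object An `sdrna_switch_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sdrna_switch_summary <- function(object, ...) {
  d <- object$by_type |>
    tidyr::pivot_longer(c("n_down", "n_unchanged", "n_up"),
                        names_to = "class", values_to = "n") |>
    dplyr::mutate(class = factor(.data$class,
                                 levels = c("n_up", "n_unchanged", "n_down"),
                                 labels = c("increased", "unchanged",
                                            "decreased")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$feature_type, y = .data$n,
                                  fill = .data$class)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n),
                       position = ggplot2::position_fill(vjust = 0.5),
                       colour = "white") +
    ggplot2::scale_fill_manual(values = c(increased = "firebrick",
                                          unchanged = "grey60",
                                          decreased = "steelblue")) +
    ggplot2::scale_y_continuous(labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(x = NULL, y = "share of expressed features",
                  fill = "in KO vs WT") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
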