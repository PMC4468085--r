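# ggplot2 views of the main result types.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col autoplot
#'   labs theme_minimal facet_wrap
NULL

#' Plot a betweenness centrality profile
#'
#' @param object A `kin_centrality`.
#' @param ... Unused.
#' @return A ggplot: centrality against residue number, chain-faceted.
#' @export
autoplot.kin_centrality <- function(object, ...) {
  df <- as_tibble(object) |>
    filter(!.data$is_ligand) |>
    tidyr::separate_wider_delim("key",
      delim = ":", names = c("chain", "pos"),
      cols_remove = FALSE
    ) |>
    mutate(pos = suppressWarnings(as.integer(gsub("[^0-9-]", "", .data$pos))))
  ggplot(df, aes(x = .data$pos, y = .data$betweenness)) +
    geom_line(colour = "grey40") +
    geom_point(size = 1) +
    facet_wrap(~chain, scales = "free_x") +
    labs(
      x = "residue", y = expression(C[b]),
      title = "Residue betweenness centrality"
    ) +
    theme_minimal()
}

#' Plot a mobility or B-factor style dynamics profile
#'
#' @param object A `kin_dynamics`.
#' @param ... Unused.
#' @return A ggplot of the per-residue mobility profile.
#' @export
autoplot.kin_dynamics <- function(object, ...) {
  df <- tidy(object) |> mutate(index = dplyr::row_number())
  ggplot(df, aes(x = .data$index, y = .data$mobility)) +
    geom_line() +
    labs(
      x = "residue index", y = "mobility (Å)",
      title = sprintf("%s mobility profile (3 lowest-frequency modes)", toupper(object$type))
    ) +
    theme_minimal()
}

#' Plot per-residue alanine-scanning results
#'
#' @param object A `kin_alascan`.
#' @param ... Unused.
#' @return A ggplot bar chart of ddG by residue.
#' @export
autoplot.kin_alascan <- function(object, ...) {
  df <- as_tibble(object) |> filter(!is.na(.data$ddG))
  ggplot(df, aes(x = .data$key, y = .data$ddG)) +
    geom_col(fill = "steelblue") +
    labs(
      x = "residue", y = expression(Delta * Delta * G[bind] ~ "(kcal/mol)"),
      title = "Computational alanine scanning"
    ) +
    theme_minimal()
}

#' Plot the per-frame MM-GBSA series
#'
#' @param object A `kin_mmgbsa`.
#' @param ... Unused.
#' @return A ggplot of the per-frame binding energy terms.
#' @export
autoplot.kin_mmgbsa <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("e_vdw", "e_elec", "dg_np", "dg_gb", "dg_frame"),
      names_to = "term", values_to = "energy"
    )
  ggplot(df, aes(x = .data$frame, y = .data$energy, colour = .data$term)) +
    geom_line() +
    labs(
      x = "frame", y = "energy (kcal/mol)",
      title = "Per-frame MM-GBSA terms"
    ) +
    theme_minimal()
}

#' Centrality against flexibility and burial
#'
#' @param joint Tibble from [joint_profiles()].
#' @return A ggplot with two panels: betweenness against B-factor and
#'   against RSA.
#' @export
plot_joint_profiles <- function(joint) {
  df <- joint |>
    tidyr::pivot_longer(c("bfactor", "rsa"), names_to = "variable", values_to = "value")
  ggplot(df, aes(x = .data$value, y = .data$betweenness)) +
    geom_point(alpha = 0.7) +
    facet_wrap(~variable, scales = "free_x") +
    labs(
      x = NULL, y = expression(C[b]),
      title = "Centrality against computed B-factor and RSA"
    ) +
    theme_minimal()
}
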