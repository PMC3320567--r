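#' @method tidy interaction_table
#' @export
tidy.interaction_table <- function(x, ...) {
  as_tibble(x)
}

#' @method glance interaction_table
#' @export
glance.interaction_table <- function(x, ...) {
  tibble(n_records = nrow(x),
         n_region_I = sum(x$region == "I"),
         n_region_II = sum(x$region == "II"),
         n_region_III = sum(x$region == "III"),
         n_flank = sum(x$region == "flank"),
         n_frames = attr(x, "n_frames"),
         threshold = attr(x, "threshold"))
}

#' @method tidy pair_profiles
#' @export
tidy.pair_profiles <- function(x, ...) {
  as_tibble(x) %>% select(-"frames")
}

#' @method tidy region_summary
#' @export
tidy.region_summary <- function(x, ...) {
  x$counts
}

#' Occupancy plot of an interaction table
#'
#' One point per stable record: ligand residue (window order) against
#' occupancy, coloured by contact kind and labelled by its receptor partner;
#' the dashed line marks the stability threshold.
#'
#' @param object An `interaction_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot interaction_table
#' @export
autoplot.interaction_table <- function(object, ...) {
  peptide <- attr(object, "peptide")
  threshold <- attr(object, "threshold")
  win <- peptide$residues
  labels <- .ligand_label(win$resname, win$resnum)
  dat <- as_tibble(object) %>%
    mutate(ligand = factor(.ligand_label(.data$ligand_resname,
                                         .data$ligand_resnum),
                           levels = labels),
           partner = .receptor_label(.data$receptor_resname,
                                     .data$receptor_resnum))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$ligand, y = .data$occupancy,
                                    colour = .data$kind)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = paste(.data$partner,
                                                  .data$class_label)),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::ylim(0, 1.05) +
    ggplot2::labs(x = "ligand residue", y = "occupancy",
                  colour = "contact kind") +
    ggplot2::theme_minimal()
}

#' Distance time-series plot
#'
#' @param object A `contact_timeseries` from [distance_timeseries()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contact_timeseries
#' @export
autoplot.contact_timeseries <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time_ps, y = .data$distance)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = "min heavy-atom distance (Å)",
                  title = paste(attr(object, "ligand"), "–",
                                attr(object, "receptor"))) +
    ggplot2::theme_minimal()
}
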