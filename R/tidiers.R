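#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a profile HMM
#'
#' One row per (match state, residue) with the emission probability, plus
#' the reference label anchored at that state when one exists.
#'
#' @param x A `profile_hmm`.
#' @param ... Unused.
#' @return A tibble with `state`, `residue`, `emission`, `reference`.
#' @export
tidy.profile_hmm <- function(x, ...) {
  ref <- setNames(names(x$reference_map), x$reference_map)
  tidyr::pivot_longer(
    dplyr::mutate(as_tibble(x$match_em), state = seq_len(x$match_count),
                  reference = unname(ref[as.character(state)])),
    cols = dplyr::all_of(AA20), names_to = "residue", values_to = "emission")
}

#' @rdname tidy.profile_hmm
#' @export
glance.profile_hmm <- function(x, ...) {
  tibble(label = x$label, match_count = x$match_count,
         calibrated = is_calibrated(x), mu = x$mu, lambda = x$lambda,
         reference_labels = length(x$reference_map))
}

#' Tidy an identity matrix
#'
#' @param x An `identity_matrix`.
#' @param ... Unused.
#' @return Long tibble with `a`, `b`, `identity`, `distance`.
#' @export
tidy.identity_matrix <- function(x, ...) {
  long <- as_tibble(x$identity, rownames = "..row", .name_repair = "minimal")
  long <- tidyr::pivot_longer(long, -"..row", names_to = "b",
                              values_to = "identity")
  names(long)[names(long) == "..row"] <- "a"
  dplyr::mutate(long, distance = 100 - .data$identity)
}

#' Tidy a presence matrix
#'
#' @param x A `presence_matrix`.
#' @param ... Unused.
#' @return Long tibble with `taxon`, `orthogroup`, `present`.
#' @export
tidy.presence_matrix <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"taxon", names_to = "orthogroup",
                      values_to = "present")
}

#' Summaries of Dollo reconstructions
#'
#' `tidy()` returns the event table; `glance()` one row per orthogroup with
#' gain interval and loss count.
#'
#' @param x A `dollo_events` tibble.
#' @param ... Unused.
#' @export
tidy.dollo_events <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.dollo_events
#' @export
glance.dollo_events <- function(x, ...) {
  gains <- dplyr::filter(as_tibble(x), .data$event == "gain")
  losses <- dplyr::count(dplyr::filter(as_tibble(x), .data$event == "loss"),
                         .data$orthogroup, name = "losses")
  dplyr::left_join(
    dplyr::select(gains, "orthogroup", gain_branch = "child",
                  gain_older = "older", gain_younger = "younger"),
    losses, by = "orthogroup") |>
    dplyr::mutate(losses = dplyr::coalesce(.data$losses, 0L))
}
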