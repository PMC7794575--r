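#' Runoff-event table for nitrate loss accounting
#'
#' Validates an event table: one row per runoff event with the NO3-
#' concentration of the water sample and the event discharge depth, labelled
#' by export pathway (subsurface interflow, surface overland flow, or a
#' whole-catchment outlet).
#'
#' @param events Data frame with columns `date`, `pathway`, `c_mg_per_L`
#'   (mg NO3--N L-1) and `q_mm` (discharge depth, mm).
#' @return The validated data frame (class `runoff_events` prepended).
#' @export
runoff_events <- function(events) {
  need <- c("date", "pathway", "c_mg_per_L", "q_mm")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("event table missing columns: ", paste(miss, collapse = ", "))
  ok_path <- c("interflow", "overland", "whole-catchment")
  bad <- which(!events$pathway %in% ok_path)
  if (length(bad))
    stop("unknown pathway in row(s) ", paste(bad, collapse = ", "),
         " (expected ", paste(ok_path, collapse = ", "), ")")
  bad <- which(events$c_mg_per_L < 0 | events$q_mm < 0)
  if (length(bad))
    stop("negative concentration or discharge in row(s) ",
         paste(bad, collapse = ", "))
  class(events) <- c("runoff_events", class(events))
  events
}

#' Annual nitrate loss flux from runoff events
#'
#' Sums the per-event loads `c_i * q_i / 100` over all monitored events:
#' with `c` in mg L-1 and `q` in mm, the division by 100 converts the product
#' directly to kg N ha-1, so the total is the annual NO3- loss flux in
#' kg N ha-1 year-1. Pathway subtotals (interflow, overland, whole-catchment)
#' are reported alongside.
#'
#' @param events A [runoff_events()] table (or a data frame accepted by it).
#'   May be empty (zero flux).
#' @return List of class `n15_flux`: `Q` (kg N ha-1 year-1), `n_events`,
#'   `contributions` (the event table with a `load_kg_ha` column) and
#'   `by_pathway` (subtotal data frame).
#' @export
#' @examples
#' ev <- data.frame(date = "2016-07-18", pathway = "overland",
#'                  c_mg_per_L = 10, q_mm = 50)
#' annual_no3_flux(ev)$Q   # 5
annual_no3_flux <- function(events) {
  if (nrow(events) == 0) {
    return(structure(list(Q = 0, n_events = 0L,
                          contributions = cbind(events,
                                                load_kg_ha = numeric(0)),
                          by_pathway = data.frame(pathway = character(0),
                                                  Q = numeric(0))),
                     class = "n15_flux"))
  }
  events <- runoff_events(as.data.frame(events))
  load <- events$c_mg_per_L * events$q_mm / 100
  by_pathway <- stats::aggregate(load, by = list(pathway = events$pathway),
                                 FUN = sum)
  names(by_pathway)[2] <- "Q"
  contributions <- cbind(as.data.frame(events), load_kg_ha = load)
  structure(list(Q = sum(load), n_events = nrow(events),
                 contributions = contributions, by_pathway = by_pathway),
            class = "n15_flux")
}

#' @export
print.n15_flux <- function(x, ...) {
  cat("<n15_flux> Q = ", signif(x$Q, 6), " kg N ha-1 year-1 over ",
      x$n_events, " events\n", sep = "")
  if (nrow(x$by_pathway)) print(x$by_pathway, digits = 4)
  invisible(x)
}
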